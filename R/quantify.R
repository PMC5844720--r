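#' TPM normalisation for small-RNA counts
#'
#' Tags-per-million scaling as used for miRNA digital counts:
#' `TPM[i,s] = 1e6 * C[i,s] / L[s]`, where `L` is the per-sample total of
#' clean reads. Note there is deliberately no length term: small-RNA tags
#' are of near-uniform length, and this is the convention for miRNA
#' sequencing despite the "per kilobase" in the acronym's long form.
#'
#' @param counts A [count_matrix()] with positive library sizes.
#' @return An [expression_matrix()] with unit `"TPM"`. When the library
#'   sizes equal the column sums, each column sums to 1e6.
#' @export
compute_tpm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  if (any(counts$library_sizes <= 0)) stop("library sizes must be positive")
  vals <- sweep(counts$counts, 2, counts$library_sizes, "/") * 1e6
  expression_matrix(vals, "TPM")
}

#' FPKM per transcript and gene-level summation
#'
#' `FPKM[i,s] = C[i,s] / (exonic_kb[i] * mapped_millions[s])` with the
#' library-size field standing in for mapped fragments. Gene-level values
#' are the sum of the FPKMs of the gene's transcripts.
#'
#' @param counts A [count_matrix()] of transcript-level counts.
#' @param annotation A [transcript_annotation()] covering every counted
#'   transcript (used for exonic lengths).
#' @return An [expression_matrix()] with unit `"FPKM"`.
#' @export
compute_fpkm <- function(counts, annotation) {
  stopifnot(inherits(counts, "count_matrix"))
  len <- exonic_length(annotation)
  ids <- rownames(counts$counts)
  miss <- setdiff(ids, names(len))
  if (length(miss))
    stop("transcripts missing from annotation: ", paste(utils::head(miss, 5), collapse = ", "))
  len <- len[ids]
  if (any(len <= 0)) stop("transcript with zero exonic length")
  kb <- len / 1e3
  mm <- counts$library_sizes / 1e6
  if (any(mm <= 0)) stop("library sizes must be positive")
  vals <- sweep(counts$counts / kb, 2, mm, "/")
  expression_matrix(vals, "FPKM")
}

#' @rdname compute_fpkm
#' @param fpkm A transcript-level `"FPKM"` [expression_matrix()].
#' @param tx2gene Named character vector mapping transcript id to gene id.
#' @export
gene_fpkm <- function(fpkm, tx2gene) {
  stopifnot(inherits(fpkm, "expression_matrix"), fpkm$unit == "FPKM")
  ids <- rownames(fpkm$values)
  g <- tx2gene[ids]
  if (anyNA(g)) stop("transcripts without a gene mapping")
  agg <- rowsum(fpkm$values, group = as.character(g), reorder = TRUE)
  expression_matrix(agg, "FPKM")
}

#' Assign small-RNA tags to known miRNAs
#'
#' A tag is assigned to a miRNA when (1) it matches the miRNA's precursor
#' exactly (no mismatches, sense strand) and (2) its placement on the
#' precursor overlaps the mature miRNA's interval by at least
#' `min_overlap` nucleotides (offsets relative to the annotated mature
#' ends are allowed). Tags matching several miRNAs are assigned once, to
#' the miRNA with the largest mature overlap, ties broken lexicographically
#' by miRNA id; tags satisfying no criterion are labelled `"novel"`.
#'
#' @param tags Named character vector of tag sequences (DNA or RNA; U is
#'   treated as T).
#' @param reference data.frame with columns `mirna_id`, `precursor`,
#'   `mature` (sequences; the mature must occur within its precursor).
#' @param min_overlap Minimum tag/mature overlap in nucleotides
#'   (default 16).
#' @return data.frame with columns `tag_id`, `mirna_id` (NA for novel),
#'   `overlap`, `status` (`"known"`/`"novel"`).
#' @export
identify_known_mirnas <- function(tags, reference, min_overlap = 16) {
  if (nrow(reference) == 0) stop("empty miRNA reference")
  to_dna <- function(s) chartr("Uu", "Tt", toupper(s))
  tags <- vapply(tags, to_dna, character(1))
  pre <- to_dna(reference$precursor)
  mat <- to_dna(reference$mature)
  mat_start <- mapply(function(p, m) {
    hit <- regexpr(m, p, fixed = TRUE)
    if (hit < 0) stop("mature sequence not found in its precursor")
    as.integer(hit)
  }, pre, mat)
  mat_end <- mat_start + nchar(mat) - 1L

  assign_one <- function(tag) {
    best_id <- NA_character_; best_ov <- 0L
    for (j in seq_along(pre)) {
      ## all exact placements of the tag on the precursor, sense strand
      hits <- gregexpr(tag, pre[j], fixed = TRUE)[[1]]
      if (hits[1] < 0) next
      for (s in as.integer(hits)) {
        e <- s + nchar(tag) - 1L
        ov <- min(e, mat_end[j]) - max(s, mat_start[j]) + 1L
        if (ov >= min_overlap && (ov > best_ov ||
            (ov == best_ov && !is.na(best_id) &&
             reference$mirna_id[j] < best_id))) {
          best_id <- reference$mirna_id[j]; best_ov <- ov
        }
      }
    }
    list(id = best_id, ov = best_ov)
  }

  res <- lapply(tags, assign_one)
  data.frame(
    tag_id = names(tags) %||% as.character(seq_along(tags)),
    mirna_id = vapply(res, function(r) r$id, character(1)),
    overlap = vapply(res, function(r) as.integer(r$ov), integer(1)),
    status = ifelse(vapply(res, function(r) is.na(r$id), logical(1)),
                    "novel", "known"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
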