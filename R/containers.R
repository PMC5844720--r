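#' Count matrix with library sizes and condition labels
#'
#' The central container for digital expression data: a features x samples
#' matrix of non-negative integer counts, per-sample library sizes (total
#' clean reads, the denominator of TPM), and a condition label per sample
#' (e.g. `"tumour"` / `"control"`).
#'
#' @param counts Integer matrix (features x samples) with unique, non-empty
#'   row and column names and no negative or non-finite entries.
#' @param condition Character vector of condition labels, one per sample
#'   (recycled names are taken from `colnames(counts)` if unnamed).
#' @param library_sizes Optional numeric vector of per-sample totals. When
#'   omitted, column sums are used. When provided, each value must be at
#'   least the corresponding column sum (a library cannot contain fewer
#'   reads than were assigned to features).
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `library_sizes`, `condition`.
#' @export
count_matrix <- function(counts, condition, library_sizes = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row (feature) and column (sample) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in count matrix")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  if (length(condition) != ncol(counts))
    stop("one condition label required per sample")
  condition <- stats::setNames(as.character(condition), colnames(counts))
  csum <- colSums(counts)
  if (is.null(library_sizes)) {
    library_sizes <- csum
  } else {
    if (length(library_sizes) != ncol(counts))
      stop("one library size required per sample")
    library_sizes <- as.numeric(library_sizes)
    if (any(library_sizes < csum - 1e-9))
      stop("library sizes smaller than column sums")
  }
  library_sizes <- stats::setNames(as.numeric(library_sizes), colnames(counts))
  structure(
    list(counts = counts, library_sizes = library_sizes, condition = condition),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d features x %d samples (conditions: %s)\n",
    nrow(x$counts), ncol(x$counts),
    paste(sprintf("%s=%d", names(table(x$condition)), table(x$condition)),
          collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Expression matrix (normalised values)
#'
#' Features x samples matrix of non-negative real expression values tagged
#' with its unit (`"TPM"` or `"FPKM"`).
#'
#' @param values Numeric matrix with dimnames.
#' @param unit One of `"TPM"`, `"FPKM"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, unit = c("TPM", "FPKM")) {
  unit <- match.arg(unit)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  structure(list(values = values, unit = unit), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d features x %d samples\n",
              x$unit, nrow(x$values), ncol(x$values)))
  invisible(x)
}

## ---- transcript annotation ------------------------------------------------

#' Construct a transcript annotation table
#'
#' One row per transcript; exon structure is carried in a parallel exon
#' table (1-based inclusive coordinates, as in GTF).
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand` (+/-), `class_code` (single
#'   character, NA allowed), `biotype` (free text, e.g. "mRNA",
#'   "lncRNA_candidate", "miRNA").
#' @param exons data.frame with columns `transcript_id`, `start`, `end`;
#'   defaults to one exon spanning each transcript.
#' @return data.frame of class `transcript_annotation` with the exon table
#'   attached as attribute `"exons"`.
#' @export
transcript_annotation <- function(transcripts, exons = NULL) {
  need <- c("transcript_id", "gene_id", "chrom", "start", "end",
            "strand", "class_code", "biotype")
  miss <- setdiff(need, names(transcripts))
  if (length(miss)) stop("missing annotation columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript ids in annotation")
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("unknown strand (must be '+' or '-')")
  if (any(transcripts$end < transcripts$start))
    stop("transcript end < start")
  if (is.null(exons)) {
    exons <- data.frame(
      transcript_id = transcripts$transcript_id,
      start = transcripts$start,
      end = transcripts$end,
      stringsAsFactors = FALSE
    )
  }
  ok <- match(exons$transcript_id, transcripts$transcript_id)
  if (anyNA(ok)) stop("exon refers to unknown transcript")
  if (any(exons$start < transcripts$start[ok] | exons$end > transcripts$end[ok]))
    stop("exon outside transcript span")
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  rownames(transcripts) <- NULL
  structure(transcripts, exons = as.data.frame(exons), class = c("transcript_annotation", "data.frame"))
}

#' Exonic length per transcript
#'
#' @param annotation A `transcript_annotation`.
#' @return Named numeric vector of summed exon lengths (bases).
#' @export
exonic_length <- function(annotation) {
  ex <- attr(annotation, "exons")
  len <- tapply(ex$end - ex$start + 1, ex$transcript_id, sum)
  out <- stats::setNames(as.numeric(len[annotation$transcript_id]),
                         annotation$transcript_id)
  out
}

## ---- internal helpers -----------------------------------------------------

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic sub-seed derivation: one RNG stream per run, one derived
## integer seed per named stage (kept below 2^31)
#' @noRd
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}
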