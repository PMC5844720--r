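#' Read and write FASTA sequence sets
#'
#' Thin wrappers over Biostrings keeping sequences as named character
#' vectors (DNA `ACGTN` or RNA `ACGUN`). Ids are the first whitespace-
#' delimited token of each header; duplicates are an error.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(s))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  stats::setNames(toupper(as.character(s)), ids)
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names")
  x <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read and write FASTQ small-RNA reads
#'
#' Reads are kept in a plain data.frame with Sanger Phred+33 quality
#' strings, the form consumed by [clean_reads()].
#'
#' @param path File path.
#' @return `read_fastq`: data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = sub("\\s.*$", "", names(s)),
    seq = as.character(s),
    qual = as.character(S4Vectors::mcols(s)$qualities),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @rdname read_fastq
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual)
  )
  invisible(path)
}

## first position j at which the read's 3' tail matches the adapter:
## either the full adapter occurs at j, or the suffix starting at j
## (length >= min_match) equals a prefix of the adapter
#' @noRd
adapter_hit <- function(seq, adapter, min_match = 8L) {
  len <- nchar(seq); alen <- nchar(adapter)
  if (alen == 0L || len < min_match) return(NA_integer_)
  for (j in seq_len(len - min_match + 1L)) {
    l <- len - j + 1L
    if (l >= alen) {
      if (substr(seq, j, j + alen - 1L) == adapter) return(j)
    } else {
      if (substr(seq, j, len) == substr(adapter, 1L, l)) return(j)
    }
  }
  NA_integer_
}

#' Clean small-RNA reads
#'
#' Applies the raw-read cleaning rules for small-RNA libraries, in order;
#' a read is counted in the first category it fails:
#' \enumerate{
#'   \item adapter: the 3' end matches the adapter (full occurrence or a
#'     suffix matching an adapter prefix of at least 8 nt). By default
#'     such reads are removed; with `adapter_policy = "trim"` the adapter
#'     is cut off and the remainder re-enters the remaining rules.
#'   \item high N: fraction of unknown bases strictly greater than
#'     `maxN_frac` (default 0.05).
#'   \item low quality: fraction of bases with Phred score less than or
#'     equal to `lowq_threshold` (default 10) strictly greater than
#'     `lowq_frac` (default 0.5).
#' }
#' Q20/Q30/GC percentages are reported for the clean reads.
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` (Phred+33).
#' @param adapter Adapter sequence; empty string skips the adapter rule.
#' @param maxN_frac,lowq_threshold,lowq_frac Rule thresholds (see above).
#' @param adapter_policy `"remove"` (default) or `"trim"`.
#' @return List with `clean` (data.frame of retained reads) and `report`
#'   (list: `n_input`, `n_adapter_removed`, `n_highN_removed`,
#'   `n_lowqual_removed`, `n_clean`, `q20`, `q30`, `gc`).
#' @export
clean_reads <- function(reads, adapter = "", maxN_frac = 0.05,
                        lowq_threshold = 10L, lowq_frac = 0.5,
                        adapter_policy = c("remove", "trim")) {
  adapter_policy <- match.arg(adapter_policy)
  if (!(maxN_frac > 0 && maxN_frac <= 1) || !(lowq_frac > 0 && lowq_frac <= 1))
    stop("fraction thresholds must lie in (0, 1]")
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad))
    stop(sprintf("malformed read record %d (%s): sequence/quality length mismatch",
                 bad[1], reads$id[bad[1]]))
  if (any(grepl("[^ACGTN]", reads$seq)))
    stop("read sequences must be over {A,C,G,T,N}")

  n <- nrow(reads)
  category <- rep("clean", n)
  seqs <- reads$seq; quals <- reads$qual
  adapter <- toupper(adapter)

  for (i in seq_len(n)) {
    if (nzchar(adapter)) {
      j <- adapter_hit(seqs[i], adapter)
      if (!is.na(j)) {
        if (adapter_policy == "remove") { category[i] <- "adapter"; next }
        if (j == 1L) { category[i] <- "adapter"; next }  # nothing left after trim
        seqs[i] <- substr(seqs[i], 1L, j - 1L)
        quals[i] <- substr(quals[i], 1L, j - 1L)
      }
    }
    len <- nchar(seqs[i])
    nN <- len - nchar(gsub("N", "", seqs[i], fixed = TRUE))
    if (nN / len > maxN_frac) { category[i] <- "highN"; next }
    phred <- utf8ToInt(quals[i]) - 33L
    if (sum(phred <= lowq_threshold) / len > lowq_frac) {
      category[i] <- "lowqual"; next
    }
  }

  keep <- category == "clean"
  clean <- data.frame(id = reads$id[keep], seq = seqs[keep],
                      qual = quals[keep], stringsAsFactors = FALSE,
                      row.names = NULL)
  if (nrow(clean)) {
    ph <- unlist(lapply(clean$qual, function(q) utf8ToInt(q) - 33L))
    bases <- strsplit(paste(clean$seq, collapse = ""), "")[[1]]
    q20 <- 100 * mean(ph >= 20); q30 <- 100 * mean(ph >= 30)
    gc <- 100 * mean(bases %in% c("G", "C"))
  } else {
    q20 <- q30 <- gc <- NA_real_
  }
  list(
    clean = clean,
    report = list(
      n_input = n,
      n_adapter_removed = sum(category == "adapter"),
      n_highN_removed = sum(category == "highN"),
      n_lowqual_removed = sum(category == "lowqual"),
      n_clean = sum(keep),
      q20 = q20, q30 = q30, gc = gc
    )
  )
}
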