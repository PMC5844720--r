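## lncRNA candidate classification: a four-step cascade over assembled
## transcripts (class code -> length -> known-lncRNA match -> coding
## potential). Retained class codes are the Cuffcompare codes denoting
## novel or non-reference structures: j (novel isoform), i (intronic),
## o (exonic overlap), u (intergenic), x (antisense).

LNC_CLASS_CODES <- c("j", "i", "o", "u", "x")

#' Step 1: retain candidate class codes
#'
#' @param annotation A [transcript_annotation()]; every record must carry
#'   a class code.
#' @return The subset with `class_code` in `{j,i,o,u,x}`.
#' @export
filter_class_codes <- function(annotation) {
  if (anyNA(annotation$class_code)) stop("missing class_code on some transcripts")
  subset_annotation(annotation, annotation$class_code %in% LNC_CLASS_CODES)
}

#' Step 2: retain transcripts of at least `min_len` bases
#'
#' Length is the summed exonic length.
#'
#' @param annotation A [transcript_annotation()].
#' @param min_len Minimum length in bases (default 200; shorter is
#'   rejected, exactly `min_len` is retained).
#' @export
filter_length <- function(annotation, min_len = 200) {
  subset_annotation(annotation, exonic_length(annotation) >= min_len)
}

#' @noRd
subset_annotation <- function(annotation, keep) {
  ex <- attr(annotation, "exons")
  out <- annotation[keep, , drop = FALSE]
  class(out) <- "data.frame"
  transcript_annotation(out, ex[ex$transcript_id %in% out$transcript_id, ,
                                drop = FALSE])
}

#' Step 3: match candidates against a known-lncRNA reference
#'
#' A stand-in for a blastn search of a lncRNA database: candidate and
#' reference pairs sharing at least one exact k-mer (default k = 11) are
#' aligned with a gapless local alignment (Biostrings, with a prohibitive
#' gap penalty); a candidate is "known" when its best alignment reaches
#' `identity_min` identity over at least `coverage_min` of the shorter
#' sequence.
#'
#' @param sequences Named character vector of candidate sequences.
#' @param reference Named character vector of known-lncRNA sequences.
#' @param identity_min Minimum alignment identity (default 0.95).
#' @param coverage_min Minimum alignment length as a fraction of the
#'   shorter sequence (default 0.90).
#' @param k Seed k-mer length (default 11).
#' @return Logical vector (named as `sequences`): TRUE = known.
#' @export
match_known_lncrnas <- function(sequences, reference,
                                identity_min = 0.95, coverage_min = 0.90,
                                k = 11L) {
  if (length(reference) == 0) stop("empty known-lncRNA reference")
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  kmers <- function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character(0))
    unique(substring(s, seq_len(n), seq_len(n) + k - 1L))
  }
  ref_kmers <- lapply(reference, kmers)
  known <- vapply(seq_along(sequences), function(i) {
    s <- sequences[[i]]
    sk <- kmers(s)
    for (j in seq_along(reference)) {
      if (!length(intersect(sk, ref_kmers[[j]]))) next
      aln <- Biostrings::pairwiseAlignment(
        s, reference[[j]], type = "local",
        substitutionMatrix = submat,
        gapOpening = 1e6, gapExtension = 1e6
      )
      alen <- Biostrings::nchar(aln)
      if (alen == 0) next
      ident <- Biostrings::nmatch(aln) / alen
      cover <- alen / min(nchar(s), nchar(reference[[j]]))
      if (ident >= identity_min && cover >= coverage_min) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
  stats::setNames(known, names(sequences))
}

#' Step 4: coding-potential assessment by ORF scan
#'
#' Scans the three forward reading frames for open reading frames
#' (ATG..stop, and open-ended ORFs running to the end of the transcript).
#' The verdict is `"coding"` when the longest ORF reaches
#' `min_orf_codons` codons (stop codon included, 100 by convention) or
#' covers at least `min_orf_coverage` of the transcript.
#'
#' @param sequence A single DNA sequence (ACGTN).
#' @param min_orf_codons Codon threshold, inclusive (default 100).
#' @param min_orf_coverage ORF-coverage threshold (default 0.5).
#' @return List: `longest_orf_codons`, `orf_coverage`, `verdict`
#'   (`"coding"`/`"noncoding"`).
#' @export
classify_coding <- function(sequence, min_orf_codons = 100,
                            min_orf_coverage = 0.5) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("sequence must be over {A,C,G,T,N}")
  len <- nchar(sequence)
  best_nt <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    n_codons <- (len - frame) %/% 3L
    if (n_codons < 1L) next
    starts <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(sequence, starts, starts + 2L)
    in_orf <- FALSE; orf_codons <- 0L
    for (cd in codons) {
      if (!in_orf) {
        if (cd == "ATG") { in_orf <- TRUE; orf_codons <- 1L }
      } else {
        orf_codons <- orf_codons + 1L
        if (cd %in% stops) {
          best_nt <- max(best_nt, 3L * orf_codons)
          in_orf <- FALSE; orf_codons <- 0L
        }
      }
    }
    if (in_orf) best_nt <- max(best_nt, 3L * orf_codons)  # open-ended ORF
  }
  codons <- best_nt %/% 3L
  coverage <- best_nt / len
  list(
    longest_orf_codons = codons,
    orf_coverage = coverage,
    verdict = if (codons >= min_orf_codons || coverage >= min_orf_coverage)
      "coding" else "noncoding"
  )
}

#' Run the full lncRNA prediction cascade
#'
#' Steps, in order: (1) retain class codes `{j,i,o,u,x}`; (2) retain
#' length >= 200; (3) label candidates matching the known-lncRNA
#' reference as `known_lncRNA`; (4) assess coding potential of the rest —
#' noncoding survivors become `novel_lncRNA`. Every input transcript
#' receives exactly one label; the known and novel lncRNAs together form
#' the downstream lncRNA set.
#'
#' @param annotation A [transcript_annotation()] of candidate transcripts.
#' @param sequences Named character vector covering all candidates.
#' @param reference Known-lncRNA reference sequences.
#' @param min_len,identity_min,coverage_min,min_orf_codons,min_orf_coverage
#'   Stage parameters (see the step functions).
#' @return data.frame with columns `transcript_id` and `label` in
#'   `{rejected_class_code, rejected_length, known_lncRNA, coding,
#'   novel_lncRNA}`.
#' @export
predict_lncrnas <- function(annotation, sequences, reference,
                            min_len = 200,
                            identity_min = 0.95, coverage_min = 0.90,
                            min_orf_codons = 100, min_orf_coverage = 0.5) {
  ids <- annotation$transcript_id
  label <- stats::setNames(rep(NA_character_, length(ids)), ids)

  s1 <- filter_class_codes(annotation)
  label[setdiff(ids, s1$transcript_id)] <- "rejected_class_code"

  s2 <- filter_length(s1, min_len = min_len)
  label[setdiff(s1$transcript_id, s2$transcript_id)] <- "rejected_length"

  cand <- s2$transcript_id
  miss <- setdiff(cand, names(sequences))
  if (length(miss)) stop("candidates without sequence: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  known <- match_known_lncrnas(sequences[cand], reference,
                               identity_min = identity_min,
                               coverage_min = coverage_min)
  label[cand[known]] <- "known_lncRNA"

  rest <- cand[!known]
  for (id in rest) {
    v <- classify_coding(sequences[[id]], min_orf_codons = min_orf_codons,
                         min_orf_coverage = min_orf_coverage)$verdict
    label[id] <- if (v == "coding") "coding" else "novel_lncRNA"
  }
  data.frame(transcript_id = ids, label = unname(label[ids]),
             stringsAsFactors = FALSE, row.names = NULL)
}
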