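## Canonical miRNA seed-site (MRE) prediction and lncRNA cis/antisense
## target assignment. All matching is done in DNA space (U -> T at the
## boundary). The seed is miRNA nucleotides 2-8 from the 5' end; the four
## canonical site classes on the target, read 5'->3', are:
##   8mer     : revcomp(miRNA 2-8) followed by A (opposite position 1)
##   7mer-m8  : revcomp(miRNA 2-8)
##   7mer-A1  : revcomp(miRNA 2-7) followed by A
##   6mer     : revcomp(miRNA 2-7)
## Every occurrence is labelled with its most specific class.

#' @noRd
revcomp_dna <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' @noRd
as_dna <- function(s) chartr("Uu", "Tt", toupper(s))

SITE_CLASSES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

#' Find canonical miRNA seed sites on target sequences
#'
#' Scans each target for perfect matches to each miRNA's seed, reporting
#' every occurrence with its most specific site class (see the site-class
#' definitions in the package vignette); output rows are ordered by
#' target, then miRNA, then position.
#'
#' @param mirnas Named character vector of mature miRNA sequences
#'   (5'->3', RNA or DNA, length >= 8).
#' @param targets Named character vector of target sequences (DNA).
#' @param site_classes Site classes to report (default all four); an
#'   occurrence is reported only when its most specific class is in this
#'   set.
#' @param predictor Provenance tag recorded on each site (default
#'   `"seed_scan"`).
#' @return data.frame of MRE sites: `mirna_id`, `target_id`, `start`,
#'   `end` (1-based inclusive on the target), `site_class`, `predictor`.
#' @export
find_seed_sites <- function(mirnas, targets,
                            site_classes = SITE_CLASSES,
                            predictor = "seed_scan") {
  bad <- setdiff(site_classes, SITE_CLASSES)
  if (length(bad)) stop("unknown site class: ", paste(bad, collapse = ", "))
  if (any(nchar(mirnas) < 8)) stop("miRNA shorter than 8 nt")
  mirnas <- vapply(mirnas, as_dna, character(1))
  targets <- vapply(targets, as_dna, character(1))

  out <- vector("list", length(mirnas) * length(targets))
  idx <- 0L
  for (mi in seq_along(mirnas)) {
    core6 <- revcomp_dna(substr(mirnas[[mi]], 2, 7))
    m8c <- chartr("ACGT", "TGCA", substr(mirnas[[mi]], 8, 8))
    for (ti in seq_along(targets)) {
      tg <- targets[[ti]]
      hits <- gregexpr(core6, tg, fixed = TRUE)[[1]]
      if (hits[1] < 0) next
      pos <- as.integer(hits)
      has_m8 <- pos > 1L & substring(tg, pos - 1L, pos - 1L) == m8c
      has_a1 <- substring(tg, pos + 6L, pos + 6L) == "A"  # "" at end: FALSE
      cls <- ifelse(has_m8 & has_a1, "8mer",
             ifelse(has_m8, "7mer-m8",
             ifelse(has_a1, "7mer-A1", "6mer")))
      start <- ifelse(has_m8, pos - 1L, pos)
      end <- ifelse(has_a1, pos + 6L, pos + 5L)
      keep <- cls %in% site_classes
      if (!any(keep)) next
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        mirna_id = names(mirnas)[mi], target_id = names(targets)[ti],
        start = as.integer(start[keep]), end = as.integer(end[keep]),
        site_class = cls[keep], predictor = predictor,
        stringsAsFactors = FALSE
      )
    }
  }
  if (idx == 0L) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      start = integer(0), end = integer(0),
                      site_class = character(0), predictor = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out[seq_len(idx)])
  res <- res[order(res$target_id, res$mirna_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Combine per-predictor target predictions
#'
#' Combination is at the gene level: a (miRNA, target) pair survives an
#' intersection when every predictor reports at least one site for it
#' (the published convention of taking the same target genes of the same
#' miRNAs), and survives a union when any predictor does.
#'
#' @param site_lists List of MRE site data.frames (one per predictor, as
#'   returned by [find_seed_sites()]).
#' @param mode `"intersection"` (default) or `"union"`.
#' @return data.frame of retained pairs: `mirna_id`, `target_id`.
#' @export
combine_predictions <- function(site_lists, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  if (!length(site_lists)) stop("at least one predictor list required")
  pair_sets <- lapply(site_lists, function(s)
    unique(paste(s$mirna_id, s$target_id, sep = "\r")))
  keys <- if (mode == "union") unique(unlist(pair_sets))
          else Reduce(intersect, pair_sets)
  if (!length(keys)) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(sort(keys), "\r", fixed = TRUE)
  data.frame(mirna_id = vapply(parts, `[[`, character(1), 1),
             target_id = vapply(parts, `[[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' @noRd
annotation_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand
  )
}

#' Assign cis target genes of lncRNAs
#'
#' A gene is a cis target of a lncRNA when the gap between their genomic
#' spans is at most `window` bases (inclusive; overlapping spans have
#' distance 0) on the same chromosome, either strand. The relation
#' (`upstream`/`downstream`) is oriented by the lncRNA's strand;
#' overlapping pairs are labelled `overlap`.
#'
#' @param lncrnas,genes [transcript_annotation()] tables (1-based
#'   inclusive coordinates; `genes` rows are transcripts and are reported
#'   by their `gene_id`, deduplicated to the smallest distance).
#' @param window Maximum gap in bases (default 10000).
#' @return data.frame: `lncrna_id`, `gene_id`, `distance`, `relation`.
#' @export
assign_cis_targets <- function(lncrnas, genes, window = 10000) {
  if (!nrow(lncrnas) || !nrow(genes)) {
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance = integer(0), relation = character(0),
                      stringsAsFactors = FALSE))
  }
  lg <- annotation_granges(lncrnas)
  gg <- annotation_granges(genes)
  hits <- GenomicRanges::findOverlaps(lg, gg, maxgap = window,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) {
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance = integer(0), relation = character(0),
                      stringsAsFactors = FALSE))
  }
  d <- GenomicRanges::distance(lg[qi], gg[si], ignore.strand = TRUE)
  overlapping <- GenomicRanges::start(gg[si]) <= GenomicRanges::end(lg[qi]) &
    GenomicRanges::end(gg[si]) >= GenomicRanges::start(lg[qi])
  gene_left <- GenomicRanges::end(gg[si]) < GenomicRanges::start(lg[qi])
  lnc_plus <- lncrnas$strand[qi] == "+"
  relation <- ifelse(overlapping, "overlap",
              ifelse(gene_left == lnc_plus, "upstream", "downstream"))
  out <- data.frame(
    lncrna_id = lncrnas$transcript_id[qi],
    gene_id = genes$gene_id[si],
    distance = as.integer(d),
    relation = relation,
    stringsAsFactors = FALSE
  )
  ## dedupe multiple transcripts of one gene: keep the closest
  out <- out[order(out$lncrna_id, out$gene_id, out$distance), , drop = FALSE]
  out <- out[!duplicated(out[, c("lncrna_id", "gene_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @noRd
longest_equal_run <- function(a, b) {
  if (nchar(a) != nchar(b) || nchar(a) == 0) return(0L)
  eq <- strsplit(a, "")[[1]] == strsplit(b, "")[[1]]
  r <- rle(eq)
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

#' Find antisense target transcripts of lncRNAs
#'
#' A transcript is an antisense target when its genomic span overlaps the
#' lncRNA's span by at least one base on the opposite strand. When
#' sequences are supplied, each pair is annotated with a complementarity
#' score: the longest contiguous perfectly complementary run between the
#' two transcripts over the overlap (a duplex-interaction stand-in;
#' reported, not thresholded). The score is computed on the genomic-span
#' projection and is only meaningful for single-exon transcripts; it is
#' NA otherwise.
#'
#' @param lncrnas,transcripts [transcript_annotation()] tables.
#' @param sequences Optional named character vector covering both sets.
#' @return data.frame: `lncrna_id`, `transcript_id`, `gene_id`,
#'   `overlap`, `complementarity`.
#' @export
find_antisense_targets <- function(lncrnas, transcripts, sequences = NULL) {
  empty <- data.frame(lncrna_id = character(0), transcript_id = character(0),
                      gene_id = character(0), overlap = integer(0),
                      complementarity = integer(0), stringsAsFactors = FALSE)
  if (!nrow(lncrnas) || !nrow(transcripts)) return(empty)
  lg <- annotation_granges(lncrnas)
  tg <- annotation_granges(transcripts)
  hits <- GenomicRanges::findOverlaps(lg, tg, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  opp <- lncrnas$strand[qi] != transcripts$strand[si] &
    lncrnas$transcript_id[qi] != transcripts$transcript_id[si]
  qi <- qi[opp]; si <- si[opp]
  if (!length(qi)) return(empty)
  os <- pmax(lncrnas$start[qi], transcripts$start[si])
  oe <- pmin(lncrnas$end[qi], transcripts$end[si])
  ov <- oe - os + 1L

  comp <- rep(NA_integer_, length(qi))
  if (!is.null(sequences)) {
    seq_of <- function(id) {
      if (id %in% names(sequences)) sequences[[id]] else NA_character_
    }
    plus_piece <- function(a_start, a_end, strand, seq, os, oe) {
      if (is.na(seq)) return(NA_character_)
      if (nchar(seq) != a_end - a_start + 1) return(NA_character_)  # multi-exon
      if (strand == "+") substr(seq, os - a_start + 1, oe - a_start + 1)
      else revcomp_dna(substr(seq, a_end - oe + 1, a_end - os + 1))
    }
    for (r in seq_along(qi)) {
      s1 <- plus_piece(lncrnas$start[qi[r]], lncrnas$end[qi[r]],
                       lncrnas$strand[qi[r]],
                       seq_of(lncrnas$transcript_id[qi[r]]), os[r], oe[r])
      s2 <- plus_piece(transcripts$start[si[r]], transcripts$end[si[r]],
                       transcripts$strand[si[r]],
                       seq_of(transcripts$transcript_id[si[r]]), os[r], oe[r])
      if (!is.na(s1) && !is.na(s2))
        comp[r] <- longest_equal_run(s1, s2)
    }
  }
  out <- data.frame(
    lncrna_id = lncrnas$transcript_id[qi],
    transcript_id = transcripts$transcript_id[si],
    gene_id = transcripts$gene_id[si],
    overlap = ov,
    complementarity = comp,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$lncrna_id, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
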