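## Synthetic-data generator: builds a transcriptome (mRNAs, lncRNA
## candidates, miRNAs) with a known, implanted sponge network and
## simulates two-condition negative-binomial counts, so that every
## pipeline stage can be validated against ground truth. Sequences are
## DNA (ACGT); mature miRNAs are reported as RNA (ACGU). Decoy
## transcripts are guaranteed free of any canonical seed site of any
## simulated miRNA; transcripts carrying implanted sites contain exactly
## the recorded sites and nothing else.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' @param n_mrna,n_lncrna,n_mirna Feature counts per class.
#' @param n_samples_per_group Samples per condition (default 3, the
#'   matched tumour/control design).
#' @param baseline_mean Expected counts per feature in the control group
#'   (default 200).
#' @param nb_dispersion Negative-binomial dispersion; variance =
#'   mean + dispersion * mean^2 (0 = Poisson; default 0.05, a typical
#'   gene-level value for high-depth bulk tissue data).
#' @param frac_de Fraction of each feature class that is differentially
#'   expressed (default 0.1).
#' @param implanted_log2fc Absolute log2 fold change implanted in DE
#'   features (default 2).
#' @param sites_per_true_pair Number of 8mer sites implanted per true
#'   (miRNA, target) pair (default 2).
#' @param genome_length Length of the simulated genome in bases
#'   (default 2e7).
#' @param seed Integer RNG seed; a fixed seed makes all outputs
#'   byte-identical across runs.
#' @param hub_frac Fraction of DE miRNAs that become sponge hubs with
#'   implanted partners (default 0.3).
#' @param known_lncrna_frac Fraction of lncRNAs included in the packaged
#'   known-lncRNA reference (default 0.3).
#' @param max_attempts Retry cap per transcript when sampling seed-free
#'   sequence (default 1000).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_mrna = 500, n_lncrna = 150, n_mirna = 200,
                       n_samples_per_group = 3, baseline_mean = 200,
                       nb_dispersion = 0.05, frac_de = 0.1,
                       implanted_log2fc = 2, sites_per_true_pair = 2,
                       genome_length = 2e7, seed = 42,
                       hub_frac = 0.3, known_lncrna_frac = 0.3,
                       max_attempts = 1000) {
  stopifnot(n_mrna >= 0, n_lncrna >= 0, n_mirna >= 0,
            n_samples_per_group >= 1, baseline_mean > 0,
            nb_dispersion >= 0, frac_de >= 0, frac_de <= 1,
            implanted_log2fc > 0, sites_per_true_pair >= 1,
            genome_length >= 1, max_attempts >= 1)
  structure(as.list(environment()), class = "sim_config")
}

## ---- seed-free sequence machinery ----------------------------------------

## all positions where a forbidden 6mer occurs in the character vector
#' @noRd
scan_cores <- function(chars, forbidden) {
  L <- length(chars)
  if (L < 6 || !length(forbidden)) return(integer(0))
  s <- paste(chars, collapse = "")
  w <- substring(s, 1:(L - 5), 6:L)
  which(w %in% forbidden)
}

## Repair a sequence in place until it contains forbidden 6mers only at
## `expected` positions. `frozen` positions are never mutated; positions
## listed in `orf` (codon-structured region, excluding start/stop codons)
## are resampled codon-wise from non-stop codons. Returns the repaired
## character vector or NULL when the repair does not converge.
#' @noRd
repair_seedfree <- function(chars, forbidden, expected = integer(0),
                            frozen = integer(0), orf_start = NA,
                            orf_end = NA, max_iter = 100L) {
  nonstop <- setdiff(apply(expand.grid(BASES, BASES, BASES), 1, paste,
                           collapse = ""), STOP_CODONS)
  for (iter in seq_len(max_iter)) {
    bad <- setdiff(scan_cores(chars, forbidden), expected)
    if (!length(bad)) return(chars)
    for (p in bad) {
      win <- p:(p + 5)
      mut <- setdiff(win, frozen)
      if (!length(mut)) return(NULL)  # core inside an immutable region
      in_orf <- !is.na(orf_start) & mut >= orf_start & mut <= orf_end
      if (any(in_orf)) {
        codon_idx <- unique((mut[in_orf] - orf_start) %/% 3)
        for (ci in codon_idx) {
          cp <- orf_start + 3 * ci
          chars[cp:(cp + 2)] <- strsplit(sample(nonstop, 1), "")[[1]]
        }
      }
      rest <- mut[!in_orf]
      if (length(rest)) chars[rest] <- sample(BASES, length(rest), replace = TRUE)
    }
  }
  NULL
}

## Build one transcript: random UTRs, optional ORF, implanted 8mer
## patterns at given positions; guaranteed to contain exactly the
## expected seed cores. Returns list(seq, ok).
#' @noRd
build_transcript <- function(length_total, forbidden, implant_patterns,
                             implant_pos, orf = NULL, noncoding_check = FALSE,
                             max_attempts = 1000L) {
  for (attempt in seq_len(max_attempts)) {
    chars <- sample(BASES, length_total, replace = TRUE)
    orf_start <- NA; orf_end <- NA
    if (!is.null(orf)) {
      ## orf = number of codons including start and stop
      orf_start <- orf$start
      orf_end <- orf$start + 3 * orf$codons - 1
      nonstop <- setdiff(apply(expand.grid(BASES, BASES, BASES), 1, paste,
                               collapse = ""), STOP_CODONS)
      body <- sample(nonstop, orf$codons - 2, replace = TRUE)
      orf_seq <- paste0("ATG", paste(body, collapse = ""),
                        sample(STOP_CODONS, 1))
      chars[orf_start:orf_end] <- strsplit(orf_seq, "")[[1]]
    }
    frozen <- integer(0)
    expected <- integer(0)
    if (length(implant_pos)) {
      for (k in seq_along(implant_pos)) {
        p <- implant_pos[k]
        chars[p:(p + 7)] <- strsplit(implant_patterns[k], "")[[1]]
        frozen <- c(frozen, p:(p + 7))
        expected <- c(expected, p + 1L)  # seed core sits at offset 2
      }
      if (!is.na(orf_start)) {
        ## start/stop codons are immutable too
        frozen <- c(frozen, orf_start:(orf_start + 2),
                    (orf_end - 2):orf_end)
      }
    } else if (!is.na(orf_start)) {
      frozen <- c(orf_start:(orf_start + 2), (orf_end - 2):orf_end)
    }
    chars <- repair_seedfree(chars, forbidden, expected = expected,
                             frozen = frozen, orf_start = orf_start,
                             orf_end = orf_end)
    if (is.null(chars)) next
    s <- paste(chars, collapse = "")
    if (!is.null(orf)) {
      if (classify_coding(s)$longest_orf_codons < orf$codons) next
    }
    if (noncoding_check) {
      if (classify_coding(s)$verdict != "noncoding") next
    }
    return(s)
  }
  stop("could not sample a seed-free transcript within the attempt cap; ",
       "sequence space too constrained for this configuration")
}

## ---- miRNA sampling -------------------------------------------------------

## Sample n mature miRNAs (22 nt) whose seed 6mer cores are pairwise
## distinct and whose 8mer site patterns contain no other miRNA's core
## (so an implanted site can never be attributed to two miRNAs).
#' @noRd
sample_mirnas <- function(n, max_attempts = 10000L) {
  matures <- character(n)
  cores <- character(0)
  patterns <- character(0)
  windows_of <- function(pat) substring(pat, 1:3, 6:8)
  i <- 1L
  attempts <- 0L
  while (i <= n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) stop("could not sample compatible miRNA seed set")
    m <- paste(sample(BASES, 22, replace = TRUE), collapse = "")
    core <- revcomp_dna(substr(m, 2, 7))
    pat <- paste0(revcomp_dna(substr(m, 2, 8)), "A")
    w <- windows_of(pat)
    ok <- !(core %in% cores) &&
      sum(w == core) == 1 &&                 # own core only at offset 2
      !any(w %in% cores) &&                  # no existing core inside new pattern
      !any(core %in% unlist(lapply(patterns, windows_of)))
    if (!ok) next
    matures[i] <- m
    cores <- c(cores, core)
    patterns <- c(patterns, pat)
    i <- i + 1L
  }
  list(mature_dna = matures, cores = cores, patterns = patterns)
}

## ---- main generator -------------------------------------------------------

#' Generate a synthetic transcriptome with an implanted sponge network
#'
#' Produces transcript annotation and sequences (mRNAs with ORFs of at
#' least 100 codons; lncRNA candidates of at least 200 nt with class
#' codes from `{j,i,o,u,x}` and no coding potential), mature/precursor
#' miRNA sequences, and a ground-truth table of implanted DE fold
#' changes, 8mer MRE sites and the sponge triplets they imply. Decoy
#' transcripts carry no canonical seed site of any simulated miRNA.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_transcriptome`: `annotation`
#'   ([transcript_annotation()] of the long transcripts), `sequences`
#'   (named DNA vector), `mirnas` (list: `mature` RNA vector,
#'   `precursor` DNA vector, `reference` data.frame for
#'   [identify_known_mirnas()]), `known_lncrna_ref` (named DNA vector),
#'   `truth` (list: `de_features`, `true_sites`, `true_triplets`),
#'   `config`.
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "transcriptome"))

  ## miRNAs
  if (config$n_mirna > 0) {
    mir <- sample_mirnas(config$n_mirna)
    mirna_ids <- sprintf("mir-%03d", seq_len(config$n_mirna))
    mature_dna <- stats::setNames(mir$mature_dna, mirna_ids)
    precursor <- stats::setNames(vapply(mir$mature_dna, function(m) {
      paste0(paste(sample(BASES, 20, replace = TRUE), collapse = ""), m,
             paste(sample(BASES, 20, replace = TRUE), collapse = ""))
    }, character(1), USE.NAMES = FALSE), mirna_ids)
    forbidden <- mir$cores
    patterns <- stats::setNames(mir$patterns, mirna_ids)
  } else {
    mirna_ids <- character(0)
    mature_dna <- precursor <- patterns <- character(0)
    forbidden <- character(0)
  }

  mrna_ids <- sprintf("TX_%04d", seq_len(config$n_mrna))
  lnc_ids <- sprintf("TCONS_%05d", seq_len(config$n_lncrna))

  ## implanted differential expression (signed log2 fold changes)
  pick_de <- function(ids) {
    n_de <- round(config$frac_de * length(ids))
    if (n_de < 1) return(stats::setNames(numeric(0), character(0)))
    chosen <- sample(ids, n_de)
    stats::setNames(sample(c(-1, 1), n_de, replace = TRUE) *
                      config$implanted_log2fc, chosen)
  }
  de_mrna <- pick_de(mrna_ids)
  de_lnc <- pick_de(lnc_ids)
  de_mir <- pick_de(mirna_ids)

  ## sponge hubs: a subset of DE miRNAs, each implanted with 1-3 DE
  ## lncRNA and 1-3 DE mRNA partners whose direction is opposite
  n_hub <- if (length(de_mir)) max(1L, round(config$hub_frac * length(de_mir))) else 0L
  pair_sites <- list()  # target_id -> named list mirna -> n sites
  triplets <- list()
  if (n_hub > 0) {
    hubs <- sample(names(de_mir), n_hub)
    for (m in hubs) {
      d <- sign(de_mir[[m]])
      lnc_pool <- names(de_lnc)[sign(de_lnc) == -d]
      g_pool <- names(de_mrna)[sign(de_mrna) == -d]
      if (!length(lnc_pool) || !length(g_pool)) next
      ls <- sample(lnc_pool, min(sample(1:3, 1), length(lnc_pool)))
      gs <- sample(g_pool, min(sample(1:3, 1), length(g_pool)))
      for (t in c(ls, gs)) {
        pair_sites[[t]] <- c(pair_sites[[t]], stats::setNames(
          list(config$sites_per_true_pair), m))
      }
      combo <- expand.grid(l = ls, g = gs, stringsAsFactors = FALSE)
      triplets[[length(triplets) + 1]] <- data.frame(
        mirna_id = m, lncrna_id = combo$l, mrna_id = combo$g,
        mirna_direction = if (d > 0) "up" else "down",
        lncrna_direction = if (d > 0) "down" else "up",
        mrna_direction = if (d > 0) "down" else "up",
        stringsAsFactors = FALSE
      )
    }
  }
  true_triplets <- if (length(triplets)) {
    tt <- unique(do.call(rbind, triplets))
    tt <- tt[order(tt$mirna_id, tt$lncrna_id, tt$mrna_id), , drop = FALSE]
    rownames(tt) <- NULL
    tt
  } else {
    data.frame(mirna_id = character(0), lncrna_id = character(0),
               mrna_id = character(0), mirna_direction = character(0),
               lncrna_direction = character(0), mrna_direction = character(0),
               stringsAsFactors = FALSE)
  }

  ## sequences: mRNAs (UTR5 + ORF + UTR3), lncRNAs; implants in the
  ## 3' region, spaced so site spans never abut
  sequences <- character(0)
  true_sites <- list()
  make_implants <- function(id, region_start, length_total) {
    want <- pair_sites[[id]]
    if (is.null(want)) return(list(pat = character(0), pos = integer(0),
                                   mir = character(0)))
    mirs <- rep(names(want), times = unlist(want))
    slots <- seq(region_start, length_total - 9L, by = 14L)
    if (length(slots) < length(mirs)) stop("implant region too small")
    pos <- sort(sample(slots, length(mirs)))
    list(pat = unname(patterns[mirs]), pos = pos, mir = mirs)
  }

  for (id in mrna_ids) {
    n_codons <- sample(110:160, 1)
    utr5 <- sample(60:120, 1)
    n_sites_here <- sum(unlist(pair_sites[[id]]))
    utr3 <- max(250, 14 * n_sites_here + 60)
    total <- utr5 + 3 * n_codons + utr3
    imp <- make_implants(id, utr5 + 3 * n_codons + 4L, total)
    s <- build_transcript(total, forbidden, imp$pat, imp$pos,
                          orf = list(start = utr5 + 1L, codons = n_codons),
                          max_attempts = config$max_attempts)
    sequences[[id]] <- s
    if (length(imp$pos)) {
      true_sites[[length(true_sites) + 1]] <- data.frame(
        mirna_id = imp$mir, target_id = id,
        start = imp$pos, end = imp$pos + 7L, site_class = "8mer",
        stringsAsFactors = FALSE)
    }
  }
  for (id in lnc_ids) {
    n_sites_here <- sum(unlist(pair_sites[[id]]))
    total <- max(sample(400:800, 1), 14 * n_sites_here + 260)
    imp <- make_implants(id, max(200L, total - 14L * n_sites_here - 40L), total)
    s <- build_transcript(total, forbidden, imp$pat, imp$pos,
                          noncoding_check = TRUE,
                          max_attempts = config$max_attempts)
    sequences[[id]] <- s
    if (length(imp$pos)) {
      true_sites[[length(true_sites) + 1]] <- data.frame(
        mirna_id = imp$mir, target_id = id,
        start = imp$pos, end = imp$pos + 7L, site_class = "8mer",
        stringsAsFactors = FALSE)
    }
  }
  true_sites <- if (length(true_sites)) {
    ts <- do.call(rbind, true_sites)
    ts <- ts[order(ts$target_id, ts$mirna_id, ts$start), , drop = FALSE]
    rownames(ts) <- NULL
    ts
  } else {
    data.frame(mirna_id = character(0), target_id = character(0),
               start = integer(0), end = integer(0),
               site_class = character(0), stringsAsFactors = FALSE)
  }

  ## genome placement: transcripts laid out with random gaps on two
  ## chromosomes; a few lncRNAs are re-placed antisense inside an mRNA
  ids <- c(mrna_ids, lnc_ids)
  lens <- nchar(sequences[ids])
  gaps <- sample(0:8000, length(ids), replace = TRUE)
  if (sum(lens) + sum(gaps) > config$genome_length)
    stop("genome_length too small for the requested transcript set")
  half <- ceiling(length(ids) / 2)
  chrom <- rep(c("chr1", "chr2"), times = c(half, length(ids) - half))
  start <- integer(length(ids))
  cur <- c(chr1 = 1L, chr2 = 1L)
  for (i in seq_along(ids)) {
    cur[chrom[i]] <- cur[chrom[i]] + gaps[i]
    start[i] <- cur[chrom[i]]
    cur[chrom[i]] <- cur[chrom[i]] + lens[i]
  }
  end <- start + lens - 1L
  strand <- sample(c("+", "-"), length(ids), replace = TRUE)
  is_lnc <- ids %in% lnc_ids
  ## antisense placements: up to 5 lncRNAs moved inside an mRNA span,
  ## opposite strand (coordinates only; sequences are unchanged)
  if (config$n_mrna > 0 && config$n_lncrna > 0) {
    n_anti <- min(5L, config$n_lncrna, config$n_mrna)
    ## sample() on a length-1 vector would sample 1:x; index explicitly
    lnc_idx <- which(is_lnc); mrna_idx <- which(!is_lnc)
    anti_l <- lnc_idx[sample.int(length(lnc_idx), n_anti)]
    host <- mrna_idx[sample.int(length(mrna_idx), n_anti, replace = n_anti > length(mrna_idx))]
    for (k in seq_len(n_anti)) {
      li <- anti_l[k]; hi <- host[k]
      if (lens[li] >= lens[hi]) next
      chrom[li] <- chrom[hi]
      start[li] <- start[hi] + sample.int(lens[hi] - lens[li], 1) - 1L
      end[li] <- start[li] + lens[li] - 1L
      strand[li] <- if (strand[hi] == "+") "-" else "+"
    }
  }

  annotation <- transcript_annotation(data.frame(
    transcript_id = ids,
    gene_id = sub("^TX_", "GENE_", sub("^TCONS_", "XLOC_", ids)),
    chrom = chrom, start = start, end = end, strand = strand,
    class_code = ifelse(is_lnc, sample(LNC_CLASS_CODES, length(ids),
                                       replace = TRUE), "="),
    biotype = ifelse(is_lnc, "lncRNA_candidate", "mRNA"),
    stringsAsFactors = FALSE
  ))

  ## known-lncRNA reference: a subset of the lncRNAs, verbatim
  n_known <- round(config$known_lncrna_frac * config$n_lncrna)
  known_ids <- if (n_known >= 1) sort(sample(lnc_ids, n_known)) else character(0)
  known_ref <- stats::setNames(unname(sequences[known_ids]),
                               sprintf("REF_%s", known_ids))

  de_features <- c(de_mrna, de_lnc, de_mir)
  out <- list(
    annotation = annotation, sequences = sequences,
    mirnas = list(
      mature = stats::setNames(chartr("T", "U", mature_dna), mirna_ids),
      precursor = precursor,
      reference = data.frame(mirna_id = mirna_ids,
                             precursor = unname(precursor),
                             mature = unname(mature_dna),
                             stringsAsFactors = FALSE)
    ),
    known_lncrna_ref = known_ref,
    truth = list(de_features = de_features,
                 true_sites = true_sites,
                 true_triplets = true_triplets),
    config = config
  )
  class(out) <- "sim_transcriptome"
  out
}

#' Simulate two-condition negative-binomial count matrices
#'
#' Control-group counts have mean `baseline_mean`; tumour-group counts
#' of a DE feature have mean `baseline_mean * 2^log2fc` (signed fold
#' change from the ground truth). Variance is
#' `mean + nb_dispersion * mean^2` (Poisson at dispersion 0). Library
#' sizes are the column sums.
#'
#' @param sim A `sim_transcriptome` from [generate_transcriptome()].
#' @param config A [sim_config()]; defaults to the one inside `sim`.
#' @return List with `long_counts` (mRNA + lncRNA transcripts) and
#'   `small_counts` (miRNAs), both [count_matrix()] objects.
#' @export
simulate_counts <- function(sim, config = sim$config) {
  truth <- sim$truth
  draw <- function(ids, stage) {
    set.seed(derive_seed(config$seed, stage))
    ns <- config$n_samples_per_group
    samples <- c(sprintf("ctr_%d", seq_len(ns)), sprintf("tum_%d", seq_len(ns)))
    condition <- rep(c("control", "tumour"), each = ns)
    lfc <- stats::setNames(rep(0, length(ids)), ids)
    known <- intersect(ids, names(truth$de_features))
    lfc[known] <- truth$de_features[known]
    mu_ctr <- rep(config$baseline_mean, length(ids))
    mu_tum <- config$baseline_mean * 2^lfc
    if (any(!is.finite(c(mu_ctr, mu_tum))) || any(c(mu_ctr, mu_tum) < 0))
      stop("negative or non-finite simulated means")
    rdraw <- function(mu) {
      if (config$nb_dispersion == 0) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    }
    mat <- matrix(0, nrow = length(ids), ncol = 2 * ns,
                  dimnames = list(ids, samples))
    for (j in seq_len(ns)) mat[, j] <- rdraw(mu_ctr)
    for (j in seq_len(ns)) mat[, ns + j] <- rdraw(unname(mu_tum))
    count_matrix(mat, condition)
  }
  long_ids <- sim$annotation$transcript_id
  small_ids <- names(sim$mirnas$mature)
  list(
    long_counts = draw(long_ids, "counts_long"),
    small_counts = if (length(small_ids)) draw(small_ids, "counts_small")
                   else NULL
  )
}

#' Simulate a small-RNA FASTQ for the read-cleaning stage
#'
#' Emits a deterministic set of reads: clean tags copied from the mature
#' miRNAs plus doomed reads exercising each removal rule (3' adapter,
#' excess N content, low quality).
#'
#' @param sim A `sim_transcriptome`.
#' @param reads_per_mirna Clean tag copies per miRNA (default 2).
#' @param adapter Adapter sequence appended to adapter-contaminated reads.
#' @return data.frame with columns `id`, `seq`, `qual` (Phred+33), plus
#'   attribute `"adapter"`.
#' @export
simulate_small_reads <- function(sim, reads_per_mirna = 2,
                                 adapter = "TGGAATTCTCGGGTGCCAAGG") {
  set.seed(derive_seed(sim$config$seed, "small_reads"))
  mat <- chartr("U", "T", sim$mirnas$mature)
  if (!length(mat)) stop("no miRNAs in this simulation")
  qual_for <- function(s, q = 40L) {
    paste(rep(intToUtf8(q + 33L), nchar(s)), collapse = "")
  }
  clean <- data.frame(
    id = sprintf("read_clean_%04d", seq_len(length(mat) * reads_per_mirna)),
    seq = rep(unname(mat), each = reads_per_mirna),
    stringsAsFactors = FALSE
  )
  clean$qual <- vapply(clean$seq, qual_for, character(1), USE.NAMES = FALSE)
  n_bad <- max(3L, length(mat) %/% 10L)
  bad_adapter <- data.frame(
    id = sprintf("read_adapter_%03d", seq_len(n_bad)),
    seq = paste0(sample(unname(mat), n_bad, replace = TRUE), adapter),
    stringsAsFactors = FALSE
  )
  bad_adapter$qual <- vapply(bad_adapter$seq, qual_for, character(1),
                             USE.NAMES = FALSE)
  mkseq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
  bad_n <- data.frame(
    id = sprintf("read_highN_%03d", seq_len(n_bad)),
    seq = vapply(seq_len(n_bad), function(i) {
      s <- strsplit(mkseq(30), "")[[1]]
      s[sample(30, 4)] <- "N"  # 13% N
      paste(s, collapse = "")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  bad_n$qual <- vapply(bad_n$seq, qual_for, character(1), USE.NAMES = FALSE)
  bad_q <- data.frame(
    id = sprintf("read_lowq_%03d", seq_len(n_bad)),
    seq = vapply(rep(30, n_bad), mkseq, character(1)),
    stringsAsFactors = FALSE
  )
  bad_q$qual <- vapply(bad_q$seq, function(s) {
    n <- nchar(s)
    low <- qual_for(substr(s, 1, ceiling(n * 0.6)), 5L)   # Phred 5
    high <- qual_for(substr(s, ceiling(n * 0.6) + 1, n), 35L)
    paste0(low, high)
  }, character(1), USE.NAMES = FALSE)
  out <- rbind(clean, bad_adapter, bad_n, bad_q)
  rownames(out) <- NULL
  attr(out, "adapter") <- adapter
  out
}

#' Write a complete fixture directory
#'
#' Emits the full file set consumed by the pipeline: GTF annotation,
#' FASTA sequence files (transcripts, miRNA matures and precursors,
#' known-lncRNA reference), count and sample TSVs for the long and small
#' libraries, a small-RNA FASTQ, a term-annotation TSV and the
#' ground-truth tables. Re-reading reproduces the inputs exactly; with a
#' fixed seed the files are byte-identical across runs.
#'
#' @param sim A `sim_transcriptome`.
#' @param counts Output of [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @param terms Optional term-annotation data.frame (defaults to
#'   [simulate_term_annotation()] output).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture <- function(sim, counts, dir, terms = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gtf(sim$annotation, p("transcripts.gtf"))
  write_fasta(sim$sequences, p("transcripts.fa"))
  if (length(sim$mirnas$mature)) {
    write_fasta(sim$mirnas$mature, p("mirna_mature.fa"))
    write_fasta(sim$mirnas$precursor, p("mirna_precursor.fa"))
  }
  if (length(sim$known_lncrna_ref))
    write_fasta(sim$known_lncrna_ref, p("known_lncrna_ref.fa"))
  write_counts(counts$long_counts, p("long_counts.tsv"), p("long_samples.tsv"))
  if (!is.null(counts$small_counts))
    write_counts(counts$small_counts, p("small_counts.tsv"),
                 p("small_samples.tsv"))
  de <- sim$truth$de_features
  utils::write.table(
    data.frame(feature_id = names(de), log2fc = unname(de),
               stringsAsFactors = FALSE),
    p("truth_de.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$true_sites, p("truth_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$true_triplets, p("truth_triplets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(terms)) terms <- simulate_term_annotation(sim)
  utils::write.table(terms, p("terms.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(sim$mirnas$mature)) {
    reads <- simulate_small_reads(sim)
    write_fastq(reads, p("small_reads.fastq"))
  }
  files <- list.files(dir, full.names = TRUE)
  invisible(stats::setNames(files, basename(files)))
}

#' Synthetic term annotation for the enrichment stage
#'
#' Random gene-to-term memberships over the simulated genes, with two
#' terms deliberately enriched for the DE genes so the enrichment stage
#' has signal to find.
#'
#' @param sim A `sim_transcriptome`.
#' @param n_terms Number of terms (default 30).
#' @return data.frame: `term_id`, `term_name`, `category`, `gene_id`.
#' @export
simulate_term_annotation <- function(sim, n_terms = 30) {
  set.seed(derive_seed(sim$config$seed, "terms"))
  genes <- unique(sim$annotation$gene_id[sim$annotation$biotype == "mRNA"])
  tx2gene <- stats::setNames(sim$annotation$gene_id,
                             sim$annotation$transcript_id)
  de_tx <- intersect(names(sim$truth$de_features), names(tx2gene))
  de_genes <- intersect(unique(tx2gene[de_tx]), genes)
  rows <- list()
  for (t in seq_len(n_terms)) {
    term_id <- sprintf("TERM:%04d", t)
    category <- if (t %% 2 == 0) "KEGG" else "GO"
    if (t <= 2 && length(de_genes) >= 4) {
      members <- unique(c(sample(de_genes, min(8, length(de_genes))),
                          sample(genes, min(5, length(genes)))))
    } else {
      size <- sample(5:40, 1)
      members <- sample(genes, min(size, length(genes)))
    }
    rows[[t]] <- data.frame(term_id = term_id,
                            term_name = sprintf("synthetic process %d", t),
                            category = category, gene_id = members,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
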