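# Shared fixtures and independent oracles, built in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

# mid-size simulation shared across test files (cached per session)
shared_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    cfg <- sim_config(n_mrna = 60, n_lncrna = 30, n_mirna = 20, seed = 42)
    .fixture_cache$sim <- generate_transcriptome(cfg)
    .fixture_cache$counts <- simulate_counts(.fixture_cache$sim)
  }
  list(sim = .fixture_cache$sim, counts = .fixture_cache$counts)
}

# a small hand-built annotation for interval/cascade tests
tiny_annotation <- function(df) {
  n <- length(df$transcript_id)
  col <- function(x, default) rep_len(x %||% default, n)
  defaults <- data.frame(
    transcript_id = df$transcript_id,
    gene_id = col(df$gene_id, sprintf("g_%s", df$transcript_id)),
    chrom = col(df$chrom, "chr1"),
    start = df$start, end = df$end,
    strand = col(df$strand, "+"),
    class_code = col(df$class_code, "u"),
    biotype = col(df$biotype, "lncRNA_candidate"),
    stringsAsFactors = FALSE
  )
  transcript_annotation(defaults)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

revcomp <- function(s) {
  chartr("ACGTU", "TGCAA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

# independent exhaustive windowed seed scan: enumerates every target
# window of lengths 6/7/8 and compares to the literal patterns, labelling
# each seed-core occurrence with the most specific matching pattern
oracle_seed_scan <- function(mirnas, targets) {
  mirnas <- vapply(mirnas, function(s) chartr("U", "T", toupper(s)), character(1))
  out <- list()
  for (m in names(mirnas)) {
    seed6 <- substr(mirnas[[m]], 2, 7)
    seed7 <- substr(mirnas[[m]], 2, 8)
    core6 <- revcomp(seed6)
    pat7m8 <- revcomp(seed7)
    patA1 <- paste0(core6, "A")
    pat8 <- paste0(pat7m8, "A")
    for (t in names(targets)) {
      tg <- targets[[t]]
      L <- nchar(tg)
      if (L < 6) next
      for (p in seq_len(L - 5)) {
        if (substr(tg, p, p + 5) != core6) next
        if (p > 1 && p + 6 <= L && substr(tg, p - 1, p + 6) == pat8) {
          row <- list(m, t, p - 1L, p + 6L, "8mer")
        } else if (p > 1 && substr(tg, p - 1, p + 5) == pat7m8) {
          row <- list(m, t, p - 1L, p + 5L, "7mer-m8")
        } else if (p + 6 <= L && substr(tg, p, p + 6) == patA1) {
          row <- list(m, t, p, p + 6L, "7mer-A1")
        } else {
          row <- list(m, t, p, p + 5L, "6mer")
        }
        out[[length(out) + 1]] <- row
      }
    }
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      start = integer(0), end = integer(0),
                      site_class = character(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    mirna_id = vapply(out, `[[`, character(1), 1),
    target_id = vapply(out, `[[`, character(1), 2),
    start = vapply(out, `[[`, integer(1), 3),
    end = vapply(out, `[[`, integer(1), 4),
    site_class = vapply(out, `[[`, character(1), 5),
    stringsAsFactors = FALSE
  )
  df[order(df$target_id, df$mirna_id, df$start), ]
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exhaustive hypergeometric upper tail by enumeration over the support
oracle_hyper_tail <- function(k, K, N, n) {
  js <- max(k, 0):min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
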