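test_that("a canonical let-7 8mer site is found at the constructed span", {
  let7 <- c(let7 = "UGAGGUAGUAGGUUGUAUAGUU")
  # seed 2-8 = GAGGUAG; target site = revcomp + A = CTACCTCA
  target <- c(t1 = paste0("GGGGGGGGGG", "CTACCTCA", "GGGGGGGGGG"))
  sites <- find_seed_sites(let7, target)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$site_class, "8mer")
  expect_equal(sites$start, 11)
  expect_equal(sites$end, 18)

  # no complementary substring: empty result
  none <- find_seed_sites(let7, c(t2 = strrep("G", 50)))
  expect_equal(nrow(none), 0)
  expect_error(find_seed_sites(c(m = "UGAGGUA"), target), "shorter")
})

test_that("site classes are mutually exclusive and most specific wins", {
  mi <- c(m = "UGAGGUAGUAGGUUGUAUAGUU")
  core6 <- "TACCTC"  # revcomp of seed 2-7 GAGGUA
  # construct one occurrence of each class in one target, separated by G runs
  t <- c(x = paste0("GG", "C", core6, "A",   # 8mer (m8 C + core + A)
                    "GGGG", "C", core6, "G", # 7mer-m8 (no A)
                    "GGGG", "G", core6, "A", # 7mer-A1 (no m8 match)
                    "GGGG", "G", core6, "G", # bare 6mer
                    "GG"))
  sites <- find_seed_sites(mi, t)
  expect_equal(sites$site_class, c("8mer", "7mer-m8", "7mer-A1", "6mer"))
  expect_equal(sites$end - sites$start + 1,
               c(8L, 7L, 7L, 6L))
  # restricting to the strict classes drops the weaker occurrences
  strict <- find_seed_sites(mi, t, site_classes = c("7mer-m8", "8mer"))
  expect_equal(strict$site_class, c("8mer", "7mer-m8"))
})

test_that("seed scanner equals the exhaustive windowed oracle on random data", {
  set.seed(101)
  mirnas <- setNames(
    vapply(1:5, function(i) chartr("T", "U", random_seq(22)), character(1)),
    paste0("m", 1:5))
  targets <- setNames(vapply(1:40, function(i) random_seq(500), character(1)),
                      paste0("t", 1:40))
  got <- find_seed_sites(mirnas, targets)
  want <- oracle_seed_scan(mirnas, targets)
  expect_equal(got[, c("mirna_id", "target_id", "start", "end", "site_class")],
               want, ignore_attr = TRUE)
})

test_that("predictor combination uses gene-level set semantics", {
  a <- data.frame(mirna_id = "m1", target_id = c("g1", "g2"),
                  stringsAsFactors = FALSE)
  b <- data.frame(mirna_id = "m1", target_id = c("g2", "g3"),
                  stringsAsFactors = FALSE)
  inter <- combine_predictions(list(a, b), "intersection")
  expect_equal(inter$target_id, "g2")
  uni <- combine_predictions(list(a, b), "union")
  expect_setequal(uni$target_id, c("g1", "g2", "g3"))
  # single predictor: identity
  one <- combine_predictions(list(a))
  expect_setequal(one$target_id, c("g1", "g2"))
  # empty intersection allowed
  c2 <- data.frame(mirna_id = "m1", target_id = "g9", stringsAsFactors = FALSE)
  expect_equal(nrow(combine_predictions(list(a, c2))), 0)
  expect_error(combine_predictions(list(a, b), "both"))
})

test_that("cis pairing respects the 10 kb inclusive window", {
  lnc <- tiny_annotation(data.frame(
    transcript_id = "l1", start = 100000, end = 101000, strand = "+"))
  genes <- tiny_annotation(data.frame(
    transcript_id = c("tA", "tB", "tC", "tD", "tE"),
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
    start = c(95500, 89000, 111002, 100000, 100500),
    end = c(96000, 89999, 112000, 100800, 100700),
    biotype = "mRNA"
  ))
  cis <- assign_cis_targets(lnc, genes, window = 10000)
  expect_setequal(cis$gene_id, c("gA", "gB", "gE"))
  # gap 3999, upstream of a + strand lncRNA
  expect_equal(cis$distance[cis$gene_id == "gA"], 3999L)
  expect_equal(cis$relation[cis$gene_id == "gA"], "upstream")
  # gap exactly 10000: included (89999 .. 100000 leaves 10000 bases)
  expect_equal(cis$distance[cis$gene_id == "gB"], 10000L)
  # overlapping gene: distance 0
  expect_equal(cis$distance[cis$gene_id == "gE"], 0L)
  expect_equal(cis$relation[cis$gene_id == "gE"], "overlap")
  # gap 10001 (gC) excluded; other chromosome (gD) excluded

  # shifting every coordinate leaves the pairing unchanged
  shift <- 12345L
  lnc2 <- tiny_annotation(data.frame(
    transcript_id = "l1", start = 100000 + shift, end = 101000 + shift,
    strand = "+"))
  g2 <- as.data.frame(genes)
  g2$start <- g2$start + shift; g2$end <- g2$end + shift
  cis2b <- assign_cis_targets(lnc2, transcript_annotation(g2), window = 10000)
  expect_equal(cis2b[, c("gene_id", "distance", "relation")],
               cis[, c("gene_id", "distance", "relation")])
})

test_that("antisense targets require overlap on the opposite strand", {
  lnc <- tiny_annotation(data.frame(
    transcript_id = "l1", start = 1000, end = 1499, strand = "+"))
  tx <- tiny_annotation(data.frame(
    transcript_id = c("same_span", "same_strand", "adjacent", "partial"),
    gene_id = paste0("g", 1:4),
    start = c(1000, 1000, 1500, 1400), end = c(1499, 1499, 1900, 1600),
    strand = c("-", "+", "-", "-"), biotype = "mRNA"
  ))
  anti <- find_antisense_targets(lnc, tx)
  expect_setequal(anti$transcript_id, c("same_span", "partial"))
  expect_equal(anti$overlap[anti$transcript_id == "same_span"], 500L)
  expect_equal(anti$overlap[anti$transcript_id == "partial"], 100L)
})

test_that("complementarity score finds the longest pairing run", {
  # opposite-strand transcripts over the same span: the minus-strand
  # sequence is the revcomp of the plus sequence over the first 30 nt,
  # then diverges
  plus_seq <- random_seq(50)
  # minus transcript stored 5'->3' on the minus strand; its plus-strand
  # projection is revcomp(minus_seq): make that equal plus_seq over the
  # first 30 genomic bases, then diverge
  minus_seq <- revcomp(paste0(substr(plus_seq, 1, 30), random_seq(20)))
  lnc <- tiny_annotation(data.frame(
    transcript_id = "l1", start = 1, end = 50, strand = "+"))
  tx <- tiny_annotation(data.frame(
    transcript_id = "t1", gene_id = "g1", start = 1, end = 50,
    strand = "-", biotype = "mRNA"))
  anti <- find_antisense_targets(lnc, tx,
                                 sequences = c(l1 = plus_seq, t1 = minus_seq))
  expect_equal(anti$overlap, 50L)
  expect_gte(anti$complementarity, 30L)
})

test_that("all implanted ground-truth sites are recovered and decoys are clean", {
  fx <- shared_sim()
  sim <- fx$sim
  det <- find_seed_sites(sim$mirnas$mature, sim$sequences)
  truth <- sim$truth$true_sites
  dk <- paste(det$mirna_id, det$target_id, det$start, det$site_class)
  tk <- paste(truth$mirna_id, truth$target_id, truth$start, truth$site_class)
  expect_true(all(tk %in% dk))       # every implanted site detectable
  expect_setequal(dk, tk)            # and nothing else anywhere (decoy purity)
})
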