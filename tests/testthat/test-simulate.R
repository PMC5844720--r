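test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_mrna = 10, n_lncrna = 6, n_mirna = 5, seed = 7)
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(a$sequences, b$sequences)
  expect_identical(as.data.frame(a$annotation), as.data.frame(b$annotation))
  expect_identical(a$truth, b$truth)
  ca <- simulate_counts(a); cb <- simulate_counts(b)
  expect_identical(ca$long_counts$counts, cb$long_counts$counts)
  expect_identical(ca$small_counts$counts, cb$small_counts$counts)
})

test_that("a configuration without miRNAs yields an empty ground truth", {
  cfg <- sim_config(n_mrna = 8, n_lncrna = 4, n_mirna = 0, seed = 3)
  sim <- generate_transcriptome(cfg)
  expect_equal(nrow(sim$truth$true_sites), 0)
  expect_equal(nrow(sim$truth$true_triplets), 0)
  cts <- simulate_counts(sim)
  expect_null(cts$small_counts)
})

test_that("an implanted site is recorded and recoverable by the scanner", {
  cfg <- sim_config(n_mrna = 15, n_lncrna = 8, n_mirna = 4,
                    sites_per_true_pair = 1, frac_de = 0.5, seed = 9)
  sim <- generate_transcriptome(cfg)
  truth <- sim$truth$true_sites
  expect_gt(nrow(truth), 0)
  for (i in seq_len(min(5, nrow(truth)))) {
    m <- truth$mirna_id[i]; t <- truth$target_id[i]
    pat <- paste0(revcomp(chartr("U", "T", substr(sim$mirnas$mature[[m]], 2, 8))), "A")
    expect_equal(substr(sim$sequences[[t]], truth$start[i], truth$end[i]), pat)
    det <- find_seed_sites(sim$mirnas$mature[m], sim$sequences[t])
    expect_true(any(det$start == truth$start[i] & det$site_class == "8mer"))
  }
})

test_that("generated transcripts honour the structural contracts", {
  fx <- shared_sim()
  sim <- fx$sim
  ann <- sim$annotation
  lnc <- ann$transcript_id[ann$biotype == "lncRNA_candidate"]
  mrna <- ann$transcript_id[ann$biotype == "mRNA"]
  # mRNAs carry an ORF of at least 100 codons
  orf <- vapply(sim$sequences[mrna[1:20]],
                function(s) classify_coding(s)$longest_orf_codons, numeric(1))
  expect_true(all(orf >= 100))
  # lncRNA candidates: >= 200 nt, noncoding, class codes in {j,i,o,u,x}
  expect_true(all(nchar(sim$sequences[lnc]) >= 200))
  verd <- vapply(sim$sequences[lnc],
                 function(s) classify_coding(s)$verdict, character(1))
  expect_true(all(verd == "noncoding"))
  expect_true(all(ann$class_code[ann$biotype == "lncRNA_candidate"] %in%
                    c("j", "i", "o", "u", "x")))
  # every triplet in the truth satisfies the sponge direction rule and
  # has implanted sites on both partners
  tr <- sim$truth$true_triplets
  sites_key <- paste(sim$truth$true_sites$mirna_id,
                     sim$truth$true_sites$target_id)
  expect_true(all(tr$lncrna_direction == tr$mrna_direction))
  expect_true(all(tr$lncrna_direction != tr$mirna_direction))
  expect_true(all(paste(tr$mirna_id, tr$lncrna_id) %in% sites_key))
  expect_true(all(paste(tr$mirna_id, tr$mrna_id) %in% sites_key))
})

test_that("counts follow the mean model (Poisson at zero dispersion)", {
  # dispersion 0, no DE: sample mean within 1% of baseline, var/mean ~ 1
  cfg <- sim_config(n_mrna = 2, n_lncrna = 1, n_mirna = 0, frac_de = 0,
                    nb_dispersion = 0, baseline_mean = 100,
                    n_samples_per_group = 2500, seed = 13)
  sim <- generate_transcriptome(cfg)
  cts <- simulate_counts(sim)
  x <- cts$long_counts$counts[1, ]   # 5000 draws of Pois(100)
  expect_equal(mean(x), 100, tolerance = 0.01)
  expect_gt(var(x) / mean(x), 0.9)
  expect_lt(var(x) / mean(x), 1.1)
})

test_that("the implanted fold change is recovered in group means", {
  # log2fc = 2 on every feature: tumour/control mean ratio near 4
  cfg <- sim_config(n_mrna = 1, n_lncrna = 1, n_mirna = 0, frac_de = 1,
                    nb_dispersion = 0, baseline_mean = 100,
                    implanted_log2fc = 2, n_samples_per_group = 2500,
                    seed = 17)
  sim <- generate_transcriptome(cfg)
  de_id <- names(sim$truth$de_features)[1]
  cts <- simulate_counts(sim)
  cm <- cts$long_counts
  ctr <- mean(cm$counts[de_id, cm$condition == "control"])
  tum <- mean(cm$counts[de_id, cm$condition == "tumour"])
  ratio <- if (sim$truth$de_features[[de_id]] > 0) tum / ctr else ctr / tum
  expect_gt(ratio, 3.8)
  expect_lt(ratio, 4.2)
})

test_that("fixture files round-trip and conserve the ground truth", {
  fx <- shared_sim()
  dir <- withr::local_tempdir()
  files <- write_fixture(fx$sim, fx$counts, dir)
  # manifest: one GTF, at least two FASTA, two count TSVs, truth tables
  expect_equal(sum(grepl("\\.gtf$", names(files))), 1)
  expect_gte(sum(grepl("\\.fa$", names(files))), 2)
  expect_true(all(c("long_counts.tsv", "small_counts.tsv",
                    "truth_triplets.tsv", "terms.tsv") %in% names(files)))
  # round trips
  ann <- read_gtf(file.path(dir, "transcripts.gtf"))
  expect_equal(as.data.frame(ann), as.data.frame(fx$sim$annotation))
  seqs <- read_fasta(file.path(dir, "transcripts.fa"))
  expect_identical(seqs[names(fx$sim$sequences)], fx$sim$sequences)
  cm <- read_counts(file.path(dir, "long_counts.tsv"),
                    file.path(dir, "long_samples.tsv"))
  expect_equal(cm$counts, fx$counts$long_counts$counts)
  # triplet conservation
  tt <- read.delim(file.path(dir, "truth_triplets.tsv"))
  expect_equal(nrow(tt), nrow(fx$sim$truth$true_triplets))
})

test_that("fixture output is byte-identical across identical runs", {
  cfg <- sim_config(n_mrna = 12, n_lncrna = 6, n_mirna = 5, seed = 23)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    sim <- generate_transcriptome(cfg)
    cts <- simulate_counts(sim)
    write_fixture(sim, cts, d)
  }
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})
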