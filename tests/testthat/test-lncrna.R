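test_that("class-code filter retains exactly {j,i,o,u,x}", {
  ann <- tiny_annotation(data.frame(
    transcript_id = paste0("t", 1:7),
    start = seq(1, 601, by = 100), end = seq(400, 1000, by = 100),
    class_code = c("=", "u", "j", "i", "o", "x", "c")
  ))
  kept <- filter_class_codes(ann)
  expect_setequal(kept$transcript_id, paste0("t", 2:6))

  ann_na <- tiny_annotation(data.frame(
    transcript_id = "t1", start = 1, end = 400, class_code = NA))
  expect_error(filter_class_codes(ann_na), "class_code")

  empty <- filter_class_codes(tiny_annotation(data.frame(
    transcript_id = character(0), start = integer(0), end = integer(0),
    class_code = character(0))))
  expect_equal(nrow(empty), 0)
})

test_that("length filter is strict below 200 and inclusive at 200", {
  ann <- tiny_annotation(data.frame(
    transcript_id = c("short", "edge", "long"),
    start = c(1, 1000, 3000), end = c(199, 1199, 12999)
  ))
  kept <- filter_length(ann)
  expect_setequal(kept$transcript_id, c("edge", "long"))
})

test_that("known-lncRNA matching tolerates scattered substitutions", {
  set.seed(11)
  ref_seq <- random_seq(600)
  # identical sequence: known
  expect_true(match_known_lncrnas(c(a = ref_seq), c(r = ref_seq))[["a"]])
  # 2% scattered substitutions: identity 0.98 >= 0.95, still known
  chars <- strsplit(ref_seq, "")[[1]]
  pos <- seq(25, 600, by = 50)  # 12 positions = 2%
  chars[pos] <- vapply(chars[pos], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                       character(1))
  mutated <- paste(chars, collapse = "")
  expect_true(match_known_lncrnas(c(b = mutated), c(r = ref_seq))[["b"]])
  # unrelated sequence sharing no 12-mer: not known
  expect_false(match_known_lncrnas(c(c = random_seq(600)), c(r = ref_seq))[["c"]])
})

test_that("raising identity_min never grows the known set", {
  set.seed(12)
  refs <- setNames(vapply(1:3, function(i) random_seq(400), character(1)),
                   paste0("r", 1:3))
  cands <- c(refs[1], x = random_seq(400))
  names(cands)[1] <- "c1"
  loose <- match_known_lncrnas(cands, refs, identity_min = 0.8)
  strict <- match_known_lncrnas(cands, refs, identity_min = 0.99)
  expect_true(all(names(which(strict)) %in% names(which(loose))))
})

test_that("coding-potential verdict follows ORF length and coverage", {
  # one continuous 100-codon ORF filling a 300 nt transcript: coding
  nonstop <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                       c("A","C","G","T")), 1, paste, collapse = ""),
                     c("TAA", "TAG", "TGA"))
  set.seed(5)
  orf <- paste0("ATG", paste(sample(nonstop, 98, replace = TRUE), collapse = ""), "TAA")
  expect_equal(nchar(orf), 300)
  r <- classify_coding(orf)
  expect_equal(r$longest_orf_codons, 100)
  expect_equal(r$verdict, "coding")

  # no ATG at all: noncoding
  expect_equal(classify_coding(strrep("CGT", 80))$verdict, "noncoding")
  # poly-A 500-mer: no stop, ORF-free (no ATG), noncoding
  expect_equal(classify_coding(strrep("A", 500))$verdict, "noncoding")
  # 99 codons but covering > half of a short transcript: coding by coverage
  short_orf <- paste0("ATG", paste(sample(nonstop, 97, replace = TRUE), collapse = ""), "TAA")
  expect_equal(classify_coding(short_orf)$verdict, "coding")
  expect_error(classify_coding("ACGTQ"), "A,C,G,T,N")
})

test_that("the cascade labels every transcript exactly once, in order", {
  fx <- shared_sim()
  sim <- fx$sim
  labels <- predict_lncrnas(sim$annotation, sim$sequences, sim$known_lncrna_ref)
  expect_equal(nrow(labels), nrow(sim$annotation))
  expect_false(anyNA(labels$label))

  # ground-truth agreement: all generated lncRNA candidates end up known
  # or novel; all mRNAs are rejected at the class-code step
  bio <- setNames(sim$annotation$biotype, sim$annotation$transcript_id)
  lnc_lab <- labels$label[bio[labels$transcript_id] == "lncRNA_candidate"]
  expect_true(all(lnc_lab %in% c("known_lncRNA", "novel_lncRNA")))
  mrna_lab <- labels$label[bio[labels$transcript_id] == "mRNA"]
  expect_true(all(mrna_lab == "rejected_class_code"))

  # the packaged known subset is recovered exactly
  known_ids <- sub("^REF_", "", names(sim$known_lncrna_ref))
  got_known <- labels$transcript_id[labels$label == "known_lncRNA"]
  expect_setequal(got_known, known_ids)

  # no transcript shorter than 200 nt in the downstream lncRNA set
  lnc_set <- labels$transcript_id[labels$label %in% c("known_lncRNA", "novel_lncRNA")]
  expect_true(all(nchar(sim$sequences[lnc_set]) >= 200))

  # order independence
  perm <- sample(nrow(sim$annotation))
  ann_perm <- transcript_annotation(
    as.data.frame(sim$annotation)[perm, ],
    attr(sim$annotation, "exons"))
  labels_perm <- predict_lncrnas(ann_perm, sim$sequences, sim$known_lncrna_ref)
  m <- match(labels$transcript_id, labels_perm$transcript_id)
  expect_equal(labels$label, labels_perm$label[m])
})

test_that("a transcript failing the length step never reaches the ORF step", {
  # 150 nt sequence that WOULD be called coding by coverage; class code ok
  nonstop <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                       c("A","C","G","T")), 1, paste, collapse = ""),
                     c("TAA", "TAG", "TGA"))
  set.seed(6)
  s <- paste0("ATG", paste(sample(nonstop, 48, replace = TRUE), collapse = ""), "TAA")
  ann <- tiny_annotation(data.frame(transcript_id = "t1", start = 1, end = nchar(s)))
  lab <- predict_lncrnas(ann, c(t1 = s), c(r = random_seq(300)))
  expect_equal(lab$label, "rejected_length")
})
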