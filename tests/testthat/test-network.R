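mk_de <- function(ids, dirs) {
  data.frame(feature_id = ids, direction = dirs, stringsAsFactors = FALSE)
}

test_that("the common-miRNA rule emits triplets only with both partner classes", {
  de <- mk_de(c("m1", "m2", "l1", "l2", "g1"),
              c("down", "down", "up", "up", "up"))
  sites <- data.frame(
    mirna_id = c("m1", "m1", "m1", "m2", "m2"),
    target_id = c("l1", "g1", "g1", "l1", "l2"),
    stringsAsFactors = FALSE
  )
  net <- build_global_network(sites, de, c("l1", "l2"), "g1")
  # m1 has a lncRNA and an mRNA partner -> one triplet, with site counts
  expect_equal(nrow(net$triplets), 1)
  expect_equal(net$triplets$mirna_id, "m1")
  expect_equal(net$triplets$n_sites_mrna, 2L)
  # m2 has only lncRNA partners: edges, no triplet
  expect_true(all(c("l1", "l2") %in%
                    net$edges$target_id[net$edges$mirna_id == "m2"]))
  expect_false("m2" %in% net$triplets$mirna_id)
})

test_that("non-DE features are excluded and missing features are an error", {
  sites <- data.frame(mirna_id = "m1", target_id = "l1",
                      stringsAsFactors = FALSE)
  de_ns <- mk_de(c("m1", "l1"), c("ns", "up"))
  expect_equal(nrow(build_global_network(sites, de_ns, "l1", character(0))$edges), 0)
  expect_error(build_global_network(sites, mk_de("m1", "down"), "l1",
                                    character(0)),
               "absent from DE")
})

test_that("the co-regulation filter enforces sponge directionality", {
  sites <- data.frame(
    mirna_id = rep(c("m1", "m2", "m3"), each = 2),
    target_id = c("l1", "g1", "l2", "g2", "l3", "g3"),
    stringsAsFactors = FALSE
  )
  de <- mk_de(c("m1", "l1", "g1",   # m down, partners up: retained
                "m2", "l2", "g2",   # partners disagree: dropped
                "m3", "l3", "g3"),  # all up: dropped
              c("down", "up", "up",
                "down", "up", "down",
                "up", "up", "up"))
  net <- build_global_network(sites, de, c("l1", "l2", "l3"),
                              c("g1", "g2", "g3"))
  expect_equal(nrow(net$triplets), 3)
  co <- filter_coregulated(net)
  expect_equal(co$triplets$mirna_id, "m1")
  # permissive mode keeps everything with non-ns directions
  perm <- filter_coregulated(net, mode = "permissive")
  expect_equal(nrow(perm$triplets), 3)
})

test_that("co-regulation filtering is monotone (a subnetwork of the input)", {
  fx <- shared_sim()
  sim <- fx$sim
  sites <- find_seed_sites(sim$mirnas$mature, sim$sequences)
  de_long <- call_differential(fx$counts$long_counts)
  de_small <- call_differential(fx$counts$small_counts)
  de <- rbind(de_long[, c("feature_id", "direction")],
              de_small[, c("feature_id", "direction")])
  lnc <- sim$annotation$transcript_id[sim$annotation$biotype == "lncRNA_candidate"]
  mrna <- sim$annotation$transcript_id[sim$annotation$biotype == "mRNA"]
  net <- build_global_network(sites, de, lnc, mrna)
  co <- filter_coregulated(net)
  key <- function(tr) paste(tr$mirna_id, tr$lncrna_id, tr$mrna_id)
  expect_true(all(key(co$triplets) %in% key(net$triplets)))
  ekey <- function(ed) paste(ed$mirna_id, ed$target_id)
  expect_true(all(ekey(co$edges) %in% ekey(net$edges)))
  # every retained triplet satisfies the direction rule
  with(co$triplets, {
    expect_true(all(lncrna_direction == mrna_direction))
    expect_true(all(lncrna_direction != mirna_direction))
  })
})

test_that("removing a supporting site never adds an edge", {
  de <- mk_de(c("m1", "l1", "g1"), c("down", "up", "up"))
  sites <- data.frame(mirna_id = c("m1", "m1"), target_id = c("l1", "g1"),
                      stringsAsFactors = FALSE)
  full <- build_global_network(sites, de, "l1", "g1")
  reduced <- build_global_network(sites[-1, , drop = FALSE], de, "l1", "g1")
  ekey <- function(n) paste(n$edges$mirna_id, n$edges$target_id)
  expect_true(all(ekey(reduced) %in% ekey(full)))
  expect_lt(nrow(reduced$edges), nrow(full$edges))
  expect_equal(nrow(reduced$triplets), 0)
})

test_that("network statistics count distinct triplet members", {
  de <- mk_de(c("m1", "l1", "g1"), c("down", "up", "up"))
  sites <- data.frame(mirna_id = c("m1", "m1"), target_id = c("l1", "g1"),
                      stringsAsFactors = FALSE)
  net <- build_global_network(sites, de, "l1", "g1")
  st <- network_stats(net)
  expect_equal(st[c("n_mirna", "n_lncrna", "n_mrna", "n_triplets")],
               list(n_mirna = 1L, n_lncrna = 1L, n_mrna = 1L, n_triplets = 1L))
  # empty network: all zeros
  st0 <- network_stats(filter_coregulated(
    build_global_network(sites, mk_de(c("m1", "l1", "g1"),
                                      c("down", "up", "down")),
                         "l1", "g1")))
  expect_equal(st0$n_triplets, 0L)
  expect_equal(st0$n_sponge_modulators, 0L)
})

test_that("export writes graphml, edge and triplet tables plus a consistent summary", {
  de <- mk_de(c("m1", "l1", "g1"), c("down", "up", "up"))
  sites <- data.frame(mirna_id = c("m1", "m1"), target_id = c("l1", "g1"),
                      stringsAsFactors = FALSE)
  net <- build_global_network(sites, de, "l1", "g1")
  dir <- withr::local_tempdir()
  paths <- export_network(net, dir)
  expect_true(all(file.exists(paths)))
  back <- read_network_graphml(paths[["graphml"]])
  expect_true(all(back$nodes$role %in% c("miRNA", "lncRNA", "mRNA")))
  summ <- jsonlite::read_json(paths[["summary"]])
  expect_equal(summ$n_triplets, network_stats(net)$n_triplets)
})
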