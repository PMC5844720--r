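## End-to-end orchestration: simulate -> clean -> quantify -> DE ->
## classify -> MRE -> network -> enrich, with a JSON run manifest
## recording per-stage record counts and output checksums. Reruns with
## an identical configuration produce byte-identical outputs.

#' Pipeline configuration
#'
#' Validates all stage parameters up front (before any stage runs).
#' Every published threshold is surfaced as a named parameter with its
#' conventional default: fold change 2 (log2 = 1), p 0.05, 200 nt
#' minimum lncRNA length, 10 kb cis window, 16 nt mature overlap, 5%
#' N-content, Phred 10 / 50% low-quality rule.
#'
#' @param out_dir Output directory.
#' @param sim A [sim_config()] describing the synthetic inputs.
#' @param min_abs_log2fc,max_p,use_adjusted DE thresholds (see
#'   [de_thresholds()]).
#' @param min_lnc_len Minimum lncRNA length (default 200).
#' @param cis_window Cis-target window in bases (default 10000).
#' @param min_mature_overlap Tag/mature overlap for known-miRNA
#'   assignment (default 16).
#' @param maxN_frac,lowq_threshold,lowq_frac Read-cleaning thresholds.
#' @param combine_mode Predictor combination (default `"intersection"`).
#' @param network_mode `"anticorrelated"` (default) or `"permissive"`.
#' @param enrich_alpha Enrichment significance level (default 0.05).
#' @param write_fixture_files Also write the simulated fixture files
#'   under `out_dir/fixture` (default TRUE).
#' @param seed Optional override of `sim$seed`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(),
                            min_abs_log2fc = 1, max_p = 0.05,
                            use_adjusted = TRUE,
                            min_lnc_len = 200, cis_window = 10000,
                            min_mature_overlap = 16,
                            maxN_frac = 0.05, lowq_threshold = 10,
                            lowq_frac = 0.5,
                            combine_mode = c("intersection", "union"),
                            network_mode = c("anticorrelated", "permissive"),
                            enrich_alpha = 0.05,
                            write_fixture_files = TRUE, seed = NULL) {
  combine_mode <- match.arg(combine_mode)
  network_mode <- match.arg(network_mode)
  thresholds <- de_thresholds(min_abs_log2fc, max_p, use_adjusted)
  stopifnot(inherits(sim, "sim_config"), min_lnc_len > 0, cis_window >= 0,
            min_mature_overlap >= 1, maxN_frac > 0, maxN_frac <= 1,
            lowq_frac > 0, lowq_frac <= 1,
            enrich_alpha > 0, enrich_alpha < 1)
  if (!is.null(seed)) sim$seed <- seed
  structure(list(
    out_dir = out_dir, sim = sim, thresholds = thresholds,
    min_lnc_len = min_lnc_len, cis_window = cis_window,
    min_mature_overlap = min_mature_overlap,
    maxN_frac = maxN_frac, lowq_threshold = lowq_threshold,
    lowq_frac = lowq_frac, combine_mode = combine_mode,
    network_mode = network_mode, enrich_alpha = enrich_alpha,
    write_fixture_files = isTRUE(write_fixture_files)
  ), class = "pipeline_config")
}

#' @noRd
cm_subset <- function(cm, ids) {
  count_matrix(cm$counts[ids, , drop = FALSE], cm$condition,
               cm$library_sizes)
}

#' @noRd
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL  # hash the scientific configuration, not the paths
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline
#'
#' Executes the eight stages in dependency order; any stage error aborts
#' the run with the stage name and cause. The returned (and written)
#' manifest records the package version, a configuration hash, per-stage
#' record counts and an MD5 checksum of every output file, so that
#' byte-level reproducibility of a rerun can be verified directly.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list), invisibly; all outputs are written
#'   under `config$out_dir` and the manifest to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  stages <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  tsv <- function(df, f) {
    utils::write.table(df, file.path(out, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  ## 1 simulate
  env <- new.env()
  run_stage("simulate", function() {
    env$sim <- generate_transcriptome(config$sim)
    env$counts <- simulate_counts(env$sim)
    env$reads <- if (config$sim$n_mirna > 0) simulate_small_reads(env$sim)
                 else NULL
    env$terms <- simulate_term_annotation(env$sim)
    if (config$write_fixture_files)
      write_fixture(env$sim, env$counts, file.path(out, "fixture"),
                    terms = env$terms)
  })
  stages$simulate <- list(
    n_transcripts = nrow(env$sim$annotation),
    n_mirna = length(env$sim$mirnas$mature),
    n_true_triplets = nrow(env$sim$truth$true_triplets)
  )

  ## 2 clean
  run_stage("clean", function() {
    if (is.null(env$reads)) {
      env$clean <- NULL
      return()
    }
    env$clean <- clean_reads(env$reads, adapter = attr(env$reads, "adapter"),
                             maxN_frac = config$maxN_frac,
                             lowq_threshold = config$lowq_threshold,
                             lowq_frac = config$lowq_frac)
    jsonlite::write_json(env$clean$report, file.path(out, "clean_report.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  stages$clean <- if (is.null(env$clean)) list(skipped = TRUE)
                  else env$clean$report

  ## 3 quantify
  run_stage("quantify", function() {
    ann <- env$sim$annotation
    env$fpkm <- compute_fpkm(env$counts$long_counts, ann)
    tx2gene <- stats::setNames(ann$gene_id, ann$transcript_id)
    env$gene_fpkm <- gene_fpkm(env$fpkm, tx2gene)
    if (!is.null(env$counts$small_counts)) {
      env$tpm <- compute_tpm(env$counts$small_counts)
      tags <- unique(env$clean$clean$seq)
      env$tag_assign <- identify_known_mirnas(
        stats::setNames(tags, sprintf("tag_%04d", seq_along(tags))),
        env$sim$mirnas$reference,
        min_overlap = config$min_mature_overlap)
      tsv(env$tag_assign, "tag_assignments.tsv")
    }
  })
  stages$quantify <- list(
    n_long_quantified = nrow(env$fpkm$values),
    n_genes = nrow(env$gene_fpkm$values),
    n_tags_known = if (!is.null(env$tag_assign))
      sum(env$tag_assign$status == "known") else 0L
  )

  ## 4 differential expression
  run_stage("de", function() {
    ann <- env$sim$annotation
    mrna_tx <- ann$transcript_id[ann$biotype == "mRNA"]
    lnc_tx <- ann$transcript_id[ann$biotype == "lncRNA_candidate"]
    env$de_mrna <- call_differential(cm_subset(env$counts$long_counts, mrna_tx),
                                     config$thresholds)
    env$de_lnc <- call_differential(cm_subset(env$counts$long_counts, lnc_tx),
                                    config$thresholds)
    env$de_mir <- if (!is.null(env$counts$small_counts))
      call_differential(env$counts$small_counts, config$thresholds)
    else NULL
    write_de_table(env$de_mrna, file.path(out, "de_mrna.tsv"))
    write_de_table(env$de_lnc, file.path(out, "de_lncrna.tsv"))
    if (!is.null(env$de_mir))
      write_de_table(env$de_mir, file.path(out, "de_mirna.tsv"))
  })
  n_called <- function(de) if (is.null(de)) c(up = 0L, down = 0L)
    else c(up = sum(de$direction == "up"), down = sum(de$direction == "down"))
  stages$de <- list(mrna = as.list(n_called(env$de_mrna)),
                    lncrna = as.list(n_called(env$de_lnc)),
                    mirna = as.list(n_called(env$de_mir)))

  ## 5 lncRNA classification
  run_stage("classify", function() {
    env$labels <- predict_lncrnas(env$sim$annotation, env$sim$sequences,
                                  env$sim$known_lncrna_ref,
                                  min_len = config$min_lnc_len)
    tsv(env$labels, "lncrna_labels.tsv")
  })
  lab <- env$labels$label
  stages$classify <- list(
    known_lncRNA = sum(lab == "known_lncRNA"),
    novel_lncRNA = sum(lab == "novel_lncRNA"),
    rejected = sum(startsWith(lab, "rejected") | lab == "coding")
  )

  ## 6 MRE prediction and lncRNA targets
  run_stage("mre", function() {
    mat <- env$sim$mirnas$mature
    seqs <- env$sim$sequences
    if (length(mat)) {
      strict <- find_seed_sites(mat, seqs, c("7mer-m8", "8mer"),
                                predictor = "strict")
      lenient <- find_seed_sites(mat, seqs, predictor = "lenient")
      pairs <- combine_predictions(list(strict, lenient),
                                   mode = config$combine_mode)
      keep <- paste(lenient$mirna_id, lenient$target_id) %in%
        paste(pairs$mirna_id, pairs$target_id)
      env$sites <- lenient[keep, , drop = FALSE]
    } else {
      env$sites <- find_seed_sites(character(0), seqs)
    }
    tsv(env$sites, "mre_sites.tsv")
    ann <- env$sim$annotation
    lnc_ids <- env$labels$transcript_id[
      env$labels$label %in% c("known_lncRNA", "novel_lncRNA")]
    lnc_ann <- subset_annotation(ann, ann$transcript_id %in% lnc_ids)
    mrna_ann <- subset_annotation(ann, ann$biotype == "mRNA")
    env$cis <- assign_cis_targets(lnc_ann, mrna_ann,
                                  window = config$cis_window)
    env$anti <- find_antisense_targets(lnc_ann, mrna_ann, seqs)
    tsv(env$cis, "cis_pairs.tsv")
    tsv(env$anti, "antisense_pairs.tsv")
  })
  stages$mre <- list(n_sites = nrow(env$sites), n_cis = nrow(env$cis),
                     n_antisense = nrow(env$anti))

  ## 7 ceRNA network
  run_stage("network", function() {
    de_all <- rbind(env$de_mrna, env$de_lnc, env$de_mir)
    lnc_ids <- env$labels$transcript_id[
      env$labels$label %in% c("known_lncRNA", "novel_lncRNA")]
    mrna_ids <- env$sim$annotation$transcript_id[
      env$sim$annotation$biotype == "mRNA"]
    env$net_global <- build_global_network(env$sites, de_all,
                                           lnc_ids, mrna_ids)
    env$net <- filter_coregulated(env$net_global, mode = config$network_mode)
    export_network(env$net, out, prefix = "cerna")
  })
  stages$network <- network_stats(env$net)[
    c("n_mirna", "n_lncrna", "n_mrna", "n_triplets", "n_edges",
      "n_sponge_modulators")]

  ## 8 enrichment
  run_stage("enrich", function() {
    ann <- env$sim$annotation
    tx2gene <- stats::setNames(ann$gene_id, ann$transcript_id)
    de_tx <- env$de_mrna$feature_id[env$de_mrna$direction != "ns"]
    universe <- unique(env$terms$gene_id)
    selected <- intersect(unique(tx2gene[de_tx]), universe)
    env$enrich <- hypergeom_enrich(selected, env$terms, universe,
                                   alpha = config$enrich_alpha)
    env$top <- top_terms(env$enrich)
    tsv(env$enrich, "enrichment.tsv")
    tsv(env$top, "enrichment_top.tsv")
  })
  stages$enrich <- list(n_terms_tested = nrow(env$enrich),
                        n_significant = sum(env$enrich$significant))

  files <- sort(list.files(out, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  checksums <- as.list(stats::setNames(
    unname(tools::md5sum(file.path(out, files))), files))
  manifest <- list(
    package = "spongeworks",
    version = as.character(utils::packageVersion("spongeworks")),
    config_hash = config_hash(config),
    seed = config$sim$seed,
    stages = stages,
    outputs = checksums
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ## expose key results alongside the manifest for programmatic use
  attr(manifest, "results") <- list(
    sim = env$sim, counts = env$counts,
    de = list(mrna = env$de_mrna, lncrna = env$de_lnc, mirna = env$de_mir),
    labels = env$labels, sites = env$sites,
    network = env$net, network_global = env$net_global,
    enrichment = env$enrich
  )
  invisible(manifest)
}
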