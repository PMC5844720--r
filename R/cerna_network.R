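## Assembly of the miRNA-centred tripartite sponge network: a sponge
## triplet (miRNA, lncRNA, mRNA) requires MRE evidence of the miRNA on
## both partners ("common miRNA") plus differential expression of all
## three; the co-regulation filter additionally demands that the two
## ceRNA partners move together and opposite to the miRNA (the sponge
## hypothesis: less miRNA means more of everything it represses).

#' @noRd
empty_network <- function() {
  structure(list(
    nodes = data.frame(id = character(0), role = character(0),
                       direction = character(0), stringsAsFactors = FALSE),
    edges = data.frame(mirna_id = character(0), target_id = character(0),
                       target_role = character(0), n_sites = integer(0),
                       stringsAsFactors = FALSE),
    triplets = data.frame(mirna_id = character(0), lncrna_id = character(0),
                          mrna_id = character(0),
                          mirna_direction = character(0),
                          lncrna_direction = character(0),
                          mrna_direction = character(0),
                          n_sites_lncrna = integer(0),
                          n_sites_mrna = integer(0),
                          stringsAsFactors = FALSE)
  ), class = "cerna_network")
}

#' @noRd
network_from_parts <- function(edges, triplets, dirs) {
  if (nrow(edges)) {
    ids <- unique(c(edges$mirna_id, edges$target_id))
    role <- c(stats::setNames(rep("miRNA", length(unique(edges$mirna_id))),
                              unique(edges$mirna_id)),
              stats::setNames(edges$target_role, edges$target_id))
    nodes <- data.frame(id = ids, role = unname(role[ids]),
                        direction = unname(dirs[ids]),
                        stringsAsFactors = FALSE)
    nodes <- nodes[order(nodes$role, nodes$id), , drop = FALSE]
    rownames(nodes) <- NULL
  } else {
    nodes <- empty_network()$nodes
  }
  structure(list(nodes = nodes, edges = edges, triplets = triplets),
            class = "cerna_network")
}

#' Build the global miRNA-ceRNA interaction network
#'
#' Restricts to differentially expressed features, adds an edge
#' miRNA-ceRNA for every (DE miRNA, DE lncRNA-or-mRNA) pair supported by
#' at least one MRE, and emits a sponge triplet for every miRNA with
#' edges to both a lncRNA and an mRNA (the common-miRNA rule). No
#' direction logic is applied here; see [filter_coregulated()].
#'
#' @param sites MRE site data.frame (or combined prediction pairs joined
#'   back to sites) with columns `mirna_id`, `target_id` (one row per
#'   site).
#' @param de A `de_result` data.frame covering every feature appearing in
#'   `sites` (miRNAs and targets); features absent from it are an error.
#' @param lncrna_ids,mrna_ids Character vectors partitioning the target
#'   ids by role; targets in neither set are ignored.
#' @return A `cerna_network`: list with `nodes` (id, role, direction),
#'   `edges` (mirna_id, target_id, target_role, n_sites) and `triplets`.
#' @export
build_global_network <- function(sites, de, lncrna_ids, mrna_ids) {
  dirs <- stats::setNames(de$direction, de$feature_id)
  feats <- unique(c(sites$mirna_id, intersect(sites$target_id,
                                              c(lncrna_ids, mrna_ids))))
  miss <- setdiff(feats, names(dirs))
  if (length(miss))
    stop("features in sites absent from DE table: ",
         paste(utils::head(miss, 5), collapse = ", "))

  s <- sites[sites$target_id %in% c(lncrna_ids, mrna_ids), , drop = FALSE]
  s <- s[dirs[s$mirna_id] != "ns" & dirs[s$target_id] != "ns", , drop = FALSE]
  if (!nrow(s)) return(empty_network())

  key <- paste(s$mirna_id, s$target_id, sep = "\r")
  n_sites <- table(key)
  uniq <- !duplicated(key)
  edges <- data.frame(
    mirna_id = s$mirna_id[uniq],
    target_id = s$target_id[uniq],
    target_role = ifelse(s$target_id[uniq] %in% lncrna_ids, "lncRNA", "mRNA"),
    n_sites = as.integer(n_sites[key[uniq]]),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$mirna_id, edges$target_id), , drop = FALSE]
  rownames(edges) <- NULL

  trip <- vector("list", 0)
  for (m in unique(edges$mirna_id)) {
    em <- edges[edges$mirna_id == m, , drop = FALSE]
    ls <- em[em$target_role == "lncRNA", , drop = FALSE]
    gs <- em[em$target_role == "mRNA", , drop = FALSE]
    if (!nrow(ls) || !nrow(gs)) next
    combo <- expand.grid(l = seq_len(nrow(ls)), g = seq_len(nrow(gs)))
    trip[[length(trip) + 1]] <- data.frame(
      mirna_id = m,
      lncrna_id = ls$target_id[combo$l],
      mrna_id = gs$target_id[combo$g],
      mirna_direction = unname(dirs[m]),
      lncrna_direction = unname(dirs[ls$target_id[combo$l]]),
      mrna_direction = unname(dirs[gs$target_id[combo$g]]),
      n_sites_lncrna = ls$n_sites[combo$l],
      n_sites_mrna = gs$n_sites[combo$g],
      stringsAsFactors = FALSE
    )
  }
  triplets <- if (length(trip)) do.call(rbind, trip) else empty_network()$triplets
  triplets <- triplets[order(triplets$mirna_id, triplets$lncrna_id,
                             triplets$mrna_id), , drop = FALSE]
  rownames(triplets) <- NULL
  network_from_parts(edges, triplets, dirs)
}

#' Retain co-regulated (sponge-consistent) triplets
#'
#' Default rule: the lncRNA and mRNA share the same DE direction, which
#' is opposite to the miRNA's (anti-correlation, as the sponge mechanism
#' predicts). `mode = "permissive"` keeps any triplet whose three
#' directions are non-ns. Edges and nodes are reduced to those
#' supporting a retained triplet, so the result is always a subnetwork
#' of the input.
#'
#' @param network A `cerna_network` from [build_global_network()].
#' @param mode `"anticorrelated"` (default) or `"permissive"`.
#' @return A filtered `cerna_network`.
#' @export
filter_coregulated <- function(network, mode = c("anticorrelated", "permissive")) {
  mode <- match.arg(mode)
  tr <- network$triplets
  if (mode == "anticorrelated") {
    keep <- tr$lncrna_direction == tr$mrna_direction &
      tr$lncrna_direction != tr$mirna_direction
  } else {
    keep <- tr$mirna_direction != "ns" & tr$lncrna_direction != "ns" &
      tr$mrna_direction != "ns"
  }
  tr <- tr[keep, , drop = FALSE]
  rownames(tr) <- NULL
  if (!nrow(tr)) return(empty_network())
  keys <- unique(c(paste(tr$mirna_id, tr$lncrna_id, sep = "\r"),
                   paste(tr$mirna_id, tr$mrna_id, sep = "\r")))
  ed <- network$edges
  ed <- ed[paste(ed$mirna_id, ed$target_id, sep = "\r") %in% keys, ,
           drop = FALSE]
  rownames(ed) <- NULL
  dirs <- stats::setNames(network$nodes$direction, network$nodes$id)
  network_from_parts(ed, tr, dirs)
}

#' Summary counts of a ceRNA network
#'
#' @param network A `cerna_network`.
#' @return List: `n_mirna`, `n_lncrna`, `n_mrna` (distinct features in at
#'   least one triplet), `n_triplets`, `n_edges`, `n_sponge_modulators`
#'   (distinct features overall), and `mirna_degree` (per-miRNA partner
#'   counts).
#' @export
network_stats <- function(network) {
  tr <- network$triplets
  deg <- if (nrow(tr)) {
    d <- lapply(split(tr, tr$mirna_id), function(x) data.frame(
      mirna_id = x$mirna_id[1],
      n_lncrna = length(unique(x$lncrna_id)),
      n_mrna = length(unique(x$mrna_id)),
      n_triplets = nrow(x), stringsAsFactors = FALSE))
    out <- do.call(rbind, d); rownames(out) <- NULL; out
  } else {
    data.frame(mirna_id = character(0), n_lncrna = integer(0),
               n_mrna = integer(0), n_triplets = integer(0),
               stringsAsFactors = FALSE)
  }
  list(
    n_mirna = length(unique(tr$mirna_id)),
    n_lncrna = length(unique(tr$lncrna_id)),
    n_mrna = length(unique(tr$mrna_id)),
    n_triplets = nrow(tr),
    n_edges = nrow(network$edges),
    n_sponge_modulators = length(unique(c(tr$mirna_id, tr$lncrna_id,
                                          tr$mrna_id))),
    mirna_degree = deg
  )
}

#' @export
print.cerna_network <- function(x, ...) {
  st <- network_stats(x)
  cat(sprintf(
    "cerna_network: %d triplets | %d miRNAs, %d lncRNAs, %d mRNAs | %d edges\n",
    st$n_triplets, st$n_mirna, st$n_lncrna, st$n_mrna, st$n_edges))
  invisible(x)
}

#' Export a ceRNA network to files
#'
#' Writes `<prefix>_edges.tsv`, `<prefix>_triplets.tsv`,
#' `<prefix>.graphml` (nodes carry role/direction/colour attributes) and
#' `<prefix>_summary.json`.
#'
#' @param network A `cerna_network`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"cerna"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_network <- function(network, dir, prefix = "cerna") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    edges = file.path(dir, paste0(prefix, "_edges.tsv")),
    triplets = file.path(dir, paste0(prefix, "_triplets.tsv")),
    graphml = file.path(dir, paste0(prefix, ".graphml")),
    summary = file.path(dir, paste0(prefix, "_summary.json"))
  )
  write_network(network, paths[["edges"]], format = "tsv")
  utils::write.table(network$triplets, paths[["triplets"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_network(network, paths[["graphml"]], format = "graphml")
  st <- network_stats(network)
  jsonlite::write_json(st[setdiff(names(st), "mirna_degree")],
                       paths[["summary"]], auto_unbox = TRUE)
  invisible(paths)
}
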