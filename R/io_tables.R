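#' Read and write GTF transcript annotation
#'
#' The writer emits `transcript` and `exon` features with `gene_id`,
#' `transcript_id`, `class_code` and `biotype` attributes (1-based
#' inclusive coordinates); output is deterministic, so identical
#' annotations produce byte-identical files. The reader parses through
#' rtracklayer and validates the result (exons inside their transcript
#' span, known strands, unique transcript ids).
#'
#' @param annotation A [transcript_annotation()].
#' @param path Output file path.
#' @return `write_gtf`: the path, invisibly. `read_gtf`: a
#'   [transcript_annotation()].
#' @export
write_gtf <- function(annotation, path) {
  ex <- attr(annotation, "exons")
  attr_str <- function(tx, code, bio) {
    s <- sprintf('gene_id "%s"; transcript_id "%s";',
                 annotation$gene_id[match(tx, annotation$transcript_id)], tx)
    cc <- ifelse(is.na(code), "", sprintf(' class_code "%s";', code))
    bt <- ifelse(is.na(bio), "", sprintf(' biotype "%s";', bio))
    paste0(s, cc, bt)
  }
  tx_lines <- sprintf(
    "%s\tspongeworks\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
    annotation$chrom, annotation$start, annotation$end, annotation$strand,
    attr_str(annotation$transcript_id, annotation$class_code,
             annotation$biotype)
  )
  i <- match(ex$transcript_id, annotation$transcript_id)
  ex_lines <- sprintf(
    "%s\tspongeworks\texon\t%d\t%d\t.\t%s\t.\t%s",
    annotation$chrom[i], ex$start, ex$end, annotation$strand[i],
    attr_str(ex$transcript_id, annotation$class_code[i],
             annotation$biotype[i])
  )
  ## interleave: each transcript followed by its exons, annotation order
  ord <- order(i, ex$start)
  lines <- character(0)
  ex_by_tx <- split(ex_lines[ord], factor(ex$transcript_id[ord],
                                          levels = annotation$transcript_id))
  for (k in seq_len(nrow(annotation))) {
    lines <- c(lines, tx_lines[k], ex_by_tx[[k]])
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gtf
#' @export
read_gtf <- function(path) {
  g <- rtracklayer::import(path, format = "gtf")
  m <- S4Vectors::mcols(g)
  if (!all(c("gene_id", "transcript_id") %in% names(m)))
    stop("GTF must carry gene_id and transcript_id attributes")
  type <- as.character(m$type)
  is_tx <- type == "transcript"
  is_ex <- type == "exon"
  if (!any(is_tx)) stop("GTF contains no transcript features")
  getcol <- function(col, idx) {
    if (col %in% names(m)) as.character(m[[col]][idx]) else rep(NA_character_, sum(idx))
  }
  tx <- data.frame(
    transcript_id = as.character(m$transcript_id[is_tx]),
    gene_id = as.character(m$gene_id[is_tx]),
    chrom = as.character(GenomicRanges::seqnames(g)[is_tx]),
    start = GenomicRanges::start(g)[is_tx],
    end = GenomicRanges::end(g)[is_tx],
    strand = as.character(GenomicRanges::strand(g)[is_tx]),
    class_code = getcol("class_code", is_tx),
    biotype = getcol("biotype", is_tx),
    stringsAsFactors = FALSE
  )
  ex <- data.frame(
    transcript_id = as.character(m$transcript_id[is_ex]),
    start = GenomicRanges::start(g)[is_ex],
    end = GenomicRanges::end(g)[is_ex],
    stringsAsFactors = FALSE
  )
  transcript_annotation(tx, if (nrow(ex)) ex else NULL)
}

#' Read and write count matrices as TSV
#'
#' The counts file has a `feature_id` column followed by one column per
#' sample; the companion samples file has columns `sample_id`,
#' `condition`, `library_size`.
#'
#' @param cm A [count_matrix()].
#' @param counts_path,samples_path File paths.
#' @return `read_counts`: a [count_matrix()].
#' @export
write_counts <- function(cm, counts_path, samples_path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  smp <- data.frame(sample_id = colnames(cm$counts),
                    condition = unname(cm$condition),
                    library_size = unname(cm$library_sizes),
                    stringsAsFactors = FALSE)
  utils::write.table(smp, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id") stop("first column must be feature_id")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$feature_id
  if (any(mat < 0)) stop("negative count entry")
  smp <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  smp <- smp[match(colnames(mat), smp$sample_id), ]
  if (anyNA(smp$sample_id)) stop("samples file does not cover all samples")
  count_matrix(mat, smp$condition, smp$library_size)
}

#' Write and read a differential-expression table
#'
#' Columns: `feature_id`, `mean_ctr`, `mean_tum`, `log2fc`, `p_raw`,
#' `p_adj`, `direction` (mirroring the usual published DE-table layout).
#'
#' @param de A `de_result` data.frame from [call_differential()].
#' @param path File path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(de) <- c("de_result", "data.frame")
  de
}

#' Write and read a ceRNA network
#'
#' `format = "tsv"` writes the edge list (`mirna_id`, `target_id`,
#' `target_role`, `n_sites`); `format = "graphml"` writes a GraphML graph
#' (via igraph) whose nodes carry `role` (miRNA/lncRNA/mRNA), `direction`
#' and the conventional display colour (orange/green/red).
#'
#' @param network A `cerna_network` (see [build_global_network()]).
#' @param path Output path.
#' @param format `"tsv"` or `"graphml"`.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  role_colour <- c(miRNA = "orange", lncRNA = "green", mRNA = "red")
  nodes <- network$nodes
  nodes$colour <- unname(role_colour[nodes$role])
  if (nrow(network$edges)) {
    ed <- data.frame(from = network$edges$mirna_id,
                     to = network$edges$target_id,
                     n_sites = network$edges$n_sites,
                     stringsAsFactors = FALSE)
  } else {
    ed <- data.frame(from = character(0), to = character(0),
                     n_sites = integer(0))
  }
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_de_table
#' @return `read_network_graphml`: list with `nodes` and `edges`
#'   data.frames recovered from a GraphML file.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  edges <- igraph::as_data_frame(g, what = "edges")
  names(nodes)[names(nodes) == "name"] <- "id"
  rownames(nodes) <- NULL
  list(nodes = nodes, edges = edges)
}
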