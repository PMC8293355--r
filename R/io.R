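#' Export a network as an edge-list CSV
#'
#' Writes the nonzero unique edges with their layer tags:
#' `node_i, node_j, weight, layer_i, layer_j`.
#'
#' @param net a `pcor_network`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_edgelist_csv <- function(net, path) {
  stopifnot(inherits(net, "pcor_network"))
  W <- net$W
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  el <- data.frame(node_i = rownames(W)[idx[, 1]],
                   node_j = colnames(W)[idx[, 2]],
                   weight = W[idx],
                   layer_i = layer_or_na(net, rownames(W)[idx[, 1]]),
                   layer_j = layer_or_na(net, colnames(W)[idx[, 2]]),
                   stringsAsFactors = FALSE)
  utils::write.csv(el, path, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' @param net a `pcor_network`.
#' @param path output GraphML path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "pcor_network"))
  g <- igraph::graph_from_adjacency_matrix(net$W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(net$layer_of))
    g <- igraph::set_vertex_attr(g, "layer",
                                 value = unname(net$layer_of[net$node_labels]))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write all artifacts of a run report
#'
#' Writes, under the report's output directory: the edge list and GraphML
#' exports, the centrality table (and the community table for multilayer
#' runs), and a machine-readable JSON report with the edge summary,
#' estimation metadata (penalty path, EBIC curve, PSD-repair magnitude),
#' modularity, and the stability summary.
#'
#' @param report a `run_report`.
#' @param dir output directory; defaults to the config's `output_dir`.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir = report$config$output_dir) {
  stopifnot(inherits(report, "run_report"))
  if (is.null(dir)) stop("no output directory set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tag <- paste(report$layers, collapse = "-")
  write_edgelist_csv(report$network, file.path(dir, paste0(tag, "_edges.csv")))
  write_graphml(report$network, file.path(dir, paste0(tag, "_network.graphml")))
  utils::write.csv(report$centrality,
                   file.path(dir, paste0(tag, "_centrality.csv")),
                   row.names = FALSE)
  if (!is.null(report$community)) {
    comm <- data.frame(node = names(report$community$assignment),
                       layer = layer_or_na(report$network,
                                           names(report$community$assignment)),
                       community = unname(report$community$assignment))
    utils::write.csv(comm, file.path(dir, paste0(tag, "_communities.csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(report_as_list(report),
                       file.path(dir, paste0(tag, "_report.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

report_as_list <- function(report) {
  net <- report$network
  out <- list(
    schema = report$schema,
    kind = report$kind,
    layers = report$layers,
    seed = report$seed,
    version = report$version,
    config = list(preset = report$config$preset, n = report$config$n,
                  input = report$config$input,
                  age_mode = report$config$age_mode,
                  gamma = report$config$gamma,
                  path_size = report$config$path_size,
                  min_ratio = report$config$min_ratio,
                  outlier_k = report$config$outlier_k),
    edge_summary = unclass(report$edge_summary),
    estimation = list(lambda_selected = net$lambda_selected,
                      lambda_path = net$lambda_path,
                      ebic = net$ebic,
                      n_effective = net$n_effective,
                      psd_repair = net$psd_repair),
    central_nodes = report$centrality$node[report$centrality$central])
  if (!is.null(report$community))
    out$community <- list(Q = as.numeric(report$community$Q),
                          Q_label = report$community$Q_label,
                          n_communities =
                            length(unique(report$community$assignment)),
                          assignment = as.list(report$community$assignment))
  if (!is.null(report$cs)) {
    prob <- attr(report$cs, "prob_ge_threshold")
    out$stability <- list(CS = as.numeric(report$cs),
                          label = attr(report$cs, "label"),
                          B = report$stability$B,
                          cor_method = report$stability$cor_method,
                          fractions = report$stability$fractions,
                          prob_ge_threshold = unname(prob))
  }
  out
}
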