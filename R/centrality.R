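#' Node strength centrality
#'
#' Strength is the sum of absolute edge weights incident to a node. When an
#' age node is present its edges contribute to every node's sum, but age
#' itself is excluded both from the reported table and from the mean/SD used
#' for z-scoring, mirroring the estimation-versus-reporting split for age.
#' A node is classified central when its z-score (sample-SD convention) is
#' at least one standard deviation above the mean, i.e. `z >= 1`; negative
#' z-scores are reported but never flagged.
#'
#' @param net a `pcor_network`.
#' @return A data.frame of class `centrality_table` with columns `node`,
#'   `layer`, `strength`, `z`, and `central`, one row per non-age node.
#' @export
node_strength <- function(net) {
  stopifnot(inherits(net, "pcor_network"))
  s <- rowSums(abs(net$W))
  keep <- non_age_nodes(net)
  if (length(keep) < 3)
    stop("z-scores require at least 3 non-age nodes")
  s <- s[keep]
  z <- (s - mean(s)) / stats::sd(s)
  if (!is.finite(stats::sd(s)) || stats::sd(s) == 0) z <- rep(NA_real_, length(s))
  out <- data.frame(node = keep,
                    layer = layer_or_na(net, keep),
                    strength = unname(s),
                    z = unname(z),
                    central = !is.na(z) & z >= 1,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("centrality_table", "data.frame")
  attr(out, "measure") <- "strength"
  out
}

#' Bridge strength centrality
#'
#' Bridge strength sums, for each node, the absolute weights of every edge
#' connecting it to nodes assigned to a *different* pre-assigned community.
#' Communities are typically supplied from [walktrap_communities()]. The
#' z-scoring and the one-SD classification rule match [node_strength()];
#' age (when present) is excluded from the reported table and from the
#' normalization, though its edges count toward the sums of nodes outside
#' its community.
#'
#' @param net a `pcor_network`.
#' @param partition a `community_partition` or a named vector/factor of
#'   community ids covering every node of `net`.
#' @return A data.frame of class `centrality_table` with columns `node`,
#'   `layer`, `community`, `bridge_strength`, `z`, and `central`.
#' @export
bridge_strength <- function(net, partition) {
  stopifnot(inherits(net, "pcor_network"))
  comm <- if (inherits(partition, "community_partition"))
    partition$assignment else partition
  comm <- stats::setNames(as.integer(comm), names(comm))
  missing_nodes <- setdiff(net$node_labels, names(comm))
  if (length(missing_nodes))
    stop("partition does not cover node(s): ",
         paste(missing_nodes, collapse = ", "))
  comm <- comm[net$node_labels]
  if (length(unique(comm)) == 1L)
    warning("partition has a single community; all bridge strengths are 0")
  A <- abs(net$W)
  cross <- outer(comm, comm, FUN = "!=")
  b <- rowSums(A * cross)
  keep <- non_age_nodes(net)
  if (length(keep) < 3)
    stop("z-scores require at least 3 non-age nodes")
  b <- b[keep]
  sdb <- stats::sd(b)
  z <- if (is.finite(sdb) && sdb > 0) (b - mean(b)) / sdb else rep(NA_real_, length(b))
  out <- data.frame(node = keep,
                    layer = layer_or_na(net, keep),
                    community = unname(comm[keep]),
                    bridge_strength = unname(b),
                    z = unname(z),
                    central = !is.na(z) & z >= 1,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("centrality_table", "data.frame")
  attr(out, "measure") <- "bridge_strength"
  out
}

layer_or_na <- function(net, nodes) {
  if (is.null(net$layer_of)) rep(NA_character_, length(nodes))
  else unname(net$layer_of[nodes])
}

#' @export
print.centrality_table <- function(x, ...) {
  cat(sprintf("%s centrality (%d nodes, %d central)\n",
              if (identical(attr(x, "measure"), "bridge_strength"))
                "Bridge strength" else "Strength",
              nrow(x), sum(x$central)))
  print.data.frame(x, digits = 3)
  invisible(x)
}
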