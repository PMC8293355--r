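#' Walktrap community detection
#'
#' Agglomerative community detection from short random walks (Pons &
#' Latapy). Edge weights are taken in absolute value — a random walk needs
#' non-negative transition probabilities, while partial-correlation networks
#' can carry negative edges; the signed matrix is untouched for every other
#' purpose. The walk distance between nodes i and j is
#' \deqn{r_{ij} = \sqrt{\sum_k (P^t_{ik} - P^t_{jk})^2 / d_k},}
#' with \eqn{P} the one-step transition matrix and \eqn{d} the weighted
#' degree. Starting from singletons, adjacent communities are merged
#' greedily by the Ward criterion (smallest increase in mean squared
#' distance), ties broken by the lowest community-index pair so runs are
#' fully deterministic; the dendrogram is cut at maximum modularity.
#' Isolated nodes become singleton communities.
#'
#' @param net a `pcor_network` (or symmetric weight matrix).
#' @param steps random-walk length (default 4).
#' @return An object of class `community_partition`: list with `assignment`
#'   (named community ids, contiguous from 1 in order of first node),
#'   `merge_history` (data.frame: step, c1, c2, height), `Q`, `Q_label`,
#'   and `steps`.
#' @references Pons, P., & Latapy, M. (2006). Computing communities in large
#'   networks using random walks. J. Graph Algorithms Appl., 10(2), 191-218.
#' @export
walktrap_communities <- function(net, steps = 4) {
  if (!inherits(net, "pcor_network")) net <- pcor_network(as.matrix(net))
  A <- abs(net$W)
  if (any(net$W < 0))
    message("walktrap_communities: negative edge weights present; ",
            "absolute values used for the random walk")
  labels <- net$node_labels
  p <- length(labels)
  d <- rowSums(A)
  act <- which(d > 0)
  merge_history <- data.frame(step = integer(0), c1 = integer(0),
                              c2 = integer(0), height = numeric(0))

  if (length(act) == 0) {
    warning("network has no nonzero edges; every node is a singleton, Q = 0")
    assignment <- stats::setNames(seq_len(p), labels)
    return(structure(list(assignment = assignment,
                          merge_history = merge_history,
                          Q = 0, Q_label = modularity_label(0), steps = steps),
                     class = "community_partition"))
  }

  Aa <- A[act, act, drop = FALSE]
  da <- d[act]
  P1 <- Aa / da
  Pt <- P1
  if (steps > 1) for (s in seq_len(steps - 1)) Pt <- Pt %*% P1
  n_act <- length(act)

  # communities indexed by creation order; initial singletons 1..n_act
  members <- as.list(seq_len(n_act))   # indices into act
  sizes <- rep(1L, n_act)
  probs <- lapply(seq_len(n_act), function(i) Pt[i, ])
  adj <- Aa > 0
  diag(adj) <- FALSE
  alive <- rep(TRUE, n_act)

  delta_sigma <- function(i, j) {
    r2 <- sum((probs[[i]] - probs[[j]])^2 / da)
    (sizes[i] * sizes[j] / (sizes[i] + sizes[j])) * r2 / n_act
  }

  # snapshots of the partition (on all p nodes) along the merge sequence
  node_comm <- seq_len(p)                       # global singleton start
  snapshots <- list(node_comm)
  step <- 0L
  repeat {
    live <- which(alive)
    best <- NULL
    best_ds <- Inf
    for (ii in seq_along(live)) {
      i <- live[ii]
      for (jj in seq_along(live)) {
        j <- live[jj]
        if (j <= i || !adj[i, j]) next
        ds <- delta_sigma(i, j)
        if (ds < best_ds - 1e-15 ||
            (abs(ds - best_ds) <= 1e-15 &&
             (is.null(best) || i < best[1] || (i == best[1] && j < best[2])))) {
          best_ds <- ds
          best <- c(i, j)
        }
      }
    }
    if (is.null(best)) break
    i <- best[1]; j <- best[2]
    step <- step + 1L
    new_id <- length(members) + 1L
    members[[new_id]] <- c(members[[i]], members[[j]])
    sizes[new_id] <- sizes[i] + sizes[j]
    probs[[new_id]] <- (sizes[i] * probs[[i]] + sizes[j] * probs[[j]]) /
      sizes[new_id]
    new_adj <- adj[i, ] | adj[j, ]
    adj <- rbind(cbind(adj, new_adj), c(new_adj, FALSE))
    alive[i] <- alive[j] <- FALSE
    alive[new_id] <- TRUE
    adj[, c(i, j)] <- FALSE
    adj[c(i, j), ] <- FALSE
    merge_history <- rbind(merge_history,
                           data.frame(step = step, c1 = i, c2 = j,
                                      height = best_ds))
    node_comm[act[members[[new_id]]]] <- p + new_id
    snapshots[[length(snapshots) + 1L]] <- node_comm
  }

  Qs <- vapply(snapshots, function(nc) {
    modularity_q(net, stats::setNames(nc, labels))
  }, numeric(1))
  pick <- max(which(Qs == max(Qs)))  # ties: the most merged partition
  assignment <- relabel_contiguous(snapshots[[pick]])
  names(assignment) <- labels
  Q <- Qs[pick]
  structure(list(assignment = assignment, merge_history = merge_history,
                 Q = Q, Q_label = modularity_label(Q), steps = steps),
            class = "community_partition")
}

relabel_contiguous <- function(ids) {
  match(ids, unique(ids))
}

#' Weighted modularity of a partition
#'
#' Newman's modularity on absolute edge weights:
#' \deqn{Q = \sum_c \left( \frac{e_c}{m} - \left(\frac{d_c}{2m}\right)^2 \right),}
#' where \eqn{e_c} is the total within-community edge weight, \eqn{d_c} the
#' total weighted degree of community c, and \eqn{m} the total edge weight.
#' A network with no edges has Q = 0.
#'
#' Values of 0.5 or above are labelled `"strong"` (reliable grouping),
#' 0.3 to 0.5 `"moderate"`, below 0.3 `"weak"`.
#'
#' @param net a `pcor_network` or symmetric weight matrix.
#' @param assignment named vector of community ids covering every node.
#' @return Modularity Q (numeric scalar) with attribute `"label"`.
#' @export
modularity_q <- function(net, assignment) {
  if (!inherits(net, "pcor_network")) net <- pcor_network(as.matrix(net))
  labels <- net$node_labels
  if (inherits(assignment, "community_partition"))
    assignment <- assignment$assignment
  unknown <- setdiff(names(assignment), labels)
  if (length(unknown))
    stop("unknown node(s) in assignment: ", paste(unknown, collapse = ", "))
  if (!all(labels %in% names(assignment)))
    stop("assignment does not cover node(s): ",
         paste(setdiff(labels, names(assignment)), collapse = ", "))
  comm <- assignment[labels]
  A <- abs(net$W)
  m <- sum(A) / 2
  if (m == 0) return(structure(0, label = modularity_label(0)))
  d <- rowSums(A)
  Q <- 0
  for (c_id in unique(comm)) {
    idx <- which(comm == c_id)
    e_c <- sum(A[idx, idx]) / 2
    d_c <- sum(d[idx])
    Q <- Q + e_c / m - (d_c / (2 * m))^2
  }
  structure(Q, label = modularity_label(Q))
}

modularity_label <- function(Q) {
  if (Q >= 0.5) "strong" else if (Q >= 0.3) "moderate" else "weak"
}

#' @export
print.community_partition <- function(x, ...) {
  k <- length(unique(x$assignment))
  cat(sprintf("Walktrap partition: %d communities, Q = %.3f (%s modularity)\n",
              k, x$Q, x$Q_label))
  for (c_id in sort(unique(x$assignment)))
    cat(sprintf("  [%d] %s\n", c_id,
                paste(names(x$assignment)[x$assignment == c_id],
                      collapse = ", ")))
  invisible(x)
}
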