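#' Case-drop bootstrap for centrality stability
#'
#' Re-estimates the network on subsamples with an increasing proportion of
#' subjects dropped and correlates (Spearman, by default, since the question
#' is about the *rank order* of centrality) each subsample's centralities
#' with the full-sample ones. The resulting distributions feed the
#' correlation-stability (CS) coefficient of [cs_coefficient()].
#'
#' Replicates where estimation fails or the correlation is undefined (e.g.
#' constant centralities) are recorded as `NA` and conservatively counted as
#' below-threshold when computing CS, so estimation failures can never
#' inflate the coefficient. A warning is raised when more than 20% of
#' replicates fail at some drop fraction.
#'
#' @param data a [multilayer_dataset].
#' @param statistic a function mapping a [multilayer_dataset] to a named
#'   numeric vector of per-node centralities over non-age nodes; see
#'   [strength_statistic()] and [bridge_strength_statistic()].
#' @param fractions grid of case-drop proportions (default 0.05 to 0.75 in
#'   steps of 0.05).
#' @param B bootstrap replicates per fraction (>= 100; the conventional
#'   published analysis uses 2000).
#' @param seed integer seed.
#' @param cor_method `"spearman"` (default) or `"pearson"`.
#' @return An object of class `stability_report`: list with `fractions`,
#'   `cors` (B x length(fractions) matrix of correlations, `NA` = failed
#'   replicate), `B`, `cor_method`, `full` (full-sample centralities), and
#'   `n`.
#' @export
case_drop_bootstrap <- function(data, statistic,
                                fractions = seq(0.05, 0.75, by = 0.05),
                                B = 2000, seed,
                                cor_method = c("spearman", "pearson")) {
  stopifnot(inherits(data, "multilayer_dataset"))
  cor_method <- match.arg(cor_method)
  if (B < 100) stop("B must be at least 100")
  if (missing(seed)) stop("seed must be supplied")
  if (any(fractions < 0 | fractions >= 1)) stop("fractions must be in [0, 1)")
  fractions <- sort(fractions)
  n <- nrow(data$values)
  full <- statistic(data)
  if (!is.numeric(full) || is.null(names(full)))
    stop("statistic must return a named numeric vector")
  set.seed(as.integer(seed))
  cors <- matrix(NA_real_, B, length(fractions),
                 dimnames = list(NULL, paste0("drop_", fractions)))
  for (fi in seq_along(fractions)) {
    n_drop <- ceiling(fractions[fi] * n)
    for (b in seq_len(B)) {
      keep <- if (n_drop == 0) seq_len(n) else
        sort(sample.int(n, n - n_drop))
      sub <- multilayer_dataset(data$values[keep, , drop = FALSE],
                                data$layer_of)
      val <- tryCatch(statistic(sub), error = function(e) NULL)
      if (is.null(val)) next
      val <- val[names(full)]
      r <- suppressWarnings(stats::cor(full, val, method = cor_method,
                                       use = "complete.obs"))
      if (is.finite(r)) cors[b, fi] <- r
    }
    fail <- mean(is.na(cors[, fi]))
    if (fail > 0.2)
      warning(sprintf("%.0f%% of replicates failed at drop fraction %.2f",
                      100 * fail, fractions[fi]))
  }
  structure(list(fractions = fractions, cors = cors, B = B,
                 cor_method = cor_method, full = full, n = n),
            class = "stability_report")
}

#' Correlation-stability (CS) coefficient
#'
#' The CS coefficient is the largest case-drop proportion on the grid at
#' which the subsample-versus-full-sample centrality correlation stays at or
#' above `cor_threshold` with empirical probability at least `prob_level`;
#' 0 if no grid fraction qualifies. Failed replicates (`NA`) count as below
#' threshold. CS >= 0.5 is labelled `"stable"`, >= 0.25 `"moderate"`,
#' otherwise `"unstable"`.
#'
#' @param report a `stability_report` from [case_drop_bootstrap()].
#' @param cor_threshold correlation to retain (default 0.7).
#' @param prob_level required probability (default 0.95).
#' @return CS value (numeric scalar) with attributes `"label"` and
#'   `"prob_ge_threshold"` (per-fraction empirical probabilities).
#' @export
cs_coefficient <- function(report, cor_threshold = 0.7, prob_level = 0.95) {
  stopifnot(inherits(report, "stability_report"))
  if (!nrow(report$cors)) stop("empty stability report")
  prob <- colMeans(!is.na(report$cors) & report$cors >= cor_threshold)
  ok <- which(prob >= prob_level)
  cs <- if (length(ok)) report$fractions[max(ok)] else 0
  label <- if (cs >= 0.5) "stable" else if (cs >= 0.25) "moderate" else "unstable"
  structure(cs, label = label,
            prob_ge_threshold = stats::setNames(prob, report$fractions))
}

#' @export
print.stability_report <- function(x, ...) {
  cs <- cs_coefficient(x)
  cat(sprintf(
    "Case-drop bootstrap (%s, B = %d, n = %d): CS = %.2f (%s)\n",
    x$cor_method, x$B, x$n, as.numeric(cs), attr(cs, "label")))
  prob <- attr(cs, "prob_ge_threshold")
  cat("P(cor >= 0.7) by drop fraction:\n")
  print(round(prob, 3))
  invisible(x)
}

#' Full-pipeline centrality extractors for the bootstrap
#'
#' `strength_statistic()` returns a function that runs pairwise-deletion
#' correlation, PSD repair, EBIC graphical lasso, and [node_strength()] on a
#' dataset, returning named strengths over non-age nodes.
#' `bridge_strength_statistic()` does the same but re-derives the Walktrap
#' community partition on each dataset (so community uncertainty propagates
#' into bridge-strength stability) before computing [bridge_strength()].
#'
#' @param gamma,path_size,min_ratio passed to [ebic_glasso()].
#' @param min_pairn passed to [pairwise_pearson()].
#' @param steps random-walk length for [walktrap_communities()].
#' @return A function `multilayer_dataset -> named numeric`.
#' @export
strength_statistic <- function(gamma = 0.5, path_size = 100, min_ratio = 0.01,
                               min_pairn = 10) {
  function(data) {
    corr <- pairwise_pearson(data, min_pairn = min_pairn)
    net <- ebic_glasso(corr, gamma = gamma, path_size = path_size,
                       min_ratio = min_ratio, layer_of = data$layer_of)
    tab <- node_strength(net)
    stats::setNames(tab$strength, tab$node)
  }
}

#' @rdname strength_statistic
#' @export
bridge_strength_statistic <- function(gamma = 0.5, path_size = 100,
                                      min_ratio = 0.01, min_pairn = 10,
                                      steps = 4) {
  function(data) {
    corr <- pairwise_pearson(data, min_pairn = min_pairn)
    net <- ebic_glasso(corr, gamma = gamma, path_size = path_size,
                       min_ratio = min_ratio, layer_of = data$layer_of)
    part <- suppressWarnings(suppressMessages(
      walktrap_communities(net, steps = steps)))
    tab <- suppressWarnings(bridge_strength(net, part))
    stats::setNames(tab$bridge_strength, tab$node)
  }
}

#' Nonparametric bootstrap confidence intervals for edge weights
#'
#' Resamples subjects with replacement, re-estimates the network per
#' replicate through the full pipeline, and reports percentile intervals
#' for every unique edge.
#'
#' @param data a [multilayer_dataset].
#' @param B bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @param gamma,path_size,min_ratio,min_pairn estimation settings, as in
#'   [strength_statistic()].
#' @return A data.frame of class `edge_ci_table` with columns `node_i`,
#'   `node_j`, `estimate`, `lower`, `upper`; attributes `B`, `level`, and
#'   `n_failed` (failed replicates).
#' @export
edge_bootstrap <- function(data, B, seed, level = 0.95, gamma = 0.5,
                           path_size = 100, min_ratio = 0.01, min_pairn = 10) {
  stopifnot(inherits(data, "multilayer_dataset"))
  if (B < 100) stop("B must be at least 100")
  if (missing(seed)) stop("seed must be supplied")
  estimate_W <- function(d) {
    corr <- pairwise_pearson(d, min_pairn = min_pairn)
    ebic_glasso(corr, gamma = gamma, path_size = path_size,
                min_ratio = min_ratio, layer_of = d$layer_of)$W
  }
  W0 <- estimate_W(data)
  ut <- upper.tri(W0)
  idx <- which(ut, arr.ind = TRUE)
  n <- nrow(data$values)
  set.seed(as.integer(seed))
  boots <- matrix(NA_real_, B, nrow(idx))
  n_failed <- 0L
  for (b in seq_len(B)) {
    take <- sample.int(n, n, replace = TRUE)
    sub <- multilayer_dataset(data$values[take, , drop = FALSE],
                              data$layer_of)
    Wb <- tryCatch(estimate_W(sub), error = function(e) NULL)
    if (is.null(Wb)) { n_failed <- n_failed + 1L; next }
    boots[b, ] <- Wb[ut]
  }
  if (n_failed > 0.2 * B)
    warning(sprintf("%d of %d bootstrap replicates failed", n_failed, B))
  a <- (1 - level) / 2
  qs <- apply(boots, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  out <- data.frame(node_i = rownames(W0)[idx[, 1]],
                    node_j = colnames(W0)[idx[, 2]],
                    estimate = W0[ut],
                    lower = qs[1, ], upper = qs[2, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("edge_ci_table", "data.frame")
  attr(out, "B") <- B
  attr(out, "level") <- level
  attr(out, "n_failed") <- n_failed
  out
}
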