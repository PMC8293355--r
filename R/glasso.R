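#' EBIC-selected graphical lasso network
#'
#' Estimates a sparse Gaussian graphical model by solving the graphical
#' lasso along a descending log-spaced penalty path and selecting the
#' penalty by the extended Bayesian information criterion
#' \deqn{EBIC_\gamma = -2\ell(\hat K) + E \log n + 4 E \gamma \log p,}
#' where \eqn{\ell(K) = (n/2)(\log\det K - tr(S K))} is the Gaussian
#' log-likelihood at the sample correlation matrix \eqn{S}, \eqn{E} the
#' number of nonzero unique off-diagonal precision entries, and \eqn{p} the
#' number of nodes. The selected precision matrix is returned as
#' partial-correlation edge weights \eqn{w_{ij} = -\kappa_{ij} /
#' \sqrt{\kappa_{ii}\kappa_{jj}}}.
#'
#' The hyperparameter `gamma = 0.5` is the conventional conservative choice
#' in regularized psychometric network estimation. The path runs from
#' \eqn{\lambda_{max}} (the largest absolute off-diagonal correlation, at
#' which the estimated network is empty) down to
#' `min_ratio * lambda_max`.
#'
#' @param corr a [correlation_estimate] (see [pairwise_pearson()]), or a
#'   plain correlation matrix (then `n` must be given).
#' @param gamma EBIC hyperparameter, >= 0 (default 0.5; 0 recovers BIC).
#' @param path_size number of penalties on the path (default 100).
#' @param min_ratio smallest penalty as a fraction of the largest
#'   (default 0.01).
#' @param n effective sample size override when `corr` is a plain matrix.
#' @param layer_of optional node-to-layer map carried into the result.
#' @param edge_threshold optional post-hoc absolute threshold applied to the
#'   selected edge weights (`NULL`, the default, applies none).
#' @param repair_psd repair an indefinite input with [nearest_psd()] first
#'   (default `TRUE`).
#' @return An object of class `pcor_network`: list with `W` (edge-weight
#'   matrix, zero diagonal), `K` (selected precision matrix),
#'   `lambda_selected`, `lambda_path`, `ebic` (per penalty), `gamma`,
#'   `n_effective`, `node_labels`, `layer_of`, `age_included`, and
#'   `psd_repair` (magnitude of any PSD repair).
#' @references Friedman, J., Hastie, T., & Tibshirani, R. (2008). Sparse
#'   inverse covariance estimation with the graphical lasso. Biostatistics,
#'   9(3), 432-441. Foygel, R., & Drton, M. (2010). Extended Bayesian
#'   information criteria for Gaussian graphical models. NeurIPS.
#' @export
ebic_glasso <- function(corr, gamma = 0.5, path_size = 100, min_ratio = 0.01,
                        n = NULL, layer_of = NULL, edge_threshold = NULL,
                        repair_psd = TRUE) {
  if (inherits(corr, "correlation_estimate")) {
    R <- corr$R
    if (is.null(n)) n <- corr$n_effective
  } else {
    R <- as.matrix(corr)
    if (is.null(n)) stop("n must be given when corr is a plain matrix")
  }
  if (gamma < 0) stop("gamma must be non-negative")
  if (min_ratio <= 0 || min_ratio >= 1) stop("min_ratio must be in (0, 1)")
  p <- ncol(R)
  labels <- colnames(R)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))

  psd_repair <- 0
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 0) {
    if (!repair_psd)
      stop(sprintf("correlation matrix is not PSD (min eigenvalue %.3g)",
                   ev_min))
    R <- nearest_psd(R)
    psd_repair <- attr(R, "psd_repair")
  }

  lambda_max <- max(abs(R[upper.tri(R)]))
  if (lambda_max == 0) lambda_max <- 1e-4  # empty correlation structure
  lambda_path <- exp(seq(log(lambda_max), log(min_ratio * lambda_max),
                         length.out = path_size))
  fit <- glasso_path_cpp(R, lambda_path)
  conv <- as.logical(fit$converged)
  if (any(!conv))
    warning(sum(!conv), " penalty value(s) did not converge and were skipped")

  ebic <- rep(NA_real_, path_size)
  for (i in which(conv)) {
    K <- fit$K[, , i]
    ld <- determinant(K, logarithm = TRUE)
    if (ld$sign <= 0) next
    ll <- (n / 2) * (as.numeric(ld$modulus) - sum(R * K))
    E <- sum(K[upper.tri(K)] != 0)
    ebic[i] <- -2 * ll + E * log(n) + 4 * E * gamma * log(p)
  }
  if (all(is.na(ebic))) stop("no penalty value produced a valid model")
  sel <- which.min(ebic)
  K <- fit$K[, , sel]
  dimnames(K) <- list(labels, labels)
  W <- precision_to_pcor(K)
  W[abs(W) < 1e-10] <- 0
  if (!is.null(edge_threshold)) W[abs(W) < edge_threshold] <- 0

  if (!is.null(layer_of)) layer_of <- layer_of[labels]
  structure(list(W = W, K = K, lambda_selected = lambda_path[sel],
                 lambda_path = lambda_path, ebic = ebic, gamma = gamma,
                 n_effective = n, node_labels = labels, layer_of = layer_of,
                 age_included = "Age" %in% labels, psd_repair = psd_repair),
            class = "pcor_network")
}

#' @export
print.pcor_network <- function(x, ...) {
  nz <- sum(x$W[upper.tri(x$W)] != 0)
  cat("Regularized partial-correlation network:", ncol(x$W), "nodes,",
      nz, "nonzero edges\n")
  cat(sprintf("lambda = %.4g (gamma = %g, n_effective = %d)\n",
              x$lambda_selected, x$gamma, x$n_effective))
  if (x$psd_repair > 0)
    cat(sprintf("PSD repair applied to input (max change %.3g)\n",
                x$psd_repair))
  invisible(x)
}

#' Construct a partial-correlation network from a weight matrix
#'
#' Wraps an explicit symmetric edge-weight matrix (e.g. a population matrix
#' or an unregularized estimate) in the same container [ebic_glasso()]
#' returns, so centrality, community, and export functions apply.
#'
#' @param W symmetric matrix, zero diagonal.
#' @param layer_of optional node-to-layer map.
#' @return A `pcor_network`.
#' @export
pcor_network <- function(W, layer_of = NULL) {
  W <- as.matrix(W)
  if (!isSymmetric(unname(W), tol = 1e-10)) stop("W must be symmetric")
  labels <- colnames(W)
  if (is.null(labels)) {
    labels <- paste0("V", seq_len(ncol(W)))
    dimnames(W) <- list(labels, labels)
  }
  diag(W) <- 0
  if (!is.null(layer_of)) layer_of <- layer_of[labels]
  structure(list(W = W, K = NULL, lambda_selected = NA_real_,
                 lambda_path = numeric(0), ebic = numeric(0), gamma = NA_real_,
                 n_effective = NA_integer_, node_labels = labels,
                 layer_of = layer_of, age_included = "Age" %in% labels,
                 psd_repair = 0),
            class = "pcor_network")
}

#' Summary statistics of the unique off-diagonal edge weights
#'
#' Mean, median, minimum, and maximum over the unique off-diagonal entries
#' of the weight matrix, with the age row/column excluded and exact zeros
#' included — the convention used to report partial-correlation networks
#' descriptively. An empty or all-age network reports all zeros.
#'
#' @param net a `pcor_network`.
#' @return An object of class `edge_summary`: list with `mean`, `median`,
#'   `min`, `max`, `n_nonzero`, and `n_edges`.
#' @export
edge_summary <- function(net) {
  stopifnot(inherits(net, "pcor_network"))
  keep <- non_age_nodes(net)
  W <- net$W[keep, keep, drop = FALSE]
  v <- W[upper.tri(W)]
  if (!length(v)) v <- 0
  structure(list(mean = mean(v), median = stats::median(v), min = min(v),
                 max = max(v), n_nonzero = sum(v != 0), n_edges = length(v)),
            class = "edge_summary")
}

#' @export
print.edge_summary <- function(x, ...) {
  cat(sprintf(
    "Edge weights (age excluded): mean = %.2f, median = %.2f, range = %.2f-%.2f (%d of %d nonzero)\n",
    x$mean, x$median, x$min, x$max, x$n_nonzero, x$n_edges))
  invisible(x)
}

non_age_nodes <- function(net) {
  if (is.null(net$layer_of)) setdiff(net$node_labels, "Age")
  else net$node_labels[net$layer_of != "age"]
}
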