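#' Population Gaussian graphical models
#'
#' A `population_ggm` holds a planted population partial-correlation matrix
#' `P` together with the covariance matrix `Sigma` it implies under unit
#' variances, node labels, and a node-to-layer map. It is the ground truth
#' from which [simulate_multilayer()] draws data.
#'
#' Under the standard GGM identity, the partial correlation between nodes
#' i and j given all others is \eqn{\rho_{ij} = -\kappa_{ij} /
#' \sqrt{\kappa_{ii}\kappa_{jj}}} for precision matrix \eqn{K}. Fixing unit
#' partial variances gives \eqn{K = I - P}, and `Sigma` is \eqn{K^{-1}}
#' rescaled to unit marginal variances (rescaling the diagonal leaves all
#' partial correlations unchanged).
#'
#' @param P symmetric partial-correlation matrix: zero diagonal, entries in
#'   (-1, 1), implied precision `I - P` positive definite.
#' @param layer_of named character vector mapping every node to a layer tag
#'   (`"cognition"`, `"grey"`, `"white"`, `"age"`).
#' @return An object of class `population_ggm` with elements `node_labels`,
#'   `layer_of`, `P`, and `Sigma`.
#' @seealso [build_preset()], [pcor_to_covariance()]
#' @export
population_ggm <- function(P, layer_of) {
  P <- as.matrix(P)
  labels <- rownames(P)
  if (is.null(labels)) stop("P must have row/column names (node labels)")
  if (!identical(labels, colnames(P))) stop("P row and column names differ")
  if (!all(labels %in% names(layer_of)))
    stop("layer_of must cover every node exactly once; missing: ",
         paste(setdiff(labels, names(layer_of)), collapse = ", "))
  layer_of <- layer_of[labels]
  Sigma <- pcor_to_covariance(P)
  structure(list(node_labels = labels, layer_of = layer_of, P = P,
                 Sigma = Sigma),
            class = "population_ggm")
}

#' @export
print.population_ggm <- function(x, ...) {
  cat("Population GGM:", length(x$node_labels), "nodes\n")
  cat("Layers:", paste(sprintf("%s (%d)", names(table(x$layer_of)),
                               table(x$layer_of)), collapse = ", "), "\n")
  nz <- sum(x$P[upper.tri(x$P)] != 0)
  cat("Nonzero population edges:", nz, "of",
      sum(upper.tri(x$P)), "\n")
  invisible(x)
}

#' Convert a partial-correlation matrix to its implied covariance
#'
#' Inverts the GGM identity: builds the precision matrix `K = I - P` (unit
#' partial variances), checks positive definiteness, and returns the inverse
#' rescaled to unit marginal variances.
#'
#' @param P symmetric matrix with zero diagonal and off-diagonal entries in
#'   (-1, 1).
#' @return Unit-variance covariance (i.e. correlation) matrix whose exact
#'   partial correlations reproduce `P`.
#' @export
pcor_to_covariance <- function(P) {
  P <- as.matrix(P)
  if (!isSymmetric(unname(P), tol = 1e-12))
    stop("P must be symmetric")
  if (any(abs(diag(P)) > 1e-12))
    stop("P must have a zero diagonal")
  if (any(abs(P[upper.tri(P)]) >= 1))
    stop("all off-diagonal entries of P must have magnitude < 1")
  K <- diag(nrow(P)) - P
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf(
      "implied precision matrix is not positive definite (min eigenvalue %.3g)",
      min(ev)))
  Sigma <- stats::cov2cor(solve(K))
  dimnames(Sigma) <- dimnames(P)
  (Sigma + t(Sigma)) / 2
}

#' Exact partial correlations of a covariance or precision matrix
#'
#' @param Sigma covariance matrix (positive definite).
#' @return Partial-correlation matrix with zero diagonal.
#' @export
covariance_to_pcor <- function(Sigma) {
  precision_to_pcor(solve(Sigma))
}

#' @rdname covariance_to_pcor
#' @param K precision (inverse covariance) matrix.
#' @export
precision_to_pcor <- function(K) {
  d <- 1 / sqrt(diag(K))
  P <- -K * outer(d, d)
  diag(P) <- 0
  # preserve exact zeros of K
  P[K == 0 & row(K) != col(K)] <- 0
  dimnames(P) <- dimnames(K)
  (P + t(P)) / 2
}
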