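#' Pairwise-deletion Pearson correlations
#'
#' Computes the Pearson correlation matrix using, for each pair of
#' variables, all subjects observed on both (pairwise deletion), together
#' with the per-pair complete-observation counts and the effective sample
#' size used downstream in the likelihood and EBIC.
#'
#' @param data a [multilayer_dataset], or a numeric matrix with column names.
#' @param min_pairn minimum complete observations required for every pair
#'   (default 10); pairs below the floor raise an error listing them.
#' @param n_effective how to define the effective sample size under pairwise
#'   deletion: `"any_observed"` (subjects with at least one observed cell;
#'   default) or `"min_pairwise"` (smallest off-diagonal pair count).
#' @return An object of class `correlation_estimate`: list with `R`
#'   (correlation matrix, unit diagonal), `Npair` (pair counts; diagonal is
#'   the per-variable observed count), and `n_effective`.
#' @export
pairwise_pearson <- function(data, min_pairn = 10,
                             n_effective = c("any_observed", "min_pairwise")) {
  n_effective <- match.arg(n_effective)
  X <- if (inherits(data, "multilayer_dataset")) data$values else as.matrix(data)
  if (is.null(colnames(X))) stop("data must have column names")
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  bad <- colnames(X)[is.na(sds) | sds == 0]
  if (length(bad))
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  obs <- !is.na(X)
  Npair <- crossprod(obs)
  off <- Npair[upper.tri(Npair)]
  if (any(off < min_pairn)) {
    idx <- which(upper.tri(Npair) & Npair < min_pairn, arr.ind = TRUE)
    stop("pair(s) below the complete-observation floor (", min_pairn, "): ",
         paste(sprintf("%s-%s (%d)", colnames(X)[idx[, 1]],
                       colnames(X)[idx[, 2]],
                       Npair[idx]), collapse = ", "))
  }
  R <- stats::cor(X, use = "pairwise.complete.obs")
  diag(R) <- 1
  n_eff <- switch(n_effective,
                  any_observed = sum(rowSums(obs) > 0L),
                  min_pairwise = min(off))
  if (n_eff <= ncol(X))
    warning("effective sample size (", n_eff,
            ") does not exceed the number of variables")
  structure(list(R = R, Npair = Npair, n_effective = n_eff,
                 n_effective_rule = n_effective),
            class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat("Pairwise-deletion correlation estimate:", ncol(x$R), "variables, ",
      "n_effective =", x$n_effective, sprintf("(%s)\n", x$n_effective_rule))
  cat("Pair counts range:", min(x$Npair[upper.tri(x$Npair)]), "-",
      max(x$Npair[upper.tri(x$Npair)]), "\n")
  invisible(x)
}

#' Nearest positive semidefinite repair of a correlation matrix
#'
#' Pairwise deletion can yield an indefinite correlation matrix. This clips
#' eigenvalues at `eps` and rescales back to unit diagonal. Already-PSD
#' input is returned unchanged.
#'
#' @param R symmetric correlation matrix.
#' @param eps eigenvalue floor (default 1e-8).
#' @return A PSD correlation matrix; attribute `"psd_repair"` records the
#'   maximum absolute change (0 when no repair was needed).
#' @export
nearest_psd <- function(R, eps = 1e-8) {
  R <- as.matrix(R)
  if (!isSymmetric(unname(R), tol = 1e-10)) stop("R must be symmetric")
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) {
    attr(R, "psd_repair") <- 0
    return(R)
  }
  v <- pmax(e$values, eps)
  R2 <- e$vectors %*% (v * t(e$vectors))
  R2 <- stats::cov2cor(R2)
  R2 <- (R2 + t(R2)) / 2
  dimnames(R2) <- dimnames(R)
  attr(R2, "psd_repair") <- max(abs(R2 - R))
  R2
}
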