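#' Missingness specification
#'
#' Describes how observations go missing in a simulated multilayer dataset:
#' whole-layer nesting (the fraction of subjects that possess each layer at
#' all, emulating nested neuroimaging subsamples) applied first, then
#' cell-level missing-completely-at-random deletion per variable.
#'
#' @param mcar named numeric vector of per-variable MCAR rates in \[0, 1\];
#'   variables not named get rate 0.
#' @param layer_fraction named numeric vector giving the fraction of subjects
#'   possessing each layer; layers not named default to 1. Layers are nested:
#'   the subjects possessing a rarer layer are drawn from within the subjects
#'   possessing the next more common one.
#' @return An object of class `missingness_spec`.
#' @export
missingness_spec <- function(mcar = numeric(0), layer_fraction = numeric(0)) {
  if (length(mcar) && (is.null(names(mcar)) || any(!nzchar(names(mcar)))))
    stop("mcar rates must be named by variable")
  if (any(mcar < 0 | mcar > 1)) stop("mcar rates must be in [0, 1]")
  if (any(layer_fraction < 0 | layer_fraction > 1))
    stop("layer fractions must be in [0, 1]")
  structure(list(mcar = mcar, layer_fraction = layer_fraction),
            class = "missingness_spec")
}

#' Construct a multilayer dataset
#'
#' @param values numeric matrix or data.frame, subjects by variables, with
#'   `NA` marking missing cells; column names must match `names(layer_of)`.
#' @param layer_of named character vector mapping variables to layer tags.
#' @return An object of class `multilayer_dataset` with elements `values`
#'   (matrix), `node_labels`, `layer_of`, and `n_layer` (subjects with at
#'   least one observed cell per layer).
#' @export
multilayer_dataset <- function(values, layer_of) {
  values <- as.matrix(values)
  labels <- colnames(values)
  if (is.null(labels)) stop("values must have column names")
  if (!all(labels %in% names(layer_of)))
    stop("layer_of does not cover variables: ",
         paste(setdiff(labels, names(layer_of)), collapse = ", "))
  layer_of <- layer_of[labels]
  structure(list(values = values, node_labels = labels, layer_of = layer_of,
                 n_layer = count_layer_n(values, layer_of)),
            class = "multilayer_dataset")
}

count_layer_n <- function(values, layer_of) {
  vapply(split(names(layer_of), layer_of), function(vars) {
    sum(rowSums(!is.na(values[, vars, drop = FALSE])) > 0L)
  }, integer(1))
}

#' @export
print.multilayer_dataset <- function(x, ...) {
  cat("Multilayer dataset:", nrow(x$values), "subjects x",
      ncol(x$values), "variables\n")
  cat("Observed subjects per layer:",
      paste(sprintf("%s=%d", names(x$n_layer), x$n_layer), collapse = ", "),
      "\n")
  miss <- mean(is.na(x$values))
  cat(sprintf("Missing cells: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Simulate a multilayer Gaussian dataset from a population network
#'
#' Draws `n` subjects from the multivariate normal distribution implied by
#' the population GGM, then applies whole-layer nesting followed by
#' cell-level MCAR deletion. With the same seed the output is bit-identical.
#'
#' @param ggm a [population_ggm].
#' @param n number of subjects (>= 10).
#' @param miss a [missingness_spec], or `NULL` for complete data.
#' @param seed integer seed; required for reproducibility.
#' @return A [multilayer_dataset].
#' @examples
#' d <- simulate_multilayer(build_preset("calm_cognitive"), n = 200, seed = 1)
#' @export
simulate_multilayer <- function(ggm, n, miss = NULL, seed) {
  stopifnot(inherits(ggm, "population_ggm"))
  if (n < 10) stop("n must be at least 10")
  if (missing(seed)) stop("seed must be supplied")
  p <- length(ggm$node_labels)
  if (n < p)
    warning("n < number of variables; downstream estimation may fail")
  set.seed(as.integer(seed))
  X <- matrix(stats::rnorm(n * p), n, p) %*% chol(ggm$Sigma)
  colnames(X) <- ggm$node_labels

  if (!is.null(miss)) {
    stopifnot(inherits(miss, "missingness_spec"))
    # layer nesting first: rarer layers nested within more common ones
    lf <- miss$layer_fraction
    lf <- lf[names(lf) %in% unique(ggm$layer_of)]
    if (length(lf)) {
      pool <- seq_len(n)
      for (layer in names(sort(lf, decreasing = TRUE))) {
        keep <- sort(sample(pool, round(lf[[layer]] * n)))
        drop <- setdiff(seq_len(n), keep)
        vars <- names(ggm$layer_of)[ggm$layer_of == layer]
        X[drop, vars] <- NA_real_
        pool <- keep
      }
    }
    # then cell-level MCAR; never resurrects nested-out cells
    for (v in intersect(names(miss$mcar), colnames(X))) {
      r <- miss$mcar[[v]]
      if (r > 0) X[stats::runif(n) < r, v] <- NA_real_
    }
  }
  multilayer_dataset(X, ggm$layer_of)
}

#' Mask cells beyond k standard deviations of their column
#'
#' Sensitivity-analysis helper: sets to missing every cell further than
#' `k` standard deviations from its column mean (both computed on observed
#' cells). Zero-variance columns are skipped with a message.
#'
#' @param data a [multilayer_dataset].
#' @param k positive SD multiplier; the conventional cutoff is 4.
#' @return The masked [multilayer_dataset]; attribute `"n_masked"` holds the
#'   per-column count of newly masked cells.
#' @export
mask_outliers <- function(data, k = 4) {
  stopifnot(inherits(data, "multilayer_dataset"))
  if (!is.numeric(k) || length(k) != 1 || k <= 0)
    stop("k must be a positive number")
  X <- data$values
  n_masked <- stats::setNames(integer(ncol(X)), colnames(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      message("mask_outliers: skipping zero-variance column ", colnames(X)[j])
      next
    }
    m <- mean(x, na.rm = TRUE)
    out <- which(!is.na(x) & abs(x - m) > k * s)
    X[out, j] <- NA_real_
    n_masked[j] <- length(out)
  }
  res <- multilayer_dataset(X, data$layer_of)
  attr(res, "n_masked") <- n_masked
  res
}

#' Write a multilayer dataset to CSV with a JSON sidecar
#'
#' One row per subject, one column per variable, `NA` for missing cells.
#' The sidecar records the layer map and any provenance passed in `meta`.
#'
#' @param data a [multilayer_dataset].
#' @param path output CSV path; the sidecar is written to `<path>.json`.
#' @param meta optional named list (e.g. preset name and seed) stored in the
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, meta = list()) {
  stopifnot(inherits(data, "multilayer_dataset"))
  utils::write.csv(as.data.frame(data$values), path, row.names = FALSE,
                   na = "NA")
  sidecar <- c(list(layer_of = as.list(data$layer_of),
                    n_layer = as.list(data$n_layer)), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a subjects-by-variables CSV as a multilayer dataset
#'
#' @param path CSV path ("NA" marks missing cells).
#' @param layer_of named character vector mapping variables to layers; if
#'   `NULL`, a `<path>.json` sidecar written by [write_dataset()] is read.
#' @return A [multilayer_dataset].
#' @export
read_multilayer_csv <- function(path, layer_of = NULL) {
  values <- as.matrix(utils::read.csv(path, check.names = FALSE))
  if (is.null(layer_of)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("no layer map given and no sidecar found at ", sidecar)
    layer_of <- unlist(jsonlite::read_json(sidecar)$layer_of)
  }
  multilayer_dataset(values, layer_of)
}
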