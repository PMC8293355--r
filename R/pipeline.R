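#' Configuration for a pipeline run
#'
#' Gathers every setting a run needs, with exactly one input source: either
#' a calibrated preset simulated at a given seed, or a subjects-by-variables
#' CSV (with `"NA"` missing markers and a layer map).
#'
#' @param preset preset name for [build_preset()], or `NULL` when reading a
#'   CSV.
#' @param n number of subjects to simulate (required with `preset`).
#' @param input path to an input CSV, or `NULL` when simulating.
#' @param layer_of layer map for CSV input (`NULL` reads the JSON sidecar).
#' @param seed integer seed driving simulation and bootstraps.
#' @param missingness `"calm"` (the study's nested design and per-task
#'   rates; default), `NULL` for complete data, or a [missingness_spec].
#' @param age_mode how age enters estimation: `"include_node"` (default;
#'   age is a node, excluded from reports), `"regress_out"` (residualize
#'   every variable on age first), or `"exclude"` (drop age).
#' @param gamma,path_size,min_ratio,min_pairn estimation settings (see
#'   [ebic_glasso()], [pairwise_pearson()]).
#' @param bootstrap `NULL` to skip stability, or a list with elements `B`
#'   (default 2000), `fractions`, and `cor_method` for
#'   [case_drop_bootstrap()].
#' @param outlier_k SD multiplier for [run_sensitivity()] (default 4).
#' @param output_dir directory for artifacts, or `NULL` to keep results in
#'   memory only.
#' @return An object of class `run_config`.
#' @export
run_config <- function(preset = NULL, n = NULL, input = NULL, layer_of = NULL,
                       seed = 1, missingness = "calm",
                       age_mode = c("include_node", "regress_out", "exclude"),
                       gamma = 0.5, path_size = 100, min_ratio = 0.01,
                       min_pairn = 10, bootstrap = NULL, outlier_k = 4,
                       output_dir = NULL) {
  age_mode <- match.arg(age_mode)
  if (is.null(preset) == is.null(input))
    stop("exactly one input source: give either `preset` or `input`")
  if (!is.null(preset) && is.null(n))
    stop("`n` is required when simulating from a preset")
  if (gamma < 0) stop("gamma must be non-negative")
  if (!is.null(outlier_k) && outlier_k <= 0)
    stop("outlier_k must be positive")
  if (!is.null(bootstrap)) {
    bootstrap <- utils::modifyList(
      list(B = 2000, fractions = seq(0.05, 0.75, by = 0.05),
           cor_method = "spearman"), bootstrap)
  }
  structure(list(preset = preset, n = n, input = input, layer_of = layer_of,
                 seed = as.integer(seed), missingness = missingness,
                 age_mode = age_mode, gamma = gamma, path_size = path_size,
                 min_ratio = min_ratio, min_pairn = min_pairn,
                 bootstrap = bootstrap, outlier_k = outlier_k,
                 output_dir = output_dir),
            class = "run_config")
}

load_input <- function(config) {
  if (!is.null(config$preset)) {
    ggm <- build_preset(config$preset)
    miss <- config$missingness
    if (identical(miss, "calm")) miss <- calm_missingness(config$preset)
    simulate_multilayer(ggm, n = config$n, miss = miss, seed = config$seed)
  } else {
    read_multilayer_csv(config$input, config$layer_of)
  }
}

apply_age_mode <- function(data, age_mode) {
  age_vars <- names(data$layer_of)[data$layer_of == "age"]
  if (!length(age_vars) || age_mode == "include_node") return(data)
  X <- data$values
  keep <- setdiff(colnames(X), age_vars)
  if (age_mode == "regress_out") {
    age <- X[, age_vars[1]]
    for (v in keep) {
      ok <- !is.na(X[, v]) & !is.na(age)
      if (sum(ok) > 2) {
        fit <- stats::lm.fit(cbind(1, age[ok]), X[ok, v])
        X[ok, v] <- fit$residuals
      }
    }
  }
  multilayer_dataset(X[, keep, drop = FALSE], data$layer_of[keep])
}

subset_layers <- function(data, layers, age_mode) {
  available <- setdiff(unique(data$layer_of), "age")
  missing_layers <- setdiff(layers, available)
  if (length(missing_layers))
    stop("layer(s) not present: ", paste(missing_layers, collapse = ", "),
         "; available: ", paste(available, collapse = ", "))
  keep_layers <- c(layers, if (age_mode != "exclude") "age")
  vars <- names(data$layer_of)[data$layer_of %in% keep_layers]
  multilayer_dataset(data$values[, vars, drop = FALSE], data$layer_of[vars])
}

estimate_network <- function(data, config) {
  corr <- pairwise_pearson(data, min_pairn = config$min_pairn)
  ebic_glasso(corr, gamma = config$gamma, path_size = config$path_size,
              min_ratio = config$min_ratio, layer_of = data$layer_of)
}

run_stability <- function(data, statistic, config) {
  if (is.null(config$bootstrap)) return(NULL)
  bs <- config$bootstrap
  case_drop_bootstrap(data, statistic, fractions = bs$fractions, B = bs$B,
                      seed = config$seed, cor_method = bs$cor_method)
}

#' Run the single-layer analysis
#'
#' Executes the full single-layer chain: pairwise-deletion correlations,
#' PSD repair, EBIC graphical lasso, descriptive edge summary, strength
#' centrality, and (when configured) the case-drop stability bootstrap.
#'
#' @param config a [run_config].
#' @param layer layer tag to analyse (e.g. `"cognition"`).
#' @param data optionally, a pre-loaded [multilayer_dataset] (used by
#'   [run_sensitivity()]); by default the config's input source is loaded.
#' @return An object of class `run_report`.
#' @export
run_single_layer <- function(config, layer, data = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (length(layer) != 1) stop("run_single_layer takes exactly one layer")
  if (is.null(data)) data <- load_input(config)
  data <- subset_layers(data, layer, config$age_mode)
  data <- apply_age_mode(data, config$age_mode)
  net <- estimate_network(data, config)
  report <- new_run_report(
    kind = "single_layer", layers = layer, config = config, network = net,
    edge_summary = edge_summary(net), centrality = node_strength(net),
    stability = run_stability(
      data, strength_statistic(config$gamma, config$path_size,
                               config$min_ratio, config$min_pairn), config))
  maybe_write_report(report)
}

#' Run the multilayer analysis
#'
#' Estimates the network over the concatenated layers (with nested
#' missingness handled by pairwise deletion), detects communities with
#' Walktrap, computes weighted modularity, and uses the Walktrap partition
#' (not the layer labels) as the pre-assignment for bridge strength, then
#' (when configured) bootstraps bridge-strength stability with the
#' partition re-derived per resample.
#'
#' @param config a [run_config].
#' @param layers two or more layer tags.
#' @param data optionally, a pre-loaded [multilayer_dataset].
#' @return An object of class `run_report`.
#' @export
run_multilayer <- function(config, layers, data = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (length(layers) < 2) stop("run_multilayer needs at least 2 layers")
  if (is.null(data)) data <- load_input(config)
  data <- subset_layers(data, layers, config$age_mode)
  data <- apply_age_mode(data, config$age_mode)
  net <- estimate_network(data, config)
  part <- walktrap_communities(net)
  bridge <- suppressWarnings(bridge_strength(net, part))
  report <- new_run_report(
    kind = "multilayer", layers = layers, config = config, network = net,
    edge_summary = edge_summary(net), centrality = bridge,
    community = part,
    stability = run_stability(
      data, bridge_strength_statistic(config$gamma, config$path_size,
                                      config$min_ratio, config$min_pairn),
      config))
  maybe_write_report(report)
}

#' Outlier-sensitivity re-run
#'
#' Runs the configured analysis twice — on the data as loaded and after
#' masking cells beyond `outlier_k` standard deviations of their column —
#' and reports the per-edge weight differences.
#'
#' @param config a [run_config]; `outlier_k` must be set.
#' @param layers one layer tag (single-layer run) or several (multilayer).
#' @param data optionally, a pre-loaded [multilayer_dataset].
#' @return List of class `sensitivity_report` with elements `original`,
#'   `masked` (both `run_report`), `edge_differences` (data.frame), and
#'   `n_masked` (cells masked per column).
#' @export
run_sensitivity <- function(config, layers, data = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$outlier_k))
    stop("outlier_k is not set; supply an SD multiplier (conventionally 4)")
  if (is.null(data)) data <- load_input(config)
  masked <- mask_outliers(data, k = config$outlier_k)
  runner <- if (length(layers) == 1) run_single_layer else run_multilayer
  rep0 <- runner(config, layers, data = data)
  rep1 <- runner(config, layers, data = masked)
  W0 <- rep0$network$W
  W1 <- rep1$network$W
  ut <- upper.tri(W0)
  idx <- which(ut, arr.ind = TRUE)
  diffs <- data.frame(node_i = rownames(W0)[idx[, 1]],
                      node_j = colnames(W0)[idx[, 2]],
                      weight_original = W0[ut], weight_masked = W1[ut],
                      difference = W1[ut] - W0[ut],
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(original = rep0, masked = rep1, edge_differences = diffs,
                 n_masked = attr(masked, "n_masked")),
            class = "sensitivity_report")
}

new_run_report <- function(kind, layers, config, network, edge_summary,
                           centrality, community = NULL, stability = NULL) {
  cs <- if (!is.null(stability)) cs_coefficient(stability) else NULL
  structure(list(kind = kind, layers = layers, config = config,
                 network = network, edge_summary = edge_summary,
                 centrality = centrality, community = community,
                 stability = stability, cs = cs,
                 version = as.character(utils::packageVersion("bridgenet")),
                 seed = config$seed,
                 schema = "bridgenet-report/1"),
            class = "run_report")
}

maybe_write_report <- function(report) {
  if (!is.null(report$config$output_dir)) write_report(report)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("bridgenet %s run: layers = %s (seed %d)\n", x$kind,
              paste(x$layers, collapse = "+"), x$seed))
  print(x$edge_summary)
  if (!is.null(x$community)) print(x$community)
  central <- x$centrality$node[x$centrality$central]
  cat("Central nodes:",
      if (length(central)) paste(central, collapse = ", ") else "(none)",
      "\n")
  if (!is.null(x$cs))
    cat(sprintf("Centrality stability: CS = %.2f (%s)\n",
                as.numeric(x$cs), attr(x$cs, "label")))
  invisible(x)
}
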