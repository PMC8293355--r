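#' Calibrated population network presets
#'
#' Returns one of the planted population partial-correlation networks that
#' emulate the CALM study's statistical structure. The matrices are explicit
#' numeric fixtures shipped with the package (`inst/extdata/preset_*.csv`)
#' and are calibrated so that the summary statistics of the unique
#' off-diagonal non-age entries reproduce the published single-layer edge
#' summaries at two decimals:
#'
#' * `calm_cognitive` — 10 cognitive tasks + age; task-task edges have mean
#'   0.08, median 0.07, range 0 to 0.63, with the reading-spelling edge
#'   planted at 0.63 and every other edge in \[0, 0.27\].
#' * `calm_cv` — 10 cortical-volume ROIs + age; mean 0.09, median 0, range
#'   -0.15 to 0.52, with the caudal-middle-frontal-to-frontal-pole edge
#'   planted at -0.15.
#' * `calm_fa` — 10 fractional-anisotropy tracts + age; mean 0.08, median 0,
#'   range 0 to 0.44.
#' * `calm_trilayer` — the three layers concatenated (30 nodes + age) with
#'   small mixed-sign cross-layer edges (|p| <= 0.06) and attenuated age
#'   partials. Cross-layer values are calibration, not published ground
#'   truth.
#'
#' @param name one of `"calm_cognitive"`, `"calm_cv"`, `"calm_fa"`,
#'   `"calm_trilayer"`.
#' @return A [population_ggm].
#' @examples
#' g <- build_preset("calm_cognitive")
#' g$P["Read", "Spell"]  # 0.63
#' @export
build_preset <- function(name) {
  name <- match.arg(name, c("calm_cognitive", "calm_cv", "calm_fa",
                            "calm_trilayer"))
  path <- system.file("extdata", paste0("preset_", name, ".csv"),
                      package = "bridgenet", mustWork = TRUE)
  P <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  g <- population_ggm(P, preset_layer_map(rownames(P)))
  g$preset <- name
  g
}

#' Layer membership of the preset node labels
#' @param labels character vector of node names.
#' @return Named character vector of layer tags.
#' @keywords internal
preset_layer_map <- function(labels) {
  cog <- c("NO", "Read", "Spell", "Pea", "MR", "DR", "BDR", "Dot", "MrX", "FI")
  cv <- c("CAC", "CMF", "FP", "MOF", "RAC", "RMF", "SFG", "STG", "SMG", "TTG")
  fa <- c("ATR", "CST", "CING", "CINGh", "FMaj", "FMin", "IFOF", "ILF",
          "SLF", "UNC")
  layer <- ifelse(labels %in% cog, "cognition",
           ifelse(labels %in% cv, "grey",
           ifelse(labels %in% fa, "white",
           ifelse(labels == "Age", "age", NA_character_))))
  if (anyNA(layer))
    stop("unknown node labels: ", paste(labels[is.na(layer)], collapse = ", "))
  stats::setNames(layer, labels)
}

#' Missingness specification matching the study conditions
#'
#' Per-variable missing-completely-at-random rates for the cognitive tasks
#' (the published per-task missing-data percentages) and layer-nesting
#' proportions reproducing the nested sample sizes (behavioral 805, cortical
#' volume 246, fractional anisotropy 165). Neural variables carry no
#' cell-level missingness beyond the nesting; age is always observed.
#'
#' @param name preset name, as in [build_preset()].
#' @return A [missingness_spec].
#' @export
calm_missingness <- function(name) {
  name <- match.arg(name, c("calm_cognitive", "calm_cv", "calm_fa",
                            "calm_trilayer"))
  cog_rates <- c(NO = 0.0994, Read = 0.0248, Spell = 0.0335, Pea = 0.0112,
                 MR = 0.0012, DR = 0.0050, BDR = 0.0311, Dot = 0.0075,
                 MrX = 0.0124, FI = 0.0683)
  nesting <- c(cognition = 1, grey = 246 / 805, white = 165 / 805, age = 1)
  switch(name,
    calm_cognitive = missingness_spec(mcar = cog_rates,
                                      layer_fraction = c(cognition = 1, age = 1)),
    calm_cv = missingness_spec(layer_fraction = c(grey = 1, age = 1)),
    calm_fa = missingness_spec(layer_fraction = c(white = 1, age = 1)),
    calm_trilayer = missingness_spec(mcar = cog_rates,
                                     layer_fraction = nesting))
}
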