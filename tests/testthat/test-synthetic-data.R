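test_that("presets reproduce the published edge summaries and planted edges", {
  specs <- list(
    calm_cognitive = list(mean = 0.08, median = 0.07, min = 0, max = 0.63),
    calm_cv = list(mean = 0.09, median = 0, min = -0.15, max = 0.52),
    calm_fa = list(mean = 0.08, median = 0, min = 0, max = 0.44))
  for (nm in names(specs)) {
    g <- build_preset(nm)
    keep <- g$node_labels[g$layer_of != "age"]
    v <- g$P[keep, keep][upper.tri(g$P[keep, keep])]
    expect_equal(round(mean(v), 2), specs[[nm]]$mean, info = nm)
    expect_equal(round(median(v), 2), specs[[nm]]$median, info = nm)
    expect_equal(round(min(v), 2), specs[[nm]]$min, info = nm)
    expect_equal(round(max(v), 2), specs[[nm]]$max, info = nm)
    # implied precision is PD (population_ggm() would have refused otherwise)
    K <- diag(nrow(g$P)) - g$P
    expect_gt(min(eigen(K, only.values = TRUE)$values), 0)
  }
  cog <- build_preset("calm_cognitive")
  expect_equal(cog$P["Read", "Spell"], 0.63)
  keep <- setdiff(cog$node_labels, c("Age"))
  others <- cog$P[keep, keep][upper.tri(cog$P[keep, keep])]
  expect_true(all(others[others != 0.63] >= 0 & others[others != 0.63] <= 0.27))
  expect_equal(build_preset("calm_cv")$P["CMF", "FP"], -0.15)

  tri <- build_preset("calm_trilayer")
  expect_setequal(unique(tri$layer_of),
                  c("cognition", "grey", "white", "age"))
  # cross-layer edges small, mixed sign; age partials positive
  cross <- outer(tri$layer_of, tri$layer_of, FUN = "!=") &
    tri$layer_of[row(tri$P)] != "age" & tri$layer_of[col(tri$P)] != "age"
  cw <- tri$P[cross]
  expect_true(all(abs(cw) <= 0.2))
  expect_true(any(cw > 0) && any(cw < 0))
  expect_true(all(tri$P["Age", tri$layer_of != "age"] > 0))

  expect_error(build_preset("calm_unknown"))
})

test_that("pcor_to_covariance matches hand-derived identities", {
  # 2 nodes: partial equals marginal
  P2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(pcor_to_covariance(P2)["a", "b"], 0.5)
  # 3-node chain: hand inversion of the precision matrix gives
  # cor(A,C) = 1/3 and cor(A,B) = 1/sqrt(3)
  S <- chain_ggm()$Sigma
  expect_equal(S["A", "C"], 1 / 3, tolerance = 1e-12)
  expect_equal(S["A", "B"], 1 / sqrt(3), tolerance = 1e-12)
  # all-zero partials: independence
  P0 <- matrix(0, 3, 3, dimnames = dimnames(S))
  expect_equal(pcor_to_covariance(P0), diag(3), ignore_attr = TRUE)
  # invalid inputs
  Pbad <- matrix(0.9, 3, 3, dimnames = dimnames(S)); diag(Pbad) <- 0
  expect_error(pcor_to_covariance(Pbad), "positive definite")
  expect_error(pcor_to_covariance(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("covariance round trip reproduces every preset exactly", {
  for (nm in c("calm_cognitive", "calm_cv", "calm_fa", "calm_trilayer")) {
    g <- build_preset(nm)
    expect_lt(max(abs(covariance_to_pcor(g$Sigma) - g$P)), 1e-10)
  }
})

test_that("simulation is seed-deterministic and recovers the population", {
  g <- build_preset("calm_cognitive")
  d1 <- simulate_multilayer(g, n = 200, seed = 42)
  d2 <- simulate_multilayer(g, n = 200, seed = 42)
  expect_identical(d1$values, d2$values)
  d3 <- simulate_multilayer(g, n = 200, seed = 43)
  expect_false(identical(d1$values, d3$values))

  # large-n marginal correlations approach Sigma (per-entry SE ~ 1/sqrt(n);
  # 0.015 is ~3 SE at n = 50,000, across 66 unique entries)
  d <- simulate_multilayer(g, n = 50000, seed = 1)
  expect_lt(max(abs(cor(d$values) - g$Sigma)), 0.015)

  # unregularized partial correlations recover the planted network
  Pest <- covariance_to_pcor(cor(d$values))
  expect_lt(max(abs(Pest - g$P)), 0.02)
})

test_that("missingness honors per-variable MCAR rates and layer nesting", {
  g <- build_preset("calm_cognitive")
  spec <- missingness_spec(mcar = c(FI = 0.0683))
  d <- simulate_multilayer(g, n = 10000, miss = spec, seed = 5)
  expect_lt(abs(mean(is.na(d$values[, "FI"])) - 0.0683), 0.01)
  expect_true(all(!is.na(d$values[, "Read"])))

  tri <- build_preset("calm_trilayer")
  d <- simulate_multilayer(tri, n = 805, miss = calm_missingness("calm_trilayer"),
                           seed = 9)
  expect_equal(unname(d$n_layer[c("cognition", "grey", "white")]),
               c(805L, 246L, 165L))
  # whole-layer missingness: a subject lacking the grey layer has all grey
  # cells missing, and white is nested within grey
  grey_vars <- names(d$layer_of)[d$layer_of == "grey"]
  white_vars <- names(d$layer_of)[d$layer_of == "white"]
  grey_obs <- rowSums(!is.na(d$values[, grey_vars])) > 0
  white_obs <- rowSums(!is.na(d$values[, white_vars])) > 0
  expect_true(all(rowSums(is.na(d$values[!grey_obs, grey_vars])) ==
                    length(grey_vars)))
  expect_true(all(white_obs[white_obs] & grey_obs[white_obs]))

  expect_error(missingness_spec(mcar = c(FI = 1.2)), "\\[0, 1\\]")
  expect_warning(simulate_multilayer(g, n = 10, seed = 1), "downstream")
})

test_that("mask_outliers masks only cells beyond k SD and validates k", {
  g <- build_preset("calm_cognitive")
  d <- simulate_multilayer(g, n = 300, seed = 2)
  # force every cell within 4 SD, then inject one extreme cell
  X <- d$values
  X[abs(scale(X)) > 3.5] <- 0
  d <- multilayer_dataset(X, d$layer_of)
  m <- mean(X[, "NO"]); s <- sd(X[, "NO"])
  X[5, "NO"] <- m + 5 * s
  di <- multilayer_dataset(X, d$layer_of)
  masked <- mask_outliers(di, k = 4)
  expect_true(is.na(masked$values[5, "NO"]))
  expect_equal(sum(is.na(masked$values)) - sum(is.na(di$values)), 1)
  expect_equal(unname(attr(masked, "n_masked")["NO"]), 1L)
  # nothing beyond 4 SD: unchanged
  expect_identical(mask_outliers(d, k = 4)$values, d$values)
  expect_error(mask_outliers(d, k = 0), "positive")
  # zero-variance column skipped with a notice
  X2 <- d$values; X2[, "FI"] <- 1
  expect_message(mask_outliers(multilayer_dataset(X2, d$layer_of), k = 4),
                 "zero-variance")
})
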