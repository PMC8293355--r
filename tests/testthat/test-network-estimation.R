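test_that("pairwise deletion records pair counts and flags bad columns", {
  set.seed(1)
  n <- 805
  x <- rnorm(n)
  X <- cbind(a = x, b = x, c = rnorm(n))
  est <- pairwise_pearson(X)
  expect_equal(est$R["a", "b"], 1)
  expect_equal(est$Npair["a", "b"], n)
  expect_equal(est$n_effective, n)

  # two variables observed on overlapping blocks: Npair = overlap size
  X2 <- cbind(a = x, b = x + rnorm(n), c = rnorm(n))
  X2[501:805, "a"] <- NA   # a observed on 1:500
  X2[1:400, "b"] <- NA     # b observed on 401:805
  est2 <- pairwise_pearson(X2)
  expect_equal(est2$Npair["a", "b"], 100)
  expect_equal(est2$Npair["a", "a"], 500)
  expect_equal(est2$n_effective, n)
  expect_equal(pairwise_pearson(X2, n_effective = "min_pairwise")$n_effective,
               100)

  X3 <- cbind(a = x, const = rep(1, n))
  expect_error(pairwise_pearson(X3), "zero-variance column\\(s\\): const")

  X4 <- X2
  X4[401:500, "a"] <- NA  # overlap now empty -> below floor
  expect_error(pairwise_pearson(X4), "a-b")
})

test_that("nearest_psd repairs indefinite matrices and leaves PSD ones alone", {
  R <- diag(3)
  expect_identical(nearest_psd(R)[,], R)
  expect_equal(attr(nearest_psd(R), "psd_repair"), 0)

  # classic indefinite pairwise-deletion pattern
  R2 <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  expect_lt(min(eigen(R2, only.values = TRUE)$values), 0)
  R2fix <- nearest_psd(R2)
  expect_gte(min(eigen(R2fix, only.values = TRUE)$values), 0)
  expect_equal(unname(diag(R2fix)), rep(1, 3))
  expect_gt(attr(R2fix, "psd_repair"), 0)
})

test_that("an identity correlation matrix yields an exactly empty network", {
  R <- diag(5)
  dimnames(R) <- list(paste0("V", 1:5), paste0("V", 1:5))
  net <- ebic_glasso(R, n = 500)
  expect_true(all(net$W == 0))
  es <- edge_summary(net)
  expect_equal(es$n_nonzero, 0)
})

test_that("vanishing penalty reproduces direct-inversion partial correlations", {
  g <- build_preset("calm_cognitive")
  d <- simulate_multilayer(g, n = 5000, seed = 3)
  R <- pairwise_pearson(d)$R
  dense <- covariance_to_pcor(R)
  fit <- bridgenet:::glasso_path_cpp(R, 1e-7)
  expect_lt(max(abs(precision_to_pcor(fit$K[, , 1]) - dense)), 1e-4)
})

test_that("EBIC-glasso recovers the chain support with an exact zero", {
  d <- simulate_multilayer(chain_ggm(), n = 50000, seed = 1)
  net <- ebic_glasso(pairwise_pearson(d), gamma = 0.5)
  expect_gt(net$W["A", "B"], 0.4)
  expect_gt(net$W["B", "C"], 0.4)
  expect_identical(net$W["A", "C"], 0)
})

test_that("sparsity is monotone along the penalty path", {
  g <- build_preset("calm_cognitive")
  d <- simulate_multilayer(g, n = 2000, seed = 4)
  R <- pairwise_pearson(d)$R
  lambda_max <- max(abs(R[upper.tri(R)]))
  lambdas <- exp(seq(log(lambda_max), log(0.01 * lambda_max), length.out = 40))
  fit <- bridgenet:::glasso_path_cpp(R, lambdas)
  counts <- vapply(seq_along(lambdas), function(i) {
    K <- fit$K[, , i]
    sum(K[upper.tri(K)] != 0)
  }, numeric(1))
  # lambdas are descending, so counts grow as the penalty relaxes; lasso
  # active sets allow transient single-edge exits, nothing more
  expect_true(all(diff(counts) >= -1))
  expect_true(all(cummax(counts) - counts <= 1))
  expect_gte(counts[length(counts)], counts[1])
})

test_that("estimation is invariant to variable order", {
  g <- build_preset("calm_cognitive")
  d <- simulate_multilayer(g, n = 1500, seed = 8)
  net <- ebic_glasso(pairwise_pearson(d), gamma = 0.5)
  perm <- sample(ncol(d$values))
  dp <- multilayer_dataset(d$values[, perm], d$layer_of)
  netp <- ebic_glasso(pairwise_pearson(dp), gamma = 0.5)
  # agreement down to the solver's convergence tolerance
  expect_lt(max(abs(netp$W[rownames(net$W), colnames(net$W)] - net$W)), 1e-5)
})

test_that("large-n estimation recovers the planted support", {
  g <- build_preset("calm_cognitive")
  d <- simulate_multilayer(g, n = 100000, seed = 3)
  net <- ebic_glasso(pairwise_pearson(d), gamma = 0.5)
  ut <- upper.tri(g$P)
  # every planted edge of at least 0.05 is detected
  expect_equal(sum(abs(g$P[ut]) >= 0.05 & net$W[ut] == 0), 0)
  # spurious edges admitted by the vanishing penalty are negligible in size
  fp <- net$W[ut][g$P[ut] == 0]
  expect_true(all(abs(fp) < 0.015))
})

test_that("edge summaries follow the reporting convention", {
  W <- matrix(0, 4, 4,
              dimnames = list(c("a", "b", "c", "Age"), c("a", "b", "c", "Age")))
  W["a", "b"] <- W["b", "a"] <- 0.63
  W["a", "c"] <- W["c", "a"] <- 0.27
  W["a", "Age"] <- W["Age", "a"] <- 0.5  # age edges never enter summaries
  es <- edge_summary(pcor_network(W))
  expect_equal(es$mean, 0.3)
  expect_equal(es$median, 0.27)
  expect_equal(c(es$min, es$max), c(0, 0.63))
  expect_equal(es$n_nonzero, 2)

  # network whose only edges touch age summarizes to all zeros
  W2 <- matrix(0, 4, 4, dimnames = dimnames(W))
  W2["a", "Age"] <- W2["Age", "a"] <- 0.4
  es2 <- edge_summary(pcor_network(W2))
  expect_equal(unlist(es2[c("mean", "median", "min", "max", "n_nonzero")]),
               c(mean = 0, median = 0, min = 0, max = 0, n_nonzero = 0))
})
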