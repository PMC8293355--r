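# Fixtures are generated in code; no data files.

# Random sparse symmetric weight matrix (mixed signs, zero diagonal).
rand_weight_matrix <- function(p, density = 0.4, seed = 1) {
  set.seed(seed)
  W <- matrix(0, p, p)
  ut <- which(upper.tri(W))
  on <- sample(ut, round(density * length(ut)))
  W[on] <- round(stats::runif(length(on), -0.3, 0.5), 3)
  W <- W + t(W)
  dimnames(W) <- list(paste0("V", 1:p), paste0("V", 1:p))
  W
}

# Two dense blocks of sizes n1, n2 with uniform weight w, optionally joined
# by a single bridge edge between the last node of block 1 and the first of
# block 2.
block_matrix <- function(n1, n2, w = 1, bridge = 0) {
  p <- n1 + n2
  W <- matrix(0, p, p)
  W[1:n1, 1:n1] <- w
  W[(n1 + 1):p, (n1 + 1):p] <- w
  diag(W) <- 0
  if (bridge > 0) W[n1, n1 + 1] <- W[n1 + 1, n1] <- bridge
  dimnames(W) <- list(letters[1:p], letters[1:p])
  W
}

# Three-node chain GGM: A - B - C with both partial correlations 0.5.
chain_ggm <- function() {
  P <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  P["A", "B"] <- P["B", "A"] <- 0.5
  P["B", "C"] <- P["C", "B"] <- 0.5
  population_ggm(P, stats::setNames(rep("cognition", 3), c("A", "B", "C")))
}

# All set partitions of 1..n as integer membership vectors (restricted
# growth strings); Bell(8) = 4140 so exhaustive search stays fast.
enumerate_partitions <- function(n) {
  out <- list()
  recurse <- function(ids, k) {
    i <- length(ids) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- ids
      return(invisible())
    }
    for (c_id in seq_len(k + 1L)) recurse(c(ids, c_id), max(k, c_id))
  }
  recurse(integer(0), 0L)
  out
}

# Exhaustive maximum modularity over all partitions of a small graph.
# Newman's Q evaluated directly so the 4000+ evaluations stay fast; the
# formula is cross-checked against modularity_q() in the community tests.
exhaustive_max_modularity <- function(W) {
  labels <- rownames(W)
  A <- abs(W)
  m <- sum(A) / 2
  d <- rowSums(A)
  qfun <- function(ids) {
    q <- 0
    for (c_id in unique(ids)) {
      idx <- ids == c_id
      q <- q + sum(A[idx, idx]) / (2 * m) - (sum(d[idx]) / (2 * m))^2
    }
    q
  }
  parts <- enumerate_partitions(nrow(W))
  qs <- vapply(parts, qfun, numeric(1))
  best <- which.max(qs)
  list(Q = qs[best], assignment = stats::setNames(parts[[best]], labels))
}

# Same partition up to community relabelling?
same_partition <- function(a, b) {
  a <- a[sort(names(a))]
  b <- b[sort(names(b))]
  identical(match(a, unique(a)), match(b, unique(b)))
}

# Minimal stability_report for unit-testing cs_coefficient on known
# correlation patterns.
fake_stability_report <- function(cors, fractions) {
  structure(list(fractions = fractions, cors = cors, B = nrow(cors),
                 cor_method = "spearman",
                 full = stats::setNames(1:5, paste0("V", 1:5)),
                 n = 100L),
            class = "stability_report")
}
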