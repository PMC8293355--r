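# Construct the planted population partial-correlation matrices, verify their
# calibration against the published single-layer edge summaries (mean, median,
# range at 2 dp; planted marker edges), check positive definiteness, and freeze
# them to inst/extdata CSVs. Run from the package root:
#   Rscript data-raw/make_presets.R write

cog_nodes <- c("NO", "Read", "Spell", "Pea", "MR", "DR", "BDR", "Dot", "MrX", "FI")
cv_nodes  <- c("CAC", "CMF", "FP", "MOF", "RAC", "RMF", "SFG", "STG", "SMG", "TTG")
fa_nodes  <- c("ATR", "CST", "CING", "CINGh", "FMaj", "FMin", "IFOF", "ILF", "SLF", "UNC")

edge <- function(i, j, w) data.frame(i = i, j = j, w = w, stringsAsFactors = FALSE)

cog_edges <- rbind(
  edge("Read", "Spell", 0.63),
  edge("DR", "BDR", 0.27),
  edge("Dot", "MrX", 0.21),
  edge("Read", "Pea", 0.16),
  edge("NO", "Read", 0.15),
  edge("NO", "MR", 0.13),
  edge("BDR", "Dot", 0.12),
  edge("Spell", "Pea", 0.12),
  edge("NO", "Pea", 0.11),
  edge("DR", "Dot", 0.10),
  edge("MR", "Dot", 0.10),
  edge("DR", "FI", 0.10),
  edge("BDR", "MrX", 0.09),
  edge("MR", "Pea", 0.09),
  edge("NO", "Spell", 0.08),
  edge("BDR", "FI", 0.08),
  edge("NO", "Dot", 0.08),
  edge("MR", "MrX", 0.08),
  edge("MrX", "FI", 0.07),
  edge("DR", "MrX", 0.07),
  edge("Dot", "FI", 0.07),
  edge("Pea", "FI", 0.07),
  edge("Read", "MR", 0.07),
  edge("NO", "FI", 0.07),
  edge("Read", "DR", 0.06),
  edge("MR", "BDR", 0.06),
  edge("Spell", "BDR", 0.05),
  edge("Pea", "DR", 0.05),
  edge("NO", "BDR", 0.04),
  edge("Read", "BDR", 0.04),
  edge("MR", "DR", 0.04),
  edge("Read", "FI", 0.03),
  edge("NO", "MrX", 0.03),
  edge("Spell", "MR", 0.03),
  edge("Pea", "Dot", 0.02),
  edge("Spell", "DR", 0.02),
  edge("Pea", "MrX", 0.02)
)

cv_edges <- rbind(
  edge("STG", "TTG", 0.52),
  edge("CMF", "FP", -0.15),
  edge("CAC", "RAC", 0.38),
  edge("CMF", "RMF", 0.36),
  edge("RMF", "SFG", 0.34),
  edge("STG", "SMG", 0.32),
  edge("MOF", "RAC", 0.30),
  edge("SFG", "CMF", 0.26),
  edge("SMG", "TTG", 0.20),
  edge("RAC", "RMF", 0.17),
  edge("SFG", "STG", 0.16),
  edge("MOF", "CMF", 0.14),
  edge("CAC", "SFG", 0.14),
  edge("SMG", "RMF", 0.12),
  edge("MOF", "FP", 0.12),
  edge("FP", "RMF", 0.10),
  edge("STG", "MOF", 0.10),
  edge("RAC", "SFG", 0.09),
  edge("TTG", "CAC", 0.08),
  edge("CAC", "CMF", 0.08),
  edge("SMG", "CAC", 0.05),
  edge("MOF", "SFG", 0.04)
)

fa_edges <- rbind(
  edge("ILF", "IFOF", 0.44),
  edge("SLF", "ILF", 0.30),
  edge("ATR", "FMin", 0.28),
  edge("CING", "CINGh", 0.26),
  edge("UNC", "IFOF", 0.25),
  edge("ATR", "CST", 0.22),
  edge("FMaj", "ILF", 0.20),
  edge("SLF", "CST", 0.18),
  edge("ATR", "CING", 0.16),
  edge("UNC", "ATR", 0.15),
  edge("FMin", "IFOF", 0.14),
  edge("CINGh", "ILF", 0.12),
  edge("FMaj", "FMin", 0.12),
  edge("SLF", "IFOF", 0.11),
  edge("UNC", "CINGh", 0.10),
  edge("CST", "CING", 0.09),
  edge("ATR", "SLF", 0.08),
  edge("FMin", "UNC", 0.08),
  edge("FMaj", "CST", 0.06),
  edge("CING", "SLF", 0.06),
  edge("ILF", "UNC", 0.05),
  edge("CINGh", "FMaj", 0.04)
)

age_cog <- c(NO = 0.15, Read = 0.15, Spell = 0.08, Pea = 0.10, MR = 0.12,
             DR = 0.08, BDR = 0.06, Dot = 0.08, MrX = 0.06, FI = 0.05)
age_cv  <- c(CAC = 0.06, CMF = 0.08, FP = 0.10, MOF = 0.06, RAC = 0.06,
             RMF = 0.08, SFG = 0.10, STG = 0.08, SMG = 0.06, TTG = 0.05)
age_fa  <- c(ATR = 0.12, CST = 0.08, CING = 0.08, CINGh = 0.06, FMaj = 0.06,
             FMin = 0.12, IFOF = 0.10, ILF = 0.10, SLF = 0.08, UNC = 0.08)

cross_edges <- rbind(
  # cognition - grey matter
  edge("Read", "STG", 0.06), edge("Pea", "STG", 0.06), edge("NO", "RMF", 0.06),
  edge("MR", "RMF", 0.06), edge("Dot", "SFG", 0.05), edge("DR", "STG", 0.04),
  edge("Spell", "SMG", 0.04), edge("FI", "CMF", -0.05), edge("MR", "SFG", 0.05),
  edge("NO", "SFG", 0.04),
  # cognition - white matter
  edge("Read", "ILF", 0.05), edge("Pea", "UNC", 0.06), edge("NO", "FMin", 0.06),
  edge("MR", "FMin", 0.05), edge("DR", "SLF", 0.04), edge("FI", "FMin", -0.04),
  edge("Dot", "CINGh", 0.04), edge("Spell", "IFOF", 0.04),
  # grey matter - white matter
  edge("STG", "ILF", 0.06), edge("RMF", "FMin", 0.06), edge("SFG", "ATR", 0.06),
  edge("CAC", "CING", 0.06), edge("SMG", "SLF", 0.05), edge("MOF", "UNC", 0.05),
  edge("FP", "FMin", -0.04), edge("TTG", "IFOF", 0.04)
)

# In the 31-node network the conditioning set is three times larger, so the
# age partials are scaled down relative to the single-layer presets.
tri_age_scale <- 0.4

build_P <- function(nodes, edges) {
  P <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    P[edges$i[k], edges$j[k]] <- edges$w[k]
    P[edges$j[k], edges$i[k]] <- edges$w[k]
  }
  P
}

summ <- function(P, non_age) {
  v <- P[non_age, non_age][upper.tri(P[non_age, non_age])]
  c(mean = mean(v), median = median(v), min = min(v), max = max(v),
    n_nonzero = sum(v != 0), second_max = sort(v, decreasing = TRUE)[2])
}

check_pd <- function(P, label) {
  K <- diag(nrow(P)) - P
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  cat(sprintf("%-16s min eig(K) = %.4f  %s\n", label, min(ev),
              if (min(ev) > 0) "PD" else "NOT PD"))
  min(ev)
}

layer_P <- function(nodes, edges, age_p) {
  all_nodes <- c(nodes, "Age")
  e <- rbind(edges, do.call(rbind, lapply(nodes, function(n) edge(n, "Age", age_p[[n]]))))
  build_P(all_nodes, e)
}

P_cog <- layer_P(cog_nodes, cog_edges, age_cog)
P_cv  <- layer_P(cv_nodes, cv_edges, age_cv)
P_fa  <- layer_P(fa_nodes, fa_edges, age_fa)

tri_nodes <- c(cog_nodes, cv_nodes, fa_nodes, "Age")
tri_edges <- rbind(cog_edges, cv_edges, fa_edges, cross_edges,
                   do.call(rbind, lapply(cog_nodes, function(n) edge(n, "Age", tri_age_scale * age_cog[[n]]))),
                   do.call(rbind, lapply(cv_nodes, function(n) edge(n, "Age", tri_age_scale * age_cv[[n]]))),
                   do.call(rbind, lapply(fa_nodes, function(n) edge(n, "Age", tri_age_scale * age_fa[[n]]))))
P_tri <- build_P(tri_nodes, tri_edges)

cat("cognitive summary (non-age):\n"); print(round(summ(P_cog, cog_nodes), 4))
cat("rounded mean/median:", round(summ(P_cog, cog_nodes)[1:2], 2), "\n")
cat("cv summary:\n"); print(round(summ(P_cv, cv_nodes), 4))
cat("rounded mean/median:", round(summ(P_cv, cv_nodes)[1:2], 2), "\n")
cat("fa summary:\n"); print(round(summ(P_fa, fa_nodes), 4))
cat("rounded mean/median:", round(summ(P_fa, fa_nodes)[1:2], 2), "\n")

check_pd(P_cog, "calm_cognitive")
check_pd(P_cv, "calm_cv")
check_pd(P_fa, "calm_fa")
check_pd(P_tri, "calm_trilayer")

# freeze if all good
args <- commandArgs(trailingOnly = TRUE)
if (length(args) && args[1] == "write") {
  dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
  wr <- function(P, f) write.csv(as.data.frame(P), file.path("inst/extdata", f))
  wr(P_cog, "preset_calm_cognitive.csv")
  wr(P_cv, "preset_calm_cv.csv")
  wr(P_fa, "preset_calm_fa.csv")
  wr(P_tri, "preset_calm_trilayer.csv")
  cat("written\n")
}
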