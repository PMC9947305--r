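# Shared fixtures and independent oracles, all built in code.

# Planted haplotype-survival data mirroring the low-survival {L,N,P} motif:
# CYP9Q3 in {L,N,P} lowers survival, CYP9Q1 in {B,E} lowers it further
# within that group, CYP9Q2 is pure noise.
gen_planted_tree_data <- function(seed, n = 1200,
                                  p_high = 0.95, p_mid = 0.70, p_low = 0.10) {
  set.seed(seed)
  q1 <- sample(c("wt", "A", "B", "D", "E", "F"), n, TRUE)
  q2 <- sample(c("wt", "G", "H", "I"), n, TRUE)
  q3 <- sample(c("wt", "K", "L", "M", "N", "O", "P"), n, TRUE)
  p <- ifelse(q3 %in% c("L", "N", "P"),
              ifelse(q1 %in% c("B", "E"), p_low, p_mid), p_high)
  list(y = stats::rbinom(n, 1, p),
       X = data.frame(CYP9Q1 = q1, CYP9Q2 = q2, CYP9Q3 = q3,
                      stringsAsFactors = FALSE))
}

# Exhaustive oracle for the best binary split of one categorical predictor
# by Gini impurity decrease: enumerate all 2^(k-1) - 1 bipartitions.
oracle_best_gini_gain <- function(y, g, min_bucket = 1) {
  lev <- sort(unique(g))
  k <- length(lev)
  gini <- function(ns, n) if (n == 0) 0 else {
    p <- ns / n; n * (1 - p^2 - (1 - p)^2)
  }
  parent <- gini(sum(y), length(y))
  best <- -Inf
  for (code in seq_len(2^(k - 1) - 1)) {
    inL <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1)))
    left <- g %in% lev[inL]
    nl <- sum(left); nr <- sum(!left)
    if (nl < min_bucket || nr < min_bucket) next
    gain <- parent - gini(sum(y[left]), nl) - gini(sum(y[!left]), nr)
    if (gain > best) best <- gain
  }
  best
}

# Independent asymptotic (infinite-workers) truth for the patriline share
# of binomial deviance under the logit-normal generative model, by
# numerical integration over colony and patriline effects.
truth_h2_logitnormal <- function(sigma_patriline, mu, sigma_colony = 0.35,
                                 n_grid = 20000, n_col_grid = 101) {
  if (sigma_patriline == 0) return(0)
  hdev <- function(p) -2 * (p * log(p) + (1 - p) * log(1 - p))
  uq <- stats::qnorm((seq_len(n_grid) - 0.5) / n_grid)
  uc <- stats::qnorm((seq_len(n_col_grid) - 0.5) / n_col_grid) * sigma_colony
  pj <- stats::plogis(mu + outer(uc, sigma_patriline * uq, "+"))
  num <- mean(apply(pj, 1, function(r) hdev(mean(r)) - mean(hdev(r))))
  den <- mean(apply(pj, 1, function(r) hdev(mean(r))))
  2 * num / den
}

# Tiny genotype CSV writers for the IO tests.
write_pair_dialect_csv <- function(path, rows) {
  writeLines(rows, path)
  path
}
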