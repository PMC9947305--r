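#' Pearson chi-squared test with optional Monte Carlo p value
#'
#' Pearson's chi-squared test on a contingency table of counts. For 2x2
#' tables the Yates continuity correction is applied by default (the
#' convention of the source analysis); set `yates = FALSE` for the raw
#' statistic. When `monte_carlo_B` is given, a Monte Carlo p value is also
#' computed from tables sampled uniformly conditional on both margins
#' (Patefield's algorithm), as
#' `p = (1 + #\{replicate chi-squared >= observed\}) / (B + 1)` using the
#' uncorrected statistic on both sides.
#'
#' @param tab matrix of non-negative integer counts, at least 2x2.
#' @param yates apply continuity correction on 2x2 tables (default TRUE).
#' @param monte_carlo_B replicate count for the Monte Carlo p (e.g. 5000),
#'   or `NULL` to skip.
#' @param seed seed for the Monte Carlo replicates.
#' @return object of class `contingency_result`: list with `statistic`,
#'   `df`, `p_value`, `yates`, and (if requested) `mc_p`, `mc_B`.
#' @export
chisq_test <- function(tab, yates = TRUE, monte_carlo_B = NULL, seed = 1L) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("zero margin in table")
  correct <- yates && nrow(tab) == 2L && ncol(tab) == 2L
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  res <- list(statistic = unname(ct$statistic), df = unname(ct$parameter),
              p_value = unname(ct$p.value), yates = correct)
  if (!is.null(monte_carlo_B)) {
    B <- as.integer(monte_carlo_B)
    stopifnot(B >= 1L)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat_fun <- function(m) sum((m - expected)^2 / expected)
    obs <- stat_fun(tab)
    res$mc_p <- with_seed(seed, {
      reps <- stats::r2dtable(B, rowSums(tab), colSums(tab))
      hits <- sum(vapply(reps, stat_fun, numeric(1)) >= obs - 1e-12)
      (1 + hits) / (B + 1)
    })
    res$mc_B <- B
  }
  structure(res, class = "contingency_result")
}

# Binomial deviance of observations y (proportions) with trial weights w
# against fitted probabilities p, with 0*log(0) := 0.
binomial_deviance <- function(y, p, w = rep(1, length(y))) {
  term <- function(a, b) ifelse(a > 0, a * log(a / b), 0)
  2 * sum(w * (term(y, p) + term(1 - y, 1 - p)))
}

#' Fit a single-factor Bernoulli/binomial logit model
#'
#' For a factor-only design the maximum-likelihood fitted probability of
#' each cell is the cell's (weighted) observed proportion, so the deviance
#' has a closed form; `method = "cells"` computes it directly. An iterative
#' reweighted fit through `stats::glm` is available as `method = "irls"`
#' and agrees with the closed form to high precision on factor-only
#' designs. Perfectly separated cells (all-0 / all-1) contribute zero
#' deviance.
#'
#' @param y outcomes: 0/1 per bee, or proportions with `weights` = trials.
#' @param f factor (one label per row of `y`).
#' @param weights binomial trial counts (default 1 per row).
#' @param method `"cells"` (closed form, default) or `"irls"`.
#' @return list with `deviance`, `fitted` (named per-level probabilities),
#'   `n_levels`.
#' @export
fit_factor_logit <- function(y, f, weights = NULL, method = c("cells", "irls")) {
  method <- match.arg(method)
  f <- if (is.factor(f)) f else factor(as.character(f))
  if (is.logical(y)) y <- as.numeric(y)
  w <- weights %||% rep(1, length(y))
  stopifnot(length(y) == length(f), length(w) == length(y))
  if (any(tabulate(f, nlevels(f)) == 0L)) stop("empty factor level")
  if (method == "cells") {
    phat <- vapply(split(seq_along(y), f), function(ix)
      sum(w[ix] * y[ix]) / sum(w[ix]), numeric(1))
    dev <- binomial_deviance(y, phat[as.integer(f)], w)
  } else {
    fit <- suppressWarnings(
      stats::glm(y ~ f, family = stats::binomial(), weights = w,
                 control = stats::glm.control(epsilon = 1e-14, maxit = 200)))
    phat <- vapply(split(fit$fitted.values, f), mean, numeric(1))
    dev <- fit$deviance
  }
  list(deviance = dev, fitted = phat, n_levels = nlevels(f))
}

#' Partition binomial deviance over colony and patriline, estimate H2
#'
#' Fits the nested model sequence intercept-only, colony, and
#' patriline-within-colony to per-bee 24-h survival by exact cell-mean
#' maximum likelihood, and partitions the null deviance D0 into the share
#' explained by colony, the share explained by patriline within colony, and
#' the residual (bees within patrilines). For haplodiploid patriline
#' designs broad-sense heritability is twice the patriline share of
#' phenotypic (here: deviance) variation: `H2 = 2 * patriline_share`.
#'
#' Because the patriline term spends one parameter per patriline, its raw
#' deviance share carries positive finite-sample bias (approximately its
#' degrees of freedom divided by D0 under the null); a df-corrected share
#' `(delta deviance - delta df) / D0`, floored at zero, and the
#' corresponding `h2_corrected` are reported alongside the raw values, as
#' is the classical adjusted-D2 variant
#' `1 - ((n - 1)/(n - p)) * (1 - D2)` of each model's explained deviance.
#'
#' @param y survival outcomes (0/1 or logical) per bee.
#' @param colony colony label per bee.
#' @param patriline patriline label per bee; each patriline must lie in a
#'   single colony (labels need not be globally unique in that case — they
#'   are checked).
#' @param weights optional binomial trial counts (for aggregated rows).
#' @return object of class `deviance_partition`: list with `D0`, `D1`,
#'   `D2`, `share_colony`, `share_patriline`, `share_residual`,
#'   `h2` (raw, = 2 x patriline share), `h2_clamped` (into `[0, 1]`),
#'   `share_patriline_corrected`, `h2_corrected`, `adjusted_d2`
#'   (per model), `n`, `params` (per model), `df` (per term).
#' @export
partition_deviance <- function(y, colony, patriline, weights = NULL) {
  if (is.logical(y)) y <- as.numeric(y)
  colony <- as.character(colony); patriline <- as.character(patriline)
  stopifnot(length(y) == length(colony), length(y) == length(patriline))
  span <- tapply(colony, patriline, function(x) length(unique(x)))
  if (any(span > 1L))
    stop("patriline(s) span multiple colonies (nesting violated): ",
         paste(names(span)[span > 1L], collapse = ", "))
  w <- weights %||% rep(1, length(y))
  cell <- paste(colony, patriline, sep = "\r")
  D0 <- fit_factor_logit(y, rep("all", length(y)), w)$deviance
  D1 <- fit_factor_logit(y, colony, w)$deviance
  D2 <- fit_factor_logit(y, cell, w)$deviance
  p0 <- 1L; p1 <- length(unique(colony)); p2 <- length(unique(cell))
  share_colony <- (D0 - D1) / D0
  share_patriline <- (D1 - D2) / D0
  share_residual <- D2 / D0
  df_pat <- p2 - p1
  share_pat_corr <- max(0, (D1 - D2 - df_pat) / D0)
  n <- sum(w)
  adj <- function(D, p) 1 - ((n - 1) / (n - p)) * (D / D0)
  out <- list(
    D0 = D0, D1 = D1, D2 = D2,
    share_colony = share_colony,
    share_patriline = share_patriline,
    share_residual = share_residual,
    h2 = h2_from_patriline_share(share_patriline),
    h2_clamped = min(1, max(0, h2_from_patriline_share(share_patriline))),
    share_patriline_corrected = share_pat_corr,
    h2_corrected = h2_from_patriline_share(share_pat_corr),
    adjusted_d2 = c(colony = adj(D1, p1), patriline = adj(D2, p2)),
    n = n, params = c(null = p0, colony = p1, patriline = p2),
    df = c(colony = p1 - p0, patriline = df_pat)
  )
  structure(out, class = "deviance_partition")
}

#' Broad-sense heritability from a patriline deviance share
#'
#' In a haplodiploid patriline design, broad-sense heritability is twice
#' the share of phenotypic variation explained by patriline.
#'
#' @param share patriline share of the null deviance (proportion).
#' @return `2 * share`.
#' @export
h2_from_patriline_share <- function(share) 2 * share

#' Build a deviance partition from reported shares
#'
#' Constructs a `deviance_partition` from colony/patriline/residual shares
#' (e.g. values read off a published partition) so downstream summaries,
#' including the H2 doubling rule, run through the same code path as
#' partitions fitted from data.
#'
#' @param share_colony,share_patriline,share_residual shares summing to 1.
#' @param tol tolerance on the sum.
#' @return a `deviance_partition` (deviances unset).
#' @export
partition_from_shares <- function(share_colony, share_patriline, share_residual,
                                  tol = 1e-6) {
  if (abs(share_colony + share_patriline + share_residual - 1) > tol)
    stop("shares must sum to 1")
  structure(list(
    D0 = NA_real_, D1 = NA_real_, D2 = NA_real_,
    share_colony = share_colony, share_patriline = share_patriline,
    share_residual = share_residual,
    h2 = h2_from_patriline_share(share_patriline),
    h2_clamped = min(1, max(0, h2_from_patriline_share(share_patriline)))
  ), class = "deviance_partition")
}

#' @export
print.deviance_partition <- function(x, ...) {
  cat("Deviance partition (binomial logit)\n")
  cat(sprintf("  colony:    %5.1f%%\n", 100 * x$share_colony))
  cat(sprintf("  patriline: %5.1f%%\n", 100 * x$share_patriline))
  cat(sprintf("  residual:  %5.1f%%\n", 100 * x$share_residual))
  cat(sprintf("  H2 = 2 x patriline share = %.1f%%\n", 100 * x$h2))
  invisible(x)
}

#' Drop workers in small patrilines
#'
#' Restricts an analysis to patrilines with at least `min_n` tested bees
#' (the "at least five workers" robustness rule).
#'
#' @param data data.frame with a `patriline` column (one row per bee).
#' @param min_n minimum tested bees per patriline (default 5).
#' @return filtered data.frame; attribute `n_patrilines_kept`.
#' @export
filter_min_workers <- function(data, min_n = 5) {
  stopifnot(min_n >= 1)
  sizes <- table(data$patriline)
  keep <- names(sizes)[sizes >= min_n]
  out <- data[data$patriline %in% keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no patriline reaches ", min_n, " tested bees")
  attr(out, "n_patrilines_kept") <- length(keep)
  out
}

#' Type-II analysis of deviance for a binomial GLM
#'
#' For each term, the likelihood-ratio chi-squared comparing the full
#' additive model with the model lacking that term; degrees of freedom are
#' the difference in estimable parameters. Appropriate for unbalanced
#' designs. A term aliased with the others gets df 0, LR 0, p 1 and a flag.
#'
#' @param y outcomes (0/1, logical, or proportions with `weights` trials).
#' @param terms named list of factors (model terms), one value per row.
#' @param weights optional binomial trial counts.
#' @return data.frame with columns `term`, `lr_chisq`, `df`, `p`, `aliased`.
#' @export
anodev_type2 <- function(y, terms, weights = NULL) {
  stopifnot(is.list(terms), !is.null(names(terms)), all(nzchar(names(terms))))
  if (is.logical(y)) y <- as.numeric(y)
  w <- weights %||% rep(1, length(y))
  dat <- data.frame(.y = y, lapply(terms, function(t) factor(as.character(t))),
                    check.names = FALSE)
  fit_dev <- function(nms) {
    # constant factors carry no parameters; dropping them keeps glm happy
    # and makes the aliasing flag fall out of the rank difference
    nms <- nms[vapply(nms, function(nm) nlevels(dat[[nm]]) >= 2L, logical(1))]
    form <- if (length(nms))
      stats::as.formula(paste(".y ~", paste(sprintf("`%s`", nms), collapse = " + ")))
    else stats::as.formula(".y ~ 1")
    fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                       data = dat, weights = w))
    c(dev = fit$deviance, rank = fit$rank)
  }
  full <- fit_dev(names(terms))
  rows <- lapply(names(terms), function(tm) {
    red <- fit_dev(setdiff(names(terms), tm))
    lr <- red[["dev"]] - full[["dev"]]
    df <- full[["rank"]] - red[["rank"]]
    aliased <- df <= 0L
    if (aliased) { lr <- 0; df <- 0L; p <- 1 }
    else p <- stats::pchisq(lr, df, lower.tail = FALSE)
    data.frame(term = tm, lr_chisq = max(0, lr), df = df, p = p,
               aliased = aliased, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson product-moment correlation test
#'
#' Sample correlation with the exact t-from-r identity
#' `t = r * sqrt(df / (1 - r^2))`, `df = n - 2`, and a two-sided p value
#' from the t distribution.
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @return list with `r`, `t`, `df`, `p_value`.
#' @export
pearson_cor_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3, all(is.finite(c(x, y))))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in input")
  r <- stats::cor(x, y)
  df <- length(x) - 2L
  t <- cor_t_from_r(r, df)
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  list(r = r, t = t, df = df, p_value = p)
}

#' t statistic implied by a correlation coefficient
#'
#' @param r correlation.
#' @param df residual degrees of freedom (n - 2).
#' @return `r * sqrt(df / (1 - r^2))` (infinite at |r| = 1).
#' @export
cor_t_from_r <- function(r, df) {
  if (abs(r) >= 1) return(sign(r) * Inf)
  r * sqrt(df / (1 - r^2))
}
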