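#!/usr/bin/env Rscript
# Step 3 -- contingency tests and the broad-sense heritability estimate.
#
# Colony difference in 24-h mortality (Yates-corrected 2x2 chi-squared with
# a fixed-margins Monte Carlo companion), per-colony patriline effect, and
# the nested binomial deviance partition giving H2 = 2 x patriline share,
# repeated with the >= 5 workers per patriline filter.
source("analysis/00_common.R")

pheno <- read_phenotypes(file.path(RESULTS, "phenotypes.csv"))
assignment <- utils::read.csv(file.path(RESULTS, "patrilines.csv"))
kept <- filter_phenotypes(pheno[pheno$dose_group == "lethal", ])
dat <- merge(kept, assignment, by = "worker_id")

colonies <- sort(unique(dat$colony))
tab <- t(vapply(colonies, function(cc) {
  d <- dat[dat$colony == cc, ]
  c(died = sum(!d$survived), survived = sum(d$survived))
}, numeric(2)))
ct <- chisq_test(tab, yates = TRUE, monte_carlo_B = 5000,
                 seed = fanout_seed(SEED, 31))
cat(sprintf("colony mortality: chi2 = %.3f, df = %d, p = %.4f (MC p = %.4f)\n",
            ct$statistic, ct$df, ct$p_value, ct$mc_p))

for (cc in colonies) {
  d <- dat[dat$colony == cc, ]
  pt <- chisq_test(as.matrix(table(d$patriline, factor(d$survived, c(FALSE, TRUE)))),
                   yates = FALSE, monte_carlo_B = 5000,
                   seed = fanout_seed(SEED, 32))
  cat(sprintf("%s patriline effect: chi2 = %.3f, df = %d, MC p = %.4f\n",
              cc, pt$statistic, pt$df, pt$mc_p))
}

part <- partition_deviance(dat$survived, dat$colony, dat$patriline)
print(part)
cat(sprintf("  df-corrected patriline share %.1f%% -> H2 = %.1f%%\n",
            100 * part$share_patriline_corrected, 100 * part$h2_corrected))

dat5 <- filter_min_workers(dat, 5)
part5 <- partition_deviance(dat5$survived, dat5$colony, dat5$patriline)
cat(sprintf("patrilines with >= 5 tested bees (%d patrilines):\n",
            attr(dat5, "n_patrilines_kept")))
print(part5)

report <- list(
  colony_chisq = unclass(ct),
  partition_full = unclass(part)[c("share_colony", "share_patriline",
                                   "share_residual", "h2", "h2_corrected")],
  partition_min5 = unclass(part5)[c("share_colony", "share_patriline",
                                    "share_residual", "h2", "h2_corrected")])
jsonlite::write_json(report, file.path(RESULTS, "heritability.json"),
                     auto_unbox = TRUE, digits = 10)
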