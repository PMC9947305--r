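#!/usr/bin/env Rscript
# Step 5 -- haplotype-survival association.
#
# Weighted binomial GLM of patriline mean survival on per-gene haplotypes
# (type-II analysis of deviance, haplotypes alongside colony), then a
# bee-level classification tree with cost-complexity pruning at the
# minimum cross-validated error.
source("analysis/00_common.R")

pheno <- read_phenotypes(file.path(RESULTS, "phenotypes.csv"))
assignment <- utils::read.csv(file.path(RESULTS, "patrilines.csv"))
labels <- utils::read.csv(file.path(RESULTS, "haplotype_labels.csv"))
kept <- filter_phenotypes(pheno[pheno$dose_group == "lethal", ])
dat <- merge(merge(kept, assignment, by = "worker_id"),
             labels, by = "worker_id")
dat <- filter_min_workers(dat, 5)

agg <- do.call(rbind, lapply(split(dat, dat$patriline), function(d)
  data.frame(patriline = d$patriline[1], colony = d$colony[1], n = nrow(d),
             surv_prop = mean(d$survived), d[1, GENES, drop = FALSE])))
cat(sprintf("weighted binomial GLM over %d patrilines:\n", nrow(agg)))
glm_rows <- haplotype_glm(agg$surv_prop, agg$n, agg[GENES], agg$colony)
print(glm_rows, row.names = FALSE)
utils::write.csv(glm_rows, file.path(RESULTS, "haplotype_glm.csv"),
                 row.names = FALSE)

tr <- grow_tree(dat$survived, dat[GENES])
tr <- prune_tree(tr, dat$survived, dat[GENES], folds = 10,
                 seed = fanout_seed(SEED, 51), cp_floor = 0.01)
cat(sprintf("\nclassification tree: %d split(s) after pruning (cp = %.3f)\n",
            count_splits(tr$root), tr$chosen_cp))
render_tree(tr)
jsonlite::write_json(
  list(n_splits = count_splits(tr$root), chosen_cp = tr$chosen_cp,
       cp_table = tr$cp_table),
  file.path(RESULTS, "tree.json"), auto_unbox = TRUE, digits = 10)
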