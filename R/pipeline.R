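#' Run the full analysis pipeline on a simulated experiment
#'
#' Orchestrates simulate -> consumption filter / control QC -> patriline
#' reconstruction -> contingency tests -> deviance partition and
#' heritability -> CYP9Q sequence round trip and haplotype catalog ->
#' weighted haplotype GLM -> classification tree, writing each stage's
#' table under `out_dir` and returning a consolidated report. One top-level
#' seed fans out deterministically to per-stage seeds
#' (see [fanout_seed()]), so reports regenerate identically.
#'
#' @param config a [sim_config()], a list of arguments for it, or a path to
#'   a YAML file holding such a list (optionally with a `params` block:
#'   `min_consumed`, `min_workers`, `min_resolved_loci`,
#'   `max_mismatch_fraction`, `mc_replicates`, `min_split`, `min_bucket`,
#'   `folds`, `cp_floor`).
#' @param out_dir output directory (created); `NULL` for no files.
#' @return a `run_report` list: `config`, `qc`, `patrilines`, `tests`,
#'   `heritability`, `haplotypes`, `association`, `artifacts` (paths).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  params <- list(min_consumed = 0.90, min_workers = 5, min_resolved_loci = 6,
                 max_mismatch_fraction = 0.05, mc_replicates = 5000,
                 min_split = 20, min_bucket = 7, folds = 10, cp_floor = 0.01)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "sim_config")) {
    if (!is.list(config)) stop("config must be a sim_config, list, or YAML path")
    if (!is.null(config$params)) {
      params[names(config$params)] <- config$params
      config$params <- NULL
    }
    if (is.null(config$seed) && is.null(config$workers_per_colony) &&
        is.null(config$n_colonies) && length(config) == 0L)
      stop("config is empty: provide a simulation block")
    config <- do.call(sim_config, config)
  }
  artifacts <- list()
  save_csv <- function(df, name) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      p <- file.path(out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      artifacts[[name]] <<- p
    }
  }

  ## stage 1: simulate
  sim <- simulate_colonies(config)
  workers <- sim$workers
  if (config$genotyping_error_rate > 0)
    workers <- apply_genotyping_errors(workers, config$genotyping_error_rate,
                                       seed = fanout_seed(config$seed, 101L))
  save_csv(workers, "workers.csv")

  ## stage 2: phenotype QC
  pheno <- workers[c("worker_id", "colony", "dose_group", "survived", "consumed_fraction")]
  ctrl <- check_control_mortality(pheno)
  kept <- suppressMessages(filter_phenotypes(pheno[pheno$dose_group == "lethal", ],
                                             params$min_consumed))
  qc <- list(control_mortality = ctrl, n_excluded_consumption = attr(kept, "n_removed"),
             n_analyzed = nrow(kept))

  ## stage 3: patrilines per colony
  lethal <- workers[workers$worker_id %in% kept$worker_id, ]
  gt <- genotypes_from_workers(lethal)
  colonies <- unique(lethal$colony)
  assign_list <- lapply(colonies, function(cc)
    reconstruct_patrilines(gt, cc, params$max_mismatch_fraction,
                           params$min_resolved_loci))
  names(assign_list) <- colonies
  assignment <- do.call(rbind, lapply(assign_list, function(a) a$patrilines$assignment))
  rownames(assignment) <- NULL
  save_csv(assignment, "patrilines.csv")

  dat <- merge(kept, assignment, by = "worker_id")
  dat <- merge(dat, lethal[c("worker_id", "true_patriline",
                             names(config$haplotype_effect_table))], by = "worker_id")

  ## stage 4: contingency tests
  col_tab <- t(vapply(colonies, function(cc) {
    d <- dat[dat$colony == cc, ]
    c(died = sum(!d$survived), survived = sum(d$survived))
  }, numeric(2)))
  chisq_colony <- if (length(colonies) >= 2L)
    chisq_test(col_tab, yates = TRUE, monte_carlo_B = params$mc_replicates,
               seed = fanout_seed(config$seed, 201L))
  else NULL
  chisq_patriline <- lapply(colonies, function(cc) {
    d <- dat[dat$colony == cc, ]
    tab <- table(d$patriline, factor(d$survived, c(FALSE, TRUE)))
    chisq_test(as.matrix(tab), yates = FALSE,
               monte_carlo_B = params$mc_replicates,
               seed = fanout_seed(config$seed, 202L))
  })
  names(chisq_patriline) <- colonies

  ## stage 5: heritability
  part_full <- partition_deviance(dat$survived, dat$colony, dat$patriline)
  dat5 <- filter_min_workers(dat, params$min_workers)
  part_min5 <- partition_deviance(dat5$survived, dat5$colony, dat5$patriline)
  herit <- list(full = part_full, min_workers = part_min5,
                ari_vs_truth = partition_agreement(dat$patriline, dat$true_patriline))

  ## stage 6: CYP9Q sequences -> haplotype catalog (round trip on the
  ## simulated drone labels of the analyzed bees)
  refs <- cyp9q_references()
  profs <- cyp9q_profiles()
  genes <- names(profs)
  called_label <- list()
  for (g in genes) {
    labs <- sort(unique(dat5[[g]]))
    seqs <- simulate_cds_set(refs[[g]],
                             lapply(labs, function(l) change_profile(g, profs[[g]][[l]])),
                             ids = labs)
    called <- lapply(labs, function(l)
      call_changes(seqs[[l]], refs[[g]], gene = g))
    names(called) <- labs
    called_label[[g]] <- called
  }
  bee_profiles <- lapply(seq_len(nrow(dat5)), function(i) {
    stats::setNames(lapply(genes, function(g) called_label[[g]][[dat5[[g]][i]]]), genes)
  })
  names(bee_profiles) <- dat5$worker_id
  catalog <- build_catalog(bee_profiles)
  save_csv(catalog$worker_labels, "haplotype_labels.csv")

  ## stage 7: weighted haplotype GLM on patriline means
  agg <- do.call(rbind, lapply(split(dat5, dat5$patriline), function(d)
    data.frame(patriline = d$patriline[1], colony = d$colony[1],
               n = nrow(d), surv_prop = mean(d$survived),
               d[1, genes, drop = FALSE], stringsAsFactors = FALSE)))
  glm_rows <- haplotype_glm(agg$surv_prop, agg$n, agg[genes], agg$colony)
  save_csv(glm_rows, "haplotype_glm.csv")

  ## stage 8: classification tree on bees
  tr <- grow_tree(dat5$survived, dat5[genes],
                  params$min_split, params$min_bucket)
  tr <- prune_tree(tr, dat5$survived, dat5[genes], folds = params$folds,
                   seed = fanout_seed(config$seed, 301L), cp_floor = params$cp_floor)

  report <- list(
    config = unclass(config), params = params,
    qc = qc,
    patrilines = list(
      n_patrilines = vapply(assign_list, function(a) length(a$patrilines$sizes), integer(1)),
      n_unassigned = vapply(assign_list, function(a) nrow(a$patrilines$unassigned), integer(1))),
    tests = list(colony = unclass(chisq_colony),
                 patriline = lapply(chisq_patriline, unclass)),
    heritability = list(
      shares = c(colony = part_full$share_colony,
                 patriline = part_full$share_patriline,
                 residual = part_full$share_residual),
      h2 = part_full$h2, h2_min_workers = part_min5$h2,
      ari_vs_truth = herit$ari_vs_truth),
    haplotypes = list(n_combinations = catalog$n_combinations,
                      per_gene = lapply(catalog$gene_catalogs, function(x) nrow(x))),
    association = list(glm = glm_rows, tree_splits = count_splits(tr$root),
                       chosen_cp = tr$chosen_cp, cp_table = tr$cp_table),
    artifacts = artifacts
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(report[setdiff(names(report), "artifacts")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, force = TRUE)
  }
  structure(report, class = "run_report")
}
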