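#' Configuration for colony simulation
#'
#' Builds the parameter set for simulating polyandrous honeybee colonies in
#' an acute-exposure survival experiment. A colony is one naturally mated
#' queen, `k_patrilines` haploid drones (fathers), and diploid workers that
#' each inherit one queen allele and their sire's single allele at every
#' microsatellite locus. Workers in the lethal-dose group die with
#' probability given by a Bernoulli-logit model:
#' `logit(p_death) = mu_logit + colony effect + patriline effect + haplotype offsets`.
#'
#' Defaults reproduce the design of the source experiment: two colonies of
#' roughly 250 exposed workers each, 26 and 21 patrilines, 11 hypervariable
#' microsatellite loci. `sigma_patriline = 1.27` puts the asymptotic
#' patriline share of deviance at ~18.9% (broad-sense heritability ~37.8%)
#' for a 22% baseline death rate; `sigma_colony = 0.35` matches the observed
#' colony spread in mortality (28% vs 16%).
#'
#' @param n_colonies number of colonies.
#' @param workers_per_colony exposed (lethal-dose) workers per colony;
#'   recycled to `n_colonies`.
#' @param k_patrilines drones per queen; recycled to `n_colonies`.
#' @param patriline_concentration Dirichlet concentration for patriline
#'   shares (1 = uniform simplex).
#' @param n_loci number of microsatellite loci.
#' @param alleles_per_locus alleles segregating at each locus.
#' @param allele_freq_model Dirichlet concentration for population allele
#'   frequencies at each locus.
#' @param mu_logit baseline logit of 24-h death probability.
#' @param sigma_colony SD of colony effects on the logit scale.
#' @param sigma_patriline SD of patriline (sire) effects on the logit scale.
#' @param haplotype_effect_table named list `gene -> named numeric` of logit
#'   offsets on death probability per haplotype label. Defaults to all-zero
#'   offsets over a catalog mimicking the observed label sets
#'   (6/4/7 haplotypes at CYP9Q1/2/3).
#' @param drone_hap_freqs named list `gene -> named numeric` of haplotype
#'   label frequencies among drones; must cover the labels in
#'   `haplotype_effect_table`.
#' @param genotyping_error_rate per-allele miscall probability (applied only
#'   via [apply_genotyping_errors()]).
#' @param consumed_below_min_rate probability a bee consumes < 90% of its
#'   dose and is excluded by the consumption filter.
#' @param n_control control (solvent-only) bees per colony; their mortality
#'   is an independent Bernoulli at `p_death_control`.
#' @param p_death_control 24-h control death probability.
#' @param seed integer RNG seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_colonies = 2,
                       workers_per_colony = c(247, 249),
                       k_patrilines = c(26, 21),
                       patriline_concentration = 1,
                       n_loci = 11,
                       alleles_per_locus = 8,
                       allele_freq_model = 1,
                       mu_logit = stats::qlogis(0.22),
                       sigma_colony = 0.35,
                       sigma_patriline = 1.27,
                       haplotype_effect_table = NULL,
                       drone_hap_freqs = NULL,
                       genotyping_error_rate = 0,
                       consumed_below_min_rate = 0.05,
                       n_control = 40,
                       p_death_control = 0.03,
                       seed = 1L) {
  if (is.null(haplotype_effect_table)) {
    haplotype_effect_table <- list(
      CYP9Q1 = stats::setNames(numeric(6), c("wt", "A", "B", "D", "E", "F")),
      CYP9Q2 = stats::setNames(numeric(4), c("wt", "G", "H", "I")),
      CYP9Q3 = stats::setNames(numeric(7), c("wt", "K", "L", "M", "N", "O", "P"))
    )
  }
  if (is.null(drone_hap_freqs)) {
    drone_hap_freqs <- lapply(haplotype_effect_table, function(eff) {
      k <- length(eff)
      # wild type common, variants share the rest
      stats::setNames(c(0.5, rep(0.5 / (k - 1), k - 1)), names(eff))
    })
  }
  cfg <- list(
    n_colonies = as.integer(n_colonies),
    workers_per_colony = rep_len(as.integer(workers_per_colony), n_colonies),
    k_patrilines = rep_len(as.integer(k_patrilines), n_colonies),
    patriline_concentration = patriline_concentration,
    n_loci = as.integer(n_loci),
    alleles_per_locus = as.integer(alleles_per_locus),
    allele_freq_model = allele_freq_model,
    mu_logit = mu_logit,
    sigma_colony = sigma_colony,
    sigma_patriline = sigma_patriline,
    haplotype_effect_table = haplotype_effect_table,
    drone_hap_freqs = drone_hap_freqs,
    genotyping_error_rate = genotyping_error_rate,
    consumed_below_min_rate = consumed_below_min_rate,
    n_control = as.integer(n_control),
    p_death_control = p_death_control,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_colonies >= 1L,
    all(cfg$workers_per_colony >= 1L),
    all(cfg$k_patrilines >= 1L),
    cfg$n_loci >= 1L,
    cfg$alleles_per_locus >= 1L,
    cfg$patriline_concentration > 0,
    cfg$allele_freq_model > 0,
    cfg$sigma_colony >= 0,
    cfg$sigma_patriline >= 0,
    cfg$genotyping_error_rate >= 0, cfg$genotyping_error_rate < 1,
    cfg$consumed_below_min_rate >= 0, cfg$consumed_below_min_rate <= 1,
    cfg$p_death_control >= 0, cfg$p_death_control <= 1
  )
  for (g in names(cfg$haplotype_effect_table)) {
    eff <- cfg$haplotype_effect_table[[g]]
    frq <- cfg$drone_hap_freqs[[g]]
    if (is.null(frq) || !all(names(eff) %in% names(frq)))
      stop("drone_hap_freqs must cover every haplotype label of gene ", g)
    if (any(frq < 0) || sum(frq) <= 0)
      stop("invalid haplotype frequencies for gene ", g)
  }
  invisible(cfg)
}

rdirichlet1 <- function(k, alpha) {
  x <- stats::rgamma(k, shape = alpha, rate = 1)
  x / sum(x)
}

locus_names <- function(n) sprintf("L%02d", seq_len(n))

#' Simulate one colony
#'
#' Draws locus-wise population allele frequencies, a diploid queen, `k`
#' haploid drones (with per-gene CYP9Q haplotype labels), Dirichlet patriline
#' shares, and workers. Each worker inherits one uniformly chosen queen
#' allele plus the sire allele per locus; survival in the lethal-dose group
#' follows the Bernoulli-logit model of [sim_config()]. Control bees carry
#' no genetic survival model. Drones that collide (identical multilocus
#' haplotype) are flagged, not rejected: two such fathers are operationally
#' one patriline.
#'
#' @param config a [sim_config()] object.
#' @param colony_index which colony (1-based) to simulate.
#' @return a list with elements `queen` (per-locus allele pair matrix),
#'   `drones` (data.frame: id, per-locus allele, per-gene haplotype label,
#'   patriline share, logit effect), `workers` (one row per bee; wide
#'   genotype columns `L01_a1, L01_a2, ...`), `allele_freqs`, `colony_effect`
#'   and `haplotype_collisions` (count of duplicated drone multilocus
#'   haplotypes).
#' @export
simulate_colony <- function(config, colony_index = 1L) {
  validate_sim_config(config)
  stopifnot(colony_index >= 1L, colony_index <= config$n_colonies)
  with_seed(fanout_seed(config$seed, colony_index), {
    simulate_colony_impl(config, colony_index)
  })
}

simulate_colony_impl <- function(config, ci) {
  nl <- config$n_loci
  na <- config$alleles_per_locus
  loci <- locus_names(nl)
  colony_id <- sprintf("C%02d", ci)

  # integer fragment lengths, locus-specific offsets so loci are disjoint
  allele_sizes <- lapply(seq_len(nl), function(l) 100L + 20L * l + 2L * (seq_len(na) - 1L))
  freqs <- lapply(seq_len(nl), function(l) rdirichlet1(na, config$allele_freq_model))

  draw_allele <- function(l, n = 1L) {
    allele_sizes[[l]][sample.int(na, n, replace = TRUE, prob = freqs[[l]])]
  }

  queen <- vapply(seq_len(nl), function(l) sort(draw_allele(l, 2L)), integer(2))
  rownames(queen) <- c("a1", "a2"); colnames(queen) <- loci

  k <- config$k_patrilines[ci]
  drone_alleles <- vapply(seq_len(nl), function(l) draw_allele(l, k), integer(k))
  if (k == 1L) drone_alleles <- matrix(drone_alleles, nrow = 1L)
  colnames(drone_alleles) <- loci
  genes <- names(config$haplotype_effect_table)
  drone_haps <- vapply(genes, function(g) {
    frq <- config$drone_hap_freqs[[g]]
    names(frq)[sample.int(length(frq), k, replace = TRUE, prob = frq)]
  }, character(k))
  if (k == 1L) drone_haps <- matrix(drone_haps, nrow = 1L, dimnames = list(NULL, genes))

  hap_key <- apply(drone_alleles, 1L, paste, collapse = ":")
  collisions <- sum(duplicated(hap_key))

  shares <- rdirichlet1(k, config$patriline_concentration)
  pat_effect <- stats::rnorm(k, 0, config$sigma_patriline)
  hap_offset <- vapply(seq_len(k), function(d) {
    sum(vapply(genes, function(g)
      config$haplotype_effect_table[[g]][[drone_haps[d, g]]], numeric(1)))
  }, numeric(1))
  colony_effect <- stats::rnorm(1, 0, config$sigma_colony)

  n <- config$workers_per_colony[ci]
  sire <- sample.int(k, n, replace = TRUE, prob = shares)
  gt <- matrix(NA_integer_, n, 2L * nl)
  colnames(gt) <- as.vector(rbind(paste0(loci, "_a1"), paste0(loci, "_a2")))
  for (l in seq_len(nl)) {
    maternal <- queen[sample.int(2L, n, replace = TRUE), l]
    paternal <- drone_alleles[sire, l]
    pair <- cbind(pmin(maternal, paternal), pmax(maternal, paternal))
    gt[, (2L * l - 1L):(2L * l)] <- pair
  }

  logit_death <- config$mu_logit + colony_effect + pat_effect[sire] + hap_offset[sire]
  died <- stats::rbinom(n, 1L, stats::plogis(logit_death)) == 1L
  low_consumed <- stats::runif(n) < config$consumed_below_min_rate
  consumed <- ifelse(low_consumed, stats::runif(n, 0.5, 0.899), stats::runif(n, 0.9, 1.0))

  workers <- data.frame(
    worker_id = sprintf("%s_W%03d", colony_id, seq_len(n)),
    colony = colony_id,
    dose_group = "lethal",
    survived = !died,
    consumed_fraction = round(consumed, 4),
    true_patriline = sprintf("%s_P%02d", colony_id, sire),
    stringsAsFactors = FALSE
  )
  for (g in genes) workers[[g]] <- drone_haps[sire, g]
  workers <- cbind(workers, as.data.frame(gt))

  if (config$n_control > 0L) {
    nc <- config$n_control
    ctrl_sire <- sample.int(k, nc, replace = TRUE, prob = shares)
    ctrl <- data.frame(
      worker_id = sprintf("%s_K%03d", colony_id, seq_len(nc)),
      colony = colony_id,
      dose_group = "control",
      survived = stats::rbinom(nc, 1L, config$p_death_control) == 0L,
      consumed_fraction = round(stats::runif(nc, 0.9, 1.0), 4),
      true_patriline = sprintf("%s_P%02d", colony_id, ctrl_sire),
      stringsAsFactors = FALSE
    )
    for (g in genes) ctrl[[g]] <- drone_haps[ctrl_sire, g]
    gtc <- matrix(NA_integer_, nc, 2L * nl, dimnames = list(NULL, colnames(gt)))
    for (l in seq_len(nl)) {
      maternal <- queen[sample.int(2L, nc, replace = TRUE), l]
      paternal <- drone_alleles[ctrl_sire, l]
      gtc[, (2L * l - 1L):(2L * l)] <- cbind(pmin(maternal, paternal), pmax(maternal, paternal))
    }
    ctrl <- cbind(ctrl, as.data.frame(gtc))
    workers <- rbind(workers, ctrl)
  }

  drones <- data.frame(
    drone_id = sprintf("%s_P%02d", colony_id, seq_len(k)),
    share = shares,
    logit_effect = pat_effect + hap_offset,
    stringsAsFactors = FALSE
  )
  for (g in genes) drones[[g]] <- drone_haps[, g]
  drones <- cbind(drones, as.data.frame(drone_alleles))

  list(queen = queen, drones = drones, workers = workers,
       allele_freqs = freqs, colony_effect = colony_effect,
       haplotype_collisions = collisions)
}

#' Simulate all colonies of a configuration
#'
#' @param config a [sim_config()] object.
#' @return list with `workers` (row-bound worker table across colonies),
#'   `colonies` (per-colony outputs of [simulate_colony()]).
#' @export
simulate_colonies <- function(config) {
  cols <- lapply(seq_len(config$n_colonies), function(ci) simulate_colony(config, ci))
  list(workers = do.call(rbind, lapply(cols, `[[`, "workers")), colonies = cols)
}

#' Inject genotyping errors into a worker table
#'
#' Each allele call is independently replaced, with probability `rate`, by a
#' different allele drawn uniformly from the other alleles observed at that
#' locus in the table. Truth columns are untouched; loci where only one
#' allele segregates cannot be miscalled.
#'
#' @param workers worker data.frame with `Lxx_a1`/`Lxx_a2` genotype columns.
#' @param rate per-call miscall probability in `[0, 1]`.
#' @param seed integer seed.
#' @return the worker table with perturbed allele calls (pairs re-sorted),
#'   with attribute `n_flipped` giving the number of altered calls.
#' @export
apply_genotyping_errors <- function(workers, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  cols <- grep("^L[0-9]+_a[12]$", names(workers), value = TRUE)
  loci <- unique(sub("_a[12]$", "", cols))
  if (rate == 0) {
    attr(workers, "n_flipped") <- 0L
    return(workers)
  }
  with_seed(seed, {
    flipped <- 0L
    for (loc in loci) {
      c1 <- paste0(loc, "_a1"); c2 <- paste0(loc, "_a2")
      universe <- sort(unique(stats::na.omit(c(workers[[c1]], workers[[c2]]))))
      if (length(universe) < 2L) next
      for (cc in c(c1, c2)) {
        x <- workers[[cc]]
        hit <- which(!is.na(x) & stats::runif(length(x)) < rate)
        if (length(hit)) {
          x[hit] <- vapply(x[hit], function(a) {
            alt <- universe[universe != a]
            alt[sample.int(length(alt), 1L)]
          }, universe[1])
          workers[[cc]] <- x
          flipped <- flipped + length(hit)
        }
      }
      # keep the unordered-pair convention
      lo <- pmin(workers[[c1]], workers[[c2]])
      hi <- pmax(workers[[c1]], workers[[c2]])
      workers[[c1]] <- lo; workers[[c2]] <- hi
    }
    attr(workers, "n_flipped") <- flipped
    workers
  })
}
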