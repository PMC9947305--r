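make_gt <- function(pairs, loci = "L01", colony = "C1") {
  # pairs: list of per-worker lists of c(a, b) per locus
  df <- data.frame(worker_id = sprintf("w%02d", seq_along(pairs)), colony = colony,
                   stringsAsFactors = FALSE)
  for (li in seq_along(loci)) {
    df[[paste0(loci[li], "_a1")]] <- vapply(pairs, function(p) as.integer(min(p[[li]])), integer(1))
    df[[paste0(loci[li], "_a2")]] <- vapply(pairs, function(p) as.integer(max(p[[li]])), integer(1))
  }
  structure(df, loci = loci, class = c("genotype_table", "data.frame"))
}

test_that("queen genotype is the unique consistency maximiser", {
  # workers {1,3},{1,4},{2,3},{2,5}: exhaustive search over pairs of {1..5}
  gt <- make_gt(list(list(c(1, 3)), list(c(1, 4)), list(c(2, 3)), list(c(2, 5))))
  # independent brute-force oracle over all candidate pairs
  cand <- t(combn(1:5, 2)); cand <- rbind(cand, cbind(1:5, 1:5))
  w <- cbind(c(1, 1, 2, 2), c(3, 4, 3, 5))
  score <- apply(cand, 1, function(q) sum(w[, 1] %in% q | w[, 2] %in% q))
  expect_identical(sort(cand[which.max(score), ]), c(1L, 2L))
  expect_equal(max(score), 4)
  expect_equal(sum(score == max(score)), 1)

  q <- infer_queen_genotype(gt)
  expect_identical(unname(q$pair[, "L01"]), c(1L, 2L))
  expect_equal(unname(q$consistency[["L01"]]), 1)
})

test_that("monomorphic locus gives a homozygous queen", {
  gt <- make_gt(rep(list(list(c(7, 7))), 4))
  q <- infer_queen_genotype(gt)
  expect_identical(unname(q$pair[, "L01"]), c(7L, 7L))
})

test_that("co-maximal queen candidates are recorded and tie-broken", {
  gt <- make_gt(list(list(c(1, 2)), list(c(1, 2))))
  q <- infer_queen_genotype(gt)
  # all pairs over {1,2} are consistent with both workers
  expect_gte(nrow(q$ambiguity[["L01"]]), 3)
  # tie-break prefers the heterozygous pair
  expect_identical(unname(q$pair[, "L01"]), c(1L, 2L))
})

test_that("paternal allele extraction follows the haplodiploid rules", {
  gt <- make_gt(list(list(c(10, 11)), list(c(10, 12))))
  q <- infer_queen_genotype(gt, max_mismatch_fraction = 0.5)
  # force a known queen for the rule checks
  q$pair[, "L01"] <- c(10L, 11L)

  w_ac <- make_gt(list(list(c(10, 12))))[1, ]
  expect_identical(extract_paternal(w_ac, q)$sets[["L01"]], 12L)

  w_ab <- make_gt(list(list(c(10, 11))))[1, ]
  p_ab <- extract_paternal(w_ab, q)
  expect_setequal(p_ab$sets[["L01"]], c(10L, 11L))
  expect_equal(p_ab$n_resolved, 0L)

  q$pair[, "L01"] <- c(10L, 10L)
  w_hom <- make_gt(list(list(c(10, 13))))[1, ]
  expect_identical(extract_paternal(w_hom, q)$sets[["L01"]], 13L)

  # mismatch: no shared allele
  q$pair[, "L01"] <- c(20L, 21L)
  p_mm <- extract_paternal(w_hom, q)
  expect_equal(p_mm$n_mismatch, 1L)
  expect_setequal(p_mm$sets[["L01"]], c(10L, 13L))
})

test_that("identical haplotypes group; distinct singletons separate", {
  h <- function(x, nres = 1L) structure(
    list(sets = list(L01 = x), n_resolved = nres, n_mismatch = 0L),
    class = "paternal_haplotype")
  res <- group_patrilines(list(w1 = h(5), w2 = h(5), w3 = h(6)),
                          min_resolved_loci = 1)
  expect_identical(unname(sort(res$sizes, decreasing = TRUE)), c(2L, 1L))
  expect_identical(res$assignment$patriline[res$assignment$worker_id == "w1"],
                   res$assignment$patriline[res$assignment$worker_id == "w2"])
})

test_that("workers below the resolved-locus threshold are left out with reasons", {
  h <- function(x, nres) structure(
    list(sets = list(L01 = x), n_resolved = nres, n_mismatch = 0L),
    class = "paternal_haplotype")
  res <- group_patrilines(list(w1 = h(5, 1L), w2 = h(5, 0L)), min_resolved_loci = 1)
  expect_identical(res$unassigned$worker_id, "w2")
  expect_match(res$unassigned$reason, "resolved loci")
})

test_that("error-free simulated colonies are reconstructed exactly", {
  cfg <- sim_config(n_colonies = 1, workers_per_colony = 249, k_patrilines = 21,
                    n_loci = 11, alleles_per_locus = 8, seed = 31, n_control = 0)
  w <- simulate_colony(cfg)$workers
  rec <- reconstruct_patrilines(genotypes_from_workers(w), "C01")
  merged <- merge(rec$patrilines$assignment,
                  w[c("worker_id", "true_patriline")], by = "worker_id")
  # a few workers are queen-ambiguous at too many loci and stay unassigned
  expect_gte(nrow(merged), 0.95 * nrow(w))
  ari <- partition_agreement(merged$patriline, merged$true_patriline)
  expect_equal(ari, 1)
  # patriline count equals the number of sires among assignable workers
  expect_equal(length(rec$patrilines$sizes), length(unique(merged$true_patriline)))
  expect_identical(sum(rec$patrilines$sizes), nrow(merged))
})

test_that("partition agreement matches the reference ARI implementation", {
  skip_if_not_installed("mclust")
  set.seed(8)
  for (i in 1:5) {
    a <- sample(letters[1:4], 60, TRUE)
    b <- sample(LETTERS[1:5], 60, TRUE)
    expect_equal(partition_agreement(a, b),
                 unname(mclust::adjustedRandIndex(a, b)), tolerance = 1e-12)
  }
  expect_equal(partition_agreement(1:10, rev(1:10)), 1)
})

test_that("adding loci never merges incompatible workers", {
  # two workers incompatible at L01 stay apart whatever L02 carries
  for (extra in list(5, 6, c(5, 6))) {
    h1 <- structure(list(sets = list(L01 = 1, L02 = 5), n_resolved = 2L,
                         n_mismatch = 0L), class = "paternal_haplotype")
    h2 <- structure(list(sets = list(L01 = 2, L02 = extra), n_resolved = 2L,
                         n_mismatch = 0L), class = "paternal_haplotype")
    res <- group_patrilines(list(w1 = h1, w2 = h2), min_resolved_loci = 1)
    expect_equal(length(res$sizes), 2L)
  }
})

test_that("reconstruction accuracy does not improve with genotyping error", {
  cfg <- sim_config(n_colonies = 1, workers_per_colony = 249, k_patrilines = 21,
                    seed = 13, n_control = 0)
  w <- simulate_colony(cfg)$workers
  # accuracy = agreement on assigned workers, down-weighted by coverage
  acc_at <- function(rate) {
    we <- apply_genotyping_errors(w, rate, seed = 99)
    rec <- reconstruct_patrilines(genotypes_from_workers(we), "C01")
    m <- merge(rec$patrilines$assignment, w[c("worker_id", "true_patriline")],
               by = "worker_id")
    if (nrow(m) < 2) return(0)
    partition_agreement(m$patriline, m$true_patriline) * nrow(m) / nrow(w)
  }
  a <- vapply(c(0, 0.02, 0.05), acc_at, numeric(1))
  expect_gt(a[1], 0.95)
  expect_true(a[1] >= a[2] - 0.02 && a[2] >= a[3] - 0.02)
})
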