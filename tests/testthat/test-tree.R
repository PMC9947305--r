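test_that("node impurity follows the Gini formula", {
  # 6 survived / 4 died: Gini = 1 - 0.6^2 - 0.4^2 = 0.48 (per observation)
  expect_equal(beetol:::gini_count(6, 4) / 10, 0.48, tolerance = 1e-12)
  expect_equal(beetol:::gini_count(10, 0), 0)
})

test_that("a constant outcome gives a single leaf", {
  X <- data.frame(g = sample(letters[1:3], 40, TRUE))
  tr <- grow_tree(rep(1L, 40), X)
  expect_equal(count_splits(tr$root), 0L)
})

test_that("ordered-category scan equals the exhaustive subset oracle", {
  set.seed(55)
  for (i in 1:40) {
    k <- sample(3:8, 1)
    n <- sample(40:120, 1)
    g <- sample(letters[1:k], n, TRUE)
    y <- rbinom(n, 1, runif(k)[match(g, letters[1:k])])
    if (length(unique(g)) < 2 || length(unique(y)) < 2) next
    sp <- beetol:::best_split_node(y, data.frame(g = g), min_bucket = 1)
    oracle <- oracle_best_gini_gain(y, g, min_bucket = 1)
    if (is.null(sp)) {
      expect_lte(oracle, 1e-12)
    } else {
      expect_equal(sp$gain, oracle, tolerance = 1e-10)
    }
  }
})

test_that("planted low-survival haplotype structure is recovered", {
  d <- gen_planted_tree_data(seed = 101)
  tr <- grow_tree(d$y, d$X)
  tr <- prune_tree(tr, d$y, d$X, folds = 10, seed = 101)
  expect_equal(count_splits(tr$root), 2L)
  expect_identical(tr$root$split$gene, "CYP9Q3")
  expect_setequal(tr$root$split$left_levels, c("L", "N", "P"))
  expect_identical(tr$root$left$split$gene, "CYP9Q1")
  expect_setequal(tr$root$left$split$left_levels, c("B", "E"))
  # CYP9Q2 is never used
  genes_used <- c(tr$root$split$gene, tr$root$left$split$gene)
  expect_false("CYP9Q2" %in% genes_used)
  # low-survival leaf is the {L,N,P} x {B,E} corner
  expect_lt(tr$root$left$left$p_surv, 0.3)
})

test_that("the pruning sequence is nested with monotone resubstitution error", {
  d <- gen_planted_tree_data(seed = 7, n = 600)
  tr <- grow_tree(d$y, d$X, min_split = 10, min_bucket = 4)
  seqs <- beetol:::cp_sequence(tr)
  leaves <- vapply(seqs, `[[`, integer(1), "leaves")
  risk <- vapply(seqs, `[[`, numeric(1), "risk")
  alphas <- vapply(seqs, `[[`, numeric(1), "alpha")
  expect_true(all(diff(leaves) < 0))
  expect_true(all(diff(risk) >= 0))       # resub error non-increasing in size
  expect_true(all(diff(alphas) >= 0))
  # nestedness: every split of subtree k+1 exists in subtree k
  collect_splits <- function(node) {
    if (beetol:::is_leaf(node)) return(character())
    c(paste(node$id, node$split$gene,
            paste(node$split$left_levels, collapse = ",")),
      collect_splits(node$left), collect_splits(node$right))
  }
  for (k in seq_len(length(seqs) - 1L)) {
    expect_true(all(collect_splits(seqs[[k + 1L]]$tree) %in%
                      collect_splits(seqs[[k]]$tree)))
  }
})

test_that("a complexity floor above the whole sequence leaves the root", {
  d <- gen_planted_tree_data(seed = 3, n = 400)
  tr <- grow_tree(d$y, d$X)
  tr <- prune_tree(tr, d$y, d$X, folds = 5, seed = 3, cp_floor = 1)
  expect_equal(count_splits(tr$root), 0L)
})

test_that("a noise outcome prunes back to the root leaf", {
  set.seed(2)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  X <- data.frame(g1 = sample(letters[1:5], n, TRUE),
                  g2 = sample(letters[6:9], n, TRUE))
  tr <- grow_tree(y, X)
  tr <- prune_tree(tr, y, X, folds = 10, seed = 2)
  expect_equal(count_splits(tr$root), 0L)
})

test_that("prediction routes to leaves and handles unseen labels", {
  d <- gen_planted_tree_data(seed = 11)
  tr <- grow_tree(d$y, d$X)
  tr <- prune_tree(tr, d$y, d$X, folds = 10, seed = 11)
  pr <- predict_tree(tr, d$X)
  expect_equal(nrow(pr), length(d$y))
  # a training bee gets its own leaf's survival proportion
  leaf_means <- tapply(d$y, pr$leaf_id, mean)
  expect_equal(unname(leaf_means[as.character(pr$leaf_id[1])]),
               pr$p_surv[1], tolerance = 1e-12)
  # all-wild-type bees land in the high-survival side
  wtX <- data.frame(CYP9Q1 = "wt", CYP9Q2 = "wt", CYP9Q3 = "wt")
  expect_gt(predict_tree(tr, wtX)$p_surv, 0.8)
  # unseen label: majority-direction routing plus a warning
  oddX <- data.frame(CYP9Q1 = "zz", CYP9Q2 = "wt", CYP9Q3 = "zz")
  expect_warning(p_odd <- predict_tree(tr, oddX), "unseen")
  expect_true(p_odd$leaf_id > 0)
})

test_that("root split agrees with the reference CART implementation", {
  skip_if_not_installed("rpart")
  d <- gen_planted_tree_data(seed = 31)
  tr <- grow_tree(d$y, d$X)
  rp <- rpart::rpart(factor(y) ~ ., data = cbind(y = d$y, d$X),
                     method = "class", cp = 0.01)
  expect_identical(tr$root$split$gene,
                   as.character(rp$frame$var[1]))
})

test_that("weighted haplotype GLM finds the planted gene and flags degenerate ones", {
  set.seed(17)
  n_pat <- 30
  q3 <- sample(c("wt", "L", "N", "P", "K"), n_pat, TRUE)
  q1 <- sample(c("wt", "A", "B"), n_pat, TRUE)
  q2 <- rep("wt", n_pat)  # constant -> inestimable
  n <- sample(5:20, n_pat, TRUE)
  p <- ifelse(q3 %in% c("L", "N", "P"), 0.3, 0.85)
  surv <- rbinom(n_pat, n, p) / n
  res <- haplotype_glm(surv, n, data.frame(CYP9Q1 = q1, CYP9Q2 = q2, CYP9Q3 = q3))
  r3 <- res[res$term == "CYP9Q3", ]
  r1 <- res[res$term == "CYP9Q1", ]
  r2 <- res[res$term == "CYP9Q2", ]
  expect_gt(r3$lr_chisq, r1$lr_chisq)
  expect_lt(r3$p, 0.001)
  expect_true(r2$aliased)
  expect_equal(r2$p, 1)

  # identical survival in every patriline: no gene explains anything
  res0 <- haplotype_glm(rep(0.5, n_pat), n,
                        data.frame(CYP9Q1 = q1, CYP9Q3 = q3))
  expect_true(all(res0$lr_chisq < 1e-6))
})
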