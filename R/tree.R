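# Classification tree for survival by categorical gene haplotypes:
# binary recursive partitioning with Gini impurity, weakest-link
# cost-complexity pruning and v-fold cross-validation. For a binary
# outcome, the optimal binary split of a categorical predictor is found by
# ordering its levels by the within-node outcome rate and scanning the
# k - 1 ordered cut points (provably optimal), so the search is linear in
# the number of levels.

gini_count <- function(n_surv, n_died) {
  n <- n_surv + n_died
  if (n == 0) return(0)
  p <- n_surv / n
  n * (1 - p^2 - (1 - p)^2)
}

best_split_node <- function(y, X, min_bucket) {
  best <- NULL
  for (gi in seq_along(X)) {
    g <- as.character(X[[gi]])
    lev <- sort(unique(g))
    if (length(lev) < 2L) next
    rate <- vapply(lev, function(l) mean(y[g == l]), numeric(1))
    cnt_s <- vapply(lev, function(l) sum(y[g == l]), numeric(1))
    cnt_n <- vapply(lev, function(l) sum(g == l), numeric(1))
    ord <- order(rate, lev)
    lev <- lev[ord]; cnt_s <- cnt_s[ord]; cnt_n <- cnt_n[ord]
    tot_s <- sum(cnt_s); tot_n <- sum(cnt_n)
    parent <- gini_count(tot_s, tot_n - tot_s)
    cs <- cumsum(cnt_s); cn <- cumsum(cnt_n)
    for (j in seq_len(length(lev) - 1L)) {
      nl <- cn[j]; nr <- tot_n - nl
      if (nl < min_bucket || nr < min_bucket) next
      gain <- unname(parent - gini_count(cs[j], nl - cs[j]) -
                       gini_count(tot_s - cs[j], nr - (tot_s - cs[j])))
      left <- lev[seq_len(j)]
      cand <- list(gene = names(X)[gi], gene_index = gi,
                   left_levels = sort(left),
                   right_levels = sort(setdiff(lev, left)), gain = gain)
      if (is.null(best) || gain > best$gain + 1e-12 ||
          (abs(gain - best$gain) <= 1e-12 && better_tiebreak(cand, best))) {
        best <- cand
      }
    }
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

# deterministic ties: earlier gene column, then smaller left subset,
# then lexicographic left-level set
better_tiebreak <- function(a, b) {
  if (a$gene_index != b$gene_index) return(a$gene_index < b$gene_index)
  if (length(a$left_levels) != length(b$left_levels))
    return(length(a$left_levels) < length(b$left_levels))
  paste(a$left_levels, collapse = ",") < paste(b$left_levels, collapse = ",")
}

new_node <- function(id, y) {
  n <- length(y); ns <- sum(y)
  list(id = id, n = n, n_surv = ns, p_surv = ns / n,
       pred = if (ns / n >= 0.5) "survived" else "died",
       split = NULL, left = NULL, right = NULL)
}

grow_node <- function(y, X, id, min_split, min_bucket) {
  node <- new_node(id, y)
  if (node$n < min_split || node$n_surv == 0L || node$n_surv == node$n)
    return(node)
  sp <- best_split_node(y, X, min_bucket)
  if (is.null(sp)) return(node)
  g <- as.character(X[[sp$gene]])
  in_left <- g %in% sp$left_levels
  node$split <- sp[c("gene", "left_levels", "right_levels")]
  node$split$majority <- if (sum(in_left) >= sum(!in_left)) "left" else "right"
  node$left <- grow_node(y[in_left], X[in_left, , drop = FALSE],
                         2L * id, min_split, min_bucket)
  node$right <- grow_node(y[!in_left], X[!in_left, , drop = FALSE],
                          2L * id + 1L, min_split, min_bucket)
  node
}

#' Grow a classification tree of survival by haplotype labels
#'
#' @param y per-bee outcome (logical or 0/1; 1 = survived).
#' @param X data.frame of categorical predictors (one gene per column; the
#'   column order is the tie-break order for equally good splits).
#' @param min_split minimum node size to attempt a split (default 20).
#' @param min_bucket minimum size of a child node (default 7).
#' @return object of class `tree_model`: list with `root` (nested nodes),
#'   `n`, `R_root` (root misclassification count), `genes`, `params`.
#' @export
grow_tree <- function(y, X, min_split = 20, min_bucket = 7) {
  if (is.logical(y)) y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(X) == length(y), ncol(X) >= 1L)
  X <- as.data.frame(lapply(X, as.character), stringsAsFactors = FALSE,
                     check.names = FALSE)
  root <- grow_node(y, X, 1L, min_split, min_bucket)
  structure(list(root = root, n = length(y),
                 R_root = min(sum(y), length(y) - sum(y)),
                 genes = names(X),
                 params = list(min_split = min_split, min_bucket = min_bucket)),
            class = "tree_model")
}

is_leaf <- function(node) is.null(node$split)

# per-subtree stats used by weakest-link pruning
node_risk <- function(node) min(node$n_surv, node$n - node$n_surv)

subtree_stats <- function(node) {
  if (is_leaf(node)) return(list(risk = node_risk(node), leaves = 1L))
  l <- subtree_stats(node$left); r <- subtree_stats(node$right)
  list(risk = l$risk + r$risk, leaves = l$leaves + r$leaves)
}

# weakest link g(t) over internal nodes; returns min and count
min_g <- function(node) {
  if (is_leaf(node)) return(Inf)
  st <- subtree_stats(node)
  g_here <- (node_risk(node) - st$risk) / (st$leaves - 1L)
  min(g_here, min_g(node$left), min_g(node$right))
}

collapse_at <- function(node, alpha) {
  if (is_leaf(node)) return(node)
  node$left <- collapse_at(node$left, alpha)
  node$right <- collapse_at(node$right, alpha)
  st <- subtree_stats(node)
  g_here <- (node_risk(node) - st$risk) / (st$leaves - 1L)
  if (g_here <= alpha + 1e-12) {
    node$split <- NULL; node$left <- NULL; node$right <- NULL
  }
  node
}

# sequence of (alpha, tree, leaves, risk) from weakest-link pruning
cp_sequence <- function(model) {
  root <- model$root
  seqs <- list()
  alpha_prev <- -Inf
  repeat {
    st <- subtree_stats(root)
    seqs[[length(seqs) + 1L]] <- list(alpha = max(alpha_prev, 0), tree = root,
                                      leaves = st$leaves, risk = st$risk)
    if (is_leaf(root)) break
    a <- min_g(root)
    root <- collapse_at(root, a)
    alpha_prev <- a
  }
  # entry k holds the subtree optimal for alpha in [alpha_k, alpha_{k+1})
  seqs
}

route_row <- function(node, row, flag_env = NULL) {
  while (!is_leaf(node)) {
    val <- as.character(row[[node$split$gene]])
    node <- if (val %in% node$split$left_levels) node$left
    else if (val %in% node$split$right_levels) node$right
    else {
      if (!is.null(flag_env)) flag_env$unseen <- flag_env$unseen + 1L
      if (node$split$majority == "left") node$left else node$right
    }
  }
  node
}

#' Predict from a classification tree
#'
#' Routes each row to a leaf. Labels never seen at a split are routed to
#' the majority-direction child and counted (with a warning).
#'
#' @param model a `tree_model`.
#' @param X data.frame of gene labels.
#' @return data.frame with `pred`, `p_surv` (leaf survival proportion),
#'   `leaf_id`.
#' @export
predict_tree <- function(model, X) {
  flag <- new.env(); flag$unseen <- 0L
  res <- lapply(seq_len(nrow(X)), function(i) {
    leaf <- route_row(model$root, X[i, , drop = FALSE], flag)
    data.frame(pred = leaf$pred, p_surv = leaf$p_surv, leaf_id = leaf$id,
               stringsAsFactors = FALSE)
  })
  if (flag$unseen > 0L)
    warning(flag$unseen, " observation(s) carried unseen labels; ",
            "routed by majority direction")
  do.call(rbind, res)
}

#' Number of splits in a (sub)tree
#'
#' @param node a tree node (e.g. `model$root`).
#' @return integer count of internal nodes.
#' @export
count_splits <- function(node) {
  if (is_leaf(node)) return(0L)
  1L + count_splits(node$left) + count_splits(node$right)
}

#' Cost-complexity pruning with cross-validated complexity choice
#'
#' Computes the weakest-link pruning sequence of the grown tree, estimates
#' the misclassification error of each complexity value by seeded,
#' outcome-stratified v-fold cross-validation (trees regrown per fold,
#' evaluated at the geometric mean of adjacent complexity values), and
#' returns the subtree at the complexity value with minimum cross-validated
#' error (ties resolved toward the smaller tree). Complexity values are
#' expressed relative to the root misclassification risk, and candidates
#' below `cp_floor` are not considered.
#'
#' @param model a grown `tree_model` (with the training data attached via
#'   `y`/`X` arguments below, used to regrow per fold).
#' @param y,X the training outcome and predictors used to grow `model`.
#' @param folds number of CV folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @param cp_floor minimum complexity value considered (default 0.01).
#' @return a `tree_model` with elements `cp_table` (data.frame cp, n_splits,
#'   rel_error, xerror, xstd), `chosen_cp`, and the pruned `root`.
#' @export
prune_tree <- function(model, y, X, folds = 10, seed = 1L, cp_floor = 0.01) {
  if (is.logical(y)) y <- as.integer(y)
  X <- as.data.frame(lapply(X, as.character), stringsAsFactors = FALSE,
                     check.names = FALSE)
  R_root <- model$R_root
  if (R_root == 0L) {  # pure outcome: root leaf is exact
    model$root <- collapse_at(model$root, Inf)
    model$cp_table <- data.frame(cp = Inf, n_splits = 0L, rel_error = 0,
                                 xerror = 0, xstd = 0)
    model$chosen_cp <- Inf
    return(model)
  }
  seqs <- cp_sequence(model)
  cp <- vapply(seqs, `[[`, numeric(1), "alpha") / R_root
  # the subtree optimal at the floor, plus every coarser subtree
  floor_idx <- max(which(cp <= cp_floor))
  cand <- sort(unique(c(floor_idx, which(cp > cp_floor))))
  cp_c <- cp[cand]
  cp_c[1L] <- max(cp_c[1L], cp_floor)
  # evaluation points: geometric mean of adjacent candidate cps
  beta <- numeric(length(cand))
  for (k in seq_along(cand)) {
    beta[k] <- if (k < length(cand)) sqrt(max(cp_c[k], 1e-10) * max(cp_c[k + 1L], 1e-10))
    else Inf
  }

  n <- length(y)
  fold_id <- with_seed(seed, {
    f <- integer(n)
    for (cls in unique(y)) {
      ix <- which(y == cls)
      f[ix] <- sample(rep_len(seq_len(folds), length(ix)))
    }
    f
  })
  loss <- matrix(0, n, length(cand))
  for (fd in seq_len(folds)) {
    test <- fold_id == fd
    if (!any(test) || length(unique(y[!test])) < 2L) next
    m_f <- grow_tree(y[!test], X[!test, , drop = FALSE],
                     model$params$min_split, model$params$min_bucket)
    for (k in seq_along(cand)) {
      pruned_root <- collapse_at(m_f$root, beta[k] * m_f$R_root)
      pm <- list(root = pruned_root)
      pred <- vapply(which(test), function(i)
        route_row(pm$root, X[i, , drop = FALSE])$pred, character(1))
      loss[test, k] <- as.integer((pred == "survived") != (y[test] == 1L))
    }
  }
  xerr_abs <- colSums(loss)
  xerror <- xerr_abs / R_root
  pbar <- xerr_abs / n
  xstd <- sqrt(pmax(pbar * (1 - pbar) * n, 0)) / R_root
  rel_error <- vapply(cand, function(k) seqs[[k]]$risk / R_root, numeric(1))
  n_splits <- vapply(cand, function(k)
    count_splits(seqs[[k]]$tree), integer(1))
  cp_table <- data.frame(cp = cp_c, n_splits = n_splits,
                         rel_error = rel_error, xerror = xerror, xstd = xstd)
  # minimum CV error; ties toward the smaller tree (larger cp)
  best_k <- which(xerror <= min(xerror) + 1e-12)
  best_k <- best_k[which.max(cp_c[best_k])]
  model$root <- seqs[[cand[best_k]]]$tree
  model$cp_table <- cp_table
  model$chosen_cp <- cp_c[best_k]
  model$pruned <- TRUE
  model
}

#' Text rendering of a classification tree
#'
#' One line per node with the split definition, node size and the percent
#' of bees surviving in that node.
#'
#' @param model a `tree_model`.
#' @return character vector of lines, invisibly; printed as a side effect.
#' @export
render_tree <- function(model) {
  lines <- character()
  walk <- function(node, depth, branch) {
    pad <- strrep("  ", depth)
    desc <- if (is_leaf(node)) "leaf" else
      sprintf("split %s: {%s} | {%s}", node$split$gene,
              paste(node$split$left_levels, collapse = ","),
              paste(node$split$right_levels, collapse = ","))
    lines <<- c(lines, sprintf("%s%s[%s] n=%d, %.0f%% survived (%s)",
                               pad, branch, desc, node$n, 100 * node$p_surv,
                               node$pred))
    if (!is_leaf(node)) {
      walk(node$left, depth + 1L, "L ")
      walk(node$right, depth + 1L, "R ")
    }
  }
  walk(model$root, 0L, "")
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Weighted binomial GLM of patriline survival on haplotype labels
#'
#' Fits patriline mean survival (weighted by the number of bees tested per
#' patriline) on per-gene haplotype labels, with colony as a covariate, and
#' reports a type-II analysis of deviance: each gene's likelihood-ratio
#' chi-squared against the model lacking that gene. A gene with a single
#' observed label is inestimable and flagged (df 0, LR 0, p 1).
#'
#' @param surv_prop per-patriline survival proportion.
#' @param n bees tested per patriline (weights).
#' @param gene_labels data.frame of per-gene haplotype labels (one row per
#'   patriline).
#' @param colony optional colony label per patriline.
#' @return data.frame from [anodev_type2()], gene rows only.
#' @export
haplotype_glm <- function(surv_prop, n, gene_labels, colony = NULL) {
  stopifnot(length(surv_prop) == length(n), nrow(gene_labels) == length(n))
  terms <- list()
  if (!is.null(colony)) terms$colony <- colony
  for (g in names(gene_labels)) terms[[g]] <- gene_labels[[g]]
  res <- anodev_type2(surv_prop, terms, weights = n)
  res[res$term %in% names(gene_labels), , drop = FALSE]
}
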