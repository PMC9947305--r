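# Patriline reconstruction from multilocus microsatellite genotypes.
#
# Workers are diploid daughters of one queen and one of several haploid
# drones. Per locus each worker carries one queen allele and its sire's
# allele, so (i) the queen's diploid genotype can be deduced as the allele
# pair consistent with the most workers, and (ii) the non-queen allele of a
# worker is its paternal allele. Workers sharing a paternal haplotype at all
# resolvable loci belong to one patriline.

#' Deduce the queen's multilocus genotype from her workers
#'
#' Per locus, every candidate diploid pair over the observed alleles
#' (heterozygous and homozygous) is scored by the number of workers that
#' share at least one allele with it; the maximally consistent pair wins.
#' Co-maximal pairs are retained as an ambiguity record; the reported pair
#' is chosen by a deterministic tie-break: heterozygous before homozygous,
#' then the pair whose alleles are most frequent among workers, then
#' numeric order. A locus whose best consistency falls below
#' `1 - max_mismatch_fraction` is marked uninformative (`NA` pair); the
#' call fails only if every locus is uninformative.
#'
#' @param table a `genotype_table` (see [read_genotypes()]).
#' @param colony colony id to use (default: all rows).
#' @param max_mismatch_fraction tolerated fraction of workers inconsistent
#'   with the queen pair (default 0.05).
#' @return object of class `queen_genotype`: list with `loci`, `pair`
#'   (2 x loci matrix, `NA` where uninformative), `ambiguity` (list of
#'   co-maximal pairs per locus), `consistency` (per-locus fraction).
#' @export
infer_queen_genotype <- function(table, colony = NULL, max_mismatch_fraction = 0.05) {
  df <- as.data.frame(table)
  if (!is.null(colony)) df <- df[df$colony == colony, , drop = FALSE]
  if (nrow(df) < 2L) stop("need at least 2 workers to infer the queen genotype")
  loci <- attr(table, "loci") %||% unique(sub("_a[12]$", "",
    grep("^.*_a[12]$", names(df), value = TRUE)))
  pair <- matrix(NA_integer_, 2L, length(loci), dimnames = list(c("a1", "a2"), loci))
  ambiguity <- vector("list", length(loci)); names(ambiguity) <- loci
  consistency <- stats::setNames(rep(NA_real_, length(loci)), loci)

  for (i in seq_along(loci)) {
    a1 <- df[[paste0(loci[i], "_a1")]]; a2 <- df[[paste0(loci[i], "_a2")]]
    ok <- !is.na(a1) & !is.na(a2)
    if (!any(ok)) next
    w1 <- a1[ok]; w2 <- a2[ok]
    alleles <- sort(unique(c(w1, w2)))
    counts <- table(factor(c(w1, w2), levels = alleles))
    cands <- cbind(rep(alleles, each = length(alleles)), rep(alleles, length(alleles)))
    cands <- unique(t(apply(cands, 1L, sort)))
    score <- apply(cands, 1L, function(q)
      sum(w1 == q[1] | w1 == q[2] | w2 == q[1] | w2 == q[2]))
    best <- max(score)
    top <- cands[score == best, , drop = FALSE]
    # tie-break: heterozygous first, then total worker-allele count, then numeric
    het <- top[, 1] != top[, 2]
    freq <- counts[as.character(top[, 1])] + counts[as.character(top[, 2])]
    ord <- order(-het, -freq, top[, 1], top[, 2])
    top <- top[ord, , drop = FALSE]
    consistency[i] <- best / sum(ok)
    ambiguity[[i]] <- top
    if (consistency[i] >= 1 - max_mismatch_fraction) pair[, i] <- top[1L, ]
  }
  if (all(is.na(pair[1L, ]))) stop("no locus yields a consistent queen genotype")
  structure(list(loci = loci, pair = pair, ambiguity = ambiguity,
                 consistency = consistency), class = "queen_genotype")
}

#' Extract a worker's paternal haplotype
#'
#' Per locus: if the worker carries exactly one allele absent from the queen
#' pair, that allele is the sire allele (resolved singleton); if both worker
#' alleles are queen alleles the locus is unresolvable and the ambiguity set
#' is the worker's allele pair; if the worker shares no allele with the
#' queen, a Mendelian mismatch is counted (genotyping error) and both worker
#' alleles are kept as candidates. Loci where the queen is uninformative, or
#' the worker is untyped, carry a `NULL` set.
#'
#' @param worker_row one row of a `genotype_table`.
#' @param queen a `queen_genotype`.
#' @return object of class `paternal_haplotype`: list with `sets` (per-locus
#'   integer vectors or `NULL`), `n_resolved`, `n_mismatch`.
#' @export
extract_paternal <- function(worker_row, queen) {
  sets <- vector("list", length(queen$loci)); names(sets) <- queen$loci
  n_resolved <- 0L; n_mismatch <- 0L
  for (i in seq_along(queen$loci)) {
    q <- queen$pair[, i]
    a <- c(worker_row[[paste0(queen$loci[i], "_a1")]],
           worker_row[[paste0(queen$loci[i], "_a2")]])
    if (any(is.na(q)) || any(is.na(a))) next
    non_queen <- a[!a %in% q]
    if (length(non_queen) == 1L) {
      sets[[i]] <- non_queen; n_resolved <- n_resolved + 1L
    } else if (length(non_queen) == 0L) {
      # both alleles maternal-compatible: sire allele is one of the two
      sets[[i]] <- unique(a)
      if (length(sets[[i]]) == 1L) n_resolved <- n_resolved + 1L
    } else {
      sets[[i]] <- unique(a); n_mismatch <- n_mismatch + 1L
    }
  }
  structure(list(sets = sets, n_resolved = n_resolved, n_mismatch = n_mismatch),
            class = "paternal_haplotype")
}

#' Group workers into patrilines by paternal-haplotype compatibility
#'
#' Greedy compatibility clustering: two haplotypes are compatible when their
#' candidate-allele sets intersect at every locus where both carry a set.
#' Workers are seeded in order of (resolved loci descending, worker id
#' ascending); each worker joins the first existing cluster it is compatible
#' with (cluster creation order), narrowing the cluster's consensus sets by
#' intersection, or founds a new cluster. Workers with fewer than
#' `min_resolved_loci` resolved loci are left unassigned.
#'
#' @param haplotypes named list of `paternal_haplotype` objects (names =
#'   worker ids), all from one colony.
#' @param min_resolved_loci minimum resolved loci for assignment (default 6).
#' @param prefix patriline id prefix.
#' @return object of class `patriline_assignment`: list with `assignment`
#'   (data.frame worker_id, patriline, n_resolved, n_mismatch), `sizes`,
#'   `consensus` (per-patriline sets), `unassigned` (data.frame worker_id,
#'   reason).
#' @export
group_patrilines <- function(haplotypes, min_resolved_loci = 6, prefix = "P") {
  ids <- names(haplotypes)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  ord <- order(-vapply(haplotypes, `[[`, integer(1), "n_resolved"), ids)
  clusters <- list()      # each: list(consensus = sets, members = ids)
  unassigned <- data.frame(worker_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  assign_rows <- list()

  compatible <- function(sets, cons) {
    for (l in seq_along(sets)) {
      if (is.null(sets[[l]]) || is.null(cons[[l]])) next
      if (!length(intersect(sets[[l]], cons[[l]]))) return(FALSE)
    }
    TRUE
  }
  merge_sets <- function(sets, cons) {
    for (l in seq_along(sets)) {
      if (is.null(cons[[l]])) {
        if (!is.null(sets[[l]])) cons[l] <- list(sets[[l]])
      } else if (!is.null(sets[[l]])) {
        cons[[l]] <- intersect(cons[[l]], sets[[l]])
      }
    }
    cons
  }

  for (j in ord) {
    h <- haplotypes[[j]]
    if (h$n_resolved < min_resolved_loci) {
      unassigned <- rbind(unassigned, data.frame(
        worker_id = ids[j],
        reason = sprintf("only %d resolved loci (< %d)", h$n_resolved, min_resolved_loci),
        stringsAsFactors = FALSE))
      next
    }
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      if (compatible(h$sets, clusters[[ci]]$consensus)) {
        clusters[[ci]]$consensus <- merge_sets(h$sets, clusters[[ci]]$consensus)
        clusters[[ci]]$members <- c(clusters[[ci]]$members, ids[j])
        placed <- TRUE; break
      }
    }
    if (!placed) clusters[[length(clusters) + 1L]] <- list(consensus = h$sets, members = ids[j])
    assign_rows[[ids[j]]] <- data.frame(
      worker_id = ids[j],
      patriline = NA_character_,  # filled below once cluster count is final
      n_resolved = h$n_resolved, n_mismatch = h$n_mismatch,
      stringsAsFactors = FALSE)
  }

  pat_ids <- sprintf("%s%02d", prefix, seq_along(clusters))
  member_of <- stats::setNames(
    rep(pat_ids, vapply(clusters, function(cl) length(cl$members), integer(1))),
    unlist(lapply(clusters, `[[`, "members")))
  assignment <- do.call(rbind, assign_rows)
  if (!is.null(assignment)) {
    assignment$patriline <- unname(member_of[assignment$worker_id])
    assignment <- assignment[order(assignment$worker_id), , drop = FALSE]
    rownames(assignment) <- NULL
  } else {
    assignment <- data.frame(worker_id = character(), patriline = character(),
                             n_resolved = integer(), n_mismatch = integer(),
                             stringsAsFactors = FALSE)
  }
  sizes <- stats::setNames(vapply(clusters, function(cl) length(cl$members), integer(1)), pat_ids)
  consensus <- stats::setNames(lapply(clusters, `[[`, "consensus"), pat_ids)
  structure(list(assignment = assignment, sizes = sizes, consensus = consensus,
                 unassigned = unassigned), class = "patriline_assignment")
}

#' Reconstruct patrilines for one colony in one call
#'
#' Convenience wrapper: queen inference, paternal-haplotype extraction and
#' compatibility clustering.
#'
#' @inheritParams infer_queen_genotype
#' @inheritParams group_patrilines
#' @return list with `queen` and `patrilines` (a `patriline_assignment`).
#' @export
reconstruct_patrilines <- function(table, colony = NULL,
                                   max_mismatch_fraction = 0.05,
                                   min_resolved_loci = 6) {
  df <- as.data.frame(table)
  if (!is.null(colony)) df <- df[df$colony == colony, , drop = FALSE]
  queen <- infer_queen_genotype(table, colony, max_mismatch_fraction)
  haps <- lapply(seq_len(nrow(df)), function(r) extract_paternal(df[r, ], queen))
  names(haps) <- df$worker_id
  pref <- if (!is.null(colony)) paste0(colony, "_P") else "P"
  list(queen = queen,
       patrilines = group_patrilines(haps, min_resolved_loci, prefix = pref))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between an inferred and a true partition of
#' the same workers; 1 means identical up to label permutation.
#'
#' @param a,b label vectors of equal length.
#' @return numeric in `[-1, 1]`.
#' @export
partition_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sum_ij <- comb2(tab)
  sum_a <- comb2(rowSums(tab)); sum_b <- comb2(colSums(tab))
  n2 <- choose(length(a), 2)
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
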