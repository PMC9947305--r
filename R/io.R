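#' Read a worker microsatellite genotype table
#'
#' Accepts two CSV dialects: one column per locus with `"a/b"` allele-pair
#' cells, or two columns per locus named `<locus>_a1` / `<locus>_a2`.
#' Either way the table must carry `worker_id` and `colony` columns and a
#' header row. Allele pairs are stored unordered (sorted ascending); empty
#' cells are missing data.
#'
#' @param path CSV file path.
#' @return a `genotype_table`: data.frame with `worker_id`, `colony` and two
#'   integer columns per locus, attribute `loci`.
#' @export
read_genotypes <- function(path) {
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) != 1L)
    stop("ragged CSV: rows have differing field counts (", paste(unique(nf), collapse = ", "), ")")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("worker_id", "colony") %in% names(df)))
    stop("genotype CSV must have 'worker_id' and 'colony' columns")
  dup <- unique(df$worker_id[duplicated(df$worker_id)])
  if (length(dup))
    stop("duplicate worker id(s): ", paste(dup, collapse = ", "))
  other <- setdiff(names(df), c("worker_id", "colony"))
  two_col <- grepl("_a[12]$", other)
  if (all(two_col) && length(other)) {
    loci <- unique(sub("_a[12]$", "", other))
    for (cc in other) {
      v <- df[[cc]]
      if (is.character(v)) v[v == ""] <- NA
      vi <- suppressWarnings(as.integer(v))
      if (any(!is.na(v) & is.na(vi))) stop("non-integer allele in column ", cc)
      df[[cc]] <- vi
    }
  } else if (!any(two_col)) {
    loci <- other
    out <- df[c("worker_id", "colony")]
    for (loc in loci) {
      cell <- as.character(df[[loc]])
      cell[is.na(cell) | cell == ""] <- NA
      parts <- strsplit(cell, "/", fixed = TRUE)
      bad <- !is.na(cell) & lengths(parts) != 2L
      if (any(bad)) stop("malformed allele cell in locus ", loc,
                         " (expected 'a/b'): '", cell[bad][1], "'")
      a <- suppressWarnings(as.integer(vapply(parts, function(p) p[1] %||% NA_character_, "")))
      b <- suppressWarnings(as.integer(vapply(parts, function(p) p[2] %||% NA_character_, "")))
      if (any(!is.na(cell) & (is.na(a) | is.na(b))))
        stop("non-integer allele in locus ", loc)
      out[[paste0(loc, "_a1")]] <- pmin(a, b)
      out[[paste0(loc, "_a2")]] <- pmax(a, b)
    }
    df <- out
  } else stop("mixed locus-column dialects in ", path)
  # normalize to sorted pairs
  for (loc in loci) {
    c1 <- paste0(loc, "_a1"); c2 <- paste0(loc, "_a2")
    lo <- pmin(df[[c1]], df[[c2]]); hi <- pmax(df[[c1]], df[[c2]])
    df[[c1]] <- lo; df[[c2]] <- hi
  }
  df <- df[c("worker_id", "colony", as.vector(rbind(paste0(loci, "_a1"), paste0(loci, "_a2"))))]
  structure(df, loci = loci, class = c("genotype_table", "data.frame"))
}

#' Write a genotype table (two-column dialect)
#'
#' @param table a `genotype_table` or compatible data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Extract the genotype table from a simulated worker table
#'
#' @param workers worker data.frame from [simulate_colony()].
#' @return a `genotype_table`.
#' @export
genotypes_from_workers <- function(workers) {
  cols <- grep("^L[0-9]+_a[12]$", names(workers), value = TRUE)
  loci <- unique(sub("_a[12]$", "", cols))
  structure(workers[c("worker_id", "colony", cols)], loci = loci,
            class = c("genotype_table", "data.frame"))
}

#' Read / write a per-worker phenotype table
#'
#' Columns: `worker_id`, `colony`, `dose_group` (lethal/field/control),
#' `survived` (logical; meaningful for exposed groups), `consumed_fraction`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("worker_id", "colony", "dose_group", "survived", "consumed_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype CSV missing column(s): ", paste(miss, collapse = ", "))
  dup <- unique(df$worker_id[duplicated(df$worker_id)])
  if (length(dup)) stop("duplicate worker id(s): ", paste(dup, collapse = ", "))
  df$survived <- as.logical(df$survived)
  df
}

#' @rdname read_phenotypes
#' @param table phenotype data.frame.
#' @export
write_phenotypes <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Apply the dose-consumption inclusion rule
#'
#' Bees that consumed less than `min_consumed` of the measured sucrose dose
#' are excluded from analysis (boundary kept: "less than"). The default 0.90
#' is the standard acute-oral-toxicity inclusion rule.
#'
#' @param table phenotype data.frame with `consumed_fraction`.
#' @param min_consumed inclusion threshold in `[0, 1]`.
#' @return filtered table; attribute `n_removed` records the exclusions.
#' @export
filter_phenotypes <- function(table, min_consumed = 0.90) {
  stopifnot(min_consumed >= 0, min_consumed <= 1)
  keep <- table$consumed_fraction >= min_consumed
  out <- table[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  if (nrow(out) == 0L) warning("all rows removed by the consumption filter")
  message(n_removed, " bee(s) excluded for consuming < ",
          format(100 * min_consumed), "% of the dose")
  attr(out, "n_removed") <- n_removed
  out
}

#' Check control-group mortality
#'
#' A toxicology run is valid only if 24-h mortality in the solvent-only
#' control group does not exceed `max_rate` (default 10%).
#'
#' @param table phenotype data.frame containing control-group rows.
#' @param max_rate maximal acceptable control death proportion.
#' @return list with `proportion_dead`, `n_control`, and `pass`.
#' @export
check_control_mortality <- function(table, max_rate = 0.10) {
  ctrl <- table[table$dose_group == "control", , drop = FALSE]
  if (nrow(ctrl) == 0L) stop("no control-group rows in phenotype table")
  p <- mean(!ctrl$survived)
  list(proportion_dead = p, n_control = nrow(ctrl), pass = p <= max_rate)
}

#' Read / write FASTA (gaps permitted)
#'
#' Thin wrappers over Biostrings returning plain named character vectors so
#' aligned, gapped sequences round-trip unchanged.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}
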