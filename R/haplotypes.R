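# Amino-acid haplotype calling for CYP9Q coding sequences.

#' Call amino-acid changes of an aligned sample CDS against a reference
#'
#' Compares a sample coding sequence, aligned to reference coordinates with
#' `-` gaps allowed, against the (gap-free) reference window and emits the
#' amino-acid change profile: substitutions, in-frame deletions and
#' truncating premature stops. Silent nucleotide changes are ignored;
#' codons containing ambiguous bases are skipped (no call). Positions are
#' numbered on the protein of the full CDS: `cds_offset` is the 1-based
#' CDS coordinate of the first alignment column, so sequencing windows that
#' start inside the CDS report Table-style residue numbers. Gap runs must
#' be codon-aligned and of length a multiple of 3; anything else is a
#' frameshift error naming the alignment column.
#'
#' @param sample_cds aligned sample sequence (character scalar, gaps `-`).
#' @param reference_cds reference sequence over the same window (no gaps).
#' @param gene gene name recorded in the profile.
#' @param cds_offset 1-based CDS position of the first column (default 1).
#' @return a [change_profile()] object.
#' @export
call_changes <- function(sample_cds, reference_cds, gene = "gene", cds_offset = 1) {
  s <- toupper(sample_cds); r <- toupper(reference_cds)
  if (nchar(s) != nchar(r))
    stop("sample and reference must have equal aligned length")
  if (grepl("-", r, fixed = TRUE)) stop("reference must be gap-free")

  # phase: first complete codon at CDS position divisible by 3 plus 1
  phase <- (cds_offset - 1L) %% 3L
  lead <- if (phase == 0L) 0L else 3L - phase
  n_cod <- (nchar(r) - lead) %/% 3L
  if (n_cod < 1L) stop("window too short for a complete codon")

  # frameshift check: gap runs must be codon-aligned multiples of 3
  gaps <- gregexpr("-+", s)[[1]]
  if (gaps[1] != -1L) {
    lens <- attr(gaps, "match.length")
    for (gi in seq_along(gaps)) {
      start <- gaps[gi]
      if (lens[gi] %% 3L != 0L || (start - 1L - lead) %% 3L != 0L)
        stop("frameshifting or codon-misaligned gap at alignment column ", start)
    }
  }

  events <- list()
  first_codon_residue <- as.integer((cds_offset - 1L + lead) %/% 3L + 1L)
  for (ci in seq_len(n_cod)) {
    at <- lead + 3L * (ci - 1L) + 1L
    cod_s <- substring(s, at, at + 2L)
    cod_r <- substring(r, at, at + 2L)
    pos <- first_codon_residue + ci - 1L
    if (cod_s == "---") {
      aa_r <- translate_codon(cod_r)
      events[[length(events) + 1L]] <-
        data.frame(type = "deletion", pos = pos, ref = aa_r, alt = "-",
                   label = format_event("deletion", pos, aa_r, "-"),
                   stringsAsFactors = FALSE)
      next
    }
    aa_s <- translate_codon(cod_s); aa_r <- translate_codon(cod_r)
    if (aa_s == "X" || aa_r == "X") next   # ambiguous: no call
    if (aa_s == aa_r) next
    if (aa_s == "*") {
      events[[length(events) + 1L]] <-
        data.frame(type = "truncation", pos = pos, ref = aa_r, alt = "*",
                   label = format_event("truncation", pos, aa_r, "*"),
                   stringsAsFactors = FALSE)
      break  # downstream residues are not part of the protein
    }
    events[[length(events) + 1L]] <-
      data.frame(type = "substitution", pos = pos, ref = aa_r, alt = aa_s,
                 label = format_event("substitution", pos, aa_r, aa_s),
                 stringsAsFactors = FALSE)
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(), pos = integer(), ref = character(),
               alt = character(), label = character(), stringsAsFactors = FALSE)
  ev <- ev[order(ev$pos), , drop = FALSE]; rownames(ev) <- NULL
  structure(list(gene = gene, events = ev), class = "change_profile")
}

#' Build a haplotype catalog across genes and workers
#'
#' Assigns a stable label to every distinct amino-acid change profile per
#' gene and forms the multigene combination string per worker. The empty
#' profile is always labelled `"wt"`; non-empty profiles get letters
#' (`A`, `B`, ...) by descending frequency, ties broken by the lexicographic
#' order of the rendered event list, so labels are a pure function of the
#' multiset of profiles. A user label map (`gene -> profile string ->
#' label`) overrides the automatic letters, e.g. for concordance with a
#' published table.
#'
#' @param profiles nested list: `profiles[[worker]][[gene]]` is a
#'   [change_profile()]. Every worker must carry every gene.
#' @param label_map optional named list `gene -> named character`
#'   (profile-string -> label).
#' @return object of class `haplotype_catalog`: list with `genes`,
#'   `gene_catalogs` (per gene: data.frame label, profile, n),
#'   `worker_labels` (data.frame worker x gene), `combo` (named character,
#'   e.g. `"B|wt|N"`), `n_combinations`.
#' @export
build_catalog <- function(profiles, label_map = NULL) {
  workers <- names(profiles)
  stopifnot(!is.null(workers), length(workers) > 0L)
  genes <- names(profiles[[1L]])
  for (wkr in workers)
    if (!identical(sort(names(profiles[[wkr]])), sort(genes)))
      stop("worker ", wkr, " does not carry every gene")

  gene_catalogs <- list()
  worker_labels <- data.frame(worker_id = workers, stringsAsFactors = FALSE)
  for (g in genes) {
    strs <- vapply(workers, function(wkr) profile_string(profiles[[wkr]][[g]]),
                   character(1))
    tab <- table(strs)
    uniq <- names(tab)
    mut <- setdiff(uniq, "wt")
    mut <- mut[order(-tab[mut], mut)]
    labels <- stats::setNames(character(length(uniq)), uniq)
    if ("wt" %in% uniq) labels["wt"] <- "wt"
    labels[mut] <- LETTERS[seq_along(mut)]
    if (!is.null(label_map[[g]])) {
      usr <- label_map[[g]]
      labels[names(usr)[names(usr) %in% uniq]] <- usr[names(usr) %in% uniq]
    }
    gene_catalogs[[g]] <- data.frame(
      label = unname(labels[uniq]), profile = uniq,
      n = as.integer(tab[uniq]), stringsAsFactors = FALSE)
    gene_catalogs[[g]] <- gene_catalogs[[g]][order(gene_catalogs[[g]]$label != "wt",
                                                   gene_catalogs[[g]]$label), , drop = FALSE]
    rownames(gene_catalogs[[g]]) <- NULL
    worker_labels[[g]] <- unname(labels[strs])
  }
  combo <- apply(worker_labels[genes], 1L, paste, collapse = "|")
  names(combo) <- workers
  structure(list(genes = genes, gene_catalogs = gene_catalogs,
                 worker_labels = worker_labels, combo = combo,
                 n_combinations = length(unique(combo))),
            class = "haplotype_catalog")
}
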