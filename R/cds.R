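# Genetic-code helpers shared by the CDS simulator and the haplotype caller.

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter", X = "Xaa")
AA1 <- stats::setNames(names(AA3), AA3)

codon_table <- function() Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  tab <- codon_table()
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) return("X")
  unname(tab[[codon]])
}

codons_for <- function(aa) {
  tab <- codon_table()
  sort(names(tab)[tab == aa])
}

hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# minimal-edit codon encoding `aa`, closest to `ref_codon` (ties: alphabetical)
closest_codon <- function(aa, ref_codon) {
  cands <- codons_for(aa)
  if (!length(cands)) stop("no codon encodes amino acid '", aa, "'")
  d <- vapply(cands, hamming, numeric(1), b = toupper(ref_codon))
  cands[which.min(d)]
}

#' Translate a coding sequence
#'
#' Standard-genetic-code translation of an in-frame CDS. Gaps (`-`) are
#' removed first; the remaining length must be a multiple of 3. Translation
#' stops at the first stop codon; a stop before the final codon sets the
#' `premature_stop` flag (truncated protein). Codons containing a
#' non-`ACGT` character translate to `X` with a warning.
#'
#' @param seq DNA string (character scalar), gaps allowed.
#' @param frame_offset bases to skip before the first codon (default 0).
#' @return list with `protein` (no stop character), `premature_stop`
#'   (logical), `stop_codon_index` (index of the stop codon, `NA` if none),
#'   and `n_codons` (codons available in the input).
#' @export
translate_cds <- function(seq, frame_offset = 0) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(gsub("-", "", seq, fixed = TRUE))
  if (frame_offset > 0) s <- substring(s, frame_offset + 1L)
  if (nchar(s) %% 3L != 0L)
    stop("gap-free CDS length (", nchar(s), ") is not a multiple of 3")
  n <- nchar(s) %/% 3L
  codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aas <- vapply(codons, translate_codon, character(1), USE.NAMES = FALSE)
  if (any(aas == "X")) warning("ambiguous base(s): codon(s) translated to 'X'")
  stop_at <- which(aas == "*")[1]
  if (!is.na(stop_at)) {
    protein <- paste(aas[seq_len(stop_at - 1L)], collapse = "")
    premature <- stop_at < n
  } else {
    protein <- paste(aas, collapse = "")
    premature <- FALSE
  }
  list(protein = protein, premature_stop = premature,
       stop_codon_index = stop_at, n_codons = n)
}

#' Amino-acid change profile
#'
#' A per-gene set of amino-acid events in the vocabulary used for CYP9Q
#' haplotypes: substitutions (`"Gln60Glu"`), in-frame single-residue
#' deletions (`"Thr302del"`), and truncating stops (`"Lys150Ter"`). Events
#' are stored sorted by position; duplicate positions are rejected.
#'
#' @param gene gene name.
#' @param events character vector of event labels (may be empty = wild type).
#' @return object of class `change_profile`: list(gene, events =
#'   data.frame(type, pos, ref, alt, label)).
#' @export
change_profile <- function(gene, events = character()) {
  ev <- do.call(rbind, lapply(events, parse_event))
  if (is.null(ev)) {
    ev <- data.frame(type = character(), pos = integer(), ref = character(),
                     alt = character(), label = character(), stringsAsFactors = FALSE)
  } else {
    if (anyDuplicated(ev$pos)) stop("duplicate event positions in profile")
    ev <- ev[order(ev$pos), , drop = FALSE]
    rownames(ev) <- NULL
  }
  structure(list(gene = gene, events = ev), class = "change_profile")
}

parse_event <- function(label) {
  m <- regmatches(label, regexec("^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2}|del|Ter)$", label))[[1]]
  if (length(m) != 4L) stop("cannot parse event label '", label, "'")
  ref3 <- m[2]; pos <- as.integer(m[3]); alt <- m[4]
  if (!ref3 %in% names(AA1)) stop("unknown amino acid '", ref3, "' in '", label, "'")
  type <- switch(alt, del = "deletion", Ter = "truncation", "substitution")
  alt1 <- if (type == "substitution") {
    if (!alt %in% names(AA1)) stop("unknown amino acid '", alt, "' in '", label, "'")
    AA1[[alt]]
  } else if (type == "truncation") "*" else "-"
  data.frame(type = type, pos = pos, ref = AA1[[ref3]], alt = alt1,
             label = label, stringsAsFactors = FALSE)
}

format_event <- function(type, pos, ref, alt) {
  switch(type,
    substitution = paste0(AA3[[ref]], pos, AA3[[alt]]),
    deletion = paste0(AA3[[ref]], pos, "del"),
    truncation = paste0(AA3[[ref]], pos, "Ter"),
    stop("unknown event type ", type))
}

profile_string <- function(profile) {
  if (!nrow(profile$events)) "wt" else paste(profile$events$label, collapse = "+")
}

#' Realize amino-acid change profiles as coding sequences
#'
#' Generates one DNA sequence per profile from a reference CDS.
#' Substitutions are realized by the minimal codon edit, in-frame deletions
#' by removing the codon (emitted as a 3-bp `---` gap so the output stays
#' aligned to the reference), truncations by editing the codon to the
#' nearest stop codon. Reference amino acids of every event are checked
#' against the translated reference; a mismatch or out-of-range position is
#' an error naming the position.
#'
#' @param reference_cds in-frame reference CDS (character scalar, no gaps,
#'   length divisible by 3).
#' @param profiles list of [change_profile()] objects (or character vectors
#'   of event labels).
#' @param ids sequence names; defaults to `hap1, hap2, ...`.
#' @param gapped if `TRUE` (default) deletions are emitted as `---` gaps
#'   (alignment preserved); if `FALSE` gap columns are removed.
#' @return named character vector of sequences.
#' @export
simulate_cds_set <- function(reference_cds, profiles, ids = NULL, gapped = TRUE) {
  ref <- toupper(reference_cds)
  if (nchar(ref) %% 3L != 0L) stop("reference length not divisible by 3")
  ref_aa <- translate_cds(ref)
  n_res <- nchar(ref_aa$protein)
  profiles <- lapply(profiles, function(p)
    if (inherits(p, "change_profile")) p else change_profile("gene", p))
  if (is.null(ids)) ids <- sprintf("hap%d", seq_along(profiles))
  out <- vapply(seq_along(profiles), function(i) {
    ev <- profiles[[i]]$events
    codons <- substring(ref, 3L * seq_len(nchar(ref) %/% 3L) - 2L,
                        3L * seq_len(nchar(ref) %/% 3L))
    for (j in seq_len(nrow(ev))) {
      pos <- ev$pos[j]
      if (pos < 1L || pos > n_res)
        stop("event position ", pos, " outside protein (1..", n_res, ")")
      have <- substring(ref_aa$protein, pos, pos)
      if (have != ev$ref[j])
        stop("reference mismatch at position ", pos, ": expected ",
             ev$ref[j], ", reference has ", have)
      codons[pos] <- switch(ev$type[j],
        substitution = closest_codon(ev$alt[j], codons[pos]),
        deletion = "---",
        truncation = closest_codon("*", codons[pos]))
    }
    s <- paste(codons, collapse = "")
    if (!gapped) s <- gsub("-", "", s, fixed = TRUE)
    s
  }, character(1))
  stats::setNames(out, ids)
}
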