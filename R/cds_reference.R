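# Synthetic reference CDS construction. Real CYP9Q reference sequences are
# not bundled; analyses and tests run against synthetic references built in
# code, long enough to host the published event positions and constrained
# to carry the required reference amino acids at those positions.

#' Build a synthetic in-frame reference CDS
#'
#' Random codons (no internal stops) for `n_res` residues plus a terminal
#' stop, with specified residues pinned at given positions so that
#' published-style event labels (e.g. `"Thr302del"`) validate against it.
#'
#' @param n_res protein length in residues.
#' @param required named character vector `position -> 1-letter amino acid`.
#' @param seed RNG seed.
#' @return DNA string of length `3 * (n_res + 1)`.
#' @export
synthetic_reference_cds <- function(n_res, required = character(), seed = 1L) {
  with_seed(seed, {
    tab <- codon_table()
    sense <- names(tab)[tab != "*"]
    codons <- sample(sense, n_res, replace = TRUE)
    if (length(required)) {
      pos <- as.integer(names(required))
      stopifnot(all(pos >= 1L), all(pos <= n_res))
      for (i in seq_along(pos)) codons[pos[i]] <- codons_for(required[[i]])[1L]
    }
    paste(c(codons, "TAA"), collapse = "")
  })
}

#' Default CYP9Q amino-acid change profiles
#'
#' The per-gene haplotype label sets used throughout the simulated
#' analyses, with event lists in the published vocabulary for CYP9Q1/3
#' (substitutions, the Thr302 in-frame deletion, one truncating haplotype)
#' and the two conservative CYP9Q2 substitutions. Labels are the simulation
#' catalog's own; profiles are synthetic stand-ins shaped like the
#' published table, not the deposited sequences.
#'
#' @return named list `gene -> named list(label -> character event vector)`.
#' @export
cyp9q_profiles <- function() {
  list(
    CYP9Q1 = list(
      wt = character(),
      A = "Gln60Glu",
      B = c("Ser213Ala", "Met252Val", "Thr257Ala"),
      D = "Ser213Ala",
      E = c("Ser213Ala", "Met252Val", "Lys300Ter"),
      F = "Pro87Ser"
    ),
    CYP9Q2 = list(
      wt = character(),
      G = "Ile248Val",
      H = "His467Tyr",
      I = c("Ile248Val", "His467Tyr")
    ),
    CYP9Q3 = list(
      wt = character(),
      K = c("Thr62Met", "Thr152Ile"),
      L = c("Thr62Met", "Met288Thr", "Val380Ala"),
      M = c("Gly238Asp", "Leu317Ile", "Val380Ala", "Ala387Pro"),
      N = c("Thr62Met", "Gly238Arg", "Leu317Ile", "Val380Ala", "Ala387Pro"),
      O = "Thr62Met",
      P = "Thr302del"
    )
  )
}

#' Synthetic reference CDS for each CYP9Q gene
#'
#' References sized like the real genes (~520 residues) and pinned so that
#' every event of [cyp9q_profiles()] validates.
#'
#' @param seed RNG seed.
#' @return named character vector of three CDS strings.
#' @export
cyp9q_references <- function(seed = 20L) {
  profs <- cyp9q_profiles()
  out <- character(0)
  for (g in names(profs)) {
    req <- character()
    for (ev in unlist(profs[[g]], use.names = FALSE)) {
      p <- parse_event(ev)
      req[as.character(p$pos)] <- p$ref
    }
    out[g] <- synthetic_reference_cds(520L, req, seed = fanout_seed(seed, match(g, names(profs))))
  }
  out
}
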