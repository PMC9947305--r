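test_that("translation handles stops, ambiguity and frame errors", {
  t1 <- translate_cds("ATGGAATAA")
  expect_identical(t1$protein, "ME")
  expect_false(t1$premature_stop)

  t2 <- translate_cds("ATGTAAGAA")
  expect_identical(t2$protein, "M")
  expect_true(t2$premature_stop)

  expect_warning(t3 <- translate_cds("ATGNNNGAA"), "ambiguous")
  expect_identical(t3$protein, "MXE")

  expect_error(translate_cds("ATGGA"), "multiple of 3")
  # gaps are removed before the frame check
  expect_identical(translate_cds("ATG---GAATAA")$protein, "ME")
})

test_that("calling changes on the reference itself yields wild type", {
  ref <- synthetic_reference_cds(100, seed = 5)
  prof <- call_changes(ref, ref, gene = "CYP9Q1")
  expect_equal(nrow(prof$events), 0L)
  expect_identical(beetol:::profile_string(prof), "wt")
})

test_that("planted substitutions, deletions and truncations are recovered", {
  ref <- synthetic_reference_cds(320, c(`62` = "T", `152` = "T", `302` = "T"),
                                 seed = 6)
  seqs <- simulate_cds_set(ref, list(
    c("Thr62Met", "Thr152Ile"),
    "Thr302del",
    "Thr152Ter"))
  p1 <- call_changes(seqs[[1]], ref)
  expect_identical(p1$events$label, c("Thr62Met", "Thr152Ile"))
  p2 <- call_changes(seqs[[2]], ref)
  expect_identical(p2$events$label, "Thr302del")
  expect_identical(p2$events$type, "deletion")
  p3 <- call_changes(seqs[[3]], ref)
  expect_identical(p3$events$type, "truncation")
  expect_identical(p3$events$pos, 152L)
})

test_that("silent codon edits are not reported", {
  ref <- "ATGCTAGAATAA"     # M L E *
  alt <- "ATGTTGGAATAA"     # CTA -> TTG, still Leu
  expect_equal(nrow(call_changes(alt, ref)$events), 0L)
})

test_that("frameshifting gaps are rejected with the offending column", {
  ref <- synthetic_reference_cds(10, seed = 7)
  s <- ref
  substr(s, 4, 5) <- "--"
  expect_error(call_changes(s, ref), "column 4")
})

test_that("windows starting inside the CDS keep full-CDS residue numbering", {
  ref <- synthetic_reference_cds(200, c(`150` = "Q"), seed = 8)
  mut <- simulate_cds_set(ref, list("Gln150Glu"))[[1]]
  # sequencing window starts at CDS nucleotide 100 (inside codon 34)
  win_ref <- substring(ref, 100, 3 * 201)
  win_mut <- substring(mut, 100, 3 * 201)
  prof <- call_changes(win_mut, win_ref, cds_offset = 100)
  expect_identical(prof$events$label, "Gln150Glu")
})

test_that("every canonical CYP9Q profile round-trips through sequence space", {
  refs <- cyp9q_references()
  profs <- cyp9q_profiles()
  for (g in names(profs)) {
    for (lab in names(profs[[g]])) {
      s <- simulate_cds_set(refs[[g]],
                            list(change_profile(g, profs[[g]][[lab]])))[[1]]
      called <- call_changes(s, refs[[g]], gene = g)
      expect_identical(called$events$label,
                       change_profile(g, profs[[g]][[lab]])$events$label,
                       info = paste(g, lab))
    }
  }
})

test_that("catalog labels are frequency-ranked, stable and order-invariant", {
  wt <- change_profile("g1")
  q60 <- change_profile("g1", "Gln60Glu")
  p87 <- change_profile("g1", "Pro87Ser")
  profs <- list(
    w1 = list(g1 = wt), w2 = list(g1 = q60), w3 = list(g1 = q60),
    w4 = list(g1 = p87), w5 = list(g1 = wt))
  cat1 <- build_catalog(profs)
  expect_identical(unname(cat1$combo[c("w2", "w3")]), c("A", "A"))
  expect_identical(unname(cat1$combo[["w4"]]), "B")
  expect_identical(unname(cat1$combo[["w1"]]), "wt")
  expect_equal(cat1$n_combinations, 3L)

  cat2 <- build_catalog(rev(profs))
  expect_identical(cat1$combo[names(cat1$combo)], cat2$combo[names(cat1$combo)])

  # user label map overrides the automatic letters
  cat3 <- build_catalog(profs, label_map = list(g1 = c(`Gln60Glu` = "Q")))
  expect_identical(unname(cat3$combo[["w2"]]), "Q")
})

test_that("multigene combination counts match the simulated drone pool", {
  cfg <- sim_config(n_colonies = 1, workers_per_colony = 150, seed = 19, n_control = 0)
  w <- simulate_colony(cfg)$workers
  genes <- c("CYP9Q1", "CYP9Q2", "CYP9Q3")
  truth_combo <- apply(w[genes], 1, paste, collapse = "|")
  profs <- cyp9q_profiles()
  refs <- cyp9q_references()
  bee_profiles <- lapply(seq_len(nrow(w)), function(i)
    stats::setNames(lapply(genes, function(g)
      change_profile(g, profs[[g]][[w[[g]][i]]])), genes))
  names(bee_profiles) <- w$worker_id
  cat <- build_catalog(bee_profiles)
  expect_equal(cat$n_combinations, length(unique(truth_combo)))
})
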