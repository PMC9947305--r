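---
title: "Patriline heritability and CYP9Q haplotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patriline heritability and CYP9Q haplotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beetol)
```

This vignette is the package's own account of the science it implements:
the generative model behind the simulator, the inference and estimation
rules with the design choices that were genuinely open, and what the
passing test suite does and does not establish about real colonies.

## The experimental design being modelled

A honeybee queen mates with many drones. Because drones are haploid, every
worker inherits one of the queen's two alleles and the sire's single
allele at each locus; workers sired by the same drone form a patriline.
All patrilines share one colony environment and one mother, so systematic
survival differences among patrilines after a standardized acute
clothianidin dose are attributable to paternal genetics, and broad-sense
heritability of the binary 24-h survival phenotype is estimated as twice
the patriline-explained share of phenotypic variation.

## The simulator: what it emulates and the parameters that matter

`sim_config()` encodes the study conditions as defaults:

| parameter | default | meaning |
|---|---|---|
| `workers_per_colony` | 247, 249 | exposed (lethal-dose) bees per colony |
| `k_patrilines` | 26, 21 | drones per queen |
| `n_loci`, `alleles_per_locus` | 11, 8 | hypervariable microsatellite panel |
| `mu_logit` | logit(0.22) | baseline 24-h death probability (109/496) |
| `sigma_colony` | 0.35 | SD of colony effects, logit scale |
| `sigma_patriline` | 1.27 | SD of patriline effects, logit scale |
| `consumed_below_min_rate` | 0.05 | bees failing the 90%-consumption rule |
| `p_death_control` | 0.03 | control mortality (validity limit 10%) |

Patriline effects are i.i.d. Normal on the logit of death probability —
the standard threshold-liability analogue for a binary trait, and the
choice that makes "true" heritability well defined: for effect SD
$\sigma$, the infinite-data patriline share of deviance is
$1 - E[h(p_j)]/h(\bar p)$ with $h$ the Bernoulli deviance (entropy)
function and $p_j = \mathrm{logit}^{-1}(\mu + u_j)$, computable by
one-dimensional integration. **σ = 1.27 was calibrated once, by that
integral, so the asymptotic patriline share is 18.9% (H² = 37.8%) at the
22% baseline death rate; σ_colony = 0.35 reproduces the observed colony
spread (28% vs 16% mortality).** Patriline shares within a queen follow a
Dirichlet with concentration 1 (the share skew is unreported in the
source design, so the uniform simplex is the neutral choice; it is a
config field). Allele fragment lengths are integers; loci are unlinked,
with no null alleles.

Drones also carry per-gene CYP9Q haplotype labels drawn from a
configurable frequency table, with logit offsets from
`haplotype_effect_table`. The default offsets are all zero, so
heritability simulations are driven purely by `sigma_patriline`; the
association analyses plant effects explicitly (and, in
`analysis/01_simulate.R`, lower σ to 1.05 so the total patriline-level
variance stays at the calibrated 1.27²).

Dose groups other than `lethal` are label-only: control bees die with a
fixed small probability, field-dose bees carry no survival model. The
generator does **not** emulate: genotyping dropout/null alleles, linkage,
queen replacement or drifting workers, real microsatellite allele-length
distributions, or heterozygous CYP9Q calls (one consensus sequence per
bee per gene). Passing tests therefore validate the algorithms under
idealized Mendelian transmission, not the full messiness of field data.

## Patriline reconstruction

Per locus, the queen's diploid genotype is the allele pair consistent
with the most workers (a worker is consistent if it shares ≥ 1 allele).
Ties are real — e.g. every worker heterozygous (a, b) — so a
deterministic tie-break is fixed: heterozygous pairs first, then the pair
whose alleles are most frequent among workers, then numeric order; all
co-maximal pairs are kept in an ambiguity record. A locus is declared
uninformative when best consistency falls below
`1 − max_mismatch_fraction` (default 0.05).

A worker's paternal allele is the allele absent from the queen pair; when
both worker alleles are queen alleles the locus is unresolvable and both
alleles stay as candidates; a worker sharing no queen allele is counted
as a Mendelian mismatch (genotyping error) but kept, with both alleles as
candidates. Workers resolving fewer than `min_resolved_loci` (default 6
of 11) are left unassigned — with 8 alleles per locus about 2% of workers
hit this information limit even with error-free data, which is why
exactness claims are stated over assigned workers.

Clustering is greedy compatibility clustering: workers ordered by
(resolved loci desc, id asc); two haplotypes are compatible when their
candidate sets intersect at every locus both carry; a worker joins the
first compatible cluster (whose consensus is narrowed by intersection) or
founds a new one. The ordering rules exist purely for reproducibility.
Two drones with identical 11-locus haplotypes are operationally one
patriline — the same limit the experimental definition has. The
compatibility rule is intentionally strict: a single miscalled resolved
locus separates a worker from its true patriline, so accuracy decays
quickly with the genotyping error rate (the test suite asserts the decay
is monotone; it makes no robustness claim beyond that). No
likelihood-based sibship reconstruction is attempted.

## Heritability from a deviance partition

For factor-only designs the binomial MLE is the cell mean, so each
model's deviance has a closed form ($0\log 0 := 0$; perfectly separated
cells contribute zero); `fit_factor_logit()` also provides an IRLS route
(`stats::glm` at tightened tolerance) which must agree to 1e-8 — a
dual-route check the tests enforce on random designs. Shares of the null
deviance are **raw** sequential shares: the published partitions sum to
100%, which raw shares do and the adjusted-D² transform does not; the
classical adjusted D² is still reported per model.

The raw patriline share spends one parameter per patriline and is
therefore biased upward in finite samples: under the null its expected
explained deviance is roughly its degrees of freedom (~45 parameters on
~500 bees inflates H² by ~0.17 — visible in the worked example). Because
the likelihood-ratio statistic is approximately noncentral chi-squared
with mean df + signal, subtracting the df gives a nearly unbiased signal
share: `share_patriline_corrected = max(0, (ΔD − Δdf)/D₀)`. The
acceptance suite checks the corrected estimator's mean over 200 simulated
colonies against the entropy-integral truth at σ ∈ {0, 0.6, 1.27} within
an absolute band of 0.05 (measured biases ≈ 0.03, 0.00, 0.04 — the
residual at large σ comes from small patrilines saturating at observed
proportions 0/1), and verifies directionally that the raw null bias
shrinks as workers-per-patriline grows. H² = 2 × share is reported raw
and clamped to [0, 1]; values above 1 are mathematically possible and
must stay visible.

2×2 contingency tables use the Yates continuity correction by default:
the published colony statistic (9.510) is the corrected one (uncorrected
≈ 10.19), so the source convention is inferred and made the default with
an off switch. Monte Carlo p values condition on both margins
(`stats::r2dtable`), default 5000 replicates, with the add-one estimator
p = (1 + hits)/(B + 1) so p ≥ 1/(B+1). Type-II analysis of deviance
compares the full additive model against the model lacking each term; LR
is floored at zero and aliased terms (rank difference 0) are flagged with
p = 1 — a nested-ML fit cannot yield a negative LR, so none is ever
reported. The Pearson correlation test uses the exact identity
t = r√(df/(1−r²)).

## CYP9Q haplotype calling

`translate_cds()` uses the standard genetic code, stops at the first stop
codon and flags premature stops; ambiguous bases translate to `X` (no
call at that codon — a deliberate no-false-positive choice). Gap runs in
aligned samples must be codon-aligned multiples of 3; anything else is a
frameshift error naming the column, because the sequenced genes are
single-exon and a frameshift would invalidate all downstream calls.
Residues are numbered on the full-CDS protein via `cds_offset`, so
sequencing windows that start inside the CDS (as the real amplicons do)
report table-style positions. Calling stops at a truncating stop:
downstream codons are not part of the protein.

Catalog labels: the wild type is always `"wt"`; mutant profiles get
letters by descending frequency, ties by lexicographic event list, making
labels a pure function of the profile multiset (order-invariant, tested).
A user `label_map` overrides letters for concordance with published
naming. Reference sequences are synthetic, built in code by
`synthetic_reference_cds()` with the published event positions pinned —
stand-ins for the real deposited sequences, clearly labelled as such, so
the round-trip property (simulate → call recovers every planted
substitution, in-frame deletion and truncation exactly) tests the caller,
not the references.

## Classification tree

Splits minimize Gini impurity; for a binary outcome the optimal binary
split of a categorical predictor is found by ordering its levels by node
survival rate and scanning the k−1 cut points, which the tests verify
against an exhaustive 2^(k−1)−1 subset oracle on every node size up to 8
labels. Ties break deterministically (gene order, then smaller left
subset, then lexicographic). Defaults `min_split = 20`, `min_bucket = 7`,
10-fold CV, complexity floor 0.01 follow classification-tree convention.
Pruning is weakest-link cost-complexity with misclassification risk;
candidate complexity values are evaluated at the geometric mean of
adjacent values by outcome-stratified seeded cross-validation, and the
subtree at minimum CV error is returned (ties toward the smaller tree).

The minimum-CV rule is noise-sensitive: CV error differences far smaller
than their standard errors can keep or drop a split, so with ~500
observations a planted two-split structure is recovered in only ~90–95%
of seeds, while at n = 1200 recovery is essentially certain — the planted
fixture in the tests uses n = 1200 for that reason, and the recovery
property (> 95% of seeds) is a statement about that regime. The unit of
analysis is the individual bee with gene labels inherited from its
patriline (a patriline-mean mode is available through the weighted GLM
instead). Unseen labels at prediction time route to the majority
direction with a warning; there are no surrogate splits.

In the `analysis/` demonstration at the real experiment's size, gene
labels are carried by ~20 drones per colony, so label effects are partly
confounded with drone-level random effects; the demo tree therefore picks
up occasional extra splits beyond the planted structure. That is the
expected behaviour of the method at this design size, not an
implementation artifact, and it is why the structural recovery tests
randomize labels at the bee level.

## Determinism and numerical conventions

Every stochastic function takes a seed; `run_pipeline()` fans one
top-level seed out to per-stage child seeds (`fanout_seed()`, kept inside
32-bit range) so stages are individually re-runnable and reports
regenerate byte-identically. Package functions restore the caller's RNG
state. Deviance uses 0·log 0 := 0 throughout; share sums are exact to
1e-10 by construction; the IRLS/closed-form agreement tolerance is 1e-8.

## Problem sizes used by the test suite

Chosen as the package's own verification design: 1000 random factor
designs for the dual-route deviance check; 100 simulated experiments
(200 colonies) per σ level for H² recovery, with 30 + 30 experiments for
the null-bias direction check; three error-free reconstructions at
k = 21, 26, 30 plus a three-level error-rate curve; 40 seeds of the
n = 1200 planted fixture for tree recovery. The full suite runs in about
a minute on one CPU.

## Known limitations

* The greedy patriline clusterer has no error model; with miscalls it
  fragments rather than misassigns (conservative, but coverage drops).
* The df-corrected H² is slightly conservative when many patrilines are
  small and effects are strong (observed −0.04 at σ = 1.27).
* Haplotype calling assumes one consensus sequence per bee per gene;
  heterozygous-peak deconvolution is out of scope.
* Control and field dose groups are labels, not models; only the lethal
  group carries the genetic survival model.
* The simulator's idealized transmission (no null alleles, no linkage)
  means reconstruction performance on real fragment data will be worse
  than the in-silico exactness results.
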