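# beetol

Genetics of clothianidin tolerance in honeybees: a reusable, tested
reimplementation of a patriline-based heritability and CYP9Q
haplotype-association analysis, built around simulated colonies so every
stage is verifiable without any external data.

## The scientific problem

Whether neonicotinoid insecticides harm honeybees is contested partly
because colonies differ genetically in tolerance. A polyandrous honeybee
queen mates with many drones; her workers fall into patrilines
(same-father families, relatedness 0.75) that share one rearing
environment. If 24-hour survival after an acute oral clothianidin dose
(the published LD50, 29 ppb) differs among patrilines within a colony,
that difference is genetic, and for haplodiploids broad-sense heritability
is

    H² = 2 × (patriline share of phenotypic variation).

Survival is binary, so the analysis partitions the null deviance D₀ of a
Bernoulli-logit model over the nested sequence

    {intercept} ⊂ {colony} ⊂ {colony : patriline}

and takes the patriline share (D₁ − D₂)/D₀ in place of a variance share.
The pipeline around this estimator covers the full experiment:

1. **simulate** — colonies with a diploid queen, haploid drones, Dirichlet
   patriline shares, Mendelian microsatellite transmission, and
   logit-normal colony/patriline effects on death probability
   (`sim_config()`, `simulate_colonies()`);
2. **patrilines** — deduce the queen's genotype per locus by exhaustive
   consistency scoring, extract each worker's paternal allele, and cluster
   compatible paternal haplotypes (`reconstruct_patrilines()`);
3. **herit** — Yates/Monte-Carlo chi-squared tests, closed-form binomial
   deviance partition, H², the ≥5-workers-per-patriline robustness filter
   (`chisq_test()`, `partition_deviance()`, `filter_min_workers()`);
4. **haplotypes** — translate aligned CYP9Q1/2/3 coding sequences, call
   amino-acid substitutions, in-frame deletions and truncating stops, and
   label multigene haplotype combinations (`call_changes()`,
   `build_catalog()`);
5. **assoc** — weighted binomial GLM with type-II analysis of deviance per
   gene, and a Gini classification tree with weakest-link cost-complexity
   pruning at the minimum cross-validated error (`haplotype_glm()`,
   `grow_tree()`, `prune_tree()`).

## Worked example

The numbered drivers under `analysis/` run the whole study on a simulated
two-colony experiment (247 + 249 exposed workers, 26 + 21 patrilines, 11
microsatellite loci):

```sh
Rscript analysis/01_simulate.R     --seed 1
Rscript analysis/02_patrilines.R   --seed 1
Rscript analysis/03_heritability.R --seed 1
Rscript analysis/04_haplotypes.R   --seed 1
Rscript analysis/05_association.R  --seed 1
```

With `--seed 1` this prints, among other things:

```
C01: 247 exposed workers, 31% died at 24 h
C02: 249 exposed workers, 40% died at 24 h
control mortality: 3.8% of 80 bees (within the 10% validity limit)
...
agreement with simulation truth: ARI = 1.000 on 453 workers
...
Deviance partition (binomial logit)
  colony:      0.8%
  patriline:  23.4%
  residual:   75.8%
  H2 = 2 x patriline share = 46.8%
  df-corrected patriline share 16.9% -> H2 = 33.9%
```

Reading: patriline reconstruction from error-free genotypes is exact
(adjusted Rand index 1 against the simulation truth); the raw patriline
share over-states heritability because it spends one parameter per
patriline (~40 parameters on ~450 bees), while the df-corrected share
recovers the generating value (the simulator is calibrated to H² ≈ 38%).
Step 5 prints the per-gene likelihood-ratio tests and a text rendering of
the pruned classification tree with per-node survival percentages.

Equivalent single-call orchestration, with artifacts and a JSON report:

```r
library(beetol)
report <- run_pipeline(sim_config(seed = 1), out_dir = "results")
```

## The methods vignette

`vignettes/bee-clothianidin-tolerance.Rmd` documents the generative model
and its calibration, the deterministic inference rules (queen tie-breaks,
compatibility clustering), the deviance-partition estimator and its
finite-sample bias, the haplotype-calling conventions, the tree's split
search and pruning, and the known limitations of the simulation as a
stand-in for real colonies.
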