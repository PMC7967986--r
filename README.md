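# otulda

Microbial subgroup discovery from 16S rRNA OTU tables by latent
Dirichlet allocation (LDA), with Dirichlet regression of subgroup
probabilities on habitual-diet and metabolic-disease covariates.

## The problem

Gut microbiota profiles are high-dimensional, sparse and compositional:
an OTU table with thousands of taxa is unusable as a regression outcome,
and the classic remedy — collapsing every sample into one of three
enterotype clusters — throws away most inter-individual structure.
`otulda` takes the topic-model view instead. Samples are "documents" of
sequencing reads, OTUs are "words", and LDA learns K latent *microbial
subgroups* — multinomial distributions over OTUs capturing taxa that
co-occur — together with each sample's fractional membership across
them:

  θᵢ ~ Dir(α),  φₖ ~ Dir(β),  zᵢⱼ ~ Mult(θᵢ),  wᵢⱼ ~ Mult(φ_{zᵢⱼ}).

The K membership probabilities θᵢ (which sum to 1) then become the
outcome of Dirichlet regressions — one model per food item, nutrient,
diet score, or disease variable, with covariate adjustment, per-SD
coefficients, Wald tests, and Bonferroni control across the battery.
The package is aimed at microbiome epidemiologists who want this whole
pipeline as tested, seeded, scriptable R functions.

What's inside:

* **Preprocessing** — total-count normalization, the joint
  abundance/prevalence OTU filter (> 0.1% within-sample abundance in
  ≥ 1% of samples), ×1000 integer rescaling, genus-level collapse with
  an unknown-genus (`"NA"`) category.
* **LDA core** — collapsed Gibbs sampler (Rcpp, bit-reproducible by
  seed), held-out perplexity via fold-in, k-fold cross-validated
  selection curve for K, best-of-m refits.
* **Dirichlet regression** — common parametrization (log-link
  coefficient vector per subgroup), BFGS with analytic gradient,
  observed-information Wald tests, exposure families with their own
  adjustment sets and exclusion rules, Bonferroni across exposures.
* **Characterization** — top genera per subgroup, subgroup-distribution
  summaries, Ward clustering of subgroups with newick export, summed
  subgroup probability over externally defined OTU lists (e.g.
  arrhythmic OTUs).
* **Enterotype comparison arm** — genus-level Jensen–Shannon + PAM
  clustering, multinomial logistic regression of cluster membership
  with per-SD odds ratios.
* **Synthetic data** — generators that draw OTU tables from the LDA
  process itself and plant covariate→subgroup effects, with full ground
  truth recorded for recovery testing.

## Worked example

Simulate a 300-sample cohort in which a diet variable ("fiber") raises
one subgroup's probability (planted per-SD coefficient 0.8), run the
full pipeline, and test the association:

```r
library(otulda)

g <- matrix(0, 1, 3, dimnames = list("fiber", NULL)); g[1, 1] <- 0.8
sim <- generate_covariate_linked_thetas(
  n_samples = 300, K = 3,
  covariate_specs = list(fiber = list(kind = "continuous",
                                      mean = 18, sd = 5)),
  gamma = g, precision = 30, seed = 2)
corp <- generate_lda_corpus(n_samples = 300, n_otus = 60, K = 3,
                            reads_per_sample = 500, seed = 2,
                            separation = 1, theta = sim$theta)

counts <- corp$counts |> normalize_total_count() |>
  filter_otus(0.001, 0.01) |> normalize_total_count() |>
  rescale_to_counts(1000)

fit <- fit_lda_gibbs(counts, lda_hyperparams(K = 3, seed = 2))
summarize_subgroups(fit$theta)
#> <subgroup_summary> 300 samples x 3 subgroups
#>   mean max-probability: 0.495
#>   subgroups > 0.01 per sample: 3.0 +/- 0.0
#>   subgroups > 0.1 per sample: 2.9 +/- 0.3
#>   subgroups > 0.25 per sample: 2.1 +/- 0.7

res <- run_association_battery(
  fit$theta, sim$covariates,
  list(diet = list(exposures = "fiber", adjustments = character())),
  m_tests = 39)
res[, c("exposure", "subgroup", "estimate", "se", "p", "p_adj")]
#>   exposure   subgroup estimate     se        p    p_adj
#> 1    fiber subgroup_1 -0.00982 0.0602 8.71e-01 1.00e+00
#> 2    fiber subgroup_2  0.82973 0.0618 3.82e-41 1.49e-39
#> 3    fiber subgroup_3  0.01166 0.0589 8.43e-01 1.00e+00

bonferroni_threshold(0.05, 39)
#> [1] 0.001282051
```

Reading the output: each sample carries all three subgroups above 1%
probability (fractional membership, not hard clusters), with about two
above 25%. The regression reports one per-SD coefficient per
(exposure, subgroup): one SD more fiber multiplies that subgroup's
Dirichlet concentration by exp(0.83) ≈ 2.3. Subgroup labels are
arbitrary (label switching), so the planted effect lands on
*subgroup_2* here; it survives the 39-test Bonferroni threshold
0.00128 while the unplanted subgroups do not.

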