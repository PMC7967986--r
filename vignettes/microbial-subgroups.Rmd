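---
title: "Microbial subgroups from OTU tables: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbial subgroups from OTU tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`otulda` treats a 16S rRNA OTU table the way a topic model treats a
document collection. Each sample (participant) $i$ is a "document" of
$N_i$ reads; each read is a "word" drawn from a vocabulary of $V$ OTUs.
Latent Dirichlet allocation posits $K$ latent *microbial subgroups*
$\phi_1,\dots,\phi_K$, each a multinomial distribution over OTUs, and a
per-sample mixing vector $\theta_i$ over subgroups:

$$
\theta_i \sim \mathrm{Dir}(\alpha), \qquad
\phi_k \sim \mathrm{Dir}(\beta), \qquad
z_{ij} \sim \mathrm{Mult}(\theta_i), \qquad
w_{ij} \sim \mathrm{Mult}(\phi_{z_{ij}}).
$$

The appeal over hard clustering (enterotypes) is *fractional
membership*: a sample's microbiota is a probability vector over
subgroups, not a single label, and a subgroup is a set of co-occurring
OTUs rather than a centroid dominated by the most abundant taxa.

## Estimation: collapsed Gibbs sampling

`fit_lda_gibbs()` integrates out $\theta$ and $\phi$ and resamples each
read's subgroup assignment from the standard collapsed conditional

$$
p(z_{ij}=k \mid \cdot) \propto (n_{ik}^{-ij} + \alpha)\,
\frac{m_{kv}^{-ij} + \beta}{m_k^{-ij} + V\beta},
$$

where $n_{ik}$ counts reads in sample $i$ assigned to subgroup $k$ and
$m_{kv}$ counts assignments of OTU $v$ to subgroup $k$. After burn-in,
$\theta$ and $\phi$ are posterior means of the smoothed ratios
$(n_{ik}+\alpha)/(N_i+K\alpha)$ and $(m_{kv}+\beta)/(m_k+V\beta)$ over
the retained sweeps, so every probability is strictly positive and each
row sums to one. The inner loop is compiled (Rcpp) with a
self-contained 64-bit Mersenne Twister, so a fit is bit-reproducible
from its seed without touching R's RNG state.

Defaults (`lda_hyperparams()`): symmetric $\alpha = 50/K$,
$\beta = 0.1$, 2000 sweeps, 1000 burn-in, every 10th retained sweep —
the conventional Gibbs-LDA settings. All are arguments; none is
estimated from data. Subgroup numbering is arbitrary (label switching),
so recovery checks always match subgroups by best bipartite matching
before comparing.

Correctness is pinned two ways in the tests. On a 2-sample, 3-OTU
micro-corpus the collapsed posterior can be enumerated exactly over all
$2^6$ assignment configurations; the Gibbs posterior-mean $\theta$
agrees within Monte-Carlo error. Because symmetric priors make that
target uniform by label symmetry, a second enumeration oracle targets
the *fold-in* conditional with a fixed asymmetric $\phi$, where the
exact answer is not symmetric — this pins the sampler's conditional
probabilities themselves.

## Preprocessing

The pipeline expects the field's usual steps, each an explicit call:

1. `normalize_total_count()` — divide each sample by its library size.
2. `filter_otus()` — keep OTUs whose within-sample relative abundance
   strictly exceeds 0.1% in at least 1% of samples (ceiling on the
   sample count). The joint reading — abundance within a sample decides
   whether that sample counts toward prevalence — is the standard one
   and is what reduces sparsity without discarding disease-restricted
   taxa.
3. `normalize_total_count()` again — filtering removes mass, so rows
   are renormalized before rescaling. Keeping this a separate call
   makes each step independently testable; whether to renormalize at
   all is a genuine choice (the alternative leaves row sums slightly
   under 1 and integer rows slightly under the factor) and we take the
   renormalizing branch so integer rows sum to ≈ the factor.
4. `rescale_to_counts()` — multiply by 1000 and round to integers, the
   form a Gibbs sampler consumes; each sample becomes a document of
   ≈1000 tokens. Rounding is half-away-from-zero, stated explicitly
   because "nearest whole number" is ambiguous at exact halves (and
   0.0005 × 1000 *is* an exact half in binary).

## Choosing K

`select_k_cv()` partitions samples into seeded folds; for each
candidate K it fits on the training folds and scores the held-out fold
by *fold-in* perplexity: held-out $\theta$ is re-estimated by Gibbs
with $\phi$ frozen, then
$\mathrm{perplexity} = \exp(-\log L / \text{reads})$. Fold-in is the
simplest defensible held-out evaluation; document-completion splits are
not attempted. The function deliberately returns the whole curve
rather than an argmax: on real microbiome data perplexity keeps
improving with K without a clear optimum, and the practical choice is
made by inspecting jumps (an optional largest-relative-improvement
heuristic can be switched on). `refit_best_of_m()` then refits the
chosen K several times from different seeds and keeps the fit with the
highest training log-likelihood — the only comparison criterion
available without a validation split.

## Dirichlet regression

The K subgroup probabilities are compositional — they sum to one — so
associations with diet and disease are modelled by Dirichlet
regression (`fit_dirichlet_regression()`): one model per exposure, all
K subgroups jointly as the outcome. We use the *common*
parametrization: every subgroup gets its own coefficient vector
through a log link on its concentration parameter,

$$
y_i \sim \mathrm{Dir}(a_{i1},\dots,a_{iK}), \qquad
\log a_{ik} = x_i^\top \gamma_k,
$$

with no reference subgroup and no separate precision submodel. This is
the parametrization that yields one coefficient per
(predictor, subgroup) cell directly, which is the shape of the results
matrix. The likelihood is maximized by BFGS with the analytic gradient
$\partial \ell / \partial \gamma_k = X^\top\!\big[a_k \odot
(\psi(a_0) - \psi(a_k) + \log y_k)\big]$ from a moment-based start
(intercepts from the mean composition and a method-of-moments
precision; slopes zero). Wald standard errors come from the inverse
observed information (numerical Hessian at the optimum);
per-coefficient z-tests give the p-values.

Numerical choices:

* **Boundary.** The Dirichlet density is undefined at the simplex
  boundary. LDA thetas are interior by construction, but serialized or
  foreign compositions may not be, so any entry ≤ 1e-12 triggers the
  standard squeeze $y' = (y(n-1) + 1/K)/n$ with a message.
* **Per-SD estimates.** Continuous predictors are divided by their
  sample SD (`standardize = TRUE`), so coefficients are per-SD and
  invariant to unit changes; a property test asserts this
  equivariance.
* **Missingness.** Rows missing any used variable are dropped and
  counted (`n_dropped`), mirroring complete-case covariate handling.
* **Zero variance.** A constant predictor is an error, not a silent
  NA.

`run_association_battery()` organizes exposures into families (diet,
disease) with family-specific adjustment sets and optional exclusion
rules (e.g. dropping non-fasted samples for serum-lipid models), and
applies a single Bonferroni multiplier equal to the *number of
exposures* across families — not exposures × subgroups — matching the
convention of correcting per fitted model (39 models → threshold
0.05/39 ≈ 0.00128). The multiplier is always taken from the
configuration, never hard-coded.

## Characterization

* `collapse_to_genus()` / `top_genera()` — sums OTU columns by genus;
  the unknown-genus sentinel `"NA"` takes part in the collapse and its
  percentage is reported, but it is excluded from the ranked
  named-genus list. Ties break lexicographically, making rankings
  deterministic.
* `summarize_subgroups()` — per-subgroup medians/IQRs, per-sample
  maximum probability, and counts of subgroups above 1%/10%/25%
  (strict inequality, reading "over" literally).
* `cluster_subgroups()` — Ward agglomerative clustering (`agnes`) on
  Euclidean distances between the *log-transformed full* K × V rows
  (not the genus collapse, which would hide species-level
  differences). Natural log with a 1e-6 pseudocount: phi is strictly
  positive in memory, but TSV round-trips can round to zero. The tree
  exports to newick via `ape`.
* `arrhythmic_fraction()` — for externally supplied OTU lists (e.g.
  OTUs that lose diurnal rhythmicity in type 2 diabetes), sums each
  subgroup's probability mass over each list, as a percentage. Unknown
  ids are an error by default (silent dropping would bias the sums
  downward); `on_missing = "warn"` opts into skip-and-warn.

## Enterotype comparison arm

`assign_enterotypes()` implements the canonical enterotyping recipe:
genus-level profiles, pairwise root Jensen–Shannon divergence (1e-9
pseudocount inside the logs), partitioning around medoids at k = 3.
Clusters are labelled C1..Ck by decreasing size and annotated with
their dominant genus; with exact size ties the labels are arbitrary
even though the partition is stable. `fit_multinomial_logit()` then
relates membership to the same exposures by multinomial logistic
regression (`nnet::multinom`, tight convergence tolerance) with a
declared reference cluster, reporting per-SD odds ratios with Wald
95% intervals. With two clusters this reduces exactly to binary
logistic regression, which the tests verify against `glm` to 1e-6.

## The synthetic-data generator

The generator produces data with exactly the statistical structure the
analysis assumes, plus recorded ground truth:

* `generate_lda_corpus()` draws reads through the LDA generative
  process itself. Planted subgroup-OTU distributions are
  block-structured; `separation` interpolates from disjoint
  vocabularies (1, trivially recoverable) to a shared background (0,
  unidentifiable) — recovery tests use 1, model-selection tests 0.9.
* `generate_covariate_linked_thetas()` plants the Dirichlet-regression
  model: $a_{ik} = s \cdot b_k \cdot \exp(\tilde{x}_i^\top \gamma_k)$
  with $\tilde{x}$ the centered per-SD covariate, so planted $\gamma$
  is on the same per-SD scale the regression estimates. Continuous
  covariates can be drawn with a stated correlation matrix to emulate
  the collinearity of real diet variables; precision $s$ defaults
  to 30, a typical dispersion for subgroup proportions.
* `generate_ancillary()` supplies taxonomy maps with a controllable
  unknown-genus fraction, disjoint OTU sets, and 5-level
  diabetes/hypertension-like labels at prevalences typical of an
  elderly population cohort (47.8% normal glucose tolerance, 10%
  diabetes, and so on).

What the generator does *not* emulate: sequencing noise and batch
effects, compositional artefacts of DNA extraction, the measurement
model behind food-frequency questionnaires, or overdispersion beyond
the Dirichlet-multinomial. Passing recovery tests therefore shows the
estimators are correct *under the model's own assumptions*; it does
not certify behaviour on real data that violates them.

## Problem sizes and tolerances used in the test-suite

The suite runs at desk scale, chosen so the full battery completes in
about a minute: topic recovery on 200 samples × 100 OTUs × 1000 reads
(3 seeds, matched total-variation distance < 0.05); model selection on
150 × 90 × 400 with 5-fold cross-validation (planted K = 3 beats
K = 1); regression recovery at n = 500 with 10 replicates (mean
estimate within ±0.1 of the planted 0.5) and a 200-replicate null
calibration (rejection 5% ± 3%); the enumeration oracle at 10,000+
retained sweeps (|Δ| < 0.02). A full-scale configuration
(≈2000 samples × ≈1700 OTUs, K = 20, K-grid 5–190) is the same code
with larger arguments.

## Known limitations

* Symmetric priors only; no hyperparameter optimization of α/β and no
  asymmetric or structured topic priors.
* Held-out likelihood uses fold-in, which slightly favours larger K
  compared with document-completion estimators.
* Wald inference only; likelihood-ratio and robust variants are out of
  scope, as are FDR-style corrections.
* The Dirichlet regression models mean composition only (no precision
  submodel); strong heteroscedasticity in θ across covariate strata is
  absorbed into the mean coefficients.
* Enterotyping is the JSD + PAM approximation of the classic recipe;
  model-based (Dirichlet-multinomial mixture) enterotyping is not
  implemented.
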