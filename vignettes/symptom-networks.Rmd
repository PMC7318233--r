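---
title: "Estimating symptom networks from binary clinical profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating symptom networks from binary clinical profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
library(dplyr)
```

## The model

symptomnet estimates psychometric networks from dichotomous symptom data:
each of p symptoms is recorded present/absent per patient, and the object
of inference is the conditional-dependence structure among symptoms — an
undirected graph whose edges are regularized partial correlations. The
pipeline is the standard one for binary symptom inventories:

1. **Tetrachoric correlations.** Binary items are modeled as thresholded
   latent standard normals: item j is present when its latent variable
   exceeds a threshold τ_j. For each pair, the latent correlation ρ is the
   tetrachoric correlation, estimated in two steps: thresholds fixed at
   the normal quantiles of the marginal absence rates, then ρ maximizing
   the bivariate-normal likelihood of the 2×2 table by bounded 1-D
   optimization over (−0.999, 0.999). Orthant probabilities use a
   deterministic Gauss–Legendre scheme (absolute accuracy ≈ 1e-15), so
   estimates are bit-reproducible. When a 2×2 cell is zero, 0.5 is added
   to every cell (continuity correction); an item entirely present or
   absent cannot identify ρ, so such pairs are flagged and set to 0.
   Pairwise estimation does not guarantee a positive-definite matrix;
   eigenvalues below a floor (default 1e-6) are clipped and the matrix
   rescaled to unit diagonal, iterating until the floor holds, with a
   `psd_repaired` flag.

2. **EBIC-selected graphical lasso.** A sparse Gaussian graphical model is
   fitted to the tetrachoric matrix by L1-penalized maximum likelihood
   (penalty on off-diagonal precision entries; block coordinate descent,
   convergence at max parameter change < 1e-6). The penalty path has 100
   logarithmically spaced values from λ_max (the largest absolute
   off-diagonal correlation) down to 0.01·λ_max. The retained model
   minimizes EBIC = −2·loglik + E·log n + 4·E·γ·log p with E the nonzero
   edge count and γ = 0.5 by default; exact ties go to the sparser model.
   Edge weights are partial correlations −κ_ij/√(κ_ii κ_jj); the lasso
   sets small edges exactly to zero (a 1e-10 tolerance guards float
   noise when counting).

3. **Spin-glass communities.** Clusters are found by minimizing a
   signed-network Potts Hamiltonian: within-community pairs contribute
   −(w_ij − γ·s_i s_j / 2W), where s_i is the absolute-strength of node i
   and 2W = Σ s_i, so absent and negative within-community links are
   penalized and the resolution γ (default 0.5) scales the
   configuration-model null. Minimization is simulated annealing with
   single-spin Metropolis updates, geometric cooling from temperature 1
   to 0.01 with factor 0.99, at most 17 spin states (capped at p),
   followed by a greedy single-move descent. The all-one and
   all-singleton partitions are always evaluated as baselines, so the
   returned energy never exceeds either. The signed variant is used
   because lasso partial-correlation networks can contain negative edges.

4. **Centrality.** Strength is the sum of absolute incident weights
   (signed "expected influence" available via `signed = TRUE`); closeness
   and betweenness use inverse absolute weight as edge length, with
   closeness scaled by the fraction of reachable nodes (isolates get 0)
   and betweenness giving fractional credit to tied shortest paths.
   Tables report raw values, z-scores, and dense ranks.

5. **Stability.** The case-dropping bootstrap re-runs the whole pipeline
   on subsamples without replacement at drop proportions 0.05–0.75 (step
   0.05) and correlates subsample centralities with the original ones.
   The CS-coefficient is the largest proportion at which ≥95% of
   replicates correlate ≥0.7, all smaller proportions also passing;
   indices are interpretable above 0.25 and preferred above 0.5.
   Product-moment correlation is the default (`cor_method = "spearman"`
   gives the rank-correlation reading of the definition; the two can
   disagree, which is why both ship). Replicates whose correlation is
   undefined — e.g. an empty selected network makes all strengths zero —
   count as failures. Nonparametric bootstrap difference tests resample
   rows with replacement and flag edge pairs or strength pairs whose
   95% percentile CI of the difference excludes zero.

## The synthetic cohort generator

No patient-level data from the motivating study are public, so the
generator is the package's ground truth. It draws latent profiles from a
multivariate normal with a user-specified correlation matrix and
dichotomizes at thresholds Φ⁻¹(1 − π_j) for target prevalences π_j — the
exact model under which the tetrachoric correlation is the population
parameter, which makes recovery tests well-posed. `reap_cohort_spec()`
reproduces the published study conditions: n = 1174 with four
region-by-income cells (403/240/38/493) whose prevalence targets are the
published region-specific rates, so pooled marginals equal the published
overall rates exactly. Its default latent structure is a synthetic sparse
partial-correlation graph over nine symptoms with AGI (psychomotor
disturbance) latently disconnected — an analogue of the published
isolated-AGI finding, *not* the unknown true structure. What passing
tests show is therefore that the pipeline recovers known latent-Gaussian
structure; they cannot show how the original cohort would behave under,
e.g., non-Gaussian latent dependence or informative missingness, which
the generator does not emulate.

```{r example}
cohort <- simulate_cohort(reap_cohort_spec(), seed = 1)
prevalence(cohort) |> head(3)
net <- symptom_network(cohort)
glance(net)
summarize_top3(centrality(net)) |> filter(index == "strength")
```

## Numerical and design choices

* **Two-step vs joint ML tetrachoric:** thresholds from margins, then 1-D
  likelihood maximization; the difference from joint ML is negligible at
  clinical sample sizes and the 1-D problem is fast and robust. The
  estimator matches a brute-force likelihood grid (step 1e-4) to 1e-3.
* **EBIC γ:** the source study prints γ = 0.5 only for the spin-glass
  call; the EBIC hyperparameter is unstated, and 0.5 — the established
  default for this pipeline — is used, separately configurable from the
  spin-glass resolution.
* **EBIC with tetrachoric input over-selects at large n.** Tetrachoric
  correlations carry roughly π/2 times the sampling SD of Pearson
  correlations at equal n, while the Gaussian likelihood inside EBIC
  assumes nominal-n precision. At n = 5000 on planted sparse structures
  this yields perfect sensitivity but a false-positive rate that
  fluctuates around 0.15 seed to seed (Gaussian input: ≈ 0.11). Recovery
  guarantees in the tests are therefore asserted on medians over a fixed
  seed battery, and users should read very small edges at large n with
  caution.
* **Seed management:** every stochastic stage (generator, annealing,
  bootstraps, layout) takes an explicit seed; bootstraps derive
  per-proportion, per-replicate streams from one master seed so any
  replicate can be reproduced in isolation. Identical data + config +
  seed gives a byte-identical JSON report (modulo the timestamp field).
* **Subgroup minimum:** subgroup analyses below n = 150 are skipped with
  a logged reason — small-subgroup networks are too unstable to
  interpret (the motivating study dropped its n = 130 subgroup for a
  CS-coefficient of 0.046).
* **Degenerate inputs:** all-zero/all-one items flag their pairs and
  contribute ρ = 0; bootstrap resamples with a constant item are skipped
  and counted; subsamples below 3p rows are skipped and counted; an
  empty network yields zero centralities, closeness 0 for isolates, and
  a repulsion-only layout.
* **Problem sizes in the shipped tests** (chosen to make each check
  informative at desk scale): oracle equivalence on 200 random 2×2
  tables and all 3-node penalized-likelihood problems; exhaustive
  spin-glass enumeration at p ≤ 6 (203 partitions); recovery at
  n = 5000 (15 seeds) and n = 50000 (single pairs); stability with 100
  bootstrap replicates per drop proportion.

## Limitations

The package covers binary items only — no polychoric (ordinal) or
polyserial estimation, no Ising or nonparanormal alternatives, no
cross-validated penalty selection, and no directed centralities. The
"average edge" language sometimes used for this pipeline is interpreted
as the partial-correlation edge weight itself. CS-coefficients are
bounded above by the largest tested drop proportion (0.75); a saturated
value means "at least 0.75", not perfect stability.
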