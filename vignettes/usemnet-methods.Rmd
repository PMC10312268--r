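---
title: "Multi-level effective connectivity with usemnet: models, search, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level effective connectivity with usemnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usemnet)
```

# The model

`usemnet` estimates directed (effective) connectivity among observed
region-of-interest time series with a unified structural equation model
(uSEM). For a vector of p endogenous node signals $x_t$ and q exogenous
task inputs $u_t$ (boxcar event trains convolved with a hemodynamic
response function), the structural form is

$$x_t = A\,x_t + \Phi\,x_{t-1} + \Lambda\,u_t + \zeta_t,
  \qquad \zeta_t \sim N(0, \mathrm{diag}(\Psi)),$$

where $A$ holds contemporaneous directed paths (zero diagonal), $\Phi$
lag-1 paths (its diagonal are the autoregressive, AR, self-paths), and
$\Lambda$ contemporaneous exogenous effects. Estimation works on the
lag-augmented observation vector $z_t = [x_{t-1}; u_{t-1}; u_t; x_t]$
(`lag_augment()`), whose predictor block is saturated: the likelihood
then factorizes so only the structural parameters and residual variances
are optimized. The discrepancy minimized is the standard ML fit function
$F = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1}) -
\log|S| - m$, with $\chi^2 = (n-1)F$ and $n$ the number of usable lag
pairs (pairs never span subject or segment boundaries).

Gradients of $F$ are analytic; optimization is quasi-Newton (BFGS) with
convergence declared at a gradient max-norm below $10^{-6}$ (cap 500
iterations, flagged otherwise). Standard errors come from the inverse
observed information (finite differences of the analytic gradient),
falling back to the expected information when the observed one is not
positive definite. Modification indices (MIs) are 1-df score tests using
the expected information over the free-plus-candidate parameter set;
they agree with likelihood-ratio refits to within a few percent on
near-optimal models, which the test suite checks directly.

Residual covariance is diagonal. This matches the estimation convention
of this model family; it is also the assumption under which the
synthetic-data generator draws innovations, so estimator and generator
are consistent by construction.

# Search procedures

Four procedures share one greedy engine: fit, compute MIs for every
admissible candidate (no paths into exogenous nodes, no contemporaneous
self-loops), add the best significant candidate, refit.

* `search_aggregate()` standardizes every subject, concatenates, and
  searches one model for the pooled data (level `"aggregate"`).
* `search_individual()` searches one subject with no group information
  (an idiographic model).
* `group_search()` iterates over subjects jointly: a candidate is added
  to the group model only when its MI is significant for at least a
  fraction `gamma` (default 0.75) of subjects; afterwards group paths
  whose estimates are significant for fewer than `gamma` of subjects
  are pruned, least-supported first.
* `finalize_individuals()` starts each subject from the group (and,
  when a robust subgrouping solution exists, subgroup) model and adds
  individual-level paths, then prunes them at $\alpha = .05$.

AR self-paths are freed in the null model of every procedure and are
never pruned: they absorb the strong temporal autocorrelation of the
BOLD-like signal so that discovered cross-paths are not proxies for it.

**Stopping rule.** The greedy searches stop when no candidate's MI
exceeds the Bonferroni-corrected $\chi^2(1)$ critical value over the
current candidate count (`stop_rule = "mi_bonferroni"`). The search
therefore runs exactly until no edge would still improve fit beyond
multiplicity-corrected chance. We also provide the alternative rule that
stops as soon as two of four fit indices reach the excellent thresholds
(`stop_rule = "excellent"`; CFI/NNFI ≥ .95, RMSEA/SRMR ≤ .05), which
some reference implementations use. We made the MI-based rule the
default after observing that the excellent-fit rule can halt while a
genuine path still carries a modification index an order of magnitude
above its critical value — with six nodes, a single missing path leaves
too little *relative* misfit to keep CFI below .95, and planted-truth
recovery suffers accordingly. The uncorrected threshold, in turn, admits
spurious paths once the true structure is recovered, because the best of
~70 null candidates is regularly "significant" at an uncorrected .05.
The Bonferroni rule resolves both failure modes and is the package's
recommended default.

Model quality is always reported against the conventional thresholds
CFI ≥ .90, NNFI ≥ .90, RMSEA ≤ .08, SRMR ≤ .08 (`evaluate_fit()`, all
comparisons inclusive), with the baseline the independence model (all
covariances zero, variances free).

Ties in candidate selection are broken deterministically: higher MI
first (for group counting, larger supporter count, then larger summed
MI), then lexicographic (from, to, lag). Re-running any search on the
same input reproduces the identical path set, and the returned search
log allows exact replay.

# Subgrouping and its validation

After the group stage, subject similarity is
$s_{ij} = |\{\text{candidates with significant MI for both } i, j\}| +
|\{\text{group paths significant with the same sign for both}\}|$
(`build_similarity()`; the two terms can be reweighted). Communities
come from Walktrap (walk length 4, merge sequence cut at maximal
modularity) on the weighted graph.

Internal validity is assessed per the preregistered logic of the study
this package operationalizes (`robustness_report()`):

1. **Stability.** For each fraction on a grid, that share of similarity
   edges is rewired to vacant pairs (weight multiset preserved), the
   perturbed matrix is re-clustered, and the mean Variation of
   Information (VI) to the original partition is recorded. The
   criterion passes when at least 20% of edges must be perturbed before
   the mean VI reaches the reference VI of a partition with a random
   20% of labels reassigned.
2. **Modularity.** The observed solution's Q must reach the 95th
   percentile of a node-exchangeable null: the observed weight multiset
   placed on uniformly random pairs, re-clustered with Walktrap.

One property of these curves is worth knowing: at extreme perturbation
fractions Walktrap tends to collapse to a single community, so the mean
VI settles at the entropy of the original partition ($\ln 2$ for two
equal blocks) *below* its mid-fraction peak. VI curves are therefore
monotone only on the rising region — which is the region the stability
criterion uses.

The subgroup-level path search (`subgroup_search()`, strict majority
within each community, default > 50%) is run only when a solution
passes both criteria; otherwise individual models are finalized from
the group model alone, mirroring the study's preregistered decision
rule.

# Heterogeneity summaries

`path_overlap()` counts, per subject, discovered paths shared with the
aggregate model, matching on (from, to, lag) and ignoring estimates —
network presence, not strength. "Sharing less than half" means a count
below `ceiling(|aggregate| / 2)`. Auto-freed AR paths are excluded from
these counts by default (they are not discovered structure; set
`include_base = TRUE` to include them). `prevalence()` tabulates how
many subjects retain each non-group path, keeping paths present in at
least `ceiling(0.20 n)` subjects by default.

# Behavioral associations

`build_features()` encodes group paths as continuous per-subject betas
(estimated for everyone) and prevalent subgroup/individual paths as
binary presence indicators. `adaptive_lasso()` standardizes the
columns, derives per-feature penalty factors $w_j = 1/|\hat\beta_{
\mathrm{ridge},j}|^\gamma$ from a 10-fold-CV ridge stage ($\gamma = 1$;
coefficients below machine tolerance receive a large finite factor),
and fits the L1 path with 10-fold CV. The penalty is chosen by the
minimum-CV-error rule by default, with the more conservative one-SE
rule available (`lambda_rule = "1se"`). The two rules trade off
sensitivity and specificity: under a global null the min-CV rule
selects any given feature at a rate of about 0.10 while the one-SE rule
is near 0.003, but the one-SE rule misses moderate (≈0.5 SD) true
effects at n ≈ 100 noticeably more often. Reported $R^2$ and adjusted
$R^2$ come from an unpenalized refit on the selected set; a
penalized-prediction $R^2$ is also returned for transparency. Binary
outcomes use the logistic variant of both stages with McFadden
pseudo-$R^2$, clearly labeled.

`posthoc_ols()` runs one simple regression per selected feature —
deliberately marginal, matching the post hoc reporting convention of
the study — plus a joint OLS for the $R^2$ report. `subgroup_anova()`
applies one-way ANOVAs per outcome with Benjamini–Hochberg correction
across the outcome family and Welch pairwise t-tests only for outcomes
passing the corrected threshold.

# The synthetic cohort generator

`make_scenario()` + `simulate_cohort()` generate cohorts from known
multi-level uSEM structures so that every stage above is testable with
ground truth. Defaults emulate the study conditions this package was
calibrated against: 103 subjects, 15 nodes plus 2 HRF-convolved task
regressors, 239 frames at TR = 2 s, 19 group paths, three subgroups
(member fractions 28/31/44 of 103; 6/14/10 distinctive paths), a
17-path individual pool at 25% inclusion, coefficient magnitudes
uniform on [0.3, 0.7] with 80% positive signs, AR coefficients uniform
on [0.4, 0.7], unit innovation SD, and per-subject coefficient jitter
of SD 0.2 around each level's value (matching the across-subject spread
of reported group-path betas, and giving beta-encoded features genuine
between-subject variance). Exogenous regressors are generated for the
default scenario but carry no structural effects unless requested
(`n_exo_paths`), consistent with the finding that no group-level task
paths were identified; they still enter estimation as saturated
predictors.

The card-guessing-style task schedule places a 6 s anticipation event
4 s into each 17 s trial and a 1 s outcome event at 10 s, with a
uniformly jittered intertrial interval. A note on arithmetic: 24 trials
with a mean 4 s ITI overshoot a 478 s scan, so the default scenario
compresses the ITI to a mean of 2.5 s (uniform 1–4 s) so that the
canonical 24 trials fit the canonical 239 frames;
`simulate_task_events()` itself defaults to the 4 s ITI and checks the
fit-in-scan precondition explicitly.

**Structure constraints.** Contemporaneous ground-truth graphs are
acyclic by default: a feedback loop in $A$ is near-unidentifiable from
a few hundred frames, making "true direction" meaningless as a
recovery target. The `benchmark_structure` flag further forbids
contemporaneous-skeleton triangles and allows at most one structural
path per node pair. Recovery benchmarks use it because two confound
patterns otherwise contaminate direction scoring: a common parent of
both endpoints lets the *reversed* path absorb the missing parent
effect (we observed the reversed candidate beating the true one by a
wide modification-index margin in exactly these configurations), and a
contemporaneous path coexisting with its reversed cross-lag twin has a
near-equivalent representation with the lags swapped. Validation
studies of this model family likewise benchmark on sparse recursive
structures. The default full-scale scenario does *not* set this flag —
realistic brain networks contain triangles — and is used for
qualitative and pipeline-level testing rather than exact recovery
scoring.

**Stationarity.** Every subject's realized system must satisfy
invertibility of $I - A$ and a companion spectral radius below 1. The
generator first retries whole coefficient draws (bounded retries). At
the full default density, however, *no* draw with magnitudes in
[0.3, 0.7] is stationary — same-signed contemporaneous chains amplify
the reduced-form dynamics past the unit circle — so a stabilization
fallback rescales an unstable subject's non-AR coefficients by a common
factor (binary search) to a companion radius of 0.9, recording the
attained values in the ground-truth ledger. Setting `stabilize = FALSE`
restores a hard generation error instead. Fitted coefficient magnitudes
in dense scenarios are therefore smaller than the nominal range, which
is the price of demanding exact stationarity at realistic density.

Innovations are Gaussian and independent across nodes; a burn-in of 50
steps (exogenous inputs zero) is discarded. Subgroup membership is
assigned by deterministic fraction blocks shuffled under the seed, and
every operation is a pure function of its inputs and seed.

**Behavioral link.** `simulate_behavior()` applies linear effects to
z-scored feature columns by default (`standardize_features = TRUE`), so
simulated effect sizes are stated per feature SD — the same convention
under which the analysis standardizes its predictors. With raw 0/1
presence indicators, a coefficient of 0.5 would amount to only ≈0.23
outcome SDs and would be undetectable at n ≈ 100 regardless of the
selector; per-SD effects keep simulated signal strengths meaningful.

**What the generator does not emulate.** No physiological noise, scanner
drift, motion artifacts, hemodynamic variability of the endogenous
nodes, or non-Gaussian innovations. Passing recovery tests on these
cohorts therefore demonstrates correctness of the estimation and search
machinery under the model's own assumptions — not robustness to the
full noise structure of real fMRI, where preprocessing quality,
unmodeled confounds, and HRF mismatch additionally matter. An optional
motion-confound generator was considered and deliberately left out of
scope; the QC module (`qc_exclude()`) operationalizes the
participant-exclusion arithmetic instead (staged rules: behavioral
compliance < 75%, low tSNR and high mean FD by one-sided Tukey fences
recomputed over the currently retained subjects, then > 25% of frames
with FD ≥ 2 mm).

# Problem sizes used in the test suite

The automated tests exercise recovery at reduced problem sizes chosen
to make the statistical properties measurable in minutes: 5–8 nodes,
150–500 frames, cohorts of 8–103 subjects, with 10-seed repetitions for
stochastic criteria. These sizes were fixed as the package's benchmark
conditions; the full-scale default scenario (103 × 15 × 239) runs
through the same code paths and is exercised for construction,
determinism, and single-subject search in the suite.

# Known limitations

* Only lag-0 and lag-1 dynamics; no bilinear task-modulated paths.
* Contemporaneous feedback loops are estimable in principle but poorly
  identified at typical scan lengths; the generator avoids planting
  them and the search may resolve such structure into lagged
  equivalents.
* Adaptive-lasso associations are in-sample; no train/test split is
  offered, and selected features should be treated as descriptive.
* The similarity definition reconstructs a one-line description from
  the source methodology; its two terms are configurable precisely
  because that reconstruction is not unique.
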