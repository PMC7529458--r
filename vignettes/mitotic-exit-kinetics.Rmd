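---
title: "Kinetic analysis of mitotic-exit dephosphorylation time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic analysis of mitotic-exit dephosphorylation time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dephoskin)
```

## The measurement and its model

In a dimethyl-labelled mitotic-exit time course, cells are released into
anaphase (typically by CDK1 inhibition after nocodazole washout) and
sampled densely — every 30 s to 10 min, then more sparsely to 60 min. All
timepoints carry the heavy label, the pooled t = 0 sample the light label,
so the H/L ratio of a phospho-peptide or protein directly measures
level(t)/level(0). A dephosphorylated site or a degraded protein therefore
traces a decaying ratio curve starting at 1.

The kinetic model throughout is plateau plus one-phase exponential decay,

$$y(t) = P + (y_0 - P)\,e^{-Kt},$$

with the asymptote $P$, rate constant $K$ (min$^{-1}$) and, after
normalization, $y_0 = 1$. The **half-life** is deliberately *not* the
exponential time constant $\ln 2 / K$: it is the time at which the fitted
curve crosses the absolute value $y = 0.5$,

$$t_{1/2} = \frac{1}{K}\ln\frac{y_0 - P}{0.5 - P},$$

which is the operationally meaningful "half the starting material is gone"
point and exists only when $P < 0.5$ and $K > 0$. Curves that never cross
0.5 within the observation window carry an infinite half-life, serialized
as the sentinel `">60"` (for a 60-min window). A profile already at or
below 0.5 at t = 0 has half-life zero.

## Preprocessing rules

The pipeline reproduces the field's standard Perseus/Excel processing
chain, each step exposed as a function:

1. `filter_sites()` — drop contaminants, reverse-database (decoy) hits and
   identifications by modification site only; keep sites with localization
   probability **strictly** greater than 0.75 (a site at exactly 0.75 is
   removed — the threshold is read literally as ">").
2. `impute_missing()` — a *single* missing value is replaced by the mean of
   its two neighbours, or by the one adjacent value at the first/last
   timepoint; runs of **two or more** consecutive missing values are left
   missing, because they more plausibly represent true zeros than missed
   quantifications. Imputation runs per replicate, before averaging, so
   each replicate's kinetics stay intact.
3. `average_replicates()` — arithmetic mean of the t/t0 ratios per
   timepoint, requiring at least two valid replicate values; the
   contribution count per cell is kept as provenance. Averaging is on the
   ratio scale, not log-ratios, matching how such time courses are
   conventionally summarized.
4. `reference_filter()` — rows must be quantified over time at least as
   well as designated reference profiles (a well-covered proteolysis
   reference such as CCNB1, a dephosphorylation reference such as
   PRC1-pT481). The coverage rule is ambiguous in practice, so both
   readings exist: `"count"` (default; at least as many quantified
   timepoints) and `"mask"` (quantified wherever the reference is). Neither
   is asserted as *the* original rule.
5. `zero_fill()` — remaining gaps become the constant 0 so that clustering
   can operate on complete rows. Zeros then participate in distances as
   real values; this is a documented caveat, not a bug, and mirrors how
   heatmap clustering tools treat filled matrices.

## Fitting and determinism

`fit_one_phase_decay()` performs bounded least squares
($0 \le P < y_0$, $K \ge 0$) from a fixed grid of starting values
($K \in \{\ln 2/2, \ln 2/10, \ln 2/40\}$, $P \in \{0, 0.25\}$), keeping the
best residual sum of squares, then polishes with a Gauss–Newton (port)
step guarded by an RSS comparison. There is no randomness: identical
profiles give bit-identical fits, and noiseless profiles are recovered to
better than $10^{-6}$ relative error. Constant profiles short-circuit to
$K = 0$ with the sentinel half-life. $y_0$ is fixed at 1 after
`normalize_to_start()`; a free-$y_0$ mode exists for diagnostics only.

Cluster half-lives default to *fit-of-mean*: average the member profiles
(mean ± SEM per timepoint), normalize to 1, fit, read off the 0.5
crossing. For perturbation comparisons the convention is *mean-of-fits*
(fit each member, average the finite half-lives), which is how per-cluster
control/perturbed half-lives are compared; both are available in
`cluster_half_life()`.

## Clustering

`cluster_profiles()` combines agglomerative clustering (Euclidean
distance, average linkage) cut at *k* with Lloyd k-means refinement seeded
from the agglomerative centroids, plus seeded random restarts. The hybrid
honors both the "hierarchical clustering" procedure and its
iteration/restart parameters (10 iterations, 1 restart for one condition;
25 and 2 when comparing two) while remaining deterministic under a seed.
Clusters are relabelled by ascending half-life; with $k = 4$ and exactly
one never-decaying cluster they get the canonical names early /
intermediate / late / stable.

For two-condition analyses, `concatenate_conditions()` joins the shared
rows as `[control | perturbed]` profiles and diverts rows quantified in
only one condition into a separate *noisy* category rather than dropping
them. `select_k()` operationalizes the iterative cluster-count search:
starting at $k = 3$, *k* grows until some cluster falls below a minimum
fraction of rows (default 0.02, the "random groupings containing very few
identifications" criterion made explicit); the largest compliant *k* wins.
`compare_conditions()` then flags clusters whose perturbed half-life is
**more than 1.5×** the control half-life (strictly; an infinite perturbed
half-life against a finite control also counts).

## Cross-mix adjustment and the steady-state screen

Steady-state differences between conditions are measured by cross-mixed
t0 samples (light t0 of one condition mixed with heavy t0 of the other).
`crosswise_adjust()` divides perturbed ratios either per entity or by the
global geometric-mean cross-mix ratio — the global mode exists because a
labelling or mixing error can invalidate individual cross-mix values while
their average remains usable. `steady_state_fold_change()` flags entities
whose adjusted perturbed t0 is strictly more than 2× the control t0. The
threshold is descriptive, not inferential; no multiple-testing correction
is applied, and the documentation says so rather than pretending a test
was performed.

## Endpoint protein half-lives

For deep (fractionated) proteome time courses sampled every 10 min,
`endpoint_half_life()` follows the endpoint procedure: subtract each
timepoint column's median, add the correction 0.85, average the 50- and
60-min adjusted ratios (the 60-min samples run systematically high) into a
remaining fraction $f$, and convert under first-order decay,
$t_{1/2} = 60\,\ln 2 / (-\ln f)$. Fractions at or above 1 are stable;
fractions are clamped below at $10^{-6}$ rather than erroring, since
median subtraction can push extremes out of range. Destruction classes cut
at 60 min (fast enough to matter for anaphase), 2 h (telophase/early G1)
and 5 h (G1); slower or sentinel half-lives are stable.

Two caveats are worth stating. First, the first-order conversion is an
assumption — the endpoint value alone cannot distinguish exponential from
lagged decay. Second, the 0.85 correction is calibrated to data in which
detection efficiency drifts over the gradient; on synthetic data whose
column medians sit at 1, a perfectly stable protein lands at $f = 0.85$
and an apparent half-life of ≈4.3 h ("G1" class), so classification of
borderline-stable proteins is conservative there. The anaphase class
(≤60 min) is robust to this.

## Motif enrichment

`enrichment()` implements iceLogo-style position-specific residue
enrichment: for each window position and residue, the experimental
frequency is compared with the distribution of frequencies in same-sized
subsets of the reference set (all clustered sites). The default mode
samples `n_samples = 2000` seeded subsets; the `"analytic"` mode uses the
binomial normal approximation $\sigma = \sqrt{\mu(1-\mu)/n}$ and is fully
deterministic — it is the mode used in property tests and the acceptance
analysis. p-values are two-sided normal, significance is $p < 0.05$ with
no multiple-testing correction (matching the plain threshold convention of
logo software), and the reported effect is the percent difference
$100(f_\mathrm{exp} - \mu)$. Padding characters (`_`) at protein termini
are excluded from the frequency denominators so truncated windows do not
dilute composition. When a residue is absent from (or fixed in) the
reference, $\sigma = 0$; such cells carry an infinite-z sentinel and are
significant exactly when the experimental frequency differs.

## The synthetic-data generator

`simulate_dataset()` is first-class, tested code, not a fixture. It
emulates: the default 28-point sampling grid (0–10 min at 30 s, then 12.5,
15, 20, 30, 40, 50, 60); 2–4 replicates; four kinetic classes with
half-lives 5, 13.5, 46 min and stable — the cluster half-lives observed
for CDK-inhibition-triggered mitotic exit, used as generator truth — with
plateaus of 0 so the configured half-life is simultaneously the
exponential half-life and the 0.5 crossing; class-conditional 15-mer
windows (threonine-centred, basic-enriched, acidic-depleted early class
grading to a serine-centred, downstream-acidic stable class);
multiplicative lognormal ratio noise with unit mean (ratios are positive
and MS ratio error is multiplicative) at default CV 0.15 — a plausible
mid-range value, varied in tests, since the true magnitude is
data-dependent; first-order missingness (default rate 0.05, run-extension
probability 0.3) generating the consecutive-missing runs the imputation
rule must leave alone; a stable proteome background with a small set of
degraded proteins following delayed-exponential destruction (lag then
exponential — two interpretable parameters and a closed-form half-life of
lag + h, approximating the delayed sigmoidal destruction of cyclin B under
checkpoint-silencing conditions); and decoy/contaminant/low-localization
nuisance records at fixed small rates so the filters have work to do.

Two-condition designs are defined *in the generator*: one configuration
with `condition_offset` (the steady-state scale between conditions,
recovered by cross-mix adjustment) and `perturbed_half_life_scale` (the
kinetic effect of the perturbation). Identity draws (class membership,
windows, flags) come from the master seed and are shared between
conditions; noise and missingness come from condition-derived streams, so
the two conditions are the same entities measured independently.

What the generator does **not** emulate: peptide-level aggregation,
intensity-dependent missingness, co-eluting isobaric interference,
correlated noise across neighbouring timepoints, or any relationship
between a site's kinetics and its protein's abundance. Passing tests
therefore demonstrate correctness of the analysis logic under the stated
noise model, not robustness to every pathology of real data.

## Problem sizes and numerical choices

The test and acceptance analyses use 150–1000 sites, four replicates and
the 28-point grid — ample for exact recovery (adjusted Rand index 1.0
against planted classes at noise CV 0.1) while keeping a full run in
seconds. Ties in cluster ordering are broken by descending size;
degenerate inputs (constant profiles, empty clusters, all-missing series,
references absent from the matrix, k exceeding the row count) error with
messages naming the violated precondition rather than guessing. One master
seed drives simulation identity, condition noise, clustering restarts and
motif sampling through independent derived streams, so a single integer
reproduces an entire run.

## Known limitations

* The Euclidean/average-linkage distance on zero-filled ratios treats
  fill-zeros as data; heavily censored rows can attract each other.
* The dependence and steady-state rules are threshold classifications
  without error control; they inherit the noise of the underlying
  half-life fits.
* Endpoint half-lives beyond a few multiples of the observation window are
  extrapolations and should be read as order-of-magnitude statements.
* The iterative *k* selection explores a single path (increasing *k*) and
  accepts the last compliant partition; it does not optimize a global
  criterion.
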