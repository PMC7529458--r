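# dephoskin

Kinetic classification of dephosphorylation and proteolysis in
high temporal-resolution mitotic-exit proteomics time courses.

## The problem

During mitotic exit, APC/C-mediated proteolysis of cyclin B inactivates
CDK1 and relieves inhibition of the counteracting phosphatases PP1 and
PP2A-B55, triggering a cascade of dephosphorylations whose order is encoded
in the sequence context of each phospho-site. Quantitative dimethyl-label
proteomics tracks this: every timepoint carries the heavy label and the
t = 0 sample the light label, so the H/L ratio of a phospho-peptide or
protein measures level(t)/level(0). `dephoskin` is for analysts who have
MaxQuant-style site and protein-group tables from such experiments and want
to classify sites by dephosphorylation kinetics, estimate half-lives,
compare perturbed against control conditions, and characterize the sequence
determinants of dephosphorylation rate.

## What it computes

* **Preprocessing** following the field's conventions: removal of
  contaminants, decoy hits and site-only identifications; localization
  probability strictly above 0.75; per-replicate replacement of *single*
  missing values (mean of neighbours, or the adjacent value at the ends —
  runs of two or more stay missing); replicate averaging requiring at least
  two valid values; coverage filtering against reference profiles; zero-fill
  before clustering.
* **Kinetics**: bounded least-squares fits of the plateau plus one-phase
  decay model `y(t) = P + (y0 − P) e^(−Kt)`, with the half-life defined as
  the time the fitted curve crosses the absolute value `y = 0.5`:
  `t½ = ln((y0 − P)/(0.5 − P))/K`. Endpoint-based protein half-lives use
  median subtraction, a 0.85 correction, averaging of the 50/60-min columns
  and first-order conversion, with destruction classes cut at 60 min, 2 h
  and 5 h.
* **Clustering**: agglomerative (Euclidean, average linkage) partitioning
  with seeded k-means refinement into kinetic classes (early, intermediate,
  late, stable), iterative cluster-count selection for two-condition runs,
  and the phosphatase-dependence rule (perturbed half-life more than 50 %
  longer than control).
* **Condition comparison**: rescaling of a perturbed condition onto the
  control scale using cross-mixed t0 samples, and the steady-state screen
  flagging sites whose t0 phosphorylation more than doubles.
* **Motifs**: iceLogo-style position-specific residue enrichment of cluster
  sequence windows against the all-clustered background, with a p < 0.05
  significance filter (sampled or analytic reference distribution).
* **Synthetic data**: a seeded generator with known kinetic classes,
  class-conditional sequence composition, lognormal ratio noise, runs of
  missing values, degraded proteins and cross-mixed two-condition designs,
  so the whole pipeline is testable with ground truth.

## Worked example

```r
library(dephoskin)

cfg <- sim_config(n_sites = 1000, n_replicates = 4, noise_cv = 0.1, seed = 1)
sim <- simulate_dataset(cfg)
res <- run_pipeline(sim$sites, run_config(motif_mode = "analytic", seed = 1),
                    proteins = sim$proteins)
print(res)
#> Pipeline result: 882 sites clustered into 4 groups
#> Cluster result: k = 4, 882 rows
#>         label   n half_life
#>         early 215  5.00 min
#>  intermediate 221 13.47 min
#>          late 238 46.27 min
#>        stable 208  > window
```

Of 1000 simulated sites, 882 survive the flag and localization filters and
cluster into the four kinetic classes; the fitted cluster half-lives
recover the generator's 5, 13.5 and 46 min truths, and the stable cluster
never crosses y = 0.5 within the 60-min window. The central-residue
composition shows the graded phospho-threonine preference of fast
dephosphorylation:

```r
res$motifs$central_composition
#>        cluster   n    S    T     Y
#> 1        early 215 0.29 0.69 0.019
#> 2 intermediate 221 0.58 0.40 0.018
#> 3         late 238 0.74 0.24 0.017
#> 4       stable 208 0.85 0.13 0.014
```

Real MaxQuant exports enter through `read_site_table()` /
`read_protein_table()` with a `time_course_design()` describing the ratio
column naming, and results leave through `write_results()` as TSV plus a
JSON summary.

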