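# memshape

Analysis of membrane-remodeling simulations in R: signed membrane
curvature from coordinate trajectories, bicelle-to-vesicle transition
kinetics under a lagged single-Poisson model, and protein
conformational-ensemble statistics.

## Who this is for

Computational biophysicists analyzing coarse-grained simulations of
finite membrane patches — e.g. DMPC/DHPC bicelles carrying curvature-
active proteins such as reticulon-homology-domain (RHD) ER-phagy
receptors — who need a tested, reproducible path from bead coordinates
to vesiculation rates and ensemble statistics. Because such trajectories
are rarely deposited, the package includes a synthetic-trajectory
generator with exactly known ground truth, so every stage of the
pipeline is validated end to end.

## The model at the core

* **Curvature.** Each frame's lipid head beads (both leaflets of the
  long-chain lipids; rim lipids excluded) are fitted with a sphere by
  least squares on the geometric residuals Σ(|xᵢ − c| − r)². The signed
  curvature is H = ±1/r: positive when the membrane curves away from the
  cytoplasmic leaflet (cytoplasmic side convex), negative toward it.
  Near-planar frames are flagged flat and reported as H = 0. Traces are
  smoothed with a centered 11-ns running mean.
* **Kinetics.** The waiting time of a replicate is the first time its
  smoothed |H| holds above the vesicle-formation threshold
  (0.15 nm⁻¹) for 3 consecutive samples. Waiting times follow a Poisson
  process with lag: p(t) = k′ e^(−k′(t−τ)) for t > τ, with t′ = 1/k′.
  The vesiculation rate is k_vesicle = 1/(t′ + τ), and acceleration
  factors are acc = k_sys / k_ref with the empty-bicelle reference
  k_ref = 1.09 × 10⁻⁵ by default. Fits by closed-form/profile maximum
  likelihood (censoring-aware) and by least squares against the
  empirical CDF; uncertainties by case-resampling bootstrap.
* **Ensembles.** Radius-of-gyration densities, RMSF about the
  post-superposition mean after Kabsch fitting (proper rotations only),
  pairwise RMSD matrices in compiled code, and gromos clustering
  (greedy neighbor counting at a 0.8-nm RMSD cutoff) with populations in
  descending order. Amphipathic-helix descriptors (mean hydrophobicity,
  Eisenberg hydrophobic moment, net charge with R/K/H vs D/E classes)
  round out the toolbox.

Details, assumptions and numerical choices are in the methods vignette,
`vignettes/membrane-remodeling-kinetics.Rmd`.

## Worked example

Simulate one bicelle replicate with known truth, measure its curvature
trace, and detect the transition:

```r
library(memshape)
p <- bicelle_params(seed = 7)           # true k' = 0.02 1/ns, tau = 150 ns
rep <- generate_bicelle_trajectory(p)
s <- smooth_series(curvature_series(rep$trajectory), window = 11)
detect_waiting_time(s)
#>     time censored
#>      166        0
rep$ground_truth$crossing_time          # truth: ramp completes at
#> [1] 162.4173                         # event + 10 ns closure
```

The detected time (166 ns) trails the true crossing (162.4 ns) by a few
nanoseconds of smoothing-and-debounce latency, as expected. Fitting the
lagged exponential to a replicate ensemble:

```r
w <- sample_waiting_times(k_prime = 0.02, tau = 150, n = 20,
                          horizon = 1000, seed = 1)
fit <- fit_lagged_exponential_mle(w)
fit
#> <lagged_exp_fit> method=mle: k'=0.0210631 1/ns, tau=156.99 ns,
#>   k_vesicle=0.00489078 1/ns (20 events, 0 censored)
acceleration_factor(fit)
#> <acceleration_result> acc=448.7 (k_sys=0.004891 / k_ref=1.09e-05)
```

With only 20 replicates the estimates scatter around the truth
(k′ = 0.02, τ = 150, k_vesicle = 1/200 = 0.005); the acceleration factor
is the fitted rate over the empty-bicelle reference. The full pipeline —
20 generated replicates, per-replicate curvature TSVs, both fits,
bootstrap intervals and a JSON report — is one call:

```r
report <- run_curvature_kinetics(list(n_replicates = 20, k_prime = 0.02,
                                      tau = 150, seed = 1,
                                      out_dir = "study"))
```

Ensemble statistics work the same way through `run_shape_analysis()`
(even subsampling, Rg density, RMSF, pairwise RMSD, gromos clustering,
JSON summary).

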