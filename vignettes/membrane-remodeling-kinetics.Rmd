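---
title: "Membrane curvature, vesiculation kinetics and conformational ensembles"
author: "memshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane curvature, vesiculation kinetics and conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memshape)
```

## The analysis problem

Coarse-grained simulations of membrane remodeling — for example, reticulon
homology domains (RHDs) of ER-phagy receptors driving disc-shaped
DMPC/DHPC bicelles to close into vesicles — produce two kinds of raw data:
coordinate trajectories of labeled beads, and, derived from them, scalar
observables whose statistics carry the biology. This package implements
the full chain from coordinates to rates:

1. a **geometric stage** that reduces each frame to a signed membrane
   curvature $H(t)$ (nm$^{-1}$) by least-squares sphere fitting of lipid
   head-bead coordinates;
2. a **kinetic stage** that extracts per-replicate waiting times for the
   bicelle-to-vesicle transition and fits a lagged single-Poisson model,
   yielding vesiculation rates and acceleration factors relative to a
   protein-free reference;
3. a **conformational stage** for protein ensembles: radius-of-gyration
   densities, RMSF after Kabsch superposition, pairwise RMSD and gromos
   clustering.

Because published simulation trajectories of this kind are rarely
deposited, the package also ships a **synthetic-data module** that
generates trajectories with exactly known ground truth. Every stage is
validated end to end against that truth; the final section discusses what
such validation does and does not establish about real data.

## Signed curvature by sphere fitting

Each frame's selected beads (by default the head beads of long-chain
lipids from *both* leaflets, excluding the short-chain rim lipids that
occupy the high-curvature bicelle edge) are fitted with a single sphere by
minimizing the geometric residuals $\sum_i (|x_i - c| - r)^2$. The
curvature magnitude is $|H| = 1/r$, and the sign is set by the leaflet
convention: if the mean distance of cytoplasmic-leaflet beads from the
fitted center exceeds that of luminal-leaflet beads, the cytoplasmic
leaflet is convex, the membrane bends away from the cytoplasm, and $H >
0$; otherwise $H < 0$. Fitting both leaflets jointly makes the fitted
radius approximate the bilayer mid-surface; the bead selection is
configurable for callers who prefer per-leaflet fits.

Numerically the fit is a multi-start Gauss–Newton iteration with
backtracking line search. The classical algebraic (Coope) linearization
provides one start; it is excellent for genuinely spherical clouds but on
two-leaflet input it reliably lands in a spurious local minimum — a small
sphere threaded between the two layers — whose geometric residual exceeds
that of the correct mid-surface solution. Two additional near-planar
starts on either side of the best-fit plane, plus an
osculating-paraboloid start, let the damped iteration track the very
shallow valley of the objective down to the mid-surface optimum. A frame
is declared flat (and $H$ reported as exactly 0) when the input is
coplanar, when no sphere candidate beats the best-fit plane, or when the
fitted radius exceeds `flat_radius_cutoff` (default 100 nm, i.e.
curvature below 0.01 nm$^{-1}$ is indistinguishable from flat at bicelle
scale). A consequence worth knowing: true curvatures in the open interval
$(0, 1/\texttt{flat\_radius\_cutoff})$ are reported as 0 by design.

Curvature traces are smoothed with a centered running mean over an 11-ns
window (the field's reporting convention); the window is expressed in
time, not frames, so irregular sampling is tolerated, and it shrinks
symmetrically at the series edges. Smoothing is deliberately single-shot:
re-smoothing a smoothed series is an error, because the recorded window
would no longer describe the effective filter.

## Waiting times and the lagged single-Poisson model

A replicate's waiting time is the first time its smoothed $|H(t)|$ stays
at or above the vesicle-formation threshold (default $0.15$ nm$^{-1}$;
the value $0.14$ sometimes used in figure annotations can be passed
instead) for `persistence = 3` consecutive samples. The persistence
debounce suppresses single-sample noise crossings; `persistence = 1`
restores the strict first crossing. Replicates that never cross are
censored at the observation horizon.

Waiting times are modeled as a Poisson process with a deterministic lag:
$$p(t) = k' e^{-k'(t - \tau)}, \qquad t > \tau,$$
where $\tau$ is the time needed for vesicle closure from the curved disc
and $t' = 1/k'$ the stochastic part. The vesiculation rate is
$k_\mathrm{vesicle} = 1/(t' + \tau)$, an identity the fit objects
preserve exactly. Two fitters are provided:

* **Maximum likelihood** (`fit_lagged_exponential_mle`). Without
  censoring, $\hat\tau = \min t_i$ and $\hat{k}' = 1/(\bar t - \min
  t_i)$. With right-censoring at the horizon $h$, $\hat\tau$ stays at the
  minimum uncensored time — the profile likelihood increases in $\tau$ up
  to the sample minimum, and censoring at the horizon cannot move it —
  and the survival terms $e^{-k'(h-\hat\tau)}$ give the closed-form
  maximizer $\hat k' = n_\mathrm{events} / \left(\sum_i (t_i - \hat\tau)
  + n_\mathrm{cens}(h - \hat\tau)\right)$.
* **CDF least squares** (`fit_lagged_exponential_cdf`), matching the
  model CDF $1 - e^{-k'(t-\tau)}$ to the empirical CDF at Hazen plotting
  positions $(i - 0.5)/n$, with censored replicates contributing only to
  $n$ and $\tau$ constrained to $[0, \min t_i]$. This mirrors how such
  fits are usually displayed against cumulative waiting-time plots.

Acceleration factors are plain rate ratios,
$\mathrm{acc} = k_\mathrm{vesicle}/k_\mathrm{ref}$ with
$k_\mathrm{ref} = 1.09\times 10^{-5}$ (the empty-bicelle reference rate)
by default. The units of the reference are the reciprocal of whatever
time unit the waiting times are measured in; since acc is a ratio, any
consistent unit choice gives the same answer, a fact covered by a
unit-invariance test. Uncertainties come from nonparametric case
resampling of replicates with percentile intervals
(`bootstrap_ci`); at $n = 20$ replicates the percentile interval
undercovers mildly (measured coverage near 90% for a nominal 95%), which
is typical for percentile bootstraps involving a sample-minimum
statistic and is documented rather than corrected.

## The synthetic bicelle generator

The generator (`generate_bicelle_trajectory`) defines the study
conditions under which the pipeline is validated. Its shape family is a
one-parameter path of spherical caps at fixed mid-surface area $A$: cap
radius $r = 1/H$, opening angle from $A = 2\pi r^2 (1 - \cos\theta)$,
with the flat disc as the $H \to 0$ limit. The true curvature follows a
linear ramp — $H = 0$ until a stochastic event time
$\tau + \mathrm{Exp}(k')$, then rising to `H_vesicle` over
`closure_duration` and holding. A linear ramp is the minimal assumption
for a gradual transition; published traces show gradual closure but no
specific functional form. Head beads are placed on a Fibonacci lattice on
each leaflet surface (offset $\pm 1$ nm along the local normal, the
cytoplasmic leaflet on the convex side, so the curvature module must
report $H > 0$ on these fixtures), rim lipids on the cap boundary circle,
and isotropic Gaussian jitter is added.

Defaults, chosen once as plausible for a small coarse-grained bicelle and
then left alone: 300 long-chain (DMPC-like) lipids and 100 short-chain
(DHPC-like) rim lipids with one head bead each; 0.6 nm$^2$ area per lipid
per leaflet (hence $A = 90$ nm$^2$); leaflet separation 2.0 nm; final
curvature $H_\mathrm{vesicle} = 0.15$ nm$^{-1}$; closure over 10 ns;
positional jitter 0.1 nm (bead-scale disorder typical of coarse-grained
head groups); frames every 1 ns over a 1000-ns horizon; 20 replicates per
study with true $k' = 0.02$ ns$^{-1}$ and $\tau = 150$ ns. At these
settings a study of 20 replicates runs in about a minute. Note that with
$A = 90$ nm$^2$ the final shape is a partial cap of the
$H = 0.15$ sphere rather than a fully closed vesicle; the curvature
estimate is unaffected, and the choice keeps fixtures small.

What the generator emulates: the geometry of flat-to-curved shape
transformations, exponential-with-lag event statistics, censoring at the
horizon, leaflet sidedness, and bead-level positional noise. What it does
not emulate: collective membrane undulations and correlated noise, the
stalk/neck geometry during closure, lipid diffusion and mixing,
protein–membrane coupling, and any force-field energetics. Passing the
end-to-end tests therefore shows that the estimators recover known truth
under idealized geometry and noise — a necessary condition — but says
nothing about force-field accuracy or about shapes far from the
spherical-cap family.

## Conformational ensembles

`radius_of_gyration` uses equal bead weights by default (coarse-grained
backbone beads are near-uniform in mass); a mass vector is accepted.
`rg_density` is a Gaussian kernel density over per-frame $R_g$ with
Silverman's rule as the default bandwidth, reporting a delta-like flag
for zero-variance ensembles. `kabsch_superpose` returns the optimal
*proper* rotation (reflections are rejected, so a mirror-image structure
retains a positive RMSD). `rmsf` superposes all frames and measures
fluctuations about the post-superposition mean structure (two passes:
align to the first frame, average, re-align to the average) — the mean,
not the first frame, is the reference. `pairwise_rmsd` computes the full
matrix in compiled code from the explicit Kabsch rotation of each pair;
the singular-value trace shortcut was rejected because it loses half the
significant digits to cancellation for near-identical frames.

`gromos_cluster` implements the greedy neighbor-counting rule: among
unassigned frames, the one with the most neighbors within the cutoff
(distance $\le$ cutoff, self excluded, ties to the lowest frame index)
becomes a center; it and its neighbors are removed, and the process
repeats. Extraction order is provably non-increasing in cluster size, so
populations are reported in descending order. Two properties worth
noting: the `gmx_cluster` tie-breaking behavior varies between versions,
so the rule here is fixed and documented; and the *number* of clusters is
**not** a monotone function of the cutoff — greedy re-partitioning can
split one more cluster at a slightly larger cutoff, and the package's
brute-force reference implementation reproduces the same behavior. Claims
that tightening a cutoff can only add clusters should not be relied on.

`subsample_evenly` takes a deterministic stride
(`round(k (N-1)/(n-1))`, 0-based, R's round-half-to-even), matching the
convention of clustering a fixed number (default 10,000) of evenly
sampled conformations; "evenly" is stride, not random, sampling here.

## Amphipathic-helix descriptors

`helix_profile` lays a sequence on an ideal helical wheel (100° per
residue) and reports the mean hydrophobicity, the Eisenberg hydrophobic
moment $\mu_H = \left| \sum_n h_n (\cos n\delta, \sin n\delta) \right| /
N$ (per-residue normalized so peptides of different lengths compare; the
raw sum is also returned), and the integer net charge with R/K/H counted
positive and D/E negative — histidine positive by the convention of the
figure legends this descriptor set follows, physiological p$K_a$ caveats
notwithstanding. Two scales are bundled (Eisenberg consensus, the common
helical-wheel default, and Kyte–Doolittle); because no single scale is
canonical, every output carries its scale name and values from different
scales should not be compared.

## Orchestration and reproducibility

`run_curvature_kinetics` and `run_shape_analysis` chain the stages under
a single configuration list (or YAML file), echo the effective
configuration into their JSON reports, and take every random seed
explicitly — identical configurations produce byte-identical reports.
Tables are TSV with a provenance comment line and full-precision floats;
censored values are written as literal `NA`. Readers and writers cover
multi-model PDB (Å on disk, nm in memory), concatenated GRO frames and
XYZ; files without time stamps default to `index × timestep` with a
configurable timestep (default 0.02 ns — the conventional reporting of a
20-fs coarse-grained integration step, configurable because the mapping
of coarse-grained to physical time is contested). Periodic-boundary
unwrapping is out of scope: inputs must be whole objects.

## Numerical choices and degenerate inputs

* Sphere fits need $\ge 4$ points; identical points are an explicit
  degenerate-input error; coplanar input sets the flat flag rather than
  erroring.
* `signed_curvature` requires beads from both leaflets and errors with
  instructions otherwise; it never guesses sidedness.
* The MLE needs $\ge 2$ uncensored times (CDF fit $\ge 3$); exactly equal
  times are a degenerate error (the rate is unbounded), while any nonzero
  spread fits and simply yields a large $\hat k'$.
* The CDF fit restarts its bounded quasi-Newton optimizer from several
  documented starting points and errors only if all fail.
* Bootstrap resamples on which a fitter fails are dropped; a failure rate
  above 20% sets a flag in the output, and collapsed (zero-width)
  intervals are flagged as degenerate.
* Kabsch superposition requires $\ge 3$ non-collinear fit beads.

## Known limitations

The single-sphere curvature model cannot describe the neck geometry
during the final closure stage or local curvature fields; it reports one
number per frame. Waiting-time modeling is single-exponential with a
shared deterministic lag — multi-exponential kinetics or hazard-varying
models are out of scope. Tests validate estimator correctness on
synthetic geometry, not the physics of any particular force field; and
cluster populations from greedy clustering depend on the cutoff in ways
that are locally non-monotone, as discussed above.
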