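---
title: "Ensemble binding free energy analysis with enfea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble binding free energy analysis with enfea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enfea)
```

## The problem

Lead optimization of a congeneric ligand series asks a ranking question:
which modification of a scaffold improves binding to the target? Two
ensemble-based molecular simulation protocol families answer it at
different cost/accuracy points:

* **End-point estimation** (MMPBSA-style): the binding free energy of one
  compound is approximated as the ensemble average of
  `G(complex) - G(receptor) - G(ligand)`, where each `G` is a sum of
  molecular-mechanics terms (`E_vdw`, `E_ele`, `E_internal`) and
  implicit-solvent terms (`G_PB`, `G_SA`). In the *1traj* protocol all
  three species are extracted from the complex trajectory, so the large,
  noisy internal-energy terms cancel frame by frame. The *1traj-ar*
  variant adds a receptor *adaptation* energy — the per-compound mean
  receptor energy relative to the series average — to account for
  compound-dependent receptor strain. The conformational entropy term is
  deliberately omitted: it rarely improves rankings, and rankings are what
  the estimates are for, so the absolute values are systematically too
  negative by construction.
* **Alchemical relative free energies** via thermodynamic integration
  (TI): for a transformation between two compounds,
  `ddG = dG(bound leg) - dG(free leg)`, each leg being the integral over
  the coupling parameter lambda of the ensemble mean of `dU/dlambda`.
  Negative `ddG` means the modification improves binding
  (`ddG = dG_bind(target) - dG_bind(ref)`).

Both protocol families are *ensemble* methods: every window or compound is
simulated as several independent replicas, and all uncertainties here are
bootstrap standard errors over replica means. Frames within a replica are
autocorrelated, so resampling is at the replica level only.

This package implements the analysis layer of that workflow — everything
downstream of the molecular dynamics — plus synthetic-data generators with
planted ground truth, so the whole pipeline can be verified without
trajectories.

## Aggregation choices

Replica aggregation is mean-of-replica-means, not pooled frames: each
replica carries equal weight regardless of how many frames it saved, which
is the ensemble philosophy of these protocols and makes a sample-count
imbalance harmless. The same rule is applied per TI window
(`window_mean()`), so the window mean is unbiased under unequal replica
lengths.

The bootstrap (`bootstrap_se()`, default `B = 5000`) resamples replica
means with replacement; in `leg_dg()` resampling is independent per
window, because each window is an independent set of simulations. Replica
means are put in canonical sorted order before resampling, which makes the
result invariant to replica relabelling under a fixed seed.

Quadrature is the composite trapezoid over the supplied lambda schedule
(validated: strictly increasing, spanning 0 to 1) — the standard choice in
ensemble-TI practice. The rule used is recorded implicitly by the
machinery; alternative quadratures can be compared by integrating the
`window_means` table of a `leg_result` directly.

The 1traj-ar formula implemented is: per-compound mean receptor energy
(replica mean of frame means) minus the grand mean over compounds, added
to the 1traj value, with standard errors combined in quadrature. This is
the reading of "adaptation in relative terms using the average energy of
the protein" that both keeps the relative adaptations summing to zero and
widens the spread of the per-compound estimates, which is the variant's
documented behaviour. Two points are genuinely open and configurable:
whether the receptor mean uses the full MMPBSA energy or the MM terms only
(`adaptation_energy = "total"` is the default — the solvation terms belong
to the receptor's energy as much as the MM terms do), and whether the
grand mean weights compounds or frames (compounds, so unequal frame counts
cannot skew the reference).

## The synthetic-data generators

`gen_ti_dataset()` builds per-window `dU/dlambda` samples around a
quadratic mean profile in lambda that is rescaled so its **trapezoidal**
(not exact) integral equals the planted leg `dG`. This makes the planted
truth the quadrature-consistent target: with zero noise the pipeline
recovers the planted `ddG` to floating-point accuracy, independent of the
schedule, so any failure isolates a defect in the analysis rather than
quadrature error. Noise has two levels, matching how ensemble simulations
scatter: a per-(edge, leg, window, replica) offset (`between_replica_sd`,
default 0.2 kcal/mol) and per-sample noise (`within_replica_sd`, default
0.3 kcal/mol). Both are zero-mean, so recovery is unbiased by
construction.

`gen_esmacs_dataset()` emulates single-trajectory extraction: receptor and
ligand component frames are drawn around fixed baselines, an interaction
term with per-compound mean equal to the planted affinity is added, and
the complex frames are the exact component-wise sum of the three — so the
1traj cancellation identity holds bit for bit. The interaction carries a
per-replica offset (`between_replica_sd`, default 1 kcal/mol) and
per-frame noise (default 2 kcal/mol), magnitudes typical of MMPBSA frame
series. Planted receptor adaptation offsets are applied to the receptor
electrostatic baseline.

`gen_compound_series()` reproduces the structure of a 150-compound kinase
inhibitor series: 140 neutral compounds in subgroups coded by modification
position (0, 1, 2, 3, 4, 14, 34 with default sizes 1, 36, 7, 25, 26, 31,
14), 10 charged compounds, pIC50 uniform between 5.03 and 8.37 with the
uncensored extremes pinned at the range limits, and 5 censored compounds
fixed at the assay floor pIC50 = 5.00. Four subgroup-14 compounds carry an
additional minor fluorine-only category-3 modification and still classify
as 14. The hub compounds are `L30` (the unmodified reference, weakest
binder) and `L2` (best binder). Because the censoring floor (5.00) lies
just below the uncensored minimum (5.03), the span of the *whole* table is
3.37 log units while the uncensored span is the range width 3.34.

**What the generators do not emulate.** Real trajectories have
autocorrelated frames, non-Gaussian tails in the energy distributions,
lambda-dependent variance (end-point windows are noisier), slow receptor
conformational transitions, and force-field error that correlates across
related compounds. Passing tests on this synthetic data therefore
demonstrate that the *analysis* is correct and unbiased under its stated
noise model — they say nothing about force fields or sampling adequacy on
real systems.

**RNG discipline.** Every random stream is derived from one root seed by
stable string hashing (`child_seed()`) keyed on (compound or edge, leg,
window, replica), so regenerating with more replicas or more edges never
perturbs existing streams, and the whole pipeline is reproducible to the
byte (tables are serialized with 6 decimal places for that reason).

## The harmonic exactness oracle

For `U(x; lambda) = ((1 - lambda) k0 + lambda k1) x^2 / 2` the alchemical
free energy is `(kT/2) log(k1/k0)` exactly, and `dU/dlambda = (k1 - k0)
x^2 / 2` can be sampled from the exact Boltzmann distribution at any
lambda. This gives an independent closed-form target for the complete TI
chain (sampling → window means → quadrature → bootstrap):

```{r harmonic}
m <- harmonic_model(k0 = 1, k1 = 4, kT = 0.5961)
analytic_harmonic_dg(m)
leg <- leg_dg(harmonic_leg_windows(m, n_replicas = 5, n_samples = 1000),
              B = 1000, seed = 1)
leg
```

With the default 13-window schedule the trapezoid bias for this model is
about +0.0014 kcal/mol, well inside the 4-standard-error band the
acceptance checks use, so coverage of the analytic value is governed by
the sampling noise as intended.

## Network diagnostics

Relative free energies are state functions, so the signed sum of
calculated `ddG` around any closed cycle (the *hysteresis*) must be zero;
`cycle_closure()` reports it together with per-leg calculated-minus-
experimental discrepancies, flagging legs above a threshold (default 0.5
kcal/mol, near typical alchemical reproducibility) because per-leg errors
can cancel around a cycle that nominally closes. `hub_triangles()`
enumerates the triangles through the two reference compounds — the cycles
a two-hub design actually contains; general cycle enumeration is
exponential and out of scope.

A modification shared by a whole subset of transformations can carry a
shared systematic error, visible as a nonzero mean signed error (MSE).
`apply_common_change_offset()` shifts all calculated values by a constant,
either supplied (e.g. the discrepancy of a reference pair) or fitted as
`-MSE`; the identity `MSE_after = MSE_before + offset` is asserted
exactly, and correlations are untouched by the shift. Sign ties in
`directional_agreement()` (a `ddG` within 1e-12 of zero on either side)
leave the denominator, with the count reported — experimental ties are
otherwise uninterpretable.

## Series evaluation

Experimental affinities are converted with `dG = -RT ln(10) pIC50`
(R = 1.9872e-3 kcal/(mol K)); the temperature default is 300 K, typical
of the simulations such assays are compared against, and configurable.
One log unit is then 1.3727 kcal/mol. Since the conversion is a negative
linear map, correlations against converted experiment and against raw
pIC50 agree up to sign; the report records the convention used.
Censored compounds are *included* in headline statistics (they carry real
ranking information at the floor) and every stratum is automatically
re-evaluated without them (`*_nocens` columns) as a sensitivity check.
Ties use mid-ranks for Spearman and tau-b for Kendall. Strata smaller
than 3 are reported as "insufficient n" rather than with meaningless
coefficients.

```{r series}
cs <- gen_compound_series(compound_series_spec(
  subgroup_sizes = c(`0` = 1, `1` = 10, `14` = 8), n_charged = 2,
  n_censored = 1, seed = 1))
est <- data.frame(compound_id = cs$compound_id,
                  dG = plant_affinity_map(setNames(cs$pIC50,
                                                   cs$compound_id),
                                          target_r = 0.9, seed = 2))
evaluate_series(cs, est)[, c("stratum", "n", "pearson", "spearman",
                             "kendall", "note")]
```

## Problem sizes and numerical choices

Defaults mirror the ensemble protocols: 25 ESMACS replicas, 5 TI replicas
per window, 400 frames per replica (a 4 ns production run saved every
10 ps — the saving frequency is this package's choice), the 13-window
schedule, bootstrap `B = 5000`. The test-suite and the acceptance script
deliberately run reduced problem sizes (for example 5-replica, 5-10-frame
ESMACS series and 1000-sample harmonic windows) — the estimators are
exactly the same code paths, and the statistical checks are calibrated to
the sizes they run at, stated in each test. Degenerate inputs error
early and specifically: misaligned (replica, frame) sets between species,
missing schedule endpoints, duplicate lambdas, non-finite components
(named), constant series in correlations, single-compound adaptation.

## Known limitations

* The end-point estimates omit entropy and are ranking scores, not
  absolute affinities.
* The offset correction assumes one shared alchemical change dominates the
  subset's systematic error; it cannot detect compound-specific error.
* Cycle analysis covers hub triangles and user-supplied cycles only.
* The synthetic noise model is Gaussian and frame-independent; see above
  for what that implies about real-data claims.
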