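---
title: "Methods: duplex thermodynamics, ion atmosphere and mechanics in groovetherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplex thermodynamics, ion atmosphere and mechanics in groovetherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groovetherm)
library(dplyr)
```

groovetherm implements the analysis layer of a study design in which basic
amino-acid cations (Arg⁺, Lys⁺ and shorter-chain analogues such as ornithine
and DABA) modulate the stability gap between AT-rich and GC-rich DNA
duplexes.  The package does not run molecular dynamics; it analyses
coordinate ensembles, melting curves and nonequilibrium work tables, and it
ships a synthetic-data generator for every input class so that each analysis
stage can be validated by parameter recovery.  This vignette records the
models, the tunable parameters, and the design decisions taken where the
underlying methods literature leaves choices open.

## Two-state melting thermodynamics

UV absorbance melting curves of a bimolecular, non-self-complementary duplex
are modelled as two-state.  The association constant is
$K(T) = \exp(\Delta S/R - \Delta H/(RT))$ with association-direction
$\Delta H < 0$ (kcal/mol) and $\Delta S < 0$ (kcal/mol/K), and the unfolded
fraction is the logistic $\theta(T) = 1/(1 + K(T)\,C_t/2)$.  The observed
absorbance adds linear folded/unfolded baselines and optional Gaussian
noise.  Under this convention the melting midpoint satisfies exactly

$$\frac{1}{T_m} = \frac{R}{\Delta H}\ln\!\frac{C_t}{2} + \frac{\Delta S}{\Delta H},$$

which is also the linear relation the fitter uses: `fit_vant_hoff()`
regresses $1/T_m$ on $\ln(C_t/2)$ by ordinary least squares and converts
slope and intercept to $\Delta H = R/s$, $\Delta S = b\,\Delta H$ and
$\Delta G_{300} = \Delta H - 300\,\Delta S$.

Two conventions deserve comment.  First, the concentration divisor: the
textbook non-self-complementary relation uses $\ln(C_t/4)$; this package
defaults to $\ln(C_t/2)$, the form used in the experimental protocol it
reproduces, and exposes `conc_divisor` on both the generator and the fitter
so the two always share a convention and round trips are exact.  Second,
direction: parameters are stored association-direction with an explicit
flag; `thermo_deltas()` reports condition-minus-reference differences with
melting-direction signs (`flip_direction()` converts explicitly), so
condition comparisons match the convention of duplex-melting reports.

$T_m$ extraction follows the smoothed-first-derivative protocol:
Savitzky–Golay smoothing (local least-squares polynomial, default window 11
points, order 3 — the experimental protocol does not state its values, these
are conventional for ~0.25–1 K grids), a central-difference derivative on
interior grid points, and a three-point quadratic refinement of the peak to
remove grid bias.  Window shrinking handles the series ends, so the
temperature grid is never altered; a derivative maximum at the edge of the
grid raises a "transition not captured" error rather than returning a
boundary value.  The one-sided endpoint derivative estimates, which carry
twice the noise of interior points, are excluded from the peak search.

```{r melting}
cts <- c(1, 5, 20, 57) * 1e-6
tm <- sapply(cts, function(ct) {
  find_tm(simulate_melting_curve(-100, -0.270, ct,
                                 t_grid = seq(310, 370, 0.25)))
})
fit_vant_hoff(tibble::tibble(ct_M = cts, tm_K = tm))
```

The synthetic generator's baselines are linear by assumption (instrument
baseline shapes are not part of the model); noise is white Gaussian in
absorbance.  Real melting curves add drift, sloped transitions and replicate
scatter, so a passing round trip validates the estimator chain, not the
instrument model.

## Helicoidal ion mapping

Ion (and water) densities around a duplex are measured in curvilinear
helicoidal coordinates relative to the instantaneous helical axis: `D`
(arclength along the axis, Å), `R` (perpendicular distance, Å) and `A`
(azimuth, degrees).  The pipeline is:

1. `compute_bp_frames()` builds one orthonormal right-handed triad per base
   pair: origin at the C1′–C1′ midpoint, y along Watson-C1′ → Crick-C1′,
   z the local helical advance (neighbouring origins, orthogonalized), and
   x = y × z toward the major groove.
2. `fit_helical_axis()` passes a cubic smoothing spline through the
   base-pair origins (per coordinate, against base-pair index).  This is a
   deliberate, documented stand-in for a Curves+-style optimal axis: every
   forward and inverse mapping in the package uses the same convention, so
   all density and round-trip results are internally consistent, but no
   claim of numerical equality with canion output is made.
3. `to_helicoidal()` projects each particle on the axis polyline.  Beyond
   the duplex ends the arclength keeps running along the terminal tangent,
   so cap volumes classify as bulk rather than piling onto the last level.
   The azimuth is measured from the base-pair y axis increasing toward −x;
   this calibration puts the canonical B-DNA minor groove at the centre of
   the published 33°–147° window, which the fixture tests verify probe by
   probe at every level.

Regions follow the published definitions: minor groove azimuth
$[33°, 147°)$ (half-open to resolve boundary ties), inner region
$R \le 10.25$ Å, outer $10.25 < R \le 20.5$ Å, bulk beyond the 20.5 Å
cutoff or outside the duplex arclength span.  `density_map()` converts mean
per-frame counts to molarity with the curvilinear cell volume
$\Delta D \cdot \bar R\,\Delta R\,\Delta A$ (exact for an annular sector),
and the bulk molarity uses the box volume minus the cutoff cylinder, so a
uniform cloud reproduces its molarity in every cell and the cell molarities
integrate back to the mean particle count (a conservation test).
`bulk_ratio()` yields the groove-enrichment numbers (maximum fold over
bulk), `convergence_series()` the running-mean and block-average occupancy
diagnostics, and `radial_distribution()` groove-resolved radial profiles.
For amino-acid cations the conventional reference atoms are NZ for lysine
and CZ for arginine (with Cα as a backbone alternative); the mapping is
agnostic — callers select atoms by name.

The ion-cloud generator draws Poisson counts per region at target molarity
and places particles uniformly in curvilinear volume; it emulates occupancy
statistics only, not electrostatics, binding kinetics or residence times.

## Helical parameters, stiffness and essential dynamics

`helpar_extract()` computes the twelve Cambridge-convention parameters with
the symmetric mid-frame (CEHS/3DNA-style) construction: the relative
rotation between consecutive base-pair triads is split into a bend of angle
$\Gamma$ about the hinge axis and a twist about the mean normal; roll and
tilt are $\Gamma\cos\phi$ and $\Gamma\sin\phi$ with $\phi$ the hinge-to-
mid-frame-y angle, and translations are projected on the mid-frame axes.
Intra-base-pair parameters apply the same decomposition to per-base triads
(the Crick triad flipped into the pairing convention).  The implementation
is validated against an exact closed-form inverse (`params → frame pair →
params` round trips at 1e-10) and is rigid-motion invariant to 1e-8.  This
is a mid-frame construction, not the Curves+ curvilinear one; all stiffness
results are therefore internally consistent rather than Curves+-identical.

Elastic force constants come from harmonic inversion:
$K = k_B T\, C^{-1}$ with $C$ the 6×6 covariance of step parameters
(kJ/mol per Å², per deg², or mixed).  Near-singular covariances fall back
to a Moore–Penrose pseudo-inverse with a warning flag.  The "overall
stiffness" scalar is not uniquely defined in the methods literature; the
package reports, per step and per molecule, the translational mean, the
rotational mean, the plain combined mean of the six diagonal constants, and
a z-scored combined mean (each constant standardized across steps), so unit
heterogeneity is visible rather than hidden.

Distributional changes between conditions are quantified with a histogram
Kullback–Leibler divergence on shared bins spanning the pooled range
(default 50 bins, pseudocount 1e-6 per bin before normalization, result in
nats).  The estimate converges to the Gaussian closed form
$\delta^2/2\sigma^2$ at large n and stays finite for disjoint supports.

Essential dynamics (`ed_eigen()`) superposes frames on a shared reference
by Kabsch least squares, eigendecomposes the positional covariance and sums
the first 10 eigenvalues; `covariance_overlap()` computes the normalized
subspace overlap $\frac{1}{k}\sum_{i,j\le k}(v_i\cdot w_j)^2$.  Whether an
ED analysis uses all heavy atoms or backbone only is left to the caller's
atom selection; both are one `select_atoms()` away, and the eigenvalue sums
are reported alongside the covariance trace so truncation effects are
visible.

Groove widths use the cross-strand phosphate proxy: at each level the
minimum P–P distance over a window of cross-strand level offsets, minus a
5.8 Å phosphate-radius correction (the El Hassan–Calladine convention).  In
level indexing the minor window is offsets +1..+4 (equivalently i−3..i−1 in
the second strand's own 5′→3′ numbering) and the major window −7..−3;
terminal levels without a full window are skipped.  Hydrogen bonds are
counted over cross-strand Watson–Crick donor/acceptor pairs with a 3.5 Å
distance cutoff and a 150° pseudo-linearity angle at the donor (anchored at
its C1′, since the coarse representation carries no hydrogens); these
criteria are stated defaults of the MD literature, not fitted values.

## Crooks free energies and thermodynamic cycles

Bidirectional nonequilibrium work ensembles are generated Gaussian with the
Crooks fluctuation theorem built in: in thermal units, forward work
$\mathcal N(\Delta G + \sigma^2/2, \sigma^2)$ and reverse work
$\mathcal N(-\Delta G + \sigma^2/2, \sigma^2)$, so
$P_F(W)/P_R(-W) = e^{W-\Delta G}$ holds exactly in distribution.  The study
ensemble size is 184 runs per direction.

`crooks_intersection()` estimates $\Delta G$ as the crossing of
Gaussian-kernel density estimates of $P_F(W)$ and $P_R(-W)$.  Numerical
choices: one common Scott's-rule bandwidth computed from the pooled
mean-centred samples (equal kernels keep the crossing of two equal-variance
densities unbiased; a `bw_scale` multiplier and a ×0.5/×1/×2 sensitivity
report are attached because the bandwidth is the estimator's main tuning
knob); among multiple crossings the one nearest the midpoint of the two
sample means is taken (the plausible single-crossing regime); the root is
refined to 1e-6 kJ/mol; identical forward and mirrored-reverse samples are
detected and return the mean midpoint with zero error.  Uncertainty comes
from a seeded 200-resample bootstrap, which conditions on the observed
sample and therefore somewhat understates the full between-experiment
spread — at the study conditions the estimator's intrinsic sd is ≈0.17
$k_BT$, set by kernel-density fluctuations at the crossing divided by the
slope of the density difference.

`bar_estimate()` is the deliberately independent cross-check: the Bennett
acceptance-ratio equation solved by the classical fixed-point iteration to
1e-8 kJ/mol with the first-order Bennett variance; it is the
minimum-variance estimator and anchors the Crooks result in tests.
Single-sample directions converge but are flagged with infinite standard
error.

`combine_cycle()` assembles the thermodynamic cycles: for each organic salt
and mutation context (the four dinucleotide mutations ApA→GpG, ApT→GpC,
TpA→CpG, TpT→CpC), $\Delta\Delta G$ is the alchemical free energy in the
salt minus in the reference salt, separately for the single-strand tetramer
leg and the duplex decamer leg, and the overall per-substitution effect is
$(\Delta\Delta G_{ds} - \Delta\Delta G_{ss})/n_{subs}$ with $n_{subs} = 2$
(the decamer mutates two base pairs; the tetramer leg enters whole).
Whether single-strand legs should also be normalized per substitution is
not settled; a `ss_per_substitution` flag exposes it, default off.
Significance per salt is a two-sided one-sample t-test of the overall
values across contexts; a zero-variance sample is flagged degenerate
(p = 0 for nonzero mean) instead of erroring.

```{r crooks}
ws <- simulate_work_set(10, sqrt(2), 184, 184, seed = 1)
tidy(crooks_intersection(ws, n_boot = 50, seed = 2))
tidy(bar_estimate(ws))
```

## Multi-duplex condensation metrics

For many-duplex systems (the study uses 15 copies of 12-mer duplexes) the
package reports three metrics.  Mean pairwise centre-of-mass distance under
the minimum-image convention, differenced against a reference system
interpolated to common times (ΔCOM).  The published ΔCOM definition is
ambiguous between mean pairwise distance and displacement from the start;
mean pairwise distance is the default and the alternative sits behind
`metric = "from_start"`.  Axis alignment is reported as the mean pairwise
|cos| between duplex axis vectors — the nematic-order convention, chosen
because duplex axes are head–tail symmetric (0.5 = isotropic, 1 = parallel
fiber); the signed cosine is reported alongside, and window means (e.g.
first/last 10 ns) are available.  Diffusion comes from the MSD averaged
over duplexes and all time origins (FFT algorithm, validated against the
brute-force definition) with $D = \mathrm{slope}/6$ over a stated lag-time
window; a quadratic-share flag marks ballistic-like windows where the
linear fit is not meaningful.

The ensemble generator is a rigid-body surrogate: Brownian COM steps of
variance $2D\,\Delta t$ per dimension (stored unwrapped) and fixed axis
vectors interpolated between an isotropic draw and a common director until
the ensemble-mean pairwise |cos| matches the target within 0.02.  It
emulates the order parameter and transport statistics of a condensing
system, not DNA–DNA forces, so condensation tests demonstrate metric
correctness, not condensation physics.

## Problem sizes, determinism and limitations

Every generator consumes one integer seed and is bit-reproducible; no
global RNG state leaks (seeding is scoped with `withr::with_seed`).  The
test suite validates parameter recovery at sizes chosen to keep the whole
suite in the low minutes while leaving comfortable statistical margins:
melting round trips use 0.1–0.25 K grids and 100 noise replicates;
stiffness recovery uses 10⁵ frames (relative Frobenius error < 5%);
Crooks/BAR comparisons use 100 replicates of 184+184 works; helicoidal
density checks use 150–500 frames of Poisson clouds; diffusion recovery
uses 15 duplexes × 10⁴ frames.  Energies are stored in kJ/mol (kcal/mol at
the melting-module boundary, converted at I/O), temperatures in kelvin,
coordinates in Å, concentrations in mol/L; all constants come from
`phys_constants()`.

Known limitations, by construction: the melting module fits no instrument
artifacts and no three-state or hairpin models; the helicoidal axis is a
smoothing spline, not an optimal axis, and the azimuth origin is calibrated
rather than inherited from Curves+; helical parameters use the mid-frame
construction; the trajectory reader handles PDB (including multi-model) and
DCD but not XTC; and the synthetic generators reproduce the statistical
structure of their targets (two-state transitions, harmonic fluctuations,
Poisson occupancy, Gaussian work pairs, Brownian transport), not the
underlying molecular physics.
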