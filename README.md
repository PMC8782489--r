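# groovetherm

Analysis toolkit for studying how basic amino-acid cations (arginine,
lysine, ornithine, DABA) reshape the sequence-dependent stability,
structure and dynamics of DNA duplexes — the setting in which AT-rich and
GC-rich duplexes, ~35 K apart in melting temperature under dilute control
buffers, move closer together in organic-cation-rich environments.

The package covers the full analysis chain such a study needs, with a
seeded synthetic-data generator for every input class so that each stage is
testable by parameter recovery:

- **Melting thermodynamics** — two-state UV melting curves, Tm by the
  smoothed first derivative, and van 't Hoff fits of `1/Tm` against
  `ln(Ct/2)` giving ΔH, ΔS and ΔG(300 K), plus condition-to-condition
  ΔTm / ΔΔH / ΔΔS / ΔΔG tables.
- **Helicoidal ion densities** — base-pair frames, an instantaneous helical
  axis, curvilinear (D, R, A) mapping, groove regions (minor groove
  33°–147°, inner radius 10.25 Å, cutoff 20.5 Å), molarity-normalized
  density maps, bulk-enrichment ratios, convergence and radial profiles.
- **Mechanics** — Cambridge-convention helical parameters via the mid-frame
  construction, Kullback–Leibler divergences between conditions, elastic
  stiffness `K = k_B T C⁻¹` by covariance inversion, groove widths
  (cross-strand P–P proxy), Watson–Crick H-bond counts, essential dynamics
  and covariance-subspace overlaps.
- **Crooks free energies** — ΔG from the intersection of forward and
  mirrored-reverse work densities (`P_F(W)/P_R(−W) = e^{β(W−ΔG)}`), a
  Bennett acceptance-ratio cross-check, and thermodynamic cycles combining
  single-strand and duplex legs into per-substitution ΔΔG values with
  one-sample t-tests.
- **Condensation metrics** — ΔCOM separation series, pairwise axis
  cross-correlation (nematic order), and MSD-based diffusion coefficients
  for multi-duplex systems.

Everything is tidyverse-native: functions take data frames and return
tibbles, fitted objects have broom-style `tidy()`/`glance()` methods, and
each result type has an `autoplot()` method.

## Worked example

Melting analysis at the four experimental strand concentrations
(1, 5, 20, 57 µM), simulated from known association parameters and
recovered end to end:

```r
library(groovetherm)

cts <- c(1, 5, 20, 57) * 1e-6
tm <- sapply(cts, function(ct) {
  find_tm(simulate_melting_curve(-100, -0.270, ct,
                                 t_grid = seq(310, 370, 0.25)))
})
round(tm, 2)
#> [1] 334.58 338.20 341.38 343.82

fit_vant_hoff(tibble::tibble(ct_M = cts, tm_K = tm))
#> Van 't Hoff fit (association direction, ln(Ct/2))
#>   dH = -100.019 kcal/mol
#>   dS = -0.270109 kcal/mol/K
#>   dG(300 K) = -18.986 kcal/mol
#>   r2 = 1.00000  (n = 4)
```

The Tm values rise with strand concentration as the two-state model
dictates, and the fit recovers the generating ΔH = −100 kcal/mol and
ΔS = −0.270 kcal/mol/K to four digits with r² = 1 — the noiseless round
trip that anchors the melting module.

Free energies from a bidirectional work ensemble at the study size
(184 runs per direction, ΔG = 10 k_BT ground truth):

```r
ws <- simulate_work_set(10, sqrt(2), 184, 184, seed = 1)
crooks_intersection(ws, n_boot = 200, seed = 2)
#> <fep_estimate> crooks_kde: dG = 24.7728 kJ/mol (9.9316 kT), se = 0.2151, nF/nR = 184/184
bar_estimate(ws)
#> <fep_estimate> bar: dG = 24.9557 kJ/mol (10.0049 kT), se = 0.1920, nF/nR = 184/184
```

Both estimators land on the 10 k_BT ground truth (24.94 kJ/mol at 300 K)
within their standard errors, and the KDE-intersection estimate agrees with
the independent Bennett acceptance-ratio solution.

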