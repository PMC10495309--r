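---
title: "Estimating the dose-dependent RBE of Ac-225 versus Lu-177 at the cellular scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the dose-dependent RBE of Ac-225 versus Lu-177 at the cellular scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbesim)
```

## The problem

PSMA-targeted radiopharmaceutical therapy of metastatic prostate cancer is
delivered either with the beta emitter Lu-177 (7400 MBq per cycle) or, for
patients who stop responding, with the alpha emitter Ac-225 (8 MBq per
cycle). Clinical dosimetry for the alpha therapy conventionally weights
absorbed dose by a flat relative biological effectiveness (RBE) of 5, a
value that ignores both the nuclide-specific alpha spectrum and the dose
dependence that repair of DNA damage introduces. This package estimates the
RBE of Ac-225 relative to Lu-177 using DNA double-strand breaks (DSBs) in
the nucleus of a central target cell as the biological endpoint, before and
after 24 h of repair, and exposes the resulting closed-form dose-dependent
RBE together with its uncertainty.

## Model overview

The pipeline has five stages, each usable on its own:

1. **Geometry.** Cells are equal-volume ellipsoids (about 4189 µm³, five
   catalog shapes) with a 10 nm membrane and a concentric spherical nucleus
   of radius 4.65 µm. Clusters are rectangular grids of identical cells
   around a central target cell, sized per axis by
   $n_i = 2\,\lceil ((\mathrm{range} + R_\mathrm{nuc})/\mathrm{HL}_i - 1)/2 \rceil + 1$,
   so the cluster reaches exactly as far as emitted particles can travel
   and still touch the central nucleus. The ranges are 280 µm (Lu-177,
   monolayer), 140 µm (Lu-177, 3D lattice, halved to curb the cell count)
   and 86.53 µm (Ac-225, the CSDA range of an 8.5 MeV alpha in water).
   Monolayers span the two axes with the largest half-lengths; this is the
   unique choice that reproduces all twenty published cluster sizes.

2. **Source planning.** Lesion activity concentrations (normalized per GBq
   injected) convert to decays per cell via $N = A\,T_{1/2}/\ln 2$ — every
   nuclide bound in a tumour cell eventually decays there (no excretion).
   The studied Lu-177 grid is 100–5000 sources per cell; Ac-225 numbers
   follow by dividing by
   $(7400\ \mathrm{MBq}\cdot 6.647\ \mathrm{d})/(8\ \mathrm{MBq}\cdot 9.92\ \mathrm{d}) \approx 619.8$,
   giving 1–10. Sources sit either on the membrane surface (area-uniform)
   or in the cytoplasm (volume-uniform).

3. **Damage induction.** A desk-scale stochastic surrogate stands in for
   event-by-event track structure. Ac-225: each source point emits the
   five chain alphas (5.8, 6.3, 7.1, 5.9, 8.4 MeV) isotropically;
   daughters decay at the emission site (their recoil ranges are
   nanometres). Alphas travel straight chords with the power law
   $R(E) = kE^p$ fitted to the printed anchors $R(8.5) = 86.53$ µm and
   $R(5.8) = 46$ µm; the energy lost inside the central nucleus is scored
   as dose (0.380 Gy/MeV for the 4.65 µm water sphere), and DSBs are a
   Poisson process along the chord with density proportional to the local
   LET $-dE/ds$, normalized to the configured yield of 165 DSB/Gy. All
   alpha-track breaks are complex. Lu-177: electron transport is condensed
   into an exponential cross-dose kernel
   $K(r) = K_0$ for $r \le R_\mathrm{nuc}$, else
   $K_0 e^{-(r - R_\mathrm{nuc})/r_0}$ with $r_0 = 30$ µm (the published
   cross-dose decays exponentially with cell distance, and this $r_0$
   keeps the 280 µm tail below $10^{-3}$ of the central value). Doses are
   the per-cell kernel expectation times the source count with unit-mean
   gamma noise per run (3% relative SD); DSB counts are Poisson with
   yield 77 DSB/Gy, positions uniform in the nucleus except for an
   intra-track doublet fraction (below).

4. **Repair.** A mechanistic rejoining surrogate: every DSB contributes two
   co-located free ends; simple-break ends fire at $\lambda_f = 2.07$ h⁻¹
   and complex ends at $\lambda_s = 0.259$ h⁻¹ (half per end, so an
   isolated break restitutes at the full class rate), over a 24 h window.
   A firing end picks its partner among all free ends with weight
   $e^{-d^2/2\sigma^2}$; joining the original (co-located) partner is a
   correct repair, anything else a misrepair. Complex breaks are outright
   unrepairable with a configurable probability. Post-repair damage is
   misrepaired plus residual (unrejoined) breaks. The event loop is exact
   (Gillespie), which is what makes the closed-form kinetic limit
   $e^{-\lambda t}$ testable.

5. **Fitting and RBE.** Per condition, the 100-point (10 levels × 10 runs)
   dose-effect datasets are fitted through the origin, unweighted:
   $N = b D$ for Ac-225 (both stages) and Lu-177 initial damage,
   $N = a D^2 + b D$ for Lu-177 post-repair damage. Equating effects gives
   the dose-dependent RBE
   $$\mathrm{RBE}(D_\mathrm{Lu}) = \frac{b_\mathrm{Ac}/b_\mathrm{Lu}}{(a/b_\mathrm{Lu})D_\mathrm{Lu} + 1},
     \qquad
     \mathrm{RBE}(D_\mathrm{Ac}) = \frac{2 b_\mathrm{Ac}}{\sqrt{b_\mathrm{Lu}^2 + 4 a b_\mathrm{Ac} D_\mathrm{Ac}} + b_\mathrm{Lu}},$$
   equal to $b_\mathrm{Ac}/b_\mathrm{Lu}$ at zero dose and crossing 1 at
   $D = (b_\mathrm{Ac} - b_\mathrm{Lu})/a$. Uncertainties propagate by the
   first-order delta method with independent parameter errors, which
   reproduces the published uncertainty ranges; parameter covariances can
   be supplied but are off by default.

## Worked example from the published fit parameters

```{r}
m <- rbe_from_fixtures(1, "internalized", "lattice_3d", "post_repair")
c(rbe_at_0 = rbe_vs_dose_lu(m, 0),
  rbe_at_50Gy_ac = rbe_vs_dose_ac(m, 50),
  crossover_Gy = crossover_dose(m)$dose,
  crossover_sd = crossover_dose(m)$sd)
```

The initial-damage RBE for the same condition is constant at
`r round(rbe_from_fixtures(1, "internalized", "lattice_3d", "initial")$b_ac /
rbe_from_fixtures(1, "internalized", "lattice_3d", "initial")$b_lu, 2)`.

## Calibration of the surrogate

The surrogate is calibrated, not predictive; four knobs are fixed once
against published summary numbers and then frozen:

* **Kernel amplitude $K_0$** is solved analytically so that the reference
  configuration — geometry 1, 29 × 29 monolayer, full internalization,
  5000 sources per cell — receives an expected nucleus dose of 2.084 Gy
  (the published mean over ten runs for that setup).
* **Intra-track doublets.** With strictly uniform DSB positions, wrong-end
  misrepair scales with DSB density and vanishes at low dose, whereas the
  published post-repair curve has a large density-independent linear term
  ($b_\mathrm{repair} \approx 0.21\, b_\mathrm{init}$). Low-LET misrepair
  is in reality dominated by lesions clustered on the same electron track,
  so 30% of Lu DSBs are laid down as doublets with a 3D Gaussian offset of
  0.15 µm. This carries the misrepair floor; the remaining uniform breaks
  carry the density-driven quadratic term.
* **Pairing scale $\sigma = 0.25$ µm** and **complex-unrepaired
  probability 0.60** were chosen on a coarse grid so that (i) the Lu mean
  post-repair count lies within 25% of $16.31 D + 1.21 D^2$ over 1–5 Gy
  and (ii) the Ac post/initial slope ratio is near the published 0.92
  (achieved: about 0.90).

## What the synthetic data do and do not show

The generator reproduces the *statistical structure* the downstream
analysis consumes: strict linearity of Ac-225 damage in dose, linear
initial / convex post-repair Lu-177 damage, Poisson counting noise,
heavy-tailed Ac dose fluctuations at low source numbers (single Bragg-peak
traversals), and the no-excretion linear scaling of dose with source
count. It does not reproduce track-structure physics: no radiolysis
chemistry, no explicit DNA geometry, no electron transport (a kernel
instead), no damage-complexity spectrum beyond the binary class, and no
daughter relocation. Consequently, passing tests validate the pipeline
and the calculus on data with the right structure — they are not evidence
about absolute DSB yields in real cells, which enter only through the
configured yields per Gy.

## Numerical choices and degenerate inputs

* Ellipsoid surface sampling uses gradient-norm rejection from the
  unit-sphere parameterization (exact, preferred over approximate
  area formulas); cytoplasm sampling uses bounding-box rejection.
* The cluster-sizing ceiling expression is implemented in the form that
  reproduces all twenty published cluster sizes.
* Chord entry/exit lengths are clipped at zero; tangent rays give
  zero-length chords; rays with the sphere behind them are misses.
* DSB positions along alpha chords are drawn by inverting the range-energy
  law in deposited energy, which is exact for the power law and
  concentrates breaks toward the Bragg peak.
* Fits require at least three points and a non-degenerate design; the
  quadratic coefficient is bounded below by zero by default (boundary
  refit with $a = 0$), matching the reported $a = 0.00$ entries; the
  bound can be disabled. $R^2$ for through-origin models uses the
  centered total sum of squares (a reporting convention only).
* Doublet partners falling outside the nucleus are reflected inward, with
  a radial projection as a last resort; the invariant that every DSB lies
  inside the nucleus is enforced by tests.
* Empty damage, zero source counts and single-value concentration ranges
  are all legal inputs with the obvious degenerate outputs.
* Seeds derive hierarchically (master → condition → run → repetition)
  through an integer mixer kept below 2³¹.

## Problem sizes

The package defaults run a desk-scale version of the full design: the
complete grid (2 nuclides × 5 geometries × 2 arrangements × 2
internalizations × 10 levels = 400 setups, 10 runs and 10 repair
repetitions each) is available behind `run_config(profile = "paper")`,
while the default profile keeps the 10-level dataset shape with 3 runs and
3 repetitions. The test suite exercises reduced grids (2 runs, 1–2
repetitions, single geometry) chosen so the structural checks retain
power; the published-value checks (cluster sizes, scaling factor, RBE
worked examples, uncertainty ranges) are exact closed-form computations
and run at full fidelity.

## Known limitations

* Damage induction and repair are sequential, not concurrent, although
  both therapies irradiate over weeks; this overstates clustering at a
  given dose for Lu-177.
* The repair surrogate's misrepair-range and complexity conventions are
  its own (documented above), not those of any specific mechanistic code;
  only the interaction rates and window are taken from the literature.
* Ac-225 chain betas (1.4, 2.0, 0.6 MeV endpoints) are omitted: their
  low-LET contribution to the central nucleus is small against the alpha
  term at these geometries.
* The nucleus is a fixed-radius sphere in a G0/G1-like state; cell-cycle
  variation of radiosensitivity is out of scope.
* Extrapolating the post-repair RBE to doses far above the simulated range
  assumes the Lu-177 quadratic term and the Ac-225 linearity persist; at
  very high doses a quadratic term for the high-LET arm would lower the
  crossover dose.
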