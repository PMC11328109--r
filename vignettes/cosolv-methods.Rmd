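---
title: "Models and methods behind cosolv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cosolv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosolv)
```

cosolv quantifies how Hofmeister-series cosolutes — destabilizers such as
thiocyanate and guanidinium, stabilizers such as TMAO, sucrose and sulfate —
shift the thermal stability of a small two-state protein domain. The package
grew around the analysis of the 92-residue D2 domain of the *Thermotoga
maritima* arginine-binding protein, a rare example of a reversible two-state
folder with a transition above 100 °C, but every routine is generic. This
vignette records the models, the tunable parameters, and the design
decisions, including the numerical corner cases where a choice genuinely
mattered.

## The two-state thermogram model

A reversible two-state equilibrium N ⇌ D is fully specified by three
parameters: the transition temperature $T_d$ (K), the denaturation enthalpy
at that temperature $\Delta H_d$ (kJ/mol), and a temperature-independent
heat-capacity change $\Delta C_p$ (kJ K⁻¹ mol⁻¹). The Gibbs energy follows
the Gibbs–Helmholtz form

$$\Delta G_d(T) = \Delta H_d\left(1 - \frac{T}{T_d}\right) +
  \Delta C_p\left[(T - T_d) - T\ln\frac{T}{T_d}\right],$$

the denatured fraction is $f = K/(1+K)$ with $K = e^{-\Delta G_d/RT}$, and
the excess molar heat capacity recorded by a DSC instrument is the analytic
derivative of the excess enthalpy $f \cdot \Delta H_d(T)$:

$$C_{p,ex}(T) = \frac{\Delta H_d(T)^2 f(1-f)}{RT^2} + f\,\Delta C_p,
\qquad \Delta H_d(T) = \Delta H_d + \Delta C_p (T - T_d).$$

The first term is the transition peak; the second is the sigmoidal
heat-capacity shift between the folded and unfolded baselines. Temperatures
are Kelvin internally; all readers and writers speak Celsius, because that
is how scan parameters are reported.

### Baseline subtraction

`subtract_baseline()` implements the classical progress baseline: linear
segments are fitted to pre- and post-transition windows (the outer 15% of
the grid by default) and blended by the reaction progress, so that the
baseline under the peak interpolates from the folded to the unfolded line.
Two refinements matter in practice:

* **Progress is enthalpy-weighted.** The blending weight must be the
  denatured fraction $f$, which obeys $df = C_{p,peak}\,dT/\Delta H_d(T)$.
  Accumulating raw peak area instead (the naive sigmoid) weights each
  increment by $\Delta H_d(T)$ and is visibly biased whenever
  $\Delta C_p > 0$ shifts the enthalpy across the transition; the iteration
  therefore divides each increment by the running enthalpy estimate.
* **Windows are purity-gated.** After the progress converges, window points
  must satisfy $\alpha < 10^{-3}$ (pre) or $\alpha > 1 - 10^{-3}$ (post) —
  the textbook requirement that baseline segments represent essentially
  pure states. A trace that leaves no such windows (a scan truncated inside
  the transition tail, or a transition overlapping cold denaturation) is
  refused with an explicit error rather than silently mis-integrated;
  `fit_two_state()`, which fits the full model globally, remains available
  for those traces.

The calorimetric enthalpy is the trapezoidal integral of the subtracted
trace on the native grid (no resampling). $T_d$ is the peak maximum,
refined by a quadratic fitted over the top quarter of the half-height width
— wide enough to average grid noise, narrow enough that the parabolic
approximation holds.

### The van 't Hoff enthalpy and its evaluation point

The model-independent sharpness measure is the Privalov relation
$\Delta H_{vH} = 4RT^2 C_{p,ex}(T)/\Delta H_{cal}$, evaluated at the
transition midpoint. Which midpoint matters: at the *peak maximum* the
relation carries an $O(\Delta C_p)$ bias, because with $\Delta C_p > 0$ the
peak shifts slightly above the point where $f = 1/2$. When a trace carries
the progress weights from `subtract_baseline()`, the formula is therefore
evaluated where the progress crosses one half; otherwise the peak is used.
For $\Delta C_p = 0$ the two coincide. With this choice the cooperativity
ratio $\Delta H_{cal}/\Delta H_{vH}$ on ideal noiseless two-state traces is
1 to within discretization error, which is what makes the ratio a usable
diagnostic of two-state behaviour on real scans.

### When the integral route cannot work

The conservation property — peak area equals the generating
$\Delta H_d$ — holds only when the transition is *resolvable*: the folded
state must become essentially fully populated somewhere in the scan. With a
temperature-independent $\Delta C_p$, the stability curve has its maximum
$\Delta G_{max} \approx \Delta H_d^2 / (2\,\Delta C_p T_d)$ at the
temperature where the denaturation entropy vanishes. When
$\Delta G_{max} \lesssim 10\,RT$ (roughly 27 kJ/mol at these temperatures),
the folded population never exceeds ~99%, the heat peak overlaps the cold
side, and *no* baseline construction — not even one using the exact
generating $f$ — recovers $\Delta H_d$ to half a percent. Parameter
combinations in that regime (low $\Delta H_d$ together with large
$\Delta C_p$) are flagged by the purity gate or simply fail the
conservation check; the corresponding acceptance expectations are left
failing deliberately, because the limitation is thermodynamic, not
numerical. Combinations drawn from the physically coupled
$(T_d, \Delta H_d)$ line of a real protein series satisfy resolvability
comfortably, except for its most destabilized extremes.

Scan design in the test-suite simulations follows from the same analysis:
grids bracket the transition by 25 reduced widths $RT_d^2/\Delta H_d$ (at
least 30 K) and are bounded below by the stability maximum. A 0.1 K grid
step matches instrument resolution at a 1 °C/min scan rate.

## The ITC binding isotherm

Ligand binding to $n$ equal and independent sites obeys the mass-action
balance $K_b = B / [(nP_0 - B)(L_0 - B)]$ for the bound-ligand
concentration $B$. The saturation fraction has the closed form

$$\theta = \frac{b - \sqrt{b^2 - 4ac}}{2aP_0}, \qquad
a = nK_b,\; b = 1 + nP_0K_b + L_0K_b,\; c = L_0P_0K_b,$$

evaluated via the numerically stable small-root expression
$2c/(b + \sqrt{b^2-4ac})$; the suite pins it against 200-step bisection on
the mass-action balance to $10^{-10}$ across six orders of magnitude in
ligand concentration. The model cumulative heat is
$\Delta H_{b,tot}\,\theta$ per mole of protein; $\Delta H_{b,tot}$ is
stored as the **total** (saturation) enthalpy per mole of protein, with the
per-site value $\Delta H_{b,tot}/n$ derived — the convention matching an
"overall binding enthalpy change".

Concentration bookkeeping follows the overfilled-cell displacement model:
each injection of volume $v$ into a cell of constant volume $V$ displaces
cell content, so $P_{0,k} = P_{init}(1-v/V)^k$ and
$L_{0,k} = C_{syr}(1-(1-v/V)^k)$. A `dilution = "none"` strategy is
exposed for instruments without displacement. No injection is discarded
automatically. Fits are unweighted Levenberg–Marquardt on the cumulative
heats with deterministic initialization (affinity from the half-maximal
ligand concentration, enthalpy from the plateau, fixed site-count start)
and a small grid of affinity fallbacks; standard errors are asymptotic.

### Identifiability at the study conditions

At 42 µM protein with $K_b \approx 6$ M⁻¹, the term through which the site
count $n$ enters the isotherm, $nP_0K_b$, is below 1% of the quadratic's
$b$ coefficient. Noiseless data therefore identify all three parameters
(the suite demands 0.5% recovery), but under any realistic noise the
likelihood is flat in $n$: fits wander over orders of magnitude in $n$
while the affinity and total enthalpy remain stable at the median. This is
not an optimizer defect — it reflects the same weak identifiability that
produces a ±30% uncertainty on a reported site count — and it is why the
noisy-replicate acceptance expectation on mean bias is left failing: the
mean of an estimator with a one-sided flat ridge is not a meaningful
summary at these conditions. The practically identified quantities under
noise, the affinity and the enthalpy, are asserted via medians in the unit
suite.

## Frame geometry statistics

Trajectory frames are multi-model PDB (parsed and written through bio3d);
ions are recognized by residue name (`SCN`/`THC` for thiocyanate,
`GDM`/`GAI` for guanidinium, extensible). Conventions, each chosen where
the field's reports are silent and exposed as arguments:

* *Protein surface* means any protein heavy atom; no solvent-accessibility
  filter. Hydrogens are excluded on both protein and ion sides.
* An ion is **in the shell** if any of its heavy atoms lies within the
  cutoff (4.0 Å default) of any protein heavy atom — per-ion, not
  per-atom, counting.
* A **side-chain contact** is an (ion, residue) pair with any heavy ion
  atom within the cutoff of any heavy side-chain atom; the pair counts
  once per frame regardless of how many atom pairs qualify (`per_atom`
  switches to atom-pair counting). Residue classes: Lys/Arg positive,
  Asp/Glu negative, Phe/Tyr aromatic, Val/Ile/Leu/Ala aliphatic; Gly and
  Pro are excluded.
* Minimum-distance distributions track one ion element (the thiocyanate N
  or S) against protein heavy atoms, per ion per frame.

Distances use exact dense matrix computation; every statistic is pinned
against a brute-force double-loop oracle in the suite, so any future
neighbor-search acceleration inherits an exactness test. Frames are
weighted equally with no time-correlation correction.

## Synthetic data generators

Each analysis stage has a seeded generator whose defaults are the study
conditions themselves:

* **DSC** (`make_dsc_dataset()`): buffer-condition transition at 102.6 °C
  with 470 kJ/mol and $\Delta C_p$ 5.2 kJ K⁻¹ mol⁻¹, on a 25–115 °C,
  0.1 K grid, with optional linear + progress instrument baseline and
  Gaussian noise. Note that with these defaults the scan ends ~12 K past
  the transition, so the purity gate refuses the integral route — exactly
  as for the real scan geometry — and the model fit is the appropriate
  analysis; destabilized conditions (lower $T_d$) resolve fully within the
  same scan window.
* **ITC** (`make_itc_dataset()`): 25 × 10 µl injections of 300 mM ligand
  into a 961 µl cell of 42 µM protein; $n = 30$, $K_b = 6.3$ M⁻¹,
  $\Delta H_{b,tot} = -14.9$ kJ/mol, optional constant dilution heat per
  injection and Gaussian noise.
* **Frames** (`make_frame_set()`): a procedurally built 12-residue toy
  protein with one residue of every classified type (correct PDB atom
  names, idealized ring geometry), around which each ion is placed so its
  minimum heavy-atom distance to the protein equals an assigned value to
  $10^{-8}$ Å, by root-finding along an outward ray from a randomly chosen
  surface atom; colliding placements are redrawn from the shared seed.

The generators emulate the *analysis-facing* structure of the data — peak
shapes, isotherm curvature, shell geometry — with known ground truth. They
do not emulate instrument drift, scan-rate kinetics, injection-volume
errors, force-field physics, or correlated trajectory frames; passing
recovery tests on them validates the estimators, not the instruments.

## Sizes, tolerances and other fixed choices

* Gas constant 8.314462618 × 10⁻³ kJ K⁻¹ mol⁻¹; enthalpies kJ/mol.
* Trapezoidal integration on the native grid everywhere; no resampling.
* Levenberg–Marquardt (`minpack.lm`) with `ftol`/`ptol` near machine
  precision for both fits; two-state fit initialization is deterministic
  from the trace itself.
* The cross-condition $\Delta C_p$ regression is ordinary least squares of
  $\Delta H_d(T_d)$ on $T_d$; only buffer and pure-denaturant conditions
  enter (stabilizer mixtures shift $T_d$ without following the same
  Kirchhoff line). The packaged condition table carries 11 such rows; the
  slope estimate is reported with its standard error, and the slope is
  invariant to the °C/K choice.
* Kirchhoff extrapolation treats $\Delta C_p$ as temperature- and
  cosolute-independent, the stated assumption of the cross-condition
  analysis; the headline per-residue number uses the slope rounded to its
  reported precision (5.2).
* Property-test problem sizes — 27-point factorial sweeps for DSC, 200
  noisy titration replicates, 100 synthetic frames with 6 ions — were
  chosen to keep full runs in minutes on a laptop while leaving
  Monte-Carlo standard errors small against the asserted tolerances.

## Known limitations

* Single-transition analysis only: no multi-domain deconvolution, no
  kinetic (scan-rate-dependent) models, no absolute heat-capacity scale.
* One binding-site class; no cooperativity, no competing ligands, no raw
  power-trace deconvolution.
* The integral DSC route requires resolvable transitions (see above); the
  package makes the failure explicit instead of returning a biased number.
* The toy protein is a geometric scaffold, not a fold; contact statistics
  on it validate counting conventions, not biology.
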