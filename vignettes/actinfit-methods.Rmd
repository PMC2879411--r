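---
title: "Models and methods behind actinfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind actinfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinfit)
library(dplyr)
```

## The problem

Several actin regulators act on both ends of the monomer-polymer balance:
they bind monomeric (G-) actin, sequestering it into complexes that cannot
polymerise, and they bind the fast-growing (barbed) end of filaments,
blocking subunit addition. The two activities produce superficially similar
dose-response curves in bulk assays, but they have different mechanistic
signatures, different natural concentration scales (nanomolar for end
capping, micromolar for sequestration), and different biological
consequences. `actinfit` implements the equilibrium and kinetic models with
which such dual-activity proteins are quantified from standard solution
assays, plus seeded simulators of every assay class so that each estimator
can be validated by parameter recovery instead of trusting a fit black-box.

## Monomer binding: the ligand-depletion isotherm

Fluorescence titrations report complex formation between labelled G-actin
(total $A_0$) and a ligand (total $L_0$) through a probe whose signal
changes on binding. Because the actin concentration needed for a usable
signal (~1.5 µM) is comparable to — or far above — the dissociation
constants of interest (50 nM to a few µM), the free ligand cannot be
approximated by the total: mass action plus both conservation laws give the
quadratic

$$(A_0 - C)(L_0 - C) = K_d\,C,$$

whose physical root `complex_concentration()` evaluates in the
cancellation-free form $C = 2A_0L_0 / (b + \sqrt{b^2 - 4A_0L_0})$,
$b = A_0 + L_0 + K_d$. The observation model is linear in occupancy:
$F = F_0 + \Delta F \cdot C/A_0$ (`predicted_signal()`), and
`fit_binding()` estimates $(K_d, F_0, \Delta F)$ jointly.

In the tight-binding regime ($A_0 \gg K_d$, e.g. 1.5 µM actin against a
50 nM constant) the titration approaches two straight lines joined at the
stoichiometric point and $K_d$ is identified only by the curvature of the
corner. Least squares remains the right estimator, but its sampling
distribution is strongly right-skewed there: at 2% noise the median
recovered constant sits ~5–10% below truth with replicate-to-replicate
scatter of a factor of ~2. This is a property of the assay design, not of
the optimiser (the package fit matches a global profile search), and it is
why recovery checks in this regime use a ±15% band on the median of 200
replicates while the well-conditioned micromolar cases recover to within a
few percent.

## Competition and two independent sites

When two ligands E and T compete for the same site, the exact ternary
equilibrium reduces to one monotone equation in free actin $a$,

$$a + \frac{E_0 a}{K_E + a} + \frac{T_0 a}{K_T + a} = A_0,$$

which `competition_solve()` brackets on $[0, A_0]$ (`uniroot`) and polishes
with Newton steps until every conservation law holds to relative $10^{-9}$.
The classical linear shortcut

$$K_{app} = K_T^0\left(1 + \frac{E_0}{K_E}\right)$$

(`apparent_kd()`, inverted by `invert_apparent_kd()`) is kept alongside the
exact solver because published analyses use it; it is valid when the shared
receptor is trace ($A_0 \ll K_E, K_T$), where it agrees with an IC50-style
read-out of the exact solve to within ~10%. Outside that domain the exact
solver is the default.

A cautionary note the package makes checkable: a frequently quoted worked
example pairs a reporter of $K_T^0 = 3$ µM with apparent constants of 9 µM
at 15 µM competitor and 14 µM at 30 µM, and then summarises the
competitor's own constant as "about 3 µM". The formula itself gives
$K_E = 15/(9/3-1) = 7.5$ µM and $30/(14/3-1) \approx 8.2$ µM — mutually
consistent within 10%, but 2.5-fold weaker than the quoted shorthand.
`invert_apparent_kd()` always reports the formula's value.

`two_site_signal()` covers the complementary case of two ligands binding
non-overlapping surfaces with additive fluorescence increments and no
cooperativity; each site's occupancy comes from its own depletion solve,
so saturation of both gives exactly $F_0 + \Delta F_1 + \Delta F_2$.

## Filament-end kinetics

Seeded growth assays measure the initial elongation rate
$V = [\mathrm{seeds}] \cdot k_+ (C - C_c)$ with $k_+ = 10\ \mu M^{-1}
s^{-1}$; `elongation_rate()` and `seeds_from_rate()` are exact inverses and
are used to calibrate free-end concentrations. Defaults for the critical
concentration are 0.1 µM (barbed) and 0.6 µM (pointed) — standard values
for Mg-ATP-actin, configurable everywhere they enter.

**Capping.** Only uncapped ends grow, so the normalized rate is 100 times
the free-end fraction. Because working end concentrations (~2 nM) are
comparable to nanomolar capping constants, `capping_curve()` defaults to
the end-depletion quadratic between ends and capper rather than the
free-ligand hyperbola $100/(1+X/K_{cap})$ (kept as an option); at 2 nM ends
and $K_{cap} = 15$ nM the two differ by several percent near the midpoint.

**Sequestration.** A 1:1 non-polymerizable complex removes monomer;
free actin follows the depletion quadratic and the normalized rate is the
polymerizable excess over $C_c$ relative to control, clipped at 0
(`sequestration_curve()`). Input rates are clipped to 0–120% of control on
ingestion — values above 100% are measurement noise on an uninhibited
control, not stimulation.

**Discrimination.** The two mechanisms separate cleanly when the same
titration is run at two actin concentrations: capping curves are invariant
to $A_0$ at fixed seeds, whereas the half-inhibition point of a
sequestration curve grows roughly linearly with $A_0$ — the curves shift
*rightward*, to higher ligand, as actin is raised.
`discriminate_mechanism()` fits both mechanisms jointly across the pair
(one shared constant each) and classifies by the lower residual sum of
squares, reporting the IC50 shift ratio as corroboration. If the two RSS
values agree within 5% the call is `"ambiguous"` rather than a forced
choice: near-indistinguishable fits should never be over-claimed from
noise. At 2% noise on 12-point grids the joint-RSS rule classifies ≥95% of
simulated pairs correctly (checked over 200 pairs per mechanism in the test
suite).

**Nucleotide exchange.** Monomer-binding ligands slow fluorescent-ATP
exchange on G-actin. The observed pseudo-first-order constant is the
occupancy-weighted mixture $k_{obs} = f_b k_{bound} + (1-f_b) k_{free}$
with $f_b$ from the depletion quadratic (`exchange_kobs()`); traces are
single-exponential rises fitted by `fit_exchange_trace()`. A 5-fold
inhibition corresponds to $k_{bound} = k_{free}/5$ at saturation.

## The fitting engine

All fits funnel through `nls_fit()`: weighted ($1/\mathrm{sd}^2$ when an
uncertainty column is present, unweighted otherwise) Levenberg–Marquardt
(`minpack.lm::nls.lm`) from a deterministic grid of starts spanning five
decades around the data-implied scale for every positive parameter, the
best converged start winning, followed by a short Gauss–Newton polish that
tightens the optimum to near machine precision (on models linear in the
parameters this reproduces the closed-form weighted least-squares solution
to $10^{-10}$, which the test suite checks against the normal equations).
A Nelder–Mead/Brent fallback handles pathological starts. Flat titrations
are rejected up front with an identifiability error instead of returning a
meaningless bound-hugging estimate.

Uncertainty comes from seeded case-resampling bootstrap
(`bootstrap_ci()`, 500 resamples by default; smaller values are used in
the examples and tests where only reproducibility, not interval accuracy,
is being exercised). All randomness flows from explicit integer seeds:
the same seed, data and model give bit-identical fits, bootstrap matrices
and JSON reports.

## The synthetic-data generators

`sim_titration()`, `sim_rate_titration()`, `sim_exchange()` and
`sim_calibration()` generate each assay from the same mechanistic curves
the fitters assume, plus homoscedastic Gaussian noise whose standard
deviation is a fraction of the curve's dynamic range (default 0.02,
matching the tight scatter of well-run fluorimetry titrations). Defaults
encode the reference assay conditions: 1.5 µM labelled actin with a 20%
saturation increment for titrations, 2 nM free ends for capping, 2 µM
G-actin over a 0.6 µM pointed-end critical concentration for
sequestration.

What the generators deliberately do **not** emulate: photobleaching and
instrument drift, heteroscedastic noise at low signal, pipetting error in
the ligand grid, and filament-age effects on end kinetics. Passing
recovery tests on these simulations therefore demonstrates that the
estimators are correct and well-conditioned under the stated noise model —
not that real instruments are free of systematic error. The master
round-trip property (every generator at zero noise is refitted to its
ground truth within $10^{-6}$ relative) is the package's basic sanity
contract and runs in the test suite.

Recovery experiments in the tests and the acceptance script use 200
replicates per constant at 2% noise on 12–15-point grids, and solver-vs-
oracle sweeps use 1000 random systems — sizes chosen so the whole suite
exercises every estimator thoroughly while remaining quick to run on a
laptop.

## Helical geometry

F-actin's genetic helix is left-handed; symmetry is expressed either as a
twist $t$ in subunits per turn or a signed per-subunit rotation
$-360^\circ/t$ (`rotation_from_twist()`, `twist_from_rotation()`).
Canonical F-actin at $t = 2.16$ gives $-166.6\overline{6}^\circ$; a
reported two-decimal value of $-166.66$ is ambiguous between truncation
and rounding, so `symmetry_report()` carries full precision alongside a
2-decimal rounding ($-166.67$) and the nearest degree. The boxing
arithmetic is elementary but easy to trip on: a box of 80 px advanced by
a 20 px stride shows each asymmetric unit in $80/20 = 4$ boxes
(`views_per_unit()`), and at 0.54 nm/px covers $80 \times 0.54 / 2.75
\approx 15.7$ subunits (`subunits_per_box()`) with the canonical 2.75 nm
rise, which is a package default (configurable), not a fitted quantity.

## Helical wheels and amphipathicity

`wheel_layout()` projects a helix at the canonical 100°/residue step
(18 residues = 5 exact turns), residue 1 at 0°, counterclockwise. Residues
are classed D/E negative, K/R/H positive, and the remainder
hydrophobic/hydrophilic by the sign of the Eisenberg consensus scale
(Kyte–Doolittle available); glyphs follow the conventional
circle/diamond/triangle/pentagon display. Amphipathicity is quantified by
the hydrophobic moment
$\mu_H = |\sum_i H_i(\cos\theta_i, \sin\theta_i)|$ — invariant under
global rotation, zero for a uniform scale over full turns — and by the
largest contiguous angular arc of hydrophobic residues
(`hydrophobic_face()`, ties broken at the smallest start angle). The
discriminating property used in the tests: an idealized amphipathic
18-mer's moment exceeds that of ≥95% of random shuffles of its own
composition.

## Hydrodynamics

Native molecular weight combines the Stokes radius $a$ (gel filtration)
with the sedimentation coefficient $s$ (glycerol gradient) through the
Siegel–Monty relation $MW = \alpha\,a\,s$. The factor $\alpha$ formally
contains solvent viscosity, density and the partial specific volume, but
those are buffer- and protein-dependent; the package follows the practical
route and calibrates $\alpha$ empirically as the through-origin slope of
standard MW against $a \times s$ (`alpha_from_standards()`). Marker
calibrations are unweighted ordinary least squares
(`linear_calibration()`), with extrapolation beyond the marker range
flagged. Shape is summarised by inverting the Perrin translational
friction function for a prolate ellipsoid (axial ratio $p \ge 1$,
$q = 1/p$):

$$\frac{f}{f_0} = \frac{\sqrt{1-q^2}}{q^{2/3}\,
\ln\!\big[(1+\sqrt{1-q^2})/q\big]},$$

inverted by bisection (`axial_ratio_prolate()`); the frictional ratio is
taken against the anhydrous minimal sphere computed from MW with a
partial specific volume of 0.73 mL/g (configurable; hydration is not
modelled beyond this constant).

## Design choices and limitations

- **Units.** µM and seconds internally, always; capping constants are
  reported in nM because that is their natural scale. Readers convert
  explicitly (`convert_conc()`); nothing guesses units.
- **Exact vs approximate.** Wherever the field uses both an exact solve
  and a linearised shortcut (competition, capping with/without end
  depletion), both are implemented, the exact form is the default, and
  the shortcut is labelled with its validity domain.
- **Ambiguity is a result.** Mechanism discrimination returns
  `"ambiguous"` within a 5% joint-RSS margin rather than forcing a call.
- **Out of scope.** Cooperative/Hill binding, anisotropy/FRET observation
  models, stochastic filament simulation, nucleation kinetics,
  ionic-strength-dependent constant prediction (low- and high-salt
  constants are treated as separate quantities), secondary-structure
  prediction, and any image processing: the helical arithmetic here
  manipulates the numbers such reconstructions report, not the images.

## A worked recovery example

```{r recovery, eval = FALSE}
# simulate one capping titration at the reference conditions and refit it
d <- sim_rate_titration("capping", K = 15,
                        grid = seq(0, 0.15, length.out = 12),
                        noise = 0.02, seed = 7)
fit <- bootstrap_ci(fit_kcap(d), n_resamples = 200, seed = 7)
tidy(fit)
autoplot(fit)
```
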