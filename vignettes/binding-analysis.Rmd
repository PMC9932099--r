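---
title: "Binding analysis of host-guest NMR titrations with cdbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding analysis of host-guest NMR titrations with cdbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdbind)
```

## The model

A host H and guest G in solution form a set of complexes
$\mathrm{H}_m\mathrm{G}_n$ with overall formation constants
$\beta_s = [\mathrm{H}_m\mathrm{G}_n]/([\mathrm{H}]^m[\mathrm{G}]^n)$
(units $\mathrm{M}^{-(m+n-1)}$). Given total concentrations the free
concentrations solve the two mass balances

$$[\mathrm{H}]_T = [\mathrm{H}] + \sum_s m_s c_s, \qquad
  [\mathrm{G}]_T = [\mathrm{G}] + \sum_s n_s c_s .$$

All concentrations are kept in molar internally; constants are reported in
both $\mathrm{M}^{-1}$ and $\mathrm{mM}^{-1}$ (the tabulation convention in
the cyclodextrin literature). For a single 1:1 complex the balance reduces
to a quadratic solved in closed form (`solve_one_to_one()`); general models
go through `solve_speciation()`.

NMR observation is assumed to be in the fast-exchange limit: each reporter
proton shows one population-averaged resonance, and after referencing
against an internal standard and subtracting the guest-free first point,

$$\Delta\delta_i \;=\; \sum_s \Delta\delta_{c,s,i}\, \frac{c_s}{[\mathrm{H}]_T}
  \;-\; \Big(\text{same at } [\mathrm{G}]_T = 0\Big),$$

with one sensitivity $\Delta\delta_{c,s,i}$ (ppm) per reporter proton and
bound species. The reference term matters only for models containing
guest-free host conformers, whose population is nonzero before any guest is
added. Activity corrections, ionic-strength effects and slow-exchange
lineshape analysis are out of scope.

## Fitting

`fit_global()` fits the formation constants shared across all reporter
protons, with the sensitivities free per proton. Because the sensitivities
enter linearly, they are profiled out at every trial value of the constants
(variable projection, via a rank-revealing SVD), and Levenberg-Marquardt
optimizes only the log-constants. Fitting in log space guarantees
positivity; the soft bounds are $K \in [10^{-2}, 10^9]\ \mathrm{M}^{-1}$
for second-order species (wider for higher-order formation constants),
spanning far beyond the $0.2$-$67\ \mathrm{mM}^{-1}$ range relevant here.

Standard errors come from the Gauss-Newton covariance of the *full*
parameter vector (constants and sensitivities) at the optimum, so the
uncertainty in the profiled sensitivities propagates into the constants'
errors. The full correlation matrix is reported because strongly
correlated parameters are the rule, not the exception, in multi-state
shift fits. The numerical rank of the Jacobian is checked (singular values
below $10^{-8}$ of the largest are treated as null); a deficient rank sets
`rank_deficient` and switches the covariance to a pseudo-inverse, with
unidentifiable directions reported as `NA` correlations rather than
fabricated numbers.

Initial guesses use an inflection heuristic -
$K \approx 1/[\mathrm{G}]_T$ at the half-maximal shift of the
largest-amplitude proton - with plateau values seeding the sensitivities.
All protons and points are weighted equally by default (per-proton
$1/\sigma$ weights are available via `weights`); the replicate standard
deviation across repeated experiments, not the single-fit standard error,
is the recommended headline uncertainty (`aggregate_replicates()`).

Numerical choices in the speciation solver: damped Newton on
$(\log[\mathrm{H}], \log[\mathrm{G}])$ with step-length capping and
halving, convergence at $10^{-12}$ relative on both balances, iteration cap
200, and a nested-bisection fallback that brackets each balance
monotonically. The degenerate composition $(0, 0)$ returns the all-zero
state, convenient at schedule edges.

## The two-state ("self-competitive") extension and identifiability

Job plots and non-monotonic reporter-proton curves can indicate that a
single 1:1 state is not the whole story. A tempting extension is two
distinct 1:1 bound states (guest "up" / "down" orientations,
`two_orientation_model()`). In fast exchange, however, that model is
*structurally unidentifiable*: the bound species share the same
concentration profile $c \propto [\mathrm{H}][\mathrm{G}]$, so only
$K_1 + K_2$ and the aggregate amplitudes
$K_1\Delta\delta_{c,1,i} + K_2\Delta\delta_{c,2,i}$ enter the observable.
The same is true of a guest-free self-included conformer
(`conformer_model()`): the conformer population change is exactly
proportional to the bound fraction
($[\mathrm{H}] - [\mathrm{H}]^0 = -[\mathrm{HG}]/(1+\beta_c)$), so its
contribution folds into effective sensitivities. `cdbind` treats this as a
theorem to exploit, not a nuisance: `effective_one_to_one_constant()`
computes the aggregated constant, the test suite asserts the equivalence
numerically, and `fit_global()` flags such fits rank-deficient instead of
reporting arbitrary constant splits.

Consequently the shipped *identifiable* two-state variants contain a
non-1:1 species, whose concentration profile has a different functional
dependence on the free concentrations:

* `host_sandwich` (default): $\mathrm{H + G \rightleftharpoons HG}$
  ($K_1$) and $\mathrm{H + HG \rightleftharpoons H_2G}$ (stepwise $K_2$,
  $\mathrm{M}^{-1}$). A second host competes for the bound guest - "self
  competition" by the host. This choice is also the physically natural one
  for cyclodextrin systems where the cavity cannot hold a second guest:
  the 2:1 state populates in host excess and depletes as the guest
  saturates, which produces non-monotonic reporter-proton curves and
  displaces the Job maximum above $r = 0.5$.
* `guest_sandwich`: $\mathrm{HG + G \rightleftharpoons HG_2}$, the 1:2
  analogue (Job maximum below 0.5).

`fit_two_state()` reports both constants with delta-method errors, the
maximum parameter correlation (flagging the fit `less_robust` above 0.95),
and warns when the secondary state's host population never exceeds 5%
(configurable), in which case its constant is essentially unconstrained.
Assignment of the constants to physical bound orientations cannot be made
from titration data alone and needs external through-space (ROESY) or
simulation evidence; the fit object carries this caveat. The objective has
boundary optima in which one state absorbs everything, so the fitter
multistarts over a small grid of secondary-constant guesses and keeps the
best converged solution.

## Job plots

`simulate_job()` sweeps the host mole fraction
$r = [\mathrm{H}]_0/([\mathrm{H}]_0+[\mathrm{G}]_0)$ at fixed total
concentration. Note $r$ is defined as the **host** fraction throughout -
continuous-variation write-ups are often ambiguous on this point, and the
choice flips which side of 0.5 a 2:1 or 1:2 species lands on. The ordinate
is the total complex concentration for ideal simulations and
$\Delta\delta\cdot[\mathrm{H}]_T$ (ppm M) for shift-based data, standard
continuous-variation practice. `locate_job_maximum()` refines the grid
argmax with a quadratic fit over a 5-point window (stated for
reproducibility) and handles boundary maxima (no extrapolation) and
flat-top curves (plateau midpoint, wide uncertainty) explicitly.
`job_deviation_report()` compares $|r^* - 0.5|$ against one grid spacing
plus three times the vertex uncertainty. Because a Job sweep covers a far
wider $[\mathrm{H}]_0/[\mathrm{G}]_0$ range than a titration, it is the
more sensitive diagnostic for multi-state behaviour - but by the
degeneracy theorem above, purely-1:1 multi-state models still peak at
exactly 0.5; only non-1:1 species move the maximum.

## Design rules and energy comparison

`check_dilute_regime()` implements the planning inequality
$[\mathrm{H}]_T K < 1$; violating it (sometimes unavoidable for strong
binders, where the required dilution destroys signal-to-noise) inflates the
uncertainty of the fitted constant. `titrant_range()` returns the
recommended guest window $[(0.2[\mathrm{H}]_T+0.25)/K,\;
(0.8[\mathrm{H}]_T+4)/K]$ and `make_schedule()` samples it (log spacing by
default, since the isotherm is closer to uniform in $\log[\mathrm{G}]_T$).
`K_to_deltaG()` converts constants with $\Delta G^\circ = -RT\ln K$,
$R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ (so $RT = 0.602$
kcal/mol at 303 K).

`correlate_affinity_energy()` regresses $\ln K$ on simulation interaction
energies $\langle U+W\rangle$ with an effective-variance weighting that
folds the energy uncertainties into the $\ln K$ uncertainties through the
current slope (iterated to self-consistency; reduces to OLS for equal
uncertainties). The "RT guide line" is reported as the reference slope
$-1/(RT)$ in $\ln K$ per kcal mol$^{-1}$: the line a pure Boltzmann
relation $K \propto e^{-E/RT}$ would follow. Phrasings like "slope RT" only
make dimensional sense once the ordinate is fixed; taking the ordinate as
$\ln K$ resolves it, and the package documents that convention rather than
leaving it implicit. Energies are consumed as given numbers with their
quoted uncertainties - they are enthalpic proxies (no conformational
entropy), and nothing here recomputes them. Neutral-host records are
excluded from the fit (their self-including arms break the trend) but kept
in the returned data for plotting.

## What the synthetic generator does and does not emulate

`scenario()` + `generate_titration()` produce referenced shift tables with
the statistical structure of real dilute-host titrations: host below
0.1 mM, a 12-point log-spaced schedule over the design window, iid Gaussian
shift noise, an exactly-zero first point (the referencing convention), and
triplicate experiments. Defaults and the reasoning behind them:

* **noise_sd = 0.002 ppm** - a realistic shift precision for a modern
  600 MHz cryoprobe instrument; configurable.
* **sensitivities** - invented defaults with cavity-facing H3/H5 protons
  large (0.10-0.15 ppm) and exterior H1/H6 small (0.015-0.04 ppm),
  magnitudes in the 0.02-0.15 ppm range typical of cyclodextrin
  complexation; the multi-state patterns include a sign flip so
  non-monotonic curves can arise. These are generator defaults, not
  measured values.
* **host totals** - chosen per scenario to satisfy $[\mathrm{H}]_T K < 1$
  wherever the affinity permits; the strongest-binding two-state scenario
  (67 mM$^{-1}$) deliberately violates it at $9\times10^{-5}$ M, as the
  corresponding real experiment had to for signal-to-noise reasons.
* **two-state schedules** - 14 points extending the design window tenfold
  at the top, so the guest sweeps past the host and the 2:1 state's
  rise-and-fall is expressed; without guest excess the secondary constant
  is near-unidentifiable at realistic noise.

The generator does **not** simulate spectra: no peak overlap, baseline or
phasing artifacts, no lineshape effects, no exchange broadening, no
dilution drift unless a per-point host column is supplied. Passing tests
therefore demonstrate the statistical machinery under the stated noise
model, not robustness to spectral pathology upstream of peak picking.

## Problem sizes and test design

The validation suite works at desk scale, chosen to exercise every code
path while keeping a full run in minutes: speciation oracle sweeps of
1,000 random conditions spanning six orders of magnitude in $K$; noiseless
round-trips for all seven built-in scenarios (recovery to $10^{-6}$
relative); coverage calibration from 100 seeded replicates per simple
scenario at 0.002 ppm noise (true $K$ inside $\pm2$ SE in roughly 90% of
fits, bias under a few percent); and triplicate two-state recovery at
0.001 ppm noise judged against the replicate standard deviation, the same
convention a real study reports.

## Known limitations

* Single-replicate two-state fits at realistic noise sit near the
  identifiability edge: the secondary constant can collapse to its bound
  for unlucky noise draws (the boundary optimum genuinely wins). This is a
  property of the experiment, not the optimizer - it is why replication
  and the aggregated mean/sd are the recommended reporting route, and why
  the correlation diagnostics exist.
* The covariance-based standard errors are asymptotic (Gauss-Newton); for
  strongly nonlinear or near-degenerate fits they understate tail risk.
* Job analysis diagnoses deviation from 1:1 stoichiometry but does not fit
  constants from Job data alone, nor does it perform formal hypothesis
  tests beyond the tolerance comparison.
* The speciation solver assumes ideal-dilute activity coefficients.
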