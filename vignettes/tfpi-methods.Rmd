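---
title: "Modelling TFPI inhibition of factor X activation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling TFPI inhibition of factor X activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfpiflow)
```

## The biochemical model

Coagulation is initiated when tissue factor (TF) exposed at a vessel
injury binds plasma factor VIIa. The TF:VIIa complex (`E`) activates
factor X (`S`) to factor Xa (`P`), the protease that ultimately drives
thrombin generation. Tissue factor pathway inhibitor (TFPI, `I`)
regulates this first step, and two inhibition routes have been
hypothesized: *direct binding*, in which TFPI captures Xa while it is
still held in the TF:VIIa:Xa product complex, and *indirect binding*,
in which the solution-phase Xa:TFPI complex binds free TF:VIIa. Both
routes converge on a transient quaternary complex (`EPI`) that relaxes,
by engagement of TFPI's Kunitz-1 domain with VIIa, into a long-lived
tight configuration (`PIE`).

`tfpiflow` tracks the nine species `E, S, ES, EP, P, I, PI, EPI, PIE`
(nM) under elementary mass-action kinetics with eight numbered
reactions:

1. `E + S <-> E:S` — substrate binding (`k_plus_1`, `k_minus_1`)
2. `E:S -> E:P` — catalysis (`k_plus_2`)
3. `E:P <-> E + P` — product release/rebinding (`k_minus_3`, `k_plus_3`)
4. `P + I <-> P:I` — solution-phase Xa-TFPI binding
5. `E + P:I <-> P:I:E` — simultaneous double binding; *removed* from the
   working scheme (a single encounter achieving two binding events is
   vanishingly unlikely next to reaction 8), but its terms are retained
   in the algebra with zero default rates so the historical full scheme
   remains expressible
6. `E:P + I <-> E:P:I` — the direct route's capture step
7. `E:P:I <-> P:I:E` — conformational change to the tight complex
8. `E + P:I <-> E:P:I` — the indirect route's docking step

The closed (static) system conserves three moieties exactly — enzyme
(`E + ES + EP + EPI + PIE`), factor X (`S + ES + EP + P + PI + EPI +
PIE`) and TFPI (`I + PI + EPI + PIE`) — and the test suite checks these
sums to 1e-8 nM along every integration.

A detail worth knowing when comparing with textbook enzyme kinetics:
catalysis here proceeds *through* the product complex (`ES -> EP ->
E + P`), so even with reactions 4–8 removed the quasi-steady activation
rate is the Michaelis–Menten rate divided by a sequestration factor
`1 + (k_plus_2/k_minus_3) * S/(K_M + S)`-style correction; at the
fitted medians `k_plus_2/k_minus_3 = 16.23/81.18` this depresses the
rate by about 8% at `S = 170` nM. The unit tests assert the exact
closed form rather than the uncorrected Michaelis–Menten value.

## Flow model and steady-state analyses

Under flow the injury site is treated as a well-mixed reaction zone
exchanging material with upstream plasma at a mass-transfer rate
`k_flow` (s^-1): factor X and TFPI flow in at their upstream
concentrations (`S_up = 170` nM, `I_up = 2.4` nM by default) and the
four solution-phase species (`S`, `P`, `I`, `PI`) wash out, while the
enzyme species remain anchored. From vessel geometry,

```
k_flow = (3/4) * (V^2 * D / (R * L)^2)^(1/3)
```

with midstream velocity `V` (um/s), diffusivity `D` (50 um^2/s for
proteins of this size), radius `R` (um) and injury length `L` (10 um).
Across reported velocities and radii from arteries to veins this spans
roughly 1e-3 to 1e3 s^-1, the default sweep range (25 log-spaced
points).

Inhibition strength is summarized by the functional enzyme
`E_functional = [E] + [E:S]`; the four pathway variants (`NI` — no
TFPI, reactions 1–3 only; `DB` — direct; `IB` — indirect; `DIB` — both)
are obtained by nullifying the corresponding reactions. Two printed
reference points anchor the analysis: with median rates and 1 nM of
enzyme, the no-TFPI steady state retains about 0.92 nM of functional
enzyme at `k_flow = 1` s^-1 and about 0.76 nM at 1e-3 s^-1. Both are
reproduced by `steady_state()` and recomputed from scratch by
`scripts/acceptance.R`.

Two design choices here were genuinely open:

* **Initial enzyme amount.** The source analyses never state `E(0)`;
  1 nM is the unique round value consistent with both printed steady
  states and with the top of the titration range (1.024 nM), so all
  flow analyses default to `enzyme_total = 1` nM.
* **Upstream concentrations.** The source text assigns 170 nM to TFPI
  and 2.4 nM to factor X, the reverse of every experimental
  concentration it uses; with `S_up = 170` and `I_up = 2.4` the two
  printed steady states are reproduced quantitatively, so the package
  adopts that orientation (overridable in `flow_config()`).

Steady states are found by relaxing the stiff system over geometrically
growing horizons and polishing with a damped Newton iteration in which
the degenerate free-enzyme balance is replaced by the enzyme-moiety
constraint; convergence demands a residual below 1e-10 nM/s in every
component. A closed-form fixed point exists for the five-species
no-TFPI subsystem and serves as an independent oracle in the tests.
"Complete inhibition" is operationalized as a steady-state
`E_functional` below 0.05 nM (5% of the enzyme), since the source claim
is qualitative.

The product-inhibition study asks how tightly Xa would need to bind
TF:VIIa for product rebinding alone to rival direct TFPI binding:
`k_minus_3` is divided by a factor `phi` (so `K_D_3` drops from 520 nM
to 520/phi), and the no-TFPI sweep is repeated. At `phi = 1000`
(`K_D_3 = 0.52` nM) the curve finally tracks the direct-binding sweep
at medium-to-high flow — far below any reported dissociation constant,
which is the quantitative sense in which product inhibition is
negligible.

## Numerical integration

The right-hand sides are compiled (C, via the deSolve compiled-model
interface) and integrated with `lsoda` at relative tolerance 1e-8 and
absolute tolerance 1e-12 nM. The system is genuinely stiff — the
conformational rate `k_plus_7` (~361 s^-1) coexists with
`k_minus_4` (~1e-4 s^-1) — and the tight tolerances are what make
1e-8-nM conservation achievable. Any concentration dipping below
-1e-9 nM aborts the integration rather than being clipped: silent
clipping would mask solver misconfiguration. The species ordering
`(E, S, ES, EP, P, I, PI, EPI, PIE)` is fixed across vectors, files
and summaries.

## Experimental protocols and observable

Two classic titration protocols define the fitting data:

* **Experiment One** — factor X (170 nM) activated by TF:VIIa at
  doubling concentrations 0.032–1.024 nM in the presence of TFPI
  (2.4 nM). One source sentence says 2.5 nM; the figure captions say
  2.4 nM, which is used throughout.
* **Experiment Two** — TFPI (2.4 nM) pre-incubated for two hours with
  Xa (0–1 nM), then combined with TF:VIIa (0.128 nM) and factor X
  (170 nM). Pre-incubation is integrated as the isolated reversible
  reaction 4; at the fitted rates its relaxation time (~1/(k_plus_4 I))
  is minutes, so the mixture sits at the binding equilibrium fixed by
  `K_D_4 = 2.63e-2` nM. Mixing is assumed dilution-free (all stated
  concentrations are post-mix). The zero-Xa condition reproduces the
  0.128 nM condition of Experiment One bit for bit, a replicate
  identity the tests assert.

The measured observable is activated factor X; the package maps a
trajectory to free Xa (`[P]`) by default. Xa sequestered in `E:P` stays
within a few percent of `[P]` under these conditions, and the
alternative mapping `[P] + [E:P]` is exposed for sensitivity checks.
The exact measurement grids of the original digitized curves are not
printed; the default design uses twelve equally spaced non-zero times
over 720 s, six Experiment One curves (the stated doublings) and four
Experiment Two pre-incubation levels (0, 0.1, 0.5, 1 nM), extensible to
the eight-curve variant that yields the original 96 + 48 measurement
count.

## Likelihood and parameterization

Measurements are modelled as independent normals centred on the model
prediction with standard deviation proportional to it
(`sd = sigma * mu`), capturing the observed heteroscedasticity; the
total log-likelihood is the sum over all measurements of both
experiments. The free vector is

```
theta = (k_plus_1, k_plus_2, k_plus_3, k_plus_4, k_plus_6, k_minus_6,
         k_plus_7, k_minus_7, k_plus_8, k_minus_8, sigma)
```

with the remaining rates derived: `k_minus_1 = K_M * k_plus_1 -
k_plus_2` (Michaelis relationship, `K_M = 238` nM fixed), `k_minus_3 =
520 * k_plus_3` and `k_minus_4 = 2.63e-2 * k_plus_4` (fixed
dissociation constants; in both published rate tables the median ratio
`k_minus_4/k_plus_4` equals 2.63e-2 to three significant figures,
which two independently sampled parameters would not do). Bounds:
bimolecular forward rates capped at the diffusion limit 1 nM^-1 s^-1,
reverse rates and `k_plus_7` at 500 s^-1, `k_minus_7` at 1e-2 s^-1,
`k_plus_2 <= K_M`, `k_minus_1 >= 0`, and `sigma` in (0, 1] (no bound
is stated for the error scale; a proportional error above 100% would
mean the assay carries no signal). The prior is uniform over this box —
the occasional description of a "normal prior" in the source is read as
describing the normal random-walk proposal — and proposals falling
outside are rejected, never clipped. Sampling is in the natural linear
scale, matching the uniform-box prior. The ratio for reaction 7 is
reported in both directions (`K_R_7 = k_plus_7/k_minus_7` and its
reciprocal), since the published table prints the reciprocal of its own
textual definition.

## Estimation pipeline

Estimation follows four steps: (i) Latin-hypercube pre-exploration of
the box (draws violating `k_minus_1 >= 0` are discarded), condensing
the best draws into a starting point and a diagonal proposal spread;
(ii) fixed-proposal random-walk Metropolis; (iii) adaptive Metropolis;
(iv) burn-in removal and thinning, with the lag-1 autocorrelation of
every retained parameter reported and a warning above 5%. The
full-scale design is 1e6 LHS draws (top 500 kept), 1e5 MA iterations,
6e6 AM iterations and stride 100, leaving 6e4 estimates per chain; the
package defaults run the same per-chain pipeline about 100x smaller
(1e4 draws / top 3 / 1e3 MA / 2e4 AM, stride 10) so a complete
parameter-recovery study fits in well under half an hour of desktop
CPU. Three independent chains, each with its own pre-exploration, are
run by default and their thinned samples pooled for all summaries:
between-chain spread then contributes to the credible intervals, which
guards against the single-chain underdispersion that short adaptive
runs are prone to. The desk-scale `top_k` of 3 keeps roughly the
full-scale retained fraction (500 of 1e6), and the desk-scale burn-in
follows the discard-first-half convention (the MA phase plus the first
half of each AM chain), which comfortably covers the annealed stretch
described below and the tail of the climb towards the mode.

The adaptive sampler is a mixture kernel rather than textbook
full-history Haario adaptation, a choice made after the latter proved
unable to reach stationarity at desk scale on this posterior (the
likelihood surface rises ~200 log-units from the best LHS draw to the
mode, and a full-history covariance stays polluted by that climb,
collapsing acceptance to ~1%). The kernel interleaves:

* full-vector Gaussian proposals (55% of iterations) with an
  exponentially forgetting (window 2000) empirical covariance scaled
  by `2.38^2/d`, a global scale factor adapted towards 23.4%
  acceptance, an occasional (15%) 3x-inflated proposal to traverse
  ridges, and a delayed-rejection second stage at one fifth of the
  scale;
* random-scan single-coordinate proposals (35%) whose per-coordinate
  scales adapt towards 44% acceptance, letting weakly identified
  coordinates (for example the conformational rates, which the data
  bound only loosely) travel their full range while sharply identified
  ones take small steps; and
* joint multiplicative moves (10%) rescaling `k_plus_3` and
  `k_plus_6` by a common lognormal factor with the standard Hastings
  correction. These two rates are correlated at 0.99 in the posterior:
  with `k_minus_3` tied to `k_plus_3` through the fixed `K_D_3`, the
  data identify essentially only the capture ratio
  `k_plus_6/k_minus_3` (how often TFPI captures the product complex
  before Xa escapes), so a ratio-preserving joint rescaling walks the
  model's sloppiest direction in one step.

In addition, the first quarter of each adaptive run is an *annealed
burn-in*: the log posterior is tempered by a factor ramping linearly
from 0.05 to 1, which lets the chain race up the likelihood surface —
the best Latin-hypercube draw typically sits hundreds of
log-likelihood units below the mode — before exact sampling begins.
The tempered stretch samples a flattened distribution, not the
posterior, and falls entirely inside the discarded burn-in;
everything summarized is sampled from the untempered target.

All moves are symmetric with the standard delayed-rejection
correction, so detailed balance holds; the unit tests verify the
sampler against analytic targets (normal moments, flat-box acceptance
counting, correlated-target adaptation) and a Laplace check at the
maximum-likelihood point of the reference synthetic dataset confirms
that the converged posterior covers the generating parameters in all
eleven marginals.

Chains cache one ODE solve per condition per likelihood evaluation
(ten solves at the default design, plus four small pre-incubation
integrations).

## Synthetic data and what it does and does not show

`make_reference_design()` fixes the study conditions: true rates at the
fitted medians (reverse rates re-derived through the fixed `K_M`,
`K_D_3`, `K_D_4` so the truth lies inside the estimable
parameterization), `sigma_true = 0.05` (the main analysis does not
print its fitted error scale; 5% proportional noise is a typical
digitization-plus-assay figure and produces curves visually comparable
to the published ones), the default condition lists and time grid, and
a fixed seed. `generate_dataset()` simulates each protocol, evaluates
the noise-free observable and adds proportional normal noise; negative
draws are redrawn rather than clipped (preserving the normal shape
near the bulk; the redraw count is recorded so heavy truncation would
be visible), and `t = 0` points are never generated since the
proportional error degenerates there.

The generator reproduces the statistical structure the analysis
assumes — protocol-faithful kinetics, independent heteroscedastic
noise. It deliberately does not emulate figure-digitization error
(uncharacterized in the source), assay chemistry (chromogenic readout,
quench), pipetting error in the initial conditions, or lipid-surface
effects. Passing recovery tests therefore demonstrate that the
pipeline is consistent and identifiable under its own assumptions, not
that those assumptions hold for any particular wet-lab dataset; the
published posterior medians themselves depend on the digitized data
and the 6e6-iteration chains and are not reproducible at desk scale.

## Problem sizes used by the test suite

The suite favours exact analytic oracles wherever one exists (moiety
sums, the no-TFPI fixed point, the pre-incubation quadratic, the
noise-free likelihood maximum). The stochastic end-to-end recovery
test runs the 1e4 / 1e3 / 2e4 desk design on the 6 + 4-curve reference
dataset (about five minutes of CPU); sweeps use the default 25-point
flow grid. Monte-Carlo checks of the noise law use 3000 replicate
draws at two measurement points.

## Known limitations

* The model is well-mixed; no spatial transport, boundary layers,
  platelet deposition or lipid surfaces.
* The flow analyses characterize steady states of the open system;
  transient behaviour is simulated but not summarized.
* The steady-state solver assumes the open system settles to a point
  attractor, which holds across the parameter ranges exercised here
  but is not proven in general.
* Desk-scale chains are adequate for recovery studies on synthetic
  data; published-scale posterior summaries require the full-scale
  counts, hours of CPU, and the original digitized measurements.
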