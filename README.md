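# tfpiflow

Kinetic modelling of how tissue factor pathway inhibitor (TFPI) shuts
down the first step of blood coagulation — the activation of factor X
by the surface-bound TF:VIIa complex — in a closed cuvette and in a
flow-through reaction zone.

The package is aimed at coagulation modellers and systems biologists
who want a tested, reusable implementation of:

* the nine-species mass-action scheme for factor X activation with
  both hypothesized TFPI routes — *direct binding* (TFPI captures Xa
  inside the TF:VIIa:Xa complex, reactions 6–7) and *indirect binding*
  (the solution-phase Xa:TFPI complex docks onto TF:VIIa, reactions
  4, 8, 7) — ending in the tight quaternary complex P:I:E;
* the flow generalization, in which the reaction zone exchanges
  solution-phase species with upstream plasma at a mass-transfer rate
  `k_flow = (3/4) (V²D/(RL)²)^{1/3}` while the enzyme stays anchored,
  plus steady-state pathway analyses built on the functional-enzyme
  metric `E_functional = [E] + [E:S]`;
* Bayesian estimation of the rate constants from factor Xa progress
  curves under a proportional-error likelihood
  `A(tᵢ) ~ N(μ(tᵢ|θ), σ·μ(tᵢ|θ))`, via Latin-hypercube
  pre-exploration, random-walk Metropolis and adaptive Metropolis,
  with a constrained parameterization (`k₋₁ = K_M k₊₁ − k₊₂` with
  `K_M = 238` nM; `K_D,3 = 520` nM and `K_D,4 = 2.63×10⁻²` nM fixed);
* a protocol-faithful synthetic-data generator (enzyme titration
  0.032–1.024 nM; two-hour TFPI/Xa pre-incubation) for end-to-end
  parameter-recovery studies without any external data.

## Worked example

Steady-state inhibition across the physiological flow range, with the
fitted median rates:

```r
library(tfpiflow)

ni <- apply_pathway_variant(table1_rates(), "NI")   # reactions 1-3 only
ss <- steady_state(ni, flow_config(k_flow = 1), enzyme_total = 1)
e_functional(ss)
#> [1] 0.9182955

e_functional(steady_state(ni, flow_config(k_flow = 1e-3), enzyme_total = 1))
#> [1] 0.7536553
```

Without TFPI, product inhibition by Xa barely dents the enzyme: at
medium flow (`k_flow = 1` s⁻¹) about 0.92 nM of the 1 nM of enzyme is
still functional at steady state, and even at near-static flow
(10⁻³ s⁻¹) it never drops below about 0.75 nM, because flow washes Xa
out of the reaction zone faster than it can rebind. The direct-binding
pathway, by contrast, inhibits essentially completely at every flow
rate:

```r
sw <- flow_sweep(table1_rates(), "DB")
range(sw$E_functional_nM)
#> [1] 0.004325215 0.007458991
```

A full recovery study — generate a synthetic dataset at the reference
design and re-estimate the rates with the desk-scale pipeline (three
pooled chains, under twenty minutes of CPU):

```r
data <- generate_dataset(make_reference_design())
fit  <- fit_kinetics(data, fit_config(seed = 1))
subset(fit$summary, parameter %in% c("k_plus_2", "k_plus_4", "sigma"))
#>  parameter       median     lower_95     upper_95
#>   k_plus_2 12.572585969 10.426459960 14.516027336
#>   k_plus_4  0.003821503  0.003552475  0.004109119
#>      sigma  0.056580909  0.049810707  0.064184575
```

The medians land within 25% of the generating values (`k₊₂ = 16.23`
s⁻¹, `k₊₄ = 3.67×10⁻³` nM⁻¹s⁻¹, `σ = 0.05`), and the 95% credible
intervals cover the truth in 9 of the 11 free parameters — the same
nine that a six-times-longer converged chain covers: for this noise
realization the data genuinely place the `k₊₂` posterior a little
below the generating value, a reminder that on finite noisy data the
posterior concentrates on the data's best explanation, not on the
generator.

## Command line

A thin wrapper over the same functions lives at `inst/cli/tfpiflow.R`:

```sh
Rscript inst/cli/tfpiflow.R simulate --enzyme-nm 0.128 --out-dir out
Rscript inst/cli/tfpiflow.R flow-sweep --phi 1,10,100,1000 --out-dir out
Rscript inst/cli/tfpiflow.R generate --seed 1 --out-dir out
Rscript inst/cli/tfpiflow.R fit --data out/synthetic_dataset.csv --out-dir out
```

See `vignettes/tfpi-methods.Rmd` for the model, the estimation
procedure, and the reasoning behind every numerical and design choice.
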