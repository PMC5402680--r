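# neuropk

Physiologically-based pharmacokinetic (PBPK) modeling of brain-derived
blood biomarkers: S100B (monomer and homodimer), GFAP and UCHL-1.

Serum levels of these proteins are used to assess traumatic brain injury
and blood–brain barrier (BBB) integrity, but they are shaped as much by
physiology as by pathology: by the baseline permeability of the BBB, the
subject's brain-to-blood volume ratio, extracranial sources such as skin,
and molecular-weight-dependent renal elimination. `neuropk` is for
researchers who want to predict — and decompose — steady-state and
post-disruption serum concentrations across neonates and adults, sexes,
skin pigmentation levels and degrees of kidney failure.

## The model

A single well-mixed blood pool of volume $V_b$ exchanges with
fixed-concentration source organs (brain, optionally skin) and is drained
by glomerular filtration:

$$
V_b\frac{dC}{dt} = \sum_i CL_i(t)\,(B_i - C) - \mathrm{GFR}\cdot C_F(MW)\cdot C
$$

- the brain's transfer clearance is gated by a 0–100 *radiologic index*
  of BBB opening: $CL_{brain}(t) = \frac{\mathrm{index}(t)}{100} CL_{max}$,
  with a steady-state leak of 2.5% of maximal in adults and 10% in
  newborns, and transient disruption events that jump the index and relax
  exponentially;
- $C_F(MW)$ is the glomerular sieving coefficient, a decreasing sigmoid
  of molecular weight clamped to $[0,1]$ (≈0.87 at 10.7 kD, 0 above
  ~74 kD);
- GFR comes from the creatinine formula with sex/race coefficient sets
  for adults and a BSA-scaled 47 ml/min/1.73 m² preset for neonates;
- the maximal transfer clearance $CL_{max}$ is calibrated against two
  empirical anchors (the 0.22 ng/ml serum S100B shift at maximal
  disruption and the post-mannitol time course
  $0.29 - 0.20\cdot0.79^{t}$) and volume-scaled to other organs.

See the methods vignette (`vignettes/biomarker-kinetics.Rmd`) for
assumptions, parameter provenance and design decisions.

## Worked example

```r
library(neuropk)

cal <- calibrate_bbb()
cal
#> <bbb_calibration> CLmax 21.32 ml/min (adult brain), tau 8.81 min, RMS 0.0146 ng/ml

model <- build_model(subject_preset("adult_male"),
                     get_biomarker("s100b_monomer"), cal,
                     events = list(disruption_event(700, 100, cal$recovery_tau)))
model
#> <compartment_model> s100b_monomer, adult male
#>   brain   1.42 l at 10.000 ng/ml, CLmax  21.32 ml/min, leak 2.5%
#>   renal  CL 89.63 ml/min (GFR 102.8 x C_F 0.872), blood 6.00 l
#>   1 disruption event(s)

res <- simulate_serum(model, duration = 1000)
glance(res)
#> # A tibble: 1 × 6
#>   final_serum_ng_ml steady_state_ng_ml steady_state_min mass_balance_ng ...
#> 1            0.0629             0.0591             638.        2.42e-11
max(res$serum_conc)
#> [1] 0.2791128
```

Reading this: starting from zero serum, adult S100B settles at
~0.059 ng/ml after ~10 h — the healthy baseline sustained by the 2.5%
barrier leak against a renal clearance of ~90 ml/min. The maximal
disruption event at t = 700 min drives a transient peak of ~0.28 ng/ml
(an increment of ~0.22 ng/ml, by construction of the calibration), which
then decays back with the marker's elimination half-life. The
mass-balance column confirms conservation to ~1e-11 ng.
`tidy(res)` gives the full time series as a tibble and `autoplot(res)`
plots it.

Scenario helpers reproduce the population contrasts:

```r
rep <- run_age_comparison("s100b_monomer")
rep$fold_ratios
#> # A tibble: 1 × 4
#>   marker        neonate  adult fold_ratio
#> 1 s100b_monomer   0.962 0.0591       16.3
```

The newborn plateau is ~16-fold higher than the adult one — the combined
effect of a leakier barrier (10% vs 2.5%), a far higher brain-to-blood
volume ratio (0.42:0.28 vs 1.42:6.0 l) and immature kidney filtration.
`run_pigmentation_comparison()`, `run_gender_comparison()` and
`run_kidney_sweep()` cover the skin, sex and renal-failure analyses;
`load_config()` / `run_from_config()` / `write_outputs()` run YAML-configured
simulations with deterministic CSV/JSON outputs, and
`inst/cli/neuropk.R` is a thin command-line wrapper over the same
functions.

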