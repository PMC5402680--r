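---
title: "Modeling brain-derived blood biomarkers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling brain-derived blood biomarkers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropk)
```

## The problem

Proteins of astrocytic and neuronal origin — S100B (as a ~10.7 kD monomer
and a ~21 kD homodimer), GFAP (~26 kD) and UCHL-1 (~26 kD) — are used as
blood biomarkers of traumatic brain injury and blood–brain barrier (BBB)
integrity. Their serum levels, however, depend on much more than the
disease state: on the permeability of the BBB, on the subject's
brain-to-blood volume ratio, on extracranial sources such as skin, and on
renal elimination, which itself depends strongly on molecular weight.
`neuropk` implements a physiologically-based pharmacokinetic (PBPK)
compartment model that makes these dependencies explicit, so that
steady-state and post-disruption serum concentrations can be predicted for
subjects of different age, sex, skin pigmentation and kidney health.

## The model

The blood is a single homogeneous, well-mixed pool of volume $V_b$.
Each source organ $i$ (the brain, optionally the skin) holds its marker at
a fixed tissue concentration $B_i$ — an infinite-reservoir assumption:
source tissue is never depleted, and injury-related glial upregulation
(gliosis) is represented simply as a raised $B_i$. Transfer into blood is
a clearance-type exchange, and elimination is glomerular:

$$
V_b \frac{dC}{dt} \;=\; \sum_i CL_i(t)\,\bigl(B_i - C\bigr)
\;-\; CL_{renal}\, C .
$$

Exchange is gradient-driven and bidirectional by default. Because
$B_i \gg C$ in every scenario considered here, the difference from a
unidirectional influx term $CL_i B_i$ is under 1%; the unidirectional form
is available as a toggle (`bidirectional = FALSE`) since the direction
convention for extracranial organs is not settled.

**Barrier gating.** The brain's transfer clearance is time-varying:
$CL_{brain}(t) = \tfrac{\mathrm{index}(t)}{100}\,CL_{max}$, where the
radiologic index is a 0–100 scale of BBB opening (100 = maximal
bi-hemispheric disruption as seen on contrast-enhanced CT) and $CL_{max}$
is the free-diffusion transfer clearance of a fully open barrier. In
health the barrier is not perfectly tight: a steady-state leak of 2.5% of
maximal (the midpoint of the observed 1–5% adult range) sustains the
baseline serum level; newborns, whose barrier is more permeable, use 10%.
A disruption event jumps the index to a peak and relaxes it back
exponentially; the single-exponential recovery is a parsimony choice (the
underlying observation is only that disruption "gradually" resolves, and
the empirical post-mannitol serum curve is itself exponential). When
events overlap, the profile takes the pointwise maximum.

**Renal elimination.** $CL_{renal} = \mathrm{GFR} \times C_F(MW)$. Adult
GFR uses the creatinine formula
$\mathrm{GFR} = f_{kid}\, A\, (SrCr/B)^{e}\, 0.993^{age}$ (ml/min) with
coefficient sets $A$ = 141/144 (Caucasian male/female) or 163/166
(African-American male/female) and $B$ = 0.9/0.7 mg/dl; $f_{kid} \in
[0,1]$ is a kidney-health multiplier. The creatinine exponent is printed
in the source table without a sign; we apply $e = -1.209$ only when
$SrCr/B > 1$, since a positive exponent would make filtration rise with
creatinine, contradicting renal physiology, and the default
$SrCr = B$ makes the term inert either way. Age is standardized at 45
years (the age term moves the result only slightly across adulthood). A
×60 factor that appears with this formula in its original hourly-solver
context is treated purely as a per-hour export conversion
(`per_hour = TRUE`); all internal rates are ml/min, matching the
minute-scale disruption kinetics. Neonatal GFR is not creatinine-based:
it is preset at 47 ml/min per 1.73 m² BSA and scaled to the neonate's
body surface area (default 0.25 m²), giving ≈6.8 ml/min absolute — the
unscaled 47 ml/min would be far too fast for a 280 ml blood pool.

The filtration (sieving) coefficient is a decreasing sigmoid of molecular
weight,

$$
C_F = -0.04094 + \frac{1.19614}{1 + 10^{\,-3.1\times10^{-5}(27096 - MW)}},
$$

clamped to $[0,1]$ because the raw curve slightly overshoots both ends
(≈1.004 as $MW \to 0$, ≈−0.041 as $MW \to \infty$). Small proteins filter
nearly freely ($C_F(10.7\,\mathrm{kD}) \approx 0.87$); above ~74 kD
filtration is zero and, since the model has no tubular or hepatic
elimination, such markers are cleared only by back-diffusion into source
organs (bidirectional mode) or not at all. The single-compartment
half-life is $t_{1/2} = \ln 2 \cdot V_b / CL_{total}$, with `Inf` as the
explicit sentinel at zero clearance.

**Total blood volume.** Nadler's formula is provided in two dialects. The
`as_printed` dialect is linear in height, which yields an implausible
~3.8 l for a 1.80 m, 80 kg male; the default `nadler_cubic` dialect cubes
the height term (the male coefficients are exactly those of the canonical
cubic Nadler formula), giving ~5.3 l. The shipped presets use the
literature volumes directly (adult blood 6.0 l, newborn 0.28 l), so the
formula only matters for custom anthropometrics.

## Calibrating the barrier transfer clearance

$CL_{max}$ and the disruption recovery constant $\tau$ are not observable
directly and are not published; `calibrate_bbb()` reconstructs them from
two empirical anchors measured in patients undergoing therapeutic osmotic
BBB disruption:

1. the linear index-to-shift map: serum S100B rises by
   $0.0022 \times \mathrm{index}$ ng/ml, i.e. 0.22 ng/ml at maximal
   disruption (treated as the transient peak, matching the saturating
   shape of the measured time course);
2. the post-mannitol serum time course
   $0.29 - 0.20 \cdot 0.79^{\,t}$ ng/ml ($t$ in minutes).

For each candidate $\tau$, an inner one-dimensional root solve finds the
$CL_{max}$ whose simulated maximal-disruption event (started from the
adult steady state) peaks at exactly 0.22 ng/ml; the outer bounded
minimisation picks the $\tau$ whose increment curve best fits the
reference curve (RMS over the first 20 min, baselines aligned — the
reference starts at 0.09 ng/ml, the model at its own steady state).
Everything is deterministic: fixed grids, fixed bracket, no randomness.
The optimum lands at $CL_{max} \approx 21.3$ ml/min, $\tau \approx 8.8$
min with an RMS residual of ≈0.015 ng/ml. A back-of-envelope impulse
balance ($CL_{max}\,B\,\tau / V_b = 0.22$) suggests the product
$CL_{max}\tau \approx 132$ ml; the fitted product is larger (~188 ml)
because elimination during the pulse attenuates the peak, which the full
ODE accounts for.

One calibrated constant serves all subjects, organs and markers: organ
maximal clearances scale proportionally to organ volume against the
adult-brain reference (1.42 l), so the neonatal brain (0.42 l) gets
$CL_{max} \cdot 0.42/1.42$ and the adult skin (7.8 l)
$CL_{max} \cdot 7.8/1.42$, the latter transferring at a fixed 2% leak.
This single volume-scaling rule is our design choice — no measured
per-organ transfer constants exist — and it is what lets one constant
reproduce the neonatal steady state and the skin contributions
simultaneously. No
marker-specific barrier permeability is modeled, because no
marker-resolved disruption data exists; markers differ through their
tissue concentrations and molecular weight only.

## Numerical choices

- Stiff-capable integration (`deSolve::lsoda`), relative tolerance 1e-8,
  absolute tolerance 1e-12 ng/ml, default output grid 0.5 min.
- Integration proceeds piecewise between disruption onsets so the
  permeability jumps are never smoothed over; onsets that coincide with a
  grid point to within 1e-9 of the span are snapped onto it.
- Cumulative transferred and excreted masses are co-integrated as extra
  states; the mass-balance discrepancy
  $|M_{in} - M_{out} - V_b \Delta C|$ is checked to stay below $10^{-6}$
  of the transferred mass on every run.
- Solver undershoot below zero is clipped only within 1e-9 ng/ml;
  anything larger raises a consistency error.
- Steady-state detection: the earliest time at which the relative
  max–min spread over a trailing 60 min window falls below 1e-4.
- No random number generation anywhere in the core; property tests use
  seeded generators.

## Scenario conventions

Scenarios place the maximal disruption event 60 min after detected steady
state and use the calibrated recovery constant; the timing is a
convention of this package. The neonatal arm keeps brain marker
concentrations equal to adult values, so the age contrast isolates
anatomy (brain:blood 0.42:0.28 vs 1.42:6.0 l), baseline leak (10% vs
2.5%) and kidney filtration. The dark-skin tissue concentration is taken
as exactly 2.0 ng/ml (reported values range from 2.0 ng/ml upward; we use
the tabulated endpoint). The pigmentation scenario considers
adult males only, and neonates never get a skin compartment. The
kidney-failure sweep uses the closed-form physiology chain; because
clearance is linear in the kidney-health fraction, the *relative*
half-life increase under renal failure is identical for every marker
(exactly 10× at $f_{kid} = 0.1$) — the often-stated high-MW
vulnerability holds at the level of *absolute* half-life increase, which
does grow steeply with molecular weight.

```{r scenarios, eval = FALSE}
rep <- run_age_comparison("s100b_monomer")
tidy(rep)
rep$fold_ratios

run_kidney_sweep() |> plot_kidney_sweep()
```

## What the tests do and do not show

The test suite checks the implementation against *itself* (ODE plateaus
vs the closed-form steady state on randomized models, mass conservation,
post-event decay vs the half-life chain, recovery of known calibration
constants from simulated traces) and against the published predictions
(steady states, fold-ratios, the index map). Randomized models span both
age classes, molecular weights of ~1.6–200 kD, and kidney-health
fractions 0.2–1, with simulations sized at 14 system time constants and
300–400 output points — small enough for a seconds-scale suite, long
enough that plateau truncation error is far below the 0.1% comparison
tolerance. None of this validates the model against patient data beyond
the anchors built into the calibration: the infinite-reservoir sources,
the single well-mixed blood pool (no arterial/venous split, no CSF or
interstitial sub-compartments), the absence of protein binding,
degradation, hepatic elimination and tubular handling, and the single
volume-scaling rule for organ clearances are all simplifications whose
adequacy is exactly what the published comparisons — and not this test
suite — speak to.

## Known limitations

- Markers above the ~74 kD sieving cutoff have zero renal clearance; in
  unidirectional mode they accumulate without bound, which is physical
  only on short horizons.
- The radiologic index is the sole disruption abstraction: mannitol
  pharmacology, infusion parameters and hemispheric laterality are out of
  scope.
- Fat tissue, although it contains measurable S100B, is excluded from the
  default sources (it is reported not to influence blood S100B, likely
  for vascularization reasons that this model does not represent).
- No pediatric maturation between the neonate and adult endpoints is
  modeled.
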