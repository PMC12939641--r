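---
title: "Estimating venous hemodynamics and vasoactive dose-response at the bedside"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating venous hemodynamics and vasoactive dose-response at the bedside}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venotone)
```

## The estimation chain

Guyton's circulation model places the control of steady-state cardiac output
on the venous side: venous return is driven by the gradient between mean
circulatory filling pressure (MCFP) and right atrial pressure, divided by a
venous resistance (Rv). `venotone` estimates both continuously from
routinely monitored signals, then asks how vasoactive infusions move them.

Per patient and time point the chain is:

1. **VO2** (mL O2/min/m², treated as indexed): the age/weight estimation
   equation `242.1 + 9.7 ln(age) − 34 ln(weight) − 9.6·SV − 11.2·CI`, with
   single-ventricle and critical-illness 0/1 flags. Natural logarithms; age
   in years, weight in kg.
2. **Cardiac index** by the Fick principle,
   `CI = VO2 / (k · Hb · (SaO2 − SvO2) · 10)`, with renal NIRS as the venous
   saturation surrogate. `k = 1.36` mL O2 per g Hb; the factor 10 converts
   hemoglobin from g/dL to g/L; dissolved oxygen is omitted. Saturations are
   handled internally as fractions (percent is divided by 100 at the
   interface; the extraction ratios are scale-invariant, Fick is not).
3. **CO = CI × BSA** (Mosteller, `sqrt(height·weight/3600)` — the BSA
   formula is configurable in the profile but Mosteller is the default
   because it behaves well across the pediatric size range).
4. **SVRi** `= (MAP − CVP) × 80 / CI`.
5. **MCFP** `= 0.96·CVP + 0.04·MAP + 0.2·CO`.
6. **Rv** `= (MCFP − CVP) / VR`.
7. **Oxygen extraction** `= (SaO2 − NIRS)/SaO2`, cerebral and renal.

### Conventions the formulas leave open

Several unit conventions are not pinned down by the formulas themselves; the
package fixes them as follows, each behind a documented toggle:

- *Venous return in the Rv denominator.* At steady state venous return
  equals cardiac output, so `VR = CO` (absolute, L/min) is the default;
  `vr_flow = "ci"` switches to indexed flow. With the default, Rv carries
  units mmHg per L/min.
- *Indexed vs absolute VO2.* The estimation equation is treated as indexed,
  so the Fick step yields CI directly; `vo2_indexed = FALSE` reinterprets it
  as absolute (Fick then yields CO and CI is derived by dividing by BSA).
- *CO in the MCFP combination* is absolute L/min. The 0.2 coefficient mixes
  mmHg and L/min; no anthropometric rescaling is applied because the
  combination is used as a calibrated bedside estimator, not a mechanistic
  identity.
- *Hemoglobin* is required by Fick but rarely charted continuously. Profiles
  carry one value per patient (synthetic cohorts draw uniformly from
  10–15 g/dL; real-data runs default to 13 g/dL when the manifest is
  silent). CI scales as 1/Hb, so this is the largest single scale
  uncertainty in the derived flows — the direction-of-effect analysis is
  unaffected because Hb is constant within patient.

Undefined intermediates are flags, not errors: rows where renal NIRS meets
or exceeds SaO2 (a physically possible artifact of the surrogate) get `NA`
in CI and in everything downstream of it, and are dropped — with a count —
when the modelling table is assembled. Nothing is imputed at this stage.

## The venous-return diagram

`guyton_diagram()` draws the affine venous-return line
`VR(RAP) = (MCFP − RAP)/Rv` (zero crossing exactly at RAP = MCFP) against a
saturating cardiac function curve
`flow(RAP) = Fmax·(1 − exp(−(RAP − RAP0)/τ))`, clipped at zero. Any monotone
saturating family would do for the operating-point machinery; this
three-parameter form was chosen because it is the simplest one with a
plateau and an adjustable foot. The operating point solves
`VR(RAP) = flow(RAP)` by bisection to 1e-9 mmHg; tests check it against a
dense-grid argmin oracle at 1e-6 mmHg. When the curves do not cross on the
grid (e.g. a cardiac curve everywhere above the line) the diagram reports an
explicit no-solution state rather than an extrapolated point.

## The synthetic cohort generator

No raw cohort accompanies the estimation chain, so the generator is the
package's test bed: it emulates a post-transplant ICU cohort with **known,
injected** drug effects, and every downstream claim is assessed as recovery
of those injections.

Structure, per patient (one RNG stream per patient, derived from the master
seed by a fixed offset, so patient k is bit-reproducible regardless of
cohort size):

- **Demographics**: age from four strata (under 1 y, 1–5, 6–10, over 10 y
  with weights 0.22/0.24/0.11/0.43, mirroring a transplant cohort's age
  mix), weight and height from simple growth relations with log-normal
  scatter, BSA by Mosteller, hemoglobin uniform 10–15 g/dL,
  single-ventricle flag Bernoulli(0.3), critical-illness flag 1 (these are
  ICU patients).
- **Baselines** drawn uniformly per patient from age-stratified plausible
  ranges (e.g. infant HR around 130, adolescent 90; MAP 55–75; CVP 6–12;
  SaO2 96–100; NIRS 55–80).
- **Dose schedules**: piecewise-constant, Poisson(6) change-points per 48 h,
  each segment zero with probability 0.3 or uniform over the drug's clinical
  range (epinephrine/norepinephrine 0–0.1 mcg/kg/min, milrinone 0–1,
  nitroprusside and nicardipine 0–3 mcg/kg/min, vasopressin
  0–1.2 milliunits/kg/min, calcium chloride 0–20 mg/kg/hr). Phenylephrine
  keeps a degenerate 0–0 range: structurally present, never dosed.
- **Effects**: each signal's mean is
  `baseline + trend·t + Σ_drugs delta·sat(dose)`, with
  `sat(d) = d/(d + k)`, `k` at the drug's mid-range. The transform is
  monotone with `sat(0) = 0`, so injected effects are monotone in dose by
  construction — the optional biphasic arterial behavior seen clinically at
  low catecholamine doses is deliberately not in the default model, which
  targets direction recovery. Effects are instantaneous functions of the
  current dose; pharmacokinetics are out of scope.
- **Noise**: per-signal AR(1), `phi = 0.9` per sample step, innovation SDs
  of 0.4–2 signal units (stationary SD ≈ 2.3× innovation). Because `phi` is
  defined per step, coarser sampling implies faster decorrelation in wall
  time; the acceptance-scale experiments sample at 0.1 Hz.
- **Missingness**: MCAR per cell at rate 0.05 by default (the time column is
  never absent). Real monitoring gaps are usually structured (probe
  changes, transport); MCAR is an assumption, and passing recovery tests
  under it says nothing about informative missingness.
- **Clipping** to physiologic bounds (saturations ≤ 100, CVP ≥ 0, ...).

### What the injected direction matrix can and cannot encode

The drug effect magnitudes were designed so the *derived* outcomes respond
with the qualitative pharmacology of each agent: epinephrine,
norepinephrine and vasopressin venoconstrict (CVP and MCFP rise, Rv rises),
milrinone and nitroprusside venodilate and arteriodilate, nicardipine is
arterial-selective, calcium chloride mainly augments regional oxygen
delivery, phenylephrine is never dosed and hence neutral.

One structural constraint deserves emphasis. Under the derivation formulas,
within a patient,

```
Rv = (MCFP − CVP)/CO = 0.04·(MAP − CVP)/CO + 0.2 = SVRi/(2000·BSA) + 0.2,
```

i.e. **Rv is an affine increasing function of SVRi**. No raw-signal effect
specification can therefore make a drug raise Rv while lowering SVRi. Where
the qualitative clinical expectation conflicts with this coupling (an
agent, like epinephrine, described as venoconstricting while
arteriodilating), the generator encodes the venous side faithfully and lets
the arterial column follow the coupling. `reference_directions()` exports
exactly what the defaults encode; the recovery experiments score against it.

## The modelling stage

One random forest per outcome (`ranger` backend): 100 trees, minimum leaf
size 2, bootstrap sampling, all 12 features considered at every split (the
regression default of the reference toolchain), single-threaded for
determinism, row-level random 80:20 split. Row-level splitting of
autocorrelated series is optimistic — adjacent near-duplicate rows land on
both sides — so held-out R² here measures interpolation, not
generalization to new patients; `group_by_patient = TRUE` offers the
conservative alternative and is the right choice when R² itself is the
quantity of interest.

- **Importance**: impurity-based (the default of the reference toolchain),
  normalized to sum to one, ties broken alphabetically.
- **Partial dependence**: 25 evenly spaced dose values between the 1st and
  99th percentile of the observed (zero-inclusive) dose — percentile
  trimming avoids extrapolated tails — averaged over a deterministic
  subsample of at most 1000 training rows, computed in a single stacked
  prediction call. A zero-variance dose column (phenylephrine) collapses to
  a single-point flat curve.
- **Direction of effect**: the PD value at the top of the grid minus the
  bottom, with a neutral deadband of `0.05` outcome standard deviations.
  The deadband exists because a direction matrix with blank cells implies
  one; 0.05 SD was fixed a priori as "smaller than any effect worth
  reporting" and is configurable (`eps`).

## Problem sizes and what the tests show

The test suite exercises the full chain at these scales, chosen to make
each property measurable in minutes on one core:

- Formula oracle equivalence: 1000 random rows against independent scalar
  recomputation at 1e-12 relative tolerance.
- Direction recovery: 10 patients × 48 h at 0.1 Hz (172,800 rows), default
  noise and missingness, five seeds; recovery means ≥ 7 of 8 drug calls per
  outcome matching `reference_directions()` for MCFP and Rv, in ≥ 4 of 5
  seeds. The persistent marginal calls are instructive: nicardipine's MCFP
  effect enters only through the 0.04·MAP term (≈ −0.3 mmHg at saturation
  against a cohort SD of ≈ 2.5 mmHg) and calcium chloride's Rv effect only
  through the Fick denominator, so both sit near the deadband — exactly the
  regime where a blank cell in a reported direction matrix would originate.
- No-signal control (targets independent of all features, n = 10,000):
  held-out R² ≤ 0.1. The stronger property one might want here — every
  direction call neutral — does **not** hold at this scale and is asserted
  (and fails, deliberately left failing) in the suite: a 100-tree,
  min-leaf-2 forest memorizes noise, and the resulting partial-dependence
  endpoint differences have a standard deviation of roughly 0.1 outcome
  SDs, twice the 0.05-SD deadband. The same magnitudes arise from the
  reference toolchain's forest with identical hyperparameters, so this is a
  property of the estimator configuration, not of this implementation.
  Practically it means isolated direction calls near the deadband carry a
  false-positive risk; calls supported by a visible monotone PD trend (as
  in the recovery experiments) do not.
- Learnable-signal floor (noise-free deterministic targets, n = 10,000):
  held-out R² ≥ 0.9 for all six outcomes.

Passing these establishes internal validity — the pipeline recovers what
was injected under its own assumptions (monotone instantaneous effects,
AR(1) noise, MCAR gaps). It does not establish that real post-transplant
data satisfy those assumptions, and cohort-level performance numbers from
real data are not reproduced here.

## Known limitations

- The two-compartment (splanchnic/peripheral) venous architecture is not
  modelled; MCFP and Rv are lumped quantities.
- The Rv–SVRi affine coupling above means the derived arterial and venous
  resistance columns are not independent evidence within a patient.
- Imputation is per-patient median over the whole window — adequate for
  MCAR gaps, biased for long structured gaps; signals entirely absent for a
  patient are flagged and that patient's affected outcomes excluded rather
  than guessed.
- Direction calls are associational. Doses respond to the patient's state
  (titration feedback); nothing here breaks that loop.
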