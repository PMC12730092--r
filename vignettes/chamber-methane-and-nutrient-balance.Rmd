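---
title: "Methods: chamber methane flux and nutrient balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chamber methane flux and nutrient balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chamberflux)
```

## What the package computes

`chamberflux` implements the measurement chain of an open-circuit
respiration chamber facility for lactating dairy cows, plus the nutrient
bookkeeping that usually accompanies it:

1. **Chamber flux**: a shared gas analyzer cycles over chamber outlets and
   the fresh-air inlet; the raw multiplexed ppm stream is turned into
   per-chamber methane emission series and daily totals.
2. **Calibration**: two-point (zero/span) analyzer corrections with linear
   drift back-correction across a measurement period, and chamber recovery
   rates from CO2 injection tests.
3. **Nutrient balance**: per-cow milk standardizations (FCM/ECM),
   marker-based digestibility, creatinine-based urine volume, nitrogen
   partition and NUE, the GE-to-ME energy cascade, and methane yield and
   intensity metrics.
4. **Simulation**: a synthetic-data generator for both the chamber sensor
   streams and the animal records, with known ground truth, so the entire
   chain can be verified end to end without access to a physical facility.

## The chamber model

The chamber is modeled as a single well-mixed compartment (a CSTR). With
emission rate $E(t)$ (L STP/min), dry-STP ventilation $Q$ (L/min), dry-STP
gas volume $V$ (L) and background concentration $C_{bg}$, the
above-background concentration $C$ (as a mixing ratio) obeys

$$\frac{dC}{dt} = \frac{E(t) - Q\,(C - C_{bg})}{V}.$$

The well-mixed assumption is reasonable here: at 140 m³/h through 23 m³ the
air turns over about six times per hour, and chambers of this type carry an
internal mixing fan. The integration uses the exact exponential update of
the linear ODE over 1-s steps with piecewise-constant coefficients; with a
time constant of roughly 10 min, a 1-s step makes discretization error
negligible (the mass-conservation test bounds it at a relative $10^{-6}$).
The state is initialized at quasi-steady state because chambers are
ventilated and conditioned for many hours before an animal enters; a
cold-start transient is not part of any measurement day.

Door openings are modeled as a 20-fold surge of the exchange rate, driving
the concentration toward background within a couple of minutes. No
published exchange rate exists for an open chamber door; the factor only
needs to be large enough that in-event data are obviously invalid, and those
data are discarded and refilled anyway.

The **true recovery rate** (the fraction of an injected tracer the system
reports) is applied as a multiplicative factor on the chamber-minus-
background difference. The flux pipeline divides by the user-supplied
recovery, so simulation and analysis are exactly inverse when given the
same value.

The analyzer model adds Gaussian noise on ppm (default SD 0.5 ppm) and a
multiplicative gain drifting linearly in time (default 0.5%/day). Neither
magnitude is a published instrument property; both are engineering
defaults, exposed in `chamber_config()`.

## The flux equation chain

Each retained reading passes through, in order: partial water pressure from
a sixth-order polynomial in chamber temperature scaled by RH/100 (validated
against the Buck formula to within 0.04% over 0–40 °C); the moisture volume
mixing ratio `VMR = 100 · PWP / pressure`; the dry ventilation rate
`DVR = WetVR · (100 − VMR)/100`; the dry-STP rate
`DSTPVR = DVR · (P/1013.25) · (273.15/(T + 273.15))`; and finally

$$\mathrm{CH_4\ (L/min)} = \frac{\mathrm{DSTPVR} \cdot \Delta\mathrm{ppm} / 10^6}{\mathrm{recovery}}.$$

Daily totals sum each slot value weighted by the full cycle length (6 min by
default), and litres convert to grams with 1 g CH₄ = 1.3962 L.

### Demultiplexing and the purge fraction

The default sampling cycle is 6 min: 2 min per source in the order RC1,
RC2, fresh air. The leading half of each 2-min slot is discarded because
the sample line still carries the previous source (the purge time is an
operational choice at the instrument; here it is the `purge_fraction`
parameter, default 0.5). The remaining readings in a slot are averaged into
one value stamped at the slot start; timestamps are interval-start labels
over half-open intervals. The fresh-air reference, observed once per cycle,
is linearly interpolated onto each chamber's retained timestamps before
subtraction.

### Gap filling and door padding

Intervals flagged in the event log (door openings, failures, manual
exclusions) are overwritten by the pooled mean of the `k = 4` nearest valid
points before and `k = 4` after the gap (8 values). The source rule ("four
data points before and after") is ambiguous between 4 total and 4 per side;
the package implements 4 per side, configurable via `fill_k`. At a series
edge the available side is used, with a warning; a gap with no valid
neighbour on either side is an error.

Door events are padded by `pad_after_min` (default 30 min, about three
chamber time constants) because after the doors close the concentration
needs that long to return to within a fraction of a percent of steady
state; without the padding, each door event biases the daily total low by
roughly 0.7%. Days are 24-h windows aligned to the first retained point
(chamber-entry alignment) by default; `day_start` overrides this. A day
whose measured (unfilled) coverage falls below `coverage_min` (default 0.9)
is flagged invalid.

## Calibration and recovery

A two-point fit maps the ultrapure-N₂ reading to zero and the certified
span reading to its certificate value. Drift over a period is assumed
linear in time: the affine correction applied at each timestamp
interpolates between the period-start and period-end fits. The correction
is applied to concentrations, not to computed emissions — the source
material does not say which the original facility used, so this is an
explicit package choice. For a 1%/period drift the residual error of the
linear interpolation is below 0.01%.

Recovery tests inject pure CO₂ at a known rate (2 L/min in the emulated
facility) until a plateau. The plateau is detected as the longest suffix
over which a trailing 15-min rolling mean stays within 1% of its final
level, and the plateau starts only after the first fully stable window so
no rise points dilute the mean. Both window and tolerance are exposed; the
detection rule itself is a package choice, since the source protocol says
only "during the plateau phase". The pipeline accepts per-chamber recovery
as a scalar or as the mean of repeated tests.

## Nutrient balance

All balance quantities are closed-form per-cow arithmetic:

* `FCM = 0.4·milk + 15·fat`; `ECM = 12.95·fat + 7.2·protein + 0.327·milk`.
* Fecal output = marker intake / fecal marker concentration, assuming full
  marker recovery (no recovery factor is applied). The default marker is
  indigestible NDF. NDF and GE are also selectable: note that using GE is
  circular by construction — the estimated fecal energy then reconstructs
  GEI identically and DE collapses to zero — so that option is only useful
  for the DM-digestibility side of the calculation.
* Apparent digestibility = `(intake − fecal)/intake × 100`, applied with
  the matching intake and fecal quantity for DM, NDF and GE.
* Urine volume = `29 mg/kg BW / creatinine concentration`.
* Nitrogen: total excretion = fecal + urinary; retained = intake − total
  excretion; productive = retained + milk; NUE = milk N / intake N. The
  identities hold exactly by construction and are enforced by tests.
* Energy: `DE = GEI − E_feces`; `E_methane = 0.0556 MJ/g`;
  `E_urine = 0.04·GEI`; `E_milk = 39.32·fat + 23.84·protein +
  16.73·lactose` (MJ/kg). Milk-energy coefficients of this magnitude are
  the standard ones; smaller printed variants circulating in parts of the
  literature are dimensionally impossible for milk components (they would
  give ~0.1 MJ/d of milk energy for a 40 kg/d cow) and are therefore not
  used. The coefficients are configurable.
* `ME = DE − E_methane − E_urine` by default. An alternative formulation
  defines ME from the absorbed side (milk + body tissue energy) plus
  fermentation energy minus urinary energy; it is available as
  `me_mode = "absorbed"` with an explicit body-energy term, but it is not
  the default because it presumes a measured body-energy change and does
  not reduce to the conventional cascade.
* `EB = ME − 0.08·BW^0.75 − E_milk`, with the maintenance coefficient kept
  exactly as specified for this protocol even though 0.08·BW^0.75 (~9.5
  MJ/d at 586 kg) is far below conventional maintenance requirements
  (~0.5 MJ/kg^0.75); the coefficient is exposed so users can substitute a
  conventional value.

Treatment summaries are means ± SEM of per-cow values, never functions of
means; inferential statistics are deliberately out of scope.

## The synthetic herd

`simulate_animal_days()` draws cow-level traits from distributions centred
on a high-producing confined Holstein herd: 26–28 kg DM/d intake of a
20.4% CP, 16.42 MJ/kg total mixed ration, ~40 kg/d milk at 3.4% fat and
3.3% protein, DM digestibility ~68%, methane yield ~16.8 g/kg DMI, body
weight ~586 kg. Urinary creatinine is centred at 700 mg/L, which with the
29 mg/kg excretion assumption gives realistic 20–30 L/d urine volumes.
Fecal marker concentrations, fecal N and urine N are derived so the true
records are internally consistent; the ground-truth balance table is then
*defined* as the balance chain applied to the noise-free records, which is
what makes the noise-free round trip exact to the bit. Observed records add
multiplicative Gaussian measurement noise (default 2% relative SD, a
typical assay-level error) to every assayed quantity; negative draws are
resampled and logged.

What the generator does **not** emulate: feeding-behaviour-driven intake
patterns, lactation-stage trends, marker recovery below 100%, correlated
errors between assays, or treatment effects on any trait (both diet labels
are drawn from the same distributions). Passing tests therefore demonstrate
that the computational chain is correct and exactly invertible — not that
the package can detect dietary treatment differences in real data.

## Problem sizes and numerical choices

The verification suite runs one-day chamber simulations at a 1-s
integration step with 30-s analyzer records (2,880 records/day), 120-min
recovery tests, herds of 3–6 cows over 2–4 days, and identity checks over
1,000 random input vectors. These sizes make every oracle exact or
near-exact while keeping the whole suite fast. Tolerances asserted in the
tests trace to derivable bounds: 0.5% for the end-to-end flux oracle
(discretization only), 0.1% for the steady-state closed form, 0.2% for
noise-free recovery estimation, 0.05% for drift back-correction, and exact
(bit-level or last-ulp) for the algebraic identities.

## Known limitations

* Heat production from CO₂/O₂ exchange is not computed; the O₂ and CO₂
  channels are carried through I/O only.
* Drift correction assumes linearity between calibrations; a step change
  (e.g. after maintenance) should be handled by splitting the period.
* The creatinine method inherits its assumed constant excretion rate; the
  29 mg/kg value is built in as a default, not re-estimated.
* Day-boundary alignment for daily totals is configurable but defaults to
  the first retained point; midnight alignment must be requested
  explicitly when comparing across chambers started at different times.
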