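---
title: "Methods: checkerboard combination-screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: checkerboard combination-screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyscreen)
```

## The analysis problem

An anchored combination screen tests one anchor drug against a library
of partner compounds, each pair laid out as a checkerboard: every
combination of the two drugs' serial dilutions, plus each drug alone,
plus vehicle. The discovery design used here is a 6×6 block (five
doses in a constant 1:5 dilution from 20 µM, plus vehicle: 25
combination wells, 10 single-agent wells, 1 vehicle well), with a
10×10 block (nine doses, 1:3 dilution, 81 combination wells) for
validation. Raw readout is optical density from a viability assay;
wells with a cytotoxic positive control and vehicle wells accompany
each plate.

This vignette describes the models the package implements, the
defaults and why they were chosen, what the synthetic-data generator
does and does not emulate, and the numerical edge cases.

## Plate QC and normalization

Z′ summarizes control separation:
$Z' = 1 - 3(\sigma_{pos} + \sigma_{neg}) / |\mu_{pos} - \mu_{neg}|$.
It is bounded above by 1, reached only with zero-variance, separated
controls, and is invariant to affine changes of the OD scale, so gain
settings of the reader do not matter. Defaults require Z′ > 0.6 for
96-well primary plates and > 0.5 for 384-well secondary plates (both
thresholds are config keys, `qc$z_min_primary` / `qc$z_min_secondary`);
failing plates are excluded from compound averages and flagged —
imputation is deliberately refused because filling missing or bad
wells would fabricate synergy evidence.

Viability is percent-of-vehicle with optional blank subtraction,
$V = 100\,(OD - \overline{OD}_{blank}) / (\overline{OD}_{veh} -
\overline{OD}_{blank})$, floored at 0. Values above 100 (growth
stimulation) are **retained**: clipping them would truncate positive
excesses and bias both synergy scores toward synergy. The vehicle cell
of each grid is set to 100 exactly, making normalization idempotent. A
block missing any sample well is rejected (`incomplete_block_error`)
rather than imputed.

## Synergy scores

Both scores operate on the viability scale in percentage points, with
negative values meaning synergy:

* **ExcessHSA** compares each combination well to the *highest single
  agent*, i.e. the more effective (lower-viability) of the two
  single-agent wells at the same marginal doses.
* **Bliss excess** compares it to the product of single-agent survival
  fractions, the Bliss-independence null.

A matrix is scored by the **sum** over combination wells, not the
mean; this follows the screen convention and makes 10×10 sums
numerically larger than 6×6 sums for the same per-well effect (the
classification thresholds are configurable for that reason, and kept
at ±20 for both designs by default). Boundary values land in the
additive class (closed interval). Single-agent wells do not contribute
to the sums; that choice is recorded in the output metadata.

Ranking averages a compound's matrix sums over the cell lines whose
plates passed QC; ties break lexicographically by compound name so
regression tests are deterministic. Class summaries are unweighted
means of compound averages per mechanism-of-action class.

Note that the two references answer different questions: an active
Bliss-null pair (neither synergy nor antagonism under independence)
still shows a negative ExcessHSA sum, because independent killing
beats either agent alone. The two scores therefore only coincide near
zero when at most one agent is active.

## Median-effect and combination-index analysis

Single agents are fitted with the median-effect model
$f_a/f_u = (D/D_m)^m$ by unweighted OLS on the linearized plot
$\log_{10}(f_a/f_u)$ vs $\log_{10} D$ — the classical procedure, chosen
over weighted variants for reproducibility. $D_m$ is recovered as
$10^{-b/m}$ and the predicted $f_a(D_m)$ is exactly 0.5 by
construction. Wells with $f_a$ outside $(\varepsilon, 1-\varepsilon)$,
$\varepsilon = 0.005$, are excluded from fits and Fa–CI curves and
counted: on the logit scale those observations have unbounded leverage
and dose-response software conventionally drops them. If all usable
points fall on one side of $f_a = 0.5$ the fit is returned with an
`extrapolated` flag rather than refused.

The combination index uses the two-term, mutually-exclusive form
$CI = d_1/D_{x1} + d_2/D_{x2}$ by default (the common software
default); the three-term mutually-nonexclusive form is available via
`form = "mutually_nonexclusive"`. Because the screen is a
checkerboard, not a fixed-ratio dilution series, CI is computed **per
combination well** rather than on constant-ratio diagonals; that
choice is recorded in the output. CI is symmetric in drug relabeling
and strictly decreasing in the observed $f_a$ at fixed doses when
$m > 0$.

IC50s come from a four-parameter logistic fitted with
Levenberg–Marquardt on a log-IC50 parameterization (which keeps the
IC50 positive without constraints); the reported IC50 is the relative
(inflection) IC50, matching common curve-fitting practice. A fitted
non-positive Hill slope — viability rising with dose — is surfaced as
a warning, not silently accepted.

## In vivo scoring

TGI is computed on arm means:
$100\,[1 - (TV_f^{t} - TV_i^{t})/(TV_f^{c} - TV_i^{c})]$, where start
and end are the first and last measurement days *shared* by the two
arms (a configurable choice; when arms end on different days the last
common day avoids comparing different treatment durations). Animals
missing at the endpoint are excluded from the final mean and counted,
rather than carried forward. A control arm with zero net growth makes
the statistic undefined and is an error. Thresholds are strict:
responder above 60%, regression above 100%. The statistic is invariant
under any common volume rescaling, so the unit (mm³ vs cm³) is
irrelevant. No caliper-to-volume conversion is applied; the pipeline
consumes volumes directly.

IRS multiplies staining intensity (0–3) by the positive-percentage
category with bins 0% → 0, 1–10 → 1, 11–50 → 2, 51–80 → 3, 81–100 → 4.
Percentages in (0, 1) fall in category 1 — any positivity scores at
least 1; the bins are integer conventions and fractional input is an
edge case we define rather than reject.

## The synthetic-data generator

`simulate_matrix` builds one plate from parametric truth: single-agent
fractions affected follow the median-effect equation; combination
inhibition is the Bliss expectation plus an interaction offset δ
(applied on the inhibition-fraction scale *before* conversion to
viability, so Bliss truth is exact by construction), clipped to [0, 1]
with the clipped fraction recorded — a warning fires above 5% so tests
can steer clear of saturated regimes. Measured OD is
`blank + (vehicle − blank) · V/100` times multiplicative lognormal
noise, σ = 0.03 by default (a typical plate-reader CV; multiplicative
noise keeps ODs positive and is scale-free). Each plate carries 6
vehicle, 6 positive-control and 4 blank wells beyond the block — the
counts are a design choice of the generator, sized so that control SD
estimates are stable. A fixed seed yields byte-identical output.

`simulate_library` replicates the discovery-screen shape: 162 partner
compounds × 4 cell lines of 6×6 blocks (648 plates, 16,200 combination
dose pairs). The default class table injects positive offsets for
targeted-agent-like classes (125 compounds) and inert-partner
additive/antagonistic chemotherapy-like classes (37 compounds), so the
true synergistic fraction is 125/162 = 77.16%. Per-compound offsets
are jittered ±20% (seeded) to spread ranks without crossing class
boundaries; anchor potency varies by cell line (Dm 0.8–2 µM). The
additive and antagonistic classes use nearly inert partners
deliberately: with an inert partner both the HSA and Bliss references
collapse to the active agent alone, so the injected offset alone
controls the score — this is what makes the truth labels exact.

`simulate_growth` uses exponential growth, control rate k = 0.1/day
from 100 mm³, with a treated rate k(1 − e) (e = 1 is stasis, e > 1
regression), 7 animals per arm measured twice weekly over 21 days,
and per-measurement lognormal noise; true TGI has the closed form
$100[1 - (e^{k(1-e)T} - 1)/(e^{kT} - 1)]$.

**What the generator does not emulate:** edge effects and spatial
plate artifacts, partner-specific off-target toxicity, non-monotone
dose-response (e.g. hormesis), pharmacokinetics, resistant subclones,
and dropout correlated with tumor burden. Passing tests therefore
demonstrate correctness of the *computations* under a clean generative
model, not robustness to every artifact of real screens.

## Numerical choices and edge cases

* fa clipping ε = 0.005 for fits and CI curves; excluded counts
  reported.
* Synergy classification: closed additive interval at the ±20
  boundaries.
* TGI/responder thresholds: strict inequalities.
* Median-effect fit refuses < 2 usable points; zero slope is an error.
* Z′ with equal control means is an error (undefined separation), as
  is fewer than 2 wells per control.
* Ranking ties: lexicographic by compound name.
* 4PL fit failure (LM non-convergence) is an error carrying the
  optimizer message; it is not silently retried.

## Problem sizes used in validation

The test suite simulates the full 648-plate screen for the design
counts and the synergistic fraction, and uses reduced problems
elsewhere: 200-seed repetitions for parameter-recovery checks
(median-effect Dm at 1% noise, 4PL IC50 at 3% noise, TGI at σ = 0.1),
30–40 plates for the noisy Bliss-null mean bound, and 6–9-compound
libraries for end-to-end ranking tests. These sizes give stable
medians and standard errors while keeping the default test run fast.

## Known limitations

* ExcessHSA classification with active Bliss-null pairs is inherently
  liberal (see above); the two metrics should be read together.
* CI values assume the median-effect model holds for both agents; poor
  linearized fits (low r) propagate into CI without an explicit
  uncertainty estimate.
* The ±20 thresholds are sum-scale-dependent; comparing 6×6 and 10×10
  sums requires either the configurable thresholds or per-well
  normalization by the caller.
* TGI is a two-timepoint statistic on arm means; it uses no
  longitudinal modeling and carries no significance test.
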