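---
title: "Methods: phototoxicity screening from microplate photokinetics and dose-response data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phototoxicity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoscreen)
```

# The screening problem

Photodynamic therapy (PDT) and antimicrobial photodynamic inhibition
(aPDI) need new photosensitizers (PS): chromophores that, once excited
by light, transfer their energy to molecular oxygen (Type II
photochemistry, producing singlet oxygen, ^1^O~2~) or electrons/H atoms
(Type I, producing radicals). Natural-product extracts — fungal pigments
in particular — are a promising but under-screened source. This package
implements a three-assay screening workflow at 96-well-plate scale:

1. a **chemical assay** for ^1^O~2~ production using the probe
   9,10-dimethylanthracene (DMA),
2. an **in vitro photo-cytotoxicity assay** (SRB endpoint) yielding
   EC~50~ values in matched dark and irradiated arms, and
3. an **interpretation rubric** that combines the evidence into five
   cases plus "inactive", and ranks extracts by photo-therapeutic
   potential.

The third experimental branch of such screens, HPLC-DAD-MS pigment
profiling, is instrumental compound identification and is represented
only as free-text metadata; it is out of computational scope.

# The DMA assay model

DMA absorbs at 377 nm. ^1^O~2~ adds across the anthracene core ([4+2])
and destroys the conjugated system, so the absorbance drop
$\Delta OD_{377}$ accumulated over a delivered light dose measures
^1^O~2~ production. Raw drops are not comparable across samples of
different colour: a weakly absorbing extract receives fewer useful
photons. The score therefore corrects by the probability of absorption
at the irradiation wavelength (Beer–Lambert),

$$f_{abs}(A) = 1 - 10^{-A},$$

and is expressed relative to a reference PS measured on the same plate
at the same dose:

$$\text{yield}\% \;=\; 100 \cdot
  \frac{\Delta OD_{377}^{(s)}}{\Delta OD_{377}^{(ref)}} \cdot
  \frac{f_{abs}(A_{ref})}{f_{abs}(A_s)}.$$

This is the standard relative-comparison method; the absorption
correction is applied to the sample and the reference alike, so the
reference anchors at exactly 100% by construction
(`relative_yield(x, a, x, a)` is identically 100). For blue-absorbing
yellow/orange extracts the natural choice of reference is berberine
(50 µg/mL ≙ 149 µM at molar mass 336.36 g/mol).

Two controls gate every call:

* **ascorbate quench** — co-incubation with L-ascorbic acid (a ^1^O~2~
  scavenger) must suppress the bleaching. We require the with/without
  drop ratio to be at most `quench_ratio_max` (default **0.5**). The
  screen's logic requires suppression but states no cutoff; 0.5 is a
  conservative default and configurable.
* **side reaction** — an extract-plus-ascorbate arm (no DMA) must stay
  flat; a drift above `side_reaction_od` (default **0.02 OD**, about
  four times the read noise) flags a direct extract/probe or
  extract/quencher reaction.

The solvent control (5% DMSO in ethanol, i.e. 10 µL DMSO in a 200 µL
well) measures direct DMA photobleaching; its drop is subtracted from
every sample's and the reference's drop before scoring. A sample whose
corrected drop lies within the noise floor (`noise_floor_od`, default
0.01 OD) scores exactly 0%, so an extract indistinguishable from the
solvent control is never called active. The positivity threshold is
`positivity_pct` = **5%** of the reference: extracts around 6% have been
treated as minimally active in practice, so 5% keeps such marginal
signals while staying above plate noise; it is configurable.

$\Delta OD_{377}$ is computed from the endpoint pair (dose 0 vs the
final dose) by default, matching how such screens report "production
after 20 min"; a least-squares `slope` mode (−slope × final dose) is
available for noisy trajectories. `bleach_rate()` additionally fits the
pseudo-first-order decay rate on log OD, which recovers efficiency
ratios exactly under exponential kinetics and serves as a diagnostic.

Standard errors come from triplicate wells and propagate to the yield
by the first-order delta method on the ratio/product expression,
including the absorbance terms through
$\partial \ln f_{abs}/\partial A = \ln 10 \cdot 10^{-A}/(1-10^{-A})$.

# Dosimetry

The LED panel delivers a constant irradiance, so the light dose
(fluence) is irradiance × time: at 20.6 mW cm^−2^ a 5-min step is
6.18 ≈ 6.2 J cm^−2^ and four steps are 24.7 J cm^−2^ (3 significant
figures; doses are kept unrounded internally and rounded only for
display). Irradiance itself is measured by ferrioxalate actinometry:
the moles of Fe^2+^ formed give the photon flux
$n_{Fe^{2+}}/(\Phi\,t)$, converted to power through the photon energy
$N_A h c/\lambda$ and the illuminated area. The ferrioxalate quantum
yield is a configuration parameter (default 0.9 in the blue) because
literature values are wavelength-dependent; it must never be treated
as a constant. Field homogeneity is assessed over the inner 60 wells
(rows B–G × columns 2–11, the only contiguous 60-well interior of a
96-well plate) via the coefficient of variation, passing at CV ≤ 10%
by default — a conventional plate-uniformity bound, configurable
because such screens report homogeneity qualitatively.

# Photo-cytotoxicity

SRB (sulforhodamine B) viability is normalized linearly between
cell-free blanks (0%) and untreated controls (100%); SRB is preferred
over MTT-type dyes, whose redox chemistry produces false positives
with photosensitizers. Each arm is fitted with the four-parameter
logistic

$$v(c) = bottom + \frac{top - bottom}{1 + (c/EC_{50})^{h}},$$

by bounded Levenberg–Marquardt least squares on log~10~ concentration
(`minpack.lm::nlsLM`), with a multistart from three EC~50~ guesses at
the minimum, midpoint and maximum of the tested log-range. Bounds:
top ∈ [80, 120], bottom ∈ [−10, 40], Hill slope unconstrained in sign.
The best-RSS converged start wins; non-convergence of all starts is
reported as `fit_ok = FALSE`, never as a silent number.

**Censoring.** A sample is reported as "EC~50~ > max tested"
(inactive) when the fitted EC~50~ exceeds the highest tested
concentration or the fitted viability change across the tested range
is below `min_effect` (default 25 percentage points). The flatness
test deliberately uses the fitted effect across the observed range
rather than the nominal `top − bottom` span: a near-zero Hill slope
can carry a large nominal span while predicting essentially no effect
anywhere, and such fits must censor, not report a spurious tiny EC~50~.

**Confidence intervals.** The 95% EC~50~ interval comes from a
case-resampling bootstrap: replicates are resampled with replacement
within each concentration and the curve is refit starting from the
point estimate (default 1000 resamples, seeded). The interval is a
t-type interval on log~10~ EC~50~,
$\log EC_{50} \pm t_{N-m}\, \widehat{SE}_{boot}\, \sqrt{N/(N-m)}$,
with $N$ data points over $m$ concentrations. The inflation factor is
not a tuning knob: resampling $n$-of-$n$ within a concentration
underestimates the within-group variance by $(n-1)/n$, and at
triplicate scale a plain percentile interval undercovers badly. With
this construction the seeded 200-simulation check in the test suite
meets the required ≥ 90% coverage at 5% viability noise.

**Activity and selectivity.** An arm is *active* when its uncensored
EC~50~ lies below the activity cap (default **50 µg/mL**, the
conventional "not active below 50 µg/mL" screening bound). The
selectivity index is

$$S.I. = \frac{EC_{50,\,dark}}{EC_{50,\,irradiated}},$$

with censoring propagated as bounds, never as point values: a dark arm
censored at the cap with an active irradiated arm yields the lower
bound $cap/EC_{50,irr}$ reported as "> bound"; an irradiated arm
censored against an active dark arm is never photo-enhanced. The
photo-enhancement call uses S.I. ≥ 2 by default — the screen's rubric
only distinguishes ⊕/⊖, so a factor-2 default separates genuine
enhancement from fit noise while remaining configurable.

# The interpretation rubric

Evidence per extract: DMA ± (quench-confirmed ^1^O~2~ production),
UV ± (evolution of the UV-Vis spectrum under irradiation, judged by
max~λ~ |ΔOD| > 0.05), CT ± (dark-cytotoxic below the cap), PCT ±
(photo-cytotoxic below the cap). The decision table is total over all
combinations:

| DMA | CT | PCT | UV | outcome |
|----|----|----|----|---------|
| + | + | + | any | case 3 — broadly toxic |
| + | − | + | any | case 5 — PDT candidate |
| + | − | − | any | case 4 — aPDI candidate |
| + | + | − | any | inactive (dark-cytotoxic only, noted) |
| − | any | + | any | case 2 — photochemical (oxygen-independent) |
| − | + | − | any | inactive (dark-cytotoxic only, noted) |
| − | − | − | + | case 1 — sun-protective or inert photochemistry |
| − | − | − | − | inactive |

A DMA signal whose ascorbate quench is not confirmed is demoted to
DMA− with a "possible Type I / artifact" note before classification —
false positives must not propagate. The two dark-cytotoxic-only rows
sit outside the five rubric cases and are reported honestly as
inactive-with-rationale rather than forced into a case.

Ranking sorts by case priority — case 5 > case 2 > case 4 > case 3 >
case 1 > inactive, i.e. selective photo-activity first, then
oxygen-independent leads, then membrane-limited ^1^O~2~ producers —
with ties broken by S.I. (descending; a censored lower bound sorts
above an equal point value, since the truth is at least the bound) and
then by DMA yield. The priority vector is an argument: the ordering
reflects screening priorities, not a law.

# The synthetic generator

No raw plate data are deposited for screens of this kind, so the
package ships a generator that produces plates with the statistical
structure the analysis assumes, with known ground truth:

* **Kinetics**: pseudo-first-order DMA decay,
  $OD_{377}(H) = OD_0\, e^{-\kappa H}$ with
  $\kappa = \kappa_0\,\phi_{eff}\,(1 - 10^{-A_{irr}})$ — the bleaching
  rate scales with the absorbed fraction and the effective ^1^O~2~
  efficiency. Screening time courses show monotone quenching without
  settling the kinetic order; endpoint scoring is insensitive to this
  choice at the doses used.
* **Arms**: ascorbate multiplies $\kappa$ by (1 − `quenchable`); the
  solvent control bleaches slowly (2×10^−4^ per J cm^−2^, ~0.004 OD
  over the full dose); the extract+ascorbate arm drifts linearly by
  `side_reaction_drift` over the schedule.
* **Noise**: additive Gaussian on OD, sd 0.005, independent across
  wells and doses — typical plate-reader repeatability.
* **Defaults as study conditions**: blue-LED schedule (468 ± 27.3 nm,
  20.6 mW cm^−2^, four 300-s steps), triplicates, $OD_0 = 0.8$,
  $\kappa_0 = 0.012$ per J cm^−2^ so the reference PS consumes ~10% of
  the DMA over the full dose (mild-bleaching regime); dose-response
  data are triplicates over seven 1:3 dilutions from 50 µg/mL with 5%
  viability noise. These defaults are fixed once; tests and the
  acceptance script run at them.

What the generator does **not** emulate: spectral overlap between
extract and probe, oxygen depletion, photoproduct absorbance at
377 nm, plate-edge effects, pipetting error correlated within
replicates, and non-logistic (e.g. hormetic) dose-response shapes.
Passing tests therefore demonstrate that the estimators recover known
truth under the assay's idealized statistical model — not that any real
extract behaves this way.

One bias is worth stating: with endpoint scoring under exponential
bleaching, the recovered yield ratio is slightly compressed towards 1
(the endpoint drop is concave in the rate), e.g. a 2.05× sensitizer
reads ≈ 1.95× at the default dose. This is a property of the endpoint
estimator itself, shared with any assay scored this way; the recovery
tests therefore assert agreement within 3 standard errors, and
`bleach_rate()` provides the bias-free kinetic alternative.

# Numerical and degenerate-input choices

* Negative blank-corrected ODs are kept (they carry noise information)
  and flagged below −0.01 OD; absorbances are clamped to 0 only within
  a 0.01 noise floor, and error beyond it.
* A quench ratio with no signal to quench (drop ≤ noise floor) is
  defined as 1 (not confirmed), avoiding 0/0.
* A transparent sample ($A_{irr} = 0$) with genuine bleaching is
  physically inconsistent and flagged rather than scored.
* Replicate aggregation with n = 1 reports SE = 0 with a warning.
* EC~50~ fits are equivariant under unit rescaling of concentration
  (the whole fit is a translation on the log axis).
* Bootstrap refits that fail to converge are dropped; fewer than 10
  usable resamples yields an NA interval rather than a fabricated one.

# Problem sizes

The test suite and the acceptance script run at the scale of the assay
itself: single 96-well plates (triplicate arms, five dose points),
dose-response series of 21 points per arm, 1000 bootstrap resamples
for reported intervals, and a 200-simulation × 199-resample run for
the coverage property.

# Repository shape

The package is organised as an analysis workflow: the computation
lives in the package functions (`R/`), and the numbered scripts under
`analysis/` are thin narrative drivers that simulate a screening
panel, score it stage by stage, and write the tables under `results/`.
There is no shell CLI; `run_screen()` plus the scripts and this
vignette are the interface, which suits a screening-analysis artifact
better than a subcommand binary.

# Known limitations

* The relative-yield formula is the standard relative method
  consistent with the stated absorption correction; laboratories using
  a different normalization (e.g. by OD directly rather than by
  absorbed fraction) will obtain different percentages for strongly
  absorbing samples. The choice is prominent in the docs and in every
  report header.
* Units for "extract-alone" absorbance measurements are carried as
  mass concentration; molar readings for undefined mixtures are not
  resolvable and not attempted.
* Censored EC~50~s propagate to S.I. only as bounds; no survival-style
  interval estimation is attempted for the index itself.
* The classifier is deliberately coarse (booleans at a fixed cap); it
  ranks screening priority and is not a potency model.
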