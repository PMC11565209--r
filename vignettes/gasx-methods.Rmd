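---
title: "Models and design choices in gasx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in gasx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasx)
```

# What the package estimates

Screening a genotype panel for photosynthetic performance produces two kinds
of gas-exchange records per plant: a steady-state light-response (A/Q) curve,
and a dynamic trace of net assimilation (A) and stomatal conductance to water
vapour (g~s~) after a step increase in irradiance. Together with stomatal
impressions of the two leaf surfaces, these support a compact set of traits
per plant:

* **QY** — apparent quantum yield, the initial slope of the A/Q curve;
* **A~sat~, g~ssat~** — A and g~s~ at saturating light (2000 µmol m⁻² s⁻¹);
* **τ~ai~, τ~i~** — time constants of A and g~s~ after a 100→1000
  µmol m⁻² s⁻¹ step;
* **W~i~** — intrinsic water use efficiency A/g~s~ at each steady state;
* **SD, anatomical g~smax~** — stomatal density and the diffusion-limited
  maximum conductance implied by stomatal anatomy.

`gasx` fits the underlying models, extracts these traits, and runs the
panel-level statistics (ANOVA, Tukey HSD with compact letters, Pearson
correlations). A synthetic-data generator emulates the measurement protocols
so the whole pipeline can be exercised and verified end to end.

# Steady-state light response

A/Q curves are fitted with the rectangular hyperbola (Michaelis–Menten form),
parameterized so that the quantum yield is a model parameter rather than a
post-hoc slope estimate:

$$A(Q) = \frac{\phi\, Q\, A_{max}}{\phi\, Q + A_{max}} - R_d$$

`phi` is exactly the derivative dA/dQ at Q = 0, `Amax` the asymptotic gross
assimilation, and `Rd` dark respiration, so the fitted curve predicts
A(0) = −R~d~. An alternative estimate of QY as an ordinary linear fit through
the dark record and the three lowest nonzero light levels is exposed as
`qy_linear()`; it systematically underestimates the true initial slope
because it is a secant over a curved region, which is why the parameter form
is the default.

A~sat~ and g~ssat~ are deliberately *measured* means of the records at the
nominal 2000 µmol m⁻² s⁻¹ level (matched with a ±5% tolerance, because lamp
set-points wobble), not model asymptotes: the asymptote of the hyperbola lies
well above any observable rate and would overstate capacity.

Fitting is deterministic. Starting values come from the data (R~d~ from the
dark records, φ from an OLS slope through the lowest light levels,
A~max~ from the maximum observed rate), a small multiplicative grid of
starts guards against local minima, and Levenberg–Marquardt least squares
(`minpack.lm`) does the refinement with the constraints φ > 0, A~max~ > 0,
R~d~ ≥ 0.

```{r light-fit}
tr <- accession_truth()
s <- simulate_light_curve(tr, seed = 1, noise = FALSE)
coef(fit_light_response(s))
```

# Induction kinetics after a light step

The dynamic response of A or g~s~ to the 100→1000 µmol m⁻² s⁻¹ step is
modelled with a Gompertz-type sigmoid with an explicit lag:

$$y(t) = y_0 + (y_f - y_0)\, e^{-e^{(\lambda - t)/k}}$$

with t measured from the step, λ the initial delay (s) and k the time
constant (s). The reported time constant τ is k; λ is estimated and reported
separately rather than folded into τ, since the two describe different
physiology (signalling delay versus aperture/activation speed). A simple
exponential rise is the small-λ special case, so one estimator covers both A
(τ~ai~) and g~s~ (τ~i~) consistently.

Two numerical choices matter here:

* **The baseline anchors y₀.** The pre-step samples enter the fit as the
  constant steady state y₀ (the model is piecewise: y₀ for t < 0, sigmoid
  after). Fitting the response phase alone leaves a flat λ–k–y₀ ridge in the
  objective: under realistic noise the optimizer can trade a higher y₀ and a
  large λ for a much smaller k while changing the residuals very little.
  Thirty baseline points pin y₀ and collapse the ridge; with this choice the
  time-constant estimator is close to unbiased across the whole 42–1235 s
  range the panel spans.
* **Multi-start over (λ, k).** Time constants span two orders of magnitude,
  so a grid λ ∈ {0, 30, 60, 120, 300} × k ∈ {30, 100, 300, 1000} s is
  screened by residual sum of squares at the initial (y₀, y~f~), and the
  best four starts are refined. The best refined fit by SSE wins;
  ties cannot occur in practice but would resolve to the first grid order,
  keeping results deterministic.

A trace whose apparent amplitude |y~f~ − y₀| is below three baseline standard
deviations is flagged `no_response` instead of fitted: a time constant
estimated from noise would be meaningless. Closing responses (y~f~ < y₀) use
the same machinery.

W~i~ = A/g~s~ is computed samplewise with conductances below
0.005 mol m⁻² s⁻¹ masked (below instrument resolution the ratio explodes);
steady-state W~i~ at each light level is the mean over the closed final
5-minute window of the corresponding phase. Windows are closed on both ends
so that "the last 5 minutes" of a 10-s-sampled phase contains every sample
it should; no intermediate 30-s thinning is applied, since the mean of a
steady signal is invariant to regular sub-sampling in expectation.

# Stomatal anatomy and maximum conductance

Stomatal density pools all counted fields of a plant–surface (total count /
total area). Geometry is averaged per plant–surface *before* entering the
conductance equation, matching how live-image measurements are summarised in
practice. The anatomical maximum conductance of one surface is the
diffusion-limited value

$$g_{smax} = \frac{d\, \mathrm{SD}\, a_{max}}
{v\left(l + \frac{\pi}{2}\sqrt{a_{max}/\pi}\right)}$$

with `a_max` the fully open pore area modelled as an ellipse (major axis =
pore length p, minor axis = p/2, so a~max~ = πp²/8), pore depth l taken as a
quarter of the guard cell length, d = 2.46 × 10⁻⁵ m² s⁻¹ the diffusivity of
water vapour in air and v = 2.44 × 10⁻² m³ mol⁻¹ the molar volume of air
(standard values at 25 °C and 101.3 kPa; both overridable via
`gasx_constants()`). The end-correction term (π/2)·√(a~max~/π) is the radius
of the circle with the pore's area; omitting the square root would make the
denominator dimensionally inconsistent. All inputs are converted to SI, and
a density below 10⁶ m⁻² raises an error because it almost certainly means a
value in mm⁻² was passed unconverted.

Whole-leaf g~smax~ is the **sum** of the two surface values: stomata on the
two epidermes are parallel diffusion pathways, and parallel conductances
add.

```{r gsmax}
anatomical_gsmax(SD = 100e6, pore_length_um = 20, guard_cell_length_um = 40)
```

The field-of-view area of the ×10 objective is instrument-specific and not
recoverable from image files; it is a required configuration value, with
0.29 mm² used as the generator's plausible default (an assumption, flagged
as such).

# Panel statistics

ANOVA uses `stats::aov` (sequential sums of squares; adequate for the mild
imbalance of 3–8 replicates per accession). Tukey's HSD is computed from the
group means and pooled mean square error with the Tukey–Kramer standard
error for unequal replication, and adjusted p-values from the studentized
range distribution (`stats::ptukey`); `stats::TukeyHSD` serves as an
independent cross-check in the test suite. Compact letters come from the
insert-and-absorb construction, which provably satisfies the display
contract — two groups share a letter exactly when their adjusted p exceeds
α — and is deterministic in sorted group order. Pearson correlations and
their two-sided p-values use the t-transform with n − 2 degrees of freedom.

Accession-level trait values are means over plant replicates; ANOVA runs on
the plant-level replicates; cross-trait correlations use accession means.

# What the synthetic generator emulates

The generator draws accession truths from ranges a sorghum diversity panel
plausibly spans, then renders the two measurement protocols:

| parameter | default range | units | note |
|---|---|---|---|
| φ | 0.04–0.07 | mol mol⁻¹ | C₄ quantum yields |
| A~max~ | 18–45 | µmol m⁻² s⁻¹ | gives A~sat~ ≈ 13–31 |
| R~d~ | 0.5–2.5 | µmol m⁻² s⁻¹ | |
| coupling slope b | 150–220 | µmol CO₂ mol⁻¹ H₂O | A = a + b·g~s~ |
| τ~i~ (k~gs~) | 42–1062 (log-uniform) | s | correlated with k~A~, ρ ≈ 0.6 |
| τ~ai~ (k~A~) | 92–1235 (log-uniform) | s | |
| λ | 20–120 | s | shared by A and g~s~ |
| SD abaxial / adaxial | 51–185 / 28–121 | mm⁻² | abaxial denser on average |
| guard cell length | 30–45 | µm | pore = 0.45–0.65 × GCL |
| σ~A~ / σ~gs~ | 0.3 / 0.005 | µmol m⁻² s⁻¹ / mol m⁻² s⁻¹ | typical IRGA noise |

Light curves render 3 steady records at each of the 12 nominal levels; step
traces sample every 10 s — 30 baseline records over 5 min, then 181 records
over 30 min (211 in total), with A and g~s~ following the sigmoid toward the
steady values implied by the light-response and coupling truths. C~i~ is
back-filled from a target C~i~/C~a~ of 0.30 at high light, relaxing toward
C~a~ below 250 µmol m⁻² s⁻¹ — the pipeline only consumes the ratio, so no
mesophyll model is pretended. Anatomy renders Poisson field counts and
normally jittered geometry (5% CV) with pore < guard cell length enforced.

**The coupling is structural, not incidental.** Each accession's g~ssat~ is
derived from its A~sat~ through a panel anchor line (slope 185, intercept −9,
the midpoints of the per-accession coupling ranges) with 5% multiplicative
scatter; the accession's own coupling slope b then fixes its intercept
a = A~sat~ − b·g~ssat~. This guarantees the tight panel-wide A~sat~–g~ssat~
relation the analysis assumes (R ≥ 0.9), keeps per-accession intercepts in a
negative range (≈ −15 to 0), and therefore makes W~i~ rise from the 100 to
the 1000 µmol m⁻² s⁻¹ steady state for essentially every accession — the two
structural properties the pipeline verifies about itself. Time-constant
pairs are drawn through a Gaussian copula whose parameter is calibrated
internally (fixed-seed root-finding) so the *level-scale* Pearson
correlation of (k~A~, k~gs~) matches the configured ρ = 0.6 despite the
log-uniform marginals.

What the generator does **not** emulate: temperature and VPD covariation,
instrument drift and autocorrelated noise, leaf-to-leaf heterogeneity within
a plant, C₄ biochemistry (C~i~ dynamics during induction are schematic), and
stomatal patchiness. Passing tests therefore demonstrate that the estimators
recover known parameters under the stated protocols and noise — not that
field data will be as kind.

# Verification sizes and determinism

The test-suite and acceptance checks use problem sizes chosen to make the
sampling distributions informative while keeping a full run interactive:
20 replicate fits per time-constant setting (at the protocol's 10-s sampling
and default noise), a 43-accession × 4-plant panel for the structural
checks, 200 random 6-group datasets for the exhaustive letter-display
contract, and 2000 null datasets for the family-wise error rate. Every
stochastic step takes an explicit integer seed; generators save and restore
the session RNG state, per-plant seeds are derived deterministically from
the master seed, and output files are written with fixed formatting, so a
rerun with the same configuration is byte-identical.

# Known limitations

* The sigmoid's λ and k remain weakly collinear for responses that finish
  within the lag-dominated regime; recovery near the slow extreme
  (τ ≳ 1000 s, where a 30-min trace covers under two time constants) has
  noticeably wider spread than in the mid range.
* `anova_table` reports sequential sums of squares; strongly unbalanced
  two-way designs would need Type II/III decompositions, which the package
  does not provide.
* The insert-and-absorb letter display is minimal-ish, not provably minimal;
  for the group counts used here the difference is immaterial.
* Traits are extracted per plant independently; no shrinkage or mixed-model
  pooling across accessions is attempted.
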