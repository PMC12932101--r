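---
title: "Quantifying AAV neutralizing antibodies: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying AAV neutralizing antibodies: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nabtiter)
library(dplyr)
```

# The measurement problem

Cell-based transduction-inhibition assays estimate neutralizing-antibody
(NAb) titers against AAV capsids by mixing a two-fold serum dilution series
(1/4 down to 1/128) with a fixed dose of a luciferase-reporter vector,
transducing cells, and reading luminescence. The readout of interest is the
ND50: the serum dilution at which transduction drops to 50% of an
antibody-free control.

The complication is that serum affects transduction through routes that
have nothing to do with antibodies. Serum pre-incubated with the vector
*enhances* transduction (capsid-binding serum components such as albumin),
saturating at a few percent serum; serum sitting on the cells *inhibits*
it. In the conventional assay format (VSC, variable serum concentration)
total serum per well rises as the test serum is less dilute, so these
matrix effects change along the dilution axis: baselines inflate above
100%, and a partially neutralizing sample can be dragged back above the
50% line — its neutralization is masked. The CSC format (constant serum
concentration) dilutes test serum in antibody-free serum so that every
well carries the same total serum (10%); matrix effects then cancel
against the format-matched control and the curve reflects antibodies
alone.

`nabtiter` implements the full analysis chain for both formats —
normalization, Bayesian ND50 estimation with censoring, serostatus
stratification with exact McNemar discordance testing, Cliff's delta and a
Bayesian practical-equivalence test — plus a synthetic plate generator
with recorded ground truth, so every stage is testable without laboratory
data.

# The synthetic plate generator

The generator is first-class, tested code, and defines the study
conditions used throughout the package's tests.

Expected luminescence of a test well at dilution $d$ is

$$\mathrm{RLU}(d) = B \cdot E\!\big(s_\mathrm{tot}(d)\big) \cdot
  I(s_\mathrm{med}) \cdot H(d) \cdot \varepsilon,$$

with baseline $B$ (`baseline_rlu`, default $10^5$ RLU) and:

* **Enhancement** $E(s) = 1 + a\,s/(s + k)$, a saturating hyperbola in the
  serum fraction $s$ pre-incubated with the vector; defaults $a = 4$
  (plateau at five-fold), $k = 0.05$ (half-saturation at 5% serum,
  matching where the enhancement visibly plateaus in titration
  experiments). The functional form is a modeling choice; only its
  qualitative shape (monotone, saturating, $E(0)=1$) is empirically
  anchored.
* **Inhibition** $I(s) = 1/(1 + b\,s^h)$ for serum in the culture medium;
  defaults $b = 4$, $h = 1$ (about a 30% loss at 10% serum). Under CSC the
  cells are seeded serum-free ($I = 1$); under VSC the medium carries
  1.25% serum for both test and control wells, so $I$ cancels in
  normalization either way — it matters only for the serum-titration
  experiment that characterizes the two effects separately
  (`simulate_serum_titration()`).
* **Neutralization survival** $H(d) = 1/\big(1 + (d/\mathrm{ND50})^n\big)$,
  a Hill curve with bottom 0 and top 1; $H \equiv 1$ for seronegative
  profiles and $H(\mathrm{ND50}) = 0.5$ by construction. Default Hill
  slope $n = 2$, a typical mid-steepness for polyclonal sera. (The
  *fitting* model does not assume bottom 0 / top 1.)
* **Serum composition**: CSC wells always carry `csc_total_serum` (0.10);
  VSC wells carry `vsc_medium_serum` (0.0125) plus $d \times 0.25$ of test
  serum — 20 µL of transduction mix into a 100 µL well. The exact per-well
  volumes of the wet protocol are not published, so this rule is a
  configurable default rather than a fixed constant.
* **Noise** $\varepsilon$ is multiplicative lognormal with log-scale SD
  `noise_sigma` (default 0.05): luminescence is positive and its
  dispersion scales with its level. Wells are deterministic given the
  design seed.

Antibody-free control wells are generated per format: CSC controls are
antibody-free serum at the full 10% ($E(0.10)$), VSC controls are plain
medium ($E(0.0125)$). Consequently a noise-free seronegative CSC curve
normalizes to exactly 100% at every dilution, while the matching VSC curve
rises above 100% toward strong serum — the baseline inflation at the heart
of the format comparison.

**The masking parameter set.** `masking_truth()` documents one
configuration where the formats disagree qualitatively: true ND50 = 1/6,
slope 2, enhancement amplitude 4. The noise-free CSC curve crosses 50%
within the tested range (30.8% at 1/4) while the VSC curve of the same
sample never drops below 50% (58.2% at 1/4), so the neutralization
classifier disagrees between formats. A true ND50 exactly at 1/4 would put
the CSC curve exactly *at* 50% — a boundary, not a crossing — hence 1/6 as
the documented low-titer choice.

What the generator does **not** emulate: complement or heat-inactivation
effects, empty-capsid decoys, plate-position (edge) effects, batch
variation in the serum matrix, or non-lognormal reader noise. Tests passing
on simulated plates therefore validate the statistical machinery under the
stated generative model, not the wet assay itself.

# Normalization

Raw luminescence is converted to transduction efficiency,
$100 \cdot \mathrm{RLU} / \overline{\mathrm{RLU}}_\mathrm{ctrl}$, against
the arithmetic mean of the antibody-free control wells in the matched
(plate, serotype, format) group; percent inhibition is its complement.
Matching is strictly within-plate — cross-plate pooling is refused rather
than silent. This ratiometric step makes curves comparable across
serotypes with different absolute transduction efficiencies, and makes
every downstream result invariant to plate-level scaling of the raw
signal (a property test multiplies all RLU by random constants and asserts
identical curves, ND50s and classifications). Blank-well subtraction is
available but off by default, since the reference protocol does not
describe one.

# ND50 estimation

## Bayesian four-parameter Hill fit

For complete sigmoidal curves (monoclonal-antibody series), transduction
is modeled as

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
  {1 + 2^{\,\mathrm{slope}\,(x - x_{50})}}, \qquad x = \log_2 d,$$

with a Normal likelihood and fitted residual SD, on replicate-level
points. Priors are weakly informative and reflect assay construction:
bottom $\sim N(0, 20)$ truncated at $-10$; top $\sim N(100, 20)$; slope
lognormal(0, 1) (positive by convention — transduction falls as serum
rises); $x_{50}$ uniform over the tested range padded by two doublings;
residual SD half-Normal(0, 10). Sampling is an adaptive random-walk
Metropolis (Haario-style covariance adaptation during warmup, frozen
proposal afterwards), 4 chains × 1500 warmup, 2000 kept draws per chain
thinned by 5. Thinning keeps the effective sample size of the retained
draws high enough for the convergence gate: fits are flagged
non-converged when any split-chain $\widehat{R}$ exceeds 1.01. The ND50 is
the posterior median of $2^{x_{50}}$ with an equal-tailed 95% credible
interval.

In a 200-curve recovery study at the generator's default conditions
(6 dilutions, 3 replicates, noise 0.05, slope 2, truths log2-uniform
inside the tested range), the 95% credible interval covers the true ND50
at the nominal rate band (90–98%) and the posterior median lands within
±0.25 log2 of truth in well over 80% of curves — these are asserted by the
test suite, which computes them fresh on every run. A known limitation:
when true Hill slopes stray far from the prior mode (e.g. 1.5–3 mixed),
the constant-SD Normal likelihood is mis-specified against the
multiplicative noise and interval coverage erodes toward ~85%.

## Linear-model fallback for serum samples

Serum curves under VSC are often incomplete or non-sigmoidal, so — to keep
the CSC/VSC comparison on one footing — all serum series are fitted with a
Bayesian simple linear regression of transduction on $\log_2 d$ under the
standard noninformative prior. That posterior is conjugate
(Normal-inverse-$\chi^2$), so draws are exact rather than MCMC. The ND50
is the posterior of the 50% crossing $(50 - \alpha)/\beta$; draws with
$\beta \ge 0$ carry no crossing, and if they are the posterior majority
the sample is censored. The `auto` policy in `estimate_nd50()` applies the
Hill model to `sample_type = "mab"` series and the linear model to
everything else.

## Censoring

Estimates weaker than the strongest tested dilution (titer below 4 when
testing from 1/4) or curves with no 50% crossing are reported as the
placeholder titer 1/1 with `censored = TRUE`, never as an extrapolated
number. Flat seronegative curves always censor.

# Serostatus stratification and discordance

Two rules, both read at the 1/4 dilution (replicate mean), thresholds
exposed in `nab_config()`:

* **Pool eligibility**: above 90% transduction → `seronegative`, else
  `ineligible`. The stringent cutoff protects reference-pool construction
  from low-titer contamination.
* **Neutralization**: below 50% → `neutralizing`, else
  `non_neutralizing`.

Both use strict inequalities; boundary values fall conservatively
(`ineligible` / `non_neutralizing`).

Paired CSC/VSC labels per sample feed a 2×2 table; the discordant fraction
and an **exact** McNemar p-value (binomial sign test on the discordant
pairs, two-sided by doubling, capped at 1) are reported per (serotype,
rule). The exact form is the default because discordant counts in small
serum panels are far below chi-square territory; the continuity-corrected
chi-square is available behind `exact = FALSE` for cross-checking.

# Effect size and practical equivalence

**Cliff's delta** is computed by the exact pairwise count
$|\mathrm{greater} - \mathrm{lesser}|/(n_x n_y)$, ties counting toward
neither; the signed variant is available since the direction of a format
difference is itself informative. The 95% CI is a percentile bootstrap
(10^4 resamples, within-group, seeded). Magnitude bands: 0.11 / 0.28 /
0.43 for small / medium / large.

**Practical equivalence on log2 ND50**: each group Normal with its own
mean and SD; priors adapt to the pooled scale (mean $\sim N(\bar{x},
2s)$, SD half-Normal$(0, 2s)$). Two titer sets are declared `different`
only when the posterior probability that their means differ by more than
the ROPE half-width (0.3 log2 units) exceeds 0.95. With a 0.2-log2
within-group SD and $n = 20$, the posterior SD of the mean difference is
≈ 0.06 log2, so a null difference essentially never clears the
0.3-log2 ROPE at 95% — the test's false-"different" rate under the null
is far below 5%, which the suite verifies over 500 simulated pairs.
Posterior draws (e.g. from `hill_nd50_draws()`) can be supplied directly
instead of raw values, in which case the ROPE rule is applied to the
difference of draws.

# Numerical choices and degenerate inputs

* Dilutions are powers of two; stored numerically they are exact binary
  fractions, and serialized CSVs carry both the decimal and a "1/8"-style
  display string, so round-trips are lossless.
* All stochastic steps (simulation, MCMC, bootstrap, posterior draws) are
  seeded; identical inputs and seeds reproduce outputs byte-for-byte, and
  every RNG use saves and restores the caller's RNG state.
* Chain initialization is deterministic and mildly dispersed around
  data-driven values, so convergence diagnostics are meaningful without
  making fits irreproducible.
* Degenerate inputs are refused loudly: fewer dilution points than
  parameters, zero predictor variance, zero control means, test groups
  with no matched control, single-value groups in the equivalence test
  (with the instruction to pass posterior draws instead).

# Desk-scale problem sizes

The test suite runs the recovery study at 200 curves, the equivalence-test
calibration at 500 null and 200 separated pairs, the noise-model check at
10^4 replicate wells, and oracle comparisons at ≤ 50×50 pairwise counts
and all discordant splits up to 30 — sizes chosen so the whole suite
exercises every statistical claim in minutes on a laptop while keeping
Monte-Carlo error well inside the asserted tolerance bands.

# Worked example

```{r example, eval = FALSE}
dir <- tempfile()
cfg <- nab_config(seed = 1, model = "linear")
sim <- nab_simulate(dir, truths = default_study_truth(seed = 1),
                    config = cfg)
res <- nab_analyze(file.path(dir, "wells.csv"), config = cfg,
                   out_dir = file.path(dir, "out"))
res$nd50
res$discordance
plot_curves(res$curves)
```
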