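---
title: "Models and methods: droplet occupancy, IL-10 sharing, calibration and kinetics"
author: "dropqs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: droplet occupancy, IL-10 sharing, calibration and kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropqs)
```

`dropqs` models how a minority population of IL-10-secreting
macrophages shapes population-level cytokine readouts in droplet
microfluidics and density-controlled bulk cultures. This vignette
documents the models, their assumptions, the tunable parameters, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Poisson cell encapsulation

Cells dispersed at concentration $c$ (cells/mL) enter droplets of
volume $v$ (nL) independently, so the occupancy $k$ of a droplet is
Poisson with mean

$$a = c \cdot v \cdot 10^{-6}.$$

`mean_occupancy()` applies this identity; the default $v = 0.8$ nL
reproduces the standard concentration-to-occupancy pairings used in
multi-cell experiments ($2.5, 5, 10, 15 \times 10^6$ cells/mL giving
$a \approx 2, 4, 8, 12$) and is always overridable for other devices.

`occupancy_pmf()` tabulates the Poisson mass $a^k e^{-a}/k!$ for
$k = 0..k_{max}$ (default $k_{max} = 30$). Two views are kept
deliberately distinct:

* `raw_terms` — the untruncated formula values, which sum to slightly
  less than 1 (the deficit is the tail mass beyond $k_{max}$). These
  are what the sharing model's truncated sums use.
* `normalized_pmf` — the same values rescaled to sum to one, used for
  simulation-free expected frequencies in goodness-of-fit work.
  `compare_occupancy()` exposes both via `renormalize`, since a
  plotted "Poisson expectation" curve may or may not have been
  renormalized after truncation; at the occupancies of interest
  ($a \le 12$, $k_{max} = 30$) the difference is below $10^{-6}$.

Simulation (`simulate_encapsulation()`) draws from the *untruncated*
Poisson: the physical loading process has no occupancy cap, so
truncation is a property of the tabulated model only.

The chi-square comparison pools bins with expected count below 1
(configurable) into the nearest retained bin at the head and tail —
the standard safeguard against sparse-cell instability — and reports
the statistic, degrees of freedom (bins − 1) and p-value. Evaluation
of the mass function goes through `dpois()`, which works on the log
scale and is finite for $k$ well beyond 170, where naive factorials
overflow.

## The multi-cell sharing model

Let $b$ be the fraction of cells that secrete IL-10 (producers). The
sharing hypothesis is all-or-none: IL-10 from one producer renders
every co-encapsulated cell positive. `dropqs` implements three
predictions of the population fraction of positive cells at mean
occupancy $a$, all truncated at $k_{max} = 30$:

**Published summation formula** (`paper_fraction_positive()`):

$$F_{formula}(a,b) = 100 \cdot
  \frac{\sum_{k=1}^{30} \frac{a^k e^{-a}}{k!}\, b\, k^2}
       {\sum_{k=1}^{30} \frac{a^k e^{-a}}{k!}\, k}.$$

The numerator counts $b k$ expected producers per droplet of size $k$,
each converting all $k$ cells. This double-counts droplets holding two
or more producers: the untruncated sums collapse to the closed form
$100\, b (1 + a)$, which is linear in $a$ and exceeds 100% once
$a > 1/b - 1$ (at $b = 0.1$: $a > 9$). The formula is implemented
verbatim because it *is* the model under study — fidelity first — and
a cap at 100% is applied by default (`cap_at_100`), with the uncapped
value always reported alongside.

**Exact expectation** (`exact_fraction_positive()`): under the same
mechanism without double counting, a droplet of size $k$ contributes
$k$ positive cells exactly when it holds $\ge 1$ producer, so

$$F_{exact}(a,b) = 100 \cdot
  \frac{\sum_k p(k)\, k \left(1-(1-b)^k\right)}{\sum_k p(k)\, k}
  \le 100.$$

Since $b k \ge 1 - (1-b)^k$, the formula is an upper bound on the
exact value, strict whenever multi-cell droplets occur and
$0 < b < 1$, with relative gap vanishing as $b \to 0$. These
inequalities are asserted as properties in the test suite.

**Stochastic simulator** (`simulate_sharing()`): occupancy
$\sim$ Poisson($a$), producers $\sim$ Binomial($k, b$), all-or-none
positivity. Its standard error treats droplets as the independent
units (ratio-estimator linearization), because positivity is perfectly
correlated within a droplet — a per-cell binomial SE would be
anti-conservative by roughly $\sqrt{E[k]}$.

### Estimating the producer fraction

`estimate_producer_fraction()` counts events above a positivity
threshold and attaches a 95% Wilson score interval (closed form; the
Wilson interval behaves well at small counts and yields a natural
one-sided interval when no event is positive). When an
unstimulated-control sample defines the gate (99th percentile by
default), the control's own exceedance of the gate — nominally 1% — is
subtracted from the event exceedance and the result floored at zero,
the usual percent-positive-minus-control convention. Without this
correction a percentile gate biases $\hat b$ upward by the gate's
false-positive rate, which matters when $b$ itself is of order 10%.

### Confidence bands

`prediction_band()` propagates replicate-to-replicate variation in
$b$. The default maps the endpoints of a t-based confidence interval
for the mean of the replicate $b$ values through the model, valid
because both models are monotone increasing in $b$ at fixed $a$. An
alternative (`method = "percentile"`) computes the t-interval across
per-replicate model curves at each $a$; for the models here the two
nearly coincide, but the mapped construction is exact under
monotonicity and is the default.

## Fluorescence calibration

`fit_titration()` supports two curve forms. The default is
piecewise-linear interpolation in log-log space: it passes exactly
through every standard, making the forward/invert round trip exact at
the knots and testable to tight tolerance between them, and it imposes
no parametric shape. The alternative is the four-parameter logistic
$y = d + (a - d)/(1 + (x/c)^{-\beta})$, the canonical immunoassay
dose-response. Internally the 4PL is parameterized as a logistic in
log-concentration ($x_{mid} = \log c$, $scal = 1/\beta$), self-started
with `stats::SSfpl` and refined by Levenberg-Marquardt
(`minpack.lm::nlsLM`) on log signals, where multiplicative assay noise
is homoscedastic; this parameterization avoids the singular gradients
the naive $(a, d, c, \beta)$ form produces at plausible starting
values.

The two forms trade off differently: the interpolant is exact at the
standards but chords a curved response between them — against a
logistic truth with half-decade standard spacing this leaves a
systematic few-percent bias in recovered amounts — while the 4PL
matches a logistic response to within fitting error but imposes its
shape. Recovery-of-truth checks in the test suite therefore use the
4PL (matched to the generative response); round-trip identity checks
use the interpolant.

`signal_to_amount()` clamps signals outside the standards' range to
the range boundary and flags them (`below_range`, `saturated`) rather
than dropping events: dropping would bias downstream fraction
estimates, and capture-antibody saturation has no agreed correction,
so it is flagged, not corrected. The `conversion` factor (pg/cell per
pg/mL, default $10^{-3}$) carries the titration geometry — how much
per-cell content a given calibration concentration corresponds to —
and should be set from the experiment (cells per calibration sample,
sample volume) when known.

Normalizations: `total_production()` rescales summed per-cell amounts
to a reference population (default $10^5$ cells);
`elisa_normalize()` computes concentration × volume / cell count ×
reference count. Both are linear and invariant to cell relabeling.

## Secretion kinetics

`interval_rates()` computes finite-difference rates between
consecutive timepoints and flags negative rates as clearance —
apparent consumption or degradation exceeding production, which
TNF$\alpha$ shows at high culture densities within 24 h. No smoothing
is applied: with 4–5 timepoints per course, finite differences are the
honest estimate and smoothing choices would dominate the result.
`rate_sum_check()` verifies the telescoping identity
$\sum_i r_i \Delta t_i = y_{last} - y_{first}$ (residual $< 10^{-9}$)
as internal plumbing.

"Stopped producing" is operationalized by `shutoff_time()`: the
earliest time the cumulative amount reaches 95% of its final value
(threshold configurable), with linear interpolation between
timepoints by default. The 95% level avoids declaring shutoff from
asymptotic creep while being insensitive to early-course noise. The
amount at $t = 0$ is taken as zero — stimulation starts the clock —
configurable for pre-loaded cultures.

## Synthetic data: what it emulates, and what it does not

`generator_config()` freezes the study conditions the package models:

| parameter | default | rationale |
|---|---|---|
| producer fraction $b$ | 0.10 | ~10% of LPS-stimulated macrophages secrete IL-10 |
| occupancy means | 2, 4, 8, 12 | the multi-cell droplet conditions |
| densities | 2.5, 5, 10, 15 ×10⁶ cells/mL | the bulk density series |
| timepoints | 0, 2, 4, 8, 24 h | the ELISA sampling design |
| per-producer secretion | lognormal, median 1 pg, GSD 2 | order-of-magnitude scale; absolute per-cell amounts are assay-dependent, so configurability over false precision |
| IL-10 shutoff by density | 24, 20, 12, 8 h | production stops earlier at higher density; the highest density is done by 8 h |
| TNFα shutoff by density | 24, 16, 8, 4 h | TNFα stops earlier than IL-10; highest density done by 4 h |
| TNFα post-peak decay | 0.05 /h at the two highest densities | produces the negative apparent rates read as clearance |
| donor effect | lognormal, SD 0.2 (log scale) | donors differ in scale; per-donor normalization removes it |

Time courses follow $y(t) = Y \left(1 - e^{-t/\tau}\right)$ with
$\tau$ = shutoff/3 (so ~95% of the plateau is reached at the shutoff
time), frozen at the plateau after shutoff, with optional exponential
decay afterwards for TNF$\alpha$. Plateau totals decrease with density,
reflecting lower per-cell production in crowded cultures.

Single-cell events are bimodal: producers draw a lognormal secreted
amount rendered through the configured 4PL fluorescence response
(multiplicative measurement noise, geometric SD 1.05), non-producers
draw lognormal background (median 60 MFI, GSD 1.5). The two modes are
separated by orders of magnitude, so a fixed inter-modal gate (300 MFI
with the defaults) classifies essentially without error. Multi-cell
events implement the exact sharing mechanism as a forward model:
positive cells receive an equal share of their droplet's total
secreted IL-10.

What the generators do **not** emulate — and what passing tests on
them therefore cannot show about real data: spectral
spillover/compensation artifacts, capture-antibody saturation and
cytokine/capture-reagent diffusion between cells, droplet size
polydispersity, cell death and doublets, partial (graded) positivity
— the sharing mechanism here is strictly binary — and any dependence
of $b$ itself on occupancy or density, which the real system appears
to have and which is precisely what comparing model to measurement is
meant to expose.

## Numerical and design choices

* Poisson masses via `dpois()` (log-scale, overflow-safe to
  $k_{max} = 170$ and beyond); tests cross-check against literal
  $a^k e^{-a}/k!$ evaluation.
* Sharing sums run $k = 1..k_{max}$; $k = 0$ droplets hold no cells
  and drop out of both numerator and denominator.
* The simulator errors when every simulated droplet is empty (tiny
  $a$ with small $n$) rather than returning 0/0.
* Titration standards must be strictly increasing in both
  concentration and signal; violations name the offending rows.
* Chi-square pooling floor: expected count 1 (configurable); head and
  tail are pooled symmetrically.
* All generators and the pipeline are deterministic given a seed, and
  `run_pipeline()` writes MD5 checksums of every output into its
  manifest so reruns are verifiable.
* Problem sizes used in the shipped checks — $10^5$ droplets for
  simulator-vs-exact agreement, 50,000 events for producer-fraction
  recovery, 500 replicates of $n = 1000$ for interval coverage,
  20,000 droplets per occupancy for the end-to-end comparison — were
  chosen so Monte-Carlo error sits well inside the tolerance being
  asserted (4 standard errors where the check is distributional).

## Known limitations

* The published formula is reproduced faithfully, including its
  double counting; it should be read as an upper bound, not an
  estimator. The exact variant is the estimator.
* The 100% cap is a reporting convention, not model content; capped
  and uncapped values are both always available.
* Log-log interpolation is undefined at zero signal or concentration;
  standards must be positive. Zero-signal events are clamped to the
  lowest standard and flagged.
* Clearance flags mark negative finite-difference rates; the package
  deliberately does not model the mechanism (consumption vs
  degradation vs assay loss), which the data cannot distinguish.
* The pipeline's background-corrected producer fraction floors at
  zero, so its sampling distribution is truncated near $b = 0$.
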