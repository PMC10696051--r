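---
title: "Temporal variation of growing microbial populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal variation of growing microbial populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempovar)
```

This vignette documents the models implemented in `tempovar`, the
assumptions behind them, the tunable parameters and their defaults, and the
numerical and design choices a maintainer would want spelled out.

## Models and assumptions

### Simple birth process

The simple birth (Yule) process assumes every individual divides
independently at a constant per-capita rate $\mu$ (units 1/hour throughout
the package), irrespective of its age. Abundance trajectories are
monotone, so the probability that the population has reached a threshold
$\Omega$ by time $t$ equals the cumulative distribution of the
first-passage time (FPT), and the FPT decomposes into independent
exponential waiting times $\mathrm{Exp}(\mu n)$, $n = n_0, \ldots,
\Omega - 1$. `fpt_moments()` exploits this: the mean is a partial harmonic
sum, the temporal variance a partial sum of inverse squares, and the
temporal standard deviation (TSD) asymptotes to $1/(\mu\sqrt{n_0})$ once
$\Omega \gtrsim 50$. The model ignores death (appropriate while birth far
exceeds death), resource limitation, and any age structure.

### Zero-truncated Poisson inocula

Pipetting a fixed volume of dilute culture yields Poisson inoculum sizes;
restricting attention to wells that grow conditions on $M \ge 1$, the
zero-truncated Poisson. With deterministic exponential growth the FPT is
$T(M) = \ln(\Omega/M)/\mu$ and the TSD is $\mathrm{sd}(\ln M)/\mu$: the
threshold cancels exactly, which is why `tsd_ztpois_exact()` takes no
$\Omega$. The delta-method expansion (`delta_moments()`) reports the mean
correction $1/(2\mu n_0)$ separately so each order can be checked; it is
flagged as unreliable below shape 5, where the expansion around the mean is
not meaningful. Note the reported "mean inoculum size" of growing wells is
the zero-truncated mean $n_0/(1 - e^{-n_0})$ (`ztpois_mean()`), not the
Poisson shape.

### Age-structured growth

`sample_age_structured_fpt()` simulates a Bellman–Harris branching
process: each individual lives an i.i.d. division time, then is replaced by
two newborns. Division times are $k$-stage Erlang — equivalently a
$\chi^2(2k)$ distribution rescaled to the configured mean — with
coefficient of variation $1/\sqrt{k}$; the default law (20 stages, 25-min
mean) has CV $\approx 22\%$, and $k = 1$ recovers exponential division
times. The simulator is an event queue (`std::priority_queue` in C++),
with the FPT recorded at the division event at which the count first
equals $\Omega$; counts change only at events and no interpolation is done
within them. Simultaneous events have probability zero in continuous time;
ties in the heap resolve by pop order and are statistically irrelevant.

Founding individuals sit at a random point of their division cycle. Three
conventions are provided for their first division:

* `"uniform"` (default): uniform on $[0, \ln 2/\mu_{\mathrm{eff}}]$ with
  $\mu_{\mathrm{eff}} = \ln 2 / \bar\tau$, i.e. uniform over one nominal
  division time;
* `"exponential"`: $\mathrm{Exp}(\bar\tau)$, the memoryless residual — with
  a 1-stage law this makes the model *exactly* a simple birth process;
* `"zero"`: newborn founders (a fresh full draw).

One subtlety worth recording: two different "matched rates" coexist. The
deterministic division-time convention relates a rate $\mu$ to a division
time $\ln 2/\mu$, and the uniform phase window uses it. But an exponential
division-time *law* with mean $\bar\tau$ is a simple birth process at rate
$1/\bar\tau$, not $\ln 2/\bar\tau$. The equivalence tests therefore match a
1-stage law of mean 60 min against $\mu = 1$/hour, and the CV-100%
interpolation endpoint for a 25-min mean is the simple birth process at
2.4/hour.

### Two-step variance accumulation

`two_step_variance()` quantifies when the noise is generated: growth is
stochastic (simple birth) until $t_s$, deterministic afterwards, giving to
leading order $\sigma_t^2 = (1 - e^{-\mu t_s})/(\mu^2 n_0)$ — half of the
asymptotic temporal variance accumulates within a single division time.
`sample_two_step_fpt()` draws $N(t_s)$ from the exact Yule marginal (a
shifted negative binomial) rather than event-simulating the first phase;
the marginal is exact, so nothing is lost. It assumes
$\Omega \gg N(t_s)$ and warns when the threshold is within a factor
20 of the expected switch abundance.

### Growth-rate inference

`infer_growth_rate()` inverts the exact TSD relation. The estimate assumes
simple-birth growth and no other noise: dispersive noise sources (media or
temperature variation, lag, inoculum variability if unaccounted) inflate
the measured TSD and make $\hat\mu$ a lower bound; focusing noise
(e.g. anticorrelated mother–daughter division times) would bias it upward.
The direction tests in the suite verify both regimes. Because the noise is
generated at small population sizes, $\hat\mu$ reports on early growth —
the regime ordinary OD measurements cannot resolve directly.
`precision_curve()` bootstraps the estimate at subsample sizes to show how
precision scales (default 5000 resamples, 68% intervals).

### Desynchronization

For the deterministic age-structured model the renewal characteristic
equation $2\hat f(s) = 1$ has, for a $k$-stage Erlang law with stage scale
$\theta = \bar\tau/k$, the closed-form roots
$s_j = (2^{1/k} e^{2\pi i j/k} - 1)/\theta$. The dominant real root $s_0$
is the Malthusian rate (slightly above $\ln 2/\bar\tau$ for finite $k$,
decreasing to it as $k \to \infty$); the leading complex pair $s_{\pm 1}$
sets the decay of growth-rate oscillations of a synchronized inoculum, at
$\exp[(\mathrm{Re}\,s_1 - s_0)\bar\tau]$ per division cycle.
`cycles_to_asymptote()` operationalizes "effectively exponential growth"
as a relative oscillation amplitude below 5% — a documented package choice
(the threshold is a parameter) that yields about three division cycles for
the default law. Only laws with rational Laplace transforms (Erlang /
exponential) are solved in closed form; `renewal_poles()` rejects others.

`renewal_rate_curve()` provides the independent time-domain check: direct
grid integration of the renewal equation started from a synchronized
newborn cohort. The default grid step of 0.02 min (horizon 160 min) keeps
the left-Riemann convolution bias well below the 5% comparison tolerance;
`oscillation_decay_rate()` fits the log-envelope through local extrema
between one and six division times, avoiding the initial transient on one
side and the integration's numerical amplitude floor on the other.

## Plate pipeline

The pipeline mirrors standard plate-reader practice: per-plate background
(mean raw OD across all wells at time 0; empirically plates sit around
0.099–0.121) is subtracted, and the subtraction is idempotent because the
corrected signal is always recomputed from raw readings. Quality control
flags wells whose *raw* OD exceeds 0.125 at 1 h — the signature of initial
condensation or a measurement artifact — and accepts a manual exclusion
list for failure modes (anaerobic growth, contamination) that cannot be
detected from the trace. Growth rates are ordinary least squares on
$\ln(\mathrm{OD})$ over a 30-min window centred on the interpolated
crossing of a threshold OD (default 0.03); wells are weighted equally in
the pooled rate. Crossing times always use linear interpolation between
bracketing samples: with 2–3-min read intervals, sample-and-hold would
bias times by up to one interval, unacceptable against TSDs of ~0.1 h.
Corrected OD values that are non-positive are masked for log operations,
never clipped. TSDs in division-time units are
$\sigma_t \mu/\ln 2$, which collapses organisms with different growth
rates onto a common curve.

The lag-phase diagnostic compares the deterministic lag-free time to reach
the CFU count at a threshold OD (via a linear OD–CFU standard curve,
calibrated on OD 0.01–0.6) with the mean observed crossing time. A planted
lag shifts the difference down by the lag duration. For exactly matched
parameters the diagnostic is *not* centred at zero for stochastic growth:
the mean stochastic crossing time exceeds the deterministic crossing of
the mean trajectory (convexity), so a small negative offset at zero lag is
the expected baseline — the tests assert exactly this, and a deterministic
fixture gives zero within grid tolerance.

## Synthetic plates

`generate_plate()` emulates the statistical structure the pipeline
assumes: per-well inocula (untruncated Poisson by default, so wells can
receive zero cells and never grow — the pipeline excludes and counts
them), stochastic growth, saturation, a linear OD-per-CFU map anchored so
OD 0.03 corresponds to $1.4 \times 10^7$ CFU, a per-plate baseline
(default 0.11) and additive Gaussian noise (default SD 0.001, a typical
reader resolution). Stochastic growth is simulated event-exactly up to a
cap (default 500 individuals) and continued deterministically at the
model's exponential rate — for the age-structured model, at the Malthusian
rate from the renewal analysis. Since contributions to the temporal
variance fall off as $1/n^2$, the variance not captured beyond the cap is
bounded by $\psi'(500)/\mu^2$, under 0.2% of the total for a single-cell
inoculum. Saturation passes abundance through unchanged below 40% of the
carrying capacity and applies a logistic slowdown above, so the sub-0.2-OD
regime used for rate estimation is exactly exponential. A planted lag
simply shifts the growth path in time. The generator does **not** emulate
condensation artifacts, evaporation, well-position effects, Beer–Lambert
nonlinearity, or mother–daughter division-time correlations — so passing
tests demonstrate correct recovery of the generating model, not robustness
to every failure mode of real plates.

## Numerical choices

* Binomial coefficients in the abundance pmf and FPT density are evaluated
  in log space (`lchoose`/`lgamma`); densities exponentiate last. Naive
  factorials overflow for $\Omega$ in the hundreds.
* Partial harmonic sums switch from direct summation (below
  $\Omega - n_0 = 10^3$, transparent and exactly equal) to
  digamma/trigamma differences, which stay exact and O(1) up to the
  $2 \times 10^7$-cell milk example and beyond.
* The zero-truncated series for $\mathrm{Var}(\ln M)$ is summed to
  $\mathrm{shape} + 12\sqrt{\mathrm{shape}} + 60$ with a checked tail
  bound below $10^{-13}$ of the mass.
* Zero-truncated Poisson draws use the inverse-CDF map through `qpois`
  above the mass at zero — exact at any shape and reproducible, unlike
  rejection.
* `abundance_pmf()` returns exactly 0 (not underflow noise) for $n < n_0$;
  degenerate inputs (non-positive rates, $n_0 \ge \Omega$, negative times)
  are rejected at construction.
* All samplers take a `seed` argument applied via `withr::local_seed()`,
  so runs are byte-reproducible and the caller's RNG state is untouched;
  the C++ simulator draws from R's RNG and obeys the same seeds.

## Problem sizes

The test suite and acceptance script use the protocol constants of the
models themselves — threshold 500, growth rate 1.66/hour, 25-min 20-stage
division law, inoculum grid 1–30 — with 2000–3000 replicates per
simulated point, $10^5$-draw Monte-Carlo oracles for closed forms, 42-well
synthetic plates, and a 400-repetition coverage study for the bootstrap
interval. These sizes were chosen so each statistical comparison has a
4-standard-error margin while the whole suite stays interactive.

## Known limitations

Pure-birth models only: no death, no steady-state fluctuation theory (the
TSD loses meaning when populations fluctuate around a carrying capacity).
The age-structured simulator draws division times i.i.d., ignoring
mother–daughter correlations and cell-size control, which can prolong
synchronization. The renewal solver covers Erlang/exponential laws only.
The plate pipeline ingests wide or long CSV with a well-metadata table;
reader-specific export formats must be converted upstream.
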