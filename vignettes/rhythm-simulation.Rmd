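---
title: "Simulating rhythmic abundance data and benchmarking rhythm detection"
author: "rhythmsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating rhythmic abundance data and benchmarking rhythm detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmsim)
```

## The model

Many biological systems — circadian gene expression above all — produce
measurements that oscillate in time. To evaluate how well an analysis method
separates rhythmic signal from noise, one needs data whose ground truth is
known. rhythmsim generates such data. The expected abundance of feature $i$
in condition $k$ at time $t$ (hours) is

$$
m_{ik}(t) = a_{ik}(t)\, f\!\left(\tfrac{2\pi}{\tau_{ik}}\,(t + \phi_{ik})\right) + b_{ik}(t),
$$

where $a$ is the amplitude, $f$ a periodic waveform with period $2\pi$
(default $\sin$), $\tau$ the period in hours (default 24), $\phi$ the phase
in hours, and $b$ the baseline. With constant $a$, $b$ and $f = \sin$ this
is exactly the cosinor model. Time-dependent $a$ gives damped rhythms;
time-dependent $b$ gives baseline drift. **Non-rhythmicity is defined by
$a = 0$** — that is what makes the negative class for detection
benchmarking unambiguous.

One convention deserves emphasis: the phase is *added* to $t$ inside the
waveform argument, so a positive phase shifts the waveform earlier, and a
sine rhythm peaks at $t = \tau/4 - \phi \pmod\tau$. Several popular rhythm
tools define phase with the opposite sign; `amp_phase_from_coefs()` and the
cosinor fit report phase in this package's convention, in hours on
$[0, \tau)$.

Measurements around $m$ come from one of two families:

* **Gaussian** — $Y \sim N(m, \sigma^2)$, $\sigma = 1$ by default. An
  idealized assay (microarray intensities, bioluminescence).
* **Negative binomial** — $Y \sim NB(\mu = 2^m,\ \alpha = g(\mu))$ with
  $\mathrm{Var}(Y) = \mu + \alpha\mu^2$, approximating RNA-seq read counts.
  Here $m$ lives on the log2-counts scale, so amplitude and baseline are in
  log2 counts. $\alpha = 0$ degenerates to Poisson. $m$ is capped at 62
  log2 units so that $2^m$ stays finite in double precision.

### The mean–dispersion curve

RNA-seq dispersion falls as expression rises. The default curve is the
two-parameter form

$$\alpha(\mu) = \alpha_0 + \alpha_1/\mu, \qquad \alpha_0 = 0.01,\ \alpha_1 = 2,$$

chosen because it is the standard parametric shape for RNA-seq
mean–dispersion trends: strongly overdispersed at low counts, approaching
the asymptote $\alpha_0$ at high counts, so prediction intervals shrink
(relative to the mean) as expression increases. $\alpha_0 = 0.01$ is a
typical asymptotic dispersion for a well-replicated bulk RNA-seq experiment
and $\alpha_1 = 2$ places the strongly-overdispersed regime below ~100
counts. Any function of $\mu$ can replace it (`dispersion =` in
`feature_group()`), including curves estimated from a user's own data with
DESeq2 or edgeR; estimating such curves is deliberately outside this
package's scope.

## Experimental designs

`design_spec()` supports three modes: evenly spaced time points
(`interval`, the default: 0–48 h every 3 h, 2 samples per time point —
17 distinct times, 34 samples), exact time points with per-time replicate
counts (`explicit`), and times drawn uniformly from a window (`uniform`,
continuous, not rounded). Designs are deterministic given the spec,
including the uniform-mode seed; uniform draws are independent across
conditions. When the window is not an integer multiple of the interval, the
sequence stops at the largest time point not exceeding the window's end.

```{r design}
build_design(design_spec())
```

## Simulating

```{r simulate}
groups = list(
  feature_group(3, amp = 0,   base = 8, family = "negbinom"),
  feature_group(3, amp = 1.5, base = 8, phase = 6, family = "negbinom"))
sim = simulate_rhythms(design_spec(interval = 2, n_per_timepoint = 1),
                       groups, seed = 1)
sim
head(sim$abundance)
```

`simulate_rhythms()` returns the long-format abundance table, the expanded
design, and a ground-truth feature table sufficient to recompute every
expected abundance exactly. Per-feature heterogeneity within a group is
expressed by passing vectors (`amp = runif(n, 0.5, 3)`, similarly `phase`,
`period`, `base`); condition-dependent rhythms by passing one group list
per condition (same group sizes and families in each). Everything is
reproducible: the same specification and seed give identical tables, and
seeded calls restore the caller's RNG state afterwards.

Prediction intervals (`prediction_interval()`) describe where a stated
fraction of *measurements* falls. Gaussian intervals are
$m \pm z_{(1+\ell)/2}\sigma$; negative binomial intervals use integer
quantiles of the count distribution, so their realized coverage is at least
the nominal level — discreteness makes them conservative, never
anti-conservative.

## Detecting rhythms and scoring detection

`cosinor_fit()` fits $y = \beta_0 + a\cos(2\pi t/\tau) + b\sin(2\pi t/\tau)$
by ordinary least squares and tests rhythmicity with the F-test against the
intercept-only model. Amplitude and phase derive from the identity
$a\cos\theta + b\sin\theta = c\sin(\theta + \varphi)$ with
$c = \sqrt{a^2+b^2}$, $\varphi = \pi/2 - \mathrm{atan2}(b, a)$. Counts are
transformed with `log_transform_counts()` (log2(counts + 1)) before
fitting; Gaussian data are used untransformed.

The package's built-in detector is this cosinor F-test. Published rhythm
benchmarks often score features with external detectors such as JTK_CYCLE;
those are separate tools, so `evaluate_detection()` exposes a `scores`
argument through which any detector's per-feature scores (larger = more
rhythmic) can be evaluated against the same ground truth, while the
built-in path keeps the pipeline self-contained.

Detection accuracy is summarized by AUROC — the probability that a randomly
chosen rhythmic feature outranks a randomly chosen non-rhythmic one, ties
counting one half (the normalized Mann–Whitney statistic). 0.5 is random,
1 is perfect.

```{r evaluate}
evaluate_detection(sim)
```

`detection_sweep()` maps AUROC against sampling interval, amplitude and
baseline in one call, simulating one negative binomial experiment per
interval with one replicate per time point over 0–48 h and one feature
group per (amplitude, baseline) cell, amplitude 0 included. Each rhythmic
group is scored against the pooled amplitude-0 features.

```{r sweep, eval = FALSE}
sw = detection_sweep(intervals = c(2, 4, 6), amps = c(0, 0.25, 0.5, 1, 2),
                     bases = c(2, 8), n_per_group = 200, seed = 85)
```

At this scale (2,000 genes per simulation) the sweep reproduces the
qualitative results expected of rhythm-detection power: AUROC rises with
amplitude, falls as the sampling interval widens, and rises with baseline
expression (because the SD of log-transformed counts of non-rhythmic genes
falls as baseline grows). Exact AUROC values depend on the detector and
the dispersion curve, so the test suite asserts these orderings rather
than specific numbers.

## Configurations and the command line

`load_config()`/`save_config()` read and write YAML configurations with
sections `seed`, `design` and `groups`; omitted values take the defaults
above, and unknown keys are errors. Because executing arbitrary code from
a config file is a safety hazard, functional parameters in configs are
restricted to registered built-ins with numeric arguments — waveforms
`sin`, `cos`, `square`, `triangle`; trends `constant`,
`exp_decay(value, rate)` ($a(t) = \mathrm{value}\cdot e^{-\mathrm{rate}\,t}$)
and `linear_drift(value, slope)` — while the programmatic API accepts any
R function. `run_simulate()` writes the abundance, ground-truth and
sample-metadata tables plus a manifest (seed, version, config echo);
`run_evaluate()` scores a written experiment. A thin command-line driver
wrapping these two functions ships at
`system.file("cli", "rhythmsim.R", package = "rhythmsim")`.

Abundances are written with 6 significant digits (counts as exact
integers) — compact, and finer than any tolerance used in validation.

## Numerical choices and degenerate inputs

* Waveforms are checked for $2\pi$-periodicity on a probe grid (tolerance
  1e-6) when a group is built.
* The cosinor fit requires at least 4 samples at 2 or more distinct times
  and errors on rank-deficient layouts (e.g., two distinct times cannot
  separate the cosine and sine terms at $\tau = 24$).
* Exactly constant input gives amplitude 0 and p-value 1; an exact
  noise-free fit gives a p-value clamped to the smallest positive double
  rather than 0, keeping p-values in (0, 1].
* $a = b = 0$ maps to amplitude 0, phase 0 by convention; fitted phases are
  reported modulo the period.
* AUROC ties count one half, matching the Mann–Whitney convention.

## What the simulation does and does not emulate

The generator reproduces the statistical properties its validation suite
measures: means and SDs of both families at dense sampling (0.1-h spacing,
100 samples per time point), the negative binomial mean–variance contract
$\mu + \alpha\mu^2$, cosinor-recoverable amplitude and phase, and
prediction-interval coverage. It deliberately does not model read-level
sequencing artifacts (positional bias, FASTQ generation), library-size or
normalization-factor variation, batch effects, missing samples, or
correlated noise across features — features are sampled independently.
Passing benchmarks here therefore speak to a detector's statistical power
under the stated noise families, not to its robustness against those
real-data complications.

## Validation scale

The test suite runs the dense-sampling validation with one feature per
parameter combination (n = 24,000 observations each), Monte-Carlo coverage
and moment checks at 100,000 draws, and the detection benchmark at 2,000
genes per simulation over intervals {2, 4, 6} h, amplitudes
{0, 0.25, 0.5, 1, 2} log2 counts and baselines {2, 8} log2 counts — sizes
at which the Monte-Carlo standard errors are small compared to every
asserted effect while the whole suite stays fast.
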