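---
title: "Space-time complexity analysis of EEG microstates: models and methods"
author: "mscomplexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-time complexity analysis of EEG microstates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscomplexity)
```

## The problem

Multichannel EEG can be read on two levels at once. Spatially, the scalp
potential field passes through brief (~80 ms) quasi-stable configurations —
*microstates* — so the recording can be compressed into a symbolic sequence
over a small alphabet of topographic templates. Temporally, each channel or
source-region series is a continuous signal whose irregularity can be
quantified directly. `mscomplexity` implements both halves: microstate
segmentation with six complexity measures of the resulting label sequence,
six complexity measures of continuous signals, sliding-window profiles of
either, and the group-statistics layer used to compare task conditions
(e.g. normal / low-light / noise environments in precision-aiming
experiments, where pre-trigger epochs of a few seconds are the unit of
analysis).

Because raw task EEG of this kind is rarely shareable, the package ships a
fully specified synthetic generator with known ground truth; every claim
the package makes about its own algorithms is tested against that ground
truth or against brute-force reimplementations of the definitions.

## Generative model of the synthetic data

A recording is built as

$$x(t) = a_t \, m_{s_t} + \varepsilon(t),$$

where $s_t \in \{1..K\}$ is a first-order Markov chain, $m_k$ are
zero-mean, unit-norm, mutually orthogonal channel maps, $a_t \sim
|N(1, 0.1^2)|$ is a per-sample positive amplitude, and $\varepsilon$ is
spatially independent $1/f^\alpha$ noise scaled so that the realized
signal-to-noise power ratio equals `snr_db` exactly.

Defaults mirror the study conditions the pipeline is designed for:
30 channels, $K = 5$, 250 Hz, 3 s pre-trigger epochs, dwell controlled by a
0.95 self-transition probability (~80 ms mean dwell at 250 Hz), $\alpha =
1$, 20 dB SNR, 30 subjects, three conditions, 60 trials per condition.
Orthogonal templates were chosen over loosely correlated random maps: the
recovery problem is only well posed when templates are mutually
distinguishable, and orthogonality realizes the pairwise
$|\mathrm{corr}| \le 0.5$ contract exactly with no rejection loop. All
randomness flows from a single seed through named sub-streams (sequence,
amplitudes, noise, per-trial), so every object is bit-reproducible.

What the generator does **not** emulate: volume conduction and realistic
forward head models, artifacts (blinks, EMG), non-stationary amplitude
envelopes, or spatially correlated noise. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration, not
robustness to every property of real scalp data.

## Preprocessing

The chain is fixed in order — zero-phase Butterworth band-pass (2–20 Hz
default for the microstate branch, 0.1–40 Hz for signal-level analysis),
anti-aliased integer decimation (e.g. 1000 Hz $\to$ 250 Hz), common
average reference — and is logged on the returned object. Filters are
specified by response contracts (mid-band gain within 5%, $\ge$ 20 dB
attenuation one octave above the upper edge) rather than by realization.
Epochs are cut over half-open spans `[trigger - 3 s, trigger)`; sliding
windows default to 1 s length and 0.2 s step, so a 3 s epoch yields 11
windows and window 5 covers 0.8–1.8 s.

## Microstate segmentation

1. **GFP.** The global field power is the spatial standard deviation of
   the potential across channels at each sample. Strict local maxima of
   the GFP curve supply the high-SNR "original maps".
2. **AAHC.** Polarity-invariant atomize-and-agglomerate clustering: every
   peak map starts as a singleton; the cluster contributing least global
   explained variance (GEV) is dissolved and its members reassigned by
   maximal $|\mathrm{corr}|$; prototypes are first principal components of
   member maps, so a map and its negation are interchangeable. For inputs
   above `max_maps` (default 1000) the maps are thinned by even
   subsampling, keeping the quadratic agglomeration affordable without
   biasing the time course.
3. **Per-K polish.** The partition snapshotted at each reported K is
   refined by a deterministic fixed-point iteration (reassign by max
   $|\mathrm{corr}|$, recompute prototypes, repeat until stable). The
   greedy agglomerative path occasionally merges two generating templates
   while keeping a split noise cluster; the polish repairs exactly this
   failure mode and leaves the path itself — and hence determinism —
   untouched. On synthetic data it raised worst-case template recovery
   from $|\mathrm{corr}| \approx 0.66$ to $\approx 0.89$.
4. **Model selection.** SSE(K) is the GFP-weighted squared residual of
   each training map against its assigned template at the least-squares
   amplitude (scaling keeps the measure polarity-consistent). The elbow is
   the K maximizing the discrete second difference of **log** SSE among K
   whose GEV reaches the 0.65 threshold. The log scale is deliberate: raw
   SSE curvature is dominated by the large early drops of the weighted
   curve, while the log statistic compares successive improvement
   *ratios* and is scale-free. Across three disjoint 20-seed families of
   the default 5-template scenario the log-scale elbow selected $K = 5$ in
   60/60 replicates, the raw-scale one in ~90%. Ties break to the smaller
   K; a curvature-free (geometric) decay falls back to the smallest
   admissible K with a warning.
5. **Back-fitting.** Every sample is labeled by the template of maximal
   absolute spatial correlation; ties go to the lowest index,
   zero-variance samples inherit the previous label (the first such sample
   gets label 1). No temporal smoothing is applied by default
   (`min_duration_ms = 0`), since the dwell structure itself is an object
   of study; an optional minimum-duration pass absorbs short runs into the
   better-correlated neighbour.

Conventional parameters (coverage, mean duration, occurrence rate,
run-level transition probabilities) are computed from contiguous runs of
the label sequence.

## Sequence complexity

Let $p_i$ be the empirical state frequencies, $p_{ij}$ the frequencies of
consecutive sample pairs and $p_{i \to j}$ the row-normalized transition
proportions. Pair counting happens at the sample level including
self-transitions by default — this keeps the metrics sensitive to dwell
time, which is where condition effects are expected — with a run-level
option (`include_self = FALSE`). Note one finite-sample subtlety: $p_i$ is
taken from symbol frequencies while the conditional rows are normalized
pair counts; the two marginals differ only by the sequence endpoint.

* **Ms-LZC** — LZ76 phrase count of the sequence over its native K-letter
  alphabet (no binarization), divided by the mean phrase count of 20
  seeded uniform reorderings. 1 for constant sequences (every permutation
  of a constant is itself) and for i.i.d. data; below 1 in the presence of
  temporal structure.
* **Ms-MIG** $= -\sum_{ij} p_{ij} \log_2 p_{i\to j}$ — expected surprisal
  of the next state; 0 for deterministic dynamics, $\log_2 K$ for i.i.d.
  uniform sequences.
* **Ms-FC** $= \sum_{ij} p_{ij} (\log_2 (p_i/p_j))^2$ — mean squared net
  information gain; 0 whenever the stationary distribution is uniform.
* **Ms-SE** $= -\sum_i p_i \log_2 p_i$.
* **Ms-ER / Ms-EE** — slope and intercept of the ordinary least-squares
  line through the plug-in block entropies $H_k$, $k = 1..6$ by default.
  $k$ is capped adaptively so that the number of blocks stays at least ten
  times the number of *observed* distinct blocks (with a warning);
  structured sequences therefore keep large $k$ while short random ones
  are fitted on the support they can estimate. With a single usable block
  length the convention is slope $H_1$, intercept 0. The slope is clamped
  at 0.

Conventions $0 \log 0 := 0$ and $0/0 := 0$ hold throughout.

## Signal complexity

* **LZC** — binarize at the median (falling back to $\ge$ when the strict
  comparison collapses a non-constant discrete signal, e.g. a ±1 series),
  LZ76 phrase count $C(N)$, normalized as $C(N)\log_2 N / N$.
* **SampEn** ($m = 2$, $r = 0.15$) — $-\ln(A/B)$ with Chebyshev matches,
  self-matches excluded; $r$ is a fraction of the signal SD (field
  convention; absolute mode available), floored at $10^{-12}$ so constant
  signals return 0. Zero matches yield `NA` with a warning — never a
  fabricated number.
* **PeEn** ($m = 5$, $\tau = 1$) — ordinal-pattern entropy normalized by
  $\log_2 m!$, forced into $[0, 1]$; ties break by temporal order (stable
  `order`).
* **Higuchi FD** (`kmax = 10`) — slope of $\ln L(k)$ against $\ln(1/k)$,
  clipped to $[1, 2]$ with a warning. `select_kmax` scans
  $k \in \{6, 8, \dots, 16\}$ and returns the first $k$ with
  $|D(k{+}2) - D(k)| < 0.02$, defaulting to 10.
* **WE / SFM** — geometric over arithmetic mean of the power spectrum,
  positive frequencies only, zero bins floored at $10^{-300}$. The PSD is
  a Bartlett average of up to 8 non-overlapping segment periodograms: the
  flatness of a *raw* periodogram converges to $e^{-\gamma} \approx 0.56$
  even for white noise (exponential ordinates), while segment averaging
  restores the near-1 reading a flat spectrum should produce.
* **SSV** — population variance of WE over 0.5 s subwindows at 50%
  overlap; indexes spectral-regime switching.

Minimum window lengths are enforced per metric when windowing (SampEn
requires 100 samples; requesting it on 25-sample windows is an error that
names the metric).

## Statistics layer

Subject-level values (trial means) enter a subjects × conditions table.
Assumption checks are advisory: Lilliefors-corrected Kolmogorov–Smirnov
per condition (parameters are estimated, so the plain KS null is wrong)
and Levene's test (mean-centered) across conditions. The omnibus test is
the classical one-way repeated-measures ANOVA,
$F = MS_\text{condition}/MS_{\text{condition}\times\text{subject}}$ with
$df = (c-1,\,(c-1)(s-1))$; omnibus p-values are Benjamini–Hochberg
corrected **across metrics**, and Scheffé contrasts (using the
repeated-measures error term, which the classical between-groups Scheffé
leaves unspecified) report pairwise direction strings uncorrected — both
choices are recorded in the output. Effect sizes use Cohen's d with bands
small < 0.2 ≤ moderate ≤ 0.8 < large; correlations use Pearson r with
bands low < 0.3 ≤ moderate ≤ 0.6 < strong and a reporting (not testing)
filter at $|r| > 0.45$.

Sample-size planning uses the noncentral-F "within factors" convention:
$\lambda = n\,m\,f^2/(1-\rho)$, $df = ((m-1)\varepsilon,\,
(n-1)(m-1)\varepsilon)$; the search returns the smallest $n$ reaching the
target power (28 at $f = 0.25$, $\alpha = 0.05$, power 0.8, $m = 3$,
$\rho = 0.5$, $\varepsilon = 1$).

One calibration subtlety: under a global null the "any metric significant
after BH" family rate is *conservative* (the six sequence metrics are
strongly positively dependent, and the BH global test is a Simes test,
exact only under independence). The package's calibration study therefore
reports both the per-metric raw rejection rate — which sits at the nominal
5% — and the family rate, which is bounded by it from below. Idempotence,
sometimes claimed for adjusted p-values, does not hold for the standard
step-up adjustment and is not asserted.

## Numerical choices and degenerate inputs

* Constant topographies have zero GFP; such samples cannot be labeled and
  inherit the previous label. Zero total GFP makes GEV undefined (error).
* SSE uses centered maps and unit-norm templates, so the least-squares
  amplitude is a plain inner product; residuals are
  $\|x\|^2 - a^2 \ge 0$ by construction.
* `log SSE` in the elbow is floored at $10^{-12}$ of the curve maximum so
  exactly-zero SSE (noiseless data) puts the kink at the first K reaching
  zero.
* `-0` from `-sum(...)` is normalized to `0`.
* All Monte-Carlo assertions in the test-suite fix their seeds; stochastic
  equivalence checks for Ms-LZC use common random numbers (the same
  shuffle ensemble through both parsers), which removes the Monte-Carlo
  wedge entirely before the 3-SE consistency check.

## Problem sizes

The test-suite and the acceptance script run at sizes chosen to make every
stochastic assertion stable: 60 s recordings for the 20-replicate
template-recovery study in the tests and 120 s in the acceptance script
(both comfortably above the point where recovery saturates), $10^5$
samples for transition-frequency convergence, 500 replicate null studies
of 10 subjects × 2 conditions for the calibration study, and 50 random
short inputs per metric for oracle equivalence.

## Known limitations

* AAHC is quadratic in the number of peak maps; very long recordings rely
  on the `max_maps` subsampling cap.
* Block-entropy estimates (Ms-ER/Ms-EE) are plug-in and biased downward on
  short sequences; the adaptive cap limits but does not remove the bias,
  and no Miller–Madow-type correction is applied.
* The EDF reader/writer supports the 16-bit single-record subset the
  package itself writes; it is not a general EDF(+) implementation.
* Sphericity corrections are taken as supplied ($\varepsilon = 1$ by
  default); Greenhouse–Geisser estimation is out of scope.
* Source localization is out of scope: region time series enter as plain
  signals.
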