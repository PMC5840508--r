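---
title: "Wavelet-information decoding of single-trial evoked potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-information decoding of single-trial evoked potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(WaveletInfo)
```

## The problem

Event-related potentials (ERPs) are stereotyped voltage deflections in EEG
or LFP recordings, time-locked to a stimulus. Because the evoked pattern is
typically several times weaker than the ongoing background activity, the
classical analysis averages many trials and then characterises the average
by its peak amplitude and latency. That summary discards information: the
*shape* of the response, combinations of components, non-peak features such
as DC shifts, and patterns distributed over channels can all differ between
experimental conditions without changing the peak.

`WaveletInfo` quantifies how much class information single trials carry by
*decoding*: each trial is classified from its waveform, and the proportion
of correctly classified trials — cross-validated so that no information
about a trial leaks into its own classifier — is the information measure.
The pipeline combines a multiresolution wavelet decomposition, an
information-driven feature selection, and a deliberately simple classifier.

## The model and its stages

### Haar multiresolution decomposition

Each epoch of $N$ samples is decomposed with an orthonormal Haar transform
into detail scales $D_1 \dots D_5$ plus a final approximation $A_5$,
yielding exactly $N$ coefficients
$X(a,b) = \langle x, \psi_{a,b}\rangle$ at dyadic scales $a_j = 2^j$ and
translations $b_{j,k} = 2^j k$. At 256 Hz the bands are approximately
64–128 Hz ($D_1$), 32–64, 16–32, 8–16, 4–8, and 0–4 Hz ($A_5$). Each
coefficient has a half-open time support $[k 2^j, (k+1) 2^j)$ samples, so
every post-stimulus sample is covered by exactly one coefficient per level.
The Haar wavelet is kept deliberately: the goal is not a faithful smooth
reconstruction but features that contrast conditions, and its scaled local
averages/differences are cheap, orthonormal and well localised.

Numerical conventions (declared choices, since several are conventions
rather than mathematics): L2 (orthonormal) normalisation, so Parseval
equality and perfect reconstruction hold to near machine precision and are
tested exactly; coefficient order $[A_5, D_5, \dots, D_1]$, time-ascending
within a block, which is part of the file contract; sign convention
positive-then-negative across each detail support; 0-based samples,
half-open windows in ms, $t = 0$ at stimulus onset. Non-dyadic epoch
lengths are an error by default; an optional symmetric-reflection padding
(`pad = "reflect"`) is available, and coefficients whose support lies
beyond the original epoch are excluded from selection, because silently
padding would distort the information estimates.

### Information-driven coefficient selection

Single-trial coefficients are too noisy for direct information estimation,
so each coefficient's mutual information with the class label,
$$I(S; w) = \sum_{s,w} P(s,w)\, \log_2 \frac{P(s,w)}{P(s)P(w)},$$
is estimated from bootstrap *sub-ensemble averages*: 200 averages per
class, each of 30 trials drawn with replacement from that class (trials may
recur within and across averages — the wording of the procedure admits both
readings and this is the one implemented). Averaging commutes with the
linear transform, so the package averages in coefficient space. Each
coefficient's sub-average values are quantized into $2^2 = 4$ equal-width
bins spanning their own min–max range — a parameter-free, scale-invariant
choice made here because the binning range is otherwise unspecified — and
the plug-in MI is computed from the empirical joint histogram. No bias
correction is applied: the estimate only has to *rank* coefficients. The 25
highest-information coefficients are selected, with a deterministic
tie-break (coarser level first, then earlier support, then channel order in
the `TrialSet`, then coefficient id) so results are reproducible and
invariant to the order channels are requested in.

With several channels the per-channel tables are pooled and the global
top 25 taken, so nothing forces the decoder to spread coefficients over
channels — an uninformative channel simply contributes none. The bootstrap
trial draws are shared across channels within a fold: a sub-ensemble is a
set of trials, and each channel contributes its average of that same set.

### Decoding

A uniform-prior naive Bayes classifier with one univariate Gaussian
likelihood per (class, coefficient) is fit on the selected coefficients and
evaluated under leave-one-out cross-validation. Critically, *selection is
redone inside every fold* on the remaining trials only, so the held-out
trial influences neither the feature set nor the fit; the package tests
this no-leakage property bit-exactly. The Gaussian family, the variance
floor ($10^{-9}\times$ the pooled variance; unit variance for a globally
constant feature) and the first-class tie-break are declared choices — only
"uniform-prior naive Bayes" is inherent to the method. Uniform priors are
implemented literally: class counts never enter the prediction.

Each fold's bootstrap draws come from an RNG substream seeded by
`(seed + 104729 * fold) mod (2^31 - 1)`, so folds are independent yet
individually reproducible; shuffles in the permutation test use an
analogous substream.

### Significance and localisation

Significance is assessed by rerunning the *entire* pipeline (including
per-fold selection) on 100 label permutations; the p-value is the
proportion of shuffle performances strictly above the observed one. The
strict reading is the default; `correction = "add-one"` gives
$(r+1)/(n+1)$ for users who need a nonzero p. The choice to rerun selection
inside each shuffle is conservative: the null then inherits any selection
optimism of the pipeline.

Because different folds may select different coefficients, the fraction of
folds selecting each coefficient (its *selection rate*) localises the
information: aggregated per channel and post-stimulus sample (averaging the
$L+1 = 6$ coefficients covering that sample), it maps where and when
discriminative activity lives.

## The synthetic benchmark

The simulator generates the four-class benchmark used throughout the test
suite: 100 trials per class, 500-ms post-stimulus epochs at 256 Hz (128
samples), each trial a class-specific sum of Gaussian components jittered
by a uniform ±5 ms latency shift and embedded in background noise three
times stronger than the pattern (per-trial SNR 0.33, enforced exactly by
rescaling each trial's noise against its own clean-pattern power).

The four class waveforms are chosen so that peak features cannot separate
them all: classes 1 and 2 share peak amplitude (1.0) and latency (150 ms)
and differ only in width (σ = 12 vs 35 ms, i.e. in shape); class 3 is a
smaller, later peak (0.8 at 210 ms, σ = 12); class 4 combines two Gaussians
(0.55 at 190 ms, σ = 12; 0.55 at 265 ms, σ = 18). These parameters are
package defaults, exposed through `defaultClassSpecs()`.

The background noise is a phase-randomised surrogate with target power
spectrum $f^{-1}$ plus a Gaussian alpha bump (centre 10 Hz, σ = 1 Hz,
height 2× the $1/f$ floor, so total alpha-peak power is 3× the floor) —
a stand-in with the amplitude/frequency character of resting EEG, including
an alpha rhythm. It is *not* a surrogate of any real recording: no real
EEG is shipped or required. Consequences worth knowing: the spectrum is
smoother and more broadband than a typical resting recording, which makes
the single-trial epoch maximum a comparatively stable estimator, so the
peak-amplitude baseline decodes somewhat better here (~47% across seeds)
than one should expect against real EEG noise; the wavelet pipeline itself
is insensitive to this (96% either way). The simulation also omits
artifacts (blinks, muscle), trial-to-trial amplitude variability and
autocorrelated non-stationarities, so passing the benchmark shows the
machinery is correct, not that any particular real dataset will decode.

On this benchmark the package reproduces the expected pattern (computed by
`scripts/acceptance.R` and the acceptance tests): wavelet-information
decoding reaches ~96% correct while peak amplitude alone stays near 47% and
peak amplitude + latency near 58%, against a four-class chance level of
25%; performance moves by less than 2 percentage points when the number of
sub-ensemble averages varies over 50–400 or when at least 1/8 of the
coefficients are selected.

## Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `nSelect` | 25 | coefficients fed to the decoder; ≥ 1/8 of the coefficients is stable on the benchmark |
| `nSubaverages` | 200 | bootstrap averages per class; performance flat over 50–400 |
| `trialsPerAverage` | 30 | trials per bootstrap average; controls sub-average SNR |
| `quantBits` | 2 | 4 equal-width bins; finer quantization does not help |
| `nLevels` | 5 | decomposition depth; bands listed above at 256 Hz |
| `seed` | 1 | master seed; every randomised stage derives substreams from it |
| `zThreshold` | 3 | baseline denoiser: post-stimulus coefficients below this z against the pre-stimulus distribution are zeroed |

## The peak baseline

The comparison method extracts each trial's peak amplitude (and optionally
latency) and feeds it to the same decoder under the same protocol. Trials
are detrended first (least-squares line removal). The published
single-trial denoising method it approximates is external to this package;
the shipped `denoiseTrials()` is a simplified stand-in that z-scores
post-stimulus coefficients per level against the pooled pre-stimulus
coefficient distribution and zeroes sub-threshold ones. It therefore
requires a pre-stimulus baseline; on purely post-stimulus epochs (like the
benchmark's) it degrades to the identity with a warning, and peak features
come from detrended raw trials. Peak search prefers an interior local
extremum and falls back to the window edge with an `edge` flag, since a
noisy trial may have no interior extremum of the right polarity.

## Degenerate inputs and numerical edges

* Constant coefficient values quantize to a single bin and contribute 0
  bits — never NaN ($0\log 0 = 0$ throughout).
* A feature constant across all training trials gets unit variance, making
  it uninformative rather than degenerate.
* Exact posterior ties predict the first class in model order,
  deterministically.
* SNR = `Inf` produces noiseless trials; zero jitter plus no noise makes
  all trials of a class identical — useful limits for testing.
* Epoch lengths must be divisible by $2^{L}$; `pad = "reflect"` handles the
  rest explicitly, never silently.

## Problem sizes

The shipped tests exercise the full benchmark (400 trials, 128 samples,
100 permutation shuffles, a 9-channel pooling experiment over 10 seeds);
property tests run on miniatures (32-sample epochs, tens of trials) chosen
to make brute-force oracles — explicit Haar basis matrices, hand-evaluated
MI sums, closed-form Gaussian posteriors — practical. The acceptance script
averages the benchmark over 5 seeds and uses the full 100-shuffle null.

## Known limitations

* The MI estimator is intentionally biased (plug-in, no correction); its
  values rank features and must not be reported as information content.
* The permutation p-value has resolution 1/100 at the default shuffle
  count; report `p < 0.01`, not `p = 0`.
* The simplified denoiser is not the published single-trial denoising
  algorithm and should not be used as one.
* Leave-one-out is the only cross-validation scheme provided, matching the
  method's definition; it is expensive for very large trial counts
  (decompositions are cached; selection is the per-fold cost).
* The simulator makes no attempt at artifacts or non-stationary noise (see
  above).
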