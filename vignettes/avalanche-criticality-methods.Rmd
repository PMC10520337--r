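---
title: "Methods: avalanche criticality analysis for sleep EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: avalanche criticality analysis for sleep EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sleepAvalanche)
```

# The analysis in one paragraph

Multichannel sleep EEG is z-score normalized per channel, and samples where
any channel's amplitude exceeds a threshold of `theta = 2` SD are clustered
into *neuronal avalanches*: maximal runs of consecutive samples with at
least one supra-threshold channel, bounded on both sides by all-channel-quiet
samples. Each avalanche has a duration `T` (seconds) and a size `s`
(integrated supra-threshold |z| over channels, in SD s). Criticality is
assessed by (i) maximum-likelihood fits of truncated power laws to the size
and duration distributions, P(s) ~ s^-tau and P(T) ~ T^-alpha; (ii) the
size-duration scaling law <s>(T) ~ T^k; (iii) the crackling-noise scaling
relation k = (alpha - 1)/(tau - 1); and (iv) a branching-parameter estimate
sigma. Mean-field directed percolation (MF-DP) predicts tau = 3/2, alpha = 2,
k = 2 and sigma = 1. Avalanche occurrence is then related to sleep
architecture through the sliding-window density F_av(t) and through phi
coefficients between the binary avalanche indicator and stage/CAP-phase
indicators.

# Detection conventions

*Threshold.* `theta` is in SD units of the z-scored signal; 2 SD is the
default because pooled amplitude histograms of burst-laden signals depart
from their Gaussian fit at about that scale (`gaussianityReport()` makes
this check; its `tolerance` is the relative density excess, default 0.2,
and "persistently" means the excess holds for 3 consecutive usable bins,
a bin being usable when the fitted density predicts at least 20 counts —
tail bins with fewer expected counts are too noisy to date an onset).
The comparison is strict (`|z| > theta`): amplitudes exactly at threshold
are measure-zero for continuous data and a convention must be fixed.

*Normalization.* z-scoring is a single global pass per channel over retained
(artifact-free) samples. Masked intervals keep their place on the time axis
so hypnogram and CAP alignment stays exact; masked samples are excluded from
moments, rasters, catalogs, densities and correlations.

*Size units.* The default size is the supra-threshold |z| summed over
channels and integrated over time (units SD s, `size_mode = "integrated"`).
Integration makes sizes comparable across recordings sampled at different
rates, which pooling requires; a raw per-sample sum (`"sample_sum"`) is
retained as an option. Only supra-threshold samples contribute, not the
whole excursion lobe.

*Truncation.* Avalanche boundaries are at sample resolution with zero gap
tolerance. Runs that touch a mask boundary or the first/last sample are
discarded: a clipped avalanche would bias both `s` and `T` downward.

*Branching parameter.* For detection catalogs, each avalanche is binned
from its onset (default bin width 4 samples) and sigma is the mean over
avalanches spanning at least two bins of (channel events starting in bin
2)/(channel events starting in bin 1), a channel event being one channel's
contiguous supra-threshold run. For branching-process samples, generations
are the bins with the seed as generation 0 (standard Galton-Watson
indexing), and sigma is the mean of Z2/Z1 over avalanches with at least one
descendant generation. This estimator is exactly unbiased
(E[Z2/Z1 | Z1 >= 1] equals the offspring mean), whereas counting the seed
as the first bin would condition on survival and inflate the estimate to
1/(1 - e^-1) ~ 1.58 at criticality.

# Fitting conventions

*Truncated power-law MLE.* The continuous density p(x) ~ x^-gamma on
[xmin, xmax] is fitted by 1-D numerical maximization of the exact truncated
log-likelihood; with `xmax = Inf` the estimate reduces to the Hill closed
form. Goodness is the Kolmogorov-Smirnov distance evaluated at the empirical
jump points (both one-sided limits). Model preference versus a truncated
exponential fitted on the identical support is the log-likelihood ratio R,
with a Vuong-type normal approximation for its significance. Integer-valued
samples (branching-process sizes and durations) are fitted with the
continuous likelihood; above xmin ~ 5 the discreteness bias is well inside
the tolerances used here.

*Headline fit ranges.* For detection catalogs the defaults are sizes on
[1, 800] SD s and durations on [0.03, 1] s — midpoints of the
systematic-error grids below, since exact headline ranges are a free choice.
Both are exposed in `pipelineConfig()`.

*Systematic error.* `systematicErrorGrid()` refits over xmin in
{0.5, 1, 2, 3, 4} (sizes) or {0.025, 0.03, 0.035, 0.04} s (durations)
crossed with 10 xmax values drawn uniformly from [550, 1000] and [0.7, 1.6] s
respectively; the SD of the exponents over the grid is reported as the
systematic error of the headline exponent.

*Scaling fit.* Durations are log-binned, the arithmetic mean size per bin is
regressed against the mean duration per bin in log-log coordinates. For
detection catalogs two regimes are fitted (below and above a 0.4 s
crossover, within 0.01 < T <= 5 s). For branching samples a single regime
over 15-150 generations is used: the critical Galton-Watson mean size
carries strong finite-duration corrections at small T (the local log-log
slope rises from ~1.4 at T ~ 4 to ~1.85 at T ~ 30 before settling near 2),
so fitting below ~15 generations reports a transient, not the scaling
exponent the relation k = (alpha - 1)/(tau - 1) refers to.

*Error propagation.* The scaling-relation check propagates exponent
uncertainties to the predicted k by the first-order delta method and flags
consistency when |k - k_pred| is below the combined one-sigma uncertainty.

# Architecture coupling conventions

*Indicators.* All indicators live on the recording's sample grid. Stage
indicators are the 30-s epoch labels upsampled to samples. A CAP *sequence*
requires at least `min_cycles = 2` consecutive A-B cycles with inter-phase
gaps of at most 60 s (the atlas convention; exposed as a parameter), and
NCAP is derived as NREM time outside CAP sequences rather than read from
file. Phi coefficients are computed over all retained samples of the
recording; an NREM-only restriction is available by masking.

*Density.* F_av(t) is the fraction of a sliding window (default
`u0 = 10` s, the order of the longest avalanches) occupied by avalanches,
with a default stride of one sample; `N_av` and `<T>` attribute avalanches
to windows by onset (unambiguous single-window assignment). Windows
intersecting masked time are invalid. The first/last N3 comparison takes the
first and last maximal contiguous N3 runs of the hypnogram and compares
their window densities with a two-sample t test.

# The synthetic-data suite

The generators provide ground truth for validation; they are calibrated to
a healthy-cohort sleep architecture but make no claim to reproduce real EEG.

*Branching process.* Fully connected Galton-Watson process with Poisson
offspring (`offspringMean` per active unit), seeded with one active unit,
absorbed at `nUnits = 10^4` simultaneous activations (a finite-size cutoff)
or after `maxGenerations = 1000` generations. At criticality this sits in
the MF-DP universality class, which is what makes it a parameter-recovery
oracle for the fitting stack. Durations are generation counts; `dtStep`
(default 0.01 s) maps them to seconds when needed.

*Hypnogram.* Semi-Markov epochs with the per-cycle visit pattern
N1 - N2 - N3 - N2 - REM and exponential dwells (1-epoch minimum). Dwell
means are derived from target stage fractions of sleep time
(N1 7.23%, N2 48.47%, N3 23.99%, REM 20.30%) over a 90-min cycle; a night
is `nCycles = 5` cycles. Exponential dwells make single-night stage
fractions genuinely variable (as real nights are); checks that compare
realized fractions or dwells against their targets therefore use long
simulated nights (20-200 cycles) so the Monte-Carlo error is inside the
tolerance being tested.

*CAP.* Within each maximal NREM run, NCAP gaps (exponential, floored at
61 s so that distinct sequences never merge under the 60-s rule) alternate
with sequences of 2 + Poisson(7.6) A-B cycles (mean ~9.6 cycles). Phase
durations are lognormal, clipped to the scoring bounds [2, 60] s, with
means 8.59 s (A) and 20.67 s (B); A subtypes are drawn per sleep stage
(A1-dominant in N3, A3-dominant in N1, mixed in N2). Gap means are set so
the expected CAP rate matches the per-stage targets
(N1 41.7%, N2 48.4%, N3 53.4%). There is no REM CAP by construction.

*Surrogate recording.* I.i.d. standard-Gaussian background per channel with
injected bursts: Poisson onsets whose rate is `baseRate` (0.3/s) times a
stage multiplier (W 0.1, N1 0.5, N2 1, N3 2, REM 0.3) times a CAP-phase
multiplier during NREM (A1 3, A2 2, A3 1.5, B 0.25, NCAP 0.35). Bursts span
a random quarter of the channels with a random sign per channel, have
power-law durations (exponent 2 on [0.2, 3] s), and an envelope
`amplitude * (0.6 + 0.4 sin(pi u))` with `amplitude = 8` SD. Two numbers
behind these defaults:

- *Amplitude.* Injected power inflates the per-channel SD, so the detector's
  2-SD threshold moves up in raw units after z-scoring. With 8-SD bursts the
  envelope floor stays near 3 post-normalization SD, making the probability
  that background noise pushes a burst sample below threshold small enough
  that injected intervals are recovered essentially intact (the
  interval-wise Jaccard criterion).
- *Phase multipliers.* The sign of phi(avalanche, NCAP) is the sign of the
  NCAP-conditional injection rate minus the whole-night mean rate, and the
  mean rate depends on the realized stage composition. With mild suppression
  (NCAP ~0.6) a REM-heavy night can flip the sign; the chosen values keep
  the NCAP- and B-conditional rates below the night mean for any REM share
  up to ~70%, so the injected sign pattern is identifiable on every
  realistic night rather than on average.

What the surrogate does *not* emulate: EEG spectra (no spindles,
K-complexes, alpha, delta oscillations), channel correlations, arousals,
non-stationary noise floors, or any physiological claim about what CAP
phases do to real cortical dynamics. Passing the end-to-end checks
demonstrates that the pipeline recovers known injected structure, not that
real sleep EEG behaves this way.

# Degenerate inputs and edge policies

Zero-variance channels abort normalization (named in the error). Catalogs
with no avalanche spanning two bins cannot yield a branching estimate.
Scaling regimes with fewer than three populated bins report a missing
exponent. Fit-range cells with fewer than 10 tail samples are rejected
(and recorded as missing inside systematic-error grids, with a warning).
Constant indicators make phi undefined and error. CAP phases outside
[2, 60] s load with a warning (annotation dialects differ); overlapping
phases are an error. A first/last-N3 comparison with constant densities
reports NA statistics rather than failing.

# Problem sizes

The shipped tests run the branching recovery at 1.5 x 10^5 avalanches, the
acceptance script at 2 x 10^5, and the end-to-end coupling checks on a
2-cycle night sampled at 128 Hz over 8 channels (the validation suite uses
a full 5-cycle night); these sizes put the Monte-Carlo error of every
checked quantity well inside its stated tolerance.

# Known limitations

Exponent error bars from single fits are not reported (only KS distance,
LLR and the range-variation systematic error); no lognormal or
stretched-exponential competitors; no avalanche shape collapse; no fit of
the cutoff's functional form; the EDF writer emits 16-bit, 1-s records and
requires an integer sampling rate.
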