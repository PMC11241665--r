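---
title: "Models and methods behind gabapool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gabapool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabapool)
```

`gabapool` analyzes inhibitory postsynaptic currents (IPSCs) recorded in
whole-cell voltage clamp and estimates presynaptic vesicle-pool parameters
from them. This vignette explains the models the package implements, the
tunable constants and why their defaults are what they are, what the
synthetic generator does and does not emulate, and the numerical choices a
maintainer would want spelled out.

## The recordings and their units

All analyses operate on `sweep_trace` objects: regularly sampled membrane
current in pA, time in ms, charge in pC. With a high-chloride internal
solution, GABA~A~ currents are inward at the holding potential, so IPSCs are
negative-going; every reported amplitude and charge is a magnitude, and
charge integration rectifies toward the event polarity so that noise
excursions above baseline cannot cancel event charge. Charges are preferred
over amplitudes for evoked responses because compound IPSCs are often
irregularly shaped; the charge integral is robust to that.

Baselines are medians, not means: a median over a 10-20 ms window is
insensitive to a spontaneous event that happens to fall inside it. Stimulus
artifacts are blanked by linear interpolation over 0.5 ms per stimulus, a
typical field-stimulation artifact width.

## Miniature IPSC detection

The detector has two stages. Candidate onsets are samples where the smoothed
current derivative crosses `k_deriv` (default 3.5) times a MAD-based noise
scale in the inward direction; a threshold run that contains several clearly
separated derivative minima is split, which resolves event pairs down to
about 0.4 ms. Candidates are then confirmed by normalized cross-correlation
(`c_min`, default 0.5) against a template built from nominal event kinetics.
The correlation window is aligned at the event *peak*, not the onset: under
noise the onset estimate jitters by a few samples and onset-aligned
correlation collapses, while peak alignment is stable. Large candidates
(amplitude at least `amp_bypass_k` = 8 noise SDs) skip the template gate
entirely — the gate exists to reject near-threshold noise shapes, and it
would otherwise spuriously reject genuine events riding on a neighbour's
decay.

With the default constants the detector recovers 99-101% of generated
events at rates between 5 and 20 Hz with a false-positive rate of
0.02-0.04 Hz on pure noise. Frequency is the detected count divided by the
recording duration, with no correction for missed events. Events with a
neighbour within 25 ms are counted for frequency but excluded from waveform
averaging.

## Decay kinetics

IPSC decays are fitted with the standard double exponential
$y(t) = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2}$ under $a_i \ge 0$,
$\tau_1 < \tau_2$. The fit is seeded from a log-spaced grid of
$(\tau_1, \tau_2)$ pairs with amplitudes solved linearly, and the best five
starts are refined by Levenberg-Marquardt; when the second component does
not reduce the residual, the single-exponential solution is returned with
$a_2 = 0$.

One numerical choice matters: the synaptic waveform is a rising phase
multiplying the decay, so the first few hundred microseconds after the
trough are *not* biexponential. Fitting from the trough sample biases
$\tau_1$ upward by several percent. The fit therefore starts where the decay
has fallen to 85% of the trough magnitude (`start_frac`) and the amplitudes
are back-extrapolated to the trough; with the default rise time constant of
0.15 ms this keeps the $\tau_1$ recovery error below 0.6%. Group-level
kinetics are fitted on each cell's mean trough-normalized waveform
(peak-aligned average of non-overlapping events), which suppresses noise
without biasing the time constants, since normalization removes amplitude
variability.

Rise times use the 20-80% convention with linear interpolation between
samples.

## The generative model

The simulator is a minimal two-pool quantal release model chosen to be the
simplest scheme consistent with the phenomena the analyses measure: a
tightly docked pool of `n_tight` vesicles (capacity `n_max`), binomial
release per stimulus with effective probability
$p_k = \min(1, p_{rel} + F_k)$, additive facilitation
$F \leftarrow (F + \Delta F)\,e^{-\Delta t/\tau_F}$, Poisson replenishment at
`replenish_rate` between closely spaced stimuli (gaps up to 20 ms), and
exponential relaxation of the pool back toward `n_tight` with
`recovery_tau` across longer gaps. Released charge is `q_charge` per vesicle
with lognormal amplitude jitter (CV `amp_cv`); a fraction `tonic_fraction`
of each stimulus's charge is spread as a slow exponential (τ = 50 ms)
asynchronous current instead of the fast kernel; Gaussian recording noise is
added; evoked responses follow the stimulus at a fixed 2.5 ms synaptic
latency. Spontaneous events are a homogeneous Poisson process at
`mini_rate`. The deterministic engine propagates expected values (real-valued
pool), and its per-pulse release sequence is the exact oracle against which
the trace-level pipeline is tested.

Every simulated cell derives its own RNG substream from a master seed via a
documented integer splitting rule (`derive_seed`), making cohorts
bit-reproducible.

### Condition presets and their calibration

`pool_preset()` ships one parameter set per condition ("sham" and "bbbd",
the post-stroke blood-brain-barrier-disruption condition). The directly
observable parameters are taken from the reported group medians: mini rates
20.25 and 12.15 Hz and fast decay constants 1.52 and 1.11 ms. The release
parameters cannot be read off directly, so they were calibrated by a coarse
grid search on the deterministic recurrence, refined through the full
trace-level pipeline: for each condition, the facilitation increment was
solved so the deterministic paired-pulse ratio at 10 ms equals the reported
median (1.27 sham, 1.58 BBBd), and the release probability and
replenishment-per-interval fraction were scanned so the phase-1
back-extrapolated intercept lands on the reported 1.89 and 1.23. The shipped
values are sham: $p_{rel} = 0.20$, $\Delta F = 0.1269$, R = 6000 vesicles/s;
BBBd: $p_{rel} = 0.10$, $\Delta F = 0.0888$, R = 4080 vesicles/s; both with
$\tau_F = 40$ ms.

Both presets share `n_tight` = 1200 and `n_max` = 1600, because the emulated
experiment reports the size of the *entire* readily releasable pool as
unchanged — the condition difference lives in release probability and
facilitation, which is exactly what the phase-1 intercept is sensitive to. A
pool of 1200 corresponds to a compound connection (many boutons recruited by
field stimulation); it also keeps the binomial sampling noise of a 12-cell
cohort median within the tolerances used in the tests. The quantal charge
0.14 pC makes a single quantum a ~40 pA event, so detection operates at
~13x the 3 pA noise floor. `tonic_fraction` = 0.25 is a free choice — the
emulated experiment observes a tonic component but does not quantify it.

### What the generator does not emulate

Between-cell heterogeneity: every simulated cell in a cohort shares the
preset parameters, so cohort spread reflects only counting and recording
noise, which is much narrower than the biological IQRs reported for real
cells. Group comparisons on simulated cohorts are therefore almost always
significant; passing them shows the pipeline's sensitivity, not realistic
statistical power. Also absent: series-resistance and dendritic filtering,
non-stationary noise, electrical artifacts, receptor saturation and
desensitization, and calcium-dependent mechanisms behind facilitation and
recovery — the model is phenomenological.

Because the minimal model couples the late-train asymptote to $1/p_{rel}$,
the phase-2 intercepts of the two presets differ even though the emulated
experiment reports them similar; phase-2 quantities are deliberately not
calibration targets.

## Evoked analyses

The input-output calibration interpolates the stimulus strength producing
65% of the plateau response. Failures are automated (peak below 3x noise SD
in the 2-20 ms post-stimulus window) in place of the visual inspection used
at the rig. The paired-pulse ratio is amplitude-based: the first response's
decay is fitted over the pre-second-stimulus segment and extrapolated under
the second response, and the second amplitude is measured after subtracting
that tail. At a 10 ms interval this overlap correction is essential — two
identical superposed responses measure at PPR = 1.00 with it, and
substantially above 1 without it. A charge-based ratio over matched windows
is reported alongside. One paired sweep per interval per cell is analyzed;
group statistics run across cells.

## Train analysis: RRP size and replenishment

The core computation decomposes a 100-pulse, 100 Hz train into tonic and
phasic components, accumulates the per-pulse phasic charges, and fits two
lines to the cumulative series.

The tonic envelope is the piecewise-linear interpolation through anchors,
each the median of the 0.5 ms immediately preceding a stimulus relative to
the pre-train baseline; the phasic trace is the remainder. Per-pulse phasic
charge is the rectified integral from each stimulus (plus 0.5 ms blank) to
the next, capped at 10 ms so recovery pulses are measured over the same
window as train pulses; kernel tails that outlast the window land in the
next pulse's window, which keeps the per-pulse charges proportional to the
released quanta without explicit tail subtraction.

The cumulative series is normalized to the first response's charge, making
every y-intercept dimensionless ("first-response equivalents") — the units
in which the reported intercepts (1.89/1.23) are reproduced. Cells whose
first pulse is a failure cannot be normalized and are excluded with a flag.
The time axis places the train onset one inter-stimulus interval before the
first pulse, so that a train of identical responses extrapolates to exactly
zero; with this convention a purely depleting train back-extrapolates to the
pool size in first-response units (asymptote $1/p$), which is what the
intercept is meant to estimate. Default windows are pulses 2-10 (first
steep phase: the tightly docked, immediately releasable subset) and 60-100
(second slower phase: the whole readily releasable pool, slope =
replenishment rate). An optional automatic breakpoint minimizes the
two-segment SSE over breakpoints in pulses 5-50; the default fixed windows
are used for all reported numbers. When the early slope is not steeper than
the late one the fit is flagged rather than rejected.

Recovery pulses at 25-3000 ms after the train are expressed as
$(Q_{rec} - Q_{ss})/(Q_1 - Q_{ss})$, clipped to [0, 1.5], and fitted with
$1 - e^{-t/\tau_{rec}}$. Two caveats are documented rather than hidden: in
the sequential protocol each recovery pulse re-depletes the pool, and slow
kernel tails leak into neighbouring windows, so the fitted
$\tau_{rec}$ from a single sweep is a biased estimate of the generative
refill time constant. The estimator itself is validated on isolated
recovery intervals (one simulated train per interval) with a fast kernel,
where it recovers the generative 500 ms within 20%.

## Statistics

Group comparison follows a fixed recipe: Lilliefors-corrected
Kolmogorov-Smirnov normality test on each group (the correction is required
because mean and SD are estimated from the sample; `nortest::lillie.test`
provides it); if both groups pass at α = 0.05, a pooled-variance Student's
t-test, otherwise a two-sided Mann-Whitney U test — exact by enumeration
when the combined sample is at most 16 without ties, normal approximation
with tie correction otherwise. Groups are reported as median [Q1, Q3] with
linear-interpolation quartiles (R type 7); no multiple-testing correction is
applied, matching the emulated workflow. Constant samples are declared
non-normal by convention.

## Problem sizes used in the shipped checks

The test suite and the acceptance script size their simulations to what the
statistics require rather than to the full experimental durations wherever
the quantity under test permits: frequency-recovery cohorts use 20 cells at
the full 100 s; detector bias uses 25 seeds of 20 s; replicate-cohort power
checks use 15 s spontaneous recordings (the group effects do not depend on
recording length); paired-pulse and train cohorts use 12 cells, one sweep
per cell, as in the emulated design.

## Known limitations

* The tonic/phasic split assigns any slow pedestal — including accumulated
  slow kernel tails — to the tonic component; with slowly decaying kernels a
  few percent of phasic charge is misattributed.
* The phase-1 window (pulses 2-10) is a convention; the "first steep phase"
  is not sharply defined, and the auto-breakpoint option exists precisely
  because of that ambiguity.
* Vesicle-scale RRP estimates require the quantal charge; in normalized
  units the estimates are scale-free and cannot distinguish a larger pool
  from a proportionally larger quantum.
* The simulator's cohorts lack biological between-cell variance (above), so
  simulated p-values say nothing about power in real data.
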