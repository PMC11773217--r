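---
title: "Models of resonant song recognition in crickets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of resonant song recognition in crickets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cricketsong)
```

## The scientific problem

Male crickets produce pulsed calling songs; females recognize conspecific
song by the temporal pattern of pulses and pauses. Behavioral tuning is
measured as a *pulse-pause field* (PPF): the strength of female phonotaxis
over a two-dimensional lattice of pulse duration $D$ and pause $P$, with
period $T = D + P$ and duty cycle $DC = D/T$. Most cricket species have
a single preferred region of this plane. The trilling species
*Anurogryllus muticus* is an outlier: females respond around the male song
period $T_s \approx 8.6$ ms (duty cycles roughly 33--80%), *and* at twice
that period -- strongly at high duty cycle, weakly at low duty cycle. Such
responses at integer multiples of a fundamental period are the signature of
a *resonant* recognition mechanism.

This package implements the computational analysis of that phenotype:

* rectangular pulse-train stimuli and PPF construction from behavioral
  tables (`render_pulse_train()`, `interpolate_field()`, transects);
* four candidate mechanisms -- delay-line autocorrelation, post-inhibitory
  rebound with coincidence detection, rebound plus feedforward inhibition,
  and a resonate-and-fire neuron (`autocorr_response()`,
  `rebound_response()`, `ffi_response()`, `rf_simulate()`);
* a five-neuron model of the cricket song-recognition network
  (`anurogryllus_network()`, `simulate_network()`);
* a leaky integrate-and-fire neuron with adaptation that can isolate
  individual resonant peaks (`lifac_field()`);
* multi-start Nelder-Mead fitting of any model to a preference field
  (`fit_model()`) with a parameter-recovery harness;
* a Monte-Carlo analysis of song-period clustering across the genus
  (`overlap_analysis()`).

## Stimuli and the phonotaxis prediction

Stimuli are rectangular envelopes with amplitude 1: `pulse_ms` of sound,
`pause_ms` of silence, repeated for 400 ms (natural trills last seconds,
but all model dynamics play out within tens of milliseconds, so a short
train with trimmed edges suffices). The predicted phonotaxis score of a
model response $r(t)$ is its average over the train excluding the first
25 ms and last 10 ms,
$p = \frac{1}{D_s - 35\,\mathrm{ms}}\int_{25}^{D_s-10} r(t)\,dt$,
which removes onset and offset transients. Fitting uses all
$(D, P)$ combinations on a 0.5 ms lattice from 0.5 to 20 ms -- 1600
stimuli. The lattice starts at one step rather than zero because a 0 ms
pulse is no stimulus and a 0 ms pause is a tone; the printed stimulus
count (1600) is preserved.

## The minimal models

**Autocorrelation** (`autocorr_params()`): the envelope is multiplied with
a copy of itself delayed by $\Delta_{ac}$ and scaled,
$r(t) = g_{ac}\, s(t)\, s(t - \Delta_{ac})$. Coincidence occurs whenever
$nT = \Delta_{ac}$, so period tuning shows peaks at *all* integer
fractions $\Delta_{ac}/n$, and responses grow with duty cycle (long pulses
overlap more), reaching their maximum for continuous tones. Both
properties disagree with the behavior, which lacks peaks at odd fractions
and dislikes very high duty cycles; the model's role is to show that a
delay alone yields resonance. The fitted delay (17 ms, i.e. $2T_s$) is the
default.

**Rebound** (`rebound_params()`): the core mechanism of the cricket
song-recognition network. The non-delayed pathway is sign-inverted and
filtered with a bi-phasic kernel (inhibitory rectangle $g_i, T_i$ followed
by excitatory rectangle $g_e, T_e$); the rectified result is a transient at
each pulse *offset* -- a post-inhibitory rebound -- which is multiplied
with the delayed envelope. Coincidence needs $nT + D \approx \Delta_{rb}$,
so peaks sit near $(\Delta_{rb} - D)/n$. Duty-cycle tuning becomes
band-pass: the rebound saturates once the pulse outlasts the inhibitory
lobe, and very short pauses truncate it.

Two numerical choices matter here. First, the kernel is applied in
*reversed time*, `conv(-s, rev(k))`: applied literally in forward time the
printed double negation places the positive transient at pulse onset and
silences continuous tones, while the reversed orientation produces onset
inhibition, an offset transient saturating at $g_i T_i$, and the
documented reduced-but-nonzero tone response. Second, discrete kernel
lobes are height-scaled so that each lobe's integral equals
$\mathrm{gain}\times\mathrm{duration}$ exactly at any sample rate, and
delays are applied with fractional-sample linear interpolation. Integer
rounding of delays and lobe supports makes the fitting objective piecewise
constant (0.25 ms plateaus at the 4 kHz fitting rate), which traps the
simplex search; the smooth discretisation removes those plateaus without
changing the model.

**Rebound + feedforward inhibition** (`ffi_params()`): a delayed copy of
the envelope passes through a second bi-phasic filter; its *negative*
components are added to the coincidence output and the sum is rectified.
Because the inhibition is delayed by $\Delta_{ffi} \approx 7$ ms while the
rebound-coincidence excitation is tied to the longer $\Delta_{rb}$, the
two inputs collide for duty cycles near 50% at twice the song period and
miss each other at lower and higher duty cycles -- reproducing the
suppression of intermediate duty cycles that the pure rebound model lacks.
When fitting this model only the five feedforward parameters move; the
underlying rebound parameters stay fixed.

**Resonate-and-fire** (`rf_params()`): a single neuron with coupled
current-like and voltage-like variables,
$\dot x = b x - \omega y + g_s s(t)$, $\dot y = \omega x + b y$, spiking
when $y \ge 1$ and resetting to $(0, 1)$. Inputs arriving in the positive
phase of the intrinsic oscillation (frequency $f_{rf}$, fitted 109.34 Hz,
period 9.15 ms) amplify it; inputs in the negative phase suppress it. The
model therefore responds at integer *multiples* of its characteristic
period but not at fractions, and at twice the period its duty-cycle tuning
is bimodal with a null at 50% (a pulse spanning one full oscillation
engages both phases equally).

Numerical choices: integration is semi-implicit Euler at 0.1 ms ($x$ is
updated first and the new $x$ drives $y$). The explicit update inflates
the oscillation amplitude by $\tfrac12(\omega\,dt)^2$ per step -- about
2.4%/ms here, overwhelming the weak fitted damping ($b = -5\times10^{-4}$
per ms) and erasing selectivity -- whereas the semi-implicit form is
neutrally stable. Spike detection uses upward-crossing semantics: because
the printed reset places $y$ exactly at threshold, a naive $y \ge 1$ test
would retrigger every step; the detector re-arms only once $y$ falls below
threshold. The spike train carries area `spike_amp` per spike so that its
integral is sample-rate invariant.

## The five-neuron network

`anurogryllus_network()` builds the rate-based network AN1 → {LN2, LN3},
LN2 → {LN5, LN4}, LN5 → LN3, LN3 → LN4: AN1 relays the envelope, LN2
provides inhibition, LN5 generates the rebound, LN3 detects
rebound/delayed-AN1 coincidence, and LN4 combines LN3 excitation with LN2
feedforward inhibition. Each neuron is a cascade of delayed, gain-scaled
synaptic inputs, linear filter lobes, static nonlinearities and divisive
normalization ($a$ a first-order low-pass of the signal;
output $= x/(x_0 + w\,a)$). The published account of this model gives the
constants but not the functional forms, so the forms here are declared
package decisions: Gaussian and exponential lobes are area-parameterized
(kernel integral = gain, which keeps the printed sigmoid shift and relu
thresholds inside their stages' operating ranges), the differentiated
Gaussian spans its stated duration with positive-lobe area equal to its
gain, and the inhibitory LN2→LN5 connection applies the printed magnitude
with negative sign. The 45 parameters marked free (`n_free_params()`)
match the published count; fixed entries are the two 1000 ms lobe
truncations, zero rectifier thresholds, divisive-normalization offsets,
and the near-delta width of LN5's rebound lobe.

A known limitation, established by a systematic scan of normalization
conventions: with these declared forms the LN5 rebound is smeared by its
$\tau = 17.3$ ms exponential lobe, the effective delay between LN3's two
inputs (`effective_ln3_input_delay()`) comes out near 19.5 ms rather than
$\approx 25$ ms, and the simulated period tuning does not develop clean
peaks at $T_s$ and $2T_s$. The acceptance suite states the published
network signature and reports its failure rather than adjusting the
printed constants; the rebound + feedforward-inhibition minimal model
demonstrates the same two-stage mechanism and does pass its checks.

## Isolating resonant peaks with adaptation

`lifac_field()` drives a leaky integrate-and-fire neuron with adaptation
(LIFAC) with the instantaneous rebound-model output:
$\tau_m \dot V = -V + I - A$, $\tau_{ada}\dot A = -A$, with $A \mathrel{+}= \alpha$
at each spike and a 1 ms refractory period; the total spike count passes
through a rectifier with threshold $\theta_{relu}$. The single drive gain
was calibrated once to 7, placing the neuron in a near-threshold regime
where the membrane time constant decides which resonant line of the
rebound field survives: a fast membrane ($\tau_m = 8.8$ ms) follows the
narrow rebound transients of the $\approx 9$ ms line, a slow membrane
($\tau_m = 12$ ms) attenuates them below threshold while the wider
transients of the $\approx 17$ ms line still spike. Changing one cellular
parameter thus moves the preference between discrete peaks without
crossing intermediates -- the proposed substrate for saltatory evolution
of song recognition.

In this regime the neuron fires at most about one spike per pulse (tens
of spikes per 400 ms train), so the published spike-count thresholds
(125 and 72) exceed any attainable count; no drive scaling we could
construct yields both the time-constant selectivity and counts of that
order, because far above threshold the count becomes adaptation-limited
and proportional to mean drive, erasing the membrane's influence. The
thresholds are kept as printed in `lifac_presets()`; the time-constant
switch is checked on raw counts.

## Fitting and parameter recovery

`fit_model()` minimizes the mean-squared error between predicted and
target scores over the stimulus lattice with Nelder-Mead, in log-parameter
space (all fitted parameters are positive; the damping magnitude is
optimized for the resonate-and-fire model). Restart 0 starts from the
hand-chosen initial vector; further restarts perturb it with seeded
log-normal jitter (default relative sd 0.1, 8 restarts). `n_rounds`
enables staged optimization in which each round warm-starts from the best
parameters so far: restarting the simplex escapes the shallow valleys
created by the near-degenerate trade-off between a lobe's gain and its
duration. Fits are bit-reproducible given the seed.

Recovery behavior, measured by refitting each model to its own generated
field: autocorrelation and rebound parameters return within 10% from
starts 30% away (the rebound needs 3 staged rounds). The
resonate-and-fire model does not fully recover: its own field is zero on
99% of the lattice and the output is an integer spike count, so the
objective is piecewise constant; the frequency returns to a fraction of a
percent, but gains stall near 15--18% and the damping -- whose entire
effect over the 365 ms window is below count quantization -- is not
identifiable from this target.

## Synthetic data

`synth_preference_field()` builds an Anurogryllus-like target as a sum of
Gaussians in (period, duty-cycle) space: a broad peak at $T_s = 8.6$ ms
centred at DC 56% (its $\pm 2\sigma$ span covers DCs 33--80%), a strong
peak at $2T_s$/DC 90% and a weak one at $2T_s$/DC 25%, with amplitudes
1.0/0.9/0.4 and spreads of 1.5 ms and 0.12 DC; an optional weak harmonic
peak at $T_s/2$ is off by default, matching its non-significance in
behavior. These constants are fixture choices emulating the relative peak
strengths, not measured values. `synth_phonotaxis_table()` adds the
behavioral sampling structure: 3--8 females per stimulus, per-female
Gaussian score noise deliberately not clipped (real phonotaxis scores can
fall below 0 or exceed 1). What the generator does not emulate: per-female
motivation drift, playlist structure, and the irregular stimulus placement
of real experiments -- so green tests certify the pipeline's arithmetic on
realistic structure, not the behavior of any real animal.
`synth_song_waveform()` gates a sinusoidal carrier (7 kHz by default) with
the pulse envelope for exercising segmentation and carrier estimation.

## Preference-field construction

`interpolate_field()` triangulates the stimulus coordinates (Bowyer-Watson
Delaunay) and interpolates linearly within each triangle -- exact at the
data points, continuous, and local. Grid nodes outside the convex hull
take the score of the nearest record; negative interpolated scores are
clipped to zero. Natural-neighbor interpolation is the reference algorithm
for this step; the Delaunay-linear interpolant satisfies the same contract
and is used here because no installed interpolation backend provides
Sibson weights. Transects read the field bilinearly along lines of
constant duty cycle (period tuning) or constant period (duty-cycle
tuning). `peak_significance()` compares per-female scores at a candidate
peak against a reference stimulus with a paired one-sided t-test; when the
paired differences have zero variance the degenerate limits (p = 0, 1, or
0.5) are returned with a warning rather than NaN.

## Song segmentation

`segment_song()` mirrors the recording analysis: square the waveform,
low-pass at 200 Hz (4th-order Butterworth, applied forward-backward so
pulse onsets are not biased), take the square root, normalize to peak 1,
and threshold at 12.5% (midpoint of the 10--15% range used in practice).
The 200 Hz cutoff bounds temporal resolution near 2.5 ms: pulse *periods*
are recovered to within 0.3 ms, while individual durations are widened by
the envelope smoothing at low thresholds (at the 50% threshold the
widening cancels and the conspecific duty cycle of 60% returns).
`carrier_frequency()` takes the magnitude-spectrum argmax above 500 Hz.

## Genus-level overlap analysis

`overlap_analysis()` asks whether the song periods of seven Anurogryllus
species cluster inside the resonant response bands of *A. muticus*
females ($6.5 \le T \le 9$ and $13.5 \le T \le 17$ ms, both ends closed).
Species with individual measurements contribute n draws from
Normal(mean, own sd) -- a declared stand-in for unpublished specimen
values, and the reason the observed overlap is reported as an average over
seeds with a tolerance of a few percentage points; the four species with a
single reported period contribute 10 draws each with the *A. muticus* sd
(0.3 ms), for 68 songs in total. The null draws 68 periods uniformly on
[0, 40] ms, 100,000 times; the analytic check is mean $= 6/40 = 15\%$ and
sd $= \sqrt{0.15\cdot 0.85/68} \approx 4.3$ points. The tail probability
of the observed overlap uses a Gaussian approximation of that null. Note
that with the binomial sd of 4.3 points, an observed overlap of 45% sits
at $z \approx 6.9$, a tail probability of order $10^{-12}$ -- just above
a strict $10^{-12}$ bound, which is met only when the null sd is rounded
down to 4 points; the acceptance suite keeps the strict bound and records
the miss.

## Reproducing the analyses

`scripts/acceptance.R --seed N --out results.json` recomputes the null
moments, the observed genus overlap, and the fitted autocorrelation delay
on the synthetic field from scratch. The test suite
(`tests/testthat/`) contains the per-module unit and property tests,
independent oracles (interval-arithmetic coincidence, step-by-step Euler
reimplementations, closed-form filters), and the acceptance checks at the
tolerances stated above. Sizes used throughout -- 400 ms trains, the 1600
stimulus lattice, 100,000 Monte-Carlo trials, 4 kHz (rebound family) and
10 kHz (autocorrelation, spiking models) simulation rates -- are the study
conditions of the analysis.

## Known limitations

* The five-neuron network reproduces structure and parameter bookkeeping
  but not the published tuning signature under our declared filter forms
  (see above); its claims are kept visible as failing acceptance checks.
* The resonate-and-fire recovery is limited by count quantization, and its
  response bands are narrow (a fraction of a millisecond at $2T_{rf}$), so
  lattice-based fields undersample them.
* Segmentation reports durations widened by the 200 Hz envelope at low
  thresholds; periods are unaffected.
* The genus analysis resamples three species from summary statistics;
  exact per-specimen values would shift the observed overlap by a few
  percentage points.
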