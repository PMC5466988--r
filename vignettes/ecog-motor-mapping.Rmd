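---
title: "Mapping motor cortex from ECoG: temporal and spectral alteration maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping motor cortex from ECoG: temporal and spectral alteration maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecogmap)
```

## The problem

During awake craniotomy, surgeons localise motor cortex before resecting
a lesion. The clinical reference is direct electrocortical stimulation
(DECS), which is time-consuming and can trigger seizures. A passive
alternative is to read the functional map out of the electrocorticogram
(ECoG) itself while the patient performs a simple cued movement (a brisk
wrist extension): electrodes over the hand motor area express a
movement-related cortical potential (MRCP) — a slow (0.05–3 Hz)
negativity time-locked to movement, consisting of a readiness ramp, a
sharp motor potential (MP) peaking roughly 100 ms after EMG onset, and a
rebound — and task-locked spectral power changes: a decrease in the
mu/beta range (8–32 Hz, event-related desynchronisation) and sometimes
an increase in the gamma range (66–90 Hz).

`ecogmap` implements both read-outs as tested, reusable code:

* the **temporal map**: per-trial correlation of each channel against a
  500 ms MRCP template, summarised per channel by a signed $R^2$;
* the **spectral map**: task-versus-rest band power contrast summarised
  by a signed activation weight $A$;
* **evaluation** of either map against stimulation ground truth
  (confusion counts, sensitivity/specificity, Yates $\chi^2$),
  Gaussian-kernel topographic maps, and a clinical risk partition;
* a **synthetic generator** producing multichannel ECoG + EMG with
  known effect channels, so every stage is testable without patient
  data (none is publicly deposited for this protocol).

## The temporal map, step by step

Channels with gross artifacts are excluded, the rest are re-referenced
to the common average (CAR). The continuous data are band-pass filtered
to 0.05–3 Hz with a 2nd-order Butterworth filter and cut into epochs
from −2000 to +4000 ms around each EMG onset (time zero). Filtering is
**zero-phase** (forward–backward): the scoring below compares waveform
latency against a template, and a causal filter would delay the MP peak
by a latency that depends on frequency content. The effective magnitude
response is therefore the squared single-pass Butterworth response,
which is what the package's tests check against the analytic formula.

Per channel, the grand average over trials is baseline-corrected by the
mean of the first 400 ms of the epoch (−2000…−1600 ms). One
*representative* channel per subject — the one whose baseline-corrected
grand average has the largest peak absolute amplitude within 0–500 ms —
contributes to the template; the template is the 0–500 ms post-onset
segment (MP + first movement-related response) of the mean
representative waveform. Ties go to the lowest channel index, and a
peak below a configurable floor (default 5 µV) flags the selection as
low-confidence rather than failing, so a pure-noise array still returns
a diagnosable result.

For every trial $i$ the *task* component (0–500 ms) and the *rest*
component (−2000…−1500 ms) are correlated with the template $y$ by the
Pearson coefficient, giving vectors $q$ (task-CC) and $t$ (rest-CC) of
equal length $n$. Per-trial components enter the correlation raw:
Pearson correlation is offset-invariant, so per-trial baseline
subtraction would be a no-op. The channel statistic is the signed
$R^2$, a between-group over total sum-of-squares with the grand
correction term

$$G = \frac{(\sum q + \sum t)^2}{2n}, \qquad
R^2 = \frac{(\sum q)^2/n + (\sum t)^2/n - G}{\sum q^2 + \sum t^2 - G},$$

signed by $\operatorname{sign}(\bar q - \bar t)$. The magnitude equals
the squared point-biserial correlation between the pooled correlation
values and their group label — the package tests pin this equivalence
against an independently coded oracle to $10^{-10}$. Because the
template is a *negative-going* potential, channels expressing the MRCP
correlate better in task than rest, so a positive $R^2$ means a
negative cortical potential; this is the sign convention the clinical
maps use.

Significance is a balanced one-way ANOVA of $q$ versus $t$ — an $F$
test with $(1, 2n-2)$ degrees of freedom, related to the statistic by
$F = |R^2|/(1-|R^2|)\,(2n-2)$ — Bonferroni-corrected by the number of
channels actually analysed (not the array's nominal size). A channel is
positive when the corrected $p < 0.01$.

Cross-validation uses `loso_template()`: the template for one subject
is the mean of the other subjects' representatives.

## The spectral map

Per trial, a 1 s *task* segment (0–1000 ms after onset) and a 1 s
*rest* segment (−3500…−2500 ms) are extracted; the spectral epoch
therefore starts at −3500 ms, and `map_recording()` re-epochs rather
than reusing the temporal window. Each segment yields a single
Hanning-tapered FFT power spectrum at 1 Hz resolution (no Welch
averaging — one taper per 1 s segment). Because the ECoG spectrum
follows a power law, raw band sums would be dominated by the lowest
bins; every spectral sample is therefore divided by the mean over the
whole ensemble (all task and rest segments together) at that frequency
and log-transformed:

$$\tilde P(f, \tau_q) = \ln P(f, \tau_q) -
\ln \frac{1}{N}\sum_{p=1}^{N} P(f, \tau_p),$$

which forces the per-frequency mean of $e^{\tilde P}$ over segments to
one — an invariant the tests check to $10^{-10}$. Band sums are
inclusive over integer-Hz bins: 8–32 Hz (mu + beta, LFB) and 66–90 Hz
(gamma, HFB, placed to avoid 50 Hz line contamination); each is 25 bins
wide.

The per-channel, per-band statistic contrasts the task band sums $m$
with the rest band sums $r$:

$$A = \operatorname{sign}(\bar m - \bar r)\,
\frac{(\bar m - \bar r)^2}{\sigma^2_{m \cup r}}\,
\frac{N_m N_r}{N_{m \cup r}^2}.$$

Two numerical conventions are deliberate. First, the denominator is the
**variance** of the pooled sample: only that reading makes $A$ the
"signed squared cross-correlation" it is described as, bounded by
$[-1, 1]$ (an SD denominator would break both the bound and dimensional
consistency). Second, the pooled variance uses the **population**
(divide-by-$N$) convention, under which two constant groups of equal
size evaluate to exactly $\pm 1$; the point-biserial oracle test pins
this choice. Desynchronisation gives $A < 0$, synchronisation $A > 0$.

Significance mirrors the temporal map (balanced ANOVA on the band sums,
corrected $p < 0.01$). Bonferroni is **per band across channels** by
default; correcting across bands × channels is available via
`correction = "pooled"` because the published wording ("across
channels") does not resolve the pooling. The ANOVA input is the
per-segment band *sums* (not means), matching the stated computation. A
channel is spectrally positive when either band is significant.

## Evaluation against stimulation

An electrode counts as stimulation-positive when its centre lies within
6 mm of a DECS-positive site (the operational rule; the 10 mm margin
cited in the clinical literature is display guidance only, not the
inclusion rule). Test-versus-truth sets give the 2×2 confusion counts,
sensitivity $100A/(A+C)$ and specificity $100D/(B+D)$, and a chi-square
independence test with Yates continuity correction — the correction is
on by default because it is the reading under which the published
worked examples reproduce, which the package verifies against R's
reference `chisq.test` implementation. The critical value at
$\alpha = 0.001$, df = 1 is 10.83.

Topographic maps place a truncated spherical Gaussian kernel (support
diameter 25 mm) at each significant electrode, scaled by its weight
(signed $R^2$ or $A$; non-significant electrodes contribute zero). The
stated kernel width $\sigma = 0.4$ carries no units; it is interpreted
here in units of the kernel radius, i.e. $\sigma = 5$ mm physical, and
is configurable. The raster defaults to 0.5 mm/pixel.

Combining the maps, electrodes positive under both methods are
*functional-convinced*; electrodes positive under exactly one are
*functional-high-risk* (candidates for confirmatory stimulation).

## What the generator emulates — and what it does not

`sim_config()` defaults restate the recording protocol: 2,000 Hz
sampling, a 4×8 grid of 4 mm contacts at 10 mm pitch, 40 trials at
inter-trial intervals uniform in 5–16 s. Per-channel content:

* **Background**: $1/f^{\alpha}$ noise (default $\alpha = 2$, the
  power-law regime of ECoG spectra) with the amplitude spectrum
  flattened below a 0.5 Hz knee — measured cortical spectra flatten at
  low frequency, and an unbounded power law would put essentially all
  variance into infra-slow drift. Broadband SD 40 µV.
* **Mu/beta rhythm**: band-limited (8–32 Hz) noise, SD 10 µV, on every
  channel — sensorimotor rhythms are widespread. On ERD channels its
  amplitude is multiplied by $(1 - d)$ (default depth $d = 0.5$, i.e.
  power drops to 25 %) during the task second, with 100 ms cosine
  ramps; the multiplicative construction guarantees a band power
  decrease without altering broadband level.
* **Gamma component**: 66–90 Hz noise, SD 3 µV, carried only by ERS
  channels and amplitude-scaled by $(1 + g)$ (default $g = 1$) during
  the task second. Elsewhere gamma content is just the 1/f background,
  matching the broadband view of ECoG gamma.
* **MRCP**: a deterministic sum of smooth components — readiness ramp,
  negative MP Gaussian peaking at +100 ms, positive rebound — scaled to
  100 µV (reported intracranial MRCPs reach 150–200 µV), with
  trial-to-trial amplitude (±20 %) and latency (±25 ms) jitter shared
  across channels, added on the MRCP cluster. The waveform is
  band-limited by construction (>99 % of its energy below 3 Hz); only
  its timing and band limitation are contractual, not biophysics.
* **EMG**: a noise floor plus a ~1 s burst at each onset, rising within
  10 ms so the one-tenth-of-maximum threshold rule recovers the onsets.
* **50 Hz line noise** defaults to off (the recording amplifier's notch
  is assumed); an optional saturation-clipping mode emulates amplifier
  overload but its realism is untested.

Amplitudes are calibrated analytically from the spectral shape rather
than normalised per realisation, so component sums can be synthesised
in a single FFT and identical seeds give bit-identical recordings; the
generator never touches the caller's RNG state.

The generator does **not** model volume conduction, electrode
impedance, cortical geometry or biophysical dipoles; channels are
conditionally independent given the shared evoked waveform. Ground
truth (`decs_positive`) is the MRCP cluster by construction. A green
parameter-recovery test therefore establishes that the pipeline
recovers known effects at realistic SNR under this idealised world — it
does not establish clinical performance, inter-subject variability, or
robustness to the artifact types an operating room produces.

One knock-on effect of the common average reference is worth knowing:
with a small array, the reference subtracts a fraction of the evoked
potential from every channel, so channels *without* an MRCP carry a
small inverted copy. At the default amplitudes this stays comfortably
below the Bonferroni threshold on essentially all null channels, but it
is the mechanism behind the occasional false positive in the recovery
experiment — on real grids the same arithmetic applies.

## Numerical choices and degenerate inputs

* Sample indexing is 0-based; epoch windows are half-open
  $[\text{onset} - \text{pre}, \text{onset} + \text{post})$, so the
  sample at epoch index $\text{pre}\cdot f_s/1000$ *is* the onset
  sample.
* Trial rejection automates the visual screening the clinical protocol
  used: the per-trial peak absolute amplitude is scored by a robust
  z (median/MAD), threshold 5 by default; data are masked, never
  deleted. A MAD of zero falls back to an epsilon denominator so a
  gross spike among otherwise identical trials is still caught.
* Onset detection rectifies the raw EMG (absolute value) and applies a
  4 s refractory period, just below the shortest plausible inter-trial
  interval (5 s).
* Zero-variance trial components yield an undefined correlation; the
  affected trial is dropped from both $q$ and $t$ to preserve balance,
  and a channel with more than half its trials dropped is marked
  unanalysable rather than scored.
* A degenerate (zero-variance) template — e.g. representatives that
  cancel — raises an error at correlation time rather than propagating
  NaNs.
* The CAR is computed after channel exclusion and before filtering,
  following the order the protocol describes; the published text does
  not resolve CAR-versus-filter order, and for a linear chain the
  difference is nil up to edge effects.
* Whether the representative's "largest amplitude" means peak-to-peak
  or peak negativity is unstated; peak *absolute* amplitude within
  0–500 ms is used. Grand averages are baseline-corrected before
  cross-subject averaging for the template (implied but not explicit in
  the source protocol).
* `filtfilt_zero_phase()` handles edges with odd-reflection padding and
  steady-state initial conditions; `bandpass_mrcp()` uses a 10 s
  padding because the 0.05 Hz edge settles slowly. Trials are epoched
  far from recording edges, so this affects only the margins.

## Null calibration

The test suite checks that under a zero-effect simulation the
uncorrected type-I rate of both channel ANOVAs stays at the nominal 5 %
(within two binomial standard errors over ~1000 channel tests). For the
temporal map the null experiment uses a fixed canonical template rather
than the recording's own representative: a template estimated from the
same trials it scores is slightly correlated with its task segments
even under the null, which would inflate the rate — the fixed-template
setup mirrors the clinical cross-subject use (the cross-validated
variant), where template and test data are independent.

## Known limitations

* The EDF reader/writer supports the subset the package writes
  (continuous 16-bit records, one sampling rate); EDF+ annotations are
  not parsed — events travel as CSV.
* Single-trial real-time MRCP detection, source localisation,
  broadband spectral decomposition and phase-coupling measures are out
  of scope.
* The evaluation assumes electrode sets, not probabilistic maps; the
  raster is for display and the risk partition, not for inference.
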