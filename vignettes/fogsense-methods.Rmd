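---
title: "Methods: FOG detection, phenotyping and muscle decoding in fogsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FOG detection, phenotyping and muscle decoding in fogsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogsense)
```

## The problem

Freezing of gait (FOG) is a paroxysmal inability to generate steps in
Parkinson's disease — patients describe their feet as glued to the ground.
Clinically it appears in at least two phenotypes: *trembling in place*
(alternating knee tremor with no forward progression, associated with a
higher fall risk) and *shuffling forward* (short quasi-periodic shuffling
steps with minimal displacement). `fogsense` analyses recordings from
shank-worn devices that sense, per leg and per muscle (tibialis anterior,
TA, and gastrocnemius, GC), the z-axis angular velocity of the shank
(gyroscope, degrees/s) and the surface EMG of the muscle under the device.
Three questions are answered per recording: *when* did the patient freeze
(step-level detection), *which phenotype* was it (spectral fusion of both
legs), and *what were the antagonist muscles doing* (activity type and
intensity decoding).

## Signal model and units

A `signal_trace` is one uniformly sampled channel; a `recording_session`
bundles the bilateral multi-muscle trace set with interval annotations
(closed label vocabulary: `regular_gait`, `shuffling_fog`,
`trembling_fog`, `rest`, `turning`). Files are plain CSV with a `t_s`
time column and `side_muscle_channel` headers. All channels of a session
share one sampling rate; heterogeneous-rate files are linearly
interpolated onto a common grid at load time. The canonical processing
rate is 200 Hz: every quantity the algorithms consume lives below 10 Hz,
so 200 Hz preserves the full algorithmic content while keeping the suite
fast. Traces entering the detector are normalized with respect to their
absolute maximum, which makes every threshold below dimensionless and
subject-independent.

## Preprocessing

The sEMG conditioning chain is the conventional one: high-pass at 3 Hz
(hum and motion artifacts), full-wave rectification, normalization to the
rectified maximum, low-pass at 10 Hz. The result — the *envelope* — lives
in $[0, 1]$ and quantifies activity intensity. Exactly this order
(rectify, normalize, then smooth) is kept, so the envelope peak can sit
slightly below 1 after smoothing. Filter family and order are not dictated
by the method itself; we use 4th-order Butterworth filters, applied
zero-phase (forward–backward) in offline mode so envelope maxima stay
aligned with gyro events, and causally (single-pass) in streaming mode.
Zero-phase runs pad the trace by odd reflection (up to 1 s per side)
because the recursive filter's start-up transient would otherwise
contaminate the edges. Two numerical guards follow from this choice:

* an input with no content above the high-pass cutoff (e.g. pure DC)
  leaves only the filter transient behind; if the rectified maximum is
  below $10^{-3}$ of the input scale the envelope is returned as all
  zeros rather than normalizing numerical residue to full scale;
* envelope samples driven negative by filter ringing are clipped at 0
  (and overshoot above 1 at 1) so every downstream ratio sees a bounded
  nonnegative denominator.

The gyro trace is smoothed with a centered moving average of 0.1 s
(edges shrink to the valid range). The window length is a free parameter:
0.1 s sits well below the ~200 ms FOG step-attempt scale and well above
the sensor noise scale. A separate zero-phase 3 Hz low-pass "gait view"
is provided for inspection only; the detector never consumes it.

## Step-window detection and the R index

Let $\overline{g}$ be the smoothed normalized gyro trace and
$\mathrm{ABS} = |\overline{g}|$. A *step window* opens at the first
sample where ABS passes from at-or-below to above $T_1 = 0.01$ and closes
where it returns to at-or-below $T_1$ (half-open sample interval). When
ABS never exceeds $T_1$ the subject is at rest and no window exists.
Windows shorter than 0.05 s are threshold chatter and are dropped; an
unterminated final window is dropped offline and reported as open by the
streaming interface.

For each window the index
$$R = \frac{\max(\mathrm{ABS})}{\mathrm{sEMG}\big|_{t = t_{\max(\mathrm{ABS})}}}$$
is the ratio of the window's peak normalized angular velocity to the
envelope value at the same instant. Regular swing phases pair a large
gyro peak with a relaxed TA (large $R$); shuffled or attempted steps pair
a small angular velocity with active muscle (small $R$). One systematic
error must be removed first: the stance phase of a *regular* step also
crosses $T_1$, and at its ABS peak the muscle is active (toe-off), which
would mimic FOG. In regular steps the stance gyro lobe is much deeper
than during FOG, so windows whose $\overline{g}$ minimum is at or below
$T_2 = -0.4$ are recognized as regular-stance lobes and skipped — no $R$
is computed for them. For all other windows, $R \ge 3$ (the demarcation
level) classifies the step as regular and $R < 3$ as FOG.

Numerical choices: the envelope denominator is floored at $10^{-6}$ so a
silent instant cannot divide by zero (the resulting $R$ is finite and
huge, i.e. confidently regular); a tie $R = 3$ resolves to *regular*,
because a missed-FOG alarm suppression (false positive for gait) is the
smaller error class here and the rule must be explicit either way.

Consecutive FOG windows separated by at most 1 s are merged into
*episodes*, kept when at least 2 windows long. This aggregation is an
artifact of this package (the step-level classification is the method's
core output); both parameters are exposed in `detector_config()`.

### Normalization scope, offline vs streaming

Whole-recording max-normalization is inherently offline. The streaming
mode resolves this with a calibration prefix (default 10 s) that fixes
the normalization constants, after which the per-window computation uses
only samples inside the window — which is what makes the ~200 ms
real-time claim coherent. On identical normalized input, the chunked
streaming segmentation and the offline one produce identical window
boundaries and $R$ values; this is asserted in the suite. Synthetic
sessions carry the generator's full-scale reference
(`meta$gyro_full_scale_dps`) so that even a rest-only recording keeps a
meaningful threshold scale; when absent, the observed maximum is used and
every statistic is invariant to a common positive rescaling of the raw
gyro.

## Phenotype index

Phenotyping fuses both legs in the frequency domain, per episode:

1. pointwise product of the normalized TA envelope and the normalized
   gyro trace of each leg — during shuffling the sEMG maxima coincide
   with the gyro minima, so the product is a train of negative peaks;
   during trembling it varies randomly around zero;
2. linear-phase FIR low-pass at 2 Hz (101 taps, Hamming, unity DC gain,
   group delay compensated) — shuffling content lies below 2 Hz;
3. right-minus-left subtraction — shuffling legs move in antiphase, so
   their fundamentals reinforce; trembling legs are uncorrelated, so
   nothing coherent survives;
4. one-sided power spectral density of the difference;
5. the phenotype index
   $$PI = \frac{\max(\mathrm{PSD})}{\mathrm{geomean}(\mathrm{PSD})}$$
   over the band $(0, 2]$ Hz.

$PI$ is a peak-to-flatness ratio: a single dominant line drives it far
above 1, an incoherent spectrum keeps it near 1. It is invariant to
uniform amplitude scaling and always $\ge 1$.

Choices made where the method leaves the estimator open: the PSD uses
Welch's method (4 s Hann segments, 50% overlap, per-segment mean
removal) for episodes of at least 8 s and a plain mean-removed
periodogram otherwise (the periodogram path satisfies Parseval exactly
and is used for the suite's energy checks). The DC bin is excluded from
the band — the product has a systematic offset that would otherwise
dominate the maximum and deflate $PI$ for shuffling. PSD values are
floored at $10^{-12}$ inside the geometric mean so an exact zero cannot
produce $-\infty$. The decision level is $PI \ge 20$ for shuffling:
reference average values for the two phenotypes are roughly 109 vs 3,
whose geometric midpoint is ≈ 18.6, rounded to 20 and exposed in
`phenotype_config()`. Episodes shorter than 2 s are not phenotyped
($PI$ would rest on fewer than a handful of band bins). The FIR design
note: at 200 Hz a 101-tap Hamming design has a transition band several
Hz wide, so the passband is gently sloped (gain ≈ 0.94 at 0.7 Hz); this
is immaterial for $PI$, which is a ratio within the band, and the suite
asserts the realized response against the design's closed form rather
than against an idealized brick wall.

## Muscle activity type and intensity

The envelope quantifies *intensity* but not *type*. The type —
contraction vs stretching — is read from the low-frequency portion of the
raw sEMG (below 10 Hz, i.e. the band the envelope chain deliberately
discards): positive sign means contraction, negative stretching. The raw
trace is low-pass filtered at 10 Hz, normalized, and decoded with a
deadband of ±0.05: within the deadband the muscle is quiescent. A raw
sign rule would flicker at every zero crossing, hence the deadband. The
normalization reference is floored at 20% of the raw-signal scale so a
recording without genuine low-frequency content (e.g. pure carrier-band
activity) decodes as quiescent instead of amplifying filter residue into
spurious labels.

Step-aligned analysis extracts segments of 1 s after each anchor
(step-window starts by default — the method's alignment is not otherwise
pinned down), resamples each to a fixed length of 200 points (time
normalization, linear interpolation) and ensemble-averages them
pointwise (mean ± SD). `gc_deficit_summary()` condenses the GC pattern
per annotation label into the fraction of samples decoded as stretching
and the mean intensity, which is the quantitative form of the toe-off
deficit: during trembling-in-place FOG the GC stays essentially
stretched at very low intensity while the TA alternates.

## The synthetic generator

No raw patient recordings are published for this class of device, so the
package ships a seeded generator that encodes the *described morphology*
of each condition, not any patient's numbers. It is the test substrate
for every other module; its defaults define the study conditions of the
validation suite and were fixed once, up front:

* **regular gait** — 1.2 s cycles; per cycle one positive raised-cosine
  swing lobe (default peak 300 dps) followed by a negative stance lobe of
  0.7× that depth (range-checked to stay ≥ 0.5 so stance minima stay
  below $T_2$ after normalization); TA raw sEMG with two bursts at the
  swing edges (the mid-swing gap is what makes swing $R$ large), mild
  activity near the stance peak, and a GC toe-off burst; legs half a
  cycle apart;
* **shuffling** — a train of shallow single negative gyro lobes (0.55 s
  period, default depth 45 dps ≈ 0.15 normalized, minima above $T_2$),
  one sEMG burst per shuffle peaking at the gyro minimum, legs in
  antiphase; the period puts the bilateral fundamental (~1.8 Hz) inside
  the $(0,2]$ Hz analysis band;
* **trembling** — band-limited (3–8 Hz) zero-mean gyro noise at 8 dps
  RMS (normalized amplitude ≲ 0.1), TA with an alternating-sign 1.5 Hz
  low-frequency component and moderate intensity, GC with a constant
  negative type component at very low intensity, no left/right phase
  relation;
* **rest** — sensor noise floors only (0.5 dps and 0.01 mV), an order of
  magnitude below $T_1$ after smoothing and normalization.

Raw sEMG is built as `intensity_profile × band-limited (20–80 Hz) noise
carrier + type component + noise floor`, so the envelope chain and the
type decoder see consistent, independently controllable signals. The
generator emits its gyro full-scale reference in the session metadata
(the subject's regular swing scale; the largest regular-segment swing
amplitude in the script, 300 dps when the script has none).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: electrode-contact and motion artifacts, hum,
inter-subject amplitude and cadence variability beyond the parameter
ranges, turning, festination, gradual transitions between conditions
(segments switch instantaneously at annotated boundaries), and any
biomechanical coupling between the gyro and sEMG channels beyond the
phase relationships described above. The synthetic performance figures
are therefore engineering checks of the implementation against its
specification, not clinical performance estimates.

## Validation problem sizes

The suite exercises, among others: 1000 random traces against a
brute-force linear-scan segmentation oracle; pooled batteries of 10
seeded sessions with ≈ 500 FOG steps and 500 regular gait cycles for the
step-level statistics; 20 seeded episodes per phenotype class for the
$PI$ separation; ±50% amplitude perturbations of the generator defaults;
and closed-form checks of the moving-average and FIR frequency responses,
Parseval's relation, and the $PI$ arithmetic. These sizes keep the whole
suite in the tens of seconds on a single CPU while leaving each check
statistically comfortable.

## Known limitations

* The detector is single-device: it consumes one gyro + sEMG pair
  (default right TA). Bilateral fusion happens only at the phenotype
  stage.
* Episodes that chain shuffling directly into trembling are aggregated
  into one episode when the inter-window gap stays below 1 s; the
  episode's $PI$ then reflects the mixture (typically the trembling
  side of the threshold, since coherence is diluted).
* The phenotype stage assumes the TA device; with GC-only recordings the
  fusion runs but the burst/minimum phase relation it exploits is weaker.
* The $R$ scale, and therefore $T_1$, presumes max-normalization over a
  recording (or calibration prefix) that contains at least some vigorous
  movement; a session consisting purely of FOG would normalize the
  shuffle lobes to full scale. The full-scale metadata override exists
  for exactly this situation.
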