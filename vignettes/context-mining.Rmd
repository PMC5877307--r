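---
title: "Mining sedentary-behaviour contexts from smartphone sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining sedentary-behaviour contexts from smartphone sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedentr)
```

## The problem

Sedentary behaviour — waking activities at or below 1.5 metabolic
equivalents in a sitting or reclining posture — is a health risk in its
own right, distinct from a lack of exercise. Monitoring it usefully
needs more than a step counter: *how long* someone sits matters, but so
does *what kind* of sitting it is (desk work, television, something
else) and whether prolonged bouts are interrupted by short breaks.
`sedentr` implements a smartphone-style two-stage recognition pipeline
at desk scale:

1. **Motion stage.** Tri-axial accelerometer data are cut into 3-s
   windows and classified as *still* or *active*.
2. **Micro-context stage.** When a one-minute epoch is judged still,
   8 s of environmental audio are classified as *watching TV*,
   *working on a PC*, or *sedentary-unknown* (anything else — reading,
   a bus, a seminar).

Both stages use a from-scratch k-nearest-neighbour classifier, and a
duty-cycled state machine decides when the (power-hungry) audio
pipeline runs at all.

## The model and its assumptions

### Orientation correction

A phone's pose in a pocket is arbitrary, so per-axis features would be
pose-dependent. Each 3-s window is orientation-corrected: gravity is
estimated as the per-axis mean of the window,
$\hat{g} = \frac{1}{N}\sum_t a_t$, and each dynamic sample
$d_t = a_t - \hat g$ is split into a signed projection on the gravity
direction (*vertical*) and the magnitude of the remainder
(*horizontal*). Both series are invariant under any fixed rotation of
the device — the package asserts this to 1e-9 under random rotations.
Estimating gravity per 3-s window (rather than with a long running
mean) is the simplest reading consistent with the windowing scheme; it
assumes orientation is effectively constant within a window, which
holds for walking and sitting but would blur rapid re-orientations.

### Motion features

Per window, on each of the vertical and horizontal series: mean,
population standard deviation, and energy
$E = \frac{1}{N}\sum_t x_t^2$ — six values. These deliberately cheap
features suffice because gait concentrates energy in the vertical
component: with the default simulator the vertical energies of still
and active windows are linearly separable with a large margin.

### Audio features (MFCC)

Each 8-s segment goes through a standard MFCC front end: pre-emphasis
($y_t = x_t - 0.97\,x_{t-1}$, with $x_0 = 0$), 25-ms Hamming frames at
a 10-ms hop, magnitude-squared FFT at the next power of two, 26
unit-peak triangular filters equally spaced on the mel scale
$\mathrm{mel}(f) = 2595\log_{10}(1 + f/700)$, natural log with a
configurable silence floor, and an orthonormal DCT-II keeping
coefficients 1–13 (the 0th, overall log-energy, is dropped so the
features are invariant to recording gain). The per-coefficient mean and
population standard deviation across a segment's frames give a 26-dim
descriptor. None of these numerics are canonical for this task — the
source material fixes only the block diagram — so all of them live in
`mfcc_config()` and are overridable; the defaults are common
speech-processing practice.

### Classification

k-NN with Euclidean distance and $k = 3$, kept deliberately free of
feature scaling: the two stages have separate stores, so units never
mix. The classifier is exact (no trees or approximations — stores hold
hundreds of instances) and deterministic: a tie in the vote goes to the
nearest neighbour's label, a tie in distance to the earlier-inserted
instance. Training follows a stratified 60:10:30
train/validation/test protocol; the validation split is held out but
unused, since $k$ is fixed rather than tuned. Before training, the
first and last `n_trim = 2` instances of every annotated run are
discarded — transition instances misrepresent their class. The
protocol names the practice but not a count; 2 is this package's
default and is configurable.

### The duty-cycled epoch engine

Inference happens on one-minute epochs. Each minute's twenty 3-s
window labels are majority-voted into a motion label (an exact tie
counts as *active*, biasing against over-counting sedentary time; the
rule is configurable). Audio is sampled only when the epoch is still
and either no check has happened since the last active epoch or the
last check is at least 15 minutes old; otherwise the carried
micro-context is reused. An active epoch clears the carried context,
so the next still epoch re-samples immediately — re-entry behaviour
the source flowchart implies but does not state. Over any continuously
still span of $S$ minutes this yields exactly $\lceil S/15 \rceil$
audio activations, and active epochs never sample audio; both are
asserted exactly in the tests. If audio is due but unavailable the
epoch is labelled *unknown* with a classed warning.

### Behaviour analytics

Epoch timelines aggregate into per-hour minutes by motion context,
per-day hours by context (active/still and, within still, tv/pc/
unknown — the micro hours partition the still hours exactly), period
percentages, short breaks, and period-over-period deltas. A *short
break* is a maximal active run of at most `max_break_min = 5` minutes
flanked on both sides by at least `min_flank_still_min = 10` still
minutes; the concept comes from the literature, the thresholds are
this package's defaults (in `break_config()`). Because "time spent in
short breaks" is ambiguous between a count and a duration, summaries
report both (`n_breaks`, `break_minutes`). Relative period change is
flagged undefined when the baseline is zero rather than reported as
infinite.

## What the simulator emulates — and what it does not

No recordings from the original study were deposited, so the package
ships a parametric simulator (`sim_config()`, `simulate_day()`) that
*is* the test world:

* **Accelerometer.** Gravity (9.81 m/s²) along a random per-recording
  orientation, plus Gaussian sensor noise (sd 0.05 m/s²) when still;
  walking adds a 2-Hz sinusoid of amplitude 2 m/s² along gravity and a
  half-amplitude quadrature horizontal component. 50 Hz sampling — a
  common smartphone rate; the original hardware rates are unstated.
* **Audio (16 kHz).** Three spectrally distinct surrogates: *tv* is
  slowly amplitude-modulated noise band-limited to the 300–3400 Hz
  speech band; *pc* is Poisson click impulses (3/s) over a low
  broadband hum; *unknown* is low-level white noise.

These surrogates are defined so that MFCCs separate them; they are
**not** acoustically realistic. A green end-to-end test therefore
establishes that the pipeline machinery is correct — windowing,
decomposition, features, k-NN, duty cycling, analytics — under a world
where the classes are separable. It does not establish the recognition
accuracy one would obtain on real televisions, offices, phone
pockets, or phones left on desks, and the original study's 93%/98%
accuracies and two-week behaviour-change percentages are context, not
reproduction targets.

The default end-to-end check trains on independent simulated
recordings (5 min per motion class; 160 s per audio class) and runs a
120-minute scheduled day covering all four contexts with several
15-min re-checks and a 3-min break. The day was first drafted at 150
minutes and scaled to 120 purely to keep a full run inside its 3-min
compute budget on one CPU; recognition was at ceiling (100%) at both
lengths, comfortably above the ≥95% motion / ≥90% micro criteria.

## Numerical choices

* Windows are half-open `[start, start + W)`; trailing partial windows
  and epochs are dropped, never padded.
* Population (1/N) standard deviations throughout, consistent with the
  energy normalisation; training and inference share the choice, which
  is all that matters for k-NN.
* The mel filterbank is evaluated at FFT-bin centre frequencies with
  unit-peak (not area-normalised) triangles; the log floor (`1e-10`)
  makes silence well-defined — a silent segment yields exactly zero
  for all retained coefficients.
* Model JSON is written with 17 significant digits, which round-trips
  IEEE doubles bit-exactly (`digits = NA` in jsonlite does not).
* A CSV-read sampling rate within 0.1% of an integer is snapped to it:
  printed timestamps carry decimal round-off that otherwise drops the
  final epoch of a recording.
* Gravity estimates below 1 m/s² warn (estimation) or error
  (decomposition): near-free-fall windows make the vertical direction
  meaningless.

## Known limitations

* Audio surrogates are parametric; no claim of acoustic realism (above).
* "Still with the phone not carried" is indistinguishable from genuine
  stillness — acknowledged as an error source in the source study and
  not solvable from signal content here.
* No resampling: audio at a rate other than the configured one is an
  error, not a conversion.
* Calendar days are 24-h blocks from the timeline origin (UTC by
  convention); timezone-aware day boundaries are out of scope.
* Micro-context changes between two re-checks (e.g. TV switched to PC
  12 minutes into a carried context) are invisible until the next
  check — inherent to the duty cycle, not a defect.
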