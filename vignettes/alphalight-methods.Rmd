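---
title: "Methods: simulating and analysing light effects on posterior alpha and spatial attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing light effects on posterior alpha and spatial attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Exposure to blue-enriched light exerts a dose-dependent alerting effect
on the human brain through intrinsically photosensitive retinal ganglion
cells. Because the brain networks that sustain alertness are
right-hemisphere dominant, and because the balance of visuospatial
attention between the hemifields tracks the hemispheric balance of
posterior alpha-band (8-13 Hz) activity, a light-induced alertness
manipulation may act *asymmetrically*: modulating right-hemisphere
parieto-occipital alpha and thereby specifically changing detection
speed for left-hemifield targets.

`alphalight` implements the complete analysis path for testing that
hypothesis on trial-level data from a lateralised random-dot-motion
(RDM) detection task — and, because the corresponding EEG recordings
are large and external, a calibrated synthetic-data generator that
reproduces the statistical structure such a study produces, so every
stage of the pipeline is testable end to end from a single seed.

The pipeline stages are:

1. **synth** — seeded trial schedules, behavioural outcomes and
   raw-like 64-channel EEG epochs;
2. **alpha** — single-trial alpha envelope estimation (band-pass,
   rectify, smooth);
3. **select** — per-session, per-hemisphere electrode selection from
   post-target alpha desynchronisation;
4. **screen** — response-time bounds, voltage-artifact screens and
   conditional-mean outlier removal;
5. **model** — multilevel models with likelihood-ratio tests,
   random-structure pruning and adjusted follow-up contrasts;
6. **mediate** — Sobel mediation of the light -> alpha -> RT pathway.

## The task and its simulation

Each simulated session mirrors the design: 3 pre-target
incoherent-motion durations (1.8/2.8/3.8 s) x 4 target quadrants x 2
coherent-motion directions = 24 trial types, each occurring exactly
twice in every 48-trial block, 7 blocks, 336 trials. The block-wise
constraint is enforced by construction: the 24-type set is duplicated
within each block and permuted with the session seed. Participants
complete three sessions (low/medium/high light, ~50/350/1400 lux in the
emulated protocol) in one of the 6 orders, counterbalanced — 4
participants per order at the default 24 participants, 72 sessions.

Coherent motion displaces 60% of dots by 0.282 degrees per frame at
21.25 frames/s, i.e. `dotMotionSpeed(0.282, 21.25)` = 5.99 ~ 6
degrees/s. Only this kinematic arithmetic is modelled; no stimuli are
rendered.

## The generative model

Per trial $i$ of a session with light level $\ell$, hemisphere
$h \in \{L, R\}$:

$$A_{ih} = A_0 \, g_{\ell h} \, e^{u} \, e^{z_i^{c} + z_{ih}} \,
  e^{\delta \, t_i}$$

where $A_0$ is the baseline alpha sinusoid amplitude (12 uV at a
full-weight electrode), $g_{\ell h}$ the light gain, $u$ a
between-subject log-normal effect (sd 0.2), $z^c_i$ a *bilateral*
trial fluctuation shared by the hemispheres and $z_{ih}$ a
hemisphere-specific remainder (total sd 0.5, cross-hemisphere
correlation 0.64 — posterior alpha co-fluctuates strongly with arousal
across the hemispheres), and $\delta = 0.1$ a time-on-task drift
($t_i$ the trial number scaled to [0, 1]): alpha grows over the
session. The rectified-sine envelope target is $2A_{ih}/\pi$.

Response times follow

$$\mathrm{RT}_i = \beta_0 + \lambda_\ell \,[\text{left target}] +
  \left(\tau\,(0.5 - t_i) + s_{hemi}\right) [\text{right target}] +
  s_0 + (\beta_{\alpha,\ell} + s_\alpha)\,
  (\log \bar\alpha_i - \overline{\log \bar\alpha}) + \varepsilon_i$$

with $\bar\alpha_i$ the pooled (two-hemisphere) envelope target,
residual sd 90 ms, and by-subject random effects $s_0, s_{hemi},
s_\alpha$ (sd 25/10/3 ms).

Calibration anchors every parameter with a printed counterpart to the
reported results:

| quantity | values (low/medium/high) | anchored to |
|---|---|---|
| left-hemifield mean RT | 499 / 497 / 490 ms | reported condition means |
| right-hemisphere log-alpha gain | 0 / 0.04 / 0.07 | reported contrasts (SE ~0.007) |
| left-hemisphere log-alpha gain | 0 / 0.01 / 0.03 | reported contrasts |
| alpha->RT slope | 12.0 / 9.2 / 7.0 ms per log-unit | reported slope *differences* (-2.8, -2.2, -5.0); the baseline slope is not printed and 12 ms/log-unit makes the overall association positive, as reported |
| accuracy | 97.4% (miss rate 2.6%) | reported ceiling accuracy |

Three simulation choices deserve emphasis because they are *choices*,
not facts from the emulated study:

* **Balanced-panel subject effects.** Random effects are drawn once
  per participant and centred across the study's participants, so the
  calibrated condition means are the exact expectation of a simulated
  study rather than a random draw around it. Parameter-recovery and
  calibration tests then have Monte-Carlo error driven by trial noise
  (~1.5 ms per condition mean), not by a 24-draw subject average.
* **Session-centred coupling.** RT couples to the *deviation* of the
  trial's log pooled envelope from its session mean. This preserves
  the within-condition alpha->RT slope — the quantity the models
  estimate — while keeping condition mean RTs exactly at their
  calibrated values (light's between-condition alpha shift expresses
  itself through the direct RT effect, as in an inconsistent-mediation
  structure).
* **Uniform missingness.** The mechanism behind the ceiling accuracy
  is not described in the emulated protocol; misses are injected
  uniformly at random at 2.6%. This is a placeholder, not an
  inference.

### EEG rendering

Epochs span -700..1198 ms around target onset at 500 Hz (950 samples)
on a 64-channel 10-10 montage. Each hemisphere's alpha source is a
10 Hz sinusoid with per-trial random phase and amplitude $A_{ih}$,
projected with weight 1.0 onto four "true" parieto-occipital
electrodes per hemisphere (P5/P7/PO7/O1 and P6/P8/PO8/O2), 0.5 onto
the other four candidates, 0 elsewhere — a planted, recoverable ground
truth for the electrode-selection stage. From 50 ms post-target the
source contralateral to the target ramps down (raised cosine, 100 ms)
to a fraction 1 - 0.5 of its amplitude, holds to 600 ms and recovers
by 700 ms. The 50% desynchronisation depth is within the range
reported for covert-attention alpha modulations and is deep enough
that per-session selection on 336 trials recovers the planted
electrodes in >= 90% of sessions — the recoverability the generator's
design requires; at shallower depths (e.g. 30%) weak-alpha
participants make the 1.0 vs 0.5 weight gap indistinguishable from
envelope measurement noise.

The background is 1/f noise (power exponent 1, 12 uV broadband per
channel): 16 independent frequency-domain-shaped streams mixed through
a seeded unit-row-norm matrix, giving spatially correlated noise as
volume conduction does. No other rhythms are simulated; passing tests
therefore say nothing about robustness to real-world line noise,
eye movements, or non-stationary broadband shifts. Voltage artifacts
(100 ms half-sine transients, 150 uV, 2% of trials) are injected to
exercise the +/-100 uV screen.

## Alpha envelope estimation

Following the standard single-trial procedure: baseline the broadband
epoch on [-100, 0) ms; band-pass 8-13 Hz with a 4th-order Butterworth
applied forward and backward (zero net phase); rectify; trim 200 ms at
each epoch edge (filter warm-up); average in 100 ms windows advancing
by 50 ms. Windows contribute only if fully inside the trimmed support
(half-open [t, t+100) convention), and grid times are window centres:
usable support -500..1000 ms. "Alpha power" throughout means this
rectified-and-smoothed amplitude envelope in microvolts — the
procedure never squares.

Numerical choice: the default band-pass realisation multiplies each
trace's DFT by the squared Butterworth magnitude response — exactly
the forward-backward response, applied circularly — because it
vectorises over all trials and channels (~4x faster across a
72-session study). `method = "filtfilt"` applies `signal::filtfilt`
trace by trace instead. The two differ only near epoch edges, which
the 200 ms trim discards; tests assert interior agreement and both
realisations' pass/stop-band contracts (10 Hz unity within 5%, DC and
2/30 Hz below -20 dB).

The pre-target summary is the mean envelope over [-500, 0) ms
(half-open, excluding the target-onset sample) and over each
hemisphere's selected electrodes, plus a combined pool for the
alpha x RT model.

## Electrode selection

Per session, each electrode's desynchronisation is the mean envelope
in the post-target window (50-600 ms) minus the same trial set's mean
pre-target (-500..0 ms) envelope, averaged separately over trials with
contralateral and ipsilateral targets. The selection metric is the
contralateral-minus-ipsilateral difference; the 4 most negative
candidates per hemisphere (strongest attention-induced contralateral
suppression) are chosen from the 8-electrode pools, with ties broken
by candidate order. Ranking by absolute magnitude is available
(`ranking = "magnitude"`), since the emulated analysis's direction of
ranking is stated only as "maximal difference"; signed ranking is the
default because attention-induced desynchronisation is a suppression.
The pre-target reference is used because no other reference is both
available in the epoch and used elsewhere in the analysis.

The cumulative light topography (High-Low) + (High-Medium) +
(Medium-Low) — algebraically 2 x (High-Low) — is computed per channel
from the screened pre-target means.

## Screening

Fixed rule order, counted per rule: no response; RT < 200 ms
(pre-emptive); RT > 1000 ms (after coherent-motion offset); broadband
voltage exceeding +/-100 uV on any channel in -500..0 ms (pre-target
analyses) or -100 ms..RT+100 ms (desynchronisation/selection
analyses). Alpha values entering models as the dependent variable are
natural-log transformed (they are strongly right-skewed); outliers
beyond 3 SDs of the participant x condition (x hemisphere for alpha)
cell mean are removed in a single pass, computed on the model's
dependent variable (RT in ms; log alpha). Single-pass removal is
deterministic; re-iterating would remove slightly more mass each round
as the cell SD shrinks, which is why the policy is applied exactly
once.

## Multilevel inference

All models are fit by maximum likelihood (lme4's optimiser under the
hood, bobyqa with a generous evaluation budget), because every
reported test is a likelihood-ratio test on fixed effects: chi-square
= 2 delta-logLik against the parameter-count difference. Factors use
fixed reference levels (low light, right hemifield, left hemisphere);
time-on-task enters as trial number scaled to [0, 1] (LRTs are
invariant to this scaling; the optimiser is better conditioned).

The default random structure is the one the emulated analysis
retained: participants nested in counterbalancing order, by-subject
slopes of target hemifield and of pre-target alpha for RT models;
intercepts only (plus hemisphere nesting) for alpha models. The
hemifield slope uses a numeric indicator (0/1 for left) rather than a
2-level factor expansion: the factor form adds a redundant variance
component that reliably fails to converge. The iterative
random-structure pruning procedure is implemented in
`pruneRandomStructure()`: candidates are tested in listed order by a
drop-one LRT, retained only when the larger model converges *and*
improves fit at p < 0.05 (the retention threshold the emulated
procedure describes qualitatively), with every comparison recorded in
an audit trail. `runPipeline()` fits the retained structure directly
by default (`prune = TRUE` reruns the procedure; it roughly doubles
the model-stage runtime).

Follow-up pairwise light contrasts take SEs from the fitted
covariance, use the normal reference, and adjust p-values over the
family by the single-step multivariate-normal max-|t| method
(Bonferroni-Holm and Bonferroni by configuration).

The light-awareness check uses a bootstrapped Yuen-Welch test: the
two-sample statistic on 20% trimmed means with winsorized variances,
with p from a seeded percentile bootstrap under centred resampling.
Null calibration at alpha = 0.05 is verified by simulation in the test
suite.

## Mediation

Treatment is binary (low vs high light, coded 0/1, the extreme
conditions only); mediator is trial-level right-hemisphere pre-target
log alpha (standardised within the mediation data; z and p are
invariant and the sd is reported for back-transformation); outcome is
RT on left-hemifield trials. Paths a (mediator ~ treatment), c
(outcome ~ treatment) and b, c' (outcome ~ treatment + mediator) come
from the same multilevel machinery as the main models. The indirect
effect is a x b with first-order Sobel SE sqrt(b^2 SE_a^2 + a^2
SE_b^2) (second-order variant by configuration), z = indirect/SE,
two-sided normal p. Mediation is "inconsistent" when c' and a x b
have opposite signs — exactly the calibrated generator's structure:
light *raises* right-hemisphere alpha (a > 0), higher alpha *slows*
RT within condition (b > 0), yet high light *speeds* left-hemifield RT
(c' < 0). Trial-level mediation is the default; a session-aggregated
mediator can be passed by pre-aggregating the table.

## Problem sizes and runtimes

The package's own test and acceptance runs use: full-pipeline studies
of 24 participants x 3 conditions x 336 trials with 64-channel EEG
(the emulated study's size; ~3 minutes per run); 50-replicate
parameter-recovery suites at behavioural level; 400-replicate LRT
size simulations; 1000-replicate Yuen-Welch null calibrations
(599 bootstrap draws each); 50-session electrode-recovery suites on a
16-channel candidate montage. Epochs are processed one session at a
time and released, so memory stays below ~1 GB.

## Known limitations

* The generator's EEG is a two-source-plus-1/f caricature: no ocular
  or muscle artifacts beyond injected transients, no line noise, no
  channel drift, a single fixed 10 Hz alpha frequency, and a scalp
  projection of exactly two weights. Recovery results bound what the
  pipeline can do under its own assumptions, not performance on real
  recordings.
* Broad-band 35 Hz low-pass filtering and average re-referencing are
  provided (`lowpassBroadband()`, `rereferenceAverage()`) for real
  data but are no-ops in the synthetic path, which is generated clean
  and referenced.
* RT residuals are Gaussian; real RT distributions are right-skewed.
  Condition-mean calibration and contrast recovery are unaffected, but
  absolute outlier-removal rates on real data will differ from the
  Gaussian 2 Phi(-3).
* Degrees-of-freedom bookkeeping for interaction LRTs involving
  separate-hemifield models is a modelling choice; the pruning audit
  trail and the report record the fitted structures explicitly rather
  than asserting equivalence to any particular historical analysis.
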