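---
title: "Layered hidden Markov models for wearable ECG arrhythmia classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered hidden Markov models for wearable ECG arrhythmia classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhmmecg)
```

## The problem

Long-term ambulatory ECG monitoring with a wearable, single-lead sensor
must classify every heart beat in real time — normal sinus beats versus
premature ventricular contractions (PVC) and atrial premature contractions
(APC) — while the wearer stands, lies down, and walks. Two practical
obstacles dominate: powerline interference couples into the analog chain
anywhere along the signal path, and walking produces motion artifacts that
distort beat morphology badly enough to mimic ectopy. `lhmmecg` implements
the full software chain for this setting: digital conditioning, a layered
pair of discrete hidden Markov models (HMMs), an accelerometer-driven
activity gate, beat-by-beat evaluation metrics, and a synthetic generator
that provides exact ground truth for every stage.

## Signal conditioning

**Notch filter.** Powerline rejection uses a single second-order IIR
section designed by constrained pole–zero placement. With normalized
angular notch frequency $\omega_0 = 2\pi f_0/f_s$ and normalized 3 dB
bandwidth $\beta = 2\pi\,\mathrm{bw}/f_s$, the zeros sit exactly on the
unit circle at $e^{\pm j\omega_0}$ and the poles share that angle at
radius $r$ with

$$ r^2 = \frac{1 - \tan(\beta/2)}{1 + \tan(\beta/2)}, \qquad
H(z) = \frac{1 - 2\cos\omega_0\, z^{-1} + z^{-2}}
            {1 - 2r\cos\omega_0\, z^{-1} + r^2 z^{-2}}. $$

At the reference spec (50 Hz notch, 360 Hz sampling, 6 Hz bandwidth) this
gives $b_1 = -1.2856$, $a_1 = -1.2199$, $a_2 = 0.9004$. The numerator is
deliberately left unnormalized (leading coefficient 1), so the passband
gain is close to, but not exactly, one; the gain at the notch frequency is
exactly zero. The tangent bandwidth mapping was chosen from the family of
standard mappings because it places the −3 dB points on a dense frequency
grid within 5% of $1/\sqrt2$ of the passband maximum at this spec. The
filter is applied as a causal direct-form difference equation with zero
initial conditions; a 60 Hz variant is the same recipe with $f_0 = 60$.

**Savitzky–Golay smoother.** The notch output carries small Gibbs ripples,
which a Savitzky–Golay filter removes while preserving the low-amplitude P
wave. Each output sample is the least-squares polynomial fit over a
sliding window evaluated at its center; at polynomial order 0 (the
default) this is a centered 15-point moving average. Edges are handled by
reflection padding without repeating the edge sample — the simplest policy
that keeps constants invariant and output length equal to input length.

## Layer 1: six-state segmentation HMM

One cardiac cycle is modeled as six hidden states in a fixed cyclic
order — ISO1, P, ISO2, QRS, ISO3, T — where the ISO states are the
isoelectric gaps between subwaves. Each ECG *sample* is a time step. The
observation alphabet is deliberately tiny: the 12-bit ADC range
$[0, 4095]$ is cut into four equal-width levels $O_1..O_4$ (0–1023 is
$O_1$, 1024–2047 is $O_2$, and so on), which keeps the model cheap enough
for on-line decoding on embedded hardware. Two structural refinements
adapt the chain to arrhythmia:

* an added ISO1→ISO2 edge lets a beat skip the P state entirely, which is
  exactly what a PVC looks like; and
* every state carries a **minimum dwell duration**, set during training to
  60% of the shortest dwell observed for that state, which suppresses
  *double-beat segmentation* (one true beat decoded as two).

Decoding maximizes the ordinary HMM path probability subject to the dwell
constraints. This is implemented exactly by replicating each state
`min_duration` times (phase 1 … d); phases below d can only advance within
the run, phase d self-loops or exits. A plain Viterbi pass over the
expanded graph — in compiled code, with predecessor lists — is then exact,
and the reported score equals the path's unconstrained log-probability. A
hidden semi-Markov decoder would generalize this, but the expanded-state
construction matches the stated model exactly and is directly testable
against brute-force enumeration, which the test suite does.

Ties are broken deterministically toward the lowest state index. Training
is supervised from annotated state paths (add-one smoothing inside the
topology mask); an optional Baum–Welch refinement (`baum_welch()`) is
available but off by default, since the synthetic generator provides exact
paths and supervised estimates are reproducible without EM.

**Millivolt-to-count calibration.** The four-level quantizer can only see
what crosses its three thresholds. `mv_to_adc()` therefore centers the
isoelectric line inside the second level (count 1535) at 7200 counts/mV:
downward deflections (the large inverted T of a PVC) reach $O_1$, P and T
waves reach $O_3$, and the QRS saturates into $O_4$. An earlier calibration
that parked the baseline inside the bottom level made inverted T waves
invisible — the mandatory T state then stole the *next* beat's P wave —
so this choice is load-bearing, and both parameters stay configurable.

## Activity classification and gating

A tri-axial accelerometer (z axis pointing down) is classified over ~3 s
sliding windows (1 s hop) by a fixed decision tree on three features: the
window mean of the magnitude $A = \sqrt{a_x^2+a_y^2+a_z^2}$, its variance,
and the mean z component. Walking requires both mean $A \ge \delta_1$ and
variance $\ge \delta_2$; otherwise lying is declared when $|\bar a_z| \le
\varepsilon$, else standing. Defaults $\delta_1 = 1.15$ g, $\delta_2 =
0.01$ g², $\varepsilon = 0.2$ g were calibrated once against the synthetic
generator's gait signature (a rectified-sine vertical bounce, which is
what raises the *mean* magnitude above one g — a symmetric oscillation
does not). "Variance of A" resolves an ambiguity in the underlying
heuristic (a covariance of a scalar stream) as the scalar variance of the
magnitude.

Each beat inherits the label of the window whose center is nearest its
fiducial. Beats labeled walking receive the *motion* observation code, and
`gate_motion()` floors the emission probability of motion-coded symbols to
$10^{-9}$ under Normal/PVC/APC, so such beats can only decode as Invalid.
This is the layered model's answer to motion artifacts: a distorted beat
during walking is declared unreadable rather than arrhythmic.

## Layer 2: four-state ergodic classification HMM

Beats are time steps. The states are Normal, PVC, APC, Invalid, fully
connected (arrhythmias occur intermittently, so no transition is
structurally forbidden). The observation is a 36-symbol product code of
four per-beat features:

| feature | codes | cut-offs |
|---|---|---|
| QRS duration | normal / wide | 120 ms (the classical PVC width criterion) |
| R-R interval | premature / normal / long | < 0.85 or > 1.15 of the running median of the preceding 8 intervals |
| P wave | present-normal / present-abnormal / absent | abnormal when the P-R interval leaves 100–200 ms |
| activity | reliable / motion | walking vs standing or lying |

The 120 ms QRS threshold is the only printed cut-off in the source
material; the remaining bins are this package's design, chosen as the
smallest alphabet that expresses the clinical descriptions: a PVC is wide,
premature, with no preceding P; an APC is narrow, premature, with a small
displaced P (encoded through the out-of-band P-R interval; prematurity is
additionally reflected in the R-R bin). T-wave polarity is *not* a
feature — it appears only in the generator's PVC morphology. Absent fields
(first beat's R-R, missing P) map to dedicated codes rather than sentinel
values.

Training is supervised add-one-smoothed counting. The Layer-2 model is
estimated on the *decoded* output of the trained Layer 1 (features from
decoded boundaries, labels transferred from ground truth by fiducial
matching): training the upper layer on the lower layer's actual output
makes the emission estimates reflect systematic decoding effects — e.g. a
small P occasionally missed — that truth-derived features would hide.
Decoding is batch Viterbi per record; a fixed-lag online mode (default lag
3 beats) serves the streaming use case and agrees with batch decoding away
from ambiguous stretches.

## Evaluation metrics

Predicted and reference beats are paired one-to-one by greedy
nearest-neighbor matching within ±150 ms (a common beat-by-beat
convention; configurable). Per record,

$$ Ac = \frac{N_t - N_e}{N_t} \times 100\%, \quad
   Se = \frac{TP}{TP+FN} \times 100\%, \quad
   +P = \frac{TP}{TP+FP} \times 100\%, $$

where $N_t$ counts reference beats of the scored classes and $N_e$ those
missed or misclassified. A beat predicted Invalid against an annotated
reference counts as an error in $N_e$ but pollutes no class's false
positives; annotation classes outside Normal/PVC/APC are excluded from
scoring entirely. Classes with no reference beats report `NA`, never 0 or
100. Across records, the summary is the beat-weighted average
$\mathrm{MWA} = \sum_i n_{b,i} M_i / \sum_i n_{b,i}$, with `NA` records
excluded from both sums. Percentages are displayed rounded half-up to two
decimals. The package ships the published 16-record MIT-BIH evaluation
table as a worked example (`mitbih_reference_scores()`); recomputing its
weighted-average row from the per-record cells reproduces every summary
cell exactly at two decimals.

A full re-run on the MIT-BIH Arrhythmia Database itself requires
downloading PhysioNet records and training choices the source material
does not specify; it is supported (`read_wfdb()`, format 212/16 and MIT
annotations, strict N/V/A mapping) but deliberately optional — no test or
script touches external data.

## The synthetic generator

`generate_record()` builds beats as concatenated subwave segments with
durations drawn from truncated normals (±2 sd, 20 ms floor), so the state
path, subwave boundaries and beat labels are exact by construction.
Defaults: 360 Hz, 75 bpm with 30 ms R-R jitter, subwave amplitudes P
0.15 mV, QRS 1.0 mV, T 0.3 mV and mean durations P 90, ISO2 60, QRS 90,
ISO3 100, T 160 ms — mid-range values for adult surface ECG. Subwave
shapes are raised-cosine bumps with a sharpening exponent so that each
deflection occupies most of its nominal duration; this keeps decoded run
widths close to the true widths, which matters because the 120 ms QRS
criterion is applied to decoded durations. Ectopic morphology follows the
clinical descriptions: PVCs drop the P segment, draw QRS width from
130–170 ms, a premature R-R target of 0.6–0.8 of the running mean and a
large inverted T; APCs carry a smaller (0.7×) earlier P with a prolonged
P-R (ISO2 ≈ 170 ms) and a 0.6–0.75 premature R-R. Disturbances are
additive after the clean waveform is built: powerline sinusoid, slow
baseline wander, white noise, and — during scheduled walking — band-limited
(1–10 Hz) artifact plus an oscillatory accelerometer trace; standing and
lying produce constant gravity on z or x respectively, with small noise.

What the generator does *not* emulate: real QRS polymorphism, respiratory
modulation of amplitudes and R-R, electrode pop and contact artifacts,
fusion and aberrantly conducted beats, and the annotation ambiguities of
real databases. Passing the closure tests therefore demonstrates that the
pipeline is internally consistent end to end under its own stated
assumptions — not that MIT-BIH-level accuracy transfers to any specific
recording.

## Numerical and design choices

* Log-domain decoding throughout; `log(0)` enters as `-Inf` and never
  produces NaN on the feasible graph. Viterbi ties break toward the lowest
  state index; equal-scoring optima can genuinely occur when observation
  symbols repeat, so tests compare achieved log-probability, not path
  identity, against enumeration.
* The decoder's backpointer matrix is the memory bound:
  states-times-samples integers (about 100 MB for a 13-minute record with
  ~90 expanded states), well within a workstation budget; longer records
  can be decoded in windows.
* Problem sizes used by the test suite — a 600 s training record, an 800 s
  (~1050 beat) closure record, 200-case brute-force sweeps with ≤ 12
  observations, and a 10,000-beat parameter-recovery corpus — were chosen
  so the whole suite exercises every stage at full fidelity in about a
  minute.
* For the parameter-recovery check, the known matrices use
  permutation-dominant transitions and moderate emission peaks so the
  add-one estimator's bias plus multinomial noise at 10,000 beats sits
  well inside the 0.02 tolerance; mid-range probabilities would make that
  check a coin flip on sampling noise rather than a test of correctness.
* The 12-bit quantizer default follows the stated 0–4095 observation
  range; where the hardware description mentions a 10-bit converter
  instead, the quantizer's `adc_max` remains configurable.
* `synth_config(seed = )` seeds R's global RNG once per record; identical
  configurations are bit-identical, and all suite randomness flows through
  fixed seeds.

## Known limitations

* Only PVC and APC are classified; bundle-branch blocks and other
  morphologies are out of scope (an RBBB would decode Normal or wide).
* The P-R codebook band (100–200 ms) is fixed, not subject-adaptive; very
  fast or slow intrinsic conduction would need recalibration.
* The activity tree distinguishes only standing/walking/lying; running,
  stairs, or in-vehicle vibration will be labeled by whichever branch the
  thresholds select.
* Layer-1 boundary placement is only as sharp as the four-level quantizer
  allows; sub-sample fiducial accuracy is not a goal.
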