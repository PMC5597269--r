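---
title: "Two-moving-average delineation of P and T waves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-moving-average delineation of P and T waves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptwave)
```

## The problem

The P wave (atrial depolarization) and the T wave (ventricular
repolarization) are the two low-amplitude deflections flanking the QRS
complex of each heartbeat. Their timing and presence carry direct clinical
meaning — absent P waves mark ventricular ectopy, merged P–T complexes
accompany bundle-branch blocks and fast rhythms — yet most delineation
methods either assume clean sinus rhythm or require heavy machinery
(wavelets, Bayesian samplers, neural networks). `ptwave` implements a
deliberately light detector built from two moving averages and a handful of
physiological duration priors, designed to keep working on arrhythmic,
noisy, long ambulatory recordings, plus the evaluation protocol and a
synthetic annotated-ECG generator that make the whole pipeline testable
offline.

The detector assumes R-peak positions are known (every common ECG database
ships beat annotations, and R detection is a solved problem treated as out
of scope). Everything downstream is anchored on consecutive R-peak pairs.

## The pipeline

For a record sampled at $f_s$ Hz with R peaks $R_1 < R_2 < \dots$:

1. **Band-pass filter** (`bandpass()`): an order-2 Butterworth with
   passband 0.5–10 Hz, applied forward and backward so the phase response
   is zero and peaks do not shift. The band keeps P/T energy and removes
   baseline wander (below 0.5 Hz) and powerline/EMG noise (above 10 Hz).
2. **QRS blanking** (`remove_qrs()`): samples in
   $[R_i - \mathrm{round}(0.083 f_s),\; R_i + \mathrm{round}(0.166 f_s)]$
   are set to zero. 83 ms + 166 ms covers the QRS support and earliest ST
   segment at the reference rhythm, leaving P and T as the dominant
   deflections.
3. **Two moving averages** (`moving_average()`): centered means with
   windows $W_1$ = 55 ms (half the normal P-wave width, so even shortened
   arrhythmic waves produce a crest) and $W_2$ = 110 ms (the full P-wave
   width). The slow average acts as a dynamic, event-related threshold for
   the fast one.
4. **Blocks of interest** (`generate_blocks()`): maximal runs where
   $MA_{W_1}[n] > MA_{W_2}[n]$ strictly; ties produce no block.
5. **Width priors** (`classify_blocks()`): blocks narrower than
   $\mathrm{round}(0.75\,W_1)$ samples are noise and rejected; blocks at
   least $\mathrm{round}(1.25\,W_1)$ wide are additionally T candidates
   (the 3:5 P:T width ratio splits the two factors around 1).
6. **RR-scaled gates** (`gates_for_interval()`): inside each interval
   $(R_i, R_{i+1})$ the T wave is sought
   166–500 ms after $R_i$ and the P wave 110–560 ms before $R_{i+1}$,
   all four offsets multiplied by the RR interval in seconds — faster
   rhythm, proportionally tighter windows. 560 ms is the PQ + QTc prior
   total (`p_gate_upper_ms()`); 110 ms is the minimum PR interval.
7. **Three scenarios** (`delineate_interval()`): no candidate block — no
   detection; one block — the P and T waves are most likely merged, and
   its crest is reported as both P and T (flagged merged) provided it lies
   in the union of the gates; several blocks — the highest crest inside
   each gate wins that gate.

`detect_pt()` chains all of this and returns a classed object with
`print()`, `summary()`, `plot()` and `as.data.frame()` methods.

```{r example}
rec <- synth_ecg(synth_spec(duration_s = 20, noise = noise_spec(0, 0, 0)))
det <- detect_pt(rec)
summary(det)
evaluate_detection(det, span_only = TRUE)
```

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `low_hz`, `high_hz` | 0.5, 10 | Hz | P/T spectral band; edges also remove drift and mains hum |
| `order` | 2 | – | transition steep enough at trivial cost; higher orders ring longer |
| `pre_s`, `post_s` | 0.083, 0.166 | s | QRS blank span around each R peak |
| `w1_ms`, `w2_ms` | 55, 110 | ms | fast/slow moving-average windows from the P-width prior |
| `p_factor`, `t_factor` | 0.75, 1.25 | ×`W1` | minimum block widths for P-/T-candidacy |
| `p_min_ms`–`p_max_ms` | 110–560 | ms | P gate before the next R, RR-scaled |
| `rt_min_ms`–`rt_max_ms` | 166–500 | ms | T gate after the current R, RR-scaled |
| `use_abs_peak` | off | – | crest by absolute amplitude, for inverted leads |
| `tol_ms` | 40 | ms | evaluation matching tolerance |

The T-gate numbers deserve a note: the minimum coincides with the end of
the QRS blank (166 ms) and the maximum with the QTc prior ceiling
(≈500 ms after R once the Q–R offset is absorbed); both are ordinary
configuration keys because published descriptions of this detector family
leave the exact RT range open.

## Numerical choices

* **Rounding.** Every ms→sample conversion uses round-half-up
  (`floor(x + 0.5)`). Base R's `round()` rounds half to even, which would
  make gate bounds flip with parity; half-up is deterministic and
  symmetric around each R peak. Moving-average windows are additionally
  forced odd so a centered window exists.
* **Zero-phase filtering.** The forward–backward pass extends the signal
  with `ceil(3 * fs / low_hz)` zeros on each side. The padding length is
  tied to the slowest (high-pass) pole so start-up transients decay inside
  the extensions; the result is exactly invariant under integer time
  shifts and symmetric under time reversal to ~1e−11 relative error.
  Zero (rather than reflected) padding leaves a step transient at the
  record edges, which never matters because delineation only happens
  between R peaks. Signals shorter than three filter lengths are rejected
  rather than silently padded.
* **Strict inequality for blocks.** `MA_fast > MA_slow` as an exact
  comparison: equality produces no block, and the comparison (hence the
  entire pipeline) is invariant under positive rescaling of the input.
* **Crest requirement.** Band-passing a tall, wide QRS (a PVC especially)
  leaves ringing outside the blanked span, and blanking itself creates
  zero stretches whose moving-average tails can still satisfy the block
  condition. A candidate block must therefore contain an actual crest:
  its extremum must be positive (non-zero under `use_abs_peak`).
  A block whose maximum lies on or below the isoelectric line is filter
  ringing, not a wave.
* **Multiplicity ties.** When several candidates sit in one gate the
  highest crest wins. When a single block wins both gates while other
  blocks exist, it is assigned to the gate whose centre is nearest its
  crest and the other gate is re-decided without it.
* **Degenerate gates.** A gate that clips to nothing inside $(R_i,
  R_{i+1})$ (possible at very short RR) yields no detection for that wave
  and is recorded in the per-interval provenance log.

## Evaluation protocol

`match_peaks()` pairs detections and reference peaks one-to-one within a
tolerance (default ±40 ms — well under half the narrowest normal P-wave
width, so a match can only be the intended wave). References are visited
in time order and matched to the earliest unmatched detection in range;
for equal-width windows on sorted sequences this attains the maximum
possible number of pairs, which the test suite verifies against an
exhaustive optimal-assignment oracle. SE $=100\,TP/(TP+FN)$ and
+P $=100\,TP/(TP+FP)$; undefined ratios are reported absent, never zero.

Aggregation over records offers both the **macro** mean of per-record
percentages (each record weighted equally — the convention under which
the shipped ten-record benchmark table's overall row reproduces exactly)
and **pooled** counts. Merged P–T detections count once toward each wave's
list, since P and T are scored independently over all beats.

One convention is specific to this package: the delineator reports
nothing before the first or after the last annotated R peak, so pipeline
tests and the acceptance script pass `span_only = TRUE`, dropping
reference peaks outside the R-anchored span. The benchmark convention
(`span_only = FALSE`, every beat counts) remains the default.

The shipped benchmark table (`pt_benchmark()`) contains a few rows whose
printed percentage cells are not exactly `100*TP/(TP+FN)` of the same
row's counts; this package always computes from counts and documents the
discrepancy rather than reproducing those cells.

## The synthetic generator

`synth_ecg()` builds records from Gaussian wave primitives — P
(0.15 mV / 110 ms), biphasic QRS (1 mV R crest with an S undershoot,
100 ms), T (0.3 mV / 160 ms), PR 160 ms, RT 300 ms — on a regular RR grid,
then adds seeded baseline wander (0.05 mV at 0.25 Hz), powerline
interference (0.02 mV at 50 Hz, configurable to 60 Hz) and white noise
(0.01 mV), magnitudes typical of ambulatory recordings. Gaussians were
chosen over a dynamical-system ECG model because the detector only needs
realistic timing/width/amplitude structure, and Gaussians make the ground
truth exact: every truth index is read off the noise-free copy as the
local argmax, so tests compare against construction, not intention.

Beat motifs: `PVC` beats arrive 20% early with a widened, larger QRS, no
P wave, and a compensatory pause; `PAC` beats arrive 15% early with their
distorted P superimposed on the previous T (one composite bump carrying
both truths); `MERGED` beats fuse their T with the following beat's P
into one wide bump (one truth index shared by both lists, matching how
the detector reports merged events).

What the generator does **not** emulate: genuinely non-stationary
morphology drift, atrial fibrillation/flutter, muscle-artifact bursts,
electrode motion, multi-lead structure, or biphasic/inverted P and T
shapes. Perfect scores on clean synthetic records therefore demonstrate
the pipeline's correctness under its stated assumptions, not clinical
performance; the shipped benchmark table is the reference point for real
arrhythmic data, and the `read_wfdb()` adapter lets the full pipeline run
on locally downloaded recordings.

A consequence worth knowing: in an interval preceding a PVC there is no P
wave, so the only block is the preceding T; the single-block rule then
reports a merged P–T there, which scores as a P false positive. That
false-positive mode is intrinsic to the three-scenario logic on
ventricular ectopy (the published per-record results show the same
signature) — the gates still guarantee no P is ever placed inside the
PVC's P window.

## Problem sizes and determinism

The test suite and the acceptance script use 10–60 s records at 360 Hz
(10–60 beats), enough for every interval type to occur several times while
keeping a full run in seconds. All randomness (noise phases, white noise,
property-test cases) is seeded; `synth_ecg()` restores the caller's RNG
state. Two runs with identical inputs and configuration produce
byte-identical detection files.

## Known limitations

* R peaks are inputs; mis-detected R peaks propagate directly (a domino
  effect shared by the whole detector family).
* Peak-only delineation: no wave onsets/offsets, no U-wave handling
  beyond not confusing gated blocks.
* The signed-crest rule assumes upright P/T polarity; use
  `use_abs_peak = TRUE` for inverted leads.
* The WFDB adapter reads single records in formats 212 and 16 with beat
  annotations — enough for the classic arrhythmia databases, not a
  general WFDB implementation.
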