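---
title: "Population modelling of APD alternans: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population modelling of APD alternans: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alternanspop)
```

## What the package computes

Action potential duration (APD) alternans — a beat-to-beat long/short
alternation of the ventricular action potential under periodic pacing — is a
cellular precursor of reentrant arrhythmia. This package asks a population
question: across combined up/down scalings of ten maximal ion-channel
conductances of a human ventricular epicardial myocyte, where in the pacing
range does alternans first appear, and which conductances dominate that
sensitivity?

The pipeline has five stages, each exposed as ordinary R functions:

1. **Ionic model** — the epicardial human ventricular myocyte model of
   ten Tusscher, Noble, Noble and Panfilov (2004): 17 state variables
   (membrane potential, 12 Hodgkin–Huxley-type gates, intracellular Na^+^,
   K^+^, Ca^2+^ and SR Ca^2+^), twelve membrane currents, and simple
   calcium-induced calcium release. The membrane equation is
   `dVm/dt = -(I_ion + I_stim)`, with currents carried per unit capacitance
   (pA/pF) so that the printed membrane capacitance of 2.0 uF/cm^2 only
   fixes the unit convention.
2. **Pacing engine** — a descending dynamic-restitution protocol: steady-state
   initialization at a 750 ms cycle length, then 74 paced beats per cycle
   length from 750 ms down to 350 ms in 50 ms decrements and on to 180 ms in
   10 ms decrements (26 cycle lengths), carrying the cell state continuously
   across stages.
3. **Alternans biomarkers** — per beat, APD90 (maximum-upstroke to the
   interpolated 90%-repolarization crossing). Per cycle length, from the
   last 11 beats: the alternans magnitude `AM = mean(|APD[i+1] - APD[i]|)`
   (10 differences), the mean APD of the last 10 beats, and their ratio, the
   normalized alternans magnitude `ANM = AM / meanAPD`. Alternans is declared
   when ANM exceeds 0.05 (strictly). Scanning the schedule from the longest
   cycle length, the first alternans-positive cycle length is the alternans
   onset cycle length (AOCL) and its meanAPD the onset meanAPD; both are 0
   when no cycle length qualifies.
4. **Population sweep** — the full 3-level factorial (50%/100%/150%) over the
   ten conductances gives 3^10 = 59,049 scenarios, enumerated as a base-3
   counter over the fixed channel order. Sweeps are deterministic,
   checkpointed and parallelizable; failures become quality-flagged rows.
5. **Dimensional stacking** — each scenario is a pixel of a 243 × 243 map:
   five channels nest the x axis (strides 81, 27, 9, 3, 1) and five the y
   axis, levels mapping to digits 0/1/2. The axis ordering is chosen to
   minimize the total absolute difference between each pixel and its four
   neighbors (edge terms omitted), which visually concentrates the most
   influential conductances on the outermost scales.

## The conductance table and its provenance

The ten varied maximal conductances default to (nS/pF): g_Ks 0.245,
g_Kr 0.096, g_K1 5.405, g_Na 14.838, g_bNa 0.00029, g_CaL 3.98e-5,
g_bCa 0.000592, g_to 0.294, g_pCa 0.025, g_pK 0.0146. All of these are the
2004 epicardial reference values except the L-type conductance: 3.98e-5 is
the value adopted in the 2006 revision of the same model family (the 2004
formulation uses 1.75e-4 with a differently scaled driving force). The
package keeps the 2004 equations throughout and takes the table as given for
the default study conditions; as a consequence the default L-type current is
substantially weaker than in the 2004 reference parameterization, baseline
APD90 is ~230 ms rather than ~276 ms, and restitution is shallow.

The implementation itself is cross-checked at the 2004 parameter point: with
`g_CaL = 1.75e-4` the model reproduces the published epicardial resting
potential (−86 mV) and baseline APD90 (within ±15 ms of 276 ms at a 1000 ms
cycle length after the bounded steady-state initialization described below).

A practical consequence, stated openly: under the default table, sustained
1:1 APD alternans (ANM > 0.05 with full capture) does not occur anywhere we
scanned in the factorial — rate-induced instability instead appears as loss
of 1:1 capture at short cycle lengths, which the pipeline flags as
incomplete capture rather than scoring. The biomarker and map machinery is
therefore validated end to end against synthetic fixtures with planted
alternans (below), independent of the ionic model.

## Numerical choices

* **Integrator**: Rush–Larsen exponential updates for all
  voltage-dependent gates (exact for the locally linearized gate equation),
  forward Euler for Vm and concentrations; default `dt = 0.02` ms. Halving
  `dt` changes baseline APD90 by well under 1 ms (asserted in the tests).
  The calcium-dependent gates (`fCa` and the SR release gate `g`) follow the
  reference model's voltage-conditional freeze rule: they may not move
  toward reopening while `Vm > -60` mV. Note one authentic quirk of the
  reference formulation: the steady state of `fCa` marginally exceeds 1
  (≈1.005) at diastolic calcium, so `fCa` is bounded by [0, 1.05] while all
  true Hodgkin–Huxley gates stay in [0, 1].
* **Stimulus**: −52 pA/pF for 1 ms, the conventional roughly twice-threshold
  pulse for this model class; both are configurable
  (`integrator_config()`).
* **Steady-state initialization**: pacing at the first scheduled cycle
  length until the maximum relative change of any state variable sampled at
  stimulus times falls below 1e-4, capped at 200 beats. The cap is the
  binding constraint in practice: intracellular Na^+^ in this model family
  drifts for thousands of beats, and the bounded criterion makes runs
  reproducible and comparable rather than fully drift-free.
* **Beat analysis**: beats are delimited by stimulus times; the pre-stimulus
  potential defines the beat's resting level, the 90% threshold is
  amplitude-relative (`Vrest + 0.1 (Vpeak − Vrest)`), and the repolarization
  crossing is linearly interpolated, so APD90 is insensitive to the trace
  storage rate (0.1 vs 0.05 ms sampling changes APD90 by < 0.2 ms).
* **Capture rules**: a beat whose peak stays below 0 mV is no-capture; a
  cycle length with any non-captured beat or missing repolarization crossing
  is excluded from AOCL determination and flags the scenario
  (`incomplete_capture`), and a scenario with no complete cycle length is
  reported as such — never as a silent (0, 0).
* **Near-singular L-type driving force**: the GHK-type factor
  `V (Ca_i e^z − 0.341 Ca_o)/(e^z − 1)` is replaced by its analytic limit
  for |z| < 1e-5.

## Alternans arithmetic

The per-cycle-length window is the last 11 beats: 10 successive absolute
APD90 differences for AM, the last 10 APDs for meanAPD. Reading the
magnitude as an absolute difference is forced by the threshold rule (signed
differences would telescope and allow negative ANM), and reading the beat
quantity as APD90 rather than voltage amplitude is forced by dimensional
consistency of ANM and by internal consistency of reported onset values
(alternating 66.3/48.8 ms beats give AM = 17.5 ms and, against an onset
meanAPD of 56.7 ms, ANM = 0.3086 ≈ the reported 0.3083). ANM is
non-negative and invariant to scaling all APDs by a common factor; both are
asserted as properties in the tests.

## Synthetic fixtures: what they emulate and what they do not

`synth_ap_train()` builds an analytic action-potential template — concave
fast upstroke (maximal slope at onset, so the detected upstroke sample is
noise-robust), plateau, logistic repolarization — whose 90% crossing is
placed in closed form at the planted APD90. It emulates exactly the features
the biomarker extractor consumes (upstroke, amplitude-relative threshold,
crossing); it does not emulate calcium transients, notch morphology or rate
memory, so passing biomarker tests demonstrate extractor correctness, not
ionic-model fidelity. `synth_scalar_field()` plants a separable field
`value = Σ w_k f(level_k) + noise` over a small factorial so the axis-order
optimizer can be checked against brute force, and `synth_summary_table()`
plants a linear AOCL–meanAPD relation with a known non-alternans fraction
for the aggregate statistics. All generators are seed-deterministic and emit
their ground truth.

## Axis-order optimization

The neighbor-difference objective is computed as twice the sum over adjacent
pixel pairs (each pair appears in both of its pixels' four-neighbor sums);
minimizers are identical under either counting. Exhaustive search enumerates
orderings modulo the x/y-swap symmetry — a valid halving only for an even
number of stacked channels, where the two axis groups have equal size; for
odd counts all orderings are enumerated. Ties break to the lexicographically
smallest ordering. The heuristic seeds with a main-effect (level-mean range)
ranking and refines by simulated annealing over pairwise swaps under a fixed
seed; on 4-channel planted fields it matches the exhaustive optimum in all
tested instances.

On separable planted fields the optimum provably places the most influential
channel on an outermost scale and nests each axis monotonically from most to
least influential — but the full interleaved ranking is not always the
global optimum (the best grouping depends on the weight gaps), so that is
the property we assert. Non-alternans pixels carry their value 0 in the
objective; they are real map pixels, gray only in rendering.

## Problem sizes used in the checks

The packaged tests run single-scenario protocols and small factorials: full
26-cycle-length runs for the three worked conductance scenarios, short
schedules (a few cycle lengths, 12–74 beats) for structural pacing
properties, 3–5-channel planted fields (27–243 scenarios) for the stacking
oracle, and the full 59,049-code enumeration for indexing/stacking
bijectivity. The full factorial sweep is a cluster-scale computation; it is
supported through `run_sweep()`'s checkpointing and `scripts/sweep.R` slices
but is not exercised by the desk checks.

## Known limitations

* Single-cell only: no electrotonic coupling, tissue heterogeneity or
  conduction, all of which modulate alternans in tissue.
* One cell type (epicardial); no endo/mid-myocardial variants, no
  temperature or drug-block models.
* Fixed-step explicit integration; the default `dt` is chosen for this
  model's stiffness and verified by step-halving, not adaptive.
* The default conductance table mixes model generations for the L-type
  current (see above); results under the default table should be read as
  properties of that stated parameterization, not of the 2004 reference
  model.
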