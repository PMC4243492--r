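---
title: "An executive controller for selective visual attention: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An executive controller for selective visual attention: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visattn)
```

## The model

`visattn` implements a runnable executive controller for visual attention in
the Selective Tuning tradition. Vision here is not a passive feedforward
classifier: a task tunes the visual hierarchy before the stimulus appears,
a first feedforward pass supports only coarse decisions, and everything
finer — localization, clean re-analysis, serial search, curve tracing — is
achieved by recurrent top-down traversals and by an executive that sequences
them. The package makes that control problem concrete: every component is
code, every run produces a model-clock event log, and every claim about
behavior is a property the test suite recomputes.

The pieces, in the order a single attentive cycle uses them:

* **Visual hierarchy (VH).** A small retinotopic feature pyramid (default 4
  levels, halving resolution per level). Each channel (e.g. `colorA`,
  `curve`) is an image plane that propagates independently. Pooling is an
  attenuation-weighted window mean — there is deliberately *no feedforward
  maximum anywhere*: max-finding that happens on the way up commits too
  early and would make the top-down selection pass impossible, which is the
  architectural point of Selective Tuning. With no attenuation the pass is
  exactly linear (the suite probes this property on random images).
* **Priming (stage B).** Task information multiplies channel gains (and
  optionally a spatial prior) before stimulus onset. Gains apply at the
  input level, so by linearity a gain of 2 scales that channel's responses
  by exactly 2 at every level. Priming events are stamped 80–300 ms (default
  150 ms) before onset on the model clock.
* **θ-WTA (stage C decision).** The winner-take-all returns, instead of a
  single unit, the spatially connected set of near-maximal responses: all
  admissible units within `(1 - θ)·max`, restricted to the connected
  component containing the peak. θ is read as a *relative* threshold — that
  keeps it dimensionless and matches the idea of selecting "the set of
  largest values" rather than histogram bins. Ties break to the smallest
  (row, col); 8-connectivity is the default. The central focus of attention
  (cFOA) is the θ-WTA over the top level, masked to units whose input-space
  centers fall within the central attentional field (default 10°) and which
  are not pathway-inhibited.
* **Recurrent localization (stage D).** From the top-level selection the
  model descends level by level: only units feeding the selection above are
  admissible, θ-WTA picks the near-maximal connected set among them, every
  supra-threshold channel at a selected location joins the sample, and a
  suppressive surround (Chebyshev annulus, default width 2 units/level,
  factor 0.1) is imposed around each level's selection *as it is formed*.
  The result is the **attentional sample**: a rooted, top-to-bottom
  connected subset of the hierarchy that is the model's representation of
  "what is attended". Two well-separated items with distinct features are
  never co-selected — the suite checks this on generated displays.
* **Re-analysis (stage E).** A second feedforward pass with the surround
  suppression in place. Because attenuation removes suppressed units from
  both the drive *and* the pooling mass (the weighted mean re-normalizes by
  the surviving weights), cleaning the surround genuinely raises the
  attended top-level response rather than merely lowering everything else.
  This is the one place the implementation departs from a fixed-normalizer
  window mean, and it is what makes "re-analysis improves the attended
  response" an arithmetical fact the suite verifies on 100 cluttered
  displays rather than a hope.
* **Disengage.** Operationally defined: lift *all* surround suppression
  (spatial and featural) and inhibit the pathways of the blackboard's
  current attentional sample. The second half is the object-based inhibition
  of return (IOR); flags persist for a configurable horizon (default 3
  attentive cycles) and then release. Pathway flags are retinotopic, so an
  overt saccade clears them — after the retina moves they no longer point at
  the previously attended object; the world-frame fixation history carries
  IOR across gaze shifts instead.
* **Fixation control.** Saliency is computed *only in the periphery*: the
  peripheral priority map (PPM) is rectified center–surround feature
  contrast, zeroed inside the central field. (This contrast operator is a
  deliberately simple saliency stand-in behind the same interface a richer
  model would use.) The fixation history map (FHM) lives in *world*
  coordinates — larger than the retina — so its inhibition survives any
  saccade sequence and prevents gaze oscillation; entries decay by λ per
  update and expire below ε. The history-biased priority map (HBPM) is
  `saliency · (1 − inhibition)` with inhibition combined by max (bounded,
  order-independent), the current cFOA marked but exempt from peripheral
  competition, and a task-demand override that ignores history entirely.
  The next fixation is the highest-priority candidate satisfying the task
  predicate; "none above the floor" (default 5 % of the map maximum) is the
  termination signal.
* **Memories.** The method long-term memory is an associative store keyed by
  exact task-descriptor terms, ranked by overlap — deterministic and
  testable, which is all fast associative access requires here. The visual
  working-memory blackboard holds the current attentional sample plus a
  bounded history (default 10; no decay is applied — capacity bounding was
  chosen over a second decay process). The task working-memory notepad is an
  append-only trace of samples, fixations and checkpoint outcomes plus a
  key–value store.
* **The executive.** Methods are directed graphs of four node kinds
  (transfer / process / select / set-parameters) with one start, one end,
  parallel groups joined at a barrier, and explicitly marked cycle-repeat
  edges as the only cycles. The task executive fetches a method, binds every
  open slot from the task (failing loudly on an unbindable slot), and walks
  the graph; the attention executive translates the task type into control
  signals and owns the staged cycle. A script monitor checks declared
  checkpoints after monitored nodes and applies a three-step remediation
  ladder: re-select barring the failed winner, refetch the next-ranked
  method, abort. Parallel groups are executed serially in declaration order
  behind the barrier contract — determinism and reproducible logs were
  preferred over concurrency machinery.

The stage policy is a fixed mapping: discrimination-class tasks run B–C
only; within-category identification adds a partial recurrent pass (D, one
level); full localization runs a complete D and the re-analysis pass E;
search and tracing run the full cycle repeatedly. One reading of the staged
account would attach E to every task with any recurrent pass; the package
runs E only for full-depth tasks, which keeps within-category
identification at "partial D" as the policy states.

## The model clock

All timestamps are model milliseconds, never wall-clock. Defaults: priming
lead 150 ms (configurable 80–300), feedforward traversal 150 ms, full
top-down pass 125 ms (configurable 100–150; a partial pass costs
proportionally), selection decision 25 ms, saccade 30 ms. The clock starts
at `-lead` so priming events precede stimulus onset at `t = 0`; every event
carries its cost, so total model time is exactly the sum of logged stage
costs (the suite recomputes this from the log). Model response time for a
task is the final clock value.

## Curve tracing

The tracing program decides whether two X markers lie on the same curve. It
orients to the first marker it detects, then repeats an attentive cycle:
localize the curve at the focus, extend the *traced set* by the along-curve
geodesic ball of radius one attentional-field radius around the focus (one
field extension per cycle), record fixation and traced pixels in the FHM,
and choose the next focus along the uninhibited curve — covertly when the
frontier is still inside the central field, by saccade through the
PPM/HBPM machinery when it is peripheral. The continuation constraint is
adjacency to the traced frontier along the curve; because successive
geodesic balls overlap, the traced set grows contiguously and can never
strand an untraced gap. The run ends "same" when the second marker enters
the traced set, "different" when no eligible continuation remains (the
other curve is never eligible: it is not curve-connected to the frontier).

Two consequences worth noting. First, when the whole curve fits inside the
central field the same program completes covertly in one cycle with no
saccades — the small-display regime. Second, the number of cycles is
proportional to the along-curve distance between the markers divided by the
field radius, so mean model RT increases monotonically with along-curve
distance, qualitatively echoing human curve-tracing RTs. The package claims
only monotonicity, not the human tracing rate — the architecture provides
no mechanism-level derivation of a degrees-per-second constant, so fitting
one would be decoration.

Whether tracing advances in many small covert sub-steps or one jump per
cycle is not settled by the architecture; the implementation advances one
field extension per attentive cycle and exposes the field radius as the
knob that sets the tracing granularity.

## The stimulus laboratory and what passing tests mean

All displays are generated in-package with exact ground truth: ring
displays (items equally spaced on a circle, per-item feature vectors,
optional intensity jitter), single-stimulus discrimination displays (class
A/B by channel, or channel-uncorrelated noise texture), and curve displays
(constrained random walks with bounded curvature, rejected and re-drawn on
self-approach or on coming within 3 px of another curve, with X markers
placed at controlled along-curve positions). Generation is a pure function
of the seed, bit for bit.

The canonical demo conditions fix the geometry: tracing uses 128×128 px at
0.1°/px with marker separations spanning 2.2–8.8° and a 1.2° attentional
field for tracing tasks, so that the longest separations need several
cycles and (for peripheral continuations) saccades; search uses rings of
2–8 items at 0.5°/px, inside the 10° field for covert search and at 12°
eccentricity for overt search, with the retina sized to cover the display
from any fixation in exhaustive-scan demonstrations. Curve width (1 px),
item size (5 px), and the minimum curve separation (3 px) are parameters of
the laboratory, not claims about stimuli.

These synthetic displays are noiseless, geometrically clean, and encode
features as separate channels rather than as pixels to be decoded. Passing
tests therefore demonstrate the *control* claims — staging, selection
structure, the two IOR mechanisms, disengage semantics, monotone tracing
RT, priming benefit — under ideal front-end conditions. They do not show
that the tiny mean-pooling pyramid would survive natural images, learned
feature confusability, sensor noise, or crowding; the hierarchy is a
placeholder for any ST-compatible front end, and the executive is the
contribution.

## Numerical choices and degenerate inputs

* Coordinates are 1-based (row, col) from the top-left, the R convention,
  applied uniformly to images, hierarchy levels and world frames.
* All ties anywhere (θ-WTA peaks, peak picking, candidate order) break
  lexicographically to the smallest (row, col); every stochastic component
  draws from the run seed. Two runs with identical configuration and seed
  produce byte-identical event logs.
* An all-zero admissible map is a first-class "no winner" signal, not an
  error: it drives target-absent negatives and scan termination.
* A blank blackboard makes disengage a no-op; an empty method memory fails
  the run with reason `"no method"`; a saccade without a prior disengage in
  the same cycle is a sequencing error by contract.
* Rectified center–surround contrast zaps float residue below 1e-9 so
  uniform images are exactly silent.
* The suppression-weighted pooling mean falls back to 0 when an entire
  window is suppressed or inhibited (zero mass).

## Known limitations

The feature hierarchy is unlearned and far shallower than any cortical
model; surround strength and extent are free parameters with defaults
(0.1, 2 units/level) chosen for clear demonstrations, not fitted to
modulation data; the saliency stand-in has no natural-scene statistics;
firing-rate time courses are out of scope — the model clock bills fixed
stage costs; and method graphs are hand-written data, since where such
programs come from (learning, composition) is an open question the
architecture itself leaves open.
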