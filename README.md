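# visattn

An executable executive controller for selective visual attention.

Most computational accounts of vision treat the visual system as a passive
feedforward classifier. `visattn` implements the opposite view, in the
Selective Tuning tradition: a task *tunes* the visual hierarchy before a
stimulus appears, a single feedforward pass supports only coarse decisions,
and localization, clean re-analysis, serial search and curve tracing are
produced by recurrent top-down selection under an executive that sequences,
monitors and repairs the whole process. The package is for computational
neuroscientists and cognitive modellers who want those control claims as
running, testable code rather than as box-and-arrow diagrams.

What is implemented:

* a retinotopic feature pyramid with top-down **priming** (multiplicative
  channel gains, 80–300 ms before onset), **surround suppression** and
  **pathway inhibition** — and no feedforward max anywhere;
* **θ-WTA** selection: the spatially connected set of responses within
  `(1 − θ)·max`, not a single unit; applied at the top of the hierarchy it
  yields the central focus of attention (cFOA);
* **recurrent localization** descending the pyramid under receptive-field
  restriction, imposing a suppressive surround per level and returning the
  **attentional sample** — the rooted, connected subset of the hierarchy
  representing what is attended — followed by a re-analysis pass that
  measurably improves the attended response;
* **fixation control**: peripheral-only saliency (PPM), a world-frame
  decaying fixation history (FHM), their combination (HBPM), next-fixation
  selection under task constraints, and saccade execution;
* two kinds of **inhibition of return** — object-based (inhibited pathways,
  the operational definition of *disengaging attention*) and location-based
  (fixation history) — arising from different mechanisms at different times;
* **memories**: an associative method store, a working-memory blackboard of
  attentional samples, and an append-only task notepad;
* a **script engine** executing cognitive-program graphs (transfer /
  process / select / set-parameters nodes, parallel groups, repeat edges)
  with slot binding, a checkpoint monitor and a three-step remediation
  ladder, under a deterministic model clock;
* five shipped programs: discrimination, covert search, overt search,
  localize/reinterpret, and curve tracing;
* a **stimulus laboratory** generating every test display (rings,
  discrimination stimuli, non-crossing curves with X markers) with exact
  ground truth, bit-reproducibly from a seed.

## A worked example: curve tracing

Decide whether two X markers lie on the same curve, on a 12.8° display with
a 1.2° attentional field (so the 6.6° along-curve separation needs several
attentive cycles and saccades):

```r
library(visattn)
d <- demo_trace_display(seed = 11, arc_deg = 6.6, same_curve = TRUE)
r <- run_curve_trace(demo_trace_task(), d$image,
                     config = list(deg_per_pixel = 0.1))
cat("outcome:", r$outcome, "\n")
cat("model RT:", r$rt_ms, "ms\n")
cat("cycles:", r$result$cycles, " saccades:", r$result$saccades, "\n")
```

```
outcome: same
model RT: 3155 ms
cycles: 7  saccades: 6
```

The decision is correct ("same"), reached after 7 attentive cycles and 6
saccades along the curve; 3155 ms is model time — the sum of the logged
stage costs (priming lead, feedforward traversals, top-down passes,
decisions, saccades), not wall-clock time. The event log shows the control
structure directly; note priming and disengage running *before* stimulus
onset:

```r
head(eventlog_df(r$log)[, c("t", "component", "event")], 12)
#>     t component           event
#>  -150       vTE      run_header
#>  -150       vTE    receive_task
#>  -150       vTE    fetch_method
#>  -150       vTE     tune_script
#>  -150       vAE stage_B_priming
#>  -150       vAE       disengage
#>  -150       vAE  set_parameters
#>  -150       vTE         barrier
#>  -150       vTE     trace_start
#>  -150       vAE       disengage
#>  -120        FC         saccade
#>    30     world  stimulus_onset
```

Covert search over a ring of eight items, with the target channel primed:

```r
ds <- demo_covert_display(seed = 3, n_items = 8, target_index = 5)
tk <- task_spec("search_covert", target = list(channel = "colorA"))
rs <- vte_run(tk, ds$image, config = list(deg_per_pixel = 0.5))
cat(rs$outcome, "in", rs$cycles, "cycle(s),", rs$model_time_ms, "ms\n")
#> done_positive in 1 cycle(s), 475 ms
```

Priming doubles the target channel's gain, so the target wins the first
θ-WTA competition; without priming the search proceeds serially under
object-based inhibition of return.

There is also a command line (`inst/cli/visattn`) with `gen`, `run`,
`trace` and `inspect` subcommands that write event logs (JSONL), fixation
traces (CSV), attentional samples (JSON) and PNG overlays.

## Documentation

The methods vignette (`vignettes/attention-executive.Rmd`) describes the
model and its assumptions, every tunable parameter with units and defaults,
what the synthetic displays do and do not emulate, and the design decisions
taken where the architecture leaves choices open.
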