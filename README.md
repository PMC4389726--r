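# rivulet

Reactive dataflow processing for experimental data streams, in R.

Modern behavior and physiology experiments juggle many asynchronous,
parallel data streams — camera frames, key presses, amplifier sample
buffers, reward-site events — and the control logic that ties them together
(trial state machines, closed-loop stimulation, triggered recording) is
awkward to express as a sequential program. rivulet models every stream as
a push-based **observable sequence** on a shared, deterministic
**virtual-time scheduler**, and builds experiments by composing streams
with a small operator algebra. It is aimed at researchers and tool builders
who want to prototype and *test* event-driven acquisition and control logic
on their desk, with scripted or synthetic inputs, before (or instead of)
touching hardware.

## The model

An observable sequence delivers notifications `next* (completed | error)?`
with non-decreasing virtual timestamps. Operators consume and produce
sequences:

* **Transforms / conditions / sinks** — `rx_map()`, `rx_filter()`,
  `rx_sink()`: element-wise, never change timing; sinks only add side
  effects.
* **Combinators** — `rx_sample(data, trigger)` (latest value at each
  trigger), `rx_merge()` (time-ordered interleave), `rx_timestamp()`,
  `rx_take(n)` (truncate, completing at the n-th element's tick),
  `rx_repeat(factory)` (resubscribe a blueprint on completion — the
  iteration primitive behind trial loops).
* **Windows** — `window_count(count, skip)`, `window_time(duration)`,
  `window_trigger(boundary)` slice a stream into sub-sequences, and
  `select_many(windows, inner)` runs a *fresh, state-isolated* inner
  dataflow per window, merging all outputs by time. A sliding mean is
  literally `window_count(k, 1)` + per-window mean
  (`moving_average(src, k)`); splitting a video into one file per trigger
  is `window_trigger` + a `frame_writer` inside `select_many`.

Timelines are written as **marble diagrams**, which double as an executable
test DSL: `"a-b|"` is a value at tick 0, one at tick 2, completion at tick
3; `(a|)` groups simultaneous notifications; `#` is an error.
`run_marble_test()` runs a pipeline over scripted hot sources and compares
the recorded output notification-by-notification:

```r
run_marble_test(list("a-b|"), function(s) rx_take(s, 1), "(a|)")
#> PASS
```

On top of the engine sit:

* a **dataflow-graph model** (`stream_node()`, `dataflow_graph()`,
  `validate_graph()`, `build_graph()`) with typed node categories (source,
  combinator, transform, condition, sink, property, nested), DAG
  validation, nested groups, externalized properties (a node parameter
  driven by another stream at runtime) and a YAML workflow format
  (`save_workflow()` / `load_workflow()`);
* **vision operators**: `grayscale()`, `threshold_range()`,
  `largest_component()` (8-connected), `blob_measure()` (image-moment
  centroid, orientation, major axis), `track_largest()`, `roi_monitor()`
  (enter/exit events for closed-loop stimulation), and a bit-exact raw
  frame container;
* **ephys operators**: `bandpass()` (causal 2nd-order biquad with state
  carried across buffer boundaries), `detect_spikes()` (threshold crossing,
  trough-aligned, refractory), `extract_triggered()` (spike-triggered
  multichannel windows), flat int16 binary I/O;
* **task control**: `chain_states()` + `rx_repeat()` for reactive state
  machines, `reaction_time_task()`, and multi-site foraging
  (`foraging_site()`, `foraging_multisite()`) where a reward is delivered
  only when a sample event coincides with an armed availability window —
  one small dataflow per site, replicated, instead of an exponentially
  growing product state machine (`fsm_explosion_count()`);
* **synthetic fixtures**: seeded generators for moving-dot / rotating-bar
  videos with ground truth (`gen_dot_video()`), multichannel signals with
  injected biphasic spikes (`gen_spike_signal()`), and scripted or Poisson
  event schedules (`gen_event_schedule()`).

## Worked example

Snapshots on key presses — the latest camera frame is sampled whenever a
key arrives:

```r
library(rivulet)
sched  <- virtual_scheduler()
frames <- events_stream(sched, times = 0:9, values = as.list(paste0("frame", 0:9)))
keys   <- events_stream(sched, times = c(2.5, 6.5))
rec    <- record(rx_sample(frames, keys))
run_until_idle(sched)
for (n in recorded_log(rec)) print(n)
#> next(frame2)@2.5
#> next(frame6)@6.5
```

Each key press captured the most recent frame, at the key's tick. A
window-based moving average (k = 3) over the ramp `1 3 5 7 9 11`:

```r
sched <- virtual_scheduler()
src   <- events_stream(sched, times = 1:6, values = as.list(c(1, 3, 5, 7, 9, 11)),
                       complete_at = 6)
out   <- record(moving_average(src, 3))
run_until_idle(sched)
for (n in recorded_log(out)) print(n)
#> next(3)@3
#> next(5)@4
#> next(7)@5
#> next(9)@6
#> completed@6
```

Each mean is emitted at the tick its window completes — time-shifted by the
two "future" samples every window waits for — and trailing partial windows
are dropped.

Command-line demos (tracking, triggered video splitting, a reaction-time
task, two-site foraging, spike detection) run over the synthetic fixtures:

```sh
Rscript inst/scripts/rivulet-cli.R demo tracking --until 300 --out out/
#> tracked 300 frames; RMS error 0.088 px
Rscript inst/scripts/rivulet-cli.R demo rt-task --until 2000 --out out/
#> completed 71 trials; mean rt 8.08 ticks
```

`validate <workflow.yaml>` and `run <workflow.yaml> --until T --out DIR`
operate on saved workflow files (schema in
`inst/extdata/workflow-schema.json`).

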