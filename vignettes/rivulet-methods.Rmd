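---
title: "Deterministic reactive dataflows for experimental streams: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic reactive dataflows for experimental streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivulet)
```

# The model

rivulet treats an experiment as a set of asynchronous event streams
composed by operators. Each stream is an *observable sequence*: a producer
pushes zero or more `next` notifications, followed by at most one terminal
(`completed` or `error`), to whoever has subscribed. The grammar
`next* (completed | error)?` and the non-decreasing-time requirement are
enforced centrally by the subscription machinery, so every operator only
needs to be correct on the common path; a misbehaving producer or a raising
observer callback cannot corrupt downstream state.

Two properties make the whole system testable in a way event-driven code
usually is not:

* **Virtual time.** All delivery is driven by a scheduler whose clock
  advances only when the caller asks it to (`advance_to()`,
  `run_until_idle()`). Ticks are unitless; fixtures typically use one tick
  per frame or per buffer. Wall-clock execution would be a drop-in
  replacement for the scheduler interface, but is deliberately out of scope
  here: determinism is the point.
* **Total event order.** Queued actions execute in
  `(time, priority, sequence)` order. `priority` is a rank assigned to each
  source at creation, so simultaneous events from different devices fire in
  source-creation order (which equals subscription order in every pipeline
  this package builds); `sequence` (assignment order) breaks all remaining
  ties. No ordering is left to chance — the same scripts always produce
  byte-identical logs. The cross-source rule is a design choice on a point
  the underlying execution model leaves open; internal bookkeeping actions
  (e.g. the resubscription step of `rx_repeat()`) rank after same-tick
  source events, with the visible consequence that an input landing exactly
  on a trial boundary belongs to no trial rather than nondeterministically
  to one of the two.

Marble diagrams serve as the executable specification language:
`parse_marble()` maps one character per tick (`-` silence, `|` completion,
`#` error, `(...)` simultaneity groups stamped with the opening index), and
`run_marble_test()` compares a pipeline's recorded output
notification-by-notification against an expected diagram.

## Hot and cold sources

Device-like sources (cameras, keyboards, amplifiers) are *hot*: they
broadcast on their own schedule and late subscribers miss earlier events.
Blueprint-like sources (timers, per-trial scripts) are *cold*: each
subscription replays the script relative to the subscription tick. This
distinction carries real semantics in the task layer: a state machine's
timer is cold (re-armed per activation), its response keys are hot (a key
nobody is listening for is simply lost, as in a real rig).

# Operator semantics worth stating

* `rx_sample(data, trigger)` emits the *latest* data value at every trigger,
  repeating an unchanged value on rapid triggers. The alternative
  ("only if new") exists in some reactive libraries; here every trigger is
  an intentional acquisition (every key press saves a snapshot), so
  repeat-latest is the right default. Output completes when the data stream
  completes; the trigger completing merely stops sampling.
* `rx_take(n)` completes *at the n-th element's tick*, not one tick later.
  This same-tick completion is what lets a `take(1)`-truncated stream act
  as a state-exit edge with zero added latency.
* `rx_repeat(factory)` resubscribes a fresh instance when the previous one
  completes, at the same tick via a queued action. A blueprint that
  completes at its own subscription tick twice in a row trips a
  "zero-time loop" error — otherwise virtual time would freeze while the
  queue grows forever.
* Property bindings (`property_binding()` / `bind_property()`) model
  externalized node parameters as a stream writing into a mutable cell.
  The entire visibility contract is: an update at tick *t* is seen by any
  element processed at a later tick; same-tick races resolve by the global
  event order, and two updates in one tick end last-writer-wins.

# Windows and per-window dataflows

`window_count(count, skip)` opens a window at elements `0, skip, 2*skip, …`;
windows close after `count` elements or at source completion. Two policy
decisions:

* **Trailing partial windows are emitted.** Conservation is the primary
  invariant — with `skip == count` the concatenated windows reproduce the
  source exactly — and any averaging policy can drop partials downstream
  (as `moving_average()` does). Suppressing them in the operator would make
  conservation unrecoverable.
* **Multiplicity.** With overlap (`skip < count`), interior elements appear
  `count/skip` times exactly when `skip` divides `count`; otherwise
  membership alternates between `floor(count/skip)` and
  `ceiling(count/skip)` — a direct consequence of covering an integer line
  with arithmetic-progression intervals. The tests assert the exact value
  on divisible pairs and the floor/ceil bound elsewhere.

`window_time(duration)` uses half-open intervals
`[k·duration, (k+1)·duration)` — an element exactly on a boundary belongs
to the later window — and emits empty windows for element-free intervals so
window indices track wall time. `window_trigger(boundary)` opens the first
window at subscription and rolls on each boundary event.

`select_many(windows, inner)` instantiates `inner` freshly per window: the
instances share the scheduler and nothing else, which is what makes
per-window file sinks (one file per trigger) and state-machine states (one
isolated dataflow per activation) safe. Same-tick outputs from overlapping
windows merge lowest-window-id first, because inners are subscribed in
window-open order.

# The dataflow-graph layer

Graphs are lists of typed nodes (source, combinator, transform, condition,
sink, property, nested) with slot-ordered edges; arity is fixed by
category. Validation returns diagnostics (naming the node and the rule)
rather than throwing, so a front end can present them all at once; building
an invalid graph is an error. The builder instantiates nodes in topological
order, multicasts every node output (one upstream run regardless of how
many taps attach), wires property nodes into their target's parameter
environment, and subscribes sinks so the pipeline runs as time advances.

The workflow file format is YAML with keys `nodes` / `edges` / `groups`
(JSON Schema in `inst/extdata/workflow-schema.json`). It is an original
design for this package — readable, diffable, and round-trip exact
(`load_workflow(save_workflow(g))` is structurally identical; numeric
parameters are written with 12 significant digits for that reason). Nested
groups use `input` placeholder sources (one per inbound edge) and a single
`output` sink; a nested node builds either as an encapsulated sub-pipeline
(`group`) or as a per-window blueprint (`select_many`).

The command-line layer (`run_cli()`, wrapped by
`inst/scripts/rivulet-cli.R`) validates and runs workflow files against
named built-in fixtures and ships six self-contained demos; it is a thin
veneer — every capability is an exported function first.

# Vision operators

Conventions, stated because image processing is where silent convention
mismatches hurt most: pixels are 0-based, origin top-left, `x` along
columns, `y` along rows downward; connectivity is 8-way; among equal-size
components the one whose first pixel comes earliest in (row, col) scan
order wins, so segmentation is deterministic even on ties.

`blob_measure()` uses the standard image-moment definitions: centroid
`(M10/M00, M01/M00)`; orientation
`0.5·atan2(2µ′11, µ′20 − µ′02)` in degrees, reported in `(-90, 90]`
measured from +x toward +y (down); major axis `4·sqrt(λ1)` with `λ1` the
larger eigenvalue of the normalized second-moment matrix (the ellipse
model: for a solid ellipse of semi-axes a ≥ b, `4·sqrt(λ1) = 2a`). These
formulas are the field's standard choice, adopted here explicitly since
orientation conventions are never self-evident. A 1×9 bar has
`µ′20 = 80/12`, hence major axis `4·sqrt(80/12) ≈ 10.33` — a handy
closed-form check.

`roi_monitor()` is edge-triggered on a half-open rectangle with initial
state "outside", so enter/exit events strictly alternate and the digital
output level is 1 exactly while inside — the shape a stimulation controller
wants.

The raw frame container (one JSON header line, then row-major 8-bit frame
bytes) exists because bit-exact round trips are a correctness primitive
here; compressed video encoding is explicitly not.

# Ephys operators

* **Filtering** is causal only — zero-phase filtering is unrealizable in an
  online stream and is deliberately not offered. The band-pass is one
  bilinear-transform Butterworth biquad (coefficients from
  `signal::butter(1, ·, "pass")`); the streaming applier carries the last
  two inputs and outputs per channel across buffer boundaries and was
  verified exactly (0 difference) against the one-sample-at-a-time
  difference equation before being adopted.
* **Spike detection** aligns events on the signal extremum (trough for
  negative thresholds) within the `refractory` span after the crossing,
  rather than on the crossing itself: trough alignment is what keeps
  spike-triggered averages sharp. Later crossings within `refractory`
  samples of the trough are suppressed. Crossings whose alignment span is
  not yet buffered are deferred to the next buffer, which is what makes
  detection invariant to chunking; at stream completion pending crossings
  are finalized over whatever samples exist.
* **Triggered extraction** serves each event the all-channel slice
  `[index − pre, index + post]` once the trailing context arrives; events
  whose window would run off either edge are dropped and counted (the count
  is exposed, not hidden). History retention is `pre + post + 1` samples
  plus two buffers of slack, because events produced by a detector
  downstream of the same source arrive up to a buffer after the samples
  they reference.
* The flat int16 format is little-endian, sample-major interleaved — the
  common denominator of flat extracellular formats — with values clipped on
  write and a hard error on files whose length is not a multiple of
  `2 × channels`.

# Task control

A state is a `state_spec`: entry actions plus an exit-trigger blueprint,
always truncated with `take(1)`. `chain_states()` emits a transition record
at each activation and hands control to the next state at the exit tick;
under `rx_repeat()` this is a trial loop. An exit stream that completes
without emitting also advances the machine — timers emit-then-complete, so
both conventions compose.

The foraging rule: each availability event arms its site until
`min(next availability, availability + w)`; a new availability *replaces*
a pending one (a single-item site — the old item rots), the first sample
while armed delivers the reward and disarms, and a sample exactly at
`availability + w` still collects (closed window). Under per-tick Bernoulli
sampling at rate λS this yields a per-availability success probability
`1 − (1 − λS)^L` with `L = min(gap − 1, w) + 1` armed ticks, the closed
form the tests check the simulation against (alongside exact agreement
with an event-sweep oracle). Multi-site foraging is literally the same
dataflow replicated per site and merged — linear growth in sites, versus
the `states^sites` product machine a single flat state machine would need
(`fsm_explosion_count()` computes both for the demo report).

Keys during the Ready state of the reaction-time task are ignored (Go only
subscribes to keys at stimulus onset) — the simplest defensible reading of
a two-state trial; aborting the trial on early presses would be a different
task.

# Synthetic fixtures: what they do and do not show

The generators are pure functions of their configuration (same seed, same
bytes) and restore the caller's RNG state. The defaults are desk-scale
stand-ins for the real thing:

* `gen_dot_video()`: 64×64 8-bit frames, a radius-6 disc of intensity 255
  (or a 40×6 bar) on a Gaussian background (mean 20, σ 5–10 in tests),
  moving on a smooth incommensurate-period path with per-frame ground
  truth. With these contrasts the binarized object is essentially
  noise-free, so tracking accuracy measures discretization (≈0.09 px RMS,
  ≤1.4° orientation error), not robustness to low contrast, occlusion,
  shadows or shape change — passing these tests says the geometry is
  computed correctly, not that a mouse in a messy arena will track.
* `gen_spike_signal()`: i.i.d. Gaussian noise per channel plus a biphasic
  template (sharp trough, slow rebound) at scripted or exponential-gap
  times, scaled 0.3× on neighbor channels. Real recordings have correlated
  noise, drift, overlapping units and amplitude variability; recovery at
  trough SNR 8 with troughs ≥ 2 refractory periods apart is the regime
  where precision = recall = 1 is the *correct* answer, and that is what is
  asserted.
* `gen_event_schedule()`: explicit lists, or geometric gaps (discrete
  Poisson) so the per-tick Bernoulli closed form above is exact rather than
  an approximation.

Problem sizes used by the verification runs — 500 random scripts of up to
30 events for the operator-oracle sweep, 10⁴ samples for the moving
average, 60 frames for triggered splitting, 100 scripted trials, ~10⁴
availabilities over 5·10⁵ ticks for foraging, 300 frames for tracking, 100
injected spikes at 30 kHz — were chosen so the full suite runs in about a
minute on one core while keeping every statistical check comfortably
powered.

# Numerical and degenerate-input choices

* Virtual times are numeric; integer ticks are conventional, fractional
  ticks legal (used to place triggers between frames).
* An empty cold script completes at the subscription tick; an empty merge
  input list is rejected (there is no scheduler to complete on).
* `take(n)` requires a positive integer at construction; band-pass corners
  must satisfy `0 < low < high < rate/2` and surface as a stream error when
  discovered on a live stream.
* Empty masks: `largest_component()` returns `NULL` (skip the frame);
  `blob_measure()` on an empty component is an error by contract.
* int16 clipping on write is silent and saturating.

# Known limitations

* The engine is single-threaded by design; "parallelism" is interleaving
  under virtual time. This is the right tool for semantics and testing, not
  a real-time acquisition runtime.
* No backpressure: producers push, consumers must keep up (an R callback
  that cannot keep up slows the virtual run, it never drops data — unlike a
  real rig).
* The scheduler's queue is a scanned vector, fine for the 10⁴–10⁵ events of
  these workloads; a heap would be the first change for much larger runs.
* Zip/combine-latest style operators, session windows and sliding time
  windows are intentionally absent; the windowing trio plus `select_many`
  covers the targeted designs.
* The YAML workflow dialect is this package's own; no interchange with any
  external editor's file format is attempted.
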