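Package: rivulet
Title: Reactive Dataflow Processing for Behavioral and Neurophysiology Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A push-based observable-sequence engine with a deterministic
    virtual-time scheduler and a marble-diagram testing DSL, together with the
    stream combinators (map, filter, sink, sample, take, repeat, merge,
    timestamp), count/time/trigger windowing with per-window dataflow
    instantiation, and a declarative dataflow-graph model with nested groups,
    externalized properties and a YAML workflow format. Ships operator packs
    for animal video tracking (threshold segmentation, connected components,
    image-moment centroid/orientation, region-of-interest events), buffered
    electrophysiology (streaming band-pass filtering, threshold spike
    detection, spike-triggered waveform extraction, raw int16 binary I/O) and
    reactive task control (state machines built from take/repeat/window
    operators, reaction-time tasks, multi-site foraging with coincidence
    detection), all exercised on seeded synthetic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
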