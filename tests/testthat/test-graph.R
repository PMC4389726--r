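two_node_graph <- function() {
  dataflow_graph(
    nodes = list(
      stream_node("src", "source", "events", params = list(times = c(1, 2))),
      stream_node("out", "sink", "log")),
    edges = list(list(from = "src", to = "out")))
}

test_that("a valid source-to-sink graph has no diagnostics", {
  expect_equal(validate_graph(two_node_graph(), default_registry()),
               character(0))
})

test_that("cycles, bad arity and unknown operators are diagnosed by name", {
  cyc <- dataflow_graph(
    nodes = list(stream_node("a", "transform", "map", list(fn = "identity")),
                 stream_node("b", "transform", "map", list(fn = "identity"))),
    edges = list(list(from = "a", to = "b"), list(from = "b", to = "a")))
  d <- validate_graph(cyc)
  expect_true(any(grepl("cycle", d)))

  bad_arity <- dataflow_graph(
    nodes = list(
      stream_node("s1", "source", "events", list(times = 1)),
      stream_node("s2", "source", "events", list(times = 2)),
      stream_node("t", "transform", "map", list(fn = "identity"))),
    edges = list(list(from = "s1", to = "t"), list(from = "s2", to = "t")))
  d <- validate_graph(bad_arity)
  expect_true(any(grepl("arity.*'t'.*transform", d)))

  unknown <- dataflow_graph(
    nodes = list(stream_node("s", "source", "warp_drive")), edges = list())
  d <- validate_graph(unknown, default_registry())
  expect_true(any(grepl("unregistered operator 'warp_drive'", d)))

  dangling <- dataflow_graph(
    nodes = list(stream_node("s", "source", "events", list(times = 1))),
    edges = list(list(from = "s", to = "ghost")))
  expect_true(any(grepl("unknown target node 'ghost'",
                        validate_graph(dangling))))
})

test_that("a single source node builds into a pipeline emitting it", {
  g <- dataflow_graph(
    nodes = list(stream_node("src", "source", "events",
                             params = list(times = c(3, 5)))),
    edges = list())
  sched <- virtual_scheduler()
  p <- build_graph(g, sched)
  vals <- collect_values(p$taps[["src"]], sched)
  expect_equal(unlist(vals), c(3, 5))
})

test_that("building an invalid graph fails loudly", {
  g <- dataflow_graph(
    nodes = list(stream_node("a", "transform", "map", list(fn = "identity"))),
    edges = list())
  sched <- virtual_scheduler()
  expect_error(build_graph(g, sched), "invalid graph")
})

test_that("the snapshot pipeline saves one grayscale frame per key press", {
  # camera -> grayscale -> sampled by keypress -> file sink
  n <- 12
  rgb_frames <- lapply(seq_len(n), function(i)
    array(rep(matrix((i * 7L) %% 256L, 4, 4), 3), dim = c(4, 4, 3)))
  key_times <- c(2.5, 6.5, 9.5)
  dir <- withr::local_tempdir()
  g <- dataflow_graph(
    nodes = list(
      stream_node("camera", "source", "fixture", params = list(name = "cam")),
      stream_node("gray", "transform", "grayscale"),
      stream_node("keys", "source", "fixture", params = list(name = "keys")),
      stream_node("snap", "combinator", "sample"),
      stream_node("save", "sink", "frame_writer",
                  params = list(path = "snaps.bin"))),
    edges = list(list(from = "camera", to = "gray"),
                 list(from = "gray", to = "snap", slot = 0),
                 list(from = "keys", to = "snap", slot = 1),
                 list(from = "snap", to = "save")))
  sched <- virtual_scheduler()
  fixtures <- list(cam = frames_stream(sched, rgb_frames),
                   keys = events_stream(sched, key_times))
  p <- build_graph(g, sched, fixtures = fixtures, out_dir = dir)
  run_until_idle(sched)
  saved <- read_frames(file.path(dir, "snaps.bin"))
  expect_equal(length(saved), length(key_times))
  # each snapshot is the latest frame before its key, in grayscale
  expect_equal(saved[[1]], matrix((3L * 7L) %% 256L, 4, 4))
  expect_equal(saved[[2]], matrix((7L * 7L) %% 256L, 4, 4))
})

test_that("property nodes retune a downstream threshold at runtime", {
  g <- dataflow_graph(
    nodes = list(
      stream_node("src", "source", "events", params = list(times = c(1, 3))),
      stream_node("knob", "source", "events", params = list(times = 2)),
      stream_node("set_thr", "property", "property",
                  params = list(target = "gate", property = "threshold")),
      stream_node("gate", "condition", "above",
                  params = list(threshold = 10)),
      stream_node("out", "sink", "log")),
    edges = list(list(from = "src", to = "gate"),
                 list(from = "knob", to = "set_thr"),
                 list(from = "gate", to = "out")))
  # knob emits its own time (2) at tick 2: threshold drops from 10 to 2,
  # so the value 1 at tick 1 is blocked and the value 3 at tick 3 passes
  sched <- virtual_scheduler()
  p <- build_graph(g, sched)
  run_until_idle(sched)
  vals <- vapply(p$logs[["out"]], function(e) e$value, numeric(1))
  expect_equal(vals, 3)
})

test_that("a group node builds its inner dataflow around the inputs", {
  inner <- dataflow_graph(
    nodes = list(
      stream_node("in0", "source", "input"),
      stream_node("double", "transform", "map", params = list(fn = "dbl_fn")),
      stream_node("res", "sink", "output")),
    edges = list(list(from = "in0", to = "double"),
                 list(from = "double", to = "res")))
  g <- dataflow_graph(
    nodes = list(
      stream_node("src", "source", "events", params = list(times = c(1, 2))),
      stream_node("grp", "nested", "group"),
      stream_node("out", "sink", "log")),
    edges = list(list(from = "src", to = "grp"),
                 list(from = "grp", to = "out")),
    groups = list(grp = inner))
  assign("dbl_fn", function(x) x * 2, envir = globalenv())
  withr::defer(rm("dbl_fn", envir = globalenv()))
  sched <- virtual_scheduler()
  p <- build_graph(g, sched)
  run_until_idle(sched)
  expect_equal(vapply(p$logs[["out"]], function(e) e$value, numeric(1)),
               c(2, 4))
})

test_that("group placeholder counts are validated", {
  inner <- dataflow_graph(
    nodes = list(stream_node("res", "sink", "output"),
                 stream_node("in0", "source", "input")),
    edges = list(list(from = "in0", to = "res")))
  g <- dataflow_graph(
    nodes = list(
      stream_node("s1", "source", "events", list(times = 1)),
      stream_node("s2", "source", "events", list(times = 2)),
      stream_node("grp", "nested", "group")),
    edges = list(list(from = "s1", to = "grp"),
                 list(from = "s2", to = "grp")),
    groups = list(grp = inner))
  d <- validate_graph(g, default_registry())
  expect_true(any(grepl("2 external inputs but 1 input placeholders", d)))
})

test_that("a select_many group runs a fresh state-isolated instance per window", {
  # the inner dataflow ends in take(2): if instances shared state, later
  # windows would be truncated to nothing
  inner <- dataflow_graph(
    nodes = list(
      stream_node("in0", "source", "input"),
      stream_node("head", "combinator", "take", params = list(n = 2)),
      stream_node("res", "sink", "output")),
    edges = list(list(from = "in0", to = "head"),
                 list(from = "head", to = "res")))
  g <- dataflow_graph(
    nodes = list(
      stream_node("src", "source", "events",
                  params = list(times = 0:8, complete_at = 8)),
      stream_node("win", "combinator", "window_count",
                  params = list(count = 3, skip = 3)),
      stream_node("sm", "nested", "select_many"),
      stream_node("out", "sink", "log")),
    edges = list(list(from = "src", to = "win"),
                 list(from = "win", to = "sm"),
                 list(from = "sm", to = "out")),
    groups = list(sm = inner))
  sched <- virtual_scheduler()
  p <- build_graph(g, sched)
  run_until_idle(sched)
  vals <- vapply(p$logs[["out"]], function(e) e$value, numeric(1))
  expect_equal(vals, c(0, 1, 3, 4, 6, 7))  # first 2 of each 3-element window
})

test_that("a named user function behaves exactly as rx_map", {
  assign("user_fn_t", function(x) x^2 + 1, envir = globalenv())
  withr::defer(rm("user_fn_t", envir = globalenv()))
  g <- dataflow_graph(
    nodes = list(
      stream_node("src", "source", "events",
                  params = list(times = c(1, 2, 3))),
      stream_node("tf", "transform", "map", params = list(fn = "user_fn_t")),
      stream_node("out", "sink", "log")),
    edges = list(list(from = "src", to = "tf"),
                 list(from = "tf", to = "out")))
  sched <- virtual_scheduler()
  p <- build_graph(g, sched)
  run_until_idle(sched)
  got <- vapply(p$logs[["out"]], function(e) e$value, numeric(1))

  sched2 <- virtual_scheduler()
  want <- unlist(collect_values(
    rx_map(events_stream(sched2, c(1, 2, 3)), function(x) x^2 + 1), sched2))
  expect_equal(got, want)
})

test_that("workflow files round-trip structurally", {
  g <- two_node_graph()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_workflow(g, path)
  expect_true(graph_equal(g, load_workflow(path)))
})

test_that("randomized graphs round-trip through YAML", {
  set.seed(71)
  for (i in 1:10) {
    n_src <- sample(1:3, 1)
    nodes <- lapply(seq_len(n_src), function(k)
      stream_node(paste0("s", k), "source", "events",
                  params = list(times = sort(sample(1:20, 3)))))
    nodes <- c(nodes, list(
      stream_node("m", "combinator", "merge"),
      stream_node("f", "condition", "above",
                  params = list(threshold = stats::runif(1))),
      stream_node("out", "sink", "log")))
    edges <- c(lapply(seq_len(n_src), function(k)
      list(from = paste0("s", k), to = "m", slot = k - 1L)),
      list(list(from = "m", to = "f"), list(from = "f", to = "out")))
    g <- dataflow_graph(nodes, edges)
    path <- withr::local_tempfile(fileext = ".yaml")
    save_workflow(g, path)
    expect_true(graph_equal(g, load_workflow(path)))
  }
})

test_that("unknown categories in workflow files are parse errors", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("nodes:",
               "- id: x",
               "  category: wormhole",
               "  operator: events"), path)
  expect_error(load_workflow(path), "unknown category")
})

test_that("build after save/load produces identical notification logs", {
  g <- dataflow_graph(
    nodes = list(
      stream_node("src", "source", "events",
                  params = list(times = c(1, 2, 3, 4), complete_at = 4)),
      stream_node("ma", "combinator", "moving_average",
                  params = list(k = 2)),
      stream_node("out", "sink", "log")),
    edges = list(list(from = "src", to = "ma"),
                 list(from = "ma", to = "out")))
  run_g <- function(graph) {
    sched <- virtual_scheduler()
    p <- build_graph(graph, sched)
    run_until_idle(sched)
    p$logs[["out"]]
  }
  path <- withr::local_tempfile(fileext = ".yaml")
  save_workflow(g, path)
  expect_identical(run_g(g), run_g(load_workflow(path)))
})

test_that("upstream taps never lag downstream taps at the same tick", {
  g <- dataflow_graph(
    nodes = list(
      stream_node("src", "source", "events", params = list(times = 1:5)),
      stream_node("tf", "transform", "map", params = list(fn = "identity")),
      stream_node("out", "sink", "log")),
    edges = list(list(from = "src", to = "tf"),
                 list(from = "tf", to = "out")))
  sched <- virtual_scheduler()
  p <- build_graph(g, sched)
  rec_up <- record(p$taps[["src"]])
  rec_down <- record(p$taps[["tf"]])
  run_until_idle(sched)
  t_up <- vapply(recorded_log(rec_up), `[[`, numeric(1), "time")
  t_down <- vapply(recorded_log(rec_down), `[[`, numeric(1), "time")
  expect_equal(t_up, 1:5 + 0)
  expect_equal(t_down, t_up)  # per-element delivery introduces no tick lag
})
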