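# End-to-end behavior of the five shipped cognitive programs.

test_that("discrimination answers yes for the target class and no otherwise", {
  spA <- display_spec(64, 64, 0.5, c("colorA", "colorB"), seed = 1)
  tk <- task_spec("discriminate", target = list(channel = "colorA"))
  rA <- vte_run(tk, make_discrimination_display(spA, "A")$image,
                config = list(deg_per_pixel = 0.5))
  expect_identical(rA$outcome, "done_positive")
  rB <- vte_run(tk, make_discrimination_display(spA, "B")$image,
                config = list(deg_per_pixel = 0.5))
  expect_identical(rB$outcome, "done_negative")
  # log follows the scripted order: tune -> priming/disengage/params ->
  # feedforward -> selection -> transfer -> decision
  df <- eventlog_df(rA$log)
  want <- c("receive_task", "fetch_method", "tune_script", "stage_B_priming",
            "disengage", "set_parameters", "barrier", "stimulus_onset",
            "stage_C_feedforward", "cfoa_selected", "transfer_cfoa",
            "decision")
  expect_identical(df$event[df$event %in% want], want)
})

test_that("covert search finds the target without saccades and repeats with disengage", {
  found_cycles <- integer(0)
  for (s in 1:6) {
    d <- demo_covert_display(s, 4, target_index = 1 + (s %% 4))
    tk <- task_spec("search_covert", target = list(channel = "colorA"),
                    priming = FALSE)
    r <- vte_run(tk, d$image, config = list(deg_per_pixel = 0.5))
    expect_identical(r$outcome, "done_positive")
    expect_lte(r$cycles, 4)
    expect_equal(r$saccades, 0L)
    found_cycles <- c(found_cycles, r$cycles)
    df <- eventlog_df(r$log)
    # each repeated cycle is preceded by a disengage
    reps <- sum(vapply(Filter(function(e) e$event == "decide_repeat", r$log),
                       function(e) identical(e$payload$decision, "repeat"),
                       TRUE))
    expect_equal(sum(df$event == "disengage" & df$t > 0), reps)
  }
  expect_gt(max(found_cycles), 1)   # the search is genuinely serial
})

test_that("overt search saccades only when the target is peripheral", {
  d <- demo_overt_display(3, 6, target_index = 4)
  tk <- task_spec("search_overt", target = list(channel = "colorA"))
  r <- vte_run(tk, d$image, config = list(deg_per_pixel = 0.5))
  expect_identical(r$outcome, "done_positive")
  expect_gte(r$saccades, 1L)
  # saccades always follow a disengage within the same cycle
  ev <- r$log
  for (i in seq_along(ev)) {
    if (ev[[i]]$event == "saccade") {
      prior <- Filter(function(e) e$event == "disengage" &&
                        identical(e$payload$cycle, ev[[i]]$payload$cycle),
                      ev[seq_len(i - 1)])
      expect_gt(length(prior), 0)
    }
  }
  # a central target needs no saccade: run the same task covert-style display
  dc <- demo_covert_display(3, 4, target_index = 2)
  rc <- vte_run(tk, dc$image, config = list(deg_per_pixel = 0.5))
  expect_identical(rc$outcome, "done_positive")
  expect_equal(rc$saccades, 0L)
})

test_that("localize/reinterpret writes one valid sample and returns its support", {
  sp <- display_spec(64, 64, 0.5, c("colorA", "colorB"), seed = 8)
  img <- list(colorA = matrix(0, 64, 64), colorB = matrix(0, 64, 64))
  img$colorA[25:32, 25:32] <- 1
  tk <- task_spec("localize", target = list(channel = "colorA"))
  r <- vte_run(tk, img, config = list(deg_per_pixel = 0.5))
  expect_identical(r$outcome, "done_positive")
  expect_identical(sample_support(r$state$vh, r$sample), img$colorA > 0)
  expect_true(isTRUE(sample_is_valid(r$state$vh, r$sample)))
  # exactly one blackboard write per run
  df <- eventlog_df(r$log)
  expect_equal(sum(df$event == "bb_write"), 1L)
})

test_that("curve tracing answers same/different and traces only the target curve", {
  for (s in 1:6) {
    same <- s %% 2 == 0
    r <- demo_trace_run(100 + s, arc_deg = 5.5, same_curve = same)
    expect_identical(r$outcome, if (same) "same" else "different")
    tgt <- traced_curve_index(r$display$truth)
    expect_true(all(curve_mask(r$display$truth, tgt)[r$trace$traced_coords]))
    if (!same) {
      om <- curve_mask(r$display$truth, if (tgt == 1) 2 else 1)
      expect_false(any(om[r$trace$traced_coords]))
    }
  }
})

test_that("a curve inside the attentional field is traced without saccades", {
  # small-display regime: the whole curve fits in the central field
  spec <- display_spec(64, 64, 0.1, c("curve", "marker"), seed = 3)
  d <- make_curve_display(spec, 1, 2.2, 2, TRUE, marker_arc_deg = 1.5,
                          marker_start_deg = 0.3)
  tk <- demo_trace_task(central_radius_deg = 4)
  r <- run_curve_trace(tk, d$image, config = list(deg_per_pixel = 0.1))
  expect_identical(r$outcome, "same")
  expect_lte(r$result$saccades, 1L)   # only the initial orienting saccade
})

test_that("model tracing time grows with along-curve distance", {
  rt <- vapply(c(2.2, 8.8), function(arc) {
    mean(vapply(1:4, function(s) demo_trace_run(s, arc, TRUE)$rt_ms, 0))
  }, 0)
  expect_gt(rt[2], rt[1])
})

test_that("priming shortens covert search", {
  cyc <- function(primed, s) {
    d <- demo_covert_display(s, 8, target_index = 1 + (s %% 8))
    tk <- task_spec("search_covert", target = list(channel = "colorA"),
                    priming = primed)
    vte_run(tk, d$image, config = list(deg_per_pixel = 0.5))$cycles
  }
  pr <- vapply(1:10, function(s) cyc(TRUE, s), 0)
  un <- vapply(1:10, function(s) cyc(FALSE, s), 0)
  expect_true(all(pr <= un))
  expect_true(all(pr == 1))   # a doubled gain makes the target win at once
})
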