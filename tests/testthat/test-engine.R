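taskA <- function(...) task_spec("discriminate", target = list(channel = "colorA"), ...)

test_that("method validation names structural violations", {
  m <- method_discrimination()
  rep <- validate_method(m)
  expect_true(rep$valid)
  expect_identical(rep$start, "receive")
  expect_identical(rep$end, "report")
  # unreachable node
  m2 <- m; m2$nodes$orphan <- cp_node("orphan", "process", "feedforward")
  rep2 <- validate_method(m2)
  expect_false(rep2$valid)
  expect_match(paste(rep2$violations, collapse = ";"), "unreachable")
  # unnamed open slot
  m3 <- m; m3$nodes$match$slots <- c("target", "")
  expect_match(paste(validate_method(m3)$violations, collapse = ";"),
               "unnamed open slot")
  # cycle without a repeat marking
  m4 <- m; m4$edges <- rbind(m4$edges, cp_edge("report", "ff"))
  expect_match(paste(validate_method(m4)$violations, collapse = ";"),
               "cycle")
  # every shipped method validates and shows all four node kinds
  for (f in list(method_discrimination, method_covert_search,
                 method_overt_search, method_localize_reinterpret,
                 method_curve_trace)) {
    m <- f()
    expect_true(validate_method(m)$valid)
    kinds <- unique(vapply(m$nodes, `[[`, "", "kind"))
    expect_setequal(kinds, c("transfer", "process", "select", "set_parameters"))
  }
})

test_that("task translation follows the stage policy deterministically", {
  expect_error(task_spec("fly_to_moon"), "unknown task_type")
  expect_error(task_spec("search_covert"), "target")
  d <- vae_translate_parameters(taskA())
  expect_identical(d$depth, "none"); expect_equal(d$max_cycles, 1L)
  w <- vae_translate_parameters(task_spec("within_category_identify"))
  expect_identical(w$depth, 1L)
  l <- vae_translate_parameters(task_spec("localize"))
  expect_identical(l$depth, "full"); expect_equal(l$max_cycles, 1L)
  s <- vae_translate_parameters(task_spec("search_overt",
                                          target = list(channel = "x")))
  expect_identical(s$depth, "full"); expect_gt(s$max_cycles, 1L)
  # overrides flow into the signals
  o <- vae_translate_parameters(taskA(overrides = list(theta = 0.1)))
  expect_equal(o$theta, 0.1)
  # priming produces a doubled gain on the target channel
  expect_equal(unname(d$bias$channel_gains["colorA"]), 2)
  expect_length(vae_translate_parameters(taskA(priming = FALSE))$bias$channel_gains, 0)
})

test_that("script construction binds slots or fails naming the slot", {
  sc <- vte_construct_script(method_discrimination(), taskA())
  expect_identical(sc$bindings$target$channel, "colorA")
  expect_identical(sc$status, "constructed")
  t_missing <- task_spec("discriminate")      # no target descriptor
  expect_error(vte_construct_script(method_covert_search(), t_missing),
               "target")
  bad <- cp_method("b", "x", list(cp_node("a", "process", "feedforward")),
                   cp_edge("a", "a"))
  expect_error(vte_construct_script(bad, taskA()), "invalid method")
})

test_that("one attentive cycle logs its stages with exact clock arithmetic", {
  d <- demo_covert_display(1, 4, 2)
  r <- vte_run(taskA(), d$image, config = list(deg_per_pixel = 0.5))
  df <- eventlog_df(r$log)
  # priming precedes stimulus onset on the model clock
  expect_lt(df$t[df$event == "stage_B_priming"], 0)
  expect_equal(df$t[df$event == "stimulus_onset"], 0)
  expect_equal(df$t[df$event == "stage_C_feedforward"], 150)
  # discrimination runs no recurrent stages
  expect_false(any(grepl("stage_D|stage_E", df$event)))
  # clock linearity: every timestamp is the running sum of stage costs
  expect_equal(df$t, cumsum(df$cost) + df$t[1])
  expect_true(all(diff(df$t) >= 0))
})

test_that("disengage lifts suppression and inhibits the attended pathways", {
  d <- demo_covert_display(2, 4, 2)
  tk <- task_spec("search_covert", target = list(channel = "colorA"),
                  priming = FALSE)
  sig <- vae_translate_parameters(tk)
  st <- visattn:::new_run_state(tk, d$image, sig, mltm_new(),
                                list(deg_per_pixel = 0.5), 1)
  # disengage on a fresh system is a no-op
  vae_disengage(st)
  expect_true(all(st$vh$inhib_left[[1]]$colorA == 0L))
  vae_run_cycle(st)
  expect_true(any(st$vh$suppression[[1]]$colorA < 1))   # stage D suppressed
  vae_disengage(st)
  expect_true(all(st$vh$suppression[[1]]$colorA == 1))  # lifted
  expect_true(any(st$vh$inhib_left[[4]]$colorA > 0L |
                    st$vh$inhib_left[[4]]$colorB > 0L)) # pathways inhibited
  dis <- Filter(function(e) e$event == "disengage", st$log)
  expect_length(dis, 2)
})

test_that("after disengage a pass equals a never-attended pass off-pathway", {
  d <- demo_covert_display(5, 4, 2)
  tk <- task_spec("search_covert", target = list(channel = "colorA"),
                  priming = FALSE)
  sig <- vae_translate_parameters(tk)
  st <- visattn:::new_run_state(tk, d$image, sig, mltm_new(),
                                list(deg_per_pixel = 0.5), 1)
  vae_run_cycle(st)
  vae_disengage(st)
  attended <- feedforward_pass(st$vh, st$image)
  vh0 <- build_hierarchy(c(64, 64), c("colorA", "colorB"),
                         central_radius_deg = 10, deg_per_pixel = 0.5)
  fresh <- feedforward_pass(vh0, d$image)
  for (l in 1:4) for (ch in c("colorA", "colorB")) {
    inh <- st$vh$inhib_left[[l]][[ch]] > 0L
    expect_identical(attended[[l]][[ch]][!inh], fresh[[l]][[ch]][!inh])
  }
  expect_true(any(unlist(lapply(1:4, function(l)
    st$vh$inhib_left[[l]]$colorA + st$vh$inhib_left[[l]]$colorB)) > 0))
})

test_that("the re-analysis pass never weakens the attended response", {
  for (s in 1:20) {
    d <- demo_clutter_display(s)
    tk <- task_spec("localize", target = list(channel = "colorA"))
    sig <- vae_translate_parameters(tk)
    st <- visattn:::new_run_state(tk, d$image, sig, mltm_new(),
                                  list(deg_per_pixel = 0.5), s)
    visattn:::stage_priming(st)
    visattn:::stage_feedforward(st)
    visattn:::stage_select_cfoa(st)
    vC <- st$cfoa$value
    visattn:::stage_localize(st)
    visattn:::stage_repass(st)
    expect_gte(st$cfoa$value, vC - 1e-12)
  }
})

test_that("the monitor remediates a forced wrong selection and then aborts", {
  d <- demo_covert_display(4, 4, 2)
  tk <- task_spec("search_covert", target = list(channel = "colorA"))
  # hook: force the first selection onto an empty corner unit
  r <- vte_run(tk, d$image,
               config = list(deg_per_pixel = 0.5,
                             hook_force_selection = c(1L, 1L)))
  expect_identical(r$outcome, "done_positive")
  df <- eventlog_df(r$log)
  expect_true(any(df$event == "monitor_mismatch"))
  expect_true(any(df$event == "monitor_remediate"))
  # remediation falls between the flagged decision and the corrected one
  expect_gte(sum(df$event == "decision"), 2)
  expect_gt(min(which(df$event == "monitor_remediate")),
            min(which(df$event == "decision")))
  expect_lt(min(which(df$event == "monitor_remediate")),
            max(which(df$event == "decision")))
})

test_that("degenerate executive inputs terminate with honest outcomes", {
  d <- demo_covert_display(6, 4, NULL)      # target absent
  tk <- task_spec("search_covert", target = list(channel = "colorA"),
                  overrides = list(max_cycles = 6))
  r <- vte_run(tk, d$image, config = list(deg_per_pixel = 0.5))
  expect_identical(r$outcome, "done_negative")
  expect_lte(r$cycles, 6)
  # every non-final cycle ends in a disengage
  df <- eventlog_df(r$log)
  expect_gte(sum(df$event == "disengage" & df$t >= 0), r$cycles - 1)
  # empty method memory
  r0 <- vte_run(tk, d$image, mltm = mltm_new(),
                config = list(deg_per_pixel = 0.5))
  expect_identical(r0$outcome, "failed")
  expect_identical(r0$fail_reason, "no method")
})

test_that("identical task, display and seed give byte-identical logs", {
  d <- demo_covert_display(7, 4, 3)
  tk <- task_spec("search_covert", target = list(channel = "colorA"))
  r1 <- vte_run(tk, d$image, config = list(deg_per_pixel = 0.5), seed = 9)
  r2 <- vte_run(tk, d$image, config = list(deg_per_pixel = 0.5), seed = 9)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  eventlog_jsonl(r1$log, f1); eventlog_jsonl(r2$log, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
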