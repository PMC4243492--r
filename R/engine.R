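# The cognitive-program engine: method graphs, script construction, the
# visual attention executive (vAE: parameter translation, disengage, the
# staged attentive cycle) and the visual task executive (vTE: method fetch,
# script execution node by node, monitoring with a three-step remediation
# ladder). All times are model-clock milliseconds, never wall clock; the clock
# starts at -priming_lead so that priming events precede stimulus onset (t=0).
#
# A method is a directed graph of four node kinds -- transfer, process,
# select, set_parameters -- with a single start and end, optional parallel
# groups joined at a barrier (serialized deterministically in declaration
# order), and explicitly marked cycle-repeat edges (the only permitted
# cycles). A script is a method with every open slot bound plus a program
# pointer.

#' Construct a cognitive-program method node
#' @param id unique node id
#' @param kind one of "transfer", "process", "select", "set_parameters"
#' @param op operation name executed by the script engine
#' @param params bound parameters
#' @param slots names of open slots that must be bound from the task
#' @param monitored should the script monitor check this node
#' @param checkpoint predicate name checked when monitored
#' @return a `cp_node` list
#' @export
cp_node <- function(id, kind, op, params = list(), slots = character(0),
                    monitored = FALSE, checkpoint = NULL) {
  stopifnot(kind %in% c("transfer", "process", "select", "set_parameters"))
  list(id = id, kind = kind, op = op, params = params, slots = slots,
       monitored = monitored, checkpoint = checkpoint)
}

#' Construct a method edge
#' @param from,to node ids
#' @param kind "normal" or "repeat" (repeat edges are the only allowed cycles)
#' @param group parallel-group tag (edges sharing a tag run as a group and
#'   join at a barrier) or NA
#' @param when branch condition matched against the executive's last decision
#'   ("positive", "negative", "repeat", "none", ...) or NA for unconditional
#' @return a one-row data.frame
#' @export
cp_edge <- function(from, to, kind = "normal", group = NA_character_,
                    when = NA_character_) {
  data.frame(from = from, to = to, kind = kind, group = group, when = when,
             stringsAsFactors = FALSE)
}

#' Construct a cognitive-program method
#' @param name method name
#' @param index_keys associative index terms for the method memory
#' @param nodes list of [cp_node()]s
#' @param edges data.frame of [cp_edge()]s (rbind them)
#' @return a `cp_method`
#' @export
cp_method <- function(name, index_keys, nodes, edges) {
  names(nodes) <- vapply(nodes, `[[`, "", "id")
  structure(list(name = name, index_keys = index_keys, nodes = nodes,
                 edges = edges), class = "cp_method")
}

#' Validate a method graph
#'
#' Checks: exactly one start (no incoming non-repeat edge) and one end (no
#' outgoing non-repeat edge); every node reachable from the start; no cycles
#' outside explicitly marked repeat edges; every open slot named.
#'
#' @param m a `cp_method`
#' @return list(valid, violations, start, end)
#' @export
validate_method <- function(m) {
  v <- character(0)
  ids <- names(m$nodes)
  e <- m$edges[m$edges$kind != "repeat", , drop = FALSE]
  bad_ref <- setdiff(unique(c(m$edges$from, m$edges$to)), ids)
  if (length(bad_ref)) v <- c(v, sprintf("edge references unknown node: %s",
                                         paste(bad_ref, collapse = ",")))
  starts <- setdiff(ids, m$edges$to)
  ends <- setdiff(ids, m$edges$from)
  if (length(starts) != 1) v <- c(v, sprintf("expected 1 start node, found %d", length(starts)))
  if (length(ends) != 1) v <- c(v, sprintf("expected 1 end node, found %d", length(ends)))
  # reachability from start
  if (length(starts) >= 1) {
    seen <- starts[1]
    repeat {
      nxt <- unique(m$edges$to[m$edges$from %in% seen])
      new <- setdiff(nxt, seen)
      if (!length(new)) break
      seen <- c(seen, new)
    }
    unreach <- setdiff(ids, seen)
    if (length(unreach))
      v <- c(v, sprintf("unreachable node: %s", paste(unreach, collapse = ",")))
  }
  # acyclicity outside repeat edges (Kahn)
  deg <- table(factor(e$to, levels = ids))
  q <- ids[deg == 0]
  order_seen <- character(0)
  ee <- e
  while (length(q)) {
    n <- q[1]; q <- q[-1]
    order_seen <- c(order_seen, n)
    out <- ee[ee$from == n, , drop = FALSE]
    ee <- ee[ee$from != n, , drop = FALSE]
    for (t in unique(out$to))
      if (!any(ee$to == t) && !t %in% c(order_seen, q)) q <- c(q, t)
  }
  if (length(order_seen) != length(ids))
    v <- c(v, "cycle outside marked repeat edges")
  for (n in m$nodes) {
    if (length(n$slots) && any(!nzchar(n$slots)))
      v <- c(v, sprintf("node %s has an unnamed open slot", n$id))
  }
  list(valid = !length(v), violations = v,
       start = if (length(starts)) starts[1] else NA_character_,
       end = if (length(ends)) ends[1] else NA_character_)
}

#' Write / read a method as a JSON graph file
#' @param m a `cp_method`
#' @param path file path
#' @return invisibly the path / the method
#' @export
write_method_json <- function(m, path) {
  x <- list(name = m$name, index_keys = m$index_keys,
            nodes = unname(m$nodes), edges = m$edges)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_method_json
#' @export
read_method_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- lapply(x$nodes, function(n)
    cp_node(n$id, n$kind, n$op, params = n$params %||% list(),
            slots = unlist(n$slots) %||% character(0),
            monitored = isTRUE(n$monitored),
            checkpoint = n$checkpoint))
  edges <- do.call(rbind, lapply(x$edges, function(e)
    cp_edge(e$from, e$to, e$kind %||% "normal",
            e$group %||% NA_character_, e$when %||% NA_character_)))
  cp_method(x$name, unlist(x$index_keys), nodes, edges)
}

# --- task specification and control signals ---------------------------------

TASK_TYPES <- c("discriminate", "categorize", "identify",
                "within_category_identify", "localize",
                "search_covert", "search_overt", "trace")

#' Create a task specification
#'
#' @param task_type one of `r paste(TASK_TYPES, collapse=", ")`
#' @param target target descriptor, e.g. `list(channel = "colorA")`; required
#'   for search and trace tasks
#' @param display display expectation (free-form, e.g. "ring8", "central")
#' @param response response mapping (free-form)
#' @param overrides named list of control-signal overrides (theta,
#'   max_cycles, central_radius_deg, suppression_factor, ...)
#' @param priming prime the target channel before stimulus onset
#' @param ior_override task-demand flag that ignores location IOR
#' @return a `task_spec`
#' @export
task_spec <- function(task_type, target = NULL, display = NULL,
                      response = NULL, overrides = list(), priming = TRUE,
                      ior_override = FALSE) {
  if (!task_type %in% TASK_TYPES)
    stop(sprintf("unknown task_type '%s'", task_type))
  if (task_type %in% c("search_covert", "search_overt", "trace") &&
      is.null(target))
    stop(sprintf("task_type '%s' requires a target descriptor", task_type))
  structure(list(task_type = task_type, target = target, display = display,
                 response = response, overrides = overrides,
                 priming = priming, ior_override = ior_override),
            class = "task_spec")
}

# associative descriptor derived from a task
task_descriptor <- function(task) {
  switch(task$task_type,
         discriminate = c("discriminate", "central", "covert"),
         categorize = c("discriminate", "categorize", "central", "covert"),
         identify = c("discriminate", "identify", "central", "covert"),
         within_category_identify = c("identify", "within_category", "central"),
         localize = c("localize", "reinterpret"),
         search_covert = c("search", "covert"),
         search_overt = c("search", "overt", "saccade"),
         trace = c("trace", "curve", "overt"))
}

#' Translate a task specification into attention control signals
#'
#' The deterministic stage policy: discrimination-class tasks (discriminate,
#' categorize, identify) need no recurrent localization (depth "none", one
#' cycle); within-category identification needs a partial recurrent pass;
#' full localization needs a complete top-down pass; search and tracing need
#' the full cycle with repetitions.
#'
#' @param task a [task_spec()]
#' @return a `control_signals` list (theta, bias, suppression geometry,
#'   central radius, max_cycles, localization depth, clock costs, FHM decay)
#' @export
vae_translate_parameters <- function(task) {
  pol <- switch(task$task_type,
                discriminate = ,
                categorize = ,
                identify = list(depth = "none", max_cycles = 1L),
                within_category_identify = list(depth = 1L, max_cycles = 1L),
                localize = list(depth = "full", max_cycles = 1L),
                search_covert = list(depth = "full", max_cycles = 12L),
                search_overt = list(depth = "full", max_cycles = 24L),
                trace = list(depth = "full", max_cycles = 60L),
                stop(sprintf("unknown task_type '%s'", task$task_type)))
  ch <- task$target$channel %||% NULL
  bias <- if (isTRUE(task$priming) && !is.null(ch))
    bias_spec(stats::setNames(2, ch)) else bias_spec()
  sig <- list(theta = 0.25, bias = bias,
              suppression_factor = 0.1, spatial_extent = 2L,
              feature_extent = character(0),
              central_radius_deg = 10,
              max_cycles = pol$max_cycles, depth = pol$depth,
              priming_lead = 150, feedforward_cost = 150,
              top_down_cost = 125, decision_cost = 25, saccade_cost = 30,
              fhm_lambda = 0.7, fhm_epsilon = 0.05,
              fix_inhib_radius = 6, pfoa_k = 5L, pfoa_excl_radius = 6,
              fix_floor_frac = 0.05)
  for (nm in names(task$overrides)) sig[[nm]] <- task$overrides[[nm]]
  stopifnot(sig$theta >= 0, sig$theta < 1,
            sig$priming_lead >= 80, sig$priming_lead <= 300,
            sig$top_down_cost >= 100, sig$top_down_cost <= 150)
  structure(sig, class = "control_signals")
}

#' Construct an executable script from a method and a task
#'
#' Binds every open slot from task fields, control signals and defaults;
#' fails naming any slot that cannot be bound.
#'
#' @param m a validated `cp_method`
#' @param task a [task_spec()]
#' @return a `cp_script`: method + bindings + program pointer
#' @export
vte_construct_script <- function(m, task) {
  rep <- validate_method(m)
  if (!rep$valid)
    stop(sprintf("cannot construct script from invalid method: %s",
                 paste(rep$violations, collapse = "; ")))
  signals <- vae_translate_parameters(task)
  bindings <- list()
  for (n in m$nodes) {
    for (s in n$slots) {
      val <- task[[s]] %||% signals[[s]] %||% NULL
      if (is.null(val))
        stop(sprintf("construction error: cannot bind slot '%s' of node %s",
                     s, n$id))
      bindings[[s]] <- val
    }
  }
  structure(list(method = m, task = task, signals = signals,
                 bindings = bindings, pointer = rep$start,
                 start = rep$start, end = rep$end, status = "constructed"),
            class = "cp_script")
}

# --- run state, clock and event log -----------------------------------------

new_run_state <- function(task, world, signals, mltm, config = list(),
                          seed = 1L) {
  st <- new.env(parent = emptyenv())
  st$task <- task
  st$signals <- signals
  st$mltm <- mltm
  st$config <- config
  st$seed <- as.integer(seed)
  st$world <- world
  wd <- dim(world[[1]])
  rd <- config$retina_dim %||% wd
  st$retina_dim <- as.integer(rd)
  crd <- signals$central_radius_deg
  dpp <- config$deg_per_pixel %||% 0.1
  st$vh <- build_hierarchy(input_dim = st$retina_dim,
                           channels = names(world),
                           n_levels = config$n_levels %||% 4L,
                           central_radius_deg = crd, deg_per_pixel = dpp,
                           ior_horizon = config$ior_horizon %||% 3L)
  center <- c(floor((wd[1] - 1) / 2) + 1, floor((wd[2] - 1) / 2) + 1)
  sac <- execute_saccade(world, make_fixation(center, "overt", 0L),
                         st$retina_dim)
  st$image <- sac$image
  st$view <- sac$view
  st$fixation <- make_fixation(center, "overt", 0L)
  st$fhm <- new_fhm(signals$fhm_lambda, signals$fhm_epsilon)
  st$bb <- bb_new(config$bb_capacity %||% 10L)
  st$np <- notepad_new()
  st$log <- list()
  st$now <- -signals$priming_lead
  st$onset_done <- FALSE
  st$cycle <- 1L
  st$saccades <- 0L
  st$disengaged_cycle <- NA_integer_
  st$ladder <- 0L
  st$exclude_mask <- NULL
  st$outcome <- NULL
  st$hook_force_selection <- config$hook_force_selection %||% NULL
  st$hook_cleared <- FALSE
  st$fix_constraint <- NULL
  st
}

ev <- function(st, component, event, payload = NULL, cost = 0) {
  st$now <- st$now + cost
  st$log[[length(st$log) + 1]] <- list(t = st$now, component = component,
                                       event = event, cost = cost,
                                       payload = payload)
  invisible(NULL)
}

#' Convert an event log to a data.frame
#' @param log list of event records (from a run result)
#' @return data.frame(t, component, event, cost)
#' @export
eventlog_df <- function(log) {
  data.frame(t = vapply(log, `[[`, 0, "t"),
             component = vapply(log, `[[`, "", "component"),
             event = vapply(log, `[[`, "", "event"),
             cost = vapply(log, `[[`, 0, "cost"),
             stringsAsFactors = FALSE)
}

#' Write an event log as JSONL
#' @param log event list
#' @param path output path
#' @return invisibly the path
#' @export
eventlog_jsonl <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in log)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null",
                                digits = NA), con)
  invisible(path)
}

# --- vAE: disengage and the staged attentive cycle --------------------------

#' Disengage attention
#'
#' Lifts all surround suppression (spatial and featural) AND inhibits the
#' pathways of the blackboard's current attentional sample (object-based
#' inhibition of return). Both effects are logged as one "disengage" event.
#' On an empty blackboard only the (trivial) lift happens.
#'
#' @param st a run state (internal; exposed for the thin drivers)
#' @return invisibly the state
#' @export
vae_disengage <- function(st) {
  st$vh <- lift_surround_suppression(st$vh)
  cur <- bb_read_sample(st$bb)
  inhibited <- FALSE
  if (!isTRUE(attr(cur, "empty")) && !is.null(cur$sample)) {
    st$vh <- inhibit_pathways(st$vh, cur$sample)
    inhibited <- TRUE
  }
  st$disengaged_cycle <- st$cycle
  ev(st, "vAE", "disengage",
     list(inhibited_sample = inhibited, cycle = st$cycle))
  invisible(st)
}

stage_priming <- function(st) {
  sig <- st$signals
  st$vh <- apply_priming(st$vh, sig$bias)
  ev(st, "vAE", "stage_B_priming",
     list(lead_ms = sig$priming_lead,
          gains = as.list(sig$bias$channel_gains)))
}

mark_onset <- function(st) {
  if (!st$onset_done) {
    ev(st, "world", "stimulus_onset", cost = st$signals$priming_lead)
    st$onset_done <- TRUE
  }
}

stage_feedforward <- function(st, stage = "stage_C_feedforward") {
  mark_onset(st)
  st$acts <- feedforward_pass(st$vh, st$image)
  ev(st, "VH", stage, list(cycle = st$cycle), cost = st$signals$feedforward_cost)
}

relevant_channels <- function(st) {
  # tracing restricts competition to the traced feature (the curve channel);
  # all other tasks let every channel compete for the cFOA
  if (identical(st$task$task_type, "trace") &&
      !is.null(st$task$target$channel)) st$task$target$channel
  else st$vh$channels
}

hooked_cfoa <- function(st) {
  sig <- st$signals
  if (!is.null(st$hook_force_selection) && st$cycle == 1L &&
      !isTRUE(st$hook_cleared)) {
    # test hook: force a (possibly wrong) first-cycle selection to exercise
    # the script monitor's remediation ladder; cleared by remediation
    p <- st$hook_force_selection
    top <- st$vh$n_levels
    rm_ <- matrix(FALSE, st$vh$dims[[top]][1], st$vh$dims[[top]][2])
    rm_[p[1], p[2]] <- TRUE
    return(list(region = matrix(p, 1), region_mask = rm_, peak = p,
                value = top_level_map(st$vh, st$acts)[p[1], p[2]],
                threshold = NA_real_, no_winner = FALSE, no_cfoa = FALSE,
                level = top))
  }
  select_cfoa(st$vh, st$acts, theta = sig$theta,
              channels = relevant_channels(st),
              exclude = st$exclude_mask)
}

stage_select_cfoa <- function(st) {
  sig <- st$signals
  st$cfoa <- hooked_cfoa(st)
  st$last_decision <- if (isTRUE(st$cfoa$no_cfoa)) "none" else "some"
  ev(st, "vAE", "cfoa_selected",
     list(peak = st$cfoa$peak, value = st$cfoa$value,
          no_cfoa = isTRUE(st$cfoa$no_cfoa), cycle = st$cycle),
     cost = sig$decision_cost)
}

# per-channel transmitted response profile at the cFOA peak
cfoa_signature <- function(st) {
  if (isTRUE(st$cfoa$no_cfoa)) return(NULL)
  p <- st$cfoa$peak
  top <- st$vh$n_levels
  vapply(st$vh$channels, function(ch)
    vh_effective(st$vh, st$acts, top, ch)[p[1], p[2]], 0)
}

stage_match_goals <- function(st) {
  sig <- cfoa_signature(st)
  tch <- st$task$target$channel %||% st$vh$channels[1]
  pos <- !is.null(sig) && max(sig) > 0 && names(sig)[which.max(sig)] == tch
  st$match_positive <- pos
  st$last_decision <- if (pos) "positive" else "negative"
  ev(st, "vTE", "decision",
     list(match = pos, attended = if (!is.null(sig)) names(sig)[which.max(sig)],
          target = tch, cycle = st$cycle))
}

stage_localize <- function(st, depth = st$signals$depth) {
  sig <- st$signals
  if (isTRUE(st$cfoa$no_cfoa)) return(invisible(NULL))
  n_down <- if (identical(depth, "full")) st$vh$n_levels - 1L else as.integer(depth)
  res <- recurrent_localize(st$vh, st$acts, st$cfoa, depth = depth,
                            theta = sig$theta, suppress = TRUE,
                            spatial_extent = sig$spatial_extent,
                            feature_extent = sig$feature_extent,
                            factor = sig$suppression_factor,
                            channels = relevant_channels(st))
  st$vh <- res$vh
  st$sample <- res$sample
  cost <- sig$top_down_cost * n_down / (st$vh$n_levels - 1L)
  ev(st, "vAE", "stage_D_localize",
     list(depth = if (identical(depth, "full")) "full" else n_down,
          cycle = st$cycle), cost = cost)
}

stage_write_bb <- function(st) {
  if (is.null(st$sample)) return(invisible(NULL))
  st$bb <- bb_write_sample(st$bb, st$sample, st$cycle)
  st$np <- notepad_append(st$np, "sample",
                          list(root = st$sample$root), st$cycle)
  ev(st, "vWM", "bb_write", list(cycle = st$cycle))
}

stage_repass <- function(st) {
  st$acts <- feedforward_pass(st$vh, st$image)
  ev(st, "VH", "stage_E_repass", list(cycle = st$cycle),
     cost = st$signals$feedforward_cost)
  st$cfoa <- hooked_cfoa(st)
  ev(st, "vAE", "cfoa_reselected",
     list(peak = st$cfoa$peak, value = st$cfoa$value, cycle = st$cycle),
     cost = st$signals$decision_cost)
}

#' Run one staged attentive cycle directly (stages B, C and optionally D, E)
#'
#' Stage B (priming) runs only before stimulus onset. Stage C is the
#' feedforward pass plus cFOA selection. When the localization depth is not
#' "none", stage D (recurrent localization with surround suppression) runs,
#' and for full-depth tasks stage E re-runs the feedforward pass with the
#' suppression in place and re-selects. Every stage is logged with its
#' model-clock cost.
#'
#' @param st a run state from the executive (see [vte_run()]); exposed so the
#'   staged cycle can be driven directly in tests and demos
#' @return invisibly the state (fields `cfoa`, `sample`, `log` updated)
#' @export
vae_run_cycle <- function(st) {
  if (!st$onset_done) stage_priming(st)
  stage_feedforward(st)
  stage_select_cfoa(st)
  if (!identical(st$signals$depth, "none") && !isTRUE(st$cfoa$no_cfoa)) {
    stage_localize(st)
    stage_write_bb(st)
    if (identical(st$signals$depth, "full")) stage_repass(st)
  }
  invisible(st)
}

# --- vTE: monitoring ---------------------------------------------------------

checkpoint_predicates <- list(
  # the selected cFOA must be the strongest admissible top-level response
  cfoa_is_max = function(st) {
    if (isTRUE(st$cfoa$no_cfoa)) return(TRUE)   # "none" is a valid outcome
    ref <- select_cfoa(st$vh, st$acts, theta = st$signals$theta,
                       channels = relevant_channels(st),
                       exclude = st$exclude_mask)
    if (isTRUE(ref$no_cfoa)) return(FALSE)
    isTRUE(all.equal(st$cfoa$value, ref$value)) &&
      all(st$cfoa$peak == ref$peak)
  },
  # a written attentional sample must be structurally valid
  sample_valid = function(st) {
    if (is.null(st$sample)) return(TRUE)
    isTRUE(sample_is_valid(st$vh, st$sample))
  }
)

#' Script monitor: check a checkpoint and apply the remediation ladder
#'
#' On a mismatch: (1) re-select excluding the failed winner (small script
#' alteration), (2) signal a refetch of the next-ranked method, (3) abort.
#' The ladder position is logged with each attempt.
#'
#' @param st run state
#' @param node the monitored node
#' @return "ok", "remediated", "refetch" or "abort"
#' @export
vte_monitor <- function(st, node) {
  pred <- checkpoint_predicates[[node$checkpoint %||% "cfoa_is_max"]]
  ok <- isTRUE(pred(st))
  st$np <- notepad_append(st$np, "checkpoint",
                          list(node = node$id, ok = ok), st$cycle)
  if (ok) {
    ev(st, "vTE", "monitor_ok", list(node = node$id))
    return("ok")
  }
  st$ladder <- st$ladder + 1L
  ev(st, "vTE", "monitor_mismatch", list(node = node$id, ladder = st$ladder))
  if (st$ladder == 1L) {
    # small alteration: bar the failed winner and re-select
    st$hook_cleared <- TRUE
    if (!is.null(st$cfoa$peak)) {
      top <- st$vh$n_levels
      excl <- st$exclude_mask %||%
        matrix(FALSE, st$vh$dims[[top]][1], st$vh$dims[[top]][2])
      excl[st$cfoa$peak[1], st$cfoa$peak[2]] <- TRUE
      st$exclude_mask <- excl
    }
    stage_select_cfoa(st)
    st$exclude_mask <- NULL   # the bar applies to the re-selection only
    ev(st, "vTE", "monitor_remediate", list(node = node$id, action = "reselect"))
    return("remediated")
  }
  if (st$ladder == 2L) {
    ev(st, "vTE", "monitor_remediate", list(node = node$id, action = "refetch"))
    return("refetch")
  }
  ev(st, "vTE", "monitor_abort", list(node = node$id, attempts = st$ladder))
  "abort"
}

# --- vTE: script execution ---------------------------------------------------

# one cycle-boundary bookkeeping step when a repeat edge is taken
advance_cycle <- function(st) {
  st$cycle <- st$cycle + 1L
  st$vh <- vh_tick_inhibition(st$vh)
  st$sample <- NULL
}

run_node <- function(st, node) {
  sig <- st$signals
  switch(node$op,
    receive_task = ev(st, "vTE", "receive_task",
                      list(task_type = st$task$task_type)),
    fetch_method = ev(st, "vTE", "fetch_method", list(method = node$params$name)),
    tune_script = ev(st, "vTE", "tune_script", NULL),
    send_task_info = ev(st, "vTE", "send_task_info", NULL),
    prime_vh = stage_priming(st),
    disengage = vae_disengage(st),
    set_parameters = ev(st, "vAE", "set_parameters",
                        list(theta = sig$theta, depth = sig$depth,
                             max_cycles = sig$max_cycles)),
    sync = ev(st, "vTE", "barrier", NULL),
    feedforward = stage_feedforward(st),
    select_cfoa = stage_select_cfoa(st),
    transfer_cfoa = ev(st, "vTE", "transfer_cfoa", list(peak = st$cfoa$peak)),
    match_goals = stage_match_goals(st),
    localize = { stage_localize(st) },
    write_bb = stage_write_bb(st),
    repass = {
      # stage E belongs to full-depth tasks; a partial recurrent pass
      # (within-category identification) ends at stage D
      if (identical(sig$depth, "full") && !isTRUE(st$cfoa$no_cfoa))
        stage_repass(st)
    },
    decide_repeat = {
      st$last_decision <-
        if (isTRUE(st$match_positive)) "positive"
        else if (isTRUE(st$cfoa$no_cfoa)) "exhausted"
        else if (st$cycle >= sig$max_cycles) "exhausted"
        else "repeat"
      if (identical(st$last_decision, "repeat")) advance_cycle(st)
      ev(st, "vTE", "decide_repeat", list(decision = st$last_decision))
    },
    decide_continue = {
      # overt variant: the cycle advances at the saccade, not here
      st$last_decision <-
        if (isTRUE(st$match_positive)) "positive"
        else if (st$cycle >= sig$max_cycles) "exhausted"
        else "continue"
      ev(st, "vTE", "decide_continue", list(decision = st$last_decision))
    },
    finish_localize = {
      st$match_positive <- !is.null(st$sample)
      st$last_decision <- if (st$match_positive) "positive" else "negative"
      ev(st, "vTE", "localize_finish",
         list(support_px = if (!is.null(st$sample))
           sum(sample_support(st$vh, st$sample)) else 0L))
    },
    compute_ppm = {
      st$ppm <- compute_ppm(st$image, sig$bias, st$vh$central_radius_px)
      ev(st, "FC", "compute_ppm", NULL)
    },
    select_pfoa = {
      st$pfoa <- select_pfoa(st$ppm, k = sig$pfoa_k,
                             excl_radius = sig$pfoa_excl_radius)
      ev(st, "FC", "select_pfoa", list(n = nrow(st$pfoa)))
    },
    update_fhm = {
      st$fhm <- update_fhm(st$fhm, st$fixation, traced = st$traced_coords,
                           radius = sig$fix_inhib_radius)
      ev(st, "vWM", "update_fhm", list(entries = length(st$fhm$entries)))
    },
    compose_hbpm = {
      st$hbpm <- if (nrow(st$pfoa) == 0 && all(st$ppm$grid == 0)) NULL
      else compose_hbpm(cfoa = st$cfoa$peak, pfoa = st$pfoa, fhm = st$fhm,
                        ppm = st$ppm, view = st$view,
                        override = isTRUE(st$task$ior_override))
      ev(st, "FC", "compose_hbpm", NULL)
    },
    select_next_fixation = {
      fx <- if (is.null(st$hbpm)) NULL
      else select_next_fixation(st$hbpm, st$view,
                                constraint = st$fix_constraint,
                                floor_frac = sig$fix_floor_frac,
                                cycle = st$cycle,
                                excl_radius = sig$pfoa_excl_radius)
      st$next_fixation <- fx
      st$last_decision <- if (is.null(fx)) "none" else "fixate"
      ev(st, "FC", "fixation_selected",
         list(pos = fx$pos, none = is.null(fx)), cost = sig$decision_cost)
    },
    execute_saccade = do_saccade(st, st$next_fixation),
    curve_trace_loop = trace_loop(st),
    trace_decide = {
      st$last_decision <- if (isTRUE(st$match_positive)) "positive" else "negative"
      ev(st, "vTE", "decision",
         list(decision = st$trace$decision %||% "failed"))
    },
    report_outcome = {
      st$outcome <- st$outcome %||%
        if (isTRUE(st$match_positive)) "done_positive" else "done_negative"
      ev(st, "vTE", "report_outcome", list(outcome = st$outcome))
    },
    stop(sprintf("unknown op '%s' in node %s", node$op, node$id))
  )
  invisible(NULL)
}

# follow the script graph from start to end; returns "done" or "refetch"
execute_script <- function(st, script) {
  m <- script$method
  nodes <- m$nodes
  edges <- m$edges
  cur <- script$start
  budget <- (st$signals$max_cycles + 2L) * length(nodes) * 6L + 50L
  steps <- 0L
  while (TRUE) {
    steps <- steps + 1L
    if (steps > budget) { st$outcome <- "failed"; st$fail_reason <- "step budget"; break }
    node <- nodes[[cur]]
    run_node(st, node)
    if (isTRUE(node$monitored)) {
      mres <- vte_monitor(st, node)
      if (mres == "refetch") return("refetch")
      if (mres == "abort") { st$outcome <- "failed"; st$fail_reason <- "monitor"; break }
      if (mres == "remediated" && node$op == "match_goals") stage_match_goals(st)
    }
    if (cur == script$end) break
    out <- edges[edges$from == cur, , drop = FALSE]
    if (!nrow(out)) break
    if (any(!is.na(out$group))) {
      # parallel group: run each branch head in declared order, then join
      joins <- character(0)
      for (i in which(!is.na(out$group))) {
        head <- out$to[i]
        run_node(st, nodes[[head]])
        nxt <- edges[edges$from == head & is.na(edges$group), , drop = FALSE]
        joins <- c(joins, nxt$to[1])
      }
      stopifnot(length(unique(joins)) == 1)
      cur <- joins[1]
      next
    }
    if (all(is.na(out$when))) {
      cur <- out$to[1]
    } else {
      hit <- out[!is.na(out$when) & out$when == st$last_decision, , drop = FALSE]
      if (!nrow(hit)) hit <- out[is.na(out$when), , drop = FALSE]
      if (!nrow(hit)) { st$outcome <- "failed"; st$fail_reason <-
        sprintf("no edge for decision '%s' at %s", st$last_decision, cur); break }
      cur <- hit$to[1]
    }
  }
  "done"
}

#' Execute a visual task end to end
#'
#' Fetches the best-matching method from the method memory, constructs a
#' script, and executes it node by node under the script monitor. The
#' remediation ladder may re-select, refetch the next-ranked method, or
#' abort. Every stage, selection, memory access and decision is logged with
#' model-clock timestamps.
#'
#' @param task a [task_spec()]
#' @param world a multi-channel world image (named list of matrices), e.g.
#'   `display$image` from the stimulus generators
#' @param mltm a loaded method memory (default: the shipped library)
#' @param config run configuration: `retina_dim`, `n_levels`,
#'   `deg_per_pixel`, `ior_horizon`, `bb_capacity`, test hooks
#' @param seed run-level seed threaded into every stochastic component and
#'   recorded in the log header
#' @return list(outcome, log, notepad, state); outcome is "done_positive",
#'   "done_negative" or "failed"
#' @export
vte_run <- function(task, world, mltm = mltm_default_library(),
                    config = list(), seed = 1L) {
  recs <- tryCatch(mltm_fetch(mltm, task_descriptor(task)),
                   error = function(e) list())
  if (!length(recs)) {
    sig <- vae_translate_parameters(task)
    st <- new_run_state(task, world, sig, mltm, config, seed)
    st$outcome <- "failed"
    st$fail_reason <- "no method"
    ev(st, "vTE", "no_method", list(descriptor = task_descriptor(task)))
    return(run_result(st))
  }
  sig <- vae_translate_parameters(task)
  st <- new_run_state(task, world, sig, mltm, config, seed)
  ev(st, "vTE", "run_header",
     list(seed = st$seed, method = recs[[1]]$method$name,
          task_type = task$task_type))
  idx <- 1L
  repeat {
    script <- vte_construct_script(recs[[idx]]$method, task)
    st$np$active_scripts <- list(list(name = script$method$name,
                                      pointer = script$start))
    status <- execute_script(st, script)
    if (status != "refetch") break
    idx <- idx + 1L
    if (idx > length(recs)) {
      st$outcome <- "failed"
      st$fail_reason <- "monitor exhaustion"
      ev(st, "vTE", "monitor_abort", list(attempts = st$ladder))
      break
    }
    ev(st, "vTE", "refetch_method", list(method = recs[[idx]]$method$name))
  }
  st$np$active_scripts <- list()
  run_result(st)
}

run_result <- function(st) {
  list(outcome = st$outcome %||% "failed",
       fail_reason = st$fail_reason %||% NULL,
       log = st$log, notepad = st$np, state = st,
       model_time_ms = st$now,
       saccades = st$saccades,
       cycles = st$cycle,
       sample = st$sample %||% NULL)
}
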