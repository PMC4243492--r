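# The shipped cognitive-program library: five method graphs (discrimination,
# covert search, overt search, localize/reinterpret, curve tracing) plus the
# curve-tracing task loop as a thin driver over the attention, fixation and
# memory components. Methods are data (validated graphs, JSON-serializable);
# the script engine interprets them.

node_seq_edges <- function(ids) {
  do.call(rbind, lapply(seq_len(length(ids) - 1L), function(i)
    cp_edge(ids[i], ids[i + 1L])))
}

# the shared front matter: receive task -> fetch -> tune -> parallel
# [prime VH || disengage || set parameters] -> barrier
method_preamble <- function() {
  nodes <- list(
    cp_node("receive", "transfer", "receive_task"),
    cp_node("fetch", "process", "fetch_method"),
    cp_node("tune", "process", "tune_script"),
    cp_node("prime", "process", "prime_vh"),
    cp_node("dis0", "process", "disengage"),
    cp_node("setp", "set_parameters", "set_parameters", slots = c("theta")),
    cp_node("barrier", "transfer", "sync"))
  edges <- rbind(
    node_seq_edges(c("receive", "fetch", "tune")),
    cp_edge("tune", "prime", group = "pre"),
    cp_edge("tune", "dis0", group = "pre"),
    cp_edge("tune", "setp", group = "pre"),
    cp_edge("prime", "barrier"),
    cp_edge("dis0", "barrier"),
    cp_edge("setp", "barrier"))
  list(nodes = nodes, edges = edges)
}

#' The discrimination method (stages B--C only)
#'
#' Encodes: receive task, fetch and tune the method, then in parallel prime
#' the hierarchy, disengage attention and set competition parameters; after
#' the barrier the stimulus flows feedforward, the cFOA is selected at the
#' top, transferred to the task executive and matched to the task goals,
#' ending positively or negatively. The match node is monitored.
#'
#' @return a validated `cp_method`
#' @export
method_discrimination <- function() {
  p <- method_preamble()
  nodes <- c(p$nodes, list(
    cp_node("ff", "process", "feedforward"),
    cp_node("sel", "select", "select_cfoa"),
    cp_node("xfer", "transfer", "transfer_cfoa"),
    cp_node("match", "select", "match_goals", slots = c("target"),
            monitored = TRUE, checkpoint = "cfoa_is_max"),
    cp_node("report", "transfer", "report_outcome")))
  edges <- rbind(p$edges,
                 node_seq_edges(c("barrier", "ff", "sel", "xfer", "match",
                                  "report")))
  cp_method("discrimination",
            c("discriminate", "categorize", "identify", "central", "covert"),
            nodes, edges)
}

# shared attentive-cycle body for the search methods: feedforward, select,
# full recurrent localization into the blackboard, re-analysis pass, match
search_cycle_nodes <- function() {
  list(
    cp_node("ff", "process", "feedforward"),
    cp_node("sel", "select", "select_cfoa"),
    cp_node("loc", "process", "localize"),
    cp_node("wbb", "transfer", "write_bb"),
    cp_node("rep", "process", "repass"),
    cp_node("xfer", "transfer", "transfer_cfoa"),
    cp_node("match", "select", "match_goals", slots = c("target"),
            monitored = TRUE, checkpoint = "cfoa_is_max"))
}

#' The covert visual-search method
#'
#' The discrimination graph extended with full localization and wrapped in a
#' cycle-repeat edge: on a non-match, attention is disengaged (object-based
#' inhibition of return via the blackboard sample) and selection repeats
#' without any saccade, until a match or cycle exhaustion.
#'
#' @return a validated `cp_method`
#' @export
method_covert_search <- function() {
  p <- method_preamble()
  nodes <- c(p$nodes, search_cycle_nodes(), list(
    cp_node("decide", "select", "decide_repeat"),
    cp_node("cyc_dis", "process", "disengage"),
    cp_node("report", "transfer", "report_outcome")))
  edges <- rbind(
    p$edges,
    node_seq_edges(c("barrier", "ff", "sel", "loc", "wbb", "rep", "xfer",
                     "match", "decide")),
    cp_edge("decide", "report", when = "positive"),
    cp_edge("decide", "report", when = "exhausted"),
    cp_edge("decide", "cyc_dis", kind = "repeat", when = "repeat"),
    cp_edge("cyc_dis", "ff", kind = "repeat"))
  cp_method("covert_search", c("search", "covert"), nodes, edges)
}

#' The overt visual-search method
#'
#' The covert-search graph extended with fixation-control nodes: compute the
#' peripheral priority map, pick peripheral foci, fold in the fixation
#' history, select the next fixation, disengage, saccade, new cycle.
#' Terminates when the cFOA matches the target or no fixation candidate
#' remains.
#'
#' @return a validated `cp_method`
#' @export
method_overt_search <- function() {
  p <- method_preamble()
  nodes <- c(p$nodes, search_cycle_nodes(), list(
    cp_node("decide", "select", "decide_continue"),
    cp_node("ppm", "process", "compute_ppm"),
    cp_node("pfoa", "select", "select_pfoa"),
    cp_node("fhmup", "process", "update_fhm"),
    cp_node("hbpm", "process", "compose_hbpm"),
    cp_node("nextfix", "select", "select_next_fixation"),
    cp_node("dis2", "process", "disengage"),
    cp_node("sac", "process", "execute_saccade"),
    cp_node("report", "transfer", "report_outcome")))
  edges <- rbind(
    p$edges,
    node_seq_edges(c("barrier", "ff", "sel", "loc", "wbb", "rep", "xfer",
                     "match", "decide")),
    cp_edge("decide", "report", when = "positive"),
    cp_edge("decide", "report", when = "exhausted"),
    cp_edge("decide", "ppm", when = "continue"),
    node_seq_edges(c("ppm", "pfoa", "fhmup", "hbpm", "nextfix")),
    cp_edge("nextfix", "report", when = "none"),
    cp_edge("nextfix", "dis2", when = "fixate"),
    cp_edge("dis2", "sac"),
    cp_edge("sac", "ff", kind = "repeat"))
  cp_method("overt_search", c("search", "overt", "saccade"), nodes, edges)
}

#' The localize/reinterpret method
#'
#' Runs stages B, C, recurrent localization at the task's depth (full for
#' localization proper, partial for within-category identification), writes
#' the attentional sample to the blackboard, and -- for full depth -- a
#' re-analysis feedforward pass. The outcome carries the sample's
#' input-level support as the localization answer.
#'
#' @return a validated `cp_method`
#' @export
method_localize_reinterpret <- function() {
  p <- method_preamble()
  nodes <- c(p$nodes, list(
    cp_node("ff", "process", "feedforward"),
    cp_node("sel", "select", "select_cfoa"),
    cp_node("loc", "process", "localize", monitored = TRUE,
            checkpoint = "sample_valid"),
    cp_node("wbb", "transfer", "write_bb"),
    cp_node("rep", "process", "repass"),
    cp_node("finish", "select", "finish_localize"),
    cp_node("report", "transfer", "report_outcome")))
  edges <- rbind(p$edges,
                 node_seq_edges(c("barrier", "ff", "sel", "loc", "wbb", "rep",
                                  "finish", "report")))
  cp_method("localize_reinterpret",
            c("localize", "reinterpret", "within_category", "identify"),
            nodes, edges)
}

#' The curve-tracing method
#'
#' The shared preamble followed by the tracing task loop (a thin driver that
#' repeatedly localizes the curve at fixation, extends the traced set,
#' inhibits it through the fixation history map, and saccades along the
#' uninhibited connected curve portion until the second marker is reached or
#' the curve is exhausted).
#'
#' @return a validated `cp_method`
#' @export
method_curve_trace <- function() {
  p <- method_preamble()
  nodes <- c(p$nodes, list(
    cp_node("loop", "process", "curve_trace_loop", slots = c("target")),
    cp_node("decide", "select", "trace_decide"),
    cp_node("report", "transfer", "report_outcome")))
  edges <- rbind(p$edges, node_seq_edges(c("barrier", "loop", "decide",
                                           "report")))
  cp_method("curve_trace", c("trace", "curve", "overt"), nodes, edges)
}

#' The shipped method library
#' @return an `mltm` loaded with the five standard methods
#' @export
mltm_default_library <- function() {
  m <- mltm_new()
  m <- mltm_store(m, method_discrimination())
  m <- mltm_store(m, method_covert_search())
  m <- mltm_store(m, method_overt_search())
  m <- mltm_store(m, method_localize_reinterpret())
  m <- mltm_store(m, method_curve_trace())
  m
}

# --- the curve-tracing task loop --------------------------------------------

# centroids of connected components in a channel, lexicographically ordered
detect_blobs <- function(m, threshold = 0.5) {
  lab <- label_components(m > threshold, 8)
  n <- max(lab)
  if (n == 0) return(matrix(0L, 0, 2))
  out <- t(vapply(seq_len(n), function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    c(round(mean(w[, 1])), round(mean(w[, 2])))
  }, c(0, 0)))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

do_saccade <- function(st, fx) {
  if (!identical(st$disengaged_cycle, st$cycle))
    stop("sequencing error: saccade without prior disengage in this cycle")
  res <- execute_saccade(st$world, fx, st$retina_dim)
  st$image <- res$image
  st$view <- res$view
  st$vh <- vh_clear_inhibition(st$vh)   # retinotopic flags are stale now
  st$fixation <- fx
  st$saccades <- st$saccades + 1L
  st$np <- notepad_append(st$np, "fixation", list(pos = fx$pos), st$cycle)
  ev(st, "FC", "saccade", list(pos = fx$pos, cycle = st$cycle),
     cost = st$signals$saccade_cost)
  advance_cycle(st)
  invisible(st)
}

# BFS geodesic distances along TRUE pixels of a mask from one or more start
# pixels (rows of an n x 2 matrix)
geodesic_dist <- function(mask, start) {
  nr <- nrow(mask); nc <- ncol(mask)
  d <- matrix(Inf, nr, nc)
  if (is.null(dim(start))) start <- matrix(start, 1)
  keep <- start[, 1] >= 1 & start[, 1] <= nr & start[, 2] >= 1 &
    start[, 2] <= nc
  start <- start[keep, , drop = FALSE]
  start <- start[mask[start], , drop = FALSE]
  if (!nrow(start)) return(d)
  d[start] <- 0
  frontier <- start
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  lvl <- 0
  while (nrow(frontier)) {
    lvl <- lvl + 1
    nxt <- NULL
    for (i in seq_len(nrow(frontier))) {
      r <- frontier[i, 1]; cc <- frontier[i, 2]
      for (k in 1:8) {
        r2 <- r + dr[k]; c2 <- cc + dc[k]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && !is.finite(d[r2, c2])) {
          d[r2, c2] <- lvl
          nxt <- rbind(nxt, c(r2, c2))
        }
      }
    }
    frontier <- nxt %||% matrix(0L, 0, 2)
  }
  d
}

# extend the traced set by the input-level read-out of the attended curve:
# the along-curve geodesic ball of arc radius `r_arc` around the current
# attentional focus (one field extension per attentive cycle)
trace_extend <- function(st, r_arc) {
  curve <- st$image[[st$trace_channel]] > 0
  gd <- geodesic_dist(curve, st$focus_ret)
  comp <- is.finite(gd) & gd <= r_arc
  if (!any(comp)) return(invisible(NULL))
  wp <- ret_to_world(st$view, mask_coords(comp))
  ok <- wp[, 1] >= 1 & wp[, 1] <= nrow(st$traced) &
    wp[, 2] >= 1 & wp[, 2] <= ncol(st$traced)
  wp <- wp[ok, , drop = FALSE]
  st$traced[wp] <- TRUE
  st$traced_coords <- mask_coords(st$traced)
  invisible(NULL)
}

# retinal mask of the already traced pixels under the current view
traced_ret_mask <- function(st) {
  m <- matrix(FALSE, st$retina_dim[1], st$retina_dim[2])
  if (is.null(st$traced_coords)) return(m)
  tc <- world_to_ret(st$view, st$traced_coords)
  ok <- tc[, 1] >= 1 & tc[, 1] <= nrow(m) & tc[, 2] >= 1 & tc[, 2] <= ncol(m)
  m[tc[ok, , drop = FALSE]] <- TRUE
  m
}

# along-curve distance of every retinal curve pixel from the traced frontier
# (multi-source BFS; Inf where unreachable, e.g. on a different curve)
trace_frontier_dist <- function(st, curve, traced_ret) {
  src <- mask_coords(curve & traced_ret)
  geodesic_dist(curve, src)
}

# covert continuation: the untraced curve pixel just beyond the traced
# frontier, within the central attentional field (the theta-WTA "next central
# focus" along the uninhibited curve); NULL when only overt continuation (or
# none) remains
trace_covert_step <- function(st, curve, traced_ret, gdf) {
  central <- disk_mask(st$retina_dim[1], st$retina_dim[2], st$view$center,
                       st$vh$central_radius_px)
  elig <- curve & !traced_ret & central & is.finite(gdf) & gdf <= 6
  if (!any(elig)) return(NULL)
  w <- which(elig, arr.ind = TRUE)
  d <- gdf[cbind(w[, 1], w[, 2])]
  w <- w[order(d, w[, 1], w[, 2]), , drop = FALSE]
  w[1, ]
}

trace_loop <- function(st) {
  sig <- st$signals
  st$trace_channel <- st$task$target$channel %||% "curve"
  wc <- st$world[[st$trace_channel]]
  wm <- st$world[["marker"]]
  if (is.null(wm)) stop("input error: trace world lacks a marker channel")
  markers <- detect_blobs(wm)
  if (nrow(markers) < 2) stop("input error: need two markers for tracing")
  m1 <- markers[1, ]; m2 <- markers[2, ]
  st$traced <- matrix(FALSE, nrow(wc), ncol(wc))
  st$traced_coords <- NULL
  r_arc <- st$vh$central_radius_px
  ev(st, "vTE", "trace_start", list(markers = nrow(markers)))

  # orient to the first marker
  vae_disengage(st)
  do_saccade(st, make_fixation(m1, "overt", st$cycle))
  st$focus_ret <- st$view$center

  decision <- NULL
  while (st$cycle <= sig$max_cycles) {
    stage_feedforward(st)
    stage_select_cfoa(st)
    if (!isTRUE(st$cfoa$no_cfoa)) {
      # cFOA can be wholly pathway-inhibited mid-trace; the frontier logic
      # below still decides the task, so localization is simply skipped then
      stage_localize(st)
      stage_write_bb(st)
      stage_repass(st)
    }
    trace_extend(st, r_arc)
    st$np <- notepad_append(st$np, "trace",
                            list(traced = sum(st$traced)), st$cycle)
    if (st$traced[m2[1], m2[2]]) { decision <- "same"; break }

    st$fhm <- update_fhm(st$fhm, st$fixation, traced = st$traced_coords,
                         radius = sig$fix_inhib_radius)
    ev(st, "vWM", "update_fhm", list(entries = length(st$fhm$entries)))

    # covert continuation first: the next central focus along the
    # uninhibited curve needs no gaze change
    ret_curve <- st$image[[st$trace_channel]] > 0
    traced_ret <- traced_ret_mask(st)
    gdf <- trace_frontier_dist(st, ret_curve, traced_ret)
    cov <- trace_covert_step(st, ret_curve, traced_ret, gdf)
    if (!is.null(cov)) {
      vae_disengage(st)
      st$focus_ret <- as.integer(cov)
      fx <- make_fixation(ret_to_world(st$view, cov)[1, ], "covert", st$cycle)
      st$fixation <- fx
      st$np <- notepad_append(st$np, "fixation", list(pos = fx$pos), st$cycle)
      ev(st, "FC", "covert_shift", list(pos = fx$pos, cycle = st$cycle),
         cost = sig$decision_cost)
      advance_cycle(st)
      next
    }

    # otherwise go overt through the priority maps
    st$ppm <- compute_ppm(st$image, sig$bias, st$vh$central_radius_px)
    ev(st, "FC", "compute_ppm", NULL)
    st$pfoa <- select_pfoa(st$ppm, k = sig$pfoa_k,
                           excl_radius = sig$pfoa_excl_radius)
    st$hbpm <- compose_hbpm(cfoa = st$cfoa$peak, pfoa = st$pfoa, fhm = st$fhm,
                            ppm = st$ppm, view = st$view,
                            override = isTRUE(st$task$ior_override))
    ev(st, "FC", "compose_hbpm", NULL)
    # constraint: on the curve, untraced, and continuing the traced portion
    # contiguously (just beyond its frontier, along the uninhibited curve)
    st_traced <- st$traced
    constraint <- function(wp, rp) {
      wr <- round(wp[1]); wcL <- round(wp[2])
      if (wr < 1 || wr > nrow(wc) || wcL < 1 || wcL > ncol(wc)) return(FALSE)
      if (wc[wr, wcL] <= 0) return(FALSE)
      if (st_traced[wr, wcL]) return(FALSE)
      rr <- rp[1]; rc <- rp[2]
      if (rr < 1 || rr > nrow(gdf) || rc < 1 || rc > ncol(gdf)) return(FALSE)
      is.finite(gdf[rr, rc]) && gdf[rr, rc] <= 6
    }
    # ties are pervasive along a uniform-contrast curve, so examine enough
    # peaks that the frontier is always among the candidates
    fx <- select_next_fixation(st$hbpm, st$view, constraint = constraint,
                               floor_frac = sig$fix_floor_frac,
                               k = 96L, excl_radius = 2,
                               cycle = st$cycle)
    ev(st, "FC", "fixation_selected",
       list(pos = if (is.null(fx)) NULL else fx$pos, none = is.null(fx)),
       cost = sig$decision_cost)
    if (is.null(fx)) { decision <- "different"; break }
    vae_disengage(st)
    do_saccade(st, fx)
    st$focus_ret <- st$view$center
  }
  if (is.null(decision)) decision <- "failed"
  st$trace <- list(traced = st$traced, traced_coords = st$traced_coords,
                   fixation = st$fixation, decision = decision,
                   steps = st$cycle)
  st$match_positive <- identical(decision, "same")
  st$outcome <- switch(decision, same = "done_positive",
                       different = "done_negative", "failed")
  ev(st, "vTE", "trace_decision", list(decision = decision,
                                       traced_px = sum(st$traced)))
  invisible(st)
}

#' Run the curve-tracing task on a world display
#'
#' Fixates the first X marker, localizes the curve at fixation, then
#' repeatedly extends the traced portion along the uninhibited connected
#' curve -- inhibition of return from the fixation history map suppresses the
#' already traced part -- saccading along the curve until the second marker
#' enters the traced set ("same") or the curve is exhausted without reaching
#' it ("different"). Model response time is the final model-clock value.
#'
#' @param task a [task_spec()] of type "trace" (a default is built if NULL)
#' @param world a multi-channel world image with "curve" and "marker" planes
#' @param config run configuration (see [vte_run()])
#' @param seed run seed
#' @return list(outcome "same"/"different", trace state, log, rt_ms, result)
#' @export
run_curve_trace <- function(task = NULL, world, config = list(), seed = 1L) {
  if (is.null(task))
    task <- task_spec("trace", target = list(channel = "curve"))
  if (is.null(config$retina_dim)) config$retina_dim <- dim(world[[1]])
  res <- vte_run(task, world, mltm = mltm_default_library(),
                 config = config, seed = seed)
  tr <- res$state$trace %||% list(decision = "failed")
  list(outcome = tr$decision, trace = tr, log = res$log,
       rt_ms = res$model_time_ms, result = res)
}
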