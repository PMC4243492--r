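# Canonical demonstration conditions. These fix the display geometry and task
# parameters used throughout the package's examples, tests and the
# reproduction script, so every consumer runs the same study conditions.
#
# Tracing: 128x128 px at 0.1 deg/px (a 12.8 degree display), two non-crossing
# curves at >= 3 px separation, X markers placed along the first curve; the
# attentional field for tracing is 1.2 degrees so that tracing a 2.2--8.8
# degree along-curve distance takes several attentive cycles (the large-
# display regime that requires gaze shifts). Search: items on a ring, one
# feature channel per item kind.

#' Canonical curve-tracing task
#' @param ... overrides merged over the canonical tracing parameters
#' @return a [task_spec()] of type "trace"
#' @export
demo_trace_task <- function(...) {
  ov <- utils::modifyList(list(central_radius_deg = 1.2,
                               fix_inhib_radius = 3), list(...))
  task_spec("trace", target = list(channel = "curve"), overrides = ov)
}

#' Canonical curve-tracing display
#'
#' @param seed display seed
#' @param arc_deg along-curve distance between the two markers (degrees)
#' @param same_curve both markers on the first curve, or one on each
#' @param n_curves number of curves
#' @return list(image, truth)
#' @export
demo_trace_display <- function(seed, arc_deg = 6.6, same_curve = TRUE,
                               n_curves = 2) {
  spec <- display_spec(128, 128, 0.1, c("curve", "marker"), seed = seed)
  make_curve_display(spec, n_curves = n_curves,
                     curve_length = arc_deg + 2.5, n_markers = 2,
                     same_curve = same_curve, marker_arc_deg = arc_deg,
                     marker_start_deg = 0.8, min_separation = 3L)
}

#' Canonical trace run under the demo conditions
#' @param seed display seed
#' @param arc_deg along-curve marker distance (degrees)
#' @param same_curve generate a same-curve or different-curve display
#' @return as [run_curve_trace()], plus the display under `$display`
#' @export
demo_trace_run <- function(seed, arc_deg = 6.6, same_curve = TRUE) {
  d <- demo_trace_display(seed, arc_deg, same_curve)
  r <- run_curve_trace(demo_trace_task(), d$image,
                       config = list(deg_per_pixel = 0.1), seed = seed)
  r$display <- d
  r
}

#' Canonical covert-search display: a ring of items inside the central field
#'
#' Item intensities are jittered so the unprimed selection order varies with
#' the seed; the target is the only item in the target channel.
#'
#' @param seed display seed
#' @param n_items ring size
#' @param target_index target position or NULL for target-absent
#' @return list(image, truth); 64x64 px at 0.5 deg/px
#' @export
demo_covert_display <- function(seed, n_items = 8, target_index = NULL) {
  spec <- display_spec(64, 64, 0.5, c("colorA", "colorB"), seed = seed)
  make_ring_display(spec, n_items = n_items, target_index = target_index,
                    target_features = c(colorA = 1),
                    distractor_features = c(colorB = 1),
                    ring_radius_deg = 7, item_half = 2L,
                    intensity_jitter = 0.2)
}

#' Canonical overt-search display: a ring outside the initial central field
#' @param seed display seed
#' @param n_items ring size
#' @param target_index target position or NULL for target-absent
#' @return list(image, truth); 128x128 px at 0.5 deg/px, ring radius 24 deg
#' @export
demo_overt_display <- function(seed, n_items = 8, target_index = NULL) {
  spec <- display_spec(128, 128, 0.5, c("colorA", "colorB"), seed = seed)
  make_ring_display(spec, n_items = n_items, target_index = target_index,
                    target_features = c(colorA = 1),
                    distractor_features = c(colorB = 1),
                    ring_radius_deg = 24, item_half = 2L)
}

#' Canonical cluttered display: one bright item among dimmer clutter
#' @param seed display seed
#' @return list(image, truth); the target is the brightest item
#' @export
demo_clutter_display <- function(seed) {
  spec <- display_spec(64, 64, 0.5, c("colorA", "colorB"), seed = seed)
  make_ring_display(spec, n_items = 8,
                    target_index = 1L + (seed %% 8L),
                    target_features = c(colorA = 1),
                    distractor_features = c(colorA = 0.45, colorB = 0.3),
                    ring_radius_deg = 7, item_half = 2L,
                    intensity_jitter = 0.2)
}
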