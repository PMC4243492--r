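# Stimulus laboratory: every display the model is tested on is generated here,
# with exact ground truth, so no external imagery is ever needed. Displays are
# multi-channel: each feature (curve, marker, colorA, ...) is its own image
# plane, which is what the visual hierarchy consumes. Coordinates are 1-based
# (row, col), origin top-left. All generation is a pure function of the seed.

#' Create a display specification
#'
#' @param width,height canvas size in pixels
#' @param deg_per_pixel degrees of visual angle per pixel (linear mapping)
#' @param channels ordered character vector of feature-channel names
#' @param seed integer seed; identical (spec, arguments, seed) give
#'   bit-identical displays and ground truth
#' @return an object of class `display_spec`
#' @export
display_spec <- function(width = 64, height = 64, deg_per_pixel = 0.1,
                         channels = c("colorA", "colorB"), seed = 1L) {
  stopifnot(width > 0, height > 0, deg_per_pixel > 0, length(channels) >= 1)
  structure(list(width = as.integer(width), height = as.integer(height),
                 deg_per_pixel = deg_per_pixel,
                 channels = as.character(channels),
                 seed = as.integer(seed)),
            class = "display_spec")
}

blank_image <- function(spec) {
  ims <- lapply(spec$channels, function(ch) matrix(0, spec$height, spec$width))
  names(ims) <- spec$channels
  structure(ims, class = "display_image",
            deg_per_pixel = spec$deg_per_pixel)
}

#' @export
print.display_spec <- function(x, ...) {
  cat(sprintf("display_spec: %dx%d px, %.3g deg/px, channels: %s, seed %d\n",
              x$height, x$width, x$deg_per_pixel,
              paste(x$channels, collapse = ","), x$seed))
  invisible(x)
}

new_ground_truth <- function(item_positions = list(), item_features = list(),
                             curve_pixel_sets = list(), marker_positions = list(),
                             marker_curve_ids = integer(0), label = NA) {
  structure(list(item_positions = item_positions,
                 item_features = item_features,
                 curve_pixel_sets = curve_pixel_sets,
                 marker_positions = marker_positions,
                 marker_curve_ids = marker_curve_ids,
                 label = label),
            class = "ground_truth")
}

# --- curve displays ----------------------------------------------------------

# Constrained random walk: unit steps with bounded heading change, steered back
# toward the canvas interior near borders. Returns the polyline vertices.
curve_walk <- function(spec, n_steps, margin) {
  h <- spec$height; w <- spec$width
  r <- stats::runif(1, margin, h - margin)
  c <- stats::runif(1, margin, w - margin)
  heading <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(0, n_steps + 1L, 2L)
  pts[1, ] <- c(r, c)
  max_turn <- 0.25
  for (i in seq_len(n_steps)) {
    heading <- heading + stats::runif(1, -max_turn, max_turn)
    # steer toward center when close to the border
    if (r < margin || r > h - margin || c < margin || c > w - margin) {
      to_center <- atan2((h / 2) - r, (w / 2) - c)
      # rotate heading a fixed fraction toward center direction
      d <- atan2(sin(to_center - heading), cos(to_center - heading))
      heading <- heading + 0.35 * d
    }
    r <- r + sin(heading)
    c <- c + cos(heading)
    pts[i + 1L, ] <- c(r, c)
  }
  pts
}

rasterize_polyline <- function(pts, nr, nc) {
  ip <- cbind(round(pts[, 1]), round(pts[, 2]))
  segs <- lapply(seq_len(nrow(ip) - 1L), function(i) bresenham(ip[i, ], ip[i + 1L, ]))
  coords <- unique(do.call(rbind, segs))
  keep <- coords[, 1] >= 1 & coords[, 1] <= nr & coords[, 2] >= 1 & coords[, 2] <= nc
  coords[keep, , drop = FALSE]
}

polyline_arc_length <- function(pts) {
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}

# index of the polyline vertex closest to a fraction of total arc length
arc_position_index <- function(pts, arc_px) {
  d <- c(0, sqrt(rowSums(diff(pts)^2)))
  cs <- cumsum(d)
  which.min(abs(cs - arc_px))
}

#' Generate a curve-tracing display
#'
#' Renders smooth non-crossing curves into a `"curve"` channel and X markers
#' into a `"marker"` channel. Curves are constrained random walks with bounded
#' curvature; a candidate curve is rejected and re-drawn when it comes within
#' `min_separation` pixels (Chebyshev) of itself (non-adjacent portions) or of
#' any previously placed curve, up to `max_retries` attempts.
#'
#' @param spec a [display_spec()]; its channels must include "curve","marker"
#' @param n_curves number of curves (>= 1)
#' @param curve_length along-curve length in degrees of visual angle
#' @param n_markers 0, 1 or 2 X markers
#' @param same_curve if TRUE both markers go on curve 1; if FALSE the second
#'   marker goes on curve 2 (requires n_curves >= 2)
#' @param marker_arc_deg along-curve distance (degrees) between the two
#'   markers when both lie on the same curve
#' @param marker_start_deg along-curve position (degrees from the curve start)
#'   of the first marker
#' @param min_separation minimum Chebyshev separation between curves in pixels
#' @param max_retries bounded rejection sampling before a placement error
#' @return list(image, truth): a `display_image` (list of channel matrices)
#'   and a `ground_truth` with curve pixel sets, marker positions,
#'   marker-to-curve assignment and a "same"/"different" label
#' @export
make_curve_display <- function(spec, n_curves = 2, curve_length = 6.6,
                               n_markers = 2, same_curve = TRUE,
                               marker_arc_deg = NULL, marker_start_deg = 0.5,
                               min_separation = 3L, max_retries = 100L) {
  stopifnot(n_curves >= 1, curve_length > 0, n_markers %in% 0:2)
  stopifnot(all(c("curve", "marker") %in% spec$channels))
  if (!same_curve && n_markers == 2 && n_curves < 2)
    stop("same_curve = FALSE needs at least two curves")
  with_seed(spec$seed, {
    n_steps <- max(4L, round(curve_length / spec$deg_per_pixel))
    margin <- max(4, min_separation + 2)
    img <- blank_image(spec)
    occupied <- matrix(FALSE, spec$height, spec$width)
    curves <- list()      # pixel sets (n x 2)
    polylines <- list()
    for (k in seq_len(n_curves)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        pts <- curve_walk(spec, n_steps, margin)
        px <- rasterize_polyline(pts, spec$height, spec$width)
        if (nrow(px) < n_steps * 0.5) next      # clipped too much at borders
        if (walk_self_close(pts, min_separation)) next
        m <- set_pixels(matrix(FALSE, spec$height, spec$width), px, TRUE)
        # separation from previously placed curves
        if (any(dilate_chebyshev(m, min_separation) & occupied)) next
        occupied <- occupied | m
        curves[[k]] <- mask_coords(m)
        polylines[[k]] <- pts
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("placement error: could not place non-crossing curve %d in %d retries",
                     k, max_retries))
    }
    for (k in seq_len(n_curves))
      img[["curve"]] <- set_pixels(img[["curve"]], curves[[k]], 1)

    marker_positions <- list()
    marker_curve_ids <- integer(0)
    if (n_markers >= 1) {
      start_px <- marker_start_deg / spec$deg_per_pixel
      i1 <- arc_position_index(polylines[[1]], start_px)
      p1 <- nearest_curve_pixel(polylines[[1]][i1, ], curves[[1]])
      marker_positions[[1]] <- p1
      marker_curve_ids[1] <- 1L
    }
    if (n_markers == 2) {
      if (same_curve) {
        arc <- marker_arc_deg %||% (curve_length * 0.6)
        i2 <- arc_position_index(polylines[[1]],
                                 marker_start_deg / spec$deg_per_pixel +
                                   arc / spec$deg_per_pixel)
        p2 <- nearest_curve_pixel(polylines[[1]][i2, ], curves[[1]])
        marker_positions[[2]] <- p2
        marker_curve_ids[2] <- 1L
      } else {
        i2 <- arc_position_index(polylines[[2]],
                                 (marker_start_deg %||% 0.5) / spec$deg_per_pixel)
        p2 <- nearest_curve_pixel(polylines[[2]][i2, ], curves[[2]])
        marker_positions[[2]] <- p2
        marker_curve_ids[2] <- 2L
      }
    }
    for (p in marker_positions)
      img[["marker"]] <- draw_x(img[["marker"]], p, arm = 2L)

    label <- if (n_markers == 2) {
      if (marker_curve_ids[1] == marker_curve_ids[2]) "same" else "different"
    } else NA_character_
    truth <- new_ground_truth(curve_pixel_sets = curves,
                              marker_positions = marker_positions,
                              marker_curve_ids = marker_curve_ids,
                              label = label)
    truth$arc_px <- vapply(polylines, polyline_arc_length, 0)
    list(image = img, truth = truth)
  })
}

# TRUE when a walk approaches its own non-adjacent portion closer than sep px;
# unit steps make vertex spacing ~1 px so a vertex check suffices
walk_self_close <- function(pts, sep) {
  n <- nrow(pts)
  window <- max(6L, 3L * sep)   # ignore the immediately preceding stretch
  for (i in seq_len(n)) {
    j <- seq_len(max(0L, i - window))
    if (!length(j)) next
    d2 <- (pts[j, 1] - pts[i, 1])^2 + (pts[j, 2] - pts[i, 2])^2
    if (min(d2) < sep^2) return(TRUE)
  }
  FALSE
}

# snap a (possibly fractional) polyline vertex to the nearest rasterized pixel
nearest_curve_pixel <- function(pt, px) {
  d <- (px[, 1] - pt[1])^2 + (px[, 2] - pt[2])^2
  as.integer(px[which.min(d), ])
}

draw_x <- function(m, center, arm = 2L) {
  r <- center[1]; c <- center[2]
  for (d in -arm:arm) {
    coords <- rbind(c(r + d, c + d), c(r + d, c - d))
    m <- set_pixels(m, coords, 1)
  }
  m
}

draw_square <- function(m, center, half, value = 1) {
  r0 <- max(1L, center[1] - half); r1 <- min(nrow(m), center[1] + half)
  c0 <- max(1L, center[2] - half); c1 <- min(ncol(m), center[2] + half)
  m[r0:r1, c0:c1] <- value
  m
}

# --- ring displays -----------------------------------------------------------

#' Generate a ring display for search tasks
#'
#' `n_items` square items equally spaced on a circle about the image center.
#' Exactly one item carries `target_features` when `target_index` is given
#' (target-present); otherwise all items carry `distractor_features`
#' (target-absent).
#'
#' @param spec a [display_spec()]
#' @param n_items number of ring items (>= 1)
#' @param target_index position of the target on the ring (1-based), or NULL
#'   for a target-absent display
#' @param target_features,distractor_features named numeric vectors of channel
#'   intensities (names must be channels of `spec`)
#' @param ring_radius_deg ring radius in degrees; default 40% of the smaller
#'   canvas dimension
#' @param item_half half-size of the square items in pixels
#' @param intensity_jitter multiplicative intensity jitter half-range applied
#'   per item (0 disables); identical seeds give identical jitter
#' @return list(image, truth) with item positions, per-item feature vectors
#'   and a "present"/"absent" label
#' @export
make_ring_display <- function(spec, n_items = 8, target_index = NULL,
                              target_features = c(colorA = 1),
                              distractor_features = c(colorB = 1),
                              ring_radius_deg = NULL, item_half = 2L,
                              intensity_jitter = 0) {
  stopifnot(n_items >= 1)
  if (!is.null(target_index))
    stopifnot(target_index >= 1, target_index <= n_items)
  stopifnot(all(names(target_features) %in% spec$channels),
            all(names(distractor_features) %in% spec$channels))
  radius_px <- if (is.null(ring_radius_deg))
    0.4 * min(spec$height, spec$width) else ring_radius_deg / spec$deg_per_pixel
  center <- c((spec$height + 1) / 2, (spec$width + 1) / 2)
  if (radius_px + item_half > min(center) - 1)
    stop("placement error: ring radius exceeds canvas")
  with_seed(spec$seed, {
    img <- blank_image(spec)
    angles <- (seq_len(n_items) - 1) * 2 * pi / n_items - pi / 2
    positions <- lapply(angles, function(a)
      c(round(center[1] + radius_px * sin(a)),
        round(center[2] + radius_px * cos(a))))
    feats <- vector("list", n_items)
    for (i in seq_len(n_items)) {
      fv <- if (!is.null(target_index) && i == target_index)
        target_features else distractor_features
      g <- if (intensity_jitter > 0)
        stats::runif(1, 1 - intensity_jitter, 1 + intensity_jitter) else 1
      full <- stats::setNames(numeric(length(spec$channels)), spec$channels)
      full[names(fv)] <- fv * g
      feats[[i]] <- full
      for (ch in names(fv))
        img[[ch]] <- draw_square(img[[ch]], positions[[i]], item_half, fv[[ch]] * g)
    }
    label <- if (is.null(target_index)) "absent" else "present"
    truth <- new_ground_truth(item_positions = positions, item_features = feats,
                              label = label)
    truth$target_index <- target_index
    list(image = img, truth = truth)
  })
}

# --- discrimination displays -------------------------------------------------

#' Generate a single-stimulus discrimination display
#'
#' One centrally located stimulus whose channel signature distinguishes class
#' A (first channel) from class B (second channel); class "noise" renders
#' channel-uncorrelated random texture.
#'
#' @param spec a [display_spec()] with at least two channels
#' @param class_id one of "A", "B", "noise"
#' @param item_half half-size of the central stimulus in pixels
#' @return list(image, truth); truth$label records the class
#' @export
make_discrimination_display <- function(spec, class_id = c("A", "B", "noise"),
                                        item_half = 4L) {
  class_id <- match.arg(class_id)
  stopifnot(length(spec$channels) >= 2)
  center <- c(round((spec$height + 1) / 2), round((spec$width + 1) / 2))
  with_seed(spec$seed, {
    img <- blank_image(spec)
    if (class_id == "noise") {
      for (ch in spec$channels) {
        patch <- matrix(stats::runif((2 * item_half + 1)^2, 0, 0.6),
                        2 * item_half + 1)
        r0 <- center[1] - item_half; c0 <- center[2] - item_half
        img[[ch]][r0:(r0 + 2 * item_half), c0:(c0 + 2 * item_half)] <- patch
      }
    } else {
      ch <- if (class_id == "A") spec$channels[1] else spec$channels[2]
      img[[ch]] <- draw_square(img[[ch]], center, item_half, 1)
    }
    truth <- new_ground_truth(item_positions = list(center),
                              label = class_id)
    list(image = img, truth = truth)
  })
}

# --- I/O ---------------------------------------------------------------------

#' Write a display to disk (one PNG per channel plus a ground-truth JSON)
#'
#' @param display list(image, truth) from a generator
#' @param dir output directory (created if missing)
#' @param stem filename stem
#' @return invisibly, the written file paths
#' @export
write_display <- function(display, dir, stem = "display") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(display$image)) {
    p <- file.path(dir, sprintf("%s_%s.png", stem, ch))
    m <- display$image[[ch]]
    png::writePNG(pmin(pmax(m, 0), 1), p)
    paths <- c(paths, p)
  }
  gt <- display$truth
  j <- list(
    curves = lapply(gt$curve_pixel_sets, function(px) unname(apply(px, 1, as.list))),
    markers = lapply(gt$marker_positions, as.list),
    marker_curve_ids = gt$marker_curve_ids,
    items = lapply(gt$item_positions, as.list),
    label = gt$label
  )
  jp <- file.path(dir, sprintf("%s_truth.json", stem))
  jsonlite::write_json(j, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}
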