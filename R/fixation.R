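# Fixation control (FC): peripheral priority map (PPM), fixation history map
# (FHM), history-biased priority map (HBPM), next-fixation selection, and
# saccade execution. Saliency here is local center--surround feature contrast
# (rectified, channel-gain weighted, summed) computed from the early
# representations; it is a deliberately simple stand-in behind the same
# interface a richer saliency model would use, and it is computed only in the
# periphery -- the PPM is identically zero inside the central attentional
# field. The FHM lives in WORLD coordinates (a frame larger than the retina),
# so its inhibition-of-return bias survives any saccade sequence.

#' A gaze view: where the retina sits in the world
#'
#' @param fixation c(row, col) world position of the current fixation
#' @param retina_dim c(rows, cols) of the retinal window
#' @return a `gaze_view` with the retina centered on the fixation
#' @export
gaze_view <- function(fixation, retina_dim) {
  rd <- as.integer(retina_dim)
  structure(list(fixation = round(as.numeric(fixation)),
                 retina_dim = rd,
                 center = floor((rd - 1) / 2) + 1),
            class = "gaze_view")
}

#' Map world coordinates to retinal coordinates under a view
#' @param view a [gaze_view()]
#' @param pos n x 2 matrix or length-2 vector of world (row, col)
#' @return same shape, retinal coordinates (may fall outside the retina)
#' @export
world_to_ret <- function(view, pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, 1)
  sweep(pos, 2, view$fixation - view$center, `-`)
}

#' Map retinal coordinates to world coordinates under a view
#' @param view a [gaze_view()]
#' @param pos n x 2 matrix or length-2 vector of retinal (row, col)
#' @return same shape, world coordinates
#' @export
ret_to_world <- function(view, pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, 1)
  sweep(pos, 2, view$fixation - view$center, `+`)
}

#' Compute the peripheral priority map
#'
#' @param image retinal multi-channel image (named list of matrices)
#' @param bias a [bias_spec()]; channel gains weight the per-channel contrast
#' @param central_radius_px central-field radius in pixels; the map is zeroed
#'   inside this radius of the retina center by construction
#' @param surround_half half-width of the surround window for the
#'   center--surround contrast
#' @return a `ppm` object: list(grid, central_radius_px, center)
#' @export
compute_ppm <- function(image, bias = bias_spec(), central_radius_px,
                        surround_half = 4L) {
  dims <- dim(image[[1]])
  grid <- matrix(0, dims[1], dims[2])
  for (ch in names(image)) {
    g <- bias$channel_gains[ch]
    g <- if (is.na(g)) 1 else g
    contrast <- image[[ch]] - box_mean(image[[ch]], surround_half)
    contrast[contrast < 1e-9] <- 0   # rectify; zap float residue on flats
    grid <- grid + g * contrast
  }
  center <- floor((dims - 1) / 2) + 1
  grid[disk_mask(dims[1], dims[2], center, central_radius_px)] <- 0
  structure(list(grid = grid, central_radius_px = central_radius_px,
                 center = center), class = "ppm")
}

# greedy non-maximum-suppression peak picking on a plain matrix
nms_peaks <- function(grid, k, excl_radius, floor = 0) {
  out <- data.frame(row = integer(0), col = integer(0), value = numeric(0))
  g <- grid
  for (i in seq_len(k)) {
    p <- argmax_lex(g)
    if (is.null(p)) break
    v <- g[p[1], p[2]]
    if (v <= floor) break
    out <- rbind(out, data.frame(row = p[1], col = p[2], value = v))
    g[disk_mask(nrow(g), ncol(g), p, excl_radius)] <- -Inf
  }
  out
}

#' Select up to k peripheral foci of attention from the PPM
#'
#' Greedy peak picking: take the global maximum, exclude a radius around it,
#' repeat. Ties break to the smallest (row, col).
#'
#' @param ppm a [compute_ppm()] result (or any object with a `grid`)
#' @param k maximum number of peaks (>= 1)
#' @param excl_radius exclusion radius around an accepted peak, pixels
#' @return data.frame(row, col, value), at most k rows, descending value;
#'   empty for an all-zero map
#' @export
select_pfoa <- function(ppm, k = 5L, excl_radius = 6) {
  stopifnot(k >= 1)
  nms_peaks(ppm$grid, k, excl_radius, floor = 0)
}

#' Create an empty fixation history map
#'
#' @param lambda per-update decay of existing entry weights, in (0, 1]
#' @param epsilon entries are dropped when their weight falls below this
#' @return an `fhm` object (world-frame entries)
#' @export
new_fhm <- function(lambda = 0.7, epsilon = 0.05) {
  stopifnot(lambda > 0, lambda <= 1, epsilon >= 0)
  structure(list(entries = list(), lambda = lambda, epsilon = epsilon,
                 center = NULL), class = "fhm")
}

#' Record a fixation (and optionally traced pixels) in the FHM
#'
#' All prior weights are multiplied by the decay `lambda`, entries whose
#' weight drops below `epsilon` are removed, and the new entry is appended
#' with weight 1. On an overt fixation the map is re-centered on the new
#' fixation; stored world positions never change (world-frame stability).
#'
#' @param fhm an [new_fhm()] object
#' @param fixation list with `pos` (world c(row, col)) and `kind`
#'   ("covert"/"overt"), e.g. from [make_fixation()]
#' @param traced optional n x 2 matrix of world pixels (e.g. the portion of a
#'   curve already traced) inhibited together with the fixation
#' @param radius inhibition radius of the fixation location, pixels
#' @return the updated FHM
#' @export
update_fhm <- function(fhm, fixation, traced = NULL, radius = 6) {
  keep <- list()
  for (e in fhm$entries) {
    e$weight <- e$weight * fhm$lambda
    if (e$weight >= fhm$epsilon || fhm$epsilon == 0) keep[[length(keep) + 1]] <- e
  }
  keep[[length(keep) + 1]] <- list(pos = as.numeric(fixation$pos),
                                   weight = 1, traced = traced,
                                   radius = radius)
  fhm$entries <- keep
  if (identical(fixation$kind, "overt")) fhm$center <- as.numeric(fixation$pos)
  fhm
}

#' Make a fixation record
#' @param pos world c(row, col)
#' @param kind "covert" or "overt" (only overt fixations move the retina)
#' @param cycle attentive-cycle index
#' @return a `fixation` object
#' @export
make_fixation <- function(pos, kind = c("overt", "covert"), cycle = NA_integer_) {
  kind <- match.arg(kind)
  structure(list(pos = as.numeric(pos), kind = kind, cycle = cycle),
            class = "fixation")
}

# retinal-frame inhibition map in [0,1]: max entry weight covering each pixel
fhm_inhibition <- function(fhm, view) {
  d <- view$retina_dim
  inh <- matrix(0, d[1], d[2])
  for (e in fhm$entries) {
    rp <- world_to_ret(view, e$pos)
    m <- disk_mask(d[1], d[2], rp[1, ], e$radius %||% 6)
    inh[m] <- pmax(inh[m], e$weight)
    if (!is.null(e$traced) && nrow(e$traced)) {
      tp <- world_to_ret(view, e$traced)
      ok <- tp[, 1] >= 1 & tp[, 1] <= d[1] & tp[, 2] >= 1 & tp[, 2] <= d[2]
      tp <- tp[ok, , drop = FALSE]
      if (nrow(tp)) inh[tp] <- pmax(inh[tp], e$weight)
    }
  }
  inh
}

#' Compose the history-biased priority map
#'
#' priority(x) = saliency(x) * (1 - inhibition(x)), where inhibition(x) is the
#' largest FHM weight whose entry covers x (location disks and traced pixel
#' sets). The current cFOA is marked but exempt from peripheral competition --
#' attending it needs no gaze change. Task demands may override the history
#' term entirely via `override`.
#'
#' @param cfoa optional central focus (retinal c(row, col)) to mark
#' @param pfoa ranked peripheral peaks from [select_pfoa()]
#' @param fhm the fixation history map
#' @param ppm the peripheral priority map
#' @param view the current [gaze_view()]
#' @param override ignore the FHM term (priorities equal raw saliency)
#' @return an `hbpm` object: list(grid, cfoa_mark, pfoa_candidates)
#' @export
compose_hbpm <- function(cfoa = NULL, pfoa = NULL, fhm, ppm, view,
                         override = FALSE) {
  if (is.null(cfoa) && (is.null(pfoa) || nrow(pfoa) == 0) &&
      all(ppm$grid == 0))
    stop("compose_hbpm needs at least one of cfoa/pfoa")
  inh <- if (override) 0 else fhm_inhibition(fhm, view)
  grid <- ppm$grid * (1 - inh)
  structure(list(grid = grid, cfoa_mark = cfoa, pfoa_candidates = pfoa),
            class = "hbpm")
}

#' Select the next fixation from the HBPM
#'
#' Candidates are peaks of the priority grid; the highest-priority candidate
#' satisfying the task predicate wins. Returns NULL ("none") when no candidate
#' exceeds the floor threshold -- this drives task termination.
#'
#' @param hbpm an [compose_hbpm()] result
#' @param view the current [gaze_view()]
#' @param constraint optional predicate `function(world_pos, ret_pos)`;
#'   e.g. on-curve-and-connected for tracing, NULL for free search
#' @param floor_frac floor as a fraction of the grid maximum
#' @param k number of candidate peaks examined
#' @param excl_radius peak exclusion radius
#' @param cycle attentive-cycle index stamped on the returned fixation
#' @return a `fixation` (kind "overt") or NULL
#' @export
select_next_fixation <- function(hbpm, view, constraint = NULL,
                                 floor_frac = 0.05, k = 12L, excl_radius = 6,
                                 cycle = NA_integer_) {
  mx <- max(hbpm$grid)
  if (mx <= 0) return(NULL)
  cand <- nms_peaks(hbpm$grid, k, excl_radius, floor = floor_frac * mx)
  if (!nrow(cand)) return(NULL)
  for (i in seq_len(nrow(cand))) {
    rp <- c(cand$row[i], cand$col[i])
    wp <- ret_to_world(view, rp)[1, ]
    if (is.null(constraint) || isTRUE(constraint(wp, rp)))
      return(make_fixation(wp, "overt", cycle))
  }
  NULL
}

#' Execute a saccade: re-center the retina on a world fixation
#'
#' The retinal view is the window of the world image centered on the fixation,
#' zero-padded where it extends beyond the world. The executive asserts (via
#' the event log) that attention was disengaged in the same cycle before any
#' saccade; calling through the engine enforces this sequencing.
#'
#' @param world multi-channel world image (named list of matrices)
#' @param fixation a `fixation` (kind "overt") within world bounds
#' @param retina_dim c(rows, cols) of the retina
#' @return list(image, view): the new retinal image and [gaze_view()]
#' @export
execute_saccade <- function(world, fixation, retina_dim) {
  wd <- dim(world[[1]])
  fp <- round(fixation$pos)
  if (fp[1] < 1 || fp[1] > wd[1] || fp[2] < 1 || fp[2] > wd[2])
    stop("fixation outside world bounds")
  view <- gaze_view(fp, retina_dim)
  r0 <- fp[1] - floor((retina_dim[1] - 1) / 2)
  c0 <- fp[2] - floor((retina_dim[2] - 1) / 2)
  image <- lapply(world, function(m) {
    out <- matrix(0, retina_dim[1], retina_dim[2])
    rr <- max(r0, 1L):min(r0 + retina_dim[1] - 1L, wd[1])
    cc <- max(c0, 1L):min(c0 + retina_dim[2] - 1L, wd[2])
    if (length(rr) && length(cc))
      out[rr - r0 + 1L, cc - c0 + 1L] <- m[rr, cc]
    out
  })
  list(image = image, view = view)
}
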