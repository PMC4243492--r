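# The visual hierarchy (VH): a small multi-level retinotopic feature pyramid.
# Level 1 is input resolution; each higher level pools a half-open window of
# the level below with a fixed stride. Pooling is an attenuation-weighted mean
# -- there is deliberately NO feedforward maximum anywhere: all max-finding is
# top-down (theta-WTA during recurrent localization), which is the point of
# the architecture. Three independent kinds of state ride on the hierarchy:
#   * gains        -- task priming (per-channel, plus an optional spatial
#                     prior at input resolution), applied at level 1,
#   * suppression  -- multiplicative surround attenuation in [0,1] per unit,
#   * inhibition   -- pathway (object-based IOR) flags with a cycle horizon.
# Resetting one never touches the others.

#' Build a visual hierarchy
#'
#' @param input_dim c(rows, cols) of the input (retinal) resolution
#' @param channels character vector of feature-channel names
#' @param n_levels number of levels including the input level (>= 3)
#' @param window pooling window edge in units of the level below (>= 2)
#' @param stride pooling stride; window == stride tiles each level exactly
#' @param central_radius_deg radius of the central attentional field, degrees
#' @param deg_per_pixel visual-angle scale at input resolution
#' @param ior_horizon pathway-inhibition lifetime in attentive cycles
#' @return an object of class `visual_hierarchy` with all gains 1, no
#'   suppression and no inhibition
#' @export
build_hierarchy <- function(input_dim = c(64L, 64L),
                            channels = c("colorA", "colorB"),
                            n_levels = 4L, window = 2L, stride = 2L,
                            central_radius_deg = 10,
                            deg_per_pixel = 0.1,
                            ior_horizon = 3L) {
  stopifnot(n_levels >= 3, window >= 2, stride >= 1, length(channels) >= 1)
  dims <- vector("list", n_levels)
  dims[[1]] <- as.integer(input_dim)
  for (l in seq_len(n_levels - 1L)) {
    d <- dims[[l]]
    if (any((d - window) %% stride != 0) || any(d < window))
      stop(sprintf("inconsistent resolutions: level %d is %dx%d, not tiled by window %d / stride %d",
                   l, d[1], d[2], window, stride))
    dims[[l + 1L]] <- as.integer((d - window) / stride + 1L)
  }
  ones <- function(d) matrix(1, d[1], d[2])
  zeros_i <- function(d) matrix(0L, d[1], d[2])
  per_level <- function(f) lapply(dims, function(d) {
    x <- lapply(channels, function(ch) f(d)); names(x) <- channels; x
  })
  structure(list(
    n_levels = as.integer(n_levels),
    channels = channels,
    dims = dims,
    window = as.integer(window),
    stride = as.integer(stride),
    channel_gains = stats::setNames(rep(1, length(channels)), channels),
    spatial_prior = NULL,
    suppression = per_level(ones),
    inhib_left = per_level(zeros_i),
    central_radius_deg = central_radius_deg,
    deg_per_pixel = deg_per_pixel,
    central_radius_px = central_radius_deg / deg_per_pixel,
    ior_horizon = as.integer(ior_horizon)
  ), class = "visual_hierarchy")
}

#' @export
print.visual_hierarchy <- function(x, ...) {
  cat(sprintf("visual_hierarchy: %d levels (%s), channels: %s\n",
              x$n_levels,
              paste(vapply(x$dims, function(d) paste(d, collapse = "x"), ""),
                    collapse = " -> "),
              paste(x$channels, collapse = ",")))
  invisible(x)
}

#' Create a bias specification for priming
#'
#' @param channel_gains named numeric vector of multiplicative channel gains
#'   (all > 0)
#' @param spatial_prior optional input-resolution gain matrix
#' @return a `bias_spec` object
#' @export
bias_spec <- function(channel_gains = numeric(0), spatial_prior = NULL) {
  stopifnot(all(channel_gains > 0))
  structure(list(channel_gains = channel_gains, spatial_prior = spatial_prior),
            class = "bias_spec")
}

#' Prime the hierarchy with top-down bias
#'
#' Updates gains multiplicatively. No response values change until the next
#' feedforward pass; the executive logs the priming event with its model-clock
#' lead (80--300 ms before stimulus onset).
#'
#' @param vh a visual hierarchy
#' @param bias a [bias_spec()]
#' @return the updated hierarchy
#' @export
apply_priming <- function(vh, bias) {
  unknown <- setdiff(names(bias$channel_gains), vh$channels)
  if (length(unknown))
    stop(sprintf("unknown channel in bias: %s", paste(unknown, collapse = ", ")))
  for (ch in names(bias$channel_gains))
    vh$channel_gains[[ch]] <- vh$channel_gains[[ch]] * bias$channel_gains[[ch]]
  if (!is.null(bias$spatial_prior)) {
    stopifnot(all(dim(bias$spatial_prior) == vh$dims[[1]]))
    sp <- vh$spatial_prior %||% matrix(1, vh$dims[[1]][1], vh$dims[[1]][2])
    vh$spatial_prior <- sp * bias$spatial_prior
  }
  vh
}

# effective transmitted output of a level: response x suppression x not-inhibited
vh_effective <- function(vh, acts, level, channel) {
  acts[[level]][[channel]] * vh$suppression[[level]][[channel]] *
    (vh$inhib_left[[level]][[channel]] == 0L)
}

# attenuation-weighted mean pooling of one channel from level l to l+1
pool_up <- function(vh, resp, s, level) {
  dlo <- vh$dims[[level]]; dhi <- vh$dims[[level + 1L]]
  k <- vh$window; st <- vh$stride
  num <- matrix(0, dhi[1], dhi[2])
  den <- matrix(0, dhi[1], dhi[2])
  base_r <- (seq_len(dhi[1]) - 1L) * st
  base_c <- (seq_len(dhi[2]) - 1L) * st
  for (dr in seq_len(k)) for (dc in seq_len(k)) {
    num <- num + (resp * s)[base_r + dr, base_c + dc, drop = FALSE]
    den <- den + s[base_r + dr, base_c + dc, drop = FALSE]
  }
  out <- num / den
  out[den == 0] <- 0
  out
}

#' Run a feedforward pass through the tuned hierarchy
#'
#' Level-1 responses are image x channel gain x spatial prior; each higher
#' unit is the attenuation-weighted mean over its receptive-field window of
#' the level below (suppressed or pathway-inhibited units contribute nothing
#' and are dropped from the pooling mass). With no suppression or inhibition
#' this reduces to the plain window mean, and the pass is linear in the image.
#'
#' @param vh a visual hierarchy
#' @param image a multi-channel image (named list of matrices) matching the
#'   input resolution and channel set
#' @return activations: list (one per level) of named lists of response
#'   matrices, class `vh_activations`
#' @export
feedforward_pass <- function(vh, image) {
  miss <- setdiff(vh$channels, names(image))
  if (length(miss))
    stop(sprintf("image lacks channels: %s", paste(miss, collapse = ", ")))
  d0 <- dim(image[[vh$channels[1]]])
  if (!all(d0 == vh$dims[[1]]))
    stop(sprintf("resolution mismatch: image %dx%d vs level-1 %dx%d",
                 d0[1], d0[2], vh$dims[[1]][1], vh$dims[[1]][2]))
  acts <- vector("list", vh$n_levels)
  sp <- vh$spatial_prior %||% 1
  acts[[1]] <- lapply(stats::setNames(vh$channels, vh$channels), function(ch)
    image[[ch]] * vh$channel_gains[[ch]] * sp)
  for (l in seq_len(vh$n_levels - 1L)) {
    acts[[l + 1L]] <- lapply(stats::setNames(vh$channels, vh$channels), function(ch) {
      s <- vh$suppression[[l]][[ch]] * (vh$inhib_left[[l]][[ch]] == 0L)
      pool_up(vh, acts[[l]][[ch]], s, l)
    })
  }
  structure(acts, class = "vh_activations")
}

# suppress a spatial annulus around selected locations at one level, and
# sibling channels at the selected locations; selected units are never touched
vh_suppress_level <- function(vh, level, sel, extent, feature_channels, factor) {
  # sel: named list channel -> logical location matrix (may share locations)
  d <- vh$dims[[level]]
  any_sel <- Reduce(`|`, sel, accumulate = FALSE) %||% matrix(FALSE, d[1], d[2])
  if (!any(any_sel)) return(vh)
  annulus <- dilate_chebyshev(any_sel, extent) & !any_sel
  for (ch in vh$channels) {
    m <- vh$suppression[[level]][[ch]]
    m[annulus] <- m[annulus] * factor
    if (ch %in% feature_channels) {
      sib <- any_sel & !(sel[[ch]] %||% matrix(FALSE, d[1], d[2]))
      m[sib] <- m[sib] * factor
    }
    vh$suppression[[level]][[ch]] <- m
  }
  vh
}

#' Impose attentive surround suppression around an attentional sample
#'
#' At each level of the sample, units within a Chebyshev annulus of width
#' `spatial_extent` around that level's selected locations -- and units of the
#' listed sibling channels at the selected locations -- have their suppression
#' multiplied by `factor`. Selected units themselves are never suppressed.
#'
#' @param vh a visual hierarchy
#' @param sample an [attentional sample][recurrent_localize()]
#' @param spatial_extent annulus width in units, per level
#' @param feature_extent channels receiving feature-surround suppression at
#'   the selected locations
#' @param factor attenuation in [0, 1)
#' @return the updated hierarchy
#' @export
impose_surround_suppression <- function(vh, sample, spatial_extent = 2L,
                                        feature_extent = character(0),
                                        factor = 0.1) {
  if (factor < 0 || factor >= 1) stop("factor must lie in [0, 1)")
  for (l in names(sample$levels)) {
    lev <- as.integer(l)
    sel <- sample_level_masks(vh, sample, lev)
    vh <- vh_suppress_level(vh, lev, sel, spatial_extent, feature_extent, factor)
  }
  vh
}

# per-channel logical masks of a sample's selections at one level
sample_level_masks <- function(vh, sample, level) {
  d <- vh$dims[[level]]
  sel <- lapply(stats::setNames(vh$channels, vh$channels),
                function(ch) matrix(FALSE, d[1], d[2]))
  units <- sample$levels[[as.character(level)]]
  if (!is.null(units) && nrow(units))
    for (i in seq_len(nrow(units)))
      sel[[units$channel[i]]][units$row[i], units$col[i]] <- TRUE
  sel
}

#' Lift all surround suppression
#'
#' Resets every suppression factor to 1. Pathway-inhibition flags and priming
#' gains are untouched (state separation).
#' @param vh a visual hierarchy
#' @return the updated hierarchy
#' @export
lift_surround_suppression <- function(vh) {
  for (l in seq_len(vh$n_levels))
    for (ch in vh$channels)
      vh$suppression[[l]][[ch]][] <- 1
  vh
}

#' Inhibit the pathways of an attentional sample (object-based IOR)
#'
#' Sets `inhibited = TRUE` for every unit in the sample; flags persist for
#' `horizon` attentive cycles ([vh_tick_inhibition()]) and then auto-release.
#'
#' @param vh a visual hierarchy
#' @param sample an attentional sample (empty sample is a no-op)
#' @param horizon lifetime in cycles; defaults to the hierarchy's setting
#' @return the updated hierarchy
#' @export
inhibit_pathways <- function(vh, sample, horizon = vh$ior_horizon) {
  if (is.null(sample) || !length(sample$levels)) return(vh)
  for (l in names(sample$levels)) {
    lev <- as.integer(l)
    units <- sample$levels[[l]]
    if (is.null(units) || !nrow(units)) next
    for (i in seq_len(nrow(units))) {
      cur <- vh$inhib_left[[lev]][[units$channel[i]]][units$row[i], units$col[i]]
      vh$inhib_left[[lev]][[units$channel[i]]][units$row[i], units$col[i]] <-
        max(cur, as.integer(horizon))
    }
  }
  vh
}

#' Clear all pathway inhibition
#'
#' Pathway flags are retinotopic; an overt saccade invalidates them (the
#' units no longer correspond to the previously attended object), so the
#' executive clears them when the retina moves. Location-based IOR in the
#' world-frame fixation history map provides the across-saccade memory.
#' @param vh a visual hierarchy
#' @return the updated hierarchy
#' @export
vh_clear_inhibition <- function(vh) {
  for (l in seq_len(vh$n_levels))
    for (ch in vh$channels)
      vh$inhib_left[[l]][[ch]][] <- 0L
  vh
}

#' Advance pathway-inhibition horizons by one attentive cycle
#' @param vh a visual hierarchy
#' @return the updated hierarchy with all positive horizons decremented
#' @export
vh_tick_inhibition <- function(vh) {
  for (l in seq_len(vh$n_levels))
    for (ch in vh$channels) {
      m <- vh$inhib_left[[l]][[ch]]
      m[m > 0L] <- m[m > 0L] - 1L
      vh$inhib_left[[l]][[ch]] <- m
    }
  vh
}

# --- geometry helpers --------------------------------------------------------

# cumulative stride (input pixels per unit step) at a level
stride_total <- function(vh, level) vh$stride^(level - 1L)

# receptive-field footprint (input pixels spanned by one unit) at a level
footprint <- function(vh, level) {
  f <- 1L
  for (l in seq_len(level - 1L)) f <- f + (vh$window - 1L) * vh$stride^(l - 1L)
  f
}

#' Input-space centers of all units at a level
#' @param vh a visual hierarchy
#' @param level level index
#' @return list(rows, cols): center coordinates in input pixels
#' @keywords internal
unit_centers <- function(vh, level) {
  st <- stride_total(vh, level)
  f <- footprint(vh, level)
  d <- vh$dims[[level]]
  list(rows = (seq_len(d[1]) - 1L) * st + (f + 1) / 2,
       cols = (seq_len(d[2]) - 1L) * st + (f + 1) / 2)
}

# window of level-l units feeding unit (i, j) at level l+1 (half-open tiling)
child_window <- function(vh, i, j) {
  list(rows = ((i - 1L) * vh$stride + 1L):((i - 1L) * vh$stride + vh$window),
       cols = ((j - 1L) * vh$stride + 1L):((j - 1L) * vh$stride + vh$window))
}

# parents at level l+1 whose windows cover (r, c) at level l
parent_units <- function(vh, level, r, c) {
  k <- vh$window; st <- vh$stride
  dhi <- vh$dims[[level + 1L]]
  i <- max(1L, ceiling((r - k) / st) + 1L):min(dhi[1], floor((r - 1L) / st) + 1L)
  j <- max(1L, ceiling((c - k) / st) + 1L):min(dhi[2], floor((c - 1L) / st) + 1L)
  expand.grid(row = i, col = j)
}
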