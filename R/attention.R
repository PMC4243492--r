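# Attention core: theta-winner-take-all selection and the recurrent top-down
# localization that produces the attentional sample (AS).
#
# theta-WTA returns, instead of a single unit, the spatially contiguous set of
# near-maximal responses: all admissible units with value >= (1 - theta) * max,
# restricted to the connected component containing the peak. theta is a
# dimensionless relative threshold ("binning threshold" read as a fraction of
# the maximum, which keeps it unit-free); theta = 0 selects the argmax alone.

#' theta-winner-take-all selection on a response map
#'
#' @param grid non-empty numeric matrix of responses (>= 0)
#' @param theta relative threshold in [0, 1); candidates are admissible units
#'   with value >= (1 - theta) * max
#' @param connectivity 4 or 8 (default 8)
#' @param mask optional logical matrix of admissible units; an all-FALSE mask
#'   is an error
#' @return list with `region` (n x 2 coordinate matrix), `region_mask`
#'   (logical matrix), `peak` (c(row, col); ties broken by smallest row, then
#'   column), `value` (peak response), `threshold`, and `no_winner` (TRUE when
#'   every admissible response is zero, in which case the region is empty)
#' @export
theta_wta <- function(grid, theta = 0.25, connectivity = 8, mask = NULL) {
  stopifnot(is.matrix(grid), length(grid) > 0, theta >= 0, theta < 1)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(grid)))
    if (!any(mask)) stop("empty mask: no admissible units")
  } else mask <- matrix(TRUE, nrow(grid), ncol(grid))
  g <- grid
  g[!mask] <- -Inf
  m <- max(g)
  if (!is.finite(m) || m <= 0) {
    return(list(region = matrix(0L, 0, 2), region_mask = mask & FALSE,
                peak = NULL, value = 0, threshold = NA_real_, no_winner = TRUE))
  }
  thr <- (1 - theta) * m
  cand <- mask & (grid >= thr)
  peak <- argmax_lex(g)
  lab <- label_components(cand, connectivity)
  region_mask <- lab == lab[peak[1], peak[2]] & cand
  list(region = mask_coords(region_mask), region_mask = region_mask,
       peak = peak, value = grid[peak[1], peak[2]], threshold = thr,
       no_winner = FALSE)
}

# top-level response map summed over the given channels, with suppression and
# pathway inhibition applied (transmitted responses)
top_level_map <- function(vh, acts, channels = vh$channels) {
  top <- vh$n_levels
  Reduce(`+`, lapply(channels, function(ch) vh_effective(vh, acts, top, ch)))
}

#' Select the central focus of attention (cFOA)
#'
#' Applies theta-WTA to the top level of the hierarchy over the task-relevant
#' channels, admitting only units whose input-space center lies within the
#' central attentional field of the current fixation and which are not
#' pathway-inhibited. Returns a "no cFOA" signal when nothing is admissible or
#' everything admissible is silent (this drives target-absent handling).
#'
#' @param vh a visual hierarchy
#' @param acts activations from [feedforward_pass()]
#' @param theta relative selection threshold
#' @param channels task-relevant channels (default all)
#' @param exclude optional logical matrix of top-level units to exclude
#'   (used by executive remediation to bar a failed winner)
#' @return as [theta_wta()], plus `level` (the top level index) and `no_cfoa`
#' @export
select_cfoa <- function(vh, acts, theta = 0.25, channels = vh$channels,
                        exclude = NULL) {
  top <- vh$n_levels
  d <- vh$dims[[top]]
  ctr <- unit_centers(vh, top)
  fix <- floor((vh$dims[[1]] - 1) / 2) + 1   # retina center in input pixels
  rr <- matrix(ctr$rows, d[1], d[2])
  cc <- matrix(ctr$cols, d[1], d[2], byrow = TRUE)
  central <- (rr - fix[1])^2 + (cc - fix[2])^2 <= vh$central_radius_px^2
  inhibited <- Reduce(`|`, lapply(channels, function(ch)
    vh$inhib_left[[top]][[ch]] > 0L))
  admissible <- central & !inhibited
  if (!is.null(exclude)) admissible <- admissible & !exclude
  if (!any(admissible)) {
    return(list(region = matrix(0L, 0, 2), region_mask = admissible,
                peak = NULL, value = 0, threshold = NA_real_,
                no_winner = TRUE, no_cfoa = TRUE, level = top))
  }
  res <- theta_wta(top_level_map(vh, acts, channels), theta = theta,
                   mask = admissible)
  res$no_cfoa <- res$no_winner
  res$level <- top
  res
}

# channels entering the sample at given locations: per location, every channel
# whose transmitted response is within theta of the strongest channel there
channels_at <- function(vh, acts, level, region, theta, channels = vh$channels) {
  eff <- lapply(stats::setNames(channels, channels),
                function(ch) vh_effective(vh, acts, level, ch))
  out <- NULL
  for (i in seq_len(nrow(region))) {
    r <- region[i, 1]; c <- region[i, 2]
    vals <- vapply(eff, function(m) m[r, c], 0)
    mx <- max(vals)
    if (mx <= 0) next
    chs <- names(vals)[vals >= (1 - theta) * mx]
    out <- rbind(out, data.frame(channel = chs, row = r, col = c,
                                 stringsAsFactors = FALSE))
  }
  out %||% data.frame(channel = character(0), row = integer(0), col = integer(0))
}

#' Recurrent top-down localization producing an attentional sample
#'
#' Starting from a top-level selection, descends level by level: the
#' admissible set at level l is the union of receptive-field windows of the
#' level-(l+1) selected units; theta-WTA is applied to the summed-channel
#' response within that restriction; every supra-threshold channel at a
#' selected location enters the sample; and surround suppression is imposed
#' around each level's selection as it is formed. Descent stops after `depth`
#' levels (a partial recurrent pass) or at the input level (`"full"`).
#'
#' @param vh a visual hierarchy
#' @param acts activations from [feedforward_pass()]
#' @param root a top-level selection from [select_cfoa()] (must be non-empty
#'   and at the top level)
#' @param depth `"full"` or a number of levels to descend below the top
#' @param theta relative selection threshold used at every level
#' @param suppress impose surround suppression during the descent
#' @param spatial_extent,feature_extent,factor surround-suppression geometry
#'   (see [impose_surround_suppression()])
#' @return list with `sample` (class `attentional_sample`: `root`, per-level
#'   unit data frames in `levels`, parent `edges`) and `vh` (the hierarchy
#'   with any suppression imposed during the descent)
#' @export
recurrent_localize <- function(vh, acts, root, depth = "full", theta = 0.25,
                               suppress = TRUE, spatial_extent = 2L,
                               feature_extent = character(0), factor = 0.1,
                               channels = vh$channels) {
  top <- vh$n_levels
  if (is.null(root$peak) || isTRUE(root$no_winner))
    stop("root selection is empty")
  if (!identical(root$level, top))
    stop("root must be a top-level selection")
  n_down <- if (identical(depth, "full")) top - 1L else as.integer(depth)
  stopifnot(n_down >= 0, n_down <= top - 1L)

  levels <- list()
  edges <- data.frame(level = integer(0), channel = character(0),
                      row = integer(0), col = integer(0),
                      parent_row = integer(0), parent_col = integer(0))
  levels[[as.character(top)]] <- channels_at(vh, acts, top, root$region, theta,
                                             channels)
  if (suppress)
    vh <- vh_suppress_level(vh, top, mask_list_from_units(vh, top, levels[[as.character(top)]]),
                            spatial_extent, feature_extent, factor)
  sel_above <- root$region_mask
  if (n_down > 0) for (l in (top - 1L):(top - n_down)) {
    d <- vh$dims[[l]]
    admissible <- matrix(FALSE, d[1], d[2])
    above <- mask_coords(sel_above)
    for (i in seq_len(nrow(above))) {
      w <- child_window(vh, above[i, 1], above[i, 2])
      admissible[w$rows, w$cols] <- TRUE
    }
    loc_map <- Reduce(`+`, lapply(channels, function(ch)
      vh_effective(vh, acts, l, ch)))
    res <- theta_wta(loc_map, theta = theta, mask = admissible)
    if (res$no_winner) break
    units <- channels_at(vh, acts, l, res$region, theta, channels)
    levels[[as.character(l)]] <- units
    # link each selected unit to a selected feeder above it
    if (nrow(units)) {
      for (i in seq_len(nrow(units))) {
        par <- parent_units(vh, l, units$row[i], units$col[i])
        sel_par <- par[sel_above[cbind(par$row, par$col)], , drop = FALSE]
        if (nrow(sel_par)) {
          edges <- rbind(edges, data.frame(
            level = l, channel = units$channel[i],
            row = units$row[i], col = units$col[i],
            parent_row = sel_par$row[1], parent_col = sel_par$col[1]))
        }
      }
    }
    if (suppress)
      vh <- vh_suppress_level(vh, l, mask_list_from_units(vh, l, units),
                              spatial_extent, feature_extent, factor)
    sel_above <- res$region_mask
  }
  sample <- structure(list(
    root = list(level = top, row = root$peak[1], col = root$peak[2]),
    levels = levels, edges = edges), class = "attentional_sample")
  list(sample = sample, vh = vh)
}

mask_list_from_units <- function(vh, level, units) {
  d <- vh$dims[[level]]
  sel <- lapply(stats::setNames(vh$channels, vh$channels),
                function(ch) matrix(FALSE, d[1], d[2]))
  if (!is.null(units) && nrow(units))
    for (i in seq_len(nrow(units)))
      sel[[units$channel[i]]][units$row[i], units$col[i]] <- TRUE
  sel
}

#' Level-1 (input-resolution) support of an attentional sample
#' @param vh a visual hierarchy
#' @param sample an attentional sample
#' @return logical matrix at input resolution
#' @export
sample_support <- function(vh, sample) {
  d <- vh$dims[[1]]
  m <- matrix(FALSE, d[1], d[2])
  units <- sample$levels[["1"]]
  if (!is.null(units) && nrow(units))
    m[cbind(units$row, units$col)] <- TRUE
  m
}

#' Structural validity of an attentional sample
#'
#' Checks that the sample is rooted at the top level, that each level's
#' selected locations form one spatially connected set, and that every
#' selected non-top unit feeds some selected unit above via its
#' receptive-field window.
#'
#' @param vh a visual hierarchy
#' @param sample an attentional sample
#' @param connectivity 4 or 8
#' @return TRUE, or a character vector of violations
#' @export
sample_is_valid <- function(vh, sample, connectivity = 8) {
  bad <- character(0)
  top <- vh$n_levels
  if (!identical(sample$root$level, top)) bad <- c(bad, "root not at top level")
  lv <- sort(as.integer(names(sample$levels)), decreasing = TRUE)
  if (!length(lv) || lv[1] != top) bad <- c(bad, "no top-level selections")
  for (l in lv) {
    units <- sample$levels[[as.character(l)]]
    if (!nrow(units)) next
    d <- vh$dims[[l]]
    m <- matrix(FALSE, d[1], d[2])
    m[cbind(units$row, units$col)] <- TRUE
    if (max(label_components(m, connectivity)) > 1L)
      bad <- c(bad, sprintf("level %d selection not spatially connected", l))
    if (l < top) {
      up <- sample$levels[[as.character(l + 1L)]]
      if (is.null(up) || !nrow(up)) {
        bad <- c(bad, sprintf("level %d has no selected level above", l))
        next
      }
      upm <- matrix(FALSE, vh$dims[[l + 1L]][1], vh$dims[[l + 1L]][2])
      upm[cbind(up$row, up$col)] <- TRUE
      locs <- unique(units[, c("row", "col")])
      for (i in seq_len(nrow(locs))) {
        par <- parent_units(vh, l, locs$row[i], locs$col[i])
        if (!any(upm[cbind(par$row, par$col)]))
          bad <- c(bad, sprintf("unit (%d,%d,%d) feeds no selected unit above",
                                l, locs$row[i], locs$col[i]))
      }
    }
  }
  if (length(bad)) bad else TRUE
}

#' Serialize an attentional sample to JSON
#' @param sample an attentional sample
#' @param path optional file path; when NULL the JSON string is returned
#' @return the JSON string, invisibly when written to a file
#' @export
sample_to_json <- function(sample, path = NULL) {
  x <- list(
    root = c(sample$root$level, sample$root$row, sample$root$col),
    levels = lapply(sample$levels, function(df)
      lapply(seq_len(nrow(df)), function(i)
        list(df$channel[i], df$row[i], df$col[i]))),
    edges = if (nrow(sample$edges)) unname(split(sample$edges, seq_len(nrow(sample$edges)))) else list()
  )
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(s, path); return(invisible(s)) }
  s
}
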