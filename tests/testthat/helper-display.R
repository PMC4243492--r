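# The tracing driver orients to the lexicographically first marker it
# detects, so the "target" curve of a run is the curve carrying that marker.
traced_curve_index <- function(truth) {
  mp <- do.call(rbind, truth$marker_positions)
  first <- order(mp[, 1], mp[, 2])[1]
  truth$marker_curve_ids[first]
}

curve_mask <- function(truth, idx, dim = 128) {
  m <- matrix(FALSE, dim, dim)
  m[truth$curve_pixel_sets[[idx]]] <- TRUE
  m
}
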