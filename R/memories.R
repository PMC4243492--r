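# Memories: the associative long-term store of cognitive-program methods
# (mLTM), the visual working-memory Blackboard holding current and recent
# attentional samples, and the task working-memory Active Script NotePad
# (script progress, the sample/fixation trace, and task-relevant knowledge).
# Associative indexing is exact-term overlap scoring -- deterministic and
# directly testable.

#' Create an empty method long-term memory
#' @return an `mltm` object
#' @export
mltm_new <- function() structure(list(records = list()), class = "mltm")

#' Store a method record in mLTM
#'
#' @param mltm an [mltm_new()] store
#' @param method a `cp_method` (must pass [validate_method()])
#' @param index_keys non-empty character set of task-descriptor terms (task
#'   type, target kind, display kind, overt/covert)
#' @return the updated store
#' @export
mltm_store <- function(mltm, method, index_keys = method$index_keys) {
  stopifnot(length(index_keys) >= 1)
  rep <- validate_method(method)
  if (!rep$valid)
    stop(sprintf("invalid method rejected: %s",
                 paste(rep$violations, collapse = "; ")))
  mltm$records[[length(mltm$records) + 1]] <-
    list(method = method, index_keys = unique(as.character(index_keys)))
  mltm
}

#' Fetch methods by associative overlap with a task descriptor
#'
#' Records are ranked by descending |descriptor intersect index_keys| /
#' |index_keys|; ties keep insertion order. Records with no overlap are not
#' returned.
#'
#' @param mltm the store
#' @param descriptor non-empty character set of task terms
#' @return list of records (each with `method`, `index_keys`, `score`),
#'   best first; empty list when nothing overlaps
#' @export
mltm_fetch <- function(mltm, descriptor) {
  stopifnot(length(descriptor) >= 1)
  descriptor <- as.character(descriptor)
  scored <- list()
  for (i in seq_along(mltm$records)) {
    rec <- mltm$records[[i]]
    ov <- length(intersect(descriptor, rec$index_keys)) / length(rec$index_keys)
    if (ov > 0) {
      rec$score <- ov
      rec$order <- i
      scored[[length(scored) + 1]] <- rec
    }
  }
  if (!length(scored)) return(list())
  ord <- order(-vapply(scored, `[[`, 0, "score"),
               vapply(scored, `[[`, 0, "order"))
  scored[ord]
}

#' Create an empty visual working-memory blackboard
#' @param capacity bound on the history of prior samples
#' @return a `blackboard`
#' @export
bb_new <- function(capacity = 10L) {
  structure(list(current = NULL, history = list(),
                 capacity = as.integer(capacity)), class = "blackboard")
}

#' Write the current attentional sample to the blackboard
#'
#' The previous current sample is pushed into the bounded history.
#' @param bb a blackboard
#' @param sample an attentional sample
#' @param cycle attentive-cycle stamp
#' @return the updated blackboard
#' @export
bb_write_sample <- function(bb, sample, cycle = NA_integer_) {
  if (!is.null(bb$current)) {
    bb$history[[length(bb$history) + 1]] <- bb$current
    if (length(bb$history) > bb$capacity)
      bb$history <- bb$history[(length(bb$history) - bb$capacity + 1):length(bb$history)]
  }
  bb$current <- list(sample = sample, cycle = cycle)
  bb
}

#' Read the current attentional sample (non-destructive)
#' @param bb a blackboard
#' @return list(sample, cycle), or NULL with an "empty" signal attribute when
#'   nothing has been written
#' @export
bb_read_sample <- function(bb) {
  if (is.null(bb$current)) return(structure(list(), empty = TRUE))
  bb$current
}

#' Create an empty Active Script NotePad
#' @return a `notepad` with an append-only trace and a knowledge store
#' @export
notepad_new <- function() {
  structure(list(active_scripts = list(), trace = list(),
                 knowledge = list()), class = "notepad")
}

#' Append a record to the NotePad trace (append-only)
#'
#' @param np a notepad
#' @param kind record kind, e.g. "sample", "fixation", "checkpoint"
#' @param payload arbitrary record content
#' @param cycle attentive-cycle stamp (non-decreasing across appends)
#' @return the updated notepad
#' @export
notepad_append <- function(np, kind, payload = NULL, cycle = NA_integer_) {
  np$trace[[length(np$trace) + 1]] <-
    list(kind = kind, payload = payload, cycle = cycle)
  np
}

#' Query NotePad trace records by kind and cycle range, preserving order
#' @param np a notepad
#' @param kind record kind to filter on
#' @param range optional c(lo, hi) cycle range (inclusive)
#' @return list of matching records in append order
#' @export
notepad_query <- function(np, kind, range = NULL) {
  out <- Filter(function(r) {
    if (!identical(r$kind, kind)) return(FALSE)
    if (!is.null(range) && !is.na(r$cycle))
      return(r$cycle >= range[1] && r$cycle <= range[2])
    TRUE
  }, np$trace)
  out
}

#' Export the NotePad trace as JSONL
#' @param np a notepad
#' @param path output file
#' @return invisibly, the path
#' @export
notepad_export_jsonl <- function(np, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in np$trace)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null",
                                digits = NA), con)
  invisible(path)
}
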