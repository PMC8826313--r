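# Trial segmentation: map stimulus sweeps onto acquired frames.
#
# Naming note: "sweep-trial" is one unidirectional sweep of the bar (the
# unit QC and the per-trial Fourier analysis operate on); "pair-trial" is
# one forward + one backward sweep of the same axis (the unit the
# hemodynamic delay correction and the reliability analysis operate on).

#' Build an event table of stimulus sweeps
#'
#' @param onset_s,offset_s sweep onset/offset times in seconds.
#' @param direction sweep direction labels (`NT`, `TN`, `IS`, `SI`).
#' @param block integer block id per sweep (default all 1).
#' @return a `data.frame` with class `event_table`, sorted by onset.
#' @export
event_table <- function(onset_s, offset_s, direction, block = 1L) {
  if (any(offset_s <= onset_s))
    isi_stop("isimap_event_error", "every sweep must have onset < offset")
  ev <- data.frame(onset_s = onset_s, offset_s = offset_s,
                   direction = as.character(direction),
                   block = as.integer(rep_len(block, length(onset_s))))
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Read / write event tables as CSV
#'
#' Columns: `onset_s, offset_s, direction, block`.
#' @param path CSV path.
#' @return an `event_table`.
#' @export
read_events <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_table(d$onset_s, d$offset_s, d$direction, d$block %||% 1L)
}

#' @rdname read_events
#' @param events an `event_table`.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(unclass(events)), path, row.names = FALSE)
  invisible(path)
}

#' Segment a continuous acquisition into direction-labelled sweep-trials
#'
#' Each sweep claims exactly the frames whose timestamp lies in the
#' half-open interval `[onset, offset)`; a frame belongs to at most one
#' sweep. Sweeps that catch no frame are excluded and reported in the
#' `empty` attribute. With nominal acquisition (e.g. 18 s sweeps sampled
#' at 10 Hz, phase-locked) every trial holds `sweep_duration * frame_rate`
#' frames (180 at the defaults).
#'
#' @param stack an `image_stack`.
#' @param events an `event_table` of sweeps.
#' @param cfg a `stim_config`; used to validate direction labels.
#' @return a `data.frame` (class `trial_set`) with one row per retained
#'   sweep-trial: `direction, block, first_frame, last_frame, n_frames`
#'   (frame indices are 1-based into the stack).
#' @export
segment_trials <- function(stack, events, cfg = stim_config()) {
  ts <- stack$timestamps
  bad_dir <- setdiff(unique(events$direction), cfg$directions)
  if (length(bad_dir))
    isi_stop("isimap_event_error", "unknown sweep direction(s): %s",
             paste(bad_dir, collapse = ", "))
  # frames are claimed on [onset, offset), so an offset up to one frame
  # period past the final timestamp is still fully covered
  dt <- if (length(ts) > 1) stats::median(diff(ts)) else 1 / stack$frame_rate
  out_of_range <- events$onset_s < ts[1] - 1e-9 |
    events$offset_s > ts[length(ts)] + dt + 1e-9
  if (any(out_of_range))
    isi_stop("isimap_segmentation_error",
             "sweep(s) %s lie outside the stack's timestamp range [%.3f, %.3f] s",
             paste(which(out_of_range), collapse = ", "), ts[1], ts[length(ts)])
  ord <- order(events$onset_s)
  claimed <- rep(FALSE, length(ts))
  rows <- vector("list", nrow(events))
  empty <- integer(0)
  for (k in ord) {
    inside <- ts >= events$onset_s[k] & ts < events$offset_s[k] & !claimed
    idx <- which(inside)
    if (!length(idx)) { empty <- c(empty, k); next }
    claimed[idx] <- TRUE
    rows[[k]] <- data.frame(direction = events$direction[k],
                            block = events$block[k],
                            first_frame = min(idx), last_frame = max(idx),
                            n_frames = length(idx))
  }
  if (length(empty))
    isi_warn("%d sweep(s) caught no frames and were excluded: %s",
             length(empty), paste(empty, collapse = ", "))
  trials <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(trials)) trials <- data.frame(direction = character(0), block = integer(0),
                                            first_frame = integer(0), last_frame = integer(0),
                                            n_frames = integer(0))
  rownames(trials) <- NULL
  attr(trials, "empty_sweeps") <- empty
  attr(trials, "unassigned_frames") <- sum(!claimed)
  class(trials) <- c("trial_set", "data.frame")
  trials
}
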