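# Time-resolved scutoid analysis: onset/duration within the interphase,
# after-mitosis classification and developmental-time normalization.

#' Track scutoid events through tracked interphases
#'
#' Given per-frame scutoid calls with persistent cell ids and per-cell
#' interphase bounds, records for each cell the first frame at which it is
#' scutoidal (onset) and the last frame of that contiguous scutoidal run
#' (end). A cell with several disjoint scutoidal runs within one interphase
#' is flagged as an anomaly and every run is reported (never silently
#' merged). Runs still scutoidal at the interphase end are right-censored
#' there.
#'
#' @param calls_list list of [detect_scutoids()] results (or data frames with
#'   `cell_id` and `is_scutoid`), one per frame, in frame order.
#' @param track data frame `cell_id, interphase_start, interphase_end`
#'   (frame numbers, 1-based), e.g. the event table of
#'   [simulate_division_series()].
#' @return Data frame of class `scutoid_events`: `cell_id, onset, end,
#'   interphase_start, interphase_end, censored, anomaly`.
#' @export
track_scutoid_events <- function(calls_list, track) {
  n_frames <- length(calls_list)
  flags <- lapply(calls_list, function(cl) cl$cell_id[cl$is_scutoid %in% TRUE])
  rows <- list()
  for (r in seq_len(nrow(track))) {
    id <- track$cell_id[r]
    if (track$interphase_end[r] <= track$interphase_start[r]) next
    i0 <- max(1L, track$interphase_start[r])
    i1 <- min(n_frames, track$interphase_end[r])
    if (i0 > i1) next
    sc <- vapply(i0:i1, function(f) id %in% flags[[f]], logical(1))
    if (!any(sc)) next
    runs <- rle(sc)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    on_runs <- which(runs$values)
    for (k in on_runs) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = id,
        onset = i0 + starts[k] - 1L,
        end = i0 + ends[k] - 1L,
        interphase_start = track$interphase_start[r],
        interphase_end = track$interphase_end[r],
        censored = (i0 + ends[k] - 1L) >= i1,
        anomaly = length(on_runs) > 1L)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(cell_id = integer(0), onset = integer(0), end = integer(0),
                    interphase_start = integer(0), interphase_end = integer(0),
                    censored = logical(0), anomaly = logical(0))
  structure(out, class = c("scutoid_events", "data.frame"))
}

#' Normalize scutoid onset and duration over the interphase
#'
#' `onset_norm = (onset - start) / (end_of_interphase - start)`;
#' `duration_norm = (end - onset + 1 frame) / interphase length`, counting
#' inclusive frames to avoid off-by-one ambiguity.
#'
#' @param events a [track_scutoid_events()] result (or any data frame with
#'   `onset, end, interphase_start, interphase_end`).
#' @return The events with `onset_norm` and `duration_norm` columns added.
#' @export
normalize_events <- function(events) {
  len <- events$interphase_end - events$interphase_start
  if (any(len <= 0)) stop("invalid interphase bounds")
  if (any(events$onset < events$interphase_start |
            events$onset > events$interphase_end))
    stop("onset outside interphase bounds")
  events$onset_norm <- (events$onset - events$interphase_start) / len
  events$duration_norm <- (events$end - events$onset + 1) / len
  events
}

#' @rdname normalize_events
#' @param onset,end,interphase_start,interphase_end scalar frame numbers.
#' @export
normalize_event <- function(onset, end, interphase_start, interphase_end) {
  ev <- normalize_events(data.frame(onset = onset, end = end,
                                    interphase_start = interphase_start,
                                    interphase_end = interphase_end))
  c(onset_norm = ev$onset_norm, duration_norm = ev$duration_norm)
}

#' Classify scutoid onsets relative to mitosis
#'
#' Onsets strictly before `threshold` of the interphase are classed
#' `"after_mitosis"`; the threshold value itself (and anything later) is
#' `"independent"`.
#'
#' @param onset_norm numeric vector of normalized onsets in `[0, 1]`.
#' @param threshold interphase fraction (default 0.15).
#' @return Character vector of classes.
#' @export
classify_onset <- function(onset_norm, threshold = 0.15) {
  if (any(onset_norm < 0 | onset_norm > 1, na.rm = TRUE))
    stop("onset_norm must lie in [0, 1]")
  ifelse(onset_norm < threshold, "after_mitosis", "independent")
}

#' Proportion of scutoids with onset after mitosis
#'
#' @param events data frame with `onset_norm` (or `onset_class`), optionally
#'   `embryo_id` for a per-embryo breakdown.
#' @param threshold interphase fraction used when classes must be derived.
#' @return List: `overall` fraction, `per_embryo` data frame (or `NULL`),
#'   and `n` events.
#' @export
proportion_after_mitosis <- function(events, threshold = 0.15) {
  if (nrow(events) == 0L) stop("no events")
  cls <- if ("onset_class" %in% names(events)) events$onset_class
         else classify_onset(events$onset_norm, threshold)
  overall <- mean(cls == "after_mitosis")
  per_embryo <- NULL
  if ("embryo_id" %in% names(events)) {
    p <- tapply(cls == "after_mitosis", events$embryo_id, mean)
    per_embryo <- data.frame(embryo_id = names(p), proportion = as.numeric(p))
  }
  list(overall = overall, per_embryo = per_embryo, n = length(cls))
}

#' Developmental clock from a division log
#'
#' Relative time 0 is the first division of the early reference stage (the
#' division that opens the next stage) and relative time 1 the first division
#' of the late reference stage. Each stage splits into a mitotic-wave window,
#' ending when at least 50% of its cells have divided, and an interphase
#' window lasting until the first division of the next stage.
#'
#' @param division_log data frame `cell_id, stage, time`.
#' @param stage0,stage1 stage labels anchoring relative time 0 and 1.
#' @return List of class `developmental_clock`: `t0`, `t1`, `waves` (data
#'   frame `stage, wave_start, wave_end, interphase_end, n_cells`) and
#'   `rel_time(t)`.
#' @export
developmental_clock <- function(division_log, stage0 = "64-cell",
                                stage1 = "512-cell") {
  need <- c(stage0, stage1)
  if (!all(need %in% division_log$stage))
    stop("division log is missing stage(s): ",
         paste(setdiff(need, division_log$stage), collapse = ", "))
  first_div <- tapply(division_log$time, division_log$stage, min)
  t0 <- as.numeric(first_div[[stage0]])
  t1 <- as.numeric(first_div[[stage1]])
  if (!(t0 < t1)) stop("stage0 must divide before stage1")
  stages <- names(sort(first_div))
  waves <- do.call(rbind, lapply(seq_along(stages), function(i) {
    st <- stages[i]
    tt <- sort(division_log$time[division_log$stage == st])
    n <- length(tt)
    wave_end <- tt[ceiling(n / 2)]
    iend <- if (i < length(stages)) as.numeric(first_div[[stages[i + 1]]]) else NA_real_
    data.frame(stage = st, wave_start = tt[1], wave_end = wave_end,
               interphase_end = iend, n_cells = n)
  }))
  structure(list(t0 = t0, t1 = t1, waves = waves,
                 rel_time = function(t) (t - t0) / (t1 - t0)),
            class = "developmental_clock")
}
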