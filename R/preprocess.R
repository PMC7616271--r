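#' Configuration of the trajectory cleaning cascade
#'
#' Thresholds for the geometric outlier filters and the smoothing step. The
#' defaults are the cascade used for 24 fps multi-camera dog tracking:
#' detections above 1.5 m or outside the room are implausible; a key point
#' more than 1 m (3D) from the per-frame centroid of the detected key points
#' is a single-point misdetection; per-axis jumps of more than 1.5 m against
#' the temporally adjacent frames are spikes; and after a first linear
#' interpolation, per-axis steps of more than 0.4 m per frame (9.6 m/s at
#' 24 fps) are removed and re-interpolated, four times in all, before a
#' centred 3-frame rolling average. All thresholds are strict (`>`).
#'
#' @param height_cap metres; detections with z above this are removed.
#' @param centroid_radius metres; 3D distance from the per-frame key-point
#'   centroid above which a detection is removed.
#' @param neighbour_jump metres; per-axis difference against adjacent frames
#'   above which a detection is a spike.
#' @param velocity_step metres per frame, per axis, for the iterated
#'   velocity filter.
#' @param velocity_iterations number of filter + re-interpolation passes.
#' @param rolling_window odd window (frames) of the rolling average.
#' @param fps frame rate, frames per second.
#' @param neighbour_mode `"spike"` removes a detection only when it deviates
#'   from every adjacent retained detection it has (isolated-spike removal);
#'   `"strict"` removes it when it deviates from either neighbour.
#' @param max_gap longest gap (frames) the linear interpolation will fill;
#'   `Inf` fills every interior gap.
#' @return A `filter_config` list.
#' @export
filter_config <- function(height_cap = 1.5, centroid_radius = 1.0,
                          neighbour_jump = 1.5, velocity_step = 0.4,
                          velocity_iterations = 4, rolling_window = 3,
                          fps = 24, neighbour_mode = c("spike", "strict"),
                          max_gap = Inf) {
  neighbour_mode <- match.arg(neighbour_mode)
  stopifnot(height_cap > 0, centroid_radius > 0, neighbour_jump > 0,
            velocity_step > 0, velocity_iterations >= 1,
            rolling_window %% 2 == 1, fps > 0, max_gap >= 1)
  structure(list(height_cap = height_cap, centroid_radius = centroid_radius,
                 neighbour_jump = neighbour_jump,
                 velocity_step = velocity_step,
                 velocity_iterations = as.integer(velocity_iterations),
                 rolling_window = as.integer(rolling_window), fps = fps,
                 neighbour_mode = neighbour_mode, max_gap = max_gap),
            class = "filter_config")
}

#' Clip a recording to the trial window
#'
#' Keeps only the frames in `[onset, onset + n_frames)` and re-bases frame
#' indices to zero. Frames of the window not covered by the recording come
#' out as gaps.
#'
#' @param traj a [kp_trajectory()].
#' @param record the [trial_record()] (provides `n_frames`).
#' @param onset first frame of the trial within the recording.
#' @return A [kp_trajectory()] with exactly `record$n_frames` frames.
#' @export
clip_to_trial <- function(traj, record, onset = 0) {
  n <- record$n_frames
  window <- onset:(onset + n - 1L)
  if (max(traj$frames) < onset || min(traj$frames) > onset + n - 1L)
    stop(sprintf("recording for %s trial %d does not overlap the trial window",
                 record$dog_id, record$trial))
  idx <- match(window, traj$frames)
  coords <- lapply(traj$coords, function(m) {
    out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
    out[!is.na(idx), ] <- m[idx[!is.na(idx)], ]
    out
  })
  reproj <- if (!is.null(traj$reproj)) {
    out <- traj$reproj[rep(NA_integer_, n), , drop = FALSE]
    out[!is.na(idx), ] <- traj$reproj[idx[!is.na(idx)], ]
    out
  }
  kp_trajectory(0:(n - 1L), coords, fps = traj$fps, reproj = reproj)
}

#' Individual filter stages
#'
#' The stages of the cleaning cascade, exposed individually. Each takes and
#' returns an n x 3 coordinate matrix with `NA` rows as gaps, plus
#' bookkeeping of what was removed or filled. [preprocess_trial()] chains
#' them in the canonical order.
#'
#' `filter_bounds()` removes detections whose (x, y) is outside the floor
#' rectangle or whose z exceeds the height cap (strictly).
#'
#' @param m numeric n x 3 matrix of coordinates with `NA`-row gaps.
#' @param geometry a [room_geometry()].
#' @param cfg a [filter_config()].
#' @return list with the filtered matrix `m` and the logical vector
#'   `removed`.
#' @export
filter_bounds <- function(m, geometry, cfg = filter_config()) {
  present <- !is.na(m[, 1])
  fl <- geometry$floor
  out <- m[, 1] < fl[1] | m[, 1] > fl[2] | m[, 2] < fl[3] | m[, 2] > fl[4] |
    m[, 3] > geometry$height_cap
  removed <- present & out
  m[removed, ] <- NA_real_
  list(m = m, removed = removed)
}

#' @rdname filter_bounds
#' @param coords named list of n x 3 matrices, one per key point (the
#'   centroid is taken across the key points detected in each frame).
#' @export
filter_centroid_outliers <- function(coords, cfg = filter_config()) {
  kps <- names(coords)
  n <- nrow(coords[[1]])
  sx <- sy <- sz <- cnt <- numeric(n)
  for (kp in kps) {
    m <- coords[[kp]]
    p <- !is.na(m[, 1])
    sx <- sx + ifelse(p, m[, 1], 0)
    sy <- sy + ifelse(p, m[, 2], 0)
    sz <- sz + ifelse(p, m[, 3], 0)
    cnt <- cnt + p
  }
  cx <- sx / cnt; cy <- sy / cnt; cz <- sz / cnt
  removed <- list()
  for (kp in kps) {
    m <- coords[[kp]]
    p <- !is.na(m[, 1])
    d <- sqrt((m[, 1] - cx)^2 + (m[, 2] - cy)^2 + (m[, 3] - cz)^2)
    rm_kp <- p & !is.na(d) & d > cfg$centroid_radius
    m[rm_kp, ] <- NA_real_
    coords[[kp]] <- m
    removed[[kp]] <- rm_kp
  }
  list(coords = coords, removed = removed)
}

#' @rdname filter_bounds
#' @details `filter_neighbour_jumps()` compares each detection per axis with
#'   the detections at the immediately preceding and following frame. Under
#'   `"spike"` semantics a detection is removed only when it deviates by more
#'   than the threshold from every adjacent detection it has, so a genuine
#'   fast displacement does not delete both endpoints; `"strict"` removes on
#'   deviation from either neighbour. Detections with no adjacent detection
#'   are kept.
#' @export
filter_neighbour_jumps <- function(m, cfg = filter_config()) {
  n <- nrow(m)
  present <- !is.na(m[, 1])
  thr <- cfg$neighbour_jump
  prev <- rbind(rep(NA_real_, 3), m[-n, , drop = FALSE])
  nxt <- rbind(m[-1, , drop = FALSE], rep(NA_real_, 3))
  has_prev <- present & !is.na(prev[, 1])
  has_next <- present & !is.na(nxt[, 1])
  viol_prev <- has_prev & (abs(m[, 1] - prev[, 1]) > thr |
                           abs(m[, 2] - prev[, 2]) > thr |
                           abs(m[, 3] - prev[, 3]) > thr)
  viol_next <- has_next & (abs(m[, 1] - nxt[, 1]) > thr |
                           abs(m[, 2] - nxt[, 2]) > thr |
                           abs(m[, 3] - nxt[, 3]) > thr)
  removed <- if (cfg$neighbour_mode == "spike") {
    (has_prev | has_next) & (!has_prev | viol_prev) & (!has_next | viol_next)
  } else {
    viol_prev | viol_next
  }
  m[removed, ] <- NA_real_
  list(m = m, removed = removed)
}

#' @rdname filter_bounds
#' @details `interpolate_gaps()` fills interior gaps per axis by linear
#'   interpolation between the nearest present frames; it never extrapolates,
#'   so leading and trailing gaps stay missing. Gaps longer than
#'   `cfg$max_gap` frames are left unfilled.
#' @return `interpolate_gaps()` returns list(`m`, `filled`) where `filled`
#'   marks interpolated frames.
#' @export
interpolate_gaps <- function(m, cfg = filter_config()) {
  n <- nrow(m)
  present <- !is.na(m[, 1])
  filled <- rep(FALSE, n)
  if (sum(present) == 0) {
    warning("series is entirely missing; nothing to interpolate")
    return(list(m = m, filled = filled))
  }
  if (all(present) || sum(present) == 1)
    return(list(m = m, filled = filled))
  idx <- which(present)
  target <- which(!present)
  target <- target[target > idx[1] & target < idx[length(idx)]]
  if (is.finite(cfg$max_gap) && length(target)) {
    # length of the gap each missing frame belongs to
    gap_id <- findInterval(target, idx)
    gap_len <- idx[gap_id + 1] - idx[gap_id] - 1
    target <- target[gap_len <= cfg$max_gap]
  }
  if (length(target)) {
    for (j in 1:3)
      m[target, j] <- approx(idx, m[idx, j], xout = target)$y
    filled[target] <- TRUE
  }
  list(m = m, filled = filled)
}

#' @rdname filter_bounds
#' @param status integer vector: 0 missing, 1 retained detection,
#'   2 interpolated value.
#' @details `filter_velocity_iterative()` runs `velocity_iterations` passes
#'   of: flag the later frame of every consecutive pair whose per-axis
#'   difference exceeds `velocity_step`; remove the flagged frames;
#'   re-interpolate interior gaps. At 24 fps the default step of 0.4 m per
#'   frame corresponds to 9.6 m/s.
#' @return `filter_velocity_iterative()` returns list(`m`, `status`,
#'   `removed_detections`) where the count refers to original (never
#'   interpolated) detections removed across iterations.
#' @export
filter_velocity_iterative <- function(m, status, cfg = filter_config()) {
  thr <- cfg$velocity_step
  removed_detections <- integer(cfg$velocity_iterations)
  for (it in seq_len(cfg$velocity_iterations)) {
    n <- nrow(m)
    d <- abs(m[-1, , drop = FALSE] - m[-n, , drop = FALSE])
    viol <- !is.na(d[, 1]) & (d[, 1] > thr | d[, 2] > thr | d[, 3] > thr)
    flag <- c(FALSE, viol)          # later frame of the violating pair
    removed_detections[it] <- sum(flag & status == 1L)
    m[flag, ] <- NA_real_
    status[flag] <- 0L
    ip <- interpolate_gaps(m, cfg)
    m <- ip$m
    status[ip$filled] <- 2L
  }
  list(m = m, status = status, removed_detections = removed_detections)
}

#' @rdname filter_bounds
#' @details `smooth_rolling()` applies a centred rolling mean per axis; at
#'   the boundaries of the covered span the window shrinks to the available
#'   frames. Missing frames stay missing.
#' @export
smooth_rolling <- function(m, cfg = filter_config()) {
  n <- nrow(m)
  half <- (cfg$rolling_window - 1L) %/% 2L
  present <- !is.na(m[, 1])
  vals <- m
  vals[!present, ] <- 0
  sums <- vals
  counts <- as.numeric(present)
  for (k in seq_len(half)) {
    up <- rbind(vals[-seq_len(k), , drop = FALSE],
                matrix(0, k, 3))
    down <- rbind(matrix(0, k, 3),
                  vals[seq_len(n - k), , drop = FALSE])
    sums <- sums + up + down
    counts <- counts +
      c(as.numeric(present[-seq_len(k)]), rep(0, k)) +
      c(rep(0, k), as.numeric(present[seq_len(n - k)]))
  }
  out <- sums / counts
  out[!present, ] <- NA_real_
  colnames(out) <- colnames(m)
  out
}

#' Run the full cleaning cascade on one trial
#'
#' Executes, in order: clip to the trial window, bounds filter, per-frame
#' centroid filter, neighbour-jump filter, linear interpolation, the iterated
#' velocity filter (each pass followed by re-interpolation) and the rolling
#' average. Every stage's removals are logged per key point in a data-loss
#' ledger, and the proportion of tracked data (retained, non-interpolated
#' detections over total trial frames) is reported per key point.
#'
#' @param traj a [kp_trajectory()].
#' @param record the [trial_record()].
#' @param geometry a [room_geometry()].
#' @param cfg a [filter_config()].
#' @param onset trial onset frame within the recording.
#' @return A `processed_traj`: list with `frames`, smoothed `coords`,
#'   per-key-point `status` vectors (0 missing / 1 retained / 2
#'   interpolated), the `ledger` data frame (columns `keypoint`, `stage`,
#'   `removed`), `n_input` and `prop_tracked` per key point.
#' @export
preprocess_trial <- function(traj, record, geometry = room_geometry(),
                             cfg = filter_config(), onset = 0) {
  stopifnot(inherits(traj, "kp_traj"))
  pre_clip <- vapply(traj$coords, function(m) sum(!is.na(m[, 1])), integer(1))
  traj <- clip_to_trial(traj, record, onset)
  coords <- traj$coords
  kps <- names(coords)
  n <- length(traj$frames)
  ledger <- list()
  log_stage <- function(kp, stage, removed)
    ledger[[length(ledger) + 1]] <<- data.frame(
      keypoint = kp, stage = stage, removed = as.integer(removed),
      stringsAsFactors = FALSE)

  n_input <- vapply(coords, function(m) sum(!is.na(m[, 1])), integer(1))
  for (kp in kps) log_stage(kp, "clip", pre_clip[kp] - n_input[kp])

  for (kp in kps) {
    fb <- filter_bounds(coords[[kp]], geometry, cfg)
    coords[[kp]] <- fb$m
    log_stage(kp, "bounds", sum(fb$removed))
  }
  fc <- filter_centroid_outliers(coords, cfg)
  coords <- fc$coords
  for (kp in kps) log_stage(kp, "centroid", sum(fc$removed[[kp]]))

  status <- list()
  for (kp in kps) {
    fj <- filter_neighbour_jumps(coords[[kp]], cfg)
    log_stage(kp, "neighbour_jump", sum(fj$removed))
    st <- ifelse(is.na(fj$m[, 1]), 0L, 1L)
    ip <- interpolate_gaps(fj$m, cfg)
    st[ip$filled] <- 2L
    fv <- filter_velocity_iterative(ip$m, st, cfg)
    for (it in seq_along(fv$removed_detections))
      log_stage(kp, sprintf("velocity_%d", it), fv$removed_detections[it])
    coords[[kp]] <- smooth_rolling(fv$m, cfg)
    status[[kp]] <- fv$status
  }
  ledger <- do.call(rbind, ledger)
  prop_tracked <- vapply(status, function(s) sum(s == 1L) / n, numeric(1))
  structure(list(frames = traj$frames, coords = coords, status = status,
                 fps = traj$fps, ledger = ledger, n_input = pre_clip,
                 prop_tracked = prop_tracked),
            class = "processed_traj")
}

#' @rdname preprocess_trial
#' @param study a `wag_study` (typically after [corrupt_study()]).
#' @return `preprocess_study()` returns the study with a `processed` element
#'   added to every trial entry.
#' @export
preprocess_study <- function(study, cfg = filter_config()) {
  stopifnot(inherits(study, "wag_study"))
  study$trials <- lapply(study$trials, function(entry) {
    entry$processed <- preprocess_trial(entry$traj, entry$record,
                                        study$geometry, cfg)
    entry
  })
  study
}

#' Data-loss accounting across a set of runs
#'
#' Binds the per-trial ledgers of a processed study into one data frame with
#' run identifiers, for Table-style summaries and conservation checks.
#'
#' @param study a study processed with [preprocess_study()].
#' @return data frame with columns `dog_id`, `trial`, `keypoint`, `stage`,
#'   `removed`.
#' @export
study_ledger <- function(study) {
  rows <- lapply(study$trials, function(entry) {
    cbind(entry$record[rep(1, nrow(entry$processed$ledger)),
                       c("dog_id", "trial")],
          entry$processed$ledger)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
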