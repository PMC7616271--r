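#' Per-trial key-point trajectory container
#'
#' A `kp_traj` holds, for one trial, a dense frame grid and one n x 3
#' coordinate matrix (columns `x`, `y`, `z`, metres) per key point. Frames
#' with no detection are rows of `NA` — gaps are represented explicitly,
#' never as zeros. An optional matrix of per-detection reprojection errors
#' (pixels, frames x key points) may be attached.
#'
#' @param frames integer vector of frame indices, strictly increasing and
#'   contiguous.
#' @param coords named list (all eight [keypoint_names()] or a subset) of
#'   numeric matrices with one row per frame and columns x, y, z.
#' @param fps frame rate in frames per second.
#' @param reproj optional numeric matrix (frames x key points) of
#'   reprojection errors.
#' @return An object of class `kp_traj`.
#' @export
kp_trajectory <- function(frames, coords, fps = 24, reproj = NULL) {
  frames <- as.integer(frames)
  if (length(frames) && any(diff(frames) != 1L))
    stop("frames must be strictly increasing and contiguous")
  if (!all(names(coords) %in% keypoint_names()))
    stop("unknown key point label(s): ",
         paste(setdiff(names(coords), keypoint_names()), collapse = ", "))
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3 || nrow(m) != length(frames))
      stop("each coordinate matrix must be length(frames) x 3")
    colnames(m) <- c("x", "y", "z")
    ok <- rowSums(is.na(m))
    if (any(ok %in% c(1, 2)))
      stop("partially missing coordinate rows are not allowed")
    if (any(!is.finite(m[ok == 0, ])))
      stop("coordinates must be finite where present")
    m
  })
  structure(list(frames = frames, coords = coords, fps = fps, reproj = reproj),
            class = "kp_traj")
}

kp_valid <- function(traj, kp) !is.na(traj$coords[[kp]][, 1])

trial_key <- function(dog_id, trial) paste(dog_id, trial, sep = ":")

#' Read a long-form tracking table
#'
#' The on-disk dialect is a long CSV with one row per detection and columns
#' `dog_id`, `condition`, `trial`, `frame`, `keypoint`, `x`, `y`, `z` and
#' optionally `reproj_error`. Gaps are encoded by absent rows. The reader is
#' strict: an unknown key point label or non-monotone frame numbers within a
#' (dog, trial, keypoint) series are format errors, so no row is ever
#' silently dropped.
#'
#' @param path path to the CSV file.
#' @param fps frame rate of the recordings.
#' @return A `trajectory_set`: a list with element `trials`, a named list
#'   (key `"dog:trial"`) of entries, each holding `info` (one-row data frame
#'   with dog_id, condition, presence flags, trial) and `traj`
#'   ([kp_trajectory()]).
#' @export
read_tracking_table <- function(path, fps = 24) {
  if (!file.exists(path)) stop("tracking table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("dog_id", "condition", "trial", "frame", "keypoint",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("tracking table misses column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(df$keypoint), keypoint_names())
  if (length(bad))
    stop("unknown key point label(s): ", paste(bad, collapse = ", "))
  if (!all(df$condition %in% condition_levels()))
    stop("unknown condition label(s): ",
         paste(setdiff(unique(df$condition), condition_levels()),
               collapse = ", "))
  grp <- paste(df$dog_id, df$trial, df$keypoint, sep = ":")
  for (g in unique(grp)) {
    f <- df$frame[grp == g]
    if (any(diff(f) <= 0))
      stop("non-monotone frames in series ", g)
  }
  has_reproj <- "reproj_error" %in% names(df)
  trials <- list()
  tkey <- paste(df$dog_id, df$trial, sep = ":")
  for (k in unique(tkey)) {
    sub <- df[tkey == k, , drop = FALSE]
    fr <- seq(min(sub$frame), max(sub$frame))
    coords <- list()
    reproj <- if (has_reproj)
      matrix(NA_real_, length(fr), length(keypoint_names()),
             dimnames = list(NULL, keypoint_names()))
    for (kp in intersect(keypoint_names(), unique(sub$keypoint))) {
      rows <- sub[sub$keypoint == kp, , drop = FALSE]
      m <- matrix(NA_real_, length(fr), 3, dimnames = list(NULL, c("x", "y", "z")))
      idx <- rows$frame - fr[1] + 1L
      m[idx, ] <- as.matrix(rows[, c("x", "y", "z")])
      coords[[kp]] <- m
      if (has_reproj) reproj[idx, kp] <- rows$reproj_error
    }
    info <- data.frame(
      dog_id = as.character(sub$dog_id[1]), condition = sub$condition[1],
      owner_present = sub$condition[1] %in% c("owner_only", "both_present"),
      stranger_present = sub$condition[1] %in% c("stranger_only", "both_present"),
      trial = as.integer(sub$trial[1]), stringsAsFactors = FALSE)
    trials[[k]] <- list(
      info = info,
      traj = kp_trajectory(fr, coords, fps = fps, reproj = reproj))
  }
  structure(list(trials = trials), class = "trajectory_set")
}

#' @rdname read_tracking_table
#' @param set a `trajectory_set` (or a study simulated with
#'   [simulate_study()]) to serialize.
#' @export
write_tracking_table <- function(set, path) {
  rows <- lapply(set$trials, function(entry) {
    info <- if (!is.null(entry$info)) entry$info else entry$record
    traj <- entry$traj
    do.call(rbind, lapply(names(traj$coords), function(kp) {
      m <- traj$coords[[kp]]
      ok <- !is.na(m[, 1])
      if (!any(ok)) return(NULL)
      data.frame(dog_id = info$dog_id, condition = info$condition,
                 trial = info$trial, frame = traj$frames[ok], keypoint = kp,
                 x = m[ok, 1], y = m[ok, 2], z = m[ok, 3],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$dog_id, out$trial, out$keypoint, out$frame), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write and re-read trial-level metric tables
#'
#' One row per dog x condition with a stable column order. Duplicate
#' (dog, condition) rows are an error.
#'
#' @param metrics data frame as produced by [compute_study_metrics()].
#' @param path output CSV path.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(is.data.frame(metrics))
  if (nrow(metrics)) {
    key <- paste(metrics$dog_id, metrics$condition)
    if (anyDuplicated(key))
      stop("duplicate (dog, condition) rows: ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  lead <- intersect(c("dog_id", "condition", "trial"), names(metrics))
  metrics <- metrics[, c(lead, setdiff(names(metrics), lead)), drop = FALSE]
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop("metrics file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(what, " table misses column(s): ", paste(missing_cols, collapse = ", "))
  df
}

#' Auxiliary study tables
#'
#' Readers for the small per-dog and per-trial side tables: morphometric
#' measurements (measured snout to head-centre distance and related head
#' distances, metres), manually scored interest-area durations (seconds), and
#' C-BARQ questionnaire subscale means (0-4 scale). All are plain CSV.
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_morphometry <- function(path) {
  df <- read_checked_csv(path, c("dog_id", "snout_head_m"), "morphometry")
  if (any(df$snout_head_m <= 0)) stop("morphometric distances must be positive")
  df
}

#' @rdname read_morphometry
#' @export
read_manual_scores <- function(path) {
  df <- read_checked_csv(
    path, c("dog_id", "condition", "trial", "owner_ia_s", "stranger_ia_s",
            "door_ia_s"), "manual scores")
  dur <- c(df$owner_ia_s, df$stranger_ia_s, df$door_ia_s)
  if (any(dur < 0, na.rm = TRUE)) stop("scored durations must be non-negative")
  df
}

#' @rdname read_morphometry
#' @export
read_cbarq <- function(path) {
  subs <- c("nonsocial_fear", "stranger_fear", "separation_problems",
            "attachment_attention")
  df <- read_checked_csv(path, c("dog_id", subs), "C-BARQ")
  vals <- unlist(df[subs])
  if (any(vals < 0 | vals > 4, na.rm = TRUE))
    stop("C-BARQ subscale means must lie in [0, 4]")
  df
}
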