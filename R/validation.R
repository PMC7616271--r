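#' Tracking-quality summary per key point
#'
#' Summarizes, across runs, the proportion of tracked data per key point
#' (valid, non-interpolated detections over total trial frames) as
#' median/min/max, plus the pooled mean reprojection error (pixels) when the
#' tracking tables carried one.
#'
#' @param study a study processed with [preprocess_study()].
#' @return data frame with one row per key point: `keypoint`, `median`,
#'   `min`, `max`, `mean_reproj_error` (`NA` when unavailable).
#' @export
tracking_summary <- function(study) {
  props <- t(vapply(study$trials, function(entry)
    entry$processed$prop_tracked[keypoint_names()],
    numeric(length(keypoint_names()))))
  colnames(props) <- keypoint_names()
  reproj <- vapply(keypoint_names(), function(kp) {
    vals <- unlist(lapply(study$trials, function(entry) {
      rp <- entry$traj$reproj
      if (is.null(rp)) NULL else rp[, kp]
    }))
    if (is.null(vals) || all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
  data.frame(
    keypoint = keypoint_names(),
    median = apply(props, 2, median),
    min = apply(props, 2, min),
    max = apply(props, 2, max),
    mean_reproj_error = reproj,
    row.names = NULL, stringsAsFactors = FALSE)
}

pearson_report <- function(x, y, comparison) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    return(data.frame(comparison = comparison, r = NA_real_, n = n,
                      df = n - 2L, p = NA_real_, stringsAsFactors = FALSE))
  }
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  data.frame(comparison = comparison, r = unname(ct$estimate), n = n,
             df = unname(ct$parameter), p = ct$p.value,
             stringsAsFactors = FALSE)
}

#' Cross-key-point consistency of distance travelled
#'
#' Pearson correlation matrix, across runs, of the distance travelled
#' computed per key point. With a rigid body all torso/head key points
#' should correlate almost perfectly; the tail tip moves partly
#' independently and correlates less.
#'
#' @param dists matrix (runs x key points) from [keypoint_distances()].
#' @return symmetric correlation matrix with unit diagonal.
#' @export
keypoint_distance_correlations <- function(dists) {
  if (nrow(dists) < 3) stop("need at least three runs")
  cor(dists, use = "pairwise.complete.obs")
}

#' Reconstructed versus measured head-snout distance
#'
#' For each dog, the median reconstructed snout to head-centre distance over
#' all frames and trials is compared with the tape-measured distance via a
#' Pearson correlation (two-sided p from the t transform with n - 2 df).
#' Dogs without a morphometry entry are excluded and listed.
#'
#' @param study a `wag_study`.
#' @param morphometry data frame with `dog_id`, `snout_head_m`; defaults to
#'   the study's own.
#' @return list with `per_dog` (dog_id, reconstructed, measured) and
#'   `report` (a one-row Pearson summary).
#' @export
head_snout_distance_check <- function(study, morphometry = study$morphometry) {
  recs <- study_records(study)
  dogs <- unique(recs$dog_id)
  med <- vapply(dogs, function(d) {
    vals <- unlist(lapply(study$trials, function(entry) {
      if (entry$record$dog_id != d) return(NULL)
      coords <- traj_coords(
        if (!is.null(entry$processed)) entry$processed else entry$traj)
      dd <- coords$snout - coords$head_centre
      sqrt(rowSums(dd^2))
    }))
    median(vals, na.rm = TRUE)
  }, numeric(1))
  per_dog <- data.frame(dog_id = dogs, reconstructed = med,
                        row.names = NULL, stringsAsFactors = FALSE)
  per_dog <- merge(per_dog, morphometry[, c("dog_id", "snout_head_m")],
                   by = "dog_id", all.x = TRUE)
  excluded <- per_dog$dog_id[is.na(per_dog$snout_head_m)]
  if (length(excluded))
    message("excluded (no morphometry): ", paste(excluded, collapse = ", "))
  per_dog <- per_dog[!is.na(per_dog$snout_head_m), ]
  list(per_dog = per_dog,
       report = pearson_report(per_dog$reconstructed, per_dog$snout_head_m,
                               "head_snout_distance"))
}

#' Agreement between tracking metrics and manual scorings
#'
#' Correlates, across runs, the tracking-based interest-area durations with
#' manually scored durations, per IA type. Runs present in only one of the
#' two tables are an error.
#'
#' @param metrics data frame from [compute_study_metrics()].
#' @param manual manual-scoring data frame (see [read_manual_scores()]).
#' @param duration trial duration (s) used to convert proportions to
#'   durations.
#' @return data frame with one Pearson report row per IA type.
#' @export
manual_vs_tracking_correlation <- function(metrics, manual, duration = 120) {
  key_m <- paste(metrics$dog_id, metrics$trial)
  key_s <- paste(manual$dog_id, manual$trial)
  unmatched <- c(setdiff(key_m, key_s), setdiff(key_s, key_m))
  if (length(unmatched))
    stop("unmatched trials: ", paste(unique(unmatched), collapse = ", "))
  manual <- manual[match(key_m, key_s), ]
  rbind(
    pearson_report(metrics$prop_owner_ia * duration, manual$owner_ia_s,
                   "owner_ia"),
    pearson_report(metrics$prop_stranger_ia * duration, manual$stranger_ia_s,
                   "stranger_ia"),
    pearson_report(metrics$prop_door_ia * duration, manual$door_ia_s,
                   "door_ia"))
}
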