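#' Trial-level behavioural metrics
#'
#' The behavioural response variables computed from a processed (or
#' noiseless) trajectory: interest-area occupancy, distance travelled,
#' average minimal object distance, grid-cell area coverage, the 3D visual
#' angle towards the owner's chair, the tail-wagging ratio and the signed 2D
#' tail angle. All metrics use only frames with a value (retained or
#' interpolated); coverage is reported so denominators are auditable.
#'
#' `time_in_area()` is the fraction of valued frames whose (x, y) falls in
#' the rectangle (closed on the lower edges, open on the upper).
#'
#' @param m n x 3 (or n x 2) coordinate matrix with `NA` rows for gaps.
#' @param rect rectangle `c(xmin, xmax, ymin, ymax)`.
#' @return A proportion in \[0, 1\], or `NA` when no frame has a value.
#' @export
time_in_area <- function(m, rect) {
  ok <- !is.na(m[, 1])
  if (!any(ok)) {
    warning("zero coverage; occupancy undefined")
    return(NA_real_)
  }
  sum(point_in_rect(m[ok, 1], m[ok, 2], rect)) / sum(ok)
}

#' @rdname time_in_area
#' @param planar if `TRUE` use only (x, y) displacements.
#' @details `distance_travelled()` sums Euclidean displacements between
#'   consecutive frames that both have values. The data are 3D, so the
#'   default includes the vertical component; `planar = TRUE` restricts to
#'   the floor plane.
#' @export
distance_travelled <- function(m, planar = FALSE) {
  ok <- !is.na(m[, 1])
  if (sum(ok) < 2) {
    warning("fewer than two valued frames; distance is 0")
    return(0)
  }
  cols <- if (planar) 1:2 else seq_len(ncol(m))
  d <- diff(m[, cols, drop = FALSE])
  keep <- !is.na(d[, 1])
  sum(sqrt(rowSums(d[keep, , drop = FALSE]^2)))
}

#' @rdname time_in_area
#' @param objects list of object reference points `c(x, y)` (plank centres
#'   at floor level; distance is horizontal).
#' @details `min_object_distance()` is the mean over the objects of the
#'   minimum, over valued frames, of the horizontal distance from the series
#'   to the object point.
#' @export
min_object_distance <- function(m, objects) {
  ok <- !is.na(m[, 1])
  if (!any(ok)) {
    warning("zero coverage; object distance undefined")
    return(NA_real_)
  }
  mean(vapply(objects, function(o)
    min(sqrt((m[ok, 1] - o[1])^2 + (m[ok, 2] - o[2])^2)), numeric(1)))
}

n_grid_cells <- function(geometry) {
  fl <- geometry$floor
  cs <- geometry$grid_cell
  c(nx = ceiling((fl[2] - fl[1]) / cs - 1e-9),
    ny = ceiling((fl[4] - fl[3]) / cs - 1e-9))
}

#' @rdname time_in_area
#' @param geometry a [room_geometry()]; the grid is anchored at the floor
#'   rectangle's minimum corner with half-open cells.
#' @details `area_covered()` is the number of grid cells containing at least
#'   one valued frame divided by the total number of cells (168 for a
#'   6 x 7 m room at 0.5 m cells).
#' @export
area_covered <- function(m, geometry) {
  ok <- !is.na(m[, 1])
  if (!any(ok)) {
    warning("zero coverage; area undefined")
    return(NA_real_)
  }
  fl <- geometry$floor
  cs <- geometry$grid_cell
  ncell <- n_grid_cells(geometry)
  ix <- pmin(floor((m[ok, 1] - fl[1]) / cs), ncell["nx"] - 1)
  iy <- pmin(floor((m[ok, 2] - fl[3]) / cs), ncell["ny"] - 1)
  length(unique(ix * ncell["ny"] + iy)) / prod(ncell)
}

#' Gaze-angle estimation from the head axis
#'
#' The looking direction is approximated from the head-centre to snout axis:
#' the eye sits at the midpoint of the two key points and the gaze is the
#' head axis rotated 45 degrees upward within the vertical plane containing
#' it. `visual_angle_series()` returns, per frame, the 3D angle in degrees
#' (0-180) between that gaze and the direction from the eye to the target
#' point. Frames where either key point is missing, the key points coincide,
#' or the head axis is vertical (the rotation plane is undefined) yield `NA`.
#'
#' @param head,snout n x 3 coordinate matrices.
#' @param target target point `c(x, y, z)` (e.g. the owner's chair seat).
#' @return numeric vector of angles, `NA` where undefined.
#' @export
visual_angle_series <- function(head, snout, target) {
  d <- snout - head
  hn <- sqrt(d[, 1]^2 + d[, 2]^2)
  dn <- sqrt(hn^2 + d[, 3]^2)
  ok <- !is.na(d[, 1]) & dn > 1e-12 & hn > 1e-12
  alpha <- atan2(d[, 3], hn) + pi / 4
  gaze <- cbind(cos(alpha) * d[, 1] / hn, cos(alpha) * d[, 2] / hn,
                sin(alpha))
  eye <- (head + snout) / 2
  tv <- cbind(target[1] - eye[, 1], target[2] - eye[, 2],
              target[3] - eye[, 3])
  tn <- sqrt(rowSums(tv^2))
  ok <- ok & tn > 1e-12
  ang <- acos(pmin(pmax(rowSums(gaze * tv) / tn, -1), 1)) * 180 / pi
  ang[!ok] <- NA_real_
  ang
}

#' @rdname visual_angle_series
#' @param angles vector of per-frame angles.
#' @export
mean_visual_angle <- function(angles) {
  if (all(is.na(angles))) return(NA_real_)
  mean(angles, na.rm = TRUE)
}

#' Tail-wagging metrics
#'
#' `tail_wag_ratio()` is the arc length travelled by the tail tip divided by
#' the arc length travelled by the tail base: values near 1 indicate a tail
#' that only follows the body, larger values indicate wagging.
#' `tail_angle_series()` is the signed planar angle (degrees, in
#' (-180, 180\]) between the atlas-to-tail-base axis and the
#' tail-base-to-tail-tip axis, projected to the floor plane; positive values
#' are deflections towards the dog's right.
#'
#' @param tip,base,atlas n x 3 coordinate matrices for the named key points.
#' @return `tail_wag_ratio()`: a non-negative scalar, `NA` when the base did
#'   not move (the ratio is undefined).
#' @export
tail_wag_ratio <- function(tip, base) {
  base_d <- distance_travelled(base)
  if (!is.finite(base_d) || base_d == 0) {
    warning("tail base did not move; wag ratio undefined")
    return(NA_real_)
  }
  distance_travelled(tip) / base_d
}

#' @rdname tail_wag_ratio
#' @export
tail_angle_series <- function(atlas, base, tip) {
  u <- base[, 1:2, drop = FALSE] - atlas[, 1:2, drop = FALSE]
  v <- tip[, 1:2, drop = FALSE] - base[, 1:2, drop = FALSE]
  un <- sqrt(rowSums(u^2))
  vn <- sqrt(rowSums(v^2))
  ok <- !is.na(un) & !is.na(vn) & un > 1e-12 & vn > 1e-12
  # with the body axis pointing backwards (atlas -> tail base), this signed
  # angle is positive for deflections towards the animal's right
  ang <- atan2(u[, 1] * v[, 2] - u[, 2] * v[, 1],
               u[, 1] * v[, 1] + u[, 2] * v[, 2]) * 180 / pi
  ang[!ok] <- NA_real_
  ang
}

#' @rdname tail_wag_ratio
#' @param angles vector of per-frame signed tail angles.
#' @export
mean_tail_angle <- function(angles) {
  if (all(is.na(angles))) return(NA_real_)
  mean(angles, na.rm = TRUE)
}

traj_coords <- function(x) {
  if (inherits(x, "processed_traj")) {
    coords <- x$coords
    for (kp in names(coords)) coords[[kp]][x$status[[kp]] == 0L, ] <- NA_real_
    coords
  } else if (inherits(x, "kp_traj")) {
    x$coords
  } else stop("expected a kp_traj or processed_traj")
}

#' Assemble all trial metrics
#'
#' Computes the full set of behavioural response variables for one trial.
#' Interest-area occupancy, distance travelled, object distance and area
#' coverage use the head-centre key point; the visual angle uses the
#' head-centre to snout axis and the owner's chair (seat centre at the
#' configured chair height); the tail metrics use atlas, tail base and tail
#' tip. The door proportion sums the two door interest areas.
#'
#' @param x a [kp_trajectory()] or the `processed_traj` from
#'   [preprocess_trial()].
#' @param geometry a [room_geometry()].
#' @param record the [trial_record()] (identifies the owner's chair).
#' @return One-row data frame with identifiers, the response variables and
#'   the head-centre coverage (fraction of frames with a value) plus, for
#'   processed input, the proportion of tracked head-centre data.
#' @export
compute_trial_metrics <- function(x, geometry, record) {
  coords <- traj_coords(x)
  need <- c("head_centre", "snout", "atlas", "tail_base", "tail_tip")
  miss <- setdiff(need, names(coords))
  if (length(miss)) stop("missing key point(s): ", paste(miss, collapse = ", "))
  hc <- coords$head_centre
  ia <- trial_interest_areas(geometry, record$owner_chair)
  chair <- geometry$chairs[[record$owner_chair]]
  target <- c(chair, geometry$chair_height)
  ang <- visual_angle_series(hc, coords$snout, target)
  tang <- tail_angle_series(coords$atlas, coords$tail_base, coords$tail_tip)
  n <- nrow(hc)
  out <- data.frame(
    dog_id = record$dog_id, condition = record$condition,
    owner_present = record$owner_present,
    stranger_present = record$stranger_present,
    trial = record$trial, age_months = record$age_months, sex = record$sex,
    prop_owner_ia = time_in_area(hc, ia$owner),
    prop_stranger_ia = time_in_area(hc, ia$stranger),
    prop_door_ia = time_in_area(hc, ia$doors[[1]]) +
      time_in_area(hc, ia$doors[[2]]),
    distance_travelled = distance_travelled(hc),
    min_object_distance = min_object_distance(hc, geometry$objects),
    area_covered = area_covered(hc, geometry),
    mean_visual_angle = mean_visual_angle(ang),
    tail_wag_ratio = tail_wag_ratio(coords$tail_tip, coords$tail_base),
    mean_tail_angle = mean_tail_angle(tang),
    coverage_head_centre = sum(!is.na(hc[, 1])) / n,
    stringsAsFactors = FALSE)
  if (inherits(x, "processed_traj"))
    out$prop_tracked_head_centre <- x$prop_tracked[["head_centre"]]
  out
}

#' @rdname compute_trial_metrics
#' @param study a `wag_study`; processed trajectories are used when present,
#'   otherwise the raw (e.g. noiseless) ones.
#' @return `compute_study_metrics()`: one row per dog x condition.
#' @export
compute_study_metrics <- function(study, geometry = study$geometry) {
  rows <- lapply(study$trials, function(entry) {
    x <- if (!is.null(entry$processed)) entry$processed else entry$traj
    compute_trial_metrics(x, geometry, entry$record)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Distance travelled per key point per run
#'
#' Support for the internal-consistency check that locomotion estimates
#' agree across key points.
#'
#' @param study a `wag_study`.
#' @return matrix (runs x key points) of distances travelled (m).
#' @export
keypoint_distances <- function(study) {
  rows <- t(vapply(study$trials, function(entry) {
    coords <- traj_coords(
      if (!is.null(entry$processed)) entry$processed else entry$traj)
    vapply(keypoint_names(), function(kp)
      if (is.null(coords[[kp]])) NA_real_ else distance_travelled(coords[[kp]]),
      numeric(1))
  }, numeric(length(keypoint_names()))))
  rownames(rows) <- names(study$trials)
  rows
}
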