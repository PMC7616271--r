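#' Parameter bundles for the synthetic study generator
#'
#' The generator emulates the structure of the 2 x 2 owner/stranger-presence
#' experiment: freely moving dogs in a 6 x 7 m room, an articulated
#' 8-key-point skeleton around a planar attraction/persistence walk,
#' lateralized tail oscillation and, optionally, realistic detection noise.
#' It exists so that every downstream stage (filter cascade, metrics,
#' validation, statistics) can be exercised against known ground truth.
#'
#' `movement_params()` controls the walk: baseline speed (m/s), heading
#' persistence (dimensionless in \[0, 1)), the probability per second of
#' resting, and non-negative attraction weights towards the owner's chair,
#' the stranger's chair, each door and each object plank. `sat_dist` is the
#' radius (m) inside which attraction fades so the walker lingers at a
#' landmark, and `margin` (m) keeps the body centre far enough from the walls
#' that every key point stays inside the room.
#'
#' @param speed baseline speed in m/s while moving.
#' @param persistence heading persistence in \[0, 1).
#' @param rest_prob probability per second of resting.
#' @param w_owner_chair,w_stranger_chair,w_doors,w_objects attraction
#'   weights (door/object weights are recycled to length 2/4).
#' @param dir_noise_sd SD of the isotropic heading noise.
#' @param sat_dist attraction saturation radius (m).
#' @param margin wall margin for the body centre (m).
#' @param dwell mean dwell time (s) at the current goal landmark before the
#'   walker re-samples a goal (weights-proportional).
#' @param rest_near per-frame resting probability while within `sat_dist` of
#'   the current goal (pausing at landmarks).
#' @param max_turn maximum heading rotation per frame (radians); bounds the
#'   per-frame displacement of key points placed away from the body centre.
#' @return A parameter list of the corresponding class.
#' @export
movement_params <- function(speed = 0.5, persistence = 0.95, rest_prob = 0.3,
                            w_owner_chair = 0.3, w_stranger_chair = 0.3,
                            w_doors = 0.5, w_objects = 1,
                            dir_noise_sd = 0.03, sat_dist = 0.6,
                            margin = 0.7, dwell = 6, rest_near = 0.5,
                            max_turn = 0.25) {
  w <- c(owner_chair = w_owner_chair, stranger_chair = w_stranger_chair,
         rep_len(w_doors, 2), rep_len(w_objects, 4))
  stopifnot(all(is.finite(w)), all(w >= 0), speed >= 0,
            persistence >= 0, persistence < 1,
            rest_prob >= 0, rest_prob <= 1, dwell > 0,
            rest_near >= 0, rest_near <= 1, max_turn > 0)
  structure(list(speed = speed, persistence = persistence,
                 rest_prob = rest_prob,
                 w_owner_chair = w_owner_chair,
                 w_stranger_chair = w_stranger_chair,
                 w_doors = rep_len(w_doors, 2),
                 w_objects = rep_len(w_objects, 4),
                 dir_noise_sd = dir_noise_sd, sat_dist = sat_dist,
                 margin = margin, dwell = dwell, rest_near = rest_near,
                 max_turn = max_turn),
            class = "movement_params")
}

#' @rdname movement_params
#' @param snout_head snout to head-centre distance (m); matched to the dog's
#'   morphometry entry.
#' @param head_forward,atlas_forward,hips_back,tail_base_back longitudinal
#'   offsets (m) of the named key points from the body centre along the
#'   heading.
#' @param tail_length tail-base to tail-tip distance in the floor plane (m).
#' @param ear_side half the inter-ear distance (m).
#' @param heights named numeric vector of standing heights (m) for
#'   `hips`, `atlas`, `head`, `ear`, `tail_base`, `tail_tip`.
#' @export
skeleton_params <- function(snout_head = 0.15, head_forward = 0.45,
                            atlas_forward = 0.25, hips_back = 0.30,
                            tail_base_back = 0.40, tail_length = 0.30,
                            ear_side = 0.06,
                            heights = c(hips = 0.45, atlas = 0.50,
                                        head = 0.55, ear = 0.55,
                                        tail_base = 0.40, tail_tip = 0.35)) {
  stopifnot(snout_head > 0, head_forward > 0, tail_length > 0,
            all(heights > 0))
  structure(list(snout_head = snout_head, head_forward = head_forward,
                 atlas_forward = atlas_forward, hips_back = hips_back,
                 tail_base_back = tail_base_back, tail_length = tail_length,
                 ear_side = ear_side, heights = heights),
            class = "skeleton_params")
}

#' @rdname movement_params
#' @param amplitude tail-wag amplitude in degrees.
#' @param frequency wag frequency in Hz.
#' @param bias lateral bias in degrees, positive towards the dog's right.
#' @export
tail_params <- function(amplitude = 25, frequency = 2.5, bias = 19) {
  stopifnot(amplitude >= 0, frequency >= 0)
  structure(list(amplitude = amplitude, frequency = frequency, bias = bias),
            class = "tail_params")
}

#' @rdname movement_params
#' @param dropout probability that a detection is missing.
#' @param teleport rate of detections replaced by points far outside the room.
#' @param glitch rate of single-key-point displacements of about 2 m (the
#'   "tip of a shoe detected as the snout" failure mode).
#' @param jump rate of single-axis displacements of 0.5-1 m (teleport jumps
#'   above the per-frame velocity threshold).
#' @param jitter_sd SD (m) of isotropic measurement jitter on every retained
#'   detection.
#' @export
noise_params <- function(dropout = 0.05, teleport = 0.002, glitch = 0.002,
                         jump = 0.004, jitter_sd = 0.01) {
  p <- c(dropout, teleport, glitch, jump)
  stopifnot(all(p >= 0), all(p <= 1), teleport + glitch + jump <= 1,
            jitter_sd >= 0)
  structure(list(dropout = dropout, teleport = teleport, glitch = glitch,
                 jump = jump, jitter_sd = jitter_sd),
            class = "noise_params")
}

#' Condition-dependent movement parameters
#'
#' The default study conditions: dogs are attracted to a person's chair when
#' that person is present, to the doors when somebody is absent, and always
#' somewhat to the novel objects; they move faster when a person is present
#' (owner more than stranger) and slow down over trials (habituation).
#'
#' @param record a [trial_record()].
#' @param base_speed baseline speed (m/s) in the both-absent condition.
#' @param owner_speed,stranger_speed additive speed effects (m/s) of the
#'   owner's / stranger's presence.
#' @param trial_speed additive speed effect (m/s) per later trial.
#' @param speed_mult per-dog multiplicative speed factor.
#' @return A [movement_params()].
#' @export
condition_movement_params <- function(record, base_speed = 0.5,
                                      owner_speed = 0.25,
                                      stranger_speed = 0.12,
                                      trial_speed = -0.04,
                                      speed_mult = 1) {
  sp <- (base_speed + owner_speed * record$owner_present +
           stranger_speed * record$stranger_present +
           trial_speed * (record$trial - 1)) * speed_mult
  movement_params(
    speed = max(sp, 0.05),
    w_owner_chair = if (record$owner_present) 3 else 0.3,
    w_stranger_chair = if (record$stranger_present) 3 else 0.3,
    w_doors = 0.5 + 1.5 * !record$owner_present +
      0.7 * !record$stranger_present,
    w_objects = 1
  )
}

sim_landmarks <- function(geometry, record, move) {
  owner_xy <- geometry$chairs[[record$owner_chair]]
  stranger_xy <- geometry$chairs[[setdiff(c("A", "B"), record$owner_chair)]]
  # door attraction targets the IA centre in front of each door, not the
  # door itself, which lies beyond the wall margin of the walk
  door_targets <- t(vapply(geometry$ia_doors, function(r)
    c(mean(r[1:2]), mean(r[3:4])), numeric(2)))
  lm <- rbind(owner_xy, stranger_xy, door_targets,
              do.call(rbind, geometry$objects))
  w <- c(move$w_owner_chair, move$w_stranger_chair, move$w_doors,
         move$w_objects)
  list(points = lm, weights = w)
}

#' Simulate one trial
#'
#' Generates a noiseless, fully rigid 8-key-point trajectory for one trial:
#' a planar attraction/persistence walk for the body centre, a skeleton
#' assembled rigidly around position and heading, and a tail tip oscillating
#' about its lateral bias angle. Alongside the trajectory the ground-truth
#' trial metrics are computed directly from the generator's internal state,
#' enabling recovery tests of the metrics module.
#'
#' @param record a [trial_record()].
#' @param move,skel,tail parameter bundles; see [movement_params()].
#' @param geometry a [room_geometry()].
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return list with elements `record`, `traj` (a [kp_trajectory()] with no
#'   gaps) and `truth` (named list of true trial metrics).
#' @export
simulate_trial <- function(record, move = condition_movement_params(record),
                           skel = skeleton_params(), tail = tail_params(),
                           geometry = room_geometry(), seed = NULL) {
  stopifnot(inherits(record, "trial_record"), inherits(move, "movement_params"),
            inherits(skel, "skeleton_params"), inherits(tail, "tail_params"))
  if (skel$head_forward + skel$snout_head > move$margin ||
      skel$tail_base_back + skel$tail_length > move$margin)
    stop("skeleton extends beyond the wall margin; enlarge `margin`")
  if (!is.null(seed)) set.seed(seed)
  n <- record$n_frames
  fps <- record$fps
  lmk <- sim_landmarks(geometry, record, move)
  rest_frame <- if (move$rest_prob >= 1) 1 else
    1 - (1 - move$rest_prob)^(1 / fps)
  w <- walk_core(n, c(0, 0), move$speed / fps, move$persistence, rest_frame,
                 lmk$points, lmk$weights, move$dir_noise_sd, geometry$floor,
                 move$margin, move$sat_dist, 1 / (move$dwell * fps),
                 move$rest_near, move$max_turn)
  pos <- w$pos
  u <- w$heading                       # unit heading
  r <- cbind(u[, 2], -u[, 1])          # dog's right (z up)
  h <- skel$heights
  at_along <- function(d, z) cbind(pos + d * u, rep(z, n))

  phase0 <- runif(1, 0, 2 * pi)
  tt <- seq_len(n) - 1
  phi_deg <- tail$bias +
    tail$amplitude * sin(2 * pi * tail$frequency * tt / fps + phase0)
  phi <- phi_deg * pi / 180
  tail_base <- at_along(-skel$tail_base_back, h[["tail_base"]])
  tail_dir <- -cos(phi) * u + sin(phi) * r
  tail_tip <- cbind(tail_base[, 1:2] + skel$tail_length * tail_dir,
                    rep(h[["tail_tip"]], n))

  head_centre <- at_along(skel$head_forward, h[["head"]])
  coords <- list(
    snout = cbind(head_centre[, 1:2] + skel$snout_head * u, rep(h[["head"]], n)),
    head_centre = head_centre,
    left_ear = cbind(head_centre[, 1:2] - skel$ear_side * r, rep(h[["ear"]], n)),
    right_ear = cbind(head_centre[, 1:2] + skel$ear_side * r, rep(h[["ear"]], n)),
    atlas = at_along(skel$atlas_forward, h[["atlas"]]),
    hips = at_along(-skel$hips_back, h[["hips"]]),
    tail_base = tail_base,
    tail_tip = tail_tip
  )
  traj <- kp_trajectory(0:(n - 1), coords, fps = fps)
  truth <- sim_truth(traj, phi_deg, geometry, record)
  list(record = record, traj = traj, truth = truth)
}

# Ground-truth metrics from the generator's own state. Written as direct
# arithmetic on the noiseless coordinates (and the realized tail phase), kept
# deliberately separate from the metrics module.
sim_truth <- function(traj, phi_deg, geometry, record) {
  hc <- traj$coords$head_centre
  n <- nrow(hc)
  ia <- trial_interest_areas(geometry, record$owner_chair)
  occ <- function(rect) sum(point_in_rect(hc[, 1], hc[, 2], rect)) / n
  seg <- sqrt(rowSums(diff(hc)^2))
  fl <- geometry$floor
  cs <- geometry$grid_cell
  nx <- ceiling((fl[2] - fl[1]) / cs - 1e-9)
  ny <- ceiling((fl[4] - fl[3]) / cs - 1e-9)
  cells <- unique(paste(pmin(floor((hc[, 1] - fl[1]) / cs), nx - 1),
                        pmin(floor((hc[, 2] - fl[3]) / cs), ny - 1)))
  obj_min <- vapply(geometry$objects, function(o)
    min(sqrt((hc[, 1] - o[1])^2 + (hc[, 2] - o[2])^2)), numeric(1))
  # gaze: the generator's head axis is horizontal, so the elevated looking
  # direction is cos45 * heading + sin45 * z-hat exactly
  sn <- traj$coords$snout
  axis <- sn[, 1:2] - hc[, 1:2]
  axis <- axis / sqrt(rowSums(axis^2))
  eye <- (hc + sn) / 2
  gaze <- cbind(axis / sqrt(2), rep(1 / sqrt(2), n))
  chair <- geometry$chairs[[record$owner_chair]]
  tgt <- cbind(chair[1] - eye[, 1], chair[2] - eye[, 2],
               geometry$chair_height - eye[, 3])
  tgt <- tgt / sqrt(rowSums(tgt^2))
  ang <- acos(pmin(pmax(rowSums(gaze * tgt), -1), 1)) * 180 / pi
  tipd <- sum(sqrt(rowSums(diff(traj$coords$tail_tip)^2)))
  based <- sum(sqrt(rowSums(diff(traj$coords$tail_base)^2)))
  list(
    prop_owner_ia = occ(ia$owner),
    prop_stranger_ia = occ(ia$stranger),
    prop_door_ia = occ(ia$doors[[1]]) + occ(ia$doors[[2]]),
    distance_travelled = sum(seg),
    min_object_distance = mean(obj_min),
    area_covered = length(cells) / (nx * ny),
    mean_visual_angle = mean(ang),
    tail_wag_ratio = if (based > 0) tipd / based else NA_real_,
    mean_tail_angle = mean(phi_deg)
  )
}

#' Inject detection noise into a complete trajectory
#'
#' Emulates the artefacts the filter cascade targets: missing detections
#' (dropout), points far outside the room (teleports), single-key-point
#' displacements of about 2 m (glitches), single-axis jumps of 0.5-1 m
#' above the per-frame velocity threshold, and small isotropic jitter on
#' every surviving detection. Corruption bookkeeping (key point, frame,
#' channel) is returned alongside; the corrupt channels are disjoint from
#' the dropout set by construction.
#'
#' @param traj a gap-free [kp_trajectory()].
#' @param noise a [noise_params()].
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param geometry room used to place teleport points outside the bounds.
#' @return list with the corrupted `traj` and a `corruption` data frame
#'   (columns `keypoint`, `frame`, `channel`).
#' @export
corrupt <- function(traj, noise = noise_params(), seed = NULL,
                    geometry = room_geometry()) {
  stopifnot(inherits(traj, "kp_traj"), inherits(noise, "noise_params"))
  if (any(!vapply(traj$coords, function(m) all(!is.na(m[, 1])), logical(1))))
    stop("corrupt() expects a complete trajectory (no gaps)")
  if (!is.null(seed)) set.seed(seed)
  fl <- geometry$floor
  book <- list()
  for (kp in names(traj$coords)) {
    m <- traj$coords[[kp]]
    n <- nrow(m)
    if (noise$jitter_sd > 0)
      m <- m + matrix(rnorm(3 * n, 0, noise$jitter_sd), n, 3)
    drop_mask <- runif(n) < noise$dropout
    u <- runif(n)
    tele <- !drop_mask & u < noise$teleport
    glitch <- !drop_mask & !tele & u < noise$teleport + noise$glitch
    jump <- !drop_mask & !tele & !glitch &
      u < noise$teleport + noise$glitch + noise$jump
    if (any(tele)) {
      k <- sum(tele)
      side <- sample(4, k, replace = TRUE)
      off <- runif(k, 1, 5)
      tx <- runif(k, fl[1], fl[2]); ty <- runif(k, fl[3], fl[4])
      tx[side == 1] <- fl[1] - off[side == 1]
      tx[side == 2] <- fl[2] + off[side == 2]
      ty[side == 3] <- fl[3] - off[side == 3]
      ty[side == 4] <- fl[4] + off[side == 4]
      m[tele, ] <- cbind(tx, ty, runif(k, 0, 1.4))
    }
    if (any(glitch)) {
      k <- sum(glitch)
      th <- runif(k, 0, 2 * pi)
      mag <- runif(k, 2.0, 2.5)
      m[glitch, 1] <- m[glitch, 1] + mag * cos(th)
      m[glitch, 2] <- m[glitch, 2] + mag * sin(th)
    }
    if (any(jump)) {
      k <- sum(jump)
      ax <- sample(3, k, replace = TRUE)
      mag <- runif(k, 0.5, 1.0) * sample(c(-1, 1), k, replace = TRUE)
      idx <- cbind(which(jump), ax)
      m[idx] <- m[idx] + mag
    }
    m[drop_mask, ] <- NA_real_
    traj$coords[[kp]] <- m
    fr <- traj$frames
    frames_hit <- c(fr[drop_mask], fr[tele], fr[glitch], fr[jump])
    book[[kp]] <- data.frame(
      keypoint = rep(kp, length(frames_hit)),
      frame = frames_hit,
      channel = rep(c("dropout", "teleport", "glitch", "jump"),
                    c(sum(drop_mask), sum(tele), sum(glitch), sum(jump))),
      stringsAsFactors = FALSE)
  }
  corruption <- do.call(rbind, book)
  rownames(corruption) <- NULL
  list(traj = traj, corruption = corruption)
}

all_condition_orders <- function() {
  # the 24 permutations of the four conditions, in lexicographic order
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  perms(condition_levels())
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# location of the parent normal such that the [lo, hi]-truncated draw has the
# requested mean (truncation at zero would otherwise inflate it)
trunc_norm_location <- function(target_mean, sd, lo, hi) {
  trunc_mean <- function(mu) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  stats::uniroot(function(mu) trunc_mean(mu) - target_mean,
                 interval = c(lo - 6 * sd, hi + 6 * sd), tol = 1e-9)$root
}

#' Simulate a full study with known ground truth
#'
#' Every dog runs all four conditions once (one trial each, 120 s at
#' 24 fps by default). Condition orders follow a balanced rotation through
#' all 24 permutations (each used as evenly as possible; with 24 dogs each
#' exactly once) and the owner's chair alternates between dogs. Alongside the
#' noiseless trajectories the generator returns per-dog morphometry (matched
#' exactly by the skeletons), C-BARQ subscale scores drawn around published
#' general-population values, and manual interest-area scorings equal to the
#' true durations plus truncated Gaussian scorer noise (SD 0.5 s).
#'
#' @param n_dogs number of subjects.
#' @param seed integer seed for the whole study.
#' @param geometry a [room_geometry()].
#' @param tail_bias population mean lateral tail bias in degrees.
#' @param fps,duration recording parameters.
#' @param scorer_sd SD (s) of the manual-scoring noise.
#' @param base_speed,owner_speed,stranger_speed,trial_speed movement effect
#'   sizes passed to [condition_movement_params()].
#' @return A `wag_study`: list with `trials` (named list of entries with
#'   `record`, `traj`, `truth`), `morphometry`, `cbarq`, `manual` data frames
#'   and the `geometry`.
#' @export
simulate_study <- function(n_dogs, seed = 1, geometry = room_geometry(),
                           tail_bias = 19, fps = 24, duration = 120,
                           scorer_sd = 0.5, base_speed = 0.5,
                           owner_speed = 0.25, stranger_speed = 0.12,
                           trial_speed = -0.04) {
  stopifnot(n_dogs >= 1)
  set.seed(seed)
  orders <- all_condition_orders()
  pop <- cbind(mean = c(0.84, 0.67, 0.60, 2.01),
               sd = c(0.77, 0.95, 0.66, 0.81))
  pop_mu <- vapply(1:4, function(j)
    trunc_norm_location(pop[j, "mean"], pop[j, "sd"], 0, 4), numeric(1))
  trials <- list()
  morph <- cbarq <- manual <- list()
  for (i in seq_len(n_dogs)) {
    dog_id <- sprintf("dog%02d", i)
    owner_chair <- if (i %% 2 == 1) "A" else "B"
    sex <- if (i %% 2 == 1) "F" else "M"
    age <- runif(1, 11, 182)
    snout_head <- runif(1, 0.10, 0.20)
    ear_side <- runif(1, 0.04, 0.08)
    size <- runif(1, 0.85, 1.15)
    skel <- skeleton_params(
      snout_head = snout_head,
      head_forward = 0.40 * size, atlas_forward = 0.25 * size,
      hips_back = 0.30 * size, tail_base_back = 0.35 * size,
      tail_length = 0.25 * size, ear_side = ear_side,
      heights = c(hips = 0.45, atlas = 0.50, head = 0.55, ear = 0.55,
                  tail_base = 0.40, tail_tip = 0.35) * size)
    morph[[i]] <- data.frame(
      dog_id = dog_id, snout_head_m = snout_head,
      head_ear_m = ear_side, inter_ear_m = 2 * ear_side,
      stringsAsFactors = FALSE)
    cb <- vapply(1:4, function(j)
      rtrunc_norm(1, pop_mu[j], pop[j, "sd"], 0, 4), numeric(1))
    cbarq[[i]] <- data.frame(
      dog_id = dog_id, nonsocial_fear = cb[1], stranger_fear = cb[2],
      separation_problems = cb[3], attachment_attention = cb[4],
      stringsAsFactors = FALSE)
    speed_mult <- exp(rnorm(1, 0, 0.12))
    dog_bias <- tail_bias + rnorm(1, 0, 5)
    order_i <- orders[[(i - 1) %% length(orders) + 1]]
    for (t in 1:4) {
      cond <- order_i[t]
      rec <- trial_record(
        dog_id,
        owner_present = cond %in% c("owner_only", "both_present"),
        stranger_present = cond %in% c("stranger_only", "both_present"),
        trial = t, fps = fps, duration = duration,
        owner_chair = owner_chair, age_months = age, sex = sex)
      move <- condition_movement_params(
        rec, base_speed = base_speed, owner_speed = owner_speed,
        stranger_speed = stranger_speed, trial_speed = trial_speed,
        speed_mult = speed_mult)
      anyone <- rec$owner_present || rec$stranger_present
      # lateral bias fluctuates a little from trial to trial around the
      # dog's own bias
      tl <- tail_params(amplitude = 25 + 20 * anyone, frequency = 2.5,
                        bias = dog_bias + rnorm(1, 0, 2))
      st <- simulate_trial(rec, move, skel, tl, geometry, seed = NULL)
      trials[[trial_key(dog_id, t)]] <- st
      manual[[trial_key(dog_id, t)]] <- data.frame(
        dog_id = dog_id, condition = cond, trial = t,
        onset_frame = 0L, offset_frame = rec$n_frames,
        owner_ia_s = pmin(pmax(
          st$truth$prop_owner_ia * duration + rnorm(1, 0, scorer_sd), 0), duration),
        stranger_ia_s = pmin(pmax(
          st$truth$prop_stranger_ia * duration + rnorm(1, 0, scorer_sd), 0), duration),
        door_ia_s = pmin(pmax(
          st$truth$prop_door_ia * duration + rnorm(1, 0, scorer_sd), 0), duration),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    trials = trials,
    morphometry = do.call(rbind, morph),
    cbarq = do.call(rbind, cbarq),
    manual = do.call(rbind, c(manual, list(make.row.names = FALSE))),
    geometry = geometry
  ), class = "wag_study")
}

#' @rdname simulate_study
#' @param study a `wag_study` with noiseless trajectories.
#' @param noise a [noise_params()].
#' @export
corrupt_study <- function(study, noise = noise_params(), seed = 1) {
  stopifnot(inherits(study, "wag_study"))
  set.seed(seed)
  study$trials <- lapply(study$trials, function(entry) {
    cr <- corrupt(entry$traj, noise, seed = NULL, geometry = study$geometry)
    entry$traj <- cr$traj
    entry$corruption <- cr$corruption
    entry
  })
  study$noise <- noise
  study
}

#' @rdname simulate_study
#' @export
study_records <- function(study) {
  do.call(rbind, c(lapply(study$trials, `[[`, "record"),
                   list(make.row.names = FALSE)))
}

#' @rdname simulate_study
#' @export
study_truth <- function(study) {
  rows <- lapply(study$trials, function(entry)
    cbind(entry$record[c("dog_id", "condition", "trial")],
          as.data.frame(entry$truth)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @rdname simulate_study
#' @param x a `wag_study`.
#' @param ... unused.
#' @export
print.wag_study <- function(x, ...) {
  cat(sprintf("<wag_study> %d dogs, %d runs%s\n",
              length(unique(study_records(x)$dog_id)), length(x$trials),
              if (is.null(x$noise)) " (noiseless)" else " (corrupted)"))
  invisible(x)
}
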