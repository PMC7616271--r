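# Independent brute-force oracles and scene-transform helpers used across the
# suite. The oracles are deliberately naive (frame loops, explicit set
# accumulation) and share no code with the package implementations.

oracle_distance <- function(m) {
  total <- 0
  last <- NULL
  for (i in seq_len(nrow(m))) {
    if (is.na(m[i, 1])) { last <- NULL; next }
    if (!is.null(last)) total <- total + sqrt(sum((m[i, ] - last)^2))
    last <- m[i, ]
  }
  total
}

oracle_min_object_distance <- function(m, objects) {
  mins <- rep(Inf, length(objects))
  for (i in seq_len(nrow(m))) {
    if (is.na(m[i, 1])) next
    for (k in seq_along(objects)) {
      d <- sqrt((m[i, 1] - objects[[k]][1])^2 + (m[i, 2] - objects[[k]][2])^2)
      if (d < mins[k]) mins[k] <- d
    }
  }
  mean(mins)
}

oracle_area_covered <- function(m, geometry) {
  fl <- geometry$floor
  cs <- geometry$grid_cell
  nx <- ceiling((fl[2] - fl[1]) / cs - 1e-9)
  ny <- ceiling((fl[4] - fl[3]) / cs - 1e-9)
  seen <- character(0)
  for (i in seq_len(nrow(m))) {
    if (is.na(m[i, 1])) next
    cx <- min(floor((m[i, 1] - fl[1]) / cs), nx - 1)
    cy <- min(floor((m[i, 2] - fl[3]) / cs), ny - 1)
    seen <- union(seen, paste(cx, cy))
  }
  length(seen) / (nx * ny)
}

# Holm step-down by hand: order the raw p-values, multiply by (m - i + 1),
# enforce monotonicity, cap at 1.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(p[o] * (m - seq_len(m) + 1), 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

# rigid scene transforms: k quarter-turns about the origin plus a translation
rotate_xy <- function(xy, k) {
  for (i in seq_len(k %% 4)) xy <- cbind(-xy[, 2], xy[, 1])
  xy
}

transform_point <- function(p, k, shift) {
  xy <- rotate_xy(matrix(p[1:2], 1), k) + rep(shift, each = 1)
  c(xy[1, ], p[-(1:2)])
}

transform_rect <- function(r, k, shift) {
  corners <- rotate_xy(cbind(c(r[1], r[2]), c(r[3], r[4])), k)
  c(range(corners[, 1]) + shift[1], range(corners[, 2]) + shift[2])
}

transform_traj <- function(traj, k, shift) {
  traj$coords <- lapply(traj$coords, function(m) {
    cbind(rotate_xy(m[, 1:2, drop = FALSE], k) +
            rep(shift, each = nrow(m)), m[, 3])
  })
  traj
}

transform_geometry <- function(geom, k, shift) {
  room_geometry(
    floor = transform_rect(geom$floor, k, shift),
    height_cap = geom$height_cap,
    doors = lapply(geom$doors, transform_point, k = k, shift = shift),
    chairs = lapply(geom$chairs, transform_point, k = k, shift = shift),
    chair_height = geom$chair_height,
    objects = lapply(geom$objects, transform_point, k = k, shift = shift),
    ia_chair_A = transform_rect(geom$ia_chair_A, k, shift),
    ia_chair_B = transform_rect(geom$ia_chair_B, k, shift),
    ia_doors = lapply(geom$ia_doors, transform_rect, k = k, shift = shift),
    grid_cell = geom$grid_cell)
}

mirror_traj <- function(traj) {
  traj$coords <- lapply(traj$coords, function(m) {
    m[, 2] <- -m[, 2]
    m
  })
  traj
}

mirror_rect <- function(r) c(r[1], r[2], -r[4], -r[3])

mirror_geometry <- function(geom) {
  mp <- function(p) c(p[1], -p[2])
  room_geometry(
    floor = mirror_rect(geom$floor), height_cap = geom$height_cap,
    doors = lapply(geom$doors, mp),
    chairs = lapply(geom$chairs, mp), chair_height = geom$chair_height,
    objects = lapply(geom$objects, mp),
    ia_chair_A = mirror_rect(geom$ia_chair_A),
    ia_chair_B = mirror_rect(geom$ia_chair_B),
    ia_doors = lapply(geom$ia_doors, mirror_rect),
    grid_cell = geom$grid_cell)
}

# a small complete trajectory with all eight key points following a smooth
# path; handy where simulation would be overkill
toy_trajectory <- function(n = 50, step = 0.02, z = 0.5) {
  xs <- cumsum(rep(step, n))
  base <- cbind(xs - 1, rep(0, n), rep(z, n))
  coords <- setNames(lapply(seq_along(keypoint_names()), function(i) {
    off <- (i - 4) * 0.05
    cbind(base[, 1] + off, base[, 2], base[, 3])
  }), keypoint_names())
  kp_trajectory(0:(n - 1), coords)
}

short_record <- function(owner = TRUE, stranger = FALSE, trial = 1,
                         duration = 10, dog = "dogT", chair = "A") {
  trial_record(dog, owner, stranger, trial, duration = duration,
               owner_chair = chair, age_months = 60, sex = "F")
}
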