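#' Room geometry for the 2 x 2 presence experiment
#'
#' Spatial reference data for the testing room: the floor rectangle, the
#' height cap on plausible detections, door and chair landmarks, the four
#' object planks and the interest areas (IAs) whose occupancy is analysed.
#'
#' Coordinates are metres in a right-handed, room-aligned frame with z up and
#' the origin at a floor mark near the room centre. The default room is
#' 6 x 7 m (x in \[-3, 3\], y in \[-3.5, 3.5\]) with two doors and chair A on
#' the wall x = xmin, chair B on the opposite wall, and four object planks
#' near the room centre. Chair and object coordinates are not dictated by the
#' design and can be overridden freely; IA dimensions are invariants
#' (chair IAs 2 x 1.4 m, door IAs 1 x 1 m) and are validated.
#'
#' Rectangles are length-4 numeric vectors `c(xmin, xmax, ymin, ymax)`.
#' Point-in-rectangle tests are closed on the lower edges and open on the
#' upper edges, so abutting rectangles never double-count a point.
#'
#' @param floor floor rectangle `c(xmin, xmax, ymin, ymax)` in metres.
#' @param height_cap detections with z above this (strictly) are implausible.
#' @param doors list of two door centre points `c(x, y)`.
#' @param chairs list with elements `A` and `B`, each a chair point `c(x, y)`.
#' @param chair_height height (m) of the chair target point used for the
#'   visual-angle metric.
#' @param objects list of four object (plank centre) points `c(x, y)`.
#' @param ia_chair_A,ia_chair_B,ia_doors interest-area rectangles; chair IAs
#'   must measure 2 x 1.4 m, door IAs 1 x 1 m (orientation free).
#' @param grid_cell grid cell edge length (m) for the area-covered metric.
#' @return An object of class `room_geometry`.
#' @export
room_geometry <- function(floor = c(-3, 3, -3.5, 3.5),
                          height_cap = 1.5,
                          doors = list(c(-3, -1.75), c(-3, 1.75)),
                          chairs = list(A = c(-2.7, 0), B = c(2.7, 0)),
                          chair_height = 0.5,
                          objects = list(c(-0.75, -0.75), c(-0.75, 0.75),
                                         c(0.75, -0.75), c(0.75, 0.75)),
                          ia_chair_A = c(-3, -1.6, -1, 1),
                          ia_chair_B = c(1.6, 3, -1, 1),
                          ia_doors = list(c(-3, -2, -2.25, -1.25),
                                          c(-3, -2, 1.25, 2.25)),
                          grid_cell = 0.5) {
  geom <- structure(list(
    floor = as.numeric(floor), height_cap = height_cap,
    doors = lapply(doors, as.numeric),
    chairs = lapply(chairs, as.numeric), chair_height = chair_height,
    objects = lapply(objects, as.numeric),
    ia_chair_A = as.numeric(ia_chair_A), ia_chair_B = as.numeric(ia_chair_B),
    ia_doors = lapply(ia_doors, as.numeric),
    grid_cell = grid_cell,
    schema_version = 1L
  ), class = "room_geometry")
  validate_geometry(geom)
  geom
}

rect_dims <- function(r) c(r[2] - r[1], r[4] - r[3])

rect_in_rect <- function(inner, outer) {
  inner[1] >= outer[1] && inner[2] <= outer[2] &&
    inner[3] >= outer[3] && inner[4] <= outer[4]
}

# closed on lower edges, open on upper edges
point_in_rect <- function(x, y, rect) {
  x >= rect[1] & x < rect[2] & y >= rect[3] & y < rect[4]
}

validate_geometry <- function(geom) {
  stopifnot(inherits(geom, "room_geometry"))
  fl <- geom$floor
  if (length(fl) != 4 || fl[1] >= fl[2] || fl[3] >= fl[4])
    stop("invalid floor rectangle")
  if (geom$height_cap <= 0) stop("height_cap must be positive")
  if (geom$grid_cell <= 0) stop("grid_cell must be positive")
  if (length(geom$doors) != 2) stop("exactly two doors required")
  if (!all(c("A", "B") %in% names(geom$chairs)))
    stop("chairs must be named 'A' and 'B'")
  if (length(geom$objects) != 4) stop("exactly four objects required")
  chk_dims <- function(rect, dims, what) {
    if (!isTRUE(all.equal(sort(rect_dims(rect)), sort(dims), tolerance = 1e-9)))
      stop(sprintf("%s must measure %g x %g m", what, dims[1], dims[2]))
    if (!rect_in_rect(rect, fl))
      stop(sprintf("%s lies outside the floor rectangle", what))
  }
  chk_dims(geom$ia_chair_A, c(2, 1.4), "chair A interest area")
  chk_dims(geom$ia_chair_B, c(2, 1.4), "chair B interest area")
  if (length(geom$ia_doors) != 2) stop("exactly two door interest areas required")
  for (i in seq_along(geom$ia_doors))
    chk_dims(geom$ia_doors[[i]], c(1, 1), sprintf("door interest area %d", i))
  invisible(geom)
}

#' Owner/stranger interest areas for a trial
#'
#' Maps the chair IAs onto owner and stranger roles using the trial's chair
#' assignment.
#'
#' @param geometry a [room_geometry()].
#' @param owner_chair `"A"` or `"B"`.
#' @return list with rectangles `owner`, `stranger` and the list `doors`.
#' @export
trial_interest_areas <- function(geometry, owner_chair = "A") {
  stopifnot(owner_chair %in% c("A", "B"))
  if (owner_chair == "A") {
    list(owner = geometry$ia_chair_A, stranger = geometry$ia_chair_B,
         doors = geometry$ia_doors)
  } else {
    list(owner = geometry$ia_chair_B, stranger = geometry$ia_chair_A,
         doors = geometry$ia_doors)
  }
}

#' Read and write room geometry configurations
#'
#' The geometry is stored as a structured key-value config, YAML or JSON by
#' file extension. Fields omitted from the file fall back to the default
#' room; the result is validated (a chair IA that is not 2 x 1.4 m, or an IA
#' outside the floor, is an error).
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_geometry()` returns a validated [room_geometry()].
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("geometry file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw$schema_version <- NULL
  defaults <- formals(room_geometry)
  known <- names(defaults)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown geometry fields: ", paste(unknown, collapse = ", "))
  # json simplification can turn a list of equal-length points into a matrix;
  # normalise every landmark container back to a list of numeric vectors
  relist <- function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) as.numeric(x[i, ]))
    else if (is.list(x)) lapply(x, as.numeric)
    else x
  }
  args <- raw
  for (nm in c("doors", "chairs", "objects", "ia_doors"))
    if (!is.null(args[[nm]])) args[[nm]] <- relist(args[[nm]])
  do.call(room_geometry, args)
}

#' @rdname read_geometry
#' @param geometry a [room_geometry()] to serialize.
#' @export
write_geometry <- function(geometry, path) {
  validate_geometry(geometry)
  out <- unclass(geometry)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' @rdname room_geometry
#' @param x a `room_geometry`.
#' @param ... unused.
#' @export
print.room_geometry <- function(x, ...) {
  d <- rect_dims(x$floor)
  cat(sprintf("<room_geometry> %g x %g m floor, height cap %g m, grid %g m\n",
              d[1], d[2], x$height_cap, x$grid_cell))
  invisible(x)
}
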