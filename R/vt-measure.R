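#' Landmark set for vocal-tract measurements
#'
#' Manually placed midsagittal landmarks in millimetres: the outer touching
#' point of the lips, the anterior lower border of the axis vertebra body,
#' the tangent point on the palate, the platform of the vocal folds, the
#' upper oesophagus point, and the pharyngeal wall as a polyline.
#'
#' @param lips,axis,palate_tangent,vocal_folds,esophagus Length-2 numeric
#'   points `(x, y)` in mm.
#' @param pharyngeal_wall `n x 2` matrix (n >= 2) of polyline vertices (mm).
#' @return Object of class `vt_landmarks`.
#' @export
landmark_set <- function(lips, axis, palate_tangent, vocal_folds,
                         esophagus, pharyngeal_wall) {
  pts <- list(lips = lips, axis = axis, palate_tangent = palate_tangent,
              vocal_folds = vocal_folds, esophagus = esophagus)
  for (nm in names(pts)) {
    p <- as.numeric(pts[[nm]])
    if (length(p) != 2L || !all(is.finite(p)))
      stop(nm, " must be a finite length-2 point")
    pts[[nm]] <- p
  }
  pharyngeal_wall <- as.matrix(pharyngeal_wall)
  if (ncol(pharyngeal_wall) != 2L || nrow(pharyngeal_wall) < 2L ||
      !all(is.finite(pharyngeal_wall)))
    stop("pharyngeal_wall must be an n x 2 matrix with n >= 2")
  structure(c(pts, list(pharyngeal_wall = pharyngeal_wall)),
            class = "vt_landmarks")
}

# first intersection (smallest ray parameter t >= 0) of the ray
# p0 + t * dir with a polyline; NULL if none
ray_polyline_intersection <- function(p0, dir, poly) {
  best_t <- Inf; best <- NULL
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    Mm <- cbind(dir, a - b)
    if (abs(det(Mm)) < 1e-12) next          # parallel segment
    ts <- solve(Mm, a - p0)
    if (ts[1] >= 0 && ts[2] >= -1e-12 && ts[2] <= 1 + 1e-12 &&
        ts[1] < best_t) {
      best_t <- ts[1]
      best <- p0 + ts[1] * dir
    }
  }
  best
}

#' Buccal cavity length
#'
#' Length of the segment from the outer lip point, along the line towards
#' the anterior lower border of the axis vertebra, up to its first
#' intersection with the pharyngeal wall.
#'
#' @param lm A [landmark_set()].
#' @return Length in mm.
#' @export
buccal_length <- function(lm) {
  stopifnot(inherits(lm, "vt_landmarks"))
  dir <- lm$axis - lm$lips
  if (sqrt(sum(dir^2)) < 1e-12) stop("lips and axis landmarks coincide")
  p <- ray_polyline_intersection(lm$lips, dir, lm$pharyngeal_wall)
  if (is.null(p))
    stop("lip-axis line does not intersect the pharyngeal wall")
  sqrt(sum((p - lm$lips)^2))
}

#' Vocal-tract height
#'
#' The upper boundary is the intersection with the pharyngeal wall of the
#' line through the palate tangent point parallel to the lip-axis line; the
#' lower boundary is the upper oesophagus point.  Height is their Euclidean
#' distance.
#'
#' @param lm A [landmark_set()].
#' @return Height in mm.
#' @export
vt_height <- function(lm) {
  stopifnot(inherits(lm, "vt_landmarks"))
  dir <- lm$axis - lm$lips
  if (sqrt(sum(dir^2)) < 1e-12) stop("lips and axis landmarks coincide")
  upper <- ray_polyline_intersection(lm$palate_tangent, dir,
                                     lm$pharyngeal_wall)
  if (is.null(upper))
    stop("palate-parallel line does not intersect the pharyngeal wall")
  sqrt(sum((upper - lm$esophagus)^2))
}

#' Vocal-tract width from plane visibility
#'
#' The width is the summed visible fraction of the vocal tract at the bottom
#' of the pharyngeal cavity across the parallel sagittal planes, times the
#' slice thickness.  Fully visible planes contribute a whole slice;
#' fractional visibility accommodates widths that are not multiples of the
#' thickness.
#'
#' @param visible_fraction Numeric vector in `[0, 1]`, one value per plane.
#' @param slice_thickness_mm Slice thickness (default 8 mm).
#' @return Width in mm.
#' @export
vt_width <- function(visible_fraction, slice_thickness_mm = 8) {
  stopifnot(all(visible_fraction >= 0), all(visible_fraction <= 1),
            slice_thickness_mm > 0)
  sum(visible_fraction) * slice_thickness_mm
}

#' Cohort summary of vocal-tract measurements
#'
#' Per-dimension mean, population standard deviation (divide by `n`, the
#' convention that reproduces the cohort tables this package ships), and
#' range (`max - min`), rounded to one decimal.
#'
#' @param measurements `data.frame` whose numeric columns are the
#'   per-speaker measurements (e.g. `length_mm`, `height_mm`, `width_mm`).
#' @return `data.frame(dimension, mean, sd, range)`.
#' @export
cohort_summary <- function(measurements) {
  stopifnot(is.data.frame(measurements), nrow(measurements) >= 1L)
  num <- names(measurements)[vapply(measurements, is.numeric, logical(1))]
  if (!length(num)) stop("no numeric measurement columns")
  # half-up rounding to one decimal (the convention of printed cohort
  # tables; round() would turn 80.25 into 80.2)
  r1 <- function(x) floor(x * 10 + 0.5) / 10
  out <- do.call(rbind, lapply(num, function(col) {
    x <- measurements[[col]]
    data.frame(dimension = col,
               mean = r1(mean(x)),
               sd = r1(sqrt(mean((x - mean(x))^2))),
               range = r1(max(x) - min(x)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read / write landmark JSON
#'
#' Landmarks are stored in mm with an optional `pixel_spacing_mm` field
#' recording the conversion used from image coordinates.
#'
#' @param lm A [landmark_set()].
#' @param path JSON path.
#' @param pixel_spacing_mm Optional scalar recorded alongside.
#' @return `read_landmarks` returns a `vt_landmarks`.
#' @export
write_landmarks <- function(lm, path, pixel_spacing_mm = NULL) {
  stopifnot(inherits(lm, "vt_landmarks"))
  obj <- unclass(lm)
  obj$pharyngeal_wall <- unname(apply(lm$pharyngeal_wall, 1, as.numeric,
                                      simplify = FALSE))
  if (!is.null(pixel_spacing_mm)) obj$pixel_spacing_mm <- pixel_spacing_mm
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  wall <- obj$pharyngeal_wall
  if (!is.matrix(wall)) wall <- do.call(rbind, lapply(wall, as.numeric))
  landmark_set(obj$lips, obj$axis, obj$palate_tangent, obj$vocal_folds,
               obj$esophagus, wall)
}
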