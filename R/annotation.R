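# Domain types for per-iris photograph annotations.
#
# Coordinate frame: image pixel coordinates, origin at the top-left corner,
# x increasing rightward, y increasing downward (raster convention used by
# photograph annotation tools). The anatomical frame is derived from it per
# annotation: for a right eye on an unmirrored image, nasal is +x and
# superior is -y; `eye_side = "left"` or `mirrored = TRUE` each flip the
# nasal axis.

POPULATIONS <- c("EastAsian", "European", "SouthAsian", "Other")

#' Construct a 2-D point in image pixel coordinates
#'
#' @param x,y Finite pixel coordinates (origin top-left, y increases downward).
#' @return An object of class `iris_point`.
#' @export
iris_point <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != 1L || length(y) != 1L || !is.finite(x) || !is.finite(y))
    stop_validation("point coordinates must be single finite numbers")
  structure(list(x = x, y = y), class = "iris_point")
}

#' Construct a circle (best-fit annotation circle)
#'
#' @param centre An [iris_point()].
#' @param radius Radius in pixels, strictly positive.
#' @return An object of class `iris_circle`.
#' @export
iris_circle <- function(centre, radius) {
  if (!inherits(centre, "iris_point")) centre <- iris_point(centre[[1]], centre[[2]])
  radius <- as.numeric(radius)
  if (length(radius) != 1L || !is.finite(radius) || radius <= 0)
    stop_validation("circle radius must be a single finite number > 0")
  structure(list(centre = centre, radius = radius), class = "iris_circle")
}

#' Construct a crypt mark
#'
#' A crypt is recorded by a click on the outermost edge (tip) of the crypt,
#' plus a flag saying whether the crypt originates from the collarette.
#' Crypts that do not originate from the collarette are always classified
#' small regardless of how far the tip extends.
#'
#' @param tip An [iris_point()] at the outermost edge of the crypt.
#' @param from_collarette Logical; does the crypt originate from the collarette?
#' @return An object of class `crypt_mark`.
#' @export
crypt_mark <- function(tip, from_collarette) {
  if (!inherits(tip, "iris_point")) tip <- iris_point(tip[[1]], tip[[2]])
  if (!is.logical(from_collarette) || length(from_collarette) != 1L ||
      is.na(from_collarette))
    stop_validation("from_collarette must be TRUE or FALSE")
  structure(list(tip = tip, from_collarette = from_collarette),
            class = "crypt_mark")
}

#' Construct a half-open angular interval
#'
#' Angles are degrees in the anatomical frame (0 = nasal axis, increasing
#' toward superior). The interval is half-open, `[start, end)`, sweeping in
#' the positive angular direction; wraparound through 0 is permitted when
#' `end < start`.
#'
#' @param start_deg,end_deg Angles in `[0, 360)`; must differ.
#' @return An object of class `arc_interval`.
#' @export
arc_interval <- function(start_deg, end_deg) {
  s <- as.numeric(start_deg); e <- as.numeric(end_deg)
  if (!is.finite(s) || !is.finite(e) || s < 0 || s >= 360 || e < 0 || e >= 360)
    stop_validation("arc angles must be finite and in [0, 360)")
  if (s == e) stop_validation("arc start and end angles must differ")
  structure(list(start_deg = s, end_deg = e), class = "arc_interval")
}

#' Construct a feature presence/extension observation
#'
#' Records, for contraction furrows or Wolfflin nodules, whether the feature
#' is present, whether it extends around more than 180 degrees of the iris
#' (strictly), and the quadrants in which it is found.
#'
#' @param present Logical.
#' @param over_180 Logical; `TRUE` requires `present`.
#' @param quadrants Logical vector of length 4 (Q1..Q4); presence requires at
#'   least one quadrant, absence requires none.
#' @return An object of class `feature_observation`.
#' @export
feature_observation <- function(present = FALSE, over_180 = FALSE,
                                quadrants = rep(FALSE, 4)) {
  quadrants <- as.logical(quadrants)
  if (length(quadrants) != 4L || anyNA(quadrants))
    stop_validation("quadrants must be 4 non-missing logical flags")
  present <- isTRUE(present); over_180 <- isTRUE(over_180)
  if (over_180 && !present)
    stop_validation("over_180 requires the feature to be present")
  if (present && !any(quadrants))
    stop_validation("a present feature must occupy at least one quadrant")
  if (!present && any(quadrants))
    stop_validation("an absent feature cannot occupy any quadrant")
  structure(list(present = present, over_180 = over_180, quadrants = quadrants),
            class = "feature_observation")
}

#' Construct the per-iris grade record
#'
#' The five ordinal/binary feature grades plus self-described colour.
#' `spot` is the collapsed pigment-spot grade (raw grades 3 and 4 merged),
#' derived from `spot_raw` and checked for consistency if supplied.
#'
#' @param crypt Integer 1-4. @param furrow,nodule Integer 1-3.
#' @param spot_raw Integer 1-4 (1: none; 2: 1-2 spots; 3: 3-5; 4: >5).
#' @param spot Integer 1-3, defaulting to `min(spot_raw, 3)`.
#' @param melanosis 0/1. @param colour Integer 1-5 or `NA`.
#' @return An object of class `feature_grades`.
#' @export
feature_grades <- function(crypt, furrow, nodule, spot_raw,
                           spot = pmin(spot_raw, 3L), melanosis = 0L,
                           colour = NA_integer_) {
  chk <- function(v, lo, hi, nm, na_ok = FALSE) {
    if (length(v) != 1L) stop_validation(sprintf("%s must be a single value", nm))
    if (is.na(v)) {
      if (na_ok) return(NA_integer_)
      stop_validation(sprintf("%s may not be missing", nm))
    }
    vi <- as.integer(v)
    if (!isTRUE(all.equal(as.numeric(v), as.numeric(vi))) || vi < lo || vi > hi)
      stop_validation(sprintf("%s must be an integer in %d..%d", nm, lo, hi))
    vi
  }
  crypt <- chk(crypt, 1L, 4L, "crypt")
  furrow <- chk(furrow, 1L, 3L, "furrow")
  nodule <- chk(nodule, 1L, 3L, "nodule")
  spot_raw <- chk(spot_raw, 1L, 4L, "spot_raw")
  spot <- chk(spot, 1L, 3L, "spot")
  melanosis <- chk(melanosis, 0L, 1L, "melanosis")
  colour <- chk(colour, 1L, 5L, "colour", na_ok = TRUE)
  if (spot != min(spot_raw, 3L))
    stop_validation("spot must be the collapse of spot_raw (raw 4 -> 3)")
  structure(list(crypt = crypt, furrow = furrow, nodule = nodule,
                 spot = spot, spot_raw = spot_raw, melanosis = melanosis,
                 colour = colour),
            class = "feature_grades")
}

# nasal axis sign in image-x for the anatomical frame
nasal_sign <- function(eye_side, mirrored = FALSE) {
  s <- if (identical(eye_side, "right")) 1 else -1
  if (isTRUE(mirrored)) s <- -s
  s
}

#' Construct a validated per-iris annotation
#'
#' Holds everything a rater records for one photographed iris: the three
#' best-fit circles (pupillary ruff, collarette, scleral boundary), the iris
#' and pupil centre points, clicked crypt tips and pigment spots, furrow and
#' nodule observations, the melanosis flag and self-described colour.
#'
#' Validation enforces circle nesting: along every ray from the iris centre
#' (360 sampled rays) the crossing distances must satisfy pupil < collarette
#' < sclera, and the iris centre must lie strictly inside all three circles.
#'
#' @param id Identifier string.
#' @param iris_centre,pupil_centre [iris_point()]s.
#' @param pupil_circle,collarette_circle,sclera_circle [iris_circle()]s.
#' @param eye_side `"right"` (default) or `"left"`.
#' @param mirrored Logical; is the image left-right mirrored?
#' @param obstructed Logical; iris too obscured to characterize (stored as
#'   recorded by the rater, never computed).
#' @param crypts List of [crypt_mark()]s.
#' @param spots List of [iris_point()]s (clicked pigment spots).
#' @param furrows,nodules [feature_observation()]s.
#' @param melanosis Logical or 0/1.
#' @param self_colour Integer 1-5 or `NA`.
#' @return An object of class `iris_annotation`.
#' @export
iris_annotation <- function(id, iris_centre, pupil_centre,
                            pupil_circle, collarette_circle, sclera_circle,
                            eye_side = "right", mirrored = FALSE,
                            obstructed = FALSE,
                            crypts = list(), spots = list(),
                            furrows = feature_observation(),
                            nodules = feature_observation(),
                            melanosis = FALSE, self_colour = NA_integer_) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_validation("id must be a non-empty string")
  if (!eye_side %in% c("right", "left"))
    stop_validation("eye_side must be 'right' or 'left'")
  stopifnot_point <- function(p, nm)
    if (!inherits(p, "iris_point")) stop_validation(sprintf("%s must be an iris_point", nm))
  stopifnot_circle <- function(cc, nm)
    if (!inherits(cc, "iris_circle")) stop_validation(sprintf("%s must be an iris_circle", nm))
  stopifnot_point(iris_centre, "iris_centre")
  stopifnot_point(pupil_centre, "pupil_centre")
  stopifnot_circle(pupil_circle, "pupil_circle")
  stopifnot_circle(collarette_circle, "collarette_circle")
  stopifnot_circle(sclera_circle, "sclera_circle")
  if (!all(vapply(crypts, inherits, logical(1), "crypt_mark")))
    stop_validation("crypts must be a list of crypt_mark objects")
  if (!all(vapply(spots, inherits, logical(1), "iris_point")))
    stop_validation("spots must be a list of iris_point objects")
  if (!inherits(furrows, "feature_observation") ||
      !inherits(nodules, "feature_observation"))
    stop_validation("furrows and nodules must be feature_observation objects")
  melanosis <- isTRUE(as.logical(melanosis))
  if (!is.na(self_colour)) {
    self_colour <- as.integer(self_colour)
    if (self_colour < 1L || self_colour > 5L)
      stop_validation("self_colour must be in 1..5 or missing")
  } else self_colour <- NA_integer_

  a <- structure(list(
    id = id, eye_side = eye_side, mirrored = isTRUE(mirrored),
    obstructed = isTRUE(obstructed),
    iris_centre = iris_centre, pupil_centre = pupil_centre,
    pupil_circle = pupil_circle, collarette_circle = collarette_circle,
    sclera_circle = sclera_circle,
    crypts = crypts, spots = spots, furrows = furrows, nodules = nodules,
    melanosis = melanosis, self_colour = self_colour), class = "iris_annotation")
  validate_annotation_geometry(a)
  a
}

# Circle-nesting check: the iris centre must be strictly inside each circle,
# and along 360 sampled rays the three crossing distances must be strictly
# ordered pupil < collarette < sclera.
validate_annotation_geometry <- function(a) {
  o <- a$iris_centre
  for (nm in c("pupil_circle", "collarette_circle", "sclera_circle")) {
    cc <- a[[nm]]
    d <- sqrt((o$x - cc$centre$x)^2 + (o$y - cc$centre$y)^2)
    if (d >= cc$radius)
      stop_validation(sprintf("iris_centre must lie strictly inside %s", nm))
  }
  ang <- seq(0, 359, by = 1)
  dp <- ray_circle_distance_vec(o, ang, a$pupil_circle)
  dc <- ray_circle_distance_vec(o, ang, a$collarette_circle)
  ds <- ray_circle_distance_vec(o, ang, a$sclera_circle)
  if (any(dp >= dc) || any(dc >= ds))
    stop_validation(
      "circles are not nested: need pupil < collarette < sclera along every ray from the iris centre")
  invisible(TRUE)
}

#' @export
print.iris_annotation <- function(x, ...) {
  cat(sprintf("<iris_annotation '%s'> %s eye%s%s\n", x$id, x$eye_side,
              if (x$mirrored) ", mirrored" else "",
              if (x$obstructed) ", OBSTRUCTED" else ""))
  cat(sprintf("  circles r = %.1f / %.1f / %.1f px (pupil/collarette/sclera)\n",
              x$pupil_circle$radius, x$collarette_circle$radius,
              x$sclera_circle$radius))
  cat(sprintf("  %d crypt mark(s), %d spot(s), furrows %s, nodules %s, melanosis %s\n",
              length(x$crypts), length(x$spots),
              if (x$furrows$present) "present" else "absent",
              if (x$nodules$present) "present" else "absent",
              if (x$melanosis) "yes" else "no"))
  invisible(x)
}

#' Construct a population-by-category contingency table
#'
#' @param counts Matrix of non-negative counts, rows = populations (groups),
#'   columns = ordered categories.
#' @param row_labels,col_labels Optional dimnames.
#' @return An integer matrix of class `contingency_table`.
#' @export
contingency_table <- function(counts, row_labels = rownames(counts),
                              col_labels = colnames(counts)) {
  m <- as.matrix(counts)
  if (any(!is.finite(m)) || any(m < 0))
    stop_validation("contingency counts must be finite and non-negative")
  if (any(abs(m - round(m)) > 1e-8))
    stop_validation("contingency counts must be integers")
  m <- round(m)
  storage.mode(m) <- "integer"
  rownames(m) <- row_labels
  colnames(m) <- col_labels
  structure(m, class = c("contingency_table", class(m)))
}
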