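# Geometric core: ray-circle crossing, annular zone classification, quadrant
# assignment, crypt-size computation, angular coverage and iris width.
#
# The three best-fit circles are drawn independently and need not share a
# centre, so all radial quantities are computed by ray-circle intersection
# from the user-defined iris centre rather than by comparing radii.

# vectorised forward ray-circle crossing; angles in image frame, degrees
ray_circle_distance_vec <- function(origin, angle_deg, circle) {
  ox <- origin$x - circle$centre$x
  oy <- origin$y - circle$centre$y
  c0 <- ox^2 + oy^2 - circle$radius^2
  if (c0 >= 0)
    stop_validation("ray origin must lie strictly inside the circle")
  th <- angle_deg * pi / 180
  b <- cos(th) * ox + sin(th) * oy
  # t^2 + 2bt + c0 = 0, c0 < 0 so there is exactly one positive root
  -b + sqrt(b^2 - c0)
}

#' Distance from an interior point to a circle along a ray
#'
#' Returns the unique positive distance at which the ray starting at
#' `origin` with direction `angle_deg` (image frame: degrees from +x toward
#' +y) crosses `circle`. The origin must lie strictly inside the circle.
#'
#' @param origin An [iris_point()] strictly inside `circle`.
#' @param angle_deg Ray direction in degrees, image frame.
#' @param circle An [iris_circle()].
#' @return Distance in pixels.
#' @export
ray_circle_distance <- function(origin, angle_deg, circle) {
  if (!inherits(origin, "iris_point")) origin <- iris_point(origin[[1]], origin[[2]])
  if (length(angle_deg) != 1L || !is.finite(angle_deg))
    stop_validation("angle_deg must be a single finite number")
  ray_circle_distance_vec(origin, angle_deg, circle)
}

# image-frame angle (degrees) of p as seen from the iris centre
.image_angle <- function(a, p) {
  dx <- p$x - a$iris_centre$x
  dy <- p$y - a$iris_centre$y
  atan2(dy, dx) * 180 / pi
}

#' Annular zone of a point
#'
#' Classifies a point relative to the annotation's three circles along the
#' ray from the iris centre through the point: `PUPIL` inside the pupillary
#' boundary, `PUPILLARY_ZONE` between pupillary boundary and collarette,
#' `CILIARY_ZONE` between collarette and scleral boundary (inclusive), and
#' `OUTSIDE` beyond the scleral boundary. The iris centre itself is `PUPIL`.
#'
#' @param a An [iris_annotation()].
#' @param p An [iris_point()].
#' @return One of `"PUPIL"`, `"PUPILLARY_ZONE"`, `"CILIARY_ZONE"`, `"OUTSIDE"`.
#' @export
zone_of_point <- function(a, p) {
  dx <- p$x - a$iris_centre$x
  dy <- p$y - a$iris_centre$y
  d <- sqrt(dx^2 + dy^2)
  if (d == 0) return("PUPIL")
  ang <- atan2(dy, dx) * 180 / pi
  dp <- ray_circle_distance_vec(a$iris_centre, ang, a$pupil_circle)
  dc <- ray_circle_distance_vec(a$iris_centre, ang, a$collarette_circle)
  ds <- ray_circle_distance_vec(a$iris_centre, ang, a$sclera_circle)
  if (d < dp) "PUPIL"
  else if (d < dc) "PUPILLARY_ZONE"
  else if (d <= ds) "CILIARY_ZONE"
  else "OUTSIDE"
}

# anatomical angle (degrees in [0,360)) of p as seen from the iris centre:
# 0 = nasal axis, increasing toward superior
anatomical_angle <- function(a, p) {
  dx <- p$x - a$iris_centre$x
  dy <- p$y - a$iris_centre$y
  if (dx == 0 && dy == 0)
    stop_validation("point coincides with the iris centre; angle undefined")
  s <- nasal_sign(a$eye_side, a$mirrored)
  (atan2(-dy, s * dx) * 180 / pi) %% 360
}

# quadrant of an anatomical angle; half-open sectors
# Q1 upper nasal [0,90), Q4 upper temporal [90,180),
# Q3 lower temporal [180,270), Q2 lower nasal [270,360)
quadrant_of_angle <- function(phi) {
  phi <- phi %% 360
  c(1L, 4L, 3L, 2L)[findInterval(phi, c(0, 90, 180, 270))]
}

#' Quadrant of a point
#'
#' Quadrants follow the anatomical layout: quadrant 1 is upper nasal,
#' quadrant 2 lower nasal, quadrant 3 lower temporal and quadrant 4 upper
#' temporal. Sector boundaries are the horizontal and vertical axes through
#' the user-defined iris centre; assignment is half-open starting at the
#' nasal axis, sweeping toward superior.
#'
#' @param a An [iris_annotation()] (supplies centre, eye side and mirroring).
#' @param p An [iris_point()], distinct from the iris centre.
#' @return Integer in 1..4.
#' @export
quadrant_of_point <- function(a, p) {
  quadrant_of_angle(anatomical_angle(a, p))
}

#' Fraction of the ciliary zone into which a point extends
#'
#' Along the ray from the iris centre through `p`, computes
#' `f = (d_p - d_collarette) / (d_sclera - d_collarette)` where the `d`s are
#' the ray crossing distances, clamped to `[0, 1]`. Points at or inside the
#' collarette give 0; points at or beyond the scleral boundary give 1 (a
#' point clicked outside the sclera circle is clamped with a warning rather
#' than rejected, tolerating annotation noise).
#'
#' @param a An [iris_annotation()]. @param p An [iris_point()].
#' @return Fraction in `[0, 1]`.
#' @export
ciliary_extension_fraction <- function(a, p) {
  dx <- p$x - a$iris_centre$x
  dy <- p$y - a$iris_centre$y
  d <- sqrt(dx^2 + dy^2)
  ang <- if (d == 0) 0 else atan2(dy, dx) * 180 / pi
  dc <- ray_circle_distance_vec(a$iris_centre, ang, a$collarette_circle)
  ds <- ray_circle_distance_vec(a$iris_centre, ang, a$sclera_circle)
  if (ds <= dc)
    stop_validation("degenerate geometry: sclera crossing not beyond collarette")
  f <- (d - dc) / (ds - dc)
  if (f > 1) warn_iris(sprintf("point (%.1f, %.1f) lies outside the sclera circle; extension clamped to 1", p$x, p$y))
  min(max(f, 0), 1)
}

#' Classify a crypt mark as large or small
#'
#' A crypt is LARGE iff it originates from the collarette and its tip
#' extends into strictly more than 50% of the ciliary zone along its ray;
#' otherwise it is SMALL. A tip at exactly 50% is SMALL (strict inequality),
#' and crypts not originating from the collarette are SMALL regardless of
#' extension.
#'
#' @param a An [iris_annotation()]. @param c A [crypt_mark()].
#' @return `"LARGE"` or `"SMALL"`.
#' @export
classify_crypt <- function(a, c) {
  if (!c$from_collarette) return("SMALL")
  f <- ciliary_extension_fraction(a, c$tip)
  if (f > 0.5) "LARGE" else "SMALL"
}

# normalise a list of arc_interval into a matrix of non-wrapping [start, end)
# segments on [0, 360)
.arc_segments <- function(arcs) {
  if (length(arcs) == 0) return(matrix(numeric(0), ncol = 2))
  segs <- lapply(arcs, function(a) {
    if (!inherits(a, "arc_interval"))
      stop_validation("arcs must be arc_interval objects")
    if (a$end_deg > a$start_deg) rbind(c(a$start_deg, a$end_deg))
    else rbind(c(a$start_deg, 360), c(0, a$end_deg))
  })
  m <- do.call(rbind, segs)
  m[m[, 2] > m[, 1], , drop = FALSE]
}

# merge possibly-overlapping segments; returns matrix of disjoint segments
.merge_segments <- function(m) {
  if (nrow(m) == 0) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    k <- nrow(out)
    if (m[i, 1] <= out[k, 2]) out[k, 2] <- max(out[k, 2], m[i, 2])
    else out <- rbind(out, m[i, ])
  }
  out
}

#' Total angular coverage of a set of arcs
#'
#' Measure (in degrees) of the union of half-open arcs, with wraparound
#' handled. The result never exceeds 360.
#'
#' @param arcs List of [arc_interval()]s (may be empty).
#' @return Degrees in `[0, 360]`.
#' @export
angular_union_degrees <- function(arcs) {
  m <- .merge_segments(.arc_segments(arcs))
  if (nrow(m) == 0) return(0)
  sum(m[, 2] - m[, 1])
}

#' Convert arcs to a feature observation
#'
#' Derives the presence / more-than-180-degrees / quadrant record that a
#' rater judges with the application's rotating centre line: the feature is
#' present if the arc union has positive measure, `over_180` iff the union
#' strictly exceeds 180 degrees, and a quadrant flag is set iff the union
#' intersects that quadrant's sector with positive measure.
#'
#' @param arcs List of [arc_interval()]s in the anatomical frame.
#' @return A [feature_observation()].
#' @export
arcs_to_observation <- function(arcs) {
  m <- .merge_segments(.arc_segments(arcs))
  total <- if (nrow(m) == 0) 0 else sum(m[, 2] - m[, 1])
  sectors <- rbind("1" = c(0, 90), "4" = c(90, 180),
                   "3" = c(180, 270), "2" = c(270, 360))
  quad <- rep(FALSE, 4)
  if (nrow(m) > 0) for (k in seq_len(4)) {
    q <- as.integer(rownames(sectors)[k])
    lo <- sectors[k, 1]; hi <- sectors[k, 2]
    ov <- pmin(m[, 2], hi) - pmax(m[, 1], lo)
    quad[q] <- any(ov > 1e-12)
  }
  feature_observation(present = total > 0, over_180 = total > 180,
                      quadrants = quad)
}

#' Iris width
#'
#' The diameter of the best-fit circle around the outer (scleral) border of
#' the iris, in pixels.
#'
#' @param a An [iris_annotation()].
#' @return Width in pixels.
#' @export
iris_width <- function(a) {
  2 * a$sclera_circle$radius
}
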