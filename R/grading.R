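# Feature grading rules and the per-iris characterization record.
#
# Grade scales (canonical 1-based encoding; subtract 1 for the 0-based
# labels used in the published frequency tables):
#   crypts  1 no crypts; 2 only small crypts; 3 at least one large crypt in
#           fewer than three quadrants; 4 at least three large crypts in
#           three or more quadrants
#   furrows/nodules  1 absent; 2 extend less than 180 degrees; 3 extend more
#           than 180 degrees (strict)
#   spots   raw: 1 none; 2 one-two; 3 three-five; 4 more than five;
#           collapsed: raw grades 3 and 4 merged
#   melanosis  0 absent / 1 present

FEATURES <- c("crypt", "furrow", "nodule", "spot", "spot_raw",
              "melanosis", "colour")
FEATURE_LEVELS <- list(crypt = 1:4, furrow = 1:3, nodule = 1:3, spot = 1:3,
                       spot_raw = 1:4, melanosis = 0:1, colour = 1:5)

#' Grade Fuchs' crypts from classified marks
#'
#' Grade 4 requires both at least three large crypts and large crypts in at
#' least three distinct quadrants (the two clauses are conjoined); any other
#' configuration with a large crypt is grade 3; only small crypts give grade
#' 2; no crypts give grade 1.
#'
#' @param classified A data.frame with columns `size` ("LARGE"/"SMALL") and
#'   `quadrant` (integer 1-4), one row per crypt mark; zero rows allowed.
#' @return Integer grade 1-4.
#' @export
grade_crypts <- function(classified) {
  if (is.null(classified) || NROW(classified) == 0) return(1L)
  size <- classified$size
  quadrant <- as.integer(classified$quadrant)
  if (!all(size %in% c("LARGE", "SMALL")))
    stop_validation("crypt size must be LARGE or SMALL")
  if (any(is.na(quadrant)) || any(quadrant < 1L) || any(quadrant > 4L))
    stop_validation("crypt quadrants must be integers in 1..4")
  large <- size == "LARGE"
  if (!any(large)) return(2L)
  if (sum(large) >= 3L && length(unique(quadrant[large])) >= 3L) return(4L)
  3L
}

#' Grade an extension-type feature (furrows or Wolfflin nodules)
#'
#' 1 if absent, 3 if the feature extends around more than 180 degrees
#' (strictly), otherwise 2. The two features share this scale.
#'
#' @param obs A [feature_observation()].
#' @return Integer grade 1-3.
#' @export
grade_extension <- function(obs) {
  if (!inherits(obs, "feature_observation"))
    stop_validation("obs must be a feature_observation")
  if (!obs$present) return(1L)
  if (obs$over_180) 3L else 2L
}

#' Grade pigment spots from a count
#'
#' `grade_spots_raw()` returns the four-grade scale (0 spots -> 1, 1-2 -> 2,
#' 3-5 -> 3, 6 or more -> 4); `grade_spots()` returns the collapsed
#' three-grade scale in which raw grades 3 and 4 are merged.
#'
#' @param n_spots Non-negative spot count.
#' @return Integer grade.
#' @export
grade_spots_raw <- function(n_spots) {
  if (length(n_spots) != 1L || !is.finite(n_spots) || n_spots < 0 ||
      n_spots != round(n_spots))
    stop_validation("n_spots must be a single non-negative integer")
  if (n_spots == 0) 1L else if (n_spots <= 2) 2L else if (n_spots <= 5) 3L else 4L
}

#' @rdname grade_spots_raw
#' @export
grade_spots <- function(n_spots) {
  min(grade_spots_raw(n_spots), 3L)
}

#' Characterize one iris
#'
#' Produces the full per-iris record the annotation program exports: the
#' five feature grades, the quadrants in which each feature was found, and
#' the iris width in pixels. Crypt quadrant flags record quadrants
#' containing *large* crypts (the convention of the published quadrant
#' table); spot flags record quadrants containing any spot; furrow and
#' nodule flags are taken from the stored observations.
#'
#' @param a An unobstructed [iris_annotation()].
#' @return A list with elements `grades` ([feature_grades()]),
#'   `quadrants` (named list of 4-logical vectors for crypt/furrow/nodule/
#'   spot), `iris_width` (pixels), and `crypt_sizes` (per-mark
#'   classification).
#' @export
characterize <- function(a) {
  if (!inherits(a, "iris_annotation"))
    stop_validation("a must be an iris_annotation")
  if (a$obstructed)
    stop_exclusion(sprintf("iris '%s' is flagged obstructed and cannot be characterized", a$id),
                   reason = "obstructed")

  if (length(a$crypts)) {
    sizes <- vapply(a$crypts, function(cm) classify_crypt(a, cm), character(1))
    quads <- vapply(a$crypts, function(cm) quadrant_of_point(a, cm$tip), integer(1))
    classified <- data.frame(size = sizes, quadrant = quads)
  } else {
    classified <- data.frame(size = character(0), quadrant = integer(0))
  }
  crypt_grade <- grade_crypts(classified)
  crypt_q <- rep(FALSE, 4)
  lg <- classified$quadrant[classified$size == "LARGE"]
  crypt_q[unique(lg)] <- TRUE

  spot_q <- rep(FALSE, 4)
  if (length(a$spots)) {
    sq <- vapply(a$spots, function(p) quadrant_of_point(a, p), integer(1))
    spot_q[unique(sq)] <- TRUE
  }
  n_spots <- length(a$spots)

  grades <- feature_grades(
    crypt = crypt_grade,
    furrow = grade_extension(a$furrows),
    nodule = grade_extension(a$nodules),
    spot_raw = grade_spots_raw(n_spots),
    melanosis = as.integer(a$melanosis),
    colour = a$self_colour)

  list(grades = grades,
       quadrants = list(crypt = crypt_q, furrow = a$furrows$quadrants,
                        nodule = a$nodules$quadrants, spot = spot_q),
       iris_width = iris_width(a),
       crypt_sizes = classified)
}

#' Apply the cohort exclusion rules
#'
#' Excludes records flagged as obstructed (too obscured or blurry to
#' characterize) or as having a pigmentation-related ocular disorder, and
#' logs exclusion counts by reason and population.
#'
#' @param cohort An `iris_cohort` data.frame (see [read_cohort()]).
#' @return A list with `included` and `excluded` cohorts and `log`, a
#'   reason-by-population count table.
#' @export
filter_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop_validation("cohort must be a data.frame")
  obst <- as.logical(cohort$obstructed) %in% TRUE
  diso <- as.logical(cohort$disorder) %in% TRUE
  reason <- ifelse(obst, "obstructed", ifelse(diso, "disorder", NA))
  drop <- !is.na(reason)
  log <- table(reason = factor(reason[drop], levels = c("obstructed", "disorder")),
               population = factor(cohort$population[drop], levels = POPULATIONS))
  list(included = cohort[!drop, , drop = FALSE],
       excluded = cohort[drop, , drop = FALSE],
       log = log)
}
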