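# Interchange formats.
#
# Annotations travel as JSON, one object per iris (JSON-lines for batches):
#   id, eye_side, mirrored, obstructed,
#   iris_centre {x,y}, pupil_centre {x,y},
#   pupil_circle / collarette_circle / sclera_circle {cx,cy,r},
#   crypts [{x,y,from_collarette}], spots [{x,y}],
#   furrows / nodules {present, over_180, quadrants[4]},
#   melanosis, self_colour (null when missing)
#
# Cohorts travel as CSV with a fixed header; any column after the fixed set
# is a genetic marker holding derived-allele copies 0/1/2 (blank = missing).

COHORT_COLUMNS <- c(
  "id", "population", "sex", "age_years", "iris_width_px",
  "crypt_grade", "furrow_grade", "nodule_grade", "spot_grade",
  "spot_raw_grade", "melanosis", "colour",
  paste0("crypt_q", 1:4), paste0("furrow_q", 1:4),
  paste0("nodule_q", 1:4), paste0("spot_q", 1:4),
  "obstructed", "disorder")

.get_field <- function(obj, field, ctx = NULL) {
  if (is.null(obj[[field]]))
    stop_format("missing required field",
                field = if (is.null(ctx)) field else paste(ctx, field, sep = "."))
  obj[[field]]
}

.parse_point <- function(obj, ctx) {
  iris_point(.get_field(obj, "x", ctx), .get_field(obj, "y", ctx))
}

.parse_circle <- function(obj, ctx) {
  iris_circle(iris_point(.get_field(obj, "cx", ctx), .get_field(obj, "cy", ctx)),
              .get_field(obj, "r", ctx))
}

.parse_observation <- function(obj, ctx) {
  feature_observation(present = isTRUE(.get_field(obj, "present", ctx)),
                      over_180 = isTRUE(.get_field(obj, "over_180", ctx)),
                      quadrants = as.logical(.get_field(obj, "quadrants", ctx)))
}

#' Read one iris annotation from JSON
#'
#' @param json A JSON string (one object) or a path to a file containing one.
#' @return A validated [iris_annotation()].
#' @export
read_annotation <- function(json) {
  if (length(json) == 1L && !grepl("^\\s*\\{", json) && file.exists(json))
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  obj <- tryCatch(jsonlite::fromJSON(json, simplifyVector = FALSE),
                  error = function(e) stop_format(paste("malformed JSON:", conditionMessage(e))))
  annotation_from_list(obj)
}

annotation_from_list <- function(obj) {
  crypts <- lapply(obj$crypts, function(cm)
    crypt_mark(.parse_point(cm, "crypts[]"),
               isTRUE(.get_field(cm, "from_collarette", "crypts[]"))))
  spots <- lapply(obj$spots, function(s) .parse_point(s, "spots[]"))
  sc <- obj$self_colour
  iris_annotation(
    id = as.character(.get_field(obj, "id")),
    eye_side = if (is.null(obj$eye_side)) "right" else obj$eye_side,
    mirrored = isTRUE(obj$mirrored),
    obstructed = isTRUE(obj$obstructed),
    iris_centre = .parse_point(.get_field(obj, "iris_centre"), "iris_centre"),
    pupil_centre = .parse_point(.get_field(obj, "pupil_centre"), "pupil_centre"),
    pupil_circle = .parse_circle(.get_field(obj, "pupil_circle"), "pupil_circle"),
    collarette_circle = .parse_circle(.get_field(obj, "collarette_circle"), "collarette_circle"),
    sclera_circle = .parse_circle(.get_field(obj, "sclera_circle"), "sclera_circle"),
    crypts = crypts, spots = spots,
    furrows = .parse_observation(.get_field(obj, "furrows"), "furrows"),
    nodules = .parse_observation(.get_field(obj, "nodules"), "nodules"),
    melanosis = isTRUE(obj$melanosis),
    self_colour = if (is.null(sc)) NA_integer_ else as.integer(sc))
}

annotation_to_list <- function(a) {
  pt <- function(p) list(x = p$x, y = p$y)
  ci <- function(cc) list(cx = cc$centre$x, cy = cc$centre$y, r = cc$radius)
  ob <- function(o) list(present = o$present, over_180 = o$over_180,
                         quadrants = o$quadrants)
  list(id = a$id, eye_side = a$eye_side, mirrored = a$mirrored,
       obstructed = a$obstructed,
       iris_centre = pt(a$iris_centre), pupil_centre = pt(a$pupil_centre),
       pupil_circle = ci(a$pupil_circle),
       collarette_circle = ci(a$collarette_circle),
       sclera_circle = ci(a$sclera_circle),
       crypts = lapply(a$crypts, function(cm)
         list(x = cm$tip$x, y = cm$tip$y, from_collarette = cm$from_collarette)),
       spots = lapply(a$spots, function(s) pt(s)),
       furrows = ob(a$furrows), nodules = ob(a$nodules),
       melanosis = a$melanosis,
       self_colour = if (is.na(a$self_colour)) NULL else a$self_colour)
}

#' Write one iris annotation as JSON
#'
#' @param a An [iris_annotation()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_annotation <- function(a, path = NULL) {
  js <- jsonlite::toJSON(annotation_to_list(a), auto_unbox = TRUE, digits = NA,
                         null = "null")
  js <- as.character(js)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read / write batches of annotations (JSON-lines)
#'
#' @param path File path; one JSON object per line.
#' @return `read_annotations()`: a list of [iris_annotation()]s.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, read_annotation)
}

#' @rdname read_annotations
#' @param annotations A list of [iris_annotation()]s.
#' @export
write_annotations <- function(annotations, path) {
  writeLines(vapply(annotations, write_annotation, character(1)), path)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' The fixed header is `r paste(COHORT_COLUMNS, collapse = ", ")`; any
#' further column is treated as a genetic marker coded as derived-allele
#' copies (0/1/2, blank for missing). Unknown population labels are mapped
#' to `Other` with a warning; out-of-range grades and genotype values raise
#' row-level errors naming the row.
#'
#' @param file Path to a CSV file, or a character vector of CSV text.
#' @return A data.frame of class `iris_cohort` with a `markers` attribute.
#' @export
read_cohort <- function(file) {
  if (length(file) > 1L || grepl("\n", file))
    file <- textConnection(paste(file, collapse = "\n"))
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols))
    stop_format("cohort CSV is missing required columns",
                field = paste(missing_cols, collapse = ", "))
  markers <- setdiff(names(df), COHORT_COLUMNS)

  unknown <- !(df$population %in% POPULATIONS)
  if (any(unknown)) {
    warn_iris(sprintf("%d row(s) with unknown population mapped to Other", sum(unknown)))
    df$population[unknown] <- "Other"
  }

  check_int_range <- function(col, lo, hi) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v != round(v) | v < lo | v > hi))
    if (length(bad))
      stop_format(sprintf("row %d: %s value %s out of range %d..%d",
                          bad[1], col, v[bad[1]], lo, hi), field = col)
    as.integer(v)
  }
  df$crypt_grade <- check_int_range("crypt_grade", 1L, 4L)
  df$furrow_grade <- check_int_range("furrow_grade", 1L, 3L)
  df$nodule_grade <- check_int_range("nodule_grade", 1L, 3L)
  df$spot_grade <- check_int_range("spot_grade", 1L, 3L)
  df$spot_raw_grade <- check_int_range("spot_raw_grade", 1L, 4L)
  df$melanosis <- check_int_range("melanosis", 0L, 1L)
  df$colour <- check_int_range("colour", 1L, 5L)
  bad_w <- which(!is.na(df$iris_width_px) & df$iris_width_px <= 0)
  if (length(bad_w))
    stop_format(sprintf("row %d: iris_width_px must be > 0", bad_w[1]),
                field = "iris_width_px")
  for (m in markers) {
    v <- df[[m]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1, 2)))
    if (length(bad))
      stop_format(sprintf("row %d: genotype value %s for marker %s not in {0,1,2}",
                          bad[1], v[bad[1]], m), field = m)
    df[[m]] <- as.integer(v)
  }
  for (q in grep("_q[1-4]$", names(df), value = TRUE))
    df[[q]] <- as.logical(df[[q]])
  df$obstructed <- as.logical(df$obstructed)
  df$disorder <- as.logical(df$disorder)
  df$id <- as.character(df$id)

  structure(df, markers = markers, class = c("iris_cohort", "data.frame"))
}

#' Write a cohort table as CSV
#'
#' @param cohort An `iris_cohort` data.frame.
#' @param path Optional file path; when `NULL` the CSV text is returned.
#' @return CSV text, invisibly when written to a file.
#' @export
write_cohort <- function(cohort, path = NULL) {
  txt <- utils::capture.output(
    utils::write.csv(as.data.frame(cohort), row.names = FALSE))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  paste(txt, collapse = "\n")
}
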