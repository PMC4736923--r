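# Seeded generators for synthetic cohorts and synthetic annotations.
#
# The cohort generator's defaults ARE the published study's stated world:
# recruited sample sizes and exclusion counts, the published per-population
# category frequencies for the five features and self-described colour, the
# reported derived-allele frequencies of the crypt-associated marker, the
# published per-genotype and per-sex odds ratios on crypt grade, and the
# published mean iris widths (with a within-population SD back-solved from
# the printed one-way ANOVA F statistic).
#
# Reproducibility: one root seed spawns fixed per-component substreams
# (substream 1..3 = cohort rows for the three populations in fixture order;
# annotation and rater generators take their own seed). Within a substream
# the draw order is fixed and documented in simulate_cohort().

# deterministic substream derivation, kept inside 32-bit signed range
substream_seed <- function(root, id) {
  (as.numeric(root) * 7919 + as.numeric(id) * 104729) %% 2147483647
}

#' Build a cohort simulation configuration
#'
#' All defaults come from the packaged published tables ([iris_fixtures()]).
#' The per-genotype odds ratios act on crypt grade through a cumulative-
#' logit model whose baseline thresholds reproduce the published crypt
#' category frequencies for the reference class; the East Asian derived-
#' homozygote odds ratio (eliminated from the published model for having
#' fewer than five carriers) is extrapolated additively as the square of the
#' heterozygote odds ratio.
#'
#' @param seed Root seed (mandatory).
#' @param n Named per-population row counts (recruited, i.e. pre-exclusion).
#' @param n_obstructed,n_disorder Per-population exclusion-flag counts.
#' @param feature_probs List of population-by-category probability matrices
#'   for crypt, furrow, nodule, spot (collapsed), melanosis and colour.
#' @param spot_raw3_share Probability that a collapsed spot grade 3 iris has
#'   raw grade 3 (3-5 spots) rather than raw grade 4 (more than 5).
#' @param allele_freq Per-population derived-allele frequency of the
#'   simulated crypt marker.
#' @param genotype_or Population-by-(het, hom) odds-ratio matrix on crypt grade.
#' @param sex_or Per-population male-vs-female odds ratio on crypt grade.
#' @param female_share Per-population proportion of females.
#' @param width_mean,width_sd Iris width normal parameters (pixels).
#' @param age_mean,age_sd,age_range Age distribution (normal, truncated).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n = NULL, n_obstructed = NULL, n_disorder = NULL,
                              feature_probs = NULL, spot_raw3_share = 0.7,
                              allele_freq = NULL, genotype_or = NULL,
                              sex_or = NULL, female_share = NULL,
                              width_mean = NULL, width_sd = 14.543,
                              age_mean = NULL, age_sd = 2.5,
                              age_range = c(18, 35)) {
  if (missing(seed) || is.null(seed)) stop_validation("seed is mandatory")
  fx <- iris_fixtures()
  pops <- fx$table1$population
  name_pops <- function(v) {
    if (is.null(v)) return(v)
    if (is.null(names(v))) {
      if (length(v) != length(pops))
        stop_validation("per-population vectors need one value per population")
      names(v) <- pops
    }
    v
  }
  n <- name_pops(n); n_obstructed <- name_pops(n_obstructed)
  n_disorder <- name_pops(n_disorder); allele_freq <- name_pops(allele_freq)
  sex_or <- name_pops(sex_or); female_share <- name_pops(female_share)
  width_mean <- name_pops(width_mean); age_mean <- name_pops(age_mean)
  if (is.null(n)) n <- stats::setNames(fx$table1$recruited, pops)
  if (is.null(n_obstructed)) n_obstructed <- stats::setNames(fx$table1$obstructed, pops)
  if (is.null(n_disorder)) n_disorder <- stats::setNames(fx$table1$disorder, pops)
  if (is.null(feature_probs))
    feature_probs <- lapply(fx$table3, function(m) {
      pm <- sweep(unclass(m), 1, rowSums(m), "/")
      rownames(pm) <- pops
      pm
    })
  for (f in names(feature_probs)) {
    s <- rowSums(feature_probs[[f]])
    if (any(abs(s - 1) > 1e-9))
      stop_validation(sprintf("feature_probs$%s rows must sum to 1", f))
  }
  if (is.null(allele_freq)) allele_freq <- fx$allele_freq
  if (any(allele_freq < 0 | allele_freq > 1))
    stop_validation("allele frequencies must be in [0, 1]")
  if (is.null(genotype_or)) {
    or2 <- fx$table2_or
    het <- or2$odds_ratio[or2$marker == "rs10235789" & or2$genotype == "het"]
    hom <- or2$odds_ratio[or2$marker == "rs10235789" & or2$genotype == "hom"]
    names(het) <- names(hom) <- or2$population[or2$marker == "rs10235789" &
                                                or2$genotype == "het"]
    hom["EastAsian"] <- het["EastAsian"]^2  # additive extrapolation
    genotype_or <- cbind(het = het[pops], hom = hom[pops])
  }
  if (any(genotype_or <= 0)) stop_validation("odds ratios must be positive")
  if (is.null(sex_or))
    sex_or <- c(EastAsian = 1.54, European = 1.72, SouthAsian = 2.07)
  if (is.null(female_share))
    female_share <- stats::setNames(fx$table1$female / fx$table1$included, pops)
  if (is.null(width_mean)) width_mean <- stats::setNames(fx$table1$mean_iris_width, pops)
  if (is.null(age_mean)) age_mean <- stats::setNames(fx$table1$mean_age, pops)

  structure(list(seed = seed, populations = pops, n = n,
                 n_obstructed = n_obstructed, n_disorder = n_disorder,
                 feature_probs = feature_probs, spot_raw3_share = spot_raw3_share,
                 allele_freq = allele_freq, genotype_or = genotype_or,
                 sex_or = sex_or, female_share = female_share,
                 width_mean = width_mean, width_sd = width_sd,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range),
            class = "simulation_config")
}

# quadrant flags consistent with an ordinal grade; an arc of more than 180
# degrees necessarily crosses at least three quadrant sectors
.draw_quadrants <- function(grade, kind) {
  q <- rep(FALSE, 4)
  n_q <- switch(kind,
    crypt = if (grade >= 4) sample(3:4, 1) else if (grade == 3) sample(1:2, 1) else 0,
    extension = if (grade >= 3) sample(3:4, 1) else if (grade == 2) sample(1:2, 1) else 0,
    spot = if (grade >= 3) sample(2:4, 1) else if (grade == 2) sample(1:2, 1) else 0)
  if (n_q > 0) q[sample.int(4, n_q)] <- TRUE
  q
}

#' Simulate a genotype-phenotype cohort
#'
#' For each population (in fixture order, each on its own substream of the
#' root seed) the draw order is: genotypes under Hardy-Weinberg at the
#' configured allele frequency; sex; crypt grade from a cumulative-logit
#' model with the configured genotype and sex log-odds-ratios; the remaining
#' features from their category probabilities (raw spot grade splitting the
#' collapsed top category); quadrant flags consistent with each grade; iris
#' width, age; finally the obstructed/disorder exclusion flags on randomly
#' chosen rows. Identical configurations produce identical cohorts.
#'
#' @param cfg A [simulation_config()].
#' @return An `iris_cohort` data.frame with marker column `rs10235789`.
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "simulation_config"))
    stop_validation("cfg must be a simulation_config")
  out <- vector("list", length(cfg$populations))
  for (k in seq_along(cfg$populations)) {
    pop <- cfg$populations[k]
    n <- cfg$n[[pop]]
    set.seed(substream_seed(cfg$seed, k))

    f <- cfg$allele_freq[[pop]]
    g <- sample(0:2, n, replace = TRUE,
                prob = c((1 - f)^2, 2 * f * (1 - f), f^2))
    sex <- ifelse(stats::runif(n) < cfg$female_share[[pop]], "female", "male")

    p_ref <- cfg$feature_probs$crypt[pop, ]
    theta <- stats::qlogis(cumsum(p_ref)[-length(p_ref)])
    eta <- log(cfg$genotype_or[pop, "het"]) * (g == 1) +
      log(cfg$genotype_or[pop, "hom"]) * (g == 2) +
      log(cfg$sex_or[[pop]]) * (sex == "male")
    cum <- stats::plogis(outer(-eta, theta, "+"))  # P(Y <= j)
    u <- stats::runif(n)
    crypt <- 1L + rowSums(u > cum)

    draw_cat <- function(pr) sample.int(length(pr), n, replace = TRUE, prob = pr)
    furrow <- draw_cat(cfg$feature_probs$furrow[pop, ])
    nodule <- draw_cat(cfg$feature_probs$nodule[pop, ])
    spot <- draw_cat(cfg$feature_probs$spot[pop, ])
    spot_raw <- ifelse(spot == 3L,
                       ifelse(stats::runif(n) < cfg$spot_raw3_share, 3L, 4L),
                       spot)
    melanosis <- draw_cat(cfg$feature_probs$melanosis[pop, ]) - 1L
    colour <- draw_cat(cfg$feature_probs$colour[pop, ])

    qf <- lapply(seq_len(n), function(i) c(
      .draw_quadrants(crypt[i], "crypt"),
      .draw_quadrants(furrow[i], "extension"),
      .draw_quadrants(nodule[i], "extension"),
      .draw_quadrants(spot[i], "spot")))
    qm <- do.call(rbind, qf)
    colnames(qm) <- c(paste0("crypt_q", 1:4), paste0("furrow_q", 1:4),
                      paste0("nodule_q", 1:4), paste0("spot_q", 1:4))

    width <- stats::rnorm(n, cfg$width_mean[[pop]], cfg$width_sd)
    age <- stats::rnorm(n, cfg$age_mean[[pop]], cfg$age_sd)
    age <- pmin(pmax(round(age, 1), cfg$age_range[1]), cfg$age_range[2])

    obstructed <- rep(FALSE, n)
    obstructed[sample.int(n, cfg$n_obstructed[[pop]])] <- TRUE
    disorder <- rep(FALSE, n)
    pool <- which(!obstructed)
    if (cfg$n_disorder[[pop]] > 0)
      disorder[sample(pool, cfg$n_disorder[[pop]])] <- TRUE

    df <- data.frame(
      id = sprintf("%s_%04d", substr(pop, 1, 2), seq_len(n)),
      population = pop, sex = sex, age_years = age,
      iris_width_px = round(width, 2),
      crypt_grade = crypt, furrow_grade = furrow, nodule_grade = nodule,
      spot_grade = spot, spot_raw_grade = spot_raw,
      melanosis = melanosis, colour = colour,
      stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(qm))
    df$obstructed <- obstructed
    df$disorder <- disorder
    df$rs10235789 <- g
    out[[k]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, markers = "rs10235789",
            class = c("iris_cohort", "data.frame"))
}

# anatomical angle in the interior of a quadrant sector (degrees)
.quadrant_angle <- function(q) {
  base <- c(`1` = 45, `2` = 315, `3` = 225, `4` = 135)[as.character(q)]
  (base + stats::runif(1, -35, 35)) %% 360
}

#' Simulate an annotation that grades back to a target
#'
#' Inverse of [characterize()]: builds a geometrically valid annotation
#' (mildly non-concentric circles so the general ray-intersection path is
#' exercised) whose crypt tips, spot clicks and arc-derived observations
#' reproduce exactly the target grades. Large-crypt tips are placed at
#' ciliary extension fractions drawn from `large_range` (strictly above 0.5)
#' and small ones from `small_range` (at most 0.5), so by the strict
#' more-than-50% rule the intended classification is guaranteed.
#'
#' @param target A [feature_grades()].
#' @param seed Seed for this annotation's RNG stream.
#' @param id Annotation identifier.
#' @param centre Image coordinates of the sclera circle centre.
#' @param sclera_r Sclera radius in pixels.
#' @param offset_frac Maximum circle-centre offset as a fraction of
#'   `sclera_r`.
#' @param large_range,small_range Extension-fraction ranges for large and
#'   small collarette crypts; `large_range` must lie strictly above 0.5 and
#'   `small_range` at or below 0.5.
#' @return An [iris_annotation()] with
#'   `characterize(a)$grades == target` (colour and melanosis passed through).
#' @export
simulate_annotation <- function(target, seed, id = "sim",
                                centre = c(600, 400), sclera_r = 200,
                                offset_frac = 0.05,
                                large_range = c(0.6, 0.9),
                                small_range = c(0.1, 0.4)) {
  if (!inherits(target, "feature_grades"))
    stop_validation("target must be a feature_grades")
  if (large_range[1] <= 0.5)
    stop_validation("large_range must lie strictly above 0.5")
  if (small_range[2] > 0.5)
    stop_validation("small_range must lie at or below 0.5")
  set.seed(seed)
  off <- function(scale) stats::runif(2, -scale, scale)
  sc_c <- centre + off(0.02 * sclera_r)
  co_c <- centre + off(offset_frac * sclera_r / 2)
  pu_c <- centre + off(0.02 * sclera_r)
  ic <- iris_point(centre[1] + stats::runif(1, -2, 2),
                   centre[2] + stats::runif(1, -2, 2))
  sclera <- iris_circle(iris_point(sc_c[1], sc_c[2]), sclera_r)
  collarette <- iris_circle(iris_point(co_c[1], co_c[2]), sclera_r / 2)
  pupil <- iris_circle(iris_point(pu_c[1], pu_c[2]), sclera_r / 4)

  # a helper annotation used only to compute ray crossings for placement
  shell <- iris_annotation(id = id, iris_centre = ic, pupil_centre = pupil$centre,
                           pupil_circle = pupil, collarette_circle = collarette,
                           sclera_circle = sclera)

  place <- function(phi, f_lo, f_hi) {
    # anatomical angle -> image direction (right eye, unmirrored)
    dx <- cos(phi * pi / 180); dy <- -sin(phi * pi / 180)
    ang <- atan2(dy, dx) * 180 / pi
    dc <- ray_circle_distance(ic, ang, collarette)
    dss <- ray_circle_distance(ic, ang, sclera)
    d <- dc + stats::runif(1, f_lo, f_hi) * (dss - dc)
    iris_point(ic$x + d * dx, ic$y + d * dy)
  }

  crypts <- list()
  add_crypt <- function(q, large, from_collarette = TRUE) {
    phi <- .quadrant_angle(q)
    rng <- if (large) large_range else small_range
    crypt_mark(place(phi, rng[1], rng[2]), from_collarette)
  }
  if (target$crypt == 2L) {
    crypts <- list(add_crypt(sample.int(4, 1), large = FALSE),
                   add_crypt(sample.int(4, 1), large = FALSE, from_collarette = FALSE))
  } else if (target$crypt == 3L) {
    crypts <- list(add_crypt(sample.int(4, 1), large = TRUE),
                   add_crypt(sample.int(4, 1), large = FALSE))
  } else if (target$crypt == 4L) {
    qs <- sample.int(4, 3)
    crypts <- lapply(qs, add_crypt, large = TRUE)
  }

  n_spots <- switch(target$spot_raw, 0L, sample(1:2, 1), sample(3:5, 1),
                    sample(6:8, 1))
  spots <- lapply(seq_len(n_spots), function(i) {
    phi <- stats::runif(1, 0, 360)
    place(phi, 0.05, 0.9)
  })

  arcs_for <- function(grade) {
    if (grade == 1L) return(list())
    len <- if (grade == 2L) stats::runif(1, 90, 160) else stats::runif(1, 210, 300)
    s <- stats::runif(1, 0, 359)
    list(arc_interval(s, (s + len) %% 360))
  }

  iris_annotation(
    id = id, iris_centre = ic, pupil_centre = pupil$centre,
    pupil_circle = pupil, collarette_circle = collarette,
    sclera_circle = sclera,
    crypts = crypts, spots = spots,
    furrows = arcs_to_observation(arcs_for(target$furrow)),
    nodules = arcs_to_observation(arcs_for(target$nodule)),
    melanosis = target$melanosis == 1L,
    self_colour = target$colour)
}

#' Simulate a re-rating of ordinal grades
#'
#' Emulates an intra- or inter-rater reliability assessment: each grade is
#' independently perturbed by one step up or down (direction equiprobable)
#' with probability `misgrade_prob`, then clamped to `1..k`.
#'
#' @param grades Integer grades in `1..k`.
#' @param misgrade_prob Per-item confusion probability in `[0, 1)`.
#' @param k Number of categories.
#' @param seed RNG seed.
#' @return Perturbed integer grades.
#' @export
simulate_rater <- function(grades, misgrade_prob, k, seed) {
  if (misgrade_prob < 0 || misgrade_prob >= 1)
    stop_validation("misgrade_prob must be in [0, 1)")
  if (any(!grades %in% 1:k)) stop_validation("grades must be integers in 1..k")
  set.seed(seed)
  n <- length(grades)
  flip <- stats::rbinom(n, 1, misgrade_prob)
  dir <- sample(c(-1L, 1L), n, replace = TRUE)
  pmin(pmax(as.integer(grades + flip * dir), 1L), as.integer(k))
}
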