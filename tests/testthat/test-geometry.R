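test_that("ray-circle distance handles the symmetric and collinear cases", {
  circ <- iris_circle(iris_point(0, 0), 100)
  for (ang in c(0, 37, 90, 215))
    expect_equal(ray_circle_distance(iris_point(0, 0), ang, circ), 100)
  expect_equal(ray_circle_distance(iris_point(10, 0), 0, circ), 90)
  expect_equal(ray_circle_distance(iris_point(10, 0), 180, circ), 110)
  expect_error(ray_circle_distance(iris_point(150, 0), 0, circ),
               class = "iris_validation_error")
})

test_that("ray-circle distance matches the bisection oracle on random configs", {
  set.seed(101)
  for (i in 1:200) {
    circ <- iris_circle(iris_point(runif(1, -50, 50), runif(1, -50, 50)),
                        runif(1, 60, 150))
    # origin strictly inside
    r <- runif(1, 0, 0.8 * circ$radius); th <- runif(1, 0, 2 * pi)
    origin <- iris_point(circ$centre$x + r * cos(th), circ$centre$y + r * sin(th))
    ang <- runif(1, 0, 360)
    expect_equal(ray_circle_distance(origin, ang, circ),
                 bisect_ray_cross(origin, ang, circ), tolerance = 1e-5)
  }
})

test_that("zone classification follows the annular partition", {
  a <- concentric_annotation(50, 100, 200, centre = c(0, 0))
  at <- function(d) iris_point(d, 0)
  expect_equal(zone_of_point(a, at(0)), "PUPIL")
  expect_equal(zone_of_point(a, at(25)), "PUPIL")
  expect_equal(zone_of_point(a, at(75)), "PUPILLARY_ZONE")
  expect_equal(zone_of_point(a, at(150)), "CILIARY_ZONE")
  expect_equal(zone_of_point(a, at(250)), "OUTSIDE")
})

test_that("zone and extension agree with dense-sampling oracles off-centre", {
  set.seed(202)
  for (i in 1:60) {
    a <- random_annotation(4000 + i)
    d <- runif(1, 5, 230); th <- runif(1, 0, 2 * pi)
    p <- iris_point(a$iris_centre$x + d * cos(th), a$iris_centre$y + d * sin(th))
    ang <- th * 180 / pi
    dp <- sample_ray_cross(a$iris_centre, ang, a$pupil_circle, step = 0.05)
    dc <- sample_ray_cross(a$iris_centre, ang, a$collarette_circle, step = 0.05)
    ds <- sample_ray_cross(a$iris_centre, ang, a$sclera_circle, step = 0.05)
    # skip draws landing within sampling resolution of a boundary
    if (min(abs(d - c(dp, dc, ds))) < 0.2) next
    want <- if (d < dp) "PUPIL" else if (d < dc) "PUPILLARY_ZONE"
            else if (d < ds) "CILIARY_ZONE" else "OUTSIDE"
    expect_equal(zone_of_point(a, p), want)
    f_oracle <- min(max((d - dc) / (ds - dc), 0), 1)
    f <- suppressWarnings(ciliary_extension_fraction(a, p))
    expect_equal(f, f_oracle, tolerance = 1e-2)
  }
})

test_that("quadrants follow the anatomical convention with half-open ties", {
  a <- concentric_annotation(centre = c(0, 0))
  at <- function(dx, dy) iris_point(dx, dy)
  # right eye, unmirrored: nasal = +x, superior = -y
  expect_equal(quadrant_of_point(a, at(10, -10)), 1L)  # upper nasal
  expect_equal(quadrant_of_point(a, at(10, 10)), 2L)   # lower nasal
  expect_equal(quadrant_of_point(a, at(-10, 10)), 3L)  # lower temporal
  expect_equal(quadrant_of_point(a, at(-10, -10)), 4L) # upper temporal
  # axis boundaries: half-open starting at each sector's lower edge
  expect_equal(quadrant_of_point(a, at(10, 0)), 1L)    # phi = 0
  expect_equal(quadrant_of_point(a, at(0, -10)), 4L)   # phi = 90
  expect_equal(quadrant_of_point(a, at(-10, 0)), 3L)   # phi = 180
  expect_equal(quadrant_of_point(a, at(0, 10)), 2L)    # phi = 270
  expect_error(quadrant_of_point(a, at(0, 0)), class = "iris_validation_error")

  # left eye and mirroring flip the nasal axis
  al <- concentric_annotation(centre = c(0, 0), eye_side = "left")
  expect_equal(quadrant_of_point(al, at(-10, -10)), 1L)
  am <- concentric_annotation(centre = c(0, 0), mirrored = TRUE)
  expect_equal(quadrant_of_point(am, at(-10, -10)), 1L)
  alm <- concentric_annotation(centre = c(0, 0), eye_side = "left", mirrored = TRUE)
  expect_equal(quadrant_of_point(alm, at(10, -10)), 1L)
})

test_that("ciliary extension fraction: closed form, clamping, monotonicity", {
  a <- concentric_annotation(50, 100, 200, centre = c(0, 0))
  expect_equal(ciliary_extension_fraction(a, iris_point(160, 0)), 0.6)
  expect_equal(ciliary_extension_fraction(a, iris_point(80, 0)), 0)
  expect_equal(ciliary_extension_fraction(a, iris_point(100, 0)), 0)
  expect_warning(f <- ciliary_extension_fraction(a, iris_point(0, 240)),
                 class = "iris_warning")
  expect_equal(f, 1)

  # concentric closed form (|p| - r_c) / (r_s - r_c) at arbitrary angles
  set.seed(7)
  for (i in 1:50) {
    d <- runif(1, 100, 200); th <- runif(1, 0, 2 * pi)
    p <- iris_point(d * cos(th), d * sin(th))
    expect_equal(ciliary_extension_fraction(a, p), (d - 100) / 100,
                 tolerance = 1e-9)
  }

  # moving radially outward never decreases the fraction (non-concentric)
  b <- random_annotation(31)
  for (th in seq(0, 2 * pi, length.out = 13)) {
    ds <- seq(10, 220, by = 5)
    fs <- vapply(ds, function(d) suppressWarnings(ciliary_extension_fraction(
      b, iris_point(b$iris_centre$x + d * cos(th),
                    b$iris_centre$y + d * sin(th)))), numeric(1))
    expect_true(all(diff(fs) >= -1e-12))
  }
})

test_that("crypt classification applies the strict more-than-50% rule", {
  a <- concentric_annotation(50, 100, 200, centre = c(0, 0))
  tip_at <- function(f) iris_point(100 + f * 100, 0)
  expect_equal(classify_crypt(a, crypt_mark(tip_at(0.6), TRUE)), "LARGE")
  expect_equal(classify_crypt(a, crypt_mark(tip_at(0.5), TRUE)), "SMALL")
  expect_equal(classify_crypt(a, crypt_mark(tip_at(0.5 + 1e-9), TRUE)), "LARGE")
  expect_equal(classify_crypt(a, crypt_mark(tip_at(0.7), FALSE)), "SMALL")
})

test_that("angular union matches examples and the grid oracle", {
  arc <- function(s, e) arc_interval(s, e)
  expect_equal(angular_union_degrees(list()), 0)
  expect_equal(angular_union_degrees(list(arc(0, 90))), 90)
  expect_equal(angular_union_degrees(list(arc(0, 120), arc(100, 200))), 200)
  expect_equal(angular_union_degrees(list(arc(350, 30), arc(20, 40))), 50)
  expect_equal(grid_union_degrees(list(arc(350, 30), arc(20, 40))), 50)

  set.seed(55)
  for (i in 1:40) {
    arcs <- lapply(seq_len(sample(1:5, 1)), function(j) {
      s <- runif(1, 0, 359.9)
      arc(s, (s + runif(1, 1, 320)) %% 360)
    })
    u <- angular_union_degrees(arcs)
    expect_lte(u, 360)
    expect_equal(u, grid_union_degrees(arcs), tolerance = 0.05)
    # order permutation and common rotation leave the measure unchanged
    expect_equal(angular_union_degrees(rev(arcs)), u)
    rot <- runif(1, 0, 360)
    rotated <- lapply(arcs, function(a)
      arc((a$start_deg + rot) %% 360, (a$end_deg + rot) %% 360))
    expect_equal(angular_union_degrees(rotated), u, tolerance = 1e-9)
  }
})

test_that("arcs_to_observation applies the strict 180-degree rule", {
  obs <- arcs_to_observation(list(arc_interval(0, 200)))
  expect_true(obs$present); expect_true(obs$over_180)
  obs <- arcs_to_observation(list(arc_interval(0, 180)))
  expect_true(obs$present); expect_false(obs$over_180)
  obs <- arcs_to_observation(list())
  expect_false(obs$present); expect_false(any(obs$quadrants))
  # quadrant flags require positive-measure overlap with each sector
  obs <- arcs_to_observation(list(arc_interval(10, 80)))
  expect_equal(obs$quadrants, c(TRUE, FALSE, FALSE, FALSE))
  obs <- arcs_to_observation(list(arc_interval(85, 100)))
  expect_equal(obs$quadrants, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("iris width doubles the sclera radius", {
  expect_equal(iris_width(concentric_annotation(rs = 188.36)), 376.72)
  expect_equal(iris_width(concentric_annotation(rs = 197.225)), 394.45)
  expect_gt(iris_width(random_annotation(8)), 0)
})
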