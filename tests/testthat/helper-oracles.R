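# Shared fixture builders and independent oracles used across the test
# files. Oracles are deliberately written from first principles (brute
# force, dense sampling, bisection) and never call the code paths they
# check.

# simple annotation with concentric circles (radii pupil/collarette/sclera)
concentric_annotation <- function(rp = 50, rc = 100, rs = 200,
                                  centre = c(500, 400), id = "fix",
                                  ...) {
  ctr <- iris_point(centre[1], centre[2])
  iris_annotation(id = id, iris_centre = ctr, pupil_centre = ctr,
                  pupil_circle = iris_circle(ctr, rp),
                  collarette_circle = iris_circle(ctr, rc),
                  sclera_circle = iris_circle(ctr, rs), ...)
}

# random mildly non-concentric annotation
random_annotation <- function(seed) {
  set.seed(seed)
  ctr <- c(500, 400)
  mk <- function(off, r) iris_circle(iris_point(ctr[1] + runif(1, -off, off),
                                                ctr[2] + runif(1, -off, off)), r)
  iris_annotation(id = paste0("rnd", seed),
                  iris_centre = iris_point(ctr[1] + runif(1, -3, 3),
                                           ctr[2] + runif(1, -3, 3)),
                  pupil_centre = iris_point(ctr[1], ctr[2]),
                  pupil_circle = mk(4, runif(1, 40, 60)),
                  collarette_circle = mk(10, runif(1, 90, 110)),
                  sclera_circle = mk(4, runif(1, 190, 210)))
}

# forward ray-circle crossing by interval bisection to 1e-6 px
bisect_ray_cross <- function(origin, angle_deg, circle, tol = 1e-6) {
  th <- angle_deg * pi / 180
  ux <- cos(th); uy <- sin(th)
  inside <- function(t)
    (origin$x + t * ux - circle$centre$x)^2 +
    (origin$y + t * uy - circle$centre$y)^2 < circle$radius^2
  lo <- 0
  hi <- sqrt((origin$x - circle$centre$x)^2 +
             (origin$y - circle$centre$y)^2) + circle$radius + 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (inside(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# dense radial-sampling crossing: first sampled distance outside the circle
sample_ray_cross <- function(origin, angle_deg, circle, step = 0.1) {
  th <- angle_deg * pi / 180
  t <- seq(0, 500, by = step)
  px <- origin$x + t * cos(th); py <- origin$y + t * sin(th)
  out <- (px - circle$centre$x)^2 + (py - circle$centre$y)^2 >= circle$radius^2
  t[which(out)[1]]
}

# union of arcs by 0.01-degree grid discretization
grid_union_degrees <- function(arcs, step = 0.01) {
  g <- seq(0, 360 - step, by = step)
  covered <- rep(FALSE, length(g))
  for (a in arcs) {
    s <- a$start_deg; e <- a$end_deg
    covered <- covered | if (e > s) (g >= s & g < e) else (g >= s | g < e)
  }
  sum(covered) * step
}

# O(n^2) pair enumeration for gamma
gamma_brute <- function(x, y) {
  C <- 0; D <- 0
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  list(C = C, D = D, G = (C - D) / (C + D))
}

# weighted kappa by the disagreement-ratio formulation
kappa_confusion_oracle <- function(r1, r2, k) {
  O <- table(factor(r1, levels = 1:k), factor(r2, levels = 1:k))
  n <- sum(O)
  v <- abs(outer(1:k, 1:k, "-")) / (k - 1)
  E <- outer(rowSums(O), colSums(O)) / n
  1 - sum(v * O) / sum(v * E)
}

# two-loop Pearson chi-square summation
chi2_naive <- function(m) {
  total <- sum(m); rs <- rowSums(m); cs <- colSums(m)
  s <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    e <- rs[i] * cs[j] / total
    s <- s + (m[i, j] - e)^2 / e
  }
  s
}

# expand per-category counts to a per-individual score vector
expand_counts <- function(counts, scores = seq_along(counts)) rep(scores, counts)

# all 216 valid collapsed grade vectors
all_grade_vectors <- function() {
  expand.grid(crypt = 1:4, furrow = 1:3, nodule = 1:3, spot = 1:3,
              melanosis = 0:1)
}
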