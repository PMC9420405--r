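test_that("RMA recovers exact lines and obeys its algebraic symmetries", {
  x <- c(0, 1, 2, 3, 4.5)
  y <- 2 * x + 1
  f <- fit_rma(x, y, intercept_ci = "analytic")
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r, 1, tolerance = 1e-12)
  set.seed(31)
  x <- rnorm(20); y <- 1.5 * x + rnorm(20, sd = 0.5)
  fxy <- fit_rma(x, y, intercept_ci = "analytic")
  fyx <- fit_rma(y, x, intercept_ci = "analytic")
  expect_equal(fyx$slope, 1 / fxy$slope, tolerance = 1e-12)
  # scaling y by c scales the slope by c
  fc <- fit_rma(x, 3 * y, intercept_ci = "analytic")
  expect_equal(fc$slope, 3 * fxy$slope, tolerance = 1e-12)
  # sign(slope) follows sign(r)
  fneg <- fit_rma(x, -y, intercept_ci = "analytic")
  expect_equal(fneg$slope, -fxy$slope, tolerance = 1e-12)
  expect_true(fxy$slope_ci[1] <= fxy$slope && fxy$slope <= fxy$slope_ci[2])
})

test_that("RMA slope minimizes the summed triangle areas (numeric-search oracle)", {
  # the triangle between a point and the line y = a + bx has area
  # (y - a - bx)^2 / (2|b|); minimizing over a gives a = mean(y) - b mean(x),
  # leaving a 1-D search over b, independent of the sd-ratio formula
  for (seed in c(101, 202, 303)) {
    set.seed(seed)
    x <- rnorm(10)
    y <- -0.7 * x + rnorm(10, sd = 0.6)
    f <- fit_rma(x, y, intercept_ci = "analytic")
    area <- function(b) sum((y - mean(y) - b * (x - mean(x)))^2) / (2 * abs(b))
    lo <- stats::optimize(area, c(-20, -1e-8))
    hi <- stats::optimize(area, c(1e-8, 20))
    b_star <- if (lo$objective < hi$objective) lo$minimum else hi$minimum
    expect_equal(f$slope, b_star, tolerance = 1e-4)
  }
})

test_that("Clarke's slope test is symmetric and null on identical fits", {
  set.seed(5)
  x <- rnorm(30); y <- 2 * x + rnorm(30)
  f1 <- fit_rma(x, y, intercept_ci = "analytic")
  same <- clarke_test(f1, f1)
  expect_equal(same$T, 0)
  expect_equal(same$p, 1)
  x2 <- rnorm(40); y2 <- 2.5 * x2 + rnorm(40)
  f2 <- fit_rma(x2, y2, intercept_ci = "analytic")
  expect_equal(clarke_test(f1, f2)$p, clarke_test(f2, f1)$p, tolerance = 1e-12)
  f3 <- fit_rma(x2, -y2, intercept_ci = "analytic")
  expect_error(clarke_test(f1, f3), "opposite")
})

test_that("Clarke's test holds its nominal size (Monte-Carlo type-I error)", {
  # two samples with the same true RMA slope; rejection rate at alpha = 0.05
  # should stay near 0.05
  set.seed(42)
  n <- 50
  reps <- 2000
  rej <- 0L
  for (i in seq_len(reps)) {
    x1 <- rnorm(n); y1 <- 2 * x1 + rnorm(n, sd = 1.5)
    x2 <- rnorm(n); y2 <- 2 * x2 + rnorm(n, sd = 1.5)
    p <- clarke_test(fit_rma(x1, y1, intercept_ci = "analytic"),
                     fit_rma(x2, y2, intercept_ci = "analytic"))$p
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / reps, 0.035)
  expect_lte(rej / reps, 0.065)
})

test_that("intercept interval comparison reports overlap correctly", {
  f <- function(ci) {
    out <- fit_rma(1:5, c(1.2, 2.1, 2.8, 4.2, 4.9), intercept_ci = "analytic")
    out$intercept_ci <- ci
    out
  }
  expect_false(compare_intercepts(f(c(0, 1)), f(c(2, 3)))$overlap)
  expect_true(compare_intercepts(f(c(0, 2)), f(c(1, 3)))$overlap)
})

test_that("BCa intercept interval brackets the analytic point estimate", {
  # line + noise model; the bootstrap interval should contain the sample
  # intercept essentially always, and the fit is reproducible under its seed
  set.seed(77)
  inside <- 0L
  n_sets <- 200
  for (i in seq_len(n_sets)) {
    x <- rnorm(25, mean = 1)
    y <- 0.8 + 1.6 * x + rnorm(25, sd = 0.8)
    f <- fit_rma(x, y, nboot = 300, seed = i)
    if (f$intercept_ci[1] <= f$intercept && f$intercept <= f$intercept_ci[2]) {
      inside <- inside + 1L
    }
  }
  expect_gte(inside / n_sets, 0.95)
  x <- rnorm(25); y <- 1 + x + rnorm(25)
  expect_identical(fit_rma(x, y, seed = 9)$intercept_ci,
                   fit_rma(x, y, seed = 9)$intercept_ci)
})

test_that("centroid angles match analytic and cosine-rule values", {
  scores <- rbind(c(0, 0), c(0, 0), c(-1, 1), c(-1, 1))
  grp <- rep("g", 4)
  stage <- c("juvenile", "juvenile", "adult", "adult")
  ang <- centroid_angles(scores, grp, stage)
  expect_equal(ang$angle_deg, 135)
  # trigonometric oracle on a generated configuration
  set.seed(12)
  sc <- matrix(rnorm(40), 20, 2)
  grp <- rep(c("a", "b"), each = 10)
  stage <- rep(rep(c("adult", "juvenile"), each = 5), 2)
  ang <- centroid_angles(sc, grp, stage)
  for (i in seq_len(nrow(ang))) {
    v <- c(ang$adult_x[i] - ang$juv_x[i], ang$adult_y[i] - ang$juv_y[i])
    cosv <- sum(v * c(1, 0)) / sqrt(sum(v^2))
    expected <- acos(cosv) * 180 / pi   # folded to [0, 180] by definition
    expect_equal(ang$angle_deg[i], expected, tolerance = 1e-9)
  }
  expect_error(centroid_angles(sc[stage == "adult", ], grp[stage == "adult"],
                               stage[stage == "adult"]), "juvenile")
})

test_that("zero-variance input is rejected", {
  expect_error(fit_rma(rep(1, 5), rnorm(5)), "variance")
  expect_error(fit_rma(rnorm(2), rnorm(2)), "n >= 3")
})
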