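# reference RMA fit on points exactly on a known line
line_fit <- function(slope, intercept, x = seq(-2, 2, length.out = 9)) {
  fit_rma(x, slope * x + intercept, intercept_ci = "analytic")
}

test_that("trajectory decomposition matches analytic geometry and labels", {
  ref <- line_fit(-3, 0)
  # target at the reference centroid
  d0 <- decompose_trajectory(ref, c(0, 0), polarity = c(1, -3))
  expect_equal(d0$along, 0, tolerance = 1e-12)
  expect_equal(d0$offset, 0, tolerance = 1e-12)
  expect_identical(d0$scaling_label, "none")
  expect_identical(d0$transposition_label, "on-trajectory")
  # target further down the line y = -3x, polarity toward +x
  d1 <- decompose_trajectory(ref, c(1, -3), polarity = c(1, -3))
  expect_equal(d1$along, sqrt(10), tolerance = 1e-10)
  expect_equal(d1$offset, 0, tolerance = 1e-10)
  expect_identical(d1$scaling_label, "peramorphic")
  expect_identical(d1$transposition_label, "on-trajectory")
  # reversed polarity flips the scaling label
  d2 <- decompose_trajectory(ref, c(1, -3), polarity = c(-1, 3))
  expect_identical(d2$scaling_label, "paedomorphic")
  # squared components add to the squared centroid distance
  d3 <- decompose_trajectory(ref, c(2, 1), polarity = c(1, -3))
  expect_equal(d3$along^2 + d3$offset^2, sum(c(2, 1)^2), tolerance = 1e-9)
  expect_identical(d3$transposition_label, "transposed")
  expect_error(decompose_trajectory(ref, c(1, 1), polarity = c(0, 0)), "polarity")
})

test_that("decomposition is equivariant under rotation of the score plane", {
  # collinear reference points refit exactly after rotation, so the whole
  # configuration can be rotated rigidly
  x <- seq(-1, 2, length.out = 8)
  y <- 0.7 * x + 0.2
  target <- c(1.4, -0.3)
  pol <- c(1, 0.7)
  base <- decompose_trajectory(fit_rma(x, y, intercept_ci = "analytic"),
                               target, pol)
  for (theta in c(0.3, -0.8, 1.2)) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    xy <- cbind(x, y) %*% t(R)
    rfit <- fit_rma(xy[, 1], xy[, 2], intercept_ci = "analytic")
    rot <- decompose_trajectory(rfit, as.vector(R %*% target),
                                as.vector(R %*% pol))
    expect_equal(rot$along, base$along, tolerance = 1e-9)
    expect_equal(rot$offset, base$offset, tolerance = 1e-9)
  }
})

test_that("mean recovered offset matches the known transposition geometry", {
  # two groups on parallel lines y = m x (+ delta); the perpendicular gap is
  # delta * cos(atan(m))
  m <- -1.5
  delta <- 0.5
  offsets <- vapply(1:200, function(seed) {
    set.seed(seed)
    x1 <- rnorm(50); y1 <- m * x1 + rnorm(50, sd = 0.02)
    x2 <- rnorm(50); y2 <- m * x2 + delta + rnorm(50, sd = 0.02)
    ref <- fit_rma(x1, y1, intercept_ci = "analytic")
    abs(decompose_trajectory(ref, c(mean(x2), mean(y2)),
                             polarity = c(1, m))$offset)
  }, 0)
  expect_equal(mean(offsets), delta * cos(atan(m)), tolerance = 0.05)
})

test_that("encephalization quotient follows its defining identities", {
  rec <- compute_eq(bm_kg = 50, ecv_cm3 = 50, a = 1, b = 1)
  expect_equal(rec$eq, 1)
  # scaling ecv and a by the same constant leaves eq unchanged
  r1 <- compute_eq(40, 400, a = 1.77, b = 0.76)
  r2 <- compute_eq(40, 400 * 3, a = 1.77 * 3, b = 0.76)
  expect_equal(r1$eq, r2$eq)
  expect_equal(r1$log_bm, log10(40))
  expect_error(compute_eq(-1, 400), "positive")
  # rank oracle: EQ ordering equals that of ecv / bm^b
  set.seed(8)
  bm <- runif(20, 20, 120)
  ecv <- runif(20, 300, 1600)
  eq <- compute_eq(bm, ecv, a = 1.77, b = 0.76)$eq
  expect_identical(order(eq), order(ecv / bm^0.76))
})

test_that("correlation matrices match a from-scratch computation", {
  set.seed(14)
  d <- data.frame(factor1 = rnorm(12), factor2 = rnorm(12),
                  log_bm = rnorm(12), log_ecv = rnorm(12), eq = rnorm(12))
  res <- cranial_associations(d)
  expect_equal(diag(res$r), rep(1, 5), ignore_attr = TRUE)
  expect_equal(res$r, t(res$r))
  manual <- function(u, v) {
    mean((u - mean(u)) * (v - mean(v))) / (stats::sd(u) * stats::sd(v)) *
      length(u) / (length(u) - 1)
  }
  expect_equal(res$r["factor1", "log_ecv"], manual(d$factor1, d$log_ecv),
               tolerance = 1e-12)
  expect_error(cranial_associations(d[1:3, ]), "at least 4")
  # grouped variant returns one matrix per level
  grp <- rep(c("a", "b"), each = 6)
  by_grp <- cranial_associations(d, group = grp)
  expect_named(by_grp, c("a", "b"))
  expect_equal(by_grp$a$r, cranial_associations(d[grp == "a", ])$r)
})

test_that("partial correlation agrees with the residual-regression oracle", {
  set.seed(23)
  n <- 40
  z <- rnorm(n)
  x <- 0.8 * z + rnorm(n)
  y <- -0.5 * z + rnorm(n)
  pc <- partial_correlation(x, y, z)
  rx <- stats::resid(stats::lm(x ~ z))
  ry <- stats::resid(stats::lm(y ~ z))
  expect_equal(pc$r, stats::cor(rx, ry), tolerance = 1e-10)
  expect_equal(pc$df, n - 3)
  # symmetry in x and y
  expect_equal(partial_correlation(y, x, z)$r, pc$r, tolerance = 1e-12)
  # a control orthogonal to both leaves the simple correlation untouched
  z0 <- stats::resid(stats::lm(rnorm(n) ~ x + y))
  expect_equal(partial_correlation(x, y, z0)$r, stats::cor(x, y),
               tolerance = 1e-10)
  expect_error(partial_correlation(x, y, x), "collinear")
})

test_that("partial-correlation test holds its size under conditional independence", {
  # x and y independent given z; nominal 5% level
  set.seed(99)
  n <- 30
  reps <- 2000
  rej <- 0L
  for (i in seq_len(reps)) {
    z <- rnorm(n)
    x <- z + rnorm(n)
    y <- z + rnorm(n)
    if (partial_correlation(x, y, z)$p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / reps, 0.03)
  expect_lte(rej / reps, 0.07)
})
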