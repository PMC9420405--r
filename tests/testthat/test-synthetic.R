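test_that("generation is bit-reproducible under the seed", {
  cfg <- two_group_config(n_per_stage = 10, seed = 5)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_dataset(two_group_config(n_per_stage = 10, seed = 6))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("isometric noise-free growth leaves shape constant", {
  g <- synthetic_group("iso", 12, 12, rep(0.4, 6), 2.1,
                       size_mean_juvenile = 1.9, size_sd = 0.08)
  ds <- generate_dataset(synthetic_config(list(g), allometry = rep(1, 6),
                                          noise_sd = 0, seed = 2))
  shp <- unclass(shape_matrix(ds))
  expect_lt(max(apply(shp, 2, stats::sd)), 1e-12)
})

test_that("noise-free transposed groups yield parallel trajectories", {
  cfg <- two_group_config(n_per_stage = 20, noise_sd = 0, seed = 4)
  ds <- generate_dataset(cfg)
  fm <- fit_factors(log_matrix(ds), k = 2)
  fits <- lapply(c("anc", "desc"), function(g) {
    sel <- ds$group == g
    fit_rma(fm$scores[sel, 1], fm$scores[sel, 2], intercept_ci = "analytic")
  })
  # noise-free scores are exactly collinear within group; the two lines
  # share the slope (shared allometry) but not the intercept (transposition)
  expect_equal(abs(fits[[1]]$r), 1, tolerance = 1e-6)
  expect_equal(fits[[1]]$slope, fits[[2]]$slope, tolerance = 1e-6)
  expect_gt(abs(fits[[1]]$intercept - fits[[2]]$intercept), 0.1)
})

test_that("a uniform intercept shift moves scores only along the size direction", {
  cfg1 <- two_group_config(n_per_stage = 25, noise_sd = 0, seed = 9)
  cfg2 <- cfg1
  cfg2$groups[[2]]$intercept <- cfg2$groups[[2]]$intercept + 0.05
  ds1 <- generate_dataset(cfg1)
  ds2 <- generate_dataset(cfg2)   # same seed: identical draws
  fm <- fit_factors(log_matrix(ds1), k = 2)
  s1 <- score_factors(fm, log_matrix(ds1))
  s2 <- score_factors(fm, log_matrix(ds2))
  shift <- colMeans((s2 - s1)[ds1$group == "desc", ])
  iso <- as.vector((rep(1, 6) / fm$sd) %*% fm$scoring)
  cos_angle <- sum(shift * iso) / sqrt(sum(shift^2) * sum(iso^2))
  expect_equal(abs(cos_angle), 1, tolerance = 1e-8)
})

test_that("per-variable allometric slopes are recovered from the latent size", {
  cfg <- two_group_config(n_per_stage = 125, noise_sd = 0.01, seed = 13)
  ds <- generate_dataset(cfg)          # n = 500
  s <- attr(ds, "latent")$log_size
  b_true <- cfg$allometry
  for (j in seq_along(cranio_vars())) {
    fit <- stats::lm(log10(as.data.frame(ds)[[cranio_vars()[j]]]) ~ s)
    est <- stats::coef(summary(fit))["s", ]
    expect_lt(abs(est["Estimate"] - b_true[j]), 3 * est["Std. Error"])
  }
})

test_that("factor-plane RMA recovers the generating allometry (coverage oracle)", {
  # two transposed groups with shared slopes; within one group the
  # population RMA slope of factor II on factor I is computed analytically
  # from the generating covariance pushed through the fitted scoring map,
  # and the fitted CI should cover it in most replicates
  reps <- 100
  covered <- 0L
  negative <- 0L
  for (i in seq_len(reps)) {
    cfg <- two_group_config(n_per_stage = 50, noise_sd = 0.01, seed = 1000 + i,
                            delta = 0.15)
    ds <- generate_dataset(cfg)        # n = 200
    fm <- fit_factors(log_matrix(ds), k = 2)
    sel <- ds$group == "anc"
    f <- fit_rma(fm$scores[sel, 1], fm$scores[sel, 2],
                 intercept_ci = "analytic")
    # population within-group covariance: size variance (stage mixture) on
    # the allometry direction plus isotropic log-scale noise
    g <- cfg$groups[[1]]
    var_s <- g$size_sd^2 + ((g$size_mean_adult - g$size_mean_juvenile) / 2)^2
    Sigma <- var_s * outer(cfg$allometry, cfg$allometry) +
      diag(cfg$noise_sd^2)
    W <- fm$scoring / fm$sd          # rows scaled: D^{-1} W
    S <- t(W) %*% Sigma %*% W
    slope_pop <- sign(S[1, 2]) * sqrt(S[2, 2] / S[1, 1])
    if (f$slope < 0) negative <- negative + 1L
    if (f$slope_ci[1] <= slope_pop && slope_pop <= f$slope_ci[2]) {
      covered <- covered + 1L
    }
  }
  expect_gte(covered / reps, 0.90)
  expect_gte(negative / reps, 0.95)
})

test_that("the hominid-like sample has the study's qualitative structure", {
  ds <- simulate_hominid_sample(seed = 1)
  expect_s3_class(validate_dataset(ds), "cranio_dataset")
  expect_gt(sum(ds$age_class == "juvenile"), 0)
  # PLS dimension 1 dominates the between-module covariation
  pls <- fit_pls(shape_matrix(ds))
  expect_gt(pls$pct_covariation[1], 90)
  # within-species ontogenies point up-left: size grows, relative
  # neurocranial size shrinks
  fm <- fit_factors(log_matrix(ds), k = 2)
  both <- intersect(ds$group[ds$age_class == "adult"],
                    ds$group[ds$age_class == "juvenile"])
  sel <- ds$group %in% both
  ang <- centroid_angles(fm$scores[sel, 1:2], ds$group[sel], ds$age_class[sel])
  expect_true(all(ang$angle_deg > 90 & ang$angle_deg < 180))
})
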