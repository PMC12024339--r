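test_that("minimum sustained RMR matches hand-computable traces", {
  expect_equal(min_window_rmr(rep(1.2, 10)), 1.2)
  expect_equal(min_window_rmr(c(5, 5, 5, 5, 5, 1, 1, 1, 1, 1)), 1.0)
  expect_error(min_window_rmr(c(1, 2, 3)), "too short")
})

test_that("minimum sustained RMR equals the exhaustive all-windows oracle", {
  set.seed(101)
  for (r in 1:100) {
    n <- sample(5:15, 1)
    w <- sample(3:5, 1)
    tr <- runif(n, 0.5, 3)
    expect_equal(min_window_rmr(tr, w), brute_min_window(tr, w))
  }
})

test_that("mass-specific conversion is plain division with a guarded domain", {
  expect_equal(to_mass_specific(30, 30), 1.0)
  expect_equal(to_mass_specific(0, 25), 0.0)
  expect_equal(to_mass_specific(45.5, 26.0), 1.75)
  expect_error(to_mass_specific(10, 0), "body_mass")
})

test_that("gradient descent recovers an exact polynomial", {
  pts <- data.frame(chamber_temp = rep(c(37.5, 35, 32.5, 30, 27.5, 25, 20), 2))
  pts$rmr <- 0.1 * (pts$chamber_temp - 30)^2 + 1.0
  fit <- fit_rmr_curve(pts, degree = 2)
  ## expand 0.1 (T - 30)^2 + 1 = 91 - 6 T + 0.1 T^2
  expect_equal(fit$coefficients, c(91, -6, 0.1), tolerance = 1e-6)
  expect_lt(fit$sse, 1e-10)
  expect_true(fit$converged)
})

test_that("gradient descent agrees with closed-form least squares in fitted values", {
  set.seed(202)
  for (r in 1:20) {
    deg <- sample(2:6, 1)
    x <- rep(c(37.5, 35, 32.5, 30, 27.5, 25, 20, 15, 10, 5),
             sample(2:5, 1))
    y <- 1.8 + 0.01 * (x - 30)^2 + rnorm(length(x), 0, 0.2)
    fit <- fit_rmr_curve(data.frame(chamber_temp = x, rmr = y), degree = deg)
    ls <- lm(y ~ poly(x, deg, raw = TRUE))
    expect_lt(max(abs(predict(fit, x) - fitted(ls))), 1e-6)
  }
})

test_that("rank-deficient temperature designs are rejected", {
  one_temp <- data.frame(chamber_temp = rep(30, 12), rmr = runif(12, 1, 2))
  expect_error(fit_rmr_curve(one_temp, degree = 2), "distinct")
  few <- data.frame(chamber_temp = rep(c(30, 25, 20), 2), rmr = runif(6))
  expect_error(fit_rmr_curve(few, degree = 4), "distinct")
})

test_that("TNZ limits of a symmetric parabola match the closed-form roots", {
  pts <- data.frame(chamber_temp = rep(seq(25, 35, 1.25), 2))
  pts$rmr <- 0.05 * (pts$chamber_temp - 30)^2 + 1
  est <- derive_tnz(fit_rmr_curve(pts, degree = 2), delta = 0.02)
  ## 2 a (T - 30) = +/- delta => T = 30 -/+ 0.2
  expect_equal(est$t_min, 30, tolerance = 1e-4)
  expect_equal(est$llt, 29.8, tolerance = 1e-4)
  expect_equal(est$ult, 30.2, tolerance = 1e-4)
  expect_equal(est$tnz_b, 0.4, tolerance = 1e-4)
  expect_identical(est$tnz_b, est$ult - est$llt)
})

test_that("a monotone curve yields a no-TNZ error", {
  curve <- structure(list(coefficients = c(0, 0.1), fit_domain = c(5, 37.5),
                          sse = 0, converged = TRUE, n_iterations = 1,
                          degree = 2),
                     class = "metabolic_curve")
  expect_error(derive_tnz(curve), "no interior minimum")
})

test_that("widening the derivative threshold never narrows the TNZ", {
  set.seed(303)
  x <- rep(c(37.5, 35, 32.5, 30, 27.5, 25, 20, 15, 10, 5), 6)
  y <- scholander_rmr(x, 29, 31, 1.8, -0.22, 0.22) + rnorm(length(x), 0, 0.05)
  curve <- fit_rmr_curve(data.frame(chamber_temp = x, rmr = y))
  deltas <- c(0.02, 0.05, 0.07, 0.1, 0.15)
  ests <- lapply(deltas, function(d) derive_tnz(curve, delta = d))
  llts <- vapply(ests, `[[`, numeric(1), "llt")
  ults <- vapply(ests, `[[`, numeric(1), "ult")
  expect_true(all(diff(llts) <= 1e-9))
  expect_true(all(diff(ults) >= -1e-9))
})

test_that("TNZ estimation is equivariant under temperature shifts", {
  set.seed(304)
  x <- rep(c(37.5, 35, 32.5, 30, 27.5, 25, 20, 15, 10, 5), 4)
  y <- scholander_rmr(x, 29, 31, 1.8, -0.22, 0.22) + rnorm(length(x), 0, 0.03)
  e0 <- derive_tnz(fit_rmr_curve(data.frame(chamber_temp = x, rmr = y)))
  for (shift in c(-3, 5)) {
    e1 <- derive_tnz(fit_rmr_curve(data.frame(chamber_temp = x + shift,
                                              rmr = y)))
    expect_equal(e1$llt, e0$llt + shift, tolerance = 1e-6)
    expect_equal(e1$ult, e0$ult + shift, tolerance = 1e-6)
    expect_equal(e1$t_min, e0$t_min + shift, tolerance = 1e-6)
    expect_equal(e1$tnz_b, e0$tnz_b, tolerance = 1e-6)
    expect_equal(e1$bmr, e0$bmr, tolerance = 1e-6)
  }
})

test_that("population pooling of a single animal reduces to the per-animal estimate", {
  cfg <- synth_config(n_sites = 2, rmr_noise_sd = 0, n_animals_rmr = 1,
                      seed = 41)
  gs <- gen_sites(cfg)
  traces <- gen_rmr_traces(gs$sites, cfg, gs$truth)$traces
  tr1 <- traces[traces$site == "S01", ]
  est <- suppressWarnings(estimate_population_tnz(tr1))
  pts <- rmr_points(tr1)
  direct <- derive_tnz(fit_rmr_curve(pts))
  expect_equal(est$llt, direct$llt, tolerance = 1e-9)
  expect_equal(est$ult, direct$ult, tolerance = 1e-9)
  ## duplicating every point leaves the least-squares fit unchanged
  est2 <- suppressWarnings(estimate_population_tnz(rbind(tr1, tr1)))
  expect_equal(est2$llt, est$llt, tolerance = 1e-7)
  expect_equal(est2$ult, est$ult, tolerance = 1e-7)
})

test_that("per-site estimates report exact breadth and respect ordering invariants", {
  cfg <- synth_config(n_sites = 3, n_animals_rmr = 3, seed = 43)
  sim <- simulate_study(cfg)
  est <- estimate_population_tnz(sim$traces)
  expect_identical(est$tnz_b, est$ult - est$llt)
  expect_true(all(est$llt < est$t_min & est$t_min < est$ult))
  expect_equal(nrow(est), 3)
})

test_that("TNZ breadth estimated across sites declines with AnnMinTemp", {
  ## end-to-end: generator -> respirometry -> curve fit -> site regression
  cfg <- synth_config(seed = 47)
  gs <- gen_sites(cfg)
  traces <- gen_rmr_traces(gs$sites, cfg, gs$truth)$traces
  est <- estimate_population_tnz(traces)
  d <- merge(est, gs$truth[, c("site", "spatial_ann_min_temp")], by = "site")
  fit <- fit_lm(d$tnz_b, d$spatial_ann_min_temp)
  expect_lt(fit$slope, 0)
  expect_lt(fit$p_value, 0.05)
})
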