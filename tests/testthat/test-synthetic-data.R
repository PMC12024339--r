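test_that("site AnnMinTemp follows the configured spatial model exactly when noiseless", {
  cfg <- synth_config(n_sites = 12, temp_noise_sd = 0, seed = 11)
  gs <- gen_sites(cfg)
  fit <- lm(ann_min_temp ~ lon + alt, data = gs$sites)
  expect_equal(unname(coef(fit)),
               c(cfg$temp_intercept, cfg$temp_lon_slope, cfg$temp_alt_slope),
               tolerance = 1e-9)
  ## per degree of longitude, AnnMinTemp moves by the longitude slope
  expect_equal(unname(coef(fit)["lon"]), 0.89, tolerance = 1e-9)
})

test_that("all-zero slopes and noise give a constant AnnMinTemp", {
  cfg <- synth_config(temp_lon_slope = 0, temp_alt_slope = 0,
                      temp_noise_sd = 0, temp_intercept = 12, seed = 2)
  gs <- gen_sites(cfg)
  expect_equal(gs$sites$ann_min_temp, rep(12, cfg$n_sites))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- synth_config(n_sites = 3, n_per_site_year = 5, n_animals_rmr = 2,
                      seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$climate, s2$climate)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$traces, s2$traces)
})

test_that("child streams decouple the generated tables", {
  cfg <- synth_config(n_sites = 3, n_per_site_year = 5, seed = 7)
  gs <- gen_sites(cfg)
  ## generating individuals in between must not change the climate series
  a <- gen_daily_min_series(gs$sites[1, ], cfg$years[1], cfg)
  invisible(gen_individuals(gs$sites, cfg))
  b <- gen_daily_min_series(gs$sites[1, ], cfg$years[1], cfg)
  expect_identical(a, b)
})

test_that("daily series mean equals the site-year ground truth by construction", {
  cfg <- synth_config(n_sites = 2, seed = 5)
  gs <- gen_sites(cfg)
  for (yr in cfg$years) {
    s <- gen_daily_min_series(gs$sites[2, ], yr, cfg)
    target <- gs$sites$ann_min_temp[2] +
      cfg$temp_year_slope * (yr - cfg$years[1])
    expect_equal(mean(s$tmin_C), target, tolerance = 1e-9)
    expect_equal(nrow(s), 365)
  }
})

test_that("flat seasonality and zero noise give a constant daily series", {
  cfg <- synth_config(n_sites = 2, seasonal_amplitude = 0,
                      daily_noise_sd = 0, temp_noise_sd = 0, seed = 5)
  gs <- gen_sites(cfg)
  s <- gen_daily_min_series(gs$sites[1, ], 2022, cfg)
  expect_equal(s$tmin_C, rep(gs$sites$ann_min_temp[1], 365))
})

test_that("the secular trend separates consecutive annual means by its slope", {
  cfg <- synth_config(n_sites = 2, daily_noise_sd = 0, temp_year_slope = 0.26,
                      seed = 8)
  gs <- gen_sites(cfg)
  m22 <- mean(gen_daily_min_series(gs$sites[1, ], 2022, cfg)$tmin_C)
  m23 <- mean(gen_daily_min_series(gs$sites[1, ], 2023, cfg)$tmin_C)
  expect_equal(m23 - m22, 0.26, tolerance = 1e-9)
})

test_that("degenerate ranges and invalid parameters are rejected", {
  expect_error(synth_config(lon_range = c(110, 100)), "degenerate")
  expect_error(synth_config(gamma_shape = -1), "gamma_shape")
  expect_error(synth_config(tnz_base_llt = 35, tnz_base_ult = 30),
               "tnz_base_llt")
  expect_error(synth_config(n_sites = 1), "n_sites")
  expect_error(synth_config(not_a_field = 1), "unknown")
})

test_that("a near-degenerate gamma with zero effects collapses onto the intercept", {
  cfg <- synth_config(n_sites = 2, n_per_site_year = 20, gamma_shape = 1e9,
                      length_temp_slope = 0, temp_noise_sd = 0,
                      sex_effect = c(length = 0, mass = 0),
                      stage_length_effects = c(juvenile = 0, subadult = 0,
                                               adult1 = 0, adult2 = 0,
                                               old = 0),
                      site_re_sd = 0, year_re_sd = 0, temp_year_slope = 0,
                      temp_lon_slope = 0, temp_alt_slope = 0,
                      temp_intercept = 12, length_intercept = 101.88,
                      seed = 3)
  gi <- gen_individuals(gen_sites(cfg)$sites, cfg)
  expect_equal(gi$records$body_length,
               rep(101.88, nrow(gi$records)), tolerance = 1e-3)
})

test_that("generated body lengths match the gamma mean/shape parameterization", {
  cfg <- synth_config(n_sites = 2, n_per_site_year = 3000,
                      length_temp_slope = 0, temp_noise_sd = 0,
                      temp_lon_slope = 0, temp_alt_slope = 0,
                      temp_year_slope = 0, temp_intercept = 12,
                      sex_effect = c(length = 0, mass = 0),
                      stage_length_effects = c(juvenile = 0, subadult = 0,
                                               adult1 = 0, adult2 = 0,
                                               old = 0),
                      site_re_sd = 0, year_re_sd = 0, seed = 21)
  gi <- gen_individuals(gen_sites(cfg)$sites, cfg)
  len <- gi$records$body_length
  n <- length(len)
  expect_gte(n, 5000)
  mu <- cfg$length_intercept
  sigma2 <- mu^2 / cfg$gamma_shape
  ## 3 Monte-Carlo SEs around the theoretical mean and variance
  expect_lt(abs(mean(len) - mu), 3 * sqrt(sigma2 / n))
  se_var <- sqrt(sigma2^2 * (2 / (n - 1) + 6 / (cfg$gamma_shape * n)))
  expect_lt(abs(var(len) - sigma2), 3 * se_var)
})

test_that("stage labels round-trip through classify_stage and pregnancy obeys its probability", {
  cfg <- synth_config(n_sites = 3, n_per_site_year = 50, seed = 13)
  gi <- gen_individuals(gen_sites(cfg)$sites, cfg)
  expect_identical(classify_stage(gi$records$body_mass), gi$records$stage)
  expect_true(all(!gi$records$pregnant | gi$records$sex == "female"))
  cfg0 <- synth_config(n_sites = 3, n_per_site_year = 50,
                       pregnancy_prob = 0, seed = 13)
  gi0 <- gen_individuals(gen_sites(cfg0)$sites, cfg0)
  expect_false(any(gi0$records$pregnant))
})

test_that("a non-positive mean body length aborts generation with advice", {
  cfg <- synth_config(n_sites = 2, length_intercept = -500, seed = 4)
  expect_error(gen_individuals(gen_sites(cfg)$sites, cfg),
               "length_intercept")
})

test_that("ground-truth TNZ breadth equals ULT minus LLT exactly", {
  gs <- gen_sites(synth_config(seed = 6))
  expect_identical(gs$truth$tnz_b, gs$truth$ult - gs$truth$llt)
})

test_that("noiseless traces follow the piecewise Scholander form", {
  cfg <- synth_config(n_sites = 2, rmr_noise_sd = 0, n_animals_rmr = 1,
                      seed = 31)
  gs <- gen_sites(cfg)
  gr <- gen_rmr_traces(gs$sites, cfg, gs$truth)
  tr <- gr$traces[gr$traces$site == "S01", ]
  truth <- gs$truth[gs$truth$site == "S01", ]
  inside <- tr$chamber_temp_C >= truth$llt & tr$chamber_temp_C <= truth$ult
  expect_equal(tr$o2_ml_per_h[inside] / tr$mass_g[inside],
               rep(cfg$bmr_level, sum(inside)), tolerance = 1e-12)
  ## one degree below the LLT the cold limb adds |cold_slope|
  expect_equal(scholander_rmr(truth$llt - 1, truth$llt, truth$ult, 1.8,
                              -0.1, 0.22), 1.9)
  ## inverted limits are rejected
  bad <- gs$truth
  bad$ult <- bad$llt - 1
  expect_error(gen_rmr_traces(gs$sites, cfg, bad), "ULT <= LLT")
})

test_that("the study writer emits readable CSVs and ground-truth YAML", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(synth_config(n_sites = 2, n_per_site_year = 4,
                                     n_animals_rmr = 2, seed = 17))
  paths <- write_synthetic_data(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(file.path(dir, "records.csv"), stringsAsFactors = FALSE)
  expect_equal(back$body_length, sim$records$body_length, tolerance = 1e-12)
  truth <- yaml::read_yaml(file.path(dir, "ground_truth.yaml"))
  expect_equal(unlist(truth$sites$tnz_b),
               sim$truth$sites$tnz_b, tolerance = 1e-9,
               ignore_attr = TRUE)
})
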