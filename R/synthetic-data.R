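#' Generate study sites with known climate ground truth
#'
#' Draws `n_sites` sites uniformly in the configured longitude, latitude and
#' altitude ranges and assigns each a true annual mean minimum temperature
#' (AnnMinTemp) from the linear generating model
#' `temp_intercept + temp_lon_slope * lon + temp_alt_slope * alt + N(0, temp_noise_sd)`.
#' The value refers to the first configured year; later years add
#' `temp_year_slope` per elapsed year (applied by [gen_daily_min_series()]).
#'
#' @param config a [synth_config()].
#' @return A list with `sites` (data.frame: `site`, `lon`, `lat`, `alt`,
#'   `ann_min_temp`) and `truth` (per-site spatial AnnMinTemp and true TNZ
#'   limits, with `tnz_b = ult - llt` exactly).
#' @examples
#' gs <- gen_sites(synth_config(n_sites = 3, temp_noise_sd = 0))
#' gs$sites
#' @export
gen_sites <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  sites <- with_stream(config$seed, "sites", {
    n <- config$n_sites
    lon <- runif(n, config$lon_range[1], config$lon_range[2])
    lat <- runif(n, config$lat_range[1], config$lat_range[2])
    alt <- runif(n, config$alt_range[1], config$alt_range[2])
    ann <- config$temp_intercept + config$temp_lon_slope * lon +
      config$temp_alt_slope * alt + rnorm(n, 0, config$temp_noise_sd)
    data.frame(site = sprintf("S%02d", seq_len(n)),
               lon = lon, lat = lat, alt = alt, ann_min_temp = ann,
               stringsAsFactors = FALSE)
  })
  ## spatial AnnMinTemp = mean over the configured years, including the
  ## secular trend; this is what the TNZ of a population responds to
  elapsed <- mean(config$years - config$years[1])
  spatial <- sites$ann_min_temp + config$temp_year_slope * elapsed
  llt <- config$tnz_base_llt + config$tnz_llt_temp_slope * spatial
  ult <- config$tnz_base_ult + config$tnz_ult_temp_slope * spatial
  truth <- data.frame(site = sites$site,
                      spatial_ann_min_temp = spatial,
                      llt = llt, ult = ult, tnz_b = ult - llt,
                      stringsAsFactors = FALSE)
  list(sites = sites, truth = truth)
}

#' Generate one site-year of daily minimum temperatures
#'
#' Builds a 365-day series as a seasonal sinusoid (coldest in mid-January)
#' plus daily noise, then re-centres it so the annual mean equals the
#' site-year's true AnnMinTemp exactly: the site's base value plus
#' `temp_year_slope` per year elapsed since the first configured year.
#'
#' @param site one row of the `sites` table from [gen_sites()].
#' @param year calendar year; must be in `config$years`.
#' @param config a [synth_config()].
#' @return A data.frame with `site`, `date` (ISO-8601), `tmin_C`.
#' @export
gen_daily_min_series <- function(site, year, config) {
  stopifnot(inherits(config, "synth_config"), nrow(site) == 1)
  if (!year %in% config$years)
    stop("year ", year, " is not in config$years", call. = FALSE)
  target <- site$ann_min_temp +
    config$temp_year_slope * (year - config$years[1])
  tmin <- with_stream(config$seed, paste("climate", site$site, year), {
    doy <- 1:365
    raw <- -config$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365) +
      rnorm(365, 0, config$daily_noise_sd)
    raw - mean(raw) + target # exact centring: only the annual mean matters
  })
  data.frame(site = site$site,
             date = as.Date(sprintf("%d-01-01", year)) + 0:364,
             tmin_C = tmin, stringsAsFactors = FALSE)
}

#' Generate daily minimum temperature series for all site-years
#'
#' @param sites the `sites` table from [gen_sites()].
#' @param config a [synth_config()].
#' @return A long data.frame (`site`, `date`, `tmin_C`), one row per site
#'   per day per configured year.
#' @export
gen_climate <- function(sites, config) {
  out <- lapply(config$years, function(yr)
    do.call(rbind, lapply(seq_len(nrow(sites)), function(i)
      gen_daily_min_series(sites[i, ], yr, config))))
  do.call(rbind, out)
}

#' Generate individual capture records
#'
#' For each site-year draws `n_per_site_year` individuals. Stage is drawn
#' first from `stage_probs`; body mass is then drawn consistently with the
#' stage's mass band (gamma around a band-centred, temperature- and
#' sex-shifted mean, falling back to a uniform draw in the band), so
#' [classify_stage()] round-trips exactly. Body length is gamma with mean
#' `length_intercept + length_temp_slope * AnnMinTemp + sex + stage +
#' site RE + year RE` and shape `gamma_shape` (scale = mean/shape).
#' Non-juvenile females are flagged pregnant with `pregnancy_prob`.
#'
#' @param sites the `sites` table from [gen_sites()].
#' @param config a [synth_config()].
#' @return A list with `records` (data.frame: `id`, `site`, `year`, `sex`,
#'   `stage`, `body_mass`, `body_length`, `pregnant`) and `truth` (realized
#'   site/year random intercepts and the generating coefficients).
#' @export
gen_individuals <- function(sites, config) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(sites) == 0) stop("sites is empty", call. = FALSE)
  bands <- stage_mass_bands()
  with_stream(config$seed, "individuals", {
    site_re <- setNames(rnorm(nrow(sites), 0, config$site_re_sd), sites$site)
    year_re <- setNames(rnorm(length(config$years), 0, config$year_re_sd),
                        as.character(config$years))
    grid <- expand.grid(si = seq_len(nrow(sites)), year = config$years,
                        KEEP.OUT.ATTRS = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(g) {
      si <- grid$si[g]; yr <- grid$year[g]
      n <- config$n_per_site_year
      t_sy <- sites$ann_min_temp[si] +
        config$temp_year_slope * (yr - config$years[1])
      sex <- sample(c("female", "male"), n, replace = TRUE)
      stage <- sample(bands$stage, n, replace = TRUE,
                      prob = config$stage_probs[bands$stage])
      mu_len <- config$length_intercept +
        config$length_temp_slope * t_sy +
        config$sex_effect[["length"]] * (sex == "male") +
        unname(config$stage_length_effects[stage]) +
        site_re[sites$site[si]] + year_re[as.character(yr)]
      if (any(mu_len <= 0))
        stop("non-positive mean body length generated; increase ",
             "length_intercept (identity-link positivity)", call. = FALSE)
      len <- rgamma(n, shape = config$gamma_shape,
                    scale = mu_len / config$gamma_shape)
      b <- bands[match(stage, bands$stage), ]
      mu_mass <- (b$lo + b$hi) / 2 +
        config$mass_temp_slope * (t_sy - config$mass_ref_temp) +
        config$sex_effect[["mass"]] * (sex == "male")
      pad <- 0.05 * (b$hi - b$lo)
      mu_mass <- pmin(pmax(mu_mass, b$lo + pad), b$hi - pad)
      mass <- draw_banded_gamma(mu_mass, config$gamma_shape, stage, b)
      preg <- sex == "female" & stage != "juvenile" &
        runif(n) < config$pregnancy_prob
      data.frame(site = sites$site[si], year = yr, sex = sex, stage = stage,
                 body_mass = mass, body_length = len, pregnant = preg,
                 stringsAsFactors = FALSE)
    })
    records <- do.call(rbind, rows)
    records <- cbind(id = sprintf("I%05d", seq_len(nrow(records))), records)
    truth <- list(site_re = site_re, year_re = year_re,
                  length_temp_slope = config$length_temp_slope,
                  mass_temp_slope = config$mass_temp_slope,
                  sex_effect = config$sex_effect,
                  stage_length_effects = config$stage_length_effects)
    list(records = records, truth = truth)
  })
}

## Gamma draws constrained to each record's stage band: accept a draw iff it
## classifies back to the assigned stage; after `tries` rejections fall back
## to a uniform draw strictly inside the band.
draw_banded_gamma <- function(mu, shape, stage, bands, tries = 50) {
  n <- length(mu)
  out <- rep(NA_real_, n)
  todo <- seq_len(n)
  for (k in seq_len(tries)) {
    if (!length(todo)) break
    cand <- rgamma(length(todo), shape = shape, scale = mu[todo] / shape)
    ok <- classify_stage(pmax(cand, 1e-6)) == stage[todo]
    out[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  if (length(todo)) {
    pad <- 0.02 * (bands$hi[todo] - bands$lo[todo])
    out[todo] <- runif(length(todo), bands$lo[todo] + pad,
                       bands$hi[todo] - pad)
  }
  out
}

#' Piecewise-linear Scholander metabolic curve
#'
#' Mass-specific resting metabolic rate as a function of ambient
#' temperature: `bmr + cold_slope * (T - llt)` below the lower limit
#' temperature, flat at `bmr` inside the thermoneutral zone, and
#' `bmr + warm_slope * (T - ult)` above the upper limit temperature.
#'
#' @param temp ambient temperature(s), degC.
#' @param llt,ult lower and upper limit temperatures, degC (`llt < ult`).
#' @param bmr basal metabolic rate, mL O2 g^-1 h^-1.
#' @param cold_slope,warm_slope limb slopes (`cold_slope < 0 < warm_slope`).
#' @return Mass-specific RMR, mL O2 g^-1 h^-1.
#' @examples
#' scholander_rmr(c(25, 30, 35), llt = 29, ult = 31, bmr = 1.8,
#'                cold_slope = -0.22, warm_slope = 0.22)
#' @export
scholander_rmr <- function(temp, llt, ult, bmr, cold_slope, warm_slope) {
  stopifnot(llt < ult)
  ifelse(temp < llt, bmr + cold_slope * (temp - llt),
         ifelse(temp > ult, bmr + warm_slope * (temp - ult), bmr))
}

#' Generate respirometry traces for every site
#'
#' For each site, `n_animals_rmr` animals are measured at the chamber
#' temperature schedule in `config$chamber_temps` (descending from 37.5 degC
#' in 2.5 degC steps to 25 degC, then 5 degC steps to 5 degC). The
#' underlying mass-specific RMR follows [scholander_rmr()] with the site's
#' true limits; each of `trace_minutes` per-minute readings adds
#' `N(0, rmr_noise_sd)` mass-specific noise before conversion to
#' whole-animal mL O2 h^-1.
#'
#' @param sites the `sites` table from [gen_sites()].
#' @param config a [synth_config()].
#' @param truth optional `truth` table from [gen_sites()]; recomputed if
#'   missing.
#' @return A list with `traces` (long data.frame: `animal_id`, `site`,
#'   `mass_g`, `chamber_temp_C`, `minute`, `o2_ml_per_h`) and `truth`.
#' @export
gen_rmr_traces <- function(sites, config, truth = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(truth)) {
    elapsed <- mean(config$years - config$years[1])
    spatial <- sites$ann_min_temp + config$temp_year_slope * elapsed
    truth <- data.frame(site = sites$site,
                        spatial_ann_min_temp = spatial,
                        llt = config$tnz_base_llt +
                          config$tnz_llt_temp_slope * spatial,
                        ult = config$tnz_base_ult +
                          config$tnz_ult_temp_slope * spatial,
                        stringsAsFactors = FALSE)
    truth$tnz_b <- truth$ult - truth$llt
  }
  if (any(truth$ult <= truth$llt))
    stop("ULT <= LLT after applying TNZ temperature slopes; ",
         "widen tnz_base_* or flatten the slopes", call. = FALSE)
  traces <- with_stream(config$seed, "rmr", {
    rows <- lapply(seq_len(nrow(sites)), function(si) {
      st <- sites$site[si]
      tr <- truth[truth$site == st, ]
      mass <- runif(config$n_animals_rmr, config$rmr_mass_range[1],
                    config$rmr_mass_range[2])
      per_animal <- lapply(seq_len(config$n_animals_rmr), function(a) {
        per_temp <- lapply(config$chamber_temps, function(tc) {
          base <- scholander_rmr(tc, tr$llt, tr$ult, config$bmr_level,
                                 config$cold_slope, config$warm_slope)
          ms <- base + rnorm(config$trace_minutes, 0, config$rmr_noise_sd)
          data.frame(animal_id = sprintf("%s_A%02d", st, a), site = st,
                     mass_g = mass[a], chamber_temp_C = tc,
                     minute = seq_len(config$trace_minutes),
                     o2_ml_per_h = pmax(ms, 0) * mass[a],
                     stringsAsFactors = FALSE)
        })
        do.call(rbind, per_temp)
      })
      do.call(rbind, per_animal)
    })
    do.call(rbind, rows)
  })
  list(traces = traces, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Runs [gen_sites()], [gen_climate()], [gen_individuals()] and
#' [gen_rmr_traces()] under one root seed with independent child streams,
#' returning every table plus the combined ground truth. Identical configs
#' give bitwise-identical results.
#'
#' @param config a [synth_config()].
#' @return A list: `config`, `sites`, `climate`, `records`, `traces`,
#'   `truth` (list with `sites` ground-truth table, realized random
#'   intercepts and generating coefficients).
#' @examples
#' sim <- simulate_study(synth_config(n_sites = 3, n_per_site_year = 5,
#'                                    n_animals_rmr = 2, seed = 7))
#' head(sim$records)
#' @export
simulate_study <- function(config = synth_config()) {
  gs <- gen_sites(config)
  climate <- gen_climate(gs$sites, config)
  gi <- gen_individuals(gs$sites, config)
  gr <- gen_rmr_traces(gs$sites, config, gs$truth)
  list(config = config,
       sites = gs$sites,
       climate = climate,
       records = gi$records,
       traces = gr$traces,
       truth = c(list(sites = gs$truth), gi$truth))
}

#' Write a simulated study to CSV/YAML files
#'
#' Writes `sites.csv`, `climate_daily.csv`, `records.csv`,
#' `rmr_traces.csv` and `ground_truth.yaml` into `dir`.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_synthetic_data <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("sites.csv", "climate_daily.csv", "records.csv",
                            "rmr_traces.csv", "ground_truth.yaml"))
  write.csv(sim$sites, paths[1], row.names = FALSE)
  cl <- sim$climate
  cl$date <- format(cl$date, "%Y-%m-%d")
  write.csv(cl, paths[2], row.names = FALSE)
  write.csv(sim$records, paths[3], row.names = FALSE)
  write.csv(sim$traces, paths[4], row.names = FALSE)
  truth <- sim$truth
  truth$sites <- as.list(truth$sites)
  truth$site_re <- as.list(truth$site_re)
  truth$year_re <- as.list(truth$year_re)
  truth$sex_effect <- as.list(truth$sex_effect)
  truth$stage_length_effects <- as.list(truth$stage_length_effects)
  yaml::write_yaml(truth, paths[5], precision = 15)
  invisible(paths)
}
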