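#' Configuration for the synthetic ecophysiology data generator
#'
#' Bundles every generating parameter for the synthetic study: site
#' geography and its link to the annual mean minimum temperature
#' (AnnMinTemp), gamma-distributed body sizes with sex/stage effects and
#' site/year random intercepts, and Scholander-type resting-metabolic-rate
#' (RMR) curves whose limit temperatures shift with site climate.
#'
#' Defaults emulate the field system the package targets: nine striped
#' field mouse populations along a subtropical elevation gradient, sampled
#' in 2022-2023, with AnnMinTemp rising 0.89 degC per degree of longitude,
#' falling 2.32 degC per km of altitude and warming 0.26 degC per year;
#' body length rising 0.99 mm per degC of AnnMinTemp; and a thermoneutral
#' zone whose lower limit rises (+0.15 degC/degC) and upper limit falls
#' (-0.19 degC/degC) with AnnMinTemp, so its breadth narrows by 0.34 degC
#' per degC. The Scholander curve floors at a basal metabolic rate of
#' 1.8 mL O2 g^-1 h^-1 with limb slopes of -/+ 0.22 mL O2 g^-1 h^-1 per
#' degC (cold limb from the extrapolation-to-body-temperature rule,
#' BMR / (T_b - LLT) with T_b ~ 37 degC).
#'
#' @param ... named overrides of any default listed below.
#' @return An object of class `synth_config` (a validated named list).
#'
#' @section Main fields:
#' \describe{
#'   \item{n_sites, lon_range, lat_range, alt_range}{site count and uniform
#'     sampling ranges (degE, degN, km).}
#'   \item{temp_intercept, temp_lon_slope, temp_alt_slope, temp_year_slope,
#'     temp_noise_sd}{linear model generating site AnnMinTemp (degC).}
#'   \item{years, n_per_site_year}{calendar years and captures per
#'     site-year.}
#'   \item{length_intercept, length_temp_slope, mass_temp_slope, sex_effect,
#'     stage_length_effects, stage_probs}{body-size linear predictors (mm,
#'     g).}
#'   \item{site_re_sd, year_re_sd, gamma_shape, pregnancy_prob}{random
#'     intercept SDs, gamma shape (mean/shape parameterisation), pregnancy
#'     probability.}
#'   \item{tnz_base_llt, tnz_base_ult, tnz_llt_temp_slope,
#'     tnz_ult_temp_slope}{site TNZ limits as linear functions of
#'     AnnMinTemp (degC).}
#'   \item{bmr_level, cold_slope, warm_slope, rmr_noise_sd, chamber_temps,
#'     trace_minutes, n_animals_rmr}{respirometry-trace generation
#'     (mL O2 g^-1 h^-1 and degC).}
#'   \item{seasonal_amplitude, daily_noise_sd}{shape of the daily
#'     minimum-temperature series (degC).}
#'   \item{seed}{root seed; identical configs give bitwise-identical
#'     output.}
#' }
#' @examples
#' cfg <- synth_config(n_sites = 4, seed = 1)
#' cfg$temp_lon_slope
#' @export
synth_config <- function(...) {
  defaults <- list(
    n_sites = 9,
    lon_range = c(105.5, 108.5),   # degE
    lat_range = c(24.6, 29.2),     # degN
    alt_range = c(0.3, 1.45),      # km
    temp_intercept = -80.9,        # degC at lon 0, alt 0
    temp_lon_slope = 0.89,         # degC per degE
    temp_alt_slope = -2.32,        # degC per km
    temp_year_slope = 0.26,        # degC per elapsed year
    temp_noise_sd = 0.3,           # degC, site-level
    years = c(2022, 2023),
    n_per_site_year = 10,
    length_intercept = 90,         # mm at AnnMinTemp 0, female sub-adult
    length_temp_slope = 0.99,      # mm per degC
    mass_temp_slope = 0.44,        # g per degC
    mass_ref_temp = 12,            # degC anchor for the mass predictor
    sex_effect = c(length = 2, mass = 1),       # male minus female
    stage_length_effects = c(juvenile = -25, subadult = 0,
                             adult1 = 6, adult2 = 12, old = 18), # mm
    stage_probs = c(juvenile = 0.10, subadult = 0.25,
                    adult1 = 0.30, adult2 = 0.25, old = 0.10),
    site_re_sd = 1,                # mm
    year_re_sd = 0.5,              # mm
    gamma_shape = 400,             # CV = 1/sqrt(shape) = 5%
    pregnancy_prob = 0.15,
    tnz_base_llt = 27.6,           # degC at AnnMinTemp 0
    tnz_base_ult = 33.7,
    tnz_llt_temp_slope = 0.15,     # degC per degC AnnMinTemp
    tnz_ult_temp_slope = -0.19,
    bmr_level = 1.8,               # mL O2 g^-1 h^-1
    cold_slope = -0.22,            # mL O2 g^-1 h^-1 per degC, below LLT
    warm_slope = 0.22,             # above ULT
    rmr_noise_sd = 0.05,           # mL O2 g^-1 h^-1, per minute reading
    chamber_temps = c(37.5, 35, 32.5, 30, 27.5, 25, 20, 15, 10, 5),
    trace_minutes = 10,
    n_animals_rmr = 6,
    rmr_mass_range = c(24, 35),    # g, adults used in respirometry
    seasonal_amplitude = 8,        # degC
    daily_noise_sd = 2,            # degC
    seed = 1234
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown synth_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(defaults, over)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  chk_range <- function(r, what) {
    if (length(r) != 2 || r[1] > r[2])
      stop("degenerate ", what, ": min > max", call. = FALSE)
  }
  chk_range(cfg$lon_range, "lon_range")
  chk_range(cfg$lat_range, "lat_range")
  chk_range(cfg$alt_range, "alt_range")
  sds <- c(cfg$temp_noise_sd, cfg$site_re_sd, cfg$year_re_sd,
           cfg$rmr_noise_sd, cfg$daily_noise_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (cfg$gamma_shape <= 0) stop("gamma_shape must be > 0", call. = FALSE)
  if (cfg$tnz_base_llt >= cfg$tnz_base_ult)
    stop("tnz_base_llt must be < tnz_base_ult", call. = FALSE)
  if (cfg$n_sites < 2) stop("n_sites must be >= 2", call. = FALSE)
  if (cfg$pregnancy_prob < 0 || cfg$pregnancy_prob > 1)
    stop("pregnancy_prob must be in [0, 1]", call. = FALSE)
  if (cfg$trace_minutes < 5)
    stop("trace_minutes must be >= 5 (minimum RMR window)", call. = FALSE)
  if (abs(cfg$seed) >= MOD31) stop("seed must be below 2^31", call. = FALSE)
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>", x$n_sites, "sites,",
      paste(range(x$years), collapse = "-"), "|",
      x$n_per_site_year, "captures/site-year | seed", x$seed, "\n")
  cat("  AnnMinTemp slopes: lon", x$temp_lon_slope, "degC/degE, alt",
      x$temp_alt_slope, "degC/km, year", x$temp_year_slope, "degC/yr\n")
  cat("  body length slope:", x$length_temp_slope, "mm/degC; TNZ slopes:",
      x$tnz_llt_temp_slope, "(LLT),", x$tnz_ult_temp_slope, "(ULT)\n")
  invisible(x)
}

## Stage body-mass bands (g): juvenile [0,16) < sub-adult [16,23] <
## adult I (23,29] < adult II (29,37] < old (37,Inf).
stage_mass_bands <- function() {
  data.frame(stage = c("juvenile", "subadult", "adult1", "adult2", "old"),
             lo = c(8, 16, 23, 29, 37),
             hi = c(16, 23, 29, 37, 48),
             stringsAsFactors = FALSE)
}

stage_levels <- function() c("juvenile", "subadult", "adult1", "adult2", "old")
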