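## AnnMinTemp aggregation from daily minimum temperature series, and the
## linear trend/effect models around it.

#' Annual mean minimum temperature for one site-year
#'
#' Arithmetic mean of the daily minimum temperatures falling in the given
#' calendar year at the given site. A completeness guard rejects site-years
#' with fewer than `min_days` daily values, which would otherwise yield a
#' seasonally biased mean.
#'
#' @param climate data.frame with columns `site`, `date` (Date or
#'   ISO-8601 character), `tmin_C`.
#' @param site site identifier.
#' @param year calendar year.
#' @param min_days completeness guard (default 300 days).
#' @return AnnMinTemp in degC.
#' @export
annual_min_temp <- function(climate, site, year, min_days = 300) {
  stopifnot(all(c("site", "date", "tmin_C") %in% names(climate)))
  dates <- as.Date(climate$date)
  sel <- climate$site == site & as.integer(format(dates, "%Y")) == year
  n <- sum(sel)
  if (n < min_days)
    stop("incomplete year: site ", site, ", year ", year, " has only ", n,
         " daily values (need >= ", min_days, ")", call. = FALSE)
  mean(climate$tmin_C[sel])
}

#' AnnMinTemp per site-year for all complete site-years
#'
#' @param climate daily series (see [annual_min_temp()]).
#' @param min_days completeness guard.
#' @return A data.frame `site`, `year`, `ann_min_temp`, one row per
#'   complete site-year (incomplete site-years are dropped silently).
#' @export
site_climate_table <- function(climate, min_days = 300) {
  dates <- as.Date(climate$date)
  yr <- as.integer(format(dates, "%Y"))
  agg <- aggregate(list(ann_min_temp = climate$tmin_C, n_days = rep(1, nrow(climate))),
                   by = list(site = climate$site, year = yr),
                   FUN = function(v) sum(v))
  ## aggregate() summed both columns; recover the mean from sum / n
  agg$ann_min_temp <- agg$ann_min_temp / agg$n_days
  agg <- agg[agg$n_days >= min_days, c("site", "year", "ann_min_temp")]
  agg[order(agg$site, agg$year), ]
}

#' Spatial AnnMinTemp for one site
#'
#' The site-level AnnMinTemp used in the spatial analyses: the mean of the
#' annual values of the listed years (by default 2022 and 2023).
#'
#' @param climate daily series (see [annual_min_temp()]).
#' @param site site identifier.
#' @param years the years to average (default `c(2022, 2023)`).
#' @param min_days completeness guard per year.
#' @return Mean AnnMinTemp in degC.
#' @export
spatial_ann_min_temp <- function(climate, site, years = c(2022, 2023),
                                 min_days = 300) {
  vals <- vapply(years, function(yr) {
    tryCatch(annual_min_temp(climate, site, yr, min_days),
             error = function(e) stop("site ", site, ": missing or ",
                                      "incomplete year ", yr, call. = FALSE))
  }, numeric(1))
  mean(vals)
}

#' Spatial AnnMinTemp table for all sites
#'
#' @inheritParams spatial_ann_min_temp
#' @return data.frame `site`, `ann_min_temp`.
#' @export
spatial_climate_table <- function(climate, years = c(2022, 2023),
                                  min_days = 300) {
  sites <- sort(unique(climate$site))
  data.frame(site = sites,
             ann_min_temp = vapply(sites, function(s)
               spatial_ann_min_temp(climate, s, years, min_days),
               numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simple linear regression with slope inference
#'
#' Ordinary least squares of `y` on a single continuous predictor `x`
#' (fit via [stats::lm()]), returning the slope, its standard error from
#' the residual variance, the two-sided t test on the slope, and R^2.
#'
#' @param y response values.
#' @param x predictor values (non-constant, `length(x) >= 3`).
#' @return An object of class `linear_fit`: `intercept`, `slope`,
#'   `slope_se`, `t_statistic`, `p_value`, `r_squared`, `n`.
#' @examples
#' fit_lm(c(0, 1, 2), c(0, 1, 2))$slope
#' @export
fit_lm <- function(y, x) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3) stop("need at least 3 complete observations", call. = FALSE)
  if (var(x) == 0)
    stop("constant predictor: slope is not identifiable", call. = FALSE)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 slope_se = sm$coefficients["x", "Std. Error"],
                 t_statistic = sm$coefficients["x", "t value"],
                 p_value = sm$coefficients["x", "Pr(>|t|)"],
                 r_squared = sm$r.squared,
                 n = n),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope %.4g +/- %.4g (t = %.3g, p = %.3g), R2 = %.3f, n = %d\n",
              x$slope, x$slope_se, x$t_statistic, x$p_value, x$r_squared,
              x$n))
  invisible(x)
}

linear_fit_row <- function(fit, model, response, predictor, scale) {
  data.frame(model = model, response = response, predictor = predictor,
             scale = scale, intercept = fit$intercept, slope = fit$slope,
             se = fit$slope_se, t = fit$t_statistic, p = fit$p_value,
             r_squared = fit$r_squared, n = fit$n,
             stringsAsFactors = FALSE)
}

#' Linear trend models for AnnMinTemp
#'
#' Fits the climate trend battery: spatially, site-level AnnMinTemp against
#' latitude, longitude and altitude; temporally, site-year AnnMinTemp
#' against year (per site). Each model is reported on the natural predictor
#' scale (degC per unit) and with the predictor standardized.
#'
#' @param site_climate data.frame `site`, `year`, `ann_min_temp` from
#'   [site_climate_table()].
#' @param sites site table with `site`, `lat`, `lon`, `alt`.
#' @param spatial_years years averaged for the spatial site-level value.
#' @return A tidy data.frame of fits (one row per model x scale).
#' @export
climate_trend_models <- function(site_climate, sites,
                                 spatial_years = c(2022, 2023)) {
  sp <- site_climate[site_climate$year %in% spatial_years, ]
  spm <- aggregate(list(ann_min_temp = sp$ann_min_temp),
                   by = list(site = sp$site), FUN = mean)
  spm <- merge(spm, sites[, c("site", "lat", "lon", "alt")], by = "site")
  rows <- list()
  for (pred in c("lat", "lon", "alt")) {
    x <- spm[[pred]]
    rows[[length(rows) + 1]] <- linear_fit_row(
      fit_lm(spm$ann_min_temp, x), "spatial_trend", "ann_min_temp", pred,
      "natural")
    rows[[length(rows) + 1]] <- linear_fit_row(
      fit_lm(spm$ann_min_temp, standardize(x)), "spatial_trend",
      "ann_min_temp", pred, "standardized")
  }
  for (st in unique(site_climate$site)) {
    d <- site_climate[site_climate$site == st, ]
    if (nrow(d) >= 3 && var(d$year) > 0) {
      rows[[length(rows) + 1]] <- linear_fit_row(
        fit_lm(d$ann_min_temp, d$year), "temporal_trend",
        paste0("ann_min_temp@", st), "year", "natural")
    }
  }
  do.call(rbind, rows)
}

#' Effect of AnnMinTemp on thermoneutral-zone parameters
#'
#' Fits the three site-level effect models — ULT, LLT and TNZ breadth each
#' regressed on AnnMinTemp — reported on both the natural (degC per degC)
#' and the standardized predictor scale.
#'
#' @param tnz_estimates data.frame from [estimate_population_tnz()] (needs
#'   `site`, `llt`, `ult`, `tnz_b`).
#' @param site_climate data.frame `site`, `ann_min_temp` (spatial values,
#'   e.g. [spatial_climate_table()]).
#' @return A tidy data.frame of six fits (3 responses x 2 scales).
#' @export
tnz_effect_models <- function(tnz_estimates, site_climate) {
  d <- merge(tnz_estimates, site_climate, by = "site")
  if (nrow(d) < 3)
    stop("effect models need >= 3 sites with both a TNZ estimate and a ",
         "climate value (got ", nrow(d), ")", call. = FALSE)
  rows <- list()
  for (resp in c("ult", "llt", "tnz_b")) {
    rows[[length(rows) + 1]] <- linear_fit_row(
      fit_lm(d[[resp]], d$ann_min_temp), "tnz_effect", resp,
      "ann_min_temp", "natural")
    rows[[length(rows) + 1]] <- linear_fit_row(
      fit_lm(d[[resp]], standardize(d$ann_min_temp)), "tnz_effect", resp,
      "ann_min_temp", "standardized")
  }
  do.call(rbind, rows)
}
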