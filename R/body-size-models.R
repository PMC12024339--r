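## Stage classification, record filters, and gamma identity-link mixed
## models for body length and mass.

#' Classify individuals into ontogenetic stages by body mass
#'
#' Body-mass bands: juvenile `[0, 16)` g, sub-adult `[16, 23]` g, adult I
#' `(23, 29]` g, adult II `(29, 37]` g, old `(37, Inf)` g. The published
#' band description gives adult I a lower bound of 16 g, which overlaps
#' the sub-adult band; by default the overlap is resolved as a
#' typographical slip (adult I starts above 23 g). Setting
#' `adult1_lower = 16` honours the printed bound instead, with the overlap
#' assigned to sub-adult.
#'
#' @param body_mass numeric vector of body masses in g (> 0).
#' @param adult1_lower lower bound of the adult I band (23 or 16).
#' @return Character vector of stages: `"juvenile"`, `"subadult"`,
#'   `"adult1"`, `"adult2"`, `"old"`.
#' @examples
#' classify_stage(c(10, 20, 25, 30, 37.5))
#' @export
classify_stage <- function(body_mass, adult1_lower = 23) {
  if (any(!is.finite(body_mass)) || any(body_mass <= 0))
    stop("body_mass must be positive and finite", call. = FALSE)
  out <- ifelse(body_mass < 16, "juvenile",
         ifelse(body_mass <= 23, "subadult",
         ifelse(body_mass <= 29, "adult1",
         ifelse(body_mass <= 37, "adult2", "old"))))
  if (adult1_lower == 16) {
    ## printed band: adult I = (16, 29]; overlap (16, 23] stays sub-adult,
    ## so the default and the printed reading coincide in practice
    out
  } else if (adult1_lower != 23) {
    stop("adult1_lower must be 23 (default) or 16 (printed band)",
         call. = FALSE)
  } else out
}

#' Drop records unsuitable for body-size modelling
#'
#' Removes juveniles, old individuals (stages not caught in every
#' site-year) and pregnant females (pregnancy confounds body mass),
#' reporting the number dropped per reason.
#'
#' @param records data.frame with at least `stage` and `pregnant`.
#' @return The retained records, with the per-reason drop counts attached
#'   as attribute `"drop_counts"` and reported via [message()].
#' @examples
#' r <- data.frame(stage = c("juvenile", "old", "adult1", "adult1",
#'                           "subadult", "adult2"),
#'                 pregnant = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
#' nrow(filter_records(r)) # 3
#' @export
filter_records <- function(records) {
  stopifnot(all(c("stage", "pregnant") %in% names(records)))
  juv <- records$stage == "juvenile"
  old <- records$stage == "old"
  preg <- !juv & !old & records$pregnant
  keep <- !(juv | old | preg)
  counts <- c(juvenile = sum(juv), old = sum(old), pregnant = sum(preg))
  message("filter_records: dropped ", counts["juvenile"], " juvenile, ",
          counts["old"], " old, ", counts["pregnant"],
          " pregnant; retained ", sum(keep), " of ", nrow(records))
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0)
    stop("all records excluded: nothing left to model", call. = FALSE)
  attr(out, "drop_counts") <- counts
  out
}

#' Standardize a continuous predictor
#'
#' Centres to mean 0 and scales to sample standard deviation 1 (n - 1
#' denominator), the convention used for every continuous predictor in the
#' regression models.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return The standardized vector.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(values) {
  if (length(unique(values[is.finite(values)])) < 2)
    stop("cannot standardize a constant vector", call. = FALSE)
  (values - mean(values)) / sd(values)
}

#' Centred study year
#'
#' Years elapsed since the start of the study period (the first year
#' becomes 0, the next 1, and so on, preserving gaps).
#'
#' @param year vector of calendar years.
#' @param origin study start (default `min(year)`).
#' @return Integer years since `origin`.
#' @examples
#' cyear(c(2013, 2014, 2020)) # 0 1 7
#' @export
cyear <- function(year, origin = min(year)) year - origin

#' Gamma identity-link mixed model for body size
#'
#' Fits a generalised linear mixed model with a gamma response
#' distribution and an identity link: the mean body size is a linear
#' function of one continuous predictor plus sex and stage fixed effects
#' and a single random intercept (site or year). Estimation maximises the
#' Laplace-approximated marginal likelihood via [glmmTMB::glmmTMB()],
#' started at an all-intercept fit so every initial conditional mean is
#' positive. Wald tests use a t reference with between-within denominator
#' degrees of freedom: terms constant within grouping levels are tested
#' against `n_groups - (number of group-level fixed terms)` df,
#' observation-level terms against `n_obs - p` df.
#'
#' @param data data.frame of (filtered) records plus any joined
#'   predictors; must contain the response, `sex`, `stage`, the grouping
#'   variable, and the predictor if given.
#' @param response name of the response column (e.g. `"body_length"`).
#' @param predictor name of the continuous predictor column, or `NULL`
#'   for the null (Sex + Stage only) model.
#' @param random name of the grouping column (`"site"` or `"year"`).
#' @param standardize_predictor if `TRUE`, the predictor is standardized
#'   before fitting (the natural-scale slope is still reported alongside).
#' @param fix_re_sd optionally fix the random-intercept SD at this value
#'   (0 is mapped to 1e-8, giving a fit equivalent to a plain gamma GLM).
#' @return An object of class `gamma_glmm_fit`: `coefficients` (data.frame
#'   `term`, `estimate`, `se`, `statistic`, `df`, `p_value`),
#'   `slope`, `slope_se`, `slope_p`, `slope_std` (slope x SD(x)/1 on the
#'   standardized-predictor scale), `random_intercept_sd`, `gamma_shape`,
#'   `log_likelihood`, `n_obs`, `n_groups`, `converged`, plus the
#'   underlying `model`.
#' @export
fit_gamma_glmm <- function(data, response, predictor = NULL,
                           random = "site", standardize_predictor = FALSE,
                           fix_re_sd = NULL) {
  stopifnot(response %in% names(data), random %in% names(data),
            all(c("sex", "stage") %in% names(data)))
  y <- data[[response]]
  if (any(!is.finite(y) | y <= 0))
    stop("response '", response, "' must be positive (gamma family)",
         call. = FALSE)
  d <- data
  d$.y <- y
  d$.grp <- factor(d[[random]])
  if (nlevels(d$.grp) < 2)
    stop("fewer than 2 grouping levels in '", random,
         "'; fit a plain gamma GLM instead", call. = FALSE)
  d$sex <- factor(d$sex, levels = c("female", "male"))
  d$stage <- factor(d$stage,
                    levels = intersect(stage_levels(), unique(d$stage)))
  if (!is.null(predictor)) {
    x_nat <- d[[predictor]]
    d$.x <- if (standardize_predictor) standardize(x_nat) else x_nat
    form <- .y ~ .x + sex + stage + (1 | .grp)
  } else {
    form <- .y ~ sex + stage + (1 | .grp)
  }
  nfix <- ncol(stats::model.matrix(stats::update(form, . ~ . - (1 | .grp)),
                                   d))
  args <- list(formula = form, data = d,
               family = stats::Gamma(link = "identity"),
               start = list(beta = c(mean(d$.y), rep(0, nfix - 1))))
  if (!is.null(fix_re_sd)) {
    args$start$theta <- log(max(fix_re_sd, 1e-8))
    args$map <- list(theta = factor(NA))
  }
  fit <- do.call(glmmTMB::glmmTMB, args)
  sm <- summary(fit)$coefficients$cond
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  stat <- est / se
  ## between-within df: group-level terms (constant within groups) are
  ## tested on the between-group scale
  X <- stats::model.matrix(fit)
  grp <- if (nrow(X) == nrow(d)) d$.grp else
    d$.grp[as.integer(rownames(X))]
  is_grp_level <- apply(X, 2, function(col)
    all(tapply(col, grp, function(v) max(v) - min(v)) < 1e-12))
  n_grp <- nlevels(d$.grp)
  df <- ifelse(is_grp_level, max(n_grp - sum(is_grp_level), 1),
               nrow(d) - ncol(X))
  pv <- 2 * pt(-abs(stat), df)
  coefs <- data.frame(term = rownames(sm), estimate = unname(est),
                      se = unname(se), statistic = unname(stat),
                      df = unname(df), p_value = unname(pv),
                      stringsAsFactors = FALSE)
  mu <- fitted(fit)
  slope <- slope_se <- slope_p <- slope_std <- NA_real_
  if (!is.null(predictor)) {
    i <- match(".x", coefs$term)
    slope <- coefs$estimate[i]; slope_se <- coefs$se[i]
    slope_p <- coefs$p_value[i]
    if (standardize_predictor) {
      ## recover the natural-scale slope for reporting symmetry
      slope <- slope / sd(x_nat)
      slope_se <- slope_se / sd(x_nat)
    }
    ## fully standardized (dimensionless) path coefficient
    slope_std <- slope * sd(x_nat) / sd(y)
    coefs$term[i] <- predictor
  }
  structure(list(coefficients = coefs,
                 slope = slope, slope_se = slope_se, slope_p = slope_p,
                 slope_std = slope_std,
                 random_intercept_sd =
                   sqrt(glmmTMB::VarCorr(fit)$cond$.grp[1]),
                 gamma_shape = 1 / sigma(fit)^2,
                 log_likelihood = as.numeric(logLik(fit)),
                 n_obs = nrow(d), n_groups = n_grp,
                 converged = isTRUE(fit$fit$convergence == 0) &&
                   all(mu > 0),
                 response = response, predictor = predictor,
                 random = random, model = fit),
            class = "gamma_glmm_fit")
}

#' @export
print.gamma_glmm_fit <- function(x, ...) {
  cat("<gamma_glmm_fit>", x$response, "~",
      if (is.null(x$predictor)) "1" else x$predictor,
      "+ sex + stage + (1 |", x$random, ")\n")
  if (!is.null(x$predictor))
    cat(sprintf("  slope %.4g +/- %.4g (p = %.3g), standardized %.3g\n",
                x$slope, x$slope_se, x$slope_p, x$slope_std))
  cat(sprintf("  RE sd %.3g, gamma shape %.4g, logLik %.2f, n = %d in %d groups%s\n",
              x$random_intercept_sd, x$gamma_shape, x$log_likelihood,
              x$n_obs, x$n_groups,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' Full battery of body-size trend and effect models
#'
#' Fits, for body length and body mass: the spatial trend models
#' (predictor latitude, longitude or altitude; site random intercept), the
#' temporal trend model (cYear; year random intercept), and the effect
#' models (AnnMinTemp or TNZ breadth; site random intercept for the
#' spatial dataset, year for the temporal). Each fit reports the slope on
#' the natural scale and standardized.
#'
#' @param records filtered capture records (see [filter_records()]).
#' @param sites site table (`site`, `lat`, `lon`, `alt`).
#' @param site_climate site-year AnnMinTemp ([site_climate_table()]).
#' @param tnz_estimates per-site TNZ table ([estimate_population_tnz()]);
#'   optional (TNZ effect models are skipped when `NULL`).
#' @param spatial_years years averaged for spatial AnnMinTemp.
#' @return A tidy data.frame: `dataset`, `response`, `predictor`, `slope`,
#'   `se`, `p`, `slope_std`, `n`, `n_groups`, `converged`. Failed fits are
#'   skipped with a warning.
#' @export
trend_and_effect_suite <- function(records, sites, site_climate,
                                   tnz_estimates = NULL,
                                   spatial_years = c(2022, 2023)) {
  spatial <- merge(records, sites[, c("site", "lat", "lon", "alt")],
                   by = "site")
  spm <- site_climate[site_climate$year %in% spatial_years, ]
  if (nrow(spm)) {
    spm <- aggregate(list(ann_min_temp = spm$ann_min_temp),
                     by = list(site = spm$site), FUN = mean)
    spatial <- merge(spatial, spm, by = "site")
  }
  if (!is.null(tnz_estimates))
    spatial <- merge(spatial, tnz_estimates[, c("site", "tnz_b")],
                     by = "site")
  temporal <- merge(records, site_climate, by = c("site", "year"))
  temporal$cyear <- cyear(temporal$year)
  if (nrow(spatial) == 0 && nrow(temporal) == 0)
    stop("empty join: no records match the climate/site tables",
         call. = FALSE)
  plan <- list(
    list("spatial", "lat", "site"), list("spatial", "lon", "site"),
    list("spatial", "alt", "site"), list("spatial", "ann_min_temp", "site"),
    list("spatial", "tnz_b", "site"),
    list("temporal", "cyear", "year"),
    list("temporal", "ann_min_temp", "year"))
  rows <- list()
  for (resp in c("body_length", "body_mass")) {
    for (pl in plan) {
      ds <- if (pl[[1]] == "spatial") spatial else temporal
      if (!pl[[2]] %in% names(ds) || nrow(ds) == 0) next
      if (length(unique(ds[[pl[[2]]]])) < 2) next
      f <- tryCatch(
        fit_gamma_glmm(ds, resp, pl[[2]], random = pl[[3]]),
        error = function(e) {
          warning("fit skipped (", resp, " ~ ", pl[[2]], "): ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(f)) next
      rows[[length(rows) + 1]] <- data.frame(
        dataset = pl[[1]], response = resp, predictor = pl[[2]],
        slope = f$slope, se = f$slope_se, p = f$slope_p,
        slope_std = f$slope_std, n = f$n_obs, n_groups = f$n_groups,
        converged = f$converged, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no model in the battery could be fit",
                          call. = FALSE)
  do.call(rbind, rows)
}
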