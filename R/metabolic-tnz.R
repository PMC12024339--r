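## Thermoneutral-zone estimation from respirometry traces: minimum-window
## RMR extraction, mass-specific conversion, gradient-descent polynomial fit
## of the RMR-temperature curve, and derivative-threshold limit temperatures.

#' Minimum sustained oxygen consumption of a trace
#'
#' Temperature-specific resting metabolic rate is the minimal oxygen
#' consumption sustained for at least `window_minutes`: the minimum, over
#' all contiguous windows of exactly `window_minutes` consecutive readings,
#' of the window mean. (Means over longer windows can never be smaller than
#' the best window of the minimum length, so the shortest admissible window
#' is the operative one.)
#'
#' @param readings numeric vector of per-minute oxygen consumption,
#'   mL O2 h^-1.
#' @param window_minutes window length in minutes (default 5).
#' @return The minimal window mean, mL O2 h^-1.
#' @examples
#' min_window_rmr(c(5, 5, 5, 5, 5, 1, 1, 1, 1, 1)) # 1
#' @export
min_window_rmr <- function(readings, window_minutes = 5) {
  stopifnot(is.numeric(readings), window_minutes >= 1)
  n <- length(readings)
  if (n < window_minutes)
    stop("trace too short: ", n, " readings < window of ", window_minutes,
         call. = FALSE)
  cs <- c(0, cumsum(readings))
  means <- (cs[(window_minutes + 1):(n + 1)] - cs[1:(n - window_minutes + 1)]) /
    window_minutes
  min(means)
}

#' Convert whole-animal to mass-specific oxygen consumption
#'
#' @param rmr oxygen consumption, mL O2 h^-1.
#' @param body_mass body mass in g (> 0).
#' @return Mass-specific rate, mL O2 g^-1 h^-1.
#' @export
to_mass_specific <- function(rmr, body_mass) {
  if (any(body_mass <= 0)) stop("body_mass must be > 0", call. = FALSE)
  rmr / body_mass
}

## -- polynomial helpers (ascending coefficients c0 + c1 t + ...) ----------

poly_eval <- function(coefs, t) {
  out <- rep(coefs[length(coefs)], length(t))
  for (k in rev(seq_len(length(coefs) - 1))) out <- out * t + coefs[k]
  out
}

poly_deriv <- function(coefs) {
  d <- length(coefs) - 1
  if (d == 0) return(0)
  coefs[-1] * seq_len(d)
}

## Expand sum_k b_k ((t - m)/s)^k into ascending coefficients of t by
## repeated convolution with the linear factor (-m/s, 1/s).
poly_unscale <- function(beta, m, s) {
  lin <- c(-m / s, 1 / s)
  out <- beta[1]
  pw <- 1
  for (k in seq_along(beta)[-1]) {
    pw <- conv_poly(pw, lin)
    out <- add_poly(out, beta[k] * pw)
  }
  out
}

conv_poly <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

add_poly <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
}

#' Fit the RMR-temperature curve by gradient descent
#'
#' Fits a degree-`degree` polynomial of mass-specific RMR on chamber
#' temperature by least squares, minimised with Nesterov-accelerated
#' gradient descent. Internally the temperature axis is mean-centred and
#' scaled to unit variance and the monomial columns are norm-scaled
#' (preconditioning keeps the step size scale-free); the step is 1/L with L
#' the largest eigenvalue of the preconditioned normal matrix, so descent
#' is monotone in exact arithmetic. Coefficients are reported back on the
#' degC scale.
#'
#' @param points data.frame with columns `chamber_temp` (degC) and `rmr`
#'   (mass-specific, mL O2 g^-1 h^-1), e.g. from [rmr_points()].
#' @param degree polynomial degree, 2-6 (default 6: a flat-bottomed U with
#'   steep limbs needs more curvature than a quartic can place at the two
#'   shoulders).
#' @param learning_rate step size on the preconditioned scale; `NULL`
#'   (default) uses 1/L.
#' @param max_iter iteration cap.
#' @param tol convergence threshold on the max-abs preconditioned gradient.
#' @return An object of class `metabolic_curve`: `coefficients` (ascending,
#'   degC scale), `fit_domain`, `sse`, `converged`, `n_iterations`,
#'   `degree`.
#' @examples
#' pts <- data.frame(chamber_temp = rep(seq(20, 37.5, 2.5), 2))
#' pts$rmr <- 0.1 * (pts$chamber_temp - 30)^2 + 1
#' fit <- fit_rmr_curve(pts, degree = 2)
#' round(fit$coefficients, 6)
#' @export
fit_rmr_curve <- function(points, degree = 6, learning_rate = NULL,
                          max_iter = 100000, tol = 1e-11) {
  stopifnot(is.data.frame(points),
            all(c("chamber_temp", "rmr") %in% names(points)))
  if (degree < 2 || degree > 6)
    stop("degree must be between 2 and 6", call. = FALSE)
  x <- points$chamber_temp
  y <- points$rmr
  n_temps <- length(unique(x))
  if (n_temps <= degree)
    stop("need more distinct chamber temperatures (", n_temps,
         ") than the polynomial degree (", degree, ")", call. = FALSE)
  mx <- mean(x); sx <- sd(x)
  z <- (x - mx) / sx
  X <- outer(z, 0:degree, `^`)
  cn <- sqrt(colSums(X^2))
  W <- sweep(X, 2, cn, `/`)
  n <- length(y)
  A <- crossprod(W) / n
  b <- drop(crossprod(W, y)) / n
  L <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  step <- if (is.null(learning_rate)) 1 / L else learning_rate
  beta <- v <- numeric(degree + 1)
  tprev <- 1
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    g <- drop(A %*% v) - b
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    beta_new <- v - step * g
    tnew <- (1 + sqrt(1 + 4 * tprev^2)) / 2
    v <- beta_new + ((tprev - 1) / tnew) * (beta_new - beta)
    beta <- beta_new
    tprev <- tnew
  }
  if (!converged)
    warning("gradient descent did not reach tol in ", max_iter,
            " iterations", call. = FALSE)
  resid <- y - drop(W %*% beta)
  coefs <- poly_unscale(beta / cn, mx, sx)
  structure(list(coefficients = coefs,
                 fit_domain = range(x),
                 sse = sum(resid^2),
                 converged = converged,
                 n_iterations = it,
                 degree = degree),
            class = "metabolic_curve")
}

#' @export
print.metabolic_curve <- function(x, ...) {
  cat("<metabolic_curve> degree", x$degree, "on [",
      paste(round(x$fit_domain, 1), collapse = ", "), "] degC; sse =",
      signif(x$sse, 4),
      if (x$converged) paste0("(converged, ", x$n_iterations, " iter)\n")
      else "(NOT converged)\n")
  invisible(x)
}

#' Predicted mass-specific RMR from a fitted curve
#'
#' @param object a `metabolic_curve`.
#' @param newdata optional data.frame with `chamber_temp`, or a numeric
#'   vector of temperatures.
#' @param ... unused.
#' @return Predicted mass-specific RMR values.
#' @export
predict.metabolic_curve <- function(object, newdata, ...) {
  t <- if (is.data.frame(newdata)) newdata$chamber_temp else newdata
  poly_eval(object$coefficients, t)
}

#' Derive thermoneutral-zone limits from a fitted curve
#'
#' Locates the interior minimum of the fitted polynomial (the basal
#' metabolic rate and its temperature), then walks outward: the lower limit
#' temperature (LLT) is the largest temperature below the minimum where the
#' curve's derivative equals `-delta`, and the upper limit temperature
#' (ULT) the smallest temperature above it where the derivative equals
#' `+delta`. Crossings are bracketed on a grid of `grid_step` and refined
#' by root-finding to <= 1e-6 degC. If the derivative never reaches the
#' threshold inside the fit domain on one side, that limit is clipped to
#' the domain boundary and flagged.
#'
#' @param curve a [fit_rmr_curve()] result.
#' @param delta derivative threshold, mL O2 g^-1 h^-1 per degC (default
#'   0.07, calibrated so noiseless Scholander-type traces on the standard
#'   chamber schedule recover their true limits; see the package vignette).
#' @param grid_step scan resolution, degC.
#' @return An object of class `tnz_estimate`: `llt`, `ult`,
#'   `tnz_b = ult - llt` (exact), `bmr` (curve minimum), `t_min` (argmin),
#'   `clipped` (named logical), `delta`.
#' @examples
#' pts <- data.frame(chamber_temp = rep(seq(25, 35, 1.25), 2))
#' pts$rmr <- 0.05 * (pts$chamber_temp - 30)^2 + 1
#' derive_tnz(fit_rmr_curve(pts, degree = 2), delta = 0.02)
#' @export
derive_tnz <- function(curve, delta = 0.07, grid_step = 0.01) {
  stopifnot(inherits(curve, "metabolic_curve"), delta > 0)
  dom <- curve$fit_domain
  dcoef <- poly_deriv(curve$coefficients)
  grid <- seq(dom[1], dom[2], by = grid_step)
  vals <- poly_eval(curve$coefficients, grid)
  derivs <- poly_eval(dcoef, grid)
  imin <- which.min(vals)
  if (imin == 1 || imin == length(grid) ||
      !any(derivs[seq_len(imin - 1)] < 0) || !any(derivs[-seq_len(imin)] > 0))
    stop("fitted curve has no interior minimum: no thermoneutral zone ",
         "can be derived", call. = FALSE)
  ## refine t_min: root of the derivative bracketed around the grid argmin
  lo <- grid[max(imin - 1, 1)]; hi <- grid[min(imin + 1, length(grid))]
  t_min <- if (sign(poly_eval(dcoef, lo)) != sign(poly_eval(dcoef, hi))) {
    uniroot(function(t) poly_eval(dcoef, t), c(lo, hi), tol = 1e-8)$root
  } else grid[imin]
  clipped <- c(llt = FALSE, ult = FALSE)
  ## LLT: largest t < t_min with deriv(t) = -delta
  below <- grid[grid < t_min]
  idx <- which(poly_eval(dcoef, below) <= -delta)
  if (length(idx)) {
    tl <- below[max(idx)]
    ub <- min(tl + grid_step, t_min)
    llt <- uniroot(function(t) poly_eval(dcoef, t) + delta, c(tl, ub),
                   tol = 1e-8, extendInt = "no")$root
  } else {
    llt <- dom[1]; clipped["llt"] <- TRUE
  }
  ## ULT: smallest t > t_min with deriv(t) = +delta
  above <- grid[grid > t_min]
  idx <- which(poly_eval(dcoef, above) >= delta)
  if (length(idx)) {
    tu <- above[min(idx)]
    lb <- max(tu - grid_step, t_min)
    ult <- uniroot(function(t) poly_eval(dcoef, t) - delta, c(lb, tu),
                   tol = 1e-8, extendInt = "no")$root
  } else {
    ult <- dom[2]; clipped["ult"] <- TRUE
  }
  structure(list(llt = llt, ult = ult, tnz_b = ult - llt,
                 bmr = poly_eval(curve$coefficients, t_min),
                 t_min = t_min, clipped = clipped, delta = delta),
            class = "tnz_estimate")
}

#' @export
print.tnz_estimate <- function(x, ...) {
  cat(sprintf("<tnz_estimate> LLT %.2f, ULT %.2f, TNZ_b %.2f degC; BMR %.3f at %.2f degC%s\n",
              x$llt, x$ult, x$tnz_b, x$bmr, x$t_min,
              if (any(x$clipped)) paste0(" [clipped: ",
                paste(names(x$clipped)[x$clipped], collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Temperature-specific mass-specific RMR points from raw traces
#'
#' Applies [min_window_rmr()] and [to_mass_specific()] to every
#' animal-by-chamber-temperature trace in a long respirometry table.
#'
#' @param traces data.frame with columns `animal_id`, `site`, `mass_g`,
#'   `chamber_temp_C`, `minute`, `o2_ml_per_h` (as written by
#'   [write_synthetic_data()]).
#' @param window_minutes minimum sustained window, minutes.
#' @return A data.frame with `site`, `animal_id`, `chamber_temp`, `rmr`
#'   (mass-specific).
#' @export
rmr_points <- function(traces, window_minutes = 5) {
  need <- c("animal_id", "site", "mass_g", "chamber_temp_C", "o2_ml_per_h")
  stopifnot(all(need %in% names(traces)))
  key <- interaction(traces$animal_id, traces$chamber_temp_C, drop = TRUE)
  parts <- split(traces, key)
  rows <- lapply(parts, function(d) {
    d <- d[order(d$minute), ]
    data.frame(site = d$site[1], animal_id = d$animal_id[1],
               chamber_temp = d$chamber_temp_C[1],
               rmr = to_mass_specific(min_window_rmr(d$o2_ml_per_h,
                                                     window_minutes),
                                      d$mass_g[1]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$site, out$animal_id, -out$chamber_temp), ]
}

#' Per-population thermoneutral-zone estimates
#'
#' For each site, pools the mass-specific RMR points of all its animals
#' (one curve per population, not per animal), fits one
#' [fit_rmr_curve()] and derives one [derive_tnz()] estimate.
#' Sites with too few distinct chamber temperatures are skipped with a
#' warning; sites with a single animal are estimated but flagged with a
#' warning.
#'
#' @param traces long respirometry table (see [rmr_points()]).
#' @param window_minutes minimum sustained RMR window, minutes.
#' @param degree polynomial degree for [fit_rmr_curve()].
#' @param delta derivative threshold for [derive_tnz()].
#' @param grid_step scan resolution for [derive_tnz()].
#' @return A data.frame keyed by `site` with `llt`, `ult`, `tnz_b`, `bmr`,
#'   `t_min`, `converged`, `clipped`, `n_animals`; fitted curves are
#'   attached as attribute `"curves"`.
#' @examples
#' sim <- simulate_study(synth_config(n_sites = 2, n_animals_rmr = 2,
#'                                    rmr_noise_sd = 0, seed = 3))
#' estimate_population_tnz(sim$traces)
#' @export
estimate_population_tnz <- function(traces, window_minutes = 5, degree = 6,
                                    delta = 0.07, grid_step = 0.01) {
  pts <- rmr_points(traces, window_minutes)
  out <- list(); curves <- list()
  for (st in unique(pts$site)) {
    p <- pts[pts$site == st, ]
    n_animals <- length(unique(p$animal_id))
    if (length(unique(p$chamber_temp)) <= degree) {
      warning("site ", st, " skipped: only ",
              length(unique(p$chamber_temp)),
              " distinct chamber temperatures (need > ", degree, ")",
              call. = FALSE)
      next
    }
    if (n_animals < 2)
      warning("site ", st, " has fewer than 2 animals; estimate may be ",
              "unstable", call. = FALSE)
    curve <- fit_rmr_curve(p, degree = degree)
    est <- derive_tnz(curve, delta = delta, grid_step = grid_step)
    curves[[st]] <- curve
    out[[st]] <- data.frame(site = st, llt = est$llt, ult = est$ult,
                            tnz_b = est$tnz_b, bmr = est$bmr,
                            t_min = est$t_min,
                            converged = curve$converged,
                            clipped = any(est$clipped),
                            n_animals = n_animals,
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    stop("no site had enough distinct chamber temperatures", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "curves") <- curves
  res
}
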