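#' Initial enzymatic rate from an absorbance time series
#'
#' Converts a blank-corrected absorbance trace to a specific activity.
#' The slope (AU/min) is taken by least squares over the initial linear
#' window, defined as the longest prefix of the series whose linear fit has
#' R^2 >= `r2_min` (minimum `min_points` points); the specific activity then
#' follows from the assay constants:
#' `rate = (slope / epsilon) * (1 / path_length) * 1e6 * volume / protein_mass`
#' in umol min^-1 mg^-1. Negative slopes beyond tolerance are clipped to 0
#' and flagged, since a blank-corrected activity cannot be negative.
#'
#' @param time time points in minutes, strictly increasing, >= 3 points.
#' @param absorbance blank-corrected absorbance (AU), same length.
#' @param epsilon molar extinction coefficient (M^-1 cm^-1), > 0.
#' @param path_length optical path (cm), default 0.4.
#' @param volume reaction volume (L), default 0.0002.
#' @param protein_mass protein amount (mg), > 0.
#' @param r2_min linear-window acceptance threshold, default 0.98.
#' @param min_points minimum window length, default 5 (capped at the
#'   series length).
#' @return list with `rate` (umol min^-1 mg^-1), `slope` (AU/min),
#'   `window` (number of points used), `clipped` flag.
#' @export
initial_rate <- function(time, absorbance, epsilon,
                         path_length = 0.4, volume = 0.0002,
                         protein_mass = 1, r2_min = 0.98, min_points = 5) {
  n <- length(time)
  tl_assert(n >= 3, "need at least 3 time points")
  tl_assert(length(absorbance) == n, "time/absorbance length mismatch")
  tl_assert(all(diff(time) > 0), "time must be strictly increasing")
  tl_assert(epsilon > 0 && path_length > 0 && volume > 0 && protein_mass > 0,
            "assay constants must be positive")
  k <- .linear_window(time, absorbance, r2_min, min(min_points, n))
  idx <- seq_len(k)
  slope <- .ls_slope(time[idx], absorbance[idx])
  rate <- (slope / epsilon) * (1 / path_length) * 1e6 * volume / protein_mass
  clipped <- FALSE
  if (rate < 0) {
    clipped <- slope < -1e-10
    rate <- 0
  }
  list(rate = rate, slope = slope, window = k, clipped = clipped)
}

.ls_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

# longest prefix with linear-fit R^2 >= r2_min (vectorised prefix sums);
# a flat prefix (zero signal variance) counts as perfectly linear
.linear_window <- function(x, y, r2_min, kmin) {
  n <- length(x)
  ks <- seq_len(n)
  sx <- cumsum(x); sy <- cumsum(y)
  sxx <- cumsum(x^2); syy <- cumsum(y^2); sxy <- cumsum(x * y)
  ssxx <- sxx - sx^2 / ks
  ssyy <- syy - sy^2 / ks
  ssxy <- sxy - sx * sy / ks
  eps <- 1e-12 * max(1, max(abs(y))^2)
  r2 <- ifelse(ssyy <= eps, 1, ssxy^2 / pmax(ssxx * ssyy, .Machine$double.xmin))
  ok <- which(r2[kmin:n] >= r2_min) + kmin - 1L
  if (length(ok)) max(ok) else kmin
}

#' Build a relative thermal activity profile
#'
#' Aggregates per-replicate specific activities into replicate means and
#' SDs per assay temperature, then expresses each mean as a percentage of
#' the maximum mean activity.
#'
#' @param rates data.frame with columns `temperature`, `replicate`, `rate`.
#' @return A `thermal_profile`: data.frame with `temperature`, `rate_mean`,
#'   `rate_sd`, `relative_activity` (percent), raw rates kept in attribute
#'   `rates`. All-zero activities yield an all-zero profile with a warning.
#' @export
build_profile <- function(rates) {
  tl_assert(all(c("temperature", "replicate", "rate") %in% names(rates)),
            "rates must have columns temperature, replicate, rate")
  temps <- sort(unique(rates$temperature))
  tl_assert(length(temps) >= 2, "cannot profile a single temperature")
  agg <- do.call(rbind, lapply(temps, function(tt) {
    r <- rates$rate[rates$temperature == tt]
    data.frame(temperature = tt, rate_mean = mean(r),
               rate_sd = if (length(r) > 1) sd(r) else NA_real_)
  }))
  mx <- max(agg$rate_mean)
  if (mx <= 0) {
    warning("all rates are zero: relative activities set to 0")
    agg$relative_activity <- 0
  } else {
    agg$relative_activity <- 100 * agg$rate_mean / mx
  }
  structure(agg, class = c("thermal_profile", "data.frame"),
            rates = rates)
}

#' Temperature of maximum activity
#'
#' Argmax of the replicate-mean activity over the tested temperature grid
#' (no interpolation by default: reported optima are tested temperatures).
#' Exact ties resolve to the lowest temperature and are flagged. The SD is
#' taken across per-replicate argmax temperatures. An optional smoothed
#' mode refines the optimum by a quadratic fit through the three grid
#' points around the peak.
#'
#' @param profile a [build_profile()] result.
#' @param method `"argmax"` (default) or `"smoothed-argmax"`.
#' @return A `topt_result`: list with `topt` (degC), `topt_sd`, `method`,
#'   `tie` flag.
#' @export
find_topt <- function(profile, method = c("argmax", "smoothed-argmax")) {
  method <- match.arg(method)
  tl_assert(inherits(profile, "thermal_profile"), "not a thermal_profile")
  tl_assert(max(profile$rate_mean) > 0, "all-zero profile: no Topt")
  mx <- max(profile$rate_mean)
  at_max <- which(profile$rate_mean == mx)
  tie <- length(at_max) > 1
  topt <- profile$temperature[min(at_max)]
  if (method == "smoothed-argmax" && !tie) {
    k <- min(at_max)
    if (k > 1 && k < nrow(profile)) {
      xx <- profile$temperature[(k - 1):(k + 1)]
      yy <- profile$rate_mean[(k - 1):(k + 1)]
      co <- coef(lm(yy ~ xx + I(xx^2)))
      if (is.finite(co[3]) && co[3] < 0) {
        v <- -co[2] / (2 * co[3])
        if (v >= min(xx) && v <= max(xx)) topt <- unname(v)
      }
    }
  }
  rates <- attr(profile, "rates")
  reps <- unique(rates$replicate)
  per_rep <- vapply(reps, function(rr) {
    sub <- rates[rates$replicate == rr, ]
    if (!nrow(sub) || max(sub$rate) <= 0) return(NA_real_)
    sub$temperature[which.max(sub$rate)]
  }, numeric(1))
  per_rep <- per_rep[is.finite(per_rep)]
  list(topt = topt,
       topt_sd = if (length(per_rep) > 1) sd(per_rep) else NA_real_,
       method = method, tie = tie)
}

#' Specific activities for a whole assay plate
#'
#' Applies [initial_rate()] to every (temperature, replicate) series of a
#' tidy kinetics table.
#'
#' @param plate data.frame with columns `temperature`, `replicate`,
#'   `time_min`, `absorbance`.
#' @param epsilon,path_length,volume,protein_mass assay constants, see
#'   [initial_rate()].
#' @param ... passed on to [initial_rate()].
#' @return data.frame with columns `temperature`, `replicate`, `rate`,
#'   `slope`, `window`, `clipped`.
#' @export
plate_rates <- function(plate, epsilon, path_length = 0.4, volume = 0.0002,
                        protein_mass = 1, ...) {
  tl_assert(all(c("temperature", "replicate", "time_min", "absorbance")
                %in% names(plate)),
            "plate must have temperature, replicate, time_min, absorbance")
  combos <- unique(plate[, c("temperature", "replicate")])
  out <- lapply(seq_len(nrow(combos)), function(k) {
    sub <- plate[plate$temperature == combos$temperature[k] &
                 plate$replicate == combos$replicate[k], ]
    sub <- sub[order(sub$time_min), ]
    r <- initial_rate(sub$time_min, sub$absorbance, epsilon,
                      path_length, volume, protein_mass, ...)
    data.frame(temperature = combos$temperature[k],
               replicate = combos$replicate[k],
               rate = r$rate, slope = r$slope,
               window = r$window, clipped = r$clipped)
  })
  do.call(rbind, out)
}
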