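#' Generator configuration
#'
#' One configuration object drives every generator so that identical
#' configurations yield identical synthetic datasets (the seed is an
#' explicit field, default 0). Defaults encode the study conditions the
#' generators emulate: a 14-site latitudinal transect for the linear
#' Topt-MAT relation, and a global-ocean seawater survey layout with a
#' piecewise Topt-MAT relation (slopes 0.45 and 6.48 around a 27.7 degC
#' breakpoint; Td slopes 0.54 and 4.45 around 25.1 degC).
#'
#' @param seed integer RNG seed.
#' @param n_sites number of sites.
#' @param relation `"linear"` or `"piecewise"` Topt-MAT relation.
#' @param slope_before,slope_after Topt-MAT slopes (degC per degC);
#'   `slope_after` is used beyond the breakpoint in piecewise mode.
#' @param breakpoint MAT breakpoint (degC), piecewise mode only.
#' @param intercept Topt at MAT = 0 (degC).
#' @param mat_range MAT range sites are drawn from (degC).
#' @param noise_sd site-level Gaussian noise on true Topt/Td (degC).
#' @param assay_noise_sd absorbance noise per kinetics reading (AU).
#' @param td_intercept,td_slope_before,td_slope_after,td_breakpoint the
#'   corresponding Td-MAT relation.
#' @param assay_duration_min,assay_dt_min kinetics trace length and
#'   sampling interval (default 180 min read every 30 s).
#' @param melt_noise_frac melting-curve noise as a fraction of amplitude.
#' @param growth_noise_sd OD600 noise (default 0.02).
#' @param replicates replicate count (default 3 everywhere).
#' @return list of class `gen_config`.
#' @export
gen_config <- function(seed = 0, n_sites = 14,
                       relation = c("linear", "piecewise"),
                       slope_before = NULL, slope_after = 6.48,
                       breakpoint = 27.7, intercept = NULL,
                       mat_range = NULL, noise_sd = 2,
                       assay_noise_sd = 0.003,
                       td_intercept = NULL, td_slope_before = NULL,
                       td_slope_after = 4.45, td_breakpoint = 25.1,
                       assay_duration_min = 180, assay_dt_min = 0.5,
                       melt_noise_frac = 0.02, growth_noise_sd = 0.02,
                       replicates = 3) {
  relation <- match.arg(relation)
  if (relation == "linear") {
    # transect defaults: Topt 20 -> 55 degC across MAT 12 -> 30 degC
    if (is.null(slope_before)) slope_before <- 35 / 18
    if (is.null(intercept)) intercept <- 20 - slope_before * 12
    if (is.null(mat_range)) mat_range <- c(12, 30)
    if (is.null(td_slope_before)) td_slope_before <- 0.9
    if (is.null(td_intercept)) td_intercept <- 39.2
  } else {
    if (is.null(slope_before)) slope_before <- 0.45
    if (is.null(intercept)) intercept <- 25
    if (is.null(mat_range)) mat_range <- c(-1.4, 29.5)
    if (is.null(td_slope_before)) td_slope_before <- 0.54
    if (is.null(td_intercept)) td_intercept <- 39.2
  }
  tl_assert(noise_sd >= 0 && assay_noise_sd >= 0, "noise SDs must be >= 0")
  cfg <- list(seed = as.integer(seed), n_sites = as.integer(n_sites),
              relation = relation, slope_before = slope_before,
              slope_after = slope_after, breakpoint = breakpoint,
              intercept = intercept, mat_range = mat_range,
              noise_sd = noise_sd, assay_noise_sd = assay_noise_sd,
              td_intercept = td_intercept,
              td_slope_before = td_slope_before,
              td_slope_after = td_slope_after,
              td_breakpoint = td_breakpoint,
              assay_duration_min = assay_duration_min,
              assay_dt_min = assay_dt_min,
              melt_noise_frac = melt_noise_frac,
              growth_noise_sd = growth_noise_sd,
              replicates = as.integer(replicates))
  class(cfg) <- "gen_config"
  cfg
}

.piecewise <- function(x, b0, s1, s2, psi) b0 + s1 * x + (s2 - s1) * pmax(x - psi, 0)

#' Generate a site dataset with known thermal ground truth
#'
#' Draws site MATs uniformly over the configured range, with pH and
#' salinity covariates drawn independently of the thermal response, and
#' computes true Topt and Td from the configured linear or piecewise
#' relation plus zero-mean Gaussian noise.
#'
#' @param cfg a [gen_config()].
#' @return data.frame with columns `site_id`, `MAT`, `pH`, `salinity`,
#'   `topt_true`, `td_true`, `variability_class`.
#' @export
gen_site_dataset <- function(cfg) {
  tl_assert(inherits(cfg, "gen_config"), "cfg must be a gen_config")
  if (cfg$relation == "piecewise")
    tl_assert(cfg$breakpoint > cfg$mat_range[1] &&
                cfg$breakpoint < cfg$mat_range[2],
              "breakpoint must lie strictly inside the MAT range")
  with_seed(cfg$seed, {
    mat <- sort(runif(cfg$n_sites, cfg$mat_range[1], cfg$mat_range[2]))
    ph <- runif(cfg$n_sites, 7.6, 8.4)
    sal <- runif(cfg$n_sites, 32, 40)
    if (cfg$relation == "linear") {
      topt <- cfg$intercept + cfg$slope_before * mat
      td <- cfg$td_intercept + cfg$td_slope_before * mat
    } else {
      topt <- .piecewise(mat, cfg$intercept, cfg$slope_before,
                         cfg$slope_after, cfg$breakpoint)
      td <- .piecewise(mat, cfg$td_intercept, cfg$td_slope_before,
                       cfg$td_slope_after, cfg$td_breakpoint)
    }
    topt <- pmax(0, topt + rnorm(cfg$n_sites, 0, cfg$noise_sd))
    td <- pmax(0, td + rnorm(cfg$n_sites, 0, cfg$noise_sd))
    data.frame(site_id = sprintf("site_%02d", seq_len(cfg$n_sites)),
               MAT = mat, pH = ph, salinity = sal,
               topt_true = topt, td_true = td,
               variability_class = "none")
  })
}

# asymmetric Gaussian thermal performance curve: decline above the optimum
# is sharper than below it
.tpc <- function(T, topt, w_lo = 12, w_hi = 6) {
  w <- ifelse(T <= topt, w_lo, w_hi)
  exp(-((T - topt) / w)^2)
}

#' Generate a kinetics assay plate for one site
#'
#' Simulates blank-corrected absorbance traces (default: readings every
#' 30 s over 180 min, three replicates per temperature). The initial slope
#' at each temperature is proportional to an asymmetric Gaussian thermal
#' performance curve peaking at the site's true Topt; traces saturate
#' mildly (first-order substrate depletion) and carry Gaussian reading
#' noise `assay_noise_sd`.
#'
#' @param site one row of [gen_site_dataset()] (or a list with
#'   `topt_true`, optionally `site_id`).
#' @param temperatures assay temperature grid (degC), >= 2 values.
#' @param cfg a [gen_config()].
#' @param peak_slope maximum initial slope (AU/min) at the optimum.
#' @return data.frame with columns `site`, `temperature`, `replicate`,
#'   `time_min`, `absorbance`; true parameters in attribute `truth`.
#' @export
gen_assay_plate <- function(site, temperatures = seq(5, 80, by = 5), cfg,
                            peak_slope = 0.2) {
  tl_assert(length(temperatures) >= 2, "need >= 2 assay temperatures")
  tl_assert(inherits(cfg, "gen_config"), "cfg must be a gen_config")
  topt <- site$topt_true
  sid <- if (!is.null(site$site_id)) site$site_id else "site"
  tgrid <- seq(0, cfg$assay_duration_min, by = cfg$assay_dt_min)
  a_inf <- 1.2  # AU at substrate exhaustion
  with_seed(cfg$seed + 1000L + sum(utf8ToInt(as.character(sid))), {
    rows <- lapply(temperatures, function(tt) {
      s <- peak_slope * .tpc(tt, topt)
      do.call(rbind, lapply(seq_len(cfg$replicates), function(rep) {
        mean_abs <- if (s > 0) a_inf * (1 - exp(-(s / a_inf) * tgrid)) else 0 * tgrid
        data.frame(site = sid, temperature = tt, replicate = rep,
                   time_min = tgrid,
                   absorbance = mean_abs +
                     rnorm(length(tgrid), 0, cfg$assay_noise_sd))
      }))
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(topt = topt, peak_slope = peak_slope)
    out
  })
}

#' Generate a CD melting curve with known Td
#'
#' Five-parameter sigmoid (baseline -20 mdeg, amplitude 15 mdeg, width
#' 2.5 degC, asymmetry 1.5) whose maximum-slope point sits exactly at
#' `td_true`, sampled on the configured thermal ramp (default 4 to 95 degC
#' every 0.5 degC) with Gaussian noise `melt_noise_frac * amplitude`.
#'
#' @param td_true true denaturation temperature (degC).
#' @param cfg a [gen_config()].
#' @param scan_range temperature scan range (degC), default `c(4, 95)`.
#' @param step ramp step (degC), default 0.5.
#' @return A [melting_curve()]; truth in attribute `truth`; attribute
#'   `out_of_range` flags a `td_true` outside the scan range.
#' @export
gen_melting_curve <- function(td_true, cfg, scan_range = c(4, 95), step = 0.5) {
  tl_assert(inherits(cfg, "gen_config"), "cfg must be a gen_config")
  out_of_range <- td_true < scan_range[1] || td_true > scan_range[2]
  if (out_of_range)
    warning(sprintf("td_true = %.1f degC lies outside the scan range", td_true))
  tgrid <- seq(scan_range[1], scan_range[2], by = step)
  b <- 2.5; cc <- 1.5; a <- 15; y0 <- -20
  t0 <- td_true - b * log(cc)
  p <- c(y0, a, t0, b, cc)
  with_seed(cfg$seed + 2000L + round(100 * td_true), {
    theta <- .sig5(tgrid, p) + rnorm(length(tgrid), 0, cfg$melt_noise_frac * a)
    mc <- melting_curve(tgrid, theta)
    attr(mc, "truth") <- list(td = td_true, params = p)
    attr(mc, "out_of_range") <- out_of_range
    mc
  })
}

#' Generate a toy constraint network with a planted rigidity transition
#'
#' A chain of bodies whose covalent skeleton (5-bar rotatable edges) is
#' floppy; parallel hydrogen-bond bars along the chain carry energies
#' drawn inside the schedule bin just above `planted_ecut`, so the single
#' spanning rigid cluster collapses into singletons exactly when the
#' dilution cutoff passes `planted_ecut`.
#'
#' @param n_bodies number of bodies (>= 2).
#' @param planted_ecut planted transition cutoff (kcal/mol, in
#'   `[-6.0, -0.1]`).
#' @param cfg a [gen_config()].
#' @return A [constraint_network()]; truth (planted cutoff and mapped
#'   temperature) in attribute `truth`.
#' @export
gen_toy_network <- function(n_bodies, planted_ecut, cfg) {
  tl_assert(n_bodies >= 2, "need >= 2 bodies")
  tl_assert(planted_ecut >= -6.0 && planted_ecut <= -0.1,
            "planted_ecut must lie in [-6.0, -0.1]")
  tl_assert(inherits(cfg, "gen_config"), "cfg must be a gen_config")
  i <- seq_len(n_bodies - 1L)
  with_seed(cfg$seed + 3000L + n_bodies, {
    # energies strictly inside (planted_ecut, planted_ecut + 0.1): all bonds
    # survive E_cut = planted_ecut + 0.1 and all are removed at planted_ecut
    e <- planted_ecut + runif(n_bodies - 1L, 0.01, 0.09)
    bars <- rbind(
      data.frame(i = i, j = i + 1L, type = "cov_rot", e_hb = NA_real_),
      data.frame(i = i, j = i + 1L, type = "hbond", e_hb = e))
    net <- constraint_network(n_bodies, bars)
    attr(net, "truth") <- list(planted_ecut = planted_ecut,
                               tp_K = ecut_to_temperature(planted_ecut))
    net
  })
}

#' Generate a random constraint network
#'
#' Random bar groups of mixed types (used to stress the pebble game
#' against the generic rigidity-matrix rank oracle).
#'
#' @param n_bodies number of bodies (>= 2).
#' @param n_edges number of bar groups to draw (pairs may repeat).
#' @param cfg a [gen_config()].
#' @return A [constraint_network()].
#' @export
gen_random_network <- function(n_bodies, n_edges, cfg) {
  tl_assert(n_bodies >= 2, "need >= 2 bodies")
  tl_assert(inherits(cfg, "gen_config"), "cfg must be a gen_config")
  with_seed(cfg$seed + 4000L, {
    i <- sample.int(n_bodies, n_edges, replace = TRUE)
    j <- sample.int(n_bodies, n_edges, replace = TRUE)
    ok <- i != j
    i <- i[ok]; j <- j[ok]
    type <- sample(c("cov_rot", "cov_lock", "hbond", "tether"),
                   length(i), replace = TRUE)
    e <- ifelse(type == "hbond", -runif(length(i), 0.1, 6), NA_real_)
    constraint_network(n_bodies,
                       data.frame(i = i, j = j, type = type, e_hb = e))
  })
}

# amplitudes chosen so the deterministic range 2*(a_seas + a_diel) plus the
# noise tail (~0.8 degC over ~26k draws at SD 0.15) matches the emulated
# annual ranges of 12.8 (HTV), 8.8 (ITV) and 6.7 degC (LTV)
.logger_params <- list(
  HTV = list(a_seas = 5.10, a_diel = 0.90),
  ITV = list(a_seas = 3.40, a_diel = 0.60),
  LTV = list(a_seas = 2.50, a_diel = 0.45))

#' Generate a sediment temperature-logger series
#'
#' Seasonal sinusoid plus a diel component plus Gaussian noise
#' (SD 0.15 degC), sampled every 30 min. The three variability classes
#' share the same mean (28.5 degC) but have decreasing amplitudes, tuned
#' so the annual ranges approximate 12.8 (HTV), 8.8 (ITV) and
#' 6.7 degC (LTV).
#'
#' @param class one of `"HTV"`, `"ITV"`, `"LTV"`.
#' @param months monitoring duration (default 18).
#' @param cfg a [gen_config()].
#' @param dt_min sampling interval in minutes (default 30).
#' @param amplitude_scale scale factor on both sinusoid amplitudes
#'   (0 gives a constant series plus noise-free mean).
#' @return data.frame with columns `time_h`, `temperature`; truth in
#'   attribute `truth`.
#' @export
gen_temperature_log <- function(class = c("HTV", "ITV", "LTV"), months = 18,
                                cfg, dt_min = 30, amplitude_scale = 1) {
  class <- match.arg(class)
  tl_assert(inherits(cfg, "gen_config"), "cfg must be a gen_config")
  pp <- .logger_params[[class]]
  t_h <- seq(0, months * 730, by = dt_min / 60)
  mean_t <- 28.5
  noise_sd <- if (amplitude_scale > 0) 0.15 else 0
  with_seed(cfg$seed + 5000L + match(class, names(.logger_params)), {
    temp <- mean_t +
      amplitude_scale * pp$a_seas * cos(2 * pi * (t_h - 5000) / 8766) +
      amplitude_scale * pp$a_diel * cos(2 * pi * t_h / 24) +
      rnorm(length(t_h), 0, noise_sd)
    out <- data.frame(time_h = t_h, temperature = temp)
    attr(out, "truth") <- list(class = class, mean = mean_t,
                               a_seas = amplitude_scale * pp$a_seas,
                               a_diel = amplitude_scale * pp$a_diel)
    out
  })
}

# growth thermal performance: optimum and (asymmetric) width per class;
# HTV is both warmer-shifted and wider above the optimum
.growth_params <- list(
  HTV = list(rmax = 0.35, topt = 37, w_lo = 12, w_hi = 9,  k_max = 8),
  ITV = list(rmax = 0.32, topt = 33, w_lo = 10, w_hi = 5.5, k_max = 5),
  LTV = list(rmax = 0.32, topt = 32, w_lo = 10, w_hi = 4.5, k_max = 5))

#' Generate OD600 growth curves for one variability class
#'
#' Logistic growth read every 3 h for 72 h (three replicates). The
#' replicate growth rate follows a thermal performance curve that is
#' widened and warm-shifted for the high-variability class; conditions
#' whose rate falls below 0.03 per hour are simulated as no-growth wells
#' (carrying capacity below the 0.15 OD threshold).
#'
#' @param class one of `"HTV"`, `"ITV"`, `"LTV"`.
#' @param assay_T incubation temperature (degC; default grid
#'   10/20/30/40/50).
#' @param cfg a [gen_config()].
#' @return data.frame with columns `class`, `temperature`, `replicate`,
#'   `time_h`, `od`; true rates in attribute `truth`.
#' @export
gen_growth_curves <- function(class = c("HTV", "ITV", "LTV"), assay_T, cfg) {
  class <- match.arg(class)
  tl_assert(inherits(cfg, "gen_config"), "cfg must be a gen_config")
  tl_assert(length(assay_T) == 1 && is.finite(assay_T), "one assay_T at a time")
  pp <- .growth_params[[class]]
  act <- .tpc(assay_T, pp$topt, pp$w_lo, pp$w_hi)
  r <- pp$rmax * act
  grows <- r >= 0.03
  k_cap <- if (grows) max(0.3, pp$k_max * act) else 0.08
  od0 <- 0.05
  t_h <- seq(0, 72, by = 3)
  with_seed(cfg$seed + 6000L + round(assay_T) +
              100L * match(class, names(.growth_params)), {
    rows <- lapply(seq_len(cfg$replicates), function(rep) {
      rr <- if (grows) r * exp(rnorm(1, 0, 0.05)) else 0
      od <- if (grows)
        k_cap / (1 + ((k_cap - od0) / od0) * exp(-rr * t_h))
      else od0 + 0.01 * (1 - exp(-t_h / 20))
      data.frame(class = class, temperature = assay_T, replicate = rep,
                 time_h = t_h,
                 # 0.005 OD detection floor keeps normalisation well defined
                 od = pmax(0.005,
                           od + rnorm(length(t_h), 0, cfg$growth_noise_sd)))
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(rate = r, grows = grows, k = k_cap)
    out
  })
}

#' Classify a temperature range into a variability class
#'
#' @param delta_t annual temperature range (degC).
#' @param thresholds class boundaries, default `c(7.75, 10.8)` (midpoints
#'   between the emulated LTV/ITV/HTV ranges).
#' @return `"LTV"`, `"ITV"` or `"HTV"`.
#' @export
classify_variability <- function(delta_t, thresholds = c(7.75, 10.8)) {
  ifelse(delta_t >= thresholds[2], "HTV",
         ifelse(delta_t >= thresholds[1], "ITV", "LTV"))
}
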