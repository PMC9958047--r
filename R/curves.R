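#' Melting curve container
#'
#' Ellipticity at 220 nm versus temperature, as recorded during a CD
#' thermal scan.
#'
#' @param temperature strictly increasing temperature grid (degrees C,
#'   at least 10 points).
#' @param theta ellipticity signal (millidegrees), same length.
#' @return data.frame of class `melting_curve`.
#' @export
melting_curve <- function(temperature, theta) {
  tl_assert(length(temperature) >= 10, "melting curve needs >= 10 points")
  tl_assert(length(temperature) == length(theta), "length mismatch")
  tl_assert(all(diff(temperature) > 0), "temperature must be strictly increasing")
  structure(data.frame(temperature = temperature, theta = theta),
            class = c("melting_curve", "data.frame"))
}

# Richards-type 5-parameter sigmoid ("sigmoid, 5 parameter" family):
# y = y0 + a / (1 + exp(-(T - T0)/b))^c
.sig5 <- function(T, p) p[1] + p[2] / (1 + exp(-(T - p[3]) / p[4]))^p[5]

#' Five-parameter sigmoid fit of a melting curve
#'
#' Least-squares fit of the asymmetric (Richards-type) logistic
#' `theta(T) = y0 + a / (1 + exp(-(T - T0)/b))^c` with width `b > 0` and
#' asymmetry `c > 0`, using deterministic multi-start optimisation (starts
#' placed at data quantiles). The denaturation temperature is the
#' temperature of maximum |d theta / dT| of the fitted curve, analytically
#' `Td = T0 + b log(c)`; its uncertainty comes from the fit covariance via
#' the delta method. A fit is flagged non-converged when the sigmoid
#' explains less than 20% of the signal variance (e.g. amplitude ~ 0).
#'
#' @param curve a [melting_curve()] (or data.frame with columns
#'   `temperature` and `theta`).
#' @param fix_c optionally fix the asymmetry parameter (e.g. `fix_c = 1`
#'   recovers the symmetric 4-parameter logistic).
#' @return A `sigmoid_fit`: list with `params` (y0, a, T0, b, c), `td`,
#'   `td_sd`, `converged`, `rss`, `r2`.
#' @export
fit_sigmoid5 <- function(curve, fix_c = NULL) {
  x <- curve$temperature; y <- curve$theta
  tl_assert(!is.null(x) && !is.null(y), "curve must have temperature and theta")
  n <- length(x)
  tss <- sum((y - mean(y))^2)
  bad <- structure(list(params = NULL, td = NA_real_, td_sd = NA_real_,
                        converged = FALSE, rss = tss, r2 = 0),
                   class = "sigmoid_fit")
  if (tss < .Machine$double.eps * n) return(bad)  # flat signal
  rng <- diff(range(x))
  amp0 <- mean(tail(y, 3)) - mean(head(y, 3))
  # theta: (y0, a, T0, log b, log c)
  obj <- function(th) {
    p <- c(th[1], th[2], th[3], exp(th[4]), if (is.null(fix_c)) exp(th[5]) else fix_c)
    r <- y - .sig5(x, p)
    sum(r * r)
  }
  starts <- lapply(c(0.25, 0.4, 0.5, 0.6, 0.75), function(q) {
    th <- c(mean(head(y, 3)), amp0, quantile(x, q, names = FALSE),
            log(rng / 10), 0)
    if (is.null(fix_c)) th else th[1:4]
  })
  best <- NULL
  for (th0 in starts) {
    f1 <- optim(th0, obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-12))
    f2 <- tryCatch(optim(f1$par, obj, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-12)),
                   error = function(e) f1)
    f <- if (f2$value <= f1$value) f2 else f1
    if (is.null(best) || f$value < best$value) best <- f
  }
  th <- best$par
  p <- c(th[1], th[2], th[3], exp(th[4]), if (is.null(fix_c)) exp(th[5]) else fix_c)
  names(p) <- c("y0", "a", "T0", "b", "c")
  rss <- best$value
  r2 <- 1 - rss / tss
  if (r2 < 0.2) { bad$rss <- rss; bad$r2 <- r2; return(bad) }
  td <- p[["T0"]] + p[["b"]] * log(p[["c"]])
  # covariance of (y0, a, T0, b, c) from the Jacobian at the optimum
  td_sd <- NA_real_
  cov <- .fit_cov(x, y, p, .sig5, fixed5 = !is.null(fix_c))
  if (!is.null(cov)) {
    g <- c(0, 0, 1, log(p[["c"]]),
           if (is.null(fix_c)) p[["b"]] / p[["c"]] else 0)
    v <- drop(t(g) %*% cov %*% g)
    if (is.finite(v) && v >= 0) td_sd <- sqrt(v)
  }
  structure(list(params = p, td = unname(td), td_sd = td_sd,
                 converged = TRUE, rss = rss, r2 = r2),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("5-parameter sigmoid: Td = %.2f +/- %.2f degC (R2 = %.3f)\n",
                x$td, x$td_sd, x$r2))
  else cat("5-parameter sigmoid: not converged\n")
  invisible(x)
}

# Gauss-Newton covariance: s^2 (J'J)^-1 with numeric Jacobian.
.fit_cov <- function(x, y, p, fn, fixed5 = FALSE) {
  np <- if (fixed5) 4L else 5L
  J <- matrix(0, length(x), np)
  for (k in seq_len(np)) {
    h <- max(1e-6, abs(p[k]) * 1e-6)
    pp <- p; pp[k] <- pp[k] + h
    pm <- p; pm[k] <- pm[k] - h
    J[, k] <- (fn(x, pp) - fn(x, pm)) / (2 * h)
  }
  dfree <- length(x) - np
  if (dfree <= 0) return(NULL)
  s2 <- sum((y - fn(x, p))^2) / dfree
  jtj <- crossprod(J)
  inv <- tryCatch(solve(jtj), error = function(e) NULL)
  if (is.null(inv)) return(NULL)
  cov <- s2 * inv
  if (fixed5) cov <- rbind(cbind(cov, 0), 0)  # pad fixed c
  cov
}

# sum of two logistic steps
.dsig <- function(T, p) {
  # p = (base, A1, T1, w1, A2, T2, w2)
  p[1] + p[2] / (1 + exp(-(T - p[3]) / p[4])) +
    p[5] / (1 + exp(-(T - p[6]) / p[7]))
}

#' Double-sigmoid fit of a cluster-entropy trajectory
#'
#' Fits `H(T)` as a sum of up to two logistic steps, initialised from the
#' two largest discrete jumps of the series. When the series supports only
#' one resolvable step (second-largest jump below 10% of the total rise),
#' a single-transition fit is returned and flagged. Each transition's slope
#' is the derivative of the fitted step at its centre, `A / (4 w)`.
#'
#' @param h entropy series (dimensionless).
#' @param t temperature series in kelvin, strictly increasing,
#'   at least 15 points.
#' @return A `double_sigmoid_fit`: list with `transitions` (data.frame
#'   `T`, `slope`, ordered by `T`), `rss`, `converged`,
#'   `single_transition` flag and `params`.
#' @export
fit_double_sigmoid <- function(h, t) {
  tl_assert(length(h) == length(t), "length mismatch")
  tl_assert(length(t) >= 15, "need >= 15 points")
  tl_assert(all(diff(t) > 0), "t must be strictly increasing")
  res <- structure(list(transitions = NULL, rss = NA_real_,
                        converged = FALSE, single_transition = FALSE,
                        params = NULL),
                   class = "double_sigmoid_fit")
  rise <- max(h) - min(h)
  if (rise < .Machine$double.eps * length(h) || sd(h) == 0) return(res)
  # local rise over a short window: robust to steps smoothed over a few
  # grid points (a raw one-point diff under-measures them)
  n <- length(h)
  kk <- seq_len(n - 1L)
  jumps <- h[pmin(kk + 2L, n)] - h[pmax(kk - 1L, 1L)]
  mids <- (t[-1] + t[-n]) / 2
  ord <- order(jumps, decreasing = TRUE)
  j1 <- ord[1]
  # second jump must be a distinct location and non-negligible
  j2 <- NA_integer_
  for (k in ord[-1]) {
    if (abs(mids[k] - mids[j1]) > 4 * mean(diff(t)) && jumps[k] > 0.1 * rise) {
      j2 <- k; break
    }
  }
  w0 <- mean(diff(t)) / 2
  w_min <- mean(diff(t)) / 4  # transitions cannot be sharper than the grid
  single <- is.na(j2)
  if (single) {
    # one resolvable step: fit a single logistic, flag it
    th0 <- c(min(h), rise, mids[j1], log(w0))
    obj <- function(th) {
      p <- c(th[1], th[2], th[3], w_min + exp(th[4]), 0, mids[j1], 1)
      sum((h - .dsig(t, p))^2)
    }
  } else {
    th0 <- c(min(h), jumps[j1], mids[j1], log(w0),
             jumps[j2], mids[j2], log(w0))
    obj <- function(th) {
      p <- c(th[1], th[2], th[3], w_min + exp(th[4]),
             th[5], th[6], w_min + exp(th[7]))
      sum((h - .dsig(t, p))^2)
    }
  }
  f1 <- optim(th0, obj, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-12))
  f2 <- tryCatch(optim(f1$par, obj, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-12)),
                 error = function(e) f1)
  f <- if (f2$value <= f1$value) f2 else f1
  th <- f$par
  if (single) {
    p <- c(th[1], th[2], th[3], w_min + exp(th[4]), 0, mids[j1], 1)
    tr <- data.frame(T = p[3], slope = p[2] / (4 * p[4]))
  } else {
    p <- c(th[1], th[2], th[3], w_min + exp(th[4]),
           th[5], th[6], w_min + exp(th[7]))
    tr <- data.frame(T = c(p[3], p[6]),
                     slope = c(p[2] / (4 * p[4]), p[5] / (4 * p[7])))
    tr <- tr[order(tr$T), ]
    rownames(tr) <- NULL
    # a vanishing second amplitude degrades to a single transition
    amps <- c(p[2], p[5])
    if (min(abs(amps)) < 0.05 * rise) {
      tr <- tr[which.max(abs(c(p[2], p[5]))[order(c(p[3], p[6]))]), , drop = FALSE]
      rownames(tr) <- NULL
      single <- TRUE
    }
  }
  res$transitions <- tr
  res$rss <- f$value
  res$converged <- TRUE
  res$single_transition <- single
  res$params <- p
  res
}

#' Select the phase transition temperature from a double-sigmoid fit
#'
#' The transition with the largest |slope| is taken as Tp, except that when
#' the denaturation temperature is above 50 degrees C and two transitions
#' exist, the second (higher-temperature) transition is chosen, focusing on
#' the decomposition of the protein core. Pure function of its inputs.
#'
#' @param fit a converged [fit_double_sigmoid()] result.
#' @param td optional denaturation temperature in degrees C.
#' @return list with `tp` (K), `slope` and `rule` (one of
#'   `"single_transition"`, `"largest_slope"`, `"td_gt_50_second"`).
#' @export
select_tp <- function(fit, td = NULL) {
  tl_assert(inherits(fit, "double_sigmoid_fit") && isTRUE(fit$converged),
            "select_tp needs a converged double-sigmoid fit")
  tr <- fit$transitions
  tl_assert(!is.null(tr) && nrow(tr) >= 1, "fit has no transitions")
  if (nrow(tr) == 1)
    return(list(tp = tr$T[1], slope = tr$slope[1], rule = "single_transition"))
  if (!is.null(td) && is.finite(td) && td > 50)
    return(list(tp = tr$T[2], slope = tr$slope[2], rule = "td_gt_50_second"))
  k <- which.max(abs(tr$slope))
  list(tp = tr$T[k], slope = tr$slope[k], rule = "largest_slope")
}
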