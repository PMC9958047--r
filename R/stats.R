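#' Simple linear regression with F-test and AIC
#'
#' Ordinary least squares of `y` on `x` with the usual two-sided F-test for
#' the slope. The AIC uses the full Gaussian log-likelihood (including
#' constant terms), so ladders built from it are directly comparable with
#' mainstream statistical software.
#'
#' @param x predictor (non-constant, n >= 3).
#' @param y response, same length.
#' @return A `regression_result`: list with `slope`, `intercept`, `r2`,
#'   `F`, `df` (treatment, residual), `p`, `aic`, `n` and the underlying
#'   `fit`.
#' @export
ols_regress <- function(x, y) {
  tl_assert(length(x) == length(y), "length mismatch")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  tl_assert(length(x) >= 3, "need n >= 3 complete cases")
  tl_assert(sd(x) > 0, "constant predictor")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = sm$r.squared,
                 F = unname(fstat[1]),
                 df = c(treatment = unname(fstat[2]),
                        residual = unname(fstat[3])),
                 p = p, aic = AIC(fit), n = length(x), fit = fit),
            class = "regression_result")
}

#' AIC model ladder over environmental covariates
#'
#' Fits all subsets of the supplied covariates (intercept-only through the
#' full model) by Gaussian maximum likelihood and ranks them by AIC; the
#' lowest AIC flags the best model. Covariate collinearity triggers a
#' condition-number warning.
#'
#' @param data data.frame containing the response and covariates.
#' @param response response column name.
#' @param covariates covariate column names (default
#'   `c("MAT", "pH", "salinity")` intersected with `names(data)`).
#' @return A `model_ladder`: data.frame with `model`, `df_treatment`,
#'   `df_residual`, `r2`, `aic`, `best`, ordered with single terms first
#'   then pairs then the full model.
#' @export
compare_models <- function(data, response,
                           covariates = intersect(c("MAT", "pH", "salinity"),
                                                  names(data))) {
  tl_assert(response %in% names(data), "response not in data")
  tl_assert(length(covariates) >= 1 && all(covariates %in% names(data)),
            "covariates not in data")
  keep <- complete.cases(data[, c(response, covariates), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  tl_assert(n > length(covariates) + 2, "too few complete cases")
  if (length(covariates) > 1) {
    xm <- scale(as.matrix(data[, covariates]))
    kappa_x <- kappa(cbind(1, xm), exact = TRUE)
    if (kappa_x > 30)
      warning(sprintf("collinear covariates (condition number %.1f)", kappa_x))
  }
  subsets <- list(character(0))
  for (k in seq_along(covariates))
    subsets <- c(subsets, combn(covariates, k, simplify = FALSE))
  rows <- lapply(subsets, function(cv) {
    fo <- if (length(cv)) stats::reformulate(cv, response)
          else stats::as.formula(paste(response, "~ 1"))
    fit <- lm(fo, data = data)
    sm <- summary(fit)
    data.frame(model = if (length(cv)) paste(cv, collapse = " + ")
                       else "Intercept",
               df_treatment = length(cv),
               df_residual = unname(fit$df.residual),
               r2 = if (length(cv)) sm$r.squared else NA_real_,
               aic = AIC(fit))
  })
  tab <- do.call(rbind, rows)
  tab$best <- tab$aic == min(tab$aic)
  class(tab) <- c("model_ladder", "data.frame")
  tab
}

#' Segmented (breakpoint) regression
#'
#' Continuous two-segment least squares
#' `y = b0 + b1 x + b2 (x - psi)_+`: the breakpoint `psi` is found by a
#' profiled grid search over the interior unique x-values (1st-99th
#' percentile, ties on RSS resolved to the smaller candidate) refined by
#' golden-section search. The improvement over a single line is tested
#' with an F-test charging the two extra parameters (slope change and
#' breakpoint).
#'
#' @param x predictor, n >= 7 with at least 3 points on each side of every
#'   candidate breakpoint.
#' @param y response.
#' @return A `segmented_fit`: list with `breakpoint`, `slope_before`,
#'   `slope_after`, `intercept`, `r2`, `rss`, `p` (improvement over
#'   linear), `converged`.
#' @export
segmented_regress <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  tl_assert(n >= 7, "need n >= 7")
  xs <- sort(unique(x))
  qs <- quantile(x, c(0.01, 0.99), names = FALSE)
  # candidates must leave >= 3 points strictly on each side
  cand <- xs[xs >= qs[1] & xs <= qs[2]]
  cand <- cand[vapply(cand, function(ps)
    sum(x < ps) >= 3 && sum(x > ps) >= 3, logical(1))]
  tl_assert(length(cand) >= 1, "no interior breakpoint candidates")
  rss_at <- function(ps) {
    xm <- cbind(1, x, pmax(x - ps, 0))
    f <- lm.fit(xm, y)
    sum(f$residuals^2)
  }
  rss_grid <- vapply(cand, rss_at, numeric(1))
  k <- which(rss_grid == min(rss_grid))[1]  # tie -> smaller breakpoint
  # refine between the neighbouring unique x-values (the optimum may fall
  # between the best candidate and the next data point)
  pos <- match(cand[k], xs)
  lo <- if (pos > 1) xs[pos - 1] else xs[pos]
  hi <- if (pos < length(xs)) xs[pos + 1] else xs[pos]
  psi <- .golden(rss_at, lo, hi, tol = 1e-8)
  if (rss_at(cand[k]) < rss_at(psi)) psi <- cand[k]
  xm <- cbind(1, x, pmax(x - psi, 0))
  f <- lm.fit(xm, y)
  rss2 <- sum(f$residuals^2)
  lin <- lm.fit(cbind(1, x), y)
  rss1 <- sum(lin$residuals^2)
  df2 <- n - 4  # b0, b1, b2, psi
  fstat <- if (rss2 > 0) ((rss1 - rss2) / 2) / (rss2 / df2) else Inf
  p <- pf(fstat, 2, df2, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  structure(list(breakpoint = unname(psi),
                 slope_before = unname(f$coefficients[2]),
                 slope_after = unname(f$coefficients[2] + f$coefficients[3]),
                 intercept = unname(f$coefficients[1]),
                 r2 = 1 - rss2 / tss, rss = rss2,
                 rss_linear = rss1, p = p, converged = TRUE, n = n),
            class = "segmented_fit")
}

.golden <- function(fn, lo, hi, tol = 1e-8) {
  if (hi - lo < tol) return((lo + hi) / 2)
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- fn(c1); f2 <- fn(c2)
  while (b - a > tol) {
    if (f1 <= f2) { b <- c2; c2 <- c1; f2 <- f1; c1 <- b - gr * (b - a); f1 <- fn(c1) }
    else { a <- c1; c1 <- c2; f1 <- f2; c2 <- a + gr * (b - a); f2 <- fn(c2) }
  }
  (a + b) / 2
}

#' Levene-type test of variance homogeneity
#'
#' One-way ANOVA on absolute deviations from the group centre; the default
#' centre is the median (Brown-Forsythe variant), with the mean available.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @param center `"median"` (default) or `"mean"`.
#' @return list with `F`, `df` (k - 1, N - k), `p`.
#' @export
levene_test <- function(groups, center = c("median", "mean")) {
  center <- match.arg(center)
  tl_assert(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  tl_assert(all(vapply(groups, length, integer(1)) >= 2),
            "each group needs n >= 2")
  cfun <- if (center == "median") median else mean
  devs <- lapply(groups, function(g) abs(g - cfun(g)))
  g <- factor(rep(seq_along(devs), vapply(devs, length, integer(1))))
  z <- unlist(devs)
  .oneway(z, g)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `F`, `df` (k - 1, N - k), `p`.
#' @export
anova_oneway <- function(groups) {
  tl_assert(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  tl_assert(all(vapply(groups, length, integer(1)) >= 2),
            "each group needs n >= 2")
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  .oneway(unlist(groups), g)
}

.oneway <- function(z, g) {
  k <- nlevels(g); N <- length(z)
  gm <- tapply(z, g, mean); ns <- tapply(z, g, length)
  ssb <- sum(ns * (gm - mean(z))^2)
  ssw <- sum((z - gm[g])^2)
  df1 <- k - 1; df2 <- N - k
  if (ssw == 0) {
    fv <- if (ssb == 0) 0 else Inf
  } else fv <- (ssb / df1) / (ssw / df2)
  list(F = fv, df = c(df1, df2),
       p = pf(fv, df1, df2, lower.tail = FALSE))
}

#' Thermal-variability summary of a temperature series
#'
#' Mean annual temperature, annual range and the percentage of time spent
#' in closed-open temperature bins (default `[-Inf, 28)`, `[28, 31)`,
#' `[31, Inf)` degrees C).
#'
#' @param series numeric temperature series (degrees C), non-empty.
#' @param bins interior bin edges, default `c(28, 31)`.
#' @return A `variability_summary`: list with `mat`, `delta_t`, `bin_freq`
#'   (percentages summing to 100) and `bins`.
#' @export
variability_summary <- function(series, bins = c(28, 31)) {
  tl_assert(length(series) >= 1, "empty series")
  edges <- c(-Inf, sort(bins), Inf)
  counts <- vapply(seq_len(length(edges) - 1L), function(k)
    sum(series >= edges[k] & series < edges[k + 1L]), numeric(1))
  labs <- character(length(counts))
  labs[1] <- sprintf("<%g", edges[2])
  labs[length(labs)] <- sprintf(">=%g", edges[length(edges) - 1L])
  if (length(labs) > 2)
    labs[2:(length(labs) - 1L)] <- sprintf("%g-%g", edges[2:(length(edges) - 2L)],
                                           edges[3:(length(edges) - 1L)])
  structure(list(mat = mean(series),
                 delta_t = max(series) - min(series),
                 bin_freq = setNames(100 * counts / length(series), labs),
                 bins = bins),
            class = "variability_summary")
}

#' Growth rate from an OD600 time series
#'
#' Normalises the series by the initial inoculum OD, classifies the well as
#' no-growth when the maximum raw OD stays below the threshold (default
#' 0.15), and otherwise reports the maximum slope of log(OD) over a sliding
#' window (default 5 points) in per-hour units. Only windows whose
#' readings are all at or above the threshold enter the maximisation
#' (below it, photometric noise dominates the log scale); when fewer than
#' one full window qualifies, all windows are used.
#'
#' @param time_h time points in hours, >= 3, strictly increasing.
#' @param od raw OD600 readings (non-negative).
#' @param threshold no-growth OD threshold, default 0.15.
#' @param window sliding-window length in points, default 5 (capped at the
#'   series length).
#' @return A `growth_result`: list with `grew`, `rate` (per hour, NA when
#'   no growth), `od_max`, `threshold`.
#' @export
growth_rate <- function(time_h, od, threshold = 0.15, window = 5) {
  n <- length(time_h)
  tl_assert(n >= 3, "need >= 3 time points")
  tl_assert(length(od) == n, "length mismatch")
  tl_assert(all(diff(time_h) > 0), "time must be strictly increasing")
  tl_assert(all(od >= 0), "negative OD readings")
  if (max(od) < threshold)
    return(structure(list(grew = FALSE, rate = NA_real_,
                          od_max = max(od), threshold = threshold),
                     class = "growth_result"))
  od0 <- od[1]
  tl_assert(od0 > 0, "initial inoculum OD must be positive for normalisation")
  lg <- log(pmax(od / od0, 1e-8))
  w <- min(window, n)
  starts <- seq_len(n - w + 1L)
  ok <- vapply(starts, function(s) all(od[s:(s + w - 1L)] >= threshold),
               logical(1))
  if (!any(ok)) ok[] <- TRUE
  slopes <- vapply(starts[ok], function(s) {
    idx <- s:(s + w - 1L)
    .ls_slope(time_h[idx], lg[idx])
  }, numeric(1))
  structure(list(grew = TRUE, rate = max(slopes),
                 od_max = max(od), threshold = threshold),
            class = "growth_result")
}
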