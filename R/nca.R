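# Noncompartmental analysis of a pooled (or dense single-subject) profile.
#
# The pooled profile is analysed "as one individual": Cmax/Tmax by peak
# detection, terminal slope by unweighted log-linear regression with
# adjusted-R2 window selection, AUC/AUMC by trapezoids (linear or
# linear-up/log-down), tail extrapolation C_last/lambda_z, MRT = AUMC/AUC.

profile_basis <- function(profile, basis = c("per_time_mean", "raw_points")) {
  basis <- match.arg(basis)
  if (basis == "per_time_mean")
    data.frame(time = profile$summary$time, conc = profile$summary$mean)
  else
    data.frame(time = profile$points$time, conc = profile$points$conc)
}

#' Peak of a pooled profile
#'
#' @param profile a [pool()]ed profile.
#' @param basis `"per_time_mean"` (default: one value per scheduled time) or
#'   `"raw_points"` (every pooled observation).
#' @return list with `cmax` (ug/mL) and `tmax` (h, earliest time attaining
#'   the maximum).
#' @export
find_cmax <- function(profile, basis = c("per_time_mean", "raw_points")) {
  pts <- profile_basis(profile, basis)
  if (all(pts$conc <= 0)) stop_domain("degenerate profile: all concentrations are zero")
  cmax <- max(pts$conc)
  list(cmax = cmax, tmax = min(pts$time[pts$conc == cmax]))
}

#' Terminal slope (lambda-z) by log-linear regression
#'
#' Unweighted least squares of ln(concentration) on time over a terminal
#' window. `"best_adjusted_r2"` evaluates every candidate window ending at
#' the last positive-concentration time with at least `min_points` points,
#' excluding Tmax itself (and always excluding the time-0 baseline, which is
#' undefined on the log scale), and keeps the window maximizing adjusted R^2,
#' breaking ties toward more points. `"manual_window"` uses `window = c(t1, t2)`.
#'
#' @param profile a [pool()]ed profile.
#' @param selection window selection strategy.
#' @param window numeric length-2 time window (h), for `"manual_window"`.
#' @param min_points minimum points in the regression (>= 3).
#' @param basis profile basis, as in [find_cmax()].
#' @return object of class `lambda_z_fit`: `lambda_z` (1/h), `t_half` (h),
#'   `n_points`, `time_window`, `adjusted_r2`, `intercept` (ln-conc at t = 0).
#' @export
fit_lambda_z <- function(profile,
                         selection = c("best_adjusted_r2", "manual_window"),
                         window = NULL, min_points = 3,
                         basis = "per_time_mean") {
  selection <- match.arg(selection)
  if (min_points < 3) stop_validation("min_points must be at least 3")
  pts <- profile_basis(profile, basis)
  pts <- pts[pts$conc > 0, , drop = FALSE]
  pts <- pts[order(pts$time), , drop = FALSE]

  fit_window <- function(t, c) {
    # plain least squares on (t, ln c); done by hand so exact exponential
    # data (zero residuals) do not trip lm's perfect-fit warnings
    y <- log(c)
    k <- length(t)
    tm <- mean(t); ym <- mean(y)
    slope <- sum((t - tm) * (y - ym)) / sum((t - tm)^2)
    intercept <- ym - slope * tm
    rss <- sum((y - intercept - slope * t)^2)
    tss <- sum((y - ym)^2)
    r2 <- if (tss == 0) 0 else 1 - rss / tss
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    list(slope = slope, intercept = intercept, adjusted_r2 = adj, n = k)
  }

  if (selection == "manual_window") {
    if (is.null(window) || length(window) != 2)
      stop_validation("manual_window selection needs window = c(t1, t2)")
    sel <- pts$time >= window[1] & pts$time <= window[2]
    if (sum(sel) < min_points)
      stop_pk("pooledPK_insufficient_data",
              "only %d positive points in window [%g, %g]; need %d",
              sum(sel), window[1], window[2], min_points)
    best <- fit_window(pts$time[sel], pts$conc[sel])
    win <- window
  } else {
    tmax <- find_cmax(profile, basis)$tmax
    cand <- pts[pts$time > tmax, , drop = FALSE]
    m <- nrow(cand)
    if (m < min_points) {
      if (tmax >= max(pts$time))
        stop_pk("pooledPK_no_terminal_phase",
                "no terminal phase: the profile rises to its last observation at %g h",
                tmax)
      stop_pk("pooledPK_insufficient_data",
              "only %d positive points after Tmax = %g h; need %d",
              m, tmax, min_points)
    }
    best <- NULL
    for (i in seq_len(m - min_points + 1)) {
      f <- fit_window(cand$time[i:m], cand$conc[i:m])
      f$first <- cand$time[i]
      if (is.null(best) || f$adjusted_r2 > best$adjusted_r2 + 1e-12 ||
          (abs(f$adjusted_r2 - best$adjusted_r2) <= 1e-12 && f$n > best$n))
        best <- f
    }
    win <- c(best$first, cand$time[m])
  }
  if (best$slope >= 0)
    stop_pk("pooledPK_no_terminal_phase",
            "no terminal phase: slope %.4g is non-negative in the best window",
            best$slope)
  lambda <- -best$slope
  structure(list(lambda_z = lambda, t_half = log(2) / lambda,
                 n_points = best$n, time_window = win,
                 adjusted_r2 = best$adjusted_r2, intercept = best$intercept,
                 selection = selection),
            class = "lambda_z_fit")
}

#' @export
print.lambda_z_fit <- function(x, ...) {
  cat(sprintf(
    "lambda-z fit: lambda = %.4g 1/h, t1/2 = %.3g h (%d points on [%g, %g] h, adj R2 = %.4f)\n",
    x$lambda_z, x$t_half, x$n_points, x$time_window[1], x$time_window[2],
    x$adjusted_r2))
  invisible(x)
}

# integral of a single segment; rule applies log-trapezoid on strictly
# decreasing positive segments, linear otherwise
segment_auc <- function(t1, t2, c1, c2, rule) {
  if (rule == "linlog" && c2 < c1 && c1 > 0 && c2 > 0)
    (t2 - t1) * (c1 - c2) / log(c1 / c2)
  else
    (t2 - t1) * (c1 + c2) / 2
}

# integral of t*C(t) on one segment under the same interpolant
segment_aumc <- function(t1, t2, c1, c2, rule) {
  if (rule == "linlog" && c2 < c1 && c1 > 0 && c2 > 0) {
    k <- log(c1 / c2) / (t2 - t1)
    (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2
  } else {
    (t2 - t1) * (t1 * c1 + t2 * c2) / 2
  }
}

# concentration at time t interpolated inside segment (t1,c1)-(t2,c2)
segment_interp <- function(t, t1, t2, c1, c2, rule) {
  if (rule == "linlog" && c2 < c1 && c1 > 0 && c2 > 0)
    c1 * (c2 / c1)^((t - t1) / (t2 - t1))
  else
    c1 + (c2 - c1) * (t - t1) / (t2 - t1)
}

check_points <- function(points) {
  if (is.unsorted(points$time, strictly = FALSE))
    stop_validation("times must be sorted increasing")
  if (anyDuplicated(points$time))
    stop_validation("duplicate times: average replicates first (per_time_mean basis)")
}

#' Trapezoidal area under the curve
#'
#' `"linear"` uses the ordinary trapezoid on every segment;
#' `"linlog"` (linear-up/log-down) uses the log-trapezoid
#' `(t2 - t1)(C1 - C2)/ln(C1/C2)` on strictly decreasing positive segments
#' and the linear rule otherwise. Partial segments at interval ends are
#' interpolated consistently with the segment's rule.
#'
#' @param points data.frame with sorted unique `time` and `conc`.
#' @param rule `"linear"` or `"linlog"`.
#' @param interval `c(t_start, t_end)` within the observed range; default the
#'   full range.
#' @return AUC in ug*h/mL.
#' @export
auc_trapezoid <- function(points, rule = c("linlog", "linear"), interval = NULL) {
  rule <- match.arg(rule)
  integrate_profile(points, rule, interval, segment_auc)
}

integrate_profile <- function(points, rule, interval, seg_fun) {
  points <- as.data.frame(points)[, c("time", "conc")]
  check_points(points)
  t <- points$time; c <- points$conc
  if (is.null(interval)) interval <- range(t)
  if (interval[1] < t[1] || interval[2] > t[length(t)] || interval[1] >= interval[2])
    stop_validation("interval [%g, %g] must lie within the observed range [%g, %g]",
                    interval[1], interval[2], t[1], t[length(t)])
  total <- 0
  for (i in seq_len(length(t) - 1)) {
    a <- max(t[i], interval[1]); b <- min(t[i + 1], interval[2])
    if (a >= b) next
    ca <- if (a == t[i]) c[i] else segment_interp(a, t[i], t[i + 1], c[i], c[i + 1], rule)
    cb <- if (b == t[i + 1]) c[i + 1] else segment_interp(b, t[i], t[i + 1], c[i], c[i + 1], rule)
    total <- total + seg_fun(a, b, ca, cb, rule)
  }
  total
}

#' Extrapolate AUC to infinity
#'
#' Adds the monoexponential tail `C_last / lambda_z` beyond the last
#' observation; `C_last` is the observed last concentration or the value
#' predicted at `t_last` by the lambda-z regression.
#'
#' @param auc_0_t AUC up to the last observation (ug*h/mL).
#' @param last_point `c(t_last, C_last)` observed.
#' @param lambda_fit a [fit_lambda_z()] result.
#' @param clast_basis `"observed"` or `"predicted"`.
#' @return list with `auc_0_inf` and `extrapolated_fraction`.
#' @export
extrapolate_auc <- function(auc_0_t, last_point, lambda_fit,
                            clast_basis = c("observed", "predicted")) {
  clast_basis <- match.arg(clast_basis)
  if (last_point[2] <= 0) stop_validation("last concentration must be positive")
  clast <- if (clast_basis == "observed") last_point[2]
           else exp(lambda_fit$intercept - lambda_fit$lambda_z * last_point[1])
  tail <- clast / lambda_fit$lambda_z
  auc_inf <- auc_0_t + tail
  list(auc_0_inf = auc_inf, extrapolated_fraction = tail / auc_inf)
}

#' AUMC to infinity and mean residence time
#'
#' AUMC by trapezoids on the first-moment curve t*C(t) (segment interpolant
#' matching `rule`) plus the analytic tail
#' `C_last*t_last/lambda + C_last/lambda^2`; MRT = AUMC(0-inf)/AUC(0-inf).
#' The extravascular MRT is reported as-is, with no absorption correction.
#' With `lambda_fit = NULL` the truncated (no-tail) MRT over the observed
#' range is returned.
#'
#' @inheritParams auc_trapezoid
#' @inheritParams extrapolate_auc
#' @return list with `aumc_0_inf` (ug*h^2/mL) and `mrt` (h).
#' @export
aumc_and_mrt <- function(points, lambda_fit = NULL, rule = c("linlog", "linear"),
                         clast_basis = c("observed", "predicted")) {
  rule <- match.arg(rule)
  clast_basis <- match.arg(clast_basis)
  points <- as.data.frame(points)[, c("time", "conc")]
  check_points(points)
  aumc <- integrate_profile(points, rule, NULL, segment_aumc)
  auc <- integrate_profile(points, rule, NULL, segment_auc)
  n <- nrow(points)
  if (!is.null(lambda_fit)) {
    tl <- points$time[n]
    clast <- if (clast_basis == "observed") points$conc[n]
             else exp(lambda_fit$intercept - lambda_fit$lambda_z * tl)
    lam <- lambda_fit$lambda_z
    aumc <- aumc + clast * tl / lam + clast / lam^2
    auc <- auc + clast / lam
  }
  list(aumc_0_inf = aumc, mrt = aumc / auc)
}

#' Options for a noncompartmental analysis run
#'
#' @param basis profile basis: `"per_time_mean"` (default, the naive pooled
#'   convention) or `"raw_points"`.
#' @param rule AUC rule, `"linlog"` (default) or `"linear"`.
#' @param lambda_selection `"best_adjusted_r2"` or `"manual_window"`.
#' @param lambda_window window for manual selection.
#' @param min_points minimum lambda-z points.
#' @param clast_basis `"observed"` or `"predicted"` last concentration.
#' @return a list of class `nca_options`.
#' @export
nca_options <- function(basis = "per_time_mean", rule = "linlog",
                        lambda_selection = "best_adjusted_r2",
                        lambda_window = NULL, min_points = 3,
                        clast_basis = "observed") {
  structure(list(basis = basis, rule = rule,
                 lambda_selection = lambda_selection,
                 lambda_window = lambda_window, min_points = min_points,
                 clast_basis = clast_basis), class = "nca_options")
}

#' Noncompartmental analysis of a pooled profile
#'
#' Orchestrates peak detection, lambda-z regression, trapezoidal AUC over the
#' observed range and over 0-24 h, tail extrapolation, AUMC and MRT. Every
#' option used is recorded in the result for provenance.
#'
#' @param profile a [pool()]ed profile.
#' @param options an [nca_options()] object.
#' @return object of class `nca` with the full parameter panel; see
#'   [coef.nca()].
#' @export
run_nca <- function(profile, options = nca_options()) {
  peak <- find_cmax(profile, options$basis)
  lam <- fit_lambda_z(profile, options$lambda_selection,
                      window = options$lambda_window,
                      min_points = options$min_points, basis = options$basis)
  pts <- profile_basis(profile, options$basis)
  # duplicate times break trapezoids; the per_time_mean basis guarantees
  # uniqueness, raw_points does not
  pts <- pts[order(pts$time), , drop = FALSE]
  tlast <- max(pts$time)
  clast_obs <- pts$conc[nrow(pts)]
  auc_0_t <- auc_trapezoid(pts, options$rule, c(min(pts$time), tlast))
  auc_0_24 <- if (tlast >= 24) {
    auc_trapezoid(pts, options$rule, c(min(pts$time), 24))
  } else {
    # extend with the monoexponential tail from t_last to 24 h
    clast <- if (options$clast_basis == "observed") clast_obs
             else exp(lam$intercept - lam$lambda_z * tlast)
    auc_0_t + clast / lam$lambda_z * (1 - exp(-lam$lambda_z * (24 - tlast)))
  }
  ext <- extrapolate_auc(auc_0_t, c(tlast, clast_obs), lam, options$clast_basis)
  mom <- aumc_and_mrt(pts, lam, options$rule, options$clast_basis)
  structure(list(
    cmax = peak$cmax, tmax = peak$tmax, lambda_fit = lam,
    auc_0_t = auc_0_t, auc_0_24 = auc_0_24,
    auc_0_inf = ext$auc_0_inf, extrapolated_fraction = ext$extrapolated_fraction,
    aumc_0_inf = mom$aumc_0_inf, mrt = mom$mrt,
    options = options, n_points = nrow(pts), t_last = tlast
  ), class = "nca")
}

#' @export
coef.nca <- function(object, ...) {
  c(cmax = object$cmax, tmax = object$tmax,
    lambda_z = object$lambda_fit$lambda_z, t_half = object$lambda_fit$t_half,
    auc_0_t = object$auc_0_t, auc_0_24 = object$auc_0_24,
    auc_0_inf = object$auc_0_inf, aumc_0_inf = object$aumc_0_inf,
    mrt = object$mrt, extrapolated_fraction = object$extrapolated_fraction)
}

#' @export
print.nca <- function(x, digits = 4, ...) {
  cat("Noncompartmental analysis (naive pooled profile)\n")
  cat(sprintf("  basis: %s; AUC rule: %s; lambda-z: %s (%d points on [%g, %g] h)\n",
              x$options$basis, x$options$rule, x$options$lambda_selection,
              x$lambda_fit$n_points, x$lambda_fit$time_window[1],
              x$lambda_fit$time_window[2]))
  print(signif(coef(x), digits))
  invisible(x)
}

#' @export
summary.nca <- function(object, ...) {
  as.data.frame(object)
}

#' Flat parameter report
#'
#' One row per parameter (name, value, units), the serialization shared with
#' the compartmental fit.
#' @param x an `nca` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.nca <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    parameter = c("Cmax", "Tmax", "lambda_z", "t_half", "AUC_0_t", "AUC_0_24",
                  "AUC_0_inf", "AUMC_0_inf", "MRT", "extrapolated_fraction"),
    value = unname(coef(x)[c("cmax", "tmax", "lambda_z", "t_half", "auc_0_t",
                             "auc_0_24", "auc_0_inf", "aumc_0_inf", "mrt",
                             "extrapolated_fraction")]),
    units = c("ug/mL", "h", "1/h", "h", "ug*h/mL", "ug*h/mL", "ug*h/mL",
              "ug*h^2/mL", "h", ""),
    method = "nca")
}

#' Write a parameter report CSV
#'
#' @param x an `nca` object or `onecomp_fit`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_report <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
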