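# PK/PD ratio assessment and Monte Carlo probability of target attainment.
#
# Fluoroquinolone efficacy targets: Cmax/MIC >= 10 and AUC0-24/MIC >= 125
# (120 accepted via config). PTA at a MIC is the fraction of simulated
# subjects whose exposure attains a target; the PK/PD cutoff is the largest
# MIC on the dilution grid where PTA still meets the adequacy level (~90%).

#' PK/PD efficacy targets
#'
#' @param cmax_over_mic_threshold minimum Cmax/MIC ratio (default 10).
#' @param auc24_over_mic_threshold minimum AUC0-24/MIC ratio in h
#'   (default 125; 120 is the other commonly used value).
#' @param pta_adequacy_level PTA level regarded as adequate (default 0.90).
#' @return object of class `pkpd_targets`.
#' @export
pkpd_targets <- function(cmax_over_mic_threshold = 10,
                         auc24_over_mic_threshold = 125,
                         pta_adequacy_level = 0.90) {
  if (cmax_over_mic_threshold <= 0 || auc24_over_mic_threshold <= 0)
    stop_domain("thresholds must be positive")
  if (pta_adequacy_level <= 0 || pta_adequacy_level > 1)
    stop_domain("pta_adequacy_level must be in (0, 1]")
  structure(list(cmax_over_mic_threshold = cmax_over_mic_threshold,
                 auc24_over_mic_threshold = auc24_over_mic_threshold,
                 pta_adequacy_level = pta_adequacy_level),
            class = "pkpd_targets")
}

exposure_values <- function(x) {
  if (inherits(x, "nca")) c(cmax = x$cmax, auc_0_24 = x$auc_0_24)
  else if (inherits(x, "onecomp_fit")) {
    p <- x$params
    auc24 <- p$dose_mg_per_kg / (p$v_over_f * p$ke) -
      auc_tail_onecomp(p, 24)
    c(cmax = x$derived$cmax, auc_0_24 = auc24)
  } else if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    if (is.null(x$cmax) || is.null(x$auc_0_24))
      stop_validation("need named elements cmax and auc_0_24")
    c(cmax = x$cmax, auc_0_24 = x$auc_0_24)
  } else stop_validation("cannot extract exposures from class %s", class(x)[1])
}

# analytic AUC from 24h to infinity under the one-compartment model
auc_tail_onecomp <- function(p, t) {
  p$dose_mg_per_kg * p$ka / (p$v_over_f * (p$ka - p$ke)) *
    (exp(-p$ke * t) / p$ke - exp(-p$ka * t) / p$ka)
}

#' Assess PK/PD ratios at a MIC breakpoint
#'
#' @param x an `nca` result, `onecomp_fit`, or a list/vector with `cmax`
#'   (ug/mL) and `auc_0_24` (ug*h/mL).
#' @param mic minimum inhibitory concentration (ug/mL, > 0).
#' @param targets a [pkpd_targets()] object.
#' @return object of class `pkpd_assessment` with the ratios and per-target
#'   attainment flags (thresholds are inclusive).
#' @export
assess_pkpd <- function(x, mic, targets = pkpd_targets()) {
  if (!is.numeric(mic) || length(mic) != 1 || mic <= 0)
    stop_domain("mic must be a single positive number")
  e <- exposure_values(x)
  cm <- unname(e["cmax"]) / mic
  au <- unname(e["auc_0_24"]) / mic
  structure(list(
    mic = mic, cmax_over_mic = cm, auc24_over_mic = au,
    # inclusive thresholds, with a tiny relative tolerance so a ratio that is
    # exactly at the target up to floating-point rounding counts as attained
    attained = c(cmax = cm >= targets$cmax_over_mic_threshold * (1 - 1e-9),
                 auc_0_24 = au >= targets$auc24_over_mic_threshold * (1 - 1e-9)),
    targets = targets), class = "pkpd_assessment")
}

#' @export
print.pkpd_assessment <- function(x, ...) {
  cat(sprintf("PK/PD assessment at MIC = %g ug/mL\n", x$mic))
  cat(sprintf("  Cmax/MIC     = %.3g  (target >= %g: %s)\n", x$cmax_over_mic,
              x$targets$cmax_over_mic_threshold,
              if (x$attained["cmax"]) "attained" else "not attained"))
  cat(sprintf("  AUC0-24/MIC  = %.3g  (target >= %g: %s)\n", x$auc24_over_mic,
              x$targets$auc24_over_mic_threshold,
              if (x$attained["auc_0_24"]) "attained" else "not attained"))
  invisible(x)
}

#' Lognormal exposure distribution for PTA simulation
#'
#' Population variability of Cmax and AUC0-24 is modelled as correlated
#' lognormals parameterized by geometric mean and coefficient of variation
#' (`sdlog = sqrt(log(1 + CV^2))`).
#'
#' @param cmax_gm geometric mean Cmax (ug/mL).
#' @param auc24_gm geometric mean AUC0-24 (ug*h/mL).
#' @param cmax_cv,auc24_cv coefficients of variation (fractions, >= 0).
#' @param correlation log-scale correlation between Cmax and AUC0-24.
#' @return object of class `exposure_distribution`.
#' @export
exposure_distribution <- function(cmax_gm, auc24_gm, cmax_cv = 0.30,
                                  auc24_cv = 0.30, correlation = 0.8) {
  if (cmax_gm <= 0 || auc24_gm <= 0) stop_domain("geometric means must be positive")
  if (cmax_cv < 0 || auc24_cv < 0) stop_domain("CVs must be non-negative")
  if (abs(correlation) > 1) stop_domain("correlation must lie in [-1, 1]")
  structure(list(cmax_gm = cmax_gm, auc24_gm = auc24_gm, cmax_cv = cmax_cv,
                 auc24_cv = auc24_cv, correlation = correlation),
            class = "exposure_distribution")
}

#' Simulate exposures for sham subjects
#'
#' Draws n correlated lognormal (Cmax, AUC0-24) pairs; reproducible given
#' the seed, and with CV = 0 every draw equals the geometric means.
#'
#' @param dist an [exposure_distribution()].
#' @param n number of simulated subjects (>= 1).
#' @param seed RNG seed.
#' @return data.frame with columns `cmax` and `auc_0_24`.
#' @export
simulate_exposures <- function(dist, n, seed = 1L) {
  if (n < 1) stop_validation("n must be at least 1")
  set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- dist$correlation * z1 +
    sqrt(1 - dist$correlation^2) * stats::rnorm(n)
  s1 <- sqrt(log1p(dist$cmax_cv^2))
  s2 <- sqrt(log1p(dist$auc24_cv^2))
  data.frame(cmax = dist$cmax_gm * exp(s1 * z1),
             auc_0_24 = dist$auc24_gm * exp(s2 * z2))
}

#' Conventional MIC doubling-dilution grid
#'
#' The microbiological dilution series snaps sub-0.1 doublings to their
#' conventional labels (0.03, 0.06) and keeps exact powers of two above:
#' `mic_dilution_grid(0.03, 8)` gives 0.03, 0.06, 0.125, 0.25, 0.5, 1, 2,
#' 4, 8.
#'
#' @param low,high grid endpoints (ug/mL, `0 < low < high`), inclusive.
#' @return numeric vector of MICs.
#' @export
mic_dilution_grid <- function(low, high) {
  if (low <= 0 || low >= high)
    stop_domain("need 0 < low < high for a dilution grid")
  k <- seq(round(log2(low)), round(log2(high)))
  v <- 2^k
  ifelse(v < 0.1, round(v, 2), v)
}

#' Monte Carlo probability of target attainment
#'
#' Simulates one cohort of sham subjects and, at each MIC of the grid,
#' computes the fraction attaining the Cmax/MIC target, the AUC0-24/MIC
#' target, and both jointly. Because the same draws are reused across the
#' grid, PTA is nonincreasing in MIC by construction (asserted on every
#' run). The PK/PD cutoff is the largest MIC at which PTA is at least the
#' adequacy level, reported per target and jointly.
#'
#' @param dist an [exposure_distribution()].
#' @param mic_grid positive, sorted MIC values (ug/mL); see
#'   [mic_dilution_grid()].
#' @param targets a [pkpd_targets()].
#' @param n number of sham subjects (default 1000).
#' @param seed RNG seed (recorded in the result).
#' @return object of class `pta`: `pta` (data.frame mic, pta_cmax, pta_auc,
#'   pta_joint), `cutoff` (named vector), `n`, `seed`, `targets`.
#' @export
run_pta <- function(dist, mic_grid, targets = pkpd_targets(), n = 1000,
                    seed = 1L) {
  if (length(mic_grid) == 0) stop_validation("mic_grid must be nonempty")
  if (any(mic_grid <= 0) || is.unsorted(mic_grid))
    stop_validation("mic_grid must be positive and sorted increasing")
  draws <- simulate_exposures(dist, n, seed)
  pta_cmax <- vapply(mic_grid, function(m)
    mean(draws$cmax >= targets$cmax_over_mic_threshold * m), numeric(1))
  pta_auc <- vapply(mic_grid, function(m)
    mean(draws$auc_0_24 >= targets$auc24_over_mic_threshold * m), numeric(1))
  pta_joint <- vapply(mic_grid, function(m)
    mean(draws$cmax >= targets$cmax_over_mic_threshold * m &
         draws$auc_0_24 >= targets$auc24_over_mic_threshold * m), numeric(1))
  stopifnot(!is.unsorted(rev(pta_cmax)), !is.unsorted(rev(pta_auc)),
            !is.unsorted(rev(pta_joint)))
  cutoff_of <- function(p) {
    ok <- which(p >= targets$pta_adequacy_level)
    if (length(ok)) mic_grid[max(ok)] else NA_real_
  }
  structure(list(
    pta = data.frame(mic = mic_grid, pta_cmax = pta_cmax, pta_auc = pta_auc,
                     pta_joint = pta_joint),
    cutoff = c(cmax = cutoff_of(pta_cmax), auc_0_24 = cutoff_of(pta_auc),
               joint = cutoff_of(pta_joint)),
    n = n, seed = seed, targets = targets, dist = dist
  ), class = "pta")
}

#' @export
print.pta <- function(x, ...) {
  cat(sprintf("Probability of target attainment (%d sham subjects, seed %s)\n",
              x$n, format(x$seed)))
  print(transform(x$pta, pta_cmax = round(pta_cmax, 3),
                  pta_auc = round(pta_auc, 3),
                  pta_joint = round(pta_joint, 3)), row.names = FALSE)
  cat(sprintf("  PK/PD cutoff at >= %.0f%% PTA: Cmax target %s, AUC target %s, joint %s ug/mL\n",
              100 * x$targets$pta_adequacy_level,
              format(x$cutoff["cmax"]), format(x$cutoff["auc_0_24"]),
              format(x$cutoff["joint"])))
  invisible(x)
}

#' @export
plot.pta <- function(x, ...) {
  graphics::matplot(x$pta$mic, 100 * as.matrix(x$pta[, c("pta_cmax", "pta_auc")]),
                    type = "b", pch = c(1, 2), lty = 1, log = "x",
                    col = c("steelblue", "firebrick"),
                    xlab = "MIC (ug/mL)", ylab = "PTA (%)",
                    main = "Probability of target attainment", ...)
  graphics::abline(h = 100 * x$targets$pta_adequacy_level, lty = 3)
  graphics::legend("bottomleft", c("Cmax/MIC", "AUC0-24/MIC"), pch = c(1, 2),
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Long-format PTA table
#'
#' One row per (mic, target): columns mic, target, pta, n, seed — the CSV
#' serialization of a PTA run.
#' @param x a `pta` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.pta <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    mic = rep(x$pta$mic, 3),
    target = rep(c("cmax_over_mic", "auc24_over_mic", "joint"),
                 each = nrow(x$pta)),
    pta = c(x$pta$pta_cmax, x$pta$pta_auc, x$pta$pta_joint),
    n = x$n, seed = x$seed)
}
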