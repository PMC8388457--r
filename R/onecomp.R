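# One-compartment model with first-order absorption (extravascular dose):
#
#   C(t) = D*ka / (V/F * (ka - ke)) * (exp(-ke*t) - exp(-ka*t))
#
# with the limiting form C(t) = D/(V/F) * ke * t * exp(-ke*t) at ka = ke.
# Dose D is mg/kg and V/F is L/kg, so C is in ug/mL.

#' One-compartment model parameters
#'
#' @param ka absorption rate constant (1/h).
#' @param ke elimination rate constant (1/h).
#' @param v_over_f apparent volume of distribution over bioavailability (L/kg).
#' @param dose_mg_per_kg dose (mg/kg).
#' @return object of class `onecomp_params`.
#' @export
onecomp_params <- function(ka, ke, v_over_f, dose_mg_per_kg = 10) {
  if (any(c(ka, ke, v_over_f, dose_mg_per_kg) <= 0))
    stop_domain("ka, ke, v_over_f and dose must all be strictly positive")
  structure(list(ka = ka, ke = ke, v_over_f = v_over_f,
                 dose_mg_per_kg = dose_mg_per_kg), class = "onecomp_params")
}

#' Predicted concentration under the one-compartment oral model
#'
#' Closed-form evaluation; at the flip-flop degeneracy ka = ke (relative
#' difference below 1e-10) the limiting form `D/(V/F)*ke*t*exp(-ke*t)` is used.
#'
#' @param params an [onecomp_params()] object.
#' @param times numeric vector of times (h, >= 0).
#' @return concentrations in ug/mL.
#' @export
predict_concentration <- function(params, times) {
  if (any(times < 0)) stop_validation("times must be non-negative")
  ka <- params$ka; ke <- params$ke
  scale <- params$dose_mg_per_kg / params$v_over_f
  if (abs(ka - ke) <= 1e-10 * max(ka, ke))
    scale * ke * times * exp(-ke * times)
  else
    scale * ka / (ka - ke) * (exp(-ke * times) - exp(-ka * times))
}

#' Closed-form secondary parameters
#'
#' `tmax = ln(ka/ke)/(ka - ke)` (symmetric in ka, ke; `1/ke` at ka = ke),
#' `cmax = C(tmax)`, `auc_0_inf = D/((V/F)*ke)`, `t_half = ln(2)/ke`.
#'
#' @param params an [onecomp_params()] object.
#' @return list with `tmax` (h), `cmax` (ug/mL), `auc_0_inf` (ug*h/mL),
#'   `t_half` (h).
#' @export
secondary_parameters <- function(params) {
  ka <- params$ka; ke <- params$ke
  tmax <- if (abs(ka - ke) <= 1e-10 * max(ka, ke)) 1 / ke
          else log(ka / ke) / (ka - ke)
  list(tmax = tmax, cmax = predict_concentration(params, tmax),
       auc_0_inf = params$dose_mg_per_kg / (params$v_over_f * ke),
       t_half = log(2) / ke)
}

# deterministic starting values: ke from lambda-z, ka by inverting the tmax
# formula at the empirical peak, V/F by matching the empirical Cmax
auto_init <- function(profile, dose) {
  peak <- find_cmax(profile, "per_time_mean")
  ke0 <- tryCatch(fit_lambda_z(profile)$lambda_z,
                  pooledPK_error = function(e) log(2) / max(profile$summary$time) * 3)
  ka0 <- tryCatch({
    g <- function(ka) log(ka / ke0) / (ka - ke0) - peak$tmax
    stats::uniroot(g, lower = ke0 * (1 + 1e-6), upper = ke0 * 1e4,
                   tol = 1e-10)$root
  }, error = function(e) 5 * ke0)
  ctmax <- ka0 / (ka0 - ke0) * (exp(-ke0 * peak$tmax) - exp(-ka0 * peak$tmax))
  v0 <- dose * ctmax / peak$cmax
  onecomp_params(ka0, ke0, max(v0, 1e-6), dose)
}

#' Fit the one-compartment oral model to pooled data
#'
#' Weighted nonlinear least squares of predicted vs observed concentrations
#' over (ka, ke, V/F), with positivity enforced by optimizing on the log
#' scale (Levenberg-Marquardt, iteration cap 500, relative tolerance 1e-10).
#' Time-zero and other non-positive observations are excluded. If the
#' optimum lands on the flip-flop mirror branch (ka < ke), the reported
#' parameters are the equivalent conventional branch (ka > ke, with V/F
#' rescaled by ke/ka) and `flip_flop = TRUE` flags it.
#'
#' @param data a [concentration_records()] table or [pool()]ed profile.
#' @param dose_mg_per_kg dose (mg/kg).
#' @param init starting [onecomp_params()], or `"auto"` for deterministic
#'   starts derived from the empirical peak and terminal slope.
#' @param weighting `"uniform"`, `"one_over_c"` or `"one_over_c2"` residual
#'   weights (by the observed concentration).
#' @return object of class `onecomp_fit`: `params`, `rss`, `weighting`,
#'   `derived` (secondary parameters), `convergence`, `flip_flop`, `data`,
#'   `fitted`.
#' @export
fit_onecomp <- function(data, dose_mg_per_kg = 10, init = "auto",
                        weighting = c("uniform", "one_over_c", "one_over_c2")) {
  weighting <- match.arg(weighting)
  profile <- if (inherits(data, "pooled_profile")) data else pool(data)
  obs <- profile$points[profile$points$conc > 0, , drop = FALSE]
  if (nrow(obs) < 4)
    stop_pk("pooledPK_insufficient_data",
            "need at least 4 positive observations to fit 3 parameters; have %d",
            nrow(obs))
  if (identical(init, "auto")) init <- auto_init(profile, dose_mg_per_kg)
  w <- switch(weighting, uniform = rep(1, nrow(obs)),
              one_over_c = 1 / obs$conc, one_over_c2 = 1 / obs$conc^2)
  resid_fun <- function(theta) {
    p <- onecomp_params(exp(theta[1]), exp(theta[2]), exp(theta[3]),
                        dose_mg_per_kg)
    sqrt(w) * (predict_concentration(p, obs$time) - obs$conc)
  }
  start <- log(c(init$ka, init$ke, init$v_over_f))
  out <- minpack.lm::nls.lm(par = start, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-10, ptol = 1e-12))
  if (out$info == 0 || out$info == 5)
    stop_convergence("one-compartment fit did not converge (info %d after %d iterations): %s",
                     out$info, out$niter, out$message)
  est <- exp(out$par)
  flip <- est[1] < est[2]
  raw <- onecomp_params(est[1], est[2], est[3], dose_mg_per_kg)
  params <- if (flip)
    onecomp_params(est[2], est[1], est[3] * est[2] / est[1], dose_mg_per_kg)
  else raw
  fitted <- predict_concentration(params, obs$time)
  structure(list(
    params = params, raw_params = raw, flip_flop = flip,
    rss = sum(w * (fitted - obs$conc)^2), weighting = weighting,
    derived = secondary_parameters(params),
    convergence = list(info = out$info, message = out$message,
                       niter = out$niter),
    data = obs, fitted = fitted
  ), class = "onecomp_fit")
}

#' @export
coef.onecomp_fit <- function(object, ...) {
  c(ka = object$params$ka, ke = object$params$ke,
    v_over_f = object$params$v_over_f)
}

#' @export
print.onecomp_fit <- function(x, digits = 4, ...) {
  cat("One-compartment first-order absorption fit (naive pooled)\n")
  print(signif(coef(x), digits))
  d <- x$derived
  cat(sprintf("  Cmax %.3g ug/mL at Tmax %.3g h; AUC0-inf %.4g ug*h/mL; t1/2 %.3g h\n",
              d$cmax, d$tmax, d$auc_0_inf, d$t_half))
  cat(sprintf("  RSS %.4g (%s weighting), %d iterations%s\n", x$rss, x$weighting,
              x$convergence$niter,
              if (x$flip_flop) "; flip-flop mirror detected, conventional branch reported"
              else ""))
  invisible(x)
}

#' @export
predict.onecomp_fit <- function(object, newdata = NULL, ...) {
  times <- if (is.null(newdata)) object$data$time
           else if (is.data.frame(newdata)) newdata$time else as.numeric(newdata)
  predict_concentration(object$params, times)
}

#' @export
residuals.onecomp_fit <- function(object, ...) {
  object$data$conc - object$fitted
}

#' @export
fitted.onecomp_fit <- function(object, ...) object$fitted

#' @export
simulate.onecomp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(object$rss / max(1, nrow(object$data) - 3))
  mu <- object$fitted
  out <- as.data.frame(replicate(nsim, pmax(0, mu + stats::rnorm(length(mu), 0, sigma))))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(time = object$data$time, out)
}

#' @export
plot.onecomp_fit <- function(x, log = "", ...) {
  tg <- seq(0, max(x$data$time) * 1.05, length.out = 200)
  graphics::plot(x$data$time, x$data$conc, log = log,
                 xlab = "time (h)", ylab = "concentration (ug/mL)",
                 main = "One-compartment fit to pooled data", ...)
  graphics::lines(tg, predict_concentration(x$params, tg), col = "steelblue")
  invisible(x)
}

#' @export
as.data.frame.onecomp_fit <- function(x, row.names = NULL, optional = FALSE, ...) {
  d <- x$derived
  data.frame(
    parameter = c("ka", "ke", "V_over_F", "Cmax", "Tmax", "AUC_0_inf", "t_half"),
    value = c(x$params$ka, x$params$ke, x$params$v_over_f,
              d$cmax, d$tmax, d$auc_0_inf, d$t_half),
    units = c("1/h", "1/h", "L/kg", "ug/mL", "h", "ug*h/mL", "h"),
    method = "one_compartment")
}
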