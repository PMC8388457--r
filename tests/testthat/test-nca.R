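# noncompartmental engine: peak, terminal slope, trapezoids, tail, MRT

test_that("peak detection works on both bases with earliest-time tie-break", {
  prof <- pool(enro_cats())
  expect_equal(find_cmax(prof, "per_time_mean"), list(cmax = 2.22, tmax = 2))
  expect_equal(find_cmax(prof, "raw_points"), list(cmax = 2.6, tmax = 2))
  one <- profile_of(1, 0.5)
  expect_equal(find_cmax(one), list(cmax = 0.5, tmax = 1))
  tie <- profile_of(c(1, 2, 3), c(1, 2, 2))
  expect_equal(find_cmax(tie)$tmax, 2)
  zero <- pool(concentration_records(c("a", "b"), c(0, 1), c(0, 0)))
  expect_error(find_cmax(zero), class = "pooledPK_domain_error")
})

test_that("lambda-z is exact on exponential data, any window", {
  prof <- profile_of(c(8, 12, 16), c(1.0, 0.5, 0.25))
  fit <- fit_lambda_z(prof, "manual_window", window = c(8, 16))
  expect_equal(fit$lambda_z, log(2) / 4, tolerance = 1e-12)
  expect_equal(fit$t_half, 4.0, tolerance = 1e-12)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-9)

  dense <- profile_of(seq(2, 40, by = 2), 5 * exp(-0.21 * seq(2, 40, by = 2)))
  for (w in list(c(2, 40), c(10, 30), c(20, 40))) {
    f <- fit_lambda_z(dense, "manual_window", window = w)
    expect_equal(f$lambda_z, 0.21, tolerance = 1e-10)
  }
})

test_that("lambda-z on the pooled study means matches hand regression", {
  prof <- pool(enro_cats())
  fit <- fit_lambda_z(prof, "manual_window", window = c(8, 24))
  # frozen from an independent lm(log(c) ~ t) on (8, 1.0), (12, 0.4), (24, 0.216)
  expect_equal(fit$lambda_z, 0.08552651, tolerance = 1e-6)
  expect_equal(fit$n_points, 3)
  # automatic selection considers windows after Tmax = 2 h and reports its pick
  auto <- fit_lambda_z(prof)
  expect_true(auto$time_window[1] > 2)
  expect_equal(auto$time_window[2], 24)
  expect_true(auto$lambda_z > 0)
})

test_that("degenerate terminal phases raise classed errors", {
  rising <- profile_of(c(1, 2, 4, 8, 12), c(0.1, 0.2, 0.4, 0.8, 1.6))
  expect_error(fit_lambda_z(rising), class = "pooledPK_no_terminal_phase")
  two <- profile_of(c(1, 2, 4), c(1, 2, 1))
  expect_error(fit_lambda_z(two), class = "pooledPK_insufficient_data")
})

test_that("trapezoid rules match geometry and closed forms", {
  # trapezium (0,0)-(1,2)-(2,2)-(3,0): two unit triangles plus a 1x2 rectangle
  tri <- data.frame(time = c(0, 1, 2, 3), conc = c(0, 2, 2, 0))
  expect_equal(auc_trapezoid(tri, "linear"), 4.0)
  expect_equal(auc_trapezoid(tri, "linear", c(0, 2)), 3.0)
  expect_equal(auc_trapezoid(study_mean_profile(), "linear"), 19.366,
               tolerance = 1e-12)
  seg <- data.frame(time = c(1, 2), conc = c(2, 1))
  expect_equal(auc_trapezoid(seg, "linlog"), 1 / log(2), tolerance = 1e-12)
  expect_error(auc_trapezoid(data.frame(time = c(2, 1), conc = c(1, 2))),
               class = "pooledPK_validation_error")
  expect_error(auc_trapezoid(data.frame(time = c(1, 1), conc = c(1, 2))),
               class = "pooledPK_validation_error")
})

test_that("AUC is additive over subintervals and linlog <= linear when falling", {
  set.seed(42)
  for (i in 1:10) {
    t <- sort(runif(8, 0, 24))
    c <- runif(8, 0.05, 4)
    pts <- data.frame(time = t, conc = c)
    b <- runif(1, t[2], t[7])
    for (rule in c("linear", "linlog")) {
      whole <- auc_trapezoid(pts, rule, c(t[1], t[8]))
      split <- auc_trapezoid(pts, rule, c(t[1], b)) +
        auc_trapezoid(pts, rule, c(b, t[8]))
      expect_equal(split, whole, tolerance = 1e-10)
    }
    down <- data.frame(time = t, conc = sort(c, decreasing = TRUE))
    expect_lte(auc_trapezoid(down, "linlog"), auc_trapezoid(down, "linear"))
  }
})

test_that("adding a positive tail segment never decreases AUC", {
  set.seed(9)
  for (i in 1:10) {
    t <- sort(runif(6, 0, 20)); c <- runif(6, 0.05, 3)
    pts <- data.frame(time = t, conc = c)
    ext <- rbind(pts, data.frame(time = t[6] + runif(1, 0.5, 5),
                                 conc = runif(1, 0.01, 3)))
    for (rule in c("linear", "linlog"))
      expect_gte(auc_trapezoid(ext, rule), auc_trapezoid(pts, rule) - 1e-12)
  }
})

test_that("tail extrapolation follows C_last/lambda", {
  lam <- structure(list(lambda_z = 0.12, t_half = log(2) / 0.12,
                        intercept = log(0.12) + 0.12 * 24, n_points = 3,
                        time_window = c(8, 24), adjusted_r2 = 1),
                   class = "lambda_z_fit")
  out <- extrapolate_auc(10, c(24, 0.12), lam, "observed")
  expect_equal(out$auc_0_inf, 11.0)
  expect_equal(out$extrapolated_fraction, 1 / 11, tolerance = 1e-12)
  # large lambda: tail vanishes
  lam$lambda_z <- 1e6
  expect_equal(extrapolate_auc(10, c(24, 0.12), lam)$auc_0_inf, 10,
               tolerance = 1e-6)
})

test_that("study-profile AUC0-inf and MRT match hand computation", {
  prof <- pool(enro_cats())
  lam <- fit_lambda_z(prof, "manual_window", window = c(8, 24))
  pts <- study_mean_profile()
  auc <- auc_trapezoid(pts, "linear")
  out <- extrapolate_auc(auc, c(24, 0.216), lam, "observed")
  # frozen from independent arithmetic: 19.366 + 0.216/0.0855265
  expect_equal(out$auc_0_inf, 21.89153, tolerance = 1e-4)
  expect_equal(out$extrapolated_fraction, 0.1153657, tolerance = 1e-4)
  mom <- aumc_and_mrt(pts, lam, "linear")
  # frozen from independent arithmetic with the stated tail formulas
  expect_equal(mom$aumc_0_inf, 222.766, tolerance = 1e-4)
  expect_equal(mom$mrt, 10.1759, tolerance = 1e-4)
})

test_that("MRT limits: uniform profile and dense monoexponential", {
  flat <- data.frame(time = seq(0, 10, by = 0.5), conc = rep(2, 21))
  expect_equal(aumc_and_mrt(flat, NULL, "linear")$mrt, 5, tolerance = 1e-12)
  t <- seq(0, 200, by = 0.1)
  iv <- data.frame(time = t, conc = exp(-0.1 * t))
  lamfit <- fit_lambda_z(profile_of(t[-1], iv$conc[-1]), "manual_window",
                         window = c(100, 200))
  expect_equal(aumc_and_mrt(iv, lamfit, "linlog")$mrt, 10,
               tolerance = 0.01)
})

test_that("full NCA on dense noise-free one-compartment data hits closed forms", {
  p <- onecomp_params(ka = 1.0, ke = 0.12, v_over_f = 3, dose_mg_per_kg = 10)
  times <- seq(0, 72, by = 0.25)
  prof <- onecomp_profile(p, times)
  res <- run_nca(prof)
  closed <- secondary_parameters(p)
  expect_equal(res$auc_0_inf, closed$auc_0_inf, tolerance = 0.005)
  expect_equal(res$lambda_fit$lambda_z, p$ke, tolerance = 0.01)
  expect_equal(res$cmax, closed$cmax, tolerance = 0.005)
  expect_equal(res$mrt, 1 / p$ke + 1 / p$ka, tolerance = 0.02)
  expect_lt(res$extrapolated_fraction, 0.01)
})

test_that("NCA on the study fixture yields a complete, modestly extrapolated panel", {
  res <- run_nca(pool(enro_cats()))
  co <- coef(res)
  expect_true(all(is.finite(co)))
  expect_lt(res$extrapolated_fraction, 0.2)
  expect_gt(res$auc_0_inf, res$auc_0_t)
  expect_equal(res$mrt, res$aumc_0_inf / res$auc_0_inf, tolerance = 1e-12)
  expect_equal(res$auc_0_24, res$auc_0_t)  # last observation at 24 h, no tail
  rep <- as.data.frame(res)
  expect_setequal(rep$parameter[1:4], c("Cmax", "Tmax", "lambda_z", "t_half"))

  two <- profile_of(c(1, 2), c(1, 0.5))
  expect_error(run_nca(two), class = "pooledPK_insufficient_data")
})
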