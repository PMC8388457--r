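# one-compartment first-order absorption model: closed forms and fitting

test_that("closed-form prediction behaves at limits and known values", {
  p <- onecomp_params(ka = 1, ke = 0.25, v_over_f = 1, dose_mg_per_kg = 10)
  expect_equal(predict_concentration(p, 0), 0)
  # vanishing elimination: C(t) -> D/(V/F) * (1 - exp(-ka t))
  tiny <- onecomp_params(ka = 1, ke = 1e-9, v_over_f = 1, dose_mg_per_kg = 10)
  t <- c(0.5, 1, 2, 5)
  expect_equal(predict_concentration(tiny, t), 10 * (1 - exp(-t)),
               tolerance = 1e-6)
  # frozen from independent arithmetic on the closed form
  pp <- onecomp_params(ka = 1.14, ke = 0.12, v_over_f = 2.985, dose_mg_per_kg = 10)
  expect_equal(predict_concentration(pp, 2.2), 2.570561, tolerance = 1e-6)
  expect_error(predict_concentration(p, -1), class = "pooledPK_validation_error")
})

test_that("secondary parameters follow their closed forms", {
  p <- onecomp_params(ka = 1.0, ke = 0.25, v_over_f = 1, dose_mg_per_kg = 10)
  s <- secondary_parameters(p)
  expect_equal(s$tmax, log(4) / 0.75, tolerance = 1e-12)
  expect_equal(s$t_half, log(2) / 0.25)
  # tmax is symmetric under exchanging ka and ke
  swapped <- onecomp_params(ka = 0.25, ke = 1.0, v_over_f = 1, dose_mg_per_kg = 10)
  expect_equal(secondary_parameters(swapped)$tmax, s$tmax, tolerance = 1e-12)
  p2 <- onecomp_params(ka = 1, ke = 0.1, v_over_f = 1, dose_mg_per_kg = 10)
  expect_equal(secondary_parameters(p2)$auc_0_inf, 100)
})

test_that("Cmax sits at Tmax and closed AUC matches numerical integration", {
  set.seed(3)
  for (i in 1:5) {
    p <- onecomp_params(ka = runif(1, 0.3, 3), ke = runif(1, 0.05, 0.25),
                        v_over_f = runif(1, 1, 5), dose_mg_per_kg = 10)
    s <- secondary_parameters(p)
    grid <- seq(0, 10 * s$tmax, length.out = 20001)
    expect_lte(max(predict_concentration(p, grid)) - s$cmax, 1e-8)
    num <- stats::integrate(function(t) predict_concentration(p, t),
                            0, 2000 / p$ke, rel.tol = 1e-10,
                            subdivisions = 2000L)$value
    expect_equal(s$auc_0_inf, num, tolerance = 1e-3)
  }
})

test_that("the ka -> ke degeneracy is continuous", {
  ke <- 0.3
  t <- c(0.5, 2, 5, 10, 20)
  exact_limit <- onecomp_params(ka = ke, ke = ke, v_over_f = 2, dose_mg_per_kg = 10)
  near <- onecomp_params(ka = ke * (1 + 1e-7), ke = ke, v_over_f = 2,
                         dose_mg_per_kg = 10)
  expect_equal(predict_concentration(exact_limit, t),
               predict_concentration(near, t), tolerance = 1e-6)
  expect_equal(secondary_parameters(exact_limit)$tmax, 1 / ke)
})

test_that("noise-free sparse data are recovered to high precision", {
  truth <- onecomp_params(ka = 1.2, ke = 0.12, v_over_f = 3, dose_mg_per_kg = 10)
  times <- c(1, 2, 4, 8, 12, 24)
  recs <- concentration_records(paste0("s", seq_along(times)), times,
                                predict_concentration(truth, times))
  fit <- fit_onecomp(recs, 10)
  expect_equal(coef(fit), c(ka = 1.2, ke = 0.12, v_over_f = 3),
               tolerance = 1e-6)
  expect_false(fit$flip_flop)
  expect_lt(fit$rss, 1e-15)
  expect_equal(fit$derived$tmax, secondary_parameters(truth)$tmax,
               tolerance = 1e-5)
})

test_that("fits on noisy data have small median bias over replicates", {
  truth <- onecomp_params(ka = 1.2, ke = 0.12, v_over_f = 3, dose_mg_per_kg = 10)
  times <- c(1, 2, 4, 8, 12, 24)
  mu <- predict_concentration(truth, rep(times, each = 5))
  set.seed(2024)
  est <- t(replicate(100, {
    obs <- mu * (1 + 0.10 * rnorm(length(mu)))
    recs <- concentration_records(paste0("s", seq_along(obs)),
                                  rep(times, each = 5), pmax(obs, 1e-6))
    coef(fit_onecomp(recs, 10))
  }))
  bias <- apply(est, 2, median) / c(1.2, 0.12, 3) - 1
  expect_true(all(abs(bias) < 0.05))
})

test_that("weighted fits and preconditions behave", {
  truth <- onecomp_params(ka = 0.9, ke = 0.15, v_over_f = 2, dose_mg_per_kg = 10)
  times <- c(0.5, 1, 2, 4, 8, 16, 24)
  recs <- concentration_records(paste0("s", seq_along(times)), times,
                                predict_concentration(truth, times))
  for (w in c("one_over_c", "one_over_c2")) {
    fit <- fit_onecomp(recs, 10, weighting = w)
    expect_equal(coef(fit), c(ka = 0.9, ke = 0.15, v_over_f = 2),
                 tolerance = 1e-5)
  }
  three <- concentration_records(c("a", "b", "c"), c(1, 4, 12), c(1, 2, 0.5))
  expect_error(fit_onecomp(three, 10), class = "pooledPK_insufficient_data")
})

test_that("flip-flop kinetics: the mirror branch is an identical curve and the conventional branch is reported", {
  # mirror identity: (ka, ke, V) and (ke, ka, V*ke/ka) predict the same curve
  a <- onecomp_params(ka = 0.4, ke = 1.5, v_over_f = 2, dose_mg_per_kg = 10)
  b <- onecomp_params(ka = 1.5, ke = 0.4, v_over_f = 2 * 1.5 / 0.4,
                      dose_mg_per_kg = 10)
  t <- seq(0.2, 12, by = 0.4)
  expect_equal(predict_concentration(a, t), predict_concentration(b, t),
               tolerance = 1e-12)
  # fitting data generated on the slow-absorption branch still reports ka > ke
  gen <- onecomp_params(ka = 0.3, ke = 1.5, v_over_f = 2, dose_mg_per_kg = 10)
  times <- c(0.25, 0.5, 1, 2, 4, 8, 12)
  recs <- concentration_records(paste0("s", seq_along(times)), times,
                                predict_concentration(gen, times))
  fit <- fit_onecomp(recs, 10)
  expect_gt(fit$params$ka, fit$params$ke)
  expect_equal(predict(fit, times), predict_concentration(gen, times),
               tolerance = 1e-5)
})

test_that("fit methods: predict, residuals, simulate, report", {
  fit <- fit_onecomp(pool(enro_cats()), 10)
  expect_equal(length(residuals(fit)), nrow(fit$data))
  expect_equal(fitted(fit) + residuals(fit), fit$data$conc, tolerance = 1e-12)
  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_equal(dim(sims), c(nrow(fit$data), 4L))
  expect_true(all(sims[, -1] >= 0))
  rep <- as.data.frame(fit)
  expect_true(all(c("ka", "ke", "V_over_F", "Cmax") %in% rep$parameter))
  expect_equal(unique(rep$method), "one_compartment")
})
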