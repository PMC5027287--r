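test_that("mid and high frames merge into one bound dwell", {
  # 0,0,0.42,0.42,0.92,0.92,0,0 at 0.1 s: one uncensored bound dwell, 0.4 s
  fr <- c(0, 0, 0.42, 0.42, 0.92, 0.92, 0, 0)
  fit <- fit_hmm(rep(fr, 4))
  dw <- extract_dwells(fit)
  bound <- dw[dw$class == "bound" & !dw$censored, ]
  expect_true(all(bound$duration_s == 0.4))
  expect_true(all(bound$to_state == "zero"))
  # thresholded input gives the same merged dwells
  dw2 <- extract_dwells(as_fret_trajectory(fr))
  expect_equal(dw2$duration_s[dw2$class == "bound"], 0.4)
})

test_that("an all-bound trace yields a single censored dwell", {
  dw <- extract_dwells(as_fret_trajectory(rep(0.9, 50)))
  expect_identical(nrow(dw[dw$class == "bound", ]), 1L)
  expect_true(dw$censored[dw$class == "bound"])
  expect_true(is.na(dw$to_state[dw$class == "bound"]))
  expect_true(dw$first_run[dw$class == "bound"])
})

test_that("dwell counts track the ground-truth transition count", {
  set.seed(31)
  sch <- two_state_scheme(k_bind = 0.5, k_off = 1)
  n_true <- 0; dwells <- empty <- NULL
  all_dw <- list()
  for (i in 1:30) {
    path <- simulate_state_path(sch, 120)
    n_true <- n_true + sum(path$state == "H")
    tr <- emit_intensities(path, sch, emission_model(), 1200)
    all_dw[[i]] <- extract_dwells(correct_trace(tr, analysis_config()))
  }
  dw <- do.call(rbind, all_dw)
  n_obs <- sum(dw$class == "bound")
  expect_lt(abs(n_obs - n_true), 4 * sqrt(n_true))
})

test_that("single-exponential MLE recovers the lifetime", {
  set.seed(32)
  x <- rexp(1e5, 1)
  fit <- fit_survival(x, model = "auto")
  expect_identical(fit$model, "single")
  expect_equal(fit$tau1_s, 1, tolerance = 0.01)
  expect_equal(fit$tau_avg_s, fit$tau1_s)
})

test_that("a clear mixture selects double and recovers tau_avg", {
  set.seed(33)
  x <- c(rexp(5e4, 1 / 0.2), rexp(5e4, 1 / 5))
  fit <- fit_survival(x, model = "auto")
  expect_identical(fit$model, "double")
  expect_equal(fit$A1, 0.5, tolerance = 0.03)
  # tau_avg = 0.5 * 0.2 + 0.5 * 5 = 2.6
  expect_equal(fit$tau_avg_s, 2.6, tolerance = 0.05 * 2.6)
})

test_that("censored dwells enter through their survival contribution", {
  set.seed(34)
  x <- rexp(4e3, 1 / 3)
  cens <- x > 2          # right-censor at 2 s
  x[cens] <- 2
  fit <- fit_survival(x, censored = cens, model = "single")
  expect_equal(fit$tau1_s, 3, tolerance = 0.1)
  # treating censored dwells as events underestimates the lifetime
  fit_obs <- fit_survival(x, censored = cens, model = "single",
                          censoring = "observed")
  expect_lt(fit_obs$tau1_s, fit$tau1_s)
  # cross-check the censoring-aware MLE against survival::survreg
  sr <- survival::survreg(survival::Surv(x, !cens) ~ 1,
                          dist = "exponential")
  expect_equal(fit$tau1_s, exp(unname(sr$coefficients)), tolerance = 1e-6)
})

test_that("the discrete likelihood removes the frame-quantization bias", {
  set.seed(35)
  dt <- 0.1
  # frame-quantized two-state observation: run lengths are geometric
  m <- rgeom(2e4, 1 - exp(-10 * dt)) + 1
  fit_c <- fit_survival(m * dt, model = "single")
  fit_d <- fit_survival(m * dt, model = "single", discrete = TRUE,
                        frame_interval_s = dt)
  expect_equal(fit_d$tau1_s, 0.1, tolerance = 0.02)
  expect_gt(fit_c$tau1_s, 0.14)  # continuous MLE overshoots by ~ dt/2
})

test_that("survival fits refuse too few dwells and flag resolution limits", {
  expect_error(fit_survival(rexp(5, 1)), "at least 20")
  fit <- fit_survival(rep(0.1, 100), model = "single",
                      frame_interval_s = 0.1)
  expect_true(fit$resolution_limited)
})

test_that("tau_avg is the amplitude-weighted lifetime", {
  expect_equal(tau_avg(1, 5, 0, 123), 5)
  expect_equal(tau_avg(1, 5, 0), 5)           # tau2 irrelevant when A2 = 0
  expect_equal(tau_avg(0.5, 2, 0.5, 4), 3)
  expect_error(tau_avg(0.7, 1, 0.7, 1), "sum to 1")
  expect_error(tau_avg(0.5, -1, 0.5, 4), "tau1")
})

test_that("photobleach correction subtracts and floors", {
  expect_equal(correct_photobleach_rate(0.5, 0)$k_actual_s, 0.5)
  est <- correct_photobleach_rate(0.0100, 0.0056)
  expect_equal(est$k_actual_s, 0.0044, tolerance = 1e-12)
  expect_equal(est$tau_avg_s, 1 / 0.0044)
  floored <- correct_photobleach_rate(0.004, 0.0056)
  expect_equal(floored$k_actual_s, 0)
  expect_true(floored$floored)
  expect_error(correct_photobleach_rate(-1, 0), "rates")
})

test_that("photobleach-correction identity holds when unfloored", {
  set.seed(36)
  for (i in 1:50) {
    ko <- runif(1, 0.01, 1); kb <- runif(1, 0, 0.009)
    est <- correct_photobleach_rate(ko, kb)
    expect_equal(est$k_actual_s + est$k_photobleach_s, ko,
                 tolerance = 1e-12)
  }
})

test_that("bleach-rate estimation recovers the simulated bleach lifetime", {
  set.seed(37)
  pre <- cas9_presets("cognate")  # bleach lifetime 180 s
  ds <- generate_dataset(pre, 150, duration = 400, seed = 37)
  trajs <- lapply(ds$traces, correct_trace,
                  config = config_from_manifest(ds$manifest))
  bl <- estimate_bleach_rate(trajs)
  expect_equal(bl$k_photobleach_s, 1 / 180, tolerance = 0.25)
})

test_that("k_on is the origin-constrained slope of rate vs concentration", {
  est <- estimate_kon(c(10e-9, 20e-9, 40e-9), c(0.06, 0.12, 0.24))
  expect_equal(est$k_on_M_s, 6e6, tolerance = 1e-9)
  expect_equal(estimate_kon(20e-9, 0.12)$k_on_M_s, 6e6)
  expect_equal(estimate_kon(c(1e-8, 2e-8), c(0, 0))$k_on_M_s, 0)
  expect_error(estimate_kon(0, 0.1), "positive")
  expect_error(estimate_kon(-1e-9, 0.1), "positive")
  # the intercept-allowed diagnostic reproduces an exact line
  d <- estimate_kon(c(1e-8, 2e-8, 4e-8), c(0.07, 0.13, 0.25),
                    allow_intercept = TRUE)
  expect_equal(d$intercept_fit$slope_M_s, 6e6, tolerance = 1e-6)
  expect_equal(d$intercept_fit$intercept_s, 0.01, tolerance = 1e-9)
})

test_that("censoring handling and post-hoc subtraction agree on bleached data", {
  # bleach lifetime (180 s) far above the true bound lifetime (2 s):
  # min-of-exponentials makes the subtraction route exact
  set.seed(38)
  n <- 4e3
  true_dwell <- rexp(n, 1 / 2)
  bleach <- rexp(n, 1 / 180)
  obs <- pmin(true_dwell, bleach)
  cens <- bleach < true_dwell
  f_mle <- fit_survival(obs, censored = cens, model = "single")
  f_obs <- fit_survival(obs, censored = cens, model = "single",
                        censoring = "observed")
  k_corr <- correct_photobleach_rate(1 / f_obs$tau1_s, 1 / 180)
  expect_equal(f_mle$tau1_s, k_corr$tau_avg_s, tolerance = 0.05 * 2)
  expect_equal(f_mle$tau1_s, 2, tolerance = 0.1)
})
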