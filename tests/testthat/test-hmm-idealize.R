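level_path <- function(states, means = c(0, 0.42, 0.92)) means[states]

test_that("Viterbi recovers a noiseless three-level path exactly", {
  set.seed(21)
  states <- rep(sample(1:3, 40, replace = TRUE), times = sample(2:6, 40,
                                                                replace = TRUE))
  fit <- fit_hmm(level_path(states))
  expect_identical(as.integer(fit$states), as.integer(states))
  expect_equal(unname(fit$means), c(0, 0.42, 0.92), tolerance = 1e-6)
})

test_that("fit_hmm recovers emission means from noisy separable data", {
  set.seed(22)
  states <- rep(sample(1:3, 60, replace = TRUE), times = sample(3:9, 60,
                                                                replace = TRUE))
  obs <- level_path(states) + rnorm(length(states), 0, 0.05)
  fit <- fit_hmm(obs)
  expect_equal(unname(fit$means), c(0, 0.42, 0.92), tolerance = 0.02)
  # with sd <= 0.05 and well-separated means, misclassification is < 1%
  expect_lt(mean(as.integer(fit$states) != states), 0.01)
})

test_that("states are relabeled in ascending order of fitted mean", {
  set.seed(23)
  # start EM from permuted means: labels must still come out ordered
  states <- rep(sample(1:3, 50, replace = TRUE), each = 4)
  obs <- level_path(states) + rnorm(length(states), 0, 0.04)
  fit <- fit_hmm(obs, init_means = c(0.92, 0, 0.42))
  expect_true(all(diff(fit$means) > 0))
  expect_lt(mean(as.integer(fit$states) != states), 0.01)
})

test_that("rows of the fitted transition matrix sum to one", {
  set.seed(24)
  states <- rep(sample(1:3, 50, replace = TRUE), each = 3)
  obs <- level_path(states) + rnorm(length(states), 0, 0.05)
  fit <- fit_hmm(obs)
  expect_equal(unname(rowSums(fit$T_p)), rep(1, 3), tolerance = 1e-9)
})

test_that("the Viterbi path is invariant to uniform intensity rescaling", {
  set.seed(25)
  sch <- two_state_scheme(k_bind = 1, k_off = 1)
  path <- simulate_state_path(sch, 60, seed = 25)
  tr <- emit_intensities(path, sch, emission_model(), 600, seed = 26)
  cfg <- analysis_config()
  f1 <- fit_hmm(correct_trace(tr, cfg))
  tr2 <- tr
  for (col in c("intensity_donor", "intensity_acceptor"))
    tr2[[col]] <- 3 * tr2[[col]]
  cfg2 <- analysis_config(background_donor = 150, background_acceptor = 150)
  f2 <- fit_hmm(correct_trace(tr2, cfg2))
  expect_identical(as.integer(f1$states), as.integer(f2$states))
})

test_that("fit_hmm flags degenerate (unoccupied) states", {
  set.seed(27)
  states <- rep(sample(c(1, 3), 30, replace = TRUE), each = 4)
  obs <- level_path(states)  # the mid level never occurs
  fit <- fit_hmm(obs)
  expect_true(fit$degenerate[["mid"]])
  expect_lt(fit$occupancy[["mid"]], 1e-6)
  expect_error(fit_hmm(rep(0.5, 10)), "at least 20")
})

test_that("pooled fits share parameters and rescue sparse trajectories", {
  set.seed(28)
  sch <- two_state_scheme(k_bind = 0.2, k_off = 5)  # rare short events
  trajs <- lapply(1:40, function(i) {
    path <- simulate_state_path(sch, 60)
    tr <- emit_intensities(path, sch, emission_model(), 600,
                           molecule_id = paste0("m", i))
    correct_trace(tr, analysis_config())
  })
  pf <- fit_hmm_pooled(trajs)
  expect_equal(pf$n_traces, 40)
  expect_lt(abs(pf$means[["zero"]]), 0.03)
  for (id in pf$idealized) expect_equal(id$means, pf$means)
  # tied sds: one shared emission width
  expect_equal(unname(pf$sds), rep(pf$sds[[1]], 3))
})

test_that("transition density records dwell-mean coordinates", {
  states <- c(1, 1, 1, 3, 3, 1, 1, 3, 3, 3, 1, 1)
  fit <- fit_hmm(rep(level_path(states), 3))
  td <- transition_density(fit)
  r <- rle(rep(states, 3))
  expect_equal(td$n_transitions, length(r$lengths) - 1)
  expect_true(all(abs(td$points$fret_before) < 0.05 |
                    abs(td$points$fret_before - 0.92) < 0.05))
  expect_true(all(abs(td$points$fret_after) < 0.05 |
                    abs(td$points$fret_after - 0.92) < 0.05))
  expect_equal(sum(td$density), td$n_transitions)
})

test_that("single-dwell trajectories yield an empty transition density", {
  fit <- fit_hmm(rep(0.92, 30))
  td <- transition_density(fit)
  expect_equal(td$n_transitions, 0)
})

test_that("transition rates follow T_p times the sampling rate", {
  base <- fit_hmm(rep(level_path(c(1, 1, 3, 3)), 10))
  # a pair that transitions on every frame maps to the sampling rate
  mk <- function(Tp) {
    f <- base
    f$T_p <- Tp
    f$occupancy <- c(zero = 0.5, mid = 0, high = 0.5)
    f$frame_interval_s <- 0.1
    f
  }
  Tp <- diag(3); dimnames(Tp) <- list(c("zero", "mid", "high"),
                                      c("zero", "mid", "high"))
  Tp["zero", "zero"] <- 0; Tp["zero", "high"] <- 1
  rates <- estimate_transition_rates(list(mk(Tp)))
  expect_equal(rates$rates["zero", "high"], 10)       # 1 / 0.1 s
  expect_equal(rates$sampling_rate_hz, 10)
  # unobserved pairs report rate zero and are flagged
  expect_equal(rates$rates["mid", "high"], 0)
  expect_true(rates$unobserved["zero", "mid"])
})

test_that("log-mean aggregation of transition probabilities is geometric", {
  base <- fit_hmm(rep(level_path(c(1, 1, 3, 3)), 10))
  mk <- function(p) {
    f <- base
    Tp <- diag(3)
    dimnames(Tp) <- list(c("zero", "mid", "high"), c("zero", "mid", "high"))
    Tp["zero", "zero"] <- 1 - p; Tp["zero", "high"] <- p
    f$T_p <- Tp
    f$occupancy <- c(zero = 0.5, mid = 0, high = 0.5)
    f$frame_interval_s <- 0.1
    f
  }
  r <- estimate_transition_rates(list(mk(0.1), mk(0.4)))
  expect_equal(r$mean_probability["zero", "high"], sqrt(0.1 * 0.4))
  # equal per-trajectory probabilities: geometric mean equals arithmetic
  r2 <- estimate_transition_rates(list(mk(0.2), mk(0.2), mk(0.2)))
  expect_equal(r2$mean_probability["zero", "high"], 0.2)
  expect_equal(r2$rates["zero", "high"], 2)
})

test_that("fitted transition probabilities match the discretized CTMC law", {
  # point-sampled three-state chain (all states visited): the fitted
  # high -> zero probability must match 1 - exp(-k dt) of the generating
  # exit rate; sampling states at frame instants isolates the HMM property
  # from camera time-averaging, which is tested elsewhere
  set.seed(29)
  k <- 2; dt <- 0.1
  Tchain <- matrix(c(0.88, 0.06, 0.06,
                     0.30, 0.65, 0.05,
                     1 - exp(-k * dt), 0.02, exp(-k * dt) - 0.02),
                   3, 3, byrow = TRUE)
  tp <- numeric(0)
  for (i in 1:100) {
    st <- integer(800); st[1] <- 1L
    for (t in 2:800)
      st[t] <- sample.int(3L, 1L, prob = Tchain[st[t - 1], ])
    obs <- c(0, 0.42, 0.92)[st] + rnorm(800, 0, 0.05)
    fit <- fit_hmm(obs)
    if (all(fit$occupancy > 0.02)) tp <- c(tp, fit$T_p["high", "zero"])
  }
  expected <- 1 - exp(-k * dt)
  expect_lt(abs(mean(tp) - expected) / expected, 0.15)
})
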