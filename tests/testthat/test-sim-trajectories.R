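test_that("a scheme with no binding never leaves the unbound state", {
  sch <- kinetic_scheme(matrix(0, 3, 3))
  path <- simulate_state_path(sch, 100, seed = 1)
  expect_identical(nrow(path), 1L)
  expect_identical(path$state, "U")
  expect_equal(path$exit_time - path$entry_time, 100)
})

test_that("bound dwells are exponential with the configured exit rate", {
  # two-state U <-> H with H exit rate 2/s: mean H dwell 0.5 s
  sch <- two_state_scheme(k_bind = 5, k_off = 2)
  set.seed(42)
  dwells <- c()
  while (length(dwells) < 1e4) {
    path <- simulate_state_path(sch, 2000)
    dwells <- c(dwells, path_dwells(path, "H"))
  }
  dwells <- dwells[seq_len(1e4)]
  se <- sd(dwells) / sqrt(length(dwells))
  expect_lt(abs(mean(dwells) - 0.5), 3 * se)
  # Kolmogorov-Smirnov against the exponential law at alpha = 0.01
  expect_gt(ks.test(dwells, "pexp", rate = 2)$p.value, 0.01)
})

test_that("long-run state occupancies match the stationary distribution", {
  sch <- ergodic_scheme()
  set.seed(7)
  occ <- c(U = 0, S = 0, H = 0)
  for (i in 1:20) {
    path <- simulate_state_path(sch, 2000)
    d <- path$exit_time - path$entry_time
    for (s in names(occ)) occ[s] <- occ[s] + sum(d[path$state == s])
  }
  occ <- occ / sum(occ)
  pi <- stationary_distribution(sch)
  expect_true(all(abs(occ - pi) < 0.02))
})

test_that("doubling concentration doubles only the unbound exit rate", {
  p1 <- cas9_presets("9-20_mm", concentration = 20e-9)[[1]]$scheme
  p2 <- cas9_presets("9-20_mm", concentration = 40e-9)[[1]]$scheme
  q1 <- scheme_generator(p1); q2 <- scheme_generator(p2)
  expect_equal(-q2["U", "U"], -2 * q1["U", "U"])
  expect_equal(-q2["S", "S"], -q1["S", "S"])
  expect_equal(-q2["H", "H"], -q1["H", "H"])
})

test_that("simulate_state_path rejects invalid inputs", {
  sch <- two_state_scheme()
  expect_error(simulate_state_path(sch, 0), "duration")
  expect_error(simulate_state_path(sch, -5), "duration")
})

test_that("noiseless frame FRET equals the occupancy-weighted state mean", {
  # hand-built path: frame 5 is split 50/50 between H (0.92) and U (0)
  sch <- two_state_scheme()
  path <- structure(
    data.frame(state = c("H", "U"), entry_time = c(0, 0.45),
               exit_time = c(0.45, 1)),
    bleach_time = Inf, duration = 1,
    class = c("state_path", "data.frame"))
  tr <- emit_intensities(path, sch, noiseless_emission(), 10)
  tf <- attr(tr, "true_fret")
  expect_equal(tf[1:4], rep(0.92, 4))
  expect_equal(tf[5], 0.46)  # half a frame in H, half in U
  expect_equal(tf[6:10], rep(0, 5))
  # with zero noise the emitted intensities invert exactly
  expect_equal(tr$intensity_acceptor / 500, tf)
})

test_that("frames after the bleach time carry background only", {
  sch <- two_state_scheme(k_bind = 1e9, k_off = 0)  # instantly bound
  path <- simulate_state_path(sch, 10, seed = 3)
  attr(path, "bleach_time") <- 5.0
  em <- emission_model(channel_noise_sd = 0)
  tr <- emit_intensities(path, sch, em, 100)
  post <- tr$frame_index > 50
  expect_equal(tr$intensity_donor[post], rep(em$background_donor, sum(post)))
  expect_equal(tr$intensity_acceptor[post],
               rep(em$background_acceptor, sum(post)))
  total_sig <- tr$intensity_donor + tr$intensity_acceptor -
    em$background_donor - em$background_acceptor
  expect_equal(total_sig[post], rep(0, sum(post)))
})

test_that("emit_intensities rejects frame spans beyond the path", {
  sch <- two_state_scheme()
  path <- simulate_state_path(sch, 10, seed = 1)
  expect_error(emit_intensities(path, sch, emission_model(), 101),
               "exceeds")
})

test_that("generate_dataset is reproducible and validates n_molecules", {
  pre <- cas9_presets("5-20_mm")
  d1 <- generate_dataset(pre, 4, duration = 10, seed = 9)
  d2 <- generate_dataset(pre, 4, duration = 10, seed = 9)
  expect_identical(d1$traces, d2$traces)
  expect_error(generate_dataset(pre, 0, duration = 10, seed = 1),
               "n_molecules")
})

test_that("datasets round-trip through TSV + JSON on disk", {
  dir <- file.path(tempdir(), "ds_roundtrip")
  ds <- generate_dataset(cas9_presets("5-20_mm"), 3, duration = 5, seed = 2)
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_setequal(names(back$traces), names(ds$traces))
  m <- names(ds$traces)[1]
  expect_equal(back$traces[[m]]$intensity_donor,
               ds$traces[[m]]$intensity_donor, tolerance = 1e-8)
  expect_equal(back$manifest$frame_interval_s, ds$manifest$frame_interval_s)
  expect_equal(back$manifest$concentration_molar,
               ds$manifest$concentration_molar)
  unlink(dir, recursive = TRUE)
})

test_that("flow-in initialization starts unbound; equilibrium mode does not", {
  pre <- cas9_presets("cognate")
  ds_flow <- generate_dataset(pre, 20, duration = 5, seed = 4,
                              init = "flow_in")
  first_states <- vapply(ds_flow$traces,
                         function(tr) attr(tr, "majority_state")[1],
                         character(1))
  expect_true(all(first_states == "U"))
  ds_eq <- generate_dataset(pre, 40, duration = 5, seed = 4,
                            init = "equilibrium")
  first_eq <- vapply(ds_eq$traces,
                     function(tr) attr(tr, "majority_state")[1],
                     character(1))
  # cognate at 20 nM after a 600 s incubation is almost fully bound
  expect_gt(mean(first_eq == "H"), 0.8)
})

test_that("first-passage into H matches the analytic two-state law", {
  # U -> H at rate 0.5/s, no return: P(ever bound by t) = 1 - exp(-0.5 t)
  sch <- two_state_scheme(k_bind = 0.5, k_off = 0)
  set.seed(11)
  n <- 400; dur <- 2
  hit <- vapply(seq_len(n), function(i) {
    path <- simulate_state_path(sch, dur)
    any(path$state == "H")
  }, logical(1))
  p_hat <- mean(hit)
  p <- 1 - exp(-0.5 * dur)
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
})
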