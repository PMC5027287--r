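# Small schemes and fixtures built in code for the tests.

# Two-state U <-> H scheme with first-order (concentration-independent)
# binding, convenient for analytic dwell checks.
two_state_scheme <- function(k_bind = 1, k_off = 2, bleach = 0,
                             fret_high = 0.92) {
  rates <- matrix(0, 3, 3)
  rates[1, 3] <- k_bind
  rates[3, 1] <- k_off
  kinetic_scheme(rates, conc_scaled = matrix(FALSE, 3, 3),
                 fret_means = c(0, 0.42, fret_high),
                 photobleach_rate = bleach, concentration = 0)
}

# Ergodic three-state scheme (all first-order) for stationary-law checks.
ergodic_scheme <- function() {
  rates <- matrix(c(0, 1.0, 0.3,
                    2.0, 0, 1.5,
                    0.7, 0.5, 0), 3, 3, byrow = TRUE)
  kinetic_scheme(rates, conc_scaled = matrix(FALSE, 3, 3),
                 photobleach_rate = 0, concentration = 0)
}

noiseless_emission <- function(frame_interval = 0.1) {
  emission_model(total_intensity = 500, channel_noise_sd = 0,
                 background_donor = 0, background_acceptor = 0,
                 leakage_fraction = 0, frame_interval = frame_interval)
}

noiseless_config <- function() {
  analysis_config(leakage_fraction = 0, background_donor = 0,
                  background_acceptor = 0)
}

# Wrap a bare FRET vector as a minimal fret_trajectory.
as_fret_trajectory <- function(fret, dt = 0.1, id = "m1") {
  structure(data.frame(time_s = (seq_along(fret) - 1) * dt, fret = fret,
                       donor_corrected = 500 * (1 - fret),
                       acceptor_corrected = 500 * fret,
                       valid = TRUE),
            molecule_id = id, valid_through = length(fret),
            frame_interval_s = dt,
            class = c("fret_trajectory", "data.frame"))
}

# Dwell times per state straight from a simulated path (ground truth).
path_dwells <- function(path, state) {
  d <- path$exit_time - path$entry_time
  sel <- path$state == state
  # drop the final (truncated) segment
  if (nrow(path) > 0 && sel[nrow(path)]) sel[nrow(path)] <- FALSE
  d[sel]
}

# Character-by-character reference matcher: subject base matches a query
# base iff the subject letter is in the query letter's IUPAC set, with
# N = {A,C,G,T,N} treated as in the package's subset convention (genome N
# is matched only by query N).
naive_count_matches <- function(genome_chars, query_chars) {
  L <- length(genome_chars); k <- length(query_chars)
  if (k > L) return(0L)
  n <- 0L
  for (i in seq_len(L - k + 1)) {
    win <- genome_chars[i:(i + k - 1)]
    ok <- (query_chars == "N" & win %in% c("A", "C", "G", "T", "N")) |
      (query_chars == win & win != "N")
    if (all(ok)) n <- n + 1L
  }
  n
}

naive_revcomp <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

random_genome <- function(n, p_N = 0) {
  sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
         prob = c(rep((1 - p_N) / 4, 4), p_N))
}
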