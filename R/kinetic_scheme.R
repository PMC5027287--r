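#' Three-state kinetic scheme for Cas9-RNA target binding
#'
#' Defines the continuous-time Markov scheme used by the trajectory
#' simulator. The three states are `U` (unbound, zero FRET), `S`
#' (sequence-nonspecific PAM-sampling mode, mid FRET) and `H` (RNA-DNA
#' heteroduplex, high FRET). Binding steps out of `U` are bimolecular and
#' scale with the Cas9-RNA concentration; all other steps are first order.
#'
#' @param rates 3x3 numeric matrix of rate constants, rows = from-state,
#'   columns = to-state, in state order `U`, `S`, `H`. Entries flagged in
#'   `conc_scaled` are second-order (per molar per second); the rest are
#'   first-order (per second). The diagonal is ignored.
#' @param conc_scaled 3x3 logical matrix marking which entries scale with
#'   concentration. Default: every transition out of `U`.
#' @param fret_means length-3 numeric, true FRET efficiency of each state,
#'   in `[0, 1]`; the unbound state must have mean 0.
#' @param photobleach_rate per-second rate of the single exponential
#'   photobleaching event that terminates a trace (either fluorophore).
#' @param concentration Cas9-RNA concentration in molar.
#'
#' @return An object of class `kinetic_scheme`.
#' @examples
#' sch <- kinetic_scheme(
#'   rates = matrix(c(0, 6e6, 0,  8, 0, 2,  0.05, 0, 0), 3, 3, byrow = TRUE),
#'   fret_means = c(0, 0.42, 0.92),
#'   photobleach_rate = 1 / 180, concentration = 20e-9)
#' effective_rates(sch)
#' @export
kinetic_scheme <- function(rates,
                           conc_scaled = NULL,
                           fret_means = c(0, 0.42, 0.92),
                           photobleach_rate = 0,
                           concentration = 20e-9) {
  states <- c("U", "S", "H")
  rates <- as.matrix(rates)
  if (!all(dim(rates) == c(3L, 3L)))
    stop("`rates` must be a 3x3 matrix (states U, S, H)")
  diag(rates) <- 0
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0")
  if (is.null(conc_scaled)) {
    conc_scaled <- matrix(FALSE, 3, 3)
    conc_scaled[1, ] <- rates[1, ] > 0  # binding steps out of U
  }
  conc_scaled <- as.matrix(conc_scaled)
  if (length(fret_means) != 3L || any(fret_means < 0) || any(fret_means > 1))
    stop("`fret_means` must be three values in [0, 1]")
  if (fret_means[1] != 0)
    stop("the unbound state must have FRET mean 0")
  if (!is.finite(photobleach_rate) || photobleach_rate < 0)
    stop("`photobleach_rate` must be finite and >= 0")
  if (!is.finite(concentration) || concentration < 0)
    stop("`concentration` must be finite and >= 0")
  dimnames(rates) <- dimnames(conc_scaled) <- list(states, states)
  structure(
    list(state_names = states,
         rates = rates,
         conc_scaled = conc_scaled,
         fret_means = setNames(as.numeric(fret_means), states),
         photobleach_rate = photobleach_rate,
         concentration = concentration),
    class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme (U = unbound, S = sampling, H = heteroduplex)\n")
  eff <- effective_rates(x)
  cat(sprintf("  concentration: %.3g M, photobleach rate: %.4g /s\n",
              x$concentration, x$photobleach_rate))
  cat("  effective first-order rates (/s):\n")
  print(round(eff, 5))
  cat("  FRET means:", paste(sprintf("%s=%.2f", x$state_names, x$fret_means),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Effective first-order rate matrix of a scheme
#'
#' Applies the concentration to the concentration-scaled (bimolecular)
#' entries, giving the 3x3 matrix of effective first-order rates in
#' per-second units (diagonal zero).
#'
#' @param scheme A [kinetic_scheme()].
#' @return 3x3 numeric matrix, per second.
#' @export
effective_rates <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  eff <- scheme$rates
  eff[scheme$conc_scaled] <- eff[scheme$conc_scaled] * scheme$concentration
  eff
}

#' Infinitesimal generator of a scheme
#'
#' @param scheme A [kinetic_scheme()].
#' @return 3x3 generator matrix `Q` (rows sum to zero), per second.
#' @export
scheme_generator <- function(scheme) {
  Q <- effective_rates(scheme)
  diag(Q) <- -rowSums(Q)
  Q
}

#' State occupancy probabilities at a given time
#'
#' Solves the master equation of the scheme by matrix exponential, giving
#' the probability of each state at time `t` from an initial distribution.
#' Photobleaching is not part of the state dynamics.
#'
#' @param scheme A [kinetic_scheme()].
#' @param t time in seconds (vectorized).
#' @param init initial distribution: a state name (`"U"`, `"S"`, `"H"`) or a
#'   probability vector of length 3.
#' @return matrix with one row per `t` and columns `U`, `S`, `H`.
#' @export
state_occupancy <- function(scheme, t, init = "U") {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  p0 <- if (is.character(init)) {
    as.numeric(scheme$state_names == match.arg(init, scheme$state_names))
  } else {
    stopifnot(length(init) == 3L, all(init >= 0), abs(sum(init) - 1) < 1e-8)
    as.numeric(init)
  }
  Q <- scheme_generator(scheme)
  out <- t(vapply(t, function(tt) {
    as.numeric(p0 %*% as.matrix(Matrix::expm(Q * tt)))
  }, numeric(3)))
  colnames(out) <- scheme$state_names
  out
}

#' Stationary distribution of a scheme
#'
#' @param scheme A [kinetic_scheme()]; must be irreducible for the result to
#'   be unique.
#' @return named probability vector over `U`, `S`, `H`.
#' @export
stationary_distribution <- function(scheme) {
  Q <- scheme_generator(scheme)
  # left null vector of Q: solve pi Q = 0, sum(pi) = 1
  A <- rbind(t(Q), rep(1, 3))
  b <- c(0, 0, 0, 1)
  pi <- qr.solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  setNames(pi / sum(pi), scheme$state_names)
}

#' Expected bound-state dwell time of a scheme
#'
#' Mean time spent contiguously in the bound states `{S, H}` per binding
#' event, starting from the state entered out of `U` (weighted by the
#' branching of the binding step). This is the ground-truth counterpart of
#' the amplitude-weighted lifetime obtained from survival fits, since for a
#' survival curve `A1*exp(-t/tau1) + A2*exp(-t/tau2)` the amplitude-weighted
#' lifetime equals the distribution mean.
#'
#' @param scheme A [kinetic_scheme()] with at least one binding step.
#' @return seconds.
#' @export
mean_bound_lifetime <- function(scheme) {
  Q <- scheme_generator(scheme)
  entry <- Q[1, 2:3]
  if (sum(entry) <= 0) stop("scheme has no binding step out of U")
  entry <- entry / sum(entry)
  # restrict to bound states actually reachable from the binding step so
  # that sampling-only schemes (no heteroduplex path) stay well posed
  reach <- entry > 0
  repeat {
    grow <- reach | (as.vector(reach %*% (Q[2:3, 2:3] > 0)) > 0)
    if (identical(grow, reach)) break
    reach <- grow
  }
  tauB <- numeric(2)
  tauB[reach] <- solve(-Q[2:3, 2:3][reach, reach, drop = FALSE],
                       rep(1, sum(reach)))
  as.numeric(entry %*% tauB)
}

#' Camera and detection-noise model for simulated traces
#'
#' Parameters of the synthetic two-channel intensity readout: total emitted
#' intensity is split between donor and acceptor according to the true FRET
#' efficiency of each frame, a fraction of donor signal bleeds into the
#' acceptor channel, constant backgrounds are added, and both channels carry
#' independent Gaussian noise.
#'
#' @param total_intensity mean total signal counts per frame.
#' @param channel_noise_sd Gaussian noise standard deviation per channel,
#'   counts.
#' @param background_donor,background_acceptor constant background counts.
#' @param leakage_fraction donor-to-acceptor bleed-through, in `[0, 0.2]`.
#' @param frame_interval camera frame interval in seconds.
#' @return An object of class `emission_model`.
#' @export
emission_model <- function(total_intensity = 500,
                           channel_noise_sd = 30,
                           background_donor = 50,
                           background_acceptor = 50,
                           leakage_fraction = 0.07,
                           frame_interval = 0.1) {
  if (total_intensity <= 0) stop("`total_intensity` must be > 0")
  if (frame_interval <= 0) stop("`frame_interval` must be > 0")
  if (channel_noise_sd < 0) stop("`channel_noise_sd` must be >= 0")
  if (leakage_fraction < 0 || leakage_fraction > 0.2)
    stop("`leakage_fraction` must be in [0, 0.2]")
  structure(
    list(total_intensity = total_intensity,
         channel_noise_sd = channel_noise_sd,
         background_donor = background_donor,
         background_acceptor = background_acceptor,
         leakage_fraction = leakage_fraction,
         frame_interval = frame_interval),
    class = "emission_model")
}

#' DNA target preset
#'
#' Couples a target label in the `x-y_mm` naming convention (contiguous
#' mismatch from position `x` to `y`, counted from the PAM-proximal end,
#' position 1 adjacent to the PAM) with the kinetic scheme encoding its
#' binding/dissociation behaviour.
#'
#' @param name target label, e.g. `"cognate"` or `"9-20_mm"`.
#' @param mismatch_interval integer vector `c(x, y)` with
#'   `1 <= x <= y <= 20`, or `NULL` for the cognate target.
#' @param scheme A [kinetic_scheme()].
#' @return An object of class `target_preset`.
#' @export
target_preset <- function(name, mismatch_interval = NULL, scheme) {
  if (!is.null(mismatch_interval)) {
    mm <- as.integer(mismatch_interval)
    if (length(mm) != 2L || mm[1] < 1L || mm[2] > 20L || mm[1] > mm[2])
      stop("`mismatch_interval` must satisfy 1 <= x <= y <= 20")
    mismatch_interval <- mm
  }
  stopifnot(inherits(scheme, "kinetic_scheme"))
  structure(list(name = name, mismatch_interval = mismatch_interval,
                 scheme = scheme),
            class = "target_preset")
}

#' @export
print.target_preset <- function(x, ...) {
  mm <- if (is.null(x$mismatch_interval)) "none" else
    paste(x$mismatch_interval, collapse = "-")
  cat(sprintf("Target preset '%s' (mismatches: %s)\n", x$name, mm))
  print(x$scheme)
  invisible(x)
}

#' Built-in DNA target presets
#'
#' Returns the default panel of target presets. The per-target kinetic
#' values are literature-derived single-molecule measurements of SpCas9
#' target binding and live in a versioned configuration file shipped with
#' the package (`system.file("extdata", "target_presets.json")`); the
#' two-step scheme built from each row is: bimolecular entry into the
#' sampling mode `U -> S`, fast partitioning of the sampling mode between
#' return to `U` and heteroduplex formation `S -> H`, and first-order
#' heteroduplex dissociation `H -> U`. The sampling mode lives ~0.1 s for
#' every target; seed/PAM quality enters through the branching fraction and
#' the heteroduplex lifetime.
#'
#' @param names optional character vector selecting presets; default all.
#' @param concentration Cas9-RNA concentration in molar applied to the
#'   bimolecular steps (default 20 nM).
#' @param photobleach_rate per-second bleaching rate shared by all presets
#'   (default `1/180`, i.e. a ~3 min bleach lifetime).
#' @return named list of [target_preset()] objects.
#' @examples
#' names(cas9_presets())
#' cas9_presets("5-20_mm")[[1]]
#' @export
cas9_presets <- function(names = NULL, concentration = 20e-9,
                         photobleach_rate = 1 / 180) {
  path <- system.file("extdata", "target_presets.json",
                      package = "cas9smfret", mustWork = TRUE)
  tab <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)$presets
  if (is.null(names)) names <- tab$name
  missing <- setdiff(names, tab$name)
  if (length(missing))
    stop("unknown preset(s): ", paste(missing, collapse = ", "))
  out <- lapply(names, function(nm) {
    row <- tab[tab$name == nm, ]
    k_sample_exit <- 1 / row$sampling_lifetime_s
    rates <- matrix(0, 3, 3)
    rates[1, 2] <- row$kon_M_s                      # U -> S (bimolecular)
    rates[2, 1] <- k_sample_exit * (1 - row$p_extend)  # S -> U
    rates[2, 3] <- k_sample_exit * row$p_extend        # S -> H
    rates[3, 1] <- row$k_HU_s                          # H -> U
    sch <- kinetic_scheme(rates,
                          fret_means = c(0, row$fret_mid, row$fret_high),
                          photobleach_rate = photobleach_rate,
                          concentration = concentration)
    mm <- if (is.na(row$mm_from)) NULL else c(row$mm_from, row$mm_to)
    target_preset(nm, mm, sch)
  })
  setNames(out, names)
}
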