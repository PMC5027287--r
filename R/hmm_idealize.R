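#' Idealize a FRET trajectory with a three-state Gaussian HMM
#'
#' Fits a hidden Markov model with three Gaussian emission states (zero,
#' mid and high FRET) to the valid frames of a corrected trajectory by
#' expectation-maximization, then Viterbi-decodes the most likely state
#' path. States are relabeled in ascending order of fitted mean, so `zero`
#' < `mid` < `high` regardless of how EM ordered them. On exact Viterbi
#' ties the lower state index wins, making the decoded path deterministic.
#'
#' Besides the EM-fitted Gaussian means, blur-robust state means are
#' estimated from dwell-interior frames (the first and last frame of every
#' decoded dwell are excluded). Camera integration time-averages frames
#' that straddle a transition, dragging boundary frames toward a mixture of
#' the adjacent state means; interior frames are free of this artifact, so
#' for states visited in short dwells the interior estimate recovers the
#' emission mean where the raw EM mean is biased toward the blurred
#' boundary values. When a state has no interior frames the EM mean is
#' reported for it unchanged.
#'
#' @param trajectory a `fret_trajectory` from [correct_trace()], or a bare
#'   numeric vector of FRET values.
#' @param init_means initial emission means (default `c(0, 0.42, 0.92)`).
#' @param fix_means if `TRUE` the emission means stay at `init_means` and
#'   only variances, transitions and start probabilities are fitted.
#' @param max_iter,tol EM stops when the log-likelihood improves by less
#'   than `tol` (default `1e-6`) or after `max_iter` (default 500)
#'   iterations.
#' @param sd_floor lower bound on fitted emission standard deviations, to
#'   keep degenerate states from collapsing onto single frames.
#' @param tie_sds share one emission standard deviation across the three
#'   states. The detection noise of the two-channel readout is
#'   state-independent, so homoscedastic emissions match the measurement
#'   physics and stop a state from inflating its variance to absorb
#'   camera-blurred transition frames; `FALSE` frees all three variances.
#' @return An `idealized_trajectory`: list with `states` (factor per valid
#'   frame: zero/mid/high), `fret` (the observations used), `means`, `sds`,
#'   `means_interior`, `T_p` (3x3 fitted transition probability matrix,
#'   rows sum to 1), `start`, `loglik`, `iterations`, `occupancy` (expected
#'   state fractions; empty states are degenerate and reported with
#'   occupancy 0), `molecule_id`, `frame_interval_s`.
#' @examples
#' lv <- c(0, 0.42, 0.92)[c(1, 1, 2, 2, 3, 3, 3, 1, 1, 1) ]
#' fit <- fit_hmm(rep(lv, 5))
#' table(fit$states)
#' @export
fit_hmm <- function(trajectory, init_means = c(0, 0.42, 0.92),
                    fix_means = FALSE, max_iter = 500, tol = 1e-6,
                    sd_floor = 0.01, tie_sds = FALSE) {
  if (inherits(trajectory, "fret_trajectory")) {
    obs <- trajectory$fret[trajectory$valid]
    mol <- attr(trajectory, "molecule_id")
    dt <- attr(trajectory, "frame_interval_s")
  } else {
    obs <- as.numeric(trajectory)
    mol <- NA_character_
    dt <- NA_real_
  }
  obs <- obs[is.finite(obs)]
  if (length(obs) < 20) stop("need at least 20 valid frames to fit the HMM")
  K <- length(init_means)

  trans0 <- matrix(0.05, K, K); diag(trans0) <- 1 - 0.05 * (K - 1)
  fit <- .hmm_em(obs, as.numeric(init_means), rep(0.1, K), trans0,
                 rep(1 / K, K), fix_means, as.integer(max_iter), tol,
                 sd_floor, tie_sds)

  ord <- order(fit$means)
  means <- fit$means[ord]; sds <- fit$sds[ord]
  T_p <- fit$trans[ord, ord, drop = FALSE]
  start <- fit$start[ord]
  occupancy <- fit$occupancy[ord]
  path <- .hmm_viterbi(obs, means, sds, T_p, start)

  lab <- c("zero", "mid", "high")
  states <- factor(lab[path], levels = lab)
  dimnames(T_p) <- list(lab, lab)
  names(means) <- names(sds) <- names(occupancy) <- lab

  # blur-robust means from dwell-interior frames
  means_interior <- means
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  interior <- rep(TRUE, length(path))
  interior[starts] <- FALSE
  interior[ends] <- FALSE
  for (k in seq_len(K)) {
    sel <- interior & path == k
    if (sum(sel) >= 5) means_interior[k] <- mean(obs[sel])
  }

  structure(list(states = states, fret = obs,
                 means = means, sds = sds,
                 means_interior = means_interior,
                 T_p = T_p, start = start,
                 loglik = fit$loglik, iterations = fit$iterations,
                 occupancy = occupancy,
                 degenerate = occupancy < 1e-6,
                 molecule_id = mol, frame_interval_s = dt),
            class = "idealized_trajectory")
}

#' @export
print.idealized_trajectory <- function(x, ...) {
  cat(sprintf("Idealized trajectory (%s): %d frames, loglik %.1f (%d EM iter)\n",
              x$molecule_id, length(x$states), x$loglik, x$iterations))
  cat("  means:", paste(sprintf("%s=%.3f", names(x$means), x$means),
                        collapse = ", "), "\n")
  cat("  occupancy:", paste(sprintf("%s=%.3f", names(x$occupancy),
                                    x$occupancy), collapse = ", "), "\n")
  invisible(x)
}

#' Idealize many trajectories
#'
#' Convenience wrapper fitting a per-molecule HMM to each trajectory (the
#' per-trajectory transition probabilities are later aggregated by their
#' log-mean, which presumes per-molecule fits). Trajectories with fewer
#' than 20 valid frames are skipped with a note.
#'
#' @param trajectories list of `fret_trajectory` objects.
#' @param ... further arguments to [fit_hmm()] (e.g. `tie_sds`).
#' @inheritParams fit_hmm
#' @return list of `idealized_trajectory` objects (named by molecule where
#'   available).
#' @export
idealize_trajectories <- function(trajectories, init_means = c(0, 0.42, 0.92),
                                  fix_means = FALSE, ...) {
  out <- list()
  skipped <- 0L
  for (tr in trajectories) {
    fit <- tryCatch(fit_hmm(tr, init_means = init_means,
                            fix_means = fix_means, ...),
                    error = function(e) NULL)
    if (is.null(fit)) { skipped <- skipped + 1L; next }
    out[[length(out) + 1L]] <- fit
    nm <- fit$molecule_id
    if (!is.na(nm)) names(out)[length(out)] <- nm
  }
  if (skipped > 0)
    message(sprintf("idealize_trajectories: skipped %d short trajectories",
                    skipped))
  out
}

#' Pooled three-state HMM across molecules
#'
#' Fits one shared set of emission means, standard deviations, transition
#' matrix and start distribution to all trajectories jointly (the E-step
#' runs per molecule, the M-step pools the sufficient statistics), then
#' Viterbi-decodes each molecule with the shared parameters. Pooling is the
#' right tool when individual traces carry too few visits of a state for a
#' per-molecule fit -- e.g. weak binders whose traces hold a handful of
#' sampling events each: a per-molecule three-state fit then collapses
#' degenerate states onto single noisy frames, while the pooled fit sees
#' thousands of event frames. Blur-robust interior means (see [fit_hmm()])
#' are computed from the pooled dwell-interior frames of all molecules.
#'
#' @param trajectories list of `fret_trajectory` objects (trajectories with
#'   fewer than 5 valid frames are dropped).
#' @inheritParams fit_hmm
#' @return A `pooled_hmm`: list with shared `means`, `sds`,
#'   `means_interior`, `T_p`, `start`, `loglik`, `occupancy`, `n_traces`,
#'   and `idealized`, a list of per-molecule `idealized_trajectory`
#'   objects carrying the shared parameters and their own Viterbi paths.
#' @export
fit_hmm_pooled <- function(trajectories, init_means = c(0, 0.42, 0.92),
                           fix_means = FALSE, max_iter = 200, tol = 1e-3,
                           sd_floor = 0.01, tie_sds = TRUE) {
  obs_list <- lapply(trajectories, function(tr) {
    o <- tr$fret[tr$valid]
    o[is.finite(o)]
  })
  keep <- vapply(obs_list, length, integer(1)) >= 5
  obs_list <- obs_list[keep]
  trajectories <- trajectories[keep]
  if (length(obs_list) == 0) stop("no usable trajectories")
  obs <- unlist(obs_list, use.names = FALSE)
  lens <- vapply(obs_list, length, integer(1))
  K <- length(init_means)

  trans0 <- matrix(0.05, K, K); diag(trans0) <- 1 - 0.05 * (K - 1)
  fit <- .hmm_em_multi(obs, as.integer(lens), as.numeric(init_means),
                       rep(0.1, K), trans0, rep(1 / K, K), fix_means,
                       as.integer(max_iter), tol, sd_floor, tie_sds)
  ord <- order(fit$means)
  means <- fit$means[ord]; sds <- fit$sds[ord]
  T_p <- fit$trans[ord, ord, drop = FALSE]
  start <- fit$start[ord]
  lab <- c("zero", "mid", "high")
  names(means) <- names(sds) <- lab
  dimnames(T_p) <- list(lab, lab)

  ideal <- vector("list", length(obs_list))
  interior_sum <- interior_n <- numeric(K)
  for (i in seq_along(obs_list)) {
    o <- obs_list[[i]]
    path <- .hmm_viterbi(o, means, sds, T_p, start)
    r <- rle(path)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    interior <- rep(TRUE, length(path))
    interior[starts] <- FALSE; interior[ends] <- FALSE
    for (k in seq_len(K)) {
      sel <- interior & path == k
      interior_sum[k] <- interior_sum[k] + sum(o[sel])
      interior_n[k] <- interior_n[k] + sum(sel)
    }
    occ_i <- vapply(seq_len(K), function(k) mean(path == k), numeric(1))
    ideal[[i]] <- structure(
      list(states = factor(lab[path], levels = lab), fret = o,
           means = means, sds = sds, means_interior = means,
           T_p = T_p, start = start,
           loglik = NA_real_, iterations = fit$iterations,
           occupancy = setNames(occ_i, lab),
           degenerate = occ_i < 1e-6,
           molecule_id = attr(trajectories[[i]], "molecule_id"),
           frame_interval_s = attr(trajectories[[i]], "frame_interval_s")),
      class = "idealized_trajectory")
  }
  nm <- vapply(ideal, function(x) x$molecule_id %||% NA_character_,
               character(1))
  if (!anyNA(nm)) names(ideal) <- nm

  means_interior <- means
  use <- interior_n >= 5
  means_interior[use] <- interior_sum[use] / interior_n[use]
  for (i in seq_along(ideal)) ideal[[i]]$means_interior <- means_interior

  structure(list(means = means, sds = sds,
                 means_interior = means_interior,
                 interior_frames = setNames(interior_n, lab),
                 T_p = T_p, start = start,
                 loglik = fit$loglik, iterations = fit$iterations,
                 occupancy = setNames(fit$occupancy[ord], lab),
                 n_traces = length(ideal),
                 idealized = ideal),
            class = "pooled_hmm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pooled_hmm <- function(x, ...) {
  cat(sprintf("Pooled 3-state HMM over %d trajectories (loglik %.1f, %d EM iter)\n",
              x$n_traces, x$loglik, x$iterations))
  cat("  means:   ", paste(sprintf("%s=%.3f", names(x$means), x$means),
                           collapse = ", "), "\n")
  cat("  interior:", paste(sprintf("%s=%.3f", names(x$means_interior),
                                   x$means_interior), collapse = ", "), "\n")
  invisible(x)
}

#' Transition density of idealized trajectories
#'
#' For every idealized state change, records one point at (mean observed
#' FRET of the preceding dwell, mean observed FRET of the following dwell)
#' and accumulates the points into a 2-D histogram at bin width 0.05. These
#' are the transition density plots used to visualize relative transition
#' frequencies between FRET states.
#'
#' @param idealized list of `idealized_trajectory` objects (or one).
#' @param lim FRET axis range (default `c(-0.2, 1.2)`).
#' @return A `transition_density`: list with `density` (square count
#'   matrix, rows = FRET before, columns = FRET after), `bin_edges`,
#'   `points` (data frame of the transition coordinates) and
#'   `n_transitions`.
#' @export
transition_density <- function(idealized, lim = c(-0.2, 1.2)) {
  if (inherits(idealized, "idealized_trajectory")) idealized <- list(idealized)
  edges <- seq(lim[1], lim[2], by = 0.05)
  nb <- length(edges) - 1
  dens <- matrix(0L, nb, nb)
  before <- after <- numeric(0)
  for (id in idealized) {
    r <- rle(as.integer(id$states))
    if (length(r$lengths) < 2) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    dwell_means <- vapply(seq_along(starts), function(i)
      mean(id$fret[starts[i]:ends[i]]), numeric(1))
    before <- c(before, dwell_means[-length(dwell_means)])
    after <- c(after, dwell_means[-1])
  }
  if (length(before)) {
    bi <- findInterval(pmin(pmax(before, lim[1]), lim[2]), edges,
                       rightmost.closed = TRUE)
    ai <- findInterval(pmin(pmax(after, lim[1]), lim[2]), edges,
                       rightmost.closed = TRUE)
    for (i in seq_along(bi)) dens[bi[i], ai[i]] <- dens[bi[i], ai[i]] + 1L
  }
  structure(list(density = dens, bin_edges = edges,
                 points = data.frame(fret_before = before,
                                     fret_after = after),
                 n_transitions = length(before)),
            class = "transition_density")
}

#' @export
print.transition_density <- function(x, ...) {
  cat(sprintf("Transition density: %d transitions over %d x %d bins\n",
              x$n_transitions, nrow(x$density), ncol(x$density)))
  invisible(x)
}

#' Transition rates from idealized trajectories
#'
#' Converts per-trajectory HMM transition probabilities into first-order
#' rates: the mean transition probability of a state pair is the geometric
#' mean, `exp(mean(log T_p))`, over trajectories with a strictly positive
#' probability for that pair (trajectories in which the pair was never
#' observed contribute nothing to the log-mean and are counted separately),
#' and the rate is the mean probability times the sampling rate
#' `1 / frame_interval_s`. With a 0.1 s frame the sampling rate is 10 per
#' second, so a pair that transitions on every frame maps to 10 per second.
#'
#' @param idealized list of `idealized_trajectory` objects.
#' @param frame_interval_s frame interval in seconds; defaults to the value
#'   stored in the fits.
#' @return list with `rates` (3x3 matrix, per second; 0 where a pair was
#'   never observed), `mean_probability` (geometric-mean transition
#'   probabilities), `n_used` and `n_zero` (per-pair trajectory counts) and
#'   `unobserved` (logical matrix).
#' @export
estimate_transition_rates <- function(idealized, frame_interval_s = NULL) {
  if (inherits(idealized, "idealized_trajectory")) idealized <- list(idealized)
  if (length(idealized) == 0) stop("no idealized trajectories")
  if (is.null(frame_interval_s))
    frame_interval_s <- idealized[[1]]$frame_interval_s
  if (!is.finite(frame_interval_s) || frame_interval_s <= 0)
    stop("`frame_interval_s` must be > 0")
  lab <- c("zero", "mid", "high")
  logsum <- nuse <- nzero <- matrix(0, 3, 3, dimnames = list(lab, lab))
  any_off <- FALSE
  for (id in idealized) {
    Tp <- id$T_p
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      # only states the trajectory actually visited carry information
      if (id$occupancy[i] < 1e-6) next
      if (Tp[i, j] > 0) {
        logsum[i, j] <- logsum[i, j] + log(Tp[i, j])
        nuse[i, j] <- nuse[i, j] + 1
        any_off <- TRUE
      } else {
        nzero[i, j] <- nzero[i, j] + 1
      }
    }
  }
  if (!any_off)
    stop("no trajectory has a nonzero off-diagonal transition probability")
  meanp <- matrix(0, 3, 3, dimnames = list(lab, lab))
  sel <- nuse > 0
  meanp[sel] <- exp(logsum[sel] / nuse[sel])
  rates <- meanp / frame_interval_s
  diag(rates) <- 0
  list(rates = rates, mean_probability = meanp,
       n_used = nuse, n_zero = nzero,
       unobserved = !sel & row(sel) != col(sel),
       sampling_rate_hz = 1 / frame_interval_s)
}

#' Write idealized paths to TSV
#'
#' @param idealized list of `idealized_trajectory` objects.
#' @param path output TSV path (columns `molecule_id`, `frame_index`,
#'   `state`, `state_mean`).
#' @return `path`, invisibly.
#' @export
write_idealized <- function(idealized, path) {
  if (inherits(idealized, "idealized_trajectory")) idealized <- list(idealized)
  tab <- do.call(rbind, lapply(idealized, function(id) {
    data.frame(molecule_id = id$molecule_id,
               frame_index = seq_along(id$states),
               state = as.character(id$states),
               state_mean = unname(id$means[as.integer(id$states)]))
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
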