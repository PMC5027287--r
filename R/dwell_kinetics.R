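#' Extract dwell times from an idealized or thresholded trajectory
#'
#' Segments a trajectory into maximal runs of bound and unbound frames.
#' The bound state merges the mid- and high-FRET states (FRET above 0.2),
#' matching the convention used for bound-state survival analysis. For
#' idealized input, per-state (`high`, `mid`) dwells with their exit
#' destinations are emitted as well, for state-resolved lifetime analysis.
#'
#' A dwell whose end is the observation boundary (trace end or photobleach)
#' is right-censored and carries no `to_state`. The first run of a trace is
#' not right-censored -- it ends in an observed transition -- but it is
#' flagged `first_run` so analyses can exclude it when the observation
#' window is known to open mid-dwell; with flow-in initialization the first
#' unbound dwell genuinely starts at time zero and is kept.
#'
#' @param x an `idealized_trajectory` ([fit_hmm()]) or `fret_trajectory`
#'   ([correct_trace()]).
#' @param config an [analysis_config()]; supplies the bound threshold and
#'   frame interval for thresholded input.
#' @return data frame with columns `molecule_id`, `class` (`bound`,
#'   `unbound`, `high`, `mid`), `duration_s`, `n_frames`, `censored`,
#'   `first_run`, `from_state`, `to_state`.
#' @examples
#' dw <- extract_dwells(fit_hmm(rep(c(0, 0, 0.42, 0.42, 0.92, 0.92, 0, 0), 4)))
#' subset(dw, class == "bound")
#' @export
extract_dwells <- function(x, config = analysis_config()) {
  if (inherits(x, "idealized_trajectory")) {
    states <- as.character(x$states)
    dt <- x$frame_interval_s
    if (!is.finite(dt)) dt <- config$frame_interval_s
    mol <- x$molecule_id
  } else if (inherits(x, "fret_trajectory")) {
    f <- x$fret[x$valid]
    states <- ifelse(f > config$bound_threshold, "bound", "zero")
    dt <- attr(x, "frame_interval_s")
    mol <- attr(x, "molecule_id")
  } else {
    stop("`x` must be an idealized or FRET trajectory")
  }
  n <- length(states)
  if (n < 1) return(empty_dwells())

  bound <- states != "zero"
  out <- runs_to_dwells(bound, ifelse(bound, "bound", "unbound"),
                        states, dt, mol)
  if (inherits(x, "idealized_trajectory")) {
    for (st in c("high", "mid")) {
      sel <- states == st
      if (!any(sel)) next
      out <- rbind(out, runs_to_dwells(sel, ifelse(sel, st, "other"),
                                       states, dt, mol, keep = st))
    }
  }
  rownames(out) <- NULL
  out
}

empty_dwells <- function() {
  data.frame(molecule_id = character(0), class = character(0),
             duration_s = numeric(0), n_frames = integer(0),
             censored = logical(0), first_run = logical(0),
             from_state = character(0), to_state = character(0),
             stringsAsFactors = FALSE)
}

# Turn a logical membership vector into dwell records. `keep` restricts the
# emitted rows to one class label (used for per-state dwells).
runs_to_dwells <- function(member, class_of, states, dt, mol, keep = NULL) {
  r <- rle(member)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(starts)
  cls <- class_of[starts]
  from <- c(NA_character_, states[starts[-1] - 1L])
  to <- c(states[ends[-k] + 1L], NA_character_)
  censored <- c(rep(FALSE, k - 1), TRUE)
  to[k] <- NA_character_
  out <- data.frame(molecule_id = mol, class = cls,
                    duration_s = r$lengths * dt,
                    n_frames = r$lengths,
                    censored = censored,
                    first_run = c(TRUE, rep(FALSE, k - 1)),
                    from_state = from, to_state = to,
                    stringsAsFactors = FALSE)
  if (!is.null(keep)) out <- out[out$class == keep, ]
  out
}

#' Extract dwells from many trajectories
#'
#' @param xs list of idealized or FRET trajectories.
#' @param config an [analysis_config()].
#' @return combined dwell data frame (see [extract_dwells()]).
#' @export
extract_dwells_all <- function(xs, config = analysis_config()) {
  out <- do.call(rbind, lapply(xs, extract_dwells, config = config))
  rownames(out) <- NULL
  out
}

#' Fit an exponential survival model to dwell times
#'
#' Maximum-likelihood fit of a single exponential or a two-component
#' exponential mixture to dwell durations. Censored dwells (ended by the
#' observation boundary rather than a transition) can enter through their
#' survival contribution (`censoring = "mle"`), or every duration can be
#' treated as an observed event (`censoring = "observed"`) -- the latter
#' reproduces the classical analysis in which photobleaching is removed
#' afterwards by rate subtraction (see [correct_photobleach_rate()]);
#' because the bleach clock is exponential, the observed rate is then the
#' sum of the true and bleach rates, so the subtraction is exact.
#'
#' Dwell durations are integer frame counts, so `discrete = TRUE` evaluates
#' the exact likelihood of frame-quantized durations (each exponential
#' component becomes a geometric law with per-frame survival
#' `exp(-dt/tau)`), removing the up-to-half-frame bias the continuous
#' likelihood incurs for dwells only a few frames long; reported lifetimes
#' are the continuous-equivalent `tau = -dt / log(q)`. For dwells much
#' longer than a frame the two likelihoods coincide. This is the correct
#' likelihood for quantized data, not a missed-event correction (none is
#' applied).
#'
#' @param dwells a dwell data frame from [extract_dwells()] (already
#'   filtered to one class), or a numeric vector of durations.
#' @param model `"single"`, `"double"`, or `"auto"` (double accepted when
#'   it improves BIC by at least 6).
#' @param censored logical vector when `dwells` is numeric; ignored for
#'   data-frame input.
#' @param censoring `"mle"` or `"observed"` (see above).
#' @param discrete use the frame-quantized likelihood (recommended whenever
#'   durations are integer frame multiples, which [extract_dwells()] output
#'   always is).
#' @param frame_interval_s frame interval, needed for `discrete = TRUE`
#'   (defaults to the smallest duration present).
#' @param min_dwells fits refuse to run with fewer uncensored dwells.
#' @param drop_first exclude dwells flagged `first_run` (data-frame input).
#' @return A `survival_fit`: `model`, amplitudes `A1`, `A2` (summing to 1),
#'   lifetimes `tau1_s <= tau2_s`, `tau_avg_s = A1*tau1 + A2*tau2`,
#'   `n_dwells`, `n_censored`, `loglik`, `bic`, `resolution_limited` flag.
#' @examples
#' fit_survival(rexp(500, 1 / 3))$tau1_s
#' @export
fit_survival <- function(dwells, model = c("auto", "single", "double"),
                         censored = NULL,
                         censoring = c("mle", "observed"),
                         discrete = FALSE, frame_interval_s = NULL,
                         min_dwells = 20, drop_first = FALSE) {
  model <- match.arg(model)
  censoring <- match.arg(censoring)
  if (is.data.frame(dwells)) {
    if (drop_first) dwells <- dwells[!dwells$first_run, , drop = FALSE]
    t <- dwells$duration_s
    cens <- dwells$censored
  } else {
    t <- as.numeric(dwells)
    cens <- if (is.null(censored)) rep(FALSE, length(t)) else censored
  }
  keep <- is.finite(t) & t > 0
  t <- t[keep]; cens <- cens[keep]
  if (censoring == "observed") cens <- rep(FALSE, length(t))
  n_ev <- sum(!cens)
  if (n_ev < min_dwells)
    stop(sprintf("need at least %d uncensored dwells, have %d",
                 min_dwells, n_ev))
  if (is.null(frame_interval_s) || !is.finite(frame_interval_s))
    frame_interval_s <- min(t)

  single <- fit_exp_single(t, cens, discrete, frame_interval_s)
  fit <- single
  if (model %in% c("double", "auto")) {
    dbl <- tryCatch(fit_exp_double(t, cens, discrete, frame_interval_s),
                    error = function(e) NULL)
    if (!is.null(dbl)) {
      if (model == "double" ||
          (model == "auto" && single$bic - dbl$bic >= 6)) fit <- dbl
    } else if (model == "double") {
      stop("double-exponential fit failed to converge")
    }
  }
  fit$n_dwells <- n_ev
  fit$n_censored <- sum(cens)
  fit$censoring <- censoring
  fit$resolution_limited <- fit$tau1_s <= frame_interval_s * (1 + 1e-9) &&
    fit$A1 > 0.01
  class(fit) <- "survival_fit"
  fit
}

fit_exp_single <- function(t, cens, discrete, dt) {
  n_ev <- sum(!cens)
  if (discrete) {
    m <- pmax(round(t / dt), 1)
    surv_frames <- sum(m[!cens] - 1) + sum(m[cens])
    q <- surv_frames / (surv_frames + n_ev)
    q <- min(max(q, 1e-9), 1 - 1e-12)
    tau <- -dt / log(q)
    ll <- surv_frames * log(q) + n_ev * log(1 - q)
  } else {
    tau <- sum(t) / n_ev
    ll <- -n_ev * log(tau) - sum(t) / tau
  }
  list(model = "single", A1 = 1, A2 = 0, tau1_s = tau, tau2_s = NA_real_,
       tau_avg_s = tau, loglik = ll,
       bic = -2 * ll + log(length(t)))
}

# log(a e^x + b e^y) stable in the exponents
log_mix <- function(la, lb) {
  m <- pmax(la, lb)
  m + log(exp(la - m) + exp(lb - m))
}

fit_exp_double <- function(t, cens, discrete = FALSE, dt = min(t)) {
  m <- pmax(round(t / dt), 1)  # frame counts, for the discrete likelihood
  nll <- function(par) {
    A1 <- stats::plogis(par[1])
    tau1 <- exp(par[2]); tau2 <- exp(par[3])
    ev <- !cens
    if (discrete) {
      lq1 <- -dt / tau1; lq2 <- -dt / tau2   # log per-frame survival
      l1m <- log1p(-exp(lq1)); l2m <- log1p(-exp(lq2))
      ll_ev <- log_mix(log(A1) + (m[ev] - 1) * lq1 + l1m,
                       log(1 - A1) + (m[ev] - 1) * lq2 + l2m)
      ll_ce <- log_mix(log(A1) + m[cens] * lq1,
                       log(1 - A1) + m[cens] * lq2)
    } else {
      ll_ev <- log_mix(log(A1) - log(tau1) - t[ev] / tau1,
                       log(1 - A1) - log(tau2) - t[ev] / tau2)
      ll_ce <- log_mix(log(A1) - t[cens] / tau1,
                       log(1 - A1) - t[cens] / tau2)
    }
    -(sum(ll_ev) + sum(ll_ce))
  }
  tev <- t[!cens]
  med <- median(tev)
  init <- c(0, log(max(mean(tev[tev <= med]), 1e-4)),
            log(max(mean(tev[tev > med]), 2e-4)))
  opt <- optim(init, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  # a second start helps when the components are very unequal
  init2 <- c(stats::qlogis(0.8), log(quantile(tev, 0.2, names = FALSE)),
             log(max(mean(tev), quantile(tev, 0.9, names = FALSE))))
  opt2 <- tryCatch(optim(init2, nll, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-10)),
                   error = function(e) NULL)
  if (!is.null(opt2) && opt2$value < opt$value) opt <- opt2
  A1 <- stats::plogis(opt$par[1])
  tau1 <- exp(opt$par[2]); tau2 <- exp(opt$par[3])
  if (tau1 > tau2) { tmp <- tau1; tau1 <- tau2; tau2 <- tmp; A1 <- 1 - A1 }
  ll <- -opt$value
  list(model = "double", A1 = A1, A2 = 1 - A1,
       tau1_s = tau1, tau2_s = tau2,
       tau_avg_s = A1 * tau1 + (1 - A1) * tau2,
       loglik = ll, bic = -2 * ll + 3 * log(length(t)))
}

#' @export
print.survival_fit <- function(x, ...) {
  if (x$model == "single") {
    cat(sprintf("Single-exponential fit: tau = %.4g s (%d dwells, %d censored)\n",
                x$tau1_s, x$n_dwells, x$n_censored))
  } else {
    cat(sprintf(
      "Double-exponential fit: A1=%.3f tau1=%.4g s, A2=%.3f tau2=%.4g s, tau_avg=%.4g s (%d dwells, %d censored)\n",
      x$A1, x$tau1_s, x$A2, x$tau2_s, x$tau_avg_s, x$n_dwells, x$n_censored))
  }
  if (isTRUE(x$resolution_limited))
    cat("  note: shortest lifetime at the frame interval (resolution-limited)\n")
  invisible(x)
}

#' Amplitude-weighted lifetime
#'
#' `tau_avg = A1*tau1 + A2*tau2` for a double-exponential survival curve
#' with amplitudes normalized to one. Equals the mean of the dwell-time
#' distribution.
#'
#' @param A1,A2 amplitudes, `A1 + A2 = 1` (within `1e-6`).
#' @param tau1,tau2 lifetimes in seconds (`tau2` is ignored when `A2 = 0`).
#' @return seconds.
#' @examples
#' tau_avg(0.5, 2, 0.5, 4)  # 3
#' @export
tau_avg <- function(A1, tau1, A2 = 1 - A1, tau2 = NA) {
  if (abs(A1 + A2 - 1) > 1e-6)
    stop("amplitudes must sum to 1")
  if (!is.finite(tau1) || tau1 <= 0) stop("`tau1` must be > 0")
  if (A2 == 0) return(A1 * tau1)
  if (!is.finite(tau2) || tau2 <= 0) stop("`tau2` must be > 0")
  A1 * tau1 + A2 * tau2
}

#' Photobleach-corrected dissociation rate
#'
#' `k_actual = k_observed - k_photobleach`, floored at zero: when the
#' observed rate does not exceed the bleach rate the molecule's stability
#' is indistinguishable from photobleaching and the corrected rate is 0
#' with `floored = TRUE`. The corrected lifetime is `1 / k_actual`.
#'
#' @param k_observed observed decay rate, per second.
#' @param k_photobleach photobleaching rate of the corresponding FRET
#'   state, per second.
#' @return A `rate_estimate`: `k_observed_s`, `k_photobleach_s`,
#'   `k_actual_s`, `tau_avg_s`, `floored`.
#' @examples
#' correct_photobleach_rate(0.0100, 0.0056)$k_actual_s  # 0.0044
#' @export
correct_photobleach_rate <- function(k_observed, k_photobleach) {
  if (!is.finite(k_observed) || k_observed < 0 ||
      !is.finite(k_photobleach) || k_photobleach < 0)
    stop("rates must be finite and >= 0")
  k <- k_observed - k_photobleach
  floored <- k < 0
  if (floored) k <- 0
  structure(list(k_observed_s = k_observed,
                 k_photobleach_s = k_photobleach,
                 k_actual_s = k,
                 tau_avg_s = if (k > 0) 1 / k else Inf,
                 floored = floored),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("k_observed = %.4g /s, k_photobleach = %.4g /s, k_actual = %.4g /s%s\n",
              x$k_observed_s, x$k_photobleach_s, x$k_actual_s,
              if (isTRUE(x$floored)) " (floored at 0)" else ""))
  if (!is.null(x$k_on_M_s))
    cat(sprintf("k_on = %.4g /M/s\n", x$k_on_M_s))
  invisible(x)
}

#' Photobleaching rate from detected bleach times
#'
#' Exponential maximum-likelihood estimate of the bleach rate from the
#' bleach frames detected per trace: traces that bleach before their end
#' contribute events, traces that never bleach contribute censored times.
#'
#' @param trajectories list of `fret_trajectory` objects.
#' @return list with `k_photobleach_s`, `tau_bleach_s`, `n_bleached`,
#'   `n_censored`.
#' @export
estimate_bleach_rate <- function(trajectories) {
  if (inherits(trajectories, "fret_trajectory"))
    trajectories <- list(trajectories)
  times <- vapply(trajectories, function(tr) {
    dt <- attr(tr, "frame_interval_s")
    vt <- attr(tr, "valid_through")
    c(max(vt, 0.5) * dt, vt < nrow(tr))
  }, numeric(2))
  tt <- times[1, ]; ev <- times[2, ] > 0
  if (sum(tt) <= 0) stop("no observation time")
  k <- sum(ev) / sum(tt)
  list(k_photobleach_s = k,
       tau_bleach_s = if (k > 0) 1 / k else Inf,
       n_bleached = sum(ev), n_censored = sum(!ev))
}

#' Bimolecular association rate constant from a concentration series
#'
#' The unbound-state decay rate grows linearly with the Cas9-RNA
#' concentration; the association constant `k_on` is the slope of a
#' weighted least-squares line through the origin (zero binding at zero
#' concentration). With a single concentration the slope reduces to
#' `rate / concentration`. An intercept-allowed variant is available as a
#' diagnostic for deviations from bimolecular behaviour.
#'
#' @param concentrations molar concentrations (> 0).
#' @param rates observed unbound-state decay rates, per second; or a list
#'   of single-exponential `survival_fit` objects, from which
#'   `1 / tau1_s` is taken.
#' @param weights optional weights for the regression (default equal).
#' @param allow_intercept also report an ordinary line with intercept.
#' @return A `rate_estimate` with `k_on_M_s`, the input series, and
#'   (optionally) `intercept_fit`.
#' @examples
#' estimate_kon(c(10e-9, 20e-9, 40e-9), c(0.06, 0.12, 0.24))$k_on_M_s # 6e6
#' @export
estimate_kon <- function(concentrations, rates, weights = NULL,
                         allow_intercept = FALSE) {
  if (is.list(rates))
    rates <- vapply(rates, function(f) 1 / f$tau1_s, numeric(1))
  concentrations <- as.numeric(concentrations)
  rates <- as.numeric(rates)
  if (length(concentrations) != length(rates) || length(rates) < 1)
    stop("`concentrations` and `rates` must have equal positive length")
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stop("concentrations must be positive")
  if (any(rates < 0)) stop("rates must be >= 0")
  w <- if (is.null(weights)) rep(1, length(rates)) else weights
  k_on <- sum(w * concentrations * rates) / sum(w * concentrations^2)
  out <- list(k_on_M_s = k_on,
              concentrations_M = concentrations,
              rates_s = rates,
              k_observed_s = rates[length(rates)],
              k_photobleach_s = 0,
              k_actual_s = rates[length(rates)])
  if (allow_intercept && length(rates) >= 2) {
    fit <- stats::lm(rates ~ concentrations, weights = w)
    cf <- stats::coef(fit)
    out$intercept_fit <- list(slope_M_s = unname(cf[2]),
                              intercept_s = unname(cf[1]))
  }
  structure(out, class = "rate_estimate")
}

#' Write a dwell table to TSV
#'
#' @param dwells dwell data frame from [extract_dwells_all()].
#' @param path output path (columns `molecule_id`, `class`, `duration_s`,
#'   `censored`, `from_state`, `to_state`).
#' @return `path`, invisibly.
#' @export
write_dwells <- function(dwells, path) {
  write.table(dwells[, c("molecule_id", "class", "duration_s", "censored",
                         "from_state", "to_state")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
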