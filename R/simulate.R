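#' Simulate a continuous-time state path
#'
#' Exact (Gillespie-style) event sampling from the kinetic scheme: dwell
#' times in each state are exponential with the state's total exit rate and
#' the destination is drawn from the relative exit rates. A photobleach time
#' is drawn independently from an exponential with the scheme's bleach rate;
#' it does not alter the state dynamics, only what is observable.
#'
#' @param scheme A [kinetic_scheme()].
#' @param duration total simulated time in seconds.
#' @param seed optional integer seed for reproducibility.
#' @param init_state state the path starts in (default `"U"`).
#' @return An object of class `state_path`: a data frame with columns
#'   `state`, `entry_time`, `exit_time` (contiguous segments covering
#'   `[0, duration]`) and attribute `bleach_time` (seconds, `Inf` if the
#'   trace never bleaches).
#' @examples
#' pre <- cas9_presets("5-20_mm")[[1]]
#' path <- simulate_state_path(pre$scheme, duration = 60, seed = 1)
#' table(path$state)
#' @export
simulate_state_path <- function(scheme, duration, seed = NULL,
                                init_state = "U") {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!is.finite(duration) || duration <= 0)
    stop("`duration` must be a positive number of seconds")
  if (!is.null(seed)) set.seed(seed)
  eff <- effective_rates(scheme)
  if (any(!is.finite(eff)) || any(eff < 0))
    stop("scheme has non-finite or negative effective rates")
  states <- scheme$state_names
  cur <- match(init_state, states)
  if (is.na(cur)) stop("unknown `init_state`")

  seg_state <- integer(0); seg_in <- numeric(0); seg_out <- numeric(0)
  t <- 0
  while (t < duration) {
    exit_rate <- sum(eff[cur, ])
    dwell <- if (exit_rate > 0) rexp(1, exit_rate) else Inf
    t_end <- min(t + dwell, duration)
    seg_state <- c(seg_state, cur)
    seg_in <- c(seg_in, t)
    seg_out <- c(seg_out, t_end)
    if (t + dwell >= duration) break
    cur <- sample.int(3L, 1L, prob = eff[cur, ])
    t <- t_end
  }
  bleach <- if (scheme$photobleach_rate > 0)
    rexp(1, scheme$photobleach_rate) else Inf
  structure(
    data.frame(state = states[seg_state],
               entry_time = seg_in,
               exit_time = seg_out,
               stringsAsFactors = FALSE),
    bleach_time = bleach,
    duration = duration,
    class = c("state_path", "data.frame"))
}

#' Bleach time of a state path
#' @param path A [simulate_state_path()] result.
#' @return seconds (`Inf` if never bleached).
#' @export
bleach_time <- function(path) attr(path, "bleach_time")

#' Render a state path as camera-frame intensities
#'
#' Converts a continuous-time path into per-frame donor/acceptor counts at
#' the camera's time resolution. The true FRET of a frame is the
#' occupancy-time-weighted average of the state FRET means within the frame
#' (states shorter than a frame are blurred, as in the measurement). Within
#' each frame, emitted signal accrues only until the photobleach time;
#' afterwards both channels contain background and noise only.
#'
#' @param path A [simulate_state_path()] result.
#' @param scheme The [kinetic_scheme()] that generated `path`.
#' @param emission An [emission_model()].
#' @param n_frames number of camera frames; the frame span
#'   `n_frames * frame_interval` must not exceed the path duration.
#' @param seed optional integer seed.
#' @return An `intensity_trace`: data frame with columns `molecule_id`,
#'   `frame_index`, `time_s`, `intensity_donor`, `intensity_acceptor`, plus
#'   attributes `true_fret` (noise-free occupancy-weighted FRET per frame),
#'   `majority_state` (state occupying most of each frame) and
#'   `bleach_frame`.
#' @export
emit_intensities <- function(path, scheme, emission, n_frames, seed = NULL,
                             molecule_id = "mol_1") {
  stopifnot(inherits(path, "state_path"), inherits(emission, "emission_model"))
  if (n_frames < 1) stop("`n_frames` must be >= 1")
  dt <- emission$frame_interval
  if (n_frames * dt > attr(path, "duration") + 1e-9)
    stop("frame span exceeds the simulated path duration")
  if (!is.null(seed)) set.seed(seed)

  bleach <- attr(path, "bleach_time")
  fret_time <- numeric(n_frames)   # integral of FRET over emitting time
  emit_time <- numeric(n_frames)   # emitting (pre-bleach) time per frame
  occ_time <- matrix(0, n_frames, 3,
                     dimnames = list(NULL, scheme$state_names))

  for (i in seq_len(nrow(path))) {
    t0 <- path$entry_time[i]; t1 <- min(path$exit_time[i], n_frames * dt)
    if (t1 <= t0) next
    f0 <- floor(t0 / dt) + 1L
    f1 <- min(ceiling(t1 / dt), n_frames)
    fr <- f0:f1
    ov <- pmin(t1, fr * dt) - pmax(t0, (fr - 1) * dt)
    occ_time[fr, path$state[i]] <- occ_time[fr, path$state[i]] + ov
    # emission only before the bleach event
    t1e <- min(t1, bleach)
    if (t1e > t0) {
      f1e <- min(ceiling(t1e / dt), n_frames)
      fre <- f0:f1e
      ove <- pmax(pmin(t1e, fre * dt) - pmax(t0, (fre - 1) * dt), 0)
      fm <- scheme$fret_means[[path$state[i]]]
      fret_time[fre] <- fret_time[fre] + ove * fm
      emit_time[fre] <- emit_time[fre] + ove
    }
  }

  true_fret <- ifelse(emit_time > 0, fret_time / emit_time, 0)
  emit_frac <- emit_time / dt
  donor_sig <- emission$total_intensity * (1 - true_fret) * emit_frac
  acceptor_sig <- emission$total_intensity * true_fret * emit_frac
  nsd <- emission$channel_noise_sd
  donor <- donor_sig + emission$background_donor +
    if (nsd > 0) rnorm(n_frames, 0, nsd) else 0
  acceptor <- acceptor_sig + emission$leakage_fraction * donor_sig +
    emission$background_acceptor +
    if (nsd > 0) rnorm(n_frames, 0, nsd) else 0

  majority <- scheme$state_names[max.col(occ_time, ties.method = "first")]
  bleach_frame <- if (is.finite(bleach))
    min(floor(bleach / dt) + 1L, n_frames) else n_frames

  structure(
    data.frame(molecule_id = molecule_id,
               frame_index = seq_len(n_frames),
               time_s = (seq_len(n_frames) - 1) * dt,
               intensity_donor = donor,
               intensity_acceptor = acceptor,
               stringsAsFactors = FALSE),
    true_fret = true_fret,
    majority_state = majority,
    bleach_frame = bleach_frame,
    bleach_time = bleach,
    class = c("intensity_trace", "data.frame"))
}

#' Generate a synthetic smFRET dataset
#'
#' Simulates one intensity trace per molecule for each target preset and
#' collects them with a manifest holding the generation parameters and the
#' ground truth. Two initialization modes are supported: `"equilibrium"`
#' draws each molecule's starting state from the scheme's occupancy after a
#' pre-imaging incubation (steady-state imaging experiments), while
#' `"flow_in"` starts every molecule unbound (the ribonucleoprotein is
#' flowed in as acquisition starts; association experiments).
#'
#' @param presets a [target_preset()] or list of them.
#' @param n_molecules number of molecules per preset.
#' @param emission An [emission_model()].
#' @param duration trace length in seconds.
#' @param seed integer seed; the dataset is reproducible given the seed.
#' @param init `"equilibrium"` or `"flow_in"`.
#' @param t_incubation pre-imaging incubation time in seconds used by the
#'   equilibrium mode (default 600).
#' @return A `cas9_dataset`: list with `traces` (list of `intensity_trace`)
#'   and `manifest` (preset names, concentration, frame interval, seed,
#'   ground-truth block).
#' @examples
#' ds <- generate_dataset(cas9_presets("5-20_mm"), n_molecules = 3,
#'                        emission = emission_model(), duration = 10,
#'                        seed = 7)
#' length(ds$traces)
#' @export
generate_dataset <- function(presets, n_molecules, emission = emission_model(),
                             duration = 120, seed = 1,
                             init = c("equilibrium", "flow_in"),
                             t_incubation = 600) {
  if (inherits(presets, "target_preset")) presets <- list(presets)
  stopifnot(all(vapply(presets, inherits, TRUE, "target_preset")))
  if (n_molecules < 1) stop("`n_molecules` must be >= 1")
  init <- match.arg(init)
  set.seed(seed)
  n_frames <- floor(duration / emission$frame_interval)

  traces <- list()
  truth <- list()
  for (pre in presets) {
    sch <- pre$scheme
    p0 <- if (init == "equilibrium")
      state_occupancy(sch, t_incubation, init = "U")[1, ]
    else c(U = 1, S = 0, H = 0)
    ids <- sprintf("%s_%04d", gsub("[^A-Za-z0-9]", "_", pre$name),
                   seq_len(n_molecules))
    if (anyDuplicated(ids)) stop("duplicate molecule ids")
    for (m in seq_len(n_molecules)) {
      start <- sample(sch$state_names, 1, prob = p0)
      path <- simulate_state_path(sch, duration, init_state = start)
      traces[[ids[m]]] <- emit_intensities(path, sch, emission, n_frames,
                                           molecule_id = ids[m])
    }
    truth[[pre$name]] <- list(
      rates = effective_rates(sch),
      fret_means = as.list(sch$fret_means),
      photobleach_rate = sch$photobleach_rate,
      mean_bound_lifetime_s = tryCatch(mean_bound_lifetime(sch),
                                       error = function(e) NA_real_),
      initial_occupancy = as.list(p0))
  }

  manifest <- list(
    presets = vapply(presets, function(p) p$name, character(1)),
    concentration_molar = presets[[1]]$scheme$concentration,
    frame_interval_s = emission$frame_interval,
    duration_s = duration,
    n_molecules = n_molecules,
    seed = seed,
    init = init,
    t_incubation_s = if (init == "equilibrium") t_incubation else NULL,
    emission = unclass(emission),
    ground_truth = truth)
  structure(list(traces = traces, manifest = manifest),
            class = "cas9_dataset")
}

#' @export
print.cas9_dataset <- function(x, ...) {
  cat(sprintf("smFRET dataset: %d traces, presets [%s], %.3g M, %.2f s frames\n",
              length(x$traces), paste(x$manifest$presets, collapse = ", "),
              x$manifest$concentration_molar, x$manifest$frame_interval_s))
  invisible(x)
}

#' Write a dataset to disk
#'
#' Writes all traces as one tab-separated file (`traces.tsv`, columns
#' `molecule_id`, `frame_index`, `time_s`, `intensity_donor`,
#' `intensity_acceptor`) and the manifest as `manifest.json`.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cas9_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- do.call(rbind, lapply(dataset$traces, function(tr) {
    tr[, c("molecule_id", "frame_index", "time_s",
           "intensity_donor", "intensity_acceptor")]
  }))
  rownames(tab) <- NULL
  write.table(format(tab, digits = 10, trim = TRUE, scientific = FALSE),
              file.path(dir, "traces.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor")
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `traces.tsv` and `manifest.json`.
#' @return A `cas9_dataset` (without per-trace ground-truth attributes,
#'   which live in the manifest only).
#' @export
read_dataset <- function(dir) {
  tab <- read.table(file.path(dir, "traces.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = TRUE)
  traces <- lapply(split(tab, tab$molecule_id), function(tr) {
    tr <- tr[order(tr$frame_index), ]
    rownames(tr) <- NULL
    class(tr) <- c("intensity_trace", "data.frame")
    tr
  })
  structure(list(traces = traces, manifest = manifest),
            class = "cas9_dataset")
}
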