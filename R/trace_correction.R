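#' Analysis configuration
#'
#' Bundles the thresholds and correction constants used across the
#' pipeline. The unbound/bound boundary is FRET 0.2 and the high-FRET
#' boundary 0.75; FRET histograms are built from the first five valid
#' frames of each molecule (ten in an alternate convention).
#'
#' @param bound_threshold FRET below this is unbound (default 0.2).
#' @param high_threshold FRET above this counts as the high-FRET bound
#'   population in histograms (default 0.75).
#' @param histogram_frames frames pooled per molecule for histograms
#'   (default 5).
#' @param leakage_fraction donor-to-acceptor bleed-through used by the
#'   correction.
#' @param background_donor,background_acceptor per-channel background
#'   estimates, counts.
#' @param frame_interval_s camera frame interval, seconds.
#' @param clamp two values: corrected FRET is clamped into this range
#'   (default `c(-0.2, 1.2)` so noise-driven excursions remain visible).
#' @param min_dwells minimum number of uncensored dwells required by
#'   survival fits (default 20).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(bound_threshold = 0.2,
                            high_threshold = 0.75,
                            histogram_frames = 5,
                            leakage_fraction = 0.07,
                            background_donor = 50,
                            background_acceptor = 50,
                            frame_interval_s = 0.1,
                            clamp = c(-0.2, 1.2),
                            min_dwells = 20) {
  if (!(bound_threshold > 0 && bound_threshold < high_threshold &&
        high_threshold < 1))
    stop("need 0 < bound_threshold < high_threshold < 1")
  if (frame_interval_s <= 0) stop("`frame_interval_s` must be > 0")
  if (histogram_frames < 1) stop("`histogram_frames` must be >= 1")
  structure(list(bound_threshold = bound_threshold,
                 high_threshold = high_threshold,
                 histogram_frames = histogram_frames,
                 leakage_fraction = leakage_fraction,
                 background_donor = background_donor,
                 background_acceptor = background_acceptor,
                 frame_interval_s = frame_interval_s,
                 clamp = clamp,
                 min_dwells = min_dwells),
            class = "analysis_config")
}

#' Analysis configuration from a dataset manifest
#'
#' Takes the correction constants (backgrounds, leakage, frame interval)
#' from a dataset's manifest, so that synthetic data are corrected with the
#' parameters that generated them; other settings are passed through to
#' [analysis_config()].
#'
#' @param manifest manifest of a `cas9_dataset`.
#' @param ... overrides forwarded to [analysis_config()].
#' @return An `analysis_config`.
#' @export
config_from_manifest <- function(manifest, ...) {
  em <- manifest$emission
  analysis_config(leakage_fraction = em$leakage_fraction,
                  background_donor = em$background_donor,
                  background_acceptor = em$background_acceptor,
                  frame_interval_s = manifest$frame_interval_s, ...)
}

#' Correct a raw two-channel trace to a FRET trajectory
#'
#' Applies background subtraction and donor leakage correction, then
#' computes the FRET efficiency `I_A / (I_D + I_A)` per frame, where `I_D`
#' and `I_A` are the corrected donor and acceptor intensities. Frames after
#' the detected photobleach (see [detect_photobleach()]) are excluded from
#' downstream statistics via `valid_through`; pre-bleach frames whose
#' corrected total intensity is not positive are flagged invalid rather
#' than raising an error.
#'
#' @param trace an `intensity_trace` (see [emit_intensities()]).
#' @param config an [analysis_config()].
#' @return A `fret_trajectory`: data frame with columns `time_s`, `fret`,
#'   `donor_corrected`, `acceptor_corrected`, `valid`; attributes
#'   `molecule_id`, `valid_through` (last pre-bleach frame index, 0 if the
#'   trace is bleached from the start) and `frame_interval_s`.
#' @export
correct_trace <- function(trace, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  i_d <- trace$intensity_donor - config$background_donor
  i_a <- trace$intensity_acceptor - config$background_acceptor -
    config$leakage_fraction * i_d
  total <- i_d + i_a
  fret <- ifelse(total > 0, i_a / total, NA_real_)
  fret <- pmin(pmax(fret, config$clamp[1]), config$clamp[2])
  valid_through <- detect_photobleach(total)
  valid <- !is.na(fret) & seq_along(fret) <= valid_through
  structure(
    data.frame(time_s = trace$time_s,
               fret = fret,
               donor_corrected = i_d,
               acceptor_corrected = i_a,
               valid = valid),
    molecule_id = trace$molecule_id[1],
    valid_through = valid_through,
    frame_interval_s = config$frame_interval_s,
    class = c("fret_trajectory", "data.frame"))
}

#' Detect the photobleaching frame of a trace
#'
#' Finds the last frame before the corrected total intensity drops below
#' 30% of its pre-drop level and stays there until the end of the trace.
#' Loss of either dye ends the FRET observable, so the detector watches the
#' total (donor plus acceptor) intensity, not a single channel. The default
#' is conservative: a trace with no terminal drop returns its final frame;
#' a trace that is dark throughout returns 0.
#'
#' @param total numeric vector of corrected total intensities (or an
#'   `intensity_trace`-like data frame with both intensity columns, from
#'   which the plain sum is used).
#' @param drop_fraction drop level relative to the pre-drop intensity
#'   (default 0.3).
#' @return integer: last frame index before bleaching (0 if bleached from
#'   the start; `length(total)` if no bleach detected).
#' @export
detect_photobleach <- function(total, drop_fraction = 0.3) {
  if (is.data.frame(total))
    total <- total$intensity_donor + total$intensity_acceptor
  n <- length(total)
  if (n < 10) return(n)
  sm <- stats::runmed(total, 5)
  # reference level: the smoothed maximum is robust to isolated spikes and,
  # unlike a fixed quantile, still finds the pre-drop level when a trace
  # bleaches early and is dark for most of its frames
  peak <- max(sm)
  # dark throughout: the "signal" level is indistinguishable from noise
  if (peak <= 3 * mad(total) || peak <= 0) return(0L)
  thr <- drop_fraction * peak
  below <- sm < thr
  if (!below[n]) return(n)
  # start of the terminal run of below-threshold frames
  runs <- rle(below)
  k <- length(runs$values)
  start_last <- n - runs$lengths[k] + 1L
  start_last - 1L
}

#' Pool trajectories into a FRET histogram and bound fraction
#'
#' Pools the first `histogram_frames` valid (pre-bleach) frames of each
#' molecule, bins them at width 0.05 over the clamp range, and reports the
#' bound fraction as the proportion of pooled data points with FRET above
#' the high threshold (0.75).
#'
#' @param trajectories list of `fret_trajectory` objects (or a single one).
#' @param config an [analysis_config()].
#' @return A `histogram_summary`: list with `bin_edges`, `counts`,
#'   `n_molecules`, `frames_per_molecule`, `n_points`, `bound_fraction`.
#' @examples
#' # a molecule contributing frames 0.9, 0.9, 0.8, 0.1, 0.5 has 3/5 above 0.75
#' @export
build_histogram <- function(trajectories, config = analysis_config()) {
  if (inherits(trajectories, "fret_trajectory"))
    trajectories <- list(trajectories)
  if (length(trajectories) == 0) stop("no trajectories supplied")
  pooled <- unlist(lapply(trajectories, function(tr) {
    f <- tr$fret[tr$valid]
    head(f, config$histogram_frames)
  }), use.names = FALSE)
  if (length(pooled) == 0) stop("no valid frames in any trajectory")
  edges <- seq(config$clamp[1], config$clamp[2], by = 0.05)
  counts <- tabulate(findInterval(pooled, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  structure(list(bin_edges = edges,
                 counts = counts,
                 n_molecules = length(trajectories),
                 frames_per_molecule = config$histogram_frames,
                 n_points = length(pooled),
                 bound_fraction = mean(pooled > config$high_threshold)),
            class = "histogram_summary")
}

#' @export
print.histogram_summary <- function(x, ...) {
  cat(sprintf(
    "FRET histogram: %d molecules x %d frames (%d points), bound fraction %.3f\n",
    x$n_molecules, x$frames_per_molecule, x$n_points, x$bound_fraction))
  invisible(x)
}

#' Write a histogram summary to CSV / JSON
#'
#' @param hist a [build_histogram()] result.
#' @param csv_path path for the per-bin CSV (`bin_left`, `bin_right`,
#'   `count`).
#' @param json_path optional path for a JSON summary with the bound
#'   fraction.
#' @return `csv_path`, invisibly.
#' @export
write_histogram <- function(hist, csv_path, json_path = NULL) {
  stopifnot(inherits(hist, "histogram_summary"))
  k <- length(hist$bin_edges)
  tab <- data.frame(bin_left = hist$bin_edges[-k],
                    bin_right = hist$bin_edges[-1],
                    count = hist$counts)
  write.table(tab, csv_path, sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(n_molecules = hist$n_molecules,
           frames_per_molecule = hist$frames_per_molecule,
           n_points = hist$n_points,
           bound_fraction = hist$bound_fraction),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
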