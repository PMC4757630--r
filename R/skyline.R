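#' Skyline trajectories
#'
#' A Bayesian skyline trajectory records median effective population size
#' through time (years BP), optionally with lower/upper bounds.  The
#' trajectory is consumed as-is — estimating it (e.g. with an external
#' MCMC) is out of scope here.
#'
#' @param times ascending years before present.
#' @param sizes effective population sizes (individuals), matching `times`.
#' @param lower,upper optional credibility bounds.
#' @return an object of class `skyline_trajectory`.
#' @export
skyline_trajectory <- function(times, sizes, lower = NULL, upper = NULL) {
  times <- as.numeric(times); sizes <- as.numeric(sizes)
  if (length(times) != length(sizes))
    stop("times and sizes must have equal length", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(sizes <= 0)) stop("sizes must be positive", call. = FALSE)
  structure(list(times = times, sizes = sizes, lower = lower,
                 upper = upper),
            class = "skyline_trajectory")
}

#' Read a skyline trajectory from a TSV table
#'
#' Expects columns `time`, `median` and optionally `lower`, `upper`.
#' @param path file to read.
#' @return a `skyline_trajectory`.
#' @export
read_skyline <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE)
  skyline_trajectory(tab$time, tab$median, lower = tab$lower,
                     upper = tab$upper)
}

#' Expansion increments from a skyline trajectory
#'
#' Interpolates the trajectory piecewise-linearly onto a regular grid
#' (default 100-year steps) and differentiates it going back in time:
#' the increment at time t is (N(t) - N(t + step)) / size_unit, expressed
#' in units of `size_unit` individuals per `time_step` years, positive
#' when the population grows towards the present.  The increments conserve
#' total change: their sum equals (N(start) - N(end)) / size_unit.
#'
#' @param traj a `skyline_trajectory` with at least two points.
#' @param time_step grid step in years (default 100).
#' @param size_unit size unit in individuals (default 100).
#' @return data frame with columns `time` (years BP) and `increment`.
#' @export
expansion_increments <- function(traj, time_step = 100, size_unit = 100) {
  stopifnot(inherits(traj, "skyline_trajectory"))
  if (length(traj$times) < 2)
    stop("trajectory needs at least two points", call. = FALSE)
  grid <- seq(min(traj$times), max(traj$times), by = time_step)
  n <- stats::approx(traj$times, traj$sizes, xout = grid)$y
  inc <- (n[-length(n)] - n[-1]) / size_unit
  data.frame(time = grid[-length(grid)], increment = inc)
}

#' Detect expansion onset and peak from an increment series
#'
#' The peak is the grid time of the maximal increment.  The onset is the
#' oldest time on the contiguous rise towards the peak at which the
#' increment still exceeds `threshold` (default 10 per cent) of the peak
#' increment.  All local maxima are also reported (useful for two-phase
#' expansions); the primary peak is the global one.  A series with no
#' positive increment has no defined expansion and is flagged.
#'
#' @param increments data frame from [expansion_increments()].
#' @param threshold onset threshold as a fraction of the peak increment.
#' @return list with `onset`, `peak`, `defined`, `local_peaks`.
#' @export
detect_expansion <- function(increments, threshold = 0.1) {
  t <- increments$time; v <- increments$increment
  if (all(v <= 0)) {
    return(list(onset = NA_real_, peak = NA_real_, defined = FALSE,
                local_peaks = numeric(0)))
  }
  ipk <- which.max(v)
  peak <- t[ipk]
  cut <- threshold * v[ipk]
  i <- ipk
  while (i < length(v) && v[i + 1] > cut) i <- i + 1  # walk to older times
  onset <- t[i]
  is_local <- vapply(seq_along(v), function(k) {
    v[k] > 0 &&
      (k == 1 || v[k] >= v[k - 1]) &&
      (k == length(v) || v[k] >= v[k + 1])
  }, NA)
  list(onset = onset, peak = peak, defined = TRUE,
       local_peaks = t[is_local])
}
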