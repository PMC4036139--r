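# Homogeneous PM chains: maximal-run extraction, the -2 cm/s stationary vs
# backwards split of PM 01 chains, chain statistics, and onset-triggered
# averages with t-based confidence intervals.

#' Extract maximal homogeneous PM runs
#'
#' Finds maximal runs of consecutive records sharing `pm_id` (no run is
#' extendable in either direction), splits runs at contiguity gaps given by
#' `segment`, and discards runs shorter than `min_len`. Indices are 1-based
#' and inclusive, referring to rows of the label vector.
#'
#' @param labels integer vector of per-record PM labels.
#' @param pm_id the PM whose runs are extracted.
#' @param min_len minimum run length in records (default 10, the minimum
#'   chain length used for homogeneous-chain analysis).
#' @param segment optional vector marking contiguous segments; runs never
#'   cross a segment boundary.
#' @param t optional per-record time stamps used to fill chain durations.
#' @return data frame of class `pm_chains`: `start`, `end` (inclusive row
#'   indices), `pm`, `n_frames`, `duration_s` (`NA` without `t`).
#' @export
extract_runs <- function(labels, pm_id, min_len = 10, segment = NULL, t = NULL) {
  n <- length(labels)
  if (is.null(segment)) segment <- rep(1L, n)
  key <- paste(segment, labels)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- labels[starts] == pm_id & !is.na(labels[starts]) & r$lengths >= min_len
  out <- data.frame(start = starts[keep], end = ends[keep],
                    pm = rep(pm_id, sum(keep)), n_frames = r$lengths[keep])
  out$duration_s <- if (!is.null(t)) t[out$end] - t[out$start] else NA_real_
  class(out) <- c("pm_chains", "data.frame")
  out
}

#' Split PM 01 chains into stationary and backwards swimming
#'
#' Classifies each chain by its mean thrust: chains with mean thrust below
#' `threshold` are backwards swimming, chains at or above it (boundary
#' inclusive) are stationary behavior. The default threshold is -2 cm/s,
#' separating reversed swimming from near-motionless probing.
#'
#' @param chains a `pm_chains` data frame of PM 01 runs.
#' @param kinematics data frame whose rows align with the label vector the
#'   chains were extracted from; must contain `thrust`.
#' @param threshold thrust threshold in cm/s.
#' @param pm_id the id of the backward-capable prototype; passing chains of a
#'   different PM is an error.
#' @return `chains` with columns `mean_thrust` and `behavior`
#'   (`"stationary"` or `"backwards"`) added.
#' @export
split_pm01 <- function(chains, kinematics, threshold = -2, pm_id = NULL) {
  if (!is.null(pm_id) && any(chains$pm != pm_id))
    stopf("split_pm01 expects chains of PM %s only", pm_id)
  if (length(unique(chains$pm)) > 1L)
    stopf("split_pm01 expects chains of a single PM")
  mt <- vapply(seq_len(nrow(chains)), function(i)
    mean(kinematics$thrust[chains$start[i]:chains$end[i]]), numeric(1))
  chains$mean_thrust <- mt
  chains$behavior <- ifelse(mt < threshold, "backwards", "stationary")
  chains
}

#' Summary statistics of a chain set
#'
#' @param chains a `pm_chains` data frame.
#' @return one-row data frame: `count`, mean and SD of chain length (frames)
#'   and duration (s). An empty chain set gives `count = 0` with `NA`
#'   statistics; a single chain reports SD 0.
#' @export
chain_statistics <- function(chains) {
  n <- nrow(chains)
  if (n == 0L)
    return(data.frame(count = 0L, mean_length = NA_real_, sd_length = NA_real_,
                      mean_duration_s = NA_real_, sd_duration_s = NA_real_))
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  data.frame(count = n,
             mean_length = mean(chains$n_frames), sd_length = sd0(chains$n_frames),
             mean_duration_s = mean(chains$duration_s),
             sd_duration_s = sd0(chains$duration_s))
}

#' Onset-triggered average of an irregularly sampled signal
#'
#' Averages a signal across events aligned to their onsets. Each onset
#' contributes the signal resampled onto a common relative time grid by
#' nearest-frame lookup (restricted to the onset's own group, e.g. session;
#' grid points whose nearest frame lies farther than `max_gap_s` away are
#' dropped). Per grid point the mean, SD, t-based 95 percent confidence
#' interval of the mean and the number of contributing events are reported;
#' bins with fewer than two contributions are masked.
#'
#' @param signals data frame with columns `t` (time, s), `value`, and
#'   optionally `group` (one time base per group).
#' @param onsets data frame with `t0` (onset times) and optionally `group`,
#'   or a numeric vector of onset times.
#' @param window numeric `c(pre, post)` in seconds relative to onset
#'   (`pre` negative to include pre-onset time).
#' @param step grid step in seconds (default 0.04, the nominal inter-pulse
#'   interval at 25 Hz).
#' @param max_gap_s maximum |time difference| for the nearest-frame lookup.
#' @return data frame of class `triggered_trace`: `t_rel`, `mean`, `sd`,
#'   `ci_lo`, `ci_hi`, `n`.
#' @export
triggered_average <- function(signals, onsets, window = c(-0.5, 1),
                              step = 0.04, max_gap_s = step) {
  if (is.numeric(onsets)) onsets <- data.frame(t0 = onsets)
  if (nrow(onsets) == 0L) stopf("no onsets supplied")
  if (is.null(signals$group)) signals$group <- 1L
  if (is.null(onsets$group)) onsets$group <- 1L
  grid <- seq(window[1], window[2], by = step)

  vals <- matrix(NA_real_, nrow(onsets), length(grid))
  sp <- split(seq_len(nrow(signals)), signals$group)
  for (i in seq_len(nrow(onsets))) {
    rows <- sp[[as.character(onsets$group[i])]]
    if (is.null(rows)) next
    tt <- signals$t[rows]
    target <- onsets$t0[i] + grid
    j <- findInterval(target, tt, all.inside = TRUE)
    j2 <- ifelse(abs(tt[pmin(j + 1L, length(tt))] - target) < abs(tt[j] - target),
                 pmin(j + 1L, length(tt)), j)
    ok <- abs(tt[j2] - target) <= max_gap_s
    vals[i, ok] <- signals$value[rows][j2[ok]]
  }
  n <- colSums(!is.na(vals))
  m <- colMeans(vals, na.rm = TRUE)
  s <- apply(vals, 2L, stats::sd, na.rm = TRUE)
  half <- ifelse(n >= 2L, stats::qt(0.975, pmax(n - 1L, 1L)) * s / sqrt(n), NA_real_)
  out <- data.frame(t_rel = grid, mean = m, sd = s,
                    ci_lo = m - half, ci_hi = m + half, n = n)
  out[n < 2L, c("mean", "sd", "ci_lo", "ci_hi")] <- NA_real_
  class(out) <- c("triggered_trace", "data.frame")
  out
}
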