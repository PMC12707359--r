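#' Windowed diffusion coefficient of one trajectory
#'
#' Slides a window of `window_frames` positions along the trajectory
#' (stride = `floor(window_frames / 2)`, i.e. 50% overlap) and estimates
#' the apparent diffusion coefficient per window from single-frame
#' squared displacements:
#' \deqn{\hat D = \langle \Delta x^2 + \Delta y^2 \rangle / (4 \Delta t)}
#' Localization noise biases the estimate upward by `sigma_loc^2/dt`;
#' with `noise_correction = TRUE` that offset is subtracted (then
#' negative values are possible and flagged via the `noise_corrected`
#' attribute).
#'
#' @param traj A trajectory table with columns `t_s`, `x_um`, `y_um`
#'   (see [render_trajectory()]); frame spacing must be uniform.
#' @param window_frames Window length in frames (>= 2).
#' @param noise_correction Subtract `sigma_loc^2/dt`?
#' @param sigma_loc Localization noise SD (um), used only if
#'   `noise_correction`.
#' @return A data frame of class `diffusivity_series` with `t_mid` (s,
#'   window midpoint) and `D_hat` (um^2/s).
#' @export
windowed_diffusion <- function(traj, window_frames = 16,
                               noise_correction = FALSE, sigma_loc = 0.02) {
  if (window_frames < 2) stop("window_frames must be >= 2")
  n <- nrow(traj)
  if (n < window_frames) stop("trajectory spans less than one window")
  dts <- diff(traj$t_s)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * dt + 1e-9))
    stop("non-uniform frame spacing within the trajectory")

  sq <- diff(traj$x_um)^2 + diff(traj$y_um)^2   # n-1 single-frame terms
  stride <- max(1L, window_frames %/% 2L)
  starts <- seq(1L, n - window_frames + 1L, by = stride)
  csum <- c(0, cumsum(sq))
  m <- window_frames - 1L                       # displacements per window
  D_hat <- (csum[starts + m] - csum[starts]) / m / (4 * dt)
  if (noise_correction) D_hat <- D_hat - sigma_loc^2 / dt
  t_mid <- traj$t_s[starts] + (window_frames - 1) * dt / 2
  out <- data.frame(t_mid = t_mid, D_hat = D_hat)
  attr(out, "particle_id") <- traj$particle_id[1]
  attr(out, "window_s") <- (window_frames - 1) * dt
  attr(out, "stride_s") <- stride * dt
  attr(out, "noise_corrected") <- noise_correction
  class(out) <- c("diffusivity_series", "data.frame")
  out
}

#' Classify bound/unbound states from a diffusivity series
#'
#' Hysteresis (Schmitt-trigger) classifier: switch to *bound* when
#' `D_hat < D_low`, to *unbound* when `D_hat > D_high`, and hold the
#' current state inside the dead band. Candidate dwells shorter than
#' `min_dwell_windows` windows are merged into the surrounding state to
#' suppress threshold chatter. The initial state is taken from the first
#' window (bound if below `D_low`; unbound if above `D_high`; otherwise
#' whichever threshold is closer on a log-ish midpoint rule).
#'
#' @param dser A `diffusivity_series` from [windowed_diffusion()].
#' @param thresholds Numeric `c(D_low, D_high)` in um^2/s, `D_low < D_high`.
#' @param min_dwell_windows Minimum dwell length in windows (>= 1).
#' @return A `state_sequence` whose interval boundaries lie halfway
#'   between consecutive window midpoints.
#' @export
classify_states <- function(dser, thresholds = c(0.05, 0.15),
                            min_dwell_windows = 2) {
  if (nrow(dser) == 0) stop("empty diffusivity series")
  D_low <- thresholds[1]; D_high <- thresholds[2]
  if (!(D_low < D_high)) stop("need D_low < D_high")
  if (min_dwell_windows < 1) stop("min_dwell_windows must be >= 1")

  D <- dser$D_hat
  n <- length(D)
  st <- logical(n)                 # TRUE = bound
  st[1] <- if (D[1] < D_low) TRUE
           else if (D[1] > D_high) FALSE
           else D[1] < (D_low + D_high) / 2
  for (i in seq_len(n)[-1]) {
    st[i] <- if (D[i] < D_low) TRUE
             else if (D[i] > D_high) FALSE
             else st[i - 1]
  }

  # merge runs shorter than min_dwell_windows into the neighbouring state
  r <- rle(st)
  while (length(r$lengths) > 1 && any(r$lengths < min_dwell_windows)) {
    j <- which.min(r$lengths)
    if (r$lengths[j] >= min_dwell_windows) break
    r$values[j] <- if (j > 1) r$values[j - 1] else r$values[j + 1]
    r <- rle(inverse.rle(r))
  }
  st <- inverse.rle(r)

  # interval edges: halfway between consecutive window midpoints
  tm <- dser$t_mid
  half <- if (n > 1) diff(tm) / 2 else attr(dser, "stride_s") / 2
  if (is.null(half) || length(half) == 0) half <- 0.5
  edges <- c(tm[1] - half[1], tm[-n] + half, tm[n] + half[length(half)])
  r <- rle(st)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- c(1, utils::head(ends_idx, -1) + 1)
  df <- data.frame(state = ifelse(r$values, "bound", "unbound"),
                   t_start = edges[starts_idx],
                   t_end = edges[ends_idx + 1],
                   stringsAsFactors = FALSE)
  new_state_sequence(df, particle_id = attr(dser, "particle_id"))
}

#' Count unbound-to-bound events per measurement interval
#'
#' A UTB event occurs at the start of every bound interval that was
#' entered from the unbound state (the first interval of a sequence is an
#' initial condition, not a transition). Each event is assigned to the
#' half-open measurement interval `[edge_i, edge_{i+1})` containing the
#' bound interval's `t_start`; bound-to-unbound transitions are ignored.
#'
#' @param states A `state_sequence`.
#' @param interval_edges Increasing vector of interval edges (s); `k`
#'   edges define `k - 1` intervals.
#' @return Integer vector of UTB counts, one per interval.
#' @export
count_utb <- function(states, interval_edges) {
  if (is.unsorted(interval_edges, strictly = TRUE))
    stop("interval_edges must be strictly increasing")
  k <- length(interval_edges) - 1L
  if (k < 1) stop("need at least two interval edges")
  if (is.null(states) || nrow(states) == 0) return(integer(k))
  bidx <- which(states$state == "bound")
  bidx <- bidx[bidx > 1]
  if (!length(bidx)) return(integer(k))
  tt <- states$t_start[bidx]
  bins <- findInterval(tt, interval_edges, rightmost.closed = FALSE,
                       left.open = FALSE)
  bins <- bins[bins >= 1L & bins <= k & tt < interval_edges[k + 1L]]
  tabulate(bins, nbins = k)
}

#' Times of unbound-to-bound events in a state sequence
#'
#' @param states A `state_sequence`.
#' @return Numeric vector of event times (s), the starts of bound
#'   intervals entered from the unbound state.
#' @export
utb_times <- function(states) {
  bidx <- which(states$state == "bound")
  bidx <- bidx[bidx > 1]
  states$t_start[bidx]
}

#' Full trajectory readout for a field of view
#'
#' Applies the readout chain (windowed diffusion, hysteresis state
#' classification, UTB counting) to every particle trajectory and sums
#' the counts into an activity trace: UTB events per particle per minute
#' for each measurement interval. Particles whose trajectories span less
#' than one diffusion window are excluded and counted in the
#' `excluded_particles` attribute.
#'
#' @param trajectories List of trajectory tables (one per particle), or a
#'   single long table with a `particle_id` column.
#' @param interval_edges Measurement interval edges in seconds, on the
#'   same clock as the trajectories.
#' @param window_frames,thresholds,min_dwell_windows,noise_correction,sigma_loc
#'   Readout parameters; see [windowed_diffusion()] and
#'   [classify_states()].
#' @return A data frame of class `activity_trace` with `t_min` (interval
#'   midpoint, minutes), `counts`, `n_particles`, `activity`
#'   (events/particle/min). Inferred per-particle state sequences are
#'   attached as the `state_sequences` attribute.
#' @export
readout_experiment <- function(trajectories, interval_edges,
                               window_frames = 16,
                               thresholds = c(0.05, 0.15),
                               min_dwell_windows = 2,
                               noise_correction = FALSE,
                               sigma_loc = 0.02) {
  if (is.data.frame(trajectories))
    trajectories <- split(trajectories, trajectories$particle_id)
  if (!length(trajectories)) stop("need at least one particle")
  k <- length(interval_edges) - 1L
  counts <- integer(k)
  excluded <- 0L
  seqs <- vector("list", length(trajectories))
  used <- 0L
  for (tr in trajectories) {
    if (nrow(tr) < window_frames) { excluded <- excluded + 1L; next }
    ds <- windowed_diffusion(tr, window_frames, noise_correction, sigma_loc)
    ss <- classify_states(ds, thresholds, min_dwell_windows)
    counts <- counts + count_utb(ss, interval_edges)
    used <- used + 1L
    seqs[[used]] <- ss
  }
  if (used == 0L) stop("no usable particles (all shorter than one window)")
  mins <- diff(interval_edges) / 60
  out <- data.frame(t_min = (utils::head(interval_edges, -1) +
                             diff(interval_edges) / 2) / 60,
                    counts = counts,
                    n_particles = used,
                    activity = counts / used / mins)
  attr(out, "excluded_particles") <- excluded
  attr(out, "state_sequences") <- seqs[seq_len(used)]
  class(out) <- c("activity_trace", "data.frame")
  out
}

#' Match inferred UTB events against ground truth
#'
#' Greedy one-to-one matching by time: an inferred event matches a true
#' event if their times differ by at most `tol_s`. Used to score the
#' end-to-end readout (sensitivity = matched / true, precision =
#' matched / inferred).
#'
#' @param true_times,inferred_times Event times (s).
#' @param tol_s Matching tolerance (s); one diffusion window by default.
#' @return List with `n_true`, `n_inferred`, `n_matched`, `sensitivity`,
#'   `precision`.
#' @export
match_events <- function(true_times, inferred_times, tol_s = 1) {
  true_times <- sort(true_times); inferred_times <- sort(inferred_times)
  i <- 1L; j <- 1L; matched <- 0L
  while (i <= length(true_times) && j <= length(inferred_times)) {
    d <- inferred_times[j] - true_times[i]
    if (abs(d) <= tol_s) { matched <- matched + 1L; i <- i + 1L; j <- j + 1L }
    else if (d < 0) j <- j + 1L
    else i <- i + 1L
  }
  list(n_true = length(true_times), n_inferred = length(inferred_times),
       n_matched = matched,
       sensitivity = if (length(true_times)) matched / length(true_times) else NA_real_,
       precision = if (length(inferred_times)) matched / length(inferred_times) else NA_real_)
}
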