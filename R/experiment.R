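#' Multiplicative sensor drift factor
#'
#' Raw sensor activity declines slowly over hours (loss of binders on
#' particles and substrate, nonspecific interactions). The decline is
#' modelled as geometric decay: after `t` hours at fractional rate `r`
#' per hour the signal is scaled by `(1 - r)^t`.
#'
#' @param t_min Time on the experiment clock (minutes), vectorized.
#' @param drift_rate Fractional decline per hour in `[0, 1)`.
#' @return Drift factor in `(0, 1]`.
#' @export
#' @examples
#' drift_factor(9 * 60, 0.05)   # 0.95^9
drift_factor <- function(t_min, drift_rate) {
  if (drift_rate < 0 || drift_rate >= 1) stop("drift_rate must be in [0, 1)")
  (1 - drift_rate)^(t_min / 60)
}

#' Estimate the per-hour drift rate from a repeated-reference series
#'
#' Log-linear regression of activity on time: `log A = a + b t` with `t`
#' in hours; the per-hour fractional decline is `1 - exp(b)`.
#'
#' @param t_min Measurement times (minutes).
#' @param activity Raw activity values (> 0).
#' @return A list with `drift_rate` (fraction/h), `percent_per_hour`,
#'   and the regression `slope` (per hour, on the log scale).
#' @export
estimate_drift <- function(t_min, activity) {
  if (length(t_min) != length(activity) || length(t_min) < 3)
    stop("need >= 3 paired (time, activity) values")
  if (any(activity <= 0)) stop("activity values must be > 0 for log regression")
  fit <- stats::lm(log(activity) ~ I(t_min / 60))
  slope <- unname(stats::coef(fit)[2])
  list(drift_rate = 1 - exp(slope),
       percent_per_hour = 100 * (1 - exp(slope)),
       slope = slope)
}

#' Simulate a full sensor experiment under a sample schedule
#'
#' Runs the injections of `schedule` on one experiment clock and produces
#' per-interval unbound-to-bound (UTB) event counts for a field of view of
#' `n_particles` tethered particles.
#'
#' In `"counts"` mode each 1-min interval draws
#' `counts ~ Poisson(n_particles * r(C) * 60 * drift(t))`, where `r(C)` is
#' the stationary UTB event rate of the two-state chain
#' ([stationary_stats()]) and `drift(t)` the geometric decay at the
#' interval midpoint. In `"trajectories"` mode every particle's state
#' sequence is simulated explicitly over each injection's measurement
#' span (binding rates scaled by the drift factor at the start of the
#' injection's measurements) and rendered into an x/y trajectory; counts
#' are then the ground-truth UTB events per interval.
#'
#' @param schedule A [sample_schedule()].
#' @param params A [kinetic_params()].
#' @param n_particles Number of tethered particles in the field of view.
#' @param mode `"counts"` (fast, Poisson summary) or `"trajectories"`
#'   (full per-particle simulation).
#' @param seed Master seed; per-particle substream seeds are derived from
#'   it so results are reproducible.
#' @return An object of class `nsw_experiment`: a list with
#'   * `activity`: data frame `t_min`, `injection_index`, `role`,
#'     `true_conc_pM`, `counts`, `n_particles`, `activity`
#'     (events/particle/min);
#'   * `trajectories` (trajectories mode): list of `nsw_trajectory`
#'     tables, one per (injection, particle);
#'   * `events` (trajectories mode): ground-truth UTB event log with
#'     `t_min`, `injection_index`, `particle_id`;
#'   * `schedule`, `params`, `mode`, `seed`.
#' @export
generate_experiment <- function(schedule, params = kinetic_params(),
                                n_particles = 4000,
                                mode = c("counts", "trajectories"),
                                seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "sample_schedule"))
  if (n_particles < 1) stop("n_particles must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  drift_rate <- attr(schedule, "drift_rate")
  iv <- schedule_intervals(schedule)

  if (mode == "counts") {
    st <- stationary_stats(params, iv$conc_pM)
    mu <- n_particles * st$utb_rate * 60 * drift_factor(iv$t_min, drift_rate)
    counts <- stats::rpois(nrow(iv), mu)
    activity <- data.frame(t_min = iv$t_min,
                           injection_index = iv$injection_index,
                           role = iv$role,
                           true_conc_pM = iv$conc_pM,
                           counts = counts,
                           n_particles = n_particles,
                           activity = counts / n_particles,
                           stringsAsFactors = FALSE)
    return(structure(list(activity = activity, schedule = schedule,
                          params = params, mode = mode, seed = seed),
                     class = "nsw_experiment"))
  }

  # trajectories mode
  trajectories <- list()
  ev_t <- numeric(0); ev_inj <- integer(0); ev_pid <- integer(0)
  counts <- integer(nrow(iv))
  t <- 0
  tr_k <- 0L
  for (i in seq_len(nrow(schedule))) {
    t <- t + schedule$flow_min[i]
    k <- schedule$n_intervals[i]
    meas_start_min <- t
    dur_s <- k * 60
    df <- drift_factor(meas_start_min, drift_rate)
    p_i <- params
    p_i$lambda_max <- params$lambda_max * df
    p_i$lambda_bg <- params$lambda_bg * df
    pseeds <- sample.int(.Machine$integer.max - 1L, 2L * n_particles)
    for (p in seq_len(n_particles)) {
      ss <- simulate_state_sequence(p_i, schedule$conc_pM[i], dur_s,
                                    seed = pseeds[2L * p - 1L])
      tr_k <- tr_k + 1L
      traj <- render_trajectory(ss, p_i, seed = pseeds[2L * p],
                                particle_id = p)
      traj$t_s <- traj$t_s + meas_start_min * 60
      attr(traj, "injection_index") <- i
      trajectories[[tr_k]] <- traj
      # ground-truth UTB events: starts of bound intervals entered from unbound
      bidx <- which(ss$state == "bound")
      bidx <- bidx[bidx > 1]
      if (length(bidx)) {
        tt <- meas_start_min + ss$t_start[bidx] / 60
        ev_t <- c(ev_t, tt)
        ev_inj <- c(ev_inj, rep(i, length(bidx)))
        ev_pid <- c(ev_pid, rep(p, length(bidx)))
      }
    }
    # bin this injection's events into its 1-min intervals [edge, edge+1)
    rows <- which(iv$injection_index == i)
    sel <- ev_inj == i
    if (any(sel)) {
      bins <- floor(ev_t[sel] - meas_start_min) + 1L
      bins <- bins[bins >= 1L & bins <= k]
      tab <- tabulate(bins, nbins = k)
      counts[rows] <- tab
    }
    t <- t + k + schedule$gap_min[i]
  }
  events <- data.frame(t_min = ev_t, injection_index = ev_inj,
                       particle_id = ev_pid)
  activity <- data.frame(t_min = iv$t_min,
                         injection_index = iv$injection_index,
                         role = iv$role,
                         true_conc_pM = iv$conc_pM,
                         counts = counts,
                         n_particles = n_particles,
                         activity = counts / n_particles,
                         stringsAsFactors = FALSE)
  structure(list(activity = activity, trajectories = trajectories,
                 events = events, schedule = schedule, params = params,
                 mode = mode, seed = seed),
            class = "nsw_experiment")
}

#' @export
print.nsw_experiment <- function(x, ...) {
  cat(sprintf("Nanoswitch experiment (%s mode): %d injections, %d intervals, %d particles\n",
              x$mode, nrow(x$schedule), nrow(x$activity),
              x$activity$n_particles[1]))
  cat(sprintf("  activity range %.3g-%.3g events/particle/min\n",
              min(x$activity$activity), max(x$activity$activity)))
  invisible(x)
}
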