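#' Construct a sample schedule
#'
#' An experiment is an ordered series of injections. Each injection flows a
#' sample through the measurement chamber for `flow_min` minutes (no
#' measurements recorded during flow), then records `n_intervals`
#' consecutive 1-minute measurement intervals in static conditions. An
#' optional idle gap can follow each injection. The raw sensor signal
#' decays multiplicatively over the experiment at `drift_rate` per hour
#' (geometric decay, see [drift_factor()]).
#'
#' @param conc_pM Analyte concentration of each injection (pM).
#' @param role One of `"blank"`, `"calibrant"`, `"norm_reference"`,
#'   `"blind"` per injection. Normalization references are the low/high
#'   anchor samples mapped to normalized signal 0 and 1.
#' @param flow_min Flow duration (min) per injection.
#' @param flow_rate_ul_min Flow rate (uL/min), metadata only.
#' @param n_intervals Number of 1-min measurement intervals per injection.
#' @param gap_min Idle time (min) after each injection's measurements.
#' @param drift_rate Fractional raw-signal decline per hour, in `[0, 1)`.
#' @return A data frame of class `sample_schedule`, one row per injection,
#'   with `drift_rate` stored as an attribute.
#' @export
#' @examples
#' sched <- sample_schedule(c(0, 500), c("blank", "calibrant"))
#' schedule_intervals(sched)
sample_schedule <- function(conc_pM, role,
                            flow_min = 1, flow_rate_ul_min = 100,
                            n_intervals = 10, gap_min = 0,
                            drift_rate = 0.05) {
  n <- length(conc_pM)
  roles_ok <- c("blank", "calibrant", "norm_reference", "blind")
  df <- data.frame(conc_pM = conc_pM,
                   role = rep_len(role, n),
                   flow_min = rep_len(flow_min, n),
                   flow_rate_ul_min = rep_len(flow_rate_ul_min, n),
                   n_intervals = as.integer(rep_len(n_intervals, n)),
                   gap_min = rep_len(gap_min, n),
                   stringsAsFactors = FALSE)
  if (any(df$conc_pM < 0)) stop("concentrations must be >= 0")
  if (!all(df$role %in% roles_ok))
    stop("roles must be one of: ", paste(roles_ok, collapse = ", "))
  if (any(df$n_intervals < 1)) stop("n_intervals must be >= 1")
  if (any(df$flow_min < 0) || any(df$gap_min < 0))
    stop("flow and gap durations must be >= 0")
  if (length(drift_rate) != 1 || drift_rate < 0 || drift_rate >= 1)
    stop("drift_rate must lie in [0, 1)")
  attr(df, "drift_rate") <- drift_rate
  class(df) <- c("sample_schedule", "data.frame")
  df
}

#' @export
print.sample_schedule <- function(x, ...) {
  iv <- schedule_intervals(x)
  cat(sprintf("Sample schedule: %d injections, %d measurement intervals, %.2f h total, drift %.3g/h\n",
              nrow(x), nrow(iv), max(iv$t_min) / 60, attr(x, "drift_rate")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Expand a schedule into its measurement intervals on one experiment clock
#'
#' Lays the injections end to end on a single clock starting at 0:
#' flow period, then the 1-min measurement intervals, then the gap. Flow
#' periods and gaps produce no rows.
#'
#' @param schedule A [sample_schedule()].
#' @return Data frame with one row per measurement interval: `t_min`
#'   (interval midpoint on the experiment clock, minutes),
#'   `injection_index`, `interval_index` (within the injection), `role`,
#'   `conc_pM`.
#' @export
schedule_intervals <- function(schedule) {
  stopifnot(inherits(schedule, "sample_schedule"))
  out <- vector("list", nrow(schedule))
  t <- 0
  for (i in seq_len(nrow(schedule))) {
    t <- t + schedule$flow_min[i]
    k <- schedule$n_intervals[i]
    starts <- t + (seq_len(k) - 1)
    out[[i]] <- data.frame(t_min = starts + 0.5,
                           injection_index = i,
                           interval_index = seq_len(k),
                           role = schedule$role[i],
                           conc_pM = schedule$conc_pM[i],
                           stringsAsFactors = FALSE)
    t <- t + k + schedule$gap_min[i]
  }
  do.call(rbind, out)
}

#' Ready-made schedules mirroring the sensor's benchmark experiments
#'
#' * `"figure3_series"`: a blank plus an ascending lactoferrin
#'   concentration series (31.3 to 1000 pM, 2-fold steps), repeated 5
#'   times over about 9 h; 1-min flow at 100 uL/min, 10 consecutive
#'   1-min intervals per injection. The blank and the top concentration
#'   double as the normalization anchors.
#' * `"figure4_milk"`: six series of five diluted-milk samples measured
#'   on one cartridge over ~13 h, with normalization references at
#'   125 pM (zero anchor) and 506 pM (unity anchor) in every series and
#'   blanks between series; 3.5-min flow, eight 1-min intervals.
#' * `"figure5_blind"`: calibrant blocks of five reference
#'   concentrations (recalibration material every ~4 h), four blind
#'   samples measured repeatedly in varying orders, the normalization
#'   pair after every five blind measurements, and periodic blanks;
#'   3.5-min flow, eight 1-min intervals, ~12 h.
#'
#' @param name One of `"figure3_series"`, `"figure4_milk"`,
#'   `"figure5_blind"`.
#' @param drift_rate Fractional raw-signal decline per hour.
#' @return A [sample_schedule()].
#' @export
preset_schedule <- function(name = c("figure3_series", "figure4_milk",
                                     "figure5_blind"),
                            drift_rate = 0.05) {
  name <- match.arg(name)
  if (name == "figure3_series") {
    series_conc <- c(0, 31.3, 62.5, 125, 250, 500, 1000)
    series_role <- c("blank", rep("calibrant", 6))
    conc <- rep(series_conc, 5)
    role <- rep(series_role, 5)
    # 35 injections x (1 flow + 10 measure + 4.4 gap) min ~ 9 h
    return(sample_schedule(conc, role, flow_min = 1,
                           flow_rate_ul_min = 100, n_intervals = 10,
                           gap_min = 4.4, drift_rate = drift_rate))
  }
  if (name == "figure4_milk") {
    milk <- c(160, 240, 330, 440, 719)        # five diluted-milk samples
    conc <- c(); role <- c()
    for (s in 1:6) {
      conc <- c(conc, 125, 506, milk, 0)
      role <- c(role, "norm_reference", "norm_reference",
                rep("calibrant", length(milk)), "blank")
    }
    return(sample_schedule(conc, role, flow_min = 3.5,
                           flow_rate_ul_min = 100, n_intervals = 8,
                           gap_min = 4, drift_rate = drift_rate))
  }
  # figure5_blind
  ref <- c(125, 250, 375, 506, 719)            # five reference concentrations
  blind <- c(160, 300, 450, 680)               # four blind milk samples
  conc <- c(); role <- c()
  add <- function(cc, rr) { conc <<- c(conc, cc); role <<- c(role, rr) }
  blind_orders <- list(c(1, 2, 3, 4, 1), c(4, 3, 2, 1, 2),
                       c(2, 4, 1, 3, 3), c(3, 1, 4, 2, 4))
  for (blk in 1:4) {
    add(ref, rep("calibrant", 5))              # calibrant block (~every 4 h)
    add(c(125, 506), rep("norm_reference", 2)) # normalization pair
    add(blind[blind_orders[[blk]]], rep("blind", 5))
    add(c(125, 506), rep("norm_reference", 2)) # pair after 5 blind samples
    add(0, "blank")
  }
  sample_schedule(conc, role, flow_min = 3.5, flow_rate_ul_min = 100,
                  n_intervals = 8, gap_min = 1.5, drift_rate = drift_rate)
}
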