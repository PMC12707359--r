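#' Extract normalization anchors from an experiment activity table
#'
#' Finds the injections with role `norm_reference`, takes the interval
#' mean of the raw activity per injection, and pairs consecutive
#' low/high-concentration references into anchor repeats. The lower of
#' the two reference concentrations is the zero anchor, the higher the
#' unity anchor; each pair is timestamped at the mean of its two
#' injection times. For schedules without `norm_reference` roles (e.g.
#' the concentration-series experiment) the blank injections and the
#' top-concentration injections can be used instead via `zero_role` /
#' `unity_role`.
#'
#' @param activity Activity table with columns `t_min`,
#'   `injection_index`, `role`, `true_conc_pM`, `activity`.
#' @param zero_role,unity_role Roles used for the anchors. Defaults pick
#'   the `norm_reference` injections and split them by concentration.
#' @return A [normalization_anchors()] object.
#' @export
extract_anchors <- function(activity, zero_role = "norm_reference",
                            unity_role = "norm_reference") {
  per_inj <- function(rows) {
    data.frame(t_min = tapply(rows$t_min, rows$injection_index, mean),
               activity = tapply(rows$activity, rows$injection_index, mean),
               conc = tapply(rows$true_conc_pM, rows$injection_index, mean))
  }
  if (zero_role == "norm_reference" && unity_role == "norm_reference") {
    nr <- activity[activity$role == "norm_reference", ]
    if (!nrow(nr)) stop("no norm_reference injections in the data")
    inj <- per_inj(nr)
    concs <- sort(unique(inj$conc))
    if (length(concs) != 2)
      stop("expected exactly two norm_reference concentrations, got ",
           length(concs))
    lo <- inj[inj$conc == concs[1], ]; hi <- inj[inj$conc == concs[2], ]
    m <- min(nrow(lo), nrow(hi))     # pair repeats in time order
    lo <- lo[order(lo$t_min), ][seq_len(m), ]
    hi <- hi[order(hi$t_min), ][seq_len(m), ]
    return(normalization_anchors(lo$t_min, lo$activity, hi$activity,
                                 unity_t_min = hi$t_min,
                                 zero_conc_pM = concs[1],
                                 unity_conc_pM = concs[2]))
  }
  lo <- per_inj(activity[activity$role == zero_role, ])
  hi <- per_inj(activity[activity$role == unity_role, ])
  if (!nrow(lo) || !nrow(hi)) stop("anchor roles not found in the data")
  m <- min(nrow(lo), nrow(hi))
  lo <- lo[order(lo$t_min), ][seq_len(m), ]
  hi <- hi[order(hi$t_min), ][seq_len(m), ]
  normalization_anchors(lo$t_min, lo$activity, hi$activity,
                        unity_t_min = hi$t_min,
                        zero_conc_pM = lo$conc[1], unity_conc_pM = hi$conc[1])
}

# Group calibrant injections into blocks: a new block starts when the gap
# to the previous calibrant injection exceeds gap_min minutes.
.calibrant_blocks <- function(activity, gap_min = 45) {
  cal <- activity[activity$role == "calibrant", ]
  if (!nrow(cal)) return(NULL)
  inj_t <- tapply(cal$t_min, cal$injection_index, min)
  o <- order(inj_t)
  inj <- as.integer(names(inj_t))[o]
  tt <- as.numeric(inj_t)[o]
  block <- cumsum(c(1, diff(tt) > gap_min))
  lapply(split(inj, block), function(ids) {
    rows <- cal[cal$injection_index %in% ids, ]
    list(injections = ids, rows = rows, t_end = max(rows$t_min))
  })
}

#' Per-sample concentration estimate
#'
#' @param sample_id Identifier (injection index or label).
#' @param conc_pM Per-interval concentration determinations (pM).
#' @param flags Per-interval inversion flags ("ok"/"below_range"/
#'   "above_range"); flagged intervals are excluded from the summary.
#' @param t_min Interval times (minutes).
#' @param true_conc_pM Known concentration if available (NA otherwise).
#' @return Object of class `concentration_estimate` with per-interval
#'   values and summary `mean`, `sd`, `cv_c` (%), `n_intervals`,
#'   `n_excluded`.
#' @export
concentration_estimate <- function(sample_id, conc_pM, flags = NULL,
                                   t_min = NULL, true_conc_pM = NA) {
  if (is.null(flags)) flags <- rep("ok", length(conc_pM))
  ok <- flags == "ok" & is.finite(conc_pM)
  vals <- conc_pM[ok]
  m <- if (length(vals)) mean(vals) else NA_real_
  s <- if (length(vals) > 1) stats::sd(vals) else NA_real_
  structure(list(sample_id = sample_id, conc_pM = conc_pM, flags = flags,
                 t_min = t_min, true_conc_pM = true_conc_pM,
                 mean = m, sd = s,
                 cv_c = if (!is.na(m) && m > 0 && !is.na(s)) 100 * s / m else NA_real_,
                 n_intervals = length(vals), n_excluded = sum(!ok)),
            class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("Sample %s: %.1f pM (SD %.1f, CV_C %.1f%%, n=%d%s)\n",
              as.character(x$sample_id), x$mean, x$sd, x$cv_c,
              x$n_intervals,
              if (x$n_excluded) sprintf(", %d excluded", x$n_excluded) else ""))
  invisible(x)
}

#' Quantify blind samples using one of three calibration strategies
#'
#' All strategies first normalize the raw activity against the
#' time-interpolated normalization anchors ([normalize_signals()]), then
#' convert each blind interval's normalized signal to a concentration by
#' inverting a 4PL calibration curve. They differ in where the curve
#' comes from:
#'
#' 1. **Repeated calibration** — refit the 4PL on the most recent
#'    calibrant block, renewing the fit as new blocks complete
#'    (recalibration period `recal_period_h`, default 4 h).
#' 2. **Single calibration** — fit once on the first calibrant block and
#'    use that curve throughout.
#' 3. **Fixed curve** — use a pre-established curve
#'    (default [fixed_calibration_curve()]); no calibrant data needed.
#'
#' Intervals whose signals fall outside the curve's plateaus are flagged
#' and excluded from the per-sample mean/SD/CV.
#'
#' @param experiment An `nsw_experiment`, or a bare activity table with
#'   columns `t_min`, `injection_index`, `role`, `true_conc_pM`,
#'   `activity`.
#' @param strategy 1, 2 or 3.
#' @param fixed_curve [calibration_curve()] for strategy 3.
#' @param recal_period_h Recalibration period for strategy 1 (hours).
#'   Calibrant blocks are detected from the data; a block is used from
#'   the moment it completes.
#' @param quantify_roles Roles to quantify (default `"blind"`; use
#'   `c("blind", "calibrant")` to also re-estimate known samples).
#' @return A list of class `quantification_result`: `estimates` (list of
#'   [concentration_estimate()]s), `curves` (the curve(s) used),
#'   `anchors`, `strategy`, and `table` (flat per-interval data frame
#'   with `sample_id`, `t_min`, `conc_pM`, `flag`).
#' @export
apply_strategy <- function(experiment, strategy = 3,
                           fixed_curve = fixed_calibration_curve(),
                           recal_period_h = 4,
                           quantify_roles = "blind") {
  activity <- if (inherits(experiment, "nsw_experiment"))
    experiment$activity else experiment
  if (!strategy %in% 1:3) stop("strategy must be 1, 2 or 3")

  anchors <- extract_anchors(activity)
  S <- normalize_signals(activity$t_min, activity$activity, anchors)
  activity$S_norm <- S

  blocks <- .calibrant_blocks(activity)
  if (strategy %in% c(1, 2) && is.null(blocks))
    stop("strategy ", strategy, " requires calibrant injections in the data")
  if (strategy == 3 && is.null(fixed_curve))
    stop("strategy 3 requires a fixed calibration curve")

  fit_block <- function(b)
    fit_calibration(b$rows$true_conc_pM, b$rows$S_norm)

  curves <- switch(as.character(strategy),
    "1" = lapply(blocks, fit_block),
    "2" = list(fit_block(blocks[[1]])),
    "3" = list(fixed_curve))
  block_ends <- if (strategy == 1)
    vapply(blocks, function(b) b$t_end, numeric(1)) else -Inf

  curve_for_time <- function(t) {
    if (strategy != 1) return(curves[[1]])
    avail <- which(block_ends <= t)
    if (!length(avail)) return(curves[[1]])
    curves[[max(avail)]]
  }

  target <- activity[activity$role %in% quantify_roles, ]
  if (!nrow(target)) stop("no injections with roles ",
                          paste(quantify_roles, collapse = "/"), " to quantify")
  est <- list(); tab <- list()
  for (inj in unique(target$injection_index)) {
    rows <- target[target$injection_index == inj, ]
    cc <- numeric(nrow(rows)); fl <- character(nrow(rows))
    for (r in seq_len(nrow(rows))) {
      cv <- curve_for_time(rows$t_min[r])
      x <- invert_sigmoid(cv, rows$S_norm[r])
      cc[r] <- as.numeric(x); fl[r] <- attr(x, "flag")
    }
    e <- concentration_estimate(inj, cc, fl, rows$t_min,
                                true_conc_pM = rows$true_conc_pM[1])
    est[[as.character(inj)]] <- e
    tab[[as.character(inj)]] <- data.frame(sample_id = inj,
                                           t_min = rows$t_min,
                                           conc_pM = cc, flag = fl,
                                           true_conc_pM = rows$true_conc_pM[1])
  }
  structure(list(estimates = est, curves = curves, anchors = anchors,
                 strategy = strategy, table = do.call(rbind, tab)),
            class = "quantification_result")
}

#' @export
print.quantification_result <- function(x, ...) {
  cat(sprintf("Quantification (strategy %d): %d samples, %d curve(s)\n",
              x$strategy, length(x$estimates), length(x$curves)))
  for (e in x$estimates) print(e)
  invisible(x)
}
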