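#' Four-parameter logistic calibration curve
#'
#' The dose-response of the sensor on the normalized-signal scale:
#' \deqn{S(X) = S_{min} + (S_{max} - S_{min}) \frac{X^n}{EC50^n + X^n}}
#' with `S_min` the bottom plateau, `S_max` the top plateau, `EC50` the
#' concentration of half-maximal response (pM) and `n` the slope factor.
#'
#' @param S_min,S_max Bottom/top plateaus (normalized-signal units).
#' @param EC50 Half-maximal concentration (pM).
#' @param n Slope factor (> 0).
#' @return Object of class `calibration_curve`.
#' @export
calibration_curve <- function(S_min, S_max, EC50, n = 1) {
  if (!(S_max > S_min)) stop("need S_max > S_min")
  if (EC50 <= 0) stop("EC50 must be > 0")
  if (n <= 0) stop("slope factor n must be > 0")
  structure(list(S_min = S_min, S_max = S_max, EC50 = EC50, n = n),
            class = "calibration_curve")
}

#' The package's fixed calibration curve
#'
#' The fixed curve used by quantification strategy 3:
#' `S_min = -0.5`, `S_max = 4`, `EC50 = 1030` pM, `n = 1`.
#'
#' @return A [calibration_curve()].
#' @export
fixed_calibration_curve <- function() {
  calibration_curve(S_min = -0.5, S_max = 4, EC50 = 1030, n = 1)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("4PL calibration curve: S_min=%.4g, S_max=%.4g, EC50=%.4g pM, n=%.4g\n",
              x$S_min, x$S_max, x$EC50, x$n))
  if (!is.null(attr(x, "fit"))) {
    f <- attr(x, "fit")
    cat(sprintf("  fitted on %d points, residual SD %.4g\n",
                f$n_points, f$sigma))
  }
  invisible(x)
}

#' Evaluate the calibration sigmoid
#'
#' @param curve A [calibration_curve()].
#' @param X Concentration (pM), `>= 0`, vectorized.
#' @return Normalized signal `S`; `S(0) = S_min`, strictly increasing.
#' @export
evaluate_sigmoid <- function(curve, X) {
  if (any(X < 0)) stop("concentration must be >= 0")
  xn <- X^curve$n
  curve$S_min + (curve$S_max - curve$S_min) * xn / (curve$EC50^curve$n + xn)
}

#' Invert the calibration sigmoid
#'
#' Exact inverse of [evaluate_sigmoid()]:
#' `X = EC50 * ((S - S_min)/(S_max - S))^(1/n)`. Signals at or below the
#' bottom plateau return 0, signals at or above the top plateau return
#' `Inf`; both carry an out-of-range flag (never silently clipped).
#'
#' @param curve A [calibration_curve()].
#' @param S Normalized signal, vectorized.
#' @return Concentration (pM) with attribute `flag`: `"ok"`,
#'   `"below_range"` or `"above_range"` per element.
#' @export
invert_sigmoid <- function(curve, S) {
  flag <- rep("ok", length(S))
  X <- rep(NA_real_, length(S))
  lo <- S <= curve$S_min
  hi <- S >= curve$S_max
  mid <- !lo & !hi
  X[lo] <- 0; flag[lo] <- "below_range"
  X[hi] <- Inf; flag[hi] <- "above_range"
  X[mid] <- curve$EC50 *
    ((S[mid] - curve$S_min) / (curve$S_max - S[mid]))^(1 / curve$n)
  attr(X, "flag") <- flag
  X
}

#' Normalization anchors
#'
#' Repeated measurements of a low ("zero") and a high ("unity") reference
#' sample, used to map the raw activity scale to normalized signal 0/1
#' and thereby cancel multiplicative sensor drift.
#'
#' @param zero_t_min,unity_t_min Measurement times (minutes) of the low
#'   and high anchor repeats, each increasing; repeats are paired by
#'   index. `unity_t_min` defaults to `zero_t_min`.
#' @param zero_activity Raw activity of the low anchor at each repeat.
#' @param unity_activity Raw activity of the high anchor at each repeat.
#' @param zero_conc_pM,unity_conc_pM Anchor concentrations (metadata).
#' @return Object of class `normalization_anchors`.
#' @export
normalization_anchors <- function(zero_t_min, zero_activity,
                                  unity_activity, unity_t_min = zero_t_min,
                                  zero_conc_pM = NA, unity_conc_pM = NA) {
  nrep <- length(zero_t_min)
  if (length(zero_activity) != nrep || length(unity_activity) != nrep ||
      length(unity_t_min) != nrep)
    stop("anchor vectors must have equal length")
  if (nrep < 1) stop("need at least one anchor pair")
  if (is.unsorted(zero_t_min) || is.unsorted(unity_t_min))
    stop("anchor timestamps must be increasing")
  if (any(unity_activity <= zero_activity))
    stop("degenerate anchors: unity activity must exceed zero activity")
  structure(list(t_min = (zero_t_min + unity_t_min) / 2,
                 zero_t_min = zero_t_min, unity_t_min = unity_t_min,
                 zero_activity = zero_activity,
                 unity_activity = unity_activity,
                 zero_conc_pM = zero_conc_pM, unity_conc_pM = unity_conc_pM),
            class = "normalization_anchors")
}

#' Normalize raw activity against time-interpolated anchors
#'
#' For each measurement time `t`, the low and high anchor levels
#' `A_low(t)`, `A_high(t)` are obtained by piecewise-linear interpolation
#' in time between consecutive anchor repeats (constant extrapolation
#' outside the anchored range), and the normalized signal is
#' `S = (A - A_low(t)) / (A_high(t) - A_low(t))`. Anchor measurements map
#' to exactly 0 and 1 at their own timestamps.
#'
#' @param t_min Measurement times (minutes).
#' @param activity Raw activity values.
#' @param anchors A [normalization_anchors()] object.
#' @return Normalized signal values.
#' @export
normalize_signals <- function(t_min, activity, anchors) {
  stopifnot(inherits(anchors, "normalization_anchors"))
  interp <- function(tt, y) {
    if (length(tt) == 1) rep(y, length(t_min))
    else stats::approx(tt, y, xout = t_min, rule = 2)$y
  }
  a_lo <- interp(anchors$zero_t_min, anchors$zero_activity)
  a_hi <- interp(anchors$unity_t_min, anchors$unity_activity)
  if (any(a_hi <= a_lo))
    stop("degenerate anchors after interpolation: A_high <= A_low")
  (activity - a_lo) / (a_hi - a_lo)
}

#' Fit the four-parameter logistic calibration curve
#'
#' Unweighted nonlinear least squares of the 4PL to (concentration,
#' normalized signal) points, via `nls` (port algorithm with box
#' constraints). Start values: `S_min = min(S)`, `S_max = max(S)`,
#' `EC50` = the concentration whose mean signal is nearest mid-signal,
#' `n = 1`; bounds `EC50` in `[1, 1e6]` pM, `n` in `[0.3, 3]`.
#' Zero-concentration points enter at `X = 0` (exactly `S_min`).
#'
#' @param X Concentrations (pM).
#' @param S Normalized signals (same length).
#' @param fix_n Optionally fix the slope factor at this value.
#' @return A [calibration_curve()] with a `fit` attribute carrying
#'   standard errors, residual SD and the point count.
#' @export
fit_calibration <- function(X, S, fix_n = NULL) {
  if (length(X) != length(S)) stop("X and S must have equal length")
  ok <- is.finite(X) & is.finite(S)
  X <- X[ok]; S <- S[ok]
  n_conc <- length(unique(X))
  need <- if (is.null(fix_n)) 4 else 3
  if (n_conc < need)
    stop("need >= ", need, " distinct concentrations to fit")
  if (stats::sd(S) == 0)
    stop("degenerate input: all signals identical; cannot fit a sigmoid")

  mid <- (min(S) + max(S)) / 2
  mS <- tapply(S, X, mean)
  concs <- as.numeric(names(mS))
  ec50_0 <- concs[which.min(abs(mS - mid))]
  ec50_0 <- min(max(ec50_0, 1), 1e6)
  df <- data.frame(X = X, S = S)
  span0 <- max(S) - min(S)

  fit <- if (is.null(fix_n)) {
    try(stats::nls(S ~ S_min + (S_max - S_min) * ifelse(X > 0, X^n / (EC50^n + X^n), 0),
                   data = df,
                   start = list(S_min = min(S), S_max = max(S),
                                EC50 = ec50_0, n = 1),
                   lower = c(S_min = -Inf, S_max = min(S), EC50 = 1, n = 0.3),
                   upper = c(S_min = max(S), S_max = Inf, EC50 = 1e6, n = 3),
                   algorithm = "port",
                   control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
        silent = TRUE)
  } else {
    n_fix <- fix_n
    try(stats::nls(S ~ S_min + (S_max - S_min) * ifelse(X > 0, X^n_fix / (EC50^n_fix + X^n_fix), 0),
                   data = df,
                   start = list(S_min = min(S), S_max = max(S), EC50 = ec50_0),
                   lower = c(S_min = -Inf, S_max = min(S), EC50 = 1),
                   upper = c(S_min = max(S), S_max = Inf, EC50 = 1e6),
                   algorithm = "port",
                   control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
        silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    stop("calibration fit did not converge (start EC50=", ec50_0,
         ", n points=", length(X), ", signal span=", signif(span0, 3), ")")
  }
  cf <- stats::coef(fit)
  n_hat <- if (is.null(fix_n)) unname(cf["n"]) else fix_n
  curve <- calibration_curve(unname(cf["S_min"]), unname(cf["S_max"]),
                             unname(cf["EC50"]), n_hat)
  # summary() can fail on an exact (zero-residual) fit; report NA SEs then
  sm <- tryCatch(summary(fit), error = function(e) NULL)
  attr(curve, "fit") <- list(
    se = if (!is.null(sm)) sm$coefficients[, "Std. Error"] else NA,
    sigma = if (!is.null(sm)) sm$sigma
            else sqrt(sum(stats::resid(fit)^2) /
                        max(1, length(X) - length(cf))),
    n_points = length(X),
    fixed_n = !is.null(fix_n),
    convergence = fit$convInfo$isConv
  )
  curve
}
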