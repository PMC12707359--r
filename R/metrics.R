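#' Coefficient of variation of concentration determinations
#'
#' CV_C = 100 * SD / mean, with the sample SD (n-1 denominator), over the
#' repeated 1-min concentration determinations of one sample.
#'
#' @param conc Per-interval concentrations (pM), >= 2 values.
#' @return CV in percent.
#' @export
#' @examples
#' cv_c(c(90, 95, 100, 100, 100, 100, 105, 110))
cv_c <- function(conc) {
  conc <- conc[is.finite(conc)]
  if (length(conc) < 2) stop("need >= 2 finite values")
  m <- mean(conc)
  if (m <= 0) stop("mean concentration must be > 0")
  100 * stats::sd(conc) / m
}

#' Blank-based limit of detection
#'
#' The LoD is the concentration whose expected normalized signal equals
#' `signal_blank + 3 * sigma_blank`, obtained by inverting the
#' calibration curve. If that signal is at or below the curve's bottom
#' plateau the LoD is below the curve floor and is reported as 0 with a
#' flag (detection limited by the curve, not quantifiable from it).
#'
#' @param signal_blank Mean blank signal (normalized units).
#' @param sigma_blank Blank signal SD (normalized units, >= 0).
#' @param curve A [calibration_curve()].
#' @return A list: `lod_pM`, `signal` (the blank + 3 sigma level) and
#'   `flag` (`"ok"` or `"below_curve_floor"`).
#' @export
#' @examples
#' lod(-0.38, 0.05, fixed_calibration_curve())
lod <- function(signal_blank, sigma_blank, curve) {
  if (sigma_blank < 0) stop("sigma_blank must be >= 0")
  s <- signal_blank + 3 * sigma_blank
  x <- invert_sigmoid(curve, s)
  fl <- attr(x, "flag")
  list(lod_pM = as.numeric(x),
       signal = s,
       flag = if (fl == "below_range") "below_curve_floor" else fl)
}

#' Precision profile
#'
#' Mean and SD of the concentration imprecision (CV_C) at each measured
#' concentration, built from repeated [concentration_estimate()]s.
#'
#' @param estimates List of `concentration_estimate` objects (or a data
#'   frame with columns `conc_pM` and `cv_c`); estimates are grouped by
#'   their true/nominal concentration.
#' @return Data frame of class `precision_profile`: `conc_pM` (strictly
#'   increasing), `mean_cv`, `sd_cv`, `n`.
#' @export
precision_profile <- function(estimates) {
  df <- if (is.data.frame(estimates)) estimates
  else data.frame(
    conc_pM = vapply(estimates, function(e)
      if (is.na(e$true_conc_pM)) e$mean else e$true_conc_pM, numeric(1)),
    cv_c = vapply(estimates, function(e) e$cv_c, numeric(1)))
  df <- df[is.finite(df$conc_pM) & is.finite(df$cv_c), ]
  if (!nrow(df)) stop("no usable (concentration, CV) pairs")
  out <- data.frame(
    conc_pM = as.numeric(names(tapply(df$cv_c, df$conc_pM, mean))),
    mean_cv = as.numeric(tapply(df$cv_c, df$conc_pM, mean)),
    sd_cv = as.numeric(tapply(df$cv_c, df$conc_pM, stats::sd)),
    n = as.integer(tapply(df$cv_c, df$conc_pM, length)))
  out <- out[order(out$conc_pM), ]
  rownames(out) <- NULL
  class(out) <- c("precision_profile", "data.frame")
  out
}

#' Lower limit of quantification from a precision profile
#'
#' The LoQ is the lowest concentration at which the mean-CV_C curve
#' crosses below `cv_threshold`, found by linear interpolation in
#' log-concentration between the bracketing points (the dose-response
#' spans decades). If every CV is already below the threshold the lowest
#' measured concentration is returned with an upper-bound flag; if none
#' is, the sample is not quantifiable in the measured range.
#'
#' @param profile A [precision_profile()] (columns `conc_pM`, `mean_cv`).
#' @param cv_threshold CV_C threshold in percent (default 10).
#' @return List: `loq_pM` (NA if not quantifiable), `flag` (`"ok"`,
#'   `"at_or_below_lowest"`, `"not_quantifiable_in_range"`).
#' @export
loq_from_profile <- function(profile, cv_threshold = 10) {
  if (nrow(profile) < 2) stop("profile needs >= 2 concentrations")
  conc <- profile$conc_pM; cv <- profile$mean_cv
  if (is.unsorted(conc, strictly = TRUE))
    stop("profile concentrations must be strictly increasing")
  below <- cv <= cv_threshold
  if (all(below))
    return(list(loq_pM = conc[1], flag = "at_or_below_lowest"))
  if (!any(below))
    return(list(loq_pM = NA_real_, flag = "not_quantifiable_in_range"))
  # lowest concentration where the curve crosses below the threshold:
  # first index i with cv[i] > threshold and cv[i+1] <= threshold
  i <- which(!below[-length(below)] & below[-1])[1]
  lc <- log(conc[i]) + (cv[i] - cv_threshold) / (cv[i] - cv[i + 1]) *
    (log(conc[i + 1]) - log(conc[i]))
  list(loq_pM = exp(lc), flag = "ok")
}

#' Correct a measured concentration for sample dilution
#'
#' @param conc_pM Concentration in the diluted sample (pM).
#' @param dilution_factor Dilution factor (>= 1).
#' @return List: `conc_pM` (undiluted, pM) and `conc_nM` (same in nM).
#' @export
#' @examples
#' dilution_correct(180, 2000)$conc_nM   # 360 nM in undiluted milk
dilution_correct <- function(conc_pM, dilution_factor) {
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1")
  und <- conc_pM * dilution_factor
  list(conc_pM = und, conc_nM = und / 1000)
}

#' Mean absolute relative difference between sensor and reference
#'
#' `MARD = 100 * mean(|sensor - reference| / reference)`, the standard
#' agreement summary for continuous monitoring against a reference
#' method. Pairs flagged out of the calibration range are excluded and
#' counted.
#'
#' @param sensor,reference Paired concentrations (pM); reference > 0.
#' @param flags Optional per-pair flags; only `"ok"` pairs are used.
#' @return List: `mard` (%), `n_pairs` used, `n_excluded`, and the
#'   slope/intercept of the linear fit sensor ~ reference.
#' @export
mard <- function(sensor, reference, flags = NULL) {
  if (length(sensor) != length(reference)) stop("pairs must be equal length")
  if (is.null(flags)) flags <- rep("ok", length(sensor))
  keep <- flags == "ok" & is.finite(sensor) & is.finite(reference)
  n_excl <- sum(!keep)
  sensor <- sensor[keep]; reference <- reference[keep]
  if (!length(sensor)) stop("no usable pairs")
  if (any(reference <= 0)) stop("reference concentrations must be > 0")
  fit <- if (length(sensor) >= 2)
    stats::coef(stats::lm(sensor ~ reference)) else c(NA_real_, NA_real_)
  list(mard = 100 * mean(abs(sensor - reference) / reference),
       n_pairs = length(sensor), n_excluded = n_excl,
       intercept = unname(fit[1]), slope = unname(fit[2]))
}

# Anderson-Darling test for composite normality (mean and SD estimated
# from the data): Stephens' small-sample adjustment and the standard
# p-value approximation (as tabulated in D'Agostino & Stephens).
.ad_test_normal <- function(x) {
  n <- length(x)
  if (n < 8) stop("Anderson-Darling test needs >= 8 values")
  z <- sort((x - mean(x)) / stats::sd(x))
  p1 <- stats::pnorm(z)
  # guard logs away from 0/1
  p1 <- pmin(pmax(p1, 1e-300), 1 - 1e-16)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(p1) + log(1 - rev(p1))))
  Astar <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (Astar <= 0.2) 1 - exp(-13.436 + 101.14 * Astar - 223.73 * Astar^2)
  else if (Astar <= 0.34) 1 - exp(-8.318 + 42.796 * Astar - 59.938 * Astar^2)
  else if (Astar < 0.6) exp(0.9177 - 4.279 * Astar - 1.38 * Astar^2)
  else if (Astar <= 10) exp(1.2937 - 5.709 * Astar + 0.0186 * Astar^2)
  else 3.7e-24
  list(statistic = A2, adjusted = Astar, p_value = min(max(p, 0), 1))
}

#' Fit normal and log-normal distributions to imprecision values
#'
#' Summarizes a collection of CV_C values: normal fit (mean, SD),
#' log-normal fit (geometric mean `exp(mean(log x))`, geometric SD
#' `exp(sd(log x))`), and an Anderson-Darling goodness-of-fit p-value for
#' each model (composite case: parameters estimated from the same data).
#'
#' @param cv_values Imprecision values in percent, all > 0, >= 8 values.
#' @return List with `normal` (mean, sd, ad_p), `lognormal`
#'   (geo_mean, geo_sd, ad_p) and `n`.
#' @export
imprecision_distribution <- function(cv_values) {
  cv_values <- cv_values[is.finite(cv_values)]
  if (length(cv_values) < 8) stop("need >= 8 finite values")
  if (any(cv_values <= 0)) stop("all values must be > 0")
  if (stats::sd(cv_values) == 0)
    stop("degenerate (constant) sample: distribution fit not applicable")
  lx <- log(cv_values)
  ad_n <- .ad_test_normal(cv_values)
  ad_l <- .ad_test_normal(lx)
  list(normal = list(mean = mean(cv_values), sd = stats::sd(cv_values),
                     ad_p = ad_n$p_value, ad_stat = ad_n$statistic),
       lognormal = list(geo_mean = exp(mean(lx)), geo_sd = exp(stats::sd(lx)),
                        ad_p = ad_l$p_value, ad_stat = ad_l$statistic),
       n = length(cv_values))
}
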