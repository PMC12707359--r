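#' Kinetic and motion parameters of the particle nanoswitch
#'
#' Bundles the rate constants and motion parameters that define the
#' stochastic behaviour of one tethered particle. The particle switches
#' between an *unbound* state (tether-confined Brownian motion, diffusion
#' coefficient `D_free`, confinement radius `R_free`) and a *bound* state
#' (sandwich complex formed, tight confinement `R_bound`, reduced mobility
#' `D_bound`). Binding is a saturating function of analyte concentration;
#' unbinding is first order with rate `k_off_sw`, set by the
#' fast-dissociating Fab of the sandwich pair.
#'
#' The unbound-to-bound rate at concentration `C` (pM) is
#' \deqn{\lambda_{on}(C) = \lambda_{bg} + \lambda_{max} \frac{C}{EC50_{kin} + C}}
#' a hyperbolic (Hill slope 1) saturation so the count-level dose response
#' has the shape of the fixed four-parameter logistic calibration curve.
#'
#' @param k_off_sw Sandwich dissociation rate (1/s). Default 0.1, the
#'   seconds-scale lifetime of the weaker Fab arm.
#' @param lambda_max Maximal per-particle binding rate at analyte
#'   saturation (1/s).
#' @param EC50_kin Concentration of half-maximal binding rate (pM).
#' @param lambda_bg Background, analyte-independent binding rate (1/s);
#'   nonzero so blanks show residual activity.
#' @param D_free Unbound diffusion coefficient (um^2/s), wall-hindered
#'   value for a 1 um sphere.
#' @param D_bound Bound-state diffusion coefficient (um^2/s).
#' @param R_free Unbound confinement radius (um), from tether contour
#'   length plus particle geometry.
#' @param R_bound Bound-state confinement radius (um).
#' @param sigma_loc Localization noise SD per axis (um).
#' @param frame_rate Camera frame rate (frames/s).
#' @return An object of class `kinetic_params` (a named list).
#' @export
#' @examples
#' p <- kinetic_params()
#' lambda_on(p, 1000)   # binding rate at 1 nM
kinetic_params <- function(k_off_sw = 0.1,
                           lambda_max = 0.05,
                           EC50_kin = 1030,
                           lambda_bg = 2e-4,
                           D_free = 0.3,
                           D_bound = 0.05,
                           R_free = 0.28,
                           R_bound = 0.03,
                           sigma_loc = 0.02,
                           frame_rate = 30) {
  p <- list(k_off_sw = k_off_sw, lambda_max = lambda_max,
            EC50_kin = EC50_kin, lambda_bg = lambda_bg,
            D_free = D_free, D_bound = D_bound,
            R_free = R_free, R_bound = R_bound,
            sigma_loc = sigma_loc, frame_rate = frame_rate)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("kinetic_params: all fields must be finite scalars; offending: ",
         paste(names(p)[!num], collapse = ", "))
  }
  if (any(unlist(p) < 0)) stop("kinetic_params: all parameters must be >= 0")
  if (p$EC50_kin <= 0) stop("kinetic_params: EC50_kin must be > 0")
  if (p$R_bound >= p$R_free) stop("kinetic_params: R_bound must be < R_free")
  if (p$D_bound > p$D_free) stop("kinetic_params: D_bound must be <= D_free")
  if (p$frame_rate <= 0) stop("kinetic_params: frame_rate must be > 0")
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Nanoswitch kinetic parameters\n")
  cat(sprintf("  k_off_sw   %.4g /s   (mean bound dwell %.3g s)\n",
              x$k_off_sw, if (x$k_off_sw > 0) 1 / x$k_off_sw else Inf))
  cat(sprintf("  lambda_max %.4g /s, lambda_bg %.4g /s, EC50_kin %.4g pM\n",
              x$lambda_max, x$lambda_bg, x$EC50_kin))
  cat(sprintf("  D_free %.3g, D_bound %.3g um^2/s; R_free %.3g, R_bound %.3g um\n",
              x$D_free, x$D_bound, x$R_free, x$R_bound))
  cat(sprintf("  sigma_loc %.3g um, frame_rate %g Hz\n",
              x$sigma_loc, x$frame_rate))
  invisible(x)
}

#' Unbound-to-bound switching rate at a given concentration
#'
#' @param params A [kinetic_params()] object.
#' @param concentration Analyte concentration (pM), scalar or vector.
#' @return Binding rate lambda_on (1/s).
#' @export
lambda_on <- function(params, concentration) {
  if (any(concentration < 0)) stop("concentration must be >= 0")
  params$lambda_bg +
    params$lambda_max * concentration / (params$EC50_kin + concentration)
}

#' Stationary state occupancies and UTB event rate of the two-state chain
#'
#' For the continuous-time two-state Markov chain with rates
#' `lambda_on(C)` (unbound to bound) and `k_off_sw` (bound to unbound), the
#' stationary unbound fraction is `k_off/(lambda_on + k_off)` and the
#' long-run rate of unbound-to-bound events per particle is
#' `lambda_on * k_off / (lambda_on + k_off)` (events/s).
#'
#' @inheritParams lambda_on
#' @return A list with `p_unbound`, `p_bound` and `utb_rate` (events/s),
#'   each vectorized over `concentration`.
#' @export
stationary_stats <- function(params, concentration) {
  lon <- lambda_on(params, concentration)
  koff <- params$k_off_sw
  tot <- lon + koff
  p_unbound <- ifelse(tot > 0, koff / tot, 1)  # no rates: stay unbound
  list(p_unbound = p_unbound,
       p_bound = 1 - p_unbound,
       utb_rate = lon * p_unbound)
}

#' Simulate the bound/unbound state sequence of one particle
#'
#' Exact (Gillespie) simulation of the continuous-time two-state Markov
#' chain: exponential dwell times with rate `lambda_on(C)` in the unbound
#' state and `k_off_sw` in the bound state. The initial state is drawn
#' from the stationary distribution.
#'
#' @inheritParams lambda_on
#' @param duration Total simulated time (s).
#' @param seed Optional integer seed for reproducibility.
#' @return A `state_sequence`: data frame with columns `state`
#'   ("unbound"/"bound"), `t_start`, `t_end` (s); contiguous, alternating
#'   intervals covering `[0, duration]`.
#' @export
#' @examples
#' s <- simulate_state_sequence(kinetic_params(), 1000, 600, seed = 1)
#' table(s$state)
simulate_state_sequence <- function(params, concentration, duration,
                                    seed = NULL) {
  if (length(concentration) != 1 || concentration < 0)
    stop("concentration must be a single value >= 0")
  if (length(duration) != 1 || duration <= 0)
    stop("duration must be a single value > 0")
  if (!is.null(seed)) set.seed(seed)

  lon <- lambda_on(params, concentration)
  koff <- params$k_off_sw
  rate <- c(unbound = lon, bound = koff)
  st <- stationary_stats(params, concentration)
  state <- if (stats::runif(1) < st$p_unbound) "unbound" else "bound"

  t_start <- numeric(0); t_end <- numeric(0); states <- character(0)
  t <- 0
  repeat {
    r <- rate[[state]]
    dwell <- if (r > 0) stats::rexp(1, r) else Inf
    t2 <- min(t + dwell, duration)
    states <- c(states, state)
    t_start <- c(t_start, t)
    t_end <- c(t_end, t2)
    t <- t2
    if (t >= duration) break
    state <- if (state == "unbound") "bound" else "unbound"
  }
  new_state_sequence(data.frame(state = states, t_start = t_start,
                                t_end = t_end, stringsAsFactors = FALSE))
}

#' Construct/validate a state sequence
#'
#' @param df Data frame with columns `state`, `t_start`, `t_end`.
#' @param particle_id Optional particle identifier attribute.
#' @return The validated data frame with class `state_sequence`.
#' @export
new_state_sequence <- function(df, particle_id = NULL) {
  stopifnot(all(c("state", "t_start", "t_end") %in% names(df)))
  if (nrow(df) == 0) stop("state sequence must have at least one interval")
  if (!all(df$state %in% c("bound", "unbound")))
    stop("states must be 'bound' or 'unbound'")
  if (any(df$t_end <= df$t_start)) stop("intervals must have t_end > t_start")
  if (nrow(df) > 1) {
    if (any(abs(df$t_start[-1] - df$t_end[-nrow(df)]) > 1e-9))
      stop("intervals must be contiguous")
    if (any(df$state[-1] == df$state[-nrow(df)]))
      stop("states must alternate")
  }
  attr(df, "particle_id") <- particle_id
  class(df) <- c("state_sequence", "data.frame")
  df
}

# Fold a radial coordinate into [0, R] by reflection at the boundary.
# Handles multiple folds for steps larger than the confinement diameter.
.reflect_radius <- function(r, R) {
  if (R <= 0) return(0)
  # reflect on [0, R]: period 2R triangular wave
  m <- r %% (2 * R)
  ifelse(m > R, 2 * R - m, m)
}

#' Render a particle trajectory from a state sequence
#'
#' Overdamped Brownian dynamics (Euler-Maruyama) in 2-D, with the
#' diffusion coefficient and confinement radius set by the current state.
#' The particle is confined to a disc centred on its tether anchor;
#' excursions beyond the state's radius are folded back by reflection.
#' Independent Gaussian localization noise (`sigma_loc` per axis) is added
#' to every recorded frame. Positions are sampled at `frame_rate`.
#'
#' @param states A `state_sequence` (see [simulate_state_sequence()]).
#' @param params A [kinetic_params()] object.
#' @param seed Optional integer seed.
#' @param particle_id Identifier copied into the output table.
#' @return A data frame of class `nsw_trajectory` with columns
#'   `particle_id`, `frame`, `t_s`, `x_um`, `y_um`.
#' @export
render_trajectory <- function(states, params, seed = NULL, particle_id = 1L) {
  if (nrow(states) == 0)
    stop("state sequence must have at least one interval")
  if (!inherits(states, "state_sequence")) states <- new_state_sequence(states)
  if (params$frame_rate <= 0) stop("frame_rate must be > 0")
  if (!is.null(seed)) set.seed(seed)

  dt <- 1 / params$frame_rate
  t0 <- states$t_start[1]
  t_total <- states$t_end[nrow(states)] - t0
  n_frames <- floor(t_total / dt) + 1L
  t_s <- t0 + (seq_len(n_frames) - 1L) * dt

  # map each frame to its state (half-open [t_start, t_end) intervals)
  idx <- findInterval(t_s, states$t_start)
  idx[idx < 1L] <- 1L
  bound <- states$state[idx] == "bound"
  D <- ifelse(bound, params$D_bound, params$D_free)
  R <- ifelse(bound, params$R_bound, params$R_free)

  sd_step <- sqrt(2 * D * dt)
  dx <- stats::rnorm(n_frames, 0, sd_step)
  dy <- stats::rnorm(n_frames, 0, sd_step)
  x <- numeric(n_frames); y <- numeric(n_frames)
  xi <- 0; yi <- 0
  for (i in seq_len(n_frames)) {
    xi <- xi + dx[i]; yi <- yi + dy[i]
    r2 <- xi * xi + yi * yi
    Ri <- R[i]
    if (r2 > Ri * Ri) {
      r <- sqrt(r2)
      rf <- .reflect_radius(r, Ri)
      if (r > 0) { s <- rf / r; xi <- xi * s; yi <- yi * s }
      else { xi <- 0; yi <- 0 }
    }
    x[i] <- xi; y[i] <- yi
  }
  if (params$sigma_loc > 0) {
    x <- x + stats::rnorm(n_frames, 0, params$sigma_loc)
    y <- y + stats::rnorm(n_frames, 0, params$sigma_loc)
  }
  out <- data.frame(particle_id = particle_id,
                    frame = seq_len(n_frames) - 1L,
                    t_s = t_s, x_um = x, y_um = y)
  class(out) <- c("nsw_trajectory", "data.frame")
  out
}
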