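#' Write / read a trajectory table
#'
#' Tab-delimited text with columns `particle_id`, `frame`, `t_s`,
#' `x_um`, `y_um`. A provenance header (lines starting with `#`) records
#' the seed and a parameter hash when available.
#'
#' @param trajectories A trajectory table, or a list of them (rows are
#'   concatenated).
#' @param path Output file path.
#' @param seed,params Optional provenance: master seed and
#'   [kinetic_params()] (hashed into the header).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path, seed = NULL,
                               params = NULL) {
  if (!is.data.frame(trajectories))
    trajectories <- do.call(rbind, trajectories)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(seed, params), con)
  utils::write.table(
    trajectories[, c("particle_id", "frame", "t_s", "x_um", "y_um")],
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse trajectory table '", path,
                             "': ", conditionMessage(e)))
  need <- c("particle_id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("trajectory table '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  if (nrow(df) == 0) stop("trajectory table '", path, "' is empty")
  split(df, df$particle_id)
}

#' Write / read an activity table
#'
#' Tab-delimited text with columns `t_min`, `injection_index`, `role`,
#' `true_conc_pM`, `counts`, `n_particles`, `activity` (the simulator
#' format) or the reduced readout format `t_min`, `counts`,
#' `n_particles`, `activity`.
#'
#' @param activity Activity data frame.
#' @param path File path.
#' @param seed,params Optional provenance for the header.
#' @return `path` invisibly / the parsed data frame.
#' @export
write_activity <- function(activity, path, seed = NULL, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(seed, params), con)
  utils::write.table(as.data.frame(activity), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_activity
#' @export
read_activity <- function(path) {
  if (!file.exists(path)) stop("activity file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse activity table '", path,
                             "': ", conditionMessage(e)))
  need <- c("t_min", "counts", "n_particles", "activity")
  if (!all(need %in% names(df)))
    stop("activity table '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  df
}

#' Serialize a calibration curve or kinetic parameters to JSON config
#'
#' Calibration curves use keys `S_min`, `S_max`, `EC50_pM`, `n`; kinetic
#' parameters use their field names.
#'
#' @param x A [calibration_curve()] or [kinetic_params()] object.
#' @param path JSON file path.
#' @return `path` invisibly.
#' @export
write_config <- function(x, path) {
  if (inherits(x, "calibration_curve")) {
    obj <- list(S_min = x$S_min, S_max = x$S_max, EC50_pM = x$EC50, n = x$n)
  } else if (inherits(x, "kinetic_params")) {
    obj <- unclass(x)
  } else obj <- x
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration curve from a JSON config
#'
#' @param path JSON file with keys `S_min`, `S_max`, `EC50_pM`, `n`.
#' @return A [calibration_curve()].
#' @export
read_curve_config <- function(path) {
  if (!file.exists(path)) stop("curve config not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("S_min", "S_max", "EC50_pM", "n")
  if (!all(need %in% names(obj)))
    stop("curve config '", path, "' must have keys: ",
         paste(need, collapse = ", "))
  calibration_curve(obj$S_min, obj$S_max, obj$EC50_pM, obj$n)
}

#' Read kinetic parameters from a JSON config
#'
#' @param path JSON file whose keys are [kinetic_params()] field names;
#'   missing keys take the defaults.
#' @return A [kinetic_params()].
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) stop("params config not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(kinetic_params, obj[names(obj) %in% names(formals(kinetic_params))])
}

.provenance_header <- function(seed = NULL, params = NULL) {
  h <- c(paste0("# nanoswitchr v",
                as.character(utils::packageVersion("nanoswitchr"))))
  if (!is.null(seed)) h <- c(h, paste0("# seed: ", seed))
  if (!is.null(params)) {
    s <- paste(names(params), unlist(params), sep = "=", collapse = ";")
    v <- utf8ToInt(s)
    hash <- sum(v * seq_along(v)) %% 2147483647  # stable config fingerprint
    h <- c(h, paste0("# params_hash: ", hash))
  }
  h
}
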