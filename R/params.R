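#' Model rate constants for the metabolic switching simulator
#'
#' Constructs the full parameter set of the two-reporter state-switching
#' model. Defaults are read from the versioned parameter file shipped with
#' the package (`inst/extdata/default_params.yaml`) and are calibrated to
#' published single-cell estimates: the mean competent-episode length
#' (252 min) sets `k_off_sucC`, and the per-state elongation-rate ratios
#' (47.4/67.7 and 63/74 %/hr) set the growth penalties.
#'
#' Units are fixed package-wide: minutes, micrometres, mM, arbitrary
#' fluorescence units (AU).
#'
#' @param ... named overrides of individual parameters (see the default
#'   file for the full list). Unknown names are an error.
#' @return An object of class `switch_params`: a named list of rates.
#' @examples
#' p <- switch_params(k_on_sucC = 0)   # competence knocked out
#' p$k_off_sucC * 252                  # ~1: mean episode length 252 min
#' @export
switch_params <- function(...) {
  defaults <- .load_default_params()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("all parameter overrides must be named", call. = FALSE)
    bad <- setdiff(names(over), names(defaults))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    defaults[names(over)] <- over
  }
  p <- structure(defaults, class = "switch_params")
  validate_switch_params(p)
  p
}

.param_file_cache <- new.env(parent = emptyenv())

.load_default_params <- function() {
  if (is.null(.param_file_cache$params)) {
    path <- system.file("extdata", "default_params.yaml", package = "metaswitch")
    stopifnot(nzchar(path))
    y <- yaml::read_yaml(path)
    .param_file_cache$params <- lapply(y$params, as.numeric)
  }
  .param_file_cache$params
}

#' @rdname switch_params
#' @param p a `switch_params` object.
#' @export
validate_switch_params <- function(p) {
  rates <- c("k_on_sucC", "k_off_sucC", "k0_alsS", "kmax_alsS", "k_off_alsS",
             "r_base", "beta_on", "beta_off", "p_A", "p_A_basal", "c_A",
             "K_alsS", "K_tox", "quorum", "div_cv", "r_cv", "length_noise_cv",
             "yield_od_per_mM", "K_C")
  for (nm in rates) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("parameter '", nm, "' must be a single non-negative number", call. = FALSE)
  }
  if (p$penalty_sucC < 0 || p$penalty_sucC > 1 || p$penalty_alsS < 0 || p$penalty_alsS > 1)
    stop("growth penalties must lie in [0, 1]", call. = FALSE)
  if (p$h_alsS < 1) stop("h_alsS must be >= 1", call. = FALSE)
  if (p$y_acetoin <= 0 || p$y_acetoin > 1)
    stop("y_acetoin must lie in (0, 1]", call. = FALSE)
  if (p$L_div <= 0) stop("L_div must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.switch_params <- function(x, ...) {
  cat("<switch_params> (min, um, mM, AU)\n")
  for (nm in names(x)) cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Scenario configuration for a simulation run
#'
#' Describes one experiment: closed batch culture, chemostatic
#' mother-machine microfluidics, or closed agarose-pad microcolony.
#'
#' @param mode one of `"batch"`, `"mother_machine"`, `"pad"`.
#' @param duration total simulated time (min). Must be a multiple of
#'   `frame_interval`.
#' @param frame_interval imaging interval (min); default 12 min, the
#'   standard timelapse frame rate.
#' @param seed integer seed; every stochastic draw in a run flows from it.
#' @param initial_env named list: `biomass` (OD-proxy), `glucose`, `malate`,
#'   `acetate`, `acetoin` (mM). Defaults give the standard batch medium
#'   (22 mM glucose, 50 mM malate) at low inoculum.
#' @param n_channels,channel_capacity mother-machine geometry: number of
#'   dead-end growth channels and cells retained per channel (excess cells
#'   are washed out at the open end).
#' @param n_founders founder cells for pad mode.
#' @param n_sample number of tracked cells representing the batch
#'   population (constant-number Monte Carlo).
#' @param media_condition mother-machine media, a named list with `acetate`
#'   (mM, held constant) and `quorum` (dimensionless multiplier on
#'   `k_on_sucC`, encoding conditioned-media activity).
#' @param comK_null,alsS_null knockout flags. `comK_null` forces
#'   `k_on_sucC = 0` (no competent/sucC+ cells); `alsS_null` forces
#'   `c_A = 0` (no acetate detoxification).
#' @param od_per_cell biomass weight of one pad cell in OD-equivalents,
#'   setting how strongly a microcolony couples to its closed environment.
#' @param substeps integration substeps per frame for cell and environment
#'   updates (fixed-step explicit scheme at `dt = frame_interval/substeps`).
#' @return An object of class `scenario_config`.
#' @examples
#' cfg <- scenario_config("batch", duration = 120, frame_interval = 30, seed = 1)
#' @export
scenario_config <- function(mode = c("batch", "mother_machine", "pad"),
                            duration = 720,
                            frame_interval = 12,
                            seed = 1L,
                            initial_env = list(),
                            n_channels = 30L,
                            channel_capacity = 6L,
                            n_founders = 6L,
                            n_sample = 1000L,
                            media_condition = list(acetate = 0, quorum = 1),
                            comK_null = FALSE,
                            alsS_null = FALSE,
                            od_per_cell = 6e-5,
                            substeps = 10L) {
  mode <- match.arg(mode)
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0", call. = FALSE)
  if (abs(duration / frame_interval - round(duration / frame_interval)) > 1e-9)
    stop("frame_interval must divide duration", call. = FALSE)
  if (mode == "mother_machine") {
    if (n_channels < 0) stop("n_channels must be >= 0", call. = FALSE)
    if (channel_capacity < 1) stop("channel_capacity must be >= 1", call. = FALSE)
  }
  env <- list(biomass = 0.05, glucose = 22, malate = 50, acetate = 0, acetoin = 0)
  if (mode == "pad") {
    # fresh pad medium: glucose only, acetate added to the mid-exponential
    # concentration, and no quorum/conditioned-media activity
    env$acetate <- 20
    env$malate <- 0
    if (missing(media_condition)) media_condition <- list(acetate = 0, quorum = 0)
  }
  if (length(initial_env)) {
    bad <- setdiff(names(initial_env), names(env))
    if (length(bad)) stop("unknown initial_env field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    env[names(initial_env)] <- initial_env
  }
  if (any(unlist(env) < 0)) stop("initial concentrations must be >= 0", call. = FALSE)
  mc <- list(acetate = 0, quorum = 1)
  mc[names(media_condition)] <- media_condition
  structure(list(mode = mode, duration = duration,
                 frame_interval = frame_interval, seed = as.integer(seed),
                 initial_env = env, n_channels = as.integer(n_channels),
                 channel_capacity = as.integer(channel_capacity),
                 n_founders = as.integer(n_founders),
                 n_sample = as.integer(n_sample),
                 media_condition = mc,
                 comK_null = isTRUE(comK_null), alsS_null = isTRUE(alsS_null),
                 od_per_cell = od_per_cell, substeps = as.integer(substeps)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> mode=%s duration=%g min frame=%g min seed=%d\n",
              x$mode, x$duration, x$frame_interval, x$seed))
  cat("  initial env:", paste(sprintf("%s=%g", names(x$initial_env),
                                      unlist(x$initial_env)), collapse = " "), "\n")
  if (x$comK_null) cat("  knockout: comK (k_on_sucC = 0)\n")
  if (x$alsS_null) cat("  knockout: alsS (c_A = 0)\n")
  invisible(x)
}

# apply knockout flags to a parameter set
.effective_params <- function(params, config) {
  if (config$comK_null) params$k_on_sucC <- 0
  if (config$alsS_null) params$c_A <- 0
  params
}
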