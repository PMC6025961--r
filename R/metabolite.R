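# Metabolite time-course analysis: production/consumption phases from
# the sign of the time derivative, and alignment with subpopulation
# fraction time courses.

#' Detect production and consumption phases of a metabolite series
#'
#' The time derivative is estimated by central finite differences
#' (one-sided at the boundaries) and smoothed with a moving average over
#' `smooth_window` samples; derivative magnitudes at or below `eps` are
#' treated as zero (suppressing instrument-scale noise). The longest
#' contiguous positive run is reported as the production phase and the
#' longest negative run as the consumption phase. The peak is the raw
#' series maximum; phase endpoints are reported at sample times, snapped
#' to the peak time when a run abuts the peak, so that production ends
#' and consumption begins at `t_peak`.
#'
#' @param series data frame with strictly increasing `t_min` and a
#'   concentration column (`concentration_mM`, or the single other
#'   numeric column), >= 3 points.
#' @param smooth_window moving-average width in samples (odd; 1 = none).
#' @param eps derivative dead-band (mM/min).
#' @param run_rule `"longest"` (default) or `"first"` for resolving
#'   multiple sign runs in noisy data.
#' @return An object of class `phase_report`: list with
#'   `production_interval`, `consumption_interval` (each `c(t_start,
#'   t_end)` in min, `NA` when absent), `t_peak`, `c_peak`,
#'   `n_production_runs`, `n_consumption_runs`, `derivative` (tibble).
#' @examples
#' s <- data.frame(t_min = (0:5) * 60, concentration_mM = c(0, 5, 12, 20, 18, 14))
#' detect_phases(s, smooth_window = 1, eps = 0)
#' @export
detect_phases <- function(series, smooth_window = 3, eps = 0.005,
                          run_rule = c("longest", "first")) {
  run_rule <- match.arg(run_rule)
  t <- series$t_min
  cn <- setdiff(names(series), "t_min")
  conc_col <- if ("concentration_mM" %in% cn) "concentration_mM" else {
    num <- cn[vapply(series[cn], is.numeric, TRUE)]
    if (length(num) != 1)
      stop("cannot identify the concentration column", call. = FALSE)
    num
  }
  x <- series[[conc_col]]
  if (length(t) < 3) stop("phase detection requires >= 3 points", call. = FALSE)
  if (any(diff(t) <= 0)) stop("t_min must be strictly increasing", call. = FALSE)

  n <- length(x)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  if (smooth_window > 1) {
    w <- as.integer(smooth_window)
    half <- w %/% 2
    d <- vapply(seq_len(n), function(i) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      mean(d[lo:hi])
    }, numeric(1))
  }
  sg <- sign(d)
  sg[abs(d) <= eps] <- 0

  pk <- which.max(x)
  t_peak <- t[pk]; c_peak <- x[pk]

  runs_of <- function(value) {
    r <- rle(sg)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values == value
    Map(c, starts[keep], ends[keep])
  }
  pick <- function(runs) {
    if (!length(runs)) return(NULL)
    if (run_rule == "first") return(runs[[1]])
    lens <- vapply(runs, function(r) r[2] - r[1], numeric(1))
    runs[[which.max(lens)]]
  }
  snap <- function(run, side) {
    if (is.null(run)) return(c(NA_real_, NA_real_))
    lo <- t[run[1]]; hi <- t[run[2]]
    if (side == "production" && abs(run[2] - pk) <= 1) hi <- t_peak
    if (side == "consumption" && run[1] - pk <= 1 && run[1] >= pk) lo <- t_peak
    c(lo, hi)
  }
  pos_runs <- runs_of(1); neg_runs <- runs_of(-1)
  prod <- snap(pick(pos_runs), "production")
  cons <- snap(pick(neg_runs), "consumption")

  structure(list(production_interval = prod, consumption_interval = cons,
                 t_peak = t_peak, c_peak = c_peak,
                 n_production_runs = length(pos_runs),
                 n_consumption_runs = length(neg_runs),
                 derivative = tibble::tibble(t_min = t, deriv = d, sign = sg),
                 smooth_window = smooth_window, eps = eps),
            class = "phase_report")
}

#' @export
print.phase_report <- function(x, ...) {
  fmt <- function(iv) if (anyNA(iv)) "none" else sprintf("%g-%g min", iv[1], iv[2])
  cat(sprintf("<phase_report> production %s | consumption %s | peak %.3g mM at %g min\n",
              fmt(x$production_interval), fmt(x$consumption_interval),
              x$c_peak, x$t_peak))
  invisible(x)
}

#' Align subpopulation fractions with metabolite phases
#'
#' For each reporter's fraction-positive series, reports the time of the
#' maximal fraction, the phase containing it, and the coverage of each
#' phase: the proportion of the phase's sample times at which the
#' fraction exceeds half its maximum.
#'
#' @param phases a [detect_phases()] report.
#' @param fractions a data frame with `t_min`, `fraction_positive` and
#'   optionally `reporter` (multiple reporters handled by group), or a
#'   named list of such frames.
#' @return tibble: `reporter`, `t_argmax`, `phase`
#'   (`production`/`consumption`/`none`), `coverage_production`,
#'   `coverage_consumption`.
#' @export
phase_alignment <- function(phases, fractions) {
  stopifnot(inherits(phases, "phase_report"))
  if (is.data.frame(fractions)) {
    fractions <- if ("reporter" %in% names(fractions))
      split(fractions, fractions$reporter) else list(reporter = fractions)
  }
  t_env <- phases$derivative$t_min
  rows <- lapply(names(fractions), function(nm) {
    f <- fractions[[nm]]
    if (max(f$t_min) < min(t_env) || min(f$t_min) > max(t_env))
      stop("fraction series and metabolite series have disjoint time supports",
           call. = FALSE)
    fr <- f$fraction_positive
    t_arg <- if (all(fr == 0)) NA_real_ else f$t_min[which.max(fr)]
    inside <- function(iv, tt) !anyNA(iv) && tt >= iv[1] && tt <= iv[2]
    phase <- if (is.na(t_arg)) "none"
      else if (inside(phases$production_interval, t_arg)) "production"
      else if (inside(phases$consumption_interval, t_arg)) "consumption"
      else "none"
    coverage <- function(iv) {
      if (anyNA(iv) || all(fr == 0)) return(0)
      sel <- f$t_min >= iv[1] & f$t_min <= iv[2]
      if (!any(sel)) return(0)
      mean(fr[sel] > max(fr) / 2)
    }
    data.frame(reporter = nm, t_argmax = t_arg, phase = phase,
               coverage_production = coverage(phases$production_interval),
               coverage_consumption = coverage(phases$consumption_interval))
  })
  tibble::as_tibble(do.call(rbind, rows))
}
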