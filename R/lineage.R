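# Lineage-level estimators: threshold-crossing activation events, dwell
# times, event rates, exponential elongation rates, per-state growth.

#' Detect activation events in a single-position trace
#'
#' An event opens at the first frame whose value is at or above
#' `threshold` following a sub-threshold frame, and closes at the first
#' subsequent frame below the closing threshold `hysteresis * threshold`
#' (default `hysteresis = 1`: a single threshold). Events touching either
#' movie boundary are flagged censored; censored events lack the missing
#' boundary time and carry no dwell time. An optional 3-frame median
#' filter can be applied before detection.
#'
#' @param trace numeric per-frame values of one lineage position (length
#'   >= 2). Frame `i` is at time `(i - 1) * frame_interval`.
#' @param threshold activation threshold (> 0, same units as `trace`).
#' @param frame_interval movie frame interval (min).
#' @param hysteresis closing-threshold fraction in (0, 1].
#' @param median_filter apply a 3-frame running median before detection.
#' @param lineage_id identifier copied into the result.
#' @return An event table (tibble): `lineage_id`, `t_on`, `t_off`,
#'   `n_frames`, `dwell_min`, `censored`. For uncensored events
#'   `dwell_min = n_frames * frame_interval` exactly.
#' @examples
#' tr <- c(0, 0, 150, 150, 150, 0, 0)
#' detect_events(tr, threshold = 100, frame_interval = 12)
#' @export
detect_events <- function(trace, threshold, frame_interval = 12,
                          hysteresis = 1, median_filter = FALSE,
                          lineage_id = 1L) {
  trace <- as.numeric(trace)
  n <- length(trace)
  stopifnot(n >= 2, threshold > 0, hysteresis > 0, hysteresis <= 1)
  if (median_filter && n >= 3) trace <- stats::runmed(trace, 3)

  if (hysteresis == 1) {
    above <- trace >= threshold
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    starts <- starts[on]; ends <- ends[on]
  } else {
    # two-threshold scan: open at >= threshold, close below h*threshold
    starts <- integer(0); ends <- integer(0)
    open <- trace[1] >= threshold
    if (open) starts <- 1L
    for (i in seq_len(n)[-1]) {
      if (!open && trace[i] >= threshold) {
        open <- TRUE; starts <- c(starts, i)
      } else if (open && trace[i] < hysteresis * threshold) {
        open <- FALSE; ends <- c(ends, i - 1L)
      }
    }
    if (open) ends <- c(ends, n)
  }

  if (!length(starts))
    return(tibble::tibble(lineage_id = integer(0), t_on = numeric(0),
                          t_off = numeric(0), n_frames = integer(0),
                          dwell_min = numeric(0), censored = logical(0)))

  cens_start <- starts == 1L
  cens_end <- ends == n
  censored <- cens_start | cens_end
  t_on <- ifelse(cens_start, NA_real_, (starts - 1L) * frame_interval)
  t_off <- ifelse(cens_end, NA_real_, ends * frame_interval)
  n_frames <- ends - starts + 1L
  dwell <- ifelse(censored, NA_real_, n_frames * frame_interval)
  tibble::tibble(lineage_id = lineage_id, t_on = t_on, t_off = t_off,
                 n_frames = n_frames, dwell_min = dwell, censored = censored)
}

#' Per-frame traces of the mother cell of each channel
#'
#' The mother is the occupant of the capped-end slot (position 1); its
#' identity changes at divisions but the position is continuously
#' observed, so each channel yields exactly one record per frame.
#'
#' @param lineage a mother-machine lineage table.
#' @param column which per-frame quantity to extract (e.g. `"state_sucC"`,
#'   `"f_alsS"`).
#' @return named list of numeric traces, one per channel, frame-ordered.
#' @export
mother_traces <- function(lineage, column = "f_sucC") {
  stopifnot(column %in% names(lineage))
  # mother = first-listed cell of each (channel, frame); the simulator
  # orders records by position within channel
  key <- paste(lineage$channel_id, lineage$frame)
  first <- !duplicated(key)
  m <- lineage[first, ]
  sp <- split(m, m$channel_id)
  lapply(sp, function(d) d[[column]][order(d$frame)])
}

#' Detect activation events for every cell of a lineage table
#'
#' Runs [detect_events()] on each cell's own per-frame trace, so events
#' are attributed to individual cell cycles (used for per-state growth
#' assignment). `lineage_id` in the result is the `cell_id`.
#'
#' @inheritParams detect_events
#' @param lineage a lineage table.
#' @param column trace column to threshold.
#' @param min_frames cells observed for fewer frames are skipped.
#' @return combined event table.
#' @export
detect_events_cells <- function(lineage, threshold, column = "f_alsS",
                                frame_interval = 12, hysteresis = 1,
                                min_frames = 2L) {
  sp <- split(lineage[, c("frame", column)], lineage$cell_id)
  out <- lapply(names(sp), function(cid) {
    d <- sp[[cid]]
    if (nrow(d) < min_frames) return(NULL)
    ev <- detect_events(d[[column]][order(d$frame)], threshold,
                        frame_interval, hysteresis,
                        lineage_id = as.integer(cid))
    if (!nrow(ev)) return(NULL)
    # event times are relative to the cell's first observed frame
    t0 <- (min(d$frame) - 1L) * frame_interval
    ev$t_on <- ev$t_on + t0; ev$t_off <- ev$t_off + t0
    ev
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(detect_events(c(0, 0), threshold = 1, frame_interval)[0, ])
  dplyr::bind_rows(out)
}

#' Activation events per 100 hours of observation
#'
#' Counts event onsets (uncensored and censored alike: an episode running
#' at a movie boundary still started) per observed mother-cell time.
#'
#' @param tables one event table or a list of event tables.
#' @param total_observed_hr total observation time (hours), > 0.
#' @return events per 100 hr (numeric scalar).
#' @examples
#' ev <- detect_events(c(0, 150, 150, 0), 100, 12)
#' events_per_100hr(ev, total_observed_hr = 250)
#' @export
events_per_100hr <- function(tables, total_observed_hr) {
  if (!is.numeric(total_observed_hr) || total_observed_hr <= 0)
    stop("total_observed_hr must be > 0", call. = FALSE)
  if (is.data.frame(tables)) tables <- list(tables)
  n_events <- sum(vapply(tables, nrow, integer(1)))
  n_events / total_observed_hr * 100
}

#' Dwell-time summary over uncensored events
#'
#' Censored events (active at a movie boundary) are excluded from the
#' dwell statistics but their count is reported. Because threshold
#' crossings are interval-censored at frame resolution, a discretization
#' correction of `+frame_interval/2` should be added to the mean when
#' comparing with continuous-time episode lengths; pass it via
#' `correction_min`.
#'
#' @param tables one event table or a list of event tables.
#' @param correction_min additive correction to the mean dwell (min);
#'   use `frame_interval / 2` for the discretization correction.
#' @return list with `mean_min` (corrected), `sd_min` (`NA` flagged when
#'   n = 1), `n`, `n_censored`, `correction_min`.
#' @examples
#' ev <- detect_events(c(0, 150, 150, 150, 0), 100, 12)
#' dwell_summary(ev)
#' @export
dwell_summary <- function(tables, correction_min = 0) {
  if (is.data.frame(tables)) tables <- list(tables)
  ev <- dplyr::bind_rows(tables)
  n_cens <- sum(ev$censored)
  d <- ev$dwell_min[!ev$censored]
  if (!length(d))
    stop("no uncensored events (", n_cens, " censored events excluded)",
         call. = FALSE)
  list(mean_min = mean(d) + correction_min,
       sd_min = if (length(d) > 1) stats::sd(d) else NA_real_,
       n = length(d), n_censored = n_cens,
       correction_min = correction_min)
}

#' Elongation rate of one cell cycle
#'
#' Least-squares slope `s` of `log(length)` against time; the rate is
#' reported as percent length increase per hour under exponential growth,
#' `100 * (exp(60 s) - 1)`, so that one doubling per hour equals
#' 100 %/hr. Windows must lie within a single cell cycle: an abrupt
#' length drop (> 40%) between frames is treated as a division and
#' rejected.
#'
#' @param lengths per-frame cell lengths (um), all > 0, length >= 3.
#' @param frame_interval frame spacing (min).
#' @return An object of class `elongation_estimate`: list with
#'   `rate_pct_per_hr`, `slope_per_min`, `window` (min), `n_frames_used`,
#'   `r2`.
#' @examples
#' L <- 2 * 2^((0:5) * 12 / 60)          # doubling per hour
#' elongation_rate(L, 12)$rate_pct_per_hr
#' @export
elongation_rate <- function(lengths, frame_interval = 12) {
  lengths <- as.numeric(lengths)
  n <- length(lengths)
  if (n < 3) stop("elongation fit requires >= 3 frames", call. = FALSE)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all lengths must be positive", call. = FALSE)
  if (any(lengths[-1] / lengths[-n] < 0.6))
    stop("length drop > 40% within window: division inside window",
         call. = FALSE)
  t <- (seq_len(n) - 1) * frame_interval
  y <- log(lengths)
  fit <- stats::lm.fit(cbind(1, t), y)
  s <- unname(fit$coefficients[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(rate_pct_per_hr = 100 * (exp(60 * s) - 1),
                 slope_per_min = unname(s),
                 window = c(0, (n - 1) * frame_interval),
                 n_frames_used = n,
                 r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "elongation_estimate")
}

#' Per-cell-cycle elongation rates for a lineage table
#'
#' Fits [elongation_rate()] to each cell's observed frames (its cell
#' cycle; cells observed < 3 frames or failing the fit preconditions are
#' skipped).
#'
#' @param lineage a lineage table.
#' @param frame_interval frame spacing (min).
#' @return tibble: `cell_id`, `channel_id`, `t_first`, `t_last`,
#'   `n_frames`, `rate_pct_per_hr`, `r2`.
#' @export
cell_cycle_rates <- function(lineage, frame_interval = 12) {
  sp <- split(lineage, lineage$cell_id)
  rows <- lapply(sp, function(d) {
    if (nrow(d) < 3) return(NULL)
    d <- d[order(d$frame), ]
    est <- try(elongation_rate(d$length_um, frame_interval), silent = TRUE)
    if (inherits(est, "try-error")) return(NULL)
    data.frame(cell_id = d$cell_id[1], channel_id = d$channel_id[1],
               t_first = min(d$t_min), t_last = max(d$t_min),
               n_frames = nrow(d), rate_pct_per_hr = est$rate_pct_per_hr,
               r2 = est$r2)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(tibble::tibble(cell_id = integer(0), channel_id = integer(0),
                          t_first = numeric(0), t_last = numeric(0),
                          n_frames = integer(0),
                          rate_pct_per_hr = numeric(0), r2 = numeric(0)))
  tibble::as_tibble(do.call(rbind, rows))
}

#' Elongation rates split by activation state
#'
#' Each cell-cycle window is assigned to the "on" class when at least 50%
#' of its frames fall inside an activation event of the same lineage
#' (ties at exactly 50% count as on); censored events still define
#' intervals for this assignment. Reports per-class mean and standard
#' error of the per-window elongation rates; the headline summary is
#' only considered reliable with >= 50 windows per class (`reliable`
#' flags this).
#'
#' @param lineage a lineage table.
#' @param events an event table whose `lineage_id` matches
#'   `lineage$cell_id` (e.g. from [detect_events_cells()]).
#' @param frame_interval frame spacing (min).
#' @return list with `state_on` and `state_off` (each `mean`, `sem`, `n`,
#'   `reliable`, or `NULL` when the class is empty) and `rates`, the
#'   per-window tibble with an `on` column.
#' @export
per_state_growth <- function(lineage, events, frame_interval = 12) {
  rates <- cell_cycle_rates(lineage, frame_interval)
  if (!nrow(rates)) stop("no valid elongation windows", call. = FALSE)
  ev <- events
  ev$t_on_fill <- ifelse(is.na(ev$t_on), -Inf, ev$t_on)
  ev$t_off_fill <- ifelse(is.na(ev$t_off), Inf, ev$t_off)
  frac_on <- function(cid, t1, t2) {
    e <- ev[ev$lineage_id == cid, ]
    if (!nrow(e)) return(0)
    ts <- seq(t1, t2, by = frame_interval)
    inside <- vapply(ts, function(tt)
      any(tt >= e$t_on_fill & tt < e$t_off_fill), logical(1))
    mean(inside)
  }
  ov <- mapply(frac_on, rates$cell_id, rates$t_first, rates$t_last)
  rates$on <- ov >= 0.5
  summarize_class <- function(r) {
    if (!nrow(r)) return(NULL)
    list(mean = mean(r$rate_pct_per_hr),
         sem = if (nrow(r) > 1) stats::sd(r$rate_pct_per_hr) / sqrt(nrow(r))
               else NA_real_,
         n = nrow(r), reliable = nrow(r) >= 50)
  }
  list(state_on = summarize_class(rates[rates$on, ]),
       state_off = summarize_class(rates[!rates$on, ]),
       rates = rates,
       rule = "window on iff >= 50% of frames inside an event; rate = 100*(exp(60*slope)-1) %/hr")
}

#' Correlation between two reporters across single cells
#'
#' Pearson and Spearman coefficients on mean-centered per-cell values
#' (centering leaves both coefficients unchanged; it mirrors plotting
#' scatter data about the population mean).
#'
#' @param x,y paired per-cell reporter means, n >= 3.
#' @return list with `pearson`, `spearman`, `n`.
#' @examples
#' reporter_correlation(1:10, (1:10) * 2)$pearson
#' @export
reporter_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 cell pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in a reporter channel",
         call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  list(pearson = stats::cor(xc, yc),
       spearman = stats::cor(xc, yc, method = "spearman"),
       n = length(x))
}
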