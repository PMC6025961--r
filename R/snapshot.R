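# Snapshot-level statistics: distribution screening and positive-cell
# classification by the mean + k*SD rule, computed per timepoint.

#' Adjusted Fisher-Pearson sample skewness
#'
#' `skewness(x) = g1 * sqrt(n(n-1))/(n-2)` where `g1 = m3/m2^(3/2)` uses
#' population moments. This is the small-sample-corrected estimator used
#' by most statistics software; heterogeneously expressed genes are
#' flagged by skew values above ~1.
#'
#' @param values numeric vector, `n >= 3`, non-degenerate.
#' @return a single dimensionless skewness value.
#' @examples
#' skewness(c(1, 2, 3))        # 0 for a symmetric sample
#' @export
skewness <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("skewness requires at least 3 values", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0)
    stop("skewness is undefined for a zero-variance sample", call. = FALSE)
  g1 <- mean((values - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Classify positive cells by the mean + k*SD rule
#'
#' A cell is called positive when its fluorescence is at or above
#' `mean + k * sd` of the same snapshot (sample SD, n-1 denominator).
#' Statistics are computed per snapshot, never pooled across timepoints,
#' because subpopulation fractions are reported at specific culture
#' densities.
#'
#' @param values numeric vector of per-cell fluorescence, `n >= 2`.
#' @param k SD multiplier (default 2, the standard positive-cell cutoff).
#' @return An object of class `classification_result`: a list with
#'   `threshold`, `labels` (logical per cell), `fraction_positive`,
#'   `mean`, `sd`, `k`, `n`.
#' @examples
#' classify_positive(c(0, 0, 0, 100))$threshold   # 25 + 2*50 = 125
#' @export
classify_positive <- function(values, k = 2) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("classification requires at least 2 values", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  m <- mean(values); s <- stats::sd(values)
  if (s == 0) {
    warning("degenerate (constant) fluorescence distribution: no positives called",
            call. = FALSE)
    labels <- rep(FALSE, n)
  } else {
    labels <- values >= m + k * s
  }
  structure(list(threshold = m + k * s, labels = labels,
                 fraction_positive = mean(labels),
                 mean = m, sd = s, k = k, n = n,
                 rule = "value >= mean + k*sd, per-snapshot statistics"),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> n=%d k=%g threshold=%.4g fraction_positive=%.4g\n",
              x$n, x$k, x$threshold, x$fraction_positive))
  invisible(x)
}

#' Fraction-positive time course
#'
#' Applies [classify_positive()] independently to each snapshot and
#' returns one fraction per timepoint, plus the time of the maximal
#' fraction (the subpopulation peak along the growth curve).
#'
#' @param samples either a data frame with columns `t_min`, `od`, `value`
#'   (one reporter, long format; extra columns ignored) or a list whose
#'   elements each have `t`/`t_min`, `od` and `values` fields.
#' @param k SD multiplier passed to [classify_positive()].
#' @return a tibble with columns `t_min`, `od`, `n`, `fraction_positive`,
#'   with attribute `t_argmax` (`NA` when all fractions are zero).
#' @examples
#' df <- data.frame(t_min = rep(c(0, 60), each = 50), od = 0.5,
#'                  value = c(rnorm(50), c(rnorm(45), rnorm(5, 8))))
#' fraction_timecourse(df)
#' @export
fraction_timecourse <- function(samples, k = 2) {
  if (is.data.frame(samples)) {
    need <- c("t_min", "od", "value")
    miss <- setdiff(need, names(samples))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    sp <- split(samples, samples$t_min)
    rows <- lapply(sp, function(d)
      data.frame(t_min = d$t_min[1], od = d$od[1], n = nrow(d),
                 fraction_positive = suppressWarnings(
                   classify_positive(d$value, k)$fraction_positive)))
  } else if (is.list(samples) && length(samples) > 0) {
    rows <- lapply(samples, function(s) {
      t <- if (!is.null(s$t_min)) s$t_min else s$t
      data.frame(t_min = t, od = if (is.null(s$od)) NA_real_ else s$od,
                 n = length(s$values),
                 fraction_positive = suppressWarnings(
                   classify_positive(s$values, k)$fraction_positive))
    })
  } else {
    stop("no snapshots supplied", call. = FALSE)
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- out[order(out$t_min), ]
  attr(out, "t_argmax") <- if (all(out$fraction_positive == 0)) NA_real_
                           else out$t_min[which.max(out$fraction_positive)]
  out
}

#' Hill fit of an acetate dose-response
#'
#' Fits `fraction = baseline + amplitude * dose^h / (K^h + dose^h)` by
#' bounded nonlinear least squares (amplitude and baseline in [0, 1],
#' `K > 0`, `h` in [0.5, 6]). `K` is initialised at the dose nearest the
#' half-maximal response and `h` at 2, which is robust on small 3-8 dose
#' designs. A flat response is returned with amplitude ~0 and flagged
#' non-identifiable for `K` and `h`.
#'
#' @param doses acetate concentrations (mM), >= 2 distinct values;
#'   a full fit needs >= 4.
#' @param fractions observed positive fractions in [0, 1], same length.
#' @return An object of class `hill_fit`: list with `amplitude`, `K`, `h`,
#'   `baseline`, `monotone` (Spearman >= 0 over dose order),
#'   `identifiable`, `n`, and `fitted`.
#' @examples
#' d <- c(0, 2, 4, 8, 12, 16, 24, 32)
#' f <- 0.02 + 0.5 * d^2 / (8^2 + d^2)
#' dose_response(d, f)
#' @export
dose_response <- function(doses, fractions) {
  stopifnot(length(doses) == length(fractions))
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  nd <- length(unique(doses))
  if (nd < 2) stop("at least 2 distinct doses required", call. = FALSE)
  mono <- if (stats::sd(fractions) == 0) TRUE else
    suppressWarnings(stats::cor(doses, fractions, method = "spearman")) >= 0

  if (nd < 4) {
    return(structure(list(amplitude = NA_real_, K = NA_real_, h = NA_real_,
                          baseline = NA_real_, monotone = mono,
                          identifiable = FALSE, n = length(doses),
                          fitted = rep(NA_real_, length(doses))),
                     class = "hill_fit"))
  }

  rng <- diff(range(fractions))
  if (rng < 1e-6) {      # flat response: amplitude ~ 0, K/h meaningless
    return(structure(list(amplitude = 0, K = NA_real_, h = NA_real_,
                          baseline = mean(fractions), monotone = mono,
                          identifiable = FALSE, n = length(doses),
                          fitted = rep(mean(fractions), length(doses))),
                     class = "hill_fit"))
  }

  half <- min(fractions) + rng / 2
  pos <- doses[doses > 0]
  K0 <- doses[which.min(abs(fractions - half))]
  if (K0 <= 0) K0 <- if (length(pos)) min(pos) else 1
  dat <- data.frame(d = doses, f = fractions)
  fit <- try(minpack.lm::nlsLM(
    f ~ baseline + amplitude * d^h / (K^h + d^h), data = dat,
    start = list(baseline = max(min(fractions), 1e-4),
                 amplitude = max(rng, 1e-3), K = K0, h = 2),
    lower = c(baseline = 0, amplitude = 0, K = 1e-6, h = 0.5),
    upper = c(baseline = 1, amplitude = 1, K = 10 * max(doses), h = 6),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(amplitude = NA_real_, K = NA_real_, h = NA_real_,
                          baseline = NA_real_, monotone = mono,
                          identifiable = FALSE, n = length(doses),
                          fitted = rep(NA_real_, length(doses))),
                     class = "hill_fit"))
  }
  cf <- stats::coef(fit)
  ident <- cf[["amplitude"]] > 0.02
  structure(list(amplitude = unname(cf["amplitude"]), K = unname(cf["K"]),
                 h = unname(cf["h"]), baseline = unname(cf["baseline"]),
                 monotone = mono, identifiable = ident, n = length(doses),
                 fitted = stats::fitted(fit)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> amplitude=%.3g K=%.3g mM h=%.3g baseline=%.3g%s%s\n",
              x$amplitude, x$K, x$h, x$baseline,
              if (isTRUE(x$monotone)) " monotone" else " non-monotone",
              if (isTRUE(x$identifiable)) "" else " [non-identifiable]"))
  invisible(x)
}
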