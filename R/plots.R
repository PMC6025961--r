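# Optional figure helpers. Numeric outputs never depend on these.

#' Snapshot histogram with the high-expressing tail shaded
#'
#' @param values per-cell fluorescence (AU).
#' @param k SD multiplier for the positive threshold.
#' @param bins histogram bins.
#' @return a ggplot object.
#' @export
plot_snapshot_hist <- function(values, k = 2, bins = 60) {
  cl <- suppressWarnings(classify_positive(values, k))
  df <- data.frame(value = values, positive = cl$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$positive)) +
    ggplot2::geom_histogram(bins = bins, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = cl$threshold, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "fluorescence (AU)", y = "cells",
                  subtitle = sprintf("threshold = mean + %g sd; %.1f%% positive",
                                     k, 100 * cl$fraction_positive)) +
    ggplot2::theme_minimal()
}

#' Overlay of fraction-positive time courses and metabolite curves
#'
#' @param env environment trajectory (from [simulate_batch()]).
#' @param fractions named list of fraction tibbles (per reporter) from
#'   [fraction_timecourse()].
#' @return a ggplot object; fractions are drawn on a secondary axis
#'   scaled to the acetate peak.
#' @export
plot_fraction_overlay <- function(env, fractions) {
  sc <- max(env$acetate_mM, 1e-9)
  met <- rbind(data.frame(t_min = env$t_min, y = env$acetate_mM, what = "acetate"),
               data.frame(t_min = env$t_min, y = env$acetoin_mM, what = "acetoin"))
  fr <- do.call(rbind, lapply(names(fractions), function(nm)
    data.frame(t_min = fractions[[nm]]$t_min,
               y = fractions[[nm]]$fraction_positive * sc,
               what = paste0(nm, "+ fraction"))))
  ggplot2::ggplot(rbind(met, fr),
                  ggplot2::aes(x = .data$t_min, y = .data$y,
                               colour = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(
      name = "concentration (mM)",
      sec.axis = ggplot2::sec_axis(~ . / sc, name = "fraction positive")) +
    ggplot2::labs(x = "time (min)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Dose-response data with the fitted Hill curve
#'
#' @param doses,fractions the fitted data.
#' @param fit a [dose_response()] result.
#' @return a ggplot object.
#' @export
plot_dose_response <- function(doses, fractions, fit) {
  df <- data.frame(dose = doses, fraction = fractions)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$fraction)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "acetate (mM)", y = "fraction positive") +
    ggplot2::theme_minimal()
  if (isTRUE(fit$identifiable)) {
    grid <- seq(min(doses), max(doses), length.out = 200)
    curve <- data.frame(dose = grid,
                        fraction = fit$baseline + fit$amplitude *
                          grid^fit$h / (fit$K^fit$h + grid^fit$h))
    gg <- gg + ggplot2::geom_line(data = curve, colour = "firebrick")
  }
  gg
}
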