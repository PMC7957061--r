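#' Plot the concentration traces of a simulation
#'
#' @param object a `calf_sim`.
#' @param ... unused.
#' @return a ggplot: calcium (nM), extracellular glutamate (uM) and sodium
#'   (mM) traces in stacked facets, with the release time marked when the
#'   protocol fired one.
#' @export
autoplot.calf_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, -"time_ms",
                              names_to = "series", values_to = "value")
  long$series <- factor(long$series, levels = c("ca_nM", "glu_uM", "na_mM"),
                        labels = c("[Ca2+]i (nM)", "[Glu]e (uM)", "[Na+]i (mM)"))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_ms, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$series), scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = sprintf("Synapse %s", object$meta$synapse_id))
  if (object$config$release_enabled) {
    p <- p + ggplot2::geom_vline(xintercept = object$config$t_release_ms,
                                 linetype = "dashed", colour = "darkgreen")
  }
  p
}

#' Plot band power against astrocytic SVR with the fitted regression
#'
#' @param object a `calf_regression`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.calf_regression <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$svr, .data$power_db)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = g$intercept, slope = g$slope) +
    ggplot2::labs(x = expression(SVR ~ (mu * m^-1)),
                  y = "100-500 Hz power (dB)",
                  subtitle = sprintf("R^2 = %.2f, slope p = %.3g",
                                     g$r.squared, g$p.value))
}

#' Population morphometrics overview
#'
#' @param pop a [make_population()] manifest.
#' @return a ggplot: SVR histogram and pre/post coverage scatter.
#' @export
plot_population_morphometrics <- function(pop) {
  d1 <- tibble(panel = "SVR (1/um)", value = pop$svr_um_inv)
  p1 <- ggplot2::ggplot(d1, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey60", colour = "grey20") +
    ggplot2::labs(x = expression(SVR ~ (mu * m^-1)), y = "synapses")
  p2 <- ggplot2::ggplot(pop, ggplot2::aes(.data$coverage_pre, .data$coverage_post)) +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "presynaptic coverage", y = "postsynaptic coverage")
  patch <- tryCatch(getNamespace("patchwork"), error = function(e) NULL)
  if (!is.null(patch)) p1 + p2 else p1
}

#' Grouped band-power summary plot
#'
#' @param grouped output of [group_powers_by_svr()], optionally with a
#'   `condition` column to dodge groups.
#' @return a ggplot of per-bin mean with SEM error bars.
#' @export
plot_group_powers <- function(grouped) {
  mapping <- if ("condition" %in% names(grouped)) {
    ggplot2::aes(.data$bin, .data$mean_db, fill = .data$condition)
  } else {
    ggplot2::aes(.data$bin, .data$mean_db)
  }
  ggplot2::ggplot(grouped, mapping) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_db - .data$sem_db,
                                        ymax = .data$mean_db + .data$sem_db),
                           width = 0.2,
                           position = ggplot2::position_dodge(0.9)) +
    ggplot2::labs(x = expression(SVR ~ bin ~ (mu * m^-1)),
                  y = "100-500 Hz power (dB)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
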