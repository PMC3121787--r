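# ggplot2 visualisations of the fitted objects.

#' Plot a turnover fit
#'
#' Observed trajectories (one line per individual) with the fitted
#' population incorporation curve(s) overlaid; one curve per demographic
#' group when fixed effects are present.
#'
#' @param object A converged one-compartment `turnover_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.turnover_fit <- function(object, ...) {
  if (!isTRUE(object$converged) || is.null(object$data)) {
    abort("Plotting needs a converged fit with stored data.")
  }
  data <- object$data
  grid <- tibble(day = seq(0, max(data$day), length.out = 200))
  est <- object$estimates
  p1 <- est[[grep("^phi1", names(est), value = TRUE)[1]]]
  p2 <- est[[grep("^phi2", names(est), value = TRUE)[1]]]
  hl <- object$half_life
  curves <- map(seq_len(nrow(hl)), function(i) {
    k <- exp(hl$log_rate[i])
    mutate(grid, .group = hl$group[i],
           delta_permil = p1 + (p2 - p1) * exp(-k * .data$day))
  }) %>% list_rbind()
  ggplot2::ggplot(data, ggplot2::aes(x = .data$day,
                                     y = .data$delta_permil)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$individual_id),
                       alpha = 0.3, linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(colour = .data$.group),
                       linewidth = 1) +
    ggplot2::labs(x = "Days since diet shift",
                  y = expression(delta ~ "(‰)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sampling-design report
#'
#' Boxplot-style summaries (from the stored per-replicate estimates) of the
#' asymptote, intercept and half-life under each candidate schedule.
#'
#' @param object A `design_report` from [run_design_sim()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.design_report <- function(object, ...) {
  est <- attr(object, "estimates")
  if (is.null(est)) abort("No per-replicate estimates attached.")
  ggplot2::ggplot(est, ggplot2::aes(x = .data$schedule_id,
                                    y = .data$estimate)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, na.rm = TRUE) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Sampling schedule", y = "Estimate") +
    ggplot2::theme_minimal()
}

#' Boxplots of discrimination by tissue, diet and demographic group
#'
#' @param records Discrimination records.
#' @param isotope Optional isotope filter.
#' @return A ggplot object.
#' @export
plot_discrimination <- function(records, isotope = NULL) {
  records <- as_tibble(records)
  if (!is.null(isotope)) {
    records <- filter(records, .data$isotope == !!isotope)
  }
  ggplot2::ggplot(records, ggplot2::aes(x = .data$tissue,
                                        y = .data$discrimination,
                                        fill = .data$diet)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~isotope, scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression(Delta ~ "(‰)"),
                  fill = "Diet") +
    ggplot2::theme_minimal()
}
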