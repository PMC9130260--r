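# Diagnostic plots for the fitted objects.

#' @describeIn fit_psychometric Plot observed hit rates and the fitted curve.
#' @param object,x A `psychometric_fit`.
#' @param ... Unused.
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  bd <- object$data$by_depth
  grid <- tibble(depth_db = seq(min(bd$depth_db), max(bd$depth_db),
                                length.out = 200))
  grid$p <- predict(object, grid$depth_db)
  gg <- ggplot2::ggplot(bd, ggplot2::aes(x = .data$depth_db)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$hit_rate, size = .data$n),
                        alpha = 0.8) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p),
                       colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$guess, linetype = 3) +
    ggplot2::labs(x = "AM depth (dB re: 100%)", y = "hit rate",
                  size = "trials",
                  title = "Psychometric function") +
    ggplot2::ylim(0, 1)
  if (object$attained) {
    gg <- gg + ggplot2::geom_vline(xintercept = object$threshold_db,
                                   linetype = 2, colour = "grey40")
  }
  gg
}

#' @describeIn neurometric Plot neural d' by depth with the logistic fit and
#'   the d' = 1 criterion.
#' @param object,x A `neurometric_result`.
#' @param ... Unused.
#' @export
autoplot.neurometric_result <- function(object, ...) {
  dpd <- object$dprime_by_depth
  gg <- ggplot2::ggplot(dpd, ggplot2::aes(x = .data$depth_db,
                                          y = .data$dprime)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::labs(x = "AM depth (dB re: 100%)", y = "neural d'",
                  title = sprintf("Neurometric function: unit %s",
                                  object$unit_id))
  if (object$fit$valid) {
    grid <- tibble(depth_db = seq(min(dpd$depth_db), max(dpd$depth_db),
                                  length.out = 200))
    grid$dprime <- predict(object$fit, grid$depth_db)
    gg <- gg + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  if (object$attained) {
    gg <- gg + ggplot2::geom_vline(xintercept = object$threshold_db,
                                   linetype = 2, colour = "grey40")
  }
  gg
}

#' @describeIn decoder_neurometric Plot decoder d' by depth with its
#'   logistic fit.
#' @param object,x A `decoder_result`.
#' @param ... Unused.
#' @export
autoplot.decoder_result <- function(object, ...) {
  bd <- object$by_depth
  gg <- ggplot2::ggplot(bd, ggplot2::aes(x = .data$depth_db,
                                         y = .data$dprime)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::labs(x = "AM depth (dB re: 100%)", y = "decoder d'",
                  title = sprintf("Population decoder (%d units)",
                                  object$n_units))
  if (!is.null(object$fit) && object$fit$valid) {
    grid <- tibble(depth_db = seq(min(bd$depth_db), max(bd$depth_db),
                                  length.out = 200))
    grid$dprime <- predict(object$fit, grid$depth_db)
    gg <- gg + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  if (object$attained) {
    gg <- gg + ggplot2::geom_vline(xintercept = object$threshold_db,
                                   linetype = 2, colour = "grey40")
  }
  gg
}

#' @describeIn fit_learning_curve Plot per-day thresholds on a log-day axis
#'   with the fitted learning curve.
#' @param object,x A `learning_curve`.
#' @param ... Unused.
#' @export
autoplot.learning_curve <- function(object, ...) {
  df <- object$data
  if (!"group" %in% names(df)) df$group <- "all"
  df$group <- factor(df$group)
  df$fitted <- fitted(object$fit)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$threshold_db,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted, group = .data$group)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "test day (log scale)",
                  y = "threshold (dB re: 100%)",
                  title = "Perceptual learning curve")
}
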