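# Perceptual-learning curves: threshold vs log10(test day) regression with an
# optional group contrast (ANCOVA-style OLS).

#' Fit a perceptual learning curve
#'
#' Ordinary-least-squares model of per-day detection thresholds against
#' log10(test day), with an optional group indicator and group-by-day
#' interaction (an ANCOVA-style analysis): threshold ~ log10(day) + group
#' (+ log10(day):group). Reports the learning slope in dB per log10(day),
#' the group offset in dB, classical F-tests, and the improvement (day-1
#' minus final-day mean threshold) per group.
#'
#' @param thresholds A data frame with columns `day` (test day, day 1 = first
#'   psychometric session), `threshold_db`, optionally `group` and
#'   `subject`.
#' @param interaction Include the group-by-log(day) interaction (default TRUE
#'   when a group column with >= 2 levels is present).
#' @return An object of class `learning_curve` with the fitted `lm`, `slope`
#'   (dB / log10(day)), `group_offset` (dB, NA without groups),
#'   `interaction_p`, `group_p`, `day_p`, and per-group `improvement`.
#' @export
fit_learning_curve <- function(thresholds, interaction = NULL) {
  stopifnot(is.data.frame(thresholds))
  if (!all(c("day", "threshold_db") %in% names(thresholds))) {
    abort("`thresholds` needs `day` and `threshold_db` columns.")
  }
  df <- as_tibble(thresholds)
  df <- df[is.finite(df$threshold_db), ]
  if (any(df$day < 1)) abort("`day` must be >= 1 (day 1 = first session).")
  if (length(unique(df$day)) < 2) {
    abort("learning slope undefined with a single test day.")
  }
  df$log_day <- log10(df$day)
  has_group <- "group" %in% names(df) && length(unique(df$group)) >= 2
  if (is.null(interaction)) interaction <- has_group
  if (has_group) {
    df$group <- factor(df$group)
    form <- if (interaction) threshold_db ~ log_day * group
            else threshold_db ~ log_day + group
  } else {
    form <- threshold_db ~ log_day
  }
  fit <- lm(form, data = df)
  an <- anova(fit)
  cf <- coef(fit)
  slope <- unname(cf["log_day"])
  group_terms <- grep("^group", names(cf), value = TRUE)
  group_terms <- setdiff(group_terms, grep(":", group_terms, value = TRUE))
  group_offset <- if (length(group_terms)) unname(cf[group_terms[1]]) else NA_real_
  pr <- an[["Pr(>F)"]]
  rn <- rownames(an)
  day_p <- if ("log_day" %in% rn) pr[rn == "log_day"] else NA_real_
  group_p <- if ("group" %in% rn) pr[rn == "group"] else NA_real_
  interaction_p <- if ("log_day:group" %in% rn) pr[rn == "log_day:group"]
                   else NA_real_
  imp <- df |>
    group_by(group = if (has_group) .data$group else "all") |>
    summarise(
      initial = mean(.data$threshold_db[.data$day == min(.data$day)]),
      final = mean(.data$threshold_db[.data$day == max(.data$day)]),
      .groups = "drop") |>
    mutate(improvement = .data$initial - .data$final)
  structure(list(fit = fit, slope = slope, group_offset = group_offset,
                 day_p = day_p, group_p = group_p,
                 interaction_p = interaction_p, improvement = imp,
                 data = df),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("Learning curve: threshold ~ log10(day)",
      if (!is.na(x$group_offset)) "+ group", "\n")
  cat(sprintf("  slope: %.2f dB per log10(day) (p = %.3g)\n",
              x$slope, x$day_p))
  if (!is.na(x$group_offset)) {
    cat(sprintf("  group offset: %.2f dB (p = %.3g)\n",
                x$group_offset, x$group_p))
    if (!is.na(x$interaction_p)) {
      cat(sprintf("  interaction p = %.3g\n", x$interaction_p))
    }
  }
  invisible(x)
}

#' @export
tidy.learning_curve <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2],
         statistic = cf[, 3], p.value = cf[, 4])
}

#' @export
glance.learning_curve <- function(x, ...) {
  tibble(slope_db_per_logday = x$slope, group_offset_db = x$group_offset,
         day_p = x$day_p, group_p = x$group_p,
         interaction_p = x$interaction_p,
         r.squared = summary(x$fit)$r.squared, n = nrow(x$data))
}
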