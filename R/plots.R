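#' Plot a day of nest temperature with detected bouts
#'
#' Temperature trace with off-bouts shaded; ambient reference dashed.
#'
#' @param trace a `nestclock_trace`.
#' @param bouts tibble from [detect_bouts()].
#' @param date the `Date` to show (default: first date in `bouts`).
#' @return a ggplot object.
#' @export
plot_bouts <- function(trace, bouts, date = NULL) {
  if (is.null(date)) date <- bouts$date[1]
  dts <- as.Date(trace$timestamp, tz = "UTC")
  day <- trace[dts == date, ]
  offs <- bouts[bouts$date == date & bouts$state == "off", ]
  p <- ggplot2::ggplot(day, ggplot2::aes(x = .data$timestamp,
                                         y = .data$temperature)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Nest temperature (°C)",
                  title = paste(attr(trace, "nest_id"), format(date)))
  if (nrow(offs)) {
    p <- p + ggplot2::geom_rect(
      data = offs,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.25
    )
  }
  amb <- attr(trace, "ambient")
  if (!is.null(amb)) {
    amb_day <- amb[as.Date(amb$timestamp, tz = "UTC") == date, ]
    p <- p + ggplot2::geom_line(data = amb_day, linetype = 2, colour = "grey40")
  }
  p
}

#' Plot variance components of a repeatability analysis
#'
#' @param object a `nestclock_repeatability`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot nestclock_repeatability
#' @export
autoplot.nestclock_repeatability <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Proportion of total variance",
                  title = sprintf("r within = %.3f, r across = %.3f",
                                  object$repeatability$r_within_year,
                                  object$repeatability$r_across_year))
}

#' Plot a fitted selection model against chronotype
#'
#' Scatter of the response against chronotype with the simulated point
#' prediction and 95% band, evaluated at the reference year and mean values
#' of the other covariates.
#'
#' @param object a `nestclock_reduction`.
#' @param n_draws,seed passed to [simulate_prediction_band()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot nestclock_reduction
#' @export
autoplot.nestclock_reduction <- function(object, n_draws = 2000, seed = 1L,
                                         ...) {
  dat <- object$spec$data
  grid <- tibble::tibble(
    chronotype = seq(min(dat$chronotype), max(dat$chronotype),
                     length.out = 80)
  )
  grid$chronotype_sq <- grid$chronotype^2
  # hold every other covariate at its mean / reference level
  other <- setdiff(all.vars(spec_formula(object$spec, object$final_terms)),
                   c(object$spec$response, "chronotype", "chronotype_sq",
                     object$spec$random %||% character()))
  for (v in other) {
    grid[[v]] <- if (is.factor(dat[[v]])) {
      factor(levels(dat[[v]])[1], levels = levels(dat[[v]]))
    } else {
      mean(dat[[v]], na.rm = TRUE)
    }
  }
  band <- simulate_prediction_band(object, grid, n_draws = n_draws,
                                   seed = seed)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$chronotype,
                                    y = .data[[object$spec$response]])) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(ymin = .data$lwr, ymax = .data$upr,
                                      y = .data$fit),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(data = band, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::labs(x = "Chronotype (standardised onset, z)",
                  y = object$spec$name)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
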