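# ggplot2 autoplot methods and broom-style tidiers for the result classes.

#' Plot rarefaction / extrapolation curves
#'
#' One panel per facet x order, solid line over the rarefied/observed range
#' and dotted over the extrapolated range, ribbons for the bootstrap CIs,
#' colour by treatment combination.
#'
#' @param object A [estimate_diversity()] result.
#' @param ribbon Draw CI ribbons (default TRUE when CIs are present).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot restodiv_curve
#' @export
autoplot.restodiv_curve <- function(object, ribbon = TRUE, ...) {
  df <- as_tibble(object) |>
    mutate(
      range = ifelse(.data$status == "extrapolated", "extrapolated", "rarefied"),
      panel_q = paste0("q = ", .data$q)
    )
  p <- ggplot(df, aes(x = .data$t, y = .data$estimate,
                      colour = .data$assemblage, group = .data$assemblage))
  if (ribbon && !all(is.na(df$ci_low))) {
    p <- p + geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high,
                             fill = .data$assemblage),
                         alpha = 0.15, colour = NA)
  }
  p +
    geom_line(data = ~ filter(.x, .data$range == "rarefied"), linetype = "solid") +
    geom_line(data = ~ filter(.x, .data$range == "extrapolated"), linetype = "dotted") +
    facet_grid(facet ~ panel_q, scales = "free_y") +
    labs(x = "sampling units", y = "effective diversity",
         colour = "treatment", fill = "treatment") +
    theme_minimal()
}

#' Plot alpha / gamma / beta estimates per treatment
#'
#' @param object A [scale_estimates()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot restodiv_scales
#' @export
autoplot.restodiv_scales <- function(object, ...) {
  df <- as_tibble(object) |> mutate(panel_q = paste0("q = ", .data$q))
  ggplot(df, aes(x = .data$assemblage, y = .data$estimate,
                 colour = .data$nutrient, shape = .data$invasion)) +
    geom_pointrange(aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    facet_grid(facet + panel_q ~ scale, scales = "free_y") +
    labs(x = NULL, y = "effective diversity", colour = "nutrient",
         shape = "invasion") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot invasion-timing effect sizes
#'
#' Late-minus-early contrasts with their CIs, one panel per facet x order,
#' a reference line at zero.
#'
#' @param object An [invasion_effects()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot restodiv_effects
#' @export
autoplot.restodiv_effects <- function(object, ...) {
  df <- as_tibble(object) |> mutate(panel_q = paste0("q = ", .data$q))
  ggplot(df, aes(x = .data$scale, y = .data$delta, colour = .data$nutrient)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_pointrange(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                    position = position_dodge(width = 0.4)) +
    facet_grid(facet ~ panel_q, scales = "free_y") +
    labs(x = "scale", y = "late - early effect", colour = "nutrient") +
    theme_minimal()
}

#' @method tidy restodiv_curve
#' @export
tidy.restodiv_curve <- function(x, ...) as_tibble(x)

#' @describeIn tidy.restodiv_curve One row per assemblage x facet x order:
#'   observed diversity, asymptotic tail of the curve, CI width at T.
#' @param x,... passed through.
#' @method glance restodiv_curve
#' @export
glance.restodiv_curve <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$assemblage, .data$facet, .data$q) |>
    summarise(
      T_obs = .data$t[.data$status == "observed"][1],
      observed = .data$estimate[.data$status == "observed"][1],
      t_max = max(.data$t),
      extrapolated_max = .data$estimate[which.max(.data$t)],
      ci_width_obs = (.data$ci_high - .data$ci_low)[.data$status == "observed"][1],
      .groups = "drop"
    )
}

#' @method tidy restodiv_scales
#' @export
tidy.restodiv_scales <- function(x, ...) as_tibble(x)

#' @method tidy restodiv_effects
#' @export
tidy.restodiv_effects <- function(x, ...) as_tibble(x)

#' @describeIn invasion_effects One row per facet x order: how many of the
#'   effect intervals exclude zero, and the mean effect per scale.
#' @param x,... passed through.
#' @method glance restodiv_effects
#' @export
glance.restodiv_effects <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$facet, .data$q) |>
    summarise(
      n_effects = dplyr::n(),
      n_excluding_zero = sum(.data$ci_low > 0 | .data$ci_high < 0, na.rm = TRUE),
      mean_delta_alpha = mean(.data$delta[.data$scale == "alpha"]),
      mean_delta_gamma = mean(.data$delta[.data$scale == "gamma"]),
      mean_delta_beta = mean(.data$delta[.data$scale == "beta"]),
      .groups = "drop"
    )
}
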