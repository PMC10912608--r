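# ggplot2 views of the emergence diagnostics. Aesthetics are deliberately
# plain; every plot returns a ggplot object the caller can restyle.

#' Plot per-generation metrics across chains
#'
#' One panel per requested metric: thin lines are individual chains, the
#' heavy line is the cross-chain mean per generation.
#'
#' @param object A metrics tibble from [generation_metrics()].
#' @param metrics Character vector of metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot partseq_metrics
#' @export
autoplot.partseq_metrics <- function(object,
                                     metrics = c(
                                       "set_error", "mean_unit_length",
                                       "entropy_bits", "zipf_r2"
                                     ),
                                     ...) {
  metrics <- intersect(metrics, names(object))
  long <- object |>
    tidyr::pivot_longer(
      dplyr::all_of(metrics),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value))
  means <- long |>
    dplyr::summarise(
      value = mean(.data$value),
      .by = c("generation", "metric")
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value)) +
    ggplot2::geom_line(
      ggplot2::aes(group = .data$chain),
      alpha = 0.35, linewidth = 0.3
    ) +
    ggplot2::geom_line(data = means, linewidth = 1) +
    ggplot2::geom_point(data = means, size = 1.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL)
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' Plot within- versus between-unit transitional probabilities
#'
#' Cross-chain mean TP per generation, one line per transition type; the
#' widening gap is the signature of increasingly clear segmentation cues.
#'
#' @param metrics A metrics tibble from [generation_metrics()].
#' @return A ggplot object.
#' @export
plot_tp_types <- function(metrics) {
  long <- metrics |>
    tidyr::pivot_longer(
      c("mean_within_tp", "mean_between_tp"),
      names_to = "type", values_to = "tp"
    ) |>
    dplyr::mutate(
      type = ifelse(.data$type == "mean_within_tp", "within", "between")
    ) |>
    dplyr::filter(!is.na(.data$tp)) |>
    dplyr::summarise(tp = mean(.data$tp), .by = c("generation", "type"))
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$generation, .data$tp, colour = .data$type)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "generation", y = "mean transitional probability",
      colour = "transition"
    )
}

#' Plot unit rank-frequency distributions by generation
#'
#' Log-log rank-frequency curves (cross-chain mean frequency at each rank),
#' one line per generation: emerging Zipfian structure shows as increasingly
#' straight, steep lines.
#'
#' @param inventories A tibble from [generation_inventories()].
#' @param generations Optional subset of generations to show.
#' @return A ggplot object.
#' @export
plot_rank_frequency <- function(inventories, generations = NULL) {
  rf <- inventories |>
    dplyr::group_split(.data$chain, .data$generation) |>
    purrr::map_dfr(function(g) {
      rank_frequency(g) |>
        dplyr::mutate(chain = g$chain[1], generation = g$generation[1])
    }) |>
    dplyr::summarise(
      frequency = mean(.data$frequency),
      .by = c("generation", "rank")
    )
  if (!is.null(generations)) {
    rf <- dplyr::filter(rf, .data$generation %in% generations)
  }
  ggplot2::ggplot(
    rf,
    ggplot2::aes(.data$rank, .data$frequency,
      colour = factor(.data$generation), group = .data$generation
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "frequency", colour = "generation")
}

#' Plot a fitted generation trend over its data
#'
#' Observed response values against generation with the fixed-effect line
#' of the fitted trend model.
#'
#' @param object A `trend_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, ...) {
  mf <- stats::model.frame(object$fit)
  resp <- names(mf)[1]
  d <- tibble::tibble(generation = mf$generation, value = mf[[resp]])
  fe <- if (inherits(object$fit, "merMod")) {
    lme4::fixef(object$fit)
  } else {
    stats::coef(object$fit)
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$generation, .data$value)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(
      intercept = fe[["(Intercept)"]], slope = fe[["generation"]],
      colour = "red"
    ) +
    ggplot2::labs(x = "generation", y = object$response)
}

#' Plot the entropy-error relation across participants
#'
#' One point per participant: entropy of the input set against mean copying
#' error, with a least-squares line.
#'
#' @param records A tibble from [participant_records()].
#' @return A ggplot object.
#' @export
plot_entropy_error <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(.data$entropy, .data$error)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "entropy of input set (bits)", y = "copying error")
}
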