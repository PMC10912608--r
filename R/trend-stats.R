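# Generation-trend models: linear mixed-effects fits of each emergence
# metric on generation, with the random-effect structures used in the
# original analyses and a documented simplification cascade for singular or
# non-converging fits. Estimation is REML via lmerTest (Satterthwaite
# p-values); the final fallback is an ordinary fixed-effects lm, which also
# covers degenerate zero-variance inputs.

new_trend_fit <- function(fit, response, term, formula_used, singular,
                          fallback_level, messages) {
  is_lmm <- inherits(fit, "merMod")
  coefs <- if (is_lmm) {
    as.data.frame(stats::coef(summary(fit)))
  } else {
    cf <- as.data.frame(stats::coef(summary(fit)))
    cf$df <- stats::df.residual(fit)
    cf[c("Estimate", "Std. Error", "df", "t value", "Pr(>|t|)")]
  }
  names(coefs) <- c("estimate", "std_error", "df", "statistic", "p_value")
  coefs <- tibble::as_tibble(coefs, rownames = "term")
  if (!term %in% coefs$term) {
    stop(sprintf("term `%s` not found in fitted model", term), call. = FALSE)
  }
  row <- coefs[coefs$term == term, ]
  structure(
    list(
      response = response,
      term = term,
      beta = row$estimate,
      se = row$std_error,
      p_value = row$p_value,
      coefficients = coefs,
      singular = singular,
      converged = TRUE,
      fallback_level = fallback_level,
      formula = formula_used,
      messages = messages,
      fit = fit
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> %s ~ ... [%s]\n  %s: beta = %.4g, se = %.3g, p = %.3g%s\n",
    x$response, deparse(x$formula), x$term, x$beta, x$se, x$p_value,
    if (x$singular) "  (singular fit)" else ""
  ))
  invisible(x)
}

# a fit that could not be attempted at all (e.g. no usable observations)
empty_trend_fit <- function(response, term, reason) {
  structure(
    list(
      response = response, term = term,
      beta = NA_real_, se = NA_real_, p_value = NA_real_,
      coefficients = tibble::tibble(
        term = term, estimate = NA_real_, std_error = NA_real_,
        df = NA_real_, statistic = NA_real_, p_value = NA_real_
      ),
      singular = FALSE, converged = FALSE, fallback_level = NA_integer_,
      formula = NULL, messages = reason, fit = NULL
    ),
    class = "trend_fit"
  )
}

# Try a cascade of model formulas; accept the first non-singular converging
# fit, otherwise the first singular one, otherwise lm on the fixed part.
fit_cascade <- function(data, formulas, lm_formula, response, term) {
  resp_var <- all.vars(lm_formula)[1]
  usable <- stats::complete.cases(data[all.vars(lm_formula)])
  if (sum(usable) < 3) {
    return(empty_trend_fit(
      response, term,
      sprintf("only %d usable observations for %s", sum(usable), resp_var)
    ))
  }
  first_singular <- NULL
  notes <- character(0)
  for (k in seq_along(formulas)) {
    f <- formulas[[k]]
    fit <- tryCatch(
      withCallingHandlers(
        lmerTest::lmer(f, data = data, REML = TRUE),
        warning = function(w) {
          notes <<- c(notes, conditionMessage(w))
          invokeRestart("muffleWarning")
        },
        message = function(m) {
          notes <<- c(notes, conditionMessage(m))
          invokeRestart("muffleMessage")
        }
      ),
      error = function(e) {
        notes <<- c(notes, conditionMessage(e))
        NULL
      }
    )
    if (is.null(fit)) next
    if (lme4::isSingular(fit, tol = 1e-4)) {
      if (is.null(first_singular)) {
        first_singular <- list(fit = fit, formula = f, level = k)
      }
      next
    }
    return(new_trend_fit(fit, response, term, f,
      singular = FALSE, fallback_level = k, messages = notes
    ))
  }
  if (!is.null(first_singular)) {
    return(new_trend_fit(
      first_singular$fit, response, term, first_singular$formula,
      singular = TRUE, fallback_level = first_singular$level, messages = notes
    ))
  }
  fit <- stats::lm(lm_formula, data = data)
  new_trend_fit(fit, response, term, lm_formula,
    singular = FALSE, fallback_level = length(formulas) + 1L, messages = notes
  )
}

#' Trend of copying error over generations
#'
#' Linear mixed model predicting per-sequence error with a fixed effect for
#' generation, a random intercept and by-chain slope for chain, and a random
#' intercept for the identity of the original generation-0 sequence (the
#' lineage `index`). Singular or failing fits are simplified stepwise
#' (drop the by-chain slope, then the lineage intercept, finally an ordinary
#' lm) and flagged.
#'
#' @param errors An error-record tibble (columns `chain`, `generation`,
#'   `index`, `error`), e.g. from [copy_errors()].
#' @return A `trend_fit` whose `beta` is the generation slope.
#' @export
fit_error_trend <- function(errors) {
  stopifnot(all(c("chain", "generation", "index", "error") %in% names(errors)))
  d <- errors |>
    dplyr::mutate(
      chain = factor(.data$chain),
      seq_id = interaction(.data$chain, .data$index, drop = TRUE)
    )
  fit_cascade(
    d,
    list(
      error ~ generation + (1 + generation | chain) + (1 | seq_id),
      error ~ generation + (1 | chain) + (1 | seq_id),
      error ~ generation + (1 | chain)
    ),
    error ~ generation,
    response = "error", term = "generation"
  )
}

#' Trend of mean unit length over generations
#'
#' Fixed effect for generation; random intercept and by-chain slope for
#' chain. Optionally excludes the generation-0 random sets.
#'
#' @param metrics A per-generation metrics tibble from [generation_metrics()]
#'   (needs `chain`, `generation`, `mean_unit_length`).
#' @param include_generation0 Keep the initial random sets in the fit?
#' @return A `trend_fit` for the generation slope.
#' @export
fit_unit_length_trend <- function(metrics, include_generation0 = TRUE) {
  d <- metrics
  if (!include_generation0) d <- dplyr::filter(d, .data$generation > 0)
  d <- dplyr::mutate(d, chain = factor(.data$chain))
  fit_cascade(
    d,
    list(
      mean_unit_length ~ generation + (1 + generation | chain),
      mean_unit_length ~ generation + (1 | chain)
    ),
    mean_unit_length ~ generation,
    response = "mean_unit_length", term = "generation"
  )
}

#' Interaction of TP type (within/between) with generation
#'
#' Predicts each transitional probability from generation, its type (within
#' a unit vs between units; `between` is the reference level) and their
#' interaction, with a random intercept and by-chain generation slope. The
#' headline coefficient is the interaction: a positive value means
#' within-unit TPs rise faster over generations than between-unit TPs.
#'
#' @param tp_records A tibble from [classify_transitions()] (or stacked over
#'   generations): columns `chain`, `generation`, `tp`, `type`.
#' @return A `trend_fit` for the `generation:typewithin` interaction.
#' @export
fit_tp_interaction <- function(tp_records) {
  stopifnot(all(c("chain", "generation", "tp", "type") %in% names(tp_records)))
  d <- tp_records |>
    dplyr::mutate(
      chain = factor(.data$chain),
      type = factor(.data$type, levels = c("between", "within"))
    )
  fit_cascade(
    d,
    list(
      tp ~ generation * type + (1 + generation | chain),
      tp ~ generation * type + (1 | chain)
    ),
    tp ~ generation * type,
    response = "tp", term = "generation:typewithin"
  )
}

#' Trend of Zipfian fit (R-squared) over generations
#'
#' Generation 0 is removed before fitting: for many chains the initial unit
#' distribution is completely flat and the log-log correlation is not
#' computable, so those sets carry no Zipf fit. Remaining `NA` values are
#' dropped.
#'
#' @inheritParams fit_unit_length_trend
#' @return A `trend_fit` for the generation slope.
#' @export
fit_r2_trend <- function(metrics) {
  d <- metrics |>
    dplyr::filter(.data$generation > 0, !is.na(.data$zipf_r2)) |>
    dplyr::mutate(chain = factor(.data$chain))
  fit_cascade(
    d,
    list(
      zipf_r2 ~ generation + (1 + generation | chain),
      zipf_r2 ~ generation + (1 | chain)
    ),
    zipf_r2 ~ generation,
    response = "zipf_r2", term = "generation"
  )
}

#' Trend of unit entropy over generations, controlling for inventory size
#'
#' Fixed effects for generation and the number of distinct units, with a
#' random intercept for chain (by-chain slopes are prone to singular fits on
#' this response and are not attempted; the size covariate ensures the
#' generation effect is not driven by shrinking inventories).
#'
#' @inheritParams fit_unit_length_trend
#' @return A `trend_fit` for the generation slope; the inventory-size
#'   coefficient is in `$coefficients` (term `n_distinct_units`).
#' @export
fit_entropy_trend <- function(metrics) {
  d <- dplyr::mutate(metrics, chain = factor(.data$chain))
  fit_cascade(
    d,
    list(
      entropy_bits ~ generation + n_distinct_units + (1 | chain)
    ),
    entropy_bits ~ generation + n_distinct_units,
    response = "entropy_bits", term = "generation"
  )
}

#' Tidy a generation-trend fit
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return A tibble of fixed-effect coefficients: `term`, `estimate`,
#'   `std_error`, `df`, `statistic`, `p_value`.
#' @method tidy trend_fit
#' @export
#' @importFrom generics tidy
tidy.trend_fit <- function(x, ...) {
  x$coefficients
}

#' One-row summary of a generation-trend fit
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `response`, `term`, `beta`, `se`, `p_value`,
#'   `singular`, `fallback_level`, `nobs`, `formula`.
#' @method glance trend_fit
#' @export
#' @importFrom generics glance
glance.trend_fit <- function(x, ...) {
  nobs <- tryCatch(stats::nobs(x$fit), error = function(e) NA_integer_)
  tibble::tibble(
    response = x$response,
    term = x$term,
    beta = x$beta,
    se = x$se,
    p_value = x$p_value,
    singular = x$singular,
    fallback_level = x$fallback_level,
    nobs = as.integer(nobs),
    formula = paste(deparse(x$formula), collapse = " ")
  )
}

#' @export
generics::tidy

#' @export
generics::glance

#' Fit all five generation-trend models of a chain dataset
#'
#' Convenience wrapper running the error, unit-length (with and without
#' generation 0), TP-interaction, Zipf-R2 and entropy trend models, plus the
#' participant-level entropy-error correlation.
#'
#' @inheritParams generation_metrics
#' @param metrics Optional precomputed [generation_metrics()] result.
#' @return A list with elements `error`, `unit_length`, `unit_length_no_gen0`,
#'   `tp_interaction`, `zipf_r2`, `entropy` (all `trend_fit`) and
#'   `entropy_error` (a one-row correlation tibble).
#' @export
fit_all_trends <- function(dataset, threshold, metrics = NULL) {
  if (is.null(metrics)) metrics <- generation_metrics(dataset, threshold)
  tp_records <- generation_sets(dataset) |>
    dplyr::group_split(.data$chain, .data$generation) |>
    purrr::map_dfr(function(g) classify_transitions(g, threshold))
  list(
    error = fit_error_trend(copy_errors(dataset)),
    unit_length = fit_unit_length_trend(metrics, include_generation0 = TRUE),
    unit_length_no_gen0 = fit_unit_length_trend(metrics, include_generation0 = FALSE),
    tp_interaction = fit_tp_interaction(tp_records),
    zipf_r2 = fit_r2_trend(metrics),
    entropy = fit_entropy_trend(metrics),
    entropy_error = entropy_error_correlation(participant_records(dataset, threshold))
  )
}
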