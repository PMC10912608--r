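# Emergence diagnostics: unit length, within/between transitional
# probabilities, rank-frequency structure, Zipf R-squared, entropy, and the
# entropy-error relation.

check_inventory <- function(inventory) {
  if (!is.data.frame(inventory) ||
      !all(c("unit", "count") %in% names(inventory)) ||
      nrow(inventory) == 0) {
    stop("`inventory` must be a non-empty tibble with columns `unit` and `count`",
      call. = FALSE
    )
  }
  invisible(inventory)
}

#' Token-weighted mean unit length
#'
#' Average length of all unit tokens in an inventory; identical units are
#' counted once per occurrence.
#'
#' @param inventory A unit inventory tibble (`unit`, `count`), e.g. from
#'   [build_inventory()].
#' @return A single number.
#' @export
mean_unit_length <- function(inventory) {
  check_inventory(inventory)
  sum(inventory$count * nchar(inventory$unit)) / sum(inventory$count)
}

#' Classify each transitional probability as within- or between-unit
#'
#' After segmentation, the TP at a boundary position (the transition that
#' crosses a cut) is "between"; every other TP is "within". For a sequence
#' segmented as RYG | R, P(G | R,Y) is within a unit while P(R | Y,G) is
#' between units. Each sequence of length L contributes exactly its L - 2
#' transitional probabilities.
#'
#' @inheritParams segment_set
#' @return A tibble with one row per TP: `chain`, `generation`, `index`,
#'   `position`, `tp`, `type` (factor, levels `between` < `within`).
#' @export
classify_transitions <- function(set, threshold, model = NULL) {
  if (!is.data.frame(set)) {
    set <- new_sequence_set(seqs_from(set), chain_id = 1L, generation = 0L)
  }
  if (is.null(model)) model <- estimate_transition_model(set$sequence)
  theta <- as_theta(threshold)
  keep <- set[nchar(set$sequence) >= 3, , drop = FALSE]
  purrr::pmap_dfr(
    keep[c("chain", "generation", "index", "sequence")],
    function(chain, generation, index, sequence) {
      prof <- ratio_profile(sequence, model)
      boundary <- !is.na(prof$ratio) & prof$ratio < theta
      tibble::tibble(
        chain = chain, generation = generation, index = index,
        position = prof$position, tp = prof$tp,
        type = factor(
          ifelse(boundary, "between", "within"),
          levels = c("between", "within")
        )
      )
    }
  )
}

#' Rank-frequency table of a unit inventory
#'
#' Unit types sorted by descending token frequency, ranked 1..K; ties are
#' broken by lexicographic order on the unit string (stable and documented;
#' tied ranks share a frequency by definition, so downstream log-log fits do
#' not depend on the tie order beyond the rank values themselves).
#'
#' @inheritParams mean_unit_length
#' @return A tibble with columns `rank`, `unit`, `frequency`.
#' @export
rank_frequency <- function(inventory) {
  check_inventory(inventory)
  inventory |>
    dplyr::arrange(dplyr::desc(.data$count), .data$unit) |>
    dplyr::transmute(
      rank = dplyr::row_number(),
      unit = .data$unit,
      frequency = .data$count
    )
}

#' Fit quality of the Zipfian rank-frequency relation
#'
#' The squared Pearson correlation between log(frequency) and log(rank):
#' 1 for an exact power law, lower for flatter or irregular distributions.
#' Base-independent. When all frequencies are equal (a completely flat
#' distribution, typical of random initial sets) the correlation is
#' undefined and `NA` is returned; such sets are dropped from trend fits.
#'
#' @param rank_freq A rank-frequency tibble from [rank_frequency()] (or any
#'   tibble with `rank` and `frequency` columns).
#' @return A single number in \[0, 1\], or `NA_real_` when not computable.
#' @export
zipf_r2 <- function(rank_freq) {
  if (!all(c("rank", "frequency") %in% names(rank_freq))) {
    stop("`rank_freq` must have `rank` and `frequency` columns", call. = FALSE)
  }
  f <- rank_freq$frequency
  if (length(f) < 2 || length(unique(f)) == 1) return(NA_real_)
  stats::cor(log(f), log(rank_freq$rank))^2
}

#' Shannon entropy of a unit inventory
#'
#' Entropy (in bits) of the unit-token relative frequencies: a direct
#' measure of how skewed the lexicon's frequency distribution is. A uniform
#' distribution over K types attains the maximum log2(K); a single type has
#' entropy 0.
#'
#' @inheritParams mean_unit_length
#' @return Entropy in bits (>= 0).
#' @export
unit_entropy <- function(inventory) {
  check_inventory(inventory)
  p <- inventory$count / sum(inventory$count)
  -sum(p * log2(p))
}

#' Correlation between input-set entropy and copying error
#'
#' Each participant contributes one point: the entropy of the unit
#' distribution of the set they were exposed to, and their mean copying
#' error on reproducing it. A positive correlation means more skewed
#' (lower-entropy) sets are easier to copy.
#'
#' @param records A tibble with columns `entropy` (of the input set) and
#'   `error` (the participant's mean normalised Levenshtein error); one row
#'   per participant. At least 3 rows, with variance in both variables.
#' @return A one-row tibble: `r`, `p_value`, `n`, `conf_low`, `conf_high`.
#' @export
entropy_error_correlation <- function(records) {
  if (!all(c("entropy", "error") %in% names(records))) {
    stop("`records` must have `entropy` and `error` columns", call. = FALSE)
  }
  records <- records[stats::complete.cases(records[c("entropy", "error")]), ]
  if (nrow(records) < 3) {
    stop("need at least 3 complete participant records", call. = FALSE)
  }
  if (sd(records$entropy) == 0 || sd(records$error) == 0) {
    stop("correlation undefined: zero variance in entropy or error",
      call. = FALSE
    )
  }
  ct <- cor.test(records$entropy, records$error)
  tibble::tibble(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = nrow(records),
    conf_low = ct$conf.int[1],
    conf_high = ct$conf.int[2]
  )
}

#' Per-participant entropy/error records from a chain dataset
#'
#' For every participant (chain x generation >= 1): the unit entropy of the
#' set they saw (the previous generation's set, segmented under the global
#' threshold) paired with their mean copying error.
#'
#' @inheritParams copy_errors
#' @param threshold A `cut_threshold` or numeric theta.
#' @return A tibble with columns `chain`, `generation`, `entropy`, `error`.
#' @export
participant_records <- function(dataset, threshold) {
  sets <- generation_sets(dataset)
  errs <- copy_errors(dataset) |>
    dplyr::summarise(
      error = mean(.data$error),
      .by = c("chain", "generation")
    )
  input_entropy <- sets |>
    dplyr::group_split(.data$chain, .data$generation) |>
    purrr::map_dfr(function(g) {
      tibble::tibble(
        chain = g$chain[1],
        generation = g$generation[1] + 1L, # this set is the next one's input
        entropy = unit_entropy(build_inventory(g, threshold))
      )
    })
  dplyr::inner_join(input_entropy, errs, by = c("chain", "generation")) |>
    dplyr::select("chain", "generation", "entropy", "error")
}

#' Per-generation emergence metrics for every chain
#'
#' Segments each chain x generation set under one global threshold and
#' reports the full panel of emergence diagnostics: token-weighted mean unit
#' length, mean within- and between-unit TPs, number of distinct units,
#' Zipf R-squared (NA for flat distributions), unit entropy in bits, and the
#' set's mean copying error (NA at generation 0, which has no targets).
#'
#' @inheritParams copy_errors
#' @param threshold A `cut_threshold` or numeric theta applied to every set.
#' @return A tibble with one row per chain x generation.
#' @export
generation_metrics <- function(dataset, threshold) {
  check_chain_dataset(dataset)
  sets <- generation_sets(dataset)
  errs <- copy_errors(dataset) |>
    dplyr::summarise(set_error = mean(.data$error), .by = c("chain", "generation"))
  rows <- sets |>
    dplyr::group_split(.data$chain, .data$generation) |>
    purrr::map_dfr(function(g) {
      model <- estimate_transition_model(g$sequence)
      inv <- build_inventory(g, threshold, model = model)
      tps <- classify_transitions(g, threshold, model = model)
      tibble::tibble(
        chain = g$chain[1],
        generation = g$generation[1],
        mean_unit_length = mean_unit_length(inv),
        mean_within_tp = mean(tps$tp[tps$type == "within"]),
        mean_between_tp = if (any(tps$type == "between")) {
          mean(tps$tp[tps$type == "between"])
        } else {
          NA_real_
        },
        n_distinct_units = nrow(inv),
        zipf_r2 = zipf_r2(rank_frequency(inv)),
        entropy_bits = unit_entropy(inv)
      )
    })
  out <- dplyr::left_join(rows, errs, by = c("chain", "generation")) |>
    dplyr::arrange(.data$chain, .data$generation)
  class(out) <- c("partseq_metrics", class(out))
  out
}

#' Unit inventories for every chain x generation
#'
#' @inheritParams generation_metrics
#' @return A tibble with columns `chain`, `generation`, `unit`, `count`.
#' @export
generation_inventories <- function(dataset, threshold) {
  generation_sets(dataset) |>
    dplyr::group_split(.data$chain, .data$generation) |>
    purrr::map_dfr(function(g) {
      build_inventory(g, threshold) |>
        dplyr::mutate(
          chain = g$chain[1], generation = g$generation[1],
          .before = 1
        )
    })
}
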