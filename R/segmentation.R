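# Trigram transitional-probability models and ratio-dip segmentation.
#
# The segmentation cue is relative: a boundary is posited where the ratio of
# a position's transitional probability to the previous position's is
# unusually low, "unusually" being calibrated as the lower-tail quantile of
# the ratio distribution found in unstructured random baseline sets.

seqs_from <- function(x, arg = "set") {
  if (is.data.frame(x)) {
    if (!"sequence" %in% names(x)) {
      stop(sprintf("`%s` must have a `sequence` column", arg), call. = FALSE)
    }
    x <- x$sequence
  }
  check_sequences(x, arg = arg)
  x
}

# overlapping windows of width `w` within one string; character(0) if too short
windows <- function(s, w) {
  L <- nchar(s)
  if (L < w) return(character(0))
  substring(s, 1:(L - w + 1), w:L)
}

#' Estimate a trigram transitional-probability model from a sequence set
#'
#' Maximum-likelihood estimates of P(c3 | c1, c2) over a whole set: the count
#' of the trigram c1c2c3 divided by the count of occurrences of the context
#' c1c2 that have some continuation. Windows are taken at every offset within
#' a sequence and never span sequence ends. Sequences shorter than 3 symbols
#' contribute no trigrams and are excluded with a warning.
#'
#' @param set A sequence-set tibble (with a `sequence` column) or a character
#'   vector of sequences.
#' @return An object of class `transition_model`: a list with named count
#'   vectors `trigram_counts` and `context_counts`, the named probability
#'   vector `tp`, and bookkeeping fields `n_sequences` and `n_excluded`.
#' @export
#' @examples
#' m <- estimate_transition_model(c("RGRG", "RGRB"))
#' m$tp[["RGR"]] # P(R | R,G) = 1
estimate_transition_model <- function(set) {
  seqs <- seqs_from(set)
  short <- nchar(seqs) < 3
  if (any(short)) {
    rlang::warn(sprintf(
      "%d sequence(s) shorter than 3 symbols excluded from transition counting",
      sum(short)
    ))
  }
  used <- seqs[!short]
  if (length(used) == 0) {
    stop("no sequences of length >= 3; cannot estimate a trigram model",
      call. = FALSE
    )
  }
  trigrams <- unlist(lapply(used, windows, w = 3), use.names = FALSE)
  tri_tab <- table(trigrams)
  trigram_counts <- setNames(as.integer(tri_tab), names(tri_tab))
  # a context is a bigram occurrence that has a continuation, i.e. the first
  # two symbols of each trigram window
  ctx_tab <- table(substr(trigrams, 1, 2))
  context_counts <- setNames(as.integer(ctx_tab), names(ctx_tab))
  tp <- trigram_counts / context_counts[substr(names(trigram_counts), 1, 2)]
  names(tp) <- names(trigram_counts)
  structure(
    list(
      trigram_counts = trigram_counts,
      context_counts = context_counts,
      tp = tp,
      n_sequences = length(used),
      n_excluded = sum(short)
    ),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf(
    "<transition_model: %d sequences, %d trigram types, %d contexts>\n",
    x$n_sequences, length(x$trigram_counts), length(x$context_counts)
  ))
  invisible(x)
}

#' Transitional probabilities and consecutive ratios along one sequence
#'
#' For a sequence s of length L, the transitional probability at position i
#' (3 <= i <= L, 1-based) is P(s_i | s_{i-2}, s_{i-1}) under `model`; the
#' ratio at position i (i >= 4) divides that probability by the one at the
#' previous position. Ratios below 1 mark drops in transitional probability.
#'
#' @param sequence A single sequence string.
#' @param model A `transition_model`, estimated from a set containing
#'   `sequence` (an unseen trigram is an error).
#' @return A tibble with one row per position 3..L: columns `position`, `tp`,
#'   and `ratio` (`NA` at position 3). Zero rows if the sequence is shorter
#'   than 3.
#' @export
ratio_profile <- function(sequence, model) {
  stopifnot(inherits(model, "transition_model"))
  check_sequences(sequence, arg = "sequence")
  if (length(sequence) != 1) {
    stop("`sequence` must be a single string", call. = FALSE)
  }
  L <- nchar(sequence)
  if (L < 3) {
    return(tibble::tibble(
      position = integer(0), tp = double(0), ratio = double(0)
    ))
  }
  tri <- windows(sequence, 3)
  tp <- unname(model$tp[tri])
  if (anyNA(tp)) {
    stop(sprintf(
      "sequence contains trigram(s) not present in the model (e.g. %s); estimate the model from a set containing this sequence",
      tri[which(is.na(tp))[1]]
    ), call. = FALSE)
  }
  tibble::tibble(
    position = 3:L,
    tp = tp,
    ratio = c(NA_real_, tp[-1] / tp[-length(tp)])
  )
}

#' Pool consecutive-TP ratios across baseline sets
#'
#' For each set (a `chain` x `generation` group), estimates its own trigram
#' model and computes every sequence's consecutive-TP ratios; all ratios are
#' then pooled. This is the aggregated baseline distribution the cutting
#' threshold is drawn from.
#'
#' @param sets A tibble of stacked sequence sets (columns `chain`,
#'   `generation`, `sequence`) or a character vector treated as one set.
#' @return A numeric vector of pooled ratios.
#' @export
pooled_tp_ratios <- function(sets) {
  if (!is.data.frame(sets)) {
    sets <- new_sequence_set(seqs_from(sets), chain_id = 1L, generation = 0L)
  }
  groups <- dplyr::group_split(sets, .data$chain, .data$generation)
  unlist(purrr::map(groups, function(g) {
    model <- estimate_transition_model(g$sequence)
    long <- g$sequence[nchar(g$sequence) >= 4]
    unlist(purrr::map(long, function(s) {
      r <- ratio_profile(s, model)$ratio
      r[!is.na(r)]
    }))
  }), use.names = FALSE)
}

#' Calibrate the boundary-cutting threshold from random baselines
#'
#' The random initial sets have no sequential structure, so their
#' consecutive-TP ratio distribution shows how large a drop arises by chance
#' alone. The cutting threshold theta is the `tail` lower-tail empirical
#' quantile (linear interpolation between order statistics) of the ratios
#' pooled across all baseline sets; per-set models are estimated separately
#' before pooling. With six regenerated 60 x length-12 balanced sets the
#' threshold lands near 0.425.
#'
#' @param baseline_sets Stacked baseline sequence sets (tibble with `chain`,
#'   `generation`, `sequence`), each set one `chain` x `generation` group.
#' @param tail Lower-tail probability (default 0.05).
#' @return An object of class `cut_threshold`: list with `theta`, `tail`,
#'   `n_ratios`, and `provenance` (the chain ids of the baseline sets).
#' @export
#' @examples
#' base <- generate_initial_sets(n_chains = 2, n_sequences = 20, seed = 1)
#' calibrate_threshold(base)
calibrate_threshold <- function(baseline_sets, tail = 0.05) {
  if (!is.numeric(tail) || length(tail) != 1 || tail < 0 || tail >= 1) {
    stop("`tail` must be a single probability in [0, 1)", call. = FALSE)
  }
  ratios <- pooled_tp_ratios(baseline_sets)
  if (length(ratios) == 0) {
    stop("no pooled ratios: baseline sets contain no sequence of length >= 4",
      call. = FALSE
    )
  }
  theta <- if (tail == 0) min(ratios) else quantile(ratios, tail, names = FALSE)
  provenance <- if (is.data.frame(baseline_sets)) {
    unique(baseline_sets$chain)
  } else {
    NA
  }
  structure(
    list(
      theta = theta, tail = tail,
      n_ratios = length(ratios), provenance = provenance
    ),
    class = "cut_threshold"
  )
}

#' @export
print.cut_threshold <- function(x, ...) {
  cat(sprintf(
    "<cut_threshold: theta = %.4f (%.0f%% lower tail of %d baseline ratios)>\n",
    x$theta, 100 * x$tail, x$n_ratios
  ))
  invisible(x)
}

as_theta <- function(threshold) {
  if (inherits(threshold, "cut_threshold")) return(threshold$theta)
  if (is.numeric(threshold) && length(threshold) == 1 && threshold >= 0) {
    return(threshold)
  }
  stop("`threshold` must be a `cut_threshold` or a single non-negative number",
    call. = FALSE
  )
}

#' Segment one sequence at sub-threshold TP-ratio dips
#'
#' Places a boundary immediately before every 1-based position whose
#' consecutive-TP ratio falls strictly below the threshold; units are the
#' maximal runs between boundaries. Because the ratio at position i compares
#' the TPs at i and i-1, the earliest possible boundary is before the fourth
#' element; a sequence with no sub-threshold ratio stays one single unit.
#'
#' @inheritParams ratio_profile
#' @param threshold A `cut_threshold` or a bare numeric theta.
#' @return A list with `sequence`, integer `boundaries` (positions b meaning
#'   a cut before element b), and character `units` whose concatenation
#'   reproduces the sequence.
#' @export
segment_sequence <- function(sequence, model, threshold) {
  theta <- as_theta(threshold)
  L <- nchar(sequence)
  if (L < 4) {
    # too short for any ratio: kept whole
    check_sequences(sequence, arg = "sequence")
    return(list(sequence = sequence, boundaries = integer(0), units = sequence))
  }
  prof <- ratio_profile(sequence, model)
  b <- prof$position[!is.na(prof$ratio) & prof$ratio < theta]
  starts <- c(1L, b)
  ends <- c(b - 1L, L)
  list(
    sequence = sequence,
    boundaries = as.integer(b),
    units = substring(sequence, starts, ends)
  )
}

#' Segment every sequence in a set
#'
#' @param set A sequence-set tibble (columns `chain`, `generation`, `index`,
#'   `sequence`) or character vector.
#' @param model A `transition_model`; estimated from `set` itself when `NULL`.
#' @inheritParams segment_sequence
#' @return A tibble with one row per unit token: `chain`, `generation`,
#'   `index`, `unit_start` (1-based offset of the unit in its sequence) and
#'   `unit`.
#' @export
segment_set <- function(set, threshold, model = NULL) {
  if (!is.data.frame(set)) {
    set <- new_sequence_set(seqs_from(set), chain_id = 1L, generation = 0L)
  }
  if (is.null(model)) model <- estimate_transition_model(set$sequence)
  theta <- as_theta(threshold)
  purrr::pmap_dfr(
    set[c("chain", "generation", "index", "sequence")],
    function(chain, generation, index, sequence) {
      seg <- segment_sequence(sequence, model, theta)
      tibble::tibble(
        chain = chain, generation = generation, index = index,
        unit_start = c(1L, seg$boundaries), unit = seg$units
      )
    }
  )
}

#' Build the unit inventory ("lexicon") of a sequence set
#'
#' Segments every sequence and counts unit tokens: the emergent lexicon of
#' one generation in one chain. Token counts conserve total length:
#' sum(count * nchar(unit)) equals the summed sequence lengths.
#'
#' @inheritParams segment_set
#' @return A tibble with columns `unit` and `count`, sorted by decreasing
#'   count with ties in lexicographic unit order.
#' @export
build_inventory <- function(set, threshold, model = NULL) {
  units <- segment_set(set, threshold, model = model)
  units |>
    dplyr::count(.data$unit, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$unit)
}
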