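# Synthetic data: random baselines come from generate_initial_set(); this
# file adds planted-lexicon sets with known boundaries (ground truth for
# segmentation checks) and a chunk-based noisy-recall agent iterated over
# transmission chains (a qualitative emergence demonstrator, not a cognitive
# model of human participants).

#' Construct a planted lexicon
#'
#' A known set of units with sampling weights, used to generate sequence
#' sets whose true boundaries are recorded. The default weights are
#' Zipfian over ranks: weight of the k-th unit proportional to k^(-s).
#'
#' @param units Character vector of unit strings over the colour alphabet.
#' @param probabilities Optional sampling weights (normalised internally);
#'   defaults to a Zipfian distribution with exponent `zipf_exponent`.
#' @param zipf_exponent Exponent s of the default rank weights.
#' @return An object of class `planted_lexicon`.
#' @export
#' @examples
#' planted_lexicon(c("RGB", "YB", "RRG"))
planted_lexicon <- function(units, probabilities = NULL, zipf_exponent = 1) {
  check_sequences(units, arg = "units")
  if (anyDuplicated(units)) stop("`units` must be distinct", call. = FALSE)
  if (is.null(probabilities)) {
    probabilities <- seq_along(units)^(-zipf_exponent)
  }
  if (length(probabilities) != length(units) || any(probabilities <= 0)) {
    stop("`probabilities` must be positive, one per unit", call. = FALSE)
  }
  structure(
    list(units = units, probabilities = probabilities / sum(probabilities)),
    class = "planted_lexicon"
  )
}

#' @export
print.planted_lexicon <- function(x, ...) {
  cat(sprintf(
    "<planted_lexicon: %d units, p = %s>\n",
    length(x$units), paste(sprintf("%.3f", x$probabilities), collapse = " ")
  ))
  invisible(x)
}

#' Generate a sequence set by concatenating planted units
#'
#' Each sequence is built by sampling units i.i.d. from the lexicon and
#' concatenating them until appending the next sampled unit would exceed
#' `target_length` (so final lengths lie in
#' \[target_length - max unit length + 1, target_length\]). True boundary
#' positions (1-based position of each unit start after the first) are
#' recorded per sequence.
#'
#' @param lexicon A [planted_lexicon()].
#' @param n_sequences Number of sequences.
#' @param target_length Length cap per sequence; at least the shortest unit.
#' @param seed Optional integer seed.
#' @param chain_id,generation Metadata for the resulting set.
#' @return A sequence-set tibble with an extra list-column
#'   `true_boundaries`.
#' @export
generate_planted_set <- function(lexicon, n_sequences, target_length,
                                 seed = NULL, chain_id = 1L, generation = 0L) {
  stopifnot(inherits(lexicon, "planted_lexicon"))
  lens <- nchar(lexicon$units)
  if (min(lens) > target_length) {
    stop("`target_length` is shorter than every unit in the lexicon",
      call. = FALSE
    )
  }
  with_seed(seed, {
    rows <- purrr::map(seq_len(n_sequences), function(i) {
      parts <- character(0)
      total <- 0L
      repeat {
        u <- sample(lexicon$units, 1, prob = lexicon$probabilities)
        if (total + nchar(u) > target_length) {
          if (total == 0L) next # first unit must fit; resample
          break
        }
        parts <- c(parts, u)
        total <- total + nchar(u)
      }
      list(
        sequence = paste(parts, collapse = ""),
        boundaries = if (length(parts) > 1) {
          as.integer(cumsum(nchar(parts))[-length(parts)] + 1L)
        } else {
          integer(0)
        }
      )
    })
    out <- new_sequence_set(
      purrr::map_chr(rows, "sequence"),
      chain_id = chain_id, generation = generation
    )
    out$true_boundaries <- purrr::map(rows, "boundaries")
    out
  })
}

#' Precision and recall of inferred segmentation boundaries
#'
#' Micro-averaged over sequences: precision is the share of inferred
#' boundaries that are true, recall the share of true boundaries recovered.
#' A denominator of zero (no inferred, or no true, boundaries) yields `NA`
#' for the affected measure.
#'
#' @param true_boundaries,inferred_boundaries Lists of integer vectors, one
#'   per sequence, in the same sequence order.
#' @return A one-row tibble: `precision`, `recall`, `n_true`, `n_inferred`,
#'   `n_hit`.
#' @export
boundary_recovery <- function(true_boundaries, inferred_boundaries) {
  if (length(true_boundaries) != length(inferred_boundaries)) {
    stop("boundary lists must cover the same sequences", call. = FALSE)
  }
  hits <- sum(purrr::map2_int(
    true_boundaries, inferred_boundaries,
    function(t, i) length(intersect(t, i))
  ))
  n_true <- sum(lengths(true_boundaries))
  n_inf <- sum(lengths(inferred_boundaries))
  tibble::tibble(
    precision = if (n_inf > 0) hits / n_inf else NA_real_,
    recall = if (n_true > 0) hits / n_true else NA_real_,
    n_true = n_true, n_inferred = n_inf, n_hit = hits
  )
}

#' Parameters of the chunk-based noisy-recall agent
#'
#' The agent segments the set it is exposed to (with the supplied cutting
#' threshold), stores the resulting unit inventory, and reproduces each
#' target as the tiling given by its segmentation. Per-symbol noise
#' (substitution, deletion, insertion) is attenuated for symbols inside
#' chunks the agent has seen often: a chunk with inventory token count c has
#' each of its noise rates divided by 1 + frequency_boost * (c - 1). With
#' `chunk_learning = FALSE` the agent applies uniform noise with no
#' segmentation, a null control.
#'
#' @param substitution,deletion,insertion Per-symbol base noise rates in
#'   \[0, 1\].
#' @param frequency_boost Strength (>= 0) of the frequency-fidelity link;
#'   0 disables it.
#' @param chunk_learning Whether the agent segments and uses chunk
#'   frequencies at all.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(substitution = 0.30, deletion = 0.15,
                         insertion = 0.05, frequency_boost = 12,
                         chunk_learning = TRUE) {
  rates <- c(substitution = substitution, deletion = deletion, insertion = insertion)
  if (any(rates < 0 | rates > 1)) {
    stop("noise rates must lie in [0, 1]", call. = FALSE)
  }
  if (frequency_boost < 0) stop("`frequency_boost` must be >= 0", call. = FALSE)
  structure(
    list(
      substitution = substitution, deletion = deletion, insertion = insertion,
      frequency_boost = frequency_boost, chunk_learning = isTRUE(chunk_learning)
    ),
    class = "agent_params"
  )
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(
    "<agent_params: sub %.3f del %.3f ins %.3f boost %.2f chunks %s>\n",
    x$substitution, x$deletion, x$insertion, x$frequency_boost,
    if (x$chunk_learning) "on" else "off"
  ))
  invisible(x)
}

# one noisy emission of `sequence`, with per-symbol attenuation factors
noisy_emit <- function(sequence, atten, params, alphabet) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (j in seq_along(ch)) {
    a <- atten[j]
    if (runif(1) < params$deletion / a) next
    sym <- ch[j]
    if (runif(1) < params$substitution / a) {
      sym <- sample(setdiff(alphabet, sym), 1)
    }
    out <- c(out, sym)
    if (runif(1) < params$insertion / a) {
      out <- c(out, sample(alphabet, 1))
    }
  }
  paste(out, collapse = "")
}

#' Simulate one participant copying a sequence set
#'
#' Builds the agent's chunk inventory from the whole input set (via
#' segmentation at `threshold`), then reproduces each target with per-symbol
#' noise attenuated inside high-frequency chunks. Responses shorter than 6
#' symbols trigger one re-presentation of that target (the second attempt is
#' final); empty emissions are redrawn.
#'
#' @param input_set A sequence-set tibble (the targets the participant sees).
#' @param params An [agent_params()].
#' @param threshold A `cut_threshold` or numeric theta used by the agent's
#'   segmentation.
#' @param seed Optional integer seed.
#' @return A tibble like `input_set` with `generation` advanced by one and
#'   `sequence` replaced by the responses (row order preserved, so responses
#'   stay aligned to their targets by `index`).
#' @export
simulate_participant <- function(input_set, params, threshold, seed = NULL) {
  stopifnot(inherits(params, "agent_params"))
  seqs <- seqs_from(input_set)
  alphabet <- colour_alphabet()
  theta <- as_theta(threshold)

  segs <- NULL
  counts <- NULL
  if (params$chunk_learning) {
    model <- estimate_transition_model(seqs)
    segs <- purrr::map(seqs, segment_sequence, model = model, threshold = theta)
    inv <- segment_set(
      new_sequence_set(seqs, chain_id = 1L, generation = 0L), theta,
      model = model
    ) |>
      dplyr::count(.data$unit, name = "count")
    counts <- setNames(inv$count, inv$unit)
  }

  attenuation <- function(k) {
    if (!params$chunk_learning) {
      return(rep(1, nchar(seqs[k])))
    }
    units <- segs[[k]]$units
    c_per_unit <- counts[units]
    c_per_unit[is.na(c_per_unit)] <- 1L
    rep(1 + params$frequency_boost * (c_per_unit - 1), nchar(units))
  }

  with_seed(seed, {
    responses <- vapply(seq_along(seqs), function(k) {
      att <- attenuation(k)
      r <- noisy_emit(seqs[k], att, params, alphabet)
      if (nchar(r) < 6) {
        # target re-presented once at the end of the block
        r2 <- noisy_emit(seqs[k], att, params, alphabet)
        if (nchar(r2) > 0) r <- r2
      }
      tries <- 0
      while (nchar(r) == 0 && tries < 25) {
        r <- noisy_emit(seqs[k], att, params, alphabet)
        tries <- tries + 1
      }
      if (nchar(r) == 0) r <- seqs[k] # pathological rates: echo the target
      r
    }, character(1))
    out <- input_set
    if (!is.data.frame(out)) {
      out <- new_sequence_set(seqs, chain_id = 1L, generation = 0L)
    }
    out$sequence <- responses
    out$generation <- out$generation + 1L
    out
  })
}

#' Run one iterated-learning transmission chain
#'
#' Starting from an initial set, each generation's responses become the next
#' generation's targets, with presentation order shuffled between
#' participants; the agent's transition model is re-estimated from the
#' current set every generation. The cutting threshold is either the global
#' one supplied (the default, matching an analysis calibrated once on
#' generation-0 baselines) or recalibrated each generation from the current
#' set's own ratio distribution (`threshold_policy = "per_generation"`).
#'
#' @param initial_set A generation-0 sequence-set tibble for one chain.
#' @param n_generations Number of participants in the chain (default 10).
#' @param params An [agent_params()].
#' @param threshold A `cut_threshold` or numeric theta.
#' @param threshold_policy `"global"` or `"per_generation"`.
#' @param seed Optional integer seed for the whole chain.
#' @return A chain dataset tibble (`chain`, `generation`, `index`, `target`,
#'   `response`): one generation-0 row per initial sequence (`response` NA)
#'   plus one row per copied sequence thereafter. `index` tracks the lineage
#'   of the original sequence.
#' @export
run_transmission_chain <- function(initial_set, n_generations = 10,
                                   params = agent_params(), threshold,
                                   threshold_policy = c("global", "per_generation"),
                                   seed = NULL) {
  threshold_policy <- match.arg(threshold_policy)
  stopifnot(is.data.frame(initial_set), "sequence" %in% names(initial_set))
  tail <- if (inherits(threshold, "cut_threshold")) threshold$tail else 0.05
  theta <- as_theta(threshold)

  with_seed(seed, {
    rows <- list(tibble::tibble(
      chain = initial_set$chain,
      generation = 0L,
      index = initial_set$index,
      target = initial_set$sequence,
      response = NA_character_
    ))
    current <- initial_set[c("chain", "generation", "index", "sequence")]
    for (g in seq_len(n_generations)) {
      shuffled <- current[sample(nrow(current)), ]
      if (threshold_policy == "per_generation") {
        theta <- quantile(pooled_tp_ratios(shuffled$sequence), tail, names = FALSE)
      }
      produced <- simulate_participant(shuffled, params, theta)
      rows[[g + 1L]] <- tibble::tibble(
        chain = shuffled$chain,
        generation = as.integer(g),
        index = shuffled$index,
        target = shuffled$sequence,
        response = produced$sequence
      )
      current <- produced
    }
    dplyr::bind_rows(rows) |>
      dplyr::arrange(.data$generation, .data$index)
  })
}

#' Simulate a full multi-chain iterated-learning experiment
#'
#' Generates one random balanced initial set per chain, calibrates the
#' global cutting threshold from those baselines, and runs every chain for
#' `n_generations` generations. The default design matches the experiment:
#' 6 chains x (1 initial + 10 produced) x 60 sequences of initial length 12.
#'
#' @param n_chains,n_generations,n_sequences,length Design constants.
#' @param params An [agent_params()].
#' @param tail Lower-tail probability for threshold calibration.
#' @param seed Optional integer seed covering the entire experiment.
#' @return A list with `dataset` (the combined chain dataset tibble),
#'   `threshold` (the global `cut_threshold`), and `initial_sets`.
#' @export
simulate_experiment <- function(n_chains = 6, n_generations = 10,
                                n_sequences = 60, length = 12,
                                params = agent_params(), tail = 0.05,
                                seed = NULL) {
  with_seed(seed, {
    initial <- generate_initial_sets(
      n_chains = n_chains, n_sequences = n_sequences, length = length
    )
    threshold <- calibrate_threshold(initial, tail = tail)
    dataset <- initial |>
      dplyr::group_split(.data$chain) |>
      purrr::map_dfr(function(s) {
        run_transmission_chain(
          s,
          n_generations = n_generations,
          params = params, threshold = threshold
        )
      })
    list(dataset = dataset, threshold = threshold, initial_sets = initial)
  })
}
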