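# Sequence sets, chain datasets, copying error, and file I/O.
#
# A sequence is a character string over the colour alphabet ("RGYB...").
# A sequence set is a tibble with columns chain, generation, index, sequence:
# the 60-sequence "language" one participant is exposed to. A chain dataset
# is a tibble with columns chain, generation, index, target, response, one
# row per sequence; generation-0 rows carry the random initial sequences in
# `target` and have NA `response`.

#' Validate a vector of colour sequences
#'
#' Checks that every element is a non-empty string whose characters are all
#' drawn from `alphabet`.
#'
#' @param x Character vector of sequences.
#' @param alphabet Character vector of allowed single-character symbols.
#' @param arg Name used in error messages.
#' @return `x`, invisibly.
#' @keywords internal
check_sequences <- function(x, alphabet = colour_alphabet(), arg = "sequences") {
  if (length(x) == 0 || !is.character(x)) {
    stop(sprintf("`%s` must be a non-empty character vector", arg), call. = FALSE)
  }
  if (anyNA(x) || any(nchar(x) == 0)) {
    stop(sprintf("`%s` contains empty or missing sequences", arg), call. = FALSE)
  }
  chars <- unique(unlist(strsplit(x, "", fixed = TRUE)))
  bad <- setdiff(chars, alphabet)
  if (length(bad) > 0) {
    stop(sprintf(
      "`%s` contains symbols outside the alphabet {%s}: %s",
      arg, paste(alphabet, collapse = ","), paste(bad, collapse = ",")
    ), call. = FALSE)
  }
  invisible(x)
}

# run code under a temporary RNG state; NULL seed leaves the RNG alone
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

new_sequence_set <- function(sequences, chain_id, generation) {
  tibble::tibble(
    chain = chain_id,
    generation = as.integer(generation),
    index = seq_along(sequences),
    sequence = sequences
  )
}

#' Generate a random initial (generation-0) sequence set
#'
#' Builds the unstructured baseline material a transmission chain starts
#' from: each sequence is an independent uniform-random permutation of the
#' balanced multiset containing `length / |alphabet|` copies of each colour,
#' so every colour is equally frequent within every sequence and there is no
#' sequential structure to exploit.
#'
#' @param n_sequences Number of sequences in the set (default 60, the set
#'   size each participant sees).
#' @param length Sequence length (default 12 lights).
#' @param alphabet Colour alphabet; `length` must be divisible by its size.
#' @param seed Optional integer seed; the same seed reproduces the same set.
#' @param chain_id Chain identifier stored in the `chain` column.
#' @return A tibble with columns `chain`, `generation` (all 0), `index`,
#'   `sequence`.
#' @export
#' @examples
#' generate_initial_set(n_sequences = 3, seed = 1)
generate_initial_set <- function(n_sequences = 60, length = 12,
                                 alphabet = colour_alphabet(), seed = NULL,
                                 chain_id = 1L) {
  if (n_sequences < 1) stop("`n_sequences` must be at least 1", call. = FALSE)
  if (length %% base::length(alphabet) != 0) {
    stop(sprintf(
      "`length` (%d) must be divisible by the alphabet size (%d) so that every colour can be equally frequent",
      length, base::length(alphabet)
    ), call. = FALSE)
  }
  balanced <- rep(alphabet, each = length / base::length(alphabet))
  seqs <- with_seed(seed, {
    vapply(seq_len(n_sequences),
      function(i) paste(sample(balanced), collapse = ""),
      character(1)
    )
  })
  new_sequence_set(seqs, chain_id = chain_id, generation = 0L)
}

#' Generate the initial sets for several chains
#'
#' One independent random balanced set per chain, as in the experimental
#' design (six chains, each with its own random initial set).
#'
#' @param n_chains Number of chains (default 6).
#' @param seed Optional integer seed governing all chains jointly.
#' @inheritParams generate_initial_set
#' @return A tibble of stacked generation-0 sequence sets, `chain` running
#'   `1:n_chains`.
#' @export
generate_initial_sets <- function(n_chains = 6, n_sequences = 60, length = 12,
                                  alphabet = colour_alphabet(), seed = NULL) {
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_chains), function(k) {
      generate_initial_set(
        n_sequences = n_sequences, length = length,
        alphabet = alphabet, seed = NULL, chain_id = as.integer(k)
      )
    })
  })
}

#' Normalised Levenshtein copying error
#'
#' Edit distance (unit-cost insertions, deletions and substitutions) between
#' target and response, divided by the length of the longer string: 0 means a
#' perfect copy, 1 a response with nothing in common with the target.
#' Vectorised over pairs.
#'
#' @param target,response Character vectors of equal length; elements are
#'   compared pairwise. Empty strings are rejected.
#' @return Numeric vector of errors in \[0, 1\].
#' @export
#' @examples
#' normalized_levenshtein("RGYB", "RGY") # one deletion / max length 4
normalized_levenshtein <- function(target, response) {
  if (length(target) != length(response)) {
    stop("`target` and `response` must have the same length", call. = FALSE)
  }
  if (length(target) == 0) {
    stop("no sequences supplied", call. = FALSE)
  }
  if (anyNA(target) || anyNA(response) ||
      any(nchar(target) == 0) || any(nchar(response) == 0)) {
    stop("empty or missing sequences are not allowed", call. = FALSE)
  }
  d <- purrr::map2_dbl(target, response, function(a, b) utils::adist(a, b)[1, 1])
  d / pmax(nchar(target), nchar(response))
}

#' Mean copying error of a whole set
#'
#' The per-sequence normalised Levenshtein error, averaged (unweighted)
#' across all sequences in the set; targets and responses are aligned by
#' position.
#'
#' @param targets,responses Character vectors of equal length.
#' @return A single number in \[0, 1\].
#' @export
set_error <- function(targets, responses) {
  if (length(targets) != length(responses)) {
    stop("`targets` and `responses` must contain the same number of sequences",
      call. = FALSE
    )
  }
  mean(normalized_levenshtein(targets, responses))
}

#' Per-sequence copying errors of a chain dataset
#'
#' One error record per produced sequence (generation >= 1): the normalised
#' Levenshtein distance between what the participant saw (`target`) and what
#' they produced (`response`). `index` identifies the lineage of the original
#' generation-0 sequence, used as a random-effect grouping factor in the
#' trend models.
#'
#' @param dataset A chain dataset tibble (columns `chain`, `generation`,
#'   `index`, `target`, `response`).
#' @return A tibble with columns `chain`, `generation`, `index`, `error`.
#' @export
copy_errors <- function(dataset) {
  check_chain_dataset(dataset)
  dataset |>
    dplyr::filter(.data$generation >= 1) |>
    dplyr::mutate(error = normalized_levenshtein(.data$target, .data$response)) |>
    dplyr::select("chain", "generation", "index", "error")
}

#' Count the sequences in a chain dataset
#'
#' Total number of sequences across all chains and generations, including
#' the generation-0 sets (the full six-chain, ten-generation design holds
#' 3960 sequences).
#'
#' @inheritParams copy_errors
#' @return An integer count.
#' @export
count_sequences <- function(dataset) {
  check_chain_dataset(dataset)
  nrow(dataset)
}

check_chain_dataset <- function(dataset) {
  needed <- c("chain", "generation", "index", "target")
  missing <- setdiff(needed, names(dataset))
  if (length(missing) > 0) {
    stop(sprintf(
      "chain dataset is missing column(s): %s",
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(dataset)
}

#' Extract per-generation sequence sets from a chain dataset
#'
#' The "language" of generation g in a chain is the set of sequences its
#' participant produced (their responses); at generation 0 it is the random
#' initial set itself.
#'
#' @inheritParams copy_errors
#' @return A tibble with columns `chain`, `generation`, `index`, `sequence`.
#' @export
generation_sets <- function(dataset) {
  check_chain_dataset(dataset)
  dataset |>
    dplyr::mutate(
      sequence = dplyr::if_else(.data$generation == 0L, .data$target, .data$response)
    ) |>
    dplyr::select("chain", "generation", "index", "sequence")
}

#' Read and write chain datasets as CSV
#'
#' The on-disk dialect is UTF-8 CSV with a header row and columns
#' `chain,generation,index,target,response`; sequences are contiguous
#' single-character colour strings (e.g. `RGYBRRGYBYGB`) and generation-0
#' rows have an empty `response` field. The write/read pair round-trips a
#' dataset exactly.
#'
#' @param path File path.
#' @return `read_chain_data()` returns the chain dataset tibble;
#'   `write_chain_data()` returns `dataset` invisibly.
#' @export
read_chain_data <- function(path) {
  dat <- readr::read_csv(
    path,
    col_types = readr::cols(
      chain = readr::col_integer(),
      generation = readr::col_integer(),
      index = readr::col_integer(),
      target = readr::col_character(),
      response = readr::col_character()
    ),
    progress = FALSE
  )
  check_chain_dataset(dat)
  dat
}

#' @rdname read_chain_data
#' @inheritParams copy_errors
#' @export
write_chain_data <- function(dataset, path) {
  check_chain_dataset(dataset)
  readr::write_csv(dataset, path, na = "")
  invisible(dataset)
}

#' Read and write plain-text sequence sets
#'
#' One sequence per line; used for single-set operations such as threshold
#' calibration on externally supplied baselines.
#'
#' @param path File path.
#' @param chain_id,generation Metadata attached to the resulting set.
#' @return `read_sequence_lines()` returns a sequence-set tibble;
#'   `write_sequence_lines()` returns its input invisibly.
#' @export
read_sequence_lines <- function(path, chain_id = 1L, generation = 0L) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nchar(lines) > 0]
  check_sequences(lines)
  new_sequence_set(lines, chain_id = chain_id, generation = generation)
}

#' @rdname read_sequence_lines
#' @param set A sequence-set tibble with a `sequence` column.
#' @export
write_sequence_lines <- function(set, path) {
  readr::write_lines(set$sequence, path)
  invisible(set)
}
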