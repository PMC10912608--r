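test_that("planted sets are exact unit concatenations with recorded boundaries", {
  lex <- planted_lexicon("RGBY")
  set <- generate_planted_set(lex, 15, 12, seed = 1)
  expect_true(all(set$sequence == "RGBYRGBYRGBY"))
  expect_true(all(vapply(
    set$true_boundaries, identical, logical(1), c(5L, 9L)
  )))

  lex2 <- planted_lexicon(c("RGB", "YY", "RBYG", "G"),
    probabilities = c(0.6, 0.2, 0.1, 0.1)
  )
  set2 <- generate_planted_set(lex2, 50, 12, seed = 2)
  max_len <- max(nchar(lex2$units))
  expect_true(all(nchar(set2$sequence) <= 12))
  expect_true(all(nchar(set2$sequence) >= 12 - max_len + 1))
  expect_true(all(unlist(set2$true_boundaries) >= 2))
  # splitting at the recorded boundaries recovers lexicon units only
  for (k in seq_len(nrow(set2))) {
    b <- set2$true_boundaries[[k]]
    s <- set2$sequence[k]
    starts <- c(1L, b)
    ends <- c(b - 1L, nchar(s))
    expect_true(all(substring(s, starts, ends) %in% lex2$units))
  }
  expect_identical(set2, generate_planted_set(lex2, 50, 12, seed = 2))
  expect_error(
    generate_planted_set(planted_lexicon("RGBYR"), 5, 3),
    "shorter than every unit"
  )
})

test_that("empirical unit frequencies converge to the sampling weights", {
  lex <- planted_lexicon(c("RGB", "YYB", "RBY", "GGR"),
    probabilities = c(0.6, 0.2, 0.1, 0.1)
  )
  set <- generate_planted_set(lex, 2000, 12, seed = 3)
  units <- unlist(purrr::map2(
    set$sequence, set$true_boundaries,
    function(s, b) substring(s, c(1L, b), c(b - 1L, nchar(s)))
  ))
  freq <- table(factor(units, levels = lex$units)) / length(units)
  se <- sqrt(lex$probabilities * (1 - lex$probabilities) / length(units))
  expect_true(all(abs(as.numeric(freq) - lex$probabilities) < 3 * se))
})

test_that("boundary recovery counts hits, misses and false alarms", {
  b <- replicate(10, c(5L, 9L), simplify = FALSE)
  expect_equal(
    boundary_recovery(b, b)[, c("precision", "recall")],
    tibble::tibble(precision = 1, recall = 1)
  )
  inferred <- replicate(10, 5L, simplify = FALSE)
  got <- boundary_recovery(b, inferred)
  expect_equal(got$precision, 1)
  expect_equal(got$recall, 0.5)
  none <- replicate(10, integer(0), simplify = FALSE)
  empty <- boundary_recovery(b, none)
  expect_equal(empty$recall, 0)
  expect_true(is.na(empty$precision))
  expect_error(boundary_recovery(b, none[1:3]), "same sequences")
})

test_that("a noise-free agent copies perfectly; seeded runs are reproducible", {
  input <- generate_initial_set(20, 12, seed = 4)
  quiet <- agent_params(
    substitution = 0, deletion = 0, insertion = 0, frequency_boost = 0
  )
  out <- simulate_participant(input, quiet, threshold = 0.4, seed = 1)
  expect_equal(out$sequence, input$sequence)
  expect_equal(out$generation, rep(1L, 20))
  expect_equal(set_error(input$sequence, out$sequence), 0)

  noisy <- agent_params()
  a <- simulate_participant(input, noisy, 0.4, seed = 9)
  b <- simulate_participant(input, noisy, 0.4, seed = 9)
  expect_identical(a, b)
  expect_false(identical(
    a$sequence, simulate_participant(input, noisy, 0.4, seed = 10)$sequence
  ))
})

test_that("substitution-only error matches the per-symbol rate", {
  q <- 0.1
  p <- agent_params(
    substitution = q, deletion = 0, insertion = 0, frequency_boost = 0,
    chunk_learning = FALSE
  )
  input <- generate_initial_set(3000, 12, seed = 5)
  out <- simulate_participant(input, p, threshold = 0.4, seed = 6)
  errs <- normalized_levenshtein(input$sequence, out$sequence)
  # equal lengths: per-sequence error is essentially Binomial(12, q)/12;
  # the edit distance occasionally undercuts the Hamming count, so allow a
  # small downward bias beyond 3 standard errors
  se <- sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs) - q), 3 * se + 0.01)
})

test_that("transmission chains keep lineage links and bookkeeping intact", {
  initial <- generate_initial_set(8, 12, seed = 7, chain_id = 3L)
  none <- run_transmission_chain(initial,
    n_generations = 0,
    threshold = 0.4, seed = 1
  )
  expect_equal(nrow(none), 8)
  expect_true(all(none$generation == 0 & is.na(none$response)))

  chain <- suppressWarnings(run_transmission_chain(
    initial,
    n_generations = 4, threshold = 0.4, seed = 2
  ))
  expect_equal(nrow(chain), 8 * 5)
  expect_true(all(chain$chain == 3L))
  # each generation's targets are the previous generation's responses,
  # matched through the lineage index
  for (g in 2:4) {
    prev <- chain[chain$generation == g - 1, ]
    cur <- chain[chain$generation == g, ]
    expect_equal(
      cur$target[order(cur$index)],
      prev$response[order(prev$index)]
    )
  }
  g1 <- chain[chain$generation == 1, ]
  g0 <- chain[chain$generation == 0, ]
  expect_equal(g1$target[order(g1$index)], g0$target[order(g0$index)])
  # responses below length 6 are rare under re-presentation but never empty
  expect_true(all(nchar(chain$response[chain$generation > 0]) >= 1))

  small <- suppressWarnings(simulate_experiment(
    n_chains = 2, n_generations = 3, n_sequences = 5, seed = 3
  ))
  expect_equal(count_sequences(small$dataset), 2 * 4 * 5)
})

test_that("planted-lexicon boundaries are recovered above permutation chance", {
  lex <- planted_lexicon(c("RGB", "YYB", "RY", "GGRB", "BR", "YGG"),
    probabilities = c(0.45, 0.2, 0.15, 0.1, 0.06, 0.04)
  )
  set <- generate_planted_set(lex, 60, 12, seed = 8)
  th <- calibrate_threshold(generate_initial_sets(n_chains = 6, seed = 8))
  model <- estimate_transition_model(set)
  inferred <- purrr::map(
    set$sequence,
    function(s) segment_sequence(s, model, th)$boundaries
  )
  got <- boundary_recovery(set$true_boundaries, inferred)
  expect_gt(got$n_inferred, 0)

  # chance level: permute inferred boundary positions within each sequence
  set.seed(88)
  chance <- replicate(50, {
    permuted <- purrr::map2(
      inferred, nchar(set$sequence),
      function(b, L) if (length(b) == 0) b else sample(4:L, length(b))
    )
    unlist(boundary_recovery(set$true_boundaries, permuted)[c("precision", "recall")])
  })
  expect_gt(got$precision, quantile(chance["precision", ], 0.95, na.rm = TRUE))
  expect_gt(got$recall, quantile(chance["recall", ], 0.95, na.rm = TRUE))
})
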