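test_that("mean unit length is token-weighted", {
  expect_equal(
    mean_unit_length(tibble::tibble(unit = "RGYBRGYBRGYB", count = 1L)), 12
  )
  expect_equal(
    mean_unit_length(tibble::tibble(unit = c("RGBY", "RG"), count = c(3L, 1L))),
    3.5
  )
  # an unsegmented set's inventory averages to the mean sequence length
  set <- generate_initial_set(10, 12, seed = 1)
  inv <- build_inventory(set, threshold = 0)
  expect_equal(mean_unit_length(inv), 12)
  expect_error(mean_unit_length(tibble::tibble()), "non-empty")
})

test_that("transitions are classified by boundary position, RYG | R style", {
  # context RY always continues with G; context YG branches three ways, so
  # the ratio at position 4 is 1/3 and a cut lands before the final element
  seqs <- c("RYGR", "RYGG", "RYGB")
  m <- estimate_transition_model(seqs)
  expect_equal(m$tp[["RYG"]], 1)
  expect_equal(m$tp[["YGR"]], 1 / 3)
  tps <- classify_transitions(seqs, threshold = 0.5, model = m)
  first <- tps[tps$index == 1, ]
  expect_equal(as.character(first$type[first$position == 3]), "within")
  expect_equal(as.character(first$type[first$position == 4]), "between")
  seg <- segment_sequence("RYGR", m, 0.5)
  expect_equal(seg$units, c("RYG", "R"))

  # no boundaries anywhere leaves the between list empty
  tps0 <- classify_transitions(seqs, threshold = 0, model = m)
  expect_true(all(tps0$type == "within"))
})

test_that("classified transitions partition all L-2 TPs of each sequence", {
  set.seed(2)
  seqs <- random_seqs(25, 3:12, colour_alphabet())
  tps <- classify_transitions(seqs, threshold = 0.4)
  expect_equal(nrow(tps), sum(nchar(seqs) - 2))
  per_seq <- table(tps$index)
  expect_equal(
    as.integer(per_seq[as.character(seq_along(seqs))]),
    nchar(seqs) - 2L
  )
})

test_that("rank-frequency sorts by count with stable lexicographic ties", {
  inv <- tibble::tibble(unit = c("d", "a", "c", "b"), count = c(1L, 5L, 2L, 2L))
  rf <- rank_frequency(inv)
  expect_equal(rf$rank, 1:4)
  expect_equal(rf$frequency, c(5L, 2L, 2L, 1L))
  expect_equal(rf$unit, c("a", "b", "c", "d"))

  flat <- rank_frequency(tibble::tibble(unit = c("x", "y"), count = c(1L, 1L)))
  expect_equal(flat$frequency, c(1L, 1L))
  single <- rank_frequency(tibble::tibble(unit = "z", count = 7L))
  expect_equal(as.data.frame(single), data.frame(rank = 1L, unit = "z", frequency = 7L))
})

test_that("Zipf R2 is 1 for exact power laws and NA for flat distributions", {
  pl <- tibble::tibble(rank = 1:4, frequency = c(12, 6, 4, 3)) # f = 12 / r
  expect_equal(zipf_r2(pl), 1)
  two <- tibble::tibble(rank = 1:2, frequency = c(9, 2))
  expect_equal(zipf_r2(two), 1)
  expect_true(is.na(zipf_r2(tibble::tibble(rank = 1:3, frequency = c(4, 4, 4)))))
  expect_true(is.na(zipf_r2(tibble::tibble(rank = 1L, frequency = 10L))))
})

test_that("Zipf R2 matches the closed-form correlation and its invariances", {
  rf <- tibble::tibble(rank = 1:4, frequency = c(8, 4, 3, 1))
  want <- oracle_pearson(log(c(8, 4, 3, 1)), log(1:4))^2
  expect_equal(zipf_r2(rf), want)
  # invariant to rescaling all frequencies and to the log base
  expect_equal(zipf_r2(dplyr::mutate(rf, frequency = frequency * 7)), want)
  expect_equal(oracle_pearson(log10(c(8, 4, 3, 1)), log10(1:4))^2, want)
})

test_that("unit entropy attains its bounds exactly when expected", {
  expect_equal(unit_entropy(tibble::tibble(unit = letters[1:4], count = rep(1L, 4))), 2)
  expect_equal(unit_entropy(tibble::tibble(unit = "a", count = 9L)), 0)
  expect_equal(unit_entropy(tibble::tibble(unit = letters[1:3], count = c(2L, 1L, 1L))), 1.5)

  # exhaustive check for K <= 4 types, counts 1..5: H <= log2(K), with
  # equality iff uniform; H = 0 iff a single type
  for (K in 1:4) {
    grids <- do.call(expand.grid, rep(list(1:5), K))
    for (r in seq_len(nrow(grids))) {
      counts <- as.integer(grids[r, ])
      H <- unit_entropy(tibble::tibble(unit = letters[seq_len(K)], count = counts))
      expect_lte(H, log2(K) + 1e-12)
      if (length(unique(counts)) == 1) {
        expect_equal(H, log2(K))
      } else {
        expect_lt(H, log2(K))
      }
      if (K == 1) expect_equal(H, 0) else expect_gt(H, 0)
    }
  }
})

test_that("entropy-error correlation matches closed-form Pearson", {
  line <- tibble::tibble(entropy = 1:6, error = 0.1 * (1:6) + 0.05)
  expect_equal(entropy_error_correlation(line)$r, 1)
  anti <- tibble::tibble(entropy = 1:6, error = -(1:6))
  expect_equal(entropy_error_correlation(anti)$r, -1)

  set.seed(3)
  pts <- tibble::tibble(entropy = rnorm(10, 5), error = runif(10, 0.1, 0.6))
  got <- entropy_error_correlation(pts)
  expect_equal(got$r, oracle_pearson(pts$entropy, pts$error))
  expect_equal(got$n, 10)
  expect_true(got$p_value >= 0 && got$p_value <= 1)

  expect_error(
    entropy_error_correlation(tibble::tibble(entropy = 1:5, error = rep(0.2, 5))),
    "zero variance"
  )
  expect_error(
    entropy_error_correlation(tibble::tibble(entropy = 1:2, error = c(0.1, 0.2))),
    "at least 3"
  )
})

test_that("generation metrics carry one coherent row per chain and generation", {
  sim <- suppressWarnings(simulate_experiment(
    n_chains = 2, n_generations = 3, n_sequences = 25, seed = 13
  ))
  mets <- suppressWarnings(generation_metrics(sim$dataset, sim$threshold))
  expect_equal(nrow(mets), 2 * 4)
  expect_true(all(is.na(mets$set_error[mets$generation == 0])))
  expect_true(all(!is.na(mets$set_error[mets$generation > 0])))
  expect_true(all(mets$entropy_bits <= log2(mets$n_distinct_units) + 1e-12))
  expect_true(all(mets$mean_between_tp < mets$mean_within_tp, na.rm = TRUE))

  # set_error agrees with a direct recomputation
  direct <- sim$dataset |>
    dplyr::filter(generation == 1, chain == 1)
  expect_equal(
    mets$set_error[mets$chain == 1 & mets$generation == 1],
    set_error(direct$target, direct$response)
  )
})

test_that("participant records pair each learner's input entropy with their error", {
  sim <- suppressWarnings(simulate_experiment(
    n_chains = 2, n_generations = 3, n_sequences = 20, seed = 17
  ))
  rec <- suppressWarnings(participant_records(sim$dataset, sim$threshold))
  expect_equal(nrow(rec), 2 * 3)
  expect_true(all(rec$generation >= 1))
  # the entropy paired with generation 1 is that of the generation-0 set
  g0 <- generation_sets(sim$dataset) |>
    dplyr::filter(chain == 1, generation == 0)
  expect_equal(
    rec$entropy[rec$chain == 1 & rec$generation == 1],
    unit_entropy(build_inventory(g0, sim$threshold))
  )
})
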