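# Independent oracles, implemented from first principles and kept free of
# any package internals: a dynamic-programming edit distance, a
# string-scanning trigram counter, a hand-rolled interpolated quantile, and
# a brute-force segmenter built on top of those.

# classic DP edit distance with unit costs
oracle_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1] <- min(
        prev[j + 1] + 1, # deletion
        cur[j] + 1, # insertion
        prev[j] + (x[i] != y[j]) # substitution / match
      )
    }
    prev <- cur
  }
  prev[m + 1]
}

oracle_norm_lev <- function(a, b) {
  oracle_levenshtein(a, b) / max(nchar(a), nchar(b))
}

# trigram / context counts by scanning substrings; returns a tp lookup
oracle_tp_table <- function(seqs) {
  tri <- list()
  ctx <- list()
  for (s in seqs) {
    L <- nchar(s)
    if (L < 3) next
    for (i in 3:L) {
      t3 <- substr(s, i - 2, i)
      c2 <- substr(s, i - 2, i - 1)
      tri[[t3]] <- (tri[[t3]] %||% 0) + 1
      ctx[[c2]] <- (ctx[[c2]] %||% 0) + 1
    }
  }
  function(trigram) {
    n <- tri[[trigram]]
    if (is.null(n)) {
      return(NA_real_)
    }
    n / ctx[[substr(trigram, 1, 2)]]
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all consecutive-TP ratios of one sequence under a tp lookup
oracle_ratios_of <- function(s, tp) {
  L <- nchar(s)
  if (L < 4) {
    return(numeric(0))
  }
  tps <- vapply(3:L, function(i) tp(substr(s, i - 2, i)), numeric(1))
  tps[-1] / tps[-length(tps)]
}

# pooled ratios of one set (own model)
oracle_pooled_ratios <- function(seqs) {
  tp <- oracle_tp_table(seqs)
  unlist(lapply(seqs, oracle_ratios_of, tp = tp))
}

# interpolated empirical quantile (type 7) by sorting, written out by hand
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force segmentation of every sequence in a set: recompute counts and
# boundaries from scratch; boundary before position i iff ratio_i < theta
oracle_segment_set <- function(seqs, theta) {
  tp <- oracle_tp_table(seqs)
  lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < 4) {
      return(list(boundaries = integer(0), units = s))
    }
    tps <- vapply(3:L, function(i) tp(substr(s, i - 2, i)), numeric(1))
    ratios <- tps[-1] / tps[-length(tps)]
    b <- (4:L)[ratios < theta]
    starts <- c(1, b)
    ends <- c(b - 1, L)
    list(
      boundaries = as.integer(b),
      units = substring(s, starts, ends)
    )
  })
}

# closed-form Pearson correlation from raw sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# random sequences over an arbitrary alphabet (not balanced)
random_seqs <- function(n, len_range, alphabet) {
  vapply(seq_len(n), function(i) {
    L <- sample(len_range, 1)
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
}
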