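# Independent brute-force oracles and random-input generators shared by
# the test files. Oracles are written as plain scalar loops so they stay
# independent of the vectorized implementation paths they check.

random_hypnogram <- function(n, states = RAW_STATES, subject = "s1",
                             treatment = "VEH") {
  hypnogram(subject, treatment, sample(states, n, replace = TRUE))
}

# per-epoch scan: compare each epoch to its predecessor
naive_segment <- function(h) {
  s <- h$states
  state <- character(0)
  onset <- integer(0)
  len <- integer(0)
  for (i in seq_along(s)) {
    if (i == 1L || s[i] != s[i - 1L]) {
      state <- c(state, s[i])
      onset <- c(onset, i - 1L)
      len <- c(len, 1L)
    } else {
      len[length(len)] <- len[length(len)] + 1L
    }
  }
  data.frame(state = state, onset_epoch = onset, n_epochs = len,
             stringsAsFactors = FALSE)
}

# pairwise enumeration of bout successions, never crossing subjects
naive_cross_tabulate <- function(bouts, states, bin = NULL) {
  K <- length(states)
  O <- matrix(0L, K, K, dimnames = list(from = states, to = states))
  for (key in unique(paste(bouts$subject_id, bouts$treatment))) {
    g <- bouts[paste(bouts$subject_id, bouts$treatment) == key, ]
    g <- g[order(g$onset_epoch), ]
    if (nrow(g) < 2L) next
    for (k in seq_len(nrow(g) - 1L)) {
      if (!is.null(bin)) {
        b <- g$bin[k + 1L]
        if (is.na(b) || b != bin) next
      }
      i <- match(g$state[k], states)
      j <- match(g$state[k + 1L], states)
      O[i, j] <- O[i, j] + 1L
    }
  }
  O
}

# cell-by-cell scalar z-statistic oracle
naive_z <- function(O, method = "pearson") {
  K <- nrow(O)
  N <- 0
  for (i in seq_len(K)) for (j in seq_len(K)) N <- N + O[i, j]
  Z <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) {
    Ri <- sum(O[i, ])
    for (j in seq_len(K)) {
      Cj <- sum(O[, j])
      E <- Ri * Cj / N
      if (E == 0) next
      den <- if (method == "pearson") sqrt(E) else {
        sqrt(E * (1 - Ri / N) * (1 - Cj / N))
      }
      Z[i, j] <- (O[i, j] - E) / den
    }
  }
  Z
}

# random zero-diagonal count matrix, K <= 7, cells <= max_count
random_zero_diag_table <- function(K, max_count = 100L) {
  O <- matrix(sample.int(max_count + 1L, K * K, replace = TRUE) - 1L, K, K)
  diag(O) <- 0L
  dimnames(O) <- list(from = LETTERS[seq_len(K)], to = LETTERS[seq_len(K)])
  O
}

# the worked 3-state example used across transition tests
worked_example_table <- function() {
  O <- matrix(0L, 3, 3, dimnames = list(from = c("A", "B", "C"),
                                        to = c("A", "B", "C")))
  O["A", "B"] <- 10L; O["A", "C"] <- 2L
  O["B", "A"] <- 8L;  O["B", "C"] <- 4L
  O["C", "A"] <- 2L;  O["C", "B"] <- 4L
  transition_table(O)
}

# independence-null transition sample with the diagonal re-assigned:
# predecessors from p, successors from q conditioned on being different
simulate_null_table <- function(N, p, q, states = LETTERS[seq_along(p)]) {
  from <- sample(seq_along(p), N, replace = TRUE, prob = p)
  to <- sample(seq_along(q), N, replace = TRUE, prob = q)
  while (any(clash <- to == from)) {  # rejection = conditional redraw
    to[clash] <- sample(seq_along(q), sum(clash), replace = TRUE, prob = q)
  }
  O <- unclass(table(factor(from, levels = seq_along(p)),
                     factor(to, levels = seq_along(q))))
  dimnames(O) <- list(from = states, to = states)
  transition_table(O)
}
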