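# Independent oracles used across the suite. These deliberately take the
# dumbest possible route (explicit loops, textbook formulas) and share no
# code with the package implementations they check.

# Brute-force error-taxonomy scanner: walks the sequence once per question.
oracle_classify <- function(outcomes) {
  choices_idx <- which(outcomes != "omission")
  first_correct <- NA_integer_
  for (i in seq_along(outcomes)) {
    if (outcomes[i] == "correct") { first_correct <- i; break }
  }
  prepotent <- 0L; reg_init <- 0L; reg_sub <- 0L
  for (i in seq_along(outcomes)) {
    if (outcomes[i] != "error") next
    if (is.na(first_correct) || i < first_correct) {
      prepotent <- prepotent + 1L
    } else {
      prev <- choices_idx[choices_idx < i]
      prev_choice <- outcomes[prev[length(prev)]]
      if (prev_choice == "correct") reg_init <- reg_init + 1L
      else reg_sub <- reg_sub + 1L
    }
  }
  list(prepotent = prepotent, regressive_initial = reg_init,
       regressive_subsequent = reg_sub,
       total = prepotent + reg_init + reg_sub)
}

# Random trial sequence over the 3-symbol alphabet.
random_sequence <- function(n, p = c(correct = 0.5, error = 0.4, omission = 0.1)) {
  sample(names(p), n, replace = TRUE, prob = p)
}

# Pooled-variance two-sample t, textbook formula.
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Exhaustive link-based NBS oracle: loops over every distinct assignment of
# n1 subjects to group 1, computes every edge t with oracle_pooled_t, and
# counts assignments whose max |t| reaches each observed |t|.
oracle_nbs_link <- function(z, labels01) {
  n <- nrow(z); n1 <- sum(labels01)
  combos <- combn(n, n1)
  t_obs <- sapply(seq_len(ncol(z)), function(e) {
    oracle_pooled_t(z[labels01 == 1, e], z[labels01 == 0, e])
  })
  max_null <- apply(combos, 2, function(g1) {
    max(abs(sapply(seq_len(ncol(z)), function(e) {
      oracle_pooled_t(z[g1, e], z[-g1, e])
    })))
  })
  sapply(abs(t_obs), function(t0) mean(max_null >= t0))
}

# Tiny balanced 2x2 dataset with known cell means for ANOVA hand checks.
balanced_cells <- function(cell_means, n_per_cell, noise) {
  a <- rep(rep(c(0, 1), each = 2), each = n_per_cell)
  b <- rep(rep(c(0, 1), times = 2), each = n_per_cell)
  mu <- rep(as.vector(cell_means), each = n_per_cell)
  list(y = mu + noise, a = a, b = b)
}
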