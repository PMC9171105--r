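# Independent oracles and fixture builders shared across the suite.

# Score oracle: string-keyed re-implementation of the per-attempt rules,
# kept separate from the package's bit-vector version.
oracle_score_contributions <- function(log) {
  seen <- character(0)
  out <- numeric(nrow(log))
  for (t in seq_len(nrow(log))) {
    f <- paste(log$first_row[t], log$first_col[t])
    s <- paste(log$second_row[t], log$second_col[t])
    if (log$first_sound[t] == log$second_sound[t]) {
      out[t] <- 10
    } else {
      out[t] <- -((f %in% seen) + (s %in% seen))
    }
    seen <- union(seen, c(f, s))
  }
  out
}

oracle_score <- function(log) sum(oracle_score_contributions(log))

# Audio-Anchor oracle: direct pairwise comparison on string keys.
oracle_anchor <- function(log) {
  f <- paste(log$first_row, log$first_col)
  if (length(f) < 2) return(0)
  sum(vapply(2:length(f), function(t) f[t] == f[t - 1], logical(1)))
}

# Random legal logs come from random agents: any agent trajectory is a
# legal play sequence by construction.
random_log <- function(seed) {
  set.seed(seed)
  cond <- sample(c("four_pair", "twelve_pair"), 1, prob = c(0.7, 0.3))
  par <- agent_params(p_encode = runif(1), p_forget = runif(1, 0, 0.3),
                      anchor_propensity = runif(1),
                      policy = sample(c("uniform_random", "systematic_scan"), 1))
  b <- new_board(cond, seed = seed + 1L)
  run_session(par, b, seed = seed + 2L)
}

# Welch t re-derived from first principles (oracle for enumeration tests).
oracle_welch_t <- function(x, y) {
  (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
}

# Balanced mixed-design table: n subjects per group, both difficulty levels.
make_model_table <- function(n_per_group, group_delta = 0, diff_delta = 0,
                             int_delta = 0, sd = 1) {
  n_subj <- 2L * n_per_group
  tab <- data.frame(
    subject_id = rep(sprintf("s%02d", seq_len(n_subj)), each = 2L),
    group = rep(c("g1", "g2"), each = n_subj),
    difficulty = rep(c("easy", "hard"), n_subj),
    age = rep(runif(n_subj, 12, 54), each = 2L),
    stringsAsFactors = FALSE)
  mu <- (tab$group == "g2") * group_delta + (tab$difficulty == "hard") * diff_delta +
    (tab$group == "g2" & tab$difficulty == "hard") * int_delta
  tab$y <- mu + rnorm(nrow(tab), sd = sd)
  tab
}

# 2-pair toy board (4 apertures) for the memoryless Markov-chain check.
toy_board <- function() {
  board_from_layout(cbind(row = c(0L, 0L, 1L, 1L), col = c(0L, 1L, 0L, 1L)),
                    c("cat", "dog", "cat", "dog"))
}
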