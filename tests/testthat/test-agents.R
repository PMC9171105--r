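# Synthetic agents and the cohort generator.

test_that("memory updates follow the encode/forget/purge rules", {
  b <- audiomemory:::fixture_board()
  st <- audiomemory:::new_agent_state(b)
  # perfect encoding, no forgetting: memory = heard, unmatched entries
  p <- agent_params(p_encode = 1, p_forget = 0)
  st1 <- audiomemory:::update_memory(st, 1L, 2L, FALSE, p)
  expect_identical(which(st1$in_memory), c(1L, 2L))
  st1 <- audiomemory:::update_memory(st1, 1L, 4L, TRUE, p)  # bee pair matched
  expect_identical(which(st1$in_memory), 2L)                # purged
  expect_true(all(st1$matched[c(1, 4)]))
  # p_encode = 0: memory stays empty
  st2 <- audiomemory:::update_memory(st, 1L, 2L, FALSE,
                                     agent_params(p_encode = 0))
  expect_false(any(st2$in_memory))
  # p_forget = 1: memory empty after every attempt
  st3 <- audiomemory:::update_memory(st, 1L, 2L, FALSE,
                                     agent_params(p_encode = 1, p_forget = 1))
  expect_false(any(st3$in_memory))
})

test_that("the decision rule plays known pairs and honors anchoring", {
  b <- audiomemory:::fixture_board()
  st <- audiomemory:::new_agent_state(b)
  # rule 1: a fully remembered pair is played immediately
  st$in_memory[c(1L, 4L)] <- TRUE  # both bee positions
  mv <- audiomemory:::agent_step(st, agent_params())
  expect_setequal(mv, c(1L, 4L))
  # rule 2: anchor_propensity = 1 re-touches the previous first block
  st <- audiomemory:::new_agent_state(b)
  st$prev_first <- 3L
  mv <- audiomemory:::agent_step(st, agent_params(p_encode = 0,
                                                  anchor_propensity = 1))
  expect_identical(mv[1], 3L)
  # rule 2 fallback: systematic scan starts at the first aperture
  st <- audiomemory:::new_agent_state(b)
  mv <- audiomemory:::agent_step(st, agent_params(p_encode = 0,
                                                  policy = "systematic_scan"))
  expect_identical(mv, c(1L, 2L))
  # rule 3: the remembered partner of the first-revealed sound is chosen
  st <- audiomemory:::new_agent_state(b)
  st$in_memory[4L] <- TRUE  # partner of aperture 1 (bee)
  mv <- audiomemory:::agent_step(st, agent_params(policy = "systematic_scan"))
  expect_identical(mv, c(1L, 4L))
})

test_that("a perfect-memory scanner finishes a 4-pair board in <= 7 attempts", {
  par <- agent_params(p_encode = 1, p_forget = 0, policy = "systematic_scan")
  for (seed in 1:100) {
    b <- new_board("four_pair", seed = seed)
    log <- run_session(par, b, seed = seed)
    expect_lte(nrow(log), 7L)
    expect_identical(sum(log$matched), 4L)
  }
})

test_that("a memoryless uniform agent matches the Markov-chain expectation", {
  # 2-pair toy board: P(match) = 1/3 while two pairs remain; after the
  # first match the remaining two apertures pair surely. E[attempts] =
  # E[Geom(1/3)] + 1 = 3 + 1 = 4.
  par <- agent_params(p_encode = 0, policy = "uniform_random")
  b <- toy_board()
  n_sessions <- 3000
  att <- vapply(seq_len(n_sessions),
                function(s) nrow(run_session(par, b, seed = s)), numeric(1))
  se <- sd(att) / sqrt(n_sessions)
  expect_lt(abs(mean(att) - 4), 3 * se)
})

test_that("anchoring propensity raises the audio-anchor index", {
  b <- new_board("four_pair", seed = 3)
  higher <- 0L
  for (seed in 1:200) {
    a1 <- compute_audio_anchor(run_session(
      agent_params(0.6, 0.05, anchor_propensity = 1), b, seed = seed))
    a0 <- compute_audio_anchor(run_session(
      agent_params(0.6, 0.05, anchor_propensity = 0), b, seed = seed))
    if (a1 >= a0) higher <- higher + 1L
  }
  expect_gt(higher, 100L)
})

test_that("sessions are reproducible from their seed", {
  par <- agent_params(0.5, 0.1, 0.3)
  b <- new_board("twelve_pair", seed = 2)
  expect_identical(run_session(par, b, seed = 11),
                   run_session(par, b, seed = 11))
  expect_false(identical(run_session(par, b, seed = 11),
                         run_session(par, b, seed = 12)))
})

test_that("the safety cap stops a non-terminating parameterization", {
  par <- agent_params(p_encode = 0, policy = "uniform_random")
  b <- new_board("twelve_pair", seed = 1)
  expect_error(run_session(par, b, seed = 1, max_attempts = 3L),
               "safety cap")
})

test_that("cohort generation is shaped, reproducible and validated", {
  spec <- cohort_spec(n_per_group = 3, master_seed = 77)
  co <- generate_cohort(spec)
  expect_identical(nrow(co$table), 3L * 2L * 2L)
  expect_identical(length(co$logs), 12L)
  # every (subject, condition) exactly once
  expect_true(all(table(co$table$subject_id, co$table$condition) == 1L))
  expect_true(all(co$table$age >= 12 & co$table$age <= 54))
  co2 <- generate_cohort(cohort_spec(n_per_group = 3, master_seed = 77))
  expect_identical(co$table, co2$table)
  expect_error(cohort_spec(n_per_group = 1), ">= 2")
  expect_error(cohort_spec(group_params = list(
    a = list(p_encode = 1.2, p_forget = 0, anchor_propensity = 0),
    b = list(p_encode = 0.5, p_forget = 0, anchor_propensity = 0))),
    "\\[0, 1\\]")
})

test_that("difficulty moves the indices in the expected directions", {
  # more pairs: more attempts per pair and a larger score ceiling, so the
  # 12-pair condition yields higher Score and higher Number of Attempts
  par <- agent_params(0.7, 0.05, 0.2)
  b4 <- new_board("four_pair", seed = 5)
  b12 <- new_board("twelve_pair", seed = 5)
  idx <- function(b, seed) compute_indices(run_session(par, b, seed = seed))
  r4 <- lapply(1:60, idx, b = b4)
  r12 <- lapply(1:60, idx, b = b12)
  m <- function(r, f) mean(vapply(r, `[[`, numeric(1), f))
  expect_gt(m(r12, "score"), m(r4, "score"))
  expect_gt(m(r12, "number_of_attempts"), m(r4, "number_of_attempts"))
  expect_gt(m(r12, "n_attempts_total"), m(r4, "n_attempts_total"))
})

test_that("default calibration separates the groups in the intended direction", {
  co <- generate_cohort(cohort_spec(master_seed = 11))
  tab <- co$table
  for (cond in c("four_pair", "twelve_pair")) {
    sub <- tab[tab$condition == cond, ]
    expect_gt(mean(sub$score[sub$group == "sighted_like"]),
              mean(sub$score[sub$group == "blind_like"]))
  }
  expect_gt(mean(tab$audio_anchor[tab$group == "blind_like"]),
            mean(tab$audio_anchor[tab$group == "sighted_like"]))
})
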