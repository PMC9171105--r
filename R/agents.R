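# Parameterized behavioral agents and the synthetic cohort generator.
#
# The agent is the smallest mechanism whose parameters map one-to-one onto
# the three indices: probabilistic encoding of heard positions (p_encode),
# per-attempt forgetting (p_forget), and a propensity to re-start the next
# attempt at the previous attempt's first block (anchor_propensity). When
# memory holds both positions of an unmatched pair, the agent plays it.

#' Behavioral parameters of a synthetic agent
#'
#' @param p_encode Probability of storing a heard (position, sound) in
#'   memory. `p_encode = 1, p_forget = 0` is the perfect-memory agent.
#' @param p_forget Per-attempt probability of losing each stored entry.
#' @param anchor_propensity Probability of starting the next attempt at the
#'   previous attempt's first block (if still in play).
#' @param policy Exploration fallback: `"systematic_scan"` (lowest row-major
#'   untouched aperture, then lowest unmatched) or `"uniform_random"`.
#' @return An `agent_params` list.
#' @export
agent_params <- function(p_encode = 1, p_forget = 0, anchor_propensity = 0,
                         policy = c("uniform_random", "systematic_scan")) {
  policy <- match.arg(policy)
  for (p in list(p_encode, p_forget, anchor_propensity))
    if (!is_prob(p)) stopf("agent probabilities must lie in [0, 1]")
  structure(list(p_encode = p_encode, p_forget = p_forget,
                 anchor_propensity = anchor_propensity, policy = policy),
            class = "agent_params")
}

# Agent-side view of a session. Positions are aperture indices on the board.
#   in_memory : logical, entry i TRUE if the agent holds (position i, sound).
#   matched   : logical, aperture covered.
#   touched   : logical, aperture touched at least once (drives the scan).
#   prev_first: aperture index of the previous attempt's first touch (or 0).
new_agent_state <- function(board) {
  n <- board$condition$n_apertures
  sound_id <- match(board$sounds, board$condition$labels)
  partner <- vapply(seq_len(n), function(i) {
    j <- which(sound_id == sound_id[i])
    j[j != i]
  }, integer(1))
  list(n = n, sound_id = sound_id, partner = partner,
       in_memory = logical(n), matched = logical(n), touched = logical(n),
       prev_first = 0L)
}

pick_uniform <- function(candidates) {
  if (length(candidates) == 1L) candidates else sample(candidates, 1L)
}

# Fallback choice of a single aperture under the exploration policy.
# systematic_scan prefers the lowest row-major untouched aperture; once
# every aperture has been touched it falls back to a uniform draw over the
# unmatched ones (a deterministic fallback could lock a memoryless scanner
# onto the same two apertures forever, violating termination).
policy_pick <- function(state, policy, exclude = 0L) {
  open <- which(!state$matched)
  open <- open[open != exclude]
  if (policy == "systematic_scan") {
    fresh <- open[!state$touched[open]]
    if (length(fresh)) return(min(fresh))
  }
  pick_uniform(open)
}

#' One decision of the agent: which two apertures to touch
#'
#' Decision rule: (1) if memory holds both positions of an unmatched pair,
#' play that pair; (2) otherwise pick the first touch — with probability
#' `anchor_propensity` the previous attempt's first block if still in play,
#' else per policy; (3) pick the second touch — the remembered partner of
#' the first-revealed sound if stored, else per policy.
#'
#' @param state Agent state from [new_agent_state()] (internal fields).
#' @param params [agent_params()].
#' @return Integer vector `c(first, second)` of aperture indices.
#' @keywords internal
agent_step <- function(state, params) {
  known_pair <- which(state$in_memory & state$in_memory[state$partner] &
                        !state$matched)
  if (length(known_pair)) {
    i <- min(known_pair)
    return(c(i, state$partner[i]))
  }
  # first touch
  first <- 0L
  if (state$prev_first > 0L && !state$matched[state$prev_first] &&
      params$anchor_propensity > 0 &&
      stats::runif(1L) < params$anchor_propensity) {
    first <- state$prev_first
  }
  if (first == 0L) first <- policy_pick(state, params$policy)
  # second touch: remembered partner of the sound just revealed at `first`
  partner <- state$partner[first]
  if (state$in_memory[partner] && partner != first) {
    second <- partner
  } else {
    second <- policy_pick(state, params$policy, exclude = first)
  }
  c(first, second)
}

#' Memory update after an attempt
#'
#' Each newly heard (position, sound) is stored with probability `p_encode`;
#' then every stored entry is independently dropped with probability
#' `p_forget`; entries of matched sounds are purged.
#'
#' @param state Agent state.
#' @param first,second Aperture indices touched this attempt.
#' @param matched Did the attempt match a pair?
#' @param params [agent_params()].
#' @return The updated state.
#' @keywords internal
update_memory <- function(state, first, second, matched, params) {
  for (i in c(first, second)) {
    if (!state$in_memory[i] && stats::runif(1L) < params$p_encode)
      state$in_memory[i] <- TRUE
  }
  if (params$p_forget > 0) {
    held <- which(state$in_memory)
    drop <- held[stats::runif(length(held)) < params$p_forget]
    state$in_memory[drop] <- FALSE
  }
  state$touched[c(first, second)] <- TRUE
  if (matched) {
    state$matched[c(first, second)] <- TRUE
    state$in_memory[c(first, second)] <- FALSE
  }
  state$prev_first <- if (matched && state$matched[first]) 0L else first
  state
}

#' Simulate one full session of an agent on a board
#'
#' Plays [agent_step()] / [update_memory()] until every pair is matched.
#' Sessions are self-paced and uncapped in principle; a configurable safety
#' cap guards against non-terminating parameterizations.
#'
#' @param params [agent_params()].
#' @param board A [new_board()] layout.
#' @param seed Optional seed; the same seed yields an identical log.
#' @param max_attempts Safety cap (default 10000); exceeding it is an error.
#' @return A validated `attempt_log`.
#' @export
run_session <- function(params, board, seed = NULL, max_attempts = 10000L) {
  stopifnot(inherits(params, "agent_params"), inherits(board, "board_layout"))
  with_seed(seed, {
    st <- new_agent_state(board)
    n_pairs <- board$condition$n_pairs
    n_matched <- 0L
    cap <- max_attempts
    fi <- integer(cap); si <- integer(cap); hit <- logical(cap)
    t <- 0L
    while (n_matched < n_pairs) {
      if (t >= cap)
        stopf("safety cap of %d attempts exceeded; agent may not terminate",
              max_attempts)
      mv <- agent_step(st, params)
      t <- t + 1L
      fi[t] <- mv[1L]; si[t] <- mv[2L]
      hit[t] <- st$sound_id[mv[1L]] == st$sound_id[mv[2L]]
      if (hit[t]) n_matched <- n_matched + 1L
      st <- update_memory(st, mv[1L], mv[2L], hit[t], params)
    }
    idx <- seq_len(t)
    log <- data.frame(
      attempt_index = idx,
      first_row = board$apertures[fi[idx], 1L],
      first_col = board$apertures[fi[idx], 2L],
      second_row = board$apertures[si[idx], 1L],
      second_col = board$apertures[si[idx], 2L],
      first_sound = board$sounds[fi[idx]],
      second_sound = board$sounds[si[idx]],
      matched = hit[idx],
      stringsAsFactors = FALSE)
    class(log) <- c("attempt_log", "data.frame")
    attr(log, "n_pairs") <- n_pairs
    log
  })
}

#' Specification of a synthetic two-group cohort
#'
#' Defaults emulate the study design: 12 subjects per group, ages drawn
#' uniformly from 12-54 years, each subject playing both difficulty
#' conditions. Group parameter means are calibration constants, not
#' estimates of human parameters: the "sighted_like" group encodes reliably,
#' forgets little and anchors rarely; the "blind_like" group encodes less
#' reliably, forgets more (the attempts-to-pair index measures exactly this
#' maintenance deficit) and anchors often.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param group_params Named list of two groups, each a list with elements
#'   `p_encode`, `p_forget`, `anchor_propensity` (means on \[0, 1\]).
#' @param spread Common SD of the per-subject parameter draws (truncated to
#'   \[0, 1\]).
#' @param age_range Two-element numeric range of ages in years.
#' @param policy Exploration policy for all agents.
#' @param master_seed Integer seed that fully determines the cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 12L,
                        group_params = list(
                          sighted_like = list(p_encode = 0.9, p_forget = 0.02,
                                              anchor_propensity = 0.1),
                          blind_like = list(p_encode = 0.6, p_forget = 0.10,
                                            anchor_propensity = 0.4)),
                        spread = 0.05,
                        age_range = c(12, 54),
                        policy = "uniform_random",
                        master_seed = 1L) {
  if (!is_count(n_per_group, min = 2L))
    stopf("`n_per_group` must be an integer >= 2")
  if (length(group_params) != 2L || is.null(names(group_params)))
    stopf("`group_params` must be a named list of two groups")
  for (g in group_params)
    for (nm in c("p_encode", "p_forget", "anchor_propensity"))
      if (!is_prob(g[[nm]]))
        stopf("group parameter `%s` must lie in [0, 1]", nm)
  if (!is_prob(spread)) stopf("`spread` must lie in [0, 1]")
  if (length(age_range) != 2L || age_range[1L] > age_range[2L])
    stopf("`age_range` must be an increasing pair of years")
  structure(list(n_per_group = as.integer(n_per_group),
                 group_params = group_params, spread = spread,
                 age_range = age_range, policy = policy,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

rtrunc01 <- function(n, mean, sd) pmin(1, pmax(0, stats::rnorm(n, mean, sd)))

#' Generate a synthetic cohort: indices table plus raw logs
#'
#' Draws per-subject agent parameters from each group's distribution, runs
#' both difficulty conditions per subject (within-subject design), and
#' returns the per-session index table together with the raw attempt logs.
#' All randomness flows from `master_seed`: subject parameters, ages and
#' per-session seeds are drawn up-front from a single seeded stream, so the
#' same spec reproduces the same cohort byte for byte.
#'
#' @param spec A [cohort_spec()].
#' @param boards Optional named list of board layouts per condition name;
#'   defaults to [new_board()] with the condition's default apertures and a
#'   seed drawn from the master stream.
#' @return A list with `table` (data frame: subject_id, group, age,
#'   condition, score, number_of_attempts, audio_anchor, n_attempts_total)
#'   and `logs` (named list of attempt logs, one per subject x condition).
#' @export
generate_cohort <- function(spec = cohort_spec(), boards = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- names(spec$group_params)
  n <- spec$n_per_group
  n_subj <- 2L * n
  conditions <- c("four_pair", "twelve_pair")
  draws <- with_seed(spec$master_seed, {
    list(
      p_encode = unlist(lapply(groups, function(g)
        rtrunc01(n, spec$group_params[[g]]$p_encode, spec$spread))),
      p_forget = unlist(lapply(groups, function(g)
        rtrunc01(n, spec$group_params[[g]]$p_forget, spec$spread))),
      anchor = unlist(lapply(groups, function(g)
        rtrunc01(n, spec$group_params[[g]]$anchor_propensity, spec$spread))),
      age = stats::runif(n_subj, spec$age_range[1L], spec$age_range[2L]),
      board_seeds = sample.int(.Machine$integer.max, length(conditions)),
      session_seeds = matrix(sample.int(.Machine$integer.max,
                                        n_subj * length(conditions)),
                             nrow = n_subj))
  })
  if (is.null(boards)) {
    boards <- stats::setNames(lapply(seq_along(conditions), function(ci)
      new_board(conditions[ci], seed = draws$board_seeds[ci])), conditions)
  }
  rows <- vector("list", n_subj * length(conditions))
  logs <- vector("list", n_subj * length(conditions))
  log_names <- character(n_subj * length(conditions))
  r <- 0L
  for (s in seq_len(n_subj)) {
    grp <- groups[(s - 1L) %/% n + 1L]
    sid <- sprintf("S%02d", s)
    par <- agent_params(p_encode = draws$p_encode[s],
                        p_forget = draws$p_forget[s],
                        anchor_propensity = draws$anchor[s],
                        policy = spec$policy)
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      log <- run_session(par, boards[[cond]],
                         seed = draws$session_seeds[s, ci])
      ind <- compute_indices(log)
      r <- r + 1L
      rows[[r]] <- data.frame(
        subject_id = sid, group = grp, age = draws$age[s], condition = cond,
        score = ind$score, number_of_attempts = ind$number_of_attempts,
        audio_anchor = ind$audio_anchor,
        n_attempts_total = ind$n_attempts_total,
        stringsAsFactors = FALSE)
      attr(log, "meta") <- list(subject_id = sid, group = grp,
                                age = draws$age[s], condition = cond,
                                seed = draws$session_seeds[s, ci])
      logs[[r]] <- log
      log_names[r] <- paste(sid, cond, sep = "_")
    }
  }
  names(logs) <- log_names
  list(table = do.call(rbind, rows), logs = logs, boards = boards,
       spec = spec)
}
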