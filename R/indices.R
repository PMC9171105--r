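# The three behavioral indices computed from a session's attempt log.
#
# Score          — cumulative memory index: a matching attempt adds +10
#                  regardless of prior touches; a non-matching attempt adds 0
#                  if both blocks are first-time touches, -1 if exactly one
#                  was touched in an earlier attempt, -2 if both were.
# Number of
#   Attempts     — per pair, the number of attempts between full discovery of
#                  its two positions and the attempt that matches it,
#                  averaged over pairs.
# Audio-Anchor   — exploration-strategy index: +1 for every attempt that
#                  starts at the same block as the previous attempt's first
#                  touch.

log_keys <- function(log) {
  list(first = pos_key(log$first_row, log$first_col),
       second = pos_key(log$second_row, log$second_col))
}

# Per-attempt Score contributions. "Previously touched" means touched in a
# strictly earlier attempt: the first touch of the current attempt does not
# make the second touch "old".
score_contributions <- function(log) {
  n <- nrow(log)
  k <- log_keys(log)
  touched <- logical(GRID_SIZE * GRID_SIZE)
  out <- integer(n)
  for (t in seq_len(n)) {
    if (log$matched[t]) {
      out[t] <- 10L
    } else {
      out[t] <- -(touched[k$first[t] + 1L] + touched[k$second[t] + 1L])
    }
    touched[c(k$first[t], k$second[t]) + 1L] <- TRUE
  }
  out
}

#' Score of a session
#'
#' Cumulative memory index starting at 0: +10 per matched pair, 0 / -1 / -2
#' for non-matching attempts touching zero / one / two previously touched
#' blocks. Computable for incomplete sessions.
#'
#' @param log A legal `attempt_log`.
#' @return Integer Score.
#' @examples
#' # the canonical worked example: 0 - 1 - 2 + 10 = 7
#' compute_score(fig_score_log())
#' @export
compute_score <- function(log) {
  validate_attempt_log(log)
  sum(score_contributions(log))
}

#' Mean number of attempts to pair discovered items
#'
#' For each pair, counts the attempts elapsed between the attempt at whose
#' end both of its positions have been revealed (discovery, `d`) and the
#' attempt that matches it (`m`). The default counting is the exclusive
#' difference `m - d`, so a pair matched on the very attempt that completes
#' its discovery contributes 0 and single-step perfect recall contributes 1;
#' `counting = "inclusive"` adds 1 to every pair. The per-pair counts are
#' averaged.
#'
#' @param log A legal `attempt_log` of a complete session.
#' @param counting `"exclusive"` (default, `m - d`) or `"inclusive"`
#'   (`m - d + 1`).
#' @param partial If `TRUE`, pairs revealed but never matched are skipped
#'   with a warning instead of raising an error.
#' @return Mean attempts per pair (non-negative rational).
#' @export
compute_number_of_attempts <- function(log,
                                       counting = c("exclusive", "inclusive"),
                                       partial = FALSE) {
  counting <- match.arg(counting)
  validate_attempt_log(log)
  n <- nrow(log)
  if (n == 0L) stopf("cannot compute Number of Attempts on an empty log")
  k <- log_keys(log)
  keys <- c(k$first, k$second)
  snds <- c(log$first_sound, log$second_sound)
  att <- rep(seq_len(n), 2L)
  labels <- unique(snds)
  counts <- numeric(0)
  skipped <- character(0)
  for (lab in labels) {
    pos <- unique(keys[snds == lab])
    m_t <- log$attempt_index[log$matched &
                               (log$first_sound == lab)]
    if (length(m_t) == 0L) {
      skipped <- c(skipped, lab)
      next
    }
    # discovery: first attempt at whose end both positions were revealed
    first_seen <- vapply(pos, function(p) min(att[keys == p]), numeric(1))
    d_t <- max(first_seen)
    counts <- c(counts, m_t - d_t + (counting == "inclusive"))
  }
  # pairs never touched at all are invisible in the log; the session-level
  # pair count (attached by session_log / run_session) exposes them
  n_pairs <- attr(log, "n_pairs")
  n_unseen <- if (is.null(n_pairs)) 0L else n_pairs - length(labels)
  if (length(skipped) || n_unseen > 0L) {
    msg <- sprintf("%d unmatched pair(s)%s",
                   length(skipped) + n_unseen,
                   if (length(skipped))
                     paste0(" (", paste(skipped, collapse = ", "),
                            if (n_unseen > 0L) ", ..." else "", ")")
                   else "")
    if (!partial)
      stopf("session incomplete: %s; use partial = TRUE", msg)
    warning(paste("skipping", msg), call. = FALSE)
  }
  if (!length(counts))
    stopf("no matched pairs in log")
  mean(counts)
}

#' Audio-Anchor exploration index
#'
#' Starting from 0, adds 1 for every attempt (from the second on) whose
#' first touch is the same block as the previous attempt's first touch.
#' Second touches never participate in the comparison.
#'
#' @param log A legal `attempt_log`.
#' @return Non-negative integer, at most `nrow(log) - 1`.
#' @examples
#' # the canonical worked example: 0 + 1 + 1 = 2
#' compute_audio_anchor(fig_anchor_log())
#' @export
compute_audio_anchor <- function(log) {
  validate_attempt_log(log)
  n <- nrow(log)
  if (n < 2L) return(0L)
  fk <- pos_key(log$first_row, log$first_col)
  sum(fk[-1L] == fk[-n])
}

#' All three indices of one session
#'
#' @inheritParams compute_number_of_attempts
#' @return A list of class `session_indices`: `score`,
#'   `number_of_attempts`, `audio_anchor`, `n_attempts_total`.
#' @export
compute_indices <- function(log, counting = c("exclusive", "inclusive"),
                            partial = FALSE) {
  counting <- match.arg(counting)
  validate_attempt_log(log)
  structure(
    list(score = compute_score(log),
         number_of_attempts = compute_number_of_attempts(log, counting,
                                                         partial = partial),
         audio_anchor = compute_audio_anchor(log),
         n_attempts_total = nrow(log)),
    class = "session_indices")
}

#' @export
print.session_indices <- function(x, ...) {
  cat(sprintf(
    "<session_indices> score = %d, number_of_attempts = %.3f, audio_anchor = %d (%d attempts)\n",
    x$score, x$number_of_attempts, x$audio_anchor, x$n_attempts_total))
  invisible(x)
}
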