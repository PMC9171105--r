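# Board geometry and game rules for the spatialized sound-pairing task.
#
# The device is a 5x5 grid of haptic blocks. Coordinates are 0-based
# (row, col), row-major, row 0 at the top. The center block (2, 2) holds the
# feedback speaker and is never a selectable aperture. A cardboard grid
# exposes a condition-specific subset of blocks ("apertures"); each hidden
# sound label is assigned to exactly two apertures.

GRID_SIZE <- 5L
CENTER <- c(2L, 2L)

# Canonical animal-call label sets for the two difficulty conditions.
FOUR_PAIR_SOUNDS <- c("bee", "lion", "frog", "rooster")
TWELVE_PAIR_SOUNDS <- c("wolf", "dog", "crow", "cat", "elephant", "birds",
                        "hen", "sheep", "donkey", "goose", "owl", "horse")

#' Difficulty condition of the pairing game
#'
#' A condition fixes the number of hidden sound pairs (4 or 12), the number
#' of selectable apertures (always twice the number of pairs), and the
#' canonical set of animal-call labels used on that board.
#'
#' @param name `"four_pair"` (8 apertures) or `"twelve_pair"` (24 apertures).
#' @return A list with elements `name`, `n_pairs`, `n_apertures`, `labels`.
#' @examples
#' game_condition("four_pair")$n_apertures  # 8
#' @export
game_condition <- function(name = c("four_pair", "twelve_pair")) {
  name <- match.arg(name)
  if (name == "four_pair") {
    list(name = name, n_pairs = 4L, n_apertures = 8L,
         labels = FOUR_PAIR_SOUNDS)
  } else {
    list(name = name, n_pairs = 12L, n_apertures = 24L,
         labels = TWELVE_PAIR_SOUNDS)
  }
}

pos_key <- function(row, col) row * GRID_SIZE + col

# All non-center grid positions in row-major order, as an n x 2 matrix.
noncenter_positions <- function() {
  rows <- rep(0:(GRID_SIZE - 1L), each = GRID_SIZE)
  cols <- rep(0:(GRID_SIZE - 1L), times = GRID_SIZE)
  keep <- !(rows == CENTER[1L] & cols == CENTER[2L])
  cbind(row = rows[keep], col = cols[keep])
}

# Default aperture layouts. The 24-aperture grid is forced by geometry
# (every block except the center). The 8-aperture arrangement is not
# recoverable from the figure, so the default is the first 8 non-center
# positions in row-major order; pass `apertures` to use another geometry.
default_apertures <- function(condition) {
  all_pos <- noncenter_positions()
  all_pos[seq_len(condition$n_apertures), , drop = FALSE]
}

validate_apertures <- function(apertures, n_expected) {
  if (!is.matrix(apertures) || ncol(apertures) != 2L)
    stopf("`apertures` must be an n x 2 matrix of (row, col)")
  storage.mode(apertures) <- "integer"
  if (nrow(apertures) != n_expected)
    stopf("condition requires %d apertures, got %d", n_expected,
          nrow(apertures))
  if (any(apertures < 0L) || any(apertures >= GRID_SIZE))
    stopf("aperture coordinates must lie in 0..%d", GRID_SIZE - 1L)
  keys <- pos_key(apertures[, 1L], apertures[, 2L])
  if (anyDuplicated(keys))
    stopf("duplicate apertures are not allowed")
  if (pos_key(CENTER[1L], CENTER[2L]) %in% keys)
    stopf("the center position (2,2) is the feedback speaker, not an aperture")
  colnames(apertures) <- c("row", "col")
  apertures
}

#' Create a board layout with a hidden pair assignment
#'
#' Assigns each of the condition's sound labels uniformly at random to two
#' distinct apertures. The same seed always yields the same layout.
#'
#' @param condition A condition name or the result of [game_condition()].
#' @param seed Integer seed controlling the label assignment.
#' @param apertures Optional n x 2 integer matrix of 0-based (row, col)
#'   aperture positions; defaults to the first `n_apertures` non-center
#'   positions in row-major order (the 24-aperture grid is all non-center
#'   blocks either way).
#' @return A `board_layout`: condition, apertures, the sound at each
#'   aperture, and the seed used.
#' @examples
#' b <- new_board("four_pair", seed = 7)
#' table(b$sounds)  # each label twice
#' @export
new_board <- function(condition, seed = NULL, apertures = NULL) {
  if (is.character(condition)) condition <- game_condition(condition)
  if (is.null(apertures)) apertures <- default_apertures(condition)
  apertures <- validate_apertures(apertures, condition$n_apertures)
  labels <- rep(condition$labels, each = 2L)
  sounds <- with_seed(seed, sample(labels))
  structure(
    list(condition = condition, apertures = apertures, sounds = sounds,
         seed = seed %||% NA_integer_),
    class = "board_layout")
}

#' Build a board from an explicit aperture/sound layout
#'
#' Low-level constructor used for hand-made fixtures and toy boards (e.g. a
#' 2-pair board); `sounds[i]` is the label hidden at `apertures[i, ]` and
#' every label must occur exactly twice.
#'
#' @param apertures n x 2 integer matrix of 0-based (row, col) positions.
#' @param sounds Character vector of length n.
#' @return A `board_layout`.
#' @export
board_from_layout <- function(apertures, sounds) {
  apertures <- validate_apertures(apertures, nrow(apertures))
  if (length(sounds) != nrow(apertures))
    stopf("`sounds` must have one label per aperture")
  tab <- table(sounds)
  if (any(tab != 2L))
    stopf("every sound label must occur on exactly two apertures")
  labels <- sort(unique(sounds))
  n_pairs <- length(labels)
  condition <- list(name = sprintf("custom_%d_pair", n_pairs),
                    n_pairs = n_pairs, n_apertures = 2L * n_pairs,
                    labels = labels)
  structure(
    list(condition = condition, apertures = apertures,
         sounds = as.character(sounds), seed = NA_integer_),
    class = "board_layout")
}

#' @export
print.board_layout <- function(x, ...) {
  cat(sprintf("<board_layout> %s: %d pairs over %d apertures (seed %s)\n",
              x$condition$name, x$condition$n_pairs, x$condition$n_apertures,
              format(x$seed)))
  invisible(x)
}

aperture_index <- function(board, pos) {
  if (length(pos) != 2L || any(is.na(pos)))
    stopf("a position is a (row, col) pair")
  i <- which(board$apertures[, 1L] == pos[1L] & board$apertures[, 2L] == pos[2L])
  if (length(i) != 1L)
    stopf("position (%d,%d) is not an aperture of this board",
          pos[1L], pos[2L])
  i
}

#' Start a fresh game session on a board
#'
#' @param board A [new_board()] layout.
#' @return A `game_session` holding the board, the touch history and the
#'   growing attempt log.
#' @export
new_session <- function(board) {
  stopifnot(inherits(board, "board_layout"))
  n <- board$condition$n_apertures
  structure(
    list(board = board,
         touched = logical(n),        # touched in any finished attempt
         matched = logical(n),        # aperture covered after its pair matched
         matched_labels = character(0),
         n_attempts = 0L,
         log_first = integer(0), log_second = integer(0),
         log_matched = logical(0)),
    class = "game_session")
}

#' Has the session matched all pairs?
#'
#' @param session A `game_session`.
#' @return `TRUE` once every sound label has been paired.
#' @export
is_complete <- function(session) {
  length(session$matched_labels) >= session$board$condition$n_pairs
}

#' Play one attempt (an ordered touch of two apertures)
#'
#' Reveals the sounds at the two positions; if they carry the same label the
#' pair is matched and both sites are covered for the rest of the session.
#' Re-touching an unmatched aperture across attempts is legal; touching a
#' covered aperture, a non-aperture, or the same aperture twice within one
#' attempt is an error, as is playing after completion.
#'
#' @param session A `game_session`.
#' @param first,second 0-based (row, col) integer pairs.
#' @return The updated `game_session`; the appended attempt is the last row
#'   of [session_log()].
#' @export
play_attempt <- function(session, first, second) {
  stopifnot(inherits(session, "game_session"))
  if (is_complete(session))
    stopf("session is complete; no further attempts are allowed")
  b <- session$board
  i <- aperture_index(b, first)
  j <- aperture_index(b, second)
  if (i == j)
    stopf("an attempt must touch two distinct apertures")
  if (session$matched[i] || session$matched[j])
    stopf("aperture (%d,%d) is covered: its pair was already matched",
          if (session$matched[i]) first[1L] else second[1L],
          if (session$matched[i]) first[2L] else second[2L])
  hit <- b$sounds[i] == b$sounds[j]
  session$n_attempts <- session$n_attempts + 1L
  session$log_first <- c(session$log_first, i)
  session$log_second <- c(session$log_second, j)
  session$log_matched <- c(session$log_matched, hit)
  session$touched[c(i, j)] <- TRUE
  if (hit) {
    session$matched[c(i, j)] <- TRUE
    session$matched_labels <- c(session$matched_labels, b$sounds[i])
  }
  session
}

#' Extract the attempt log of a session
#'
#' @param session A `game_session`.
#' @return An `attempt_log` data frame with columns `attempt_index`,
#'   `first_row`, `first_col`, `second_row`, `second_col`, `first_sound`,
#'   `second_sound`, `matched`.
#' @export
session_log <- function(session) {
  b <- session$board
  fi <- session$log_first
  si <- session$log_second
  log <- data.frame(
    attempt_index = seq_along(fi),
    first_row = b$apertures[fi, 1L], first_col = b$apertures[fi, 2L],
    second_row = b$apertures[si, 1L], second_col = b$apertures[si, 2L],
    first_sound = b$sounds[fi], second_sound = b$sounds[si],
    matched = session$log_matched,
    stringsAsFactors = FALSE)
  class(log) <- c("attempt_log", "data.frame")
  attr(log, "n_pairs") <- b$condition$n_pairs
  log
}

#' Build an attempt log directly from vectors
#'
#' Convenience constructor for fixtures and tests; the result is validated
#' against the game rules.
#'
#' @param first,second n x 2 matrices (or 2-column data frames) of 0-based
#'   positions.
#' @param first_sound,second_sound Character vectors of revealed labels.
#' @return A validated `attempt_log`.
#' @export
attempt_log <- function(first, second, first_sound, second_sound) {
  first <- as.matrix(first); second <- as.matrix(second)
  log <- data.frame(
    attempt_index = seq_len(nrow(first)),
    first_row = as.integer(first[, 1L]), first_col = as.integer(first[, 2L]),
    second_row = as.integer(second[, 1L]), second_col = as.integer(second[, 2L]),
    first_sound = as.character(first_sound),
    second_sound = as.character(second_sound),
    matched = as.character(first_sound) == as.character(second_sound),
    stringsAsFactors = FALSE)
  class(log) <- c("attempt_log", "data.frame")
  validate_attempt_log(log)
}

LOG_COLUMNS <- c("attempt_index", "first_row", "first_col", "second_row",
                 "second_col", "first_sound", "second_sound", "matched")

#' Validate an attempt log against the game rules
#'
#' Checks the structural invariants every legal play sequence satisfies:
#' positions on the grid and off the center, two distinct apertures per
#' attempt, the match flag consistent with the revealed labels, a stable
#' position-to-sound mapping, and no touch of an already-matched site.
#'
#' @param log An `attempt_log` data frame.
#' @return The log, invisibly, or an error naming the offending attempt.
#' @export
validate_attempt_log <- function(log) {
  miss <- setdiff(LOG_COLUMNS, names(log))
  if (length(miss))
    stopf("attempt log is missing columns: %s", paste(miss, collapse = ", "))
  n <- nrow(log)
  if (n == 0L) return(invisible(log))
  if (!identical(as.integer(log$attempt_index), seq_len(n)))
    stopf("attempt_index must run 1..%d", n)
  pos <- c(log$first_row, log$first_col, log$second_row, log$second_col)
  if (any(pos < 0L | pos >= GRID_SIZE))
    stopf("positions must lie on the 5x5 grid (0-based)")
  fk <- pos_key(log$first_row, log$first_col)
  sk <- pos_key(log$second_row, log$second_col)
  ck <- pos_key(CENTER[1L], CENTER[2L])
  bad <- which(fk == ck | sk == ck)
  if (length(bad))
    stopf("attempt %d touches the center feedback speaker", bad[1L])
  bad <- which(fk == sk)
  if (length(bad))
    stopf("attempt %d touches the same aperture twice", bad[1L])
  bad <- which(log$matched != (log$first_sound == log$second_sound))
  if (length(bad))
    stopf("attempt %d: matched flag disagrees with the revealed labels",
          bad[1L])
  # position -> sound mapping must never change
  keys <- c(fk, sk)
  snds <- c(log$first_sound, log$second_sound)
  for (k in unique(keys)) {
    if (length(unique(snds[keys == k])) > 1L)
      stopf("position (%d,%d) reveals more than one sound",
            k %/% GRID_SIZE, k %% GRID_SIZE)
  }
  # matched apertures are covered: they must not appear later
  covered <- integer(0)
  for (t in seq_len(n)) {
    if (fk[t] %in% covered || sk[t] %in% covered)
      stopf("attempt %d touches an aperture whose pair was already matched", t)
    if (log$matched[t]) covered <- c(covered, fk[t], sk[t])
  }
  invisible(log)
}
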