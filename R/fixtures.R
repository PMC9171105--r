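# Canonical worked-example logs used in documentation and tests.
#
# All three fixtures live on the default 4-pair board geometry (first 8
# non-center positions in row-major order) with a fixed hand-written pair
# assignment:
#   a1=(0,0) bee   a2=(0,1) lion  a3=(0,2) frog    a4=(0,3) bee
#   a5=(0,4) rooster  a6=(1,0) lion  a7=(1,1) frog  a8=(1,2) rooster

fixture_board <- function() {
  ap <- default_apertures(game_condition("four_pair"))
  board_from_layout(ap, c("bee", "lion", "frog", "bee",
                          "rooster", "lion", "frog", "rooster"))
}

fx_pos <- function(i) {
  ap <- default_apertures(game_condition("four_pair"))
  ap[i, ]
}

#' Worked-example log for the Score index
#'
#' Four attempts: two first-time touches without a match (0), one old and
#' one new touch without a match (-1), two old touches without a match
#' (-2), then a matched pair (+10). Running total 0 - 1 - 2 + 10 = 7.
#'
#' @return An `attempt_log` scoring exactly 7.
#' @export
fig_score_log <- function() {
  b <- fixture_board()
  s <- new_session(b)
  s <- play_attempt(s, fx_pos(1), fx_pos(2))  # bee, lion   -> 0
  s <- play_attempt(s, fx_pos(1), fx_pos(3))  # bee, frog   -> -1
  s <- play_attempt(s, fx_pos(2), fx_pos(3))  # lion, frog  -> -2
  s <- play_attempt(s, fx_pos(1), fx_pos(4))  # bee, bee    -> +10
  session_log(s)
}

#' Worked-example log for the Audio-Anchor index
#'
#' Three attempts in which attempts 2 and 3 each begin at the same block as
#' the previous attempt's first touch: 0 + 1 + 1 = 2.
#'
#' @return An `attempt_log` with Audio-Anchor exactly 2.
#' @export
fig_anchor_log <- function() {
  b <- fixture_board()
  s <- new_session(b)
  s <- play_attempt(s, fx_pos(1), fx_pos(2))  # bee, lion
  s <- play_attempt(s, fx_pos(1), fx_pos(3))  # starts at a1 again -> +1
  s <- play_attempt(s, fx_pos(1), fx_pos(5))  # starts at a1 again -> +1
  session_log(s)
}

#' Perfect-memory optimal session on the 4-pair fixture board
#'
#' Seven attempts in which every non-matching attempt touches two new
#' blocks (contribution 0) and all four pairs are matched (+10 each):
#' Score 40.
#'
#' @return A complete `attempt_log` scoring 40.
#' @export
perfect_memory_log <- function() {
  b <- fixture_board()
  s <- new_session(b)
  s <- play_attempt(s, fx_pos(1), fx_pos(2))  # bee, lion      0
  s <- play_attempt(s, fx_pos(3), fx_pos(5))  # frog, rooster  0
  s <- play_attempt(s, fx_pos(4), fx_pos(6))  # bee, lion      0
  s <- play_attempt(s, fx_pos(1), fx_pos(4))  # bee pair     +10
  s <- play_attempt(s, fx_pos(2), fx_pos(6))  # lion pair    +10
  s <- play_attempt(s, fx_pos(7), fx_pos(3))  # frog pair    +10
  s <- play_attempt(s, fx_pos(8), fx_pos(5))  # rooster pair +10
  session_log(s)
}

#' Write the canonical fixture logs and board to a directory
#'
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths.
#' @export
make_fixtures <- function(dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    score_example = file.path(dir, "score_example_log.tsv"),
    anchor_example = file.path(dir, "anchor_example_log.tsv"),
    perfect_memory = file.path(dir, "perfect_memory_log.tsv"),
    board = file.path(dir, "fixture_board.json"))
  write_attempt_log(fig_score_log(), paths[["score_example"]])
  write_attempt_log(fig_anchor_log(), paths[["anchor_example"]])
  write_attempt_log(perfect_memory_log(), paths[["perfect_memory"]])
  write_board(fixture_board(), paths[["board"]])
  paths
}
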