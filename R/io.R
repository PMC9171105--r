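# Serialization: attempt logs (flat TSV table or line-delimited JSON
# records, chosen by file extension), board layouts and pipeline
# configuration as JSON, cohort/index tables as TSV.

META_COLUMNS <- c("subject_id", "group", "age", "condition")

log_is_jsonl <- function(path) grepl("\\.jsonl$", path, ignore.case = TRUE)

#' Write an attempt log to disk
#'
#' `.jsonl` paths get one JSON record per attempt; any other extension gets
#' a tab-separated table with a header. Session metadata (`subject_id`,
#' `group`, `age`, `condition`) stored in the log's `meta` attribute is
#' written as leading columns.
#'
#' @param log An `attempt_log`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_attempt_log <- function(log, path) {
  validate_attempt_log(log)
  df <- as.data.frame(log)
  meta <- attr(log, "meta")
  if (!is.null(meta))
    for (nm in rev(META_COLUMNS))
      if (!is.null(meta[[nm]])) df <- cbind(stats::setNames(
        data.frame(rep(meta[[nm]], nrow(df))), nm), df)
  if (log_is_jsonl(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(df)))
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read an attempt log
#'
#' Auto-detects the dialect from the extension (`.jsonl` = line-delimited
#' records, otherwise TSV). The log is validated; malformed rows raise an
#' error naming the line.
#'
#' @param path File written by [write_attempt_log()].
#' @return A validated `attempt_log` (metadata columns, if present, are
#'   moved to the `meta` attribute).
#' @export
read_attempt_log <- function(path) {
  if (log_is_jsonl(path)) {
    lines <- readLines(path)
    recs <- lapply(seq_along(lines), function(i) {
      tryCatch(jsonlite::fromJSON(lines[[i]]),
               error = function(e) stopf("%s: malformed record on line %d: %s",
                                         path, i, conditionMessage(e)))
    })
    df <- do.call(rbind, lapply(recs, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE),
      error = function(e) stopf("%s: %s", path, conditionMessage(e)))
  }
  miss <- setdiff(LOG_COLUMNS, names(df))
  if (length(miss))
    stopf("%s: missing columns: %s", path, paste(miss, collapse = ", "))
  for (nm in c("attempt_index", "first_row", "first_col", "second_row",
               "second_col")) {
    v <- df[[nm]]
    nv <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(nv) | nv != round(nv))
    if (length(bad))
      stopf("%s: malformed value in column %s on line %d", path, nm,
            bad[1L] + 1L)  # +1 for the header line
    df[[nm]] <- as.integer(nv)
  }
  df$matched <- as.logical(df$matched)
  if (anyNA(df$matched))
    stopf("%s: malformed `matched` flag", path)
  meta <- NULL
  if (all(c("subject_id", "condition") %in% names(df)))
    meta <- list(subject_id = df$subject_id[1L], group = df$group[1L],
                 age = df$age[1L], condition = df$condition[1L])
  log <- df[, LOG_COLUMNS]
  class(log) <- c("attempt_log", "data.frame")
  tryCatch(validate_attempt_log(log),
           error = function(e) stopf("%s: %s", path, conditionMessage(e)))
  attr(log, "meta") <- meta
  log
}

#' Write / read a board layout as a small JSON document
#'
#' @param board A `board_layout`.
#' @param path File path.
#' @return `path` (write) or the reconstructed `board_layout` (read).
#' @export
write_board <- function(board, path) {
  stopifnot(inherits(board, "board_layout"))
  doc <- list(condition = board$condition$name,
              n_pairs = board$condition$n_pairs,
              seed = board$seed,
              apertures = unname(apply(board$apertures, 1L, as.integer,
                                       simplify = FALSE)),
              sounds = board$sounds)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}

#' @rdname write_board
#' @export
read_board <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ap <- doc$apertures
  if (is.list(ap)) ap <- do.call(rbind, ap)
  storage.mode(ap) <- "integer"
  board <- board_from_layout(ap, doc$sounds)
  if (doc$condition %in% c("four_pair", "twelve_pair"))
    board$condition <- game_condition(doc$condition)
  board$seed <- doc$seed %||% NA_integer_
  board
}

#' Write / read the per-session index table (TSV)
#'
#' @param table Data frame as produced by [generate_cohort()] or
#'   [cmd_score()].
#' @param path File path.
#' @export
write_index_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_index_table
#' @export
read_index_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
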