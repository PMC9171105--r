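# Pipeline: configuration, the simulate / score / analyze stages and a
# small command-line front end. A config fully determines every output.

#' Pipeline configuration
#'
#' Bundles the cohort specification, optional per-condition aperture
#' geometries, and the statistics settings. Everything is serializable to
#' JSON ([write_config()] / [read_config()]), and all randomness flows from
#' the recorded seeds.
#'
#' @param cohort A [cohort_spec()].
#' @param apertures Optional named list (`four_pair`, `twelve_pair`) of
#'   n x 2 aperture matrices overriding the default geometry.
#' @param n_perm Permutations for every test in the cascade.
#' @param stat_seed Seed of the statistics stage.
#' @param scheme Permutation scheme of the follow-up ANOVAs
#'   (`"raw"` or `"residual"`).
#' @param strata Use subject-restricted permutations in the multivariate
#'   test (`FALSE` reproduces free row permutation).
#' @param alpha Significance threshold of the cascade gates.
#' @param verbosity 0 = silent, 1 = stage progress lines.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(), apertures = NULL,
                            n_perm = 999L, stat_seed = 1L,
                            scheme = "raw", strata = FALSE, alpha = 0.05,
                            verbosity = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (!is_count(n_perm, 1L)) stopf("`n_perm` must be a positive integer")
  structure(list(cohort = cohort, apertures = apertures,
                 n_perm = as.integer(n_perm),
                 stat_seed = as.integer(stat_seed), scheme = scheme,
                 strata = isTRUE(strata), alpha = alpha,
                 verbosity = verbosity),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  doc <- unclass(config)
  doc$cohort <- unclass(doc$cohort)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  gp <- lapply(doc$cohort$group_params, as.list)
  ap <- doc$apertures
  if (!length(ap)) ap <- NULL       # NULL serializes as the empty object
  if (!is.null(ap)) ap <- lapply(ap, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "integer"; m
  })
  pipeline_config(
    cohort = cohort_spec(
      n_per_group = doc$cohort$n_per_group, group_params = gp,
      spread = doc$cohort$spread, age_range = doc$cohort$age_range,
      policy = doc$cohort$policy, master_seed = doc$cohort$master_seed),
    apertures = ap, n_perm = doc$n_perm, stat_seed = doc$stat_seed,
    scheme = doc$scheme, strata = doc$strata, alpha = doc$alpha,
    verbosity = doc$verbosity)
}

say <- function(config, fmt, ...) {
  if ((config$verbosity %||% 1L) >= 1L)
    message(sprintf(paste0("[audiomemory] ", fmt), ...))
}

config_boards <- function(config) {
  if (!length(config$apertures)) return(NULL)
  seeds <- with_seed(config$cohort$master_seed,
                     sample.int(.Machine$integer.max, 2L))
  conds <- c("four_pair", "twelve_pair")
  stats::setNames(lapply(seq_along(conds), function(i) {
    ap <- config$apertures[[conds[i]]]
    new_board(conds[i], seed = seeds[i], apertures = ap)
  }), conds)
}

#' Simulate a cohort and write it to disk
#'
#' Writes the cohort index table (`cohort.tsv`), one attempt log per
#' subject x condition under `logs/`, the board layouts, and a JSON
#' manifest of every seed used.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return The cohort list from [generate_cohort()], invisibly.
#' @export
cmd_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(file.path(out_dir, "logs"), showWarnings = FALSE,
             recursive = TRUE)
  say(config, "simulating cohort (master_seed = %d)",
      config$cohort$master_seed)
  cohort <- generate_cohort(config$cohort, boards = config_boards(config))
  write_index_table(cohort$table, file.path(out_dir, "cohort.tsv"))
  for (nm in names(cohort$logs))
    write_attempt_log(cohort$logs[[nm]],
                      file.path(out_dir, "logs", paste0(nm, ".tsv")))
  for (cond in names(cohort$boards))
    write_board(cohort$boards[[cond]],
                file.path(out_dir, paste0("board_", cond, ".json")))
  manifest <- list(
    master_seed = config$cohort$master_seed,
    session_seeds = lapply(cohort$logs, function(l) attr(l, "meta")$seed),
    n_sessions = length(cohort$logs))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "manifest.json"))
  say(config, "wrote %d sessions to %s", length(cohort$logs), out_dir)
  invisible(cohort)
}

#' Score a set of attempt-log files
#'
#' @param paths Character vector of log files ([write_attempt_log()]
#'   dialects).
#' @param counting Passed to [compute_number_of_attempts()].
#' @param partial Score incomplete sessions: Score and Audio-Anchor are
#'   always computable; Number of Attempts skips unmatched pairs with a
#'   machine-parsable warning and is `NA` when no pair was matched.
#'   `partial = FALSE` insists on complete sessions and errors otherwise.
#' @return One index row per session file: any metadata columns, then
#'   `score`, `number_of_attempts`, `audio_anchor`, `n_attempts_total`.
#' @export
cmd_score <- function(paths, counting = "exclusive", partial = TRUE) {
  rows <- lapply(paths, function(p) {
    log <- read_attempt_log(p)
    noa <- if (partial) {
      tryCatch(compute_number_of_attempts(log, counting, partial = TRUE),
               error = function(e) {
                 warning(sprintf("partial-session scoring: %s: %s",
                                 basename(p), conditionMessage(e)),
                         call. = FALSE)
                 NA_real_
               })
    } else compute_number_of_attempts(log, counting)
    meta <- attr(log, "meta")
    base <- if (!is.null(meta))
      data.frame(subject_id = meta$subject_id, group = meta$group,
                 age = meta$age, condition = meta$condition,
                 stringsAsFactors = FALSE)
    else data.frame(file = basename(p), stringsAsFactors = FALSE)
    cbind(base, data.frame(score = compute_score(log),
                           number_of_attempts = noa,
                           audio_anchor = compute_audio_anchor(log),
                           n_attempts_total = nrow(log)))
  })
  do.call(rbind, rows)
}

#' Run the full inference cascade on a cohort index table
#'
#' Stage 1: the distance-based multivariate permutation test with terms
#' Group, Difficulty, Age and their interactions. Stage 2 (age gate): if no
#' age term is significant at `alpha`, age is dropped and follow-up
#' mixed-design permutation ANOVAs are run per index, provided some
#' non-age term was significant. Stage 3: Bonferroni-corrected permutation
#' t-tests per index (group within each condition, condition within each
#' group; family size 4).
#'
#' @param table Cohort index table (columns `subject_id`, `group`, `age`,
#'   `condition`, `score`, `number_of_attempts`, `audio_anchor`).
#' @param config A [pipeline_config()].
#' @return An `analysis_report` list: `manova`, `age_dropped`, `anova` (per
#'   index), `posthoc` (per index), `group_means`.
#' @export
cmd_analyze <- function(table, config = pipeline_config()) {
  req <- c("subject_id", "group", "age", "condition", "score",
           "number_of_attempts", "audio_anchor")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stopf("index table is missing columns: %s", paste(miss, collapse = ", "))
  tab <- table
  tab$difficulty <- tab$condition
  dz <- mixed_design(tab)  # validates the repeated-measures structure
  indices <- c("score", "number_of_attempts", "audio_anchor")
  alpha <- config$alpha
  say(config, "multivariate permutation test (n_perm = %d)", config$n_perm)
  manova <- dist_perm_manova(
    tab, response_cols = indices, n_perm = config$n_perm,
    seed = config$stat_seed,
    strata = if (config$strata) tab$subject_id else NULL)
  age_terms <- grep("age", names(manova), value = TRUE)
  age_ps <- vapply(manova[age_terms], `[[`, numeric(1), "p_perm")
  age_dropped <- all(age_ps >= alpha)
  other <- setdiff(names(manova), age_terms)
  other_ps <- vapply(manova[other], `[[`, numeric(1), "p_perm")
  run_followups <- any(other_ps < alpha)

  anova <- posthoc <- NULL
  if (run_followups) {
    say(config, "follow-up permutation ANOVAs (%s scheme)%s", config$scheme,
        if (age_dropped) ", age dropped" else " (age kept: interpret with care)")
    anova <- lapply(stats::setNames(indices, indices), function(resp)
      perm_anova(tab, resp, n_perm = config$n_perm,
                 seed = config$stat_seed, scheme = config$scheme))
    groups <- sort(unique(tab$group))
    conds <- sort(unique(tab$condition))
    posthoc <- lapply(stats::setNames(indices, indices), function(resp) {
      cmp <- list()
      for (cond in conds) {
        sub <- tab[tab$condition == cond, ]
        cmp[[paste0("group_within_", cond)]] <- perm_t_test(
          sub[[resp]][sub$group == groups[1L]],
          sub[[resp]][sub$group == groups[2L]],
          n_perm = config$n_perm, seed = config$stat_seed)
      }
      for (g in groups) {
        sub <- tab[tab$group == g, ]
        cmp[[paste0("condition_within_", g)]] <- perm_t_test(
          sub[[resp]][sub$condition == conds[1L]],
          sub[[resp]][sub$condition == conds[2L]],
          n_perm = config$n_perm, seed = config$stat_seed)
      }
      raw_p <- vapply(cmp, `[[`, numeric(1), "p_perm")
      adj <- bonferroni(raw_p, family = length(raw_p))
      for (i in seq_along(cmp)) cmp[[i]]$p_bonferroni <- adj[[i]]
      cmp
    })
  } else {
    say(config, "no significant non-age term: follow-ups skipped")
  }
  gm <- stats::aggregate(tab[indices],
                         by = list(group = tab$group,
                                   condition = tab$condition), mean)
  structure(list(manova = manova, age_dropped = age_dropped,
                 followups_run = run_followups, anova = anova,
                 posthoc = posthoc, group_means = gm,
                 alpha = alpha, n_perm = config$n_perm,
                 seed = config$stat_seed),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("== analysis report (n_perm = %d, seed = %d, alpha = %.2f) ==\n",
              x$n_perm, x$seed, x$alpha))
  cat("-- multivariate permutation test --\n")
  for (tm in names(x$manova)) {
    r <- x$manova[[tm]]
    cat(sprintf("  %-24s pseudo-F = %8.3f  p = %.4f  eta2 = %.3f%s\n",
                tm, r$statistic, r$p_perm, r$effect_size,
                if (r$p_perm < x$alpha) " *" else ""))
  }
  cat(sprintf("-- age %s; follow-ups %s --\n",
              if (x$age_dropped) "dropped (no age term significant)"
              else "kept",
              if (x$followups_run) "run" else "skipped"))
  if (x$followups_run) {
    for (resp in names(x$anova)) {
      cat(sprintf("-- ANOVA: %s --\n", resp))
      for (tm in names(x$anova[[resp]])) {
        r <- x$anova[[resp]][[tm]]
        cat(sprintf("  %-24s F = %8.3f  p = %.4f  eta2 = %.3f%s\n",
                    tm, r$statistic, r$p_perm, r$effect_size,
                    if (r$p_perm < x$alpha) " *" else ""))
      }
      for (cm in names(x$posthoc[[resp]])) {
        r <- x$posthoc[[resp]][[cm]]
        cat(sprintf("  post hoc %-24s t = %7.3f  p = %.4f  p_bonf = %.4f  d = %.3f\n",
                    cm, r$statistic, r$p_perm, r$p_bonferroni,
                    r$effect_size))
      }
    }
  }
  cat("-- group means --\n")
  print(x$group_means, row.names = FALSE)
  invisible(x)
}

#' Flatten an analysis report into a results table
#'
#' @param report An `analysis_report`.
#' @return Data frame: stage, index, term, statistic, p_perm, p_bonferroni,
#'   n_perm, effect_size, effect_size_kind, seed.
#' @export
report_table <- function(report) {
  rows <- list()
  add <- function(stage, index, term, r, p_bonf = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, index = index, term = term, statistic = r$statistic,
      p_perm = r$p_perm, p_bonferroni = p_bonf, n_perm = r$n_perm,
      effect_size = r$effect_size, effect_size_kind = r$effect_size_kind,
      seed = r$seed, stringsAsFactors = FALSE)
  }
  for (tm in names(report$manova))
    add("manova", "multivariate", tm, report$manova[[tm]])
  if (report$followups_run) {
    for (resp in names(report$anova))
      for (tm in names(report$anova[[resp]]))
        add("anova", resp, tm, report$anova[[resp]][[tm]])
    for (resp in names(report$posthoc))
      for (cm in names(report$posthoc[[resp]]))
        add("posthoc", resp, cm, report$posthoc[[resp]][[cm]],
            report$posthoc[[resp]][[cm]]$p_bonferroni)
  }
  do.call(rbind, rows)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --config <json> --out <dir>`,
#' `score --out <tsv> <log files...>`,
#' `analyze --config <json> --table <tsv> --out <dir>`,
#' `report --config <json> --out <dir>` (simulate + score + analyze),
#' `fixtures --out <dir>`.
#'
#' @param args Character vector (default: the actual command line).
#' @return Exit status, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: audiomemory <simulate|score|analyze|report|fixtures> [options]",
    "  simulate --config cfg.json --out DIR",
    "  score    [--out FILE.tsv] LOG...",
    "  analyze  --config cfg.json --table cohort.tsv --out DIR",
    "  report   --config cfg.json --out DIR",
    "  fixtures --out DIR", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[[1L]]; args <- args[-1L]
  opt <- list(files = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (a %in% c("--config", "--out", "--table")) {
      if (i == length(args)) stopf("missing value for %s", a)
      opt[[sub("^--", "", a)]] <- args[[i + 1L]]
      i <- i + 2L
    } else { opt$files <- c(opt$files, a); i <- i + 1L }
  }
  get_config <- function() {
    if (is.null(opt$config)) pipeline_config() else read_config(opt$config)
  }
  switch(cmd,
    simulate = {
      if (is.null(opt$out)) stopf("simulate needs --out")
      cmd_simulate(get_config(), opt$out)
    },
    score = {
      if (!length(opt$files)) stopf("score needs log files")
      tab <- cmd_score(opt$files)
      if (is.null(opt$out)) {
        utils::write.table(tab, stdout(), sep = "\t", quote = FALSE,
                           row.names = FALSE)
      } else write_index_table(tab, opt$out)
    },
    analyze = {
      if (is.null(opt$table) || is.null(opt$out))
        stopf("analyze needs --table and --out")
      config <- get_config()
      rep <- cmd_analyze(read_index_table(opt$table), config)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      write_index_table(report_table(rep),
                        file.path(opt$out, "results.tsv"))
      sink(file.path(opt$out, "report.txt")); print(rep); sink()
    },
    report = {
      if (is.null(opt$out)) stopf("report needs --out")
      config <- get_config()
      cohort <- cmd_simulate(config, opt$out)
      rep <- cmd_analyze(cohort$table, config)
      write_index_table(report_table(rep),
                        file.path(opt$out, "results.tsv"))
      sink(file.path(opt$out, "report.txt")); print(rep); sink()
    },
    fixtures = {
      if (is.null(opt$out)) stopf("fixtures needs --out")
      make_fixtures(opt$out)
    },
    { message(usage); return(invisible(1L)) })
  invisible(0L)
}
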