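# Permutation inference cascade: Welch t-tests by permutation, a two-factor
# (between x within) mixed-design permutation ANOVA with partial eta
# squared, and a distance-based multivariate permutation test (pseudo-F
# partitioning of a Gower-centered distance matrix) with a covariate.
#
# Conventions: Monte-Carlo p-values use the add-one correction
# p = (b + 1) / (n_perm + 1); exhaustive enumerations report the exact
# proportion (including the identity relabeling) and set exhaustive = TRUE.

stat_result <- function(statistic, p_perm, n_perm, effect_size,
                        effect_size_kind, exhaustive, seed, df = NULL) {
  structure(list(statistic = statistic, p_perm = p_perm, n_perm = n_perm,
                 effect_size = effect_size,
                 effect_size_kind = effect_size_kind,
                 exhaustive = exhaustive, seed = seed %||% NA_integer_,
                 df = df),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> statistic = %.4g, p_perm = %.4g (n_perm = %d%s), %s = %.4g\n",
              x$statistic, x$p_perm, x$n_perm,
              if (x$exhaustive) ", exhaustive" else "",
              x$effect_size_kind, x$effect_size))
  invisible(x)
}

#' Welch's t statistic
#'
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with sample variances
#' (denominator n - 1). If both variances are zero and the means are equal
#' the statistic is 0; if the means differ the statistic is infinite and a
#' warning is raised.
#'
#' @param x,y Numeric samples of length >= 2.
#' @return The t statistic.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stopf("both samples need at least 2 observations")
  num <- mean(x) - mean(y)
  den <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  if (den == 0) {
    if (num == 0) return(0)
    warning("zero variance in both samples with unequal means: infinite t",
            call. = FALSE)
    return(sign(num) * Inf)
  }
  num / den
}

#' Cohen's d (pooled standard deviation)
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with
#' `s_pooled^2 = ((nx-1) s2x + (ny-1) s2y) / (nx + ny - 2)`.
#'
#' @param x,y Numeric samples of length >= 2.
#' @return The standardized mean difference.
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stopf("both samples need at least 2 observations")
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) stopf("zero pooled variance: Cohen's d undefined")
  (mean(x) - mean(y)) / sqrt(sp2)
}

# Welch t from pooled vector + index set of the x-group (fast inner loop).
welch_t_split <- function(z, idx, nx, ny) {
  x <- z[idx]; y <- z[-idx]
  num <- sum(x) / nx - sum(y) / ny
  vx <- (sum(x^2) - sum(x)^2 / nx) / (nx - 1)
  vy <- (sum(y^2) - sum(y)^2 / ny) / (ny - 1)
  den <- sqrt(vx / nx + vy / ny)
  if (den == 0) return(if (num == 0) 0 else sign(num) * Inf)
  num / den
}

#' Two-sided permutation test on Welch's t
#'
#' The reference distribution is Welch's t over relabelings of the pooled
#' sample into groups of the original sizes. When the number of distinct
#' splits `choose(nx + ny, nx)` does not exceed `exhaustive_threshold`, all
#' splits are enumerated and the exact proportion with `|t*| >= |t_obs|` is
#' reported; otherwise `n_perm` Monte-Carlo relabelings are drawn and the
#' add-one estimate `p = (b + 1) / (n_perm + 1)` is used. Cohen's d is
#' attached as the effect size.
#'
#' @param x,y Numeric samples of length >= 2.
#' @param n_perm Monte-Carlo permutations (ignored when exhaustive).
#' @param seed Optional seed for the Monte-Carlo draw.
#' @param alternative Only `"two_sided"` is provided.
#' @param exhaustive_threshold Enumerate exhaustively when the number of
#'   splits is at most this value.
#' @return A `stat_result` with the observed t, the permutation p-value and
#'   Cohen's d.
#' @export
perm_t_test <- function(x, y, n_perm = 5000L, seed = NULL,
                        alternative = "two_sided",
                        exhaustive_threshold = 20000L) {
  alternative <- match.arg(alternative, "two_sided")
  t_obs <- welch_t(x, y)
  d <- tryCatch(cohens_d(x, y), error = function(e) NA_real_)
  z <- c(x, y)
  nx <- length(x); ny <- length(y); n <- nx + ny
  n_splits <- choose(n, nx)
  eps <- 1e-12
  if (n_splits <= exhaustive_threshold) {
    splits <- utils::combn(n, nx)
    tstar <- apply(splits, 2L, function(idx) welch_t_split(z, idx, nx, ny))
    p <- mean(abs(tstar) >= abs(t_obs) - eps)
    return(stat_result(t_obs, p, as.integer(n_splits), d, "cohens_d",
                       exhaustive = TRUE, seed = seed))
  }
  b <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n, nx)
      if (abs(welch_t_split(z, idx, nx, ny)) >= abs(t_obs) - eps)
        hits <- hits + 1L
    }
    hits
  })
  stat_result(t_obs, (b + 1) / (n_perm + 1), as.integer(n_perm), d,
              "cohens_d", exhaustive = FALSE, seed = seed)
}

# ---------------------------------------------------------------------------
# Two-factor mixed-design ANOVA (Group between, Difficulty within subject)

# Precompute the integer index structure of a balanced mixed design.
# data must have columns subject_id, group, difficulty and be complete:
# every subject appears once per difficulty level.
mixed_design <- function(data) {
  req <- c("subject_id", "group", "difficulty")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stopf("model table is missing columns: %s", paste(miss, collapse = ", "))
  subj <- factor(data$subject_id)
  grp <- factor(data$group)
  dif <- factor(data$difficulty)
  if (nlevels(dif) != 2L)
    stopf("the within factor must have exactly 2 levels")
  tab <- table(subj, dif)
  if (any(tab != 1L))
    stopf("unbalanced design: every subject needs exactly one row per difficulty level")
  sg <- tapply(as.character(grp), subj, function(g) unique(g))
  if (any(lengths(sg) != 1L))
    stopf("a subject cannot belong to two groups")
  n_per_group <- table(factor(unlist(sg), levels = levels(grp)))
  if (any(n_per_group < 2L))
    stopf("each group needs at least 2 subjects")
  cell <- interaction(grp, dif, drop = TRUE)
  list(subj = as.integer(subj), grp = as.integer(grp), dif = as.integer(dif),
       cell = as.integer(cell),
       n_subj = nlevels(subj), a = nlevels(grp), b = nlevels(dif),
       n_cells = nlevels(cell),
       grp_of_subj = as.integer(factor(unlist(sg), levels = levels(grp))),
       grp_levels = levels(grp), dif_levels = levels(dif))
}

# Classical mixed-design sums of squares / F statistics for a response y.
# Between-subject stratum: Group tested against subject-within-group;
# within-subject stratum: Difficulty and Group:Difficulty tested against
# the difficulty x subject-within-group residual.
mixed_anova_F <- function(y, dz) {
  N <- length(y)
  gm <- mean(y)
  subj_sum <- rowsum(y, dz$subj, reorder = TRUE)
  subj_mean <- subj_sum / dz$b
  grp_sum <- rowsum(y, dz$grp, reorder = TRUE)
  n_g <- tabulate(dz$grp)
  dif_sum <- rowsum(y, dz$dif, reorder = TRUE)
  n_d <- tabulate(dz$dif)
  cell_sum <- rowsum(y, dz$cell, reorder = TRUE)
  n_c <- tabulate(dz$cell)

  ss_total <- sum(y^2) - N * gm^2
  ss_between_subj <- dz$b * sum((subj_mean - gm)^2)
  ss_group <- sum(grp_sum^2 / n_g) - N * gm^2
  ss_subj_g <- ss_between_subj - ss_group
  ss_dif <- sum(dif_sum^2 / n_d) - N * gm^2
  ss_cells <- sum(cell_sum^2 / n_c) - N * gm^2
  ss_int <- ss_cells - ss_group - ss_dif
  ss_err_w <- ss_total - ss_between_subj - ss_dif - ss_int

  df_group <- dz$a - 1L
  df_subj_g <- dz$n_subj - dz$a
  df_dif <- dz$b - 1L
  df_int <- df_group * df_dif
  df_err_w <- df_subj_g * df_dif

  ms <- function(ss, df) if (df > 0) ss / df else NA_real_
  safe_F <- function(ss_e, df_e, ss_r, df_r) {
    mse <- ms(ss_r, df_r)
    if (is.na(mse) || mse <= 0) {
      if (ss_e <= 1e-12) return(0)
      return(Inf)
    }
    ms(ss_e, df_e) / mse
  }
  list(
    F = c(group = safe_F(ss_group, df_group, ss_subj_g, df_subj_g),
          difficulty = safe_F(ss_dif, df_dif, ss_err_w, df_err_w),
          group_x_difficulty = safe_F(ss_int, df_int, ss_err_w, df_err_w)),
    ss = c(group = ss_group, difficulty = ss_dif,
           group_x_difficulty = ss_int,
           subj_within_group = ss_subj_g, error_within = ss_err_w),
    eta = c(group = if (ss_group + ss_subj_g > 0)
                      ss_group / (ss_group + ss_subj_g) else 0,
            difficulty = if (ss_dif + ss_err_w > 0)
                           ss_dif / (ss_dif + ss_err_w) else 0,
            group_x_difficulty = if (ss_int + ss_err_w > 0)
                                   ss_int / (ss_int + ss_err_w) else 0),
    df = c(group = df_group, difficulty = df_dif,
           group_x_difficulty = df_int,
           subj_within_group = df_subj_g, error_within = df_err_w))
}

# Freedman-Lane residual permutation: permute residuals of the reduced model
# (cell-mean fits without the tested term), add back the reduced fit.
fl_reduced_fit <- function(y, dz, term) {
  gm <- mean(y)
  grp_mean <- (rowsum(y, dz$grp) / tabulate(dz$grp))[, 1L]
  dif_mean <- (rowsum(y, dz$dif) / tabulate(dz$dif))[, 1L]
  cell_mean <- (rowsum(y, dz$cell) / tabulate(dz$cell))[, 1L]
  switch(term,
    group = dif_mean[dz$dif],                         # ~ difficulty
    difficulty = grp_mean[dz$grp],                    # ~ group
    group_x_difficulty = grp_mean[dz$grp] + dif_mean[dz$dif] - gm)
}

#' Two-factor mixed-design permutation ANOVA
#'
#' Classical repeated-measures F statistics (Group tested against the
#' subject-within-group stratum; Difficulty and the interaction against the
#' difficulty-by-subject residual) with permutation p-values. The
#' permutation layer replaces only the reference distribution, never the
#' statistic. Two schemes: `"raw"` permutes the response values freely
#' (default); `"residual"` is Freedman-Lane permutation of reduced-model
#' residuals per term. Partial eta squared uses each term's own error
#' stratum: `SS_term / (SS_term + SS_error_for_that_term)`.
#'
#' @param data Data frame with columns `subject_id`, `group`, `difficulty`
#'   and the response; balanced: each subject once per difficulty level.
#' @param response Name of the response column.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @param scheme `"raw"` or `"residual"`.
#' @return A named list of `stat_result` (terms `group`, `difficulty`,
#'   `group_x_difficulty`).
#' @export
perm_anova <- function(data, response, n_perm = 5000L, seed = NULL,
                       scheme = c("raw", "residual")) {
  scheme <- match.arg(scheme)
  if (!response %in% names(data))
    stopf("response column `%s` not found", response)
  dz <- mixed_design(data)
  y <- as.numeric(data[[response]])
  if (anyNA(y)) stopf("missing responses are not allowed")
  obs <- mixed_anova_F(y, dz)
  terms <- c("group", "difficulty", "group_x_difficulty")
  eps <- 1e-12
  hits <- with_seed(seed, {
    h <- c(group = 0L, difficulty = 0L, group_x_difficulty = 0L)
    if (scheme == "raw") {
      for (i in seq_len(n_perm)) {
        Fs <- mixed_anova_F(sample(y), dz)$F
        h <- h + (Fs >= obs$F - eps)
      }
    } else {
      red <- lapply(stats::setNames(terms, terms),
                    function(tm) fl_reduced_fit(y, dz, tm))
      res <- lapply(red, function(f) y - f)
      for (i in seq_len(n_perm)) {
        p <- sample.int(length(y))
        for (tm in terms) {
          ystar <- red[[tm]] + res[[tm]][p]
          Fs <- mixed_anova_F(ystar, dz)$F
          h[tm] <- h[tm] + (Fs[tm] >= obs$F[tm] - eps)
        }
      }
    }
    h
  })
  out <- lapply(stats::setNames(terms, terms), function(tm)
    stat_result(obs$F[[tm]], (hits[[tm]] + 1) / (n_perm + 1),
                as.integer(n_perm), obs$eta[[tm]], "partial_eta_sq",
                exhaustive = FALSE, seed = seed,
                df = c(obs$df[[tm]],
                       if (tm == "group") obs$df[["subj_within_group"]]
                       else obs$df[["error_within"]])))
  attr(out, "scheme") <- scheme
  attr(out, "ss") <- obs$ss
  out
}

# ---------------------------------------------------------------------------
# Distance-based multivariate permutation test (pseudo-F partitioning)

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Sequential hat matrices for a term sequence; returns per-term projector
# differences and degrees of freedom.
sequential_projectors <- function(mf, terms) {
  n <- nrow(mf)
  X <- matrix(1, n, 1L)
  H_prev <- matrix(1 / n, n, n)
  rank_prev <- 1L
  Hs <- list(); dfs <- integer(0)
  for (tm in terms) {
    mm <- stats::model.matrix(stats::as.formula(paste("~", tm)), mf)
    X <- cbind(X, mm[, -1L, drop = FALSE])
    qrX <- qr(X)
    rank <- qrX$rank
    Q <- qr.Q(qrX)[, seq_len(rank), drop = FALSE]
    H <- tcrossprod(Q)
    Hs[[tm]] <- H - H_prev
    dfs <- c(dfs, rank - rank_prev)
    H_prev <- H
    rank_prev <- rank
  }
  list(term_proj = Hs, df = stats::setNames(dfs, terms),
       resid_proj = diag(n) - H_prev, df_resid = n - rank_prev)
}

#' Distance-based multivariate permutation test with covariate
#'
#' Partitions a Gower-centered distance matrix among sequentially added
#' model terms (Type-I sums of squares) and tests each term's pseudo-F by
#' permuting rows of the distance matrix, optionally within strata. With a
#' univariate response and Euclidean distances the pseudo-F of a single
#' between factor reduces to the classical one-way ANOVA F.
#'
#' @param data Data frame holding the model variables.
#' @param response_cols Character vector of response column names; columns
#'   are z-standardized before Euclidean distances when `standardize` is
#'   `TRUE` (the indices are on incommensurate scales).
#' @param terms Model terms added in order (interactions in formula syntax,
#'   e.g. `"group:age"`). Default: main effects `group`, `difficulty`,
#'   `age`, then all their interactions.
#' @param n_perm Monte-Carlo permutations.
#' @param seed Optional seed.
#' @param strata Optional factor (e.g. subject id) restricting permutations
#'   to within-stratum rearrangements. The default (`NULL`) permutes rows
#'   freely.
#' @param standardize z-standardize response columns first.
#' @param exhaustive_threshold Enumerate all row permutations when
#'   `factorial(n)` is at most this value (and `strata` is `NULL`).
#' @return Named list of `stat_result` per term, effect size = multivariate
#'   partial eta squared `SS_term / (SS_term + SS_residual)`.
#' @export
dist_perm_manova <- function(data, response_cols,
                             terms = c("group", "difficulty", "age",
                                       "group:difficulty", "group:age",
                                       "difficulty:age",
                                       "group:difficulty:age"),
                             n_perm = 999L, seed = NULL, strata = NULL,
                             standardize = TRUE,
                             exhaustive_threshold = 0L) {
  miss <- setdiff(response_cols, names(data))
  if (length(miss))
    stopf("response columns not found: %s", paste(miss, collapse = ", "))
  Y <- as.matrix(data[, response_cols, drop = FALSE])
  if (anyNA(Y)) stopf("missing responses are not allowed")
  n <- nrow(Y)
  if (n < 2L) stopf("need at least 2 rows")
  if (standardize) {
    sds <- apply(Y, 2L, stats::sd)
    if (any(sds == 0)) stopf("cannot standardize a constant response column")
    Y <- scale(Y)
  }
  D <- as.matrix(stats::dist(Y))
  G <- gower_center(D)
  ss_total <- sum(diag(G))
  if (ss_total <= 0) stopf("zero total sum of squares")
  proj <- sequential_projectors(data, terms)
  if (any(proj$df == 0L))
    stopf("singular term (no variation): %s",
          paste(terms[proj$df == 0L], collapse = ", "))
  tr_term <- vapply(proj$term_proj, function(H) sum(H * G), numeric(1))
  ss_res <- sum(proj$resid_proj * G)
  F_obs <- (tr_term / proj$df) / (ss_res / proj$df_resid)
  eta <- tr_term / (tr_term + ss_res)
  eps <- 1e-12

  perm_F <- function(p) {
    Gp <- G[p, p]
    ssr <- sum(proj$resid_proj * Gp)
    tt <- vapply(proj$term_proj, function(H) sum(H * Gp), numeric(1))
    (tt / proj$df) / (ssr / proj$df_resid)
  }

  exhaustive <- is.null(strata) && factorial(n) <= exhaustive_threshold
  if (exhaustive) {
    perms <- all_permutations(n)
    Fstar <- vapply(seq_len(nrow(perms)),
                    function(i) perm_F(perms[i, ]),
                    numeric(length(terms)))      # terms x n!
    hits <- rowSums(matrix(Fstar >= F_obs - eps, nrow = length(terms)))
    p_val <- hits / nrow(perms)
    n_used <- nrow(perms)
  } else {
    if (!is.null(strata)) {
      strata <- as.integer(factor(strata))
      if (length(strata) != n) stopf("`strata` must have one entry per row")
      groups <- split(seq_len(n), strata)
    }
    hits <- with_seed(seed, {
      h <- numeric(length(terms))
      for (i in seq_len(n_perm)) {
        p <- if (is.null(strata)) sample.int(n) else {
          out <- integer(n)
          for (g in groups) out[g] <- g[sample.int(length(g))]
          out
        }
        h <- h + (perm_F(p) >= F_obs - eps)
      }
      h
    })
    p_val <- (hits + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  out <- lapply(seq_along(terms), function(k)
    stat_result(F_obs[[k]], p_val[[k]], as.integer(n_used), eta[[k]],
                "partial_eta_sq", exhaustive = exhaustive, seed = seed,
                df = c(proj$df[[k]], proj$df_resid)))
  names(out) <- terms
  attr(out, "ss") <- c(stats::setNames(tr_term, terms),
                       residual = ss_res, total = ss_total)
  out
}

# Gower double-centering of a distance matrix: G = J A J with
# A = -D^2 / 2 and J = I - 11'/n.
gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size and caps at 1.
#'
#' @param p Vector of p-values in (0, 1].
#' @param family Family size; defaults to `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, family = length(p)) {
  if (!length(p)) stopf("empty p-value list")
  if (any(p <= 0 | p > 1)) stopf("p-values must lie in (0, 1]")
  pmin(p * family, 1)
}
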