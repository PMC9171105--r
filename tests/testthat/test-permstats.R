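# Permutation inference cascade against independent oracles.

test_that("welch_t matches the closed formula and t.test", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  expect_equal(welch_t(x, y), oracle_welch_t(x, y))
  expect_equal(welch_t(x, y), unname(t.test(x, y)$statistic))
  set.seed(1)
  for (i in 1:25) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1), sd = 2)
    expect_equal(welch_t(x, y), unname(t.test(x, y)$statistic))
    expect_equal(welch_t(y, x), -welch_t(x, y))
  }
  expect_identical(welch_t(c(1, 1), c(1, 1)), 0)
  expect_warning(tt <- welch_t(c(1, 1), c(2, 2)), "infinite")
  expect_identical(tt, -Inf)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("cohens_d matches the pooled-SD formula", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_identical(cohens_d(c(1, 2), c(1, 2)), 0)
  expect_error(cohens_d(c(0, 0), c(1, 1)), "pooled variance")
  set.seed(2)
  x <- rnorm(8); y <- rnorm(5)
  sp <- sqrt((7 * var(x) + 4 * var(y)) / 11)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp)
})

test_that("exhaustive permutation p equals brute-force enumeration", {
  x <- c(1, 2); y <- c(10, 11)
  r <- perm_t_test(x, y)
  expect_true(r$exhaustive)
  expect_identical(r$n_perm, 6L)
  z <- c(x, y)
  tstar <- apply(combn(4, 2), 2, function(idx)
    oracle_welch_t(z[idx], z[-idx]))
  expect_equal(r$p_perm, mean(abs(tstar) >= abs(oracle_welch_t(x, y)) - 1e-12))
  # (3,3): 20 splits
  set.seed(3)
  x <- rnorm(3); y <- rnorm(3, 2)
  r <- perm_t_test(x, y)
  expect_identical(r$n_perm, 20L)
  z <- c(x, y)
  tstar <- apply(combn(6, 3), 2, function(idx)
    oracle_welch_t(z[idx], z[-idx]))
  expect_equal(r$p_perm, mean(abs(tstar) >= abs(oracle_welch_t(x, y)) - 1e-12))
})

test_that("permutation p is invariant to shifts and label swaps", {
  set.seed(4)
  x <- rnorm(4); y <- rnorm(4, 1)
  r1 <- perm_t_test(x, y)
  r2 <- perm_t_test(x + 100, y + 100)   # location shift of the pooled sample
  r3 <- perm_t_test(y, x)               # swapping group labels
  expect_equal(r1$p_perm, r2$p_perm)
  expect_equal(r1$p_perm, r3$p_perm)
  expect_equal(r1$statistic, -r3$statistic)
})

test_that("Monte-Carlo p agrees with the exhaustive proportion", {
  set.seed(5)
  x <- rnorm(5); y <- rnorm(5, 1.2)
  exact <- perm_t_test(x, y)$p_perm            # C(10,5) = 252, enumerated
  n_perm <- 4000
  mc <- perm_t_test(x, y, n_perm = n_perm, seed = 9,
                    exhaustive_threshold = 0)$p_perm
  expect_false(perm_t_test(x, y, n_perm = 10, seed = 1,
                           exhaustive_threshold = 0)$exhaustive)
  se <- sqrt(exact * (1 - exact) / n_perm)
  expect_lt(abs(mc - exact), 3 * se + 1 / n_perm)
  # add-one convention: p is never 0 and at least 1/(n_perm+1)
  mc2 <- perm_t_test(c(1, 2, 3), c(101, 102, 103) * 5, n_perm = 99, seed = 1,
                     exhaustive_threshold = 0)
  expect_gte(mc2$p_perm, 1 / 100)
})

test_that("mixed-design F statistics reproduce the classical aov strata", {
  set.seed(6)
  for (i in 1:8) {
    tab <- make_model_table(n_per_group = sample(3:8, 1),
                            group_delta = runif(1, 0, 2),
                            diff_delta = runif(1, 0, 2),
                            int_delta = runif(1, 0, 1))
    r <- perm_anova(tab, "y", n_perm = 5, seed = 1)
    ao <- summary(aov(y ~ group * difficulty + Error(subject_id / difficulty),
                      data = tab))
    f_between <- ao[["Error: subject_id"]][[1]]
    f_within <- ao[[grep("difficulty", names(ao))[1]]][[1]]
    fv <- function(tab, term) tab[trimws(rownames(tab)) == term, "F value"]
    expect_equal(r$group$statistic, fv(f_between, "group"),
                 tolerance = 1e-10)
    expect_equal(r$difficulty$statistic, fv(f_within, "difficulty"),
                 tolerance = 1e-10)
    expect_equal(r$group_x_difficulty$statistic,
                 fv(f_within, "group:difficulty"), tolerance = 1e-10)
  }
})

test_that("constant responses give zero F and zero effect size", {
  tab <- make_model_table(4)
  tab$y <- 5
  r <- perm_anova(tab, "y", n_perm = 20, seed = 1)
  for (tm in names(r)) {
    expect_identical(r[[tm]]$statistic, 0)
    expect_identical(r[[tm]]$effect_size, 0)
  }
})

test_that("perm_anova detects an injected group effect, raw and residual", {
  set.seed(7)
  tab <- make_model_table(12, group_delta = 2)
  for (scheme in c("raw", "residual")) {
    r <- perm_anova(tab, "y", n_perm = 400, seed = 2, scheme = scheme)
    expect_lt(r$group$p_perm, 0.05)
    expect_gt(r$difficulty$p_perm, 0.05)
    expect_gt(r$group$effect_size, 0.1)
  }
})

test_that("raw-scheme Monte-Carlo p matches exhaustive response enumeration", {
  # tiny design: 2 subjects per group, 8 responses -> 8! = 40320 relabelings
  set.seed(8)
  tab <- make_model_table(2, group_delta = 1.5)
  r <- perm_anova(tab, "y", n_perm = 4000, seed = 3, scheme = "raw")
  # independent oracle: enumerate all 40320 permutations; the group-term F
  # is computed from subject means by an explicit one-way decomposition
  group_F <- function(y) {
    sm <- (y[c(1, 3, 5, 7)] + y[c(2, 4, 6, 8)]) / 2  # subject means
    g <- c(1, 1, 2, 2)
    ssb <- 2 * sum(tapply(sm, g, function(v) length(v) * (mean(v) - mean(sm))^2))
    ssw <- 2 * sum((sm - ave(sm, g))^2)
    (ssb / 1) / (ssw / 2)
  }
  perms <- audiomemory:::all_permutations(8L)
  f_obs <- group_F(tab$y)
  fstar <- apply(perms, 1, function(p) group_F(tab$y[p]))
  exact <- mean(fstar >= f_obs - 1e-12)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(r$group$p_perm - exact), 3 * se + 1 / 4000)
})

test_that("unbalanced or malformed model tables are rejected", {
  tab <- make_model_table(3)
  expect_error(perm_anova(tab[-1, ], "y", n_perm = 10), "unbalanced")
  expect_error(perm_anova(tab, "z", n_perm = 10), "not found")
  tab2 <- make_model_table(2)
  tab2$group[1:2] <- "g2"  # leaves one group with a single subject
  expect_error(perm_anova(tab2, "y", n_perm = 10), "at least 2 subjects")
})

test_that("univariate euclidean pseudo-F reduces to the classical F", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(c(9, 12, 15), 1)
    d <- data.frame(group = rep(c("a", "b", "c"), n / 3), y = rnorm(n))
    r <- dist_perm_manova(d, "y", terms = "group", n_perm = 19, seed = 1,
                          standardize = FALSE)
    f_cl <- anova(lm(y ~ group, d))[["F value"]][1]
    expect_lt(abs(r$group$statistic - f_cl), 1e-9)
  }
})

test_that("pseudo-F per term matches vegan::adonis2 sequential partitioning", {
  set.seed(10)
  n <- 10
  meta <- data.frame(group = rep(c("a", "b"), each = n),
                     difficulty = rep(c("e", "h"), n),
                     age = runif(2 * n, 12, 54))
  Y <- matrix(rnorm(2 * n * 3), ncol = 3,
              dimnames = list(NULL, c("i1", "i2", "i3")))
  tab <- cbind(meta, Y)
  terms <- c("group", "difficulty", "age", "group:difficulty")
  r <- dist_perm_manova(tab, colnames(Y), terms = terms, n_perm = 19,
                        seed = 2, standardize = TRUE)
  ad <- vegan::adonis2(scale(Y) ~ group + difficulty + age + group:difficulty,
                       data = meta, method = "euclidean", by = "terms",
                       permutations = 19)
  for (k in seq_along(terms)) {
    expect_equal(r[[terms[k]]]$statistic, ad$F[k], tolerance = 1e-8)
    expect_equal(attr(r, "ss")[[terms[k]]], ad$SumOfSqs[k], tolerance = 1e-8)
  }
})

test_that("exhaustive row enumeration matches a brute-force oracle", {
  set.seed(11)
  d <- data.frame(group = rep(c("a", "b"), each = 3),
                  y1 = rnorm(6), y2 = rnorm(6))
  r <- dist_perm_manova(d, c("y1", "y2"), terms = "group",
                        exhaustive_threshold = 720, standardize = FALSE)
  expect_true(r$group$exhaustive)
  expect_identical(r$group$n_perm, 720L)
  # oracle: explicit hat-matrix pseudo-F over all 720 row permutations
  Y <- as.matrix(d[, c("y1", "y2")])
  D2 <- as.matrix(dist(Y))^2
  n <- 6
  J <- diag(n) - 1 / n
  G <- J %*% (-D2 / 2) %*% J
  X <- model.matrix(~group, d)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  H0 <- matrix(1 / n, n, n)
  pseudoF <- function(p) {
    Gp <- G[p, p]
    ss_t <- sum((H - H0) * Gp)
    ss_r <- sum((diag(n) - H) * Gp)
    (ss_t / 1) / (ss_r / (n - 2))
  }
  perms <- audiomemory:::all_permutations(6L)
  f_obs <- pseudoF(1:6)
  expect_equal(r$group$statistic, f_obs, tolerance = 1e-10)
  fstar <- apply(perms, 1, pseudoF)
  expect_equal(r$group$p_perm, mean(fstar >= f_obs - 1e-12))
})

test_that("duplicating every row preserves the SS partition proportions", {
  set.seed(12)
  d <- data.frame(group = rep(c("a", "b"), each = 4),
                  difficulty = rep(c("e", "h"), 4),
                  age = runif(8, 12, 54),
                  y1 = rnorm(8), y2 = rnorm(8))
  d2 <- rbind(d, d)
  terms <- c("group", "difficulty", "age")
  r1 <- dist_perm_manova(d, c("y1", "y2"), terms = terms, n_perm = 19,
                         seed = 1, standardize = FALSE)
  r2 <- dist_perm_manova(d2, c("y1", "y2"), terms = terms, n_perm = 19,
                         seed = 1, standardize = FALSE)
  ss1 <- attr(r1, "ss"); ss2 <- attr(r2, "ss")
  # every SS component exactly doubles, so eta^2 per term is unchanged
  for (tm in terms) {
    expect_equal(ss2[[tm]], 2 * ss1[[tm]], tolerance = 1e-9)
    expect_equal(r2[[tm]]$effect_size, r1[[tm]]$effect_size,
                 tolerance = 1e-9)
  }
})

test_that("strata-restricted permutation stays within subjects", {
  set.seed(13)
  n <- 8
  d <- data.frame(subject = rep(sprintf("s%d", 1:n), each = 2),
                  group = rep(c("a", "b"), each = n),
                  difficulty = rep(c("e", "h"), n),
                  age = rep(runif(n, 12, 54), each = 2),
                  y1 = rnorm(2 * n), y2 = rnorm(2 * n))
  # within-subject strata cannot move rows across groups: with `group` as
  # the only term both SS traces are permutation-invariant, so p must be 1
  r <- dist_perm_manova(d, c("y1", "y2"), terms = "group",
                        n_perm = 99, seed = 4, strata = d$subject)
  expect_equal(r$group$p_perm, 1, tolerance = 1e-12)
  # difficulty does vary within subject, so its p is a proper estimate
  r2 <- dist_perm_manova(d, c("y1", "y2"), terms = "difficulty",
                         n_perm = 99, seed = 4, strata = d$subject)
  expect_true(r2$difficulty$p_perm <= 1 && r2$difficulty$p_perm > 0)
  expect_identical(
    r2$difficulty$p_perm,
    dist_perm_manova(d, c("y1", "y2"), terms = "difficulty", n_perm = 99,
                     seed = 4, strata = d$subject)$difficulty$p_perm)
})

test_that("bonferroni multiplies by the family size and caps at 1", {
  expect_equal(bonferroni(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni(0.2), 0.2)
  expect_equal(bonferroni(c(0.6, 0.9)), c(1, 1))
  expect_equal(bonferroni(c(0.01, 0.04), family = 4), c(0.04, 0.16))
  expect_error(bonferroni(numeric(0)), "empty")
  expect_error(bonferroni(c(0.5, 0)), "lie in")
})
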