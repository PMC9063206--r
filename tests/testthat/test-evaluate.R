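# Metrics: DeLong AUROC vs the exhaustive pairwise oracle, confusion
# arithmetic, cohort comparison statistics, and grouped Shapley
# properties on a closed-form surrogate.

test_that("AUROC: separation, ties, and exact agreement with the pairwise oracle", {
  expect_equal(auroc_delong(c(1, 2, 3, 10, 11, 12),
                            c(F, F, F, T, T, T))$auroc, 1.0)
  expect_equal(auroc_delong(rep(1, 10), rep(c(TRUE, FALSE), 5))$auroc, 0.5)
  expect_error(auroc_delong(1:5, rep(TRUE, 5)))

  set.seed(21)
  for (n in c(20, 87, 240)) {
    y <- runif(n) < 0.4
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n, mean = as.numeric(y)), 1)  # induces ties
    expect_equal(auroc_delong(s, y)$auroc, brute_auroc(s, y),
                 tolerance = 1e-12)
  }
})

test_that("DeLong interval brackets the point estimate and respects [0,1]", {
  set.seed(2)
  y <- rep(c(TRUE, FALSE), each = 40)
  s <- rnorm(80, as.numeric(y) * 3)   # near-perfect separation
  r <- auroc_delong(s, y)
  expect_lte(r$ci_low, r$auroc)
  expect_gte(r$ci_high, r$auroc)
  expect_lte(r$ci_high, 1)
  expect_gte(r$ci_low, 0)
})

test_that("confusion-matrix metrics follow their definitions", {
  # TP=8 FP=2 FN=2 TN=8 at threshold 0.5
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.8, 2), rep(0.2, 8))
  labels <- c(rep(TRUE, 8), rep(TRUE, 2), rep(FALSE, 2), rep(FALSE, 8))
  m <- classification_metrics(scores, labels)
  expect_equal(m$precision, 0.8)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f_score, 0.8)
  expect_equal(m$n, 20L)
  expect_equal(m$n_positive, 10L)

  m2 <- classification_metrics(c(0.9, 0.8, 0.7, 0.2), c(T, T, T, F))
  expect_equal(m2$accuracy, 1)
  expect_warning(
    m3 <- classification_metrics(c(0.1, 0.2, 0.3, 0.4), c(T, F, T, F)),
    "no predicted positives")
  expect_equal(m3$precision, 0)
})

test_that("cohort comparison: t-tests, chi-square and degenerate cases", {
  a <- data.frame(x = c(rnorm(50)), g = rep(c("u", "v"), 25), z = 1)
  r <- compare_cohorts(a, a)
  expect_equal(r$p_value[r$variable == "x"], 1)
  expect_equal(r$statistic[r$variable == "g"], 0)
  expect_equal(r$p_value[r$variable == "z"], 1)
  expect_match(r$note[r$variable == "z"], "zero variance")

  # balanced 2x2 table -> statistic 0
  b <- data.frame(g = rep(c("u", "v"), each = 50))
  r2 <- compare_cohorts(b, b)
  expect_equal(r2$statistic, 0)

  # a one-sd mean shift at n = 500/500 is detected
  set.seed(3)
  r3 <- compare_cohorts(data.frame(x = rnorm(500)),
                        data.frame(x = rnorm(500, 1)))
  expect_lt(r3$p_value, 0.05)
  expect_true(r3$significant)

  expect_error(compare_cohorts(a, b), class = "dreamHF_config_error")
})

test_that("grouped Shapley: exact efficiency, dummy player, and seed stability", {
  set.seed(9)
  d <- 8
  X <- matrix(rnorm(60 * d), 60, d)
  base <- rnorm(d)
  groups <- list(g1 = 1:3, g2 = 4:5, g3 = 6:8)

  # linear model: phi_g = sum_{j in g} a_j (x_j - base_j), in closed form
  a <- c(1, -2, 0.5, 3, 0, -1, 2, 0.25)
  f_lin <- function(M) as.numeric(M %*% a)
  sh <- grouped_shapley(f_lin, X, groups, base, n_perm = 8, seed = 1)
  closed <- sapply(groups, function(g)
    mean(abs(t(t(X[, g, drop = FALSE]) - base[g]) %*% a[g])))
  expect_equal(sh$mean_abs, unname(closed), tolerance = 1e-10)

  # nonlinear model: efficiency still holds per instance
  f_nl <- function(M) as.numeric(tanh(M[, 1] * M[, 4]) + M[, 6]^2)
  sh2 <- grouped_shapley(f_nl, X, groups, base, n_perm = 20, seed = 2)
  expect_equal(sum(sh2$mean_signed), mean(f_nl(X)) -
                 mean(f_nl(matrix(base, 60, d, byrow = TRUE))),
               tolerance = 1e-10)

  # dummy group: model ignores g2 entirely
  f_dummy <- function(M) as.numeric(M[, 1] + M[, 7])
  sh3 <- grouped_shapley(f_dummy, X, groups, base, n_perm = 5, seed = 3)
  expect_equal(sh3$mean_abs[sh3$group == "g2"], 0, tolerance = 1e-12)

  # two seeds agree within Monte-Carlo error
  sh4 <- grouped_shapley(f_nl, X, groups, base, n_perm = 40, seed = 4)
  sh5 <- grouped_shapley(f_nl, X, groups, base, n_perm = 40, seed = 5)
  expect_true(all(abs(sh4$mean_abs - sh5$mean_abs) <=
                    3 * (sh4$mc_se + sh5$mc_se) + 1e-9))

  expect_error(grouped_shapley(f_lin, X, list(g = 1:3), base),
               class = "dreamHF_config_error")
})

test_that("feature-family partition covers every column exactly once", {
  sp <- small_pipeline()
  log <- build_event_log(sp$tables, sp$split$validation, sp$art)
  X <- tss_matrix(log, sp$net, sp$alphas)
  g <- feature_groups(sp$net, colnames(X), paste0("d", 1:8),
                      c("charlson", "elixhauser"))
  idx <- sort(unlist(g))
  expect_equal(unname(idx), seq_len(ncol(X) + 10))
  expect_true(all(c("severity", "demographics", "comorbidity_events",
                    "lab_events", "admission_events") %in% names(g)))
})
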