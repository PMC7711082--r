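test_that("wilcoxon rank-sum handles identical groups and rejects empty ones", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact wilcoxon p equals assignment enumeration", {
  # hand example: all mass on one side
  res <- wilcoxon_rank_sum(c(1, 2), c(10, 20))
  expect_equal(res$p_value, 1 / 3)
  expect_true(res$exact)
  # random tie-free instances across sizes
  set.seed(71)
  for (rep in 1:40) {
    nx <- sample(2:5, 1)
    ny <- sample(2:5, 1)
    vals <- sample(1000, nx + ny) / 7
    x <- vals[seq_len(nx)]
    y <- vals[-seq_len(nx)]
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, enum_wilcoxon_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact p at moderate n", {
  set.seed(72)
  x <- c(2.1, 5.3, 1.7, 8.2, 4.4, 6.6)
  y <- c(9.9, 3.2, 12.5, 10.1, 7.7, 11.3)
  exact_p <- enum_wilcoxon_p(x, y)
  approx_p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  expect_equal(signif(approx_p, 2), signif(exact_p, 2), tolerance = 0.05)
})

test_that("roc_auc reproduces canonical and enumerated values", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_equal(roc_auc(c(3, 1, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("roc_auc equals pair counting on random instances", {
  set.seed(73)
  for (rep in 1:60) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(round(rnorm(n), 1))  # induces occasional ties
    expect_equal(roc_auc(scores, labels)$auc,
                 pair_count_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("ROC curve is monotone and consistent with its AUC", {
  set.seed(74)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4)
  res <- roc_auc(scores, labels)
  expect_true(all(diff(res$roc$fpr) >= 0))
  expect_true(all(diff(res$roc$tpr) >= 0))
  expect_equal(res$roc$fpr[1], 0)
  expect_equal(res$roc$tpr[nrow(res$roc)], 1)
  # complement symmetry for tie-free scores
  tie_free <- rank(scores) / 10
  expect_equal(roc_auc(tie_free, labels)$auc +
                 roc_auc(-tie_free, labels)$auc, 1)
})

test_that("median_split applies the <=-median tie rule", {
  g <- median_split(c(1, 2, 3, 4))
  expect_equal(as.vector(table(g)), c(2, 2))
  g2 <- median_split(c(1, 2, 2, 3))
  expect_equal(as.character(g2), c("low", "low", "low", "high"))
  g3 <- median_split(c(1, 2, 3))
  expect_equal(as.character(g3), c("low", "low", "high"))
  expect_error(median_split(5), "at least 2")
})

test_that("log-rank matches the hand-computed four-sample example", {
  groups <- c("A", "A", "B", "B")
  res <- km_logrank(groups, time = c(1, 2, 3, 4), event = rep(1, 4))
  # O_A = 2, E_A = 1/2 + 1/3, V = 1/4 + 2/9 -> chi-square = 49/17
  expect_equal(res$chisq, 49 / 17, tolerance = 1e-6)
  expect_false(res$degenerate)
})

test_that("identical groups give chi-square 0 and p 1", {
  groups <- rep(c("A", "B"), each = 3)
  res <- km_logrank(groups, time = c(1, 2, 3, 1, 2, 3),
                    event = rep(1, 6))
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
})

test_that("log-rank is invariant to relabeling the groups", {
  set.seed(75)
  n <- 40
  groups <- rep(c("low", "high"), each = n / 2)
  time <- rexp(n, 0.1)
  event <- rbinom(n, 1, 0.8)
  a <- km_logrank(groups, time, event)
  swapped <- ifelse(groups == "low", "high", "low")
  b <- km_logrank(swapped, time, event)
  expect_equal(a$chisq, b$chisq, tolerance = 1e-10)
})

test_that("KM curves are valid survival functions", {
  set.seed(76)
  n <- 30
  groups <- rep(c("low", "high"), each = n / 2)
  time <- rexp(n, 0.2)
  event <- rbinom(n, 1, 0.7)
  res <- km_logrank(groups, time, event)
  for (curve in res$curves) {
    expect_true(all(diff(curve$survival) <= 1e-12))
    expect_true(all(curve$survival >= 0 & curve$survival <= 1))
  }
  # with no censoring the KM curve equals the empirical survival function
  res2 <- km_logrank(groups, time, rep(1, n))
  for (g in c("low", "high")) {
    curve <- res2$curves[[g]]
    tg <- time[groups == g]
    emp <- vapply(curve$time, function(t) mean(tg > t), numeric(1))
    expect_equal(curve$survival, emp, tolerance = 1e-12)
  }
})

test_that("degenerate survival input is flagged", {
  # all of group B censored before any event
  groups <- c("A", "A", "A", "B", "B")
  res <- km_logrank(groups, time = c(1, 2, 3, 0.5, 0.5),
                    event = c(1, 1, 1, 0, 0))
  expect_true(res$degenerate)
  # no events at all: statistic undefined
  res2 <- km_logrank(c("A", "A", "B", "B"), time = 1:4, event = rep(0, 4))
  expect_true(res2$degenerate)
  expect_true(is.na(res2$chisq))
})

test_that("spearman correlation matches direct rank computation", {
  expect_equal(spearman_corr(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_corr(1:3, c(30, 20, 10))$rho, -1)
  res <- spearman_corr(1:4, c(2, 1, 4, 3))
  expect_equal(res$rho, 0.6)
  expect_true(spearman_corr(c(1, 1, 1), c(1, 2, 3))$degenerate)
  expect_error(spearman_corr(1:2, 1:2), "at least 3")
})

test_that("spearman p-value uses the t approximation", {
  set.seed(77)
  x <- rnorm(20)
  y <- x + rnorm(20, sd = 2)
  res <- spearman_corr(x, y)
  want <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
  expect_equal(res$p_value, want, tolerance = 1e-10)
})

test_that("evaluate_cohort assembles per-stratum results", {
  co <- simulate_cohort(simulation_params(
    n_genes = 300, n_samples = 120, n_signal_genes = 60,
    effect_size = 1.5, hazard_coef = 1.5, seed = 3))
  sig <- truth_signature(co$truth)
  s <- score_samples(co$expression, sig, n_permutations = 60, seed = 1)
  co$clinical$erg_expr <- co$truth$latent_activity + rnorm(120, sd = 0.3)
  rep <- evaluate_cohort(s, co$clinical, evaluation_config(
    correlation_columns = "erg_expr"))
  expect_s3_class(rep, "evaluation_report")
  allstr <- rep$all
  expect_false(allstr$skipped)
  expect_lt(allstr$fusion_comparison$p_value, 1e-6)
  expect_gt(allstr$fusion_roc$auc, 0.9)
  expect_lt(allstr$survival$p_value, 0.05)
  expect_gt(allstr$survival$high_score_excess_events, 0)
  expect_gt(allstr$correlations$erg_expr$rho, 0.5)
  expect_false(rep$gleason_7$skipped)
})

test_that("empty strata are recorded as skipped with a reason", {
  co <- tiny_cohort(seed = 12)
  co$clinical$gleason <- 6L  # no Gleason-7 samples
  sig <- truth_signature(co$truth)
  s <- score_samples(co$expression, sig, n_permutations = 30, seed = 1)
  rep <- evaluate_cohort(s, co$clinical)
  expect_true(rep$gleason_7$skipped)
  expect_equal(rep$gleason_7$n, 0L)
  expect_match(rep$gleason_7$reason, "empty")
})

test_that("binary outcome columns get their own ROC", {
  co <- tiny_cohort(seed = 14)
  sig <- truth_signature(co$truth)
  s <- score_samples(co$expression, sig, n_permutations = 30, seed = 1)
  co$clinical$outcome <- ifelse(s > median(s), "lethal", "indolent")
  rep <- evaluate_cohort(s, co$clinical,
                         evaluation_config(roc_columns = "outcome"))
  expect_equal(rep$all$outcome_roc$outcome$auc, 1.0)
})
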