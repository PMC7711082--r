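# Independent oracles used to validate the package implementations.
# Each one is a deliberately naive re-derivation (loops, enumeration,
# brute-force optimization) kept separate from the code paths it checks.

# Running-sum pre-score by explicit loop over every cut position.
brute_prescore <- function(v) {
  v <- unname(v)
  n <- length(v)
  vsum <- sum(v)
  bsum <- n - vsum
  best <- -Inf
  best_d <- 0
  best_k <- 1
  fg_raw <- 0
  bg_raw <- 0
  for (k in seq_len(n)) {
    fg_raw <- fg_raw + v[k]
    bg_raw <- bg_raw + (1 - v[k])
    d <- fg_raw / vsum - (if (bsum == 0) k / n else bg_raw / bsum)
    if (abs(d) > best) {  # strict: smallest k wins ties
      best <- abs(d)
      best_d <- d
      best_k <- k
    }
  }
  list(score = best_d, k = best_k)
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating every
# assignment of the pooled values to the two groups.
enum_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  u_stat <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_stat(x, y)
  u_all <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  p_lo <- mean(u_all <= u_obs + 1e-12)
  p_hi <- mean(u_all >= u_obs - 1e-12)
  min(1, 2 * min(p_lo, p_hi))
}

# AUC by exhaustive pair counting (ties count one half).
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Logistic-regression MLE by Newton-Raphson on the binomial
# log-likelihood, written from the likelihood directly.
newton_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- t(X) %*% (y - p)
    w <- p * (1 - p)
    hess <- t(X) %*% (X * w)
    step <- solve(hess, grad)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(hess)))
  z <- beta / se
  list(coef = beta, se = se, p = 2 * pnorm(-abs(z)))
}

# Normalized score recomputed by replaying the same seeded permutation
# stream with the brute-force pre-score.
replay_normalized_score <- function(magnitudes_ranked, n_perm, seed) {
  pre <- brute_prescore(magnitudes_ranked)$score
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(length(magnitudes_ranked)))
  null_abs <- apply(perms, 2, function(p) {
    abs(brute_prescore(magnitudes_ranked[p])$score)
  })
  pre / mean(null_abs)
}

# Small deterministic cohort for I/O and evaluation tests.
tiny_cohort <- function(seed = 42, ...) {
  simulate_cohort(simulation_params(n_genes = 60, n_samples = 24,
                                    n_signal_genes = 12, seed = seed, ...))
}
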