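#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Exact enumeration p-value when the combined sample size is at most 12
#' and there are no ties; normal approximation with tie correction (and
#' continuity correction) otherwise. This is the test used for all
#' score-by-group and covariate-by-fusion contrasts.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param labels character vector of length 2 naming the groups.
#' @return A list of class \code{"group_comparison"}: group labels and
#'   sizes, per-group medians, the rank-sum statistic W, and the
#'   two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, labels = c("x", "y")) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  exact <- (length(x) + length(y) <= 12) &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = !exact))
  structure(list(
    labels = labels,
    n = c(length(x), length(y)),
    medians = c(stats::median(x), stats::median(y)),
    statistic = unname(ht$statistic),
    p_value = min(unname(ht$p.value), 1),
    exact = exact
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank-sum (%s): %s n=%d median=%.4g vs %s n=%d median=%.4g; W=%g, p=%.3g\n",
    if (x$exact) "exact" else "normal approx.",
    x$labels[1], x$n[1], x$medians[1],
    x$labels[2], x$n[2], x$medians[2], x$statistic, x$p_value))
  invisible(x)
}

#' ROC curve and AUC by pair counting
#'
#' The AUC is computed as the Mann-Whitney probability that a random
#' positive outranks a random negative, with ties counting one half —
#' i.e. the U statistic divided by n_pos * n_neg. The ROC curve is built
#' by sweeping the sorted unique scores as thresholds.
#'
#' @param scores numeric vector of per-sample scores.
#' @param labels binary vector (1/TRUE = positive class).
#' @return A list of class \code{"classification_result"} with \code{auc}
#'   and a \code{roc} data.frame (columns \code{fpr}, \code{tpr}).
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(y) != length(scores)) {
    stop("scores and labels must be aligned", call. = FALSE)
  }
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  # rank-based Mann-Whitney U with midranks handling ties
  r <- rank(scores, ties.method = "average")
  u <- sum(r[y == 1]) - n_pos * (n_pos + 1) / 2
  auc <- u / (n_pos * n_neg)

  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    fpr = vapply(thresholds, function(t) sum(scores >= t & y == 0), 0) / n_neg,
    tpr = vapply(thresholds, function(t) sum(scores >= t & y == 1), 0) / n_pos
  )
  structure(list(auc = auc, roc = roc, n_pos = n_pos, n_neg = n_neg),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Median (or quantile) split into high/low groups
#'
#' Samples with score less than or equal to the threshold quantile go to
#' the low group; scores strictly above it go to the high group. Placing
#' ties at the threshold in the low group is a fixed, deterministic rule.
#'
#' @param scores numeric vector (length >= 2).
#' @param quantile split quantile (default 0.5, the median).
#' @return Factor with levels \code{"low"}, \code{"high"} and attribute
#'   \code{threshold}.
#' @export
median_split <- function(scores, quantile = 0.5) {
  if (length(scores) < 2) stop("need at least 2 samples", call. = FALSE)
  thr <- stats::quantile(scores, quantile, names = FALSE, type = 7)
  grp <- factor(ifelse(scores <= thr, "low", "high"),
                levels = c("low", "high"))
  attr(grp, "threshold") <- thr
  grp
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival curves per group and the standard two-group
#' log-rank chi-square (1 df) from observed-minus-expected event counts
#' with hypergeometric variances at each distinct event time.
#'
#' @param groups factor/vector with two levels assigning each sample to a
#'   group (e.g. the output of [median_split()]).
#' @param time non-negative survival/censoring times.
#' @param event binary event indicator (1 = event observed).
#' @return A list of class \code{"survival_stratification"}: per-group KM
#'   curves (time, at-risk, survival), the log-rank chi-square and
#'   p-value, per-group observed/expected event counts, and a
#'   \code{degenerate} flag set when no events occur or a group
#'   contributes no risk time.
#' @export
km_logrank <- function(groups, time, event) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    stop("both groups must contain at least one sample", call. = FALSE)
  }
  if (any(time < 0)) stop("times must be >= 0", call. = FALSE)
  event <- as.integer(event)

  fit <- survival::survfit(survival::Surv(time, event) ~ groups)
  strata_names <- sub("^groups=", "", names(fit$strata))
  idx <- rep(seq_along(fit$strata), fit$strata)
  curves <- lapply(seq_along(fit$strata), function(i) {
    sel <- idx == i
    data.frame(time = fit$time[sel], n_risk = fit$n.risk[sel],
               survival = fit$surv[sel])
  })
  names(curves) <- strata_names

  degenerate <- sum(event) == 0 ||
    any(tapply(event, groups, sum) == sum(event))
  if (sum(event) == 0) {
    chisq <- NA_real_
    p <- NA_real_
    obs <- tapply(event, groups, sum)
    exp <- obs * NA_real_
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ groups, rho = 0)
    chisq <- unname(sd$chisq)
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    obs <- sd$obs
    exp <- sd$exp
  }
  structure(list(
    groups = levels(groups),
    n = as.vector(table(groups)),
    curves = curves,
    observed = obs,
    expected = exp,
    chisq = chisq,
    p_value = p,
    degenerate = degenerate
  ), class = "survival_stratification")
}

#' @export
print.survival_stratification <- function(x, ...) {
  cat(sprintf("Log-rank: chi-square = %.4g (1 df), p = %.3g%s\n",
              x$chisq, x$p_value,
              if (x$degenerate) " [degenerate]" else ""))
  for (g in names(x$curves)) {
    cat(sprintf("  %s: n = %d, events = %g\n", g,
                x$n[match(g, x$groups)], x$observed[match(g, x$groups)]))
  }
  invisible(x)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of average ranks; the p-value uses the
#' t approximation with n - 2 degrees of freedom.
#'
#' @param x,y aligned numeric vectors, n >= 3.
#' @return List with \code{rho}, \code{p_value}, \code{n}, and a
#'   \code{degenerate} flag (TRUE when either vector has zero variance,
#'   in which case rho and p are NA).
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be aligned", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                degenerate = TRUE))
  }
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, degenerate = FALSE)
}

#' Default evaluation configuration
#'
#' Strata are named filters (R expressions on clinical columns, as
#' strings). For each non-empty stratum the report contains the
#' score-by-fusion rank-sum comparison, fusion-status ROC/AUC, ROC/AUC
#' for each configured binary outcome column, the median-split log-rank
#' survival stratification, and the Spearman correlation of the score
#' with each configured continuous covariate column.
#'
#' @param strata named list of filter expressions (strings; \code{NULL} =
#'   all samples).
#' @param roc_columns character vector of binary clinical columns to
#'   classify by score (besides fusion status).
#' @param correlation_columns character vector of numeric clinical
#'   columns to correlate with the score.
#' @param split_quantile quantile for the survival split (default 0.5).
#' @return A list of class \code{"evaluation_config"}.
#' @export
evaluation_config <- function(strata = list(
                                all = NULL,
                                fusion_positive = "fusion_status == 'positive'",
                                fusion_negative = "fusion_status == 'negative'",
                                gleason_7 = "gleason == 7"),
                              roc_columns = character(),
                              correlation_columns = character(),
                              split_quantile = 0.5) {
  structure(list(strata = strata, roc_columns = roc_columns,
                 correlation_columns = correlation_columns,
                 split_quantile = split_quantile),
            class = "evaluation_config")
}

#' Evaluate signature scores against clinical annotation
#'
#' Reproduces the standard evaluation surfaces of a fusion signature on
#' one cohort, per configured stratum: does the score separate
#' fusion-positive from fusion-negative samples (rank-sum test, ROC/AUC)?
#' Does a median split of the score stratify survival (Kaplan-Meier +
#' log-rank)? Does the score correlate with continuous covariates such as
#' ERG expression or immune-infiltration fractions (Spearman)? Any binary
#' clinical column (e.g. indolent/lethal outcome) can additionally be
#' classified by score. P-values are reported unadjusted.
#'
#' @param scores named numeric score vector (names = sample ids), e.g.
#'   from [score_samples()].
#' @param clinical clinical table covering all scored samples.
#' @param config an [evaluation_config()].
#' @return A list of class \code{"evaluation_report"}, one entry per
#'   stratum; empty strata are recorded as skipped with a reason. The
#'   report is JSON-serializable via [write_report()].
#' @export
evaluate_cohort <- function(scores, clinical,
                            config = evaluation_config()) {
  clinical <- check_clinical(clinical, require_survival = FALSE)
  if (is.null(names(scores))) {
    stop("scores must be named by sample id", call. = FALSE)
  }
  missing <- setdiff(names(scores), clinical$sample_id)
  if (length(missing)) {
    stop("clinical table does not cover scored sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  clin <- clinical[match(names(scores), clinical$sample_id), , drop = FALSE]

  report <- lapply(names(config$strata), function(stratum) {
    filt <- config$strata[[stratum]]
    keep <- if (is.null(filt)) {
      rep(TRUE, nrow(clin))
    } else {
      sel <- eval(parse(text = filt), envir = clin)
      sel & !is.na(sel)
    }
    if (!any(keep)) {
      return(list(stratum = stratum, skipped = TRUE,
                  reason = "empty stratum", n = 0L))
    }
    s <- scores[keep]
    cl <- clin[keep, , drop = FALSE]
    out <- list(stratum = stratum, skipped = FALSE, n = length(s))

    is_pos <- cl$fusion_status == "positive"
    is_neg <- cl$fusion_status == "negative"
    if (any(is_pos) && any(is_neg)) {
      out$fusion_comparison <- wilcoxon_rank_sum(
        s[is_pos], s[is_neg], labels = c("positive", "negative"))
      sub <- is_pos | is_neg
      out$fusion_roc <- roc_auc(s[sub], as.integer(is_pos[sub]))
    }
    for (col in config$roc_columns) {
      vals <- cl[[col]]
      ok <- !is.na(vals)
      if (length(unique(vals[ok])) == 2) {
        lab <- as.integer(factor(vals[ok])) - 1L
        out$outcome_roc[[col]] <- roc_auc(s[ok], lab)
      }
    }
    if (all(c("time", "event") %in% names(cl)) &&
        !all(is.na(cl$time)) && length(s) >= 2) {
      grp <- median_split(s, config$split_quantile)
      if (nlevels(droplevels(grp)) == 2) {
        out$survival <- km_logrank(grp, cl$time, cl$event)
        out$survival$threshold <- attr(grp, "threshold")
        # direction of the association: positive means the high-score
        # group has more events than expected (poorer prognosis)
        if (!out$survival$degenerate) {
          oe <- out$survival$observed - out$survival$expected
          out$survival$high_score_excess_events <-
            unname(oe[match("high", out$survival$groups)])
        }
      }
    }
    for (col in config$correlation_columns) {
      vals <- cl[[col]]
      ok <- !is.na(vals)
      if (sum(ok) >= 3) {
        out$correlations[[col]] <- spearman_corr(s[ok], vals[ok])
      }
    }
    out
  })
  names(report) <- names(config$strata)
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  for (st in x) {
    if (isTRUE(st$skipped)) {
      cat(sprintf("[%s] skipped (%s)\n", st$stratum, st$reason))
      next
    }
    cat(sprintf("[%s] n = %d\n", st$stratum, st$n))
    if (!is.null(st$fusion_comparison)) {
      cat("  "); print(st$fusion_comparison)
      cat(sprintf("  fusion AUC = %.4f\n", st$fusion_roc$auc))
    }
    if (!is.null(st$survival)) {
      cat(sprintf("  median-split log-rank p = %.3g%s\n",
                  st$survival$p_value,
                  if (st$survival$degenerate) " [degenerate]" else ""))
    }
    for (col in names(st$correlations)) {
      cat(sprintf("  Spearman(score, %s): rho = %.3f, p = %.3g\n",
                  col, st$correlations[[col]]$rho,
                  st$correlations[[col]]$p_value))
    }
  }
  invisible(x)
}
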