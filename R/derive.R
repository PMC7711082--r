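#' Per-gene covariate-adjusted logistic regression
#'
#' Fits the maximum-likelihood logistic model
#' \code{fusion ~ expression + age + gleason} for a single gene and
#' returns the expression coefficient with its two-sided Wald p-value.
#' Fusion status is the response; age and Gleason score (treated as a
#' numeric ordinal covariate) adjust for clinical confounding. Degenerate
#' fits — constant expression, rank-deficient design, non-convergence, or
#' complete separation — are flagged non-informative and carry
#' coefficient 0 and p-value 1 so that rank-based selection ignores them.
#'
#' @param expr_row numeric vector of per-sample expression values.
#' @param fusion_labels binary vector (0/1 or logical) per sample; 1 =
#'   fusion positive.
#' @param covariates data.frame with numeric columns \code{age} and
#'   \code{gleason}, one row per sample. Rows with missing covariates are
#'   dropped from the fit.
#' @param gene gene identifier recorded in the result.
#' @return A one-row data.frame (\code{gene}, \code{coefficient},
#'   \code{p_value}, \code{informative}).
#' @export
fit_gene_logistic <- function(expr_row, fusion_labels, covariates,
                              gene = "gene") {
  y <- as.integer(fusion_labels)
  n <- length(expr_row)
  if (length(y) != n || nrow(covariates) != n) {
    stop("expression, labels, and covariates must cover the same samples",
         call. = FALSE)
  }
  keep <- !is.na(covariates$age) & !is.na(covariates$gleason) &
    !is.na(expr_row) & !is.na(y)
  if (!all(keep)) {
    message(sprintf("fit_gene_logistic: dropping %d sample(s) with missing values",
                    sum(!keep)))
  }
  y <- y[keep]
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stop("need at least 2 samples in each fusion class", call. = FALSE)
  }
  x <- cbind(`(Intercept)` = 1, expr = expr_row[keep],
             age = covariates$age[keep], gleason = covariates$gleason[keep])

  uninformative <- data.frame(gene = gene, coefficient = 0, p_value = 1,
                              informative = FALSE, stringsAsFactors = FALSE)
  if (stats::sd(x[, "expr"]) == 0) return(uninformative)

  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(x, y, family = stats::binomial(),
                                    control = list(epsilon = 1e-12,
                                                   maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(uninformative)
  beta <- fit$coefficients["expr"]
  if (is.na(beta)) return(uninformative)
  # complete separation: fitted probabilities pinned at 0/1 and an
  # exploding coefficient; flag rather than penalize
  if (any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10) &&
      abs(beta) * stats::sd(x[, "expr"]) > 15) {
    return(uninformative)
  }
  # Fisher information at the final coefficients (the IRLS working
  # weights stored on the fit lag one iteration behind)
  mu <- fit$fitted.values
  info <- crossprod(x * sqrt(mu * (1 - mu)))
  se <- tryCatch(sqrt(diag(solve(info)))[["expr"]], error = function(e) NA)
  if (!is.finite(se) || se <= 0) return(uninformative)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  if (!is.finite(p)) return(uninformative)
  data.frame(gene = gene, coefficient = unname(beta),
             p_value = max(p, .Machine$double.xmin), informative = TRUE,
             stringsAsFactors = FALSE)
}

#' Select the most significant genes
#'
#' Keeps the \code{K} informative genes with the smallest p-values.
#' Ties are broken deterministically: ascending p-value, then ascending
#' gene identifier.
#'
#' @param stats data.frame of per-gene fits as returned by
#'   [fit_gene_logistic()] (rows bound together).
#' @param K number of genes to keep; must not exceed the number of
#'   informative genes.
#' @return The selected rows, ordered by increasing p-value.
#' @export
select_top_genes <- function(stats, K) {
  if (!(length(K) == 1 && is.numeric(K) && K >= 1 && K == round(K))) {
    stop("K must be a positive integer", call. = FALSE)
  }
  inf <- stats[stats$informative, , drop = FALSE]
  if (K > nrow(inf)) {
    stop(sprintf(
      "K = %d exceeds the %d informative genes available; lower K",
      K, nrow(inf)), call. = FALSE)
  }
  ord <- order(inf$p_value, inf$gene)
  inf[ord[seq_len(K)], , drop = FALSE]
}

#' Assign signed weights to selected genes
#'
#' Maps each selected gene to a weight in [-1, 1]: the magnitude is the
#' gene's -log10 p-value normalized by the largest -log10 p-value among
#' the selected genes (so the most significant gene has |weight| = 1),
#' and the sign is the sign of its logistic-regression coefficient
#' (positive = upregulated in fusion-positive samples).
#'
#' @param selected data.frame of selected gene fits (see
#'   [select_top_genes()]).
#' @return A \code{fusion_signature}. Genes whose normalized magnitude is
#'   exactly zero (p-value of 1) are dropped with a warning, since zero
#'   weights carry no information.
#' @export
assign_weights <- function(selected) {
  if (nrow(selected) == 0) stop("no genes selected", call. = FALSE)
  p <- selected$p_value
  if (any(p <= 0)) {
    warning("p-values of 0 clamped to smallest positive double before log")
    p <- pmax(p, .Machine$double.xmin)
  }
  neglog <- -log10(p)
  top <- max(neglog)
  if (top == 0) {
    stop("all selected p-values are 1; no weights can be assigned",
         call. = FALSE)
  }
  w <- sign(selected$coefficient) * neglog / top
  zero <- w == 0
  if (any(zero)) {
    warning(sprintf("dropping %d gene(s) with zero weight", sum(zero)))
  }
  new_signature(selected$gene[!zero], w[!zero], id = "derived")
}

#' Derive a fusion signature from a labeled cohort
#'
#' Runs the covariate-adjusted logistic regression of
#' [fit_gene_logistic()] on every gene of the expression matrix, selects
#' the \code{K} most significant genes, and converts them into a signed,
#' weighted signature via [assign_weights()]. Fusion-positive samples are
#' coded 1; all other samples (fusion-negative, including any
#' \code{erg_other} samples) are coded 0.
#'
#' @param expr numeric expression matrix, genes x samples, with row and
#'   column names.
#' @param clinical clinical table covering every matrix sample (columns
#'   \code{sample_id}, \code{fusion_status}, \code{age}, \code{gleason}).
#' @param K number of genes to select (default 700, the size used for
#'   the published fusion signature).
#' @return A list with \code{signature} (a \code{fusion_signature}) and
#'   \code{gene_stats} (the full per-gene fit table for audit).
#' @examples
#' cohort <- simulate_cohort(simulation_params(n_genes = 200,
#'   n_samples = 120, n_signal_genes = 40, seed = 1))
#' res <- derive_signature(cohort$expression, cohort$clinical, K = 40)
#' head(res$signature)
#' @export
derive_signature <- function(expr, clinical, K = 700) {
  check_expression_matrix(expr)
  clinical <- check_clinical(clinical, require_survival = FALSE)
  missing_samples <- setdiff(colnames(expr), clinical$sample_id)
  if (length(missing_samples)) {
    stop("clinical table does not cover sample(s): ",
         paste(utils::head(missing_samples, 5), collapse = ", "),
         call. = FALSE)
  }
  clin <- clinical[match(colnames(expr), clinical$sample_id), , drop = FALSE]
  labels <- as.integer(clin$fusion_status == "positive")
  if (sum(labels) < 2 || sum(1 - labels) < 2) {
    stop("need at least 2 fusion-positive and 2 fusion-negative samples",
         call. = FALSE)
  }
  covariates <- clin[, c("age", "gleason")]

  stats_list <- lapply(rownames(expr), function(g) {
    fit_gene_logistic(expr[g, ], labels, covariates, gene = g)
  })
  gene_stats <- do.call(rbind, stats_list)
  selected <- select_top_genes(gene_stats, K)
  list(signature = assign_weights(selected), gene_stats = gene_stats)
}
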