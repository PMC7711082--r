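#' Rank the genes of one sample
#'
#' Orders genes by descending expression; exact ties are broken by
#' ascending gene identifier so the ranking is deterministic across
#' platforms. The ranking — not the expression values — is what the
#' scoring statistic consumes, which makes scores invariant to any
#' strictly increasing transform of a sample's expression.
#'
#' @param sample_expr named numeric vector of expression values for one
#'   sample (names are gene ids).
#' @return Character vector of gene ids, most highly expressed first, with
#'   attribute \code{tie_rule = "ascending_gene_id"}.
#' @export
rank_genes <- function(sample_expr) {
  if (is.null(names(sample_expr))) {
    stop("sample expression must be named by gene id", call. = FALSE)
  }
  bad <- names(sample_expr)[!is.finite(sample_expr)]
  if (length(bad)) {
    stop("missing/non-finite expression for gene(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  ord <- order(-sample_expr, names(sample_expr), method = "radix")
  ranking <- names(sample_expr)[ord]
  attr(ranking, "tie_rule") <- "ascending_gene_id"
  ranking
}

#' Weighted running-sum pre-score
#'
#' The single-sample enrichment statistic. Walking down the ranked gene
#' list, two cumulative distributions are tracked: the foreground
#' \eqn{F(k) = \sum_{i \le k} v_i / \sum_i v_i} accumulates the weight
#' magnitudes of signature genes, and the background
#' \eqn{B(k) = \sum_{i \le k} (1 - v_i) / \sum_i (1 - v_i)} accumulates
#' their complement. The pre-score is the signed deviation
#' \eqn{D(k^*) = F(k^*) - B(k^*)} at the position \eqn{k^*} maximizing
#' \eqn{|F(k) - B(k)|} (smallest k on ties). It lies in [-1, 1] and is
#' positive when the weighted genes concentrate at the top of the
#' ranking.
#'
#' @param magnitudes numeric vector of weight magnitudes in [0, 1] in
#'   ranked gene order (0 for genes outside the signature set).
#' @return The pre-score, with attribute \code{k_star}.
#' @export
running_sum_score <- function(magnitudes) {
  v <- as.numeric(magnitudes)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop("magnitudes must lie in [0, 1]", call. = FALSE)
  }
  vsum <- sum(v)
  if (vsum == 0) stop("all magnitudes are zero", call. = FALSE)
  n <- length(v)
  bsum <- n - vsum
  fg <- cumsum(v) / vsum
  # bsum == 0 only when every gene has magnitude 1; the background is then
  # uniform over all genes and the contrast degenerates to zero
  bg <- if (bsum == 0) seq_len(n) / n else cumsum(1 - v) / bsum
  d <- fg - bg
  k_star <- which.max(abs(d))  # first maximum = smallest k
  out <- d[k_star]
  attr(out, "k_star") <- k_star
  out
}

#' Normalize a pre-score against a gene-permutation null
#'
#' Draws \code{n_permutations} uniform random permutations of the
#' magnitude vector over the gene universe (destroying any association
#' between weights and ranks), recomputes the pre-score for each, and
#' divides the observed pre-score by the mean absolute permuted
#' pre-score. The normalization is sign-preserving and scale-free: a
#' score of 0 stays 0, and |score| around 1 means "no stronger than a
#' random gene set of the same weights". Reproducible for a fixed seed.
#'
#' @param pre_score observed pre-score from [running_sum_score()].
#' @param magnitudes magnitude vector in ranked order (as used for the
#'   observed pre-score).
#' @param n_permutations number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @return The normalized score.
#' @export
normalize_score <- function(pre_score, magnitudes, n_permutations = 1000,
                            seed = 0) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  perms <- replicate(n_permutations, sample.int(length(magnitudes)))
  scale <- permutation_scale(magnitudes, perms)
  if (scale == 0) {
    stop("degenerate magnitude vector: permuted pre-scores are all zero",
         call. = FALSE)
  }
  as.numeric(pre_score) / scale
}

# mean absolute pre-score over a fixed matrix of permutations
# (columns = permutations of the gene universe)
permutation_scale <- function(magnitudes, perms) {
  mean(vapply(seq_len(ncol(perms)), function(m) {
    abs(as.numeric(running_sum_score(magnitudes[perms[, m]])))
  }, numeric(1)))
}

#' Score every sample of a cohort against a signature
#'
#' For each sample the signature is split into its up-set (positive
#' weights) and down-set (negative weights). Each set is scored with the
#' weighted running-sum statistic over the sample's full gene ranking
#' (genes outside the set participate as background with magnitude 0) and
#' normalized against the permutation null; the sample score is the
#' normalized up-set score minus the normalized down-set score, so high
#' scores mean "up-genes high AND down-genes low". Both sets share the
#' same seeded permutation stream, which makes the score exactly
#' antisymmetric under negation of all signature weights.
#'
#' @param expr numeric expression matrix, genes x samples.
#' @param signature a \code{fusion_signature} (see [new_signature()] /
#'   [read_signature()]). Signature genes absent from the matrix are
#'   dropped with a warning; it is an error if none remain.
#' @param n_permutations permutations per sample for normalization.
#' @param seed integer master seed; each sample's permutation stream is
#'   derived deterministically from it.
#' @return Named numeric vector of per-sample scores with attributes
#'   \code{n_permutations}, \code{seed}, \code{signature_id}, and
#'   \code{dropped_genes}.
#' @examples
#' cohort <- simulate_cohort(simulation_params(n_genes = 100,
#'   n_samples = 12, n_signal_genes = 20, seed = 2))
#' sig <- truth_signature(cohort$truth)
#' score_samples(cohort$expression, sig, n_permutations = 50, seed = 1)
#' @export
score_samples <- function(expr, signature, n_permutations = 1000, seed = 0) {
  check_expression_matrix(expr)
  validate_signature(signature)
  present <- signature$gene %in% rownames(expr)
  if (!any(present)) {
    stop("no signature genes found in the expression matrix", call. = FALSE)
  }
  dropped <- signature$gene[!present]
  if (length(dropped)) {
    warning(sprintf("%d signature gene(s) absent from matrix; dropped",
                    length(dropped)))
  }
  sig <- signature[present, , drop = FALSE]

  genes <- rownames(expr)
  n_genes <- length(genes)
  mag_up <- stats::setNames(numeric(n_genes), genes)
  mag_dn <- mag_up
  up <- sig$weight > 0
  mag_up[sig$gene[up]] <- sig$weight[up]
  mag_dn[sig$gene[!up]] <- -sig$weight[!up]
  has_up <- any(mag_up > 0)
  has_dn <- any(mag_dn > 0)

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)

  scores <- vapply(seq_len(ncol(expr)), function(j) {
    ranking <- rank_genes(expr[, j])
    vu <- mag_up[ranking]
    vd <- mag_dn[ranking]
    # one permutation stream per (sample, seed), shared by both sets
    set.seed(sample_perm_seed(seed, j))
    perms <- replicate(n_permutations, sample.int(n_genes))
    s_up <- 0
    if (has_up) {
      pre <- as.numeric(running_sum_score(vu))
      s_up <- pre / permutation_scale(vu, perms)
    }
    s_dn <- 0
    if (has_dn) {
      pre <- as.numeric(running_sum_score(vd))
      s_dn <- pre / permutation_scale(vd, perms)
    }
    s_up - s_dn
  }, numeric(1))

  names(scores) <- colnames(expr)
  attr(scores, "n_permutations") <- n_permutations
  attr(scores, "seed") <- seed
  attr(scores, "signature_id") <-
    attr(signature, "signature_id") %||% "signature"
  attr(scores, "dropped_genes") <- dropped
  attr(scores, "statistic") <- "weighted-running-sum/perm-mean-abs"
  scores
}

# deterministic per-sample seed derived from the master seed; kept within
# 32-bit integer range
sample_perm_seed <- function(seed, sample_index) {
  as.integer((abs(seed) * 7919 + sample_index * 104729) %% 2147483647L)
}
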