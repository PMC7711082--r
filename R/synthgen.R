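#' Simulation parameters for a synthetic fusion cohort
#'
#' Bundles and validates every knob of the cohort generator. The defaults
#' describe a mid-sized prostate-cancer expression cohort: a few thousand
#' genes on a log-intensity-like continuous scale, roughly half the tumors
#' carrying the TMPRSS2-ERG fusion, a block of signal genes shifted up or
#' down in fusion-positive samples, clinical covariates (age, Gleason
#' grade), and right-censored survival whose hazard depends on the latent
#' fusion-pathway activity through an exponential proportional-hazards
#' model.
#'
#' @param n_genes number of genes in the expression matrix.
#' @param n_samples number of samples (patients).
#' @param fraction_positive proportion of fusion-positive samples, in (0,1).
#' @param n_signal_genes number of genes truly shifted by fusion-pathway
#'   activity; must not exceed \code{n_genes}.
#' @param fraction_up proportion of signal genes upregulated in
#'   fusion-positive samples (the rest are downregulated), in [0,1].
#' @param effect_size mean log-expression shift of a signal gene, in units
#'   of the noise standard deviation; must be >= 0.
#' @param noise_sd per-gene Gaussian noise standard deviation, > 0.
#' @param age_mean,age_sd mean and standard deviation of patient age (years).
#' @param gleason_probs probability vector over Gleason scores 6, 7, 8, 9;
#'   must sum to 1. The default makes Gleason 7 the most common grade, as
#'   it is at diagnosis.
#' @param hazard_coef log-hazard increment per unit of latent pathway
#'   activity (0 decouples survival from activity).
#' @param baseline_hazard baseline event rate per time unit, > 0. Time
#'   units are abstract.
#' @param censor_rate rate of the independent exponential censoring
#'   process, >= 0; 0 means no censoring (all events observed).
#' @param activity_jitter standard deviation of Gaussian jitter added to
#'   the latent activity of every sample (default 0: activity is exactly
#'   1 for fusion-positive, 0 for fusion-negative).
#' @param erg_other_fraction proportion of fusion-negative samples relabeled
#'   \code{"erg_other"} and given latent activity 1, emulating ERG fusions
#'   with partners other than TMPRSS2 (default 0). The prevalence of this
#'   subpopulation is a free parameter because it is not well
#'   characterized; it is off unless requested.
#' @param seed integer RNG seed; identical parameters give byte-identical
#'   cohorts.
#'
#' @return An object of class \code{"simulation_params"} (a validated list).
#' @seealso [simulate_cohort()]
#' @export
simulation_params <- function(n_genes = 2000,
                              n_samples = 300,
                              fraction_positive = 0.5,
                              n_signal_genes = 200,
                              fraction_up = 0.5,
                              effect_size = 1.5,
                              noise_sd = 1,
                              age_mean = 62,
                              age_sd = 8,
                              gleason_probs = c(`6` = 0.25, `7` = 0.45,
                                                `8` = 0.2, `9` = 0.1),
                              hazard_coef = 1,
                              baseline_hazard = 0.05,
                              censor_rate = 0.02,
                              activity_jitter = 0,
                              erg_other_fraction = 0,
                              seed = 0) {
  p <- list(n_genes = n_genes, n_samples = n_samples,
            fraction_positive = fraction_positive,
            n_signal_genes = n_signal_genes, fraction_up = fraction_up,
            effect_size = effect_size, noise_sd = noise_sd,
            age_mean = age_mean, age_sd = age_sd,
            gleason_probs = gleason_probs, hazard_coef = hazard_coef,
            baseline_hazard = baseline_hazard, censor_rate = censor_rate,
            activity_jitter = activity_jitter,
            erg_other_fraction = erg_other_fraction, seed = seed)
  validate_simulation_params(p)
  class(p) <- "simulation_params"
  p
}

validate_simulation_params <- function(p) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) {
      stop(sprintf("invalid simulation parameter '%s': %s", field, msg),
           call. = FALSE)
    }
  }
  pos_int <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
    x >= 1 && x == round(x)
  scalar <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)

  chk(pos_int(p$n_genes), "n_genes", "must be a positive integer")
  chk(pos_int(p$n_samples), "n_samples", "must be a positive integer")
  chk(scalar(p$fraction_positive) && p$fraction_positive > 0 &&
        p$fraction_positive < 1,
      "fraction_positive", "must lie strictly in (0, 1)")
  chk(length(p$n_signal_genes) == 1 && is.numeric(p$n_signal_genes) &&
        p$n_signal_genes == round(p$n_signal_genes) && p$n_signal_genes >= 0,
      "n_signal_genes", "must be a non-negative integer")
  chk(p$n_signal_genes <= p$n_genes, "n_signal_genes",
      "must not exceed n_genes")
  chk(scalar(p$fraction_up) && p$fraction_up >= 0 && p$fraction_up <= 1,
      "fraction_up", "must lie in [0, 1]")
  chk(scalar(p$effect_size) && p$effect_size >= 0, "effect_size",
      "must be >= 0")
  chk(scalar(p$noise_sd) && p$noise_sd > 0, "noise_sd", "must be > 0")
  chk(scalar(p$age_mean), "age_mean", "must be a finite number")
  chk(scalar(p$age_sd) && p$age_sd >= 0, "age_sd", "must be >= 0")
  chk(is.numeric(p$gleason_probs) && length(p$gleason_probs) == 4 &&
        all(p$gleason_probs >= 0) &&
        abs(sum(p$gleason_probs) - 1) <= 1e-9,
      "gleason_probs", "must be 4 non-negative values summing to 1")
  chk(scalar(p$hazard_coef), "hazard_coef", "must be a finite number")
  chk(scalar(p$baseline_hazard) && p$baseline_hazard > 0, "baseline_hazard",
      "must be > 0")
  chk(scalar(p$censor_rate) && p$censor_rate >= 0, "censor_rate",
      "must be >= 0")
  chk(scalar(p$activity_jitter) && p$activity_jitter >= 0, "activity_jitter",
      "must be >= 0")
  chk(scalar(p$erg_other_fraction) && p$erg_other_fraction >= 0 &&
        p$erg_other_fraction < 1,
      "erg_other_fraction", "must lie in [0, 1)")
  chk(pos_int(abs(p$seed) + 1), "seed", "must be an integer")
  invisible(p)
}

#' Simulate a fusion-labeled expression cohort
#'
#' Generates an expression matrix, a clinical table, and the generating
#' ground truth under the model the downstream analysis assumes:
#' \itemize{
#'   \item Latent pathway activity is 1 for fusion-positive samples and 0
#'     for fusion-negative samples (plus optional Gaussian jitter);
#'     optionally a fraction of negatives is relabeled \code{erg_other}
#'     with activity 1.
#'   \item Gene expression is \code{baseline + direction * effect_size *
#'     activity + N(0, noise_sd)} on a log-like continuous scale, with a
#'     per-gene baseline drawn once; only signal genes have a nonzero
#'     direction.
#'   \item Survival times are exponential with log-hazard
#'     \code{log(baseline_hazard) + hazard_coef * activity}; censoring
#'     times are exponential with rate \code{censor_rate}; the event
#'     indicator is 1 when the event precedes censoring.
#'   \item Age is Gaussian, Gleason score is drawn from
#'     \code{gleason_probs} independently of fusion status.
#' }
#'
#' @param params a [simulation_params()] object (or plain list with the
#'   same fields, which is validated).
#'
#' @return A list with components \code{expression} (numeric matrix, genes
#'   x samples), \code{clinical} (data.frame with columns \code{sample_id},
#'   \code{fusion_status}, \code{age}, \code{gleason}, \code{time},
#'   \code{event}), and \code{truth} (list with \code{signal_genes}
#'   data.frame of \code{gene}, \code{direction}, \code{effect_size} and
#'   \code{latent_activity} named vector).
#' @examples
#' cohort <- simulate_cohort(simulation_params(n_genes = 50, n_samples = 20,
#'                                             seed = 1))
#' dim(cohort$expression)
#' table(cohort$clinical$fusion_status)
#' @export
simulate_cohort <- function(params = simulation_params()) {
  if (!inherits(params, "simulation_params")) {
    validate_simulation_params(params)
  }
  p <- params
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(p$seed)

  genes <- sprintf("g%04d", seq_len(p$n_genes))
  samples <- sprintf("s%04d", seq_len(p$n_samples))

  n_pos <- round(p$fraction_positive * p$n_samples)
  n_pos <- min(max(n_pos, 1), p$n_samples - 1)
  fusion <- rep(c("positive", "negative"),
                c(n_pos, p$n_samples - n_pos))
  # erg_other: a subset of negatives that shares the activated pathway
  n_other <- round(p$erg_other_fraction * (p$n_samples - n_pos))
  if (n_other > 0) {
    idx_other <- which(fusion == "negative")[seq_len(n_other)]
    fusion[idx_other] <- "erg_other"
  }
  activity <- as.numeric(fusion %in% c("positive", "erg_other"))
  if (p$activity_jitter > 0) {
    activity <- activity + stats::rnorm(p$n_samples, 0, p$activity_jitter)
  }
  names(activity) <- samples

  n_up <- round(p$fraction_up * p$n_signal_genes)
  direction <- integer(p$n_genes)
  if (p$n_signal_genes > 0) {
    direction[seq_len(p$n_signal_genes)] <-
      rep(c(1L, -1L), c(n_up, p$n_signal_genes - n_up))
  }

  baseline <- stats::rnorm(p$n_genes, 0, 1)
  shift <- outer(direction * p$effect_size, activity)  # genes x samples
  noise <- matrix(stats::rnorm(p$n_genes * p$n_samples, 0, p$noise_sd),
                  nrow = p$n_genes)
  expr <- baseline + shift + noise
  dimnames(expr) <- list(genes, samples)

  age <- round(stats::rnorm(p$n_samples, p$age_mean, p$age_sd), 1)
  gleason <- sample(6:9, p$n_samples, replace = TRUE,
                    prob = p$gleason_probs)

  hazard <- p$baseline_hazard * exp(p$hazard_coef * activity)
  event_time <- stats::rexp(p$n_samples, rate = hazard)
  censor_time <- if (p$censor_rate > 0) {
    stats::rexp(p$n_samples, rate = p$censor_rate)
  } else {
    rep(Inf, p$n_samples)
  }
  obs_time <- pmin(event_time, censor_time)
  event <- as.integer(event_time <= censor_time)

  clinical <- data.frame(
    sample_id = samples,
    fusion_status = fusion,
    age = age,
    gleason = gleason,
    time = obs_time,
    event = event,
    stringsAsFactors = FALSE
  )

  truth <- list(
    signal_genes = data.frame(
      gene = genes[direction != 0],
      direction = ifelse(direction[direction != 0] > 0, "up", "down"),
      effect_size = rep(p$effect_size, sum(direction != 0)),
      stringsAsFactors = FALSE
    ),
    latent_activity = activity
  )

  list(expression = expr, clinical = clinical, truth = truth,
       params = p)
}

#' Build the oracle signature of a simulated cohort
#'
#' Converts the generator's ground truth into a signature with weight +1
#' for every upregulated signal gene and -1 for every downregulated one.
#' Useful for testing the scorer independently of signature derivation.
#'
#' @param truth the \code{truth} component of a [simulate_cohort()] result.
#' @return A \code{fusion_signature} object.
#' @export
truth_signature <- function(truth) {
  sg <- truth$signal_genes
  if (nrow(sg) == 0) stop("truth contains no signal genes", call. = FALSE)
  new_signature(sg$gene, ifelse(sg$direction == "up", 1, -1),
                id = "simulation-truth")
}

# Save/restore the global RNG state so seeded package functions do not
# perturb the caller's random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
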