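#' Configuration for the synthetic label-free proteomics generator
#'
#' Emulates a paired RNA pull-down LFQ experiment comparing a folded
#' quadruplex bait (WT) with its 7-deaza-guanine unfolded version (7dG):
#' four paired biological replicates per condition, a fraction of proteins
#' with a true binding preference, replicate batch shifts shared within a
#' pair, and intensity-dependent (missing-not-at-random) dropout applied
#' on the raw intensity scale.
#'
#' @param n_proteins Number of (non-flagged) protein groups.
#' @param n_pairs Paired replicates per condition (>= 2; default 4).
#' @param frac_differential Fraction of proteins with a true condition
#'   effect.
#' @param true_log2_effect Signed effect size in log2 units; positive
#'   means WT-preferring (the WT - 7dG mean difference equals this value).
#' @param baseline_mean,baseline_sd Log2-intensity distribution across
#'   proteins (defaults 27 and 2, typical MaxQuant LFQ scale).
#' @param noise_sd Residual replicate noise sd (log2 units).
#' @param pair_sd Sd of the per-protein, per-pair batch shift shared by
#'   the two conditions of a pair (log2 units).
#' @param mnar_midpoint,mnar_slope Logistic dropout: an entry with true
#'   log2 intensity `x` is missing with probability
#'   `plogis(mnar_slope * (mnar_midpoint - x))`; with `mnar_slope = 0`
#'   dropout is constant at 0.5 (MCAR limit).
#' @param contaminant_frac Fraction of additional rows flagged as
#'   contaminants (plus two reverse-hit decoys), exercising the filter.
#' @param seed Integer seed.
#'
#' @return An object of class `sim_lfq_config`.
#' @export
sim_lfq_config <- function(n_proteins = 1000L, n_pairs = 4L,
                           frac_differential = 0.1,
                           true_log2_effect = 1.5,
                           baseline_mean = 27, baseline_sd = 2,
                           noise_sd = 0.3, pair_sd = 0.25,
                           mnar_midpoint = 24, mnar_slope = 1,
                           contaminant_frac = 0.02, seed = 1L) {
  n_proteins <- check_count(n_proteins, "n_proteins", min = 1L)
  n_pairs <- check_count(n_pairs, "n_pairs", min = 0L)
  if (n_pairs < 2L) {
    stop("n_pairs must be >= 2 (paired test undefined otherwise)",
         call. = FALSE)
  }
  stopifnot(frac_differential >= 0, frac_differential <= 1,
            baseline_sd >= 0, noise_sd >= 0, pair_sd >= 0,
            mnar_slope >= 0, contaminant_frac >= 0, contaminant_frac < 1)
  structure(list(n_proteins = n_proteins, n_pairs = n_pairs,
                 frac_differential = frac_differential,
                 true_log2_effect = true_log2_effect,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, pair_sd = pair_sd,
                 mnar_midpoint = mnar_midpoint, mnar_slope = mnar_slope,
                 contaminant_frac = contaminant_frac,
                 seed = as.integer(seed)),
            class = "sim_lfq_config")
}

#' Simulate a paired LFQ protein-group table with known truth
#'
#' Per protein and pair, true log2 intensities are
#' `baseline + pair effect (+ condition effect for differential proteins)
#' + noise`; the observed table is on the raw intensity scale (`2^log2`)
#' with entries set to 0 (the MaxQuant missing-value token) according to
#' the logistic MNAR rule. Contaminant and reverse decoy rows are appended
#' and flagged.
#'
#' @param config A [sim_lfq_config()].
#'
#' @return A list with `table` (data.frame: `protein_id`,
#'   `contaminant_flag`, `reverse_flag`, then `WT_1..WT_n`, `7dG_1..7dG_n`
#'   raw intensities with 0 = missing), `truth` (per real protein:
#'   `protein_id`, `label` in WT-preferring/7dG-preferring/null,
#'   `true_effect`), and `config`.
#' @export
simulate_lfq <- function(config) {
  stopifnot(inherits(config, "sim_lfq_config"))
  with_seed(config$seed, {
    n <- config$n_proteins
    np <- config$n_pairs
    ids <- sprintf("P%05d", seq_len(n))

    n_diff <- round(config$frac_differential * n)
    diff_idx <- if (n_diff > 0) sample.int(n, n_diff) else integer()
    effect <- numeric(n)
    effect[diff_idx] <- config$true_log2_effect
    label <- rep("null", n)
    label[effect > 0] <- "WT-preferring"
    label[effect < 0] <- "7dG-preferring"

    baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    pair_eff <- matrix(stats::rnorm(n * np, 0, config$pair_sd), n, np)
    noise <- function() matrix(stats::rnorm(n * np, 0, config$noise_sd),
                               n, np)
    wt <- baseline + pair_eff + effect + noise()
    dg <- baseline + pair_eff + noise()

    true_log2 <- cbind(wt, dg)
    p_miss <- stats::plogis(config$mnar_slope *
                              (config$mnar_midpoint - true_log2))
    drop <- matrix(stats::runif(length(p_miss)) < p_miss,
                   nrow = n)
    raw <- 2^true_log2
    raw[drop] <- 0

    flagged_n <- round(config$contaminant_frac * n)
    decoys <- NULL
    if (flagged_n + 2L > 0L) {
      dn <- flagged_n + 2L
      dint <- 2^matrix(stats::rnorm(dn * 2 * np, config$baseline_mean,
                                    config$baseline_sd), dn)
      decoys <- data.frame(
        protein_id = c(sprintf("CON__%03d", seq_len(flagged_n)),
                       "REV__001", "REV__002"),
        contaminant_flag = c(rep("+", flagged_n), "", ""),
        reverse_flag = c(rep("", flagged_n), "+", "+"))
      decoys <- cbind(decoys, as.data.frame(dint))
    }

    tab <- data.frame(protein_id = ids, contaminant_flag = "",
                      reverse_flag = "")
    tab <- cbind(tab, as.data.frame(raw))
    if (!is.null(decoys)) {
      names(decoys) <- names(tab)
      tab <- rbind(tab, decoys)
    }
    names(tab)[-(1:3)] <- c(paste0("WT_", seq_len(np)),
                            paste0("7dG_", seq_len(np)))
    rownames(tab) <- NULL

    list(table = tab,
         truth = data.frame(protein_id = ids, label = label,
                            true_effect = effect),
         true_log2 = true_log2,
         config = config)
  })
}
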