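#' Configuration for the RP-MS differential-binding analysis
#'
#' Defaults follow the standard Perseus-style workflow for RNA pull-down
#' LFQ data: at least 3 valid values in one condition, imputation from a
#' downshifted Gaussian (width 0.3 and downshift 1.8, in units of each
#' sample's sd), sign-flip permutation FDR at q <= 0.05, and a 1.5-fold
#' WT/7dG ratio cutoff for classification.
#'
#' @param min_valid_per_condition Minimal valid intensities a protein
#'   needs in at least one condition to be retained (>= 2; default 3).
#' @param impute_width Gaussian width as a fraction of the sample sd.
#' @param impute_downshift Downshift in multiples of the sample sd.
#' @param q_cutoff FDR level for significance.
#' @param fold_cutoff Linear WT/7dG ratio cutoff (> 1).
#' @param n_permutations `"exhaustive"` (all `2^n` sign patterns when
#'   `n <= 12`) or a count of random sign patterns.
#' @param s0 Variance-stabilization offset added to the standard error:
#'   `"auto"` (the default) uses the median per-protein standard error of
#'   the paired differences, the classic SAM-style fudge factor that
#'   keeps near-zero-variance proteins from dominating the permutation
#'   null at small replicate numbers; any non-negative number (including
#'   0) can be given instead.
#' @param require_both_conditions Require `min_valid_per_condition` in
#'   both conditions instead of at least one.
#' @param ratio_on_imputed Compute the WT/7dG ratio from post-imputation
#'   means (default) rather than observed-only means.
#' @param seed Integer seed (imputation and random permutations).
#'
#' @return An object of class `ms_config`.
#' @export
ms_config <- function(min_valid_per_condition = 3L, impute_width = 0.3,
                      impute_downshift = 1.8, q_cutoff = 0.05,
                      fold_cutoff = 1.5, n_permutations = "exhaustive",
                      s0 = "auto", require_both_conditions = FALSE,
                      ratio_on_imputed = TRUE, seed = 1L) {
  min_valid_per_condition <- check_count(min_valid_per_condition,
                                         "min_valid_per_condition",
                                         min = 2L)
  stopifnot(impute_width > 0, impute_downshift >= 0,
            q_cutoff > 0, q_cutoff < 1, fold_cutoff > 1,
            identical(s0, "auto") || (is.numeric(s0) && s0 >= 0))
  if (!identical(n_permutations, "exhaustive")) {
    n_permutations <- check_count(n_permutations, "n_permutations",
                                  min = 1L)
  }
  structure(list(min_valid_per_condition = min_valid_per_condition,
                 impute_width = impute_width,
                 impute_downshift = impute_downshift,
                 q_cutoff = q_cutoff, fold_cutoff = fold_cutoff,
                 n_permutations = n_permutations, s0 = s0,
                 require_both_conditions = require_both_conditions,
                 ratio_on_imputed = ratio_on_imputed,
                 seed = as.integer(seed)),
            class = "ms_config")
}

is_flagged <- function(x) {
  !is.na(x) & (x == "+" | x == "TRUE" | x == "1" | x == TRUE)
}

lfq_columns <- function(tab) {
  wt <- grep("^WT_[0-9]+$", names(tab), value = TRUE)
  dg <- grep("^7dG_[0-9]+$", names(tab), value = TRUE)
  wi <- sort(as.integer(sub("^WT_", "", wt)))
  di <- sort(as.integer(sub("^7dG_", "", dg)))
  if (length(wi) == 0L || !identical(wi, di)) {
    stop("unpaired replicate labels: WT_{i} and 7dG_{i} columns must match",
         call. = FALSE)
  }
  list(wt = paste0("WT_", wi), dg = paste0("7dG_", di), n = length(wi))
}

#' Filter and log2-transform a raw LFQ protein-group table
#'
#' Removes contaminant- and reverse-flagged rows, treats zero or absent
#' intensities as missing, applies log2 to observed values, and retains
#' proteins with at least `min_valid_per_condition` valid values in at
#' least one condition (both, with `require_both_conditions`). Dropped
#' proteins are reported with the reason (`flagged` / `excluded`).
#'
#' @param tab data.frame with `protein_id`, `contaminant_flag`,
#'   `reverse_flag` and intensity columns `WT_1..WT_n`, `7dG_1..7dG_n`.
#' @param config An [ms_config()].
#'
#' @return A list: `log2` (retained proteins x samples matrix with `NA`
#'   for missing), `wt`, `dg` (column names), `n_pairs`, `n_valid_wt`,
#'   `n_valid_dg` (per retained protein), `dropped` (data.frame of
#'   `protein_id`, `reason`).
#' @export
preprocess_lfq <- function(tab, config = ms_config()) {
  stopifnot(is.data.frame(tab), "protein_id" %in% names(tab))
  cols <- lfq_columns(tab)
  flagged <- is_flagged(tab$contaminant_flag) |
    is_flagged(tab$reverse_flag)
  m <- as.matrix(tab[c(cols$wt, cols$dg)])
  mode(m) <- "numeric"
  m[!is.finite(m) | m <= 0] <- NA
  m <- log2(m)
  rownames(m) <- tab$protein_id
  m <- m[!flagged, , drop = FALSE]

  nw <- rowSums(!is.na(m[, cols$wt, drop = FALSE]))
  nd <- rowSums(!is.na(m[, cols$dg, drop = FALSE]))
  minv <- config$min_valid_per_condition
  keep <- if (config$require_both_conditions) {
    nw >= minv & nd >= minv
  } else {
    nw >= minv | nd >= minv
  }
  dropped <- rbind(
    data.frame(protein_id = tab$protein_id[flagged],
               reason = if (any(flagged)) "flagged" else character()),
    data.frame(protein_id = rownames(m)[!keep],
               reason = if (any(!keep)) "excluded" else character()))
  list(log2 = m[keep, , drop = FALSE],
       wt = cols$wt, dg = cols$dg, n_pairs = cols$n,
       n_valid_wt = nw[keep], n_valid_dg = nd[keep],
       dropped = dropped)
}

#' Impute missing log2 intensities from a downshifted Gaussian
#'
#' Per sample column with observed mean `m` and sd `s`, each missing
#' entry is an independent draw from
#' `Normal(m - impute_downshift * s, (impute_width * s)^2)` — the
#' Perseus-style "lowest range of intensities" imputation. Observed
#' entries are untouched; draws are reproducible under `config$seed`.
#'
#' @param mat Proteins x samples log2 matrix with `NA` for missing.
#' @param config An [ms_config()].
#'
#' @return The completed matrix.
#' @export
impute_mnar <- function(mat, config = ms_config()) {
  stopifnot(is.matrix(mat))
  n_obs <- colSums(!is.na(mat))
  if (any(n_obs < 2L)) {
    stop("sample column(s) with fewer than 2 observed values: ",
         paste(colnames(mat)[n_obs < 2L], collapse = ", "), call. = FALSE)
  }
  with_seed(config$seed, {
    for (j in seq_len(ncol(mat))) {
      miss <- is.na(mat[, j])
      if (!any(miss)) next
      obs <- mat[!miss, j]
      mu <- mean(obs) - config$impute_downshift * stats::sd(obs)
      sdev <- config$impute_width * stats::sd(obs)
      mat[miss, j] <- stats::rnorm(sum(miss), mu, sdev)
    }
    mat
  })
}

row_sds <- function(x) {
  mu <- rowMeans(x)
  sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
}

paired_t <- function(D, s0) {
  md <- rowMeans(D)
  se <- row_sds(D) / sqrt(ncol(D))
  t <- md / (s0 + se)
  if (s0 == 0) {
    zero <- se == 0
    t[zero] <- sign(md[zero]) * Inf
    t[zero & md == 0] <- 0
  }
  t
}

sign_patterns <- function(n, config) {
  exhaustive <- identical(config$n_permutations, "exhaustive") ||
    (is.numeric(config$n_permutations) && n <= 12L &&
       config$n_permutations >= 2^n)
  if (exhaustive) {
    if (n > 12L) {
      stop("exhaustive sign-flip enumeration limited to n <= 12 pairs; ",
           "set n_permutations to a count", call. = FALSE)
    }
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    with_seed(config$seed + 1L, {
      matrix(sample(c(1, -1), config$n_permutations * n, replace = TRUE),
             ncol = n)
    })
  }
}

# The identity pattern and its global negation reproduce the observed |t|
# exactly; they carry no information about the null and, kept in, would
# floor the FDR at 2 / n_patterns. They are dropped from the null (the
# per-protein permutation p-value still uses all patterns).
trivial_pattern <- function(patterns) {
  rowSums(patterns == 1) == ncol(patterns) |
    rowSums(patterns == -1) == ncol(patterns)
}

#' Paired sign-flip permutation test with SAM-style FDR
#'
#' For each protein the paired differences `d_i = log2 WT_i - log2 7dG_i`
#' give the statistic `t = mean(d) / (s0 + sd(d)/sqrt(n))`. The null is
#' built by flipping the signs of the difference vectors — exhaustively
#' over all `2^n` patterns for `n <= 12` pairs, otherwise over random
#' patterns — with every pattern applied identically to all proteins.
#' The identity pattern and its global negation reproduce the observed
#' statistics and are excluded from the null (they would floor the FDR
#' at `2 / 2^n`); the per-protein permutation p-value `p_perm` is still
#' computed over all patterns.
#' For a threshold `theta`, `FDR(theta)` is the mean number of null
#' `|t| >= theta` per pattern divided by the observed count; each
#' protein's q-value is the minimum FDR over thresholds at or below its
#' `|t|`, monotone in rank and capped at 1. With `s0 = 0`,
#' zero-variance nonzero differences get infinite `|t|` (ranked top and
#' flagged); all-zero differences get `t = 0`.
#'
#' @param mat Complete proteins x samples log2 matrix with columns
#'   `WT_1..WT_n`, `7dG_1..7dG_n`.
#' @param config An [ms_config()].
#'
#' @return data.frame: `protein_id`, `t_stat`, `p_perm`, `q_value`,
#'   `zero_variance`.
#' @export
paired_permutation_test <- function(mat, config = ms_config()) {
  cols <- lfq_columns(as.data.frame(matrix(0, 1, ncol(mat),
                                           dimnames = list(NULL, colnames(mat)))))
  n <- cols$n
  if (n < 2L) stop("need at least 2 replicate pairs", call. = FALSE)
  if (anyNA(mat)) stop("matrix must be complete (impute first)",
                       call. = FALSE)
  D <- mat[, cols$wt, drop = FALSE] - mat[, cols$dg, drop = FALSE]
  s0 <- if (identical(config$s0, "auto")) {
    stats::median(row_sds(D) / sqrt(n))
  } else {
    config$s0
  }
  t_obs <- paired_t(D, s0)
  abs_obs <- abs(t_obs)

  patterns <- sign_patterns(n, config)
  null_list <- vector("list", nrow(patterns))
  for (k in seq_len(nrow(patterns))) {
    Dk <- sweep(D, 2L, patterns[k, ], `*`)
    null_list[[k]] <- abs(paired_t(Dk, s0))
  }
  trivial <- trivial_pattern(patterns)
  if (all(trivial)) {
    stop("no informative sign-flip patterns; increase n_permutations",
         call. = FALSE)
  }
  null_abs <- unlist(null_list[!trivial], use.names = FALSE)
  n_pat <- sum(!trivial)

  count_ge <- function(sorted, theta) {
    length(sorted) - findInterval(theta, sorted, left.open = TRUE)
  }

  # per-protein permutation p over ALL patterns (identity included)
  all_null <- do.call(cbind, null_list)
  p_perm <- rowMeans(all_null >= abs_obs)

  # thresholds at the observed |t| values, strictest first
  th <- sort(unique(abs_obs), decreasing = TRUE)
  obs_sorted <- sort(abs_obs)
  null_sorted <- sort(null_abs)
  obs_count <- vapply(th, function(x) count_ge(obs_sorted, x), 0L)
  null_count <- vapply(th, function(x) count_ge(null_sorted, x), 0L)
  fdr <- pmin(1, (null_count / n_pat) / obs_count)
  # q at threshold j: best FDR at this or any weaker threshold
  q_th <- rev(cummin(rev(fdr)))
  q <- q_th[match(abs_obs, th)]

  out <- data.frame(protein_id = rownames(mat) %||%
                      as.character(seq_len(nrow(mat))),
                    t_stat = t_obs, p_perm = p_perm, q_value = q,
                    zero_variance = is.infinite(t_obs),
                    row.names = NULL)
  attr(out, "s0") <- s0
  out
}

#' Classify proteins into RG4-BPs and G-rich-BPs
#'
#' Proteins in `background_ids` (non-specific bead/bait binders) are
#' classed `background`; otherwise significant proteins
#' (`q <= q_cutoff`) with a WT/7dG ratio `>= fold_cutoff` are `RG4-BP`
#' (folded-quadruplex binders), those with ratio `<= 1/fold_cutoff` are
#' `G-rich-BP` (unfolded G-rich binders), and everything else is
#' `unclassified`.
#'
#' @param results data.frame with `protein_id`, `log2_ratio`, `q_value`.
#' @param config An [ms_config()].
#' @param background_ids Character vector of background protein ids (may
#'   be empty).
#'
#' @return `results` with a `class` column added.
#' @export
classify_binders <- function(results, config = ms_config(),
                             background_ids = character()) {
  ratio <- 2^results$log2_ratio
  cls <- rep("unclassified", nrow(results))
  sig <- !is.na(results$q_value) & results$q_value <= config$q_cutoff
  cls[sig & ratio >= config$fold_cutoff] <- "RG4-BP"
  cls[sig & ratio <= 1 / config$fold_cutoff] <- "G-rich-BP"
  cls[results$protein_id %in% background_ids] <- "background"
  results$class <- cls
  results
}

#' Full differential-binding analysis of a raw LFQ table
#'
#' Composes [preprocess_lfq()] -> [impute_mnar()] ->
#' [paired_permutation_test()] -> [classify_binders()]. The WT/7dG ratio
#' is computed from post-imputation log2 means by default (the imputation
#' exists precisely to make these ratios well defined); observed-only
#' means are reported as a diagnostic column.
#'
#' @param tab Raw LFQ protein-group data.frame (see [preprocess_lfq()]).
#' @param config An [ms_config()].
#' @param background_ids Character vector of background protein ids.
#'
#' @return A list with `results` (one row per input protein:
#'   `protein_id`, `log2_ratio`, `log2_ratio_observed`, `t_stat`,
#'   `q_value`, `n_valid_wt`, `n_valid_dg`, `zero_variance`, `class` —
#'   dropped proteins carry class `excluded`/`background` and `NA`
#'   statistics) and `summary` (class counts, number of retained
#'   proteins, and the count of proteins valid in all replicates).
#' @export
run_differential <- function(tab, config = ms_config(),
                             background_ids = character()) {
  pre <- preprocess_lfq(tab, config)
  imp <- impute_mnar(pre$log2, config)
  test <- paired_permutation_test(imp, config)

  lr_imp <- rowMeans(imp[, pre$wt, drop = FALSE]) -
    rowMeans(imp[, pre$dg, drop = FALSE])
  lr_obs <- rowMeans(pre$log2[, pre$wt, drop = FALSE], na.rm = TRUE) -
    rowMeans(pre$log2[, pre$dg, drop = FALSE], na.rm = TRUE)

  res <- data.frame(protein_id = rownames(imp),
                    log2_ratio = if (config$ratio_on_imputed) lr_imp else
                      lr_obs,
                    log2_ratio_observed = lr_obs,
                    t_stat = test$t_stat, q_value = test$q_value,
                    n_valid_wt = pre$n_valid_wt,
                    n_valid_dg = pre$n_valid_dg,
                    zero_variance = test$zero_variance,
                    row.names = NULL)
  res <- classify_binders(res, config, background_ids)

  if (nrow(pre$dropped)) {
    drop_res <- data.frame(protein_id = pre$dropped$protein_id,
                           log2_ratio = NA_real_,
                           log2_ratio_observed = NA_real_,
                           t_stat = NA_real_, q_value = NA_real_,
                           n_valid_wt = NA_integer_,
                           n_valid_dg = NA_integer_,
                           zero_variance = NA,
                           class = ifelse(
                             pre$dropped$protein_id %in% background_ids,
                             "background", "excluded"))
    res <- rbind(res, drop_res)
  }
  res <- res[match(tab$protein_id, res$protein_id), ]
  rownames(res) <- NULL

  all_valid <- sum(pre$n_valid_wt == pre$n_pairs &
                     pre$n_valid_dg == pre$n_pairs)
  counts <- table(factor(res$class, levels = c("RG4-BP", "G-rich-BP",
                                               "unclassified",
                                               "background", "excluded")))
  list(results = res,
       summary = list(class_counts = counts,
                      n_retained = nrow(imp),
                      n_significant = sum(res$class %in%
                                            c("RG4-BP", "G-rich-BP")),
                      n_all_valid = all_valid),
       config = config)
}
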