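mk_table <- function(mat, ids = sprintf("P%02d", seq_len(nrow(mat))),
                     con = "", rev = "") {
  tab <- data.frame(protein_id = ids, contaminant_flag = con,
                    reverse_flag = rev)
  tab <- cbind(tab, as.data.frame(mat))
  names(tab)[-(1:3)] <- c(paste0("WT_", 1:(ncol(mat) / 2)),
                          paste0("7dG_", 1:(ncol(mat) / 2)))
  tab
}

test_that("preprocess keeps one-condition-valid proteins and drops flagged rows", {
  m <- rbind(
    c(2^20, 2^21, 2^20, 2^21, 0, 0, 0, 0),        # 4/4 WT, 0/4 7dG: keep
    c(2^20, 2^21, 0, 0, 2^20, 2^21, 0, 0),        # 2/4 and 2/4: exclude
    c(2^20, 2^21, 2^20, 2^21, 2^20, 2^21, 2^20, 2^21))
  tab <- mk_table(m, con = c("", "", "+"))
  pre <- preprocess_lfq(tab, ms_config())
  expect_equal(rownames(pre$log2), "P01")
  expect_equal(unname(pre$n_valid_wt), 4)
  expect_equal(unname(pre$n_valid_dg), 0)
  expect_setequal(pre$dropped$protein_id, c("P02", "P03"))
  expect_equal(pre$dropped$reason[pre$dropped$protein_id == "P03"],
               "flagged")
  # strict both-conditions mode drops the one-sided protein too
  pre2 <- preprocess_lfq(tab, ms_config(require_both_conditions = TRUE))
  expect_equal(nrow(pre2$log2), 0L)
})

test_that("preprocess rejects unpaired replicate labels", {
  tab <- data.frame(protein_id = "P1", contaminant_flag = "",
                    reverse_flag = "", WT_1 = 1, WT_2 = 1, `7dG_1` = 1,
                    check.names = FALSE)
  expect_error(preprocess_lfq(tab, ms_config()), "unpaired")
})

test_that("imputation draws from the downshifted Gaussian only at missing cells", {
  m <- matrix(c(24, 26, NA, NA, 23, 25, NA, 27), ncol = 2,
              dimnames = list(paste0("p", 1:4), c("WT_1", "7dG_1")))
  cfg <- ms_config(seed = 5L)
  imp <- impute_mnar(m, cfg)
  expect_false(anyNA(imp))
  expect_equal(imp[!is.na(m)], m[!is.na(m)])
  expect_identical(impute_mnar(m, cfg), imp)
  expect_false(identical(impute_mnar(m, ms_config(seed = 6L)), imp))
  # no missing entries -> identity
  full <- matrix(rnorm(8, 25), 4, 2)
  expect_identical(impute_mnar(full, cfg), full)
  # a column with < 2 observed values cannot define (m, s)
  bad <- matrix(c(24, NA, NA, NA, 23, 25, 26, 27), ncol = 2,
                dimnames = list(NULL, c("WT_1", "7dG_1")))
  expect_error(impute_mnar(bad, cfg), "fewer than 2")
})

test_that("imputed values sit below observed values in every column", {
  lfq <- simulate_lfq(sim_lfq_config(n_proteins = 400L, seed = 31L))
  pre <- preprocess_lfq(lfq$table, ms_config())
  imp <- impute_mnar(pre$log2, ms_config(seed = 2L))
  for (j in seq_len(ncol(imp))) {
    miss <- is.na(pre$log2[, j])
    expect_lt(mean(imp[miss, j]), mean(imp[!miss, j]))
  }
})

test_that("exhaustive sign-flip q-values match the 16-pattern case", {
  m <- matrix(c(2, 2.2, 1.8, 2.1, 1, 1, 1, 1), nrow = 1,
              dimnames = list("P1", c("WT_1", "WT_2", "WT_3", "WT_4",
                                      "7dG_1", "7dG_2", "7dG_3", "7dG_4")))
  res <- paired_permutation_test(m, ms_config(s0 = 0))
  # only the identity and the global flip reach the observed |t|
  expect_equal(res$p_perm, 2 / 16)
  expect_false(res$zero_variance)

  # a random-pattern run covering all 16 patterns gives identical q
  res16 <- paired_permutation_test(m, ms_config(s0 = 0,
                                                n_permutations = 16L))
  expect_equal(res$q_value, res16$q_value)
  expect_equal(res$t_stat, res16$t_stat)
})

test_that("degenerate difference vectors are handled as specified", {
  # all differences zero for every protein -> q = 1 everywhere
  m <- cbind(matrix(20, 3, 4), matrix(20, 3, 4))
  colnames(m) <- c(paste0("WT_", 1:4), paste0("7dG_", 1:4))
  rownames(m) <- paste0("p", 1:3)
  res <- paired_permutation_test(m, ms_config(s0 = 0))
  expect_true(all(res$q_value == 1))
  expect_true(all(res$t_stat == 0))

  # zero-variance nonzero difference with s0 = 0: infinite t, flagged
  m[1, 1:4] <- 21
  res <- paired_permutation_test(m, ms_config(s0 = 0))
  expect_true(is.infinite(res$t_stat[1]))
  expect_true(res$zero_variance[1])
  expect_error(paired_permutation_test(m[, c(1, 5)], ms_config()),
               "at least 2")
  expect_error(paired_permutation_test(m * NA, ms_config()), "complete")
})

test_that("classification applies the FDR gate and symmetric fold cutoffs", {
  res <- data.frame(
    protein_id = c("a", "b", "c", "d", "e"),
    log2_ratio = c(log2(2), log2(0.5), log2(3), log2(1.2), log2(4)),
    q_value = c(0.01, 0.01, 0.2, 0.01, 0.01))
  out <- classify_binders(res, ms_config(), background_ids = "e")
  expect_equal(out$class,
               c("RG4-BP", "G-rich-BP", "unclassified", "unclassified",
                 "background"))
})

test_that("run_differential composes the stages into a coherent result", {
  lfq <- simulate_lfq(sim_lfq_config(n_proteins = 300L, seed = 41L))
  cfg <- ms_config(seed = 8L)
  run <- run_differential(lfq$table, cfg)
  res <- run$results
  expect_equal(nrow(res), nrow(lfq$table))
  # partition: every protein gets exactly one class
  expect_true(all(res$class %in% c("RG4-BP", "G-rich-BP", "unclassified",
                                   "background", "excluded")))
  expect_equal(sum(run$summary$class_counts), nrow(lfq$table))
  # class invariants
  sig <- res$class == "RG4-BP" & !is.na(res$q_value)
  expect_true(all(res$q_value[sig] <= cfg$q_cutoff))
  expect_true(all(2^res$log2_ratio[sig] >= cfg$fold_cutoff))
  gsig <- res$class == "G-rich-BP" & !is.na(res$q_value)
  expect_true(all(2^res$log2_ratio[gsig] <= 1 / cfg$fold_cutoff))
  # flagged decoys are excluded regardless of intensities
  flagged <- lfq$table$protein_id[is_con <-
    lfq$table$contaminant_flag == "+" | lfq$table$reverse_flag == "+"]
  expect_true(all(res$class[res$protein_id %in% flagged] == "excluded"))
  # determinism of the full composition
  expect_identical(run_differential(lfq$table, cfg)$results, res)
})

test_that("the paired test outperforms an unpaired test under batch shifts", {
  paired_power <- numeric(20)
  unpaired_power <- numeric(20)
  for (s in 1:20) {
    cfg <- sim_lfq_config(n_proteins = 200L, frac_differential = 0.2,
                          true_log2_effect = 1.0, pair_sd = 0.6,
                          mnar_midpoint = -1e6, contaminant_frac = 0,
                          seed = 700L + s)
    lfq <- simulate_lfq(cfg)
    truth_pos <- lfq$truth$protein_id[lfq$truth$label == "WT-preferring"]
    run <- run_differential(lfq$table, ms_config(seed = 800L + s))
    res <- run$results
    paired_power[s] <- mean(truth_pos %in%
                              res$protein_id[res$q_value <= 0.05 &
                                               !is.na(res$q_value)])
    ints <- log2(as.matrix(lfq$table[, -(1:3)]))
    pu <- apply(ints, 1, function(x) {
      stats::t.test(x[1:4], x[5:8], var.equal = FALSE)$p.value
    })
    qu <- stats::p.adjust(pu, "BH")
    unpaired_power[s] <- mean(truth_pos %in%
                                lfq$table$protein_id[qu <= 0.05])
  }
  expect_gte(mean(paired_power), mean(unpaired_power))
})
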