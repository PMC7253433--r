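# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: run detection by direct window checks, combination
# enumeration via combn, hypergeometric tails via choose().

# surrogate G-score, restated from its definition
oracle_score <- function(g, l1, l2, l3, maxlen = 30) {
  20 * (g - 2) + 0.5 * (maxlen - 4 * g - (l1 + l2 + l3)) -
    (pmax(l1, l2, l3) - pmin(l1, l2, l3))
}

# exhaustive QGRS enumeration over all (run-position, g) tuples
brute_qgrs <- function(sequence, params = rg4_params()) {
  s <- chartr("uU", "TT", toupper(sequence))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  isG <- chars == "G"
  maxlen <- params$max_qgrs_length
  rows <- list()
  for (g in params$min_g_run:max(params$min_g_run, maxlen %/% 4)) {
    if (n < 4 * g) break
    pos <- which(vapply(seq_len(n - g + 1L),
                        function(i) all(isG[i:(i + g - 1L)]), TRUE))
    if (length(pos) < 4L) next
    for (p1 in pos) {
      sub <- pos[pos > p1 & pos <= p1 + maxlen - g]
      if (length(sub) < 3L) next
      cmb <- utils::combn(sub, 3L)
      for (j in seq_len(ncol(cmb))) {
        p <- c(p1, cmb[, j])
        l <- c(p[2] - (p[1] + g), p[3] - (p[2] + g), p[4] - (p[3] + g))
        if (any(l < params$loop_min | l > params$loop_max)) next
        if ((p[4] + g - 1L) - p[1] + 1L > maxlen) next
        rows[[length(rows) + 1L]] <-
          data.frame(start = p[1] - 1L, end = p[4] + g - 1L, g_run = g,
                     l1 = l[1], l2 = l[2], l3 = l[3])
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      g_run = integer(), l1 = integer(), l2 = integer(),
                      l3 = integer(), score = numeric()))
  }
  cand <- do.call(rbind, rows)
  cand$score <- oracle_score(cand$g_run, cand$l1, cand$l2, cand$l3,
                             maxlen)
  ord <- order(cand$start, cand$end, -cand$g_run, -cand$score,
               cand$l1, cand$l2, cand$l3)
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[!duplicated(cand[c("start", "end")]), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

# two-sided Fisher p by direct binomial-coefficient enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n_ <- c + d
  k <- a + c
  kk <- max(0L, k - n_):min(k, m)
  dens <- exp(lchoose(m, kk) + lchoose(n_, k - kk) - lchoose(m + n_, k))
  min(1, sum(dens[dens <= dens[kk == a] * (1 + 1e-7)]))
}

random_seq <- function(len, p_g = 0.35) {
  probs <- c(A = (1 - p_g) / 3, C = (1 - p_g) / 3, G = p_g,
             T = (1 - p_g) / 3)
  paste(sample(names(probs), len, replace = TRUE, prob = probs),
        collapse = "")
}

# small transcriptome + catalog fixture shared by enrichment tests
small_sim <- function(seed = 3L, n_transcripts = 12L) {
  simulate_transcriptome(sim_transcriptome_config(
    n_transcripts = n_transcripts,
    region_lengths = list(utr5 = c(150, 40), cds = c(600, 150),
                          utr3 = c(450, 120)),
    seed = seed))
}
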