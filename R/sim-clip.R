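#' Configuration for the synthetic CLIP-site generator
#'
#' @param n_sites Number of binding sites to place.
#' @param site_length_mean,site_length_sd Site length distribution (nt);
#'   drawn lengths are rounded and floored at 5 nt. Defaults emulate
#'   called CLIP peaks of about 40 nt.
#' @param g4_enrichment_factor Placement-propensity ratio (>= 0) of start
#'   positions whose site would overlap a planted G4 versus all others.
#'   `1` means placement is uniform over eligible start positions; `0`
#'   forbids any overlap with planted motifs.
#' @param seed Integer seed.
#'
#' @return An object of class `sim_clip_config`.
#' @export
sim_clip_config <- function(n_sites = 500L, site_length_mean = 40,
                            site_length_sd = 10,
                            g4_enrichment_factor = 1, seed = 1L) {
  n_sites <- check_count(n_sites, "n_sites", min = 1L)
  stopifnot(site_length_mean >= 5, site_length_sd >= 0,
            is.numeric(g4_enrichment_factor), g4_enrichment_factor >= 0)
  structure(list(n_sites = n_sites, site_length_mean = site_length_mean,
                 site_length_sd = site_length_sd,
                 g4_enrichment_factor = g4_enrichment_factor,
                 seed = as.integer(seed)),
            class = "sim_clip_config")
}

# merged [start, end] (1-based, inclusive) intervals of valid start
# positions whose site of length L overlaps a planted motif; tt is the
# per-transcript truth table, sorted by start
overlap_start_intervals <- function(tt, L, n_starts) {
  if (is.null(tt) || nrow(tt) == 0L || n_starts < 1L) return(NULL)
  s <- pmax(1L, tt$start - L + 2L)
  e <- pmin(n_starts, tt$end)
  keep <- s <= e
  s <- s[keep]
  e <- e[keep]
  if (!length(s)) return(NULL)
  out_s <- s[1]
  out_e <- e[1]
  j <- 1L
  for (i in seq_along(s)[-1]) {
    if (s[i] <= out_e[j] + 1L) {
      out_e[j] <- max(out_e[j], e[i])
    } else {
      j <- j + 1L
      out_s[j] <- s[i]
      out_e[j] <- e[i]
    }
  }
  cbind(out_s, out_e)
}

# complement of an interval set within [1, n]
complement_intervals <- function(iv, n) {
  if (n < 1L) return(NULL)
  if (is.null(iv)) return(cbind(1L, n))
  s <- c(1L, iv[, 2] + 1L)
  e <- c(iv[, 1] - 1L, n)
  keep <- s <= e
  if (!any(keep)) return(NULL)
  cbind(s[keep], e[keep])
}

# uniform draw of m start positions over a named list of interval sets
pick_uniform_starts <- function(iv_by_tx, m) {
  iv_by_tx <- iv_by_tx[!vapply(iv_by_tx, is.null, TRUE)]
  if (!length(iv_by_tx)) {
    stop("no eligible start positions available", call. = FALSE)
  }
  tx <- rep(names(iv_by_tx), vapply(iv_by_tx, nrow, 0L))
  st <- unlist(lapply(iv_by_tx, function(x) x[, 1]), use.names = FALSE)
  en <- unlist(lapply(iv_by_tx, function(x) x[, 2]), use.names = FALSE)
  cw <- cumsum(as.numeric(en - st + 1L))
  u <- floor(stats::runif(m) * cw[length(cw)]) + 1
  ri <- findInterval(u - 1, cw) + 1L
  off <- as.integer(u - 1 - c(0, cw)[ri])
  list(tx = tx[ri], start = st[ri] + off)
}

#' Simulate CLIP binding sites over a synthetic transcriptome
#'
#' Sites are placed by weighted sampling over valid start positions: a
#' start whose interval would overlap a planted G4 motif carries weight
#' `g4_enrichment_factor`, all others weight 1. Site lengths are drawn
#' from the configured normal distribution and clipped to transcript
#' bounds; placement is with replacement (real CLIP peaks from distinct
#' proteins may coincide).
#'
#' @param transcriptome Result of [simulate_transcriptome()] (uses
#'   `$regions` and `$truth`).
#' @param config A [sim_clip_config()].
#'
#' @return A `GRanges` of sites (seqnames = transcript ids, sense strand)
#'   with seqlengths set and an `overlaps_planted` metadata column.
#' @export
simulate_clip_sites <- function(transcriptome, config) {
  stopifnot(inherits(config, "sim_clip_config"))
  regions <- transcriptome$regions
  truth <- transcriptome$truth
  if (nrow(truth) &&
      !all(truth$transcript_id %in% regions$transcript_id)) {
    stop("truth table refers to transcripts absent from the transcriptome",
         call. = FALSE)
  }
  tx_len <- stats::setNames(regions$length, regions$transcript_id)
  f <- config$g4_enrichment_factor

  with_seed(config$seed, {
    lens <- pmax(5L, round(stats::rnorm(config$n_sites,
                                        config$site_length_mean,
                                        config$site_length_sd)))
    lens <- pmin(lens, max(tx_len))
    mean_len <- round(config$site_length_mean)
    avail <- sum(pmax(0L, tx_len - mean_len + 1L))
    if (config$n_sites > avail) {
      stop(sprintf("n_sites (%d) exceeds available start positions (%d)",
                   config$n_sites, avail), call. = FALSE)
    }

    out_tx <- character(config$n_sites)
    out_start <- integer(config$n_sites)
    out_len <- integer(config$n_sites)
    out_ov <- logical(config$n_sites)
    idx <- 0L
    truth_by_tx <- split(truth, factor(truth$transcript_id,
                                       levels = names(tx_len)))

    for (L in sort(unique(lens))) {
      k <- sum(lens == L)
      n_starts <- stats::setNames(pmax(0L, tx_len - L + 1L),
                                  names(tx_len))
      use <- names(tx_len)[n_starts > 0L]
      if (!length(use)) {
        stop(sprintf("site length %d exceeds every transcript", L),
             call. = FALSE)
      }
      ov <- lapply(use, function(tx) {
        overlap_start_intervals(truth_by_tx[[tx]], L, n_starts[[tx]])
      })
      names(ov) <- use
      n_ov <- vapply(ov, function(x) {
        if (is.null(x)) 0 else sum(x[, 2] - x[, 1] + 1)
      }, 0)
      O <- sum(n_ov)
      Tt <- sum(as.numeric(n_starts[use]))
      p_ov <- if (f * O + (Tt - O) > 0) f * O / (f * O + (Tt - O)) else 0
      take_ov <- stats::rbinom(k, 1L, p_ov) == 1L

      m_ov <- sum(take_ov)
      m_un <- k - m_ov
      res_tx <- character(k)
      res_start <- integer(k)
      if (m_ov > 0L) {
        pick <- pick_uniform_starts(ov, m_ov)
        res_tx[take_ov] <- pick$tx
        res_start[take_ov] <- pick$start
      }
      if (m_un > 0L) {
        comp <- lapply(use, function(tx) {
          complement_intervals(ov[[tx]], n_starts[[tx]])
        })
        names(comp) <- use
        pick <- pick_uniform_starts(comp, m_un)
        res_tx[!take_ov] <- pick$tx
        res_start[!take_ov] <- pick$start
      }
      at <- idx + seq_len(k)
      out_tx[at] <- res_tx
      out_start[at] <- res_start
      out_len[at] <- L
      out_ov[at] <- take_ov
      idx <- idx + k
    }

    gr <- GenomicRanges::GRanges(
      seqnames = out_tx,
      ranges = IRanges::IRanges(start = out_start, width = out_len),
      strand = "+",
      overlaps_planted = out_ov,
      seqlengths = tx_len)
    names(gr) <- sprintf("site%05d", seq_along(gr))
    sort(gr)
  })
}
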