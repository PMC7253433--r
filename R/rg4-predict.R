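#' Parameters for QGRS-style RG4 prediction
#'
#' Holds the settings of the quadruplex scanner: the minimal G-run (tetrad)
#' length, the maximal motif span, the allowed loop lengths and the G-score
#' acceptance threshold. Defaults mirror the QGRS Mapper defaults with the
#' commonly used acceptance score of 19.
#'
#' @param min_g_run Minimal length of each of the four G-runs (>= 2).
#' @param max_qgrs_length Maximal motif span in nt (default 30).
#' @param loop_min,loop_max Allowed loop lengths in nt (defaults 0 and 36).
#' @param score_threshold Minimal G-score for an accepted hit (default 19).
#'
#' @return An object of class `rg4_params` (a validated list).
#' @examples
#' rg4_params()
#' rg4_params(min_g_run = 3)
#' @export
rg4_params <- function(min_g_run = 2L, max_qgrs_length = 30L,
                       loop_min = 0L, loop_max = 36L,
                       score_threshold = 19) {
  min_g_run <- check_count(min_g_run, "min_g_run", min = 2L)
  max_qgrs_length <- check_count(max_qgrs_length, "max_qgrs_length", min = 1L)
  loop_min <- check_count(loop_min, "loop_min", min = 0L)
  loop_max <- check_count(loop_max, "loop_max", min = 0L)
  stopifnot(loop_min <= loop_max,
            max_qgrs_length >= 4L * min_g_run + 3L * loop_min,
            is.numeric(score_threshold), length(score_threshold) == 1L)
  structure(list(min_g_run = min_g_run, max_qgrs_length = max_qgrs_length,
                 loop_min = loop_min, loop_max = loop_max,
                 score_threshold = as.numeric(score_threshold)),
            class = "rg4_params")
}

#' Find maximal G-runs in a nucleotide sequence
#'
#' Reports all maximal runs of consecutive guanines of at least `min_run`
#' nt, left to right. U and T are equivalent; case is ignored; `N` never
#' counts as G.
#'
#' @param sequence A nucleotide string (or `XString`) over A/C/G/T/U/N.
#' @param min_run Minimal run length to report.
#'
#' @return A data.frame with columns `start` (0-based) and `length`.
#' @examples
#' find_g_runs("GGGAAGGGAAGGGAAGGG", 2)
#' @export
find_g_runs <- function(sequence, min_run = 2L) {
  min_run <- check_count(min_run, "min_run", min = 1L)
  s <- norm_seq(sequence)
  runs <- g_run_table(s)
  runs <- runs[runs$length >= min_run, , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

# maximal G-runs of any length; start is 0-based
g_run_table <- function(s) {
  if (nchar(s) == 0L) {
    return(data.frame(start = integer(), length = integer()))
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  r <- rle(chars == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1L, length = r$lengths[keep])
}

#' G-score of a quadruplex candidate
#'
#' Deterministic score rewarding more stacked tetrads, shorter loops and
#' even loop lengths:
#' `20 * (g - 2) + 0.5 * (max_qgrs_length - 4 * g - l1 - l2 - l3) -
#' (max(l) - min(l))`.
#' It is strictly increasing in the tetrad number `g` at fixed loops,
#' maximal for equal loops at fixed total loop length, and non-increasing
#' in total loop length. The canonical G3A2 motif (g = 3, loops 2/2/2)
#' scores 26.
#'
#' @param g_run Tetrad number (length of the four G-runs); vectorized.
#' @param l1,l2,l3 The three loop lengths in nt; vectorized.
#' @param params An [rg4_params()] object (supplies `max_qgrs_length`).
#'
#' @return Numeric vector of scores.
#' @examples
#' gscore(3, 2, 2, 2)  # 26
#' @export
gscore <- function(g_run, l1, l2, l3, params = rg4_params()) {
  stopifnot(inherits(params, "rg4_params"))
  lmat <- cbind(l1, l2, l3)
  20 * (g_run - 2) +
    0.5 * (params$max_qgrs_length - 4 * g_run - rowSums(lmat)) -
    (pmax(l1, l2, l3) - pmin(l1, l2, l3))
}

#' Enumerate QGRS candidates in a sequence
#'
#' Scans the sense strand for windows of at most `max_qgrs_length` nt
#' containing four equal-length G-runs of length `g >= min_g_run` separated
#' by three loops within `[loop_min, loop_max]`. For each distinct span the
#' maximal-`g`, best-scoring decomposition is emitted; same-span candidates
#' with smaller `g` are suppressed.
#'
#' @param sequence Nucleotide string; U/T equivalent, case-insensitive.
#' @param params An [rg4_params()] object.
#'
#' @return A data.frame with columns `start`, `end` (0-based half-open),
#'   `g_run`, `l1`, `l2`, `l3`, `score`, ordered by `start` then `end`.
#' @examples
#' enumerate_qgrs("GGGAAGGGAAGGGAAGGG")
#' @export
enumerate_qgrs <- function(sequence, params = rg4_params()) {
  stopifnot(inherits(params, "rg4_params"))
  s <- norm_seq(sequence)
  empty <- data.frame(start = integer(), end = integer(), g_run = integer(),
                      l1 = integer(), l2 = integer(), l3 = integer(),
                      score = numeric())
  runs <- g_run_table(s)
  if (nrow(runs) < 1L) return(empty)
  maxlen <- params$max_qgrs_length
  lmin <- params$loop_min
  lmax <- params$loop_max
  g_top <- min(max(runs$length), (maxlen - 3L * lmin) %/% 4L)
  if (g_top < params$min_g_run) return(empty)

  rows <- vector("list", 64L)
  n_rows <- 0L
  for (g in params$min_g_run:g_top) {
    ok <- runs$length >= g
    if (!any(ok)) next
    # 0-based start positions of every (sub-)run of exactly g Gs
    P <- unlist(lapply(which(ok), function(i) {
      seq.int(runs$start[i], runs$start[i] + runs$length[i] - g)
    }), use.names = FALSE)
    P <- sort(P)
    for (p1 in P) {
      p4_lim <- p1 + maxlen - g           # last admissible run start
      P2 <- P[P >= p1 + g + lmin & P <= min(p1 + g + lmax, p4_lim)]
      for (p2 in P2) {
        P3 <- P[P >= p2 + g + lmin & P <= min(p2 + g + lmax, p4_lim)]
        for (p3 in P3) {
          P4 <- P[P >= p3 + g + lmin & P <= min(p3 + g + lmax, p4_lim)]
          for (p4 in P4) {
            n_rows <- n_rows + 1L
            if (n_rows > length(rows)) rows <- c(rows, vector("list", length(rows)))
            rows[[n_rows]] <- c(p1, p2, p3, p4, g)
          }
        }
      }
    }
  }
  if (n_rows == 0L) return(empty)
  m <- do.call(rbind, rows[seq_len(n_rows)])
  cand <- data.frame(
    start = m[, 1L],
    end   = m[, 4L] + m[, 5L],
    g_run = m[, 5L],
    l1    = m[, 2L] - (m[, 1L] + m[, 5L]),
    l2    = m[, 3L] - (m[, 2L] + m[, 5L]),
    l3    = m[, 4L] - (m[, 3L] + m[, 5L])
  )
  cand$score <- gscore(cand$g_run, cand$l1, cand$l2, cand$l3, params)
  # per span keep maximal g, then best score, then lexicographic loops
  ord <- order(cand$start, cand$end, -cand$g_run, -cand$score,
               cand$l1, cand$l2, cand$l3)
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[!duplicated(cand[c("start", "end")]), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Select accepted, non-overlapping RG4 hits
#'
#' Drops candidates scoring below `params$score_threshold`, then resolves
#' overlaps greedily: the highest-scoring remaining candidate is kept and
#' all candidates sharing at least one nt with it are discarded. Ties are
#' broken by smaller start, then shorter span.
#'
#' @param candidates Candidate table from [enumerate_qgrs()].
#' @param params An [rg4_params()] object.
#'
#' @return The accepted subset of `candidates`, ordered by `start`.
#' @export
select_hits <- function(candidates, params = rg4_params()) {
  stopifnot(inherits(params, "rg4_params"))
  cand <- candidates[candidates$score >= params$score_threshold, , drop = FALSE]
  if (nrow(cand) <= 1L) {
    rownames(cand) <- NULL
    return(cand)
  }
  ord <- order(-cand$score, cand$start, cand$end - cand$start)
  cand <- cand[ord, , drop = FALSE]
  acc_start <- integer()
  acc_end <- integer()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(acc_start < cand$end[i] & cand$start[i] < acc_end)) {
      keep[i] <- TRUE
      acc_start <- c(acc_start, cand$start[i])
      acc_end <- c(acc_end, cand$end[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

region_of <- function(start, utr5_end, cds_end) {
  ifelse(start < utr5_end, "utr5", ifelse(start < cds_end, "cds", "utr3"))
}

REGIONS <- c("utr5", "cds", "utr3")

#' Predict an RG4 catalog over an annotated transcriptome
#'
#' Runs enumerate -> score -> select on the sense strand of every
#' transcript and assigns each accepted hit to the 5'UTR, CDS or 3'UTR by
#' its start position. Region boundaries are 0-based half-open:
#' `[0, utr5_end)` is the 5'UTR, `[utr5_end, cds_end)` the CDS and
#' `[cds_end, length)` the 3'UTR.
#'
#' @param sequences Named character vector or `Biostrings::DNAStringSet`
#'   of transcript sequences.
#' @param regions data.frame with columns `transcript_id`, `utr5_end`,
#'   `cds_end`, `length`.
#' @param params An [rg4_params()] object.
#'
#' @return An object of class `rg4_catalog`: a list with `hits` (data.frame
#'   of accepted hits with a `region` column), `region_summary` (per-region
#'   hit counts and total region length in nt), `params`, and `scorer`
#'   (identity of the scoring function, recorded in output metadata).
#' @examples
#' seqs <- c(tx1 = paste0(strrep("ACT", 20), "GGGAAGGGAAGGGAAGGG",
#'                        strrep("TCA", 20)))
#' reg <- data.frame(transcript_id = "tx1", utr5_end = 30, cds_end = 90,
#'                   length = nchar(seqs))
#' predict_catalog(seqs, reg)
#' @export
predict_catalog <- function(sequences, regions, params = rg4_params()) {
  if (is(sequences, "XStringSet")) {
    sequences <- as.character(sequences)
  }
  stopifnot(is.character(sequences), !is.null(names(sequences)),
            is.data.frame(regions),
            all(c("transcript_id", "utr5_end", "cds_end", "length") %in%
                  names(regions)))
  missing_tx <- setdiff(names(sequences), regions$transcript_id)
  if (length(missing_tx)) {
    stop("no region annotation for transcript(s): ",
         paste(utils::head(missing_tx, 5L), collapse = ", "), call. = FALSE)
  }
  regions <- regions[match(names(sequences), regions$transcript_id), ]
  if (any(regions$cds_end <= regions$utr5_end)) {
    stop("empty CDS annotation (cds_end <= utr5_end)", call. = FALSE)
  }
  if (any(regions$utr5_end < 0) || any(regions$cds_end > regions$length)) {
    stop("region boundaries outside [0, length]", call. = FALSE)
  }
  if (any(nchar(sequences) != regions$length)) {
    stop("annotated length disagrees with sequence length", call. = FALSE)
  }

  hit_list <- lapply(seq_along(sequences), function(i) {
    h <- select_hits(enumerate_qgrs(sequences[[i]], params), params)
    if (nrow(h) == 0L) return(NULL)
    h$transcript_id <- names(sequences)[i]
    h$region <- region_of(h$start, regions$utr5_end[i], regions$cds_end[i])
    h
  })
  hits <- do.call(rbind, hit_list)
  if (is.null(hits)) {
    hits <- data.frame(start = integer(), end = integer(), g_run = integer(),
                       l1 = integer(), l2 = integer(), l3 = integer(),
                       score = numeric(), transcript_id = character(),
                       region = character())
  }
  hits <- hits[c("transcript_id", "start", "end", "g_run",
                 "l1", "l2", "l3", "score", "region")]
  region_nt <- c(
    utr5 = sum(regions$utr5_end),
    cds  = sum(regions$cds_end - regions$utr5_end),
    utr3 = sum(regions$length - regions$cds_end)
  )
  region_summary <- data.frame(
    region = REGIONS,
    n_hits = as.integer(table(factor(hits$region, levels = REGIONS))),
    region_nt = as.numeric(region_nt[REGIONS])
  )
  structure(list(hits = hits, region_summary = region_summary,
                 params = params, scorer = "surrogate_gscore_v1"),
            class = "rg4_catalog")
}

#' @export
print.rg4_catalog <- function(x, ...) {
  cat("RG4 catalog:", nrow(x$hits), "accepted hits",
      sprintf("(scorer: %s, threshold >= %g)\n",
              x$scorer, x$params$score_threshold))
  print(x$region_summary, row.names = FALSE)
  invisible(x)
}

#' Write an RG4 catalog as BED6 plus annotation columns
#'
#' BED columns: transcript, start, end, name (`region`), score, strand
#' (always `+`; prediction is sense-strand only), followed by `g_run`,
#' `l1`, `l2`, `l3`.
#'
#' @param catalog An `rg4_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog_bed <- function(catalog, path) {
  stopifnot(inherits(catalog, "rg4_catalog"))
  h <- catalog$hits
  bed <- data.frame(h$transcript_id, h$start, h$end, h$region, h$score, "+",
                    h$g_run, h$l1, h$l2, h$l3)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
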