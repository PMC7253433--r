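#' Configuration for the synthetic transcriptome generator
#'
#' Describes a transcriptome with annotated 5'UTR/CDS/3'UTR regions into
#' which exact quadruplex motifs are planted at controlled per-region
#' rates. Defaults emulate a compact mRNA transcriptome: 5'UTRs around
#' 200 nt, coding regions around 1.2 kb, 3'UTRs around 800 nt, 45% GC,
#' and RG4 motifs planted preferentially in untranslated regions.
#'
#' @param n_transcripts Number of transcripts.
#' @param region_lengths Named list `utr5`/`cds`/`utr3`, each `c(mean, sd)`
#'   of the region length in nt. CDS lengths are rounded to multiples of 3.
#' @param gc_content Background GC fraction in `[0, 1]`.
#' @param g4_rate_per_region Named vector `utr5`/`cds`/`utr3`: expected
#'   planted motifs per kb of region.
#' @param planted_g_run G-run (tetrad) length of planted motifs (>= 2).
#' @param planted_loops Three loop lengths (0-36 nt) of planted motifs.
#' @param seed Integer seed; all randomness is private to this seed.
#'
#' @return An object of class `sim_transcriptome_config`.
#' @export
sim_transcriptome_config <- function(n_transcripts = 100L,
                                     region_lengths = list(
                                       utr5 = c(200, 80),
                                       cds  = c(1200, 400),
                                       utr3 = c(800, 300)),
                                     gc_content = 0.45,
                                     g4_rate_per_region = c(utr5 = 1,
                                                            cds = 0.3,
                                                            utr3 = 1),
                                     planted_g_run = 3L,
                                     planted_loops = c(2L, 2L, 2L),
                                     seed = 1L) {
  n_transcripts <- check_count(n_transcripts, "n_transcripts", min = 1L)
  stopifnot(is.list(region_lengths),
            all(REGIONS %in% names(region_lengths)),
            all(vapply(region_lengths, length, 1L) == 2L),
            is.numeric(gc_content), gc_content >= 0, gc_content <= 1,
            all(REGIONS %in% names(g4_rate_per_region)),
            all(g4_rate_per_region >= 0),
            length(planted_loops) == 3L,
            all(planted_loops >= 0L), all(planted_loops <= 36L))
  planted_g_run <- check_count(planted_g_run, "planted_g_run", min = 2L)
  structure(list(n_transcripts = n_transcripts,
                 region_lengths = region_lengths[REGIONS],
                 gc_content = gc_content,
                 g4_rate_per_region = g4_rate_per_region[REGIONS],
                 planted_g_run = planted_g_run,
                 planted_loops = as.integer(planted_loops),
                 seed = as.integer(seed)),
            class = "sim_transcriptome_config")
}

# break every background G-run of length >= g by substituting non-G bases
# at in-run offsets g, 2g, ... (1-based); guarantees no run of length >= g
break_g_runs <- function(chars, g) {
  r <- rle(chars == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- which(r$values & r$lengths >= g)
  for (i in long) {
    at <- seq.int(starts[i] + g - 1L, ends[i], by = g)
    chars[at] <- sample(c("A", "C", "T"), length(at), replace = TRUE)
  }
  chars
}

#' Simulate a transcriptome with planted RG4 motifs
#'
#' Generates i.i.d. background sequence at the requested GC content,
#' then removes every background G-run of length `>= planted_g_run` so
#' that planted motifs are provably the only quadruplexes of the planted
#' tetrad class, and plants exact four-G-run motifs at per-region Poisson
#' rates. Planted motifs never overlap, keep at least `max_qgrs_length`
#' nt between each other (so no scanning window mixes two motifs), lie
#' fully inside their region, and are flanked by non-G bases so the
#' planted G-runs stay maximal. Loop bases are drawn from A/C/T.
#'
#' @param config A [sim_transcriptome_config()].
#' @param max_qgrs_length Spacing guard between planted motifs (nt);
#'   keep equal to the scanner's `max_qgrs_length`.
#'
#' @return A list with `sequences` (named character vector), `regions`
#'   (transcript table: `transcript_id`, `utr5_end`, `cds_end`, `length`),
#'   `truth` (planted motifs: `transcript_id`, `region`, `start`, `end`,
#'   `g_run`, `motif`) and `config`.
#' @examples
#' sim <- simulate_transcriptome(sim_transcriptome_config(n_transcripts = 3,
#'                                                        seed = 7))
#' head(sim$truth)
#' @export
simulate_transcriptome <- function(config, max_qgrs_length = 30L) {
  stopifnot(inherits(config, "sim_transcriptome_config"))
  g <- config$planted_g_run
  loops <- config$planted_loops
  motif_len <- 4L * g + sum(loops)
  with_seed(config$seed, {
    n <- config$n_transcripts
    draw_len <- function(ms, floor_nt) {
      pmax(floor_nt, round(stats::rnorm(n, ms[1], ms[2])))
    }
    utr5_len <- draw_len(config$region_lengths$utr5, 30L)
    cds_len <- draw_len(config$region_lengths$cds, 60L)
    cds_len <- 3L * pmax(20L, round(cds_len / 3))
    utr3_len <- draw_len(config$region_lengths$utr3, 30L)
    tx_len <- utr5_len + cds_len + utr3_len

    base_probs <- c(A = (1 - config$gc_content) / 2,
                    C = config$gc_content / 2,
                    G = config$gc_content / 2,
                    T = (1 - config$gc_content) / 2)

    sequences <- character(n)
    names(sequences) <- sprintf("tx%04d", seq_len(n))
    truth <- vector("list", n)
    gap <- as.integer(max_qgrs_length)

    for (i in seq_len(n)) {
      chars <- sample(names(base_probs), tx_len[i], replace = TRUE,
                      prob = base_probs)
      chars <- break_g_runs(chars, g)

      bounds <- list(utr5 = c(0L, utr5_len[i]),
                     cds  = c(utr5_len[i], utr5_len[i] + cds_len[i]),
                     utr3 = c(utr5_len[i] + cds_len[i], tx_len[i]))
      placed_start <- integer()
      placed_region <- character()
      for (region in REGIONS) {
        rlen <- bounds[[region]][2] - bounds[[region]][1]
        n_plant <- stats::rpois(1L, config$g4_rate_per_region[[region]] *
                                  rlen / 1000)
        if (n_plant == 0L) next
        if (rlen < motif_len) {
          stop(sprintf(
            "transcript %s: %s region (%d nt) too short to host a planted motif (%d nt)",
            names(sequences)[i], region, rlen, motif_len), call. = FALSE)
        }
        # capacity cap: motifs need `gap` nt between each other
        capacity <- 1L + (rlen - motif_len) %/% (motif_len + gap)
        n_plant <- min(n_plant, capacity)
        lo <- bounds[[region]][1]
        hi <- bounds[[region]][2] - motif_len
        for (k in seq_len(n_plant)) {
          ok <- FALSE
          for (try in seq_len(500L)) {
            s0 <- sample.int(hi - lo + 1L, 1L) + lo - 1L
            if (!length(placed_start) ||
                all(abs(s0 - placed_start) >= motif_len + gap)) {
              ok <- TRUE
              break
            }
          }
          if (!ok) break  # region saturated for this draw; plant fewer
          placed_start <- c(placed_start, s0)
          placed_region <- c(placed_region, region)
        }
      }

      motifs <- character(length(placed_start))
      for (k in seq_along(placed_start)) {
        loops_seq <- vapply(loops, function(l) {
          paste(sample(c("A", "C", "T"), l, replace = TRUE), collapse = "")
        }, character(1))
        motif <- paste0(strrep("G", g), loops_seq[1], strrep("G", g),
                        loops_seq[2], strrep("G", g), loops_seq[3],
                        strrep("G", g))
        motifs[k] <- motif
        s0 <- placed_start[k]
        chars[(s0 + 1L):(s0 + motif_len)] <- strsplit(motif, "")[[1]]
        # non-G flanks keep planted runs maximal
        if (s0 >= 1L && chars[s0] == "G") {
          chars[s0] <- sample(c("A", "C", "T"), 1L)
        }
        after <- s0 + motif_len + 1L
        if (after <= tx_len[i] && chars[after] == "G") {
          chars[after] <- sample(c("A", "C", "T"), 1L)
        }
      }
      sequences[i] <- paste(chars, collapse = "")
      if (length(placed_start)) {
        ord <- order(placed_start)
        truth[[i]] <- data.frame(
          transcript_id = names(sequences)[i],
          region = placed_region[ord],
          start = placed_start[ord],
          end = placed_start[ord] + motif_len,
          g_run = g,
          motif = motifs[ord])
      }
    }

    truth <- do.call(rbind, truth)
    if (is.null(truth)) {
      truth <- data.frame(transcript_id = character(), region = character(),
                          start = integer(), end = integer(),
                          g_run = integer(), motif = character())
    }
    rownames(truth) <- NULL
    list(sequences = sequences,
         regions = data.frame(transcript_id = names(sequences),
                              utr5_end = utr5_len,
                              cds_end = utr5_len + cds_len,
                              length = tx_len),
         truth = truth,
         config = config)
  })
}
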