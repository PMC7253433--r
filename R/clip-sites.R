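#' Read binding sites from a BED6 file
#'
#' Strict reader for 0-based half-open BED6: chrom, start, end, name,
#' score, strand. Malformed lines are rejected with their line numbers.
#'
#' @param path Path to a BED6 file.
#'
#' @return A `GRanges` (1-based internally, as usual for Bioconductor)
#'   with `name` and `score` metadata columns.
#' @export
read_sites <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no BED records in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("BED line(s) with fewer than 6 fields: line ",
         paste(lineno[nf < 6L], collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  score <- suppressWarnings(as.numeric(m[, 5]))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop("non-integer start/end at line ",
         paste(lineno[bad], collapse = ", "), call. = FALSE)
  }
  bad <- start >= end | start < 0L
  if (any(bad)) {
    stop("invalid interval (start >= end or start < 0) at line ",
         paste(lineno[bad], collapse = ", "), call. = FALSE)
  }
  bad <- is.na(score) & m[, 5] != "."
  if (any(bad)) {
    stop("non-numeric score at line ",
         paste(lineno[bad], collapse = ", "), call. = FALSE)
  }
  bad <- !m[, 6] %in% c("+", "-")
  if (any(bad)) {
    stop("unknown strand at line ",
         paste(lineno[bad], collapse = ", "), call. = FALSE)
  }
  GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = m[, 6],
    name = m[, 4],
    score = score)
}

#' Write sites as BED6
#'
#' @param sites A `GRanges`; `name`/`score` metadata columns are used when
#'   present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  mc <- S4Vectors::mcols(sites)
  name <- if ("name" %in% names(mc)) mc$name else
    names(sites) %||% rep(".", length(sites))
  score <- if ("score" %in% names(mc)) mc$score else rep(0, length(sites))
  bed <- data.frame(
    as.character(GenomicRanges::seqnames(sites)),
    GenomicRanges::start(sites) - 1L,
    GenomicRanges::end(sites),
    name, score,
    as.character(GenomicRanges::strand(sites)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extend sites symmetrically, clipping at sequence bounds
#'
#' Each site is grown by `flank` nt on both ends and clipped to
#' `[0, length)` of its transcript; strand is preserved.
#'
#' @param sites A `GRanges`.
#' @param flank Extension in nt (>= 0).
#' @param seqlens Named vector of sequence lengths; taken from
#'   `seqlengths(sites)` when omitted.
#'
#' @return The extended `GRanges`.
#' @export
extend_sites <- function(sites, flank = 25L, seqlens = NULL) {
  flank <- check_count(flank, "flank", min = 0L)
  if (is.null(seqlens)) {
    seqlens <- GenomeInfoDb::seqlengths(sites)
  }
  sq <- as.character(GenomicRanges::seqnames(sites))
  if (any(is.na(seqlens[sq]))) {
    stop("sequence lengths unknown for some sites; supply `seqlens`",
         call. = FALSE)
  }
  new_start <- pmax(1L, GenomicRanges::start(sites) - flank)
  new_end <- pmin(as.integer(seqlens[sq]),
                  GenomicRanges::end(sites) + flank)
  out <- sites
  IRanges::ranges(out) <- IRanges::IRanges(start = new_start, end = new_end)
  out
}

region_bounds <- function(regions, region) {
  switch(region,
         all  = cbind(0L, regions$length),
         utr5 = cbind(0L, regions$utr5_end),
         cds  = cbind(regions$utr5_end, regions$cds_end),
         utr3 = cbind(regions$cds_end, regions$length),
         stop("unknown region '", region, "'", call. = FALSE))
}

#' Sample random background sites of fixed length
#'
#' Places `n` intervals of exactly `site_length` nt with start positions
#' uniform over the valid starts of the sampling space: starts inside the
#' requested region such that the interval fits in the transcript.
#' Reproducible under `seed`.
#'
#' @param regions Transcript table (`transcript_id`, `utr5_end`,
#'   `cds_end`, `length`).
#' @param n Number of background sites (default 10000).
#' @param site_length Site length in nt (use the rounded mean length of
#'   the observed, unextended sites).
#' @param seed Integer seed.
#' @param region One of `"all"`, `"utr5"`, `"cds"`, `"utr3"`: the
#'   region-stratified sampling space.
#'
#' @return A `GRanges` of background sites on the sense strand, with
#'   seqlengths set.
#' @export
sample_background <- function(regions, n = 10000L, site_length, seed = 1L,
                              region = "all") {
  n <- check_count(n, "n", min = 1L)
  site_length <- check_count(site_length, "site_length", min = 1L)
  b <- region_bounds(regions, region)
  # valid 0-based starts: [b1, min(b2, length - L + 1))
  lo <- b[, 1]
  hi <- pmin(b[, 2], regions$length - site_length + 1L)
  counts <- pmax(0L, hi - lo)
  if (sum(counts) == 0L) {
    stop(sprintf("site_length %d exceeds every sequence in the %s space",
                 site_length, region), call. = FALSE)
  }
  with_seed(seed, {
    tx_i <- sample.int(nrow(regions), n, replace = TRUE, prob = counts)
    off <- floor(stats::runif(n) * counts[tx_i])  # 0 .. counts-1
    start0 <- lo[tx_i] + off
    GenomicRanges::GRanges(
      seqnames = regions$transcript_id[tx_i],
      ranges = IRanges::IRanges(start = start0 + 1L, width = site_length),
      strand = "+",
      seqlengths = stats::setNames(regions$length, regions$transcript_id))
  })
}

#' Annotate sites with their transcript region
#'
#' Assigns each site to 5'UTR/CDS/3'UTR by its start position (the same
#' rule used for RG4 hits).
#'
#' @param sites A `GRanges` over transcripts.
#' @param regions Transcript table.
#' @return `sites` with a `region` metadata column.
#' @export
annotate_sites_region <- function(sites, regions) {
  i <- match(as.character(GenomicRanges::seqnames(sites)),
             regions$transcript_id)
  if (anyNA(i)) {
    stop("sites on transcripts absent from the region table",
         call. = FALSE)
  }
  start0 <- GenomicRanges::start(sites) - 1L
  S4Vectors::mcols(sites)$region <-
    region_of(start0, regions$utr5_end[i], regions$cds_end[i])
  sites
}
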