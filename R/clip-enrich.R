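#' Configuration for CLIP-site enrichment analysis
#'
#' @param flank Extension of sites on both ends before overlap (default
#'   25 nt).
#' @param n_background Number of random background sites (default 10000).
#' @param seed Integer seed for background sampling.
#' @param min_overlap Minimal shared nt counting as overlap (default 1).
#'
#' @return An object of class `enrich_config`.
#' @export
enrich_config <- function(flank = 25L, n_background = 10000L, seed = 1L,
                          min_overlap = 1L) {
  structure(list(flank = check_count(flank, "flank", min = 0L),
                 n_background = check_count(n_background, "n_background",
                                            min = 1L),
                 seed = as.integer(seed),
                 min_overlap = check_count(min_overlap, "min_overlap",
                                           min = 1L)),
            class = "enrich_config")
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact two-sided p as the sum of hypergeometric probabilities of all
#' tables (with the observed margins) at most as probable as the observed
#' one, using the standard relative tolerance `1 + 1e-7` at ties.
#'
#' @param a,b Observed sites with / without an RG4 (first row).
#' @param c,d Background sites with / without an RG4 (second row).
#'
#' @return The p-value in `(0, 1]`.
#' @examples
#' fisher_exact_p(30, 70, 10, 90)
#' @export
fisher_exact_p <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b
  n_ <- c + d
  k <- a + c
  support <- max(0L, k - n_):min(k, m)
  dens <- stats::dhyper(support, m, n_, k)
  obs <- dens[support == a]
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

catalog_granges <- function(catalog) {
  h <- catalog$hits
  GenomicRanges::GRanges(
    seqnames = h$transcript_id,
    ranges = IRanges::IRanges(start = h$start + 1L, end = h$end),
    strand = "+",
    region = h$region,
    score = h$score)
}

# same-strand overlap count, tolerant of disjoint seqlevel sets
overlaps_any <- function(query, subject, min_overlap = 1L) {
  if (length(query) == 0L || length(subject) == 0L) {
    return(logical(length(query)))
  }
  lev <- union(GenomeInfoDb::seqlevels(query),
               GenomeInfoDb::seqlevels(subject))
  GenomeInfoDb::seqlevels(query) <- lev
  GenomeInfoDb::seqlevels(subject) <- lev
  GenomicRanges::countOverlaps(query, subject,
                               minoverlap = min_overlap) > 0L
}

#' Fisher enrichment of RG4s in observed versus background sites
#'
#' Builds, per region present in the site annotations, the 2x2 table
#' `a` = observed sites overlapping an accepted RG4 by at least
#' `min_overlap` nt, `b` = the rest, and `c`, `d` likewise for background
#' sites; computes the two-sided Fisher exact p and the sample odds ratio
#' `(a*d)/(b*c)` (with the Haldane-Anscombe 0.5 correction when any cell
#' is zero, flagged in the output).
#'
#' @param obs_sites,bg_sites `GRanges` with a `region` metadata column
#'   (see [annotate_sites_region()]); pass region `"all"` sites for an
#'   unstratified contrast.
#' @param catalog An `rg4_catalog`.
#' @param config An [enrich_config()].
#'
#' @return A data.frame with one row per region: counts `a`-`d`,
#'   `odds_ratio`, `haldane`, `p_value`, `neg_log10_p`.
#' @export
fisher_enrichment <- function(obs_sites, bg_sites, catalog,
                              config = enrich_config()) {
  if (length(obs_sites) == 0L) {
    stop("empty observed site set", call. = FALSE)
  }
  hits <- catalog_granges(catalog)
  obs_region <- S4Vectors::mcols(obs_sites)$region
  bg_region <- S4Vectors::mcols(bg_sites)$region
  if (is.null(obs_region) || is.null(bg_region)) {
    stop("sites must carry a `region` metadata column", call. = FALSE)
  }
  obs_hit <- overlaps_any(obs_sites, hits, config$min_overlap)
  bg_hit <- overlaps_any(bg_sites, hits, config$min_overlap)
  out <- lapply(unique(obs_region), function(r) {
    oi <- obs_region == r
    bi <- bg_region == r
    a <- sum(obs_hit[oi]); b <- sum(!obs_hit[oi])
    cc <- sum(bg_hit[bi]); dd <- sum(!bg_hit[bi])
    haldane <- any(c(a, b, cc, dd) == 0L)
    or <- if (haldane) {
      ((a + 0.5) * (dd + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      (a * dd) / (b * cc)
    }
    p <- fisher_exact_p(a, b, cc, dd)
    data.frame(region = r, a = a, b = b, c = cc, d = dd,
               odds_ratio = or, haldane = haldane,
               p_value = p, neg_log10_p = -log10(p))
  })
  do.call(rbind, out)
}

#' RG4 density per Mb of a site set
#'
#' Number of accepted RG4s overlapping the site set divided by the total
#' merged site length, scaled to hits per Mb. Overlapping sites are
#' merged before the length computation so covered nt are not counted
#' twice.
#'
#' @param sites A `GRanges`.
#' @param catalog An `rg4_catalog`.
#' @param min_overlap Minimal shared nt (default 1).
#'
#' @return Density in RG4s per Mb.
#' @export
rg4_density <- function(sites, catalog, min_overlap = 1L) {
  merged <- GenomicRanges::reduce(sites)
  total_nt <- sum(as.numeric(IRanges::width(merged)))
  if (total_nt <= 0) stop("total site length must be > 0", call. = FALSE)
  hits <- catalog_granges(catalog)
  n <- sum(overlaps_any(hits, merged, min_overlap))
  n / total_nt * 1e6
}

#' Fraction of catalog RG4s bound by a site set, per region
#'
#' Per region, the fraction of accepted RG4s overlapped by at least
#' `min_overlap` nt of any (typically flank-extended) site.
#'
#' @param catalog An `rg4_catalog`.
#' @param sites A `GRanges` (extend first if desired).
#' @param min_overlap Minimal shared nt (default 1).
#'
#' @return data.frame with `region`, `n_rg4`, `n_bound`, `fraction_bound`
#'   (`NA` for regions with an empty catalog).
#' @export
fraction_rg4_bound <- function(catalog, sites, min_overlap = 1L) {
  hits <- catalog_granges(catalog)
  bound <- overlaps_any(hits, sites, min_overlap)
  region <- factor(S4Vectors::mcols(hits)$region, levels = REGIONS)
  n_rg4 <- as.integer(table(region))
  n_bound <- as.integer(tapply(bound, region, sum, default = 0L))
  data.frame(region = REGIONS, n_rg4 = n_rg4, n_bound = n_bound,
             fraction_bound = ifelse(n_rg4 > 0, n_bound / n_rg4, NA_real_))
}

#' Intersection of two target identifier sets
#'
#' @param ids_a,ids_b Character vectors of identifiers (deduplicated
#'   case-sensitively before intersecting).
#'
#' @return List with `shared` (sorted intersection), `n_a`, `n_b`,
#'   `n_shared`.
#' @examples
#' intersect_target_sets(c("x", "y", "z"), c("y", "z", "w"))
#' @export
intersect_target_sets <- function(ids_a, ids_b) {
  a <- unique(as.character(ids_a))
  b <- unique(as.character(ids_b))
  shared <- sort(intersect(a, b))
  list(shared = shared, n_a = length(a), n_b = length(b),
       n_shared = length(shared))
}

#' Full CLIP enrichment analysis against a random-site background
#'
#' Orchestrates the per-region enrichment pipeline: observed sites are
#' annotated to regions by their start position and extended by
#' `config$flank`; background sites are drawn region-stratified (plus an
#' unstratified `"all"` contrast) at the rounded mean length of the raw
#' observed sites and extended by the same flank, keeping observed and
#' background geometry comparable; Fisher tables, RG4 densities and
#' bound fractions are then computed.
#'
#' @param sites Raw (unextended) CLIP sites as a `GRanges`.
#' @param catalog An `rg4_catalog` from [predict_catalog()].
#' @param regions Transcript table.
#' @param config An [enrich_config()].
#' @param regions_use Contrasts to compute; any subset of
#'   `c("all", "utr5", "cds", "utr3")`.
#'
#' @return A list with `enrichment` (per-region Fisher results plus
#'   densities), `fraction_bound`, `mean_site_length`, and `config`.
#' @export
clip_enrichment <- function(sites, catalog, regions,
                            config = enrich_config(),
                            regions_use = c("all", REGIONS)) {
  if (length(sites) == 0L) stop("empty observed site set", call. = FALSE)
  seqlens <- stats::setNames(regions$length, regions$transcript_id)
  sites <- annotate_sites_region(sites, regions)
  mean_len <- max(1L, round(mean(IRanges::width(sites))))
  ext_obs <- extend_sites(sites, config$flank, seqlens)

  stopifnot(all(regions_use %in% c("all", REGIONS)))
  res <- lapply(seq_along(regions_use), function(ri) {
    r <- regions_use[ri]
    oi <- if (r == "all") rep(TRUE, length(sites)) else
      S4Vectors::mcols(sites)$region == r
    if (!any(oi)) return(NULL)
    bg <- sample_background(regions, config$n_background, mean_len,
                            seed = config$seed + ri - 1L, region = r)
    ext_bg <- extend_sites(bg, config$flank, seqlens)
    obs_r <- ext_obs[oi]
    S4Vectors::mcols(obs_r)$region <- r
    S4Vectors::mcols(ext_bg)$region <- r
    fe <- fisher_enrichment(obs_r, ext_bg, catalog, config)
    fe$density_obs <- rg4_density(obs_r, catalog, config$min_overlap)
    fe$density_bg <- rg4_density(ext_bg, catalog, config$min_overlap)
    fe
  })
  enrichment <- do.call(rbind, res)
  frac <- fraction_rg4_bound(catalog, ext_obs, config$min_overlap)
  list(enrichment = enrichment, fraction_bound = frac,
       mean_site_length = mean_len, config = config)
}
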