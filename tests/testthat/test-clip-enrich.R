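fake_catalog <- function(hits) {
  structure(list(hits = hits,
                 region_summary = NULL,
                 params = rg4_params(),
                 scorer = "surrogate_gscore_v1"),
            class = "rg4_catalog")
}

test_that("fisher_exact_p matches fisher.test and the choose() oracle", {
  expect_lt(abs(fisher_exact_p(30, 70, 10, 90) - fisher_oracle(30, 70, 10, 90)),
            1e-12)
  expect_lt(abs(fisher_exact_p(30, 70, 10, 90) -
                  fisher.test(matrix(c(30, 70, 10, 90), 2,
                                     byrow = TRUE))$p.value), 1e-10)
  # identical proportions: no association
  expect_equal(fisher_exact_p(20, 80, 20, 80), 1)

  set.seed(3)
  for (i in 1:200) {
    tab <- sample(0:40, 4, replace = TRUE)
    p1 <- fisher_exact_p(tab[1], tab[2], tab[3], tab[4])
    p2 <- fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    expect_lt(abs(p1 - p2), 1e-10)
  }
})

test_that("fisher_enrichment builds correct tables, ORs and Haldane flags", {
  hits <- data.frame(transcript_id = "tx", start = c(0L, 100L),
                     end = c(18L, 118L), g_run = 3L, l1 = 2L, l2 = 2L,
                     l3 = 2L, score = 26, region = "utr5")
  cat1 <- fake_catalog(hits)
  obs <- GenomicRanges::GRanges("tx", IRanges::IRanges(
    start = c(5L, 5L, 300L, 400L), width = 10L), strand = "+",
    region = "utr5")
  bg <- GenomicRanges::GRanges("tx", IRanges::IRanges(
    start = rep(300L, 10L), width = 10L), strand = "+", region = "utr5")
  fe <- fisher_enrichment(obs, bg, cat1, enrich_config())
  expect_equal(unlist(fe[c("a", "b", "c", "d")], use.names = FALSE),
               c(2L, 2L, 0L, 10L))
  expect_true(fe$haldane)
  expect_equal(fe$odds_ratio, (2.5 * 10.5) / (2.5 * 0.5))
  expect_equal(fe$p_value, fisher_oracle(2, 2, 0, 10), tolerance = 1e-12)

  # sample OR without zero cells
  bg2 <- GenomicRanges::GRanges("tx", IRanges::IRanges(
    start = c(5L, rep(300L, 9L)), width = 10L), strand = "+",
    region = "utr5")
  fe2 <- fisher_enrichment(obs, bg2, cat1, enrich_config())
  expect_false(fe2$haldane)
  expect_equal(fe2$odds_ratio, (2 * 9) / (2 * 1))

  expect_error(fisher_enrichment(obs[0], bg, cat1), "empty")
})

test_that("overlaps are strand-aware", {
  hits <- data.frame(transcript_id = "tx", start = 0L, end = 18L,
                     g_run = 3L, l1 = 2L, l2 = 2L, l3 = 2L, score = 26,
                     region = "utr5")
  cat1 <- fake_catalog(hits)
  minus <- GenomicRanges::GRanges("tx", IRanges::IRanges(5, 14),
                                  strand = "-", region = "utr5")
  plus <- GenomicRanges::GRanges("tx", IRanges::IRanges(5, 14),
                                 strand = "+", region = "utr5")
  fb_minus <- fraction_rg4_bound(cat1, minus)
  fb_plus <- fraction_rg4_bound(cat1, plus)
  expect_equal(fb_minus$fraction_bound[fb_minus$region == "utr5"], 0)
  expect_equal(fb_plus$fraction_bound[fb_plus$region == "utr5"], 1)
})

test_that("rg4_density follows its definition and scaling law", {
  # 50 RG4s over 2 Mb of (disjoint) sites -> 25 per Mb
  hits <- data.frame(transcript_id = "chr",
                     start = seq(0L, by = 40000L, length.out = 50L),
                     end = seq(0L, by = 40000L, length.out = 50L) + 18L,
                     g_run = 3L, l1 = 2L, l2 = 2L, l3 = 2L, score = 26,
                     region = "cds")
  cat1 <- fake_catalog(hits)
  sites <- GenomicRanges::GRanges("chr", IRanges::IRanges(
    start = seq(1L, by = 40000L, length.out = 50L), width = 40000L),
    strand = "+")
  expect_equal(rg4_density(sites, cat1), 25.0)

  # doubling covered length with unchanged count halves the density
  sites2 <- c(sites, GenomicRanges::shift(sites, 2000000L))
  expect_equal(rg4_density(sites2, cat1), 12.5)

  # overlapping sites are merged before the length computation
  expect_equal(rg4_density(c(sites, sites), cat1), 25.0)

  # no RG4s
  far <- GenomicRanges::GRanges("chr",
                                IRanges::IRanges(9000001, 10000000),
                                strand = "+")
  expect_equal(rg4_density(far, cat1), 0.0)
})

test_that("fraction_rg4_bound covers the boundary cases", {
  sim <- small_sim(seed = 8L, n_transcripts = 10L)
  cat1 <- predict_catalog(sim$sequences, sim$regions)
  # sites covering every transcript -> all fractions 1
  all_sites <- GenomicRanges::GRanges(
    sim$regions$transcript_id,
    IRanges::IRanges(1L, sim$regions$length), strand = "+")
  fb <- fraction_rg4_bound(cat1, all_sites)
  expect_true(all(fb$fraction_bound[fb$n_rg4 > 0] == 1))
  # disjoint sites -> 0
  none <- GenomicRanges::GRanges(sim$regions$transcript_id[1],
                                 IRanges::IRanges(1, 1), strand = "-")
  fb0 <- fraction_rg4_bound(cat1, none)
  expect_true(all(fb0$fraction_bound[fb0$n_rg4 > 0] == 0))
})

test_that("fraction bound is non-decreasing in the flank", {
  sim <- small_sim(seed = 19L, n_transcripts = 8L)
  cat1 <- predict_catalog(sim$sequences, sim$regions)
  seqlens <- stats::setNames(sim$regions$length,
                             sim$regions$transcript_id)
  set.seed(31)
  for (i in 1:20) {
    sites <- simulate_clip_sites(sim, sim_clip_config(
      n_sites = 60L, g4_enrichment_factor = sample(1:5, 1),
      seed = 500L + i))
    flanks <- c(0L, 10L, 25L, 60L)
    fr <- sapply(flanks, function(fl) {
      fb <- fraction_rg4_bound(cat1, extend_sites(sites, fl, seqlens))
      sum(fb$n_bound) / sum(fb$n_rg4)
    })
    expect_true(all(diff(fr) >= 0))
  }
})

test_that("target-set intersection reports sorted overlap and counts", {
  r <- intersect_target_sets(c("x", "y", "z"), c("y", "z", "w"))
  expect_equal(r$shared, c("y", "z"))
  expect_equal(c(r$n_a, r$n_b, r$n_shared), c(3L, 3L, 2L))

  expect_equal(intersect_target_sets("a", "b")$n_shared, 0L)
  sub <- intersect_target_sets(c("a", "b"), c("a", "b", "c"))
  expect_equal(sub$shared, c("a", "b"))
  # case-sensitive deduplication
  r <- intersect_target_sets(c("A", "a", "a"), c("a"))
  expect_equal(c(r$n_a, r$n_shared), c(2L, 1L))
})

test_that("the full enrichment pipeline detects planted enrichment", {
  sim <- small_sim(seed = 23L, n_transcripts = 15L)
  cat1 <- predict_catalog(sim$sequences, sim$regions)
  sites <- simulate_clip_sites(sim, sim_clip_config(
    n_sites = 300L, g4_enrichment_factor = 8, seed = 7L))
  enr <- clip_enrichment(sites, cat1, sim$regions,
                         enrich_config(n_background = 2000L, seed = 5L))
  all_row <- enr$enrichment[enr$enrichment$region == "all", ]
  expect_lt(all_row$p_value, 1e-6)
  expect_gt(all_row$odds_ratio, 1)
  expect_gt(all_row$density_obs, all_row$density_bg)
  expect_equal(all_row$a + all_row$b, length(sites))
  expect_equal(all_row$c + all_row$d, 2000L)
  expect_true(all(c("all", "utr5", "cds", "utr3") %in%
                    enr$enrichment$region))
})
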