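uniform_cm <- function(n = 60, binsize = 4e4, value = 5) {
  g <- genome_model(stats::setNames(n * binsize, "c1"))
  pairs <- expand.grid(b1 = 0:(n - 1), b2 = 0:(n - 1))
  pairs <- pairs[pairs$b1 <= pairs$b2, ]
  rec <- data.frame(chrom1 = "c1", pos1 = pairs$b1 * binsize + 1,
                    chrom2 = "c1", pos2 = pairs$b2 * binsize + 1,
                    count = value)
  bin_contacts(rec, g, binsize)
}

test_that("a uniform matrix has zero insulation and no boundaries", {
  cm <- uniform_cm()
  tr <- insulation_track(cm, "c1", window = 4e5, delta_span = 1.6e5,
                         balanced = FALSE)
  expect_true(all(abs(stats::na.omit(tr$ins)) < 1e-12))
  expect_equal(nrow(boundaries(tr)), 0)
  # 1-Mb window at 40-kb bins spans 25 bins
  expect_equal(as.integer(1e6 / 4e4), 25)
})

test_that("two disconnected blocks yield exactly one boundary at the junction", {
  n <- 60; bs <- 4e4
  g <- genome_model(c(c1 = n * bs))
  pairs <- expand.grid(b1 = 0:(n - 1), b2 = 0:(n - 1))
  pairs <- pairs[pairs$b1 <= pairs$b2, ]
  same_block <- (pairs$b1 < 30) == (pairs$b2 < 30)
  pairs <- pairs[same_block, ]
  rec <- data.frame(chrom1 = "c1", pos1 = pairs$b1 * bs + 1,
                    chrom2 = "c1", pos2 = pairs$b2 * bs + 1, count = 10)
  cm <- bin_contacts(rec, g, bs)
  tr <- insulation_track(cm, "c1", window = 4e5, delta_span = 2e5,
                         balanced = FALSE)
  b <- boundaries(tr)
  expect_equal(nrow(b), 1)
  expect_lte(abs(b$bin - 29), 1)
})

test_that("planted TAD boundaries are recovered within one bin on a 50-Mb chromosome", {
  tf <- fx_tads()
  b <- boundaries(tf$track)
  true_bins <- floor(tf$edges / 4e4)
  hit <- vapply(true_bins, function(tb) any(abs(b$bin - tb) <= 1), logical(1))
  expect_gte(mean(hit), 0.9)
  false_calls <- sum(vapply(b$bin, function(x) min(abs(x - true_bins)) > 1,
                            logical(1)))
  expect_lte(false_calls, 2)
})

test_that("called boundaries translate with the planted structure", {
  g <- genome_model(c(c1 = 2e7))
  bs <- 4e4
  mk <- function(shift_bins) {
    edges <- seq(4e6, 16e6, by = 2e6) + shift_bins * bs
    b <- boundaries(insulation_track(bin_contacts(simulate_contact_map(
      g, structure_spec(tads = data.frame(chrom = "c1",
                                          start = head(edges, -1),
                                          end = edges[-1], enrich = 3)),
      2e6, seed = 77, binsize = bs), g, bs), "c1", balanced = FALSE))
    list(bins = b$bin, edges = floor(edges / bs))
  }
  b0 <- mk(0); b3 <- mk(3)
  # interior boundaries (terminal structured/unstructured transitions are
  # broader minima and not part of the translation property)
  int0 <- b0$edges[2:6]; int3 <- b3$edges[2:6]
  expect_true(all(vapply(int0, function(e) any(abs(b0$bins - e) <= 1),
                         logical(1))))
  expect_true(all(vapply(int3, function(e) any(abs(b3$bins - e) <= 1),
                         logical(1))))
})

test_that("differential boundaries require both FDR and the quantile gate", {
  bf <- fx_diffbound()
  conds <- list(
    control = boundaries(insulation_track(
      pool_matrices(bf$cms[names(bf$grp)[bf$grp == "control"]]), "chr1",
      balanced = FALSE)),
    case = boundaries(insulation_track(
      pool_matrices(bf$cms[names(bf$grp)[bf$grp == "case"]]), "chr1",
      balanced = FALSE)))
  merged <- merge_boundaries(conds)
  tracks <- lapply(bf$cms, function(cm) insulation_track(cm, "chr1",
                                                         balanced = FALSE))
  db <- differential_boundaries(tracks, bf$grp, merged)
  is_new <- vapply(merged$bin, function(b) min(abs(b - bf$new_bins)) <= 1,
                   logical(1))
  expect_gte(sum(db$flagged & is_new), 8)
  expect_lte(sum(db$flagged & !is_new), 1)
  # identical group values can never be flagged
  const_tracks <- tracks
  db2 <- differential_boundaries(tracks[c(1, 2, 1, 2)] |>
                                   stats::setNames(c("a1", "a2", "b1", "b2")),
                                 c(a1 = "g1", a2 = "g1", b1 = "g2", b2 = "g2"),
                                 merged)
  expect_false(any(db2$flagged))
  # an effect below the difference quantile is not flagged even at tiny FDR
  cut <- stats::quantile(abs(db$diff), 0.5, na.rm = TRUE)
  expect_false(any(db$flagged & abs(db$diff) <= cut))
  expect_error(differential_boundaries(tracks[c("ctrl1", "ctrl2", "case1")],
                                       bf$grp[c("ctrl1", "ctrl2", "case1")],
                                       merged),
               ">= 2 samples")
})

test_that("the domain score matches its hand-computed oracle and invariances", {
  g <- genome_model(c(c1 = 1.6e5))
  rec <- data.frame(chrom1 = "c1",
                    pos1 = c(1, 1, 4e4 + 1, 1, 4e4 + 1),
                    chrom2 = "c1",
                    pos2 = c(1, 4e4 + 1, 4e4 + 1, 8e4 + 1, 1.2e5 + 1),
                    count = c(5, 10, 5, 2, 3))
  cm <- bin_contacts(rec, g, 4e4)
  tad <- data.frame(chrom = "c1", start_bin = 0, end_bin = 1)
  expect_equal(domain_score(cm, tad), 0.8)     # 20 / 25 exactly
  # global scaling leaves the score unchanged
  cm2 <- cm; cm2$mats$c1 <- cm$mats$c1 * 3.7
  expect_equal(domain_score(cm2, tad), 0.8)
  # a TAD contacting only itself scores 1
  rec1 <- rec[1:3, ]
  expect_equal(domain_score(bin_contacts(rec1, g, 4e4), tad), 1.0)
  expect_error(domain_score(cm, data.frame(chrom = "c1", start_bin = 0,
                                           end_bin = 9)), "bounds")
})

test_that("domain scores are bounded and monotone in planted enrichment", {
  g <- genome_model(c(c1 = 2e7))
  bs <- 4e4
  scores <- sapply(c(1, 2, 4), function(e) {
    tads <- data.frame(chrom = "c1", start = 8e6, end = 1.2e7, enrich = e)
    sp <- if (e == 1) structure_spec() else structure_spec(tads = tads)
    cm <- bin_contacts(simulate_contact_map(g, sp, 2e6, seed = 50 + e,
                                            binsize = bs), g, bs)
    domain_score(cm, data.frame(chrom = "c1", start_bin = 8e6 / bs,
                                end_bin = 1.2e7 / bs - 1))
  })
  expect_true(all(scores > 0 & scores <= 1))
  expect_true(all(diff(scores) > 0))
})

test_that("differential D-scores flag planted changes and respect both gates", {
  df <- fx_dscore()
  sc <- domain_score_table(df$cms, df$tads)
  ds <- differential_domain_scores(sc, df$grp)
  expect_gte(sum(ds$flagged[df$changed]), 4)
  expect_true(all(ds$direction[df$changed][ds$flagged[df$changed]] ==
                    "increased"))
  expect_equal(sum(ds$flagged[-df$changed]), 0)
  # constant scores are never flagged
  sc2 <- sc; sc2[1, ] <- 0.5
  ds2 <- differential_domain_scores(sc2, df$grp)
  expect_false(ds2$flagged[1])
  # fold change below the 70% quantile cannot be flagged
  cut <- stats::quantile(abs(ds$log2fc), 0.7, na.rm = TRUE)
  expect_false(any(ds$flagged & abs(ds$log2fc) <= cut))
})

test_that("consensus TADs require two conditions and a minimal size", {
  bsets <- list(c1 = data.frame(bin = c(10, 30, 50), strength = 1),
                c2 = data.frame(bin = c(10, 31, 70), strength = 0.8),
                c3 = data.frame(bin = c(50, 70), strength = 0.5))
  tads <- consensus_tads(bsets, "chr1", min_conditions = 2)
  # boundaries at 10, 30/31 (merged), 50, 70 all supported by >= 2 conditions
  expect_equal(nrow(tads), 3)
  expect_true(all(tads$end_bin > tads$start_bin))
  # interior-bin convention: adjacent TADs are disjoint
  expect_true(all(tads$start_bin[-1] > tads$end_bin[-nrow(tads)]))
  # a 2-bin TAD is discarded
  b2 <- list(a = data.frame(bin = c(10, 13), strength = 1),
             b = data.frame(bin = c(10, 13), strength = 1))
  expect_equal(nrow(consensus_tads(b2, "chr1")), 0)
})
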