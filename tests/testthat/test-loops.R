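test_that("a pure decay map yields at most one false loop call", {
  lf <- fx_loops()
  calls0 <- call_loops(lf$cm0, fdr = 0.1)
  expect_lte(nrow(calls0), 1)
})

test_that("planted 5x peaks are recovered with high recall and precision", {
  lf <- fx_loops()
  calls <- lf$calls
  hit <- mapply(function(b1, b2)
    any(abs(calls$bin1 - b1) <= 1 & abs(calls$bin2 - b2) <= 1),
    lf$bins1, lf$bins2)
  prec <- mapply(function(b1, b2)
    any(abs(lf$bins1 - b1) <= 1 & abs(lf$bins2 - b2) <= 1),
    calls$bin1, calls$bin2)
  expect_gte(mean(hit), 0.8)
  expect_gte(mean(prec), 0.8)
})

test_that("a single strong planted peak produces one call containing its bin pair", {
  g <- genome_model(c(c1 = 8e6))
  bs <- 1e4
  loop <- data.frame(chrom = "c1", pos1 = 3.005e6, pos2 = 3.305e6, enrich = 5)
  rec <- simulate_contact_map(g, structure_spec(loops = loop), 5e6, seed = 44,
                              binsize = bs)
  calls <- call_loops(bin_contacts(rec, g, bs), fdr = 0.1)
  expect_equal(nrow(calls), 1)
  expect_lte(abs(calls$bin1 - 300), 1)
  expect_lte(abs(calls$bin2 - 330), 1)
})

test_that("calls within the merge distance collapse to one", {
  g <- genome_model(c(c1 = 6e6))
  bs <- 5e3
  # two peaks 15 kb apart (3 bins) at 5-kb resolution, merge distance 15 kb
  loops <- data.frame(chrom = "c1", pos1 = c(2.0025e6, 2.0175e6),
                      pos2 = c(2.5025e6, 2.5175e6), enrich = 8)
  rec <- simulate_contact_map(g, structure_spec(loops = loops), 8e6, seed = 45,
                              binsize = bs)
  cm <- bin_contacts(rec, g, bs)
  calls <- call_loops(cm, fdr = 0.1,
                      merge_distances = c("5000" = 15000))
  expect_equal(nrow(calls), 1)
})

test_that("loop calls are invariant under global scaling of the matrix", {
  lf <- fx_loops()
  cm2 <- lf$cm
  cm2$mats <- lapply(cm2$mats, function(m) m * 2)   # integer counts remain
  cm2$cis_total <- cm2$cis_total * 2
  calls2 <- call_loops(cm2, fdr = 0.1)
  key <- function(x) paste(x$chrom, x$bin1, x$bin2)
  # monotone in depth: every original call survives doubling
  expect_true(all(key(lf$calls) %in% key(calls2)))
  # rank stability: the planted peaks stay the top-ranked calls (deterministic
  # doubling halves relative dispersion, so the Poisson tail beyond them
  # sharpens; their dominance is the scale-invariant property)
  top <- calls2[order(calls2$q, -calls2$obs), ][seq_along(lf$bins1), ]
  hit2 <- mapply(function(b1, b2)
    any(abs(top$bin1 - b1) <= 1 & abs(top$bin2 - b2) <= 1),
    lf$bins1, lf$bins2)
  expect_gte(mean(hit2), 0.8)
})

test_that("APA is enriched on planted loops, flat on random anchors, and count-normalized", {
  lf <- fx_loops()
  planted <- data.frame(chrom = "chr1", bin1 = lf$bins1, bin2 = lf$bins2)
  ap <- apa(lf$cm, planted)
  expect_gte(ap$center_score, 1.5)
  set.seed(9)
  rnd <- data.frame(chrom = "chr1", bin1 = sample(300:1000, 20))
  rnd$bin2 <- rnd$bin1 + sample(40:150, 20)
  ap0 <- apa(lf$cm, rnd)
  expect_lt(abs(ap0$center_score - 1), 0.2)
  # duplicating the loop list changes nothing (normalized by loop count)
  ap2 <- apa(lf$cm, rbind(planted, planted))
  expect_equal(ap2$matrix, ap$matrix)
  # near-diagonal loops are excluded; all-near-diagonal input is degenerate
  near <- data.frame(chrom = "chr1", bin1 = 500:504, bin2 = 505:509)
  expect_error(apa(lf$cm, near, flank = 10), "degenerate")
})

test_that("differential loops recover planted 2x enhancements with strata and direction", {
  dl <- fx_diffloops()
  res <- differential_loops(dl$union, dl$cms, dl$grp)
  expect_gte(sum(res$flagged[dl$idx_up] &
                   res$direction[dl$idx_up] == "enhanced"), 15)
  expect_lte(sum(res$flagged[-dl$idx_up]), 2)
  # stratum assignment by anchor midpoint separation around the 150-kb split
  mk <- dl$union[1:2, ]
  mk$bin2 <- mk$bin1 + c(10, 20)                 # 100 kb and 200 kb
  mk$start2 <- mk$bin2 * dl$binsize; mk$end2 <- mk$start2 + dl$binsize
  res2 <- differential_loops(mk, dl$cms, dl$grp)
  expect_equal(res2$stratum, c("short", "long"))
})

test_that("label-permuted null cohorts stay within the nominal FDR budget", {
  dl <- fx_diffloops()
  fr <- sapply(1:5, function(r) {
    set.seed(r)
    gp <- stats::setNames(sample(rep(c("control", "case"), each = 4)),
                          names(dl$cms0))
    mean(differential_loops(dl$union, dl$cms0, gp)$flagged)
  })
  expect_lte(stats::median(fr), 0.15)
})

test_that("CTCF orientation classes match a brute-force oracle over all configurations", {
  bs <- 1e4
  strands <- c("+", "-", NA)
  grid <- expand.grid(s1 = strands, s2 = strands, stringsAsFactors = FALSE)
  loops <- data.frame(chrom = "c1",
                      start1 = (seq_len(nrow(grid)) - 1) * 1e6,
                      start2 = (seq_len(nrow(grid)) - 1) * 1e6 + 5e5)
  loops$end1 <- loops$start1 + bs
  loops$end2 <- loops$start2 + bs
  motifs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    rbind(
      if (!is.na(grid$s1[k]))
        data.frame(chrom = "c1", pos = loops$start1[k] + 100,
                   strand = grid$s1[k], score = 5),
      if (!is.na(grid$s2[k]))
        data.frame(chrom = "c1", pos = loops$start2[k] + 100,
                   strand = grid$s2[k], score = 5))
  }))
  got <- classify_ctcf_orientation(loops, motifs)$classes$class
  oracle <- apply(grid, 1, function(r) {
    if (is.na(r[1]) && is.na(r[2])) return("none")
    if (is.na(r[1]) || is.na(r[2])) return("single-anchor")
    if (r[1] == "+" && r[2] == "-") return("convergent")
    if (r[1] == "-" && r[2] == "+") return("divergent")
    "tandem"
  })
  expect_equal(got, unname(oracle))
  # inverted-fragment case: a tandem pair becomes convergent after the
  # downstream anchor's strand is flipped back to native orientation
  lp <- loops[1, ]
  mt <- data.frame(chrom = "c1", pos = c(lp$start1 + 100, lp$start2 + 100),
                   strand = c("+", "+"), score = 5)
  expect_equal(classify_ctcf_orientation(lp, mt)$classes$class, "tandem")
  lp$flip1 <- FALSE; lp$flip2 <- TRUE
  expect_equal(classify_ctcf_orientation(lp, mt)$classes$class, "convergent")
  # the highest-scoring motif wins at an anchor
  mt2 <- rbind(mt, data.frame(chrom = "c1", pos = lp$start2 + 200,
                              strand = "-", score = 50))
  lp$flip2 <- FALSE
  expect_equal(classify_ctcf_orientation(lp, mt2)$classes$class, "convergent")
  expect_error(classify_ctcf_orientation(lp, data.frame(chrom = "c1",
                                                        pos = 1, strand = "x")),
               "strand")
})
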