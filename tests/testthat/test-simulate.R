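test_that("contact-map simulation is seeded-deterministic and depth-calibrated", {
  g <- genome_model(c(chr1 = 4e6))
  sp <- structure_spec()
  r1 <- simulate_contact_map(g, sp, cis_depth = 2e5, seed = 3, binsize = 2e4)
  r2 <- simulate_contact_map(g, sp, cis_depth = 2e5, seed = 3, binsize = 2e4)
  expect_identical(r1, r2)
  r3 <- simulate_contact_map(g, sp, cis_depth = 2e5, seed = 4, binsize = 2e4)
  expect_false(identical(r1, r3))
  # total cis count within Poisson fluctuation of the target depth
  expect_lt(abs(sum(r1$count) - 2e5), 5 * sqrt(2e5))
  # canonical orientation: pos1 <= pos2 within a chromosome
  expect_true(all(r1$pos1 <= r1$pos2))
})

test_that("distance decay of a structureless map fits the planted exponent", {
  d <- fx_decay()
  prof <- expected_by_distance(d$cm, "chr1", balanced = FALSE)
  rng <- 10:200
  fit <- stats::lm(log(prof$mean[rng + 1]) ~ log(rng + 1))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1), 0.1)
})

test_that("a planted TAD doubles intra-TAD contacts relative to same-distance flanks", {
  g <- genome_model(c(chr1 = 2e7))
  bs <- 2e4
  tad <- data.frame(chrom = "chr1", start = 8e6, end = 1e7, enrich = 2)
  rec <- simulate_contact_map(g, structure_spec(tads = tad), cis_depth = 4e6,
                              seed = 9, binsize = bs)
  cm <- bin_contacts(rec, g, bs)
  M <- as.matrix(cis_matrix(cm, "chr1"))
  b1 <- 8e6 / bs; b2 <- 1e7 / bs - 1
  ratio <- sapply(5:40, function(d) {
    i <- (b1 + 1):(b2 + 1 - d)
    intra <- mean(M[cbind(i, i + d)])
    io <- setdiff(seq_len(nrow(M) - d), b1:(b2 + 1))  # rows outside the TAD
    io <- io[io + d <= b1 | io > b2 + 1]              # both anchors outside
    intra / mean(M[cbind(io, io + d)])
  })
  expect_lt(abs(mean(ratio) - 2), 0.2)
})

test_that("rearrangement planting honours the clonal-fraction null and read contract", {
  s <- fx_sv()
  g <- s$genome
  rec <- simulate_contact_map(g, structure_spec(), cis_depth = 1e5, seed = 31,
                              binsize = 1e4)
  null_spec <- rearrangement_spec("translocation", "chr1", 5e6, "left",
                                  "chr2", 6e6, "right", fraction = 0,
                                  n_chimeric = 6, n_decoy = 5)
  pl0 <- plant_rearrangement(rec, g, null_spec, seed = 32)
  expect_identical(pl0$contacts$count, rec$count)
  expect_equal(sum(pl0$reads$linker == 0), 0)
  expect_equal(sum(pl0$reads$linker == 1), 5)
  # requested junction reads are emitted exactly at the breakpoints
  pl <- s$planted
  junc <- pl$reads[pl$reads$linker == 0, ]
  expect_equal(nrow(junc), 6)
  expect_true(all(junc$pos1 == s$rspec$bpA & junc$pos2 == s$rspec$bpB))
})

test_that("a clonal junction enriches near-junction trans contacts over distant blocks", {
  s <- fx_sv()
  Tm <- trans_matrix(s$cm, "chr1", "chr2")
  bs <- 1e4
  bA <- floor((s$rspec$bpA - 1) / bs); bB <- floor((s$rspec$bpB - 1) / bs)
  w <- 10  # 100 kb
  near <- sum(Tm[(bA - w):(bA + 1) + 1, (bB + 1):(bB + w) + 1])
  far <- sum(Tm[(bA - w):(bA + 1) + 1 - 300, (bB + 1):(bB + w) + 1 + 150])
  expect_gte(near / max(far, 1), 5)
})

test_that("inversion specs require a single chromosome and translocations two", {
  expect_error(rearrangement_spec("inversion", "chr1", 1e6, "left",
                                  "chr2", 2e6, "right"),
               "one chromosome")
  expect_error(rearrangement_spec("translocation", "chr1", 1e6, "left",
                                  "chr1", 2e6, "right"),
               "different chromosomes")
  expect_error(rearrangement_spec("translocation", "chr1", 1e6, "left",
                                  "chr2", 2e6, "right", fraction = 1.2),
               "clonal fraction")
  # neo-loop anchors must sit on the fused flanks
  expect_error(rearrangement_spec(
    "translocation", "chr1", 1e6, "left", "chr2", 2e6, "right",
    neo_loops = data.frame(posA = 1.5e6, posB = 2.5e6, enrich = 4)),
    "fused flanks")
})

test_that("expression simulation recovers planted fold changes and is seeded", {
  g <- genome_model(c(chr1 = 1e7),
                    genes = data.frame(gene = sprintf("g%04d", 1:1000),
                                       chrom = "chr1",
                                       start = round(seq(1e3, 9.5e6,
                                                         length.out = 1000)),
                                       end = round(seq(1e3, 9.5e6,
                                                       length.out = 1000)) + 5e3,
                                       strand = "+"))
  ex0 <- simulate_expression(g, numeric(0), n_per_group = 10,
                             dispersion = 0.1, seed = 2)
  de0 <- de_table(ex0)
  expect_lt(abs(mean(de0$logFC)), 0.05)
  coupled <- stats::setNames(rep(1, 20), sprintf("g%04d", seq(10, 200, by = 10)))
  ex1 <- simulate_expression(g, coupled, n_per_group = 10, dispersion = 0.1,
                             seed = 2)
  de1 <- de_table(ex1)
  est <- de1$logFC[match(names(coupled), de1$gene)]
  expect_lt(abs(mean(est) - 1), 0.3)
  ex2 <- simulate_expression(g, coupled, n_per_group = 10, dispersion = 0.1,
                             seed = 2)
  expect_identical(ex1$counts, ex2$counts)
  expect_error(simulate_expression(g, coupled, 10, dispersion = 0, seed = 1),
               "dispersion")
})

test_that("cohort truth is config-driven and invariant to the sampling seed", {
  cfg <- demo_cohort_config(n_per_group = 2)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  s1 <- simulate_cohort(cfg, seed = 1, out_dir = d1)
  s2 <- simulate_cohort(cfg, seed = 2, out_dir = d2)
  expect_identical(s1$truth, s2$truth)
  r1 <- read_pairs(s1$samples$pairs[1])
  r2 <- read_pairs(s2$samples$pairs[1])
  expect_false(identical(r1$count, r2$count))
  # planted differential sets reflect the config exactly
  expect_equal(nrow(s1$truth$compartment_flips), 2)
  expect_equal(nrow(s1$truth$loop_gains), 2)
  # a no-difference config lists empty differential sets
  cfg0 <- cfg
  cfg0$specs$case <- cfg0$specs$control
  cfg0$events <- NULL
  s0 <- simulate_cohort(cfg0, seed = 1, out_dir = file.path(tempdir(), "coh0"))
  expect_equal(length(s0$truth$differential_boundaries), 0)
  expect_equal(nrow(s0$truth$compartment_flips), 0)
  expect_equal(nrow(s0$truth$loop_gains), 0)
})
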