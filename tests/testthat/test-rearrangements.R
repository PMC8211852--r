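test_that("block detection finds the planted event, none on null maps", {
  s <- fx_sv()
  expect_equal(nrow(s$blocks), 1)
  expect_false(s$blocks$control_present)
  # the refined 100-kb block brackets both true breakpoints
  expect_true(s$blocks$startA <= s$rspec$bpA && s$blocks$endA >= s$rspec$bpA)
  expect_true(s$blocks$startB <= s$rspec$bpB && s$blocks$endB >= s$rspec$bpB)
  # a null sample yields no candidates
  null_blocks <- detect_interchrom_blocks(s$cmC, list())
  expect_equal(nrow(null_blocks), 0)
})

test_that("events present in controls are flagged control-present and filtered", {
  s <- fx_sv()
  g <- s$genome
  recC <- simulate_contact_map(g, structure_spec(), cis_depth = 2e6,
                               seed = 21, binsize = 1e4)
  plC <- plant_rearrangement(recC, g, s$rspec, seed = 22)
  cmC <- bin_contacts(plC$contacts, g, 1e4)
  blocks <- detect_interchrom_blocks(s$cm, list(cmC))
  expect_equal(nrow(blocks), 1)
  expect_true(blocks$control_present)
})

test_that("breakpoint refinement follows the modal, strict more-than-three rule", {
  s <- fx_sv()
  ev <- s$events
  expect_true(ev$refined)
  expect_equal(ev$bpA, s$rspec$bpA)      # exact single-bp coordinates
  expect_equal(ev$bpB, s$rspec$bpB)
  expect_equal(ev$sideA, "left")
  expect_equal(ev$sideB, "right")
  expect_equal(ev$support, 6L)
  mkreads <- function(n, linker = 0L)
    data.frame(read_id = sprintf("r%d", seq_len(n)),
               chrom1 = "chr1", pos1 = s$rspec$bpA, strand1 = "+",
               chrom2 = "chr2", pos2 = s$rspec$bpB, strand2 = "+",
               linker = linker)
  # exactly 3 supporting reads: NOT refined ("more than three" is strict)
  ev3 <- refine_breakpoints(s$blocks, mkreads(3), s$genome)
  expect_false(ev3$refined)
  expect_equal(ev3$support, 3L)
  ev4 <- refine_breakpoints(s$blocks, mkreads(4), s$genome)
  expect_true(ev4$refined)
  # linker-positive reads are religation products and are discarded
  ev_l <- refine_breakpoints(s$blocks, mkreads(5, linker = 1L), s$genome)
  expect_false(ev_l$refined)
  expect_equal(ev_l$support, 0L)
  expect_error(refine_breakpoints(s$blocks, {
    r <- mkreads(4); r$chrom1 <- "chrX"; r
  }, s$genome), "unknown")
})

test_that("the reassembly transform is a bijection on covered intervals", {
  s <- fx_sv()
  rmap <- reassemble_matrix(s$cm, s$events)
  set.seed(1)
  pos <- sample.int(1.2e7, 100)
  rp <- map_to_reassembled(rmap, rep("chr1", 100), pos)
  covered <- !is.na(rp)
  expect_gt(sum(covered), 0)
  nat <- map_to_native(rmap, rp[covered])
  expect_equal(nat$pos, pos[covered])
  expect_true(all(nat$chrom == "chr1"))
  pos2 <- sample.int(1.2e7, 100)
  rp2 <- map_to_reassembled(rmap, rep("chr2", 100), pos2)
  nat2 <- map_to_native(rmap, rp2[!is.na(rp2)])
  expect_equal(nat2$pos, pos2[!is.na(rp2)])
})

test_that("the reassembled junction shows contiguous decay only for the true configuration", {
  s <- fx_sv()
  true_cont <- junction_continuity(reassemble_matrix(s$cm, s$events))
  expect_gt(true_cont, 0.8)
  sides <- expand.grid(a = c("left", "right"), b = c("left", "right"),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(sides))) {
    if (sides$a[k] == "left" && sides$b[k] == "right") next
    ev <- s$events
    ev$sideA <- sides$a[k]; ev$sideB <- sides$b[k]
    ev$inverted <- (ev$sideA == "right") || (ev$sideB == "left")
    expect_lt(junction_continuity(reassemble_matrix(s$cm, ev)), true_cont)
  }
})

test_that("inversion-type reassembly mirrors the reversed fragment (oracle check)", {
  g <- genome_model(c(chr1 = 8e6))
  bs <- 1e4
  rec <- simulate_contact_map(g, structure_spec(), cis_depth = 1.5e6,
                              seed = 61, binsize = bs)
  rsp <- rearrangement_spec("inversion", "chr1", 2.4e6, "left",
                            "chr1", 6.2e6, "left", fraction = 1,
                            n_chimeric = 5, n_decoy = 0)
  pl <- plant_rearrangement(rec, g, rsp, seed = 62)
  cm <- bin_contacts(pl$contacts, g, bs)
  ev <- data.frame(chromA = "chr1", bpA = 2.4e6, sideA = "left",
                   chromB = "chr1", bpB = 6.2e6, sideB = "left",
                   inverted = TRUE, support = 5L, refined = TRUE,
                   control_present = FALSE)
  rmap <- reassemble_matrix(cm, ev, flank = 1e6)
  fA <- rmap$fragments[1, ]; fB <- rmap$fragments[2, ]
  expect_false(fA$reversed)
  expect_true(fB$reversed)
  M <- as.matrix(cis_matrix(cm, "chr1"))
  R <- rmap$matrix
  # oracle: independent index arithmetic for 50 random native contacts
  set.seed(2)
  for (k in 1:50) {
    a <- sample(fA$start_bin:fA$end_bin, 1)
    b <- sample(fB$start_bin:fB$end_bin, 1)
    ra <- a - fA$start_bin + 1                      # forward fragment
    rb <- rmap$junction_bin + (fB$end_bin - b) + 1  # mirrored fragment
    expect_equal(R[ra, rb], M[a + 1, b + 1])
  }
  # anti-monotone: larger native position maps earlier in the fragment
  rp <- map_to_reassembled(rmap, rep("chr1", 2),
                           c(fB$start_bin * bs + 5, fB$end_bin * bs + 5))
  expect_gt(rp[1], rp[2])
})

test_that("planted neo-loops are recovered at native coordinates with control filtering", {
  s <- fx_sv()
  rmap <- reassemble_matrix(s$cm, s$events)
  cmap <- reassemble_matrix(s$cmC, s$events)
  nl <- detect_neo_loops(rmap, cmap)
  expect_equal(nrow(nl), 1)
  bs <- 1e4
  planted <- s$rspec$neo_loops
  expect_lte(abs(floor((nl$pos1 - 1) / bs) - floor((planted$posA - 1) / bs)), 1)
  expect_lte(abs(floor((nl$pos2 - 1) / bs) - floor((planted$posB - 1) / bs)), 1)
  expect_true(all(nl$spans_junction))
  # the control average was zero there, so the comparison is flagged skipped
  expect_true(nl$control_zero || nl$control_fold >= 2)
  # an event without planted neo-loops yields no calls
  g <- s$genome
  rec2 <- simulate_contact_map(g, structure_spec(), cis_depth = 2e6,
                               seed = 71, binsize = 1e4)
  rsp2 <- rearrangement_spec("translocation", "chr1", 5123456, "left",
                             "chr2", 7654321, "right", fraction = 1,
                             n_chimeric = 6, n_decoy = 0)
  pl2 <- plant_rearrangement(rec2, g, rsp2, seed = 72)
  cm2 <- bin_contacts(pl2$contacts, g, 1e4)
  nl2 <- detect_neo_loops(reassemble_matrix(cm2, s$events),
                          reassemble_matrix(s$cmC, s$events))
  expect_equal(nrow(nl2), 0)
  # overlap flags: planted anchors marked when pre-existing anchors coincide
  pre <- data.frame(chrom = "chr1", start1 = planted$posA - 5e3,
                    end1 = planted$posA + 5e3,
                    start2 = planted$posA + 1e5, end2 = planted$posA + 1.1e5)
  nl3 <- detect_neo_loops(rmap, cmap, preexisting = pre,
                          motifs = data.frame(chrom = "chr2",
                                              pos = planted$posB,
                                              strand = "+"))
  expect_true(nl3$at_preexisting_anchor)
  expect_true(nl3$at_ctcf)
})

test_that("event annotation applies the novelty, location and expression rules", {
  genes <- data.frame(gene = c("gA", "gB", "gC"),
                      chrom = c("chr1", "chr1", "chr2"),
                      start = c(4.9e6, 6e6, 7.4e6),
                      end = c(5.2e6, 6.1e6, 7.5e6), strand = "+")
  g <- genome_model(c(chr1 = 1.2e7, chr2 = 1.2e7), genes = genes)
  ev <- data.frame(chromA = "chr1", bpA = 5.1e6, sideA = "left",
                   chromB = "chr2", bpB = 7.54e6, sideB = "right",
                   inverted = FALSE, support = 6L, refined = TRUE,
                   control_present = FALSE)
  fpkm <- matrix(c(3, 1, 1, 1, 1, 1), nrow = 3,
                 dimnames = list(c("gA", "gB", "gC"), c("case", "ctrl")))
  ann <- annotate_event(ev, g,
                        known = data.frame(chrom = "chr1", bp = 5.15e6),
                        fpkm = fpkm, carrier_sample = "case",
                        control_samples = "ctrl")
  # breakpoint A: inside gA, 50 kb from a known breakpoint -> not novel
  expect_equal(ann$nearest_gene[1], "gA")
  expect_true(ann$coding[1])
  expect_false(ann$novel[1])
  # FPKM 3 vs control mean 1: >1 and >= 2x -> upregulated
  expect_equal(ann$expression_status[1], "up")
  # breakpoint B: intergenic, 40 kb from gC, novel
  expect_equal(ann$nearest_gene[2], "gC")
  expect_false(ann$coding[2])
  expect_equal(ann$distance[2], 4e4)
  expect_true(ann$novel[2])
  expect_error(annotate_event(ev, genome_model(c(chr1 = 1.2e7, chr2 = 1.2e7))),
               "gene catalog")
})

test_that("ten varied simulated events all refine to the exact planted base pair", {
  g <- genome_model(c(chr1 = 1e7, chr2 = 1e7))
  sides <- expand.grid(a = c("left", "right"), b = c("left", "right"),
                       stringsAsFactors = FALSE)
  hits <- 0L
  for (k in 1:10) {
    bpA <- 2e6 + k * 513457
    bpB <- 8e6 - k * 417883
    frac <- c(0.5, 0.75, 1)[k %% 3 + 1]
    sd <- sides[k %% 4 + 1, ]
    rsp <- rearrangement_spec("translocation", "chr1", bpA, sd$a,
                              "chr2", bpB, sd$b, fraction = frac,
                              n_chimeric = 5, n_decoy = 8)
    rec <- simulate_contact_map(g, structure_spec(), cis_depth = 1.5e6,
                                seed = 1000 + k, binsize = 1e4)
    pl <- plant_rearrangement(rec, g, rsp, seed = 2000 + k)
    cm <- bin_contacts(pl$contacts, g, 1e4)
    blocks <- detect_interchrom_blocks(cm, list())
    ev <- refine_breakpoints(blocks, pl$reads, g)
    ok <- any(ev$refined & ev$bpA == bpA & ev$bpB == bpB &
                ev$sideA == sd$a & ev$sideB == sd$b)
    hits <- hits + ok
  }
  expect_equal(hits, 10L)
})
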