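# Shared simulated fixtures, built once per test run and cached. All seeds
# fixed; all sizes chosen as the package's study conditions (documented in
# the methods vignette).

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# plain decay map: 20-Mb chromosome, 20-kb bins, all multipliers 1
fx_decay <- function() fx("decay", function() {
  g <- genome_model(c(chr1 = 2e7))
  rec <- simulate_contact_map(g, structure_spec(), cis_depth = 2e6, seed = 1,
                              binsize = 20000)
  cm <- kr_balance(bin_contacts(rec, g, 20000))
  list(genome = g, records = rec, cm = cm)
})

# 50-Mb chromosome at 40-kb bins with 20 planted TADs (21 edges)
fx_tads <- function() fx("tads", function() {
  g <- genome_model(c(chr1 = 5e7))
  edges <- seq(2e6, 48e6, length.out = 21)
  tads <- data.frame(chrom = "chr1", start = head(edges, -1), end = edges[-1],
                     enrich = 3)
  rec <- simulate_contact_map(g, structure_spec(tads = tads), cis_depth = 4e6,
                              seed = 5, binsize = 40000)
  cm <- kr_balance(bin_contacts(rec, g, 40000))
  list(genome = g, edges = edges, tads = tads, cm = cm,
       track = insulation_track(cm, "chr1"))
})

# 4 vs 4 cohort: 10 boundaries present only in the case group
fx_diffbound <- function() fx("diffbound", function() {
  g <- genome_model(c(chr1 = 5e7))
  bs <- 40000
  edges <- seq(2e6, 48e6, by = 2.3e6)
  tads_ctrl <- data.frame(chrom = "chr1", start = head(edges, -1),
                          end = edges[-1], enrich = 2)
  split_idx <- seq(1, 19, by = 2)
  tads_case <- do.call(rbind, lapply(seq_len(nrow(tads_ctrl)), function(k) {
    t <- tads_ctrl[k, ]
    if (k %in% split_idx) {
      mid <- round((t$start + t$end) / 2 / bs) * bs
      data.frame(chrom = "chr1", start = c(t$start, mid), end = c(mid, t$end),
                 enrich = 2)
    } else t
  }))
  spC <- structure_spec(tads = tads_ctrl)
  spK <- structure_spec(tads = tads_case)
  cms <- list(); grp <- c()
  for (i in 1:4) {
    cms[[paste0("ctrl", i)]] <- bin_contacts(
      simulate_contact_map(g, spC, 4e6, seed = 100 + i, binsize = bs), g, bs)
    grp[paste0("ctrl", i)] <- "control"
  }
  for (i in 1:4) {
    cms[[paste0("case", i)]] <- bin_contacts(
      simulate_contact_map(g, spK, 4e6, seed = 200 + i, binsize = bs), g, bs)
    grp[paste0("case", i)] <- "case"
  }
  new_bins <- floor((head(edges, -1)[split_idx] + edges[-1][split_idx]) / 2 / bs)
  list(genome = g, binsize = bs, cms = cms, grp = grp,
       split_idx = split_idx, new_bins = new_bins, edges = edges)
})

# 4 vs 4 cohort: 25 TADs, 5 with doubled intra-TAD enrichment in the case
fx_dscore <- function() fx("dscore", function() {
  g <- genome_model(c(chr1 = 5e7))
  bs <- 40000
  edges <- seq(2e6, 48e6, length.out = 26)
  tads <- data.frame(chrom = "chr1", start = head(edges, -1), end = edges[-1],
                     enrich = 2)
  changed <- seq(1, 25, by = 5)
  tads_case <- tads
  tads_case$enrich[changed] <- 4
  spC <- structure_spec(tads = tads)
  spK <- structure_spec(tads = tads_case)
  cms <- list(); grp <- c()
  for (i in 1:4) {
    cms[[paste0("ctrl", i)]] <- bin_contacts(
      simulate_contact_map(g, spC, 4e6, seed = 300 + i, binsize = bs), g, bs)
    grp[paste0("ctrl", i)] <- "control"
  }
  for (i in 1:4) {
    cms[[paste0("case", i)]] <- bin_contacts(
      simulate_contact_map(g, spK, 4e6, seed = 400 + i, binsize = bs), g, bs)
    grp[paste0("case", i)] <- "case"
  }
  tb <- data.frame(chrom = "chr1",
                   start_bin = floor(head(edges, -1) / bs) + 1L,
                   end_bin = floor(edges[-1] / bs) - 1L)
  list(genome = g, binsize = bs, cms = cms, grp = grp, tads = tb,
       changed = changed)
})

# pooled-depth loop-calling fixture: 20 planted 5x peaks + matched null map
fx_loops <- function() fx("loops", function() {
  g <- genome_model(c(chr1 = 2e7))
  bs <- 10000
  set.seed(42)
  a1 <- sort(sample(200:1700, 20)) * bs
  sep <- sample(30:150, 20) * bs
  loops <- data.frame(chrom = "chr1", pos1 = a1 + 5000,
                      pos2 = pmin(a1 + sep + 5000, 2e7), enrich = 5)
  rec <- simulate_contact_map(g, structure_spec(loops = loops),
                              cis_depth = 1.2e7, seed = 7, binsize = bs)
  cm <- bin_contacts(rec, g, bs)
  rec0 <- simulate_contact_map(g, structure_spec(), cis_depth = 1.2e7,
                               seed = 8, binsize = bs)
  cm0 <- bin_contacts(rec0, g, bs)
  list(genome = g, binsize = bs, loops = loops, cm = cm, cm0 = cm0,
       bins1 = floor((loops$pos1 - 1) / bs), bins2 = floor((loops$pos2 - 1) / bs),
       calls = call_loops(cm, fdr = 0.1))
})

# 4 vs 4 differential-loop cohort (100 loops, 20 enhanced 2x in case) plus
# an 8-sample homogeneous cohort for permutation nulls
fx_diffloops <- function() fx("diffloops", function() {
  g <- genome_model(c(chr1 = 2e7))
  bs <- 10000
  set.seed(21)
  a1 <- sort(sample(200:1700, 100)) * bs
  sep <- sample(10:80, 100, replace = TRUE) * bs
  loops <- data.frame(chrom = "chr1", pos1 = a1 + 5000,
                      pos2 = pmin(a1 + sep + 5000, 2e7), enrich = 5)
  idx_up <- seq(1, 100, by = 5)
  loopsK <- loops
  loopsK$enrich[idx_up] <- 10
  spC <- structure_spec(loops = loops)
  spK <- structure_spec(loops = loopsK)
  cms <- list(); grp <- c()
  for (i in 1:4) {
    cms[[paste0("ctrl", i)]] <- bin_contacts(
      simulate_contact_map(g, spC, 5e6, seed = 500 + i, binsize = bs), g, bs)
    grp[paste0("ctrl", i)] <- "control"
  }
  for (i in 1:4) {
    cms[[paste0("case", i)]] <- bin_contacts(
      simulate_contact_map(g, spK, 5e6, seed = 600 + i, binsize = bs), g, bs)
    grp[paste0("case", i)] <- "case"
  }
  cms0 <- list()
  for (i in 1:8) cms0[[paste0("s", i)]] <- bin_contacts(
    simulate_contact_map(g, spC, 5e6, seed = 700 + i, binsize = bs), g, bs)
  ul <- data.frame(chrom = "chr1", res = bs,
                   bin1 = floor((loops$pos1 - 1) / bs),
                   bin2 = floor((loops$pos2 - 1) / bs))
  ul$start1 <- ul$bin1 * bs; ul$end1 <- ul$start1 + bs
  ul$start2 <- ul$bin2 * bs; ul$end2 <- ul$start2 + bs
  list(genome = g, binsize = bs, cms = cms, grp = grp, cms0 = cms0,
       union = ul, idx_up = idx_up)
})

# one translocation fixture: case map with planted event + matched control
fx_sv <- function() fx("sv", function() {
  g <- genome_model(c(chr1 = 1.2e7, chr2 = 1.2e7))
  sp <- structure_spec()
  rec <- simulate_contact_map(g, sp, cis_depth = 2e6, seed = 11, binsize = 1e4)
  rsp <- rearrangement_spec(
    "translocation", "chr1", 5123456, "left", "chr2", 7654321, "right",
    fraction = 1,
    neo_loops = data.frame(posA = 5123456 - 4e5, posB = 7654321 + 6e5,
                           enrich = 8),
    n_chimeric = 6, n_decoy = 10)
  pl <- plant_rearrangement(rec, g, rsp, seed = 12)
  cm <- bin_contacts(pl$contacts, g, 1e4)
  recC <- simulate_contact_map(g, sp, cis_depth = 2e6, seed = 13, binsize = 1e4)
  cmC <- bin_contacts(recC, g, 1e4)
  blocks <- detect_interchrom_blocks(cm, list(cmC))
  events <- refine_breakpoints(blocks, pl$reads, g)
  list(genome = g, rspec = rsp, planted = pl, cm = cm, cmC = cmC,
       blocks = blocks, events = events)
})

# demo pipeline run (criterion: completes end-to-end with a manifest)
fx_demo <- function() fx("demo", function() {
  out <- file.path(tempdir(), "nls_demo")
  manifest <- run_pipeline(list(simulate = demo_cohort_config()), seed = 1,
                           out_dir = out)
  list(out = out, manifest = manifest)
})

# decay-continuity statistic across the junction of a reassembled map:
# correlation between log mean junction-crossing contact and log distance
junction_continuity <- function(rmap, kmax = 60) {
  M <- rmap$matrix
  n <- nrow(M); jb <- rmap$junction_bin
  ds <- 1:min(kmax, n - 1)
  mu <- vapply(ds, function(d) {
    i <- seq_len(n - d); j <- i + d
    sel <- i <= jb & j > jb
    if (!any(sel)) return(NA_real_)
    mean(M[cbind(i[sel], j[sel])])
  }, numeric(1))
  ok <- !is.na(mu) & mu > 0
  if (sum(ok) < 5) return(0)
  -stats::cor(log(mu[ok]), log(ds[ok] + 1))
}
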