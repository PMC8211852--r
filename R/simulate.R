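#' Structure specification for simulated Hi-C maps
#'
#' Encodes the structural layers a Hi-C map is built from: power-law distance
#' decay, A/B checkerboard compartments, TAD blocks and focal loop peaks.
#' All intervals are in bp on the genome the spec will be simulated on.
#'
#' @param decay_exponent power-law exponent of the distance decay
#'   `(d/binsize + 1)^exponent`; default -1.
#' @param compartments data.frame `chrom, start, end, label` with label in
#'   `{"A","B"}`; bins outside any block carry no compartment factor.
#' @param compartment_strength checkerboard multiplier (>= 1): pairs sharing a
#'   label are scaled by it, opposite labels by its inverse.
#' @param tads data.frame `chrom, start, end, enrich` of non-overlapping
#'   intra-TAD enrichment blocks (enrich >= 1).
#' @param loops data.frame `chrom, pos1, pos2, enrich` of focal peaks
#'   (enrich >= 1).
#' @return object of class `structure_spec`.
#' @export
structure_spec <- function(decay_exponent = -1, compartments = NULL,
                           compartment_strength = 1, tads = NULL,
                           loops = NULL) {
  if (compartment_strength < 1) stop("multipliers must be >= 1")
  if (!is.null(tads)) {
    stopifnot(all(c("chrom", "start", "end", "enrich") %in% names(tads)))
    if (any(tads$enrich < 1)) stop("multipliers must be >= 1")
    for (ch in unique(tads$chrom)) {
      tt <- tads[tads$chrom == ch, ]
      tt <- tt[order(tt$start), ]
      if (nrow(tt) > 1 && any(tt$start[-1] < tt$end[-nrow(tt)]))
        stop("TADs overlap on ", ch)
    }
  }
  if (!is.null(loops)) {
    stopifnot(all(c("chrom", "pos1", "pos2", "enrich") %in% names(loops)))
    if (any(loops$enrich < 1)) stop("multipliers must be >= 1")
  }
  structure(list(decay_exponent = decay_exponent, compartments = compartments,
                 compartment_strength = compartment_strength, tads = tads,
                 loops = loops),
            class = "structure_spec")
}

# per-bin compartment label vector (NA where unlabeled)
.comp_labels <- function(spec, chrom, n, binsize) {
  lab <- rep(NA_character_, n)
  cc <- spec$compartments
  if (!is.null(cc)) {
    cc <- cc[cc$chrom == chrom, , drop = FALSE]
    for (k in seq_len(nrow(cc))) {
      b1 <- pos_to_bin(cc$start[k], binsize) + 1L
      b2 <- min(pos_to_bin(cc$end[k], binsize) + 1L, n)
      lab[b1:b2] <- cc$label[k]
    }
  }
  lab
}

#' Simulate a Hi-C contact map with planted structure
#'
#' Expected intensity at bin pair (i, j) of distance d bins is
#' `scale * (d + 1)^exponent * compartment factor * TAD factor * loop factor`,
#' with `scale` chosen so the expected cis total equals `cis_depth`. Counts
#' are sampled per bin pair as Poisson and expanded to contact records at bin
#' midpoints. Deterministic given `seed`.
#'
#' @param genome a `genome_model`.
#' @param spec a `structure_spec`.
#' @param cis_depth target expected total cis contact count.
#' @param seed integer RNG seed.
#' @param binsize simulation bin size in bp (default 10,000).
#' @param max_distance cap on simulated pair distance in bp (default: full
#'   chromosome).
#' @return data.frame of contact records `chrom1 pos1 chrom2 pos2 count` with
#'   a `sim` attribute carrying the model scale for downstream planting.
#' @export
simulate_contact_map <- function(genome, spec, cis_depth, seed,
                                 binsize = 10000, max_distance = NULL) {
  stopifnot(cis_depth > 0)
  if (!is.null(spec$tads))
    .check_within(spec$tads$chrom, spec$tads$end, genome$chrom_lengths, "spec TADs")
  if (!is.null(spec$loops)) {
    .check_within(spec$loops$chrom, spec$loops$pos1, genome$chrom_lengths, "spec loops")
    .check_within(spec$loops$chrom, spec$loops$pos2, genome$chrom_lengths, "spec loops")
  }
  set.seed(seed)
  nb <- n_bins(genome, binsize)
  alpha <- spec$decay_exponent
  per <- list()
  for (ch in names(nb)) {
    n <- nb[[ch]]
    maxd <- if (is.null(max_distance)) n - 1L else
      min(n - 1L, as.integer(max_distance / binsize))
    ii <- sequence(n - 0:maxd) - 1L               # 0-based bin i for d = 0..maxd
    dd <- rep.int(0:maxd, n - 0:maxd)
    jj <- ii + dd
    lam <- (dd + 1)^alpha
    lab <- .comp_labels(spec, ch, n, binsize)
    if (spec$compartment_strength > 1 && any(!is.na(lab))) {
      li <- lab[ii + 1L]; lj <- lab[jj + 1L]
      both <- !is.na(li) & !is.na(lj)
      same <- both & li == lj
      diff <- both & li != lj
      lam[same] <- lam[same] * spec$compartment_strength
      lam[diff] <- lam[diff] / spec$compartment_strength
    }
    tt <- spec$tads
    if (!is.null(tt)) {
      tt <- tt[tt$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(tt))) {
        b1 <- pos_to_bin(tt$start[k], binsize); b2 <- pos_to_bin(tt$end[k], binsize)
        sel <- ii >= b1 & jj <= b2
        lam[sel] <- lam[sel] * tt$enrich[k]
      }
    }
    ll <- spec$loops
    if (!is.null(ll)) {
      ll <- ll[ll$chrom == ch, , drop = FALSE]
      if (nrow(ll) > 0) {
        b1 <- pmin(pos_to_bin(ll$pos1, binsize), pos_to_bin(ll$pos2, binsize))
        b2 <- pmax(pos_to_bin(ll$pos1, binsize), pos_to_bin(ll$pos2, binsize))
        idx <- match(b1 * n + b2, ii * n + jj)
        ok <- !is.na(idx)
        lam[idx[ok]] <- lam[idx[ok]] * ll$enrich[ok]
      }
    }
    per[[ch]] <- list(ii = ii, jj = jj, lam = lam)
  }
  total <- sum(vapply(per, function(p) sum(p$lam), numeric(1)))
  scale <- cis_depth / total
  out <- list()
  for (ch in names(per)) {
    p <- per[[ch]]
    cnt <- stats::rpois(length(p$lam), p$lam * scale)
    keep <- cnt > 0
    if (!any(keep)) next
    half <- as.integer(binsize / 2)
    len <- genome$chrom_lengths[[ch]]
    out[[ch]] <- data.frame(
      chrom1 = ch, pos1 = pmin(p$ii[keep] * binsize + half, len),
      chrom2 = ch, pos2 = pmin(p$jj[keep] * binsize + half, len),
      count = cnt[keep], stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  attr(rec, "sim") <- list(binsize = binsize, scale = scale, alpha = alpha,
                           cis_depth = cis_depth)
  rec
}

#' Rearrangement specification
#'
#' Describes one clonal structural event: a translocation (two chromosomes)
#' or an inversion-type junction (one chromosome). `sideA`/`sideB` name the
#' flank of each breakpoint that fuses at the junction (`"left"` = coordinates
#' below the breakpoint). Planted neo-loops are native-coordinate anchor pairs
#' with one anchor on each fused flank.
#'
#' @param type `"translocation"` or `"inversion"`.
#' @param chromA,bpA,sideA first breakpoint (chrom, bp, fused flank).
#' @param chromB,bpB,sideB second breakpoint.
#' @param fraction clonal fraction in `[0, 1]`.
#' @param neo_loops data.frame `posA, posB, enrich` (native bp on the fused
#'   flanks of A and B respectively), or NULL.
#' @param n_chimeric junction-spanning chimeric reads to emit (linker-free).
#' @param n_decoy random religation decoy reads to emit (linker-present).
#' @return object of class `rearrangement_spec`.
#' @export
rearrangement_spec <- function(type = c("translocation", "inversion"),
                               chromA, bpA, sideA, chromB, bpB, sideB,
                               fraction = 1, neo_loops = NULL,
                               n_chimeric = 6, n_decoy = 10) {
  type <- match.arg(type)
  if (type == "inversion" && chromA != chromB)
    stop("inversion breakpoints must be on one chromosome")
  if (type == "translocation" && chromA == chromB)
    stop("translocation breakpoints must be on different chromosomes")
  if (fraction < 0 || fraction > 1) stop("clonal fraction must be in [0,1]")
  stopifnot(sideA %in% c("left", "right"), sideB %in% c("left", "right"))
  if (!is.null(neo_loops)) {
    stopifnot(all(c("posA", "posB", "enrich") %in% names(neo_loops)))
    okA <- if (sideA == "left") neo_loops$posA <= bpA else neo_loops$posA >= bpA
    okB <- if (sideB == "left") neo_loops$posB <= bpB else neo_loops$posB >= bpB
    if (!all(okA & okB))
      stop("neo-loop anchors must lie on the fused flanks (opposite sides of the junction)")
  }
  structure(list(type = type, chromA = chromA, bpA = bpA, sideA = sideA,
                 chromB = chromB, bpB = bpB, sideB = sideB,
                 fraction = fraction, neo_loops = neo_loops,
                 n_chimeric = n_chimeric, n_decoy = n_decoy),
            class = "rearrangement_spec")
}

# native bin index (0-based) at junction offset da (bins) on a fused flank
.flank_bins <- function(bp, side, binsize, nbins, kmax) {
  b0 <- pos_to_bin(bp, binsize)
  if (side == "left") {
    k <- min(kmax, b0 + 1L)
    b0 - seq_len(k) + 1L          # b0, b0-1, ...
  } else {
    k <- min(kmax, nbins - b0)
    b0 + seq_len(k) - 1L          # b0, b0+1, ...
  }
}

#' Plant a clonal rearrangement into a simulated contact map
#'
#' Adds junction-spanning contacts that follow the map's distance decay from
#' the junction point, scaled by the clonal fraction; adds planted neo-loop
#' peaks; and emits chimeric reads whose two segments sit at the exact
#' breakpoint coordinates (bridge-linker flag 0) plus random religation decoy
#' reads (flag 1). Segment strand encodes the fused flank: '+' on A for a
#' left-flank fusion, '+' on B for a right-flank fusion.
#'
#' @param contacts record data.frame from [simulate_contact_map()] (its `sim`
#'   attribute supplies the model scale).
#' @param genome the `genome_model` the contacts were simulated on.
#' @param rspec a `rearrangement_spec`.
#' @param seed integer RNG seed.
#' @param kmax maximal junction offset simulated, in bins (default 250).
#' @return list with `contacts` (input plus junction records, `sim` attribute
#'   preserved), `reads` (chimeric-read data.frame), and `truth` (the rspec).
#' @export
plant_rearrangement <- function(contacts, genome, rspec, seed, kmax = 250) {
  sim <- attr(contacts, "sim")
  if (is.null(sim)) stop("contacts must come from simulate_contact_map")
  .check_within(rspec$chromA, rspec$bpA, genome$chrom_lengths, "rearrangement")
  .check_within(rspec$chromB, rspec$bpB, genome$chrom_lengths, "rearrangement")
  set.seed(seed)
  binsize <- sim$binsize; alpha <- sim$alpha
  half <- as.integer(binsize / 2)
  nb <- n_bins(genome, binsize)
  reads <- data.frame(read_id = character(0), chrom1 = character(0),
                      pos1 = integer(0), strand1 = character(0),
                      chrom2 = character(0), pos2 = integer(0),
                      strand2 = character(0), linker = integer(0),
                      stringsAsFactors = FALSE)
  # decoy religation reads at random positions (exercise the linker filter)
  if (rspec$n_decoy > 0) {
    chs <- names(genome$chrom_lengths)
    c1 <- sample(chs, rspec$n_decoy, replace = TRUE)
    c2 <- sample(chs, rspec$n_decoy, replace = TRUE)
    reads <- rbind(reads, data.frame(
      read_id = sprintf("decoy%03d", seq_len(rspec$n_decoy)),
      chrom1 = c1,
      pos1 = sapply(c1, function(ch) sample.int(genome$chrom_lengths[[ch]], 1)),
      strand1 = sample(c("+", "-"), rspec$n_decoy, replace = TRUE),
      chrom2 = c2,
      pos2 = sapply(c2, function(ch) sample.int(genome$chrom_lengths[[ch]], 1)),
      strand2 = sample(c("+", "-"), rspec$n_decoy, replace = TRUE),
      linker = 1L, stringsAsFactors = FALSE))
  }
  if (rspec$fraction == 0)
    return(list(contacts = contacts, reads = reads, truth = rspec))
  binsA <- .flank_bins(rspec$bpA, rspec$sideA, binsize, nb[[rspec$chromA]], kmax)
  binsB <- .flank_bins(rspec$bpB, rspec$sideB, binsize, nb[[rspec$chromB]], kmax)
  grid <- expand.grid(ka = seq_along(binsA) - 1L, kb = seq_along(binsB) - 1L)
  lam <- sim$scale * rspec$fraction * (grid$ka + grid$kb + 1)^alpha
  cnt <- stats::rpois(nrow(grid), lam)
  keep <- cnt > 0
  lenA <- genome$chrom_lengths[[rspec$chromA]]
  lenB <- genome$chrom_lengths[[rspec$chromB]]
  jx <- data.frame(
    chrom1 = rspec$chromA,
    pos1 = pmin(binsA[grid$ka[keep] + 1L] * binsize + half, lenA),
    chrom2 = rspec$chromB,
    pos2 = pmin(binsB[grid$kb[keep] + 1L] * binsize + half, lenB),
    count = cnt[keep], stringsAsFactors = FALSE)
  # neo-loop peaks on top of the junction background
  nl <- rspec$neo_loops
  if (!is.null(nl) && nrow(nl) > 0) {
    da <- abs(pos_to_bin(nl$posA, binsize) - pos_to_bin(rspec$bpA, binsize))
    db <- abs(pos_to_bin(nl$posB, binsize) - pos_to_bin(rspec$bpB, binsize))
    lamp <- sim$scale * rspec$fraction * (da + db + 1)^alpha * (nl$enrich - 1)
    cp <- stats::rpois(nrow(nl), lamp)
    pk <- data.frame(chrom1 = rspec$chromA,
                     pos1 = pmin(pos_to_bin(nl$posA, binsize) * binsize + half, lenA),
                     chrom2 = rspec$chromB,
                     pos2 = pmin(pos_to_bin(nl$posB, binsize) * binsize + half, lenB),
                     count = cp, stringsAsFactors = FALSE)
    jx <- rbind(jx, pk[pk$count > 0, ])
  }
  if (rspec$n_chimeric > 0) {
    reads <- rbind(reads, data.frame(
      read_id = sprintf("junc%03d", seq_len(rspec$n_chimeric)),
      chrom1 = rspec$chromA, pos1 = as.integer(rspec$bpA),
      strand1 = if (rspec$sideA == "left") "+" else "-",
      chrom2 = rspec$chromB, pos2 = as.integer(rspec$bpB),
      strand2 = if (rspec$sideB == "right") "+" else "-",
      linker = 0L, stringsAsFactors = FALSE))
  }
  out <- rbind(contacts, jx)
  attr(out, "sim") <- sim
  list(contacts = out, reads = reads, truth = rspec)
}

#' Simulate a negative-binomial expression table
#'
#' Per-gene, per-sample counts from a negative-binomial model; the second
#' group's mean is shifted by the planted log2 fold change. FPKM is derived
#' by gene-length and library-depth normalization.
#'
#' @param genome a `genome_model` with a gene catalog.
#' @param coupling named numeric vector gene -> planted log2 fold change
#'   (genes absent from it have logFC 0).
#' @param n_per_group samples per group (two groups, `control` and `case`).
#' @param dispersion NB dispersion (> 0); `size = 1/dispersion`.
#' @param seed integer RNG seed.
#' @param base_mean_log mean of the log-normal baseline expression (default
#'   log(100)).
#' @return list with `counts` and `fpkm` (genes x samples matrices),
#'   `samples` (sample/group data.frame) and `truth` (planted logFC per gene).
#' @export
simulate_expression <- function(genome, coupling = numeric(0), n_per_group,
                                dispersion = 0.1, seed,
                                base_mean_log = log(100)) {
  if (dispersion <= 0) stop("dispersion must be positive")
  stopifnot(n_per_group >= 2)
  genes <- genome$genes
  if (is.null(genes)) stop("genome has no gene catalog")
  set.seed(seed)
  ng <- nrow(genes)
  lfc <- stats::setNames(rep(0, ng), genes$gene)
  lfc[names(coupling)] <- coupling
  mu0 <- stats::rlnorm(ng, meanlog = base_mean_log, sdlog = 1)
  samples <- data.frame(
    sample = c(sprintf("ctrl%02d", seq_len(n_per_group)),
               sprintf("case%02d", seq_len(n_per_group))),
    group = rep(c("control", "case"), each = n_per_group),
    stringsAsFactors = FALSE)
  counts <- matrix(0L, ng, nrow(samples),
                   dimnames = list(genes$gene, samples$sample))
  for (s in seq_len(nrow(samples))) {
    mu <- if (samples$group[s] == "case") mu0 * 2^lfc else mu0
    counts[, s] <- stats::rnbinom(ng, mu = mu, size = 1 / dispersion)
  }
  len_kb <- (genes$end - genes$start + 1) / 1000
  depth <- colSums(counts)
  fpkm <- sweep(counts / len_kb, 2, depth / 1e6, "/")
  list(counts = counts, fpkm = fpkm, samples = samples, truth = lfc)
}

#' Simulate coupled structural statistics and expression changes
#'
#' Generates per-gene D-score-change and loop-strength-change test
#' statistics from one latent structural signal, converts them to two-sided
#' p-values with direction signs, and draws the expression log2 fold change
#' conditional on the resulting signed structural score at a planted
#' population correlation. The planted `r` is therefore the correlation of
#' exactly the quantity [combined_structural_p()] estimates.
#'
#' @param n_genes number of genes.
#' @param r planted Pearson correlation between the signed structural score
#'   and expression logFC, in [-1, 1].
#' @param seed integer RNG seed.
#' @param component_noise sd of the noise added to the latent signal in each
#'   structural component (default 0.3).
#' @param lfc_sd sd of the expression logFC (default 1).
#' @return data.frame `gene, dscore_p, dscore_sign, loop_p, loop_sign,
#'   logFC`.
#' @export
simulate_structure_expression <- function(n_genes, r, seed,
                                          component_noise = 0.3, lfc_sd = 1) {
  stopifnot(abs(r) <= 1)
  set.seed(seed)
  z <- stats::rnorm(n_genes)
  t1 <- z + stats::rnorm(n_genes) * component_noise
  t2 <- z + stats::rnorm(n_genes) * component_noise
  p1 <- 2 * stats::pnorm(-abs(t1))
  p2 <- 2 * stats::pnorm(-abs(t2))
  score <- combined_structural_p(p1, p2, sign(t1), sign(t2))$table$signed_score
  s <- as.numeric(scale(score))
  lfc <- (r * s + sqrt(1 - r^2) * stats::rnorm(n_genes)) * lfc_sd
  data.frame(gene = sprintf("g%05d", seq_len(n_genes)),
             dscore_p = p1, dscore_sign = sign(t1),
             loop_p = p2, loop_sign = sign(t2), logFC = lfc,
             stringsAsFactors = FALSE)
}
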