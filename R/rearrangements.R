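#' @keywords internal
# aggregate a sparse rectangular matrix into coarser square bins
.rebin_mat <- function(m, factor) {
  tr <- Matrix::summary(m)
  if (nrow(tr) == 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = ceiling(dim(m) / factor)))
  Matrix::sparseMatrix(i = (tr$i - 1L) %/% factor + 1L,
                       j = (tr$j - 1L) %/% factor + 1L, x = tr$x,
                       dims = ceiling(dim(m) / factor))
}

# cluster significant pixels of a logical matrix into 8-connected blocks
.cluster_pixels <- function(sig_idx, nrow) {
  if (nrow(sig_idx) == 0) return(list())
  pts <- sig_idx
  assigned <- rep(0L, nrow(pts))
  blocks <- list()
  bid <- 0L
  for (k in seq_len(nrow(pts))) {
    if (assigned[k] > 0) next
    bid <- bid + 1L
    queue <- k; assigned[k] <- bid
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- which(assigned == 0 &
                    abs(pts$i - pts$i[cur]) <= 1 & abs(pts$j - pts$j[cur]) <= 1)
      assigned[nb] <- bid
      queue <- c(queue, nb)
    }
    blocks[[bid]] <- pts[assigned == bid, ]
  }
  blocks
}

# Poisson scan of one trans matrix at one resolution against a uniform
# background; returns significant-pixel table with BH q-values
.scan_trans <- function(m, min_enrichment, alpha) {
  total <- sum(m)
  npix <- prod(dim(m))
  rate <- (total + 1) / npix              # pseudocount floor for sparse trans
  tr <- Matrix::summary(m)
  if (nrow(tr) == 0) return(tr)
  p <- stats::ppois(tr$x - 1, rate, lower.tail = FALSE)
  # BH over all pixels: zero-count pixels have p = 1 and occupy the top ranks
  o <- order(p)
  q <- numeric(length(p))
  q[o] <- rev(cummin(rev(p[o] * npix / seq_along(p))))
  tr$q <- pmin(q, 1)
  tr$fold <- tr$x / rate
  tr[tr$q < alpha & tr$fold >= min_enrichment, ]
}

#' Detect interchromosomal translocation blocks
#'
#' Coarse-to-fine Poisson scan of trans contact matrices against a uniform
#' trans background estimated from the sample's own trans totals: blocks of
#' 8-connected significant pixels at the coarse resolution are refined at
#' the fine resolution within the block's bounding box. Candidates whose
#' block is also significant in any control are flagged `control_present`
#' (and excluded from downstream reporting).
#'
#' @param sample_cm the sample `contact_matrix` (with trans pairs).
#' @param control_cms list of control `contact_matrix` objects (may be
#'   empty).
#' @param resolutions two bp resolutions, coarse then fine (default 1 Mb and
#'   100 kb); must be multiples of the matrix binsize.
#' @param min_enrichment minimal observed/expected fold (default 5).
#' @param alpha BH-corrected significance level (default 0.05).
#' @return data.frame of candidate blocks: `chromA, startA, endA, chromB,
#'   startB, endB, count, max_fold, control_present` (bp intervals, 0-based
#'   half-open).
#' @export
detect_interchrom_blocks <- function(sample_cm, control_cms = list(),
                                     resolutions = c(1e6, 1e5),
                                     min_enrichment = 5, alpha = 0.05) {
  binsize <- sample_cm$binsize
  f1 <- as.integer(resolutions[1] / binsize)
  f2 <- as.integer(resolutions[2] / binsize)
  chroms <- names(sample_cm$genome$chrom_lengths)
  out <- list()
  for (a in seq_along(chroms)) for (b in seq_along(chroms)) {
    if (b <= a) next
    key <- .trans_key(chroms[a], chroms[b])
    Tm <- sample_cm$mats[[key]]
    if (is.null(Tm) || sum(Tm) == 0) next
    C1 <- .rebin_mat(Tm, f1)
    sig <- .scan_trans(C1, min_enrichment, alpha)
    if (nrow(sig) == 0) next
    blocks <- .cluster_pixels(sig, nrow(C1))
    ctrl_sigs <- lapply(control_cms, function(cc) {
      cm <- cc$mats[[key]]
      if (is.null(cm) || sum(cm) == 0) return(NULL)
      .scan_trans(.rebin_mat(cm, f1), min_enrichment, alpha)
    })
    for (blk in blocks) {
      # fine refinement inside the coarse bounding box (expanded by 1 pixel)
      i0 <- (min(blk$i) - 2L) * f1; i1 <- (max(blk$i) + 1L) * f1  # base bins
      j0 <- (min(blk$j) - 2L) * f1; j1 <- (max(blk$j) + 1L) * f1
      i0 <- max(i0, 0L); j0 <- max(j0, 0L)
      i1 <- min(i1, nrow(Tm)); j1 <- min(j1, ncol(Tm))
      sub <- Tm[(i0 + 1L):i1, (j0 + 1L):j1, drop = FALSE]
      C2 <- .rebin_mat(sub, f2)
      rate2 <- (sum(Tm) + 1) / (prod(ceiling(dim(Tm) / f2)))
      tr2 <- Matrix::summary(C2)
      sig2 <- tr2[stats::ppois(tr2$x - 1, rate2, lower.tail = FALSE) *
                    prod(ceiling(dim(Tm) / f2)) < alpha &
                    tr2$x / rate2 >= min_enrichment, , drop = FALSE]
      if (nrow(sig2) > 0) {
        sA <- i0 * binsize + (min(sig2$i) - 1L) * f2 * binsize
        eA <- i0 * binsize + max(sig2$i) * f2 * binsize
        sB <- j0 * binsize + (min(sig2$j) - 1L) * f2 * binsize
        eB <- j0 * binsize + max(sig2$j) * f2 * binsize
      } else {
        sA <- (min(blk$i) - 1L) * f1 * binsize; eA <- max(blk$i) * f1 * binsize
        sB <- (min(blk$j) - 1L) * f1 * binsize; eB <- max(blk$j) * f1 * binsize
      }
      ctrl_present <- any(vapply(ctrl_sigs, function(cs) {
        if (is.null(cs) || nrow(cs) == 0) return(FALSE)
        any(cs$i %in% blk$i & cs$j %in% blk$j)
      }, logical(1)))
      out[[length(out) + 1]] <- data.frame(
        chromA = chroms[a], startA = sA, endA = eA,
        chromB = chroms[b], startB = sB, endB = eB,
        count = sum(blk$x), max_fold = max(blk$fold),
        control_present = ctrl_present, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chromA = character(0), startA = numeric(0),
                      endA = numeric(0), chromB = character(0),
                      startB = numeric(0), endB = numeric(0),
                      count = numeric(0), max_fold = numeric(0),
                      control_present = logical(0)))
  do.call(rbind, out)
}

#' Refine breakpoints to single-bp from chimeric reads
#'
#' Bridge-linker-positive reads are discarded (religation, not genomic
#' junctions). Remaining chimeric reads are assigned to a candidate block
#' when both segments fall within the block extended by `window`; the modal
#' exact coordinate pair becomes the refined breakpoint when supported by
#' strictly more than `min_support` reads. Fused flanks are inferred from
#' segment strands by majority ('+' on A = left flank fused; '+' on B =
#' right flank fused); strand ties leave the candidate unrefined.
#'
#' @param candidates block data.frame from [detect_interchrom_blocks()].
#' @param reads chimeric-read data.frame (`read_id, chrom1, pos1, strand1,
#'   chrom2, pos2, strand2, linker`).
#' @param genome a `genome_model` (read coordinates are validated).
#' @param min_support refinement requires support > this (default 3).
#' @param window match radius in bp around the block (default 100,000).
#' @return data.frame of `translocation_event` rows: `chromA, bpA, sideA,
#'   chromB, bpB, sideB, inverted, support, refined, control_present`.
#' @export
refine_breakpoints <- function(candidates, reads, genome, min_support = 3,
                               window = 1e5) {
  if (nrow(reads) > 0) {
    .check_within(reads$chrom1, reads$pos1, genome$chrom_lengths, "chimeric reads")
    .check_within(reads$chrom2, reads$pos2, genome$chrom_lengths, "chimeric reads")
  }
  reads <- reads[reads$linker == 0, , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(candidates))) {
    cd <- candidates[k, ]
    inA <- function(ch, p) ch == cd$chromA & p >= cd$startA - window &
      p <= cd$endA + window
    inB <- function(ch, p) ch == cd$chromB & p >= cd$startB - window &
      p <= cd$endB + window
    fwd <- inA(reads$chrom1, reads$pos1) & inB(reads$chrom2, reads$pos2)
    rev <- inA(reads$chrom2, reads$pos2) & inB(reads$chrom1, reads$pos1)
    sup <- rbind(
      if (any(fwd)) data.frame(pA = reads$pos1[fwd], sA = reads$strand1[fwd],
                               pB = reads$pos2[fwd], sB = reads$strand2[fwd]),
      if (any(rev)) data.frame(pA = reads$pos2[rev], sA = reads$strand2[rev],
                               pB = reads$pos1[rev], sB = reads$strand1[rev]))
    ev <- data.frame(chromA = cd$chromA, bpA = NA_real_, sideA = NA_character_,
                     chromB = cd$chromB, bpB = NA_real_, sideB = NA_character_,
                     inverted = NA, support = 0L, refined = FALSE,
                     control_present = cd$control_present,
                     startA = cd$startA, endA = cd$endA,
                     startB = cd$startB, endB = cd$endB,
                     stringsAsFactors = FALSE)
    if (!is.null(sup) && nrow(sup) > 0) {
      key <- paste(sup$pA, sup$pB)
      tab <- sort(table(key), decreasing = TRUE)
      modal <- names(tab)[1]
      support <- as.integer(tab[1])
      ev$support <- support
      if (support > min_support) {
        sel <- key == modal
        pa <- sup$pA[sel][1]; pb <- sup$pB[sel][1]
        nA_plus <- sum(sup$sA[sel] == "+"); nA_minus <- sum(sup$sA[sel] == "-")
        nB_plus <- sum(sup$sB[sel] == "+"); nB_minus <- sum(sup$sB[sel] == "-")
        if (nA_plus != nA_minus && nB_plus != nB_minus) {
          ev$bpA <- pa; ev$bpB <- pb
          ev$sideA <- if (nA_plus > nA_minus) "left" else "right"
          ev$sideB <- if (nB_plus > nB_minus) "right" else "left"
          # a fragment is reversed when its fused flank faces away from the
          # junction in the derivative chromosome
          ev$inverted <- (ev$sideA == "right") || (ev$sideB == "left")
          ev$refined <- TRUE
        }
      }
    }
    out[[k]] <- ev
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chromA = character(0), bpA = numeric(0), sideA = character(0),
               chromB = character(0), bpB = numeric(0), sideB = character(0),
               inverted = logical(0), support = integer(0),
               refined = logical(0), control_present = logical(0),
               startA = numeric(0), endA = numeric(0), startB = numeric(0),
               endB = numeric(0))
  class(res) <- c("translocation_event", "data.frame")
  res
}

#' Build the reassembled (derivative-chromosome) map of an event
#'
#' Extracts the two fused fragments (each `flank` bp into the fused flank of
#' its breakpoint, snapped to the bin grid), orients them so the junction
#' lies between them (reversed fragments are flipped), and maps cis and
#' cross contacts through the coordinate transform into one square matrix.
#' The transform is a bijection on the covered intervals.
#'
#' @param cm the sample `contact_matrix`.
#' @param event one-row `translocation_event` (refined).
#' @param flank bp of sequence kept on each side of the junction (clipped at
#'   chromosome ends with a warning).
#' @return object of class `reassembled_map`: list with `matrix` (dense),
#'   `fragments` (data.frame `chrom, start_bin, end_bin, reversed, offset`),
#'   `junction_bin` (count of fragment-A bins), `binsize`, `genome`,
#'   `cis_total` (of the source matrix).
#' @export
reassemble_matrix <- function(cm, event, flank = 2e6) {
  stopifnot(nrow(event) == 1)
  if (!isTRUE(event$refined)) stop("event must be refined")
  binsize <- cm$binsize
  nb <- n_bins(cm$genome, cm$binsize)
  frag <- function(chrom, bp, side, junction_at_right) {
    b0 <- pos_to_bin(bp, binsize)
    fb <- as.integer(flank / binsize)
    if (side == "left") {
      s <- b0 - fb + 1L; e <- b0
      if (s < 0) { warning("flank clipped at chromosome start"); s <- 0L }
      reversed <- !junction_at_right    # left flank has junction at its right
    } else {
      s <- b0; e <- b0 + fb - 1L
      if (e > nb[[chrom]] - 1L) { warning("flank clipped at chromosome end")
        e <- nb[[chrom]] - 1L }
      reversed <- junction_at_right     # right flank has junction at its left
    }
    data.frame(chrom = chrom, start_bin = s, end_bin = e, reversed = reversed,
               stringsAsFactors = FALSE)
  }
  fA <- frag(event$chromA, event$bpA, event$sideA, junction_at_right = TRUE)
  fB <- frag(event$chromB, event$bpB, event$sideB, junction_at_right = FALSE)
  if (fA$chrom == fB$chrom) {   # inversion-type event: keep fragments disjoint
    if (fA$end_bin >= fB$start_bin && fA$start_bin <= fB$end_bin) {
      if (event$sideB == "left") fB$start_bin <- max(fB$start_bin, fA$end_bin + 1L)
      else fA$end_bin <- min(fA$end_bin, fB$start_bin - 1L)
    }
  }
  bins <- function(f) {
    b <- f$start_bin:f$end_bin
    if (f$reversed) rev(b) else b
  }
  mapA <- bins(fA); mapB <- bins(fB)
  nA <- length(mapA); nB <- length(mapB)
  fA$offset <- 0L; fB$offset <- nA
  MA <- as.matrix(cis_matrix(cm, fA$chrom))[mapA + 1L, mapA + 1L, drop = FALSE]
  MB <- as.matrix(cis_matrix(cm, fB$chrom))[mapB + 1L, mapB + 1L, drop = FALSE]
  if (fA$chrom == fB$chrom) {
    X <- as.matrix(cis_matrix(cm, fA$chrom))[mapA + 1L, mapB + 1L, drop = FALSE]
  } else {
    chroms <- names(cm$genome$chrom_lengths)
    if (match(fA$chrom, chroms) < match(fB$chrom, chroms)) {
      X <- as.matrix(trans_matrix(cm, fA$chrom, fB$chrom))[mapA + 1L, mapB + 1L,
                                                           drop = FALSE]
    } else {
      X <- t(as.matrix(trans_matrix(cm, fB$chrom, fA$chrom)))[mapA + 1L,
                                                              mapB + 1L,
                                                              drop = FALSE]
    }
  }
  R <- rbind(cbind(MA, X), cbind(t(X), MB))
  structure(list(matrix = R,
                 fragments = rbind(fA, fB),
                 junction_bin = nA, binsize = binsize, genome = cm$genome,
                 cis_total = cm$cis_total),
            class = "reassembled_map")
}

#' @export
print.reassembled_map <- function(x, ...) {
  cat("reassembled_map:", nrow(x$matrix), "bins at",
      format(x$binsize, big.mark = ","), "bp; junction after bin",
      x$junction_bin, "\n")
  print(x$fragments)
  invisible(x)
}

#' Map native positions to reassembled coordinates
#' @param map a `reassembled_map`.
#' @param chrom,pos native chromosome and 1-based bp position (vectors).
#' @return 1-based reassembled bp positions (NA outside covered intervals).
#' @export
map_to_reassembled <- function(map, chrom, pos) {
  bs <- map$binsize
  out <- rep(NA_real_, length(pos))
  for (k in seq_len(nrow(map$fragments))) {
    f <- map$fragments[k, ]
    s <- f$start_bin * bs + 1; e <- (f$end_bin + 1) * bs
    sel <- chrom == f$chrom & pos >= s & pos <= e & is.na(out)
    off <- f$offset * bs
    out[sel] <- if (f$reversed) off + (e - pos[sel] + 1) else
      off + (pos[sel] - s + 1)
  }
  out
}

#' Map reassembled positions back to native coordinates
#' @param map a `reassembled_map`.
#' @param rpos 1-based reassembled bp positions.
#' @return data.frame `chrom, pos` (NA outside the assembly).
#' @export
map_to_native <- function(map, rpos) {
  bs <- map$binsize
  chrom <- rep(NA_character_, length(rpos))
  pos <- rep(NA_real_, length(rpos))
  for (k in seq_len(nrow(map$fragments))) {
    f <- map$fragments[k, ]
    nlen <- (f$end_bin - f$start_bin + 1) * bs
    off <- f$offset * bs
    sel <- rpos > off & rpos <= off + nlen & is.na(pos)
    s <- f$start_bin * bs + 1; e <- (f$end_bin + 1) * bs
    chrom[sel] <- f$chrom
    pos[sel] <- if (f$reversed) e - (rpos[sel] - off) + 1 else
      s + (rpos[sel] - off) - 1
  }
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Detect translocation-mediated neo-loops on a reassembled map
#'
#' Runs the local-enrichment loop caller on the reassembled sample matrix
#' restricted to junction-spanning pixels; calls must additionally be
#' enriched at least `min_control_enrich`-fold over the control-average
#' value at the same reassembled pixel (3x3 neighborhoods, both maps
#' depth-scaled to a common cis total). Anchors are mapped back to native
#' coordinates and flagged for overlap with pre-existing loop anchors and
#' CTCF motifs.
#'
#' @param sample_map `reassembled_map` of the sample.
#' @param control_map `reassembled_map` built with the same transform from
#'   the control-average matrix (or NULL to skip the control comparison).
#' @param fdr loop-call FDR (default 0.1).
#' @param min_control_enrich minimal sample/control fold (default 2).
#' @param preexisting optional loop data.frame (`chrom, start1, end1, start2,
#'   end2`) of native pre-existing anchors.
#' @param motifs optional CTCF motif data.frame (`chrom, pos, strand`).
#' @param anchor_pad bp pad for overlap flags (default one bin).
#' @param ... further arguments to the pixel caller (donut radii).
#' @return data.frame of neo-loops: reassembled bins, native anchors
#'   (`chrom1, pos1, chrom2, pos2`), `obs, q, control_fold, control_zero,
#'   spans_junction, at_preexisting_anchor, at_ctcf`, and `flip1`/`flip2`
#'   (anchor inside a reversed fragment).
#' @export
detect_neo_loops <- function(sample_map, control_map = NULL, fdr = 0.1,
                             min_control_enrich = 2, preexisting = NULL,
                             motifs = NULL, anchor_pad = NULL, ...) {
  M <- sample_map$matrix
  n <- nrow(M)
  jb <- sample_map$junction_bin
  prof_mean <- vapply(0:(n - 1), function(d)
    mean(M[cbind(seq_len(n - d), seq_len(n - d) + d)]), numeric(1))
  calls <- .call_pixels(M, prof_mean, min_d = 2L, max_d = n - 1L, fdr = fdr,
                        pixel_keep = function(i, j) i <= jb & j > jb, ...)
  calls <- .merge_calls(calls, merge_bins = 2L)
  if (nrow(calls) == 0) {
    return(data.frame(rbin1 = integer(0), rbin2 = integer(0),
                      chrom1 = character(0), pos1 = numeric(0),
                      chrom2 = character(0), pos2 = numeric(0),
                      obs = numeric(0), q = numeric(0),
                      control_fold = numeric(0), control_zero = logical(0),
                      spans_junction = logical(0),
                      at_preexisting_anchor = logical(0), at_ctcf = logical(0),
                      flip1 = logical(0), flip2 = logical(0)))
  }
  bs <- sample_map$binsize
  if (is.null(anchor_pad)) anchor_pad <- bs
  # control comparison on depth-scaled 3x3 neighborhoods
  cf <- rep(NA_real_, nrow(calls)); czero <- rep(FALSE, nrow(calls))
  keep <- rep(TRUE, nrow(calls))
  if (!is.null(control_map)) {
    C <- control_map$matrix
    fs <- 1e6 / sample_map$cis_total
    fc <- 1e6 / control_map$cis_total
    for (k in seq_len(nrow(calls))) {
      ri <- max(1, calls$i[k] - 1):min(n, calls$i[k] + 1)
      rj <- max(1, calls$j[k] - 1):min(n, calls$j[k] + 1)
      sv <- sum(M[ri, rj]) * fs
      cv <- sum(C[ri, rj]) * fc
      if (cv == 0) { czero[k] <- TRUE; next }
      cf[k] <- sv / cv
      if (cf[k] < min_control_enrich) keep[k] <- FALSE
    }
  }
  calls <- calls[keep, ]; cf <- cf[keep]; czero <- czero[keep]
  if (nrow(calls) == 0) calls <- calls
  mid <- function(b) (b - 1) * bs + bs / 2   # reassembled bin -> bp midpoint
  nat1 <- map_to_native(sample_map, mid(calls$i))
  nat2 <- map_to_native(sample_map, mid(calls$j))
  frag_of <- function(rb) ifelse(rb <= sample_map$junction_bin, 1L, 2L)
  rev1 <- sample_map$fragments$reversed[frag_of(calls$i)]
  rev2 <- sample_map$fragments$reversed[frag_of(calls$j)]
  at_pre <- rep(FALSE, nrow(calls)); at_ctcf <- rep(FALSE, nrow(calls))
  near_anchor <- function(chrom, pos, anchors) {
    any((anchors$chrom == chrom &
           pos >= anchors$start - anchor_pad & pos <= anchors$end + anchor_pad))
  }
  if (!is.null(preexisting) && nrow(preexisting) > 0) {
    anch <- rbind(
      data.frame(chrom = preexisting$chrom, start = preexisting$start1,
                 end = preexisting$end1),
      data.frame(chrom = preexisting$chrom, start = preexisting$start2,
                 end = preexisting$end2))
    for (k in seq_len(nrow(calls)))
      at_pre[k] <- near_anchor(nat1$chrom[k], nat1$pos[k], anch) ||
        near_anchor(nat2$chrom[k], nat2$pos[k], anch)
  }
  if (!is.null(motifs) && nrow(motifs) > 0) {
    for (k in seq_len(nrow(calls)))
      at_ctcf[k] <- any(motifs$chrom == nat1$chrom[k] &
                          abs(motifs$pos - nat1$pos[k]) <= anchor_pad) ||
        any(motifs$chrom == nat2$chrom[k] &
              abs(motifs$pos - nat2$pos[k]) <= anchor_pad)
  }
  data.frame(rbin1 = calls$i - 1L, rbin2 = calls$j - 1L,
             chrom1 = nat1$chrom, pos1 = nat1$pos,
             chrom2 = nat2$chrom, pos2 = nat2$pos,
             obs = calls$obs, q = calls$q,
             control_fold = cf, control_zero = czero,
             spans_junction = TRUE,
             at_preexisting_anchor = at_pre, at_ctcf = at_ctcf,
             flip1 = rev1, flip2 = rev2,
             stringsAsFactors = FALSE)
}

#' Annotate a translocation event
#'
#' Per breakpoint: nearest gene and distance, coding/noncoding location
#' (inside any gene body or not), compartment label at the breakpoint bin,
#' novelty (no known breakpoint within 100 kb), and nearest-gene expression
#' status: upregulated if its FPKM in the carrier sample exceeds 1 AND is at
#' least twice the mean of control samples (downregulated symmetric).
#'
#' @param event one-row `translocation_event`.
#' @param genome a `genome_model` with a gene catalog.
#' @param known data.frame `chrom, bp` of known breakpoints (may be empty).
#' @param fpkm genes x samples FPKM matrix.
#' @param carrier_sample column name of the event-carrying sample.
#' @param control_samples column names of samples without nearby breakpoints.
#' @param consensus optional consensus-compartment data.frame (`bin` plus a
#'   label column named by `consensus_group`) at `consensus_binsize` bp.
#' @param consensus_group,consensus_binsize see `consensus`.
#' @param novelty_distance bp radius of the novelty rule (default 100,000).
#' @return data.frame with one row per breakpoint: `chrom, bp, nearest_gene,
#'   distance, coding, compartment, novel, expression_status`.
#' @export
annotate_event <- function(event, genome, known = NULL, fpkm = NULL,
                           carrier_sample = NULL, control_samples = NULL,
                           consensus = NULL, consensus_group = NULL,
                           consensus_binsize = NULL,
                           novelty_distance = 1e5) {
  genes <- genome$genes
  if (is.null(genes) || nrow(genes) == 0) stop("empty gene catalog")
  one <- function(chrom, bp) {
    g <- genes[genes$chrom == chrom, ]
    if (nrow(g) == 0) stop("no genes on ", chrom)
    d <- ifelse(bp >= g$start & bp <= g$end, 0,
                pmin(abs(g$start - bp), abs(g$end - bp)))
    k <- which.min(d)
    nearest <- g$gene[k]; dist <- d[k]
    coding <- dist == 0
    novel <- TRUE
    if (!is.null(known) && nrow(known) > 0)
      novel <- !any(known$chrom == chrom & abs(known$bp - bp) <= novelty_distance)
    comp <- NA_character_
    if (!is.null(consensus)) {
      b <- pos_to_bin(bp, consensus_binsize)
      row <- consensus[consensus$bin == b, ]
      if (nrow(row) == 1) comp <- row[[consensus_group]]
    }
    status <- NA_character_
    if (!is.null(fpkm) && nearest %in% rownames(fpkm) &&
        !is.null(carrier_sample) && length(control_samples) > 0) {
      v <- fpkm[nearest, carrier_sample]
      cv <- mean(fpkm[nearest, control_samples])
      status <- if (v > 1 && v >= 2 * cv) "up"
        else if (cv > 1 && cv >= 2 * v) "down" else "unchanged"
    }
    data.frame(chrom = chrom, bp = bp, nearest_gene = nearest,
               distance = dist, coding = coding, compartment = comp,
               novel = novel, expression_status = status,
               stringsAsFactors = FALSE)
  }
  rbind(one(event$chromA, event$bpA), one(event$chromB, event$bpB))
}
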