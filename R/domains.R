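#' Insulation-score track and boundary calls
#'
#' Sliding-square insulation: the per-bin score is the mean contact value in
#' the `(window/binsize)`-bin square offset diagonally at the bin,
#' log2-normalized by the chromosome mean. The delta track is the mean
#' insulation over the left span minus the right span; boundaries sit at
#' delta down-crossings of zero whose local delta amplitude exceeds the
#' noise threshold (defaults mirror common insulation-caller parameters:
#' 1-Mb window, 200-kb delta span, mean metric, 0.1 threshold).
#'
#' @param cm a `contact_matrix` (40-kb bins by convention).
#' @param chrom chromosome name.
#' @param window insulation square size in bp (default 1,000,000).
#' @param delta_span delta averaging span in bp (default 200,000).
#' @param noise_threshold minimal delta amplitude for a boundary (default 0.1).
#' @param balanced use balanced values if weights are available.
#' @return object of class `insulation_track`: data.frame `bin, score, ins,
#'   delta` with a `boundaries` attribute (data.frame `bin, strength`) and
#'   attributes `chrom`, `binsize`, `span_bins`.
#' @export
insulation_track <- function(cm, chrom, window = 1e6, delta_span = 2e5,
                             noise_threshold = 0.1,
                             balanced = !is.null(cm$weights[[chrom]])) {
  binsize <- cm$binsize
  w <- as.integer(window / binsize)
  s <- as.integer(delta_span / binsize)
  if (w < 2) stop("window must span at least 2 bins")
  M <- as.matrix(cis_matrix(cm, chrom, balanced = balanced))
  if (balanced) {
    bad <- is.na(cm$weights[[chrom]])
    M[bad, ] <- NA; M[, bad] <- NA
  }
  n <- nrow(M)
  score <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    blk <- M[(i - w):(i - 1), (i + 1):(i + w)]
    if (all(is.na(blk))) next
    score[i] <- mean(blk, na.rm = TRUE)
  }
  m0 <- mean(score, na.rm = TRUE)
  ins <- log2(score / m0)
  ins[!is.finite(ins)] <- NA
  delta <- rep(NA_real_, n)
  for (i in (s + 1):(n - s)) {
    l <- ins[(i - s):(i - 1)]; r <- ins[(i + 1):(i + s)]
    if (all(is.na(l)) || all(is.na(r))) next
    delta[i] <- mean(l, na.rm = TRUE) - mean(r, na.rm = TRUE)
  }
  bnd <- list()
  for (i in seq_len(n - 1)) {
    if (is.na(delta[i]) || is.na(delta[i + 1])) next
    if (delta[i] > 0 && delta[i + 1] <= 0) {
      lo <- max(1, i - s); hi <- min(n, i + 1 + s)
      amp <- suppressWarnings(max(delta[lo:i], na.rm = TRUE) -
                                min(delta[(i + 1):hi], na.rm = TRUE))
      if (is.finite(amp) && amp > noise_threshold) {
        # boundary at the local insulation minimum of the crossing pair
        b <- if (!is.na(ins[i + 1]) && (is.na(ins[i]) || ins[i + 1] < ins[i]))
          i + 1 else i
        bnd[[length(bnd) + 1]] <- data.frame(bin = b - 1L, strength = amp)
      }
    }
  }
  boundaries <- if (length(bnd)) do.call(rbind, bnd) else
    data.frame(bin = integer(0), strength = numeric(0))
  # keep the strongest when crossings land on adjacent bins
  if (nrow(boundaries) > 1) {
    boundaries <- boundaries[order(boundaries$bin), ]
    keep <- rep(TRUE, nrow(boundaries))
    for (k in 2:nrow(boundaries)) {
      if (boundaries$bin[k] - boundaries$bin[k - 1] <= 1) {
        drop <- if (boundaries$strength[k] >= boundaries$strength[k - 1]) k - 1 else k
        keep[drop] <- FALSE
      }
    }
    boundaries <- boundaries[keep, ]
    rownames(boundaries) <- NULL
  }
  structure(data.frame(bin = 0:(n - 1), score = score, ins = ins, delta = delta),
            class = c("insulation_track", "data.frame"),
            boundaries = boundaries, chrom = chrom, binsize = binsize,
            span_bins = s)
}

#' Boundaries of an insulation track
#' @param track an `insulation_track`.
#' @return data.frame `bin, strength`.
#' @export
boundaries <- function(track) attr(track, "boundaries")

#' Merge boundary sets across conditions
#'
#' Boundary bins within `merge_radius` are merged to the position with the
#' maximal pooled strength; each merged boundary records how many conditions
#' detected it.
#'
#' @param boundary_sets named list of per-condition boundary data.frames
#'   (`bin, strength`).
#' @param merge_radius merge radius in bins (default 1).
#' @return data.frame `bin, strength, n_conditions, conditions`.
#' @export
merge_boundaries <- function(boundary_sets, merge_radius = 1) {
  all <- do.call(rbind, lapply(names(boundary_sets), function(cond) {
    b <- boundary_sets[[cond]]
    if (nrow(b) == 0) return(NULL)
    data.frame(bin = b$bin, strength = b$strength, cond = cond,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all) || nrow(all) == 0)
    return(data.frame(bin = integer(0), strength = numeric(0),
                      n_conditions = integer(0), conditions = character(0)))
  all <- all[order(all$bin), ]
  grp <- cumsum(c(1, diff(all$bin) > merge_radius))
  out <- do.call(rbind, lapply(split(all, grp), function(g) {
    data.frame(bin = g$bin[which.max(g$strength)],
               strength = max(g$strength),
               n_conditions = length(unique(g$cond)),
               conditions = paste(sort(unique(g$cond)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Consensus TADs from multi-condition boundaries
#'
#' A TAD is the interval between consecutive boundaries detected in at least
#' `min_conditions` conditions; TADs shorter than `min_size` bins are
#' discarded. Boundary bins themselves belong to neither flanking domain, so
#' adjacent TADs are disjoint and their domain scores do not share contacts.
#'
#' @param boundary_sets named list of per-condition boundary data.frames.
#' @param chrom chromosome name recorded on the output.
#' @param min_conditions minimal supporting conditions per boundary
#'   (default 2).
#' @param min_size minimal TAD size in bins (default 3).
#' @param merge_radius boundary merge radius in bins.
#' @return data.frame `chrom, start_bin, end_bin` (inclusive bin interval).
#' @export
consensus_tads <- function(boundary_sets, chrom, min_conditions = 2,
                           min_size = 3, merge_radius = 1) {
  mb <- merge_boundaries(boundary_sets, merge_radius)
  mb <- mb[mb$n_conditions >= min_conditions, ]
  if (nrow(mb) < 2)
    return(data.frame(chrom = character(0), start_bin = integer(0),
                      end_bin = integer(0)))
  b <- sort(mb$bin)
  tads <- data.frame(chrom = chrom, start_bin = b[-length(b)] + 1L,
                     end_bin = b[-1] - 1L)
  tads <- tads[tads$end_bin - tads$start_bin + 1 >= min_size, ]
  rownames(tads) <- NULL
  tads
}

# per-sample delta amplitude at a boundary bin: max delta over the span to
# the left minus min delta over the span to the right (the track's own
# relative insulation measure used for differential testing)
.delta_amplitude <- function(track, bin) {
  s <- attr(track, "span_bins")
  d <- track$delta
  i <- bin + 1L
  lo <- max(1, i - s); hi <- min(length(d), i + s)
  l <- suppressWarnings(max(d[lo:i], na.rm = TRUE))
  r <- suppressWarnings(min(d[i:hi], na.rm = TRUE))
  if (!is.finite(l) || !is.finite(r)) return(NA_real_)
  l - r
}

#' Differential TAD boundaries between two groups
#'
#' Per merged boundary, each sample contributes its delta amplitude at the
#' boundary bin; groups are compared with a two-sided Welch t-test,
#' Benjamini-Hochberg corrected. A boundary is flagged when FDR is below
#' `fdr` and the absolute group-mean difference exceeds the `diff_quantile`
#' quantile of all boundaries' absolute differences.
#'
#' @param tracks named list of per-sample `insulation_track` objects.
#' @param groups named character vector sample -> group (two groups).
#' @param merged merged boundary table from [merge_boundaries()] (pooled over
#'   group tracks).
#' @param fdr FDR threshold (default 0.01).
#' @param diff_quantile quantile cut on |difference| (default 0.5).
#' @return data.frame `bin, mean_<g1>, mean_<g2>, diff, p, fdr, flagged`.
#' @export
differential_boundaries <- function(tracks, groups, merged, fdr = 0.01,
                                    diff_quantile = 0.5) {
  gl <- unique(groups)
  stopifnot(length(gl) == 2)
  if (any(table(factor(groups, levels = gl)) < 2))
    stop("need >= 2 samples per group")
  vals <- sapply(tracks, function(t)
    vapply(merged$bin, function(b) .delta_amplitude(t, b), numeric(1)))
  vals <- matrix(vals, nrow = nrow(merged),
                 dimnames = list(NULL, names(tracks)))
  g1 <- names(groups)[groups == gl[1]]
  g2 <- names(groups)[groups == gl[2]]
  res <- t(apply(vals, 1, function(v) {
    a <- v[g1]; b <- v[g2]
    p <- if (all(!is.na(a)) && all(!is.na(b)) &&
             (stats::sd(a) > 0 || stats::sd(b) > 0))
      tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1) else 1
    c(mean(a, na.rm = TRUE), mean(b, na.rm = TRUE), p)
  }))
  diff <- res[, 1] - res[, 2]
  q <- stats::p.adjust(res[, 3], method = "BH")
  cut <- stats::quantile(abs(diff), diff_quantile, na.rm = TRUE)
  out <- data.frame(bin = merged$bin, m1 = res[, 1], m2 = res[, 2],
                    diff = diff, p = res[, 3], fdr = q,
                    flagged = q < fdr & abs(diff) > cut)
  names(out)[2:3] <- paste0("mean_", gl)
  out
}

#' Domain score of TADs
#'
#' Per TAD: the sum of contacts with both anchors inside the TAD divided by
#' the sum of cis contacts with at least one anchor inside it (diagonal
#' included). Invariant under global matrix scaling; bounded in (0, 1].
#'
#' @param cm a `contact_matrix`.
#' @param tads data.frame `chrom, start_bin, end_bin` (inclusive bins).
#' @param balanced use balanced values if available.
#' @return numeric vector of domain scores (NA where the denominator is 0).
#' @export
domain_score <- function(cm, tads, balanced = FALSE) {
  out <- numeric(nrow(tads))
  for (ch in unique(tads$chrom)) {
    M <- cis_matrix(cm, ch, balanced = balanced && !is.null(cm$weights[[ch]]))
    n <- nrow(M)
    rs <- Matrix::rowSums(M)
    dg <- Matrix::diag(M)
    idx <- which(tads$chrom == ch)
    for (k in idx) {
      s <- tads$start_bin[k] + 1L; e <- tads$end_bin[k] + 1L
      if (s < 1 || e > n || e <= s) stop("TAD outside matrix bounds")
      sub <- M[s:e, s:e, drop = FALSE]
      intra_full <- sum(sub)
      intra <- (intra_full + sum(dg[s:e])) / 2       # unique intra pairs
      connected <- sum(rs[s:e]) - intra_full + intra # >= 1 anchor in TAD
      out[k] <- if (connected > 0) intra / connected else NA_real_
    }
  }
  out
}

#' Per-sample domain-score table
#' @param cms named list of per-sample `contact_matrix` objects.
#' @param tads TAD data.frame (`chrom, start_bin, end_bin`).
#' @param balanced use balanced values if available.
#' @return matrix TADs x samples of domain scores.
#' @export
domain_score_table <- function(cms, tads, balanced = FALSE) {
  sapply(cms, function(cm) domain_score(cm, tads, balanced = balanced))
}

#' Differential domain scores between two groups
#'
#' Per-TAD two-sided Welch t-test with BH correction; a TAD is flagged when
#' FDR < `fdr` and its absolute log2 fold change exceeds the `fc_quantile`
#' quantile of all TADs' absolute log2 fold changes. Direction records
#' whether the D-score increased or decreased in the second group.
#'
#' @param scores matrix TADs x samples from [domain_score_table()].
#' @param groups named character vector sample -> group (two groups; the
#'   second level is the "case" direction).
#' @param fdr FDR threshold (default 0.01).
#' @param fc_quantile quantile cut on |log2 FC| (default 0.7).
#' @return data.frame `mean_<g1>, mean_<g2>, log2fc, p, fdr, flagged,
#'   direction`.
#' @export
differential_domain_scores <- function(scores, groups, fdr = 0.01,
                                       fc_quantile = 0.7) {
  gl <- unique(groups)
  stopifnot(length(gl) == 2)
  if (any(table(factor(groups, levels = gl)) < 2))
    stop("need >= 2 samples per group")
  g1 <- names(groups)[groups == gl[1]]
  g2 <- names(groups)[groups == gl[2]]
  res <- t(apply(scores, 1, function(v) {
    a <- v[g1]; b <- v[g2]
    p <- if (all(!is.na(a)) && all(!is.na(b)) &&
             (stats::sd(a) > 0 || stats::sd(b) > 0))
      tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1) else 1
    c(mean(a, na.rm = TRUE), mean(b, na.rm = TRUE), p)
  }))
  lfc <- log2(res[, 2] / res[, 1])
  q <- stats::p.adjust(res[, 3], method = "BH")
  cut <- stats::quantile(abs(lfc), fc_quantile, na.rm = TRUE)
  flagged <- q < fdr & abs(lfc) > cut & is.finite(lfc)
  out <- data.frame(m1 = res[, 1], m2 = res[, 2], log2fc = lfc,
                    p = res[, 3], fdr = q, flagged = flagged,
                    direction = ifelse(lfc > 0, "increased", "decreased"))
  names(out)[1:2] <- paste0("mean_", gl)
  out
}
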