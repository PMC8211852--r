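#' @keywords internal
# Four-background focal-enrichment loop caller on one dense cis matrix.
#
# For each in-band pixel (i < j) the local expectation is estimated from four
# neighborhoods (donut ring, lower-left quadrant, horizontal stripe, vertical
# stripe), each scaled by the distance-decay expectation; the pixel p-value is
# the worst Poisson upper tail across the four. BH correction uses the full
# number of scanned in-band pixels. Fold gates (1.75x donut/lower-left, 1.5x
# stripes) follow the usual local-enrichment defaults.
.region_offsets <- function(r_out, r_in) {
  g <- expand.grid(di = -r_out:r_out, dj = -r_out:r_out)
  ring <- g[pmax(abs(g$di), abs(g$dj)) > r_in, ]
  list(
    donut = ring[ring$di != 0 & ring$dj != 0, ],
    lower_left = g[g$di >= 1 & g$di <= r_out & g$dj <= -1 & g$dj >= -r_out &
                     pmax(abs(g$di), abs(g$dj)) > r_in, ],
    horizontal = g[abs(g$di) <= 1 & abs(g$dj) > r_in, ],
    vertical = g[abs(g$dj) <= 1 & abs(g$di) > r_in, ]
  )
}

.call_pixels <- function(M, expected, min_d = 2L, max_d = nrow(M) - 1L,
                         fdr = 0.1, donut_outer = 5L, donut_inner = 2L,
                         pixel_keep = NULL, min_count = 4,
                         prescreen_fold = 1.5) {
  n <- nrow(M)
  offs <- .region_offsets(donut_outer, donut_inner)
  exp_at <- function(d) {
    d <- abs(d)
    e <- expected[pmin(d, length(expected) - 1L) + 1L]
    e[is.na(e) | e <= 0] <- min(expected[expected > 0], na.rm = TRUE)
    e
  }
  marg <- rowSums(M)
  # scanned pixel universe: in-band, both bins covered
  n_tests <- 0L
  cand <- list()
  for (d in min_d:max_d) {
    i <- seq_len(n - d); j <- i + d
    ok <- marg[i] > 0 & marg[j] > 0
    if (!is.null(pixel_keep)) ok <- ok & pixel_keep(i, j)
    n_tests <- n_tests + sum(ok)
    ed <- exp_at(d)
    v <- M[cbind(i, j)]
    sel <- ok & v >= min_count & v >= prescreen_fold * ed
    if (any(sel))
      cand[[length(cand) + 1]] <- data.frame(i = i[sel], j = j[sel],
                                             obs = v[sel])
  }
  empty <- data.frame(i = integer(0), j = integer(0), obs = numeric(0),
                      lambda_donut = numeric(0), lambda_ll = numeric(0),
                      lambda_h = numeric(0), lambda_v = numeric(0),
                      p = numeric(0), q = numeric(0))
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  lam <- matrix(NA_real_, nrow(cand), 4)
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    for (r in 1:4) {
      o <- offs[[r]]
      ri <- i + o$di; rj <- j + o$dj
      keep <- ri >= 1 & ri <= n & rj >= 1 & rj <= n & ri < rj
      if (!any(keep)) { lam[k, r] <- Inf; next }
      obs_sum <- sum(M[cbind(ri[keep], rj[keep])])
      exp_sum <- sum(exp_at(rj[keep] - ri[keep]))
      lam[k, r] <- exp_at(j - i) * obs_sum / exp_sum
    }
  }
  lam[!is.finite(lam) | lam <= 0] <- min(expected[expected > 0], na.rm = TRUE)
  p <- vapply(seq_len(nrow(cand)), function(k)
    max(stats::ppois(cand$obs[k] - 1, lam[k, ], lower.tail = FALSE)),
    numeric(1))
  # BH over the full scanned universe: candidates hold the smallest ranks
  o <- order(p)
  q <- numeric(length(p))
  q[o] <- rev(cummin(rev(p[o] * n_tests / seq_along(p))))
  q <- pmin(q, 1)
  fold_ok <- cand$obs >= 1.75 * lam[, 1] & cand$obs >= 1.75 * lam[, 2] &
    cand$obs >= 1.5 * lam[, 3] & cand$obs >= 1.5 * lam[, 4]
  res <- data.frame(i = cand$i, j = cand$j, obs = cand$obs,
                    lambda_donut = lam[, 1], lambda_ll = lam[, 2],
                    lambda_h = lam[, 3], lambda_v = lam[, 4], p = p, q = q)
  res <- res[res$q < fdr & fold_ok, ]
  rownames(res) <- NULL
  res
}

# collapse calls within a Chebyshev merge distance to the strongest pixel
.merge_calls <- function(calls, merge_bins) {
  if (nrow(calls) < 2) return(calls)
  calls <- calls[order(calls$q, -calls$obs), ]
  kept <- calls[0, ]
  for (k in seq_len(nrow(calls))) {
    if (nrow(kept) > 0) {
      close <- abs(kept$i - calls$i[k]) <= merge_bins &
        abs(kept$j - calls$j[k]) <= merge_bins
      if (any(close)) next
    }
    kept <- rbind(kept, calls[k, ])
  }
  kept[order(kept$i, kept$j), ]
}

#' Call chromatin loops by local-background enrichment
#'
#' Scans cis matrices at one or more resolutions for pixels enriched over
#' four local background estimates (donut, lower-left, horizontal and
#' vertical stripes) with Poisson p-values, BH-corrected over all scanned
#' in-band pixels. Calls within the per-resolution merge distance collapse to
#' the strongest pixel; across resolutions, a coarser call within the merge
#' distance of a finer call is absorbed by the finer one.
#'
#' @param cms a `contact_matrix` or named list of them keyed by resolution
#'   (names = binsize in bp, e.g. `list("5000" = cm5, "10000" = cm10)`).
#' @param fdr FDR threshold (default 0.1).
#' @param merge_distances named numeric vector resolution -> merge distance
#'   in bp (default 15,000 at 5 kb and 20,000 at 10 kb; other resolutions
#'   default to 2 bins).
#' @param max_distance maximal anchor separation scanned, bp (default 2 Mb).
#' @param min_distance minimal separation, bp (default 2 bins).
#' @param donut_outer,donut_inner donut radii in bins (defaults 5 and 2).
#' @return data.frame of loop calls: `chrom, res, bin1, bin2, start1, end1,
#'   start2, end2, obs, lambda_donut, lambda_ll, lambda_h, lambda_v, p, q`
#'   (anchor intervals 0-based half-open bp).
#' @export
call_loops <- function(cms, fdr = 0.1,
                       merge_distances = c("5000" = 15000, "10000" = 20000),
                       max_distance = 2e6, min_distance = NULL,
                       donut_outer = 5L, donut_inner = 2L) {
  if (inherits(cms, "contact_matrix")) {
    cms <- stats::setNames(list(cms), as.character(cms$binsize))
  }
  ress <- as.integer(names(cms))
  if (any(is.na(ress))) stop("cms must be named by resolution (binsize in bp)")
  per_res <- list()
  for (r in seq_along(cms)) {
    cm <- cms[[r]]; res <- ress[r]
    if (cm$binsize != res) stop("no matrix at resolution ", res)
    md <- if (as.character(res) %in% names(merge_distances))
      merge_distances[[as.character(res)]] else 2 * res
    out <- list()
    for (ch in names(cm$genome$chrom_lengths)) {
      M <- as.matrix(cis_matrix(cm, ch))
      if (sum(M) == 0) next
      prof <- expected_by_distance(cm, ch, balanced = FALSE)
      min_d <- if (is.null(min_distance)) 2L else
        max(2L, as.integer(min_distance / res))
      calls <- .call_pixels(M, prof$mean, min_d = min_d,
                            max_d = min(nrow(M) - 1L,
                                        as.integer(max_distance / res)),
                            fdr = fdr, donut_outer = donut_outer,
                            donut_inner = donut_inner)
      calls <- .merge_calls(calls, merge_bins = as.integer(md / res))
      if (nrow(calls) == 0) next
      calls$chrom <- ch
      out[[ch]] <- calls
    }
    if (length(out) == 0) next
    df <- do.call(rbind, out)
    df$res <- res
    df$bin1 <- df$i - 1L; df$bin2 <- df$j - 1L
    df$start1 <- df$bin1 * res; df$end1 <- df$start1 + res
    df$start2 <- df$bin2 * res; df$end2 <- df$start2 + res
    per_res[[as.character(res)]] <- df
  }
  if (length(per_res) == 0)
    return(data.frame(chrom = character(0), res = integer(0),
                      bin1 = integer(0), bin2 = integer(0),
                      start1 = numeric(0), end1 = numeric(0),
                      start2 = numeric(0), end2 = numeric(0),
                      obs = numeric(0), lambda_donut = numeric(0),
                      lambda_ll = numeric(0), lambda_h = numeric(0),
                      lambda_v = numeric(0), p = numeric(0), q = numeric(0)))
  # cross-resolution reconciliation: keep the finer call
  ord <- order(ress)
  merged <- per_res[[as.character(ress[ord[1]])]]
  if (length(per_res) > 1) {
    for (k in ord[-1]) {
      coarse <- per_res[[as.character(ress[k])]]
      if (is.null(coarse)) next
      md <- if (as.character(ress[k]) %in% names(merge_distances))
        merge_distances[[as.character(ress[k])]] else 2 * ress[k]
      keep <- rep(TRUE, nrow(coarse))
      for (m in seq_len(nrow(coarse))) {
        same <- merged$chrom == coarse$chrom[m]
        if (!any(same)) next
        c1 <- (coarse$start1[m] + coarse$end1[m]) / 2
        c2 <- (coarse$start2[m] + coarse$end2[m]) / 2
        f1 <- (merged$start1[same] + merged$end1[same]) / 2
        f2 <- (merged$start2[same] + merged$end2[same]) / 2
        if (any(abs(f1 - c1) <= md & abs(f2 - c2) <= md)) keep[m] <- FALSE
      }
      merged <- rbind(merged, coarse[keep, ])
    }
  }
  cols <- c("chrom", "res", "bin1", "bin2", "start1", "end1", "start2", "end2",
            "obs", "lambda_donut", "lambda_ll", "lambda_h", "lambda_v",
            "p", "q")
  merged <- merged[order(merged$chrom, merged$bin1, merged$bin2), cols]
  rownames(merged) <- NULL
  merged
}

#' Aggregate peak analysis
#'
#' Element-wise sum of observed/expected submatrices centered on each loop,
#' normalized by the number of contributing loops. Loops closer to the
#' diagonal than `flank + 2` bins are excluded. The center score is the
#' center pixel divided by the mean of the four 3x3 corner blocks.
#'
#' @param cm a `contact_matrix` at the loops' resolution.
#' @param loops loop data.frame with `chrom, bin1, bin2` (0-based bins).
#' @param flank half-width of the aggregate window in bins (default 10).
#' @return object of class `apa_result`: list with `matrix`
#'   ((2*flank+1)^2 aggregate), `n_loops`, `center_score`.
#' @export
apa <- function(cm, loops, flank = 10L) {
  f <- as.integer(flank)
  agg <- matrix(0, 2 * f + 1, 2 * f + 1)
  n_used <- 0L
  for (ch in unique(loops$chrom)) {
    M <- as.matrix(cis_matrix(cm, ch))
    prof <- expected_by_distance(cm, ch, balanced = FALSE)
    emin <- min(prof$mean[prof$mean > 0], na.rm = TRUE)
    n <- nrow(M)
    sub <- loops[loops$chrom == ch, ]
    for (k in seq_len(nrow(sub))) {
      i <- sub$bin1[k] + 1L; j <- sub$bin2[k] + 1L
      if (j - i < f + 2L) next                       # too close to diagonal
      if (i - f < 1 || j + f > n || i + f >= j - f) next
      ri <- (i - f):(i + f); rj <- (j - f):(j + f)
      D <- abs(outer(ri, rj, "-"))
      E <- matrix(prof$mean[D + 1], 2 * f + 1)
      E[is.na(E) | E <= 0] <- emin
      agg <- agg + M[ri, rj] / E
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) stop("degenerate input: no eligible loops for APA")
  agg <- agg / n_used
  c0 <- f + 1L
  corner <- function(ri, rj) mean(agg[ri, rj])
  corners <- c(corner(1:3, 1:3), corner(1:3, (2 * f - 1):(2 * f + 1)),
               corner((2 * f - 1):(2 * f + 1), 1:3),
               corner((2 * f - 1):(2 * f + 1), (2 * f - 1):(2 * f + 1)))
  structure(list(matrix = agg, n_loops = n_used,
                 center_score = agg[c0, c0] / mean(corners)),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat("apa_result:", x$n_loops, "loops; center score",
      round(x$center_score, 3), "\n")
  invisible(x)
}

#' Distance-stratified differential loops
#'
#' Quantifies each loop in every sample as the cis-depth-normalized sum over
#' the 3x3 neighborhood of its anchor pixel, then tests the two groups with
#' a Welch t-test on log2(x + 1), BH-corrected within each distance stratum
#' (short: < `split`; long: > `split`, by anchor midpoint separation).
#'
#' @param loops loop data.frame (`chrom, res, bin1, bin2, start1, end1,
#'   start2, end2`): the union of loops called in any condition.
#' @param cms named list of per-sample `contact_matrix` at the loop
#'   resolution.
#' @param groups named character vector sample -> group (two groups; the
#'   second is the "enhanced" direction).
#' @param split distance split in bp (default 150,000).
#' @param fdr FDR threshold within stratum (default 0.1).
#' @param target depth-normalization target (default 1e6 cis contacts).
#' @return the loop data.frame with added `stratum, log2fc, p, fdr, flagged,
#'   direction` plus per-sample quantification columns `q_<sample>`.
#' @export
differential_loops <- function(loops, cms, groups, split = 150000, fdr = 0.1,
                               target = 1e6) {
  gl <- unique(groups)
  stopifnot(length(gl) == 2)
  if (any(table(factor(groups, levels = gl)) < 2))
    stop("need >= 2 samples per group")
  quant <- sapply(names(cms), function(s) {
    cm <- cms[[s]]
    f <- target / cm$cis_total
    vapply(seq_len(nrow(loops)), function(k) {
      M <- cm$mats[[loops$chrom[k]]]
      if (is.null(M)) return(0)
      n <- nrow(M)
      ri <- pmax(1, loops$bin1[k]):pmin(n, loops$bin1[k] + 2L)
      rj <- pmax(1, loops$bin2[k]):pmin(n, loops$bin2[k] + 2L)
      sum(M[ri, rj]) * f
    }, numeric(1))
  })
  quant <- matrix(quant, nrow = nrow(loops), dimnames = list(NULL, names(cms)))
  sep <- abs((loops$start2 + loops$end2) / 2 - (loops$start1 + loops$end1) / 2)
  stratum <- ifelse(sep < split, "short", "long")
  g1 <- names(groups)[groups == gl[1]]
  g2 <- names(groups)[groups == gl[2]]
  lx <- log2(quant + 1)
  stat <- t(apply(lx, 1, function(v) {
    a <- v[g1]; b <- v[g2]
    p <- if (stats::sd(a) > 0 || stats::sd(b) > 0)
      tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1) else 1
    c(mean(b) - mean(a), p)
  }))
  qv <- rep(NA_real_, nrow(loops))
  for (st in unique(stratum)) {
    sel <- stratum == st
    qv[sel] <- stats::p.adjust(stat[sel, 2], method = "BH")
  }
  out <- loops
  out$stratum <- stratum
  out$log2fc <- stat[, 1]
  out$p <- stat[, 2]
  out$fdr <- qv
  out$flagged <- qv < fdr
  out$direction <- ifelse(stat[, 1] > 0, "enhanced", "reduced")
  for (s in colnames(quant)) out[[paste0("q_", s)]] <- quant[, s]
  out
}

#' Classify loop anchors by CTCF motif orientation
#'
#' For each anchor the highest-scoring motif within `anchor_pad` of the
#' anchor interval is selected; the loop class is convergent (upstream
#' anchor '+', downstream '-'), tandem (same strand), divergent ('-','+'),
#' single-anchor (motif at one anchor) or none. For anchors inside inverted
#' rearrangement fragments, pass `flip1`/`flip2` columns so motif strands are
#' flipped to the native orientation before classification.
#'
#' @param loops data.frame with anchor intervals `chrom1, start1, end1,
#'   chrom2, start2, end2` (or a single `chrom` column for cis loops) and
#'   optional logical `flip1`, `flip2` columns.
#' @param motifs data.frame `chrom, pos, strand, score`.
#' @param anchor_pad bp added on both sides of each anchor (default 0).
#' @return list with `classes` (per-loop data.frame `class, strand1,
#'   strand2`) and `summary` (class fractions over both-anchor-motif loops,
#'   plus `frac_convergent_all` over all loops).
#' @export
classify_ctcf_orientation <- function(loops, motifs, anchor_pad = 0) {
  if (is.null(motifs$strand) || any(!motifs$strand %in% c("+", "-")))
    stop("motifs must carry strand (+/-)")
  if (is.null(motifs$score)) motifs$score <- 1
  if (is.null(loops$chrom1)) {
    loops$chrom1 <- loops$chrom
    loops$chrom2 <- loops$chrom
  }
  best_motif <- function(chrom, start, end) {
    m <- motifs[motifs$chrom == chrom & motifs$pos >= start - anchor_pad &
                  motifs$pos <= end + anchor_pad, ]
    if (nrow(m) == 0) return(NA_character_)
    m$strand[which.max(m$score)]
  }
  s1 <- s2 <- character(nrow(loops))
  for (k in seq_len(nrow(loops))) {
    s1[k] <- best_motif(loops$chrom1[k], loops$start1[k], loops$end1[k])
    s2[k] <- best_motif(loops$chrom2[k], loops$start2[k], loops$end2[k])
    if (isTRUE(loops$flip1[k]) && !is.na(s1[k]))
      s1[k] <- if (s1[k] == "+") "-" else "+"
    if (isTRUE(loops$flip2[k]) && !is.na(s2[k]))
      s2[k] <- if (s2[k] == "+") "-" else "+"
  }
  cls <- ifelse(is.na(s1) & is.na(s2), "none",
         ifelse(is.na(s1) | is.na(s2), "single-anchor",
         ifelse(s1 == "+" & s2 == "-", "convergent",
         ifelse(s1 == "-" & s2 == "+", "divergent", "tandem"))))
  both <- !is.na(s1) & !is.na(s2)
  summ <- if (any(both)) {
    tab <- table(factor(cls[both],
                        levels = c("convergent", "tandem", "divergent")))
    as.list(tab / sum(both))
  } else list(convergent = NA_real_, tandem = NA_real_, divergent = NA_real_)
  summ$n_both <- sum(both)
  summ$frac_convergent_all <- mean(cls == "convergent")
  list(classes = data.frame(class = cls, strand1 = s1, strand2 = s2,
                            stringsAsFactors = FALSE),
       summary = summ)
}
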