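#' A/B compartment eigenvector track
#'
#' First eigenvector of the Pearson-correlation matrix of the
#' observed/expected cis matrix, computed per chromosome (100-kb resolution
#' by convention). The eigenvector sign is oriented so that its correlation
#' with a supplied per-bin activity proxy (e.g. gene density) is positive;
#' positive values are labeled A, negative B.
#'
#' @param cm a balanced `contact_matrix` (100-kb bins by convention).
#' @param chrom chromosome name.
#' @param reference_track numeric per-bin activity proxy covering the
#'   chromosome (length = bin count).
#' @return data.frame `bin, value, label` of class `compartment_track` with
#'   attributes `chrom` and `binsize`; masked bins have `NA` value and label
#'   `"masked"`.
#' @export
compartment_track <- function(cm, chrom, reference_track) {
  M <- as.matrix(cis_matrix(cm, chrom, balanced = !is.null(cm$weights[[chrom]])))
  n <- nrow(M)
  if (length(reference_track) != n)
    stop("reference_track must cover the chromosome (", n, " bins)")
  marg <- rowSums(M)
  masked <- marg == 0
  if (!is.null(cm$weights[[chrom]])) masked <- masked | is.na(cm$weights[[chrom]])
  keep <- which(!masked)
  if (length(keep) < 10) stop("degenerate input: fewer than 10 unmasked bins")
  prof <- expected_by_distance(cm, chrom)
  Msub <- M[keep, keep, drop = FALSE]
  D <- abs(outer(keep, keep, "-"))
  E <- matrix(prof$mean[D + 1], nrow(Msub))
  OE <- Msub / E
  OE[!is.finite(OE)] <- NA
  sds <- apply(OE, 2, stats::sd, na.rm = TRUE)
  if (all(!is.finite(sds) | sds == 0))
    stop("degenerate input: observed/expected has no variance")
  ok <- which(is.finite(sds) & sds > 0)
  C <- suppressWarnings(stats::cor(OE[ok, ok, drop = FALSE],
                                   use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- 0
  ev <- eigen(C, symmetric = TRUE)$vectors[, 1]
  ref <- reference_track[keep][ok]
  s <- suppressWarnings(stats::cor(ev, ref))
  if (is.finite(s) && s < 0) ev <- -ev
  value <- rep(NA_real_, n)
  value[keep[ok]] <- ev
  label <- ifelse(is.na(value), "masked", ifelse(value > 0, "A", "B"))
  structure(data.frame(bin = 0:(n - 1), value = value, label = label,
                       stringsAsFactors = FALSE),
            class = c("compartment_track", "data.frame"),
            chrom = chrom, binsize = cm$binsize)
}

#' Consensus compartments and A/B switches between two groups
#'
#' Per-bin group labels by the strict majority rule: a bin is A (or B) only
#' when the fraction of the group's samples carrying that label strictly
#' exceeds `majority`; otherwise "other". Bins masked in at least half of a
#' group's samples are dropped. The switch table lists bins whose consensus
#' differs between the two groups, excluding bins labeled "other" in either.
#'
#' @param tracks_by_group named list of two groups, each a list of
#'   `compartment_track` objects on the same bin grid.
#' @param majority strict majority threshold (default 0.7, i.e. "over 70%").
#' @return list with `consensus` (data.frame `bin, <group1>, <group2>,
#'   frac_<group>`) and `switches` (data.frame `bin, from, to, type`).
#' @export
consensus_and_switches <- function(tracks_by_group, majority = 0.7) {
  stopifnot(length(tracks_by_group) == 2)
  gnames <- names(tracks_by_group)
  nb <- unique(unlist(lapply(tracks_by_group, function(g)
    vapply(g, nrow, integer(1)))))
  if (length(nb) != 1) stop("mismatched bin grids across tracks")
  if (any(vapply(tracks_by_group, length, integer(1)) < 2))
    stop("need >= 2 samples per group")
  cons <- lapply(tracks_by_group, function(g) {
    labs <- matrix(vapply(g, function(t) t$label, character(nb)),
                   nrow = nb)                    # bins x samples
    fa <- rowMeans(labs == "A")
    fb <- rowMeans(labs == "B")
    fm <- rowMeans(labs == "masked")
    lab <- ifelse(fm >= 0.5, "masked",
                  ifelse(fa > majority, "A", ifelse(fb > majority, "B", "other")))
    list(label = lab, frac = pmax(fa, fb))
  })
  consensus <- data.frame(bin = 0:(nb - 1),
                          g1 = cons[[1]]$label, g2 = cons[[2]]$label,
                          frac1 = cons[[1]]$frac, frac2 = cons[[2]]$frac,
                          stringsAsFactors = FALSE)
  names(consensus)[2:5] <- c(gnames, paste0("frac_", gnames))
  ab <- consensus[[gnames[1]]] %in% c("A", "B") &
        consensus[[gnames[2]]] %in% c("A", "B")
  sw <- consensus[ab & consensus[[gnames[1]]] != consensus[[gnames[2]]], ]
  switches <- data.frame(bin = sw$bin, from = sw[[gnames[1]]],
                         to = sw[[gnames[2]]],
                         type = if (nrow(sw) > 0)
                           paste0(sw[[gnames[1]]], "-to-", sw[[gnames[2]]])
                         else character(0),
                         stringsAsFactors = FALSE)
  rownames(switches) <- NULL
  list(consensus = consensus, switches = switches)
}
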