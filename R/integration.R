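#' Virtual 4C profiles
#'
#' Per-sample profile = the viewpoint bin's row of the depth-normalized cis
#' matrix (10-kb resolution by convention); group profiles are sample means
#' and a group-difference track (group2 - group1) is returned when groups
#' are supplied.
#'
#' @param cms named list of per-sample `contact_matrix` (depth-normalized)
#'   or a single matrix.
#' @param chrom viewpoint chromosome.
#' @param viewpoint 1-based bp position of the viewpoint.
#' @param groups optional named character vector sample -> group (two
#'   groups).
#' @return list with `profiles` (bins x samples matrix), `viewpoint_bin`,
#'   and, when groups are given, `group_means` and `difference`
#'   (group2 mean - group1 mean).
#' @export
virtual_4c <- function(cms, chrom, viewpoint, groups = NULL) {
  if (inherits(cms, "contact_matrix")) cms <- list(sample = cms)
  vb <- pos_to_bin(viewpoint, cms[[1]]$binsize)
  profiles <- sapply(cms, function(cm) {
    M <- cis_matrix(cm, chrom)
    row <- as.numeric(M[vb + 1L, ])
    if (sum(row) == 0) stop("degenerate input: viewpoint bin is masked")
    row
  })
  profiles <- matrix(profiles, ncol = length(cms),
                     dimnames = list(NULL, names(cms)))
  out <- list(profiles = profiles, viewpoint_bin = vb)
  if (!is.null(groups)) {
    gl <- unique(groups)
    stopifnot(length(gl) == 2)
    gm <- sapply(gl, function(g)
      rowMeans(profiles[, names(groups)[groups == g], drop = FALSE]))
    out$group_means <- gm
    out$difference <- gm[, 2] - gm[, 1]
  }
  out
}

#' Quantify interaction of named regions with a viewpoint
#'
#' Per sample and region: the mean V4C profile value over the region's bins;
#' per region: group means, a two-sided Welch t-test and BH FDR over
#' regions.
#'
#' @param profiles bins x samples profile matrix (from [virtual_4c()]).
#' @param regions data.frame `name, start, end` (bp, on the viewpoint
#'   chromosome).
#' @param groups named character vector sample -> group (two groups).
#' @param binsize profile bin size in bp.
#' @return data.frame `name, mean_<g1>, mean_<g2>, log2fc, p, fdr` plus
#'   per-sample score columns.
#' @export
quantify_region_interactions <- function(profiles, regions, groups, binsize) {
  gl <- unique(groups)
  stopifnot(length(gl) == 2)
  scores <- t(vapply(seq_len(nrow(regions)), function(k) {
    b1 <- pos_to_bin(regions$start[k], binsize) + 1L
    b2 <- min(pos_to_bin(regions$end[k], binsize) + 1L, nrow(profiles))
    colMeans(profiles[b1:b2, , drop = FALSE])
  }, numeric(ncol(profiles))))
  g1 <- names(groups)[groups == gl[1]]
  g2 <- names(groups)[groups == gl[2]]
  stat <- t(apply(scores, 1, function(v) {
    a <- v[g1]; b <- v[g2]
    p <- if (stats::sd(a) > 0 || stats::sd(b) > 0)
      tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1) else 1
    c(mean(a), mean(b), p)
  }))
  out <- data.frame(name = regions$name, m1 = stat[, 1], m2 = stat[, 2],
                    log2fc = log2((stat[, 2] + 1e-9) / (stat[, 1] + 1e-9)),
                    p = stat[, 3],
                    fdr = stats::p.adjust(stat[, 3], method = "BH"),
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mean_", gl)
  cbind(out, as.data.frame(scores))
}

#' Combine structural p-values and correlate with expression
#'
#' Per gene, the D-score and loop-strength-change p-values are combined by
#' Fisher's method (chi-square with 2k degrees of freedom; a missing
#' component passes the other through). The signed structural score is
#' `-log10(combined p)` times the sign of the dominant (smaller-p)
#' component's direction; its Pearson correlation with the expression log
#' fold change is reported.
#'
#' @param dscore_p,loop_p numeric per-gene p-values (NA = missing).
#' @param dscore_sign,loop_sign per-gene direction signs (+1 increase /
#'   -1 decrease; default +1).
#' @param expression_lfc per-gene expression log2 fold change (optional;
#'   needed for the correlation).
#' @param method `"fisher"` (default) or `"stouffer"`.
#' @return list with `table` (data.frame `combined_p, signed_score`) and
#'   `pearson_r` (NA without expression input).
#' @export
combined_structural_p <- function(dscore_p, loop_p,
                                  dscore_sign = NULL, loop_sign = NULL,
                                  expression_lfc = NULL,
                                  method = c("fisher", "stouffer")) {
  method <- match.arg(method)
  n <- max(length(dscore_p), length(loop_p))
  pm <- cbind(rep_len(dscore_p, n), rep_len(loop_p, n))
  if (any(pm <= 0 | pm > 1, na.rm = TRUE)) stop("p-values must be in (0, 1]")
  if (is.null(dscore_sign)) dscore_sign <- rep(1, n)
  if (is.null(loop_sign)) loop_sign <- rep(1, n)
  sm <- cbind(rep_len(dscore_sign, n), rep_len(loop_sign, n))
  comb <- vapply(seq_len(n), function(k) {
    p <- pm[k, ]; ok <- !is.na(p)
    if (!any(ok)) return(NA_real_)
    if (sum(ok) == 1) return(p[ok])
    if (method == "fisher") {
      stats::pchisq(-2 * sum(log(p[ok])), df = 2 * sum(ok),
                    lower.tail = FALSE)
    } else {
      z <- sum(stats::qnorm(p[ok] / 2, lower.tail = FALSE) * sm[k, ok]) /
        sqrt(sum(ok))
      2 * stats::pnorm(abs(z), lower.tail = FALSE)
    }
  }, numeric(1))
  dominant <- ifelse(is.na(pm[, 1]), sm[, 2],
               ifelse(is.na(pm[, 2]), sm[, 1],
               ifelse(pm[, 2] < pm[, 1], sm[, 2], sm[, 1])))
  signed <- -log10(pmax(comb, 1e-300)) * dominant
  r <- if (!is.null(expression_lfc))
    suppressWarnings(stats::cor(signed, expression_lfc,
                                use = "complete.obs")) else NA_real_
  list(table = data.frame(combined_p = comb, signed_score = signed),
       pearson_r = r)
}

#' Differential-expression statistics for a synthetic cohort
#'
#' Moment log2 fold change plus a Welch t-test on log2(count + 1) with BH
#' correction: a stand-in DE table generator for simulated expression data
#' (real cohorts supply DE statistics from a dedicated caller).
#'
#' @param expr list from [simulate_expression()] (`counts`, `samples`).
#' @return data.frame `gene, logFC, p, fdr, mean_control, mean_case`.
#' @export
de_table <- function(expr) {
  ctrl <- expr$samples$sample[expr$samples$group == "control"]
  case <- expr$samples$sample[expr$samples$group == "case"]
  cc <- expr$counts
  lx <- log2(cc + 1)
  p <- apply(lx, 1, function(v) {
    a <- v[ctrl]; b <- v[case]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
    tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
  })
  mc <- rowMeans(cc[, ctrl, drop = FALSE])
  mk <- rowMeans(cc[, case, drop = FALSE])
  data.frame(gene = rownames(cc), logFC = log2((mk + 0.5) / (mc + 0.5)),
             p = p, fdr = stats::p.adjust(p, method = "BH"),
             mean_control = mc, mean_case = mk, stringsAsFactors = FALSE)
}

#' Associate differentially expressed genes with structural changes
#'
#' Applies the read filters (a gene is excluded if more than
#' `read_filter_frac` of samples have fewer than `read_filter_min` reads, or
#' its mean count is below 2) and DE thresholds (FDR < 0.01, |fold change| >
#' 2), assigns each gene its overlapping structural events (gene-body bin
#' overlap for compartment switches and differential boundaries,
#' TSS-containing TAD for D-scores, promoter TSS+/-5 kb anchor overlap for
#' loops), and tests each structural class with a one-sided Wilcoxon
#' rank-sum test of member log fold changes against structurally stable
#' genes (direction: B-to-A / increased / enhanced -> up).
#'
#' @param de DE table (`gene, logFC, fdr`) from [de_table()] or external.
#' @param counts genes x samples count matrix (for the read filters).
#' @param genome a `genome_model` with gene catalog.
#' @param binsize bin size of the structural bin coordinates below.
#' @param switches switch table (`bin, type`) from
#'   [consensus_and_switches()], single chromosome, or with a `chrom`
#'   column.
#' @param boundary_table flagged boundary table from
#'   [differential_boundaries()] (needs `bin, flagged`, optional `chrom`,
#'   `diff`).
#' @param tads TAD data.frame aligned with `dscore_table` rows.
#' @param dscore_table flagged TAD table from
#'   [differential_domain_scores()].
#' @param loop_table differential loop table from [differential_loops()].
#' @param chrom default chromosome for bin-coordinate tables lacking a
#'   `chrom` column.
#' @param promoter_pad promoter half-window around the TSS (default 5,000).
#' @param de_fdr,de_fc DE thresholds (defaults 0.01 and 2).
#' @param read_filter_min,read_filter_frac read-filter parameters (defaults
#'   5 reads, 0.2).
#' @return list with `genes` (per-gene association table) and `class_tests`
#'   (per structural class: n, one-sided Wilcoxon p, direction tested).
#' @export
associate_degs <- function(de, counts, genome, binsize,
                           switches = NULL, boundary_table = NULL,
                           tads = NULL, dscore_table = NULL,
                           loop_table = NULL, chrom = NULL,
                           promoter_pad = 5000, de_fdr = 0.01, de_fc = 2,
                           read_filter_min = 5, read_filter_frac = 0.2) {
  genes <- genome$genes
  miss <- setdiff(rownames(counts), genes$gene)
  if (length(miss) > 0)
    stop("gene universe mismatch; missing from catalog: ",
         paste(utils::head(miss, 5), collapse = ", "))
  low <- rowMeans(counts < read_filter_min) > read_filter_frac |
    rowMeans(counts) < 2
  keep <- rownames(counts)[!low]
  tab <- merge(data.frame(gene = keep, stringsAsFactors = FALSE), de,
               by = "gene")
  tab <- merge(tab, genes[, c("gene", "chrom", "start", "end", "strand")],
               by = "gene")
  tab$de <- tab$fdr < de_fdr & abs(tab$logFC) > log2(de_fc)
  tab$tss <- ifelse(tab$strand == "-", tab$end, tab$start)
  chrom_of <- function(x) if (!is.null(x$chrom)) x$chrom else chrom
  # compartment switches: gene body overlapping a switch bin (majority type)
  tab$switch <- NA_character_
  if (!is.null(switches) && nrow(switches) > 0) {
    sch <- chrom_of(switches)
    for (k in seq_len(nrow(tab))) {
      gb <- pos_to_bin(tab$start[k], binsize):pos_to_bin(tab$end[k], binsize)
      hit <- switches$type[switches$bin %in% gb & sch == tab$chrom[k]]
      if (length(hit) > 0)
        tab$switch[k] <- names(sort(table(hit), decreasing = TRUE))[1]
    }
  }
  # differential boundaries: gene body overlapping a flagged boundary bin
  tab$boundary <- NA_character_
  if (!is.null(boundary_table) && any(boundary_table$flagged)) {
    bt <- boundary_table[boundary_table$flagged, ]
    bch <- chrom_of(bt)
    for (k in seq_len(nrow(tab))) {
      gb <- pos_to_bin(tab$start[k], binsize):pos_to_bin(tab$end[k], binsize)
      hit <- bt$bin %in% gb & bch == tab$chrom[k]
      if (any(hit))
        tab$boundary[k] <- if (!is.null(bt$diff) && mean(bt$diff[hit]) < 0)
          "gained" else "changed"
    }
  }
  # D-scores: TSS-containing TAD
  tab$dscore <- NA_character_
  if (!is.null(dscore_table) && any(dscore_table$flagged)) {
    sel <- which(dscore_table$flagged)
    for (s in sel) {
      td <- tads[s, ]
      hit <- tab$chrom == td$chrom &
        pos_to_bin(tab$tss, binsize) >= td$start_bin &
        pos_to_bin(tab$tss, binsize) <= td$end_bin
      tab$dscore[hit] <- dscore_table$direction[s]
    }
  }
  # loops: promoter window overlapping a flagged loop anchor
  tab$loop <- NA_character_
  if (!is.null(loop_table) && any(loop_table$flagged)) {
    lt <- loop_table[loop_table$flagged, ]
    for (k in seq_len(nrow(tab))) {
      pw <- c(tab$tss[k] - promoter_pad, tab$tss[k] + promoter_pad)
      hit <- lt$chrom == tab$chrom[k] &
        ((lt$start1 <= pw[2] & lt$end1 >= pw[1]) |
           (lt$start2 <= pw[2] & lt$end2 >= pw[1]))
      if (any(hit))
        tab$loop[k] <- names(sort(table(lt$direction[hit]),
                                  decreasing = TRUE))[1]
    }
  }
  up_classes <- c("B-to-A", "increased", "enhanced", "gained")
  layers <- list(switch = "switch", boundary = "boundary",
                 dscore = "dscore", loop = "loop")
  tests <- list()
  for (ly in names(layers)) {
    vals <- tab[[ly]]
    stable <- tab$logFC[is.na(vals)]
    for (cl in unique(stats::na.omit(vals))) {
      member <- tab$logFC[!is.na(vals) & vals == cl]
      if (length(member) < 2 || length(stable) < 2) next
      dir_up <- cl %in% up_classes
      p <- stats::wilcox.test(member, stable,
                              alternative = if (dir_up) "greater" else "less",
                              exact = FALSE)$p.value
      tests[[length(tests) + 1]] <- data.frame(
        layer = ly, class = cl, n = length(member),
        direction = if (dir_up) "up" else "down", p = p,
        stringsAsFactors = FALSE)
    }
  }
  class_tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(layer = character(0), class = character(0), n = integer(0),
               direction = character(0), p = numeric(0))
  list(genes = tab, class_tests = class_tests)
}
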