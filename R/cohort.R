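#' Simulate a multi-sample Hi-C cohort with planted truth
#'
#' Generates per-sample contact maps (and chimeric reads for samples
#' carrying rearrangements), writes all pipeline inputs to disk, and emits a
#' truth file describing the planted structures. Structure placement is
#' config-driven (identical across seeds); only the count sampling depends
#' on the seed, through per-sample streams derived from the root seed.
#'
#' @param config cohort configuration list with fields:
#'   \describe{
#'     \item{chrom_lengths}{named chromosome lengths (bp).}
#'     \item{sim_binsize}{simulation bin size (default 10,000).}
#'     \item{cis_depth}{expected cis contacts per sample.}
#'     \item{groups}{named integer vector of group sizes (>= 2 groups with
#'       >= 2 samples each).}
#'     \item{specs}{named list group -> `structure_spec`.}
#'     \item{events}{optional named list group -> list of
#'       `rearrangement_spec` (applied to every sample of the group).}
#'     \item{genes,motifs}{optional catalogs (see [genome_model()]).}
#'     \item{expression}{optional list `coupling` (gene -> planted log2 FC
#'       in the second group), `dispersion`, `base_mean_log`.}
#'   }
#' @param seed root integer seed.
#' @param out_dir output directory (created; must be writable).
#' @return list with `dir`, `samples` (sample/group/path table), `genome`,
#'   and `truth` (planted structures and group-differential sets).
#' @export
simulate_cohort <- function(config, seed, out_dir) {
  config$specs <- lapply(config$specs, .as_structure_spec)
  if (!is.null(config$events))
    config$events <- lapply(config$events, function(evs) {
      if (is.data.frame(evs))   # parsed JSON collapses event lists to rows
        evs <- lapply(seq_len(nrow(evs)), function(k) {
          e <- as.list(evs[k, ])
          e$neo_loops <- if (is.list(e$neo_loops)) e$neo_loops[[1]] else NULL
          e
        })
      lapply(evs, .as_rearrangement_spec)
    })
  if (!is.null(config$chrom_lengths)) config$chrom_lengths <- unlist(config$chrom_lengths)
  if (!is.null(config$groups)) config$groups <- unlist(config$groups)
  if (!is.null(config$expression$coupling))
    config$expression$coupling <- unlist(config$expression$coupling)
  groups <- config$groups
  if (length(groups) < 2 || any(groups < 2))
    stop("config must name >= 2 groups with >= 2 samples each")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  sim_binsize <- if (is.null(config$sim_binsize)) 10000 else config$sim_binsize
  genome <- genome_model(config$chrom_lengths, genes = config$genes,
                         motifs = config$motifs)
  samples <- do.call(rbind, lapply(names(groups), function(g)
    data.frame(sample = sprintf("%s%02d", g, seq_len(groups[[g]])),
               group = g, stringsAsFactors = FALSE)))
  samples$pairs <- file.path(out_dir, paste0(samples$sample, ".pairs"))
  samples$chimeric <- file.path(out_dir, paste0(samples$sample, ".chimeric.tsv"))
  for (k in seq_len(nrow(samples))) {
    g <- samples$group[k]
    sseed <- (as.integer(seed) %% 100000L) * 10000L + k * 13L
    rec <- simulate_contact_map(genome, config$specs[[g]], config$cis_depth,
                                seed = sseed, binsize = sim_binsize)
    reads <- NULL
    evs <- config$events[[g]]
    if (!is.null(evs)) {
      for (e in seq_along(evs)) {
        pl <- plant_rearrangement(rec, genome, evs[[e]], seed = sseed + e)
        rec <- pl$contacts
        reads <- rbind(reads, pl$reads)
      }
    }
    write_pairs(rec, samples$pairs[k], genome, binsize = sim_binsize)
    if (is.null(reads))
      reads <- data.frame(read_id = character(0), chrom1 = character(0),
                          pos1 = integer(0), strand1 = character(0),
                          chrom2 = character(0), pos2 = integer(0),
                          strand2 = character(0), linker = integer(0))
    write_chimeric(reads, samples$chimeric[k])
  }
  expr <- NULL
  if (!is.null(config$expression) && !is.null(genome$genes)) {
    ex <- config$expression
    n_expr <- min(groups)
    expr <- simulate_expression(
      genome, coupling = if (is.null(ex$coupling)) numeric(0) else ex$coupling,
      n_per_group = n_expr,
      dispersion = if (is.null(ex$dispersion)) 0.1 else ex$dispersion,
      seed = (as.integer(seed) %% 100000L) * 10000L + 999L,
      base_mean_log = if (is.null(ex$base_mean_log)) log(100) else
        ex$base_mean_log)
    utils::write.table(expr$counts, file.path(out_dir, "counts.tsv"),
                       quote = FALSE, sep = "\t")
    utils::write.table(round(expr$fpkm, 4),
                       file.path(out_dir, "expression.tsv"),
                       quote = FALSE, sep = "\t")
  }
  if (!is.null(genome$genes))
    write_genes_tsv(genome$genes, file.path(out_dir, "genes.tsv"))
  if (!is.null(genome$motifs))
    write_motifs_bed(genome$motifs, file.path(out_dir, "motifs.bed"))
  truth <- .cohort_truth(config, genome)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  list(dir = out_dir, samples = samples, genome = genome, truth = truth,
       expression = expr)
}

# config-driven truth bookkeeping: per-group structures plus differential
# sets between the first (reference) and second group
.cohort_truth <- function(config, genome) {
  gl <- names(config$groups)
  edges <- lapply(gl, function(g) {
    tt <- config$specs[[g]]$tads
    if (is.null(tt)) return(list())
    lapply(split(tt, tt$chrom), function(x) sort(unique(c(x$start, x$end))))
  })
  names(edges) <- gl
  truth <- list(groups = as.list(config$groups),
                tad_edges = edges,
                specs = lapply(config$specs, unclass),
                events = lapply(config$events, function(evs)
                  lapply(evs, unclass)))
  if (length(gl) >= 2) {
    g1 <- gl[1]; g2 <- gl[2]
    diff_edges <- list()
    chroms <- union(names(edges[[g1]]), names(edges[[g2]]))
    for (ch in chroms) {
      e1 <- edges[[g1]][[ch]]; e2 <- edges[[g2]][[ch]]
      extra <- setdiff(e2, e1)
      if (length(extra)) diff_edges[[ch]] <- extra
    }
    truth$differential_boundaries <- diff_edges
    l1 <- config$specs[[g1]]$loops; l2 <- config$specs[[g2]]$loops
    if (!is.null(l1) && !is.null(l2)) {
      m <- merge(l1, l2, by = c("chrom", "pos1", "pos2"),
                 suffixes = c("_1", "_2"))
      truth$loop_gains <- m[m$enrich_2 > m$enrich_1, ]
      truth$loop_stable <- m[m$enrich_2 == m$enrich_1, ]
    }
    c1 <- config$specs[[g1]]$compartments; c2 <- config$specs[[g2]]$compartments
    if (!is.null(c1) && !is.null(c2)) {
      m <- merge(c1, c2, by = c("chrom", "start", "end"),
                 suffixes = c("_1", "_2"))
      truth$compartment_flips <- m[m$label_1 != m$label_2, ]
    }
    tt1 <- config$specs[[g1]]$tads; tt2 <- config$specs[[g2]]$tads
    if (!is.null(tt1) && !is.null(tt2)) {
      m <- merge(tt1, tt2, by = c("chrom", "start", "end"),
                 suffixes = c("_1", "_2"))
      truth$dscore_changes <- m[m$enrich_1 != m$enrich_2, ]
      truth$dscore_stable <- m[m$enrich_1 == m$enrich_2, ]
    }
    if (!is.null(config$expression$coupling))
      truth$expression_coupling <- as.list(config$expression$coupling)
  }
  truth
}

# coerce plain lists (e.g. parsed JSON) to spec objects
.as_structure_spec <- function(x) {
  if (inherits(x, "structure_spec")) return(x)
  do.call(structure_spec, x[intersect(names(x),
    c("decay_exponent", "compartments", "compartment_strength", "tads",
      "loops"))])
}

.as_rearrangement_spec <- function(x) {
  if (inherits(x, "rearrangement_spec")) return(x)
  do.call(rearrangement_spec, x[intersect(names(x),
    c("type", "chromA", "bpA", "sideA", "chromB", "bpB", "sideB", "fraction",
      "neo_loops", "n_chimeric", "n_decoy"))])
}

#' Demonstration cohort configuration
#'
#' A small two-chromosome, two-group cohort exercising every pipeline stage:
#' compartment blocks with planted group flips, TADs with case-only
#' boundaries and D-score changes, focal loops with case-enhanced subsets, a
#' clonal case-group translocation carrying a planted neo-loop, CTCF motifs,
#' and expression coupled to the planted structural changes. Cis depth
#' follows the protocol's map resolution (~0.25 cis contacts per bp).
#'
#' @param n_per_group samples per group (default 4).
#' @return a cohort configuration list for [simulate_cohort()].
#' @export
demo_cohort_config <- function(n_per_group = 4) {
  len1 <- 1.6e7; len2 <- 1.2e7
  # chr1: compartments + TADs + loops; chr2: translocation partner
  blocks <- data.frame(chrom = "chr1",
                       start = seq(0, len1 - 1e6, by = 1e6) + 1,
                       end = seq(1e6, len1, by = 1e6),
                       label = rep(c("A", "B"), length.out = 16))
  blocks_case <- blocks
  blocks_case$label[c(3, 8)] <- ifelse(blocks$label[c(3, 8)] == "A", "B", "A")
  edges <- seq(1e6, 15e6, by = 2e6)
  tads <- data.frame(chrom = "chr1", start = utils::head(edges, -1),
                     end = edges[-1], enrich = 2)
  tads_case <- tads
  tads_case$enrich[2] <- 4                       # D-score gain
  mid5 <- round((tads$start[5] + tads$end[5]) / 2 / 4e4) * 4e4
  tads_case <- rbind(tads_case[-5, ],
                     data.frame(chrom = "chr1",
                                start = c(tads$start[5], mid5),
                                end = c(mid5, tads$end[5]), enrich = 2))
  loops <- data.frame(chrom = "chr1",
                      pos1 = c(2.05e6, 4.55e6, 7.05e6, 9.55e6, 12.05e6),
                      pos2 = c(2.45e6, 5.15e6, 7.35e6, 10.15e6, 12.55e6),
                      enrich = 6)
  loops_case <- loops
  loops_case$enrich[c(2, 4)] <- 12               # enhanced in case
  genes <- data.frame(gene = sprintf("gene%03d", 1:60),
                      chrom = rep(c("chr1", "chr2"), c(40, 20)),
                      start = c(seq(2e5, len1 - 4e5, length.out = 40),
                                seq(2e5, len2 - 4e5, length.out = 20)),
                      stringsAsFactors = FALSE)
  genes$start <- round(genes$start)
  genes$end <- genes$start + 2e4
  genes$strand <- "+"
  anchors <- sort(unique(c(loops$pos1, loops$pos2)))
  motifs <- data.frame(chrom = "chr1",
                       pos = c(anchors, seq(1e6, 15e6, by = 2.1e6)),
                       strand = c(rep(c("+", "-"), length.out = length(anchors)),
                                  rep("+", 7)),
                       score = 10)
  ev <- rearrangement_spec("translocation", "chr1", 6543210, "left",
                           "chr2", 4567890, "right", fraction = 1,
                           neo_loops = data.frame(posA = 6143210,
                                                  posB = 5067890,
                                                  enrich = 8),
                           n_chimeric = 6, n_decoy = 10)
  # couple expression to the planted flips (B->A up in case at block 3)
  flip_genes <- genes$gene[genes$chrom == "chr1" &
                             genes$start >= 2e6 & genes$end <= 3e6]
  coupling <- stats::setNames(rep(1.5, length(flip_genes)), flip_genes)
  list(chrom_lengths = c(chr1 = len1, chr2 = len2),
       sim_binsize = 10000,
       cis_depth = 0.25 * (len1 + len2),
       groups = stats::setNames(c(n_per_group, n_per_group),
                                c("control", "case")),
       specs = list(
         control = structure_spec(compartments = blocks,
                                  compartment_strength = 2, tads = tads,
                                  loops = loops),
         case = structure_spec(compartments = blocks_case,
                               compartment_strength = 2, tads = tads_case,
                               loops = loops_case)),
       events = list(case = list(ev)),
       genes = genes, motifs = motifs,
       expression = list(coupling = coupling, dispersion = 0.1))
}
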