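#' Run the full Hi-C alteration pipeline
#'
#' Orchestrates the stages end-to-end from one configuration: simulate (or
#' load) a cohort, bin and balance matrices, call compartments, domains and
#' loops with their group differentials, detect translocations and
#' neo-loops, and integrate structure with expression. Writes per-stage
#' outputs and a run manifest (parameters, seed, file checksums) under
#' `out_dir`; identical config + seed reproduce identical outputs.
#'
#' @param config configuration list (or path to a JSON file). Fields:
#'   `simulate` (a cohort config for [simulate_cohort()]) or `samples` (a
#'   data.frame with `sample, group, pairs, chimeric` paths plus
#'   `chrom_lengths`); optional per-stage parameters
#'   `binsize_domains` (40,000), `binsize_compartments` (100,000),
#'   `binsize_loops` (10,000), `loop_fdr` (0.1), `diff_fdr` (0.01),
#'   `sv_min_enrichment` (5), `neo_control_enrich` (2).
#' @param seed root integer seed.
#' @param out_dir output directory.
#' @return the run manifest (invisibly also written as
#'   `<out_dir>/manifest.json`), a list with per-stage summaries and output
#'   checksums.
#' @export
run_pipeline <- function(config, seed, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  par <- function(name, default)
    if (is.null(config[[name]])) default else config[[name]]
  bs_dom <- par("binsize_domains", 40000)
  bs_comp <- par("binsize_compartments", 100000)
  bs_loop <- par("binsize_loops", 10000)
  manifest <- list(seed = seed,
                   parameters = list(binsize_domains = bs_dom,
                                     binsize_compartments = bs_comp,
                                     binsize_loops = bs_loop),
                   stages = list())
  t0 <- proc.time()[["elapsed"]]
  stage_done <- function(name, info = list()) {
    manifest$stages[[name]] <<- c(list(elapsed_s = round(
      proc.time()[["elapsed"]] - t0, 2)), info)
  }

  # --- stage: inputs -------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- simulate_cohort(config$simulate, seed = seed,
                           out_dir = file.path(out_dir, "cohort"))
    samples <- sim$samples
    genome <- sim$genome
    expr <- sim$expression
    stage_done("simulate", list(n_samples = nrow(samples)))
  } else {
    samples <- config$samples
    genome <- genome_model(config$chrom_lengths, genes = config$genes,
                           motifs = config$motifs)
    expr <- NULL
    stage_done("load", list(n_samples = nrow(samples)))
  }
  gl <- unique(samples$group)
  if (length(gl) != 2) stop("pipeline expects exactly two groups")
  grp <- stats::setNames(samples$group, samples$sample)

  # --- stage: matrices -----------------------------------------------------
  recs <- lapply(seq_len(nrow(samples)), function(k) read_pairs(samples$pairs[k]))
  names(recs) <- samples$sample
  bin_all <- function(bs) lapply(recs, function(r) bin_contacts(r, genome, bs))
  cms_dom <- lapply(bin_all(bs_dom), kr_balance)
  cms_comp <- lapply(bin_all(bs_comp), kr_balance)
  cms_loop <- bin_all(bs_loop)
  stage_done("matrices", list(cis_totals = lapply(cms_dom, function(x)
    round(x$cis_total))))

  # --- stage: compartments -------------------------------------------------
  chroms <- names(genome$chrom_lengths)
  gene_density <- function(ch) {
    nb <- n_bins(genome, bs_comp)[[ch]]
    dens <- numeric(nb)
    if (!is.null(genome$genes)) {
      gg <- genome$genes[genome$genes$chrom == ch, ]
      for (k in seq_len(nrow(gg))) {
        b <- pos_to_bin(gg$start[k], bs_comp):pos_to_bin(gg$end[k], bs_comp)
        dens[b + 1] <- dens[b + 1] + 1
      }
    }
    dens
  }
  comp <- list()
  for (ch in chroms) {
    ref <- gene_density(ch)
    tracks <- lapply(cms_comp, function(cm)
      tryCatch(compartment_track(cm, ch, ref), error = function(e) NULL))
    ok <- !vapply(tracks, is.null, logical(1))
    if (sum(ok) < 4) next
    tg <- lapply(gl, function(g)
      tracks[names(which(ok & grp[names(tracks)] == g))])
    names(tg) <- gl
    if (any(vapply(tg, length, integer(1)) < 2)) next
    cs <- consensus_and_switches(tg)
    cs$switches$chrom <- if (nrow(cs$switches)) ch else character(0)
    comp[[ch]] <- cs
    write_bedgraph(tracks[ok][[1]]$value, ch, bs_comp,
                   file.path(out_dir, paste0("compartment_", ch, ".bedGraph")))
  }
  switches <- do.call(rbind, lapply(comp, function(x) x$switches))
  if (!is.null(switches) && nrow(switches) > 0)
    utils::write.table(switches, file.path(out_dir, "switches.tsv"),
                       quote = FALSE, sep = "\t", row.names = FALSE)
  stage_done("compartments",
             list(n_switches = if (is.null(switches)) 0 else nrow(switches)))

  # --- stage: domains ------------------------------------------------------
  pooled_group <- lapply(gl, function(g)
    pool_matrices(cms_dom[samples$sample[samples$group == g]]))
  names(pooled_group) <- gl
  pooled_all <- pool_matrices(cms_dom)
  all_tads <- list(); bnd_tables <- list(); ds_tables <- list()
  for (ch in chroms) {
    conds <- c(lapply(pooled_group, function(pm)
      boundaries(insulation_track(pm, ch, balanced = FALSE))),
      list(pooled = boundaries(insulation_track(pooled_all, ch,
                                                balanced = FALSE))))
    tads <- consensus_tads(conds, ch, min_conditions = 2)
    if (nrow(tads) == 0) next
    all_tads[[ch]] <- tads
    tr <- lapply(cms_dom, function(cm) insulation_track(cm, ch))
    merged <- merge_boundaries(conds)
    bt <- differential_boundaries(tr, grp, merged, fdr = par("diff_fdr", 0.01))
    bt$chrom <- ch
    bnd_tables[[ch]] <- bt
    sc <- domain_score_table(cms_dom, tads)
    ds <- differential_domain_scores(sc, grp, fdr = par("diff_fdr", 0.01))
    ds$chrom <- ch
    ds_tables[[ch]] <- cbind(tads, ds[, setdiff(names(ds), "chrom")])
  }
  tads_df <- do.call(rbind, all_tads)
  bnd_df <- do.call(rbind, bnd_tables)
  ds_df <- do.call(rbind, ds_tables)
  for (nm in c("tads_df", "bnd_df", "ds_df")) {
    obj <- get(nm)
    if (!is.null(obj))
      utils::write.table(obj, file.path(out_dir, paste0(sub("_df", "", nm),
                                                        ".tsv")),
                         quote = FALSE, sep = "\t", row.names = FALSE)
  }
  stage_done("domains", list(
    n_tads = if (is.null(tads_df)) 0 else nrow(tads_df),
    n_diff_boundaries = if (is.null(bnd_df)) 0 else sum(bnd_df$flagged),
    n_diff_dscores = if (is.null(ds_df)) 0 else sum(ds_df$flagged)))

  # --- stage: loops --------------------------------------------------------
  pooled_loop <- lapply(gl, function(g)
    pool_matrices(cms_loop[samples$sample[samples$group == g]]))
  names(pooled_loop) <- gl
  loop_sets <- lapply(pooled_loop, function(pm)
    call_loops(pm, fdr = par("loop_fdr", 0.1)))
  union_loops <- unique(do.call(rbind, loop_sets)[, c("chrom", "res", "bin1",
                                                      "bin2")])
  if (!is.null(union_loops) && nrow(union_loops) > 0) {
    union_loops$start1 <- union_loops$bin1 * union_loops$res
    union_loops$end1 <- union_loops$start1 + union_loops$res
    union_loops$start2 <- union_loops$bin2 * union_loops$res
    union_loops$end2 <- union_loops$start2 + union_loops$res
    dl <- differential_loops(union_loops, cms_loop, grp,
                             fdr = par("loop_fdr", 0.1))
    write_loops_bedpe(dl, file.path(out_dir, "loops.bedpe"))
    utils::write.table(dl, file.path(out_dir, "differential_loops.tsv"),
                       quote = FALSE, sep = "\t", row.names = FALSE)
    ctcf <- if (!is.null(genome$motifs))
      classify_ctcf_orientation(dl, genome$motifs,
                                anchor_pad = bs_loop) else NULL
  } else {
    dl <- NULL; ctcf <- NULL
  }
  stage_done("loops", list(
    n_union = if (is.null(dl)) 0 else nrow(dl),
    n_enhanced = if (is.null(dl)) 0 else sum(dl$flagged & dl$direction ==
                                               "enhanced"),
    n_reduced = if (is.null(dl)) 0 else sum(dl$flagged & dl$direction ==
                                              "reduced"),
    ctcf = if (is.null(ctcf)) NULL else ctcf$summary))

  # --- stage: structural variants -----------------------------------------
  ctrl_samples <- samples$sample[samples$group == gl[1]]
  case_samples <- samples$sample[samples$group == gl[2]]
  ctrl_cms <- cms_loop[ctrl_samples]
  ctrl_pool <- pool_matrices(ctrl_cms)
  events <- list(); neoloops <- list()
  for (s in case_samples) {
    blocks <- detect_interchrom_blocks(cms_loop[[s]], ctrl_cms,
                                       min_enrichment = par("sv_min_enrichment", 5))
    if (nrow(blocks) == 0) next
    chim_path <- if (is.null(samples$chimeric)) NA_character_ else
      samples$chimeric[samples$sample == s]
    reads <- if (!is.na(chim_path) && file.exists(chim_path))
      read_chimeric(chim_path)
    else
      data.frame(read_id = character(0), chrom1 = character(0),
                 pos1 = numeric(0), strand1 = character(0),
                 chrom2 = character(0), pos2 = numeric(0),
                 strand2 = character(0), linker = integer(0))
    evs <- refine_breakpoints(blocks, reads, genome)
    evs <- evs[!evs$control_present, , drop = FALSE]
    if (nrow(evs) == 0) next
    evs$sample <- s
    events[[s]] <- evs
    for (k in which(evs$refined)) {
      rmap <- reassemble_matrix(cms_loop[[s]], evs[k, ])
      cmap <- reassemble_matrix(ctrl_pool, evs[k, ])
      nl <- detect_neo_loops(rmap, cmap,
                             min_control_enrich = par("neo_control_enrich", 2),
                             preexisting = if (!is.null(dl) && nrow(dl))
                               data.frame(chrom = dl$chrom, start1 = dl$start1,
                                          end1 = dl$end1, start2 = dl$start2,
                                          end2 = dl$end2) else NULL,
                             motifs = genome$motifs)
      if (nrow(nl) > 0) {
        nl$sample <- s
        nl$event <- k
        neoloops[[paste(s, k)]] <- nl
      }
    }
  }
  events_df <- do.call(rbind, events)
  neoloops_df <- do.call(rbind, neoloops)
  if (!is.null(events_df))
    utils::write.table(events_df, file.path(out_dir, "events.tsv"),
                       quote = FALSE, sep = "\t", row.names = FALSE)
  if (!is.null(neoloops_df))
    utils::write.table(neoloops_df, file.path(out_dir, "neoloops.tsv"),
                       quote = FALSE, sep = "\t", row.names = FALSE)
  stage_done("sv", list(
    n_events = if (is.null(events_df)) 0 else nrow(events_df),
    n_refined = if (is.null(events_df)) 0 else sum(events_df$refined),
    n_neoloops = if (is.null(neoloops_df)) 0 else nrow(neoloops_df)))

  # --- stage: integration --------------------------------------------------
  assoc <- NULL
  if (!is.null(expr)) {
    de <- de_table(expr)
    assoc <- associate_degs(
      de, expr$counts, genome, binsize = bs_comp,
      switches = switches,
      boundary_table = bnd_df,
      tads = if (is.null(ds_df)) NULL else
        ds_df[, c("chrom", "start_bin", "end_bin")],
      dscore_table = ds_df,
      loop_table = dl)
    utils::write.table(assoc$genes, file.path(out_dir, "associations.tsv"),
                       quote = FALSE, sep = "\t", row.names = FALSE)
    utils::write.table(assoc$class_tests,
                       file.path(out_dir, "class_tests.tsv"),
                       quote = FALSE, sep = "\t", row.names = FALSE)
  }
  stage_done("integration", list(
    n_classes = if (is.null(assoc)) 0 else nrow(assoc$class_tests)))

  # --- manifest ------------------------------------------------------------
  outs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outs <- setdiff(outs, file.path(out_dir, "manifest.json"))
  sums <- tools::md5sum(outs)
  manifest$outputs <- stats::setNames(as.list(unname(sums)),
                                      substring(outs, nchar(out_dir) + 2))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(manifest)
}
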