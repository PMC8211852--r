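#' Genome model
#'
#' Minimal genome reference used throughout the pipeline: chromosome names and
#' lengths, an optional gene catalog and an optional CTCF motif catalog.
#' Coordinates are 1-based inclusive for genes/motif positions; text I/O
#' converts explicitly (pairs files are 1-based, BED is 0-based half-open).
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param genes optional data.frame with columns `gene`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param motifs optional data.frame with columns `chrom`, `pos`, `strand`,
#'   `score` (CTCF motif midpoints).
#' @return an object of class `genome_model`.
#' @export
genome_model <- function(chrom_lengths, genes = NULL, motifs = NULL) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  chrom_lengths <- round(chrom_lengths)
  if (!is.null(genes)) {
    stopifnot(all(c("gene", "chrom", "start", "end", "strand") %in% names(genes)))
    .check_within(genes$chrom, genes$end, chrom_lengths, "genes")
  }
  if (!is.null(motifs)) {
    stopifnot(all(c("chrom", "pos", "strand") %in% names(motifs)))
    if (is.null(motifs$score)) motifs$score <- 1
    .check_within(motifs$chrom, motifs$pos, chrom_lengths, "motifs")
  }
  structure(list(chrom_lengths = chrom_lengths, genes = genes, motifs = motifs),
            class = "genome_model")
}

.check_within <- function(chrom, pos, lens, what) {
  if (any(!chrom %in% names(lens)))
    stop(sprintf("%s reference unknown chromosomes", what))
  if (any(pos < 1 | pos > lens[chrom]))
    stop(sprintf("%s coordinates outside chromosome bounds", what))
  invisible(TRUE)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chrom_lengths), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp\n")
  for (ch in names(x$chrom_lengths))
    cat(" ", ch, format(x$chrom_lengths[[ch]], big.mark = ","), "bp\n")
  if (!is.null(x$genes)) cat("  genes:", nrow(x$genes), "\n")
  if (!is.null(x$motifs)) cat("  CTCF motifs:", nrow(x$motifs), "\n")
  invisible(x)
}

#' Number of bins per chromosome at a bin size
#'
#' The last bin may be partial.
#' @param genome a `genome_model`.
#' @param binsize bin size in bp.
#' @return named integer vector of bin counts.
#' @export
n_bins <- function(genome, binsize) {
  stats::setNames(as.integer(ceiling(genome$chrom_lengths / binsize)),
                  names(genome$chrom_lengths))
}

#' Map a 1-based position to a 0-based bin index
#' @param pos 1-based bp position.
#' @param binsize bin size in bp.
#' @return integer 0-based bin index, `floor((pos - 1) / binsize)`.
#' @export
pos_to_bin <- function(pos, binsize) as.integer(floor((pos - 1) / binsize))
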