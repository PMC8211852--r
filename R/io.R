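#' Write contact records as a pairs-like text file
#'
#' Whitespace-separated `chrom1 pos1 chrom2 pos2 count`, 1-based positions,
#' with `#` header lines declaring the genome and bin size.
#'
#' @param records contact record data.frame.
#' @param path output path.
#' @param genome a `genome_model`.
#' @param binsize simulation bin size recorded in the header (optional).
#' @export
write_pairs <- function(records, path, genome, binsize = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#genome: ",
                    paste(names(genome$chrom_lengths), genome$chrom_lengths,
                          sep = "=", collapse = " ")), con)
  if (!is.null(binsize)) writeLines(paste0("#binsize: ", binsize), con)
  utils::write.table(records[, c("chrom1", "pos1", "chrom2", "pos2", "count")],
                     con, quote = FALSE, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a pairs-like text file
#' @param path input path.
#' @return contact record data.frame with attributes `genome_lengths` and
#'   `binsize` when declared in the header.
#' @export
read_pairs <- function(path) {
  hdr <- character(0)
  con <- file(path, "r")
  while (length(line <- readLines(con, 1)) > 0 && startsWith(line, "#"))
    hdr <- c(hdr, line)
  close(con)
  rec <- utils::read.table(path, comment.char = "#",
                           col.names = c("chrom1", "pos1", "chrom2", "pos2",
                                         "count"),
                           colClasses = c("character", "numeric", "character",
                                          "numeric", "numeric"))
  gl <- grep("^#genome:", hdr, value = TRUE)
  if (length(gl) == 1) {
    kv <- strsplit(strsplit(sub("^#genome: *", "", gl), " ")[[1]], "=")
    attr(rec, "genome_lengths") <-
      stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                      vapply(kv, `[`, "", 1))
  }
  bl <- grep("^#binsize:", hdr, value = TRUE)
  if (length(bl) == 1) attr(rec, "binsize") <- as.numeric(sub("^#binsize: *", "", bl))
  rec
}

#' Write / read chimeric-read tables
#'
#' TSV `read_id chrom1 pos1 strand1 chrom2 pos2 strand2 linker` with linker
#' in {0, 1}.
#' @param reads chimeric-read data.frame.
#' @param path file path.
#' @export
write_chimeric <- function(reads, path) {
  utils::write.table(reads, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_chimeric
#' @export
read_chimeric <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "numeric",
                                   "character", "character", "numeric",
                                   "character", "integer"))
}

#' Write / read CTCF motifs as BED6
#'
#' 0-based half-open intervals; the motif position is the interval start + 1
#' on reading. Strand in column 6.
#' @param motifs data.frame `chrom, pos, strand, score` (pos 1-based).
#' @param path file path.
#' @param width motif width in bp (default 20).
#' @export
write_motifs_bed <- function(motifs, path, width = 20) {
  bed <- data.frame(chrom = motifs$chrom, start = motifs$pos - 1,
                    end = motifs$pos - 1 + width,
                    name = sprintf("ctcf_%d", seq_len(nrow(motifs))),
                    score = if (is.null(motifs$score)) 0 else motifs$score,
                    strand = motifs$strand)
  utils::write.table(bed, path, quote = FALSE, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_motifs_bed
#' @export
read_motifs_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t",
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"),
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "numeric", "character"))
  data.frame(chrom = bed$chrom, pos = bed$start + 1, strand = bed$strand,
             score = bed$score, stringsAsFactors = FALSE)
}

#' Write / read a gene catalog as BED-like TSV
#' @param genes data.frame `gene, chrom, start, end, strand`.
#' @param path file path.
#' @export
write_genes_tsv <- function(genes, path) {
  utils::write.table(genes, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_genes_tsv
#' @export
read_genes_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a contact matrix as COO TSV plus JSON sidecar
#'
#' COO rows `chrom1 bin1 chrom2 bin2 value` (0-based bins); the sidecar
#' carries binsize, genome, cis total and balancing weights.
#' @param cm a `contact_matrix`.
#' @param prefix output path prefix (writes `<prefix>.coo.tsv` and
#'   `<prefix>.json`).
#' @export
write_matrix_coo <- function(cm, prefix) {
  rows <- list()
  for (key in names(cm$mats)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    c1 <- parts[1]; c2 <- if (length(parts) > 1) parts[2] else parts[1]
    tr <- Matrix::summary(cm$mats[[key]])
    if (c1 == c2) tr <- tr[tr$i <= tr$j, , drop = FALSE]   # upper triangle
    if (nrow(tr) == 0) next
    rows[[key]] <- data.frame(chrom1 = c1, bin1 = tr$i - 1L, chrom2 = c2,
                              bin2 = tr$j - 1L, value = tr$x)
  }
  utils::write.table(do.call(rbind, rows), paste0(prefix, ".coo.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  side <- list(binsize = cm$binsize,
               chrom_lengths = as.list(cm$genome$chrom_lengths),
               cis_total = cm$cis_total,
               weights = cm$weights)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(prefix)
}

#' Write loops as BEDPE
#'
#' 0-based half-open anchor intervals with observed count and q-value
#' columns.
#' @param loops loop data.frame from [call_loops()].
#' @param path file path.
#' @export
write_loops_bedpe <- function(loops, path) {
  chrom1 <- if (!is.null(loops$chrom1)) loops$chrom1 else loops$chrom
  chrom2 <- if (!is.null(loops$chrom2)) loops$chrom2 else loops$chrom
  score <- if (!is.null(loops[["obs"]])) loops[["obs"]] else
    rep(NA_real_, nrow(loops))
  qv <- if (!is.null(loops[["q"]])) loops[["q"]] else
    if (!is.null(loops[["fdr"]])) loops[["fdr"]] else rep(NA_real_, nrow(loops))
  bed <- data.frame(chrom1 = chrom1, start1 = loops$start1, end1 = loops$end1,
                    chrom2 = chrom2, start2 = loops$start2, end2 = loops$end2,
                    obs = score, q = qv)
  utils::write.table(bed, path, quote = FALSE, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a per-bin track as bedGraph
#' @param values numeric per-bin values (NA bins skipped).
#' @param chrom chromosome name.
#' @param binsize bin size in bp.
#' @param path file path.
#' @export
write_bedgraph <- function(values, chrom, binsize, path) {
  ok <- which(!is.na(values))
  bg <- data.frame(chrom = chrom, start = (ok - 1) * binsize,
                   end = ok * binsize, value = values[ok])
  utils::write.table(bg, path, quote = FALSE, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
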