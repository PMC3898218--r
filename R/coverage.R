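#' Per-nucleotide coverage track
#'
#' Read depth at every genome position for one sample. The default protocol
#' modelled here is non-directional (randomly primed, second-strand cDNA), so
#' tracks are unstranded unless \code{plus}/\code{minus} components are given.
#'
#' @param sample_id Sample identifier.
#' @param depth Numeric vector of non-negative depths, one per genome position
#'   (unstranded mode), or \code{NULL} when \code{plus}/\code{minus} are given.
#' @param plus,minus Optional per-strand depth vectors (stranded mode).
#' @return An object of class \code{coverage_track}.
#' @export
coverage_track <- function(sample_id, depth = NULL, plus = NULL, minus = NULL) {
  stranded <- is.null(depth)
  if (stranded) {
    stopifnot(!is.null(plus), !is.null(minus), length(plus) == length(minus))
    depth <- plus + minus
  }
  if (any(depth < 0)) stop("validation error: negative coverage depth")
  structure(list(sample_id = sample_id, depth = as.numeric(depth),
                 stranded = stranded,
                 plus = if (stranded) as.numeric(plus),
                 minus = if (stranded) as.numeric(minus)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> ", x$sample_id, ": ", length(x$depth), " nt, mean depth ",
      format(mean(x$depth), digits = 4),
      if (x$stranded) " (stranded)" else " (unstranded)", "\n", sep = "")
  invisible(x)
}

#' Read a coverage track from bedGraph
#'
#' Positions not covered by any interval get depth 0; overlapping intervals
#' are summed. bedGraph intervals are 0-based half-open.
#'
#' @param path Path to a bedGraph file.
#' @param genome_length Genome length in nucleotides.
#' @param sample_id Sample identifier; defaults to the file base name.
#' @return A \code{coverage_track}.
#' @export
read_coverage <- function(path, genome_length,
                          sample_id = sub("\\.bedgraph$", "", basename(path),
                                          ignore.case = TRUE)) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  gr <- rtracklayer::import.bedGraph(path)
  depth <- numeric(genome_length)
  if (length(gr)) {
    if (max(GenomicRanges::end(gr)) > genome_length)
      stop("validation error: bedGraph interval exceeds genome length")
    rle <- IRanges::coverage(GenomicRanges::ranges(gr),
                                   weight = as.numeric(S4Vectors::mcols(gr)$score),
                                   width = genome_length)
    depth <- as.numeric(rle)
  }
  coverage_track(sample_id, depth)
}

#' Write a coverage track to bedGraph
#'
#' Runs of equal depth are emitted as single intervals; zero-depth runs are
#' omitted, as is conventional for bedGraph.
#'
#' @param track A \code{coverage_track}.
#' @param path Output path.
#' @param genome_id Chromosome name for column 1.
#' @return \code{path}, invisibly.
#' @export
write_coverage <- function(track, path, genome_id = "genome") {
  r <- rle(track$depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths            # 0-based
  keep <- r$values != 0
  df <- data.frame(chrom = genome_id, start = starts[keep], end = ends[keep],
                   value = r$values[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-gene read counts for one sample
#'
#' @param sample_id Sample identifier.
#' @param counts Named integer vector, gene_id -> perfectly mapped read count.
#' @param total_mapped Total mapped reads in the sample.
#' @return An object of class \code{gene_counts}.
#' @export
gene_counts <- function(sample_id, counts, total_mapped) {
  stopifnot(total_mapped > 0)
  if (any(counts > total_mapped))
    stop("validation error: gene count exceeds total mapped reads")
  if (any(counts < 0)) stop("validation error: negative count")
  structure(list(sample_id = sample_id, counts = counts,
                 total_mapped = as.numeric(total_mapped)),
            class = "gene_counts")
}

#' Read a gene count table
#'
#' TSV with a header: column \code{gene_id} plus one column per sample.
#' Total mapped reads per sample are supplied separately (they include reads
#' outside gene regions).
#'
#' @param path TSV path.
#' @param total_mapped Named numeric vector of per-sample totals; when
#'   \code{NULL} the per-sample column sums are used.
#' @return A named list of \code{gene_counts}, one per sample column.
#' @export
read_counts <- function(path, total_mapped = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(df)) stop("count table lacks a gene_id column")
  samples <- setdiff(names(df), "gene_id")
  out <- lapply(samples, function(s) {
    tot <- if (is.null(total_mapped)) sum(df[[s]]) else total_mapped[[s]]
    gene_counts(s, stats::setNames(df[[s]], df$gene_id), tot)
  })
  stats::setNames(out, samples)
}

#' Write per-sample gene counts to TSV
#'
#' @param counts_list Named list of \code{gene_counts}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(counts_list, path) {
  genes <- names(counts_list[[1L]]$counts)
  df <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (gc in counts_list) df[[gc$sample_id]] <- as.vector(gc$counts[genes])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
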