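# GFF3/BED/TSV emission of called features.

utr_granges <- function(utrs, annotation) {
  if (!nrow(utrs)) return(GenomicRanges::GRanges())
  orfs <- annotation$orfs
  idx <- match(utrs$gene_id, orfs$gene_id)
  s0 <- integer(nrow(utrs)); e0 <- integer(nrow(utrs))
  for (k in seq_len(nrow(utrs))) {
    g <- orfs[idx[k], ]
    left <- (g$strand == "+") == (utrs$kind[k] == "5prime")
    if (left) { s0[k] <- g$start - utrs$length[k]; e0[k] <- g$start }
    else      { s0[k] <- g$end;                    e0[k] <- g$end + utrs$length[k] }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$genome_id,
    ranges = IRanges::IRanges(start = s0 + 1L, end = e0),
    strand = orfs$strand[idx])
  S4Vectors::mcols(gr)$type <- ifelse(utrs$kind == "5prime",
                                      "five_prime_UTR", "three_prime_UTR")
  S4Vectors::mcols(gr)$ID <- paste0(utrs$gene_id, "_", utrs$kind)
  S4Vectors::mcols(gr)$n_samples <- utrs$n_samples
  gr
}

operon_granges <- function(map, annotation) {
  if (!length(map$operons)) return(GenomicRanges::GRanges())
  orfs <- annotation$orfs
  rows <- lapply(seq_along(map$operons), function(k) {
    o <- map$operons[[k]]
    idx <- match(o$genes, orfs$gene_id)
    c(start = min(orfs$start[idx]), end = max(orfs$end[idx]))
  })
  m <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$genome_id,
    ranges = IRanges::IRanges(start = m[, "start"] + 1L, end = m[, "end"]),
    strand = vapply(map$operons, `[[`, "", "strand"))
  S4Vectors::mcols(gr)$type <- "operon"
  S4Vectors::mcols(gr)$ID <- sprintf("operon_%03d", seq_along(map$operons))
  S4Vectors::mcols(gr)$genes <- vapply(map$operons,
                                       function(o) paste(o$genes,
                                                         collapse = ","), "")
  gr
}

novel_granges <- function(novel, annotation) {
  if (!nrow(novel)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$genome_id,
    ranges = IRanges::IRanges(start = novel$start + 1L, end = novel$end),
    strand = novel$strand)
  S4Vectors::mcols(gr)$type <- "transcript_region"
  S4Vectors::mcols(gr)$ID <- sprintf("novel_%03d", seq_len(nrow(novel)))
  if (!is.null(novel$n_samples)) S4Vectors::mcols(gr)$n_samples <- novel$n_samples
  gr
}

#' Write called features to GFF3 and BED
#'
#' Emits \code{operons}, \code{utrs} and \code{novel} feature files (GFF3,
#' 1-based inclusive; BED6, 0-based half-open) into a directory. Zero-length
#' UTRs never reach the UTR set, so none are written.
#'
#' @param operons An \code{operon_map} (or NULL).
#' @param utrs A \code{utr_set} (or NULL).
#' @param novel A \code{novel_set} (or NULL).
#' @param annotation The \code{genome_annotation}.
#' @param dir Output directory (created if needed).
#' @return Character vector of paths written, invisibly.
#' @export
write_features <- function(operons, utrs, novel, annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(gr, stem) {
    gff <- file.path(dir, paste0(stem, ".gff3"))
    bed <- file.path(dir, paste0(stem, ".bed"))
    rtracklayer::export.gff3(gr, gff)
    grb <- gr
    if (length(grb)) {
      S4Vectors::mcols(grb) <- S4Vectors::DataFrame(
        name = S4Vectors::mcols(gr)$ID, score = 0L)
    }
    rtracklayer::export.bed(grb, bed)
    c(gff, bed)
  }
  if (!is.null(operons))
    paths <- c(paths, emit(operon_granges(operons, annotation), "operons"))
  if (!is.null(utrs))
    paths <- c(paths, emit(utr_granges(utrs, annotation), "utrs"))
  if (!is.null(novel))
    paths <- c(paths, emit(novel_granges(novel, annotation), "novel"))
  invisible(paths)
}

#' Write an operon map to TSV
#'
#' @param map An \code{operon_map}.
#' @param path Output TSV.
#' @return \code{path}, invisibly.
#' @export
write_operons <- function(map, path) {
  df <- data.frame(
    operon_id = sprintf("operon_%03d", seq_along(map$operons)),
    genes = vapply(map$operons, function(o) paste(o$genes, collapse = ","), ""),
    size = vapply(map$operons, function(o) length(o$genes), 1L),
    strand = vapply(map$operons, `[[`, "", "strand"),
    min_pair_support = vapply(map$operons, function(o)
      as.numeric(o$min_pair_support), 1),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference operon map from TSV
#'
#' Expected columns: \code{operon_id} and \code{genes} (comma-separated gene
#' ids), e.g. an export from a prediction database.
#'
#' @param path TSV path.
#' @param annotation A \code{genome_annotation} giving the gene universe and
#'   strands.
#' @return An \code{operon_map}.
#' @export
read_reference_operons <- function(path, annotation) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  orfs <- annotation$orfs
  operons <- lapply(seq_len(nrow(df)), function(k) {
    genes <- strsplit(df$genes[k], ",", fixed = TRUE)[[1L]]
    list(genes = genes,
         strand = orfs$strand[match(genes[1L], orfs$gene_id)],
         min_pair_support = NA_real_)
  })
  n_og <- length(unlist(lapply(operons, `[[`, "genes")))
  structure(list(operons = operons,
                 genome_operon_rate = if (nrow(orfs)) n_og / nrow(orfs) else 0,
                 n_genes = nrow(orfs)),
            class = "operon_map")
}

#' Write a UTR set to TSV
#'
#' @param utrs A \code{utr_set}.
#' @param path Output TSV.
#' @return \code{path}, invisibly.
#' @export
write_utrs <- function(utrs, path) {
  utils::write.table(as.data.frame(utrs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
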