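#' Genome annotation container
#'
#' An ordered set of ORF models over a single (typically circular) bacterial
#' chromosome. Coordinates are stored 0-based half-open internally; GFF3 I/O
#' converts to/from the 1-based inclusive convention.
#'
#' @param genome_id Chromosome/contig identifier.
#' @param genome_length Genome length in nucleotides.
#' @param orfs A data.frame with columns \code{gene_id}, \code{start},
#'   \code{end}, \code{strand} and optionally \code{partition} (core/flexible/
#'   unknown), \code{cog}, \code{deg_hit}, \code{pathway}, \code{is_ribosomal}.
#'   \code{start < end}, 0-based half-open.
#' @return An object of class \code{genome_annotation}.
#' @export
genome_annotation <- function(genome_id, genome_length, orfs) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            is.numeric(genome_length), genome_length >= 0)
  orfs <- as.data.frame(orfs, stringsAsFactors = FALSE)
  required <- c("gene_id", "start", "end", "strand")
  missing_cols <- setdiff(required, names(orfs))
  if (length(missing_cols))
    stop("annotation is missing columns: ", paste(missing_cols, collapse = ", "))
  for (col in c("partition", "cog", "pathway"))
    if (is.null(orfs[[col]])) orfs[[col]] <- rep(NA_character_, nrow(orfs))
  if (is.null(orfs$deg_hit)) orfs$deg_hit <- rep(NA, nrow(orfs))
  if (is.null(orfs$is_ribosomal)) orfs$is_ribosomal <- rep(FALSE, nrow(orfs))
  if (nrow(orfs)) {
    if (anyDuplicated(orfs$gene_id))
      stop("duplicate gene identifiers in annotation")
    if (any(orfs$start >= orfs$end))
      stop("validation error: ORF with end <= start")
    if (any(orfs$end - orfs$start < 3))
      stop("validation error: ORF shorter than 3 nt")
    if (any(orfs$start < 0) || any(orfs$end > genome_length))
      stop("validation error: ORF coordinates outside [0, genome_length)")
    if (!all(orfs$strand %in% c("+", "-")))
      stop("validation error: strand must be '+' or '-'")
    orfs <- orfs[order(orfs$start, orfs$end, orfs$gene_id), , drop = FALSE]
    rownames(orfs) <- NULL
  }
  structure(list(genome_id = genome_id,
                 genome_length = as.integer(genome_length),
                 orfs = orfs),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", x$genome_id, ": ", x$genome_length, " nt, ",
      nrow(x$orfs), " ORFs\n", sep = "")
  invisible(x)
}

orf_lengths <- function(annotation) {
  with(annotation$orfs, stats::setNames(end - start, gene_id))
}

#' Read an ORF annotation from GFF3
#'
#' Reads a GFF3 feature file and returns a \code{\link{genome_annotation}}.
#' The 1-based inclusive GFF3 coordinates become 0-based half-open. Optional
#' attributes \code{partition}, \code{cog}, \code{deg_hit}, \code{pathway} and
#' \code{is_ribosomal} are picked up from the attribute column when present.
#'
#' @param path Path to a GFF3 file.
#' @param genome_length Genome length; when \code{NULL} it is taken from the
#'   \code{##sequence-region} pragma (or the maximal feature end).
#' @param feature_types GFF3 \code{type} values treated as ORFs.
#' @return A \code{genome_annotation}.
#' @export
read_annotation <- function(path, genome_length = NULL,
                            feature_types = c("CDS", "gene")) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- tryCatch(rtracklayer::import.gff3(path),
                 error = function(e) stop("GFF3 parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (length(gr)) gr <- gr[as.character(gr$type) %in% feature_types]
  genome_id <- if (length(gr)) as.character(GenomicRanges::seqnames(gr)[1L])
               else as.character(GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(gr))[1L])
  if (is.null(genome_length)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    genome_length <- if (length(sl) && !is.na(sl[1L])) sl[[1L]]
                     else if (length(gr)) max(GenomicRanges::end(gr)) else 0L
    # honour a ##sequence-region pragma (not all parsers surface it)
    header <- readLines(path, n = 50L)
    sr <- grep("^##sequence-region", header, value = TRUE)
    if (length(sr)) {
      parts <- strsplit(trimws(sr[[1L]]), "[ \t]+")[[1L]]
      if (length(parts) >= 4L) genome_length <- as.integer(parts[[4L]])
    }
  }
  attr_col <- function(name, default) {
    v <- S4Vectors::mcols(gr)[[name]]
    if (is.null(v)) rep(default, length(gr)) else v
  }
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
  if (is.null(ids)) ids <- paste0("orf", seq_along(gr))
  orfs <- data.frame(
    gene_id = as.character(ids),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    partition = as.character(attr_col("partition", NA_character_)),
    cog = as.character(attr_col("cog", NA_character_)),
    deg_hit = as.logical(attr_col("deg_hit", NA)),
    pathway = as.character(attr_col("pathway", NA_character_)),
    is_ribosomal = as.logical(attr_col("is_ribosomal", FALSE)),
    stringsAsFactors = FALSE)
  orfs$is_ribosomal[is.na(orfs$is_ribosomal)] <- FALSE
  genome_annotation(genome_id, genome_length, orfs)
}

annotation_to_granges <- function(annotation) {
  orfs <- annotation$orfs
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$genome_id,
    ranges = IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
    strand = orfs$strand)
  S4Vectors::mcols(gr)$ID <- orfs$gene_id
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  for (col in c("partition", "cog", "deg_hit", "pathway", "is_ribosomal"))
    S4Vectors::mcols(gr)[[col]] <- orfs[[col]]
  GenomeInfoDb::seqlengths(gr) <- annotation$genome_length
  gr
}

#' Write an annotation to GFF3
#'
#' @param annotation A \code{genome_annotation}.
#' @param path Output GFF3 path.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  rtracklayer::export.gff3(annotation_to_granges(annotation), path)
  # make the genome length explicit so readers recover it
  txt <- readLines(path)
  pragma <- sprintf("##sequence-region %s 1 %d", annotation$genome_id,
                    annotation$genome_length)
  writeLines(c(txt[1L], pragma, txt[-1L]), path)
  invisible(path)
}
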