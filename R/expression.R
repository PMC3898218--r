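#' RPKM for one sample
#'
#' rpkm(g) = count(g) / (length(g)/1000) / (total_mapped/1e6). Counts are
#' taken as provided (read pairs or mates, whichever the upstream counter
#' produced); RPKM is invariant under joint scaling of count and total.
#'
#' @param counts A \code{\link{gene_counts}} object.
#' @param annotation A \code{\link{genome_annotation}}; every counted gene
#'   must be annotated.
#' @return Named numeric vector of per-gene RPKM.
#' @export
compute_rpkm <- function(counts, annotation) {
  lens <- orf_lengths(annotation)
  genes <- names(counts$counts)
  missing_genes <- setdiff(genes, names(lens))
  if (length(missing_genes))
    stop("genes absent from annotation: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  len <- lens[genes]
  if (any(len == 0)) stop("validation error: gene of length 0")
  counts$counts / (len / 1000) / (counts$total_mapped / 1e6)
}

#' Genome background depth threshold
#'
#' The per-sample background is the nearest-rank tenth percentile of the
#' multiset of per-nucleotide depths restricted to annotated gene regions
#' (union of ORF spans). Positions at or below this depth are treated as
#' untranscribed noise by the boundary caller (criterion 3).
#'
#' @param track A \code{coverage_track}.
#' @param annotation A \code{genome_annotation} with at least one ORF.
#' @param prob Percentile as a fraction (default 0.1).
#' @return A single depth value.
#' @export
genome_background <- function(track, annotation, prob = 0.1) {
  orfs <- annotation$orfs
  if (!nrow(orfs)) stop("validation error: empty annotation")
  in_gene <- logical(length(track$depth))
  for (k in seq_len(nrow(orfs)))
    in_gene[(orfs$start[k] + 1L):orfs$end[k]] <- TRUE
  d <- sort(track$depth[in_gene])
  d[[max(1L, ceiling(prob * length(d)))]]
}

#' Per-sample gene expression cutoff
#'
#' The cutoff is the mean RPKM of the lowest decile of genes ranked by RPKM
#' (ceiling(0.1 n) genes). A gene counts as expressed in a sample iff its
#' RPKM is strictly greater than the cutoff.
#'
#' @param rpkm Named numeric vector of per-gene RPKM for one sample.
#' @param prob Fraction of lowest-expressed genes averaged (default 0.1).
#' @return A single RPKM threshold.
#' @export
gene_expression_cutoff <- function(rpkm, prob = 0.1) {
  n <- length(rpkm)
  if (n < 10L) stop("validation error: fewer than 10 genes")
  k <- ceiling(prob * n)
  mean(sort(rpkm)[seq_len(k)])
}

#' Fraction of the genome transcribed
#'
#' A position is transcribed when its depth strictly exceeds the background.
#' With several tracks, \code{mode = "any"} gives the fraction transcribed in
#' at least one sample (union) and \code{mode = "all"} in every sample
#' (intersection).
#'
#' @param tracks A \code{coverage_track} or list of them.
#' @param background Depth threshold, or vector of per-sample thresholds.
#' @param mode One of \code{"any"}, \code{"all"} (ignored for one track).
#' @return Fraction in [0, 1].
#' @export
transcribed_fraction <- function(tracks, background, mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  background <- rep_len(background, length(tracks))
  above <- mapply(function(tr, bg) tr$depth > bg, tracks, background)
  hit <- if (mode == "any") rowSums(above) > 0 else rowSums(above) == ncol(above)
  mean(hit)
}

#' Gene x sample RPKM matrix with per-sample cutoffs
#'
#' @param counts_list Named list of \code{gene_counts} (one per sample).
#' @param annotation A \code{genome_annotation}.
#' @param tracks Optional named list of \code{coverage_track}s; when given,
#'   per-sample genome backgrounds are computed too.
#' @return An object of class \code{expression_matrix}: list with \code{rpkm}
#'   (gene x sample matrix), \code{gene_cutoff}, \code{genome_background}
#'   (or NULL) and \code{expressed} (logical matrix, RPKM > cutoff).
#' @export
expression_matrix <- function(counts_list, annotation, tracks = NULL) {
  rpkm <- sapply(counts_list, compute_rpkm, annotation = annotation)
  if (is.null(dim(rpkm))) rpkm <- matrix(rpkm, ncol = length(counts_list),
    dimnames = list(names(counts_list[[1L]]$counts), names(counts_list)))
  cutoffs <- apply(rpkm, 2L, gene_expression_cutoff)
  backgrounds <- if (!is.null(tracks))
    vapply(tracks, genome_background, numeric(1L), annotation = annotation)
  structure(list(rpkm = rpkm, gene_cutoff = cutoffs,
                 genome_background = backgrounds,
                 expressed = sweep(rpkm, 2L, cutoffs, ">")),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$rpkm), " genes x ", ncol(x$rpkm),
      " samples\n  expressed per sample: ",
      paste(colSums(x$expressed), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write an RPKM matrix and its per-sample cutoffs to TSV
#'
#' @param em An \code{expression_matrix}.
#' @param path Output TSV for the RPKM matrix; cutoffs go to a
#'   \code{*.cutoffs.tsv} sidecar.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$rpkm), em$rpkm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- data.frame(sample_id = colnames(em$rpkm),
                     gene_cutoff = em$gene_cutoff,
                     genome_background = if (is.null(em$genome_background)) NA
                                         else em$genome_background)
  utils::write.table(side, sub("\\.tsv$", ".cutoffs.tsv", path), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
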