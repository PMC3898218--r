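# Operon assembly from co-transcribed adjacent ORF pairs.

adjacent_same_strand_pairs <- function(annotation) {
  orfs <- annotation$orfs
  n <- nrow(orfs)
  if (n < 2L) return(data.frame(gene_a = character(), gene_b = character(),
                                stringsAsFactors = FALSE))
  same <- orfs$strand[-n] == orfs$strand[-1L]
  data.frame(gene_a = orfs$gene_id[-n][same], gene_b = orfs$gene_id[-1L][same],
             stringsAsFactors = FALSE)
}

#' Is an adjacent same-strand ORF pair co-transcribed in one sample?
#'
#' TRUE iff no sharp coverage decline (criteria 1-3) occurs anywhere in the
#' intergenic gap between the two ORFs, scanning from the transcriptionally
#' upstream gene's stop toward the downstream gene, AND both genes exceed the
#' sample's gene expression cutoff (so that a flat-zero gap cannot pass as
#' "no decline").
#'
#' @param track A \code{coverage_track}.
#' @param annotation A \code{genome_annotation}.
#' @param gene_a,gene_b Gene ids of ORFs adjacent in annotation order, on the
#'   same strand (a precedes b in genome coordinates).
#' @param background Sample background depth.
#' @param rpkm Named per-gene RPKM for this sample (NULL skips the
#'   expression gate).
#' @param cutoff Sample gene expression cutoff.
#' @param ... Passed to \code{detect_boundary}.
#' @return Logical.
#' @export
pair_is_cotranscribed <- function(track, annotation, gene_a, gene_b,
                                  background, rpkm = NULL, cutoff = NULL,
                                  ...) {
  orfs <- annotation$orfs
  ia <- match(gene_a, orfs$gene_id); ib <- match(gene_b, orfs$gene_id)
  if (is.na(ia) || is.na(ib)) stop("unknown gene id")
  if (ib != ia + 1L) stop("validation error: genes are not adjacent")
  if (orfs$strand[ia] != orfs$strand[ib])
    stop("validation error: genes on opposite strands")
  if (!is.null(rpkm)) {
    if (!(rpkm[[gene_a]] > cutoff && rpkm[[gene_b]] > cutoff)) return(FALSE)
  }
  gap <- orfs$start[ib] - orfs$end[ia]
  if (gap < 0L) gap <- 0L
  # scan from the transcriptionally upstream gene's stop across the gap
  if (orfs$strand[ia] == "+") {
    anchor <- orfs$end[ia] - 1L; away <- +1L
  } else {
    anchor <- orfs$start[ib]; away <- -1L
  }
  b <- detect_boundary(track, anchor, away, background, max_scan = gap, ...)
  is.null(b)
}

#' Assemble operons from pairwise co-transcription support
#'
#' Pairs supported in at least \code{min_support} samples are kept; operons
#' are maximal chains of kept pairs (pairwise support suffices; the same
#' samples need not support every pair of a chain). Singleton genes are not
#' operons.
#'
#' @param pair_support data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{n_samples} (and optionally \code{samples}).
#' @param annotation A \code{genome_annotation}.
#' @param min_support Minimal number of supporting samples (default 3).
#' @return An object of class \code{operon_map}: list with \code{operons}
#'   (list of \code{(genes, strand, min_pair_support)}),
#'   \code{genome_operon_rate} and \code{n_genes}.
#' @export
assemble_operons <- function(pair_support, annotation, min_support = 3L) {
  orfs <- annotation$orfs
  kept <- pair_support[pair_support$n_samples >= min_support, , drop = FALSE]
  linked <- stats::setNames(rep(NA_real_, nrow(orfs)), orfs$gene_id)
  # linked[g] = support linking gene g to its successor
  ok <- match(kept$gene_a, orfs$gene_id) + 1L == match(kept$gene_b, orfs$gene_id)
  if (!all(ok)) stop("pair_support contains non-adjacent pairs")
  linked[kept$gene_a] <- kept$n_samples
  operons <- list()
  k <- 1L
  n <- nrow(orfs)
  while (k <= n) {
    j <- k
    while (j < n && !is.na(linked[[j]]) &&
           orfs$strand[j + 1L] == orfs$strand[k]) j <- j + 1L
    if (j > k) {
      operons[[length(operons) + 1L]] <- list(
        genes = orfs$gene_id[k:j], strand = orfs$strand[k],
        min_pair_support = min(linked[k:(j - 1L)]))
    }
    k <- j + 1L
  }
  n_operon_genes <- sum(vapply(operons, function(o) length(o$genes), 1L))
  structure(list(operons = operons,
                 genome_operon_rate = if (n) n_operon_genes / n else 0,
                 n_genes = n),
            class = "operon_map")
}

#' Build an operon map from coverage tracks
#'
#' Evaluates \code{\link{pair_is_cotranscribed}} for every adjacent
#' same-strand pair in every sample, then assembles operons with the
#' \code{min_support} rule.
#'
#' @param tracks Named list of \code{coverage_track}s.
#' @param annotation A \code{genome_annotation}.
#' @param em An \code{expression_matrix} (for backgrounds and per-sample
#'   expression gates).
#' @param min_support Minimal supporting samples (default 3).
#' @param ... Passed to \code{detect_boundary}.
#' @return An \code{operon_map}; the pair support table is attached as
#'   attribute \code{"pair_support"}.
#' @export
call_operons <- function(tracks, annotation, em, min_support = 3L, ...) {
  pairs <- adjacent_same_strand_pairs(annotation)
  support <- integer(nrow(pairs))
  samples <- character(nrow(pairs))
  for (s in names(tracks)) {
    bg <- em$genome_background[[s]]
    co <- vapply(seq_len(nrow(pairs)), function(p)
      pair_is_cotranscribed(tracks[[s]], annotation, pairs$gene_a[p],
                            pairs$gene_b[p], bg,
                            rpkm = em$rpkm[, s], cutoff = em$gene_cutoff[[s]],
                            ...),
      logical(1L))
    support <- support + co
    samples <- ifelse(co, ifelse(samples == "", s, paste(samples, s, sep = ",")),
                      samples)
  }
  pairs$n_samples <- support
  pairs$samples <- samples
  om <- assemble_operons(pairs, annotation, min_support = min_support)
  attr(om, "pair_support") <- pairs
  om
}

#' @export
print.operon_map <- function(x, ...) {
  sizes <- vapply(x$operons, function(o) length(o$genes), 1L)
  cat("<operon_map> ", length(x$operons), " operons covering ", sum(sizes),
      "/", x$n_genes, " genes (rate ",
      format(x$genome_operon_rate, digits = 4), ")\n", sep = "")
  if (length(sizes))
    cat("  2-gene operons: ", format(mean(sizes == 2L), digits = 4), "\n",
        sep = "")
  invisible(x)
}

operon_gene_ids <- function(map) unlist(lapply(map$operons, `[[`, "genes"))

#' Compare an observed operon map with a reference map
#'
#' Each observed operon is classified against the reference gene sets:
#' \code{hit} (identical to some reference operon), \code{large} (proper
#' superset), \code{small} (proper subset), \code{partial} (overlaps at least
#' one reference operon but is neither subset nor superset), \code{new}
#' (shares no gene with any reference operon). Classification priority is
#' hit > large > small > partial.
#'
#' @param observed,reference \code{operon_map}s over the same gene universe.
#' @return An object of class \code{operon_comparison}: named count vector
#'   over the five categories.
#' @export
compare_operon_maps <- function(observed, reference) {
  ref_sets <- lapply(reference$operons, `[[`, "genes")
  cats <- vapply(observed$operons, function(o) {
    g <- o$genes
    has_overlap <- FALSE; is_large <- FALSE; is_small <- FALSE
    for (r in ref_sets) {
      inter <- length(intersect(g, r))
      if (!inter) next
      if (inter == length(g) && inter == length(r)) return("hit")
      if (inter == length(r) && length(g) > length(r)) is_large <- TRUE
      if (inter == length(g) && length(g) < length(r)) is_small <- TRUE
      has_overlap <- TRUE
    }
    if (is_large) "large" else if (is_small) "small"
    else if (has_overlap) "partial" else "new"
  }, character(1L))
  counts <- vapply(c("hit", "large", "partial", "small", "new"),
                   function(k) sum(cats == k), 1L)
  structure(counts, class = "operon_comparison")
}

#' @export
print.operon_comparison <- function(x, ...) {
  cat("<operon_comparison>\n")
  print(unclass(x))
  invisible(x)
}

#' Operon rates and size spectrum for named gene sets
#'
#' rate(S) = |operon genes in S| / |S|; normalised rate divides by the whole
#' genome operon rate. The size histogram and two-gene fraction are computed
#' over operons restricted to each set (an operon counts for a set when at
#' least one member gene is in the set).
#'
#' @param map An \code{operon_map}.
#' @param gene_sets Named list of character vectors of gene ids.
#' @return data.frame with one row per set: \code{set}, \code{n},
#'   \code{n_operon_genes}, \code{rate}, \code{normalized},
#'   \code{two_gene_fraction}.
#' @export
operon_stats <- function(map, gene_sets) {
  og <- operon_gene_ids(map)
  rows <- lapply(names(gene_sets), function(nm) {
    S <- gene_sets[[nm]]
    if (!length(S))
      return(data.frame(set = nm, n = 0L, n_operon_genes = NA_integer_,
                        rate = NA_real_, normalized = NA_real_,
                        two_gene_fraction = NA_real_, stringsAsFactors = FALSE))
    k <- length(intersect(og, S))
    in_set <- vapply(map$operons, function(o) any(o$genes %in% S), TRUE)
    sizes <- vapply(map$operons[in_set], function(o) length(o$genes), 1L)
    data.frame(set = nm, n = length(S), n_operon_genes = k,
               rate = k / length(S),
               normalized = if (map$genome_operon_rate > 0)
                 (k / length(S)) / map$genome_operon_rate else NA_real_,
               two_gene_fraction = if (length(sizes)) mean(sizes == 2L)
                                   else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
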