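# Per-sample expression quartile classes and cross-sample stability.

#' Classify genes in one sample (HEG/MEG/LEG/NEG)
#'
#' Genes at or below the cutoff are NEG. Expressed genes are ranked by
#' descending RPKM (ties broken by gene id, lexicographically): the top
#' floor(n/4) are HEG, the bottom floor(n/4) LEG, the remainder MEG. The
#' rank rule makes the classification invariant under strictly monotone
#' transforms of RPKM.
#'
#' @param rpkm Named per-gene RPKM for one sample.
#' @param cutoff The sample's gene expression cutoff.
#' @return Named factor with levels HEG, MEG, LEG, NEG.
#' @export
classify_sample <- function(rpkm, cutoff) {
  cls <- rep("NEG", length(rpkm))
  names(cls) <- names(rpkm)
  expressed <- rpkm > cutoff
  n <- sum(expressed)
  if (n > 0L) {
    ids <- names(rpkm)[expressed]
    o <- ids[order(-rpkm[expressed], ids)]        # descending, ties by id
    q <- n %/% 4L
    cls[o] <- "MEG"
    if (q > 0L) {
      cls[o[seq_len(q)]] <- "HEG"
      cls[o[(n - q + 1L):n]] <- "LEG"
    }
  }
  factor(cls, levels = c("HEG", "MEG", "LEG", "NEG"))
}

#' Classify every sample of an expression matrix
#'
#' @param em An \code{expression_matrix}.
#' @return Gene x sample character matrix of classes.
#' @export
classify_all_samples <- function(em) {
  out <- sapply(colnames(em$rpkm), function(s)
    as.character(classify_sample(em$rpkm[, s], em$gene_cutoff[[s]])))
  rownames(out) <- rownames(em$rpkm)
  out
}

#' Constant vs variable expression across samples (CEG/VEG)
#'
#' A gene is CEG when its class is identical in every sample (any of the four
#' classes, NEG included); otherwise VEG. With fewer than 3 samples the
#' designation is weakly defined and a warning is issued.
#'
#' @param classes Gene x sample matrix of classes (from
#'   \code{\link{classify_all_samples}}).
#' @return data.frame with \code{gene_id}, \code{stability} (CEG/VEG) and
#'   \code{constant_class} (the class for CEG, NA for VEG).
#' @export
classify_across_samples <- function(classes) {
  if (ncol(classes) < 2L) stop("validation error: need >= 2 samples")
  if (ncol(classes) < 3L)
    warning("stability is weakly defined with fewer than 3 samples")
  if (anyNA(classes)) stop("validation error: gene missing in a sample")
  constant <- apply(classes, 1L, function(v) all(v == v[[1L]]))
  data.frame(gene_id = rownames(classes),
             stability = ifelse(constant, "CEG", "VEG"),
             constant_class = ifelse(constant, classes[, 1L], NA_character_),
             stringsAsFactors = FALSE)
}

# Five-subgroup label per gene: CEG genes keep their constant class,
# VEG genes are "VEG".
subgroup_labels <- function(stability) {
  ifelse(stability$stability == "CEG", stability$constant_class, "VEG")
}

#' Expression-subclass composition of the core and flexible genomes
#'
#' For each partition, fractions of the five subgroups (constant HEG, MEG,
#' LEG, NEG, and VEG) summing to 1, with a one-tailed Fisher p-value for the
#' enrichment of each subgroup in that partition against the rest of the
#' labelled universe. Genes with unknown partition are excluded.
#'
#' @param stability Output of \code{\link{classify_across_samples}}.
#' @param partition Named character vector gene_id -> "core"/"flexible" (or
#'   NA/"unknown" to exclude).
#' @return data.frame with columns \code{partition}, \code{subgroup},
#'   \code{n}, \code{fraction}, \code{p_enriched}.
#' @export
subclass_composition <- function(stability, partition) {
  lab <- subgroup_labels(stability)
  part <- partition[stability$gene_id]
  keep <- !is.na(part) & part %in% c("core", "flexible")
  lab <- lab[keep]; part <- part[keep]
  subgroups <- c("HEG", "MEG", "LEG", "NEG", "VEG")
  rows <- list()
  for (p in c("core", "flexible")) {
    in_p <- part == p
    for (g in subgroups) {
      a <- sum(in_p & lab == g); b <- sum(in_p & lab != g)
      c_ <- sum(!in_p & lab == g); d <- sum(!in_p & lab != g)
      rows[[length(rows) + 1L]] <- data.frame(
        partition = p, subgroup = g, n = a,
        fraction = if (a + b > 0) a / (a + b) else NA_real_,
        p_enriched = fisher_one_tailed(a, b, c_, d, "greater")$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
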