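# One-tailed Fisher's exact enrichment, used throughout the pipeline.

#' One-tailed Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric tail probability for the table
#' \code{(a, b; c, d)} = (in-set & in-class, in-set & not, not-set & in-class,
#' not-set & not). \code{direction = "greater"} tests enrichment of the class
#' within the set, \code{"less"} depletion. A degenerate margin (a+b = 0 or
#' a+c = 0) yields p = 1 with a flag.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param direction "greater" (enrichment, default) or "less".
#' @return List with \code{p}, \code{fold} (observed/expected in-set class
#'   rate, NA when undefined) and \code{degenerate}.
#' @export
fisher_one_tailed <- function(a, b, c, d, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (any(c(a, b, c, d) < 0)) stop("validation error: negative cell count")
  K <- a + c                    # class size
  n <- a + b                    # set size
  N <- a + b + c + d
  if (n == 0L || K == 0L)
    return(list(p = 1, fold = NA_real_, degenerate = TRUE))
  p <- if (direction == "greater")
    stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
  else
    stats::phyper(a, K, N - K, n, lower.tail = TRUE)
  fold <- (a / n) / (K / N)
  list(p = unname(p), fold = unname(fold), degenerate = FALSE)
}

#' Enrichment scan over gene sets x class sets
#'
#' Builds the 2x2 table of every (gene set, class set) pair against the
#' universe and reports the one-tailed p (enrichment) and fold enrichment.
#' Genes outside every class set (e.g. genes without a COG letter) remain in
#' the universe so the enrichment is fully representative.
#'
#' @param gene_sets Named list of character vectors (e.g. expression
#'   subclasses).
#' @param class_sets Named list of character vectors (e.g. COG categories).
#' @param universe Character vector of all gene ids.
#' @param adjust Apply Benjamini-Hochberg correction across the scan
#'   (default FALSE: raw one-tailed p-values, as is conventional for this
#'   analysis).
#' @return data.frame with \code{set}, \code{class}, \code{a,b,c,d},
#'   \code{fold}, \code{p} (and \code{p_adj} when \code{adjust}).
#' @export
enrichment_scan <- function(gene_sets, class_sets, universe, adjust = FALSE) {
  for (s in gene_sets) if (length(setdiff(s, universe)))
    stop("validation error: gene set not contained in universe")
  for (s in class_sets) if (length(setdiff(s, universe)))
    stop("validation error: class set not contained in universe")
  N <- length(universe)
  rows <- list()
  for (gs in names(gene_sets)) {
    G <- unique(gene_sets[[gs]])
    for (cs in names(class_sets)) {
      C <- unique(class_sets[[cs]])
      a <- length(intersect(G, C)); b <- length(G) - a
      c_ <- length(C) - a; d <- N - a - b - c_
      ft <- fisher_one_tailed(a, b, c_, d, "greater")
      rows[[length(rows) + 1L]] <- data.frame(
        set = gs, class = cs, a = a, b = b, c = c_, d = d,
        fold = ft$fold, p = if (ft$degenerate) NA_real_ else ft$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
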