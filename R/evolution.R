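# Molecular-evolution and mRNA-stability statistics.

#' Per-gene mean nonsynonymous rate (Ka)
#'
#' Arithmetic mean of the available pairwise Ka values (up to three reference
#' species); genes with no pair present are excluded.
#'
#' @param ka_pairs Numeric matrix or data.frame, genes x ortholog pairs, NA
#'   for missing orthologs; rownames are gene ids.
#' @return Named numeric vector of mean Ka (genes with >= 1 pair).
#' @export
mean_ka <- function(ka_pairs) {
  m <- as.matrix(ka_pairs)
  if (any(m < 0, na.rm = TRUE)) stop("validation error: negative rate")
  n_pairs <- rowSums(!is.na(m))
  out <- rowMeans(m, na.rm = TRUE)[n_pairs > 0]
  out
}

#' Spearman rank correlation with two-sided p
#'
#' Average ranks for ties; p-value from the t approximation (the sample sizes
#' used here are in the hundreds to thousands).
#'
#' @param x,y Numeric vectors; pairs with any NA are dropped.
#' @return List \code{(rho, n, p)}; \code{rho} is NA (flagged) for constant
#'   input.
#' @export
spearman_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("validation error: need >= 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, n = n, p = NA_real_, constant = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), n = n, p = ct$p.value, constant = FALSE)
}

#' Two-tailed group comparison
#'
#' Kruskal-Wallis for >= 2 groups, Mann-Whitney U (Wilcoxon rank-sum) or
#' Student's t for exactly 2. The Mann-Whitney p is exact for small tie-free
#' groups and uses the normal approximation with continuity correction
#' otherwise (the standard stats::wilcox.test behaviour).
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @param test "kruskal", "mannwhitney" or "ttest".
#' @param alternative Passed to the two-sample tests (default "two.sided").
#' @return List \code{(statistic, p, test, n)}.
#' @export
compare_groups <- function(values, groups,
                           test = c("kruskal", "mannwhitney", "ttest"),
                           alternative = "two.sided") {
  test <- match.arg(test)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups)[ok]
  tab <- table(groups)
  if (any(tab == 0L) || length(tab) < 2L)
    stop("validation error: need >= 2 non-empty groups")
  if (test != "kruskal" && length(tab) != 2L)
    stop("validation error: ", test, " requires exactly 2 groups")
  ht <- switch(test,
    kruskal = stats::kruskal.test(values, factor(groups)),
    mannwhitney = stats::wilcox.test(values[groups == names(tab)[1L]],
                                     values[groups == names(tab)[2L]],
                                     alternative = alternative),
    ttest = stats::t.test(values[groups == names(tab)[1L]],
                          values[groups == names(tab)[2L]],
                          alternative = alternative))
  list(statistic = unname(ht$statistic), p = ht$p.value, test = test,
       n = length(values))
}

#' Pathway expression profiles normalised to ribosomal genes
#'
#' Per-gene expression is the mean RPKM across samples; per pathway, the mean
#' and median of member values are divided by the mean and median of the
#' ribosomal reference set.
#'
#' @param em An \code{expression_matrix}.
#' @param pathway_sets Named list of gene-id vectors.
#' @param reference Gene ids of the ribosomal reference set (non-empty).
#' @return data.frame with \code{pathway}, \code{n}, \code{norm_mean},
#'   \code{norm_median} (NA-flagged for empty pathways).
#' @export
pathway_profile <- function(em, pathway_sets, reference) {
  expr <- rowMeans(em$rpkm)
  reference <- intersect(reference, names(expr))
  if (!length(reference) || !any(expr[reference] > 0))
    stop("validation error: reference set empty or unexpressed")
  ref_mean <- mean(expr[reference]); ref_median <- stats::median(expr[reference])
  rows <- lapply(names(pathway_sets), function(nm) {
    S <- intersect(pathway_sets[[nm]], names(expr))
    data.frame(pathway = nm, n = length(S),
               norm_mean = if (length(S)) mean(expr[S]) / ref_mean else NA_real_,
               norm_median = if (length(S))
                 stats::median(expr[S]) / ref_median else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

top_decile <- function(x) {
  k <- ceiling(0.1 * length(x))
  x >= sort(x, decreasing = TRUE)[[k]]
}

#' Expression vs mRNA half-life analysis
#'
#' Spearman correlation of mean expression with half-life, Kruskal-Wallis
#' across the constant HEG/MEG/LEG subclasses plus the HEG-vs-LEG
#' Mann-Whitney contrast, and an exception list: genes jointly in the top
#' expression decile and the top half-life decile (abundantly transcribed
#' yet slowly degraded).
#'
#' @param mean_expr Named per-gene mean expression (RPKM).
#' @param half_life Named per-gene half-lives in minutes (subset of genes).
#' @param stability Output of \code{\link{classify_across_samples}}.
#' @return List with \code{correlation} (rho, n, p), \code{kruskal},
#'   \code{heg_vs_leg} and \code{exceptions} (gene ids).
#' @export
halflife_analysis <- function(mean_expr, half_life, stability) {
  if (any(half_life <= 0, na.rm = TRUE))
    stop("validation error: half-lives must be positive")
  genes <- intersect(names(mean_expr), names(half_life))
  genes <- genes[!is.na(half_life[genes])]
  if (!length(genes)) stop("validation error: no genes with both datasets")
  corr <- spearman_corr(mean_expr[genes], half_life[genes])
  lab <- stats::setNames(subgroup_labels(stability), stability$gene_id)[genes]
  keep <- lab %in% c("HEG", "MEG", "LEG")
  kr <- if (length(unique(lab[keep])) >= 2L)
    compare_groups(half_life[genes][keep], lab[keep], "kruskal")
  hm <- if (all(c("HEG", "LEG") %in% lab)) {
    sel <- lab %in% c("HEG", "LEG")
    compare_groups(half_life[genes][sel], lab[sel], "mannwhitney")
  }
  exceptions <- genes[top_decile(mean_expr[genes]) &
                      top_decile(half_life[genes])]
  list(correlation = corr, kruskal = kr, heg_vs_leg = hm,
       exceptions = exceptions)
}
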