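# End-to-end orchestration: expression -> boundaries -> operons -> classes
# -> enrichment -> evolution statistics.

#' Pipeline run configuration
#'
#' Collects every tunable constant of the pipeline with the standard
#' defaults: boundary window \code{w = 90} nt, window divisor 7, coverage
#' ratios 2 and 5, binomial alpha 0.01, minimal operon support 3 samples,
#' maximal UTR scan 500 nt, minimal novel-unit length 50 nt. Either
#' synthetic-study parameters (\code{simulate = TRUE}) or input paths are
#' given. A YAML file with the same field names can be loaded via
#' \code{path}.
#'
#' @param ... Named overrides of the defaults.
#' @param path Optional YAML file of overrides (applied before \code{...}).
#' @return A \code{run_config} list.
#' @export
run_config <- function(..., path = NULL) {
  cfg <- list(
    # boundary criteria constants
    w = 90L, divisor = 7, ratio1 = 2, ratio2 = 5, alpha_binom = 0.01,
    refractory = 10L,
    # operon / UTR / novel calling
    min_support = 3L, max_scan = 500L, min_novel_len = 50L,
    # classification
    quartile = 0.25,
    # geometry
    circular = FALSE,
    # synthetic study
    simulate = TRUE, n_genes = 1965L, n_samples = 10L,
    # inputs (used when simulate = FALSE)
    annotation = NULL, coverage = NULL, counts = NULL, attributes = NULL,
    total_mapped = NULL,
    # optional reference operon map (TSV) for the comparison table
    reference_operons = NULL,
    # output
    outdir = NULL, seed = 1L)
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    cfg[names(y)] <- y
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$w > 0, cfg$divisor > 0, cfg$ratio1 > 0, cfg$ratio2 > 0,
            cfg$alpha_binom > 0, cfg$min_support > 0, cfg$max_scan > 0,
            cfg$min_novel_len > 0)
  structure(cfg, class = "run_config")
}

load_inputs <- function(cfg) {
  if (isTRUE(cfg$simulate)) {
    sim <- simulate_truth_set(n_genes = cfg$n_genes,
                              n_samples = cfg$n_samples, seed = cfg$seed)
    return(sim)
  }
  if (is.null(cfg$annotation)) stop("stage input: annotation path missing")
  annotation <- read_annotation(cfg$annotation)
  tracks <- NULL
  if (!is.null(cfg$coverage)) {
    paths <- if (length(cfg$coverage) == 1L && dir.exists(cfg$coverage))
      list.files(cfg$coverage, pattern = "\\.bedgraph$", full.names = TRUE,
                 ignore.case = TRUE)
    else cfg$coverage
    if (!length(paths)) stop("stage input: no bedGraph files found")
    tracks <- lapply(paths, read_coverage,
                     genome_length = annotation$genome_length)
    names(tracks) <- vapply(tracks, `[[`, "", "sample_id")
  }
  if (is.null(cfg$counts)) stop("stage input: counts path missing")
  counts <- read_counts(cfg$counts, total_mapped = cfg$total_mapped)
  attrs <- if (!is.null(cfg$attributes)) read_attributes(cfg$attributes)
  list(truth = NULL, tracks = tracks, counts = counts, attrs = attrs,
       annotation = annotation)
}

boundary_args <- function(cfg) {
  list(w = cfg$w, divisor = cfg$divisor, ratio1 = cfg$ratio1,
       ratio2 = cfg$ratio2, alpha = cfg$alpha_binom,
       refractory = cfg$refractory, circular = cfg$circular)
}

#' Run the full transcriptome-architecture pipeline
#'
#' Executes expression quantification, UTR and novel-transcript boundary
#' calling, operon assembly, expression classification, enrichment scans and
#' the evolution/half-life statistics, on either a simulated study or files
#' named in the configuration. All stages are deterministic given the
#' configuration and seed; when \code{outdir} is set, every table is written
#' (TSV/GFF3/BED) together with a machine-readable \code{summary.json}
#' echoing the parameters and seed.
#'
#' @param config A \code{\link{run_config}}.
#' @return An object of class \code{txmap_run} with components
#'   \code{annotation}, \code{em} (expression matrix), \code{utrs},
#'   \code{novel}, \code{operons}, \code{classes}, \code{stability},
#'   \code{composition}, \code{enrichment}, \code{evolution},
#'   \code{operon_comparison} (when a reference map is given), \code{truth}
#'   (when simulated) and \code{summary}.
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- config
  inputs <- load_inputs(cfg)
  annotation <- if (!is.null(inputs$truth)) inputs$truth$annotation
                else inputs$annotation
  tracks <- inputs$tracks
  ## expression ---------------------------------------------------------------
  em <- expression_matrix(inputs$counts, annotation, tracks = tracks)
  orfs <- annotation$orfs
  partition <- stats::setNames(orfs$partition, orfs$gene_id)
  ## boundaries / operons / novel ---------------------------------------------
  utrs <- NULL; novel <- NULL; operons <- NULL
  if (!is.null(tracks)) {
    bg <- em$genome_background
    ba <- boundary_args(cfg)
    utrs <- do.call(call_utrs, c(list(tracks, annotation, bg,
                                      expressed = em$expressed,
                                      max_scan = cfg$max_scan), ba))
    novel <- detect_novel_transcripts(tracks, annotation, bg,
                                      min_len = cfg$min_novel_len,
                                      utrs = utrs)
    operons <- do.call(call_operons,
                       c(list(tracks, annotation, em,
                              min_support = cfg$min_support), ba))
  }
  ## classes ------------------------------------------------------------------
  classes <- classify_all_samples(em)
  stability <- classify_across_samples(classes)
  composition <- subclass_composition(stability, partition)
  subgroup <- stats::setNames(subgroup_labels(stability), stability$gene_id)
  subgroup_sets <- split(names(subgroup), subgroup)
  ## enrichment ---------------------------------------------------------------
  universe <- orfs$gene_id
  cog_sets <- split(orfs$gene_id, orfs$cog)
  core_genes <- orfs$gene_id[orfs$partition %in% "core"]
  enrichment <- list(
    # COG enrichment of the constant-HEG subclass within the core genome
    cog_heg_core = if (length(cog_sets))
      enrichment_scan(list(HEG = intersect(subgroup_sets$HEG, core_genes)),
                      lapply(cog_sets, intersect, y = core_genes),
                      core_genes),
    # essential-gene enrichment in the partitions
    deg_partition = enrichment_scan(
      list(core = core_genes,
           flexible = orfs$gene_id[orfs$partition %in% "flexible"]),
      list(deg_hit = orfs$gene_id[orfs$deg_hit %in% TRUE]),
      universe))
  ## evolution / half-life ----------------------------------------------------
  evolution <- NULL
  if (!is.null(inputs$attrs)) {
    attrs <- inputs$attrs
    ka <- mean_ka(attr_ka_matrix(attrs))
    mean_expr <- rowMeans(em$rpkm)
    shared <- intersect(names(ka), names(mean_expr))
    lab <- subgroup[shared]
    keep3 <- lab %in% c("HEG", "MEG", "LEG")
    stab <- stats::setNames(stability$stability, stability$gene_id)[shared]
    og <- operon_gene_ids(operons)
    in_op <- shared %in% og
    hl <- attr_half_life(attrs)
    deg <- stats::setNames(attrs$deg_hit, attrs$gene_id)
    deg_lab <- ifelse(deg[names(mean_expr)] %in% TRUE, "hit", "miss")
    pathway_sets <- split(orfs$gene_id, orfs$pathway)
    evolution <- list(
      expr_ka = spearman_corr(mean_expr[shared], ka[shared]),
      ka_by_class = if (length(unique(lab[keep3])) >= 2L)
        compare_groups(ka[shared][keep3], lab[keep3], "kruskal"),
      ka_ceg_vs_veg = compare_groups(ka[shared], stab, "mannwhitney"),
      ka_operon_vs_not = if (!is.null(operons) && any(in_op) && !all(in_op))
        compare_groups(ka[shared], ifelse(in_op, "operon", "non_operon"),
                       "mannwhitney"),
      rpkm_deg = compare_groups(mean_expr, deg_lab, "ttest"),
      pathways = if (length(pathway_sets) && any(orfs$is_ribosomal))
        pathway_profile(em, pathway_sets,
                        orfs$gene_id[orfs$is_ribosomal]),
      halflife = if (length(hl) && any(!is.na(hl)))
        halflife_analysis(mean_expr, hl, stability),
      ka_halflife = if (length(hl) && sum(!is.na(hl[names(ka)])) >= 3)
        spearman_corr(ka, hl[names(ka)]))
  }
  ## operon statistics / comparison -------------------------------------------
  op_stats <- NULL; op_cmp <- NULL
  if (!is.null(operons)) {
    sets <- c(subgroup_sets[intersect(c("HEG", "MEG", "LEG", "VEG"),
                                      names(subgroup_sets))],
              list(core = core_genes,
                   flexible = orfs$gene_id[orfs$partition %in% "flexible"]))
    op_stats <- operon_stats(operons, sets)
    if (!is.null(cfg$reference_operons)) {
      ref <- read_reference_operons(cfg$reference_operons, annotation)
      op_cmp <- compare_operon_maps(operons, ref)
    }
  }
  ## summary ------------------------------------------------------------------
  expressed_rate <- function(genes) {
    idx <- intersect(genes, rownames(em$expressed))
    colMeans(em$expressed[idx, , drop = FALSE])
  }
  summary <- list(
    parameters = unclass(cfg)[c("w", "divisor", "ratio1", "ratio2",
                                "alpha_binom", "min_support", "max_scan",
                                "min_novel_len", "quartile", "circular",
                                "seed")],
    n_genes = nrow(orfs), n_samples = ncol(em$rpkm),
    expression_rate = list(
      all = expressed_rate(orfs$gene_id),
      core = expressed_rate(core_genes),
      flexible = expressed_rate(orfs$gene_id[orfs$partition %in% "flexible"])),
    expressed_fraction_any = mean(rowSums(em$expressed) > 0),
    expressed_fraction_all = mean(rowSums(em$expressed) == ncol(em$expressed)))
  if (!is.null(tracks)) {
    summary$transcribed_fraction_any <-
      transcribed_fraction(tracks, em$genome_background, "any")
    summary$transcribed_fraction_all <-
      transcribed_fraction(tracks, em$genome_background, "all")
    summary$n_operons <- length(operons$operons)
    summary$operon_rate <- operons$genome_operon_rate
    sizes <- vapply(operons$operons, function(o) length(o$genes), 1L)
    summary$two_gene_operon_fraction <- if (length(sizes)) mean(sizes == 2L)
    summary$n_utr5 <- sum(utrs$kind == "5prime")
    summary$n_utr3 <- sum(utrs$kind == "3prime")
    summary$median_utr5 <- if (any(utrs$kind == "5prime"))
      stats::median(utrs$length[utrs$kind == "5prime"])
    summary$n_novel <- nrow(novel)
  }
  run <- structure(list(config = cfg, annotation = annotation, em = em,
                        utrs = utrs, novel = novel, operons = operons,
                        classes = classes, stability = stability,
                        composition = composition, enrichment = enrichment,
                        evolution = evolution, operon_stats = op_stats,
                        operon_comparison = op_cmp, truth = inputs$truth,
                        summary = summary),
                   class = "txmap_run")
  if (!is.null(cfg$outdir)) write_run(run, cfg$outdir)
  run
}

#' Write all pipeline outputs to a directory
#'
#' @param run A \code{txmap_run}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(run$annotation, file.path(dir, "annotation.gff3"))
  write_expression(run$em, file.path(dir, "rpkm.tsv"))
  cls <- data.frame(gene_id = rownames(run$classes), run$classes,
                    stability = run$stability$stability,
                    constant_class = run$stability$constant_class,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cls, file.path(dir, "classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$composition, file.path(dir, "subclass_composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$operons)) {
    write_operons(run$operons, file.path(dir, "operons.tsv"))
    write_utrs(run$utrs, file.path(dir, "utrs.tsv"))
    write_features(run$operons, run$utrs, run$novel, run$annotation, dir)
  }
  if (!is.null(run$operon_stats))
    utils::write.table(run$operon_stats, file.path(dir, "operon_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  stats_json <- list(summary = run$summary,
                     evolution = run$evolution,
                     operon_comparison = if (!is.null(run$operon_comparison))
                       as.list(unclass(run$operon_comparison)))
  jsonlite::write_json(stats_json, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' @export
print.txmap_run <- function(x, ...) {
  cat("<txmap_run> ", x$summary$n_genes, " genes x ", x$summary$n_samples,
      " samples\n", sep = "")
  cat("  expressed in >=1 sample: ",
      format(100 * x$summary$expressed_fraction_any, digits = 4), "%\n",
      sep = "")
  if (!is.null(x$operons)) {
    cat("  operons: ", x$summary$n_operons, " (operon rate ",
        format(x$summary$operon_rate, digits = 4), ", 2-gene fraction ",
        format(x$summary$two_gene_operon_fraction, digits = 4), ")\n",
        sep = "")
    cat("  UTRs: ", x$summary$n_utr5, " 5' (median ", x$summary$median_utr5,
        " nt), ", x$summary$n_utr3, " 3'; novel units: ",
        x$summary$n_novel, "\n", sep = "")
  }
  if (!is.null(x$evolution))
    cat("  expression~Ka Spearman rho = ",
        format(x$evolution$expr_ka$rho, digits = 3), " (n = ",
        x$evolution$expr_ka$n, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.txmap_run <- function(object, ...) {
  print(object)
  cat("\nSubclass composition (fractions):\n")
  print(object$composition[, c("partition", "subgroup", "fraction",
                               "p_enriched")])
  invisible(object$summary)
}

#' Simulate a study and write its input files
#'
#' Emits the exact formats the pipeline reads: \code{annotation.gff3},
#' per-sample \code{<sample>.bedgraph}, \code{counts.tsv},
#' \code{attributes.tsv}, \code{total_mapped.tsv} and \code{truth.json}.
#'
#' @param dir Output directory.
#' @param n_genes,n_samples,seed Study parameters.
#' @param ... Passed to \code{\link{generate_genome}}.
#' @return \code{dir}, invisibly.
#' @export
simulate_to_files <- function(dir, n_genes = 1965L, n_samples = 10L,
                              seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_truth_set(n_genes = n_genes, n_samples = n_samples,
                            seed = seed, ...)
  annotation <- sim$truth$annotation
  write_annotation(annotation, file.path(dir, "annotation.gff3"))
  for (s in names(sim$tracks))
    write_coverage(sim$tracks[[s]], file.path(dir, paste0(s, ".bedgraph")),
                   genome_id = annotation$genome_id)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  totals <- data.frame(sample_id = names(sim$counts),
                       total_mapped = vapply(sim$counts, `[[`, 1,
                                             "total_mapped"))
  utils::write.table(totals, file.path(dir, "total_mapped.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_attributes(sim$attrs, file.path(dir, "attributes.tsv"))
  truth <- sim$truth
  truth_json <- list(
    seed = truth$seed, params = truth$params,
    operon_truth = lapply(truth$operon_truth, identity),
    utr_truth = truth$utr_truth, novel_truth = truth$novel_truth,
    units = truth$units)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
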