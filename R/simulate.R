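# Synthetic genomes, coverage and attributes with planted ground truth.
#
# The generator emulates the statistical regime of a deeply sequenced compact
# cyanobacterial transcriptome: ~2000 ORFs on a ~1.8 Mb two-strand genome,
# ten samples, a majority of operons with two genes, short 5'UTRs (median
# ~29 nt), mean gene coverage in the tens-to-hundreds (several million 90-bp
# reads on a ~1.7 Mb genome), and gene attributes rank-coupled to expression.

default_operon_size_probs <- c(`2` = 0.63, `3` = 0.20, `4` = 0.09, `5` = 0.05,
                               `6` = 0.02, `7` = 0.007, `8` = 0.003)

# per-partition stationary subgroup proportions (constant HEG/MEG/LEG/NEG, VEG)
default_class_probs_core <- c(HEG = 0.177, MEG = 0.268, LEG = 0.044,
                              NEG = 0.015, VEG = 0.496)
default_class_probs_flex <- c(HEG = 0.115, MEG = 0.153, LEG = 0.020,
                              NEG = 0.066, VEG = 0.646)
# per-sample class distribution of variably expressed units: condition-
# specific genes sit low in most conditions; the NEG weight is set so the
# per-sample gene expression rate lands near the observed ~91%
default_veg_probs <- c(HEG = 0.15, MEG = 0.30, LEG = 0.45, NEG = 0.10)

# intended mean per-nucleotide depth of each class band
default_depth_bands <- c(HEG = 400, MEG = 150, LEG = 60, NEG = 0)

default_pathway_profiles <- list(
  photosynthesis = list(units = 18, probs = c(HEG = .50, MEG = .30, LEG = 0,
                                              NEG = 0, VEG = .20)),
  carbon         = list(units = 12, probs = c(HEG = .30, MEG = .45, LEG = 0,
                                              NEG = 0, VEG = .25)),
  nitrogen       = list(units = 8,  probs = c(HEG = 0, MEG = .30, LEG = .40,
                                              NEG = 0, VEG = .30)),
  phosphate      = list(units = 6,  probs = c(HEG = 0, MEG = .40, LEG = .20,
                                              NEG = 0, VEG = .40)),
  hli            = list(units = 8,  probs = c(HEG = .30, MEG = 0, LEG = 0,
                                              NEG = 0, VEG = .70)),
  phage          = list(units = 10, probs = c(HEG = 0, MEG = 0, LEG = .30,
                                              NEG = .40, VEG = .30)))

#' Generate a synthetic annotated genome with planted architecture
#'
#' Lays out \code{n_genes} ORFs on a linear genome as transcription units:
#' operon chains (contiguous, same strand) and singletons, with planted 5'
#' and 3' UTR lengths per unit, intergenic gaps of at least 40 nt, and
#' optional planted intergenic (novel) transcript units. Units carry
#' partition (core/flexible), expression-stability (constant class or
#' variable), pathway, COG and essentiality labels. One 20-gene
#' ribosomal-protein-style operon is planted on large genomes.
#'
#' @param n_genes Number of ORFs (>= 20).
#' @param operon_fraction Target fraction of genes inside operons.
#' @param operon_size_probs Named probabilities over operon sizes 2..8.
#' @param core_fraction Probability that a unit is core.
#' @param class_probs_core,class_probs_flex Stationary subgroup proportions
#'   (HEG/MEG/LEG/NEG constant classes plus VEG) per partition.
#' @param utr5_meanlog,utr5_sdlog,utr3_meanlog,utr3_sdlog Log-normal UTR
#'   length parameters (defaults: median 29 nt 5'UTRs with ~9% over 100 nt;
#'   median 40 nt 3'UTRs with ~1/3 over 60 nt).
#' @param gap_range Inter-unit intergenic gap range (nt).
#' @param gene_length_meanlog,gene_length_sdlog ORF length distribution.
#' @param n_novel Number of planted intergenic transcript units.
#' @param pathway_profiles Pathway unit quotas and class-probability
#'   overrides (scaled with \code{n_genes}).
#' @param seed RNG seed; the truth set is fully reproducible from
#'   (parameters, seed).
#' @return A \code{truth_set}: list with \code{annotation}, \code{units}
#'   (per-unit table), \code{operon_truth} (gene chains), \code{utr_truth},
#'   \code{novel_truth}, \code{params}, \code{seed}.
#' @export
generate_genome <- function(n_genes = 1965L,
                            operon_fraction = 0.555,
                            operon_size_probs = default_operon_size_probs,
                            core_fraction = 0.637,
                            class_probs_core = default_class_probs_core,
                            class_probs_flex = default_class_probs_flex,
                            utr5_meanlog = log(29), utr5_sdlog = 0.92,
                            utr3_meanlog = log(40), utr3_sdlog = 1.0,
                            gap_range = c(100L, 400L),
                            gene_length_meanlog = log(750),
                            gene_length_sdlog = 0.45,
                            n_novel = 7L,
                            pathway_profiles = default_pathway_profiles,
                            seed = 1L) {
  if (n_genes < 20L) stop("validation error: n_genes must be >= 20")
  set.seed(seed)
  ## --- operon size plan ----------------------------------------------------
  target <- round(operon_fraction * n_genes)
  sizes <- integer(0)
  rib_unit <- NA_integer_
  if (n_genes >= 300L && target >= 20L) { sizes <- 20L; rib_unit <- 1L }
  repeat {
    if (sum(sizes) >= target - 1L) break
    s <- as.integer(sample(names(operon_size_probs), 1L,
                           prob = operon_size_probs))
    if (sum(sizes) + s > target) {
      rem <- target - sum(sizes)
      if (rem >= 2L) sizes <- c(sizes, rem)
      break
    }
    sizes <- c(sizes, s)
  }
  n_singletons <- n_genes - sum(sizes)
  unit_sizes <- c(sizes, rep(1L, n_singletons))
  is_rib <- if (is.na(rib_unit)) rep(FALSE, length(unit_sizes))
            else seq_along(unit_sizes) == rib_unit
  ord <- sample.int(length(unit_sizes))
  unit_sizes <- unit_sizes[ord]; is_rib <- is_rib[ord]
  n_units <- length(unit_sizes)

  ## --- unit labels ---------------------------------------------------------
  strand <- sample(c("+", "-"), n_units, replace = TRUE)
  partition <- ifelse(stats::runif(n_units) < core_fraction, "core", "flexible")
  partition[is_rib] <- "core"
  subgroups <- c("HEG", "MEG", "LEG", "NEG", "VEG")
  subgroup <- character(n_units)
  for (u in seq_len(n_units)) {
    pr <- if (partition[u] == "core") class_probs_core else class_probs_flex
    subgroup[u] <- sample(subgroups, 1L, prob = pr[subgroups])
  }
  subgroup[is_rib] <- "HEG"
  ## pathways: quotas scale with genome size; class-probability overrides
  pathway <- rep(NA_character_, n_units)
  pathway[is_rib] <- "ribosomal"
  scale <- n_genes / 1965
  eligible <- which(!is_rib)
  for (pw in names(pathway_profiles)) {
    quota <- max(1L, round(pathway_profiles[[pw]]$units * scale))
    pick <- sample(eligible, min(quota, length(eligible)))
    pathway[pick] <- pw
    pr <- pathway_profiles[[pw]]$probs
    for (u in pick) subgroup[u] <- sample(subgroups, 1L, prob = pr[subgroups])
    eligible <- setdiff(eligible, pick)
  }

  ## --- geometry ------------------------------------------------------------
  n_elements <- n_units + n_novel
  novel_slots <- if (n_novel > 0L) sort(sample.int(n_elements, n_novel))
                 else integer(0)
  margin <- 400L
  cursor <- margin
  gene_id <- character(n_genes); gstart <- integer(n_genes)
  gend <- integer(n_genes); gstrand <- character(n_genes)
  gunit <- integer(n_genes)
  unit_start <- integer(n_units); unit_end <- integer(n_units)
  utr5 <- integer(n_units); utr3 <- integer(n_units)
  novel_start <- integer(n_novel); novel_end <- integer(n_novel)
  gi <- 0L; ui <- 0L; ni <- 0L
  gaps <- sample(gap_range[1L]:gap_range[2L], n_elements, replace = TRUE)
  for (el in seq_len(n_elements)) {
    gap <- gaps[el]
    cursor <- cursor + gap
    # UTR budget: half of the flanking gap on each side, so that two
    # neighbouring transcript spans always leave >= 10 untranscribed nt
    gap_after <- if (el < n_elements) gaps[el + 1L] else margin
    half_l <- max(0L, (gap - 10L) %/% 2L)
    half_r <- max(0L, (gap_after - 10L) %/% 2L)
    if (el %in% novel_slots) {
      ni <- ni + 1L
      len <- sample(150:400, 1L)
      novel_start[ni] <- cursor; novel_end[ni] <- cursor + len
      cursor <- cursor + len
    } else {
      ui <- ui + 1L
      half5 <- if (strand[ui] == "+") half_l else half_r   # 5'UTR side
      half3 <- if (strand[ui] == "+") half_r else half_l
      u5 <- min(round(stats::rlnorm(1L, utr5_meanlog, utr5_sdlog)), half5)
      u3 <- min(round(stats::rlnorm(1L, utr3_meanlog, utr3_sdlog)), half3)
      utr5[ui] <- u5; utr3[ui] <- u3
      unit_start[ui] <- cursor
      for (k in seq_len(unit_sizes[ui])) {
        gi <- gi + 1L
        len <- as.integer(pmin(pmax(round(
          stats::rlnorm(1L, gene_length_meanlog, gene_length_sdlog)), 120), 3000))
        if (is_rib[ui]) len <- sample(250:700, 1L)   # ribosomal proteins are short
        gene_id[gi] <- sprintf("g%04d", gi)
        gstart[gi] <- cursor; gend[gi] <- cursor + len
        gstrand[gi] <- strand[ui]; gunit[gi] <- ui
        cursor <- cursor + len
        if (k < unit_sizes[ui]) cursor <- cursor + sample(3:40, 1L)
      }
      unit_end[ui] <- cursor
    }
  }
  genome_length <- cursor + margin

  ## --- per-gene labels -----------------------------------------------------
  cog_pool <- c("E", "F", "G", "H", "I", "K", "L", "M", "N", "O", "P", "Q",
                "R", "S", "T")
  cog <- character(n_genes); deg <- logical(n_genes)
  for (g in seq_len(n_genes)) {
    u <- gunit[g]
    cog[g] <- if (is_rib[u]) "J"
      else if (!is.na(pathway[u]) && pathway[u] %in% c("photosynthesis", "carbon")) "C"
      else if (partition[u] == "core" && subgroup[u] == "HEG" &&
               stats::runif(1L) < 0.3) "O"
      else if (stats::runif(1L) < 0.25) NA_character_
      else sample(cog_pool, 1L)
    deg[g] <- stats::runif(1L) <
      if (partition[u] == "core") 0.613 else 0.146
  }

  orfs <- data.frame(gene_id = gene_id, start = gstart, end = gend,
                     strand = gstrand, partition = partition[gunit],
                     cog = cog, deg_hit = deg, pathway = pathway[gunit],
                     is_ribosomal = is_rib[gunit], stringsAsFactors = FALSE)
  annotation <- genome_annotation("synthetic_genome", genome_length, orfs)

  units <- data.frame(unit_id = seq_len(n_units), size = unit_sizes,
                      strand = strand, start = unit_start, end = unit_end,
                      utr5 = utr5, utr3 = utr3, partition = partition,
                      subgroup = subgroup, pathway = pathway,
                      is_ribosomal = is_rib, stringsAsFactors = FALSE)
  first_gene <- gene_id[match(seq_len(n_units), gunit)]
  gene_unit <- stats::setNames(gunit, gene_id)
  operon_truth <- lapply(which(unit_sizes >= 2L),
                         function(u) gene_id[gunit == u])
  # the 5'UTR anchors at the unit's transcriptionally first gene, the 3'UTR
  # at its last; both at the same gene for singletons
  utr_truth <- do.call(rbind, lapply(seq_len(n_units), function(u) {
    g <- gene_id[gunit == u]
    five <- if (strand[u] == "+") g[1L] else g[length(g)]
    three <- if (strand[u] == "+") g[length(g)] else g[1L]
    data.frame(unit_id = u,
               gene_5prime = five, utr5 = utr5[u],
               gene_3prime = three, utr3 = utr3[u],
               stringsAsFactors = FALSE)
  }))
  novel_truth <- data.frame(start = novel_start, end = novel_end,
                            stringsAsFactors = FALSE)

  structure(list(annotation = annotation, units = units,
                 gene_unit = gene_unit,
                 operon_truth = operon_truth, utr_truth = utr_truth,
                 novel_truth = novel_truth,
                 expression_truth = NULL, ka_truth = NULL,
                 halflife_truth = NULL,
                 params = list(n_genes = n_genes,
                               operon_fraction = operon_fraction,
                               core_fraction = core_fraction),
                 seed = seed),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("<truth_set> ", length(x$gene_unit), " genes, ",
      length(x$operon_truth), " planted operons, ",
      nrow(x$novel_truth), " novel units, genome ",
      x$annotation$genome_length, " nt (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Simulate coverage tracks and gene counts from a truth set
#'
#' Coverage is a step function over transcript units (operon span plus
#' planted UTRs) at the unit's intended depth, with per-position count noise
#' (Poisson by default, negative binomial for overdispersion) and a small
#' uniform noise floor. Constant units keep their class band in every
#' sample; variable units redraw their class per sample. Per-gene counts are
#' the gene-span coverage sums divided by a read-length proxy, so counts and
#' coverage are mutually consistent.
#'
#' @param truth A \code{truth_set} from \code{\link{generate_genome}}.
#' @param n_samples Number of samples (default 10).
#' @param depth_scale Multiplier on all class depth bands.
#' @param depth_bands Named intended depths for HEG/MEG/LEG/NEG.
#' @param veg_probs Per-sample class distribution of variable units.
#' @param noise \code{"poisson"}, \code{"negbin"} or \code{"none"}
#'   (deterministic rounded intensities).
#' @param negbin_size Negative binomial size (dispersion) parameter.
#' @param band_sd Log-normal sd of the per-unit per-sample band jitter.
#' @param gene_sd Log-normal sd of the fixed per-gene depth multiplier.
#' @param noise_floor Mean background depth added everywhere.
#' @param read_length Read-length proxy dividing coverage into counts.
#' @param tracks Generate per-nucleotide tracks (TRUE) or only counts drawn
#'   directly from the same intensity model (FALSE; faster for
#'   expression-level analyses).
#' @param seed RNG seed.
#' @return List with \code{tracks} (named list of \code{coverage_track} or
#'   NULL), \code{counts} (named list of \code{gene_counts}) and \code{truth}
#'   (input truth with \code{expression_truth} filled in: per-gene per-sample
#'   intended depth and intended class, plus per-gene multipliers).
#' @export
simulate_coverage <- function(truth, n_samples = 10L, depth_scale = 1,
                              depth_bands = default_depth_bands,
                              veg_probs = default_veg_probs,
                              noise = c("poisson", "negbin", "none"),
                              negbin_size = 10,
                              band_sd = 0.12, gene_sd = 0.08,
                              noise_floor = 0.01, read_length = 90,
                              tracks = TRUE, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(depth_scale > 0)
  set.seed(seed)
  units <- truth$units
  orfs <- truth$annotation$orfs
  n_units <- nrow(units); n_genes <- nrow(orfs)
  L <- truth$annotation$genome_length
  sample_ids <- sprintf("s%02d", seq_len(n_samples))
  classes4 <- c("HEG", "MEG", "LEG", "NEG")

  # per-unit per-sample class
  unit_class <- matrix(NA_character_, n_units, n_samples,
                       dimnames = list(NULL, sample_ids))
  for (u in seq_len(n_units)) {
    unit_class[u, ] <- if (units$subgroup[u] == "VEG")
      sample(classes4, n_samples, replace = TRUE, prob = veg_probs[classes4])
    else rep(units$subgroup[u], n_samples)
  }
  # per-unit per-sample intended depth; per-gene fixed multiplier
  band <- depth_bands[unit_class] * depth_scale
  dim(band) <- dim(unit_class)
  unit_depth <- band * exp(matrix(stats::rnorm(n_units * n_samples, 0, band_sd),
                                  n_units, n_samples))
  unit_depth[band == 0] <- 0
  colnames(unit_depth) <- sample_ids
  gene_mult <- exp(stats::rnorm(n_genes, 0, gene_sd))
  names(gene_mult) <- orfs$gene_id
  uidx <- truth$gene_unit[orfs$gene_id]
  gene_depth <- unit_depth[uidx, , drop = FALSE] * gene_mult
  rownames(gene_depth) <- orfs$gene_id
  gene_class <- unit_class[uidx, , drop = FALSE]
  rownames(gene_class) <- orfs$gene_id

  glen <- orfs$end - orfs$start
  draw <- function(lambda) {
    switch(noise,
           poisson = stats::rpois(length(lambda), lambda),
           negbin = stats::rnbinom(length(lambda), mu = lambda,
                                   size = negbin_size),
           none = round(lambda))
  }
  novel_depth <- depth_bands[["MEG"]] * depth_scale   # planted novel units: constant
  out_tracks <- if (tracks) vector("list", n_samples)
  out_counts <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    if (tracks) {
      lambda <- rep(noise_floor, L)
      for (u in seq_len(n_units)) {
        if (unit_depth[u, s] <= 0) next
        span_start <- if (units$strand[u] == "+") units$start[u] - units$utr5[u]
                      else units$start[u] - units$utr3[u]
        span_end <- if (units$strand[u] == "+") units$end[u] + units$utr3[u]
                    else units$end[u] + units$utr5[u]
        idx <- (span_start + 1L):span_end
        lambda[idx] <- lambda[idx] + unit_depth[u, s]
      }
      for (g in seq_len(n_genes)) {    # per-gene multiplier applies on ORF span
        if (gene_depth[g, s] <= 0 || gene_mult[g] == 1) next
        idx <- (orfs$start[g] + 1L):orfs$end[g]
        lambda[idx] <- noise_floor + gene_depth[g, s]
      }
      for (k in seq_len(nrow(truth$novel_truth))) {
        idx <- (truth$novel_truth$start[k] + 1L):truth$novel_truth$end[k]
        lambda[idx] <- lambda[idx] + novel_depth
      }
      depth <- draw(lambda)
      cnt <- round(vapply(seq_len(n_genes), function(g)
        sum(depth[(orfs$start[g] + 1L):orfs$end[g]]), numeric(1L)) / read_length)
      total <- max(round(sum(depth) / read_length), sum(cnt), 1)
      out_tracks[[s]] <- coverage_track(sample_ids[s], depth)
    } else {
      cnt <- draw((gene_depth[, s] + noise_floor) * glen / read_length)
      total <- sum(cnt) +
        round(noise_floor * (L - sum(glen)) / read_length) + 1
    }
    out_counts[[s]] <- gene_counts(sample_ids[s],
                                   stats::setNames(cnt, orfs$gene_id), total)
  }
  if (tracks) names(out_tracks) <- sample_ids
  names(out_counts) <- sample_ids
  truth$expression_truth <- list(gene_depth = gene_depth,
                                 gene_class = gene_class,
                                 unit_class = unit_class,
                                 gene_mult = gene_mult,
                                 depth_bands = depth_bands * depth_scale)
  list(tracks = out_tracks, counts = out_counts, truth = truth)
}

#' Simulate gene attributes rank-coupled to planted expression
#'
#' Ka and mRNA half-life are generated by a Gaussian-copula rank coupling to
#' the planted mean expression (the copula parameter is chosen as
#' 2 sin(pi rho / 6) so the target Spearman correlation holds in
#' expectation). Core genes carry all three ortholog pairs; flexible genes
#' usually lack orthologs in the comparator species. A planted exception set
#' receives top-decile expression and top-decile half-life.
#'
#' @param truth A \code{truth_set} with \code{expression_truth} (run
#'   \code{\link{simulate_coverage}} first).
#' @param rho_ka Target Spearman correlation of mean expression with Ka
#'   (default -0.68).
#' @param rho_halflife Target Spearman correlation of mean expression with
#'   half-life (default -0.43; combined with \code{rho_ka} this implies a
#'   Ka-half-life rank correlation near +0.29).
#' @param n_exceptions Number of high-expression long-half-life exception
#'   genes.
#' @param ka_meanlog,ka_sdlog,hl_meanlog,hl_sdlog Marginal log-normal
#'   parameters for Ka (substitutions/site) and half-life (minutes).
#' @param flex_ortholog_prob Probability that a flexible gene has orthologs.
#' @param hl_missing Fraction of genes without a half-life measurement.
#' @param seed RNG seed.
#' @return List with \code{attrs} (a \code{gene_attributes} table) and
#'   \code{truth} (with \code{ka_truth} and \code{halflife_truth} filled in).
#' @export
simulate_attributes <- function(truth, rho_ka = -0.68, rho_halflife = -0.43,
                                n_exceptions = 7L,
                                ka_meanlog = log(0.08), ka_sdlog = 0.7,
                                hl_meanlog = log(2.4), hl_sdlog = 0.45,
                                flex_ortholog_prob = 0.05, hl_missing = 0.1,
                                seed = 1L) {
  stopifnot(abs(rho_ka) <= 1, abs(rho_halflife) <= 1)
  if (is.null(truth$expression_truth))
    stop("run simulate_coverage() before simulate_attributes()")
  set.seed(seed)
  orfs <- truth$annotation$orfs
  n <- nrow(orfs)
  mu <- rowMeans(truth$expression_truth$gene_depth)
  z <- stats::qnorm((rank(mu, ties.method = "first") - 0.5) / n)

  couple <- function(rho, meanlog, sdlog) {
    r <- 2 * sin(pi * rho / 6)           # copula parameter hitting Spearman rho
    zc <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
    stats::qlnorm(stats::pnorm(zc), meanlog, sdlog)
  }
  ka <- couple(rho_ka, ka_meanlog, ka_sdlog)
  hl <- couple(rho_halflife, hl_meanlog, hl_sdlog)

  has_orth <- orfs$partition == "core" |
    stats::runif(n) < flex_ortholog_prob
  ka_pairs <- matrix(NA_real_, n, 3L, dimnames = list(orfs$gene_id, ka_cols))
  ks_pairs <- matrix(NA_real_, n, 3L, dimnames = list(orfs$gene_id, ks_cols))
  for (g in which(has_orth)) {
    k <- if (orfs$partition[g] == "core") 3L else sample(1:3, 1L)
    cols <- seq_len(k)
    ka_pairs[g, cols] <- ka[g] * exp(stats::rnorm(k, 0, 0.15))
    ks_pairs[g, cols] <- ka_pairs[g, cols] / stats::runif(k, 0.05, 0.4)
  }

  hl[stats::runif(n) < hl_missing] <- NA
  exceptions <- character(0)
  if (n_exceptions > 0L) {
    top_expr <- which(top_decile(mu))
    exceptions <- orfs$gene_id[sample(top_expr, min(n_exceptions,
                                                    length(top_expr)))]
    idx <- match(exceptions, orfs$gene_id)
    hl[idx] <- max(hl, na.rm = TRUE) * stats::runif(length(idx), 1.0, 1.2)
  }

  attrs <- gene_attributes(data.frame(
    gene_id = orfs$gene_id,
    ka_pairs, ks_pairs,
    half_life_min = hl,
    partition = orfs$partition, cog = orfs$cog, deg_hit = orfs$deg_hit,
    pathway = orfs$pathway, is_ribosomal = orfs$is_ribosomal,
    stringsAsFactors = FALSE, check.names = FALSE))
  truth$ka_truth <- list(rho_ka = rho_ka, ka = stats::setNames(ka, orfs$gene_id))
  truth$halflife_truth <- list(rho_halflife = rho_halflife,
                               half_life = stats::setNames(hl, orfs$gene_id),
                               exceptions = exceptions)
  list(attrs = attrs, truth = truth)
}

#' Generate a complete synthetic study (genome, coverage, counts, attributes)
#'
#' Convenience wrapper chaining \code{\link{generate_genome}},
#' \code{\link{simulate_coverage}} and \code{\link{simulate_attributes}};
#' sub-seeds are derived deterministically from \code{seed}.
#'
#' @param n_genes,n_samples Study size (defaults 1965 genes, 10 samples).
#' @param seed Master RNG seed.
#' @param tracks Generate per-nucleotide coverage tracks.
#' @param ... Passed to \code{\link{generate_genome}}.
#' @return List with \code{truth}, \code{tracks}, \code{counts},
#'   \code{attrs}.
#' @export
simulate_truth_set <- function(n_genes = 1965L, n_samples = 10L, seed = 1L,
                               tracks = TRUE, ...) {
  truth <- generate_genome(n_genes = n_genes, seed = seed, ...)
  cov <- simulate_coverage(truth, n_samples = n_samples, tracks = tracks,
                           seed = seed + 1000L)
  att <- simulate_attributes(cov$truth, seed = seed + 2000L)
  list(truth = att$truth, tracks = cov$tracks, counts = cov$counts,
       attrs = att$attrs)
}
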