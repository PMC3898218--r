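# class settings that keep every unit expressed (deep, well-separated bands)
expressed_probs <- c(HEG = 0.25, MEG = 0.40, LEG = 0.35, NEG = 0, VEG = 0)

test_that("the truth set is byte-identical for a fixed seed", {
  g1 <- generate_genome(n_genes = 60, seed = 42)
  g2 <- generate_genome(n_genes = 60, seed = 42)
  expect_identical(g1, g2)
  s1 <- simulate_coverage(g1, n_samples = 3, seed = 5)
  s2 <- simulate_coverage(g2, n_samples = 3, seed = 5)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$counts, s2$counts)
  a1 <- simulate_attributes(s1$truth, seed = 6)
  a2 <- simulate_attributes(s2$truth, seed = 6)
  expect_identical(a1$attrs, a2$attrs)
  g3 <- generate_genome(n_genes = 60, seed = 43)
  expect_false(identical(g1$annotation, g3$annotation))
})

test_that("genome layout honours the planted architecture", {
  truth <- generate_genome(n_genes = 200, operon_fraction = 0.5, seed = 2)
  sizes <- vapply(truth$operon_truth, length, 1L)
  expect_true(all(sizes >= 2L))
  expect_lte(abs(sum(sizes) - 100L), 1L)          # operon genes within 1
  # planted operon members are adjacent and same-strand
  orfs <- truth$annotation$orfs
  for (chain in truth$operon_truth) {
    idx <- match(chain, orfs$gene_id)
    expect_equal(idx, seq(idx[1L], by = 1L, length.out = length(idx)))
    expect_length(unique(orfs$strand[idx]), 1L)
  }
  # inter-unit ORF gaps stay comfortably apart
  unit_of <- truth$gene_unit[orfs$gene_id]
  gap <- orfs$start[-1L] - orfs$end[-nrow(orfs)]
  between_units <- unit_of[-1L] != unit_of[-nrow(orfs)]
  expect_true(all(gap[between_units] >= 40L))
  expect_true(all(truth$utr_truth$utr5 >= 0L))
  none <- generate_genome(n_genes = 30, operon_fraction = 0, seed = 2)
  expect_length(none$operon_truth, 0L)
})

test_that("noise-free coverage is an exact step function", {
  truth <- generate_genome(n_genes = 25, operon_fraction = 0, n_novel = 0,
                           class_probs_core = expressed_probs,
                           class_probs_flex = expressed_probs,
                           pathway_profiles = list(), seed = 3)
  sim <- simulate_coverage(truth, n_samples = 1, noise = "none",
                           noise_floor = 0, seed = 3)
  tr <- sim$tracks[[1L]]
  orfs <- truth$annotation$orfs
  for (g in seq_len(5L)) {
    span <- (orfs$start[g] + 1L):orfs$end[g]
    expected <- sim$truth$expression_truth$gene_depth[orfs$gene_id[g], 1L]
    expect_equal(tr$depth[span], rep(round(expected), length(span)))
  }
  # coverage is zero outside planted transcript spans
  u <- truth$units
  covered <- logical(truth$annotation$genome_length)
  for (k in seq_len(nrow(u))) {
    lo <- u$start[k] - ifelse(u$strand[k] == "+", u$utr5[k], u$utr3[k])
    hi <- u$end[k] + ifelse(u$strand[k] == "+", u$utr3[k], u$utr5[k])
    covered[(lo + 1L):hi] <- TRUE
  }
  expect_true(all(tr$depth[!covered] == 0))
})

test_that("Poisson coverage matches intended depths on average", {
  truth <- generate_genome(n_genes = 40, operon_fraction = 0, n_novel = 0,
                           class_probs_core = expressed_probs,
                           class_probs_flex = expressed_probs,
                           pathway_profiles = list(), seed = 11)
  sim <- simulate_coverage(truth, n_samples = 2, seed = 11)
  orfs <- truth$annotation$orfs
  for (g in seq_len(10L)) {
    span <- (orfs$start[g] + 1L):orfs$end[g]
    lam <- sim$truth$expression_truth$gene_depth[orfs$gene_id[g], 1L]
    obs <- mean(sim$tracks[[1L]]$depth[span])
    expect_lt(abs(obs - lam), 3 * sqrt(lam / length(span)) + 0.1)
  }
})

test_that("counts are conserved and consistent with coverage", {
  sim <- simulate_truth_set(n_genes = 60, n_samples = 3, seed = 9)
  for (gc in sim$counts) {
    expect_lte(sum(gc$counts), gc$total_mapped)
    expect_true(all(gc$counts >= 0))
  }
  # counts-only mode reproduces the same expression regime
  cov2 <- simulate_coverage(sim$truth, n_samples = 3, tracks = FALSE,
                            seed = 10)
  expect_null(cov2$tracks[[1L]])
  expect_equal(names(cov2$counts[[1L]]$counts), names(sim$counts[[1L]]$counts))
})

test_that("planted non-expressed genes fall below the expression cutoff", {
  set.seed(23)
  below <- 0L; total <- 0L
  for (rep in 1:5) {
    truth <- generate_genome(n_genes = 150, seed = 100 + rep)
    sim <- simulate_coverage(truth, n_samples = 2, tracks = FALSE,
                             seed = 200 + rep)
    em <- expression_matrix(sim$counts, truth$annotation)
    for (s in 1:2) {
      neg <- sim$truth$expression_truth$gene_class[, s] == "NEG"
      total <- total + sum(neg)
      below <- below + sum(!em$expressed[neg, s])
    }
  }
  expect_gte(below / total, 0.95)
})

test_that("attribute coupling hits its target rank correlations", {
  # an all-expressed genome: distinct mean depths, so the no-noise copula
  # limit is exact (silent genes would tie at zero)
  truth <- generate_genome(n_genes = 400, seed = 15,
                           class_probs_core = expressed_probs,
                           class_probs_flex = expressed_probs,
                           pathway_profiles = list())
  cov <- simulate_coverage(truth, n_samples = 4, tracks = FALSE, seed = 15)
  mu <- rowMeans(cov$truth$expression_truth$gene_depth)
  # copula limit: rho = -1 reverses ranks exactly
  att <- simulate_attributes(cov$truth, rho_ka = -1, hl_missing = 0,
                             n_exceptions = 0, seed = 16)
  ka <- att$truth$ka_truth$ka
  expect_equal(oracle_spearman(mu, ka), -1)
  # moderate coupling recovered within sampling error
  rhos <- vapply(1:5, function(k) {
    a <- simulate_attributes(cov$truth, rho_ka = -0.7, seed = 20 + k)
    oracle_spearman(mu, a$truth$ka_truth$ka)
  }, numeric(1L))
  expect_lt(abs(mean(rhos) + 0.7), 0.07)
  # exceptions live in both top deciles
  a2 <- simulate_attributes(cov$truth, n_exceptions = 5, seed = 30)
  exc <- a2$truth$halflife_truth$exceptions
  hl <- a2$truth$halflife_truth$half_life
  expect_length(exc, 5L)
  expect_true(all(hl[exc] >= sort(hl, decreasing = TRUE)[ceiling(0.1 * sum(!is.na(hl)))]))
  expect_error(simulate_attributes(truth, seed = 1), "simulate_coverage")
})
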