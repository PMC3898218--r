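# Two + strand ORFs [100,400) and [430,700) with a 30 nt gap.
pair_fixture <- function(gap_depth, gene_depth = 40, genome_length = 1000L) {
  ann <- toy_annotation(c(100L, 430L), c(400L, 700L), c("+", "+"),
                        ids = c("a", "b"), genome_length = genome_length)
  d <- numeric(genome_length)
  d[101:400] <- gene_depth
  d[431:700] <- gene_depth
  d[401:430] <- gap_depth
  list(ann = ann, track = toy_track(d))
}

test_that("co-transcription holds iff the gap shows no sharp decline", {
  fx <- pair_fixture(gap_depth = 40)
  expect_true(pair_is_cotranscribed(fx$track, fx$ann, "a", "b",
                                    background = 0))
  # gap falls to background for >= 1 nt: criterion 3
  fx2 <- pair_fixture(gap_depth = 40)
  fx2$track$depth[415L] <- 0
  expect_false(pair_is_cotranscribed(fx2$track, fx2$ann, "a", "b",
                                     background = 0, refractory = 0L))
  # gap steps 40 -> 4: ratio 10 and 4 < 40/7: criterion 2
  fx3 <- pair_fixture(gap_depth = 4)
  expect_false(pair_is_cotranscribed(fx3$track, fx3$ann, "a", "b",
                                     background = 0))
})

test_that("the expression gate vetoes unexpressed pairs", {
  fx <- pair_fixture(gap_depth = 40)
  rpkm <- c(a = 10, b = 1)
  expect_false(pair_is_cotranscribed(fx$track, fx$ann, "a", "b",
                                     background = 0, rpkm = rpkm,
                                     cutoff = 5))
  expect_true(pair_is_cotranscribed(fx$track, fx$ann, "a", "b",
                                    background = 0, rpkm = rpkm,
                                    cutoff = 0.5))
})

test_that("pair validation rejects bad geometry", {
  ann <- toy_annotation(c(0L, 100L, 200L), c(50L, 150L, 280L),
                        c("+", "-", "+"))
  tr <- toy_track(rep(5, 1000L))
  expect_error(pair_is_cotranscribed(tr, ann, "g01", "g03", 0),
               "not adjacent")
  expect_error(pair_is_cotranscribed(tr, ann, "g01", "g02", 0),
               "opposite strands")
})

chain_annotation <- function(n = 5L) {
  toy_annotation(starts = seq(0L, by = 500L, length.out = n),
                 ends = seq(300L, by = 500L, length.out = n),
                 strands = rep("+", n),
                 ids = LETTERS[seq_len(n)])
}

test_that("operon assembly enforces the three-sample support rule", {
  ann <- chain_annotation(3L)
  two <- data.frame(gene_a = "A", gene_b = "B", n_samples = 2L)
  expect_length(assemble_operons(two, ann)$operons, 0L)
  chain <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                      n_samples = c(4L, 3L))
  map <- assemble_operons(chain, ann)
  expect_length(map$operons, 1L)
  expect_equal(map$operons[[1L]]$genes, c("A", "B", "C"))
  expect_equal(map$operons[[1L]]$min_pair_support, 3L)
  expect_equal(map$genome_operon_rate, 1)
  none <- data.frame(gene_a = character(), gene_b = character(),
                     n_samples = integer())
  expect_equal(assemble_operons(none, ann)$genome_operon_rate, 0)
})

test_that("operon membership partitions genes and support is monotone", {
  set.seed(3)
  ann <- chain_annotation(12L)
  pairs <- data.frame(gene_a = LETTERS[1:11], gene_b = LETTERS[2:12],
                      n_samples = sample(0:10, 11L, replace = TRUE))
  prev_genes <- Inf
  for (ms in 1:8) {
    map <- assemble_operons(pairs, ann, min_support = ms)
    genes <- unlist(lapply(map$operons, `[[`, "genes"))
    expect_false(anyDuplicated(genes) > 0)
    expect_equal(length(genes), sum(vapply(map$operons,
                                           function(o) length(o$genes), 1L)))
    expect_lte(length(genes), prev_genes)          # raising support: fewer genes
    prev_genes <- length(genes)
  }
})

ref_map <- function(ann, sets) {
  structure(list(operons = lapply(sets, function(g)
    list(genes = g, strand = "+", min_pair_support = NA_real_)),
    genome_operon_rate = 0.5, n_genes = nrow(ann$orfs)),
    class = "operon_map")
}

test_that("operon map comparison classifies the five categories", {
  ann <- chain_annotation(10L)
  obs <- ref_map(ann, list(c("A", "B"),            # hit
                           c("C", "D", "E"),       # large vs (C,D)
                           c("F", "G"),            # small vs (F,G,H)
                           c("I", "J")))           # new
  ref <- ref_map(ann, list(c("A", "B"), c("C", "D"), c("F", "G", "H")))
  cmp <- compare_operon_maps(obs, ref)
  expect_equal(unclass(cmp)[c("hit", "large", "small", "new")],
               c(hit = 1L, large = 1L, small = 1L, new = 1L))
  expect_equal(sum(cmp), 4L)                       # counts sum to operons
  # partial: overlaps but neither subset nor superset
  obs2 <- ref_map(ann, list(c("B", "C")))
  ref2 <- ref_map(ann, list(c("A", "B")))
  expect_equal(unclass(compare_operon_maps(obs2, ref2))[["partial"]], 1L)
})

test_that("operon rates normalise against the genome rate", {
  ann <- chain_annotation(10L)
  map <- assemble_operons(data.frame(gene_a = c("A", "C", "E"),
                                     gene_b = c("B", "D", "F"),
                                     n_samples = 5L), ann)
  # operons: (A,B), (C,D), (E,F): rate 0.6
  expect_equal(map$genome_operon_rate, 0.6)
  st <- operon_stats(map, list(all = LETTERS[1:10],
                               some = c("A", "B", "C", "G", "H", "I"),
                               none = character(0)))
  expect_equal(st$normalized[st$set == "all"], 1)
  expect_equal(st$rate[st$set == "some"], 0.5)
  expect_equal(st$normalized[st$set == "some"], 0.5 / 0.6)
  expect_true(is.na(st$rate[st$set == "none"]))
  # size spectrum: three 2-gene operons and one 4-gene operon
  chain4 <- data.frame(gene_a = c("A", "C", "E", "G", "H", "I"),
                       gene_b = c("B", "D", "F", "H", "I", "J"),
                       n_samples = 5L)
  map4 <- assemble_operons(chain4, ann)
  st4 <- operon_stats(map4, list(all = LETTERS[1:10]))
  expect_equal(st4$two_gene_fraction, 0.75)
})

test_that("coverage-driven operon calling recovers a planted chain", {
  ann <- chain_annotation(4L)
  # one transcript over A,B,C; D silent; 3 samples
  mk <- function(id) {
    d <- numeric(2500L)
    d[1:1300] <- 60
    coverage_track(id, d)
  }
  tracks <- list(s1 = mk("s1"), s2 = mk("s2"), s3 = mk("s3"))
  counts <- lapply(tracks, function(tr) {
    cnt <- vapply(seq_len(4L), function(g)
      sum(tr$depth[(ann$orfs$start[g] + 1L):ann$orfs$end[g]]) / 90,
      numeric(1L))
    gene_counts(tr$sample_id, setNames(round(cnt), ann$orfs$gene_id),
                total_mapped = max(1, round(sum(tr$depth) / 90)))
  })
  # cutoffs need >= 10 genes; build the matrix by hand instead
  rpkm <- sapply(counts, compute_rpkm, annotation = ann)
  em <- structure(list(rpkm = rpkm,
                       gene_cutoff = setNames(rep(1, 3), names(tracks)),
                       genome_background = setNames(rep(0, 3), names(tracks)),
                       expressed = rpkm > 1),
                  class = "expression_matrix")
  map <- call_operons(tracks, ann, em, min_support = 3L)
  expect_length(map$operons, 1L)
  expect_equal(map$operons[[1L]]$genes, c("A", "B", "C"))
})
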