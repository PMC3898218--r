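test_that("GFF3 coordinates convert to 0-based half-open and back", {
  ann <- toy_annotation(starts = c(10L, 50L), ends = c(40L, 80L),
                        strands = c("+", "-"), genome_length = 200L)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(ann, path)
  txt <- readLines(path)
  feat <- txt[!startsWith(txt, "#")]
  f1 <- strsplit(feat[1L], "\t")[[1L]]
  expect_equal(as.integer(f1[4:5]), c(11L, 40L))   # 1-based inclusive on disk
  back <- read_annotation(path, genome_length = 200L)
  expect_equal(back$orfs$start, ann$orfs$start)
  expect_equal(back$orfs$end, ann$orfs$end)
  expect_equal(back$orfs$strand, ann$orfs$strand)
})

test_that("annotation validates and orders its ORFs", {
  ann <- toy_annotation(starts = c(100L, 10L), ends = c(150L, 40L),
                        strands = c("+", "+"), ids = c("b", "a"))
  expect_equal(ann$orfs$gene_id, c("a", "b"))      # sorted by start
  expect_error(toy_annotation(10L, 10L, "+"), "end <= start")
  expect_error(toy_annotation(c(1L, 1L), c(50L, 50L), c("+", "+"),
                              ids = c("x", "x")), "duplicate")
  empty <- genome_annotation("g", 100L,
                             data.frame(gene_id = character(),
                                        start = integer(), end = integer(),
                                        strand = character()))
  expect_equal(nrow(empty$orfs), 0L)
})

test_that("bedGraph coverage reads with zero fill and overlap summation", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("toy\t0\t5\t7"), path)
  tr <- read_coverage(path, genome_length = 10L)
  expect_equal(tr$depth, c(rep(7, 5), rep(0, 5)))

  writeLines(c("toy\t0\t3\t2", "toy\t2\t4\t3"), path)
  tr <- read_coverage(path, genome_length = 10L)
  expect_equal(tr$depth[3L], 5)                    # overlapping intervals sum
  # conservation: track total equals sum of interval length x value
  expect_equal(sum(tr$depth), 2 * 3 + 3 * 2)

  writeLines(character(0), path)
  expect_equal(read_coverage(path, genome_length = 10L)$depth, rep(0, 10))

  writeLines("toy\t5\t20\t1", path)
  expect_error(read_coverage(path, genome_length = 10L), "exceeds genome")
})

test_that("coverage write/read round-trips", {
  set.seed(1)
  d <- rpois(500L, 3)
  tr <- toy_track(d)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_coverage(tr, path, genome_id = "toy")
  expect_equal(read_coverage(path, 500L)$depth, as.numeric(d))
})

test_that("count tables round-trip and validate", {
  gc1 <- gene_counts("s1", c(a = 10, b = 0), total_mapped = 100)
  gc2 <- gene_counts("s2", c(a = 5, b = 7), total_mapped = 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(list(s1 = gc1, s2 = gc2), path)
  back <- read_counts(path, total_mapped = c(s1 = 100, s2 = 50))
  expect_equal(back$s1$counts, gc1$counts)
  expect_equal(back$s2$total_mapped, 50)
  expect_error(gene_counts("s", c(a = 10), total_mapped = 5), "exceeds")
  expect_error(gene_counts("s", c(a = 1), total_mapped = 0))
})

test_that("feature emission writes round-trippable GFF3 with BED sidecars", {
  ann <- toy_annotation(starts = c(10L, 50L), ends = c(40L, 80L),
                        strands = c("+", "+"), genome_length = 300L)
  map <- assemble_operons(data.frame(gene_a = "g01", gene_b = "g02",
                                     n_samples = 5L), ann)
  utrs <- structure(data.frame(gene_id = "g01", kind = "5prime", length = 6L,
                               consensus_coord = 4L, n_samples = 3L,
                               stringsAsFactors = FALSE),
                    class = c("utr_set", "data.frame"))
  novel <- data.frame(start = 100L, end = 200L, strand = "*",
                      n_samples = 2L, samples = "s1,s2", mean_depth = 9)
  dir <- withr::local_tempdir()
  paths <- write_features(map, utrs, novel, ann, dir)
  expect_true(all(file.exists(file.path(dir, c("operons.gff3", "operons.bed",
                                               "utrs.gff3", "novel.bed")))))
  op <- rtracklayer::import.gff3(file.path(dir, "operons.gff3"))
  expect_equal(GenomicRanges::start(op), 11L)      # operon spans both genes
  expect_equal(GenomicRanges::end(op), 80L)
  ut <- rtracklayer::import.gff3(file.path(dir, "utrs.gff3"))
  expect_equal(c(GenomicRanges::start(ut), GenomicRanges::end(ut)), c(5L, 10L))
  # empty maps still give valid files
  empty_map <- assemble_operons(data.frame(gene_a = character(),
                                           gene_b = character(),
                                           n_samples = integer()), ann)
  paths2 <- write_features(empty_map, NULL, NULL, ann, withr::local_tempdir())
  expect_true(all(file.exists(paths2)))
})

test_that("attribute tables validate rates and round-trip", {
  df <- data.frame(gene_id = c("a", "b"), ka_mit9313 = c(0.1, NA),
                   ks_mit9313 = c(0.5, NA), half_life_min = c(2.5, NA),
                   partition = c("core", "flexible"),
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_attributes(gene_attributes(df), path)
  back <- read_attributes(path)
  expect_equal(back$ka_mit9313, df$ka_mit9313)
  df$ka_mit9313[1L] <- -0.1
  expect_error(gene_attributes(df), "negative")
})
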