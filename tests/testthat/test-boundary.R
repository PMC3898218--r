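test_that("binomial_cdf matches the pmf definition exactly", {
  expect_equal(binomial_cdf(1, 11, 0.5), 12 / 2048)         # C(11,0)+C(11,1)
  expect_equal(binomial_cdf(7, 7, 0.3), 1.0)
  expect_equal(binomial_cdf(0, 1, 0.5), 0.5)
  expect_error(binomial_cdf(5, 3, 0.5), "x <= n")
  expect_error(binomial_cdf(1, 2, 1.5), "p <= 1")
  for (n in c(0:8, 15)) for (p in c(0.1, 0.5, 0.9)) for (x in 0:n)
    expect_equal(binomial_cdf(x, n, p), oracle_binom_cdf(x, n, p),
                 tolerance = 1e-12)
  # monotone nondecreasing in x
  expect_true(all(diff(binomial_cdf(0:20, 20, 0.37)) >= 0))
})

test_that("interior window mean averages the 90 ORF-side depths", {
  expect_equal(interior_window_mean(rep(14, 200), 100, +1L), 14)
  d <- numeric(200); d[100:11] <- 1:90            # window walking leftward
  expect_equal(interior_window_mean(d, 100, -1L), 45.5)
  expect_equal(interior_window_mean(d, 100, -1L, w = 1L), d[100])
  expect_warning(m <- interior_window_mean(rep(3, 50), 10, -1L), "truncated")
  expect_equal(m, 3)
  # circular wrap instead of truncation
  expect_equal(interior_window_mean(rep(3, 50), 10, -1L, circular = TRUE), 3)
})

# scan setup: ORF occupying the right half, boundary scanned leftward from
# its start; `flank` gives the depths at i = 1, 2, ... upstream
decline_track <- function(interior, flank, genome_length = 400L) {
  d <- rep(interior, genome_length)
  anchor <- 200L
  d[seq_len(anchor)] <- rev(c(flank, rep(0, anchor - length(flank))))
  list(track = toy_track(d), anchor = anchor)     # 0-based anchor = 200
}

test_that("detect_boundary applies the three criteria as stated", {
  # weak flank: 20 -> 2, ratio 10 >= 5 and 2 < 20/7: criterion 2 at i = 0
  s <- decline_track(20, flank = rep(0, 0))
  b <- detect_boundary(s$track, s$anchor, -1L, background = 0)
  expect_equal(b$i, 0L); expect_equal(b$criterion, 2L)

  s2 <- decline_track(20, flank = rep(2, 150))
  b2 <- detect_boundary(s2$track, s2$anchor, -1L, background = 0,
                        refractory = 0L)
  expect_equal(b2$i, 0L); expect_equal(b2$criterion, 2L)

  # strong flank: 20 -> 5, 5 > 20/7 so criterion 1 owns it;
  # binomial_cdf(5, 25, 0.5) = 68406/2^25 < 0.01
  s3 <- decline_track(20, flank = rep(5, 150))
  expect_equal(binomial_cdf(5, 25, 0.5), 68406 / 2^25)
  b3 <- detect_boundary(s3$track, s3$anchor, -1L, background = 0,
                        refractory = 0L)
  expect_equal(b3$i, 0L); expect_equal(b3$criterion, 1L)

  # flat positive coverage: no decline, no boundary
  flat <- toy_track(rep(9, 400))
  expect_null(detect_boundary(flat, 200L, -1L, background = 0,
                              max_scan = 100L))

  # criterion 3: the position beyond the boundary at or below background
  s4 <- decline_track(20, flank = rep(4, 150))    # ratio 5 but 4 > 20/7? no: 4 >= 2.857
  b4 <- detect_boundary(s4$track, s4$anchor, -1L, background = 4,
                        refractory = 0L)
  expect_equal(b4$criterion, 1L)                  # 4 > 20/7, ratio 5, cdf tiny
  b5 <- detect_boundary(s4$track, s4$anchor, -1L, background = 0,
                        refractory = 0L)
  expect_equal(b5$criterion, 1L)
})

test_that("zero coverage one step out is an infinite ratio, not an error", {
  s <- decline_track(20, flank = rep(0, 10))
  b <- detect_boundary(s$track, s$anchor, -1L, background = -1)  # disable crit 3
  expect_equal(b$i, 0L)
  expect_equal(b$criterion, 2L)                   # 20/0 -> Inf >= 5, 0 < 20/7
})

test_that("the transient-dip post-filter skips single-position dropouts", {
  d <- rep(50, 400)
  d[150L] <- 2                                    # lone dip 50 nt upstream
  d[1:100] <- 0                                   # true boundary at i = 100
  tr <- toy_track(d)
  b <- detect_boundary(tr, 200L, -1L, background = 0, max_scan = 150L)
  expect_equal(b$i, 100L)                         # dip skipped, true edge found
  b0 <- detect_boundary(tr, 200L, -1L, background = 0, max_scan = 150L,
                        refractory = 0L)
  expect_equal(b0$i, 50L)                         # without it, the dip fires
})

test_that("depth scaling never weakens a firing ratio criterion", {
  set.seed(11)
  for (rep in 1:25) {
    interior <- sample(20:60, 1)
    flank_val <- sample(0:10, 1)
    s <- decline_track(interior, flank = rep(flank_val, 120))
    b1 <- detect_boundary(s$track, s$anchor, -1L, background = 0,
                          refractory = 0L)
    k <- sample(2:6, 1)
    s2 <- decline_track(interior * k, flank = rep(flank_val * k, 120))
    b2 <- detect_boundary(s2$track, s2$anchor, -1L, background = 0,
                          refractory = 0L)
    if (!is.null(b1) && b1$i == 0L && b1$criterion %in% c(1L, 2L)) {
      expect_false(is.null(b2))
      if (b1$criterion == 1L) {
        # with a fixed ratio the binomial clause only strengthens as counts grow
        p1 <- binomial_cdf(flank_val, interior + flank_val, 0.5)
        p2 <- binomial_cdf(flank_val * k, (interior + flank_val) * k, 0.5)
        expect_lte(p2, p1)
      }
    }
  }
})

test_that("planted boundaries on noisy step coverage are recovered closely", {
  set.seed(5)
  hits <- 0L; total <- 0L
  for (rep in 1:30) {
    depth <- sample(50:300, 1)
    utr <- sample(5:120, 1)
    L <- 600L
    lambda <- c(rep(0, 200L - utr), rep(depth, L - 200L + utr))
    tr <- toy_track(rpois(L, lambda))
    b <- detect_boundary(tr, 200L, -1L, background = 0, max_scan = 180L)
    total <- total + 1L
    if (!is.null(b) && abs(b$i - utr) <= 3L) hits <- hits + 1L
  }
  expect_gte(hits / total, 0.9)
})
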