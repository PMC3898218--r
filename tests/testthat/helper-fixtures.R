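# Small in-code fixtures and independent oracles shared across tests.

# annotation with explicitly placed ORFs
toy_annotation <- function(starts, ends, strands,
                           ids = sprintf("g%02d", seq_along(starts)),
                           genome_length = max(ends) + 500L, ...) {
  genome_annotation("toy", genome_length,
                    data.frame(gene_id = ids, start = starts, end = ends,
                               strand = strands, ...,
                               stringsAsFactors = FALSE))
}

# coverage track from an explicit depth vector
toy_track <- function(depth, sample_id = "s1") coverage_track(sample_id, depth)

# step-function track: ORF plus UTRs at `depth`, elsewhere 0
step_track <- function(genome_length, span_start, span_end, depth,
                       sample_id = "s1") {
  d <- numeric(genome_length)
  d[(span_start + 1L):span_end] <- depth
  coverage_track(sample_id, d)
}

# --- independent oracles -----------------------------------------------------

# brute-force binomial lower tail from the pmf definition
oracle_binom_cdf <- function(x, n, p) {
  k <- 0:x
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

# hypergeometric tail by explicit enumeration over all tables with the
# observed margins (choose()-based pmf, no stats:: tail functions)
oracle_fisher_greater <- function(a, b, c, d) {
  K <- a + c; n <- a + b; N <- a + b + c + d
  amin <- max(0L, n - (N - K)); amax <- min(n, K)
  av <- amin:amax
  probs <- choose(K, av) * choose(N - K, n - av) / choose(N, n)
  sum(probs[av >= a])
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mannwhitney_two_sided <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(sel) {
    xs <- pooled[sel]; ys <- pooled[-sel]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  us <- apply(idx, 2L, u_of)
  u_obs <- u_of(seq_len(n1))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Spearman rho from first principles (average ranks)
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))
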