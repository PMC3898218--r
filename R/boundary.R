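#' Exact lower-tail binomial CDF
#'
#' Probability of observing up to \code{x} successes in \code{n} independent
#' trials with success probability \code{p}. Used by the boundary caller to
#' test whether the read count one step beyond a candidate boundary is
#' improbably small under an even-split null (p = 0.5).
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials.
#' @param p Success probability.
#' @return Lower-tail probability.
#' @export
binomial_cdf <- function(x, n, p) {
  if (any(x < 0) || any(x > n)) stop("validation error: require 0 <= x <= n")
  if (any(p < 0) || any(p > 1)) stop("validation error: require 0 <= p <= 1")
  stats::pbinom(x, n, p)
}

#' Mean coverage of the 90-bp window on the ORF-interior side
#'
#' Arithmetic mean of the \code{w} depths starting at \code{pos} and stepping
#' toward the ORF interior. On a linear genome a window that runs off the end
#' is truncated (with a warning); with \code{circular = TRUE} it wraps.
#'
#' @param depth Numeric depth vector (one value per genome position).
#' @param pos 1-based position of the window edge (the candidate boundary).
#' @param interior_step +1 or -1: direction from \code{pos} toward the ORF.
#' @param w Window width in nt (default 90).
#' @param circular Wrap the window across the origin.
#' @return Mean depth over the window.
#' @export
interior_window_mean <- function(depth, pos, interior_step, w = 90L,
                                 circular = FALSE) {
  L <- length(depth)
  idx <- pos + interior_step * (0:(w - 1L))
  if (circular) {
    idx <- ((idx - 1L) %% L) + 1L
  } else {
    inside <- idx >= 1L & idx <= L
    if (!all(inside)) {
      warning("interior window truncated at genome edge")
      idx <- idx[inside]
    }
  }
  mean(depth[idx])
}

cov_ratio <- function(num, den) {
  if (den > 0) num / den else if (num > 0) Inf else 0
}

#' Detect a sharp coverage decline (transcript boundary)
#'
#' Scans positions i = 0, 1, 2, ... away from an anchor (a translation start,
#' scanning upstream, or a translation stop, scanning downstream) and returns
#' the first i at which one of three criteria fires, where cov(i) is the depth
#' at the position i steps from the anchor and m is the mean depth of the
#' 90-bp window on the ORF-interior side of i:
#' \itemize{
#'   \item Criterion 1 (highly transcribed flank, cov(i+1) > m/7):
#'     cov(i)/cov(i+1) >= 2 and binomial_cdf(cov(i+1), cov(i)+cov(i+1), 0.5)
#'     < 0.01.
#'   \item Criterion 2 (weakly transcribed flank, cov(i+1) < m/7):
#'     cov(i)/cov(i+1) >= 5 or cov(i)/cov(i+2) >= 5.
#'   \item Criterion 3: cov(i+1) <= background.
#' }
#' Equality with m/7 routes to criterion 1. A zero denominator counts as an
#' infinite ratio when the numerator is positive. Calls where coverage climbs
#' back above m/2 within \code{refractory} nt beyond the boundary are treated
#' as transient dips and skipped (a deterministic stand-in for manual
#' proofreading of coverage fluctuations).
#'
#' @param track A \code{coverage_track}.
#' @param anchor 0-based genome coordinate of i = 0 (the anchor nucleotide).
#' @param away +1 or -1: scan direction away from the ORF.
#' @param background Genome background depth (criterion 3 threshold).
#' @param max_scan Maximal i scanned; callers clip this at the nearest
#'   annotated ORF.
#' @param w,divisor,ratio1,ratio2,alpha Criterion constants (90, 7, 2, 5,
#'   0.01).
#' @param refractory Post-filter look-ahead in nt (default 10; 0 disables).
#' @param circular Treat the genome as circular.
#' @return A list \code{(i, position, criterion)} with \code{position} the
#'   0-based coordinate of the last transcribed nucleotide, or \code{NULL} if
#'   no criterion fires within \code{max_scan}.
#' @export
detect_boundary <- function(track, anchor, away, background, max_scan = 500L,
                            w = 90L, divisor = 7, ratio1 = 2, ratio2 = 5,
                            alpha = 0.01, refractory = 10L, circular = FALSE) {
  depth <- track$depth
  L <- length(depth)
  at <- function(i) {                      # depth at step i; NA when outside
    p <- anchor + away * i + 1L            # 1-based index
    if (circular) p <- ((p - 1L) %% L) + 1L
    if (p >= 1L && p <= L) depth[[p]] else NA_real_
  }
  for (i in 0:max_scan) {
    ci <- at(i); ci1 <- at(i + 1L)
    if (is.na(ci) || is.na(ci1)) return(NULL)
    m <- interior_window_mean(depth, anchor + away * i + 1L, -away, w = w,
                              circular = circular)
    crit <- 0L
    if (ci1 > m / divisor) {
      if (cov_ratio(ci, ci1) >= ratio1 &&
          binomial_cdf(ci1, ci + ci1, 0.5) < alpha) crit <- 1L
    } else {
      ci2 <- if (i + 2L <= max_scan + 1L) at(i + 2L) else NA_real_
      r2 <- cov_ratio(ci, ci1) >= ratio2 ||
            (!is.na(ci2) && cov_ratio(ci, ci2) >= ratio2)
      if (r2 && ci1 < m / divisor) crit <- 2L
    }
    if (crit == 0L && ci1 <= background) crit <- 3L
    if (crit > 0L) {
      if (refractory > 0L) {
        ahead <- vapply((i + 1L):(i + refractory), at, numeric(1L))
        if (any(ahead > m / 2, na.rm = TRUE)) next   # transient dip
      }
      pos <- anchor + away * i
      if (circular) pos <- pos %% L
      return(list(i = i, position = pos, criterion = crit))
    }
  }
  NULL
}
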