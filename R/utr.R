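# UTR calling and intergenic (novel) transcript detection.

# Scan geometry for one gene side. side: "5prime" scans upstream of the
# translation start, "3prime" downstream of the stop, in the gene's own
# orientation. Returns anchor (0-based), away step and the scan clip imposed
# by the nearest annotated ORF on either strand.
scan_geometry <- function(annotation, gene_idx, side, max_scan) {
  orfs <- annotation$orfs
  g <- orfs[gene_idx, ]
  leftward <- (g$strand == "+") == (side == "5prime")
  if (leftward) {
    anchor <- g$start
    away <- -1L
    prev_ends <- orfs$end[orfs$end <= g$start]
    lim <- if (length(prev_ends)) g$start - max(prev_ends) else g$start
  } else {
    anchor <- g$end - 1L
    away <- +1L
    next_starts <- orfs$start[orfs$start >= g$end]
    lim <- if (length(next_starts)) min(next_starts) - g$end
           else annotation$genome_length - g$end
  }
  list(anchor = anchor, away = away, max_scan = max(0L, min(max_scan, lim)))
}

#' Call 5' and 3' UTRs across samples
#'
#' For each gene and side, a per-sample boundary is sought with
#' \code{\link{detect_boundary}}; the scan is clipped at the nearest annotated
#' ORF on either strand (unstranded coverage cannot disambiguate overlapping
#' transcription) and at \code{max_scan}. Samples in which the gene is not
#' expressed (via \code{expressed}, or when absent: the anchor-side 90-bp
#' interior window does not exceed the background) contribute nothing, so
#' noise-floor fluctuations of silent genes cannot vote. The consensus
#' boundary is the
#' median of per-sample boundary offsets, ties resolved toward the ORF; genes
#' whose consensus lies at the anchor (offset 0) get no UTR record, and genes
#' with no detectable boundary in any sample are omitted.
#'
#' @param tracks Named list of \code{coverage_track}s.
#' @param annotation A \code{genome_annotation}.
#' @param backgrounds Named per-sample background depths.
#' @param expressed Optional gene x sample logical matrix (e.g. the
#'   \code{expressed} component of an \code{expression_matrix}); only samples
#'   where the gene is expressed are scanned.
#' @param max_scan Maximal UTR length scanned (default 500 nt).
#' @param ... Further arguments passed to \code{detect_boundary}.
#' @return An object of class \code{utr_set}: data.frame with columns
#'   \code{gene_id}, \code{kind}, \code{length}, \code{consensus_coord}
#'   (0-based coordinate of the last transcribed nucleotide),
#'   \code{n_samples}.
#' @export
call_utrs <- function(tracks, annotation, backgrounds, expressed = NULL,
                      max_scan = 500L, ...) {
  stopifnot(length(tracks) >= 1L)
  orfs <- annotation$orfs
  rows <- vector("list", 2L * nrow(orfs))
  ri <- 0L
  for (k in seq_len(nrow(orfs))) {
    for (side in c("5prime", "3prime")) {
      geo <- scan_geometry(annotation, k, side, max_scan)
      if (geo$max_scan < 1L) next
      offs <- integer(0)
      for (s in names(tracks)) {
        tr <- tracks[[s]]; bg <- backgrounds[[s]]
        if (!is.null(expressed)) {
          if (!isTRUE(expressed[orfs$gene_id[k], s])) next
        } else {
          m0 <- interior_window_mean(tr$depth, geo$anchor + 1L, -geo$away)
          if (!(m0 > bg)) next                   # gene silent in this sample
        }
        b <- detect_boundary(tr, geo$anchor, geo$away, bg,
                             max_scan = geo$max_scan, ...)
        if (!is.null(b)) offs <- c(offs, b$i)
      }
      if (!length(offs)) next
      cons <- sort(offs)[ceiling(length(offs) / 2)]  # median, ties toward ORF
      if (cons == 0L) next                           # zero-length UTR: no record
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        gene_id = orfs$gene_id[k], kind = side, length = cons,
        consensus_coord = geo$anchor + geo$away * cons,
        n_samples = length(offs), stringsAsFactors = FALSE)
    }
  }
  utrs <- if (ri) do.call(rbind, rows[seq_len(ri)])
          else data.frame(gene_id = character(), kind = character(),
                          length = integer(), consensus_coord = integer(),
                          n_samples = integer(), stringsAsFactors = FALSE)
  structure(utrs, class = c("utr_set", "data.frame"))
}

#' @export
print.utr_set <- function(x, ...) {
  cat("<utr_set> ", sum(x$kind == "5prime"), " 5'UTRs (median ",
      stats::median(x$length[x$kind == "5prime"]), " nt), ",
      sum(x$kind == "3prime"), " 3'UTRs\n", sep = "")
  invisible(x)
}

intergenic_mask <- function(annotation) {
  mask <- rep(TRUE, annotation$genome_length)
  orfs <- annotation$orfs
  for (k in seq_len(nrow(orfs)))
    mask[(orfs$start[k] + 1L):orfs$end[k]] <- FALSE
  mask
}

#' Detect intergenic (novel) transcript units in one sample
#'
#' Maximal runs of intergenic positions with depth strictly above the
#' background, of length at least \code{min_len}, become transcript units;
#' sub-background gaps are never bridged. Runs contiguous with an annotated
#' ORF (the position immediately beyond either run end lies inside an ORF)
#' are gene-linked transcription — UTR flanks — not novel units, and are
#' dropped. Unit ends are then confirmed by the
#' boundary logic applied from the run's interior outward (with the
#' transient-dip post-filter off, so the background rule owns the edge).
#'
#' @param track A \code{coverage_track}.
#' @param annotation A \code{genome_annotation}.
#' @param background Background depth for this sample.
#' @param min_len Minimal unit length in nt (default 50).
#' @param exclude Optional data.frame of 0-based half-open \code{start},
#'   \code{end} intervals removed from the intergenic complement (typically
#'   called UTR spans, whose weak tails would otherwise surface as spurious
#'   fragments).
#' @return data.frame with 0-based half-open \code{start}, \code{end},
#'   \code{strand} (\code{"*"}: unstranded protocol), \code{mean_depth}.
#' @export
detect_intergenic_transcripts <- function(track, annotation, background,
                                          min_len = 50L, exclude = NULL) {
  mask <- intergenic_mask(annotation)
  if (!is.null(exclude) && nrow(exclude))
    for (k in seq_len(nrow(exclude))) {
      lo <- max(1L, exclude$start[k] + 1L)
      hi <- min(length(mask), exclude$end[k])
      if (lo <= hi) mask[lo:hi] <- FALSE
    }
  hot <- mask & (track$depth > background)
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(start = integer(), end = integer(), strand = character(),
                    mean_depth = numeric(), stringsAsFactors = FALSE)
  in_orf <- !mask
  for (j in which(keep)) {
    s <- starts[j]; e <- ends[j]                 # 1-based inclusive run
    if ((s > 1L && in_orf[s - 1L]) ||
        (e < length(mask) && in_orf[e + 1L])) next   # ORF-contiguous: UTR flank

    for (edge in c("left", "right")) {
      away <- if (edge == "left") -1L else +1L
      anchor <- if (edge == "left") s - 1L else e - 1L   # 0-based run edge
      b <- detect_boundary(track, anchor, away, background,
                           max_scan = min_len, refractory = 0L)
      if (!is.null(b)) {
        if (edge == "left") s <- b$position + 1L else e <- b$position + 1L
      }
    }
    out <- rbind(out, data.frame(
      start = s - 1L, end = e, strand = "*",
      mean_depth = mean(track$depth[s:e]), stringsAsFactors = FALSE))
  }
  out
}

#' Detect novel transcript units across samples
#'
#' Per-sample units are merged by overlap; the merged unit spans the union of
#' the per-sample spans and records which samples detected it.
#'
#' @param tracks Named list of \code{coverage_track}s.
#' @param annotation A \code{genome_annotation}.
#' @param backgrounds Named per-sample backgrounds.
#' @param min_len Minimal unit length (nt).
#' @param utrs Optional \code{utr_set}; called UTR spans are excluded from
#'   the intergenic scan.
#' @return An object of class \code{novel_set}: data.frame with \code{start},
#'   \code{end} (0-based half-open), \code{strand}, \code{n_samples},
#'   \code{samples} (comma-separated) and \code{mean_depth} (across detecting
#'   samples).
#' @export
detect_novel_transcripts <- function(tracks, annotation, backgrounds,
                                     min_len = 50L, utrs = NULL) {
  exclude <- if (!is.null(utrs) && nrow(utrs)) {
    gr <- utr_granges(utrs, annotation)
    data.frame(start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr))
  }
  per <- lapply(names(tracks), function(s)
    cbind(detect_intergenic_transcripts(tracks[[s]], annotation,
                                        backgrounds[[s]], min_len,
                                        exclude = exclude),
          sample_id = s))
  per <- do.call(rbind, per)
  if (is.null(per) || !nrow(per)) {
    out <- data.frame(start = integer(), end = integer(), strand = character(),
                      n_samples = integer(), samples = character(),
                      mean_depth = numeric(), stringsAsFactors = FALSE)
    return(structure(out, class = c("novel_set", "data.frame")))
  }
  ir <- IRanges::IRanges(start = per$start + 1L, end = per$end)
  merged <- IRanges::reduce(ir)
  ov <- IRanges::findOverlaps(ir, merged)
  idx <- factor(S4Vectors::subjectHits(ov), levels = seq_along(merged))
  out <- data.frame(
    start = IRanges::start(merged) - 1L, end = IRanges::end(merged),
    strand = "*",
    n_samples = as.integer(tapply(per$sample_id, idx,
                                  function(v) length(unique(v)))),
    samples = as.character(tapply(per$sample_id, idx,
                                  function(v) paste(sort(unique(v)),
                                                    collapse = ","))),
    mean_depth = as.numeric(tapply(per$mean_depth, idx, mean)),
    stringsAsFactors = FALSE)
  structure(out, class = c("novel_set", "data.frame"))
}

#' @export
print.novel_set <- function(x, ...) {
  cat("<novel_set> ", nrow(x), " intergenic transcript units\n", sep = "")
  invisible(x)
}
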