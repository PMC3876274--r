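#' Count read starts in variable bins
#'
#' A read is assigned to the unique bin whose half-open interval
#' `[start, end)` contains the read's 0-based 5' start. Reads falling
#' outside all bins (including beyond the dropped terminal partial bin) are
#' counted in the `n_outside` attribute.
#'
#' @param aln deduplicated alignments (`chrom`, `start`).
#' @param bins bin table from [build_variable_bins()].
#' @return the bin table with a `raw_count` column added; attribute
#'   `n_outside`.
#' @export
count_reads_in_bins <- function(aln, bins) {
  counts <- integer(nrow(bins))
  outside <- 0L
  for (ch in unique(bins$chrom)) {
    b <- which(bins$chrom == ch)
    st <- sort(aln$start[aln$chrom == ch])
    edges <- c(bins$start[b], bins$end[b[length(b)]])
    j <- findInterval(st, edges)
    inside <- j >= 1 & j <= length(b) & st < bins$end[b[length(b)]] & st >= bins$start[b[1]]
    outside <- outside + sum(!inside)
    tab <- tabulate(j[inside], nbins = length(b))
    counts[b] <- tab
  }
  outside <- outside + sum(!aln$chrom %in% bins$chrom)
  out <- bins
  out$raw_count <- counts
  attr(out, "n_outside") <- outside
  out
}

#' Compute per-bin logR from raw counts
#'
#' Order of operations: a pseudocount is added to every bin's count, bins
#' with GC below `gc_min` are discarded, and logR is the log2 ratio of each
#' retained bin's pseudocounted count to the mean pseudocounted count over
#' the retained bins genome-wide.
#'
#' @param counted bin table with `raw_count` and `gc` columns.
#' @param pseudocount value added to every raw count (default 1).
#' @param gc_min GC fraction below which bins are discarded (default 0.28).
#' @return data.frame of retained bins with `logr`; attribute
#'   `n_gc_filtered`.
#' @export
compute_logr <- function(counted, pseudocount = 1, gc_min = 0.28) {
  stopifnot(all(counted$raw_count >= 0))
  keep <- counted$gc >= gc_min
  if (!any(keep)) stop("all bins removed by the GC filter")
  out <- counted[keep, , drop = FALSE]
  cnt <- out$raw_count + pseudocount
  out$logr <- log2(cnt / mean(cnt))
  rownames(out) <- NULL
  attr(out, "n_gc_filtered") <- sum(!keep)
  out
}

#' Loess GC correction and median normalisation of a logR track
#'
#' Fits a locally weighted regression (Loess: tricube weights, the given
#' span and polynomial degree) of logR on per-bin GC over retained bins,
#' subtracts the fitted GC trend, then subtracts the genome-wide median so
#' the corrected track is centred at 0. If the GC range is degenerate the
#' fit is skipped and the track is median-centred only, with a warning.
#'
#' @param track logR track from [compute_logr()] (or any data.frame with
#'   `logr` and `gc`).
#' @param span Loess span (default 0.3).
#' @param degree Loess polynomial degree (default 2).
#' @param min_bins minimum retained bins required for a stable fit.
#' @return the track with `logr` replaced by the corrected values and the
#'   input preserved as `logr_uncorrected`.
#' @export
gc_correct <- function(track, span = 0.3, degree = 2, min_bins = 30L) {
  if (nrow(track) < min_bins) {
    stop("need at least ", min_bins, " bins for GC correction")
  }
  out <- track
  out$logr_uncorrected <- track$logr
  if (diff(range(track$gc)) < 1e-8) {
    warning("degenerate GC range; skipping Loess fit, median-centring only")
    corrected <- track$logr
  } else {
    fit <- loess(logr ~ gc, data = track, span = span, degree = degree)
    corrected <- track$logr - predict(fit, track$gc)
  }
  out$logr <- corrected - median(corrected)
  out
}

#' Estimate average ploidy from a reference region
#'
#' The per-cell scaling factor Psi converting logR ratios to absolute copy
#' numbers is anchored on a large region of known copy number free of large
#' aberrations: \eqn{\Psi = CN_{ref} \times 2^{-\overline{logR}_{ref}}}.
#'
#' @param track corrected logR track (binned).
#' @param ref_region list/data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param ref_cn assumed integer copy number of the region (default 2).
#' @param min_bins warn when the region overlaps fewer retained bins.
#' @return list with `psi`, `reference_region`, `reference_cn`, `n_bins`,
#'   `mean_logr`.
#' @export
estimate_ploidy <- function(track, ref_region, ref_cn = 2, min_bins = 20L) {
  hit <- track$chrom == ref_region$chrom &
    track$start < ref_region$end & track$end > ref_region$start
  if (!any(hit)) stop("reference region overlaps no retained bins")
  if (sum(hit) < min_bins) {
    warning("reference region overlaps only ", sum(hit), " bins")
  }
  m <- mean(track$logr[hit])
  list(psi = ref_cn * 2^(-m), reference_region = ref_region,
       reference_cn = ref_cn, n_bins = sum(hit), mean_logr = m)
}

#' Integer copy number calls from segments and ploidy
#'
#' Per segment, continuous copy number is \eqn{2^{logR} \times \Psi}
#' evaluated at the segment mean; the integer call rounds half-up and floors
#' at 0.
#'
#' @param segments segment table from [segment_track()] (`chrom`, `start`,
#'   `end`, `n_bins`, `mean`).
#' @param psi average ploidy (a number or the list from
#'   [estimate_ploidy()]).
#' @return segments with `cn_continuous` and `cn_integer` columns.
#' @export
call_integer_cn <- function(segments, psi) {
  if (is.list(psi)) psi <- psi$psi
  stopifnot(psi > 0)
  out <- segments
  out$cn_continuous <- 2^segments$mean * psi
  out$cn_integer <- pmax(0L, as.integer(floor(out$cn_continuous + 0.5)))
  out
}

#' Single-cell copy-number profile, end to end
#'
#' Convenience wrapper chaining the pipeline on binned alignments:
#' count -> pseudocount + GC filter -> logR -> Loess GC correction + median
#' normalisation -> per-chromosome PCF -> ploidy from the reference region
#' -> integer copy number.
#'
#' @param aln deduplicated alignments.
#' @param bins variable bins.
#' @param ref_region,ref_cn reference region of known copy number.
#' @param gamma,kmin PCF parameters (defaults 25 and 5, the sequencing-mode
#'   settings).
#' @param pseudocount,gc_min,span,degree upstream tunables, see the stage
#'   functions.
#' @return list with `track` (corrected logR bins), `segments` (with CN
#'   calls), `ploidy`.
#' @export
single_cell_cn_profile <- function(aln, bins, ref_region, ref_cn = 2,
                                   gamma = 25, kmin = 5L, pseudocount = 1,
                                   gc_min = 0.28, span = 0.3, degree = 2) {
  counted <- count_reads_in_bins(aln, bins)
  track <- compute_logr(counted, pseudocount = pseudocount, gc_min = gc_min)
  track <- gc_correct(track, span = span, degree = degree)
  stopifnot(all(track$gc >= gc_min))   # GC filter holds downstream of logR
  segs <- segment_track(track, gamma = gamma, kmin = kmin)
  ploidy <- estimate_ploidy(track, ref_region, ref_cn = ref_cn)
  list(track = track,
       segments = call_integer_cn(segs, ploidy),
       ploidy = ploidy)
}

#' Process an aCGH probe logR track
#'
#' Probe-mode processing for array CGH measurements of the same cells:
#' values below the floor are set to the floor (default -2 on the log2
#' scale, suppressing extreme negative outliers), the track is recentred so
#' the genome-wide mean is exactly 0, optionally Loess-GC-corrected when a
#' `gc` column is present (and recentred again), and finally segmented per
#' chromosome by PCF with the probe-mode parameters (default gamma 60,
#' kmin 25 probes per segment).
#'
#' @param probes data.frame sorted by (chrom, pos) with `chrom`, `pos`
#'   (1-based), `logr`, optional `gc`.
#' @param floor lowest admissible log2 value.
#' @param gamma,kmin PCF parameters for probe data.
#' @param gc_correct_flag apply Loess GC correction when possible.
#' @param span,degree Loess parameters.
#' @return list with `probes` (processed) and `segments` (`chrom`, `start`,
#'   `end` half-open in bp around the probe positions, `n_bins`, `mean`).
#' @export
process_acgh_track <- function(probes, floor = -2, gamma = 60, kmin = 25L,
                               gc_correct_flag = FALSE, span = 0.3, degree = 2) {
  stopifnot(all(c("chrom", "pos", "logr") %in% names(probes)))
  x <- probes[order(probes$chrom, probes$pos), , drop = FALSE]
  x$logr <- pmax(x$logr, floor)
  x$logr <- x$logr - mean(x$logr)
  if (gc_correct_flag) {
    if (!"gc" %in% names(x)) {
      warning("gc column absent; skipping GC correction")
    } else if (diff(range(x$gc)) < 1e-8) {
      warning("degenerate GC range; skipping GC correction")
    } else {
      fit <- loess(logr ~ gc, data = x, span = span, degree = degree)
      x$logr <- x$logr - predict(fit, x$gc)
      x$logr <- x$logr - mean(x$logr)
    }
  }
  track <- data.frame(chrom = x$chrom, start = x$pos - 1L, end = x$pos,
                      logr = x$logr, stringsAsFactors = FALSE)
  segs <- segment_track(track, gamma = gamma, kmin = kmin)
  list(probes = x, segments = segs)
}
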