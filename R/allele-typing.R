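#' Digital SNP B-allele fractions
#'
#' BAF at a known heterozygous SNP is the fraction of reads carrying the
#' alternate allele. Because a single WGA cell yields shallow, uneven
#' coverage, BAF is only computed at sites with total depth of at least
#' `min_depth` reads (default 8); shallower sites are flagged
#' uninformative and carry no BAF.
#'
#' @param counts data.frame `chrom`, `pos` (1-based), `ref_count`,
#'   `alt_count`.
#' @param min_depth minimum reads for an informative site.
#' @return the table with `depth`, `informative`, `baf` (NA when
#'   uninformative) added.
#' @export
compute_baf <- function(counts, min_depth = 8L) {
  stopifnot(all(counts$ref_count >= 0), all(counts$alt_count >= 0))
  out <- counts
  out$depth <- counts$ref_count + counts$alt_count
  out$informative <- out$depth >= min_depth
  out$baf <- ifelse(out$informative, counts$alt_count / out$depth, NA_real_)
  out
}

#' Classify per-segment allelic state from BAF
#'
#' Allele dropout during WGA makes single-site BAF unreliable, so states are
#' called at segment level from the fraction of informative sites with
#' extreme BAF. Because a copy-neutral LOH region need not coincide with a
#' dosage segment (its total copy number is unchanged), the copy-number
#' segments are first refined: mirrored BAF (`max(baf, 1-baf)`) is itself
#' PCF-segmented per chromosome and the resulting allelic breakpoints split
#' the copy-number segments. Each refined segment is then classified:
#' \describe{
#'   \item{LOH}{at least `loh_site_fraction` of its informative sites have
#'     BAF <= `low` or >= `high` (minimum `min_sites` sites).}
#'   \item{cnLOH}{LOH and the covering copy-number segment has integer CN 2.}
#'   \item{imbalanced}{not LOH but mean mirrored BAF > 0.65.}
#'   \item{balanced}{otherwise.}
#'   \item{uncalled}{fewer than `min_sites` informative sites.}
#' }
#'
#' @param baf_track output of [compute_baf()].
#' @param cn_profile segment table with `cn_integer` (from
#'   [call_integer_cn()]).
#' @param low,high extreme-BAF thresholds.
#' @param loh_site_fraction fraction of extreme sites required for LOH.
#' @param min_sites minimum informative sites per segment.
#' @param refine PCF-refine segment boundaries on mirrored BAF (default
#'   TRUE); when FALSE the copy-number segments are classified as-is.
#' @param baf_gamma,baf_kmin PCF parameters for the mirrored-BAF refinement
#'   (in site-index space).
#' @return data.frame of refined segments with `chrom`, `start`, `end`,
#'   `cn_integer`, `n_informative`, `loh_fraction`, `mean_mirrored_baf`,
#'   `state`.
#' @export
classify_allelic_state <- function(baf_track, cn_profile,
                                   low = 0.15, high = 0.85,
                                   loh_site_fraction = 0.9, min_sites = 10L,
                                   refine = TRUE, baf_gamma = 3, baf_kmin = 10L) {
  sites <- baf_track[baf_track$informative, , drop = FALSE]
  segs <- cn_profile[order(cn_profile$chrom, cn_profile$start), , drop = FALSE]
  pieces <- list()
  for (ch in unique(segs$chrom)) {
    s <- segs[segs$chrom == ch, , drop = FALSE]
    edges <- sort(unique(c(s$start, s$end)))
    if (refine) {
      sc <- sites[sites$chrom == ch, , drop = FALSE]
      sc <- sc[order(sc$pos), , drop = FALSE]
      if (nrow(sc) >= baf_kmin) {
        mb <- pmax(sc$baf, 1 - sc$baf)
        fit <- pcf_segment(mb, gamma = baf_gamma, kmin = baf_kmin)
        if (length(fit$breakpoints) > 0) {
          # allelic breakpoint between site b and b+1: cut midway
          cut_at <- floor((sc$pos[fit$breakpoints] + sc$pos[fit$breakpoints + 1]) / 2)
          edges <- sort(unique(c(edges, cut_at)))
        }
      }
    }
    edges <- edges[edges >= min(s$start) & edges <= max(s$end)]
    starts <- edges[-length(edges)]; ends <- edges[-1]
    j <- findInterval(starts, s$start)
    pieces[[length(pieces) + 1]] <- data.frame(
      chrom = ch, start = starts, end = ends,
      cn_integer = s$cn_integer[j], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  out$n_informative <- 0L
  out$loh_fraction <- NA_real_
  out$mean_mirrored_baf <- NA_real_
  out$state <- "uncalled"
  for (i in seq_len(nrow(out))) {
    inseg <- sites$chrom == out$chrom[i] &
      sites$pos - 1L >= out$start[i] & sites$pos - 1L < out$end[i]
    b <- sites$baf[inseg]
    out$n_informative[i] <- length(b)
    if (length(b) < min_sites) next
    extreme <- b <= low | b >= high
    out$loh_fraction[i] <- mean(extreme)
    out$mean_mirrored_baf[i] <- mean(pmax(b, 1 - b))
    if (out$loh_fraction[i] >= loh_site_fraction) {
      out$state[i] <- if (out$cn_integer[i] == 2) "cnLOH" else "LOH"
    } else if (out$mean_mirrored_baf[i] > 0.65) {
      out$state[i] <- "imbalanced"
    } else {
      out$state[i] <- "balanced"
    }
  }
  rownames(out) <- NULL
  out
}
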