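#' Gain/neutral/loss status track from integer copy number
#'
#' @param cn_profile segment table with `cn_integer`.
#' @param baseline copy number considered neutral (default 2; near-diploid
#'   tumors). Pass `round(psi)` to use the cell's own ploidy instead.
#' @return data.frame `chrom`, `start`, `end`, `status`.
#' @export
status_track <- function(cn_profile, baseline = 2L) {
  data.frame(chrom = cn_profile$chrom, start = cn_profile$start,
             end = cn_profile$end,
             status = ifelse(cn_profile$cn_integer > baseline, "gain",
                             ifelse(cn_profile$cn_integer < baseline, "loss", "neutral")),
             stringsAsFactors = FALSE)
}

#' Base-pair-weighted concordance of two status tracks
#'
#' Intersects the two tracks' windows on their shared chromosomes and
#' reports the fraction of intersected base pairs on which the gain /
#' neutral / loss status agrees. This is a package definition of
#' "concordant copy-number profiles": status agreement, not integer-CN
#' equality, weighted by base pairs.
#'
#' @param a,b status tracks from [status_track()].
#' @return list with `concordance`, `concordant_bp`, `compared_bp`, and
#'   `per_chromosome` breakdown.
#' @export
concordance <- function(a, b) {
  shared <- intersect(unique(a$chrom), unique(b$chrom))
  if (length(shared) == 0) stop("tracks share no chromosomes")
  rows <- lapply(shared, function(ch) {
    x <- a[a$chrom == ch, , drop = FALSE]
    y <- b[b$chrom == ch, , drop = FALSE]
    lo <- max(min(x$start), min(y$start))
    hi <- min(max(x$end), max(y$end))
    if (hi <= lo) return(data.frame(chrom = ch, concordant_bp = 0, compared_bp = 0))
    edges <- sort(unique(c(x$start, x$end, y$start, y$end)))
    edges <- edges[edges >= lo & edges <= hi]
    starts <- edges[-length(edges)]; ends <- edges[-1]
    sx <- x$status[findInterval(starts, x$start)]
    sy <- y$status[findInterval(starts, y$start)]
    w <- ends - starts
    data.frame(chrom = ch, concordant_bp = sum(w[sx == sy]),
               compared_bp = sum(w), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  conc_bp <- sum(per$concordant_bp); comp_bp <- sum(per$compared_bp)
  if (comp_bp == 0) stop("tracks have no overlapping extent")
  list(concordance = conc_bp / comp_bp, concordant_bp = conc_bp,
       compared_bp = comp_bp, per_chromosome = per)
}

# merge adjacent same-status windows into events; returns non-neutral runs
status_events <- function(track) {
  out <- list()
  for (ch in unique(track$chrom)) {
    x <- track[track$chrom == ch, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    run <- cumsum(c(TRUE, x$status[-1] != x$status[-nrow(x)] |
                      x$start[-1] != x$end[-nrow(x)]))
    for (r in unique(run)) {
      i <- which(run == r)
      if (x$status[i[1]] == "neutral") next
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = x$start[i[1]], end = x$end[i[length(i)]],
        status = x$status[i[1]], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      status = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# dosage-changing events of a tumor_truth, with the summed fraction of
# clones carrying each; cnLOH events are dosage-neutral and excluded
truth_dosage_events <- function(truth) {
  ev <- list()
  for (cl in truth$clones) {
    e <- cl$events
    e <- e[e$kind != "cnLOH" & e$change != 0, , drop = FALSE]
    if (nrow(e) == 0) next
    e$status <- ifelse(e$change > 0, "gain", "loss")
    e$fraction <- cl$fraction
    ev[[length(ev) + 1]] <- e[, c("chrom", "start", "end", "status", "fraction")]
  }
  if (length(ev) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      status = character(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, ev)
  key <- paste(ev$chrom, ev$start, ev$end, ev$status)
  agg <- tapply(ev$fraction, key, sum)
  ev <- ev[!duplicated(key), , drop = FALSE]
  ev$fraction <- as.numeric(agg[paste(ev$chrom, ev$start, ev$end, ev$status)])
  rownames(ev) <- NULL
  ev
}

jaccard_bp <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  union <- (e1 - s1) + (e2 - s2) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Classify single-cell events against the primary tumor
#'
#' Non-neutral runs of the cell's status track are matched to primary-tumor
#' events of the same direction by base-pair Jaccard overlap. A matched
#' event is `clonal-shared` when the primary clone fraction carrying it is
#' at least `subclonal_max_fraction`, else `subclonal-shared`; unmatched
#' cell events are `dtc-private` and unmatched primary events
#' `primary-private`.
#'
#' @param dtc_profile the cell's integer-CN segment table (with
#'   `cn_integer`), or a ready status track with a `status` column.
#' @param primary either a `tumor_truth` (events and clone fractions are
#'   extracted; cnLOH events are dosage-neutral and not compared) or a
#'   data.frame `chrom`, `start`, `end`, `status`, `fraction`.
#' @param baseline neutral copy number for the cell profile.
#' @param min_jaccard minimum bp Jaccard to accept a match.
#' @param subclonal_max_fraction clone-fraction threshold separating clonal
#'   from subclonal primary events.
#' @return list with `dtc_events` (label per cell event) and
#'   `primary_events` (with `shared` flag; unshared rows are
#'   primary-private).
#' @export
classify_events <- function(dtc_profile, primary, baseline = 2L,
                            min_jaccard = 0.5, subclonal_max_fraction = 0.8) {
  dtc <- if ("status" %in% names(dtc_profile)) {
    status_events(dtc_profile)
  } else {
    status_events(status_track(dtc_profile, baseline))
  }
  prim <- if (inherits(primary, "tumor_truth")) truth_dosage_events(primary) else primary
  dtc$label <- NA_character_
  dtc$matched_fraction <- NA_real_
  prim$shared <- FALSE
  if (nrow(dtc) > 0) {
    for (i in seq_len(nrow(dtc))) {
      jc <- rep(0, nrow(prim))
      if (nrow(prim) > 0) {
        same <- prim$chrom == dtc$chrom[i] & prim$status == dtc$status[i]
        jc[same] <- vapply(which(same), function(k) {
          jaccard_bp(dtc$start[i], dtc$end[i], prim$start[k], prim$end[k])
        }, numeric(1))
      }
      if (length(jc) > 0 && max(jc) >= min_jaccard) {
        k <- which.max(jc)
        prim$shared[k] <- TRUE
        dtc$matched_fraction[i] <- prim$fraction[k]
        dtc$label[i] <- if (prim$fraction[k] >= subclonal_max_fraction)
          "clonal-shared" else "subclonal-shared"
      } else {
        dtc$label[i] <- "dtc-private"
      }
    }
  }
  prim$label <- ifelse(prim$shared, "shared", "primary-private")
  list(dtc_events = dtc, primary_events = prim)
}
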