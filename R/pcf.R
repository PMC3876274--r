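#' Exact piecewise-constant fitting (PCF) by penalised least squares
#'
#' Finds the global minimiser of
#' \deqn{\sum_{segments} SSE(segment) + \gamma \times (\#breakpoints)}
#' over all segmentations of an ordered numeric series whose segments each
#' contain at least `kmin` points. Solved by exact dynamic programming on
#' prefix sums (O(n^2)), affordable and fully testable at the bin counts
#' this package targets (up to a few thousand per chromosome). Ties are
#' broken toward fewer breakpoints, then toward the lexicographically
#' smallest (leftmost) breakpoint vector; outputs are fully deterministic.
#'
#' The penalty is charged per breakpoint; charging it per segment instead
#' shifts every candidate objective by the same constant and selects the
#' same segmentation.
#'
#' @param values finite numeric series.
#' @param gamma breakpoint penalty, >= 0.
#' @param kmin minimum points per segment, >= 1.
#' @return list of class `pcf_fit` with `breakpoints` (indices `b` such that
#'   a segment ends at `b`; excludes `n`), `segments` (data.frame
#'   `start_idx`, `end_idx`, `n_points`, `mean`), and `objective`.
#' @export
pcf_segment <- function(values, gamma, kmin = 1L) {
  n <- length(values)
  if (any(!is.finite(values))) stop("values must be finite")
  if (gamma < 0) stop("gamma must be >= 0")
  if (kmin < 1) stop("kmin must be >= 1")
  if (n < kmin) stop("series shorter than kmin")
  S <- c(0, cumsum(values))
  S2 <- c(0, cumsum(values^2))
  sse <- function(i, j) {                       # vectorised over i, 1-based inclusive
    len <- j - i + 1
    S2[j + 1] - S2[i] - (S[j + 1] - S[i])^2 / len
  }
  # suffix DP: G[i] = optimal cost of values[i..n]; B[i] = min #breakpoints
  # among cost-optimal suffix segmentations. A first segment [i, e] is
  # admissible when it has >= kmin points and either ends the series or
  # leaves an admissible suffix (G[e+1] finite).
  G <- rep(Inf, n + 1); G[n + 1] <- 0
  B <- rep(NA_integer_, n + 1); B[n + 1] <- 0L
  for (i in n:1) {
    if (i + kmin - 1 > n) next               # no admissible first segment
    e <- seq(i + kmin - 1, n)
    ok <- e == n | is.finite(G[e + 1])
    e <- e[ok]
    if (length(e) == 0) next
    cost <- sse(i, e) + ifelse(e < n, gamma, 0) + G[e + 1]
    G[i] <- min(cost)
    at <- which(cost == G[i])
    B[i] <- min(ifelse(e[at] < n, 1L, 0L) + B[e[at] + 1])
  }
  if (!is.finite(G[1])) stop("no admissible segmentation")   # unreachable for n >= kmin
  # forward greedy reconstruction: at each segment start take the smallest
  # admissible end achieving (G, B) -- lexicographically smallest breakpoints
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  repeat {
    e <- seq(i + kmin - 1, n)
    ok <- e == n | is.finite(G[e + 1])
    e <- e[ok]
    cost <- sse(i, e) + ifelse(e < n, gamma, 0) + G[e + 1]
    bk <- ifelse(e < n, 1L, 0L) + B[e + 1]
    pick <- e[which(cost == G[i] & bk == B[i])[1]]
    starts <- c(starts, i); ends <- c(ends, pick)
    if (pick == n) break
    i <- pick + 1L
  }
  means <- (S[ends + 1] - S[starts]) / (ends - starts + 1)
  structure(list(
    breakpoints = ends[-length(ends)],
    segments = data.frame(start_idx = starts, end_idx = ends,
                          n_points = ends - starts + 1, mean = means),
    objective = G[1]), class = "pcf_fit")
}

#' Exhaustive segmentation oracle
#'
#' Enumerates every admissible breakpoint subset (segment lengths >= kmin)
#' for short series and returns the optimum under the identical
#' (cost, fewer breakpoints, leftmost) ordering used by [pcf_segment()].
#' Exists purely as an independent check of the dynamic program; refuses
#' series longer than 15 points.
#'
#' @inheritParams pcf_segment
#' @return a `pcf_fit`, as [pcf_segment()].
#' @export
segment_oracle <- function(values, gamma, kmin = 1L) {
  n <- length(values)
  if (n > 15) stop("oracle restricted to series of length <= 15")
  if (any(!is.finite(values))) stop("values must be finite")
  if (n < kmin) stop("series shorter than kmin")
  S <- c(0, cumsum(values))
  S2 <- c(0, cumsum(values^2))
  seg_sse <- function(i, j) S2[j + 1] - S2[i] - (S[j + 1] - S[i])^2 / (j - i + 1)
  best <- NULL
  recurse <- function(start, ends_so_far, cost_so_far) {
    lo <- start + kmin - 1L
    if (lo > n) return(invisible(NULL))
    for (e in lo:n) {
      cost <- cost_so_far + seg_sse(start, e)
      if (e == n) {
        cand <- list(ends = c(ends_so_far, n),
                     cost = cost + gamma * length(ends_so_far))
        if (is.null(best) || better_fit(cand, best)) best <<- cand
      } else if (n - e >= kmin) {
        recurse(e + 1L, c(ends_so_far, e), cost)
      }
    }
  }
  recurse(1L, integer(0), 0)
  ends <- best$ends
  starts <- c(1L, head(ends, -1) + 1L)
  means <- (S[ends + 1] - S[starts]) / (ends - starts + 1)
  structure(list(
    breakpoints = ends[-length(ends)],
    segments = data.frame(start_idx = starts, end_idx = ends,
                          n_points = ends - starts + 1, mean = means),
    objective = best$cost), class = "pcf_fit")
}

# ordering: smaller cost (tolerance for float path differences), then fewer
# breakpoints, then lexicographically smaller breakpoint vector
better_fit <- function(a, b, tol = 1e-12) {
  scale <- max(1, abs(a$cost), abs(b$cost))
  if (a$cost < b$cost - tol * scale) return(TRUE)
  if (a$cost > b$cost + tol * scale) return(FALSE)
  na <- length(a$ends); nb <- length(b$ends)
  if (na != nb) return(na < nb)
  d <- which(a$ends != b$ends)
  if (length(d) == 0) return(FALSE)
  a$ends[d[1]] < b$ends[d[1]]
}

#' Segment a genome-ordered value track per chromosome
#'
#' Applies [pcf_segment()] independently within each chromosome (a segment
#' never crosses a chromosome boundary) and maps segment indices back to
#' genomic extents: a segment spans from the start of its first bin to the
#' end of its last bin. Chromosomes with fewer than `kmin` bins are emitted
#' as a single unsegmented segment with a warning.
#'
#' @param track data.frame sorted by (chrom, start) with columns `chrom`,
#'   `start`, `end`, and the value column named by `value_col`.
#' @param gamma breakpoint penalty.
#' @param kmin minimum bins per segment.
#' @param value_col name of the value column (default `"logr"`).
#' @return data.frame `chrom`, `start`, `end`, `n_bins`, `mean`.
#' @export
segment_track <- function(track, gamma, kmin = 1L, value_col = "logr") {
  stopifnot(value_col %in% names(track))
  out <- lapply(unique(track$chrom), function(ch) {
    x <- track[track$chrom == ch, , drop = FALSE]
    v <- x[[value_col]]
    if (length(v) < kmin) {
      warning("chromosome ", ch, " has fewer than kmin bins; left unsegmented")
      return(data.frame(chrom = ch, start = x$start[1], end = x$end[nrow(x)],
                        n_bins = nrow(x), mean = mean(v), stringsAsFactors = FALSE))
    }
    fit <- pcf_segment(v, gamma, kmin)
    data.frame(chrom = ch,
               start = x$start[fit$segments$start_idx],
               end = x$end[fit$segments$end_idx],
               n_bins = fit$segments$n_points,
               mean = fit$segments$mean, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
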