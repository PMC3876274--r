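#' Simulate allele-specific tumor truth (clones and copy-number events)
#'
#' A tumor is modelled as a set of clones, each with a cell fraction and a
#' list of allele-specific copy-number events applied to a diploid genome
#' (one A and one B parental copy everywhere). Event kinds:
#' \describe{
#'   \item{arm / focal}{add `change` copies to allele `A`, `B` or `both`
#'     over `[start, end)`; the distinction is descriptive (extent).}
#'   \item{cnLOH}{copy-neutral LOH: the B allele is lost and the A allele
#'     duplicated, leaving total copy number unchanged.}
#'   \item{shatter}{chromothripsis-like: expanded (with the given seed) into
#'     an oscillating run of focal one-copy gains and losses on alternating
#'     alleles inside `[start, end)`.}
#' }
#' Per-allele copy number must remain non-negative everywhere; an event plan
#' that drives an allele below zero is rejected.
#'
#' @param genome list as returned by [simulate_genome()], or a named
#'   [Biostrings::DNAStringSet]; only chromosome names/lengths are used.
#' @param event_plan list of clones; each clone is a list with `id`,
#'   `fraction`, and `events` — a data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open), `allele` (`"A"`, `"B"`, `"both"`), `change`
#'   (signed integer; ignored for cnLOH), `kind`.
#' @param normal_fraction fraction of admixed normal (diploid) cells in the
#'   bulk; clone fractions plus `normal_fraction` must sum to 1.
#' @param seed integer seed (used only to expand `shatter` events).
#' @param shatter_pieces number of oscillating pieces a shatter event is
#'   broken into.
#' @return an object of class `tumor_truth`: list with `clones`,
#'   `normal_fraction`, `chrom_lengths`.
#' @export
simulate_tumor_truth <- function(genome, event_plan, normal_fraction = 0,
                                 seed = 1L, shatter_pieces = 10L) {
  genome <- genome_of(genome)
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  fr <- vapply(event_plan, function(cl) cl$fraction, numeric(1))
  if (any(fr < 0) || abs(sum(fr) + normal_fraction - 1) > 1e-9) {
    stop("clone fractions plus normal_fraction must sum to 1")
  }
  clones <- with_seed(seed, lapply(event_plan, function(cl) {
    ev <- normalize_events(cl$events, chrom_lengths, shatter_pieces)
    list(id = cl$id, fraction = cl$fraction, events = ev)
  }))
  truth <- structure(list(clones = clones, normal_fraction = normal_fraction,
                          chrom_lengths = chrom_lengths),
                     class = "tumor_truth")
  # reject plans driving any allele negative
  for (cl in truth$clones) {
    segs <- clone_cn_segments(truth, cl$id)
    if (any(segs$cnA < 0 | segs$cnB < 0)) {
      stop(sprintf("event plan for clone '%s' drives an allele below 0 copies", cl$id))
    }
  }
  truth
}

genome_of <- function(genome) {
  if (is.list(genome) && !is.null(genome$genome)) genome$genome else genome
}

normalize_events <- function(events, chrom_lengths, shatter_pieces) {
  if (is.null(events) || nrow(events) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      allele = character(), change = integer(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  out <- list()
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (!e$chrom %in% names(chrom_lengths)) stop("event on unknown chromosome: ", e$chrom)
    if (e$start < 0 || e$end > chrom_lengths[[e$chrom]] || e$start >= e$end) {
      stop("invalid event interval on ", e$chrom)
    }
    if (identical(e$kind, "shatter")) {
      bp <- sort(sample(seq(e$start + 1, e$end - 1), shatter_pieces - 1))
      edges <- c(e$start, bp, e$end)
      for (j in seq_len(length(edges) - 1)) {
        out[[length(out) + 1]] <- data.frame(
          chrom = e$chrom, start = edges[j], end = edges[j + 1],
          allele = if (j %% 2 == 1) "A" else "B",
          change = if (j %% 2 == 1) 1L else -1L,
          kind = "shatter", stringsAsFactors = FALSE)
      }
    } else {
      out[[length(out) + 1]] <- data.frame(
        chrom = e$chrom, start = as.integer(e$start), end = as.integer(e$end),
        allele = e$allele, change = as.integer(e$change), kind = e$kind,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-clone allele-specific copy-number segments
#'
#' Applies a clone's events, in order, to a diploid baseline and returns the
#' resulting piecewise-constant allele-specific copy-number track.
#'
#' @param truth a `tumor_truth`.
#' @param clone_id clone identifier.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `cnA`, `cnB`, `cn_total`, tiling every chromosome.
#' @export
clone_cn_segments <- function(truth, clone_id) {
  cl <- clone_by_id(truth, clone_id)
  out <- lapply(names(truth$chrom_lengths), function(ch) {
    L <- truth$chrom_lengths[[ch]]
    ev <- cl$events[cl$events$chrom == ch, , drop = FALSE]
    edges <- sort(unique(c(0L, L, ev$start, ev$end)))
    n <- length(edges) - 1
    cnA <- rep(1, n); cnB <- rep(1, n)
    starts <- edges[-length(edges)]; ends <- edges[-1]
    if (nrow(ev) > 0) {
      for (i in seq_len(nrow(ev))) {
        hit <- starts >= ev$start[i] & ends <= ev$end[i]
        if (identical(ev$kind[i], "cnLOH")) {
          cnA[hit] <- cnA[hit] + cnB[hit]
          cnB[hit] <- 0
        } else if (ev$allele[i] == "both") {
          cnA[hit] <- cnA[hit] + ev$change[i]
          cnB[hit] <- cnB[hit] + ev$change[i]
        } else if (ev$allele[i] == "A") {
          cnA[hit] <- cnA[hit] + ev$change[i]
        } else {
          cnB[hit] <- cnB[hit] + ev$change[i]
        }
      }
    }
    data.frame(chrom = ch, start = starts, end = ends, cnA = cnA, cnB = cnB,
               cn_total = cnA + cnB, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

clone_by_id <- function(truth, clone_id) {
  ids <- vapply(truth$clones, `[[`, "", "id")
  i <- match(clone_id, ids)
  if (is.na(i)) stop("unknown clone: ", clone_id)
  truth$clones[[i]]
}

#' Bulk (clone-fraction-weighted) copy-number segments
#'
#' Mixture of all clones plus the normal fraction: at every position the bulk
#' total CN is the fraction-weighted mean of clone total CN (normal cells
#' contribute 2), and the bulk B-allele CN likewise (normal contributes 1).
#'
#' @param truth a `tumor_truth`.
#' @return data.frame with `chrom`, `start`, `end`, `cn_total`, `cnB`
#'   (fraction-weighted, generally non-integer).
#' @export
bulk_cn_segments <- function(truth) {
  per_clone <- lapply(truth$clones, function(cl) clone_cn_segments(truth, cl$id))
  out <- lapply(names(truth$chrom_lengths), function(ch) {
    edges <- sort(unique(unlist(lapply(per_clone, function(s) {
      s <- s[s$chrom == ch, ]; c(s$start, s$end)
    }))))
    starts <- edges[-length(edges)]; ends <- edges[-1]
    tot <- rep(truth$normal_fraction * 2, length(starts))
    bb <- rep(truth$normal_fraction * 1, length(starts))
    for (k in seq_along(truth$clones)) {
      s <- per_clone[[k]]; s <- s[s$chrom == ch, ]
      idx <- findInterval(starts, s$start)
      tot <- tot + truth$clones[[k]]$fraction * s$cn_total[idx]
      bb <- bb + truth$clones[[k]]$fraction * s$cnB[idx]
    }
    data.frame(chrom = ch, start = starts, end = ends, cn_total = tot,
               cnB = bb, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Copy number at single positions for one clone
#'
#' @param truth a `tumor_truth`; @param clone_id clone identifier.
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @return data.frame with `cnA`, `cnB`, `cn_total` per queried position.
#' @export
clone_cn_at <- function(truth, clone_id, chrom, pos) {
  segs <- clone_cn_segments(truth, clone_id)
  n <- length(pos)
  cnA <- numeric(n); cnB <- numeric(n)
  for (ch in unique(chrom)) {
    s <- segs[segs$chrom == ch, ]
    idx <- which(chrom == ch)
    j <- findInterval(pos[idx], s$start)
    cnA[idx] <- s$cnA[j]; cnB[idx] <- s$cnB[j]
  }
  data.frame(cnA = cnA, cnB = cnB, cn_total = cnA + cnB)
}
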