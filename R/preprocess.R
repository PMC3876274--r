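#' Profile a recurrent adapter prefix across raw reads
#'
#' WGA adapter sequence contaminates the 5' end of single-cell reads. This
#' inspects per-position base frequencies over the first `max_len` positions
#' (capped at the first 100,000 reads) and suggests a trim length: the
#' longest leading run of positions whose modal base frequency is at least
#' `dominance`.
#'
#' @param reads data.frame with a `seq` column, or a character vector.
#' @param max_len positions to profile.
#' @param dominance modal-base frequency required to call a position
#'   adapter-like.
#' @return list with `freq` (4 x max_len matrix, rows A/C/G/T, columns
#'   summing to 1 where reads reach) and `suggested_trim`.
#' @export
profile_adapter <- function(reads, max_len = 50L, dominance = 0.8) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (length(seqs) == 0) stop("no reads to profile")
  seqs <- head(seqs, 100000L)
  dss <- Biostrings::DNAStringSet(seqs)
  width <- pmin(Biostrings::width(dss), max_len)
  cm <- Biostrings::consensusMatrix(Biostrings::subseq(dss, 1, width))
  bases <- c("A", "C", "G", "T")
  freq <- matrix(0, 4, max_len, dimnames = list(bases, NULL))
  take <- min(ncol(cm), max_len)
  for (b in bases) if (b %in% rownames(cm)) freq[b, seq_len(take)] <- cm[b, seq_len(take)]
  tot <- colSums(freq)
  freq <- sweep(freq, 2, pmax(tot, 1), "/")
  modal <- apply(freq, 2, max)
  covered <- tot > 0
  run <- which(!(modal >= dominance & covered))
  suggested <- if (length(run) == 0) max_len else run[1] - 1L
  if (suggested == max_len) {
    warning("reads are adapter-like over the whole profiled length")
  }
  list(freq = freq, suggested_trim = as.integer(suggested))
}

#' Trim a fixed-length prefix from reads
#'
#' Each read loses its first `n` bases; reads shorter than `n` are dropped
#' and counted.
#'
#' @param reads data.frame with `qname`, `seq` (and optional `qual`), or a
#'   character vector.
#' @param n bases to remove from the 5' end (default 32, the WGA adapter
#'   length).
#' @return data.frame of trimmed reads with attribute `n_dropped`.
#' @export
trim_reads <- function(reads, n = 32L) {
  stopifnot(n >= 0)
  if (!is.data.frame(reads)) {
    reads <- data.frame(qname = sprintf("read%07d", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  }
  keep <- nchar(reads$seq) >= n
  out <- reads[keep, , drop = FALSE]
  out$seq <- substring(out$seq, n + 1L)
  if ("qual" %in% names(out)) out$qual <- substring(out$qual, n + 1L)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Exact-match toy mapper
#'
#' Places each read where its sequence, or its reverse complement, matches
#' the genome exactly. Reads matching more than one locus are discarded as
#' multi-mappers; reads matching none are discarded as unmapped. This is the
#' desk-scale stand-in for a real aligner and makes the multi-mapper policy
#' (discard) explicit.
#'
#' @param reads data.frame with `qname`, `seq` (trimmed reads).
#' @param genome genome list or named [Biostrings::DNAStringSet].
#' @return data.frame `qname`, `chrom`, `start` (0-based), `strand`, with
#'   attribute `counters` = list(n_mapped, n_unmapped, n_multi).
#' @export
map_reads_exact <- function(reads, genome) {
  genome <- genome_of(genome)
  n <- nrow(reads)
  hits_chrom <- character(n); hits_start <- integer(n); hits_strand <- character(n)
  nhit <- integer(n)
  clean <- !grepl("[^ACGT]", reads$seq) & nchar(reads$seq) > 0
  idx_by_width <- split(which(clean), nchar(reads$seq[clean]))
  first_start <- function(mindex, who) {
    si <- Biostrings::startIndex(mindex)
    vapply(si[who], `[[`, integer(1), 1L)
  }
  for (w in names(idx_by_width)) {
    idx <- idx_by_width[[w]]
    fwd <- Biostrings::DNAStringSet(reads$seq[idx])
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(Biostrings::reverseComplement(fwd))
    for (ch in names(genome)) {
      mf <- Biostrings::matchPDict(pd_f, genome[[ch]])
      mr <- Biostrings::matchPDict(pd_r, genome[[ch]])
      cf <- S4Vectors::elementNROWS(mf)
      cr <- S4Vectors::elementNROWS(mr)
      has_f <- which(cf > 0)
      if (length(has_f) > 0) {
        hits_chrom[idx[has_f]] <- ch
        hits_start[idx[has_f]] <- first_start(mf, has_f) - 1L
        hits_strand[idx[has_f]] <- "+"
      }
      only_r <- which(cr > 0 & cf == 0)       # do not clobber a forward hit
      if (length(only_r) > 0) {
        hits_chrom[idx[only_r]] <- ch
        hits_start[idx[only_r]] <- first_start(mr, only_r) - 1L
        hits_strand[idx[only_r]] <- "-"
      }
      nhit[idx] <- nhit[idx] + cf + cr
    }
  }
  keep <- nhit == 1
  counters <- list(n_mapped = sum(keep),
                   n_unmapped = sum(nhit == 0),
                   n_multi = sum(nhit > 1))
  out <- data.frame(qname = reads$qname[keep], chrom = hits_chrom[keep],
                    start = hits_start[keep], strand = hits_strand[keep],
                    stringsAsFactors = FALSE)
  attr(out, "counters") <- counters
  out
}

#' Remove PCR duplicates from alignments
#'
#' Among alignments sharing (chrom, 5' start, strand) — the standard
#' single-end duplicate key — exactly one is kept (first by read-name
#' order). Output is sorted by coordinate. Idempotent.
#'
#' @param aln data.frame `qname`, `chrom`, `start`, `strand`.
#' @return deduplicated data.frame with attribute `n_removed`.
#' @export
dedup_alignments <- function(aln) {
  if (nrow(aln) == 0) { attr(aln, "n_removed") <- 0L; return(aln) }
  ord <- order(aln$qname)
  x <- aln[ord, , drop = FALSE]
  key <- paste(x$chrom, x$start, x$strand, sep = "\r")
  keep <- !duplicated(key)
  out <- x[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Breadth and depth of coverage
#'
#' `depth_genome` is alignment count x read length over the genome size
#' (genome-relative depth); `breadth` is the fraction of reference positions
#' covered at least once (interval union); `depth_covered` is the mean depth
#' over covered positions only. The three satisfy the identity
#' `depth_covered * breadth = depth_genome` exactly.
#'
#' @param aln deduplicated alignments (`chrom`, `start`, `strand`).
#' @param genome_length total reference length (bp).
#' @param read_length alignment footprint (bp).
#' @return list with `breadth`, `depth_genome`, `depth_covered`.
#' @export
coverage_stats <- function(aln, genome_length, read_length) {
  if (nrow(aln) == 0) {
    warning("no alignments: coverage undefined, reporting zeros")
    return(list(breadth = 0, depth_genome = 0, depth_covered = 0))
  }
  depth_genome <- nrow(aln) * read_length / genome_length
  covered <- sum(vapply(split(aln$start, aln$chrom), function(st) {
    ir <- IRanges::IRanges(start = st + 1L, width = read_length)
    sum(IRanges::width(IRanges::reduce(ir)))
  }, numeric(1)))
  breadth <- covered / genome_length
  list(breadth = breadth, depth_genome = depth_genome,
       depth_covered = depth_genome / breadth)
}

#' Depth over covered bases from genome-relative depth and breadth
#'
#' The coverage identity rearranged: mean depth over covered positions is
#' genome-relative depth divided by breadth. Useful for recomputing
#' covered-base depth from summary statistics alone (e.g. a cell sequenced
#' to genome-relative depth 2.92x with breadth 0.339 has covered-base depth
#' 8.61x).
#'
#' @param depth_genome genome-relative mean depth.
#' @param breadth fraction of genome covered >= 1x, in (0, 1].
#' @return depth over covered bases.
#' @export
depth_on_covered <- function(depth_genome, breadth) {
  stopifnot(breadth > 0, breadth <= 1, depth_genome >= 0)
  depth_genome / breadth
}
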