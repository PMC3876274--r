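#' Specify a synthetic reference genome
#'
#' The simulated reference is a small stand-in for a real assembly: random
#' sequence with a smoothly varying GC landscape (linear interpolation
#' between control points) and optional planted exact duplications, which
#' create multi-mapping regions for the mappability stage to discover.
#'
#' @param n_chroms number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length length of every chromosome in bp.
#' @param gc_landscape data.frame with columns `pos` (bp, 0-based) and `gc`
#'   (target GC fraction in `[0,1]`); interpolated along each chromosome.
#'   Default is flat 0.45.
#' @param duplications list of duplication descriptors, each a list with
#'   `chrom`, `start`, `end` (0-based half-open source interval),
#'   `target_chrom`, `target_start`; the source block is copied verbatim over
#'   the target. Source and target must not overlap.
#' @param seed integer seed.
#' @return an object of class `sim_genome_spec`.
#' @export
sim_genome_spec <- function(n_chroms = 1, chrom_length = 1e5,
                            gc_landscape = data.frame(pos = 0, gc = 0.45),
                            duplications = list(), seed = 1L) {
  stopifnot(n_chroms >= 1, chrom_length > 0)
  if (any(gc_landscape$gc < 0 | gc_landscape$gc > 1)) {
    stop("gc_landscape values must lie in [0,1]")
  }
  for (d in duplications) {
    if (d$start < 0 || d$end > chrom_length || d$start >= d$end) {
      stop("duplication source interval outside chromosome")
    }
    w <- d$end - d$start
    if (d$target_start < 0 || d$target_start + w > chrom_length) {
      stop("duplication target outside chromosome")
    }
    if (d$chrom == d$target_chrom &&
        d$target_start < d$end && d$start < d$target_start + w) {
      stop("duplication target overlaps its source")
    }
  }
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 gc_landscape = gc_landscape,
                 duplications = duplications,
                 seed = as.integer(seed)),
            class = "sim_genome_spec")
}

#' Simulate a reference genome
#'
#' Bases are drawn independently with per-position P(G or C) given by the
#' interpolated GC landscape, so realized GC in 10 kb windows tracks the
#' control curve to within sampling noise. Planted duplications are applied
#' after sampling and are exact copies.
#'
#' @param spec a [sim_genome_spec()].
#' @return list with `genome` (named [Biostrings::DNAStringSet]) and
#'   `gc_target` (function of 0-based position returning the control GC).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_genome_spec"))
  L <- spec$chrom_length
  gl <- spec$gc_landscape
  gc_at <- if (nrow(gl) == 1) {
    function(pos) rep(gl$gc[1], length(pos))
  } else {
    function(pos) approx(gl$pos, gl$gc, xout = pos, rule = 2)$y
  }
  seqs <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_chroms), function(i) {
      gc <- gc_at(seq_len(L) - 1)
      is_gc <- runif(L) < gc
      half <- runif(L) < 0.5
      base <- character(L)
      base[is_gc & half] <- "G"
      base[is_gc & !half] <- "C"
      base[!is_gc & half] <- "A"
      base[!is_gc & !half] <- "T"
      paste(base, collapse = "")
    })
  })
  names(seqs) <- paste0("chr", seq_len(spec$n_chroms))
  for (d in spec$duplications) {
    block <- substr(seqs[[d$chrom]], d$start + 1, d$end)
    w <- d$end - d$start
    substr(seqs[[d$target_chrom]], d$target_start + 1, d$target_start + w) <- block
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  list(genome = genome, gc_target = gc_at)
}

#' GC fraction over genomic intervals
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param chrom chromosome names (recycled against start/end).
#' @param start,end 0-based half-open interval bounds.
#' @return numeric vector of GC fractions (non-ACGT bases count toward the
#'   denominator only).
#' @export
gc_fraction <- function(genome, chrom, start, end) {
  genome <- genome_of(genome)
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n); end <- rep_len(end, n)
  out <- numeric(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    v <- Biostrings::Views(genome[[ch]], start = start[idx] + 1L, end = end[idx])
    f <- Biostrings::letterFrequency(v, letters = c("G", "C"))
    out[idx] <- rowSums(f) / (end[idx] - start[idx])
  }
  out
}
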