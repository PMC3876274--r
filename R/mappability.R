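#' Uniquely mappable positions of a genome
#'
#' A start position is uniquely mappable for a given read length `k` iff the
#' k-mer starting there occurs exactly once in the genome. By default
#' occurrences are counted on both strands: a k-mer equal to the reverse
#' complement of a k-mer elsewhere counts as a second occurrence (an aligner
#' maps reads from either strand). Windows containing non-ACGT bases are
#' never unique. Positions within `read_length` of a chromosome end (where
#' no full window fits) are not mappable.
#'
#' The scan uses a rolling-hash k-mer dictionary in compiled code; the
#' exact string-dictionary implementation [unique_positions_bruteforce()]
#' serves as its independent oracle on small genomes.
#'
#' @param genome genome list from [simulate_genome()] or a named
#'   [Biostrings::DNAStringSet].
#' @param read_length window length in bp (default 69, a 101-bp read after
#'   32 bp of adapter trimming).
#' @param both_strands count reverse-complement occurrences (default TRUE).
#' @return named list of logical vectors, one per chromosome, each of the
#'   chromosome's length.
#' @export
compute_unique_positions <- function(genome, read_length = 69L, both_strands = TRUE) {
  genome <- genome_of(genome)
  stopifnot(read_length >= 1)
  seqs <- as.character(genome)
  .kmer_unique_mask(seqs, as.integer(read_length), both_strands)
}

#' @rdname compute_unique_positions
#' @details `unique_positions_bruteforce` builds the full k-mer string
#'   dictionary in R and refuses genomes above 200 kb; it exists to verify
#'   the compiled scan.
#' @export
unique_positions_bruteforce <- function(genome, read_length = 69L, both_strands = TRUE) {
  genome <- genome_of(genome)
  if (sum(Biostrings::width(genome)) > 200000) {
    stop("brute-force mask is restricted to genomes <= 200 kb")
  }
  k <- as.integer(read_length)
  seqs <- as.character(genome)
  kmers <- list()
  for (ch in names(seqs)) {
    L <- nchar(seqs[[ch]])
    n <- L - k + 1
    if (n <= 0) { kmers[[ch]] <- character(0); next }
    kmers[[ch]] <- substring(seqs[[ch]], 1:n, k:L)
  }
  all_k <- unlist(kmers, use.names = FALSE)
  valid <- !grepl("[^ACGT]", all_k)
  key <- all_k
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(ifelse(valid, all_k, strrep("A", k)))))
    key <- pmin(all_k, rc)
  }
  key[!valid] <- NA
  counts <- table(key)
  uniq <- valid & (as.integer(counts[key]) == 1)
  uniq[is.na(uniq)] <- FALSE
  out <- list()
  off <- 0
  for (ch in names(seqs)) {
    L <- nchar(seqs[[ch]])
    m <- rep(FALSE, L)
    n <- length(kmers[[ch]])
    if (n > 0) m[seq_len(n)] <- uniq[off + seq_len(n)]
    out[[ch]] <- m
    off <- off + n
  }
  out
}

#' Build variable-width bins holding a fixed count of unique positions
#'
#' Scanning each chromosome left to right, a bin closes immediately after
#' accumulating `target_unique` uniquely mappable positions; the next bin
#' starts where the previous ended, so bins tile the chromosome contiguously
#' with no gaps. The trailing partial bin (fewer than `target_unique`
#' uniques) is dropped, keeping all bins statistically exchangeable. Physical
#' bin width therefore varies inversely with local mappability. Per-bin GC is
#' measured over the full physical span.
#'
#' @param mask mask list from [compute_unique_positions()].
#' @param genome matching genome (for GC).
#' @param target_unique unique positions per bin (50 kb of unique positions
#'   at full human-genome scale; scale down for toy genomes).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `unique_count`, `gc`. Chromosomes with fewer than `target_unique`
#'   unique positions contribute no bins (with a message).
#' @export
build_variable_bins <- function(mask, genome, target_unique) {
  stopifnot(target_unique >= 1)
  genome <- genome_of(genome)
  out <- list()
  for (ch in names(mask)) {
    upos <- which(mask[[ch]]) - 1L         # 0-based unique starts
    nbin <- length(upos) %/% target_unique
    if (nbin == 0) {
      message("chromosome ", ch, " has fewer than ", target_unique,
              " unique positions; no bins emitted")
      next
    }
    closers <- upos[seq_len(nbin) * target_unique]   # last unique in each bin
    ends <- closers + 1L                   # bin closes right after it
    starts <- c(0L, ends[-nbin])
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            unique_count = as.integer(target_unique),
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      unique_count = integer(), gc = numeric(),
                      stringsAsFactors = FALSE))
  }
  bins <- do.call(rbind, out)
  bins$gc <- gc_fraction(genome, bins$chrom, bins$start, bins$end)
  rownames(bins) <- NULL
  bins
}

#' Summarise physical bin widths after trimming the widest bins
#'
#' Removes the largest `trim_top_fraction` of bins by physical width (the
#' long bins spanning unmappable deserts) and reports mean and sample SD of
#' the remaining widths.
#'
#' @param bins bin table from [build_variable_bins()].
#' @param trim_top_fraction fraction of widest bins to drop (default 0.01).
#' @return list with `mean` and `sd` (bp).
#' @export
bin_size_summary <- function(bins, trim_top_fraction = 0.01) {
  if (nrow(bins) == 0) stop("empty bin set")
  w <- bins$end - bins$start
  n_drop <- floor(trim_top_fraction * length(w))
  if (n_drop >= length(w)) stop("trim fraction removes all bins")
  if (n_drop > 0) w <- sort(w, decreasing = TRUE)[-seq_len(n_drop)]
  list(mean = mean(w), sd = if (length(w) > 1) sd(w) else 0)
}
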