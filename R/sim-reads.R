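#' Default WGA adapter prefix (32 bp) used by the read simulator
#' @export
DEFAULT_ADAPTER <- "TGTGTTGGGTGTGTTTGGAGTGGTAGTGTGGA"

#' Specify single-cell WGA read simulation
#'
#' The generative model for one whole-genome-amplified cell: each allele copy
#' of the genome is partitioned into amplicons (lengths ~ Normal, truncated
#' below); every amplicon-by-copy combination carries an independent
#' multiplicative amplification factor drawn from a mean-1 Gamma with
#' variance `amplification_dispersion` (shape `1/dispersion`; dispersion 0
#' means no amplification noise, recovering Poisson-like bin counts).
#' Read starts are then sampled proportionally to amplicon weight x a
#' log-linear GC factor `exp(gc_bias_coeff * (gc_amplicon - mean_gc))`.
#' Raw reads are the fixed adapter prefix followed by genomic sequence;
#' a `duplicate_rate` fraction of reads are PCR duplicates, i.e. exact
#' copies of earlier reads.
#'
#' @param read_length_raw raw read length in bp (adapter included).
#' @param adapter_prefix fixed adapter sequence contaminating the 5' end.
#' @param n_reads total reads to emit (duplicates included).
#' @param amplicon_length_mean,amplicon_length_sd amplicon length model (bp).
#' @param amplification_dispersion variance of the mean-1 Gamma amplicon
#'   multiplier; 0 disables amplification noise.
#' @param gc_bias_coeff slope of the log-linear coverage-vs-GC effect.
#' @param duplicate_rate fraction of emitted reads that are PCR duplicates.
#' @param error_rate uniform substitution rate on read bases (0 = error-free).
#' @param lognormal_amplification use a mean-1 lognormal amplicon multiplier
#'   of the same variance instead of the Gamma.
#' @param seed integer seed.
#' @return object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(read_length_raw = 101L, adapter_prefix = DEFAULT_ADAPTER,
                          n_reads = 10000L, amplicon_length_mean = 10000,
                          amplicon_length_sd = 2000,
                          amplification_dispersion = 0.25,
                          gc_bias_coeff = 0, duplicate_rate = 0.02,
                          error_rate = 0, lognormal_amplification = FALSE,
                          seed = 1L) {
  trimmed <- read_length_raw - nchar(adapter_prefix)
  if (trimmed < 1) stop("read_length_raw must exceed the adapter length")
  if (duplicate_rate < 0 || duplicate_rate > 1) stop("duplicate_rate must be in [0,1]")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0,1]")
  if (amplification_dispersion < 0) stop("amplification_dispersion must be >= 0")
  structure(list(read_length_raw = as.integer(read_length_raw),
                 adapter_prefix = adapter_prefix,
                 read_length = as.integer(trimmed),
                 n_reads = as.integer(n_reads),
                 amplicon_length_mean = amplicon_length_mean,
                 amplicon_length_sd = amplicon_length_sd,
                 amplification_dispersion = amplification_dispersion,
                 gc_bias_coeff = gc_bias_coeff,
                 duplicate_rate = duplicate_rate,
                 error_rate = error_rate,
                 lognormal_amplification = lognormal_amplification,
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

# draw n mean-1 multipliers with variance d
amp_multiplier <- function(n, d, lognormal = FALSE) {
  if (d == 0) return(rep(1, n))
  if (lognormal) {
    s2 <- log1p(d)
    rlnorm_local(n, -s2 / 2, sqrt(s2))
  } else {
    shape <- 1 / d
    rgamma(n, shape = shape, rate = shape)
  }
}

rlnorm_local <- function(n, meanlog, sdlog) exp(rnorm(n, meanlog, sdlog))

#' Simulate raw reads for one single cell (one clone)
#'
#' @param genome list from [simulate_genome()] or a named
#'   [Biostrings::DNAStringSet].
#' @param truth a `tumor_truth` from [simulate_tumor_truth()].
#' @param clone_id which clone this cell is drawn from (a DTC is one pure
#'   clone).
#' @param spec a [read_sim_spec()].
#' @return list with:
#'   \describe{
#'     \item{reads}{data.frame `qname`, `seq` (raw reads, adapter-prefixed).}
#'     \item{alignments}{data.frame `qname`, `chrom`, `start` (0-based start
#'       of the trimmed 69-mer footprint), `strand`, `is_duplicate` — the
#'       true alignments, one per read.}
#'     \item{n_duplicates}{count of emitted PCR duplicates.}
#'   }
#' @export
simulate_cell_reads <- function(genome, truth, clone_id, spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  genome <- genome_of(genome)
  rl <- spec$read_length
  empty <- list(
    reads = data.frame(qname = character(), seq = character(), stringsAsFactors = FALSE),
    alignments = data.frame(qname = character(), chrom = character(),
                            start = integer(), strand = character(),
                            is_duplicate = logical(), stringsAsFactors = FALSE),
    n_duplicates = 0L)
  if (spec$n_reads == 0) return(empty)
  segs <- clone_cn_segments(truth, clone_id)

  with_seed(spec$seed, {
    # amplicons tile each constant-CN interval; weight = width x GC factor x
    # summed per-copy amplification multipliers
    amp <- list()
    for (i in seq_len(nrow(segs))) {
      s0 <- segs$start[i]; e0 <- segs$end[i]
      if (segs$cn_total[i] <= 0) next
      w <- e0 - s0
      n_amp <- max(1L, round(w / spec$amplicon_length_mean))
      lens <- pmax(500, rnorm(n_amp, spec$amplicon_length_mean, spec$amplicon_length_sd))
      edges <- s0 + round(cumsum(lens) / sum(lens) * w)
      starts <- c(s0, edges[-n_amp]); ends <- edges
      keep <- ends > starts
      starts <- starts[keep]; ends <- ends[keep]
      mult <- vapply(seq_along(starts), function(j) {
        sum(amp_multiplier(segs$cn_total[i], spec$amplification_dispersion,
                           spec$lognormal_amplification))
      }, numeric(1))
      amp[[length(amp) + 1]] <- data.frame(chrom = segs$chrom[i],
                                           start = starts, end = ends,
                                           mult = mult, stringsAsFactors = FALSE)
    }
    amp <- do.call(rbind, amp)
    chrom_len <- setNames(Biostrings::width(genome), names(genome))
    # valid start positions: footprint must fit on the chromosome
    amp$lim <- pmin(amp$end, chrom_len[amp$chrom] - rl + 1)
    amp <- amp[amp$lim > amp$start, , drop = FALSE]
    amp$gc <- gc_fraction(genome, amp$chrom, amp$start, amp$end)
    mean_gc <- sum(amp$gc * (amp$end - amp$start)) / sum(amp$end - amp$start)
    gcfac <- exp(spec$gc_bias_coeff * (amp$gc - mean_gc))
    weight <- (amp$lim - amp$start) * amp$mult * gcfac

    is_dup <- runif(spec$n_reads) < spec$duplicate_rate
    is_dup[1] <- FALSE
    n_orig <- sum(!is_dup)
    ai <- sample.int(nrow(amp), n_orig, replace = TRUE, prob = weight)
    pos <- amp$start[ai] + floor(runif(n_orig) * (amp$lim[ai] - amp$start[ai]))
    strand <- ifelse(runif(n_orig) < 0.5, "+", "-")
    chrom <- amp$chrom[ai]

    # assemble in emission order: duplicates copy a uniformly chosen original
    ord_orig <- which(!is_dup)
    chrom_all <- character(spec$n_reads)
    pos_all <- integer(spec$n_reads)
    strand_all <- character(spec$n_reads)
    src <- integer(spec$n_reads)           # index into originals
    src[ord_orig] <- seq_len(n_orig)
    dup_idx <- which(is_dup)
    if (length(dup_idx) > 0) src[dup_idx] <- sample.int(n_orig, length(dup_idx), replace = TRUE)
    chrom_all <- chrom[src]; pos_all <- pos[src]; strand_all <- strand[src]

    # trimmed-footprint sequences (reverse-complemented on the minus strand)
    seq69 <- character(spec$n_reads)
    for (ch in unique(chrom_all)) {
      idx <- which(chrom_all == ch)
      v <- Biostrings::Views(genome[[ch]], start = pos_all[idx] + 1L,
                             end = pos_all[idx] + rl)
      s <- as.character(Biostrings::DNAStringSet(v))
      neg <- strand_all[idx] == "-"
      if (any(neg)) {
        s[neg] <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s[neg])))
      }
      seq69[idx] <- s
    }
    if (spec$error_rate > 0) {
      seq69 <- inject_errors(seq69, spec$error_rate)
    }
    qname <- sprintf("read%07d", seq_len(spec$n_reads))
    list(
      reads = data.frame(qname = qname,
                         seq = paste0(spec$adapter_prefix, seq69),
                         stringsAsFactors = FALSE),
      alignments = data.frame(qname = qname, chrom = chrom_all,
                              start = as.integer(pos_all), strand = strand_all,
                              is_duplicate = is_dup, stringsAsFactors = FALSE),
      n_duplicates = sum(is_dup))
  })
}

inject_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (length(hit) == 0) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Build a heterozygous SNP panel over a simulated genome
#'
#' Sites are placed on a regular grid with small jitter; the reference base
#' is read from the genome, the alternate base drawn from the remaining
#' three, and the parental phase (`b_is_alt`) assigned at random so that on
#' average half the sites carry the alternate allele on parental copy B.
#'
#' @param genome genome list or [Biostrings::DNAStringSet].
#' @param spacing mean distance between sites (bp).
#' @param seed integer seed.
#' @return data.frame `chrom`, `pos` (1-based), `ref`, `alt`, `b_is_alt`.
#' @export
make_snp_panel <- function(genome, spacing = 2000, seed = 1L) {
  genome <- genome_of(genome)
  with_seed(seed, {
    out <- lapply(names(genome), function(ch) {
      L <- Biostrings::width(genome[names(genome) == ch])
      grid <- seq(spacing, L - spacing, by = spacing)
      pos0 <- pmin(L - 1, pmax(0, grid + sample(-500:500, length(grid), replace = TRUE)))
      pos0 <- sort(unique(pos0))
      ref <- strsplit(as.character(Biostrings::DNAStringSet(
        Biostrings::Views(genome[[ch]], start = pos0 + 1L, width = 1L))), "")
      ref <- vapply(ref, `[[`, "", 1L)
      ok <- ref %in% c("A", "C", "G", "T")
      pos0 <- pos0[ok]; ref <- ref[ok]
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    character(1), USE.NAMES = FALSE)
      data.frame(chrom = ch, pos = pos0 + 1L, ref = ref, alt = alt,
                 b_is_alt = runif(length(pos0)) < 0.5, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate digital SNP allele counts for one cell
#'
#' Site depth is Poisson with mean `mean_depth * cn_total / 2` (optionally
#' Gamma-overdispersed to mimic WGA); the alternate-read count is Binomial
#' with success probability equal to the copy fraction of the parental
#' allele carrying the alternate base. Sites in CN-0 regions get depth 0.
#'
#' @param genome genome list or [Biostrings::DNAStringSet] (unused except for
#'   validation that sites fall inside chromosomes).
#' @param truth a `tumor_truth`; @param clone_id clone sampled.
#' @param panel SNP panel from [make_snp_panel()] (or [read_snp_vcf()]).
#' @param mean_depth expected depth at a diploid site.
#' @param overdispersion variance of a mean-1 Gamma depth multiplier (0 = pure
#'   Poisson).
#' @param error_rate probability a read reports the wrong allele.
#' @param seed integer seed.
#' @return data.frame `chrom`, `pos` (1-based), `ref_count`, `alt_count`.
#' @export
simulate_snp_counts <- function(genome, truth, clone_id, panel,
                                mean_depth = 12, overdispersion = 0,
                                error_rate = 0, seed = 1L) {
  genome <- genome_of(genome)
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  if (nrow(panel) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref_count = integer(), alt_count = integer(),
                      stringsAsFactors = FALSE))
  }
  if (any(panel$pos < 1 | panel$pos > chrom_len[panel$chrom])) {
    stop("panel sites outside genome")
  }
  cn <- clone_cn_at(truth, clone_id, panel$chrom, panel$pos - 1L)
  with_seed(seed, {
    lambda <- mean_depth * cn$cn_total / 2
    if (overdispersion > 0) lambda <- lambda * amp_multiplier(nrow(panel), overdispersion)
    depth <- rpois(nrow(panel), lambda)
    depth[cn$cn_total == 0] <- 0L
    alt_cn <- ifelse(panel$b_is_alt, cn$cnB, cn$cnA)
    p_alt <- ifelse(cn$cn_total > 0, alt_cn / cn$cn_total, 0)
    p_alt <- p_alt * (1 - error_rate) + (1 - p_alt) * error_rate
    alt <- rbinom(nrow(panel), depth, p_alt)
    data.frame(chrom = panel$chrom, pos = panel$pos,
               ref_count = as.integer(depth - alt), alt_count = as.integer(alt),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a bulk primary-tumor probe track
#'
#' Probes on a regular grid report logR = log2(bulk total CN / 2) plus
#' Gaussian noise, and BAF plus noise (clipped to [0,1]). Bulk CN is the
#' clone-fraction-weighted mixture from [bulk_cn_segments()]. Each probe
#' carries a germline genotype: homozygous probes have true BAF 0 or 1;
#' heterozygous probes report the bulk B-allele copy fraction. Per-probe GC
#' is measured on a window around the probe for downstream GC correction.
#'
#' @param genome genome list or [Biostrings::DNAStringSet].
#' @param truth a `tumor_truth`.
#' @param probe_spacing distance between probes (bp), > 0.
#' @param noise_sd Gaussian noise SD applied to both logR and BAF.
#' @param het_fraction fraction of probes heterozygous in the germline.
#' @param gc_window window width for per-probe GC (bp).
#' @param seed integer seed.
#' @return data.frame `chrom`, `pos` (1-based), `logr`, `baf`, `gc`.
#' @export
simulate_primary_track <- function(genome, truth, probe_spacing = 5000,
                                   noise_sd = 0.1, het_fraction = 0.33,
                                   gc_window = 1000, seed = 1L) {
  stopifnot(probe_spacing > 0)
  genome <- genome_of(genome)
  bulk <- bulk_cn_segments(truth)
  out <- lapply(names(genome), function(ch) {
    L <- Biostrings::width(genome[names(genome) == ch])
    pos0 <- seq(0, L - 1, by = probe_spacing)
    s <- bulk[bulk$chrom == ch, ]
    j <- findInterval(pos0, s$start)
    tot <- s$cn_total[j]; bb <- s$cnB[j]
    ws <- pmax(0, pos0 - gc_window %/% 2)
    we <- pmin(L, pos0 + gc_window %/% 2 + 1)
    data.frame(chrom = ch, pos = pos0 + 1L,
               logr_true = ifelse(tot > 0, log2(tot / 2), -8),
               baf_true = ifelse(tot > 0, bb / tot, NA_real_),
               gc = gc_fraction(genome, ch, ws, we),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  with_seed(seed, {
    u <- runif(nrow(out))
    geno <- ifelse(u < het_fraction, "AB",
                   ifelse(u < het_fraction + (1 - het_fraction) / 2, "AA", "BB"))
    out$baf_true <- ifelse(geno == "AA", 0, ifelse(geno == "BB", 1, out$baf_true))
    out$logr <- out$logr_true + rnorm(nrow(out), 0, noise_sd)
    out$baf <- pmin(1, pmax(0, out$baf_true + rnorm(nrow(out), 0, noise_sd)))
    out[, c("chrom", "pos", "logr", "baf", "gc", "logr_true", "baf_true")]
  })
}
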