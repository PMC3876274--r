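#' Simulate the reference single-cell validation study
#'
#' A self-contained benchmark cell used to validate integer-copy-number
#' recovery end to end: a 10 Mb two-chromosome genome (oscillating GC
#' landscape), one pure tumor clone carrying an arm-level one-copy gain
#' (CN 3), a focal one-copy deletion (CN 1) and a copy-neutral LOH region,
#' with a large untouched CN-2 reference region for ploidy anchoring; WGA
#' reads with amplicon noise, GC bias and PCR duplicates at roughly 15
#' deduplicated reads per 4000-unique-position bin; and a heterozygous SNP
#' panel with digital allele counts.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param chrom_length per-chromosome length (bp).
#' @param n_reads raw reads to simulate.
#' @param bin_unique unique positions per variable bin.
#' @param snp_spacing SNP panel spacing (bp).
#' @return list with `genome`, `truth`, `cell` (reads + true alignments),
#'   `panel`, `snp_counts`, `bin_unique`, `ref_region`, and the planted
#'   event coordinates (`arm_gain`, `focal_del`, `cnloh`).
#' @export
simulate_reference_cell_study <- function(seed = 1L, chrom_length = 5000000L,
                                          n_reads = 40000L, bin_unique = 4000L,
                                          snp_spacing = 2000) {
  L <- as.integer(chrom_length)
  gspec <- sim_genome_spec(n_chroms = 2, chrom_length = L,
                           gc_landscape = wavy_gc_landscape(L, period = 250000),
                           seed = stage_seed(seed, "genome"))
  gen <- simulate_genome(gspec)
  arm_gain <- list(chrom = "chr1", start = as.integer(L * 0.5), end = L)
  focal_del <- list(chrom = "chr2", start = as.integer(L * 0.2), end = as.integer(L * 0.3))
  cnloh <- list(chrom = "chr2", start = as.integer(L * 0.6), end = as.integer(L * 0.8))
  events <- data.frame(
    chrom = c(arm_gain$chrom, focal_del$chrom, cnloh$chrom),
    start = c(arm_gain$start, focal_del$start, cnloh$start),
    end = c(arm_gain$end, focal_del$end, cnloh$end),
    allele = c("A", "B", "B"),
    change = c(1L, -1L, 0L),
    kind = c("arm", "focal", "cnLOH"),
    stringsAsFactors = FALSE)
  truth <- simulate_tumor_truth(gen, list(list(id = "cell", fraction = 1, events = events)),
                                seed = stage_seed(seed, "truth"))
  rspec <- read_sim_spec(n_reads = n_reads, duplicate_rate = 0.05,
                         amplification_dispersion = 0.25, gc_bias_coeff = 0.6,
                         seed = stage_seed(seed, "reads"))
  cell <- simulate_cell_reads(gen, truth, "cell", rspec)
  panel <- make_snp_panel(gen, spacing = snp_spacing, seed = stage_seed(seed, "panel"))
  snp_counts <- simulate_snp_counts(gen, truth, "cell", panel, mean_depth = 12,
                                    seed = stage_seed(seed, "snp"))
  list(genome = gen, truth = truth, cell = cell, panel = panel,
       snp_counts = snp_counts, bin_unique = as.integer(bin_unique),
       read_spec = rspec,
       ref_region = list(chrom = "chr1", start = 0L, end = as.integer(L * 0.5)),
       arm_gain = arm_gain, focal_del = focal_del, cnloh = cnloh)
}

#' Run the copy-number recovery benchmark
#'
#' Executes the complete analysis on [simulate_reference_cell_study()] —
#' adapter trim, exact mapping, duplicate removal, mappability binning,
#' logR with GC correction, PCF at gamma 25, ploidy from the reference
#' region, integer CN, BAF and allelic states — and measures recovery
#' against the simulator's truth.
#'
#' @param seed integer seed passed to the study simulation.
#' @param study optionally a pre-built study list (to reuse across checks).
#' @return list with `cn_accuracy_bp` (bp-weighted fraction of the binned
#'   genome assigned the true integer CN), `cnloh_called_fraction`
#'   (fraction of the planted cnLOH region's extent labeled LOH or cnLOH),
#'   `psi`, `mean_reads_per_bin`, `coverage`, `n_bins`, plus the `profile`
#'   and `states` tables.
#' @export
cn_recovery_benchmark <- function(seed = 1L, study = NULL) {
  if (is.null(study)) study <- simulate_reference_cell_study(seed)
  gen <- study$genome
  trimmed <- trim_reads(study$cell$reads, n = nchar(study$read_spec$adapter_prefix))
  aln <- map_reads_exact(trimmed, gen)
  dedup <- dedup_alignments(aln)
  mask <- compute_unique_positions(gen, read_length = study$read_spec$read_length)
  bins <- build_variable_bins(mask, gen, target_unique = study$bin_unique)
  profile <- single_cell_cn_profile(dedup, bins, study$ref_region, ref_cn = 2,
                                    gamma = 25, kmin = 5)
  chrom_lengths <- setNames(Biostrings::width(gen$genome), names(gen$genome))
  cov <- coverage_stats(dedup, sum(chrom_lengths), study$read_spec$read_length)

  # bp-weighted accuracy of integer CN over the segmented extent
  segs <- profile$segments
  truth_segs <- clone_cn_segments(study$truth, "cell")
  acc_num <- 0; acc_den <- 0
  for (i in seq_len(nrow(segs))) {
    ts <- truth_segs[truth_segs$chrom == segs$chrom[i], ]
    lo <- pmax(segs$start[i], ts$start); hi <- pmin(segs$end[i], ts$end)
    w <- pmax(0, hi - lo)
    acc_den <- acc_den + sum(w)
    acc_num <- acc_num + sum(w[ts$cn_total == segs$cn_integer[i]])
  }

  baf <- compute_baf(study$snp_counts, min_depth = 8)
  states <- classify_allelic_state(baf, segs)
  reg <- study$cnloh
  st <- states[states$chrom == reg$chrom, ]
  lo <- pmax(reg$start, st$start); hi <- pmin(reg$end, st$end)
  w <- pmax(0, hi - lo)
  cnloh_frac <- if (sum(w) > 0) sum(w[st$state %in% c("LOH", "cnLOH")]) / sum(w) else 0

  list(cn_accuracy_bp = acc_num / acc_den,
       cnloh_called_fraction = cnloh_frac,
       psi = profile$ploidy$psi,
       mean_reads_per_bin = nrow(dedup) / nrow(bins),
       coverage = cov,
       n_bins = nrow(bins),
       profile = profile, states = states, bins = bins, dedup = dedup)
}

#' Concordance calibration on constructed primary/DTC pairs
#'
#' For each requested private-genome fraction `f`, simulates `reps`
#' primary/DTC status-track pairs on a windowed genome: the primary carries
#' random gain/loss events; the DTC copies the primary except on a
#' constructed fraction `f` of windows where its status is forced to
#' differ. On noise-free truth the measured bp-weighted concordance should
#' equal `1 - f`.
#'
#' @param fractions numeric vector of private-genome fractions.
#' @param reps replicates per fraction.
#' @param n_windows windows per genome.
#' @param window_bp window width (bp).
#' @param seed integer seed.
#' @return data.frame with `fraction`, `mean_concordance`, `max_abs_error`.
#' @export
concordance_calibration <- function(fractions = c(0.01, 0.1, 0.25), reps = 50L,
                                    n_windows = 1000L, window_bp = 10000L,
                                    seed = 1L) {
  with_seed(seed, {
    rows <- lapply(fractions, function(f) {
      meas <- vapply(seq_len(reps), function(r) {
        status <- rep("neutral", n_windows)
        # a few random primary events
        for (k in seq_len(3)) {
          w <- sort(sample.int(n_windows, 2))
          status[w[1]:w[2]] <- sample(c("gain", "loss"), 1)
        }
        starts <- (seq_len(n_windows) - 1) * window_bp
        prim <- data.frame(chrom = "chr1", start = starts,
                           end = starts + window_bp, status = status,
                           stringsAsFactors = FALSE)
        dtc <- prim
        n_priv <- round(f * n_windows)
        priv <- sample.int(n_windows, n_priv)
        flip <- function(s) c(gain = "loss", loss = "neutral", neutral = "gain")[s]
        dtc$status[priv] <- unname(flip(prim$status[priv]))
        concordance(dtc, prim)$concordance
      }, numeric(1))
      data.frame(fraction = f, mean_concordance = mean(meas),
                 max_abs_error = max(abs(meas - (1 - f))))
    })
    do.call(rbind, rows)
  })
}
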