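#' Default pipeline configuration
#'
#' All tunables with their defaults: adapter trim 32 bp leaving 69-bp reads,
#' pseudocount 1, GC filter at 0.28, PCF gamma 25 / kmin 5 for sequencing
#' bins, gamma 60 / kmin 25 and floor -2 for aCGH probes, BAF minimum depth
#' 8 reads. Simulation-scale knobs (genome size, bin target, read counts)
#' default to a desk-scale demo patient.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    # simulation scale
    n_chroms = 2L, chrom_length = 2000000L,
    bin_unique = 2000L,
    n_reads = 30000L, duplicate_rate = 0.05,
    amplicon_length_mean = 10000, amplicon_length_sd = 2000,
    amplification_dispersion = 0.25, gc_bias_coeff = 0.6,
    snp_spacing = 2000, snp_mean_depth = 12,
    probe_spacing = 1000, probe_noise_sd = 0.15,
    normal_fraction = 0.2, subclone_fraction = 0.3,
    # analysis parameters
    trim = 32L, read_length = 69L,
    pseudocount = 1, gc_min = 0.28,
    gamma_seq = 25, kmin_seq = 5L,
    gamma_acgh = 60, kmin_acgh = 25L, floor_acgh = -2,
    min_depth = 8L,
    baf_low = 0.15, baf_high = 0.85,
    loh_site_fraction = 0.9, min_sites = 10L,
    span = 0.3, degree = 2,
    ref_cn = 2L
  )
}

config_checks <- list(
  seed = function(v) is.numeric(v) && v == round(v),
  trim = function(v) is.numeric(v) && v >= 0,
  read_length = function(v) is.numeric(v) && v >= 1,
  pseudocount = function(v) is.numeric(v) && v >= 0,
  gc_min = function(v) is.numeric(v) && v >= 0 && v <= 1,
  gamma_seq = function(v) is.numeric(v) && v >= 0,
  gamma_acgh = function(v) is.numeric(v) && v >= 0,
  kmin_seq = function(v) is.numeric(v) && v >= 1,
  kmin_acgh = function(v) is.numeric(v) && v >= 1,
  min_depth = function(v) is.numeric(v) && v >= 1,
  duplicate_rate = function(v) is.numeric(v) && v >= 0 && v <= 1,
  normal_fraction = function(v) is.numeric(v) && v >= 0 && v < 1,
  subclone_fraction = function(v) is.numeric(v) && v >= 0 && v < 1,
  baf_low = function(v) is.numeric(v) && v >= 0 && v <= 0.5,
  baf_high = function(v) is.numeric(v) && v >= 0.5 && v <= 1,
  loh_site_fraction = function(v) is.numeric(v) && v > 0 && v <= 1
)

#' Validate and resolve a pipeline configuration
#'
#' Accepts a named list or a path to a JSON file; fills in defaults,
#' rejects unknown keys, and aggregates all range/type errors rather than
#' stopping at the first.
#'
#' @param config named list or JSON file path (an empty object means all
#'   defaults).
#' @return the resolved configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (length(config) > 0 && is.null(names(config))) stop("config must be a named list")
  defaults <- default_config()
  errors <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    errors <- c(errors, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  resolved <- defaults
  for (k in intersect(names(config), names(defaults))) resolved[[k]] <- config[[k]]
  for (k in names(config_checks)) {
    if (!config_checks[[k]](resolved[[k]])) {
      errors <- c(errors, paste0("invalid value for '", k, "': ", resolved[[k]]))
    }
  }
  if (resolved$read_length < 1) errors <- c(errors, "read_length must be >= 1")
  if (length(errors) > 0) {
    stop("configuration errors:\n  - ", paste(errors, collapse = "\n  - "))
  }
  resolved
}

#' Oscillating GC landscape for simulated genomes
#'
#' Real GC content varies on the isochore scale (hundreds of kb), much
#' shorter than chromosome arms, so GC is essentially uncorrelated with
#' arm-level copy-number events. Control points alternate between `gc_lo`
#' and `gc_hi` every `period` bp.
#'
#' @param chrom_length chromosome length (bp).
#' @param period distance between control points.
#' @param gc_lo,gc_hi alternating GC levels.
#' @return data.frame with `pos`, `gc` for [sim_genome_spec()].
#' @export
wavy_gc_landscape <- function(chrom_length, period = max(50000, chrom_length / 16),
                              gc_lo = 0.36, gc_hi = 0.54) {
  pos <- seq(0, chrom_length, by = period)
  data.frame(pos = pos, gc = rep_len(c(gc_lo, gc_hi), length(pos)))
}

#' Build the demo patient's tumor event plan
#'
#' Two tumor clones mirroring the analysis scenario: a founding clone
#' (arm-level gain, a focal deletion, a chromothripsis-like shattered
#' region) and a descendant subclone that additionally carries a
#' copy-neutral LOH where the founder had a subclonal deletion, a gain, and
#' a whole-chromosome-analog trisomy private to the disseminated cell. The
#' DTC is a pure cell of the subclone.
#'
#' @param chrom_length chromosome length used by the demo genome.
#' @param subclone_fraction fraction of the bulk occupied by the subclone.
#' @param normal_fraction admixed normal fraction.
#' @return event-plan list for [simulate_tumor_truth()].
#' @export
demo_event_plan <- function(chrom_length = 2000000L, subclone_fraction = 0.3,
                            normal_fraction = 0.2) {
  L <- chrom_length
  founder_events <- data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = as.integer(c(L * 0.55, L * 0.10, L * 0.60)),
    end = as.integer(c(L, L * 0.18, L * 0.80)),
    allele = c("A", "B", "A"),
    change = c(1L, -1L, 0L),
    kind = c("arm", "focal", "shatter"),
    stringsAsFactors = FALSE)
  subclone_events <- rbind(founder_events, data.frame(
    chrom = c("chr2", "chr1"),
    start = as.integer(c(L * 0.05, L * 0.30)),
    end = as.integer(c(L * 0.25, L * 0.42)),
    allele = c("B", "A"),
    change = c(0L, 2L),          # focal two-copy amplification in the DTC
    kind = c("cnLOH", "focal"),
    stringsAsFactors = FALSE))
  main_fraction <- 1 - normal_fraction - subclone_fraction
  list(
    list(id = "founder", fraction = main_fraction, events = founder_events),
    list(id = "subclone", fraction = subclone_fraction, events = subclone_events)
  )
}

#' Run the full demo pipeline
#'
#' Chains every stage on a self-simulated patient: genome + tumor truth ->
#' WGA single-cell reads -> adapter profiling, trimming, exact mapping,
#' dedup, coverage -> variable bins -> logR -> GC correction -> PCF ->
#' integer CN -> SNP BAF + allelic states -> bulk primary probe track
#' (sequencing- and aCGH-mode) -> concordance and event classification.
#' All artifacts are written under `outdir` (standard text formats) along
#' with the resolved configuration and a checksum manifest; reruns with the
#' same config and seed are byte-identical.
#'
#' @param config list or JSON path, see [validate_config()].
#' @param outdir output directory (created).
#' @return (invisibly) a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("scellcn_run_")) {
  cfg <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(outdir, f)
  jsonlite::write_json(cfg, pth("config.json"), auto_unbox = TRUE, digits = NA)

  # --- simulate ---
  gspec <- sim_genome_spec(
    n_chroms = cfg$n_chroms, chrom_length = cfg$chrom_length,
    gc_landscape = wavy_gc_landscape(cfg$chrom_length),
    seed = stage_seed(cfg$seed, "genome"))
  gen <- simulate_genome(gspec)
  truth <- simulate_tumor_truth(
    gen, demo_event_plan(cfg$chrom_length, cfg$subclone_fraction, cfg$normal_fraction),
    normal_fraction = cfg$normal_fraction, seed = stage_seed(cfg$seed, "truth"))
  rspec <- read_sim_spec(
    read_length_raw = cfg$read_length + cfg$trim,
    adapter_prefix = substr(strrep(DEFAULT_ADAPTER, 3), 1, cfg$trim),
    n_reads = cfg$n_reads, duplicate_rate = cfg$duplicate_rate,
    amplicon_length_mean = cfg$amplicon_length_mean,
    amplicon_length_sd = cfg$amplicon_length_sd,
    amplification_dispersion = cfg$amplification_dispersion,
    gc_bias_coeff = cfg$gc_bias_coeff, seed = stage_seed(cfg$seed, "reads"))
  cell <- simulate_cell_reads(gen, truth, "subclone", rspec)
  panel <- make_snp_panel(gen, spacing = cfg$snp_spacing,
                          seed = stage_seed(cfg$seed, "panel"))
  snp_counts <- simulate_snp_counts(gen, truth, "subclone", panel,
                                    mean_depth = cfg$snp_mean_depth,
                                    seed = stage_seed(cfg$seed, "snp"))
  probes <- simulate_primary_track(gen, truth, probe_spacing = cfg$probe_spacing,
                                   noise_sd = cfg$probe_noise_sd,
                                   seed = stage_seed(cfg$seed, "probes"))
  chrom_lengths <- setNames(Biostrings::width(gen$genome), names(gen$genome))
  write_genome_fasta(gen$genome, pth("genome.fa"))
  write_truth_bed(truth, pth("truth_events.tsv"))
  write_reads_fastq(cell$reads, pth("cell_raw.fastq"))
  true_bed <- data.frame(chrom = cell$alignments$chrom,
                         start = cell$alignments$start,
                         end = cell$alignments$start + cfg$read_length,
                         name = cell$alignments$qname,
                         score = 0L, strand = cell$alignments$strand,
                         stringsAsFactors = FALSE)
  write_bed(true_bed, pth("cell_true_alignments.bed"))
  write_snp_vcf(panel, chrom_lengths, pth("snp_panel.vcf"))
  write_tsv(snp_counts, pth("snp_counts.tsv"))
  write_tsv(probes, pth("primary_probes.tsv"))

  # --- preprocess ---
  adapter <- profile_adapter(cell$reads)
  trimmed <- trim_reads(cell$reads, n = cfg$trim)
  aln <- map_reads_exact(trimmed, gen)
  dedup <- dedup_alignments(aln)
  cov <- coverage_stats(dedup, sum(chrom_lengths), cfg$read_length)
  write_alignments_sam(dedup, chrom_lengths, cfg$read_length, pth("cell_dedup.sam"))

  # --- binning + copy number ---
  mask <- compute_unique_positions(gen, read_length = cfg$read_length)
  bins <- build_variable_bins(mask, gen, target_unique = cfg$bin_unique)
  # the demo gain sits on chr1; anchor ploidy on the untouched chr2 tail
  ref_region <- list(chrom = "chr2", start = round(cfg$chrom_length * 0.82),
                     end = cfg$chrom_length)
  profile <- single_cell_cn_profile(
    dedup, bins, ref_region, ref_cn = cfg$ref_cn,
    gamma = cfg$gamma_seq, kmin = cfg$kmin_seq,
    pseudocount = cfg$pseudocount, gc_min = cfg$gc_min,
    span = cfg$span, degree = cfg$degree)
  write_tsv(profile$track[, c("chrom", "start", "end", "raw_count", "gc", "logr")],
            pth("logr_track.tsv"))
  write_tsv(profile$segments, pth("cn_segments.tsv"))

  # --- allele typing ---
  baf <- compute_baf(snp_counts, min_depth = cfg$min_depth)
  states <- classify_allelic_state(baf, profile$segments,
                                   low = cfg$baf_low, high = cfg$baf_high,
                                   loh_site_fraction = cfg$loh_site_fraction,
                                   min_sites = cfg$min_sites)
  write_tsv(baf, pth("baf_sites.tsv"))
  write_tsv(states, pth("allelic_states.tsv"))

  # --- aCGH-mode processing of the probe track ---
  acgh <- process_acgh_track(probes, floor = cfg$floor_acgh,
                             gamma = cfg$gamma_acgh, kmin = cfg$kmin_acgh,
                             gc_correct_flag = TRUE)
  write_tsv(acgh$segments, pth("acgh_segments.tsv"))

  # --- compare against the primary truth ---
  dtc_status <- status_track(profile$segments)
  primary_status <- truth_status_track(truth)
  conc <- concordance(dtc_status, primary_status)
  events <- classify_events(profile$segments, truth)
  write_tsv(dtc_status, pth("dtc_status.tsv"))
  write_tsv(events$dtc_events, pth("event_comparison.tsv"))

  report <- list(
    adapter_suggested_trim = adapter$suggested_trim,
    reads_total = nrow(cell$reads),
    reads_after_trim = nrow(trimmed),
    mapping = attr(aln, "counters"),
    duplicates_removed = attr(dedup, "n_removed"),
    coverage = cov,
    n_bins = nrow(bins),
    bin_width = bin_size_summary(bins),
    ploidy = profile$ploidy$psi,
    concordance = conc$concordance)
  jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE, digits = NA)

  files <- list.files(outdir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[manifest$file != "manifest.json", ]
  jsonlite::write_json(manifest, pth("manifest.json"), digits = NA)

  invisible(list(config = cfg, truth = truth, profile = profile, baf = baf,
                 states = states, acgh = acgh, concordance = conc,
                 events = events, report = report, manifest = manifest,
                 outdir = outdir))
}

#' Status track of the dominant tumor genotype from truth
#'
#' Majority-clone (fraction-weighted, rounded) total copy number per atomic
#' interval, thresholded against diploid. Used as the noise-free primary
#' comparison track in the demo.
#'
#' @param truth a `tumor_truth`.
#' @param baseline neutral total CN.
#' @return status track data.frame.
#' @export
truth_status_track <- function(truth, baseline = 2) {
  bulk <- bulk_cn_segments(truth)
  # renormalise away the normal admixture: status of the tumor component
  tumor_fr <- 1 - truth$normal_fraction
  tumor_cn <- (bulk$cn_total - truth$normal_fraction * 2) / tumor_fr
  data.frame(chrom = bulk$chrom, start = bulk$start, end = bulk$end,
             status = ifelse(round(tumor_cn) > baseline, "gain",
                             ifelse(round(tumor_cn) < baseline, "loss", "neutral")),
             stringsAsFactors = FALSE)
}
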