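#!/usr/bin/env Rscript
# The core copy-number analysis of the demo DTC: bin counts -> pseudocount
# and GC filter -> logR -> Loess GC correction + median normalisation ->
# PCF segmentation (gamma 25) -> ploidy from a reference region -> integer
# copy number. Also processes the bulk primary probe track in aCGH mode
# (floor -2, recentre, gamma 60 / kmin 25) for comparison.

source("analysis/_demo.R")

inp <- demo_inputs()
cfg <- inp$cfg

trimmed <- trim_reads(inp$cell$reads, n = cfg$trim)
dedup <- dedup_alignments(map_reads_exact(trimmed, inp$genome))
mask <- compute_unique_positions(inp$genome, read_length = cfg$read_length)
bins <- build_variable_bins(mask, inp$genome, target_unique = cfg$bin_unique)

ref_region <- list(chrom = "chr2", start = round(cfg$chrom_length * 0.82),
                   end = cfg$chrom_length)
profile <- single_cell_cn_profile(dedup, bins, ref_region, ref_cn = cfg$ref_cn,
                                  gamma = cfg$gamma_seq, kmin = cfg$kmin_seq)

cat(sprintf("Ploidy anchored on %s:%d-%d (assumed CN %d): Psi = %.3f\n",
            ref_region$chrom, ref_region$start, ref_region$end,
            cfg$ref_cn, profile$ploidy$psi))
cat("\nSegments and integer copy-number calls:\n")
print(profile$segments[, c("chrom", "start", "end", "n_bins", "mean",
                           "cn_continuous", "cn_integer")])

write_tsv(profile$track[, c("chrom", "start", "end", "raw_count", "gc", "logr")],
          file.path(results_dir, "dtc_logr_track.tsv"))
write_tsv(profile$segments, file.path(results_dir, "dtc_cn_segments.tsv"))

# aCGH-mode processing of the bulk primary probe track
probes <- simulate_primary_track(inp$genome, inp$truth,
                                 probe_spacing = cfg$probe_spacing,
                                 noise_sd = cfg$probe_noise_sd,
                                 seed = stage_seed(demo_seed, "probes"))
acgh <- process_acgh_track(probes, floor = cfg$floor_acgh,
                           gamma = cfg$gamma_acgh, kmin = cfg$kmin_acgh,
                           gc_correct_flag = TRUE)
cat(sprintf("\naCGH mode: %d probes, post-processing mean %.2e, %d segments\n",
            nrow(acgh$probes), mean(acgh$probes$logr), nrow(acgh$segments)))
print(acgh$segments)
write_tsv(acgh$segments, file.path(results_dir, "primary_acgh_segments.tsv"))
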