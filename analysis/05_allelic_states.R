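#!/usr/bin/env Rscript
# Digital SNP BAF typing of the demo DTC and per-segment allelic-state
# classification: BAF at sites covered by >= 8 reads, mirrored-BAF PCF
# refinement of the dosage segments, then balanced / imbalanced / LOH /
# cnLOH calls. The planted copy-neutral LOH is invisible to read depth and
# only appears here.

source("analysis/_demo.R")

inp <- demo_inputs()
cfg <- inp$cfg

panel <- make_snp_panel(inp$genome, spacing = cfg$snp_spacing,
                        seed = stage_seed(demo_seed, "panel"))
counts <- simulate_snp_counts(inp$genome, inp$truth, "subclone", panel,
                              mean_depth = cfg$snp_mean_depth,
                              seed = stage_seed(demo_seed, "snp"))
baf <- compute_baf(counts, min_depth = cfg$min_depth)
cat(sprintf("SNP panel: %d sites, %d informative (>= %d reads)\n",
            nrow(panel), sum(baf$informative), cfg$min_depth))

# rebuild the copy-number segments (same seeded pipeline as 04_copy_number.R)
trimmed <- trim_reads(inp$cell$reads, n = cfg$trim)
dedup <- dedup_alignments(map_reads_exact(trimmed, inp$genome))
mask <- compute_unique_positions(inp$genome, read_length = cfg$read_length)
bins <- build_variable_bins(mask, inp$genome, target_unique = cfg$bin_unique)
ref_region <- list(chrom = "chr2", start = round(cfg$chrom_length * 0.82),
                   end = cfg$chrom_length)
profile <- single_cell_cn_profile(dedup, bins, ref_region, ref_cn = cfg$ref_cn,
                                  gamma = cfg$gamma_seq, kmin = cfg$kmin_seq)

states <- classify_allelic_state(baf, profile$segments,
                                 low = cfg$baf_low, high = cfg$baf_high,
                                 loh_site_fraction = cfg$loh_site_fraction,
                                 min_sites = cfg$min_sites)
cat("\nAllelic states:\n")
print(states)

loh <- states[states$state %in% c("LOH", "cnLOH"), ]
if (nrow(loh) > 0) {
  cat("\nLOH / copy-neutral LOH calls (planted cnLOH: chr2",
      round(cfg$chrom_length * 0.05), "-", round(cfg$chrom_length * 0.25), "):\n")
  print(loh[, c("chrom", "start", "end", "cn_integer", "n_informative", "state")])
}

write_tsv(baf, file.path(results_dir, "dtc_baf_sites.tsv"))
write_tsv(states, file.path(results_dir, "dtc_allelic_states.tsv"))
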