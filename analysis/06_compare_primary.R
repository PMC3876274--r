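#!/usr/bin/env Rscript
# DTC-versus-primary comparison: bp-weighted gain/neutral/loss concordance
# between the cell's profile and the primary tumor's dominant genotype, and
# classification of each event as clonal-shared, subclonal-shared or
# private. The demo subclone's private amplification and cnLOH mark the DTC
# as descending from a minor subclone of the primary.

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

dtc_status <- status_track(profile$segments)
primary_status <- truth_status_track(inp$truth)
conc <- concordance(dtc_status, primary_status)
cat(sprintf("DTC vs primary concordance: %.1f%% of %.1f Mb compared\n",
            100 * conc$concordance, conc$compared_bp / 1e6))
print(conc$per_chromosome)

events <- classify_events(profile$segments, inp$truth)
cat("\nDTC events vs primary clones:\n")
print(events$dtc_events[, c("chrom", "start", "end", "status",
                            "matched_fraction", "label")])
cat("\nPrimary events:\n")
print(events$primary_events[, c("chrom", "start", "end", "status",
                                "fraction", "label")])

write_tsv(conc$per_chromosome, file.path(results_dir, "concordance_by_chromosome.tsv"))
write_tsv(events$dtc_events, file.path(results_dir, "dtc_event_labels.tsv"))
write_tsv(events$primary_events, file.path(results_dir, "primary_event_labels.tsv"))
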