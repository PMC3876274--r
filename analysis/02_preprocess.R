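#!/usr/bin/env Rscript
# Read preprocessing for the demo DTC: detect the recurrent WGA adapter
# prefix, trim it, map the 69-mers exactly, remove PCR duplicates, and
# report breadth/depth of coverage.

source("analysis/_demo.R")

inp <- demo_inputs()

prof <- profile_adapter(inp$cell$reads)
cat("Suggested adapter trim:", prof$suggested_trim, "bases",
    "(reads are", unique(nchar(inp$cell$reads$seq)), "bp raw)\n")

trimmed <- trim_reads(inp$cell$reads, n = prof$suggested_trim)
cat("Trimmed reads:", nrow(trimmed), "x", unique(nchar(trimmed$seq)), "bp;",
    attr(trimmed, "n_dropped"), "dropped as too short\n")

aln <- map_reads_exact(trimmed, inp$genome)
cnt <- attr(aln, "counters")
cat(sprintf("Mapping: %d placed, %d multi-mappers discarded, %d unmapped\n",
            cnt$n_mapped, cnt$n_multi, cnt$n_unmapped))

dedup <- dedup_alignments(aln)
cat("PCR duplicates removed:", attr(dedup, "n_removed"),
    sprintf("(%.1f%% of alignments; %d simulated)\n",
            100 * attr(dedup, "n_removed") / nrow(aln), inp$cell$n_duplicates))

gl <- inp$cfg$n_chroms * inp$cfg$chrom_length
cov <- coverage_stats(dedup, gl, inp$cfg$read_length)
cat(sprintf("Coverage: breadth %.1f%%, depth %.3fx (genome-relative), %.3fx (covered bases)\n",
            100 * cov$breadth, cov$depth_genome, cov$depth_covered))

write_tsv(data.frame(metric = c("suggested_trim", "n_mapped", "n_multi",
                                "n_unmapped", "n_dup_removed", "breadth",
                                "depth_genome", "depth_covered"),
                     value = c(prof$suggested_trim, cnt$n_mapped, cnt$n_multi,
                               cnt$n_unmapped, attr(dedup, "n_removed"),
                               cov$breadth, cov$depth_genome, cov$depth_covered)),
          file.path(results_dir, "preprocess_stats.tsv"))
dir.create("scratch/analysis", recursive = TRUE, showWarnings = FALSE)
chrom_lengths <- setNames(rep(inp$cfg$chrom_length, inp$cfg$n_chroms),
                          names(inp$genome$genome))
write_alignments_sam(dedup, chrom_lengths, inp$cfg$read_length,
                     "scratch/analysis/dtc_dedup.sam")
cat("Wrote", file.path(results_dir, "preprocess_stats.tsv"), "\n")
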