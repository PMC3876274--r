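#!/usr/bin/env Rscript
# Simulate the demo patient: a two-clone breast tumor (founder + descendant
# subclone, 20% normal admixture) and one disseminated tumor cell (DTC)
# drawn as a pure cell of the subclone, sequenced after WGA with adapter
# contamination, amplicon-level amplification noise, GC bias and PCR
# duplicates. Writes the planted truth and input files.

source("analysis/_demo.R")

inp <- demo_inputs()

cat("Genome:", length(inp$genome$genome), "chromosomes x",
    inp$cfg$chrom_length / 1e6, "Mb\n")
for (cl in inp$truth$clones) {
  cat(sprintf("Clone %-9s fraction %.2f, %d events\n",
              cl$id, cl$fraction, nrow(cl$events)))
}
cat("Normal fraction:", inp$truth$normal_fraction, "\n")
cat("DTC reads simulated:", nrow(inp$cell$reads),
    sprintf("(%d marked PCR duplicates)\n", inp$cell$n_duplicates))

dir.create("scratch/analysis", recursive = TRUE, showWarnings = FALSE)
write_genome_fasta(inp$genome$genome, "scratch/analysis/genome.fa")
write_reads_fastq(inp$cell$reads, "scratch/analysis/dtc_raw.fastq")
write_truth_bed(inp$truth, file.path(results_dir, "truth_events.tsv"))

cat("\nPlanted events (written to", file.path(results_dir, "truth_events.tsv"), "):\n")
print(read_truth_bed(file.path(results_dir, "truth_events.tsv")))
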