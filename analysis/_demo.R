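# Shared demo-patient construction for the numbered analysis scripts.
# Everything is seeded, so each script can rebuild exactly the same inputs
# in a couple of seconds instead of passing binary state around.

library(scellcn)

demo_seed <- 1L

demo_inputs <- function(seed = demo_seed) {
  cfg <- validate_config(list())
  gspec <- sim_genome_spec(
    n_chroms = cfg$n_chroms, chrom_length = cfg$chrom_length,
    gc_landscape = wavy_gc_landscape(cfg$chrom_length),
    seed = stage_seed(seed, "genome"))
  gen <- simulate_genome(gspec)
  truth <- simulate_tumor_truth(
    gen, demo_event_plan(cfg$chrom_length, cfg$subclone_fraction, cfg$normal_fraction),
    normal_fraction = cfg$normal_fraction, seed = stage_seed(seed, "truth"))
  rspec <- read_sim_spec(
    n_reads = cfg$n_reads, duplicate_rate = cfg$duplicate_rate,
    amplicon_length_mean = cfg$amplicon_length_mean,
    amplicon_length_sd = cfg$amplicon_length_sd,
    amplification_dispersion = cfg$amplification_dispersion,
    gc_bias_coeff = cfg$gc_bias_coeff, seed = stage_seed(seed, "reads"))
  cell <- simulate_cell_reads(gen, truth, "subclone", rspec)
  list(cfg = cfg, genome = gen, truth = truth, read_spec = rspec, cell = cell)
}

results_dir <- "results/analysis"
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)
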