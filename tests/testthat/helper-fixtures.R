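# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# the reference single-cell validation study and its full analysis
bench_fixture <- function() {
  memo("bench", function() {
    study <- simulate_reference_cell_study(seed = 1)
    res <- cn_recovery_benchmark(seed = 1, study = study)
    list(study = study, res = res)
  })
}

# small genome with a planted duplication (multi-mapping regions)
dup_genome <- function(len = 30000, dup_from = 5000, dup_to = 12000,
                       dup_len = 5000, seed = 7) {
  spec <- sim_genome_spec(
    n_chroms = 2, chrom_length = len,
    duplications = list(list(chrom = "chr1", start = dup_from,
                             end = dup_from + dup_len,
                             target_chrom = "chr2", target_start = dup_to)),
    seed = seed)
  simulate_genome(spec)
}

# random series for PCF sweeps
random_series <- function(n, seed) {
  with_seed_test(seed, round(rnorm(n, sd = 2) + rep(c(0, 3), each = ceiling(n / 2))[1:n], 3))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
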