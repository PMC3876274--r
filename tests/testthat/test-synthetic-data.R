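test_that("genome simulation honors GC landscape, determinism, and duplications", {
  spec <- sim_genome_spec(n_chroms = 1, chrom_length = 100000,
                          gc_landscape = data.frame(pos = 0, gc = 0.5), seed = 11)
  g1 <- simulate_genome(spec)
  gc <- gc_fraction(g1, "chr1", 0, 100000)
  expect_gte(gc, 0.45); expect_lte(gc, 0.55)
  # realized GC tracks the control curve in 10 kb windows
  win <- seq(0, 90000, by = 10000)
  gcw <- gc_fraction(g1, "chr1", win, win + 10000)
  expect_true(all(abs(gcw - 0.5) < 0.05))

  g2 <- simulate_genome(spec)
  expect_identical(as.character(g1$genome), as.character(g2$genome))

  g3 <- dup_genome()
  b1 <- substr(as.character(g3$genome[["chr1"]]), 5001, 10000)
  b2 <- substr(as.character(g3$genome[["chr2"]]), 12001, 17000)
  expect_identical(b1, b2)

  expect_error(sim_genome_spec(chrom_length = 10000, duplications = list(
    list(chrom = "chr1", start = 1000, end = 3000,
         target_chrom = "chr1", target_start = 2000))), "overlaps")
})

test_that("tumor truth applies events correctly and rejects impossible plans", {
  g <- simulate_genome(sim_genome_spec(n_chroms = 2, chrom_length = 50000, seed = 2))
  ev <- data.frame(chrom = c("chr1", "chr2"),
                   start = c(10000L, 5000L), end = c(30000L, 20000L),
                   allele = c("A", "B"), change = c(1L, 0L),
                   kind = c("arm", "cnLOH"), stringsAsFactors = FALSE)
  truth <- simulate_tumor_truth(g, list(list(id = "c1", fraction = 1, events = ev)))
  segs <- clone_cn_segments(truth, "c1")
  inside <- segs$chrom == "chr1" & segs$start >= 10000 & segs$end <= 30000
  expect_true(all(segs$cn_total[inside] == 3))
  expect_true(all(segs$cn_total[segs$chrom == "chr1" & !inside] == 2))
  loh <- segs$chrom == "chr2" & segs$start >= 5000 & segs$end <= 20000
  expect_true(all(segs$cn_total[loh] == 2))
  expect_true(all(segs$cnB[loh] == 0))

  # subclonal mixture arithmetic: 0.6 * 2 + 0.4 * 1 = 1.6
  ev2 <- data.frame(chrom = "chr1", start = 10000L, end = 20000L,
                    allele = "B", change = -1L, kind = "focal",
                    stringsAsFactors = FALSE)
  truth2 <- simulate_tumor_truth(g, list(
    list(id = "major", fraction = 0.6, events = ev2[0, ]),
    list(id = "minor", fraction = 0.4, events = ev2)))
  bulk <- bulk_cn_segments(truth2)
  at <- bulk$chrom == "chr1" & bulk$start >= 10000 & bulk$end <= 20000
  expect_equal(unique(bulk$cn_total[at]), 1.6)

  bad <- data.frame(chrom = "chr1", start = 0L, end = 50000L,
                    allele = "B", change = -2L, kind = "arm",
                    stringsAsFactors = FALSE)
  expect_error(simulate_tumor_truth(g, list(list(id = "x", fraction = 1, events = bad))),
               "below 0")
})

test_that("read simulator: conservation, adapter prefix, dosage and duplicates", {
  g <- simulate_genome(sim_genome_spec(n_chroms = 1, chrom_length = 200000, seed = 3))
  ev <- data.frame(chrom = "chr1", start = 100000L, end = 200000L,
                   allele = "both", change = 1L, kind = "arm",
                   stringsAsFactors = FALSE)
  truth <- simulate_tumor_truth(g, list(list(id = "c", fraction = 1, events = ev)))
  spec <- read_sim_spec(n_reads = 20000, amplification_dispersion = 0,
                        gc_bias_coeff = 0, duplicate_rate = 0.2,
                        amplicon_length_mean = 2000, seed = 5)
  out <- simulate_cell_reads(g, truth, "c", spec)

  expect_equal(nrow(out$reads), 20000)
  expect_equal(nrow(out$alignments), nrow(out$reads))
  expect_true(all(startsWith(out$reads$seq, spec$adapter_prefix)))
  expect_true(all(nchar(out$reads$seq) == 101))

  # CN-4 region attracts ~2x the reads of the CN-2 region
  hi <- sum(out$alignments$start >= 100000)
  lo <- sum(out$alignments$start < 100000)
  expect_gt(hi / lo, 1.8); expect_lt(hi / lo, 2.2)

  # dedup removes ~ the duplicate fraction
  dd <- dedup_alignments(out$alignments)
  removed <- 1 - nrow(dd) / nrow(out$alignments)
  expect_gt(removed, 0.17); expect_lt(removed, 0.23)

  # determinism
  out2 <- simulate_cell_reads(g, truth, "c", spec)
  expect_identical(out$reads, out2$reads)

  # empty request is not an error
  empty <- simulate_cell_reads(g, truth, "c", read_sim_spec(n_reads = 0))
  expect_equal(nrow(empty$reads), 0)
})

test_that("bin counts are Poisson-like when amplification noise is off", {
  g <- simulate_genome(sim_genome_spec(n_chroms = 1, chrom_length = 500000, seed = 4))
  truth <- simulate_tumor_truth(g, list(list(id = "c", fraction = 1, events = NULL)))
  spec <- read_sim_spec(n_reads = 25000, amplification_dispersion = 0,
                        gc_bias_coeff = 0, duplicate_rate = 0, seed = 6)
  out <- simulate_cell_reads(g, truth, "c", spec)
  brk <- seq(0, 500000, by = 1000)
  counts <- tabulate(findInterval(out$alignments$start, brk), nbins = length(brk) - 1)
  # footprint-end effects shrink the last bin; drop it
  counts <- counts[-length(counts)]
  ratio <- var(counts) / mean(counts)
  expect_gt(ratio, 0.8); expect_lt(ratio, 1.3)
})

test_that("SNP counts reflect allelic copy number", {
  g <- simulate_genome(sim_genome_spec(n_chroms = 1, chrom_length = 1100000, seed = 8))
  ev <- data.frame(chrom = "chr1", start = 500000L, end = 1000000L,
                   allele = "B", change = 0L, kind = "cnLOH",
                   stringsAsFactors = FALSE)
  truth <- simulate_tumor_truth(g, list(list(id = "c", fraction = 1, events = ev)))
  panel <- make_snp_panel(g, spacing = 1000, seed = 9)
  cnt <- simulate_snp_counts(g, truth, "c", panel, mean_depth = 20, seed = 10)
  depth <- cnt$ref_count + cnt$alt_count
  balanced <- panel$pos <= 500000 & depth > 0
  baf <- cnt$alt_count / pmax(depth, 1)
  expect_gt(mean(baf[balanced]), 0.45); expect_lt(mean(baf[balanced]), 0.55)
  loh <- panel$pos > 500000 & panel$pos <= 1000000 & depth > 0
  expect_true(all(baf[loh] %in% c(0, 1)))

  empty <- simulate_snp_counts(g, truth, "c", panel[0, ], seed = 1)
  expect_equal(nrow(empty), 0)
})

test_that("primary probe track matches mixture arithmetic closed forms", {
  g <- simulate_genome(sim_genome_spec(n_chroms = 1, chrom_length = 200000, seed = 12))
  ev_gain <- data.frame(chrom = "chr1", start = 0L, end = 100000L,
                        allele = "A", change = 1L, kind = "arm",
                        stringsAsFactors = FALSE)
  ev_loss <- data.frame(chrom = "chr1", start = 100000L, end = 200000L,
                        allele = "B", change = -1L, kind = "arm",
                        stringsAsFactors = FALSE)
  # clonal CN-3 on the left; 50% subclonal one-copy loss on the right
  truth <- simulate_tumor_truth(g, list(
    list(id = "a", fraction = 0.5, events = rbind(ev_gain, ev_loss)),
    list(id = "b", fraction = 0.5, events = ev_gain)))
  pr <- simulate_primary_track(g, truth, probe_spacing = 5000, noise_sd = 0, seed = 1)
  left <- pr$pos <= 100000
  expect_equal(unique(pr$logr[left]), log2(1.5), tolerance = 1e-12)
  expect_equal(unique(pr$logr[!left]), log2(0.75), tolerance = 1e-12)

  # diploid genome: logr 0, BAF in {0, 1/2, 1}
  truth0 <- simulate_tumor_truth(g, list(list(id = "n", fraction = 1, events = NULL)))
  pr0 <- simulate_primary_track(g, truth0, probe_spacing = 5000, noise_sd = 0, seed = 1)
  expect_true(all(pr0$logr == 0))
  expect_true(all(pr0$baf %in% c(0, 0.5, 1)))
})

test_that("truth events round-trip through the BED-style table", {
  g <- simulate_genome(sim_genome_spec(n_chroms = 2, chrom_length = 50000, seed = 2))
  plan <- demo_event_plan(50000L)
  truth <- simulate_tumor_truth(g, plan, normal_fraction = 0.2, seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_truth_bed(truth, path)
  back <- read_truth_bed(path)
  flat <- do.call(rbind, lapply(truth$clones, function(cl) {
    cbind(cl$events[, c("chrom", "start", "end")], clone = cl$id,
          fraction = cl$fraction, cl$events[, c("allele", "change", "kind")])
  }))
  rownames(flat) <- NULL
  expect_equal(back, flat)
})
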