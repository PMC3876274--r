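make_random_reads <- function(n, len, seed) {
  with_seed_test(seed, vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1)))
}

test_that("adapter profiling finds the shared prefix length", {
  adapter <- DEFAULT_ADAPTER                       # 32 bases
  body <- make_random_reads(300, 69, seed = 21)
  reads <- paste0(adapter, body)
  prof <- profile_adapter(reads)
  expect_equal(prof$suggested_trim, 32L)
  expect_true(all(abs(colSums(prof$freq) - 1) < 1e-12))

  expect_equal(profile_adapter(make_random_reads(300, 60, seed = 22))$suggested_trim, 0L)

  same <- rep(paste0(adapter, adapter), 50)        # identical over max_len
  expect_warning(p3 <- profile_adapter(same, max_len = 50), "whole profiled length")
  expect_equal(p3$suggested_trim, 50L)

  expect_error(profile_adapter(character(0)), "no reads")
})

test_that("trimming removes the prefix and drops too-short reads", {
  reads <- data.frame(qname = c("a", "b", "c"),
                      seq = c(strrep("A", 101), strrep("C", 30), strrep("G", 101)),
                      stringsAsFactors = FALSE)
  tr <- trim_reads(reads, 32)
  expect_equal(nrow(tr), 2)
  expect_true(all(nchar(tr$seq) == 69))
  expect_equal(attr(tr, "n_dropped"), 1L)
  # n = 0 is the identity
  tr0 <- trim_reads(reads, 0)
  expect_equal(tr0$seq, reads$seq)
  expect_equal(attr(tr0, "n_dropped"), 0L)
  # trim is idempotent once applied with n = 0 afterwards
  expect_equal(trim_reads(tr, 0)$seq, tr$seq)
})

test_that("exact mapper places unique reads, discards multi-mappers and mismatches", {
  g <- dup_genome(len = 20000, dup_from = 3000, dup_to = 8000, dup_len = 2000)
  chr1 <- as.character(g$genome[["chr1"]])
  uniq_read <- substr(chr1, 12001, 12069)              # outside the duplication
  dup_read <- substr(chr1, 3501, 3569)                 # inside the duplicated block
  mm_read <- uniq_read
  substr(mm_read, 35, 35) <- setdiff(c("A", "C", "G", "T"),
                                     substr(uniq_read, 35, 35))[1]
  rc_read <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(uniq_read)))
  reads <- data.frame(qname = c("u", "d", "m", "r"),
                      seq = c(uniq_read, dup_read, mm_read, rc_read),
                      stringsAsFactors = FALSE)
  aln <- map_reads_exact(reads, g)
  cnt <- attr(aln, "counters")
  expect_equal(cnt$n_mapped, 2L)     # u and its reverse-complement twin r
  expect_equal(cnt$n_multi, 1L)
  expect_equal(cnt$n_unmapped, 1L)
  u <- aln[aln$qname == "u", ]
  expect_equal(u$chrom, "chr1"); expect_equal(u$start, 12000L)
  expect_equal(u$strand, "+")
  r <- aln[aln$qname == "r", ]
  expect_equal(r$start, 12000L); expect_equal(r$strand, "-")
})

test_that("mapper recovers true positions of simulated error-free reads", {
  study <- list()
  g <- simulate_genome(sim_genome_spec(n_chroms = 1, chrom_length = 100000, seed = 31))
  truth <- simulate_tumor_truth(g, list(list(id = "c", fraction = 1, events = NULL)))
  spec <- read_sim_spec(n_reads = 2000, duplicate_rate = 0, seed = 32,
                        amplicon_length_mean = 5000)
  cell <- simulate_cell_reads(g, truth, "c", spec)
  trimmed <- trim_reads(cell$reads, 32)
  aln <- map_reads_exact(trimmed, g)
  m <- merge(aln, cell$alignments, by = "qname", suffixes = c("", "_true"))
  expect_equal(nrow(m), nrow(aln))
  expect_true(all(m$start == m$start_true))
  expect_true(all(m$strand == m$strand_true))
})

test_that("duplicate removal keeps one alignment per key and is idempotent", {
  aln <- data.frame(
    qname = c("r3", "r1", "r2", "r4", "r5"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(100L, 100L, 100L, 100L, 100L),
    strand = c("+", "+", "+", "-", "+"),
    stringsAsFactors = FALSE)
  dd <- dedup_alignments(aln)
  expect_equal(nrow(dd), 3)                           # (+,100), (-,100), chr2
  expect_true("r1" %in% dd$qname)                     # first by name among dups
  expect_false(any(c("r2", "r3") %in% dd$qname))
  expect_equal(attr(dd, "n_removed"), 2L)
  dd2 <- dedup_alignments(dd)
  expect_equal(dd2[, names(aln)], dd[, names(aln)])
  expect_equal(attr(dd2, "n_removed"), 0L)
})

test_that("coverage statistics and their identity", {
  # single read covering a whole 69 bp genome
  one <- data.frame(qname = "r", chrom = "chr1", start = 0L, strand = "+",
                    stringsAsFactors = FALSE)
  cs <- coverage_stats(one, genome_length = 69, read_length = 69)
  expect_equal(cs$breadth, 1); expect_equal(cs$depth_genome, 1)
  expect_equal(cs$depth_covered, 1)

  # overlapping + disjoint reads: breadth from the interval union
  aln <- data.frame(qname = c("a", "b", "c"), chrom = "chr1",
                    start = c(0L, 50L, 200L), strand = "+",
                    stringsAsFactors = FALSE)
  cs2 <- coverage_stats(aln, genome_length = 1000, read_length = 69)
  expect_equal(cs2$breadth, (119 + 69) / 1000)
  expect_equal(cs2$depth_genome, 3 * 69 / 1000)
  expect_equal(cs2$depth_covered * cs2$breadth, cs2$depth_genome, tolerance = 1e-12)

  expect_warning(z <- coverage_stats(one[0, ], 1000, 69), "no alignments")
  expect_equal(z$depth_covered, 0)
})
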