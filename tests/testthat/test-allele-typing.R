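test_that("BAF is computed only at sites with at least min_depth reads", {
  counts <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                       ref_count = c(4L, 4L, 0L), alt_count = c(4L, 3L, 8L),
                       stringsAsFactors = FALSE)
  baf <- compute_baf(counts, min_depth = 8)
  expect_equal(baf$baf[1], 0.5)          # 4 alt of 8
  expect_true(is.na(baf$baf[2]))         # 7 reads: below the cutoff
  expect_false(baf$informative[2])
  expect_equal(baf$baf[3], 1.0)          # 8 alt of 8
})

baf_sites <- function(n, baf_values, chrom = "chr1", from = 0, to = 1e6, depth = 20L) {
  pos <- as.integer(seq(from + 1000, to - 1000, length.out = n))
  alt <- as.integer(round(baf_values * depth))
  data.frame(chrom = chrom, pos = pos, ref_count = depth - alt, alt_count = alt,
             stringsAsFactors = FALSE)
}

test_that("allelic-state rules: cnLOH requires LOH at copy number 2", {
  segs <- data.frame(chrom = "chr1", start = 0L, end = 1000000L,
                     n_bins = 100, mean = 0, cn_integer = 2L,
                     stringsAsFactors = FALSE)
  extreme <- with_seed_test(1, sample(c(0, 1), 50, replace = TRUE))
  counts <- baf_sites(50, extreme)
  st <- classify_allelic_state(compute_baf(counts), segs, refine = FALSE)
  expect_equal(st$state, "cnLOH")

  segs$cn_integer <- 1L
  st2 <- classify_allelic_state(compute_baf(counts), segs, refine = FALSE)
  expect_equal(st2$state, "LOH")

  # too few informative sites: uncalled
  st3 <- classify_allelic_state(compute_baf(baf_sites(5, rep(1, 5))), segs,
                                refine = FALSE)
  expect_equal(st3$state, "uncalled")
})

test_that("balanced regions stay balanced across replicates", {
  segs <- data.frame(chrom = "chr1", start = 0L, end = 1000000L,
                     n_bins = 100, mean = 0, cn_integer = 2L,
                     stringsAsFactors = FALSE)
  ok <- 0; reps <- 100
  for (r in seq_len(reps)) {
    b <- with_seed_test(900 + r, rbinom(500, 12, 0.5) / 12)
    counts <- baf_sites(500, b, depth = 12L)
    st <- classify_allelic_state(compute_baf(counts), segs, refine = FALSE)
    if (identical(st$state, "balanced")) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.95)
})

test_that("state calls are invariant under ref/alt relabeling", {
  segs <- data.frame(chrom = "chr1",
                     start = c(0L, 500000L), end = c(500000L, 1000000L),
                     n_bins = 50, mean = 0, cn_integer = c(2L, 2L),
                     stringsAsFactors = FALSE)
  b1 <- with_seed_test(41, rbinom(100, 20, 0.5) / 20)
  counts <- rbind(baf_sites(100, b1, from = 0, to = 500000),
                  baf_sites(80, rep(c(0, 1), 40), from = 500000, to = 1000000))
  mirrored <- counts
  mirrored$ref_count <- counts$alt_count
  mirrored$alt_count <- counts$ref_count
  s1 <- classify_allelic_state(compute_baf(counts), segs)
  s2 <- classify_allelic_state(compute_baf(mirrored), segs)
  expect_equal(s1$state, s2$state)
  expect_equal(s1$state[s1$start >= 500000], rep("cnLOH", sum(s1$start >= 500000)))
})

test_that("planted cnLOH inside a long CN-2 segment is found via BAF refinement", {
  # one dosage segment; allelic change only in the middle third
  segs <- data.frame(chrom = "chr1", start = 0L, end = 1500000L,
                     n_bins = 150, mean = 0, cn_integer = 2L,
                     stringsAsFactors = FALSE)
  mid_baf <- rep(c(0, 1), 50)
  flank1 <- with_seed_test(51, rbinom(100, 20, 0.5) / 20)
  flank2 <- with_seed_test(52, rbinom(100, 20, 0.5) / 20)
  counts <- rbind(baf_sites(100, flank1, from = 0, to = 500000),
                  baf_sites(100, mid_baf, from = 500000, to = 1000000),
                  baf_sites(100, flank2, from = 1000000, to = 1500000))
  st <- classify_allelic_state(compute_baf(counts), segs)
  called <- st[st$state %in% c("LOH", "cnLOH"), ]
  expect_equal(nrow(called), 1)
  expect_equal(called$state, "cnLOH")
  # recovered extent overlaps the planted middle third almost entirely
  ov <- max(0, min(called$end, 1000000) - max(called$start, 500000))
  expect_gt(ov / 500000, 0.9)
  expect_lt((called$end - called$start - ov) / 500000, 0.1)
})
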