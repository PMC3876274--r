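toy_bins <- function(n = 3, width = 1000, gc = 0.45, chrom = "chr1") {
  data.frame(chrom = chrom, start = (seq_len(n) - 1) * width,
             end = seq_len(n) * width, unique_count = width,
             gc = rep_len(gc, n), stringsAsFactors = FALSE)
}

test_that("reads are assigned to the bin containing their 5' start", {
  bins <- toy_bins(5)
  aln <- data.frame(qname = sprintf("r%d", 1:12), chrom = "chr1",
                    start = c(rep(3500L, 10), 1000L, 999L), strand = "+",
                    stringsAsFactors = FALSE)
  counted <- count_reads_in_bins(aln, bins)
  # 10 reads in bin 4; the boundary read at 1000 belongs to the bin starting
  # at 1000 (half-open), the read at 999 to the first bin
  expect_equal(counted$raw_count, c(1, 1, 0, 10, 0))
  # outside reads are counted, not dropped silently
  out <- data.frame(qname = "x", chrom = "chr1", start = 99999L, strand = "+",
                    stringsAsFactors = FALSE)
  counted2 <- count_reads_in_bins(out, bins)
  expect_equal(attr(counted2, "n_outside"), 1L)
  expect_equal(sum(counted2$raw_count), 0)
})

test_that("uniform reads distribute uniformly over equal bins", {
  bins <- toy_bins(50)
  st <- with_seed_test(77, sample.int(50000, 20000, replace = TRUE) - 1L)
  aln <- data.frame(qname = sprintf("r%d", seq_along(st)), chrom = "chr1",
                    start = st, strand = "+", stringsAsFactors = FALSE)
  counted <- count_reads_in_bins(aln, bins)
  p <- suppressWarnings(chisq.test(counted$raw_count)$p.value)
  expect_gt(p, 0.01)
})

test_that("logR: pseudocount, GC filter, and the hand-worked example", {
  bins <- toy_bins(3)
  bins$raw_count <- c(1, 1, 7)
  tr <- compute_logr(bins, pseudocount = 1, gc_min = 0.28)
  expect_equal(tr$logr, c(-1, -1, 1))        # counts' 2,2,8; mean 4

  bins$raw_count <- c(5, 5, 5)
  expect_true(all(compute_logr(bins)$logr == 0))

  bins$gc <- c(0.25, 0.45, 0.45)
  bins$raw_count <- c(100, 3, 3)
  tr2 <- compute_logr(bins)
  expect_equal(nrow(tr2), 2)                  # low-GC bin filtered before the mean
  expect_true(all(tr2$logr == 0))
  expect_equal(attr(tr2, "n_gc_filtered"), 1L)

  bins$gc <- 0.1
  expect_error(compute_logr(bins), "all bins removed")
})

test_that("logR is invariant to rescaling raw counts (pseudocount 0)", {
  bins <- toy_bins(40)
  bins$raw_count <- with_seed_test(5, rpois(40, 20) + 1)
  t1 <- compute_logr(bins, pseudocount = 0)
  bins$raw_count <- bins$raw_count * 7
  t2 <- compute_logr(bins, pseudocount = 0)
  expect_equal(t1$logr, t2$logr, tolerance = 1e-12)
})

test_that("Loess GC correction removes an injected log-linear bias", {
  n <- 1000
  gc <- with_seed_test(13, runif(n, 0.3, 0.6))
  noise <- with_seed_test(14, rnorm(n, 0, 0.1))
  track <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 1000,
                      end = seq_len(n) * 1000,
                      gc = gc, logr = 0.8 * (gc - mean(gc)) + noise,
                      stringsAsFactors = FALSE)
  corr <- gc_correct(track)
  expect_lt(abs(cor(corr$logr, corr$gc, method = "spearman")), 0.1)
  expect_equal(median(corr$logr), 0, tolerance = 1e-9)

  # no bias: correction is essentially centring
  track$logr <- noise
  corr2 <- gc_correct(track)
  recentred <- track$logr - median(track$logr)
  expect_lt(max(abs(corr2$logr - recentred)), 0.05)

  # constant logr: corrected all ~0
  track$logr <- rep(0.7, n)
  corr3 <- gc_correct(track)
  expect_lt(max(abs(corr3$logr)), 1e-6)

  # degenerate GC: median-centring only, with a warning
  track$gc <- 0.5
  track$logr <- noise
  expect_warning(corr4 <- gc_correct(track), "degenerate")
  expect_equal(corr4$logr, noise - median(noise))
})

test_that("ploidy anchoring follows the closed form", {
  track <- data.frame(chrom = "chr1", start = (0:99) * 1000, end = (1:100) * 1000,
                      logr = rep(0, 100), gc = 0.5, stringsAsFactors = FALSE)
  ref <- list(chrom = "chr1", start = 0, end = 100000)
  expect_equal(estimate_ploidy(track, ref)$psi, 2)
  track$logr <- rep(-0.3, 100)
  expect_equal(estimate_ploidy(track, ref)$psi, 2 * 2^0.3, tolerance = 1e-12)
  track$logr <- rep(1, 100)
  expect_equal(estimate_ploidy(track, ref, ref_cn = 4)$psi, 2)
  expect_error(estimate_ploidy(track, list(chrom = "chr5", start = 0, end = 1e5)),
               "no retained bins")
})

test_that("integer CN calls round half-up from 2^logR x Psi", {
  segs <- data.frame(chrom = "chr1", start = 0, end = 1000, n_bins = 10,
                     mean = c(0, 1, 0.45, -8), stringsAsFactors = FALSE)
  cn <- call_integer_cn(segs, psi = 2)
  expect_equal(cn$cn_continuous[1:3], c(2, 4, 2^0.45 * 2), tolerance = 1e-12)
  expect_equal(cn$cn_integer, c(2L, 4L, 3L, 0L))
  expect_true(all(cn$cn_integer >= 0))
})

test_that("aCGH-mode processing: floor, recentring, GC handling, step recovery", {
  # degenerate all -5 input: floored to -2, recentred to 0, one segment
  pr <- data.frame(chrom = "chr1", pos = (1:60) * 1000, logr = -5)
  res <- process_acgh_track(pr, kmin = 25)
  expect_true(all(res$probes$logr == 0))
  expect_equal(nrow(res$segments), 1)

  # recentring contract on arbitrary input
  pr2 <- data.frame(chrom = "chr1", pos = (1:200) * 1000,
                    logr = with_seed_test(3, rnorm(200, 1, 0.5)))
  res2 <- process_acgh_track(pr2, kmin = 25)
  expect_lt(abs(mean(res2$probes$logr)), 1e-9)

  # missing gc column with the flag: warn and skip
  expect_warning(process_acgh_track(pr2, gc_correct_flag = TRUE), "gc column absent")

  # gc correction path keeps the mean at 0
  pr2$gc <- with_seed_test(4, runif(200, 0.3, 0.6))
  pr2$logr <- pr2$logr + 0.8 * (pr2$gc - mean(pr2$gc))
  res3 <- process_acgh_track(pr2, gc_correct_flag = TRUE, kmin = 25)
  expect_lt(abs(mean(res3$probes$logr)), 1e-9)
})

test_that("full single-cell profile keeps the GC filter downstream", {
  fx <- bench_fixture()
  expect_true(all(fx$res$profile$track$gc >= 0.28))
  # median normalisation leaves the corrected track centred
  expect_equal(median(fx$res$profile$track$logr), 0, tolerance = 1e-9)
})
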