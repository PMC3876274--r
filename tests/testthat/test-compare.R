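cn_segs <- function(cn, width = 100000L, chrom = "chr1") {
  n <- length(cn)
  data.frame(chrom = chrom, start = (seq_len(n) - 1L) * width,
             end = seq_len(n) * width, n_bins = 10, mean = 0,
             cn_integer = as.integer(cn), stringsAsFactors = FALSE)
}

test_that("status track thresholds integer CN against the baseline", {
  st <- status_track(cn_segs(c(1, 2, 4)))
  expect_equal(st$status, c("loss", "neutral", "gain"))
  expect_true(all(status_track(cn_segs(c(2, 2)))$status == "neutral"))
  # baseline can follow ploidy
  st4 <- status_track(cn_segs(c(3, 4, 5)), baseline = 4)
  expect_equal(st4$status, c("loss", "neutral", "gain"))
})

test_that("concordance is bp-weighted, symmetric, and exact on constructions", {
  a <- status_track(cn_segs(c(2, 3, 2, 1, 2)))
  expect_equal(concordance(a, a)$concordance, 1)

  b <- a; b$status <- ifelse(a$status == "gain", "loss",
                             ifelse(a$status == "loss", "gain", "gain"))
  expect_equal(concordance(a, b)$concordance, 0)

  # differ on exactly 10% of compared bp, with mismatched window grids
  a10 <- status_track(cn_segs(rep(2, 10)))                    # 10 x 100 kb
  b10 <- status_track(cn_segs(rep(c(2, 2, 2, 2, 3), 2), width = 100000L))
  b10$status[5] <- "gain"; b10$status[10] <- "neutral"
  got <- concordance(a10, b10)
  expect_equal(got$concordance, 0.9, tolerance = 1e-9)
  expect_equal(got$concordance, concordance(b10, a10)$concordance)

  expect_error(concordance(a, data.frame(chrom = "chrX", start = 0, end = 1,
                                         status = "gain")), "share no chromosomes")
})

test_that("event classification separates clonal, subclonal, and private events", {
  g <- simulate_genome(sim_genome_spec(n_chroms = 2, chrom_length = 1000000, seed = 61))
  clonal_gain <- data.frame(chrom = "chr1", start = 600000L, end = 1000000L,
                            allele = "A", change = 1L, kind = "arm",
                            stringsAsFactors = FALSE)
  sub_gain <- data.frame(chrom = "chr2", start = 100000L, end = 400000L,
                         allele = "B", change = 1L, kind = "focal",
                         stringsAsFactors = FALSE)
  primary_only_loss <- data.frame(chrom = "chr2", start = 700000L, end = 900000L,
                                  allele = "A", change = -1L, kind = "focal",
                                  stringsAsFactors = FALSE)
  truth <- simulate_tumor_truth(g, list(
    list(id = "major", fraction = 0.6, events = rbind(clonal_gain, primary_only_loss)),
    list(id = "minor", fraction = 0.4, events = rbind(clonal_gain, sub_gain))))

  # the DTC carries a whole-chr1 gain (superset of the clonal arm gain) and
  # the subclone's chr2 gain
  dtc2 <- rbind(cn_segs(rep(3, 10), chrom = "chr1"),
                cn_segs(c(2, 3, 3, 3, 2, 2, 2, 2, 2, 2), chrom = "chr2"))

  res <- classify_events(dtc2, truth, min_jaccard = 0.3)
  ev <- res$dtc_events
  # chr2 gain matches the 0.4-fraction subclone event
  sub <- ev[ev$chrom == "chr2" & ev$status == "gain", ]
  expect_equal(sub$label, "subclonal-shared")
  expect_equal(sub$matched_fraction, 0.4)
  # whole-chr1 gain overlaps the clonal event at Jaccard 0.4, above the
  # relaxed threshold used here; both clones carry it, so fraction 1
  chr1 <- ev[ev$chrom == "chr1", ]
  expect_equal(chr1$label, "clonal-shared")
  # the primary-only loss is not in the DTC
  prim <- res$primary_events
  expect_equal(prim$label[prim$chrom == "chr2" & prim$status == "loss"],
               "primary-private")

  # exact clonal match labels clonal-shared at the default threshold
  dtc3 <- rbind(cn_segs(c(2, 2, 2, 2, 2, 2, 3, 3, 3, 3), chrom = "chr1"),
                cn_segs(rep(2, 10), chrom = "chr2"))
  res3 <- classify_events(dtc3, truth)
  expect_equal(res3$dtc_events$label, "clonal-shared")
  expect_equal(res3$dtc_events$matched_fraction, 1)
})

test_that("concordance calibration reproduces 1 - f on constructed pairs", {
  cal <- concordance_calibration(fractions = c(0.1), reps = 10, seed = 3)
  expect_lt(cal$max_abs_error, 0.02)
  expect_equal(cal$mean_concordance, 0.9, tolerance = 0.02)
})
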