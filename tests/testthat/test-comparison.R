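mkCalls <- function(position, alt, frequency) {
  data.frame(position = position, ref = "A", alt = alt,
             depth = 10000L, alt_count = as.integer(frequency * 100),
             frequency = frequency)
}

test_that("compareRuns classifies concordant, discrepant and exclusive variants", {
  a <- mkCalls(c(100L, 200L, 300L), c("T", "C", "G"), c(50.2, 2.0, 10))
  b <- mkCalls(c(100L, 300L, 400L), c("T", "G", "T"), c(50.0, 11, 1.5))
  cmp <- compareRuns(a, b, thresholdPp = 0.5)
  rec <- cmp$records
  expect_equal(rec$klass[rec$position == 100], "concordant")  # delta 0.2
  expect_equal(rec$klass[rec$position == 200], "exclusive_rcrs")
  expect_equal(rec$klass[rec$position == 300], "discrepant")  # delta 1.0
  expect_equal(rec$klass[rec$position == 400], "exclusive_combined")
  s <- cmp$summary
  expect_equal(s@nUnion, 4L)
  expect_equal(s@nConcordant + s@nDiscrepant + s@nExclusiveRcrs +
                 s@nExclusiveCombined, s@nUnion)

  # identical call sets: 100% concordant, no exclusives
  cmp2 <- compareRuns(a, a)
  expect_equal(cmp2$summary@pctConcordant, 100)
  expect_equal(cmp2$summary@nExclusiveRcrs, 0L)
  expect_equal(cmp2$summary@nExclusiveCombined, 0L)

  # same position, different allele -> two exclusives
  a3 <- mkCalls(500L, "T", 5)
  b3 <- mkCalls(500L, "C", 5)
  cmp3 <- compareRuns(a3, b3)
  expect_equal(cmp3$summary@nUnion, 2L)
  expect_equal(cmp3$summary@nExclusiveRcrs, 1L)
  expect_equal(cmp3$summary@nExclusiveCombined, 1L)

  expect_error(compareRuns(a, b, thresholdPp = 0), "> 0")
})

test_that("scatter data puts exclusives on the absent axis and subsets <4%", {
  a <- mkCalls(c(10L, 20L, 30L), c("T", "T", "T"), c(10, 2, 3))
  b <- mkCalls(c(10L, 30L), c("T", "T"), c(10, 3.2))
  sc <- scatterData(compareRuns(a, b)$records)
  f <- sc$full
  expect_equal(f$x_combined[f$position == 10], 10)
  expect_equal(f$y_rcrs_only[f$position == 10], 10)
  expect_equal(f$x_combined[f$position == 20], 0)  # exclusive_rcrs at (0, 2)
  expect_equal(f$y_rcrs_only[f$position == 20], 2)
  expect_setequal(sc$low_frequency$position, c(20L, 30L))
})

test_that("NUMT coverage track counts overlapping projections per bin", {
  empty <- numtCoverageTrack(
    data.frame(numt_id = character(), mito_start = integer(),
               length = integer()), 16569, binSize = 1000)
  expect_true(all(empty$coverage == 0))

  numts <- data.frame(numt_id = c("n1", "n2"),
                      mito_start = c(5001L, 16001L),
                      length = c(3000L, 1000L))  # n2 wraps 16001..432
  tr <- numtCoverageTrack(numts, 16569, binSize = 1000)
  expect_equal(tr$coverage[6:8], c(1, 1, 1))   # bins 5001..8000
  expect_equal(tr$coverage[1], 1)              # wrap tail 1..432
  expect_equal(tr$coverage[17], 1)             # 16001..16569
  expect_equal(tr$coverage[10], 0)

  # base-resolution track sums to total projected bases
  tr1 <- numtCoverageTrack(numts, 16569, binSize = 1)
  expect_equal(sum(tr1$coverage), 3000 + 1000)
})

test_that("positional histograms bin inflated and rCRS-exclusive variants", {
  rec <- data.frame(position = c(100L, 5500L, 5600L, 9000L),
                    alt = "T",
                    freq_rcrs_only = c(5, 2, 3, 1),
                    freq_combined = c(4, NA, NA, 1.2),
                    delta = c(1, NA, NA, 0.2),
                    klass = c("discrepant", "exclusive_rcrs",
                              "exclusive_rcrs", "concordant"))
  h <- positionalHistogram(rec, 16569, binSize = 1000)
  expect_equal(sum(h$n_inflated), 1)
  expect_equal(h$n_inflated[1], 1)          # position 100, rcrs higher
  expect_equal(sum(h$n_exclusive_rcrs), 2)
  expect_equal(h$n_exclusive_rcrs[6], 2)    # both exclusives in 5001..6000

  h0 <- positionalHistogram(rec[rec$klass == "concordant", ], 16569, 1000)
  expect_true(all(h0$n_inflated == 0) && all(h0$n_exclusive_rcrs == 0))
})

test_that("proportionTest reproduces the exact hypergeometric oracle", {
  expect_equal(proportionTest(5, 100, 5, 100), 1.0)

  # oracle: two-sided Fisher on [[0,10],[10,0]] by direct enumeration of the
  # hypergeometric support: only the two extreme tables are as extreme
  pOracle <- 2 / choose(20, 10)
  expect_equal(proportionTest(0, 10, 10, 10), pOracle, tolerance = 1e-9)

  # condition-level contrast at the reported per-condition rates
  # (9-amplicon: 5.5% of 2486 vs 0.2% of 260)
  expect_lt(proportionTest(137, 2486, 1, 260), 0.01)
  # 180-amplicon: 3.0% vs 0.4%
  expect_lt(proportionTest(75, 2486, 1, 260), 0.01)

  expect_error(proportionTest(11, 10, 1, 10), "k <= n")
})

test_that("rotation permutation test detects clustering and not uniformity", {
  L <- 10000L
  trackU <- rep(1, L)
  sites <- c(100L, 2000L, 7000L)
  resU <- permutationPositionTest(sites, trackU, nPermutations = 500,
                                  seed = 1)
  expect_equal(resU$p_value, 1)  # constant track: all rotations tie

  track <- rep(0, L)
  track[4000:5000] <- 1
  # sites span the whole non-zero region: only the identity rotation keeps
  # every site on the region, so the null mass at the observed statistic is
  # ~1/L per rotation
  clustered <- seq(4000L, 5000L, by = 100L)
  resC <- permutationPositionTest(clustered, track,
                                  nPermutations = 10000, seed = 2)
  expect_lte(resC$p_value, 0.01)

  # determinism
  resC2 <- permutationPositionTest(clustered, track,
                                   nPermutations = 10000, seed = 2)
  expect_identical(resC$p_value, resC2$p_value)

  expect_error(permutationPositionTest(sites, trackU, nPermutations = 50),
               ">= 100")
})

test_that("similarity statistics summarize the registry", {
  w <- makeWorld(mitoLength = 16569, numtCount = 200, seed = 9)
  st <- numtSimilarityStats(worldNumts(w))
  expect_lt(abs(st$mean - 0.86), 0.015)
  expect_gt(st$sd, 0.02)

  one <- worldNumts(w)[1, ]
  expect_equal(numtSimilarityStats(one)$sd, 0)
  same <- worldNumts(w)[c(1, 1, 1), ]
  expect_equal(numtSimilarityStats(same)$sd, 0)
  expect_error(numtSimilarityStats(worldNumts(w)[0, ]), "empty")
})

test_that("comparison report writes consistent JSON and CSVs", {
  a <- mkCalls(c(100L, 200L), c("T", "C"), c(10, 2))
  b <- mkCalls(100L, "T", 9.9)
  cmp <- compareRuns(a, b, thresholdPp = 0.5)
  d <- withr::local_tempdir()
  paths <- writeComparisonReport(cmp, dir = d,
                                 metadata = list(seed = 42))
  js <- jsonlite::read_json(file.path(d, "comparison_summary.json"),
                            simplifyVector = TRUE)
  expect_equal(js$threshold_pp, 0.5)
  expect_equal(js$n_concordant + js$n_discrepant + js$n_exclusive_rcrs +
                 js$n_exclusive_combined, js$n_variants_union)
  expect_equal(js$metadata$seed, 42)

  # re-writing with the same inputs is byte-identical
  d2 <- withr::local_tempdir()
  writeComparisonReport(cmp, dir = d2, metadata = list(seed = 42))
  expect_identical(readLines(file.path(d, "scatter_full.csv")),
                   readLines(file.path(d2, "scatter_full.csv")))
})
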