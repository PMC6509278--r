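test_that("mito reference generation honours length, determinism and bounds", {
  m <- generateMitoReference(16569, seed = 1)
  expect_equal(mitoLength(m), 16569L)
  expect_true(grepl("^[ACGT]+$", mitoSequence(m)))

  a <- generateMitoReference(1000, seed = 7)
  b <- generateMitoReference(1000, seed = 7)
  expect_identical(mitoSequence(a), mitoSequence(b))
  expect_false(identical(mitoSequence(a),
                         mitoSequence(generateMitoReference(1000, seed = 8))))

  expect_error(generateMitoReference(999, seed = 1), "1,000")
})

test_that("heteroplasmy planting validates positions, alleles and frequencies", {
  m <- generateMitoReference(2000, seed = 1)
  tr <- plantHeteroplasmy(m, data.frame(position = 100, alt = altAt(m, 100),
                                        frequency = 0.03))
  expect_equal(tr$frequency, 0.03)
  expect_equal(tr$ref, substr(mitoSequence(m), 100, 100))

  homo <- plantHeteroplasmy(m, data.frame(position = 100,
                                          alt = altAt(m, 100),
                                          frequency = 1.0))
  expect_equal(homo$frequency, 1.0)

  expect_error(plantHeteroplasmy(m, data.frame(
    position = c(100, 100), alt = c(altAt(m, 100), altAt(m, 100)),
    frequency = c(0.03, 0.1))), "duplicate")
  expect_error(plantHeteroplasmy(m, data.frame(
    position = 100, alt = substr(mitoSequence(m), 100, 100),
    frequency = 0.1)), "equals the reference")
  expect_error(plantHeteroplasmy(m, data.frame(
    position = 100, alt = altAt(m, 100), frequency = 0)), "in \\(0, 1\\]")
  expect_error(plantHeteroplasmy(m, data.frame(
    position = 3000, alt = "A", frequency = 0.1)), "outside")
})

test_that("NUMT generation recovers the similarity model and size law", {
  m <- generateMitoReference(16569, seed = 2)
  ng <- generateNumts(m, count = 750, sizeRange = c(100, 6000),
                      similarityMean = 0.86, similaritySd = 0.041,
                      seed = 3)
  expect_equal(nrow(ng$numts), 750L)
  expect_equal(length(ng$contigs), 750L)

  st <- numtSimilarityStats(ng$numts)
  expect_lt(abs(st$mean - 0.86), 0.01)
  expect_lt(abs(st$sd - 0.041), 0.01)

  # sizes uniform over the range: all inside, mean near the midpoint
  lens <- ng$numts$length
  expect_true(all(lens >= 100 & lens <= 6000))
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - (100 + 6000) / 2), 3 * se)

  expect_equal(nrow(generateNumts(m, count = 0, seed = 1)$numts), 0L)
  expect_error(generateNumts(m, count = -1, seed = 1), ">= 0")
  expect_error(generateNumts(m, count = 5, sizeRange = c(600, 100),
                             seed = 1), "inverted")
})

test_that("realized NUMT divergence matches the binomial substitution model", {
  m <- generateMitoReference(16569, seed = 4)
  # similaritySd = 0: every NUMT mutates at exactly rate 1 - s
  s <- 0.9
  ng <- generateNumts(m, count = 50, sizeRange = c(500, 3000),
                      similarityMean = s, similaritySd = 0, seed = 5)
  mismFrac <- ng$numts$n_mismatch / ng$numts$length
  binomSe <- sqrt(s * (1 - s) / ng$numts$length)
  expect_true(all(abs(mismFrac - (1 - s)) <= 3 * binomSe))

  # registry mismatch counts agree with a direct sequence comparison
  w <- new("World", mito = m,
           truth = plantHeteroplasmy(m, data.frame(position = integer(),
                                                   alt = character(),
                                                   frequency = numeric())),
           numts = ng$numts, nuclearContigs = ng$contigs, seed = 5L)
  for (i in c(1, 25, 50)) {
    pos <- numtMismatchPositions(w, ng$numts$numt_id[i])
    expect_length(pos, ng$numts$n_mismatch[i])
  }
})

test_that("world files round-trip losslessly and are seed-deterministic", {
  w <- makeWorld(mitoLength = 5000, numtCount = 3, sizeRange = c(100, 1200),
                 flankLength = 300, nHet = 3, nHomo = 2, seed = 11)
  d1 <- withr::local_tempdir()
  writeWorld(w, d1)
  w2 <- readWorld(d1)
  expect_identical(mitoSequence(worldMito(w2)), mitoSequence(worldMito(w)))
  expect_identical(as.character(nuclearContigs(w2)),
                   as.character(nuclearContigs(w)))
  expect_equal(worldNumts(w2), worldNumts(w))
  expect_equal(worldTruth(w2), worldTruth(w), ignore_attr = TRUE)
  expect_identical(w2@seed, w@seed)

  # identical seed => byte-identical files
  d2 <- withr::local_tempdir()
  writeWorld(makeWorld(mitoLength = 5000, numtCount = 3,
                       sizeRange = c(100, 1200), flankLength = 300,
                       nHet = 3, nHomo = 2, seed = 11), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("file", f))
  }
})

test_that("BED projection splits origin-wrapping NUMTs and scores similarity", {
  m <- generateMitoReference(5000, seed = 6)
  w <- toyWorld(m, numtSpecs = list(
    list(start = 1000, len = 400, mismatchOffsets = c(10, 20)),
    list(start = 4801, len = 400, mismatchOffsets = 5),
    list(start = 2000, len = 150, mismatchOffsets = 7)))
  d <- withr::local_tempdir()
  writeWorld(w, d)
  bed <- read.delim(file.path(d, "numt_projection.bed"), header = FALSE)
  expect_equal(nrow(bed), 4L)  # 3 NUMTs, one split at the origin
  wrap <- bed[bed$V4 == "numt_002", ]
  expect_equal(sort(wrap$V2), c(0L, 4800L))
  expect_equal(sort(wrap$V3), c(200L, 5000L))
  expect_equal(bed$V5[bed$V4 == "numt_001"],
               round(1000 * (1 - 2 / 400)))

  # empty truth => header-only truth TSV
  tr <- readLines(file.path(d, "heteroplasmy_truth.tsv"))
  expect_equal(length(tr), 1L)
  expect_match(tr, "^POS\tREF\tALT\tFREQ$")
})
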