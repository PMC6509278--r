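test_that("amplicon panels tile the circle with the prescribed geometry", {
  m <- generateMitoReference(16569, seed = 1)

  p2 <- designAmpliconPanel(m, 2, primerLength = 25, minOverlap = 100)
  a2 <- amplicons(p2)
  expect_equal(nrow(a2), 2L)
  # closed form: each amplicon ~ (L + n*overlap)/n = 8384.5
  expect_true(all(abs(a2$length - (16569 + 2 * 100) / 2) <= 1))

  p180 <- designAmpliconPanel(m, 180, primerLength = 20, minOverlap = 30)
  a180 <- amplicons(p180)
  expect_equal(nrow(a180), 180L)
  expect_true(all(abs(a180$length - 122) <= 1))
  # short-amplicon regime: inside the typical 100-2000 bp window
  expect_true(all(a180$length >= 100 & a180$length <= 2000))

  # full-circle coverage with the stated overlap between neighbours
  L <- 16569L
  covered <- logical(L)
  for (i in seq_len(nrow(a180))) {
    covered[((a180$start[i] - 1L + seq_len(a180$length[i]) - 1L) %% L) +
              1L] <- TRUE
  }
  expect_true(all(covered))
  nxt <- c(a180$start[-1], a180$start[1] + L)
  expect_true(all(a180$start + a180$length - nxt >= 30))

  expect_error(designAmpliconPanel(generateMitoReference(1000, seed = 1),
                                   2000), "infeasible")
})

test_that("co-amplification needs both primer footprints inside the NUMT", {
  m <- generateMitoReference(16569, seed = 2)
  # NUMT spanning 2000..3499, divergent only in the interval interior
  w <- toyWorld(m, numtSpecs = list(
    list(start = 2000, len = 1500, mismatchOffsets = seq(200, 1300, by = 50))))
  p180 <- designAmpliconPanel(m, 180, primerLength = 20, minOverlap = 30)
  a <- amplicons(p180)
  inside <- which(a$start >= 2100 & (a$start + a$length) <= 3400)
  outside <- which(a$start > 4000 & a$start < 10000)
  expect_true(numtCoamplified(w, "numt_001", inside[1], p180))
  expect_false(numtCoamplified(w, "numt_001", outside[1], p180))

  # an amplicon longer than the NUMT can never contain both footprints
  p2 <- designAmpliconPanel(m, 2, primerLength = 25, minOverlap = 100)
  expect_false(any(vapply(1:2, function(i)
    numtCoamplified(w, "numt_001", i, p2), logical(1))))

  # footprint divergence above the mismatch cap blocks priming
  w2 <- toyWorld(m, numtSpecs = list(
    list(start = 2000, len = 1500,
         mismatchOffsets = (a$start[inside[1]] - 2000) + c(2, 5, 8, 11, 14))))
  expect_false(numtCoamplified(w2, "numt_001", inside[1], p180,
                               maxPrimerMismatches = 2))
  expect_true(numtCoamplified(w2, "numt_001", inside[1], p180,
                              maxPrimerMismatches = 5))
})

test_that("amplify conserves haplotype weight fractions and NUMT stoichiometry", {
  m <- generateMitoReference(16569, seed = 3)
  # heteroplasmy at 3% inside one amplicon, no NUMTs
  w <- toyWorld(m, truthSites = data.frame(position = 5000,
                                           alt = altAt(m, 5000),
                                           frequency = 0.03))
  p <- designAmpliconPanel(m, 9, primerLength = 25, minOverlap = 100)
  pool <- amplify(w, p, Stoichiometry(100, 2, 50, pcrJackpotSd = 0))
  info <- poolInfo(pool)
  covering <- info[info$mito_start <= 5000 &
                     5000 < info$mito_start + info$mito_length, ]
  altW <- sum(covering$weight[grepl("alt5000", covering$molecule_id)])
  expect_equal(altW / sum(covering$weight), 0.03, tolerance = 1e-12)

  # one co-amplified diploid NUMT against C = 198: weight fraction 1%
  w2 <- toyWorld(m, numtSpecs = list(
    list(start = 2000, len = 1500, mismatchOffsets = seq(200, 1300, 50))))
  p180 <- designAmpliconPanel(m, 180, primerLength = 20, minOverlap = 30)
  pool2 <- amplify(w2, p180, Stoichiometry(198, 2, 10, pcrJackpotSd = 0))
  info2 <- poolInfo(pool2)
  numtMol <- info2[info2$origin == "numt_001", ]
  expect_gt(nrow(numtMol), 0)
  amp1 <- info2[info2$mito_start == numtMol$mito_start[1], ]
  expect_equal(sum(amp1$weight[amp1$origin == "numt_001"]) /
                 sum(amp1$weight), 2 / (198 + 2), tolerance = 1e-12)

  # long-range panel co-amplifies nothing when amplicons exceed NUMT sizes
  p2 <- designAmpliconPanel(m, 2, primerLength = 25, minOverlap = 100)
  pool3 <- amplify(w2, p2, Stoichiometry(198, 2, 10, pcrJackpotSd = 0))
  expect_true(all(poolInfo(pool3)$origin == "mito"))
})

test_that("MDA fragments follow copy-number-weighted source sampling", {
  m <- generateMitoReference(16569, seed = 4)
  w0 <- toyWorld(m)  # no NUMTs
  pool0 <- mdaFragments(w0, Stoichiometry(100, 2, 10, 0),
                        nFragments = 2000, seed = 1)
  expect_true(all(poolInfo(pool0)$origin == "mito"))

  # closed form: fraction of NUMT-overlapping-site fragments ~ 2k/(C+2k)
  w1 <- toyWorld(m, numtSpecs = list(
    list(start = 6000, len = 5000, mismatchOffsets = seq(100, 4900, 100))),
    flank = 2000)
  C <- 100
  site <- 8500  # mid-NUMT mito position
  frac <- vapply(1:10, function(s) {
    pool <- mdaFragments(w1, Stoichiometry(C, 2, 10, 0),
                         fragmentLengthMean = 500, fragmentLengthSd = 0,
                         nFragments = 20000, seed = s)
    info <- poolInfo(pool)
    cov <- !is.na(info$mito_start) &
      ((site - info$mito_start) %% 16569) < info$mito_length
    sum(cov & info$origin == "numt_001") / sum(cov)
  }, numeric(1))
  expected <- 2 / (C + 2)
  mcSe <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - expected), 3 * mcSe + 1e-9)

  # determinism
  p1 <- mdaFragments(w1, Stoichiometry(C, 2, 10, 0), nFragments = 500,
                     seed = 42)
  p2 <- mdaFragments(w1, Stoichiometry(C, 2, 10, 0), nFragments = 500,
                     seed = 42)
  expect_identical(as.character(poolSequences(p1)),
                   as.character(poolSequences(p2)))
  expect_identical(poolInfo(p1), poolInfo(p2))
})
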