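#' Compare variant calls between the two reference modes
#'
#' Joins the two call sets on (position, alternate allele) and classifies
#' each variant of the union: `concordant` when called in both modes with an
#' absolute frequency difference below `thresholdPp` percentage points
#' (default 0.5, an absolute difference, matching the "differing by <0.5%"
#' convention), `discrepant` when called in both modes but differing by at
#' least the threshold, and `exclusive_rcrs` / `exclusive_combined` when
#' called under exactly one reference. A different allele at the same
#' position counts as two exclusives.
#'
#' @param callsRcrs calls from the mito-only alignment mode.
#' @param callsCombined calls from the combined-reference mode.
#' @param thresholdPp concordance threshold in percentage points (> 0).
#' @return list with `records` (per-variant data.frame: `position`, `alt`,
#'   `freq_rcrs_only`, `freq_combined`, `delta`, `klass`) and `summary`
#'   (a [ComparisonSummary-class]).
#' @export
compareRuns <- function(callsRcrs, callsCombined, thresholdPp = 0.5) {
  if (thresholdPp <= 0) stop("thresholdPp must be > 0")
  a <- data.frame(position = callsRcrs$position, alt = callsRcrs$alt,
                  freq_rcrs_only = callsRcrs$frequency)
  b <- data.frame(position = callsCombined$position, alt = callsCombined$alt,
                  freq_combined = callsCombined$frequency)
  rec <- merge(a, b, by = c("position", "alt"), all = TRUE)
  rec <- rec[order(rec$position, rec$alt), , drop = FALSE]
  rownames(rec) <- NULL
  both <- !is.na(rec$freq_rcrs_only) & !is.na(rec$freq_combined)
  rec$delta <- ifelse(both, abs(rec$freq_rcrs_only - rec$freq_combined),
                      NA_real_)
  rec$klass <- ifelse(both,
                      ifelse(rec$delta < thresholdPp, "concordant",
                             "discrepant"),
                      ifelse(is.na(rec$freq_combined), "exclusive_rcrs",
                             "exclusive_combined"))
  n <- nrow(rec)
  nCon <- sum(rec$klass == "concordant")
  summary <- new("ComparisonSummary",
                 nUnion = n, nConcordant = nCon,
                 nDiscrepant = sum(rec$klass == "discrepant"),
                 nExclusiveRcrs = sum(rec$klass == "exclusive_rcrs"),
                 nExclusiveCombined = sum(rec$klass == "exclusive_combined"),
                 pctConcordant = if (n > 0) 100 * nCon / n else NaN,
                 thresholdPp = thresholdPp)
  list(records = rec, summary = summary)
}

#' Scatter-plot data for the mode-versus-mode frequency comparison
#'
#' Returns the full-range table (x = combined-reference frequency,
#' y = mito-only frequency, reference-exclusive variants plotted at 0 on
#' their absent axis) and the low-frequency subset with both coordinates
#' below 4%.
#'
#' @param records per-variant records from [compareRuns()].
#' @return list with `full` and `low_frequency` data.frames (columns
#'   `position`, `alt`, `x_combined`, `y_rcrs_only`, `klass`).
#' @export
scatterData <- function(records) {
  full <- data.frame(
    position = records$position, alt = records$alt,
    x_combined = ifelse(is.na(records$freq_combined), 0,
                        records$freq_combined),
    y_rcrs_only = ifelse(is.na(records$freq_rcrs_only), 0,
                         records$freq_rcrs_only),
    klass = records$klass)
  low <- full[full$x_combined < 4 & full$y_rcrs_only < 4, , drop = FALSE]
  rownames(low) <- NULL
  list(full = full, low_frequency = low)
}

#' Per-bin NUMT projection coverage over the mito circle
#'
#' Counts, for each bin of the mito coordinate system, how many NUMT mito
#' projections overlap it; NUMTs wrapping the origin count in every bin they
#' touch. With `binSize = 1` the track sums to the total NUMT-projected
#' base count.
#'
#' @param numts NUMT registry data.frame (from [worldNumts()]).
#' @param mitoLen mito reference length.
#' @param binSize bin width in bp (>= 1).
#' @return data.frame with columns `bin_start` (1-based), `bin_end`,
#'   `coverage`.
#' @export
numtCoverageTrack <- function(numts, mitoLen, binSize = 500L) {
  binSize <- as.integer(binSize)
  if (binSize < 1L) stop("binSize must be >= 1")
  starts <- seq.int(1L, mitoLen, by = binSize)
  bins <- IRanges::IRanges(start = starts,
                           end = pmin(starts + binSize - 1L, mitoLen))
  cov <- integer(length(bins))
  for (i in seq_len(nrow(numts))) {
    s <- numts$mito_start[i]
    e <- s + numts$length[i] - 1L
    ir <- if (e <= mitoLen) {
      IRanges::IRanges(s, e)
    } else {  # wraps the origin
      IRanges::IRanges(c(s, 1L), c(mitoLen, e - mitoLen))
    }
    cov <- cov + (IRanges::countOverlaps(bins, ir) > 0L)
  }
  data.frame(bin_start = IRanges::start(bins), bin_end = IRanges::end(bins),
             coverage = cov)
}

#' Positional histograms of frequency-inflated and rCRS-exclusive variants
#'
#' Bins (aligned with [numtCoverageTrack()]) the positions of (a) variants
#' whose mito-only frequency exceeds their combined-reference frequency and
#' (b) variants called only against the mito reference.
#'
#' @param records per-variant records from [compareRuns()].
#' @param mitoLen mito reference length.
#' @param binSize bin width in bp.
#' @return data.frame with columns `bin_start`, `bin_end`, `n_inflated`,
#'   `n_exclusive_rcrs`.
#' @export
positionalHistogram <- function(records, mitoLen, binSize = 500L) {
  binSize <- as.integer(binSize)
  starts <- seq.int(1L, mitoLen, by = binSize)
  binOf <- function(pos) findInterval(pos, starts)
  inflated <- records$klass == "discrepant" &
    records$freq_rcrs_only > records$freq_combined
  excl <- records$klass == "exclusive_rcrs"
  nbin <- length(starts)
  data.frame(
    bin_start = starts, bin_end = pmin(starts + binSize - 1L, mitoLen),
    n_inflated = tabulate(binOf(records$position[inflated]), nbin),
    n_exclusive_rcrs = tabulate(binOf(records$position[excl]), nbin))
}

#' Exact two-sided test for a difference of two proportions
#'
#' Fisher's exact test on the 2x2 table (event vs non-event, condition A vs
#' condition B); used for the per-condition discrepancy-rate contrasts. An
#' exact test is preferred because reference-exclusive counts can be very
#' small.
#'
#' @param k1,n1 events and trials in condition A.
#' @param k2,n2 events and trials in condition B.
#' @return two-sided p-value.
#' @export
proportionTest <- function(k1, n1, k2, n2) {
  if (k1 > n1 || k2 > n2 || n1 < 1 || n2 < 1) stop("need k <= n and n >= 1")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  stats::fisher.test(tab)$p.value
}

#' Circular-rotation permutation test for positional clustering
#'
#' Tests whether variant positions preferentially sit where a per-base track
#' (typically NUMT coverage) is high. The statistic is the mean track value
#' at the observed positions; the null distribution rotates the whole
#' position set by a uniform random offset around the circle, preserving the
#' positions' relative spacing. The p-value uses add-one smoothing:
#' `(1 + #{rotations with statistic >= observed}) / (nPermutations + 1)`.
#' A constant track therefore always yields p = 1.
#'
#' @param positions 1-based variant positions.
#' @param track numeric per-base weight vector of length L.
#' @param nPermutations number of random rotations (>= 100).
#' @param seed integer seed.
#' @return list with `p_value`, `observed` statistic and the permutation
#'   statistics.
#' @export
permutationPositionTest <- function(positions, track, nPermutations = 10000L,
                                    seed = NULL) {
  nPermutations <- as.integer(nPermutations)
  if (nPermutations < 100L) stop("nPermutations must be >= 100")
  L <- length(track)
  positions <- as.integer(positions)
  if (!length(positions)) stop("no positions supplied")
  if (any(positions < 1L | positions > L)) stop("position outside the track")
  observed <- mean(track[positions])
  withSeed(seed, {
    offsets <- sample.int(L, nPermutations, replace = TRUE)
    perm <- vapply(offsets, function(r)
      mean(track[((positions - 1L + r) %% L) + 1L]), numeric(1))
    p <- (1 + sum(perm >= observed)) / (nPermutations + 1)
    list(p_value = p, observed = observed, permuted = perm)
  })
}

#' Mean and standard deviation of realized NUMT similarity
#'
#' @param numts NUMT registry data.frame (>= 1 row).
#' @return list with `mean` and `sd` (sd is 0 for a single NUMT, by
#'   convention).
#' @export
numtSimilarityStats <- function(numts) {
  if (!nrow(numts)) stop("empty NUMT set")
  s <- numts$similarity
  list(mean = mean(s), sd = if (length(s) > 1L) stats::sd(s) else 0)
}

#' Write the comparison report
#'
#' Emits a machine-readable JSON summary (class counts, threshold, run
#' metadata), the scatter tables and the positional histograms as CSVs.
#'
#' @param comparison output of [compareRuns()].
#' @param histograms output of [positionalHistogram()] (optional).
#' @param coverage output of [numtCoverageTrack()] (optional).
#' @param tests named list of test results to record (optional).
#' @param metadata named list of seeds/parameters to record (optional).
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeComparisonReport <- function(comparison, histograms = NULL,
                                  coverage = NULL, tests = NULL,
                                  metadata = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- comparison$summary
  js <- list(
    threshold_pp = s@thresholdPp,
    n_variants_union = s@nUnion,
    n_concordant = s@nConcordant,
    n_discrepant = s@nDiscrepant,
    n_exclusive_rcrs = s@nExclusiveRcrs,
    n_exclusive_combined = s@nExclusiveCombined,
    pct_concordant = s@pctConcordant,
    tests = tests, metadata = metadata)
  paths <- c(summary = file.path(dir, "comparison_summary.json"),
             records = file.path(dir, "comparison_records.csv"),
             scatter = file.path(dir, "scatter_full.csv"),
             scatter_low = file.path(dir, "scatter_low_frequency.csv"))
  jsonlite::write_json(js, paths["summary"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  utils::write.csv(comparison$records, paths["records"], row.names = FALSE)
  sc <- scatterData(comparison$records)
  utils::write.csv(sc$full, paths["scatter"], row.names = FALSE)
  utils::write.csv(sc$low_frequency, paths["scatter_low"], row.names = FALSE)
  if (!is.null(histograms)) {
    p <- file.path(dir, "positional_histograms.csv")
    utils::write.csv(histograms, p, row.names = FALSE)
    paths <- c(paths, histograms = p)
  }
  if (!is.null(coverage)) {
    p <- file.path(dir, "numt_coverage_track.csv")
    utils::write.csv(coverage, p, row.names = FALSE)
    paths <- c(paths, coverage = p)
  }
  invisible(paths)
}
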