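#' Run the full dual-reference pipeline on a synthetic world
#'
#' Chains enrichment (amplicon PCR preset or MDA), read simulation, optional
#' primer trimming, competitive mapping under the mito-only and combined
#' references, pileup and calling in both modes, and the discrepancy
#' comparison. All stage seeds are derived from `seed` and returned in the
#' metadata.
#'
#' @param world a [World-class].
#' @param strategy `"lrpcr2"`, `"pcr9"`, `"pcr180"` (amplicon presets) or
#'   `"mda"`.
#' @param stoich a [Stoichiometry-class] (see [stoichPreset()]).
#' @param nReads total reads to simulate.
#' @param readLength,errorRate,primerErrorRate see [sequenceReads()].
#' @param trim apply [trimPrimers()] before mapping.
#' @param fragmentLengthMean,fragmentLengthSd,nFragments MDA parameters
#'   (ignored for amplicon strategies).
#' @param maxPrimerMismatches see [numtCoamplified()].
#' @param k,minIdentity mapper parameters.
#' @param minDepth,minFrequency caller parameters.
#' @param thresholdPp comparison threshold in percentage points.
#' @param seed master integer seed.
#' @return list with `calls_rcrs_only`, `calls_combined`, `records`,
#'   `summary`, `pileup_rcrs_only`, `pileup_combined`, `map_stats`,
#'   `panel` (NULL for MDA), `metadata`.
#' @export
runPipeline <- function(world,
                        strategy = c("lrpcr2", "pcr9", "pcr180", "mda"),
                        stoich = stoichPreset("pooled_cells"),
                        nReads = 150000L, readLength = 150L,
                        errorRate = 0.002, primerErrorRate = 0.02,
                        trim = FALSE,
                        fragmentLengthMean = 500, fragmentLengthSd = 150,
                        nFragments = 100000L, maxPrimerMismatches = 2L,
                        k = 15L, minIdentity = 0.88, minDepth = 100L,
                        minFrequency = 0.2, thresholdPp = 0.5, seed = 1L) {
  strategy <- match.arg(strategy)
  seeds <- stageSeeds(seed, 2L)

  pool <- if (strategy == "mda") {
    mdaFragments(world, stoich, fragmentLengthMean, fragmentLengthSd,
                 nFragments, seed = seeds[1])
  } else {
    panel <- ampliconPanelPreset(world@mito, strategy)
    amplify(world, panel, stoich, maxPrimerMismatches, seed = seeds[1])
  }
  panel <- if (strategy == "mda") NULL else panel

  reads <- sequenceReads(pool, readLength, nReads, errorRate,
                         primerErrorRate, seed = seeds[2])
  if (trim) reads <- trimPrimers(reads, panel)

  mitoIdx <- worldIndex(world, "rcrs_only", k = k)
  combIdx <- worldIndex(world, "combined", k = k)
  maps <- mapAll(reads, mitoIdx, combIdx, minIdentity)

  puR <- pileup(maps$rcrs_only, reads, world@mito)
  puC <- pileup(maps$combined, reads, world@mito)
  callsR <- callSites(puR, world@mito, minDepth, minFrequency)
  callsC <- callSites(puC, world@mito, minDepth, minFrequency)
  cmp <- compareRuns(callsR, callsC, thresholdPp)

  list(calls_rcrs_only = callsR, calls_combined = callsC,
       records = cmp$records, summary = cmp$summary,
       pileup_rcrs_only = puR, pileup_combined = puC,
       map_stats = maps$stats, panel = panel,
       metadata = list(strategy = strategy, seed = seed,
                       stage_seeds = seeds, n_reads = nReads,
                       read_length = readLength, error_rate = errorRate,
                       primer_error_rate = primerErrorRate, trim = trim,
                       k = k, min_identity = minIdentity,
                       min_depth = minDepth, min_frequency = minFrequency,
                       threshold_pp = thresholdPp,
                       mito_copies_per_cell = stoich@mitoCopiesPerCell,
                       pcr_jackpot_sd = stoich@pcrJackpotSd))
}

# discrepant + exclusive tally used by the strategy-ordering analyses
nDiscordant <- function(summary) {
  summary@nDiscrepant + summary@nExclusiveRcrs + summary@nExclusiveCombined
}

#' Count of non-concordant variants in a comparison
#'
#' Convenience tally of discrepant plus reference-exclusive variants, the
#' quantity that grows as amplicon size shrinks and peaks under MDA.
#'
#' @param summary a [ComparisonSummary-class].
#' @return integer count.
#' @export
discordantCount <- function(summary) nDiscordant(summary)
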