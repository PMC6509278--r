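#' Stoichiometry constructor and presets
#'
#' `Stoichiometry()` builds the template copy-number model; `stoichPreset()`
#' returns the built-in starting-material presets. Mito copies per cell are
#' not quantified in typical study reports; the presets are configuration
#' defaults chosen to reproduce the qualitative ordering between
#' starting materials: `"pooled_cells"` (C = 100, strong jackpot noise from
#' low-template PCR), `"homogenate"` (C = 500, no jackpot noise) and `"csf"`
#' (C = 100, strong jackpot noise; the cell-poor fluid used with MDA).
#'
#' @param mitoCopiesPerCell mtDNA copies per cell (C >= 1).
#' @param nuclearCopies nuclear genome copies per cell (2 = diploid).
#' @param cells number of input cells.
#' @param pcrJackpotSd lognormal sigma of per-template amplification noise.
#' @return a [Stoichiometry-class].
#' @export
Stoichiometry <- function(mitoCopiesPerCell = 500, nuclearCopies = 2,
                          cells = 1000, pcrJackpotSd = 0) {
  new("Stoichiometry", mitoCopiesPerCell = mitoCopiesPerCell,
      nuclearCopies = nuclearCopies, cells = cells,
      pcrJackpotSd = pcrJackpotSd)
}

#' @rdname Stoichiometry
#' @param preset one of `"pooled_cells"`, `"homogenate"`, `"csf"`.
#' @export
stoichPreset <- function(preset = c("pooled_cells", "homogenate", "csf")) {
  switch(match.arg(preset),
    pooled_cells = Stoichiometry(100, 2, 500, 0.5),
    homogenate = Stoichiometry(500, 2, 10000, 0),
    csf = Stoichiometry(100, 2, 200, 0.5))
}

#' Design a circular amplicon tiling panel
#'
#' Places `nAmplicons` near-equal, evenly spaced amplicons around the mito
#' circle so adjacent amplicons overlap by at least `minOverlap` bp. The
#' construction is deterministic: amplicon i starts at
#' `floor(i * L / n) + 1` and ends `minOverlap` bases into its successor, so
#' each amplicon is about `L/n + minOverlap` bp.
#'
#' The presets of the common enrichment strategies are available through
#' [ampliconPanelPreset()]: a 2-amplicon long-range PCR (~8.4 kb amplicons,
#' longer than any typical NUMT), a 9-amplicon panel (~1.9 kb) and a
#' 180-amplicon panel (~122 bp, inside the usual 100-2,000 bp short-amplicon
#' regime).
#'
#' @param mito a [MitoReference-class].
#' @param nAmplicons number of amplicons (>= 1).
#' @param primerLength primer footprint length in bp.
#' @param minOverlap minimum adjacent overlap in bp.
#' @return an [AmpliconPanel-class].
#' @export
designAmpliconPanel <- function(mito, nAmplicons, primerLength = 20L,
                                minOverlap = 30L) {
  stopifnot(is(mito, "MitoReference"))
  n <- as.integer(nAmplicons)
  primerLength <- as.integer(primerLength)
  minOverlap <- as.integer(minOverlap)
  if (is.na(n) || n < 1L) stop("nAmplicons must be >= 1")
  L <- length(mito@sequence)
  starts <- as.integer(floor((seq_len(n) - 1L) * L / n)) + 1L
  nextStart <- c(starts[-1L], L + starts[1L])
  lens <- as.integer(nextStart + minOverlap - starts)
  if (n == 1L) lens <- L
  minLen <- min(lens)
  if (minLen < 2L * primerLength + 10L)
    stop("infeasible tiling: amplicons too short for two primer footprints")
  if (minLen > L)
    stop("infeasible tiling: amplicon longer than the circle")
  new("AmpliconPanel",
      amplicons = data.frame(amplicon = seq_len(n), start = starts,
                             length = lens),
      primerLength = primerLength, minOverlap = minOverlap,
      mitoLength = L)
}

#' @rdname designAmpliconPanel
#' @param strategy one of `"lrpcr2"`, `"pcr9"`, `"pcr180"`.
#' @export
ampliconPanelPreset <- function(mito,
                                strategy = c("lrpcr2", "pcr9", "pcr180")) {
  switch(match.arg(strategy),
    lrpcr2 = designAmpliconPanel(mito, 2L, primerLength = 25L,
                                 minOverlap = 100L),
    pcr9 = designAmpliconPanel(mito, 9L, primerLength = 25L,
                               minOverlap = 100L),
    pcr180 = designAmpliconPanel(mito, 180L, primerLength = 20L,
                                 minOverlap = 30L))
}

#' @describeIn designAmpliconPanel accessor for the amplicon table.
#' @param panel an [AmpliconPanel-class].
#' @export
amplicons <- function(panel) panel@amplicons

#' Would a NUMT be co-amplified by a given amplicon?
#'
#' A NUMT template yields an amplicon product only when both primer
#' footprints (the terminal `primerLength` bases of the amplicon's mito
#' interval) lie entirely within the NUMT's mito projection *and* the NUMT's
#' realized divergence within each footprint does not exceed
#' `maxPrimerMismatches`. An amplicon longer than a NUMT can therefore never
#' co-amplify it: this is the protective mechanism of long-range PCR.
#'
#' @param world a [World-class].
#' @param numtId a `numt_id` from the registry.
#' @param ampliconIndex row index into `amplicons(panel)`.
#' @param panel an [AmpliconPanel-class].
#' @param maxPrimerMismatches tolerated mismatches per primer footprint.
#' @return `TRUE` if the NUMT is co-amplified.
#' @export
numtCoamplified <- function(world, numtId, ampliconIndex, panel,
                            maxPrimerMismatches = 2L) {
  nu <- world@numts[world@numts$numt_id == numtId, ]
  if (nrow(nu) != 1L) stop("unknown numt_id: ", numtId)
  amp <- panel@amplicons[ampliconIndex, ]
  L <- panel@mitoLength
  p <- panel@primerLength
  if (!circularContains(nu$mito_start, nu$length, amp$start, amp$length, L))
    return(FALSE)
  numtSeq <- numtMitoCopy(world, nu)
  refChar <- as.character(world@mito@sequence)
  # footprint offsets within the NUMT copy
  off <- (amp$start - nu$mito_start) %% L
  fp5numt <- substr(numtSeq, off + 1L, off + p)
  fp3numt <- substr(numtSeq, off + amp$length - p + 1L, off + amp$length)
  fp5ref <- subCircular(refChar, amp$start, p, L)
  fp3ref <- subCircular(refChar,
                        ((amp$start + amp$length - p - 1L) %% L) + 1L, p, L)
  cpp_mismatch_count(fp5numt, fp5ref) <= maxPrimerMismatches &&
    cpp_mismatch_count(fp3numt, fp3ref) <= maxPrimerMismatches
}

# molecule sequence of one amplicon from a template (character, mito-forward),
# with both primer footprints overwritten by reference primer sequence:
# primers impose their own (reference-derived) bases on the product.
ampliconMolecule <- function(templateChar, templateStart, amp, refChar, L,
                             primerLength) {
  off <- (amp$start - templateStart) %% L
  if (off + amp$length > nchar(templateChar)) {
    # circular full-length template: wrap-extend (never triggers for the
    # linear NUMT copies, whose containment is checked upstream)
    templateChar <- paste0(templateChar, templateChar)
  }
  body <- substr(templateChar, off + 1L, off + amp$length)
  fp5 <- subCircular(refChar, amp$start, primerLength, L)
  fp3 <- subCircular(refChar,
                     ((amp$start + amp$length - primerLength - 1L) %% L) + 1L,
                     primerLength, L)
  paste0(fp5, substr(body, primerLength + 1L, amp$length - primerLength), fp3)
}

#' Simulate amplicon PCR enrichment
#'
#' For every amplicon of the panel, one template molecule is emitted per true
#' mito haplotype class — the background haplotype (reference plus all
#' homoplasmic variants) and, for every sub-homoplasmic site the amplicon
#' covers, a haplotype carrying that site's alternate allele — weighted by
#' `C * cells * frequency`. Every NUMT passing the co-amplification test
#' ([numtCoamplified()]) contributes one molecule weighted by
#' `copy_number * cells`. Primer footprints of every product are the
#' reference primer sequence. Each weight is finally multiplied by a
#' lognormal "jackpot" factor with sigma `pcrJackpotSd` (low-template PCR
#' stochasticity); with sigma 0 the weight fractions within an amplicon equal
#' the true haplotype frequencies exactly.
#'
#' @param world a [World-class].
#' @param panel an [AmpliconPanel-class].
#' @param stoich a [Stoichiometry-class].
#' @param maxPrimerMismatches tolerated mismatches per primer footprint.
#' @param seed integer seed (jackpot noise only).
#' @return a [MoleculePool-class].
#' @export
amplify <- function(world, panel, stoich, maxPrimerMismatches = 2L,
                    seed = NULL) {
  stopifnot(is(world, "World"), is(panel, "AmpliconPanel"),
            is(stoich, "Stoichiometry"))
  L <- panel@mitoLength
  p <- panel@primerLength
  refChar <- as.character(world@mito@sequence)
  truth <- world@truth
  homo <- truth[truth$frequency >= 1, , drop = FALSE]
  het <- truth[truth$frequency < 1, , drop = FALSE]
  background <- mutateTo(refChar, homo$position, homo$alt)

  mitoBase <- stoich@mitoCopiesPerCell * stoich@cells
  seqs <- character()
  info <- list()

  for (i in seq_len(nrow(panel@amplicons))) {
    amp <- panel@amplicons[i, ]
    covered <- if (nrow(het)) {
      off <- (het$position - amp$start) %% L
      which(off < amp$length)
    } else integer()
    fsum <- sum(het$frequency[covered])
    refW <- mitoBase * max(0, 1 - fsum)
    if (refW > 0) {
      seqs <- c(seqs, ampliconMolecule(background, 1L, amp, refChar, L, p))
      info[[length(info) + 1L]] <- data.frame(
        molecule_id = sprintf("amp%03d_bg", i), origin = "mito",
        weight = refW, mito_start = amp$start, mito_length = amp$length,
        fp5 = p, fp3 = p)
    }
    for (j in covered) {
      hap <- mutateTo(background, het$position[j], het$alt[j])
      seqs <- c(seqs, ampliconMolecule(hap, 1L, amp, refChar, L, p))
      info[[length(info) + 1L]] <- data.frame(
        molecule_id = sprintf("amp%03d_alt%d", i, het$position[j]),
        origin = "mito", weight = mitoBase * het$frequency[j],
        mito_start = amp$start, mito_length = amp$length, fp5 = p, fp3 = p)
    }
    for (ni in seq_len(nrow(world@numts))) {
      nu <- world@numts[ni, ]
      if (!numtCoamplified(world, nu$numt_id, i, panel,
                           maxPrimerMismatches)) next
      numtSeq <- numtMitoCopy(world, nu)
      seqs <- c(seqs, ampliconMolecule(numtSeq, nu$mito_start, amp,
                                       refChar, L, p))
      info[[length(info) + 1L]] <- data.frame(
        molecule_id = sprintf("amp%03d_%s", i, nu$numt_id),
        origin = nu$numt_id, weight = nu$copy_number * stoich@cells,
        mito_start = amp$start, mito_length = amp$length, fp5 = p, fp3 = p)
    }
  }

  info <- do.call(rbind, info)
  if (stoich@pcrJackpotSd > 0) {
    info$weight <- info$weight *
      withSeed(seed, stats::rlnorm(nrow(info), 0, stoich@pcrJackpotSd))
  }
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- info$molecule_id
  new("MoleculePool", sequences = ss, info = info)
}

# apply given alt alleles at given positions of a character sequence
mutateTo <- function(seqChar, positions, alts) {
  if (!length(positions)) return(seqChar)
  for (i in seq_along(positions))
    substr(seqChar, positions[i], positions[i]) <- alts[i]
  seqChar
}

#' Simulate multiple displacement amplification (MDA) fragments
#'
#' MDA amplifies everything in the tube. Each fragment's source (the mito
#' circle, or one of the NUMT-bearing nuclear contigs) is drawn with
#' probability proportional to copy-number-weighted source length; the start
#' is uniform on the source (mito fragments may wrap the origin) and the
#' length is `Normal(fragmentLengthMean, fragmentLengthSd)` truncated at
#' 100 bp. Mito fragments carry each covered sub-homoplasmic alternate allele
#' with its true frequency (homoplasmic variants always). At a mito site
#' covered by k diploid NUMT copies the expected NUMT-derived fraction of
#' templates is `2k / (C + 2k)`.
#'
#' @param world a [World-class].
#' @param stoich a [Stoichiometry-class].
#' @param fragmentLengthMean,fragmentLengthSd fragment length model in bp.
#' @param nFragments number of fragments to draw (>= 1).
#' @param seed integer seed.
#' @return a [MoleculePool-class].
#' @export
mdaFragments <- function(world, stoich, fragmentLengthMean = 500,
                         fragmentLengthSd = 150, nFragments = 100000L,
                         seed = NULL) {
  stopifnot(is(world, "World"), is(stoich, "Stoichiometry"))
  nFragments <- as.integer(nFragments)
  if (is.na(nFragments) || nFragments < 1L) stop("nFragments must be >= 1")
  L <- length(world@mito@sequence)
  truth <- world@truth
  refChar <- as.character(world@mito@sequence)

  contigs <- world@nuclearContigs
  contigLens <- if (length(contigs)) Biostrings::width(contigs) else integer()
  copy <- if (nrow(world@numts)) {
    world@numts$copy_number[match(names(contigs),
                                  world@numts$nuclear_contig)]
  } else integer()
  srcWeights <- c(stoich@mitoCopiesPerCell * stoich@cells * L,
                  copy * stoich@cells * contigLens)

  withSeed(seed, {
    src <- sample.int(length(srcWeights), nFragments, replace = TRUE,
                      prob = srcWeights)
    lens <- pmax(100L, as.integer(round(
      stats::rnorm(nFragments, fragmentLengthMean, fragmentLengthSd))))
    isMito <- src == 1L
    starts <- integer(nFragments)
    starts[isMito] <- sample.int(L, sum(isMito), replace = TRUE)
    seqs <- character(nFragments)

    if (any(isMito)) {
      doubled <- paste0(refChar, refChar)
      lens[isMito] <- pmin(lens[isMito], L)
      seqs[isMito] <- substring(doubled, starts[isMito],
                                starts[isMito] + lens[isMito] - 1L)
      # haplotype assignment: flip each covered truth allele by frequency
      mIdx <- which(isMito)
      for (t in seq_len(nrow(truth))) {
        off <- (truth$position[t] - starts[mIdx]) %% L
        cover <- off < lens[mIdx]
        hit <- cover & (stats::runif(length(mIdx)) < truth$frequency[t])
        w <- mIdx[hit]
        if (length(w)) {
          q <- off[hit] + 1L
          substr(seqs[w], q, q) <- truth$alt[t]
        }
      }
    }

    for (ci in seq_along(contigs)) {
      idx <- which(src == ci + 1L)
      if (!length(idx)) next
      cl <- contigLens[ci]
      # start uniform over the whole contig, fragments truncated at the end:
      # keeps per-base coverage proportional to copy-weighted length, so the
      # NUMT template fraction at an interior site converges to 2k/(C+2k)
      starts[idx] <- 1L + as.integer(floor(stats::runif(length(idx)) * cl))
      lens[idx] <- pmin(lens[idx], cl - starts[idx] + 1L)
      seqs[idx] <- substring(as.character(contigs[[ci]]), starts[idx],
                             starts[idx] + lens[idx] - 1L)
    }

    origin <- rep("mito", nFragments)
    mitoStart <- ifelse(isMito, starts, NA_integer_)
    mitoLen <- ifelse(isMito, lens, NA_integer_)
    if (length(contigs)) {
      nuByContig <- match(names(contigs), world@numts$nuclear_contig)
      for (ci in seq_along(contigs)) {
        idx <- which(src == ci + 1L)
        if (!length(idx)) next
        nu <- world@numts[nuByContig[ci], ]
        insStart <- nu$nuclear_offset
        insEnd <- nu$nuclear_offset + nu$length - 1L
        fragEnd <- starts[idx] + lens[idx] - 1L
        overlaps <- starts[idx] <= insEnd & fragEnd >= insStart
        origin[idx] <- ifelse(overlaps, nu$numt_id,
                              paste0(nu$numt_id, "_flank"))
        inside <- starts[idx] >= insStart & fragEnd <= insEnd
        if (any(inside)) {
          w <- idx[inside]
          offIns <- starts[w] - insStart  # offset within the insert
          if (nu$strand == "+") {
            mitoStart[w] <- ((nu$mito_start - 1L + offIns) %% L) + 1L
          } else {
            mitoStart[w] <- ((nu$mito_start - 1L + nu$length -
                                (offIns + lens[w])) %% L) + 1L
          }
          mitoLen[w] <- lens[w]
        }
      }
    }

    weight <- if (stoich@pcrJackpotSd > 0) {
      stats::rlnorm(nFragments, 0, stoich@pcrJackpotSd)
    } else rep(1, nFragments)

    info <- data.frame(
      molecule_id = sprintf("frag%07d", seq_len(nFragments)),
      origin = origin, weight = weight,
      mito_start = as.integer(mitoStart), mito_length = as.integer(mitoLen),
      fp5 = 0L, fp3 = 0L)
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- info$molecule_id
    new("MoleculePool", sequences = ss, info = info)
  })
}

#' @describeIn amplify accessor for the molecule metadata table.
#' @param pool a [MoleculePool-class].
#' @export
poolInfo <- function(pool) pool@info

#' @describeIn amplify accessor for the molecule sequences.
#' @export
poolSequences <- function(pool) pool@sequences

#' Write a molecule pool as FASTA plus a sidecar TSV
#'
#' @param pool a [MoleculePool-class].
#' @param fastaPath,tsvPath output paths.
#' @export
writePool <- function(pool, fastaPath, tsvPath) {
  Biostrings::writeXStringSet(pool@sequences, fastaPath, width = 80L)
  utils::write.table(pool@info, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fastaPath, tsvPath))
}
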