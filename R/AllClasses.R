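#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib numtshadow, .registration = TRUE
NULL

#' MitoReference: a circular mitochondrial reference sequence
#'
#' Holds the mtDNA reference against which reads are mapped and variants are
#' reported. The human rCRS is 16,569 bp; synthetic stand-ins default to the
#' same length. The sequence is always treated as circular.
#'
#' @slot name contig name used in alignments and variant output.
#' @slot sequence a [Biostrings::DNAString] over A/C/G/T.
#' @slot circular logical flag; always `TRUE` for mtDNA.
#'
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @exportClass MitoReference
setClass("MitoReference",
  slots = c(name = "character", sequence = "DNAString", circular = "logical"),
  prototype = prototype(name = "chrM", circular = TRUE)
)

setValidity("MitoReference", function(object) {
  msg <- character()
  if (length(object@sequence) < 1000L)
    msg <- c(msg, "mito reference must be at least 1,000 bp")
  freq <- Biostrings::alphabetFrequency(object@sequence)
  if (sum(freq[c("A", "C", "G", "T")]) != length(object@sequence))
    msg <- c(msg, "sequence must contain only A/C/G/T")
  if (!isTRUE(object@circular))
    msg <- c(msg, "mtDNA reference must be circular")
  if (length(msg)) msg else TRUE
})

#' World: complete synthetic ground truth
#'
#' A `World` bundles everything the downstream pipeline consumes: the circular
#' mito reference, the heteroplasmy truth table (1-based positions, ref/alt
#' alleles, true minor-allele fractions; frequency 1 encodes a homoplasmic
#' variant), the NUMT registry (one nuclear-inserted divergent copy of a mito
#' interval per record, with realized similarity), and the NUMT-bearing
#' nuclear contigs.
#'
#' @slot mito a [MitoReference-class].
#' @slot truth data.frame with columns `position`, `ref`, `alt`, `frequency`.
#' @slot numts data.frame with columns `numt_id`, `mito_start`, `length`,
#'   `strand`, `similarity`, `n_mismatch`, `copy_number`, `nuclear_contig`,
#'   `nuclear_offset`. Intervals are 1-based and may wrap the origin;
#'   arithmetic is modulo the mito length.
#' @slot nuclearContigs [Biostrings::DNAStringSet] of NUMT-bearing contigs.
#' @slot seed integer seed the world was generated from (`NA` if assembled
#'   by hand).
#'
#' @exportClass World
setClass("World",
  slots = c(mito = "MitoReference", truth = "data.frame",
            numts = "data.frame", nuclearContigs = "DNAStringSet",
            seed = "integer"),
  prototype = prototype(seed = NA_integer_)
)

setValidity("World", function(object) {
  msg <- character()
  L <- length(object@mito@sequence)
  tr <- object@truth
  need <- c("position", "ref", "alt", "frequency")
  if (!all(need %in% names(tr))) {
    msg <- c(msg, "truth table lacks required columns")
  } else if (nrow(tr)) {
    if (anyDuplicated(tr$position))
      msg <- c(msg, "duplicate heteroplasmy positions")
    if (any(tr$position < 1L | tr$position > L))
      msg <- c(msg, "heteroplasmy position outside mito reference")
    if (any(tr$frequency <= 0 | tr$frequency > 1))
      msg <- c(msg, "heteroplasmy frequencies must be in (0, 1]")
    refbases <- strsplit(as.character(object@mito@sequence), "")[[1]]
    if (any(tr$ref != refbases[tr$position]))
      msg <- c(msg, "truth ref allele disagrees with reference base")
    if (any(tr$alt == tr$ref))
      msg <- c(msg, "alt allele equals reference base")
  }
  nu <- object@numts
  if (nrow(nu)) {
    if (!all(nu$nuclear_contig %in% names(object@nuclearContigs)))
      msg <- c(msg, "NUMT registry names a missing nuclear contig")
    if (any(nu$similarity <= 0 | nu$similarity >= 1))
      msg <- c(msg, "NUMT similarity must be in (0, 1)")
    if (any(nu$copy_number < 1L))
      msg <- c(msg, "NUMT copy number must be >= 1")
    if (any(nu$length < 1L | nu$length > L))
      msg <- c(msg, "NUMT length outside [1, L]")
  }
  if (length(msg)) msg else TRUE
})

#' AmpliconPanel: circular tiling of PCR amplicons over the mito genome
#'
#' Amplicons are stored as (start, length) on the circular mito coordinate
#' system (1-based; intervals may wrap the origin). The terminal
#' `primerLength` bases at each amplicon end are the primer footprints:
#' primer-derived sequence that copies the reference, not the template.
#'
#' @slot amplicons data.frame with columns `amplicon`, `start`, `length`.
#' @slot primerLength primer footprint size in bp.
#' @slot minOverlap minimum overlap between adjacent amplicons in bp.
#' @slot mitoLength length of the circle being tiled.
#'
#' @exportClass AmpliconPanel
setClass("AmpliconPanel",
  slots = c(amplicons = "data.frame", primerLength = "integer",
            minOverlap = "integer", mitoLength = "integer")
)

#' Stoichiometry: template copy numbers and PCR jackpot noise
#'
#' Captures the mito:nuclear template ratio that bounds the expected NUMT
#' read fraction, plus a lognormal per-template amplification ("jackpot")
#' noise term standing in for low-template PCR stochasticity.
#'
#' @slot mitoCopiesPerCell mtDNA copies per cell (C).
#' @slot nuclearCopies nuclear copies per cell (2 for diploid).
#' @slot cells number of input cells.
#' @slot pcrJackpotSd lognormal sigma of per-template amplification noise
#'   (0 disables it).
#'
#' @exportClass Stoichiometry
setClass("Stoichiometry",
  slots = c(mitoCopiesPerCell = "numeric", nuclearCopies = "numeric",
            cells = "numeric", pcrJackpotSd = "numeric")
)

setValidity("Stoichiometry", function(object) {
  msg <- character()
  if (object@mitoCopiesPerCell < 1) msg <- c(msg, "mitoCopiesPerCell must be >= 1")
  if (object@cells < 1) msg <- c(msg, "cells must be >= 1")
  if (object@pcrJackpotSd < 0) msg <- c(msg, "pcrJackpotSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' MoleculePool: enriched template molecules with origin labels
#'
#' The output of an enrichment simulation. Each molecule carries its origin
#' (`"mito"` or a NUMT id), a relative template abundance (`weight`), its
#' projected interval on the mito circle when one exists, and the lengths of
#' primer-derived footprints at its two ends (0 for MDA fragments).
#'
#' @slot sequences [Biostrings::DNAStringSet] of template molecules, in mito
#'   forward orientation for amplicons and source orientation for fragments.
#' @slot info data.frame with columns `molecule_id`, `origin`, `weight`,
#'   `mito_start`, `mito_length` (NA when no mito projection), `fp5`, `fp3`.
#'
#' @exportClass MoleculePool
setClass("MoleculePool",
  slots = c(sequences = "DNAStringSet", info = "data.frame")
)

setValidity("MoleculePool", function(object) {
  msg <- character()
  if (length(object@sequences) != nrow(object@info))
    msg <- c(msg, "info rows must match sequences")
  if (nrow(object@info) && any(object@info$weight <= 0))
    msg <- c(msg, "molecule weights must be positive")
  if (length(msg)) msg else TRUE
})

#' ReadSet: simulated reads with full provenance
#'
#' Reads are stored with a provenance table mapping every read back to its
#' source molecule, offset, strand and footprint geometry; the provenance is
#' what makes oracle checks (and provenance-based primer trimming) possible.
#'
#' @slot sequences named character vector of read sequences (names = read ids).
#' @slot provenance data.frame with columns `read_id`, `molecule_id`,
#'   `origin`, `offset`, `length`, `strand`, `truncated`, `mol_length`,
#'   `fp5`, `fp3`.
#' @slot quality single quality character used for every base (constant
#'   quality model).
#'
#' @exportClass ReadSet
setClass("ReadSet",
  slots = c(sequences = "character", provenance = "data.frame",
            quality = "character"),
  prototype = prototype(quality = "?")
)

setValidity("ReadSet", function(object) {
  if (length(object@sequences) != nrow(object@provenance))
    return("provenance must cover every read")
  TRUE
})

#' ReferenceIndex: contig set prepared for k-mer seed mapping
#'
#' A lightweight handle holding the contigs, the seed k-mer size and the
#' circularity flags; the k-mer table itself is built in compiled code when
#' reads are mapped. The mito contig is wrap-extended at query time so that
#' reads spanning the origin map at their true (modulo-L) position.
#'
#' @slot contigs named character vector of contig sequences.
#' @slot circular logical vector flagging circular contigs.
#' @slot k seed k-mer size (11..31).
#'
#' @exportClass ReferenceIndex
setClass("ReferenceIndex",
  slots = c(contigs = "character", circular = "logical", k = "integer")
)

setValidity("ReferenceIndex", function(object) {
  msg <- character()
  if (object@k < 11L || object@k > 31L)
    msg <- c(msg, "k must be in [11, 31]")
  if (any(nchar(object@contigs) < object@k))
    msg <- c(msg, "contig shorter than k")
  if (is.null(names(object@contigs)) || any(names(object@contigs) == ""))
    msg <- c(msg, "contigs must be named")
  if (length(msg)) msg else TRUE
})

#' ComparisonSummary: per-condition discrepancy tally
#'
#' Counts of the four concordance classes over the union of variants called
#' under the two reference modes, with the absolute frequency-difference
#' threshold (percentage points) that separates concordant from discrepant.
#'
#' @slot nUnion number of distinct (position, alt) variants across both modes.
#' @slot nConcordant,nDiscrepant,nExclusiveRcrs,nExclusiveCombined class counts.
#' @slot pctConcordant percentage of the union that is concordant.
#' @slot thresholdPp concordance threshold in percentage points.
#'
#' @exportClass ComparisonSummary
setClass("ComparisonSummary",
  slots = c(nUnion = "integer", nConcordant = "integer",
            nDiscrepant = "integer", nExclusiveRcrs = "integer",
            nExclusiveCombined = "integer", pctConcordant = "numeric",
            thresholdPp = "numeric")
)

setValidity("ComparisonSummary", function(object) {
  tot <- object@nConcordant + object@nDiscrepant +
    object@nExclusiveRcrs + object@nExclusiveCombined
  if (tot != object@nUnion) "class counts must sum to the union count" else TRUE
})

setMethod("show", "MitoReference", function(object) {
  cat("MitoReference '", object@name, "': ", length(object@sequence),
      " bp, circular\n", sep = "")
})

setMethod("show", "World", function(object) {
  cat("World: mito", length(object@mito@sequence), "bp |",
      nrow(object@truth), "truth sites |",
      nrow(object@numts), "NUMTs in",
      length(object@nuclearContigs), "nuclear contigs\n")
  if (nrow(object@numts))
    cat("  NUMT similarity: mean", round(mean(object@numts$similarity), 3),
        "sd", round(stats::sd(object@numts$similarity), 3), "\n")
})

setMethod("show", "AmpliconPanel", function(object) {
  cat("AmpliconPanel:", nrow(object@amplicons), "amplicons tiling",
      object@mitoLength, "bp circle | primer", object@primerLength,
      "bp | min overlap", object@minOverlap, "bp\n")
})

setMethod("show", "Stoichiometry", function(object) {
  cat("Stoichiometry: C =", object@mitoCopiesPerCell,
      "mito copies/cell |", object@nuclearCopies, "nuclear copies |",
      object@cells, "cells | jackpot sd", object@pcrJackpotSd, "\n")
})

setMethod("show", "MoleculePool", function(object) {
  nNumt <- sum(object@info$origin != "mito")
  cat("MoleculePool:", nrow(object@info), "molecules (",
      nrow(object@info) - nNumt, "mito /", nNumt, "nuclear-derived )\n")
})

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet:", length(object@sequences), "reads\n")
})

setMethod("show", "ReferenceIndex", function(object) {
  cat("ReferenceIndex:", length(object@contigs), "contigs, k =",
      object@k, "\n")
})

setMethod("show", "ComparisonSummary", function(object) {
  cat("ComparisonSummary (threshold ", object@thresholdPp, " pp): ",
      object@nUnion, " variants | ", object@nConcordant, " concordant (",
      round(object@pctConcordant, 1), "%) | ", object@nDiscrepant,
      " discrepant | ", object@nExclusiveRcrs, " rCRS-only | ",
      object@nExclusiveCombined, " combined-only\n", sep = "")
})
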