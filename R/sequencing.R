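#' Simulate single-end reads from a molecule pool
#'
#' Molecules are sampled proportionally to their weights; the read start is
#' uniform on the molecule and the strand uniform. Each base is substituted
#' independently with probability `errorRate`, except bases originating from
#' a primer footprint, which use `primerErrorRate` — an amplicon-end artefact
#' rate standing in for oligo synthesis errors and mispriming (0 for MDA
#' fragments, which have no footprints). Reads longer than their molecule are
#' truncated to the molecule length and flagged. Qualities are a constant
#' Q30 symbol; downstream calling is count-based.
#'
#' @param pool a [MoleculePool-class].
#' @param readLength read length in bp (>= 36).
#' @param totalReads number of reads to draw.
#' @param errorRate per-base substitution probability, in `[0, 0.1)`.
#' @param primerErrorRate per-base substitution probability for
#'   primer-footprint bases.
#' @param seed integer seed.
#' @return a [ReadSet-class].
#' @export
sequenceReads <- function(pool, readLength = 150L, totalReads = 100000L,
                          errorRate = 0.002, primerErrorRate = 0.02,
                          seed = NULL) {
  stopifnot(is(pool, "MoleculePool"))
  if (!nrow(pool@info)) stop("cannot sequence an empty molecule pool")
  readLength <- as.integer(readLength)
  if (readLength < 36L) stop("readLength must be >= 36")
  if (errorRate < 0 || errorRate >= 0.1)
    stop("errorRate must be in [0, 0.1)")
  totalReads <- as.integer(totalReads)

  molChar <- as.character(pool@sequences)
  molLens <- nchar(molChar)
  info <- pool@info

  withSeed(seed, {
    mi <- sample.int(length(molChar), totalReads, replace = TRUE,
                     prob = info$weight)
    ml <- molLens[mi]
    span <- pmax(1L, ml - readLength + 1L)
    offset <- 1L + as.integer(floor(stats::runif(totalReads) * span))
    len <- pmin(readLength, ml - offset + 1L)
    truncated <- len < readLength
    strand <- sample(c("+", "-"), totalReads, replace = TRUE)

    seqs <- substring(molChar[mi], offset, offset + len - 1L)

    # error injection in molecule orientation: footprint overlap at read ends
    fp5 <- info$fp5[mi]
    fp3 <- info$fp3[mi]
    t5 <- pmin(pmax(0L, fp5 - offset + 1L), len)
    t3 <- pmin(pmax(0L, (offset + len - 1L) - (ml - fp3)), len)
    if (errorRate > 0 || any(t5 > 0L) || any(t3 > 0L)) {
      seqs <- as.character(cpp_mutate_bases(seqs, t5, t3, errorRate,
                                            primerErrorRate))
    }
    neg <- strand == "-"
    if (any(neg)) seqs[neg] <- revCompChar(seqs[neg])

    ids <- sprintf("read%08d", seq_len(totalReads))
    names(seqs) <- ids
    prov <- data.frame(
      read_id = ids, molecule_id = info$molecule_id[mi],
      origin = info$origin[mi], offset = offset, length = len,
      strand = strand, truncated = truncated, mol_length = ml,
      fp5 = fp5, fp3 = fp3)
    new("ReadSet", sequences = seqs, provenance = prov, quality = "?")
  })
}

#' Trim primer-derived bases from reads
#'
#' Uses the provenance to remove, from each read end, the bases that
#' originate from a primer footprint of the source molecule (the terminal
#' `fp5`/`fp3` bases of the molecule). Reads wholly interior to the molecule
#' body are unchanged; reads from pools without footprints (MDA) are
#' returned as-is.
#'
#' @param reads a [ReadSet-class].
#' @param panel an [AmpliconPanel-class] (its primer length is recorded in
#'   the provenance already; accepted for interface symmetry and checked).
#' @return a trimmed [ReadSet-class] (reads trimmed to zero length are
#'   dropped).
#' @export
trimPrimers <- function(reads, panel = NULL) {
  stopifnot(is(reads, "ReadSet"))
  pr <- reads@provenance
  if (!nrow(pr)) return(reads)
  if (!is.null(panel) && !is(panel, "AmpliconPanel"))
    stop("panel must be an AmpliconPanel")
  t5 <- pmin(pmax(0L, pr$fp5 - pr$offset + 1L), pr$length)
  t3 <- pmin(pmax(0L, (pr$offset + pr$length - 1L) -
                    (pr$mol_length - pr$fp3)), pr$length)
  over <- t5 + t3 > pr$length  # read entirely primer-derived
  t5 <- ifelse(over, pr$length, t5)
  t3 <- ifelse(over, 0L, t3)

  seqs <- reads@sequences
  pos <- pr$strand == "+"
  # molecule-left trim is the read start on '+', the read end on '-'
  from <- ifelse(pos, t5 + 1L, t3 + 1L)
  to <- pr$length - ifelse(pos, t3, t5)
  newLen <- pmax(0L, to - from + 1L)
  seqs <- substring(seqs, from, to)

  keep <- newLen > 0L
  pr$offset <- pr$offset + t5
  pr$length <- newLen
  pr$fp5 <- 0L
  pr$fp3 <- 0L
  pr <- pr[keep, , drop = FALSE]
  seqs <- seqs[keep]
  names(seqs) <- pr$read_id
  new("ReadSet", sequences = seqs, provenance = pr, quality = reads@quality)
}

#' @describeIn sequenceReads accessor for the read sequences.
#' @param reads a [ReadSet-class].
#' @export
readSequences <- function(reads) reads@sequences

#' @describeIn sequenceReads accessor for the provenance table.
#' @export
readProvenance <- function(reads) reads@provenance

#' Write reads as FASTQ (constant-quality model)
#'
#' @param reads a [ReadSet-class].
#' @param path output FASTQ path (uncompressed).
#' @export
writeReadsFastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads@sequences)
  quals <- Biostrings::BStringSet(strrep(reads@quality,
                                         Biostrings::width(ss)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a ReadSet (no provenance)
#'
#' @param path FASTQ path.
#' @return a [ReadSet-class] with an empty-provenance placeholder table
#'   (user-supplied reads carry no simulation provenance).
#' @export
readReadsFastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- as.character(ss)
  ids <- sub("\\s.*$", "", names(ss))
  names(seqs) <- ids
  n <- length(seqs)
  prov <- data.frame(
    read_id = ids, molecule_id = NA_character_, origin = NA_character_,
    offset = NA_integer_, length = nchar(seqs), strand = NA_character_,
    truncated = NA, mol_length = NA_integer_, fp5 = 0L, fp3 = 0L)
  new("ReadSet", sequences = seqs, provenance = prov, quality = "?")
}
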