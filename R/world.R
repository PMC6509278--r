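#' Generate a random circular mitochondrial reference
#'
#' Produces a uniform-random A/C/G/T sequence standing in for the rCRS; a real
#' mtDNA FASTA can be loaded with [loadMitoReference()] instead. The default
#' length is the rCRS length, 16,569 bp.
#'
#' @param length reference length in bp (>= 1,000).
#' @param seed integer seed; identical seeds give identical sequences.
#' @param name contig name (default `"chrM"`).
#' @return a [MitoReference-class].
#' @examples
#' mito <- generateMitoReference(2000, seed = 1)
#' @export
generateMitoReference <- function(length = 16569L, seed = NULL, name = "chrM") {
  length <- as.integer(length)
  if (is.na(length) || length < 1000L)
    stop("mito reference length must be at least 1,000 bp")
  seqc <- withSeed(seed, randomDnaString(length))
  new("MitoReference", name = name,
      sequence = Biostrings::DNAString(seqc), circular = TRUE)
}

#' Load a mitochondrial reference from a FASTA file
#'
#' @param path FASTA file with a single mtDNA record.
#' @param name contig name to use (defaults to the FASTA record name).
#' @return a [MitoReference-class].
#' @export
loadMitoReference <- function(path, name = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stop("expected exactly one FASTA record")
  nm <- if (is.null(name)) sub("\\s.*$", "", names(ss)[1]) else name
  new("MitoReference", name = nm, sequence = ss[[1]], circular = TRUE)
}

#' Plant heteroplasmic (and homoplasmic) variants
#'
#' Validates a specification of true mitochondrial variants against the
#' reference and returns the truth table used throughout the pipeline.
#' A frequency of 1 encodes a homoplasmic variant; anything in (0, 1)
#' is heteroplasmic.
#'
#' @param mito a [MitoReference-class].
#' @param sites data.frame with columns `position` (1-based), `alt`
#'   and `frequency`.
#' @return data.frame with columns `position`, `ref`, `alt`, `frequency`.
#' @examples
#' mito <- generateMitoReference(2000, seed = 1)
#' plantHeteroplasmy(mito, data.frame(position = 100, alt = "A",
#'                                    frequency = 0.03))
#' @export
plantHeteroplasmy <- function(mito, sites) {
  stopifnot(is(mito, "MitoReference"))
  if (!nrow(sites)) {
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), frequency = numeric()))
  }
  L <- length(mito@sequence)
  pos <- as.integer(sites$position)
  if (any(is.na(pos) | pos < 1L | pos > L))
    stop("heteroplasmy position outside the reference")
  if (anyDuplicated(pos))
    stop("duplicate heteroplasmy positions")
  if (any(sites$frequency <= 0 | sites$frequency > 1))
    stop("frequencies must be in (0, 1]")
  refbases <- strsplit(as.character(mito@sequence), "")[[1]][pos]
  alt <- toupper(as.character(sites$alt))
  if (any(!alt %in% DNA_BASES))
    stop("alt alleles must be A/C/G/T")
  if (any(alt == refbases))
    stop("alt allele equals the reference base")
  ord <- order(pos)
  data.frame(position = pos, ref = refbases, alt = alt,
             frequency = as.numeric(sites$frequency))[ord, , drop = FALSE]
}

# mutatePositions alternative: sample alt alleles for random truth sites
randomTruth <- function(mito, nHet = 10L, nHomo = 20L,
                        freqRange = c(0.01, 0.5)) {
  L <- length(mito@sequence)
  n <- nHet + nHomo
  if (n == 0L) return(plantHeteroplasmy(mito, data.frame()))
  pos <- sample.int(L, n)
  refbases <- strsplit(as.character(mito@sequence), "")[[1]][pos]
  alt <- vapply(refbases, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  freq <- c(exp(stats::runif(nHet, log(freqRange[1]), log(freqRange[2]))),
            rep(1, nHomo))
  plantHeteroplasmy(mito, data.frame(position = pos, alt = alt,
                                     frequency = freq))
}

#' Generate NUMTs: divergent nuclear copies of mito intervals
#'
#' Each NUMT copies a random interval of the mito circle (wrapping the origin
#' is allowed), substitutes each base independently with probability
#' `1 - s` where `s ~ Normal(similarityMean, similaritySd)` truncated to
#' `[0.70, 0.995]`, optionally reverse-complements it, and embeds it in a
#' fresh random nuclear contig with `flankLength` random bases on each side
#' (one contig per NUMT). NUMT lengths are uniform over `sizeRange`. The
#' registry records the mito projection and the realized per-copy similarity.
#'
#' Defaults follow the reported human NUMT landscape: ~750 NUMTs per
#' individual, sizes ~100-6,000 bp, NUMT/mtDNA similarity ~86% with 4.1% SD.
#'
#' @param mito a [MitoReference-class].
#' @param count number of NUMTs (>= 0).
#' @param sizeRange length range in bp, within `[50, L]`.
#' @param similarityMean,similaritySd parameters of the per-NUMT similarity
#'   distribution.
#' @param flankLength random nuclear flank on each side of the insert, bp.
#' @param copyNumber copies per NUMT locus (2 = diploid).
#' @param region optional `c(start, end)` restricting NUMT placement to a
#'   non-wrapping mito interval (used to build positionally clustered worlds).
#' @param seed integer seed.
#' @return list with `numts` (registry data.frame) and `contigs`
#'   ([Biostrings::DNAStringSet]).
#' @export
generateNumts <- function(mito, count = 750L, sizeRange = c(100L, 6000L),
                          similarityMean = 0.86, similaritySd = 0.041,
                          flankLength = 2000L, copyNumber = 2L,
                          region = NULL, seed = NULL) {
  stopifnot(is(mito, "MitoReference"))
  count <- as.integer(count)
  if (is.na(count) || count < 0L) stop("count must be >= 0")
  L <- length(mito@sequence)
  if (sizeRange[1] > sizeRange[2]) stop("sizeRange is inverted")
  if (count > 0L && (sizeRange[1] < 50L || sizeRange[2] > L))
    stop("sizeRange must lie within [50, L]")
  if (similarityMean <= 0 || similarityMean >= 1)
    stop("similarityMean must be in (0, 1)")

  emptyReg <- data.frame(
    numt_id = character(), mito_start = integer(), length = integer(),
    strand = character(), similarity = numeric(), n_mismatch = integer(),
    copy_number = integer(), nuclear_contig = character(),
    nuclear_offset = integer())
  if (count == 0L)
    return(list(numts = emptyReg, contigs = Biostrings::DNAStringSet()))

  mitoChar <- as.character(mito@sequence)
  withSeed(seed, {
    lens <- sizeRange[1] +
      sample.int(sizeRange[2] - sizeRange[1] + 1L, count, replace = TRUE) - 1L
    if (is.null(region)) {
      starts <- sample.int(L, count, replace = TRUE)
    } else {
      region <- as.integer(region)
      stopifnot(region[1] >= 1L, region[2] <= L, region[1] < region[2])
      lens <- pmin(lens, region[2] - region[1] + 1L)
      starts <- region[1] + vapply(lens, function(len)
        sample.int(region[2] - len + 1L - region[1] + 1L, 1L),
        integer(1)) - 1L
    }
    sims <- rtruncNorm(count, similarityMean, similaritySd, 0.70, 0.995)
    strands <- sample(c("+", "-"), count, replace = TRUE)

    contigSeqs <- character(count)
    nMis <- integer(count)
    realSim <- numeric(count)
    for (i in seq_len(count)) {
      src <- subCircular(mitoChar, starts[i], lens[i], L)
      hits <- which(stats::runif(lens[i]) < (1 - sims[i]))
      mut <- mutatePositions(src, hits)
      nMis[i] <- length(hits)
      realSim[i] <- 1 - nMis[i] / lens[i]
      ins <- if (strands[i] == "-") revCompChar(mut) else mut
      contigSeqs[i] <- paste0(randomDnaString(flankLength), ins,
                              randomDnaString(flankLength))
    }
    ids <- sprintf("numt_%03d", seq_len(count))
    contigNames <- paste0(ids, "_ctg")
    reg <- data.frame(
      numt_id = ids, mito_start = as.integer(starts),
      length = as.integer(lens), strand = strands,
      similarity = realSim, n_mismatch = nMis,
      copy_number = as.integer(copyNumber),
      nuclear_contig = contigNames,
      nuclear_offset = as.integer(flankLength + 1L))
    contigs <- Biostrings::DNAStringSet(contigSeqs)
    names(contigs) <- contigNames
    list(numts = reg, contigs = contigs)
  })
}

#' Assemble a complete synthetic world
#'
#' One-stop constructor: mito reference, planted heteroplasmies (explicit via
#' `truthSites`, or randomly drawn), and NUMT-bearing nuclear contigs. All
#' stage seeds are derived from `seed` and recorded.
#'
#' @param mitoLength mito reference length in bp.
#' @param numtCount number of NUMTs (~750 emulates a human individual).
#' @param sizeRange,similarityMean,similaritySd,flankLength,copyNumber,region
#'   passed to [generateNumts()].
#' @param truthSites optional data.frame for [plantHeteroplasmy()]; if `NULL`,
#'   `nHet` heteroplasmic sites (log-uniform frequencies in `freqRange`) and
#'   `nHomo` homoplasmic variants are planted at random positions.
#' @param nHet,nHomo,freqRange random truth parameters.
#' @param seed master integer seed.
#' @return a [World-class].
#' @export
makeWorld <- function(mitoLength = 16569L, numtCount = 750L,
                      sizeRange = c(100L, 6000L), similarityMean = 0.86,
                      similaritySd = 0.041, flankLength = 2000L,
                      copyNumber = 2L, region = NULL, truthSites = NULL,
                      nHet = 10L, nHomo = 20L, freqRange = c(0.01, 0.5),
                      seed = 1L) {
  seeds <- stageSeeds(seed, 3L)
  mito <- generateMitoReference(mitoLength, seed = seeds[1])
  truth <- if (is.null(truthSites)) {
    withSeed(seeds[2], randomTruth(mito, nHet, nHomo, freqRange))
  } else {
    plantHeteroplasmy(mito, truthSites)
  }
  ng <- generateNumts(mito, count = numtCount, sizeRange = sizeRange,
                      similarityMean = similarityMean,
                      similaritySd = similaritySd, flankLength = flankLength,
                      copyNumber = copyNumber, region = region,
                      seed = seeds[3])
  new("World", mito = mito, truth = truth, numts = ng$numts,
      nuclearContigs = ng$contigs, seed = as.integer(seed))
}

#' Mito-coordinate positions where a NUMT diverges from the reference
#'
#' Recomputed on demand by comparing the embedded NUMT copy against its mito
#' source interval; these are the positions at which NUMT-derived reads show
#' non-reference alleles when forced onto the mito reference.
#'
#' @param world a [World-class].
#' @param numtId a `numt_id` from the registry.
#' @return sorted integer vector of 1-based mito positions.
#' @export
numtMismatchPositions <- function(world, numtId) {
  nu <- world@numts[world@numts$numt_id == numtId, ]
  if (nrow(nu) != 1L) stop("unknown numt_id: ", numtId)
  L <- length(world@mito@sequence)
  src <- subCircular(as.character(world@mito@sequence),
                     nu$mito_start, nu$length, L)
  ins <- substr(as.character(world@nuclearContigs[[nu$nuclear_contig]]),
                nu$nuclear_offset, nu$nuclear_offset + nu$length - 1L)
  if (nu$strand == "-") ins <- revCompChar(ins)
  a <- strsplit(src, "")[[1]]
  b <- strsplit(ins, "")[[1]]
  off <- which(a != b)
  sort(circularPositions(nu$mito_start, nu$length, L)[off])
}

# NUMT sequence in mito-forward orientation plus its mito interval
numtMitoCopy <- function(world, numtRow) {
  ins <- substr(as.character(world@nuclearContigs[[numtRow$nuclear_contig]]),
                numtRow$nuclear_offset,
                numtRow$nuclear_offset + numtRow$length - 1L)
  if (numtRow$strand == "-") ins <- revCompChar(ins)
  ins
}

#' Write a world to disk as plain-text reference files
#'
#' Writes the mito FASTA, the multi-contig nuclear FASTA, the NUMT registry
#' (full fields, TSV), the NUMT mito projections as BED (0-based half-open;
#' NUMTs wrapping the origin are split into two intervals; score =
#' `round(1000 * similarity)`), the heteroplasmy truth TSV (1-based `POS`,
#' `REF`, `ALT`, `FREQ`) and a JSON metadata file recording the seed.
#' [readWorld()] reconstructs an identical [World-class] from the directory.
#'
#' @param world a [World-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths written.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  L <- length(world@mito@sequence)

  paths <- c(mito = file.path(dir, "mito.fasta"),
             nuclear = file.path(dir, "nuclear.fasta"),
             registry = file.path(dir, "numt_registry.tsv"),
             bed = file.path(dir, "numt_projection.bed"),
             truth = file.path(dir, "heteroplasmy_truth.tsv"),
             meta = file.path(dir, "world_meta.json"))

  mitoSet <- Biostrings::DNAStringSet(as.character(world@mito@sequence))
  names(mitoSet) <- world@mito@name
  Biostrings::writeXStringSet(mitoSet, paths["mito"], width = 80L)
  Biostrings::writeXStringSet(world@nuclearContigs, paths["nuclear"],
                              width = 80L)

  utils::write.table(world@numts, paths["registry"], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  bed <- do.call(rbind, lapply(seq_len(nrow(world@numts)), function(i) {
    nu <- world@numts[i, ]
    score <- round(1000 * nu$similarity)
    end <- nu$mito_start + nu$length - 1L
    if (end <= L) {
      data.frame(chrom = world@mito@name, start = nu$mito_start - 1L,
                 end = end, name = nu$numt_id, score = score,
                 strand = nu$strand)
    } else {  # wraps the origin: split into two half-open intervals
      data.frame(chrom = world@mito@name,
                 start = c(nu$mito_start - 1L, 0L),
                 end = c(L, end - L), name = nu$numt_id, score = score,
                 strand = nu$strand)
    }
  }))
  if (is.null(bed))
    bed <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = integer(), strand = character())
  utils::write.table(bed, paths["bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  truth <- data.frame(POS = world@truth$position, REF = world@truth$ref,
                      ALT = world@truth$alt, FREQ = world@truth$frequency)
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  meta <- list(mito_name = world@mito@name, mito_length = L,
               circular = TRUE, seed = world@seed)
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a world back from a directory written by [writeWorld()]
#'
#' @param dir directory containing the world files.
#' @return a [World-class]; sequences, registry and truth round-trip
#'   losslessly (similarity is reconstituted exactly from `n_mismatch`).
#' @export
readWorld <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "world_meta.json"),
                              simplifyVector = TRUE)
  mito <- loadMitoReference(file.path(dir, "mito.fasta"),
                            name = meta$mito_name)
  contigs <- Biostrings::readDNAStringSet(file.path(dir, "nuclear.fasta"))
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  reg <- utils::read.delim(file.path(dir, "numt_registry.tsv"),
                           stringsAsFactors = FALSE)
  if (nrow(reg)) {
    reg$similarity <- 1 - reg$n_mismatch / reg$length  # exact round trip
  } else {
    reg <- data.frame(
      numt_id = character(), mito_start = integer(), length = integer(),
      strand = character(), similarity = numeric(), n_mismatch = integer(),
      copy_number = integer(), nuclear_contig = character(),
      nuclear_offset = integer())
  }
  tr <- utils::read.delim(file.path(dir, "heteroplasmy_truth.tsv"),
                          stringsAsFactors = FALSE,
                          colClasses = c("integer", "character",
                                         "character", "numeric"))
  truth <- data.frame(position = tr$POS, ref = tr$REF, alt = tr$ALT,
                      frequency = tr$FREQ)
  new("World", mito = mito, truth = truth, numts = reg,
      nuclearContigs = contigs,
      seed = if (is.null(meta$seed)) NA_integer_ else as.integer(meta$seed))
}

#' @describeIn makeWorld accessor for the truth table.
#' @param world a [World-class].
#' @export
worldTruth <- function(world) world@truth

#' @describeIn makeWorld accessor for the NUMT registry.
#' @export
worldNumts <- function(world) world@numts

#' @describeIn makeWorld accessor for the nuclear contigs.
#' @export
nuclearContigs <- function(world) world@nuclearContigs

#' @describeIn makeWorld accessor for the mito reference.
#' @export
worldMito <- function(world) world@mito

#' @describeIn makeWorld mito reference length in bp.
#' @param mito a [MitoReference-class].
#' @export
mitoLength <- function(mito) length(mito@sequence)

#' @describeIn makeWorld mito reference sequence as a character scalar.
#' @export
mitoSequence <- function(mito) as.character(mito@sequence)
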