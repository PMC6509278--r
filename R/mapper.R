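#' Build a reference index for k-mer seed mapping
#'
#' Prepares a contig set for the ungapped seed-and-extend mapper. The index
#' is a handle (contigs + k); the exact k-mer table is constructed in
#' compiled code when reads are mapped. Circular contigs (the mito
#' reference) are wrap-extended at query time so reads spanning the origin
#' map at their true position modulo L.
#'
#' @param references a [MitoReference-class], a named character vector, or a
#'   [Biostrings::DNAStringSet].
#' @param k seed k-mer size, in `[11, 31]`.
#' @param circular names of circular contigs (defaults to `"chrM"`-style
#'   detection: the contig name of a supplied `MitoReference`).
#' @return a [ReferenceIndex-class].
#' @export
buildIndex <- function(references, k = 15L, circular = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 11L || k > 31L) stop("k must be in [11, 31]")
  if (is(references, "MitoReference")) {
    contigs <- stats::setNames(as.character(references@sequence),
                               references@name)
    if (is.null(circular)) circular <- references@name
  } else if (is(references, "DNAStringSet")) {
    contigs <- stats::setNames(as.character(references), names(references))
  } else {
    contigs <- references
  }
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("reference contigs must be named")
  if (any(nchar(contigs) < k)) stop("contig shorter than k")
  circ <- names(contigs) %in% circular
  new("ReferenceIndex", contigs = contigs, circular = circ, k = k)
}

#' @rdname buildIndex
#' @param world a [World-class].
#' @param mode `"rcrs_only"` indexes the mito reference alone;
#'   `"combined"` adds every nuclear contig.
#' @export
worldIndex <- function(world, mode = c("rcrs_only", "combined"), k = 15L) {
  mode <- match.arg(mode)
  contigs <- stats::setNames(as.character(world@mito@sequence),
                             world@mito@name)
  if (mode == "combined" && length(world@nuclearContigs)) {
    contigs <- c(contigs, stats::setNames(
      as.character(world@nuclearContigs), names(world@nuclearContigs)))
  }
  buildIndex(contigs, k = k, circular = world@mito@name)
}

#' Map reads by ungapped k-mer seed-and-extend
#'
#' Candidate loci are collected from every exact k-mer seed hit of the read
#' and its reverse complement (deterministic order, capped at
#' `maxCandidates` distinct loci), then scored by full-length ungapped
#' comparison (+1 match, -1 mismatch). The best locus is reported if its
#' identity reaches `minIdentity` and the best score is unique; a tie across
#' distinct loci yields status `"ambiguous"` (such reads are excluded from
#' pileups, mimicking mapping-quality-zero filtering); otherwise
#' `"unmapped"`. Mito positions are reported modulo the mito length.
#'
#' @param reads a [ReadSet-class] or character vector of read sequences.
#' @param index a [ReferenceIndex-class].
#' @param minIdentity minimum accepted identity. The default 0.88 sits below
#'   typical NUMT similarity plus sequencing error, so high-similarity
#'   NUMT reads are accepted by the mito-only reference — the phenomenon
#'   under study — while strongly diverged NUMTs stay unmapped.
#' @param maxCandidates candidate-locus cap per read.
#' @return data.frame with columns `read_id`, `status`, `contig`,
#'   `position` (1-based), `strand`, `score`, `mismatches`, `identity`.
#' @export
mapReads <- function(reads, index, minIdentity = 0.88, maxCandidates = 200L) {
  stopifnot(is(index, "ReferenceIndex"))
  seqs <- if (is(reads, "ReadSet")) reads@sequences else reads
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read%08d", seq_along(seqs))
  res <- cpp_map_reads(unname(index@contigs), index@circular, index@k,
                       unname(seqs), minIdentity, as.integer(maxCandidates))
  data.frame(
    read_id = ids,
    status = c("unmapped", "mapped", "ambiguous")[res$status + 1L],
    contig = names(index@contigs)[res$contig],
    position = res$pos0 + 1L,
    strand = res$strand,
    score = res$score,
    mismatches = res$mismatches,
    identity = res$identity)
}

#' @rdname mapReads
#' @param read a single read sequence (character scalar).
#' @export
mapRead <- function(read, index, minIdentity = 0.88, maxCandidates = 200L) {
  mapReads(stats::setNames(read, "read"), index, minIdentity, maxCandidates)
}

#' Map the same reads under both reference modes
#'
#' Runs [mapReads()] against the mito-only index and the combined
#' (mito + nuclear) index, returning both alignment sets together with
#' per-mode mapping statistics. Because the combined reference can only
#' draw reads away from the mito contig, the set of reads mito-assigned in
#' combined mode is a subset of the rcrs-only set.
#'
#' @param reads a [ReadSet-class] or named character vector.
#' @param mitoIndex,combinedIndex [ReferenceIndex-class] objects sharing the
#'   mito contig.
#' @param minIdentity,maxCandidates see [mapReads()].
#' @return list with elements `rcrs_only`, `combined` (alignment
#'   data.frames) and `stats` (per-mode mapped/ambiguous/unmapped counts).
#' @export
mapAll <- function(reads, mitoIndex, combinedIndex, minIdentity = 0.88,
                   maxCandidates = 200L) {
  mitoName <- names(mitoIndex@contigs)[mitoIndex@circular][1]
  if (!mitoName %in% names(combinedIndex@contigs))
    stop("indexes do not share the mito contig")
  a <- mapReads(reads, mitoIndex, minIdentity, maxCandidates)
  b <- mapReads(reads, combinedIndex, minIdentity, maxCandidates)
  a$mode <- "rcrs_only"
  b$mode <- "combined"
  stats <- data.frame(
    mode = c("rcrs_only", "combined"),
    mapped = c(sum(a$status == "mapped"), sum(b$status == "mapped")),
    ambiguous = c(sum(a$status == "ambiguous"),
                  sum(b$status == "ambiguous")),
    unmapped = c(sum(a$status == "unmapped"), sum(b$status == "unmapped")),
    mito_mapped = c(sum(a$status == "mapped" & a$contig == mitoName,
                        na.rm = TRUE),
                    sum(b$status == "mapped" & b$contig == mitoName,
                        na.rm = TRUE)))
  list(rcrs_only = a, combined = b, stats = stats)
}

#' Write alignments as a SAM-like TSV
#'
#' @param alignments alignment data.frame from [mapReads()].
#' @param path output path.
#' @export
writeAlignments <- function(alignments, path) {
  utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
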