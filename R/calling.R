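#' Per-site base pileup over the circular mito reference
#'
#' Tallies A/C/G/T read bases at every mito position from mito-assigned,
#' uniquely mapped alignments. Minus-strand reads are complemented back onto
#' the forward reference; reads spanning the origin contribute to positions
#' on both sides of the wrap.
#'
#' @param alignments alignment data.frame from [mapReads()].
#' @param reads the [ReadSet-class] (or named character vector) the
#'   alignments came from.
#' @param mito a [MitoReference-class] (supplies length and contig name).
#' @return integer matrix, 4 x L, rows named A/C/G/T.
#' @export
pileup <- function(alignments, reads, mito) {
  stopifnot(is(mito, "MitoReference"))
  L <- length(mito@sequence)
  seqs <- if (is(reads, "ReadSet")) reads@sequences else reads
  keep <- alignments$status == "mapped" & alignments$contig == mito@name
  keep[is.na(keep)] <- FALSE
  al <- alignments[keep, , drop = FALSE]
  if (any(al$position < 1L | al$position > L))
    stop("alignment position outside contig bounds")
  rs <- seqs[match(al$read_id, names(seqs))]
  counts <- cpp_pileup(unname(rs), al$position - 1L, al$strand == "-", L)
  rownames(counts) <- DNA_BASES
  counts
}

#' Call per-site variants from a pileup
#'
#' At every position with depth >= `minDepth`, the highest-count
#' non-reference allele is reported as a variant when its frequency
#' (`100 * count / depth`, in percent) reaches `minFrequency`. The calling
#' floor defaults to 0.2% — deliberately below the 0.5 percentage-point
#' concordance threshold used downstream, so that the comparison module,
#' not the caller, governs the discrepancy classes. Only the single best
#' non-reference allele is reported per site.
#'
#' @param pileupCounts 4 x L matrix from [pileup()].
#' @param mito a [MitoReference-class].
#' @param minDepth minimum depth to consider a site (>= 1).
#' @param minFrequency minimum variant frequency in percent, in (0, 50).
#' @return data.frame with columns `position`, `ref`, `alt`, `depth`,
#'   `alt_count`, `frequency` (percent).
#' @export
callSites <- function(pileupCounts, mito, minDepth = 100L,
                      minFrequency = 0.2) {
  stopifnot(is(mito, "MitoReference"))
  if (minDepth < 1L) stop("minDepth must be >= 1")
  if (minFrequency <= 0 || minFrequency >= 50)
    stop("minFrequency must be in (0, 50) percent")
  L <- length(mito@sequence)
  stopifnot(ncol(pileupCounts) == L)
  depth <- colSums(pileupCounts)
  refbases <- strsplit(as.character(mito@sequence), "")[[1]]
  refIdx <- match(refbases, DNA_BASES)

  nonref <- pileupCounts
  nonref[cbind(refIdx, seq_len(L))] <- -1L  # exclude ref from the argmax
  top <- max.col(t(nonref), ties.method = "first")
  topCount <- nonref[cbind(top, seq_len(L))]
  freq <- ifelse(depth > 0, 100 * topCount / depth, 0)

  sel <- which(depth >= minDepth & topCount > 0 & freq >= minFrequency)
  data.frame(position = sel, ref = refbases[sel], alt = DNA_BASES[top[sel]],
             depth = as.integer(depth[sel]),
             alt_count = as.integer(topCount[sel]),
             frequency = freq[sel], row.names = NULL)
}

#' Write variant calls as TSV and minimal VCF
#'
#' The TSV carries `POS`, `REF`, `ALT`, `DEPTH`, `ALT_COUNT`, `FREQ`
#' (percent); the VCF is a minimal VCFv4.2 with `DP` and `AF` (fraction)
#' in INFO. Positions are 1-based in both.
#'
#' @param calls data.frame from [callSites()].
#' @param tsvPath output TSV path.
#' @param vcfPath optional output VCF path.
#' @param contig contig name for the VCF.
#' @param contigLength contig length for the VCF header.
#' @export
writeCalls <- function(calls, tsvPath, vcfPath = NULL, contig = "chrM",
                       contigLength = NA_integer_) {
  out <- data.frame(POS = calls$position, REF = calls$ref, ALT = calls$alt,
                    DEPTH = calls$depth, ALT_COUNT = calls$alt_count,
                    FREQ = calls$frequency)
  utils::write.table(out, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(vcfPath)) {
    hdr <- c("##fileformat=VCFv4.2",
             "##source=numtshadow",
             if (!is.na(contigLength))
               sprintf("##contig=<ID=%s,length=%d>", contig, contigLength)
             else sprintf("##contig=<ID=%s>", contig),
             "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    rows <- if (nrow(calls)) {
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.6f",
              contig, calls$position, calls$ref, calls$alt, calls$depth,
              calls$frequency / 100)
    } else character()
    writeLines(c(hdr, rows), vcfPath)
  }
  invisible(tsvPath)
}

#' Read a calls TSV written by [writeCalls()]
#'
#' @param tsvPath path to the TSV.
#' @return data.frame in [callSites()] layout.
#' @export
readCalls <- function(tsvPath) {
  x <- utils::read.delim(tsvPath, stringsAsFactors = FALSE,
                         colClasses = c("integer", "character", "character",
                                        "integer", "integer", "numeric"))
  data.frame(position = x$POS, ref = x$REF, alt = x$ALT, depth = x$DEPTH,
             alt_count = x$ALT_COUNT, frequency = x$FREQ)
}
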