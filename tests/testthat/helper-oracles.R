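# Independent oracles and hand-built fixtures used across the suite.

# Brute-force all-positions ungapped mapper: scores every (contig, position,
# strand) locus, applies the identity floor, and reports the unique best or
# an ambiguity. Deliberately independent of the k-mer seed path.
bruteForceMap <- function(read, contigs, minIdentity = 0.88) {
  m <- nchar(read)
  rdChars <- strsplit(read, "")[[1]]
  rcChars <- strsplit(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(read))),
    "")[[1]]
  best <- list(score = -Inf, contig = NA, pos = NA, strand = NA, n = 0L)
  for (cn in names(contigs)) {
    refChars <- strsplit(contigs[[cn]], "")[[1]]
    P <- length(refChars) - m + 1L
    if (P < 1L) next
    refMat <- vapply(seq_len(m), function(i) refChars[seq_len(P) + i - 1L],
                     character(P))
    if (P == 1L) refMat <- matrix(refMat, nrow = 1L)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") rdChars else rcChars
      matches <- rowSums(refMat == matrix(q, nrow = P, ncol = m,
                                          byrow = TRUE))
      ok <- which(matches / m >= minIdentity)
      for (p in ok) {
        sc <- 2L * matches[p] - m
        if (sc > best$score) {
          best <- list(score = sc, contig = cn, pos = p, strand = strand,
                       n = 1L)
        } else if (sc == best$score) {
          best$n <- best$n + 1L
        }
      }
    }
  }
  if (best$n == 0L) return(list(status = "unmapped"))
  list(status = if (best$n > 1L) "ambiguous" else "mapped",
       contig = best$contig, position = best$pos, strand = best$strand,
       score = best$score)
}

# Per-read base tally oracle for the pileup (linear loop, no shared code).
brutePileup <- function(seqs, positions, strands, L) {
  counts <- matrix(0L, nrow = 4, ncol = L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "")[[1]]
    if (strands[i] == "-") chars <- rev(unname(comp[chars]))
    for (j in seq_along(chars)) {
      p <- ((positions[i] - 1L + j - 1L) %% L) + 1L
      counts[chars[j], p] <- counts[chars[j], p] + 1L
    }
  }
  counts
}

# Hand-built world with fully controlled NUMTs: each NUMT is specified as
# (mito_start, length, mismatch positions relative to the interval start).
# Gives exact control over divergence placement (e.g. keeping primer
# footprints clean).
toyWorld <- function(mito, numtSpecs = list(), truthSites = NULL,
                     flank = 300L, copyNumber = 2L, seed = 99L) {
  ms <- mitoSequence(mito)
  L <- mitoLength(mito)
  truth <- if (is.null(truthSites)) {
    plantHeteroplasmy(mito, data.frame(position = integer(),
                                       alt = character(),
                                       frequency = numeric()))
  } else {
    plantHeteroplasmy(mito, truthSites)
  }
  regs <- list()
  contigs <- character()
  withr::with_seed(seed, {
    for (i in seq_along(numtSpecs)) {
      sp <- numtSpecs[[i]]
      src <- numtshadow:::subCircular(ms, sp$start, sp$len, L)
      chars <- strsplit(src, "")[[1]]
      for (off in sp$mismatchOffsets) {
        stopifnot(off >= 1, off <= sp$len)
        chars[off] <- setdiff(c("A", "C", "G", "T"), chars[off])[1]
      }
      ins <- paste(chars, collapse = "")
      ctg <- paste0(numtshadow:::randomDnaString(flank), ins,
                    numtshadow:::randomDnaString(flank))
      id <- sprintf("numt_%03d", i)
      regs[[i]] <- data.frame(
        numt_id = id, mito_start = as.integer(sp$start),
        length = as.integer(sp$len), strand = "+",
        similarity = 1 - length(sp$mismatchOffsets) / sp$len,
        n_mismatch = length(sp$mismatchOffsets),
        copy_number = as.integer(copyNumber),
        nuclear_contig = paste0(id, "_ctg"),
        nuclear_offset = flank + 1L)
      contigs <- c(contigs, stats::setNames(ctg, paste0(id, "_ctg")))
    }
  })
  reg <- if (length(regs)) do.call(rbind, regs) else
    data.frame(numt_id = character(), mito_start = integer(),
               length = integer(), strand = character(),
               similarity = numeric(), n_mismatch = integer(),
               copy_number = integer(), nuclear_contig = character(),
               nuclear_offset = integer())
  ctgSet <- if (length(contigs)) {
    x <- Biostrings::DNAStringSet(contigs)
    names(x) <- names(contigs)
    x
  } else Biostrings::DNAStringSet()
  new("World", mito = mito, truth = truth, numts = reg,
      nuclearContigs = ctgSet, seed = as.integer(seed))
}

# alt allele different from the reference base at a position
altAt <- function(mito, position) {
  setdiff(c("A", "C", "G", "T"),
          substr(mitoSequence(mito), position, position))[1]
}
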