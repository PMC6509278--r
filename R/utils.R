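DNA_BASES <- c("A", "C", "G", "T")

randomDnaString <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# positions of a circular interval (1-based start, length len) on a circle of
# length L, in order
circularPositions <- function(start, len, L) {
  ((start - 1L + seq_len(len) - 1L) %% L) + 1L
}

# does the circular interval (innerStart, innerLen) lie entirely within
# (outerStart, outerLen)?
circularContains <- function(outerStart, outerLen, innerStart, innerLen, L) {
  off <- (innerStart - outerStart) %% L
  (off + innerLen) <= outerLen
}

# substring of a circular sequence (character scalar), wrapping the origin
subCircular <- function(seqChar, start, len, L) {
  stopifnot(len <= L)
  if (start + len - 1L <= L) {
    substr(seqChar, start, start + len - 1L)
  } else {
    paste0(substr(seqChar, start, L),
           substr(seqChar, 1L, start + len - 1L - L))
  }
}

# truncated normal via inverse-CDF (exact, vectorized, RNG-frugal)
rtruncNorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# substitute bases at `positions` of a character-scalar sequence; each new
# base drawn uniformly from the 3 non-current bases
mutatePositions <- function(seqChar, positions) {
  if (!length(positions)) return(seqChar)
  chars <- strsplit(seqChar, "")[[1]]
  cur <- chars[positions]
  repl <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  chars[positions] <- repl
  paste(chars, collapse = "")
}

revCompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

withSeed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# derive independent per-stage seeds from one master seed (all < 2^31)
stageSeeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
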