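# Independent mini-oracles used to cross-check the package's digest
# arithmetic by a different route than the implementation takes.

# double digest via explicit cut-site marking on the molecule
ddsBySiteMarking <- function(aOrdered, bOrdered) {
  L <- sum(aOrdered)
  sites <- sort(unique(c(0, cumsum(aOrdered), cumsum(bOrdered))))
  diff(sites)  # zero-length fragments vanish here: coincident sites merge
}

# multiset symmetric difference by explicit element pairing
mismatchByPairing <- function(x, y) {
  for (v in x) {
    hit <- match(v, y)
    if (!is.na(hit)) {
      y <- y[-hit]
      x <- x[-match(v, x)]
      return(mismatchByPairing(x, y))
    }
  }
  length(x) + length(y)
}

randomFragmentVector <- function(maxLen = 12L, maxVal = 50L) {
  n <- sample.int(maxLen, 1L)
  sample.int(maxVal, n, replace = TRUE)
}

# is `sub` a subsequence of `seq`? (two-pointer scan)
isSubsequence <- function(sub, seq_) {
  j <- 1L
  for (x in seq_) {
    if (j <= length(sub) && identical(sub[j], x)) j <- j + 1L
  }
  j == length(sub) + 1L
}

solutionKeys <- function(solutions) {
  vapply(solutions, function(s) paste(c(s$mu, 0L, s$nu), collapse = ","),
         character(1))
}
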