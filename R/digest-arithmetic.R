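#' Prefix-sum (accumulative sum) vector of a fragment vector
#'
#' Maps fragment lengths to cut positions: entry j is the position of the
#' j-th cut measured from the left end of the molecule (the last entry is
#' the total length).
#'
#' @param v non-empty numeric vector of fragment lengths.
#' @return integer vector of partial sums.
#' @examples
#' accumulativeSum(c(1, 5, 3, 2))  # 1 6 9 11
#' @export
accumulativeSum <- function(v) {
  if (length(v) == 0L) stop("empty fragment vector")
  cumsum(as.integer(v))
}

#' Step-difference vector (inverse of the prefix sum)
#'
#' Maps a non-decreasing vector of cut positions back to fragment lengths:
#' entry 1 is v[1], entry j is v[j] - v[j-1]. Repeated positions (coincident
#' cuts) yield zero-length fragments.
#'
#' @param v non-decreasing numeric vector of positions.
#' @return integer vector with \code{accumulativeSum(stepDifference(v)) == v}.
#' @examples
#' stepDifference(c(1, 3, 5, 6, 7, 9, 11))  # 1 2 2 1 1 2 2
#' @export
stepDifference <- function(v) {
  if (length(v) == 0L) stop("empty position vector")
  if (is.unsorted(v)) stop("positions must be non-decreasing")
  v <- as.integer(v)
  diff(c(0L, v))
}

#' Reorder a fragment vector by a permutation
#'
#' Gather convention: \code{result[i] = v[p[i]]}, so \code{p} lists, in map
#' order, which original fragment occupies each position.
#'
#' @param v fragment vector.
#' @param p integer permutation of \code{seq_along(v)} in one-line notation.
#' @return reordered fragment vector (same multiset).
#' @examples
#' permuteFragments(c(1, 2, 3, 5), c(1, 4, 3, 2))  # 1 5 3 2
#' @export
permuteFragments <- function(v, p) {
  p <- as.integer(p)
  if (length(v) != length(p))
    stop(sprintf("size mismatch: %d fragments vs permutation of degree %d",
                 length(v), length(p)))
  if (!.isPermutation(p))
    stop("'p' is not a permutation in one-line notation")
  as.integer(v)[p]
}

.isPermutation <- function(p) {
  length(p) > 0L && !anyNA(p) && all(sort.int(p) == seq_along(p))
}

#' Combining sequence of two single digests
#'
#' Concatenates the cut positions of the A-ordering with the *interior* cut
#' positions of the B-ordering (the shared final position, the molecule
#' length, is kept once). The result has m + n - 1 entries.
#'
#' @param a,b fragment vectors with equal totals, in map order.
#' @return integer vector of m + n - 1 positions (unsorted).
#' @examples
#' combineDigests(c(1, 5, 3, 2), c(3, 2, 2, 4))  # 1 6 9 11 3 5 7
#' @export
combineDigests <- function(a, b) {
  if (sum(a) != sum(b))
    stop(sprintf("invalid pair: totals differ (%d vs %d)", sum(a), sum(b)))
  asA <- accumulativeSum(a)
  asB <- accumulativeSum(b)
  c(asA, asB[-length(asB)])
}

#' Double digest sequence implied by orderings of the single digests
#'
#' Overlays the cut sites of the two orderings and reads off the resulting
#' fragment lengths: sort the combining sequence, then take step
#' differences. Zero entries mark positions cut by both enzymes.
#'
#' @inheritParams combineDigests
#' @return integer vector of m + n - 1 fragment lengths summing to sum(a).
#' @examples
#' doubleDigestSequence(c(1, 5, 3, 2), c(3, 2, 2, 4))  # 1 2 2 1 1 2 2
#' @export
doubleDigestSequence <- function(a, b) {
  stepDifference(sort.int(combineDigests(a, b), method = "radix"))
}

#' Multiset symmetric difference size
#'
#' Number of elements (counted with multiplicity) by which the two operands
#' differ when regarded as unordered multisets: |x| + |y| - 2 |x intersect y|.
#'
#' @param x,y numeric vectors regarded as multisets.
#' @return non-negative integer; 0 iff x and y are equal as multisets.
#' @examples
#' multisetMismatch(c(2, 1, 2, 2, 0, 3, 1), c(1, 1, 1, 2, 2, 2, 2))  # 4
#' @export
multisetMismatch <- function(x, y) {
  vals <- unique(c(x, y))
  sum(abs(tabulate(match(x, vals), length(vals)) -
          tabulate(match(y, vals), length(vals))))
}

#' Fitness of a chromosome against a canonical instance
#'
#' \deqn{f(\mu, \nu) = 1 / (1 + |DDS(a^\mu, b^\nu) \oplus c|)}
#' where \eqn{\oplus} is the multiset symmetric difference. Fitness lies in
#' (0, 1] and equals 1 exactly for solutions of the instance.
#'
#' @param mu,nu integer permutations over m and n.
#' @param instance a valid, canonical (k = m + n - 1) [DDPInstance-class];
#'   see [padToCanonical()].
#' @return numeric fitness in (0, 1].
#' @examples
#' ins <- DDPInstance(c(1, 2, 3, 5), c(2, 2, 3, 4), c(1, 1, 1, 2, 2, 2, 2))
#' chromosomeFitness(c(1, 4, 3, 2), c(3, 1, 2, 4), ins)  # 1
#' chromosomeFitness(c(2, 4, 3, 1), c(3, 1, 2, 4), ins)  # 0.2
#' @export
chromosomeFitness <- function(mu, nu, instance) {
  .checkCanonical(instance)
  d <- doubleDigestSequence(permuteFragments(instance@a, mu),
                            permuteFragments(instance@b, nu))
  1 / (1 + multisetMismatch(d, instance@c))
}

.checkCanonical <- function(instance) {
  if (!isValidInstance(instance))
    stop("instance is invalid: ", validateInstance(instance)$message)
  if (!isCanonical(instance))
    stop("instance is not canonical (k != m + n - 1); apply padToCanonical()")
  invisible(TRUE)
}

#' Extract the double-digest permutation from an exact solution
#'
#' For an exact chromosome \eqn{(\mu, \nu)} the implied double digest
#' sequence equals \code{c} as a multiset; this recovers the permutation
#' \eqn{\pi} with \code{permuteFragments(c, pi)} equal to the implied
#' sequence *entrywise*. Ties among equal fragment lengths are resolved by
#' ascending original index (stable sort), making \eqn{\pi} deterministic.
#' Runs in O(k log k).
#'
#' @inheritParams chromosomeFitness
#' @return integer permutation over k.
#' @examples
#' ins <- DDPInstance(c(1, 2, 3, 5), c(2, 2, 3, 4), c(1, 1, 1, 2, 2, 2, 2))
#' extractPi(c(1, 4, 3, 2), c(3, 1, 2, 4), ins)  # 1 4 5 2 3 6 7
#' @export
extractPi <- function(mu, nu, instance) {
  .checkCanonical(instance)
  d <- doubleDigestSequence(permuteFragments(instance@a, mu),
                            permuteFragments(instance@b, nu))
  if (multisetMismatch(d, instance@c) != 0L)
    stop("chromosome is not an exact solution; pi is defined only at fitness 1")
  ordD <- order(d)            # stable: ties by ascending position
  ordC <- order(instance@c)
  pi <- integer(length(d))
  pi[ordD] <- ordC
  pi
}

#' Normalized displacement between two reconstructed maps
#'
#' Operationalizes the relative error between two maps of the same molecule
#' as the order-matched L1 displacement of their interior cut positions,
#' normalized by the total length: \eqn{\sum_i |u_i - w_i| / L}, where u and
#' w are the sorted interior cut positions implied by each record's double
#' digest sequence. Zero iff the two cut sets are identical; symmetric.
#'
#' @param sol1,sol2 [SolutionRecord-class] objects built on instances of the
#'   same total length with equal k.
#' @param L common total length of the molecule.
#' @return numeric relative displacement >= 0.
#' @export
mapDistance <- function(sol1, sol2, L) {
  u <- cumsum(sol1@dds)
  w <- cumsum(sol2@dds)
  if (length(u) != length(w))
    stop(sprintf("size error: maps have %d and %d fragments",
                 length(u), length(w)))
  u <- sort.int(u[-length(u)])
  w <- sort.int(w[-length(w)])
  sum(abs(u - w)) / L
}
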