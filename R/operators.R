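## A chromosome is a plain list(mu = <perm>, nu = <perm>); permutations are
## 1-based integer vectors in one-line notation. Operators consume R's
## global RNG stream, so callers seed once per run.

#' Create a chromosome from a pair of permutations
#' @param mu,nu integer permutations over m and n.
#' @return list with elements \code{mu} and \code{nu}.
#' @export
newChromosome <- function(mu, nu) {
  mu <- as.integer(mu); nu <- as.integer(nu)
  if (!.isPermutation(mu) || !.isPermutation(nu))
    stop("mu and nu must be permutations in one-line notation")
  list(mu = mu, nu = nu)
}

#' Roulette-wheel (fitness-proportional) selection
#'
#' Draws \code{count} population indices with replacement, each index chosen
#' with probability proportional to its fitness.
#'
#' @param fitnesses positive numeric vector.
#' @param count number of indices to draw.
#' @return integer vector of length \code{count}.
#' @export
rwsSelect <- function(fitnesses, count) {
  if (length(fitnesses) == 0L) stop("empty population")
  if (any(fitnesses <= 0)) stop("all fitnesses must be positive")
  if (count < 1L) stop("count must be at least 1")
  sample.int(length(fitnesses), count, replace = TRUE, prob = fitnesses)
}

#' Permutation-composition crossover (PCC)
#'
#' Composes the parents' permutations componentwise, with
#' \eqn{(p \circ q)(i) = p(q(i))}: offspring 1 is
#' \eqn{(\mu_1 \circ \mu_2, \nu_1 \circ \nu_2)} and offspring 2 the
#' composition in the opposite order.
#'
#' @param ch1,ch2 chromosomes (see [newChromosome()]) of matching degrees.
#' @return list of two chromosomes.
#' @export
pccCross <- function(ch1, ch2) {
  if (length(ch1$mu) != length(ch2$mu) || length(ch1$nu) != length(ch2$nu))
    stop("degree mismatch between parent chromosomes")
  list(newChromosome(ch1$mu[ch2$mu], ch1$nu[ch2$nu]),
       newChromosome(ch2$mu[ch1$mu], ch2$nu[ch1$nu]))
}

#' Referenced sorting of a sequence against a reference
#'
#' Rearranges \code{target} into the order in which its elements occur in
#' \code{reference}: the output is the subsequence of \code{reference}
#' realizing \code{target}'s multiset, found by greedy right-to-left
#' occurrence matching (rightmost occurrences win). Elements may repeat;
#' each element of \code{target} must occur in \code{reference} with at
#' least the required multiplicity.
#'
#' @param target vector to rearrange.
#' @param reference vector supplying the order.
#' @return \code{target}'s multiset in reference order.
#' @examples
#' referSort(c(1, 3, 4, 2, 2), c(1, 2, 2, 2, 4, 3, 3, 1))  # 2 2 4 3 1
#' referSort(c(2, 4, 3, 3, 1), c(1, 3, 2, 1, 3, 4, 2, 2))  # 3 1 3 4 2
#' @export
referSort <- function(target, reference) {
  need <- target
  take <- logical(length(reference))
  for (i in rev(seq_along(reference))) {
    j <- match(reference[i], need)
    if (!is.na(j)) {
      take[i] <- TRUE
      need <- need[-j]
    }
  }
  if (length(need))
    stop("unmatchable items: target not contained in reference with ",
         "sufficient multiplicity (missing: ",
         paste(need, collapse = ", "), ")")
  reference[take]
}

#' Referenced-sorting recombination of two sequences at a fixed point
#'
#' The deterministic core of the RSC crossover: each offspring keeps one
#' parent's prefix up to \code{point} and carries that parent's suffix
#' rearranged into the other parent's order via [referSort()].
#'
#' @param p1,p2 equal-length sequences over a common alphabet.
#' @param point crossover point in 1..length-1.
#' @return list of the two offspring sequences.
#' @examples
#' rscCombine(c(1, 3, 2, 1, 3, 4, 2, 2), c(1, 2, 2, 2, 4, 3, 3, 1), 3)
#' @export
rscCombine <- function(p1, p2, point) {
  n <- length(p1)
  if (length(p2) != n) stop("degree mismatch between parents")
  if (point < 1L || point >= n) stop("crossover point out of range")
  suffix <- (point + 1L):n
  list(c(p1[seq_len(point)], referSort(p1[suffix], p2)),
       c(p2[seq_len(point)], referSort(p2[suffix], p1)))
}

#' Referenced-sorting crossover (RSC, order-preserving)
#'
#' Applies [rscCombine()] to the \eqn{\mu} and \eqn{\nu} components
#' independently, each with its own crossover point drawn uniformly from
#' 1..degree-1. On permutations (distinct indices) the referenced sort is
#' exact, so offspring are valid permutations.
#'
#' @inheritParams pccCross
#' @return list of two chromosomes.
#' @export
rscCross <- function(ch1, ch2) {
  m <- length(ch1$mu); n <- length(ch1$nu)
  if (m != length(ch2$mu) || n != length(ch2$nu))
    stop("degree mismatch between parent chromosomes")
  if (m < 2L || n < 2L) stop("degree must be at least 2 for crossover")
  mus <- rscCombine(ch1$mu, ch2$mu, sample.int(m - 1L, 1L))
  nus <- rscCombine(ch1$nu, ch2$nu, sample.int(n - 1L, 1L))
  list(newChromosome(mus[[1L]], nus[[1L]]),
       newChromosome(mus[[2L]], nus[[2L]]))
}

#' Four-point mutation (P4X)
#'
#' Exchanges two elements of \eqn{\mu} and two elements of \eqn{\nu} (one
#' transposition per component, positions drawn without replacement).
#'
#' @param ch a chromosome.
#' @return mutated chromosome.
#' @export
p4xMutate <- function(ch) {
  if (length(ch$mu) < 2L || length(ch$nu) < 2L)
    stop("degree must be at least 2 for mutation")
  list(mu = .transpose(ch$mu), nu = .transpose(ch$nu))
}

.transpose <- function(p) {
  ij <- sample.int(length(p), 2L)
  p[ij] <- p[rev(ij)]
  p
}

.drawSegment <- function(n) {
  # uniform over all pairs i < j
  sort.int(sample.int(n, 2L))
}

#' Fragment-flip mutation (FLP)
#'
#' Reverses a contiguous segment of the permutation; endpoints i < j are
#' drawn uniformly over all pairs unless supplied.
#'
#' @param p integer permutation.
#' @param i,j optional fixed segment endpoints (both or neither).
#' @return mutated permutation.
#' @examples
#' flpMutate(c(2, 5, 4, 1), 1, 4)  # 1 4 5 2
#' @export
flpMutate <- function(p, i = NULL, j = NULL) {
  if (length(p) < 2L) stop("degree must be at least 2 for mutation")
  if (is.null(i)) { ij <- .drawSegment(length(p)); i <- ij[1L]; j <- ij[2L] }
  stopifnot(i >= 1L, j <= length(p), i < j)
  p[i:j] <- p[j:i]
  p
}

#' Cyclic-shift mutation (CSH)
#'
#' Rotates a contiguous segment left by one position; endpoints as in
#' [flpMutate()].
#'
#' @inheritParams flpMutate
#' @return mutated permutation.
#' @examples
#' cshMutate(c(2, 5, 4, 1), 1, 4)  # 5 4 1 2
#' @export
cshMutate <- function(p, i = NULL, j = NULL) {
  if (length(p) < 2L) stop("degree must be at least 2 for mutation")
  if (is.null(i)) { ij <- .drawSegment(length(p)); i <- ij[1L]; j <- ij[2L] }
  stopifnot(i >= 1L, j <= length(p), i < j)
  s <- i:j
  p[s] <- p[c(s[-1L], s[1L])]
  p
}

#' Cyclic linearly adaptive mutation probability
#'
#' The mutation probability climbs linearly within each cycle of
#' \code{cycleLength} generations from 2/(m+n) at the cycle start to
#' \code{ceiling} at the cycle end, then resets. The ceiling 0.55 guarantees
#' a non-negative within-cycle increment for every problem size (at
#' m = n = 2 the floor is already 0.5).
#'
#' @param generation generation counter >= 0 (0 = initial population).
#' @param m,n degrees of the two permutations.
#' @param cycleLength cycle length in generations (default 200).
#' @param ceiling end-of-cycle probability (default 0.55).
#' @return mutation probability in (0, 1).
#' @examples
#' mutationProbability(0, 2, 2)    # 0.5
#' mutationProbability(199, 6, 6)  # 0.55
#' @export
mutationProbability <- function(generation, m, n,
                                cycleLength = 200L, ceiling = 0.55) {
  if (m + n < 2L) stop("m + n must be at least 2")
  # for m + n < 4 the start value 2/(m+n) would exceed the ceiling; clamp so
  # the within-cycle increment stays non-negative (schedule then constant)
  floorP <- min(2 / (m + n), ceiling)
  phase <- generation %% cycleLength
  floorP + (ceiling - floorP) * (phase / (cycleLength - 1L))
}

#' Parse an operator-set specification
#'
#' Accepts the names \code{rws}, \code{pcc}, \code{rsc}, \code{p4x},
#' \code{flp}, \code{csh} and \code{all} (case-insensitive), comma-separated
#' or as a character vector. \code{rws} (selection) is always active and may
#' be listed for readability; \code{all} enables both crossovers and all
#' three mutations.
#'
#' @param spec character vector or single comma-separated string.
#' @return list with character elements \code{crossovers} and
#'   \code{mutations}.
#' @examples
#' parseOperators("rws,rsc,flp")
#' parseOperators("all")
#' @export
parseOperators <- function(spec = "all") {
  ops <- tolower(trimws(unlist(strsplit(spec, ",", fixed = TRUE))))
  ops <- ops[nzchar(ops)]
  known <- c("rws", "pcc", "rsc", "p4x", "flp", "csh", "all")
  bad <- setdiff(ops, known)
  if (length(bad))
    stop("unknown operator name(s): ", paste(bad, collapse = ", "))
  if ("all" %in% ops)
    return(list(crossovers = c("pcc", "rsc"),
                mutations = c("p4x", "flp", "csh")))
  list(crossovers = intersect(c("pcc", "rsc"), ops),
       mutations = intersect(c("p4x", "flp", "csh"), ops))
}

#' Standard benchmark operator combinations
#'
#' The six runnable single-crossover + single-mutation pairs together with
#' the full set ("all"), used for operator-effect benchmarking.
#'
#' @return named list of operator-set lists as returned by
#'   [parseOperators()].
#' @export
benchmarkCombos <- function() {
  combos <- list()
  for (x in c("pcc", "rsc"))
    for (mt in c("p4x", "flp", "csh"))
      combos[[paste(x, mt, sep = "+")]] <-
        list(crossovers = x, mutations = mt)
  combos[["all"]] <- parseOperators("all")
  combos
}
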