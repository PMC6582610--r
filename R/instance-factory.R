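#' Generate a random, certified-solvable DDP instance
#'
#' Samples m - 1 interior cut positions for enzyme A and n - 1 for enzyme B
#' uniformly without replacement from 1..L-1 (per enzyme; coincidences
#' *between* the enzymes are allowed and surface as zero-length double
#' digest fragments after padding). The double digest \code{c} is read off
#' the overlaid cut sites, with zero-length entries dropped as a real
#' experiment would drop them. The output \code{a} and \code{b} are emitted
#' in shuffled order, and the generating orderings are returned as a ground
#' truth that certifies exact solvability after [padToCanonical()].
#'
#' When \code{rhoCMax} is set, draws are rejected until the largest double
#' digest fragment is at most \code{rhoCMax} (feasible only when
#' \code{rhoCMax * (m + n - 1) >= L}).
#'
#' @param m,n fragment counts of the two single digests (>= 1).
#' @param L total molecule length (L >= m, L >= n).
#' @param rhoCMax optional cap on the largest double digest fragment.
#' @param seed optional integer seed.
#' @param maxResample rejection-loop cap before raising (default 10,000).
#' @param name instance label.
#' @return list with elements \code{instance} (a [DDPInstance-class]) and
#'   \code{groundTruth} (a [SolutionRecord-class] with fitness 1 on the
#'   padded instance).
#' @examples
#' gen <- randomInstance(4, 4, 40, seed = 1)
#' isValidInstance(gen$instance)
#' gen$groundTruth@fitness
#' @export
randomInstance <- function(m, n, L, rhoCMax = NULL, seed = NULL,
                           maxResample = 10000L, name = "random") {
  m <- as.integer(m); n <- as.integer(n); L <- as.integer(L)
  if (m < 1L || n < 1L) stop("infeasible: m and n must be at least 1")
  if (L < m || L < n)
    stop(sprintf("infeasible: L = %d cannot host %d and %d positive fragments",
                 L, m, n))
  k <- m + n - 1L
  if (!is.null(rhoCMax)) {
    rhoCMax <- as.integer(rhoCMax)
    if (rhoCMax < 1L || rhoCMax * as.numeric(k) < L)
      stop(sprintf(
        "infeasible: %d fragments capped at %d cannot sum to L = %d",
        k, rhoCMax, L))
  }
  if (!is.null(seed)) set.seed(seed)

  for (draw in seq_len(maxResample)) {
    cutsA <- if (m > 1L) sort.int(sample.int(L - 1L, m - 1L)) else integer(0)
    cutsB <- if (n > 1L) sort.int(sample.int(L - 1L, n - 1L)) else integer(0)
    aTrue <- diff(c(0L, cutsA, L))
    bTrue <- diff(c(0L, cutsB, L))
    cAll <- diff(c(0L, sort.int(unique(c(cutsA, cutsB))), L))
    if (is.null(rhoCMax) || max(cAll) <= rhoCMax) {
      ordA <- sample.int(m); ordB <- sample.int(n)
      inst <- DDPInstance(aTrue[ordA], bTrue[ordB], cAll, name = name)
      mu <- order(ordA); nu <- order(ordB)   # inverse of the shuffles
      truth <- .solutionRecord(mu, nu, padToCanonical(inst), 0L)
      return(list(instance = inst, groundTruth = truth))
    }
  }
  stop(sprintf(
    "resample cap reached: no draw with max double-digest fragment <= %d in %d attempts",
    rhoCMax, maxResample))
}

.roundHalfUp <- function(x) floor(x + 0.5)  # half-away-from-zero on x >= 0

#' Suggest a power-of-ten scale factor for a hard instance
#'
#' Smallest power of ten 10^-e (strongest shrink) such that the smallest
#' positive double digest fragment still scales to at least 1; e.g. a
#' smallest fragment of 1120 suggests 0.001.
#'
#' @param x a [DDPInstance-class].
#' @return numeric scale factor in (0, 1].
#' @export
suggestScaleFactor <- function(x) {
  minC <- min(x@c[x@c > 0L])
  10^(-floor(log10(minC)))
}

#' Select the first valid candidate of a scaling transform
#'
#' Given named candidate instances (in preference order), reports all sum
#' triples and returns the name of the first candidate whose three totals
#' agree, or "failed".
#'
#' @param candidates named list of [DDPInstance-class] candidates.
#' @return list with \code{variant} (name or "failed") and \code{sums}
#'   (matrix, one row per candidate, columns a/b/c).
#' @export
selectScalingVariant <- function(candidates) {
  sums <- t(vapply(candidates,
                   function(ins) c(a = sum(ins@a), b = sum(ins@b),
                                   c = sum(ins@c)),
                   numeric(3)))
  valid <- vapply(candidates, isValidInstance, logical(1))
  variant <- if (any(valid)) names(candidates)[which(valid)[1L]] else "failed"
  list(variant = variant, sums = sums)
}

#' Scaling-rounding-adjusting transform for numerically hard instances
#'
#' Multiplies all fragment lengths by \code{factor} and rounds; because
#' rounding typically breaks the equal-totals restriction, two adjusted
#' candidates are also formed by rounding \code{x*factor + t} (up) and
#' \code{x*factor - t} (down). The first valid candidate in the order given
#' by \code{preference} is selected; all three sum triples are reported for
#' auditability. A solution of the scaled surrogate approximates the map of
#' the original instance.
#'
#' @param x a valid [DDPInstance-class].
#' @param factor scale factor in (0, 1].
#' @param t adjusting constant in [0.0001, 0.4999] (default 0.1).
#' @param preference candidate order (default plain, up, down).
#' @return a [ScalingReport-class].
#' @examples
#' ins <- DDPInstance(c(14, 26), c(19, 21), c(14, 5, 21))
#' scaleRoundAdjust(ins, 0.1)
#' @export
scaleRoundAdjust <- function(x, factor, t = 0.1,
                             preference = c("plain", "up", "down")) {
  if (!isValidInstance(x))
    stop("cannot scale an invalid instance: ", validateInstance(x)$message)
  if (factor <= 0 || factor > 1) stop("parameter error: factor must be in (0, 1]")
  if (t < 0.0001 || t > 0.4999)
    stop("parameter error: t must lie in [0.0001, 0.4999]")
  preference <- match.arg(preference, c("plain", "up", "down"),
                          several.ok = TRUE)

  mk <- function(shift, tag) {
    DDPInstance(.roundHalfUp(x@a * factor + shift),
                .roundHalfUp(x@b * factor + shift),
                .roundHalfUp(x@c * factor + shift),
                name = paste(x@name, tag, sep = "-"))
  }
  candidates <- list(plain = mk(0, "plain"), up = mk(t, "up"),
                     down = mk(-t, "down"))
  sel <- selectScalingVariant(candidates[preference])
  variant <- sel$variant
  allSums <- t(vapply(candidates,
                      function(ins) c(a = sum(ins@a), b = sum(ins@b),
                                      c = sum(ins@c)),
                      numeric(3)))
  new("ScalingReport", factor = factor, t = t, variant = variant,
      candidates = candidates, sums = allSums,
      scaled = if (variant == "failed") NULL else candidates[[variant]])
}

setMethod("show", "ScalingReport", function(object) {
  cat(sprintf("ScalingReport: factor %g, t %g, selected variant: %s\n",
              object@factor, object@t, object@variant))
  for (v in rownames(object@sums))
    cat(sprintf("  %-5s sums: %s\n", v,
                paste(object@sums[v, ], collapse = "/")))
  invisible(object)
})

#' Packaged reference instances and operator test vectors
#'
#' Bit-exact copies of the worked instances and operator examples used
#' throughout the documentation and tests: the four-fragment teaching
#' instance (\code{example1}), the scaled hard instance in its plain, up
#' and down rounding variants (\code{scaledPlain}, \code{scaledUp},
#' \code{ins2prime} -- only the down-rounding variant is valid), and the
#' printed referenced-sorting crossover parents/offspring and segment
#' mutation fragments.
#'
#' @return named list of [DDPInstance-class] objects and plain vectors.
#' @examples
#' fx <- ddpFixtures()
#' validateInstance(fx$ins2prime)$sums  # 48 48 48
#' @export
ddpFixtures <- function() {
  list(
    example1 = DDPInstance(c(1, 2, 3, 5), c(2, 2, 3, 4),
                           c(1, 1, 1, 2, 2, 2, 2), name = "example1"),
    ins2prime = DDPInstance(c(5, 6, 6, 7, 7, 17), c(3, 5, 6, 6, 7, 21),
                            c(1, 2, 2, 3, 3, 3, 4, 4, 5, 5, 16),
                            name = "ins2prime"),
    scaledPlain = DDPInstance(c(6, 6, 7, 7, 7, 17), c(4, 5, 6, 6, 7, 21),
                              c(1, 2, 3, 3, 3, 4, 4, 4, 5, 6, 16),
                              name = "scaled-plain"),
    scaledUp = DDPInstance(c(6, 6, 7, 7, 7, 17), c(4, 5, 6, 6, 8, 21),
                           c(1, 2, 3, 3, 3, 4, 4, 4, 5, 6, 16),
                           name = "scaled-up"),
    rscParents = list(p1 = c(1, 3, 2, 1, 3, 4, 2, 2),
                      p2 = c(1, 2, 2, 2, 4, 3, 3, 1),
                      point = 3L,
                      c1 = c(1, 3, 2, 2, 2, 4, 3, 1),
                      c2 = c(1, 2, 2, 3, 1, 3, 4, 2)),
    flpExample = list(input = c(2, 5, 4, 1), output = c(1, 4, 5, 2)),
    cshExample = list(input = c(2, 5, 4, 1), output = c(5, 4, 1, 2))
  )
}
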