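#' @import methods
NULL

## Fragment-length vectors are plain non-negative integer vectors throughout;
## zero entries are legal only as products of padding or coincident cut sites.

.checkFragments <- function(v, what) {
  if (length(v) == 0L)
    return(sprintf("'%s' must contain at least one fragment", what))
  if (anyNA(v))
    return(sprintf("'%s' contains missing values", what))
  if (any(v < 0L))
    return(sprintf("'%s' contains negative fragment lengths", what))
  if (sum(as.numeric(v)) <= 0)
    return(sprintf("'%s' must have positive total length", what))
  TRUE
}

#' DDPInstance: a double digest problem instance
#'
#' Holds the three fragment-length multisets of a double digest experiment:
#' \code{a} (digest by enzyme A alone, m fragments), \code{b} (enzyme B
#' alone, n fragments) and \code{c} (both enzymes, k fragments). An instance
#' is *valid* when the three totals agree; validity is a property reported
#' by [validateInstance()], not an object-construction requirement, so that
#' defective laboratory inputs can still be loaded and diagnosed.
#'
#' @slot a integer vector of A-digest fragment lengths (base pairs).
#' @slot b integer vector of B-digest fragment lengths.
#' @slot c integer vector of double-digest fragment lengths.
#' @slot name single character label for the instance.
#' @export
setClass("DDPInstance",
  representation(a = "integer", b = "integer", c = "integer",
                 name = "character"),
  validity = function(object) {
    msgs <- character()
    for (s in c("a", "b", "c")) {
      ok <- .checkFragments(slot(object, s), s)
      if (!isTRUE(ok)) msgs <- c(msgs, ok)
    }
    if (length(object@name) != 1L)
      msgs <- c(msgs, "'name' must be a single string")
    if (length(msgs)) msgs else TRUE
  })

#' GAConfig: genetic algorithm configuration
#'
#' Evolution-strategy parameters for [evolveDDP()]. Defaults follow the
#' standard strategy: population 50, at most 10,000 generations, crossover
#' probability 0.85, elitism with one elitist, and a mutation probability
#' that climbs linearly from 2/(m+n) to 0.55 in cycles of 200 generations.
#'
#' @slot populationSize integer, number of chromosomes per generation.
#' @slot maxGenerations integer, generation cap (generation 0 is the
#'   initial population).
#' @slot crossoverProb probability that a selected parent pair is crossed
#'   (otherwise the parents are cloned).
#' @slot crossovers character subset of \code{c("pcc","rsc")}.
#' @slot mutations character subset of \code{c("p4x","flp","csh")}.
#' @slot cycleLength integer, mutation-schedule cycle length in generations.
#' @slot mutationCeiling upper end of the mutation-probability cycle.
#' @slot eliteCount number of best chromosomes copied unchanged.
#' @slot seed integer seed driving every stochastic choice of a run.
#' @export
setClass("GAConfig",
  representation(populationSize = "integer", maxGenerations = "integer",
                 crossoverProb = "numeric", crossovers = "character",
                 mutations = "character", cycleLength = "integer",
                 mutationCeiling = "numeric", eliteCount = "integer",
                 seed = "integer"),
  validity = function(object) {
    msgs <- character()
    if (object@populationSize < 2L)
      msgs <- c(msgs, "populationSize must be at least 2")
    if (object@maxGenerations < 0L)
      msgs <- c(msgs, "maxGenerations must be non-negative")
    if (object@crossoverProb <= 0 || object@crossoverProb > 1)
      msgs <- c(msgs, "crossoverProb must be in (0, 1]")
    if (!all(object@crossovers %in% c("pcc", "rsc")))
      msgs <- c(msgs, "crossovers must be a subset of {pcc, rsc}")
    if (!all(object@mutations %in% c("p4x", "flp", "csh")))
      msgs <- c(msgs, "mutations must be a subset of {p4x, flp, csh}")
    if (length(object@crossovers) + length(object@mutations) == 0L)
      msgs <- c(msgs, "at least one crossover or mutation operator required")
    if (object@cycleLength < 2L)
      msgs <- c(msgs, "cycleLength must be at least 2")
    if (object@mutationCeiling <= 0 || object@mutationCeiling >= 1)
      msgs <- c(msgs, "mutationCeiling must be in (0, 1)")
    if (object@eliteCount < 1L || object@eliteCount >= object@populationSize)
      msgs <- c(msgs, "eliteCount must satisfy 1 <= eliteCount < populationSize")
    if (length(msgs)) msgs else TRUE
  })

#' SolutionRecord: a realized double digest map
#'
#' A chromosome \eqn{(\mu, \nu)} together with the double digest sequence it
#' implies, its multiset mismatch against the observed \code{c}, the fitness
#' \eqn{1/(1+\mathrm{mismatch})}, and (for exact solutions) the permutation
#' \eqn{\pi} aligning \code{c} to the implied double digest sequence.
#'
#' @slot mu,nu integer permutations (one-line notation, 1-based).
#' @slot pi integer permutation over k for exact solutions, else empty.
#' @slot dds integer vector, realized double digest sequence.
#' @slot mismatch integer, multiset symmetric difference size.
#' @slot fitness numeric in (0, 1]; 1 iff mismatch is 0.
#' @slot generationFound integer generation at which the record was attained.
#' @export
setClass("SolutionRecord",
  representation(mu = "integer", nu = "integer", pi = "integer",
                 dds = "integer", mismatch = "integer", fitness = "numeric",
                 generationFound = "integer"),
  validity = function(object) {
    msgs <- character()
    if (!isTRUE(all.equal(object@fitness, 1 / (1 + object@mismatch))))
      msgs <- c(msgs, "fitness must equal 1/(1 + mismatch)")
    if ((object@mismatch == 0L) != (object@fitness == 1))
      msgs <- c(msgs, "mismatch 0 and fitness 1 must coincide")
    if (length(msgs)) msgs else TRUE
  })

#' GAResult: outcome of one evolutionary run
#'
#' @slot best best [SolutionRecord] ever observed.
#' @slot success logical, TRUE iff an exact solution (fitness 1) was found.
#' @slot generationsUsed last generation evaluated.
#' @slot fitnessTrace best population fitness per generation (non-decreasing
#'   under elitism).
#' @slot config the [GAConfig] used.
#' @slot seed the seed actually used for the run.
#' @slot runtime elapsed seconds (informational only).
#' @export
setClass("GAResult",
  representation(best = "SolutionRecord", success = "logical",
                 generationsUsed = "integer", fitnessTrace = "numeric",
                 config = "GAConfig", seed = "integer", runtime = "numeric"))

#' TrialStats: aggregate over repeated seeded runs
#'
#' @slot nTrials number of independent trials.
#' @slot successRate exact fraction successes/nTrials.
#' @slot meanGenerations mean generation of first exact solution over all
#'   trials (failed trials contribute the generation cap).
#' @slot meanRuntime mean elapsed seconds per trial (informational).
#' @slot trials list of per-trial [GAResult] objects.
#' @export
setClass("TrialStats",
  representation(nTrials = "integer", successRate = "numeric",
                 meanGenerations = "numeric", meanRuntime = "numeric",
                 trials = "list"))

#' ScalingReport: outcome of the scaling-rounding-adjusting transform
#'
#' @slot factor scale factor applied to all fragment lengths.
#' @slot t adjusting constant used by the rounding-up/down variants.
#' @slot variant one of "plain", "up", "down" (the selected candidate) or
#'   "failed" when no candidate has equal totals.
#' @slot candidates named list of the three candidate [DDPInstance]s.
#' @slot sums 3 x 3 numeric matrix of candidate totals (rows plain/up/down,
#'   columns a/b/c).
#' @slot scaled the selected valid [DDPInstance], or NULL on failure.
#' @export
setClass("ScalingReport",
  representation(factor = "numeric", t = "numeric", variant = "character",
                 candidates = "list", sums = "matrix", scaled = "ANY"))

#' OracleResult: exhaustive enumeration of a small instance
#'
#' @slot solutions list of exact chromosomes, each a list with elements
#'   \code{mu} and \code{nu}, in lexicographic order of (mu, nu).
#' @slot minMismatch smallest multiset mismatch over all chromosomes.
#' @slot searched number of chromosomes enumerated (m! * n!).
#' @slot canonicalCount solutions counted up to mirror symmetry.
#' @slot histogram named integer vector: chromosome counts per mismatch
#'   value.
#' @export
setClass("OracleResult",
  representation(solutions = "list", minMismatch = "integer",
                 searched = "numeric", canonicalCount = "integer",
                 histogram = "integer"))
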