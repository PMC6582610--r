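test_that("prefix sums and step differences are exact inverses on examples", {
  expect_identical(accumulativeSum(c(1, 5, 3, 2)), c(1L, 6L, 9L, 11L))
  expect_identical(accumulativeSum(7), 7L)
  expect_identical(accumulativeSum(c(0, 0, 5)), c(0L, 0L, 5L))
  expect_error(accumulativeSum(integer(0)), "empty")

  expect_identical(stepDifference(c(1, 3, 5, 6, 7, 9, 11)),
                   c(1L, 2L, 2L, 1L, 1L, 2L, 2L))
  expect_identical(stepDifference(5), 5L)
  # a repeated cut position yields a zero-length fragment
  expect_identical(stepDifference(c(2, 3, 5, 7, 7, 10, 11)),
                   c(2L, 1L, 2L, 2L, 0L, 3L, 1L))
  expect_error(stepDifference(c(3, 2)), "non-decreasing")
})

test_that("round-trip SD(AS(v)) = v holds over random fragment vectors", {
  set.seed(101)
  for (i in 1:500) {
    v <- randomFragmentVector()
    expect_identical(stepDifference(accumulativeSum(v)), as.integer(v))
  }
})

test_that("permuteFragments follows the gather convention", {
  expect_identical(permuteFragments(c(2, 2, 3, 4), c(3, 1, 2, 4)),
                   c(3L, 2L, 2L, 4L))
  expect_identical(permuteFragments(c(1, 2, 3, 5), 1:4), c(1L, 2L, 3L, 5L))
  expect_identical(permuteFragments(c(1, 2, 3, 5), c(1, 4, 3, 2)),
                   c(1L, 5L, 3L, 2L))
  expect_error(permuteFragments(1:3, 1:4), "size mismatch")
  expect_error(permuteFragments(1:3, c(1, 1, 2)), "not a permutation")
})

test_that("combining sequence concatenates cut positions, dropping b's tail", {
  expect_identical(combineDigests(c(1, 5, 3, 2), c(3, 2, 2, 4)),
                   c(1L, 6L, 9L, 11L, 3L, 5L, 7L))
  expect_identical(combineDigests(9, 9), 9L)
  expect_identical(combineDigests(c(1, 1), c(1, 1)), c(1L, 2L, 1L))
  expect_error(combineDigests(c(1, 2), c(4)), "invalid pair")
})

test_that("double digest sequence matches worked examples, with zeros at coincident cuts", {
  expect_identical(doubleDigestSequence(c(1, 5, 3, 2), c(3, 2, 2, 4)),
                   c(1L, 2L, 2L, 1L, 1L, 2L, 2L))
  expect_identical(doubleDigestSequence(c(2, 5, 3, 1), c(3, 2, 2, 4)),
                   c(2L, 1L, 2L, 2L, 0L, 3L, 1L))
  expect_identical(doubleDigestSequence(c(1, 1), c(1, 1)), c(1L, 0L, 1L))
})

test_that("dds agrees with independent site-marking and conserves totals", {
  set.seed(202)
  for (i in 1:300) {
    m <- sample(1:6, 1); n <- sample(1:6, 1); L <- sample(20:60, 1)
    gen <- randomInstance(m, n, L)
    a <- fragmentsA(gen$instance)[gen$groundTruth@mu]
    b <- fragmentsB(gen$instance)[gen$groundTruth@nu]
    d <- doubleDigestSequence(a, b)
    expect_identical(length(d), m + n - 1L)
    expect_identical(sum(d), sum(a))
    expect_identical(as.integer(d[d > 0L]), as.integer(ddsBySiteMarking(a, b)))
    # zeros appear exactly where both enzymes cut the same site
    nCoincident <- length(intersect(cumsum(a)[-m], cumsum(b)[-n]))
    expect_identical(sum(d == 0L), nCoincident)
  }
})

test_that("multiset mismatch counts multiplicity excess and is symmetric", {
  expect_identical(multisetMismatch(c(2, 1, 2, 2, 0, 3, 1),
                                    c(1, 1, 1, 2, 2, 2, 2)), 4L)
  expect_identical(multisetMismatch(c(1, 2, 2), c(1, 2, 3)), 2L)
  set.seed(303)
  for (i in 1:200) {
    x <- randomFragmentVector(8, 6); y <- randomFragmentVector(8, 6)
    expect_identical(multisetMismatch(x, y), multisetMismatch(y, x))
    expect_identical(multisetMismatch(x, y), mismatchByPairing(x, y))
    expect_identical(multisetMismatch(x, x), 0L)
  }
})

test_that("mismatch parity is even for equal-length operands", {
  set.seed(304)
  for (i in 1:200) {
    n <- sample(1:10, 1)
    x <- sample.int(5, n, replace = TRUE)
    y <- sample.int(5, n, replace = TRUE)
    expect_identical(multisetMismatch(x, y) %% 2L, 0L)
  }
})

test_that("fitness is 1/(1+mismatch), positive, and 1 only at exact solutions", {
  ex1 <- ddpFixtures()$example1
  expect_identical(chromosomeFitness(c(1, 4, 3, 2), c(3, 1, 2, 4), ex1), 1)
  expect_identical(chromosomeFitness(c(2, 4, 3, 1), c(3, 1, 2, 4), ex1), 0.2)
  set.seed(404)
  for (i in 1:50) {
    f <- chromosomeFitness(sample.int(4), sample.int(4), ex1)
    expect_gt(f, 0)
    expect_lte(f, 1)
  }
  unpadded <- DDPInstance(c(1, 1), c(1, 1), c(1, 1))
  expect_error(chromosomeFitness(1:2, 1:2, unpadded), "canonical")
})

test_that("extractPi aligns c to the realized double digest entrywise", {
  ex1 <- ddpFixtures()$example1
  pi <- extractPi(c(1, 4, 3, 2), c(3, 1, 2, 4), ex1)
  expect_identical(pi, c(1L, 4L, 5L, 2L, 3L, 6L, 7L))
  d <- doubleDigestSequence(c(1, 5, 3, 2), c(3, 2, 2, 4))
  expect_identical(permuteFragments(fragmentsC(ex1), pi), d)
  # identity when dds already equals c entrywise
  flat <- DDPInstance(c(2, 2), c(1, 3), c(1, 1, 2))
  expect_identical(extractPi(1:2, 1:2, flat), 1:3)
  expect_error(extractPi(c(2, 4, 3, 1), c(3, 1, 2, 4), ex1), "not an exact")
})

test_that("extractPi holds entrywise for every enumerated exact solution", {
  ex1 <- ddpFixtures()$example1
  for (sol in solveExhaustive(ex1)@solutions) {
    d <- doubleDigestSequence(permuteFragments(fragmentsA(ex1), sol$mu),
                              permuteFragments(fragmentsB(ex1), sol$nu))
    pi <- extractPi(sol$mu, sol$nu, ex1)
    expect_identical(permuteFragments(fragmentsC(ex1), pi), d)
  }
})

test_that("mapDistance is the normalized L1 gap between sorted cut sets", {
  mkSol <- function(dds) new("SolutionRecord", mu = 1L, nu = 1L,
                             pi = integer(0), dds = as.integer(dds),
                             mismatch = 1L, fitness = 0.5,
                             generationFound = 0L)
  s1 <- mkSol(c(2, 3, 5)); s2 <- mkSol(c(3, 2, 5))
  expect_identical(mapDistance(s1, s1, 10), 0)
  expect_identical(mapDistance(s1, s2, 10), 0.1)  # cuts {2,5} vs {3,5}
  expect_identical(mapDistance(s1, s2, 10), mapDistance(s2, s1, 10))
  expect_error(mapDistance(s1, mkSol(c(5, 5)), 10), "size error")
})
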