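test_that("referenced sorting reproduces the worked offspring chains", {
  expect_identical(referSort(c(1, 3, 4, 2, 2), c(1, 2, 2, 2, 4, 3, 3, 1)),
                   c(2, 2, 4, 3, 1))
  expect_identical(referSort(c(2, 4, 3, 3, 1), c(1, 3, 2, 1, 3, 4, 2, 2)),
                   c(3, 1, 3, 4, 2))
  ref <- c(4, 1, 3, 2)
  expect_identical(referSort(ref, ref), ref)
  expect_error(referSort(c(1, 1), c(1, 2)), "unmatchable")
})

test_that("referenced sorting returns a multiset-equal subsequence of the reference", {
  set.seed(11)
  for (i in 1:200) {
    ref <- sample.int(5, sample(3:10, 1), replace = TRUE)
    target <- sample(ref, sample.int(length(ref), 1))
    out <- referSort(target, ref)
    expect_identical(multisetMismatch(out, target), 0L)
    expect_true(isSubsequence(as.integer(out), as.integer(ref)))
  }
})

test_that("fixed-point RSC recombination matches the printed offspring", {
  fx <- ddpFixtures()$rscParents
  kids <- rscCombine(fx$p1, fx$p2, fx$point)
  expect_identical(kids[[1]], fx$c1)
  expect_identical(kids[[2]], fx$c2)
  expect_error(rscCombine(fx$p1, fx$p2, 8), "out of range")
})

test_that("composition crossover follows (p o q)(i) = p(q(i))", {
  id <- newChromosome(1:3, 1:4)
  ch <- newChromosome(c(2, 3, 1), c(4, 1, 3, 2))
  kids <- pccCross(ch, id)
  expect_identical(kids[[1]], ch)   # identity on the right
  expect_identical(kids[[2]], ch)   # identity on the left
  swap <- newChromosome(c(2, 1, 3), c(2, 1, 3, 4))
  expect_identical(pccCross(swap, swap)[[1]]$mu, 1:3)  # involution
  inv <- newChromosome(c(3, 1, 2), 1:4)
  fwd <- newChromosome(c(2, 3, 1), 1:4)
  expect_identical(pccCross(fwd, inv)[[1]]$mu, 1:3)
  expect_identical(pccCross(inv, fwd)[[1]]$mu, 1:3)
  expect_error(pccCross(id, newChromosome(1:4, 1:4)), "degree mismatch")
})

test_that("segment mutations reproduce printed fragments and their algebra", {
  fx <- ddpFixtures()
  expect_identical(flpMutate(fx$flpExample$input, 1, 4), fx$flpExample$output)
  expect_identical(cshMutate(fx$cshExample$input, 1, 4), fx$cshExample$output)
  p <- c(5, 2, 4, 1, 3)
  expect_identical(flpMutate(flpMutate(p, 2, 4), 2, 4), p)  # involution
  expect_identical(flpMutate(p, 2, 3), c(5, 4, 2, 1, 3))    # adjacent swap
  expect_identical(cshMutate(p, 2, 3), c(5, 4, 2, 1, 3))    # length 2 = swap
  q <- p
  for (i in 1:3) q <- cshMutate(q, 2, 4)                    # full cycle
  expect_identical(q, p)
  expect_error(flpMutate(1L), "at least 2")
})

test_that("all operators map valid chromosomes to valid chromosomes", {
  set.seed(12)
  isPerm <- function(p) identical(sort(as.integer(p)), seq_along(p))
  for (i in 1:100) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    ch1 <- newChromosome(sample.int(m), sample.int(n))
    ch2 <- newChromosome(sample.int(m), sample.int(n))
    for (kid in c(pccCross(ch1, ch2), rscCross(ch1, ch2),
                  list(p4xMutate(ch1)))) {
      expect_true(isPerm(kid$mu))
      expect_true(isPerm(kid$nu))
    }
    expect_true(isPerm(flpMutate(ch1$mu)))
    expect_true(isPerm(cshMutate(ch1$nu)))
  }
})

test_that("P4X touches exactly one transposition per component", {
  set.seed(13)
  for (i in 1:50) {
    ch <- newChromosome(sample.int(6), sample.int(7))
    kid <- p4xMutate(ch)
    expect_identical(sum(kid$mu != ch$mu), 2L)  # without replacement
    expect_identical(sum(kid$nu != ch$nu), 2L)
    expect_identical(sort(kid$mu), 1:6)
  }
  forced <- p4xMutate(newChromosome(1:2, 2:1))
  expect_identical(forced$mu, c(2L, 1L))
  expect_identical(forced$nu, 1:2)
})

test_that("roulette-wheel selection is fitness-proportional", {
  expect_error(rwsSelect(numeric(0), 1), "empty")
  expect_error(rwsSelect(c(1, 0), 1), "positive")
  set.seed(14)
  # uniform fitness: chi-square goodness of fit at alpha = 0.01
  draws <- rwsSelect(rep(1, 5), 10000)
  expect_gt(stats::chisq.test(tabulate(draws, 5))$p.value, 0.01)
  # 3:1 fitness ratio: frequency of the first index within 3 sigma of 0.75
  draws <- rwsSelect(c(3, 1), 40000)
  sigma <- sqrt(0.75 * 0.25 / 40000)
  expect_lt(abs(mean(draws == 1) - 0.75), 3 * sigma)
})

test_that("mutation schedule climbs linearly from 2/(m+n) to the ceiling", {
  expect_identical(mutationProbability(0, 2, 2), 0.5)
  expect_identical(mutationProbability(400, 2, 2), 0.5)  # cycle restart
  expect_equal(mutationProbability(199, 6, 6), 0.55)
  expect_equal(mutationProbability(199, 2, 2), 0.55)
  expect_identical(mutationProbability(0, 10, 10), 0.1)
  # non-negative increment within a cycle for every m + n >= 2
  for (mn in 2:40) {
    p <- vapply(0:199, mutationProbability, numeric(1),
                m = 1, n = mn - 1)
    expect_true(all(diff(p) >= 0))
    expect_equal(p[1], min(2 / mn, 0.55))  # floor clamped at the ceiling
    expect_equal(p[200], 0.55)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("operator-set parsing accepts the documented names", {
  expect_identical(parseOperators("all"),
                   list(crossovers = c("pcc", "rsc"),
                        mutations = c("p4x", "flp", "csh")))
  expect_identical(parseOperators("RWS,RSC,FLP"),
                   list(crossovers = "rsc", mutations = "flp"))
  expect_identical(parseOperators(c("pcc", "csh"))$mutations, "csh")
  expect_error(parseOperators("rws,xyz"), "unknown operator")
  combos <- benchmarkCombos()
  expect_identical(length(combos), 7L)
  expect_true(all(vapply(combos[1:6], function(x)
    length(x$crossovers) == 1 && length(x$mutations) == 1, logical(1))))
})
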