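test_that("generated instances are valid and certified by their ground truth", {
  set.seed(31)
  for (i in 1:40) {
    m <- sample(1:6, 1); n <- sample(1:6, 1); L <- sample(30:120, 1)
    gen <- randomInstance(m, n, L)
    expect_true(isValidInstance(gen$instance))
    expect_identical(totalLength(gen$instance), as.integer(L))
    padded <- padToCanonical(gen$instance)
    expect_identical(chromosomeFitness(gen$groundTruth@mu,
                                       gen$groundTruth@nu, padded), 1)
    # k before padding: m + n - 1 minus the A/B cut coincidences
    expect_lte(length(fragmentsC(gen$instance)), m + n - 1L)
    expect_true(all(fragmentsC(gen$instance) > 0L))
  }
})

test_that("the trivial generator case returns a single-fragment instance", {
  gen <- randomInstance(1, 1, 25, seed = 1)
  expect_identical(fragmentsA(gen$instance), 25L)
  expect_identical(fragmentsB(gen$instance), 25L)
  expect_identical(fragmentsC(gen$instance), 25L)
  expect_identical(gen$groundTruth@fitness, 1)
})

test_that("the rho cap is honoured by every accepted draw", {
  set.seed(32)
  for (i in 1:300) {
    gen <- randomInstance(4, 4, 40, rhoCMax = 12, seed = 3200 + i)
    expect_lte(max(fragmentsC(gen$instance)), 12L)
  }
})

test_that("infeasible generator requests are refused", {
  expect_error(randomInstance(4, 4, 3), "infeasible")
  # 7 fragments capped at 5 cannot sum to 100
  expect_error(randomInstance(4, 4, 100, rhoCMax = 5), "infeasible")
  # feasible in principle, unreachable by rejection within the cap
  expect_error(randomInstance(6, 6, 300, rhoCMax = 28, seed = 1,
                              maxResample = 10L), "resample cap")
})

test_that("scaling-rounding-adjusting reports all candidates and picks the first valid", {
  # synthetic, checked by direct arithmetic (half-away-from-zero rounding):
  # a=(14,26)*0.1: plain (1,3)=4, up (2,3)=5, down (1,3)=4  [2.5 -> 3]
  # b=(19,21)*0.1: plain (2,2)=4, up (2,2)=4, down (2,2)=4
  # c=(14,5,21)*0.1: plain (1,1,2)=4 [0.5 -> 1], up (2,1,2)=5, down (1,0,2)=3
  ins <- DDPInstance(c(14, 26), c(19, 21), c(14, 5, 21))
  rep_ <- scaleRoundAdjust(ins, 0.1, 0.1)
  expect_identical(unname(rep_@sums["plain", ]), c(4, 4, 4))
  expect_identical(unname(rep_@sums["up", ]), c(5, 4, 5))
  expect_identical(unname(rep_@sums["down", ]), c(4, 4, 3))
  expect_identical(rep_@variant, "plain")
  expect_true(isValidInstance(rep_@scaled))

  # identity: factor 1 on an integer instance keeps it unchanged
  ex1 <- ddpFixtures()$example1
  rep1 <- scaleRoundAdjust(ex1, 1, 0.1)
  expect_identical(rep1@variant, "plain")
  expect_identical(fragmentsA(rep1@scaled), fragmentsA(ex1))

  expect_error(scaleRoundAdjust(ex1, 0, 0.1), "factor")
  expect_error(scaleRoundAdjust(ex1, 0.5, 0.6), "t must lie")
  expect_error(scaleRoundAdjust(ddpFixtures()$scaledUp, 1), "invalid")
})

test_that("variant selection walks plain, up, down and reports the sums", {
  fx <- ddpFixtures()
  sel <- selectScalingVariant(list(plain = fx$scaledPlain, up = fx$scaledUp,
                                   down = fx$ins2prime))
  expect_identical(sel$variant, "down")
  expect_identical(unname(sel$sums["plain", ]), c(50, 49, 51))
  expect_identical(unname(sel$sums["up", ]), c(50, 50, 51))
  expect_identical(unname(sel$sums["down", ]), c(48, 48, 48))
  none <- selectScalingVariant(list(plain = fx$scaledPlain,
                                    up = fx$scaledUp))
  expect_identical(none$variant, "failed")
})

test_that("the suggested scale factor brings the smallest fragment to >= 1", {
  big <- DDPInstance(c(3000, 45502), c(20000, 28502),
                     c(1120, 1880, 45502))
  expect_identical(suggestScaleFactor(big), 0.001)
  expect_identical(suggestScaleFactor(ddpFixtures()$example1), 1)
})

test_that("packaged fixtures are bit-exact", {
  fx <- ddpFixtures()
  expect_identical(fragmentsA(fx$ins2prime), c(5L, 6L, 6L, 7L, 7L, 17L))
  expect_identical(fragmentsB(fx$ins2prime), c(3L, 5L, 6L, 6L, 7L, 21L))
  expect_identical(fragmentsC(fx$ins2prime),
                   c(1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 5L, 5L, 16L))
  expect_identical(totalLength(fx$example1), 11L)
  expect_identical(unname(validateInstance(fx$scaledUp)$sums),
                   c(50L, 50L, 51L))
  expect_identical(fx$rscParents$point, 3L)
})
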