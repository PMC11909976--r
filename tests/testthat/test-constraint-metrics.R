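# independent grid oracle: evaluates the Poisson pmf from its formula
# (lambda^k e^-lambda / k!) rather than through dpois
oracleBounds <- function(k, lambda, step = 0.001, gridMax = 2) {
  x <- seq(0, gridMax, by = step)
  lam <- x * lambda
  logpmf <- ifelse(lam == 0, ifelse(k == 0, 0, -Inf),
                   k * log(lam) - lam - lgamma(k + 1))
  pmf <- exp(logpmf)
  cum <- cumsum(pmf) / sum(pmf)
  c(x[which(cum >= 0.05)[1]], x[which(cum >= 0.95)[1]])
}

test_that("grid bounds match the worked examples", {
  b <- poissonBounds(0, 30)
  # closed form for k = 0: cumulative is a geometric partial sum
  q <- exp(-30 * 0.001)
  closed <- 0.001 * (ceiling(log(1 - 0.95 * (1 - q^2001)) / log(q)) - 1)
  expect_lt(abs(b$upper - closed), 0.001 + 1e-12)
  expect_lt(abs(b$upper - 0.1), 0.002)
  b10 <- poissonBounds(10, 10)
  expect_lt(b10$lower, 1)
  expect_gt(b10$upper, 1)
  # doubling the expected count tightens the k = 0 upper bound
  expect_lt(poissonBounds(0, 60)$upper, poissonBounds(0, 30)$upper)
})

test_that("grid bounds agree with the independent oracle on a small lattice", {
  for (lambda in c(1, 5, 10)) {
    for (k in c(0:6, 10, 15)) {
      got <- poissonBounds(k, lambda)
      want <- oracleBounds(k, lambda)
      expect_lt(abs(got$lower - want[1]), 0.001 + 1e-12)
      expect_lt(abs(got$upper - want[2]), 0.001 + 1e-12)
    }
  }
})

test_that("bounds are monotone in observed and expected counts", {
  ks <- c(0, 2, 5, 10, 20)
  up <- poissonBounds(ks, 10)$upper
  expect_true(all(diff(up) > 0))  # non-decreasing in k
  lams <- c(5, 10, 20, 50)
  upl <- poissonBounds(5, lams)$upper
  expect_true(all(diff(upl) < 1e-12))  # non-increasing in lambda'
  expect_error(poissonBounds(5, 0), "positive")
  expect_error(poissonBounds(-1, 5), "non-negative")
  expect_error(poissonBounds(2.5, 5), "integer")
})

test_that("computeOeuf flags power at expected >= 10 and degenerate inputs", {
  res <- computeOeuf(c(5, 10, 0), c(9.9, 10, 0), c("a", "b", "c"))
  expect_equal(res$powered, c(FALSE, TRUE, FALSE))
  expect_true(is.na(res[3, ]$upper))  # expected 0: not computable
  resEq <- computeOeuf(12, 12, "e")
  expect_equal(resEq$ratio, 1)
  expect_true(resEq$lower < 1 && resEq$upper > 1)
})

test_that("decile cut-off takes the maximum of the most constrained bin", {
  d <- decileCutoff(1:100)
  expect_equal(d$cutoff, 10)
  expect_equal(sort(unique(d$decile)), 1:10)
  expect_equal(d$decile[1:10], rep(1L, 10))
  # degenerate: all values equal
  expect_equal(decileCutoff(rep(3.3, 20))$cutoff, 3.3)
  # n = 25: the lowest bin holds floor(25/10) = 2 values
  v <- sort(runif(25))
  d25 <- decileCutoff(v)
  expect_equal(sum(d25$decile == 1L), 2L)
  expect_equal(d25$cutoff, v[2])
  expect_error(decileCutoff(1:9), "at least 10")
  # about a tenth of tie-free values sit at or below the cutoff
  set.seed(8)
  x <- rnorm(1000)
  dc <- decileCutoff(x)
  expect_equal(mean(x <= dc$cutoff), 0.1, tolerance = 1e-9)
})

test_that("frame-respect flag is a strict comparison over powered pairs", {
  expect_true(frameRespectFlag(0.6, 0.933))
  expect_false(frameRespectFlag(0.9, 0.9))
  expect_true(is.na(frameRespectFlag(0.6, 0.9, moeufPowered = FALSE)))
})

test_that("regional UTR constraint needs deciles separated by two others", {
  expect_true(regionalUtrConstraint(c(1, 4)))
  expect_false(regionalUtrConstraint(c(1, 3)))
  expect_true(regionalUtrConstraint(c(2, 2, 7)))
  expect_false(regionalUtrConstraint(5))
  # powered and length filters drop UTRs before the comparison
  expect_false(regionalUtrConstraint(c(1, 4), expected = c(12, 3)))
  expect_false(regionalUtrConstraint(c(1, 4), lengths = c(900, 100),
                                     minLen = 800))
  expect_true(regionalUtrConstraint(c(1, 9, 4), expected = c(12, 2, 15)))
  expect_error(regionalUtrConstraint(c(1, 4), minLen = 800), "lengths")
})

test_that("oeufTable assembles the three constraint classes with deciles", {
  set.seed(21)
  n <- 30
  ids <- sprintf("e%02d", 1:n)
  obs <- data.table(sorf_id = rep(ids, each = 5),
                    consequence = rep(c("synonymous", "missense", "stop_gain",
                                        "stop_loss", "start_loss"), n),
                    observed = rpois(5 * n, 8))
  ex <- data.table(sorf_id = rep(ids, each = 5),
                   consequence = rep(c("synonymous", "missense", "stop_gain",
                                       "stop_loss", "start_loss"), n),
                   n_possible = 10L, rate_sum = 1,
                   expected = runif(5 * n, 4, 12))
  res <- oeufTable(obs, ex)
  expect_equal(nrow(res), 3 * n)
  expect_setequal(unique(res$class), c("SNVOEUF", "MOEUF", "LOEUF"))
  expect_true(all(res$upper >= res$lower, na.rm = TRUE))
  expect_true(all(res$upper <= 2, na.rm = TRUE))
  snv <- res[class == "SNVOEUF"]
  expect_true(all(snv$powered == (snv$expected >= 10)))
  expect_true(all(!is.na(snv[powered == TRUE, decile])))
})
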