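# Statistical toolkit against brute-force oracles.

test_that("pearson on exact linear relations", {
  x <- c(1, 2, 3, 4, 7)
  expect_equal(pearson(x, 2 * x + 3)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  # hand-computed from the definition: r = 3 / sqrt(5 * 5)
  expect_equal(pearson(1:4, c(2, 1, 4, 3))$r, 0.6)
  expect_error(pearson(x, rep(1, 5)), "constant")
  expect_equal(pearson(x, 5 - 0.01 * x)$r, -1)  # sign follows the slope
})

# brute-force Mann-Whitney: exact two-sided p by enumerating every assignment
# of the pooled values into groups of the observed sizes
mw_brute <- function(a, b) {
  pool <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pool), n)
  ustat <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  obs <- ustat(a, b)
  us <- apply(idx, 2, function(i) ustat(pool[i], pool[-i]))
  mu <- n * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

test_that("Mann-Whitney exact p matches enumeration for all group sizes <= 8", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  set.seed(99)
  sizes <- list(c(2, 2), c(2, 3), c(2, 6), c(3, 3), c(3, 5), c(4, 4),
                c(4, 8), c(5, 8), c(8, 8))
  for (s in sizes) {
    a <- round(rnorm(s[1]), 3)
    b <- round(rnorm(s[2], 0.5), 3)
    got <- mann_whitney(a, b)
    expect_equal(got$p, mw_brute(a, b), tolerance = 1e-10,
                 label = sprintf("m=%d n=%d", s[1], s[2]))
  }
})

test_that("identical samples give p near 1", {
  a <- c(1.2, 3.4, 5.6, 7.8)
  expect_gt(mann_whitney(a, a)$p, 0.99)
})

test_that("star mapping follows the 0.05/0.01/0.001 thresholds", {
  expect_equal(p_stars(c(0.2, 0.04, 0.004, 4e-4)),
               c("", "*", "**", "***"))
})

test_that("partial correlation recovers a planted single driver", {
  set.seed(7)
  n <- 1000
  X <- matrix(runif(n * 6), n, 6,
              dimnames = list(NULL, paste0("p", 1:6)))
  y <- 3 * X[, 2] + rnorm(n, 0, 0.05)
  pc <- partial_correlation(X, y)
  expect_gt(pc$pcc[pc$parameter == "p2"], 0.99)
  expect_true(all(abs(pc$pcc[pc$parameter != "p2"]) < 0.1))
  expect_lt(pc$p[pc$parameter == "p2"], 1e-10)
})

test_that("partial correlation equals pearson for a single parameter", {
  set.seed(8)
  x <- rnorm(30)
  y <- 0.8 * x + rnorm(30)
  pc <- partial_correlation(matrix(x, ncol = 1, dimnames = list(NULL, "x")), y)
  expect_equal(pc$pcc, pearson(x, y)$r, tolerance = 1e-12)
})

test_that("partial correlation signs match plain correlation on an orthogonal design", {
  set.seed(9)
  X <- lhs_sample(400, seed = 5)[, 1:5]
  y <- 2 * X[, 1] - 1.5 * X[, 3] + 0.5 * X[, 5] + rnorm(400, 0, 0.3)
  pc <- partial_correlation(X, y)
  plain <- apply(X, 2, function(col) pearson(col, y)$r)
  # parameters with real effects keep their sign; null parameters stay small
  planted <- c(1, 3, 5)
  expect_true(all(sign(pc$pcc[planted]) == sign(plain[planted])))
  expect_true(all(sign(pc$pcc[planted]) == c(1, -1, 1)))
  expect_true(all(abs(pc$pcc[-planted]) < 0.2))
})

test_that("rank-deficient designs are reported with the offending column", {
  X <- cbind(a = 1:20, b = (1:20) * 2, c = rnorm(20))
  expect_error(partial_correlation(X, rnorm(20)), "collinear")
})
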