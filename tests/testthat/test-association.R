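# Permutation-framework association test and cutpoint search against
# independent oracles.

test_that("degenerate inputs return p = 1 by convention", {
  y <- c(0, 0, 1, 1, 0, 1)
  # constant predictor
  r <- association_test(rep(2, 6), y)
  expect_equal(r$p_value, 1); expect_equal(r$statistic, 0)
  # pure node (all negatives): V = 0
  r <- association_test(1:6, rep(0, 6))
  expect_equal(r$p_value, 1)
  expect_error(association_test(1:6, y, w = c(-1, rep(1, 5))), "negative")
})

test_that("asymptotic p matches the exact enumeration for the separable worked case", {
  x <- 1:6; y <- c(0, 0, 0, 1, 1, 1)
  r <- association_test(x, y)
  # frozen from the moment formulas: T = 15, mu = 10.5, Cov = 5.25
  expect_equal(r$statistic, 4.5 / sqrt(5.25), tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pnorm(-4.5 / sqrt(5.25)), tolerance = 1e-12)
  # exact enumeration over all choose(6,3) = 20 assignments: 0.10 with the
  # inclusive (>=) convention, 0.05 with the mid-p convention for a fully
  # discrete null; the asymptotic value sits between them
  expect_equal(exact_perm_p(x, y), 0.10, tolerance = 1e-12)
  expect_equal(exact_perm_midp(x, y), 0.05, tolerance = 1e-12)
  expect_lt(abs(r$p_value - exact_perm_midp(x, y)), 0.05)
  # the exact enumeration variance equals the closed-form moment
  expect_equal(exact_perm_var(x, y), 5.25, tolerance = 1e-12)
})

test_that("asymptotic p converges to the Monte Carlo permutation p", {
  # at moderate n with a well-behaved predictor the normal approximation
  # must track the true permutation distribution closely; this checks the
  # conditional moment formulas end to end
  set.seed(42)
  worst <- 0
  for (i in 1:8) {
    n <- 60; k <- 18
    x <- rnorm(n)
    y <- sample(c(rep(1, k), rep(0, n - k)))
    p_asym <- association_test(x, y)$p_value
    tobs <- sum(x[y == 1])
    Ts <- replicate(30000, sum(x[sample(n, k)]))
    p_mc <- mean(abs(Ts - mean(Ts)) >= abs(tobs - mean(Ts)) - 1e-9)
    worst <- max(worst, abs(p_asym - p_mc))
  }
  expect_lt(worst, 0.03)
})

test_that("statistic is invariant under affine transforms of x (up to sign)", {
  set.seed(9)
  x <- rlnorm(60, 1, 1.5)
  y <- rbinom(60, 1, 0.3)
  s0 <- association_test(x, y)$statistic
  expect_equal(association_test(3.7 * x - 12, y)$statistic, s0, tolerance = 1e-9)
  expect_equal(association_test(-x, y)$statistic, s0, tolerance = 1e-9)
})

test_that("nominal predictors use the chi-square quadratic form", {
  set.seed(10)
  x <- factor(sample(c("a", "b", "c", "d"), 200, replace = TRUE))
  y <- rbinom(200, 1, ifelse(x == "a", 0.6, 0.2))
  g <- encode_predictor(x)
  expect_equal(dim(g), c(200L, 4L))
  expect_true(all(rowSums(g) == 1))
  r <- association_test(g, y)
  expect_equal(r$df, 3L)  # indicators sum to 1, so rank k - 1
  # cross-check against the classical Pearson chi-square statistic, to
  # which the quadratic form reduces for a one-way indicator matrix
  # (up to the W/(W-1) permutation-variance factor)
  cs <- suppressWarnings(chisq.test(table(x, y), correct = FALSE))$statistic
  expect_equal(r$statistic, as.numeric(cs) * (200 - 1) / 200, tolerance = 1e-9)
})

test_that("weighted test equals the test on expanded records", {
  set.seed(11)
  x <- rnorm(30)
  y <- rbinom(30, 1, 0.4)
  w <- sample(0:3, 30, replace = TRUE)
  if (sum(w > 0) < 2 || var(y[w > 0]) == 0) skip("degenerate draw")
  idx <- rep(seq_along(x), w)
  a <- association_test(x, y, w = w)
  b <- association_test(x[idx], y[idx])
  expect_equal(a$statistic, b$statistic, tolerance = 1e-9)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
})

test_that("cutpoint search equals brute-force maximization on random instances", {
  set.seed(12)
  for (i in 1:30) {
    n <- sample(20:60, 1)
    x <- sample(round(rlnorm(n, 1, 1), 1))  # ties on purpose
    y <- rbinom(n, 1, 0.35)
    if (var(y) == 0) next
    mb <- sample(1:5, 1)
    got <- find_cutpoint(x, y, minbucket = mb)
    want <- brute_cutpoint(x, y, minbucket = mb)
    expect_identical(is.null(got), is.null(want))
    if (!is.null(got)) {
      expect_equal(got$cutpoint, want$cutpoint)
      expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
    }
  }
})

test_that("perfect separation yields the boundary cutpoint, ties to the left", {
  r <- find_cutpoint(c(1, 1, 2, 2), c(0, 0, 1, 1), minbucket = 1)
  expect_equal(r$cutpoint, 1)  # reported as the largest left-going value
  # no admissible candidate under minbucket
  expect_null(find_cutpoint(c(1, 1, 2, 2), c(0, 0, 1, 1), minbucket = 3))
  # constant x
  expect_null(find_cutpoint(rep(1, 10), rbinom(10, 1, 0.5), minbucket = 1))
})

test_that("cutpoint recovery at a strong planted jump lands near the cutoff", {
  set.seed(13)
  hits <- replicate(100, {
    tg <- rlnorm(1000, log(3), 1.97)
    y <- rbinom(1000, 1, ifelse(tg > 35, 0.563, 0.058))
    if (var(y) == 0) return(NA)
    cp <- find_cutpoint(tg, y, minbucket = 7)$cutpoint
    abs(cp - 35) / 35 <= 0.15
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.90)
})

test_that("Bonferroni selection keeps the signal variable and stops on noise", {
  # m = 1: adjusted p equals raw p
  set.seed(14)
  d1 <- data.frame(tg = rlnorm(300, 1, 1))
  y1 <- rbinom(300, 1, ifelse(d1$tg > 3, 0.5, 0.1))
  sel <- select_split_variable(d1, y1, alpha = 0.05)
  expect_equal(sel$variable, "tg")
  expect_equal(sel$p_adj, sel$p_raw)
  # Bonferroni arithmetic: 9 noise predictors, best raw p multiplied by 9
  expect_error(select_split_variable(d1[, 0], y1), "empty predictor")
  # signal-only-in-Tg planted design: whenever a split variable passes the
  # Bonferroni gate it is Tg in >= 95% of seeds, and the gate opens in the
  # large majority of them
  set.seed(15)
  picks <- replicate(100, {
    n <- 500
    d <- data.frame(tg = rlnorm(n, log(3), 1.97), age = rnorm(n, 49, 14),
                    raiu = rlnorm(n, log(4.4), 0.9),
                    sex = factor(sample(c("M", "F"), n, TRUE)))
    y <- rbinom(n, 1, ifelse(d$tg > 35, 0.563, 0.058))
    if (var(y) == 0) return(NA_character_)
    s <- select_split_variable(d, y, alpha = 0.05)
    if (is.null(s)) "stop" else s$variable
  })
  picks <- picks[!is.na(picks)]
  selected <- picks[picks != "stop"]
  expect_gte(mean(selected == "tg"), 0.95)
  expect_gte(length(selected) / length(picks), 0.80)
})
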