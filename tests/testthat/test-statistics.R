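test_that("exact signed-rank p-values equal brute-force enumeration", {
  # worked small cases
  expect_equal(wilcoxon_paired(c(0, 0, 0), c(1, 2, 3))$p_value, 2 / 8)
  r <- wilcoxon_paired(1:9, (1:9) + 1)
  expect_equal(r$p_value, 2 / 512)

  # random cases incl. ties and zero differences, n <= 10: exact equality
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    d <- sample(c(-3, -2, -1, 0, 1, 2, 3, 0.5, 1.5), n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    p_impl <- wilcoxon_paired(rep(0, n), d)$p_value
    expect_identical(p_impl, brute_signed_rank_p(d))
  }

  # agreement with the reference implementation when there are no ties
  set.seed(8)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(wilcoxon_paired(x, y)$p_value,
               stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)

  # all-zero differences
  expect_warning(r0 <- wilcoxon_paired(c(1, 2), c(1, 2)), "zero")
  expect_equal(r0$p_value, 1)
})

test_that("normal approximation reproduces clinically reported p-values", {
  # nine all-positive differences: exact 0.0039, normal approximation 0.008
  ref <- load_reference_indices()
  pre <- ref[ref$state == "pre", ]; post <- ref[ref$state == "post", ]
  expect_equal(wilcoxon_paired(pre$mpa_vo, post$mpa_vo)$p_value, 2 / 512)
  expect_equal(
    wilcoxon_paired(pre$mpa_vo, post$mpa_vo, method = "normal_approx")$p_value,
    0.008, tolerance = 0.05)
  # energy dissipation pairs: exact 0.031, tie-corrected normal 0.033
  expect_equal(wilcoxon_paired(pre$ed_mw, post$ed_mw)$p_value, 0.031,
               tolerance = 0.02)
  expect_equal(
    wilcoxon_paired(pre$ed_mw, post$ed_mw, method = "normal_approx")$p_value,
    0.033, tolerance = 0.02)
})

test_that("rank-sum test enumerates group assignments exactly", {
  expect_equal(wilcoxon_ranksum(c(1, 2), c(3, 4))$p_value, 2 / 6,
               tolerance = 1e-12)
  r <- wilcoxon_ranksum(c(5, 6), c(5, 6))
  expect_equal(r$p_value, 1)
  expect_error(wilcoxon_ranksum(numeric(0), 1), "non-empty")

  # agreement with the reference implementation (no ties)
  set.seed(13)
  x <- rnorm(7); y <- rnorm(6) + 0.5
  expect_equal(wilcoxon_ranksum(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)

  # exact vs continuity-corrected normal approximation close at the study's
  # group size
  set.seed(17)
  agree <- replicate(20, {
    a <- rnorm(9); b <- rnorm(9) + runif(1, -1, 1)
    abs(wilcoxon_ranksum(a, b)$p_value -
          wilcoxon_ranksum(a, b, method = "normal_approx",
                           correct = TRUE)$p_value)
  })
  expect_lt(max(agree), 0.02)
})

test_that("exact signed-rank test keeps its nominal size under the null", {
  set.seed(19)
  n <- 9; reps <- 4000
  rej <- 0
  for (i in seq_len(reps)) {
    d <- rnorm(n)
    if (wilcoxon_paired(rep(0, n), d)$p_value <= 0.05) rej <- rej + 1
  }
  expect_lte(rej / reps, 0.06)
})

test_that("screened regression recovers known coefficients", {
  # noiseless: exact recovery
  set.seed(3)
  X <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  y <- 2 * X$x1 - 1.5 * X$x2 + 3
  rep <- screened_regression(X, y)
  expect_setequal(rep$screened, c("x1", "x2"))
  est <- rep$multivariable$estimate[match(c("x1", "x2"),
                                          rep$multivariable$variable)]
  expect_equal(est, c(2, -1.5), tolerance = 1e-10)

  # with noise: true effects within 2 SE, null covariate screened out
  set.seed(4)
  n <- 200
  X2 <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y2 <- 1.5 * X2$x1 - 0.8 * X2$x2 + rnorm(n)
  rep2 <- screened_regression(X2, y2)
  expect_true(all(c("x1", "x2") %in% rep2$screened))
  m <- rep2$multivariable
  for (v in c("x1", "x2")) {
    truth <- c(x1 = 1.5, x2 = -0.8)[[v]]
    i <- match(v, m$variable)
    expect_lt(abs(m$estimate[i] - truth), 2 * m$se[i])
  }

  # duplicated covariates: rank-deficiency error naming the column
  X3 <- data.frame(x1 = rnorm(50))
  X3$x2 <- X3$x1
  y3 <- 3 * X3$x1 + rnorm(50, sd = 0.1)
  expect_error(screened_regression(X3, y3), "collinear")

  # constant covariate guard
  expect_error(screened_regression(data.frame(x1 = rep(1, 10)), rnorm(10)),
               "constant")
})

test_that("lowering alpha never enlarges the screened set", {
  set.seed(6)
  n <- 60
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  y <- 1.2 * X$x1 - 0.4 * X$x2 + rnorm(n)
  sets <- lapply(c(0.2, 0.1, 0.05, 0.01), function(a) {
    screened_regression(X, y, alpha = a)$screened
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("factors are screened through their overall F test", {
  set.seed(9)
  n <- 80
  g <- factor(sample(c("low", "high"), n, replace = TRUE))
  x <- rnorm(n)
  y <- ifelse(g == "high", 2, 0) + 0.5 * x + rnorm(n, sd = 0.5)
  rep <- screened_regression(data.frame(group = g, x = x), y)
  expect_true("group" %in% rep$screened)
})
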