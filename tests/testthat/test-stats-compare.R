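test_that("two time points need no sphericity adjustment", {
  set.seed(1)
  Y <- matrix(rnorm(20), 10, 2)
  r <- rmAnova(longFromWide(Y))
  expect_identical(r@epsilonGG, 1)
  expect_true(r@sphericityApplied)
  expect_true(is.na(r@mauchlyW))
  # with k = 2 the RM-ANOVA F equals the squared paired t statistic
  tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
  expect_equal(r@F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r@p, tt$p.value, tolerance = 1e-10)
})

test_that("F, epsilon and Mauchly agree with independent oracles", {
  set.seed(42)
  Y <- matrix(rnorm(12), 4, 3) + rep(c(0, 0.5, 1), each = 4)
  r <- rmAnova(longFromWide(Y))
  # explicit sums-of-squares oracle
  br <- bruteRmAnovaF(Y)
  expect_equal(r@F, br$F, tolerance = 1e-10)
  expect_equal(r@pUncorrected, br$p, tolerance = 1e-10)

  # multivariate-model oracles from stats and car
  fit <- lm(Y ~ 1)
  idata <- data.frame(time = factor(1:3))
  mt <- mauchly.test(fit, X = ~1)
  expect_equal(r@mauchlyW, unname(mt$statistic), tolerance = 1e-8)
  expect_equal(r@mauchlyP, mt$p.value, tolerance = 1e-8)
  s <- summary(car::Anova(fit, idata = idata, idesign = ~time, type = 3),
               multivariate = FALSE)
  expect_equal(r@epsilonGG, unname(s$pval.adjustments["time", "GG eps"]),
               tolerance = 1e-8)
})

test_that("listwise deletion drops incomplete subjects", {
  d <- longFromWide(matrix(rnorm(30), 10, 3))
  d <- d[!(d$subject == 1 & d$time == 3), ]   # censor one subject
  r <- rmAnova(d)
  expect_identical(r@nSubjects, 9L)
  expect_error(rmAnova(d[d$subject == 1, ]), "insufficient")
  expect_error(
    rmAnova(rbind(d, d[1, ])), "at most once")
})

test_that("the F statistic is invariant under adding a constant", {
  set.seed(5)
  d <- longFromWide(matrix(rnorm(24), 8, 3))
  r1 <- rmAnova(d)
  d2 <- d; d2$value <- d2$value + 1234.5
  r2 <- rmAnova(d2)
  expect_equal(r1@F, r2@F, tolerance = 1e-9)
  expect_equal(r1@epsilonGG, r2@epsilonGG, tolerance = 1e-9)
})

test_that("epsilon stays within its theoretical bounds on random designs", {
  set.seed(11)
  for (i in 1:200) {
    k <- sample(3:5, 1)
    n <- sample((k + 2):12, 1)
    Y <- matrix(rnorm(n * k), n, k) %*%
      chol(crossprod(matrix(rnorm(k * k), k)) + diag(k))
    r <- rmAnova(longFromWide(Y))
    expect_gte(r@epsilonGG, 1 / (k - 1) - 1e-9)
    expect_lte(r@epsilonGG, 1 + 1e-9)
  }
})

test_that("Bonferroni adjustment is the capped multiple of the raw p", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 3), 1.0)
  expect_equal(bonferroni(c(0.2, 0.01), 1), c(0.2, 0.01))
  expect_error(bonferroni(0.1, 0), "at least 1")
  # monotone, order preserving
  p <- sort(runif(20))
  adj <- bonferroni(p, 20)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p))
})

test_that("post-tests appear only when the omnibus test is significant", {
  set.seed(2)
  base <- matrix(rnorm(30, sd = 0.2), 10, 3)
  strong <- base + rep(c(0, 2, 4), each = 10)
  r <- rmAnova(longFromWide(strong))
  expect_lt(r@p, 0.05)
  expect_identical(nrow(r@posthoc), 3L)
  expect_true(all(r@posthoc$pAdj >= r@posthoc$pRaw))
  expect_true(all(r@posthoc$pAdj <= 1))

  weak <- matrix(rnorm(30), 10, 3)
  rw <- rmAnova(longFromWide(weak))
  if (rw@p >= 0.05) expect_identical(nrow(rw@posthoc), 0L)
})

test_that("statSummary reports mean, n-1 SD and n per cell", {
  d <- data.frame(g = c("a", "a", "a", "b"), v = c(100, 200, 300, 7))
  s <- statSummary(d, value = "v", by = "g")
  a <- s[s$cell == "a", ]
  expect_equal(a$mean, 200)
  expect_equal(a$sd, 100)
  expect_identical(a$n, 3L)
  expect_true(is.na(s$sd[s$cell == "b"]))

  # two-pass oracle on a random table
  set.seed(8)
  d2 <- data.frame(g = sample(letters[1:3], 60, TRUE), v = rnorm(60))
  s2 <- statSummary(d2, value = "v", by = "g")
  for (gl in unique(d2$g)) {
    v <- d2$v[d2$g == gl]
    m <- sum(v) / length(v)
    expect_equal(s2$mean[s2$cell == gl], m, tolerance = 1e-12)
    expect_equal(s2$sd[s2$cell == gl],
                 sqrt(sum((v - m)^2) / (length(v) - 1)), tolerance = 1e-12)
  }
})
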