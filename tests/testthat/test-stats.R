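test_that("normality gate behaves at its nominal level", {
  set.seed(70)
  parametric <- replicate(200, normality_gate(rnorm(50))$parametric)
  expect_gte(mean(parametric), 0.90)
  expect_lte(mean(parametric), 0.99)
  heavy <- replicate(100, normality_gate(rlnorm(50))$parametric)
  expect_lte(mean(heavy), 0.10)
  expect_error(normality_gate(c(1, 2)), "n >= 3")
})

test_that("paired_compare handles the degenerate all-equal case", {
  s <- paired_sample(1:5, c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  r <- paired_compare(s)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_match(r$test_name, "degenerate")
})

test_that("paired t equals the closed-form statistic on toy pairs", {
  a <- c(1.0, 2.1, 3.4, 4.2, 5.1)
  b <- a + c(0.6, 1.3, 0.8, 1.6, 1.1)
  r <- paired_compare(paired_sample(1:5, a, b))
  d <- b - a
  expect_equal(r$test_name, "paired t-test")
  expect_equal(r$statistic, mean(d) / (sd(d) / sqrt(5)))
  expect_equal(r$df, 4)
  expect_equal(r$means, c(mean(a), mean(b)))
  expect_equal(r$ses, c(sd(a) / sqrt(5), sd(b) / sqrt(5)))
})

test_that("strongly non-normal differences route to the Wilcoxon branch", {
  # four identical differences plus one outlier fail the Shapiro gate
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 3, 4, 5, 7)
  r <- paired_compare(paired_sample(1:5, a, b))
  expect_equal(r$test_name, "Wilcoxon signed-rank")
  expect_lt(r$normality_p, 0.05)
  expect_true(is.na(r$df))
})

test_that("p-values are invariant to joint animal reordering", {
  set.seed(71)
  a <- rnorm(12)
  b <- rnorm(12, 0.5)
  p1 <- paired_compare(paired_sample(1:12, a, b))$p_value
  o <- sample(12)
  p2 <- paired_compare(paired_sample(1:12, a[o], b[o]))$p_value
  expect_equal(p1, p2)
})

test_that("rejection rate grows with the true shift", {
  set.seed(72)
  reps <- 400
  rates <- vapply(c(0, 0.5, 1.0), function(shift) {
    mean(replicate(reps, {
      a <- rnorm(15)
      b <- rnorm(15, shift)
      paired_compare(paired_sample(1:15, a, b))$p_value < 0.05
    }))
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_lt(rates[1], 0.1)
  expect_gt(rates[3], 0.6)
})

test_that("rm-ANOVA reduces to the paired t at k = 2", {
  set.seed(73)
  m <- matrix(rnorm(20), 10, 2)
  r <- rm_anova_gg(m, posthoc = FALSE)
  tt <- t.test(m[, 1], m[, 2], paired = TRUE)
  expect_equal(r$epsilon, 1)
  expect_equal(r$F, unname(tt$statistic)^2)
  expect_equal(r$p_value, tt$p.value)
})

test_that("identical columns give F = 0, p = 1", {
  m <- matrix(rnorm(8), 8, 1)[, c(1, 1, 1)]
  r <- rm_anova_gg(m, posthoc = FALSE)
  expect_equal(r$F, 0)
  expect_equal(r$p_value, 1)
})

test_that("rm-ANOVA matches an independent sums-of-squares oracle", {
  oracle <- function(m) {
    n <- nrow(m); k <- ncol(m)
    gm <- mean(m)
    ssc <- 0
    for (j in 1:k) ssc <- ssc + n * (mean(m[, j]) - gm)^2
    sse <- 0
    for (i in 1:n) for (j in 1:k) {
      sse <- sse + (m[i, j] - mean(m[, j]) - mean(m[i, ]) + gm)^2
    }
    S <- cov(m)
    H <- diag(k) - matrix(1 / k, k, k)
    lam <- Re(eigen(H %*% S %*% H, only.values = TRUE)$values)
    eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
    list(F = (ssc / (k - 1)) / (sse / ((k - 1) * (n - 1))), eps = eps)
  }
  set.seed(74)
  for (i in 1:30) {
    m <- matrix(rnorm(18, sd = runif(1, 0.5, 3)), 6, 3)
    r <- rm_anova_gg(m, posthoc = FALSE)
    o <- oracle(m)
    expect_equal(r$F, o$F, tolerance = 1e-10)
    expect_equal(r$epsilon, o$eps, tolerance = 1e-10)
    expect_equal(r$df1, o$eps * 2, tolerance = 1e-10)
    expect_equal(r$df2, o$eps * 10, tolerance = 1e-10)
  }
})

test_that("epsilon stays within its theoretical bounds", {
  set.seed(75)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    n <- sample((k + 1):12, 1)
    m <- matrix(rnorm(n * k), n, k)
    eps <- rm_anova_gg(m, posthoc = FALSE)$epsilon
    expect_gte(eps, 1 / (k - 1) - 1e-12)
    expect_lte(eps, 1 + 1e-12)
  }
})

test_that("Huynh-Feldt epsilon is at least Greenhouse-Geisser and at most 1", {
  set.seed(76)
  m <- matrix(rnorm(24), 8, 3)
  gg <- rm_anova_gg(m, posthoc = FALSE)$epsilon
  hf <- rm_anova_gg(m, correction = "huynh-feldt",
                    posthoc = FALSE)$epsilon
  expect_gte(hf, gg)
  expect_lte(hf, 1)
})

test_that("post-hoc table carries Holm-adjusted pairwise comparisons", {
  set.seed(77)
  m <- matrix(rnorm(30), 10, 3)
  m[, 3] <- m[, 3] + 2
  colnames(m) <- c("normoxia", "hypoxia", "hypercapnia")
  r <- rm_anova_gg(m)
  expect_equal(nrow(r$posthoc), 3)
  expect_true(all(r$posthoc$p_holm >= r$posthoc$p_value))
  expect_equal(r$posthoc$p_holm,
               p.adjust(r$posthoc$p_value, method = "holm"))
})

test_that("results_table lays out comparisons and round-trips as CSV", {
  expect_equal(nrow(results_table(list())), 0)
  r <- paired_compare(paired_sample(1:6, rnorm(6), rnorm(6, 1),
                                    conditions = c("normoxia", "hypoxia"),
                                    measure = "SWS count per bin"))
  tab <- results_table(list(r))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n, 6)
  path <- withr::local_tempfile(fileext = ".csv")
  results_table(list(r), path)
  tab2 <- read.csv(path)
  expect_equal(tab2$p_value, tab$p_value, tolerance = 1e-12)
  expect_equal(tab2$comparison, tab$comparison)
})

test_that("missing cells are refused", {
  m <- matrix(rnorm(12), 4, 3)
  m[2, 2] <- NA
  expect_error(rm_anova_gg(m), "missing")
})
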