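# Cohort statistics against independent oracles.

test_that("Spearman correlation matches the rank-formula oracle", {
  # monotone decreasing, no ties
  r <- spearman_rho(1:8, 8:1)
  expect_equal(r$rho, -1)
  expect_lt(r$p_value, 0.01)
  # all-pairs rank oracle: d = rank differences, rho = 1 - 6 sum d^2 / (n(n^2-1))
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  d <- rank(x) - rank(y)
  expect_equal(spearman_rho(x, y)$rho, 1 - 6 * sum(d^2) / (5 * 24))
  expect_equal(spearman_rho(x, y)$rho, 0.8)
  # agreement with the reference implementation under ties
  xt <- c(1, 2, 2, 3, 4, 4, 5); yt <- c(2, 1, 3, 3, 5, 4, 6)
  expect_equal(spearman_rho(xt, yt)$rho,
               unname(cor(xt, yt, method = "spearman")))
})

test_that("Spearman null simulation stays near zero and input is validated", {
  withr::with_seed(101, {
    x <- rnorm(2000); y <- rnorm(2000)
    expect_lt(abs(spearman_rho(x, y)$rho), 0.05)
  })
  expect_error(spearman_rho(rep(1, 10), 1:10), "constant")
  expect_error(spearman_rho(1:3, 3:1), "at least 4")
  # ACR letters are coded A=1..D=4
  expect_equal(spearman_rho(c(4, 3, 2, 1), c("A", "B", "C", "D"))$rho, -1)
  expect_error(acr_code("E"), "A, B, C, D")
})

test_that("Kruskal-Wallis handles degenerate and identical groups", {
  # four identical groups: H = 0, p = 1
  r <- kruskal_wallis_holm(rep(1:3, 4), rep(c("A", "B", "C", "D"), each = 3))
  expect_equal(r$H, 0)
  expect_equal(r$p_global, 1)
  expect_error(kruskal_wallis_holm(1:5, rep("A", 5)), "2 non-empty groups")
})

test_that("exact Kruskal-Wallis p matches exhaustive permutation enumeration", {
  # separated pairs: the documented case where the chi-squared approximation
  # is off by far more than the enumeration tolerance
  v <- c(1, 2, 3, 4, 5, 6); g <- rep(c("a", "b", "c"), each = 2)
  r <- kruskal_wallis_holm(v, g)
  expect_equal(r$method_global, "exact permutation")
  expect_equal(r$p_global, kw_perm_oracle(v, g), tolerance = 1e-12)
  expect_equal(r$p_global, 6 / 90)  # 6 of the 90 distinct assignments
  expect_equal(r$H, kw_H_reference(v, g), tolerance = 1e-12)
  # random small configurations, including ties and unequal sizes
  withr::with_seed(5, {
    for (rep in 1:6) {
      n <- sample(5:7, 1)
      v <- sample(1:4, n, replace = TRUE)
      g <- sample(c("a", "b", "c"), n, replace = TRUE)
      if (length(unique(g)) < 2) next
      r <- kruskal_wallis_holm(v, g)
      expect_equal(r$H, kw_H_reference(v, g), tolerance = 1e-10)
      expect_equal(r$p_global, kw_perm_oracle(v, g), tolerance = 0.005)
    }
  })
})

test_that("pairwise rank-sum p-values match permutation enumeration and Holm", {
  v1 <- c(1, 2, 5); v2 <- c(3, 6, 7, 9)
  r <- kruskal_wallis_holm(c(v1, v2), rep(c("a", "b"), c(3, 4)))
  expect_equal(r$pairwise$p_raw, ranksum_perm_oracle(v1, v2), tolerance = 1e-12)
  # Holm's step-down rule applied by hand to (0.01, 0.02, 0.04)
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "holm"), c(0.03, 0.04, 0.04))
  # adjusted p never below raw p
  withr::with_seed(9, {
    v <- rnorm(40); g <- rep(c("A", "B", "C", "D"), 10)
    rr <- kruskal_wallis_holm(v, g)
    expect_true(all(rr$pairwise$p_holm >= rr$pairwise$p_raw - 1e-15))
    expect_true(all(rr$pairwise$p_raw >= 0 & rr$pairwise$p_holm <= 1))
  })
})

test_that("Cohen's kappa matches the hand formula and edge cases", {
  # perfect agreement across >= 2 categories
  r <- cohens_kappa(c("A", "B", "A", "C"), c("A", "B", "A", "C"))
  expect_equal(r$kappa, 1)
  # 2x2 agreement table [[40, 10], [5, 45]] computed from marginals by hand:
  # po = 0.85, pe = (45*50 + 55*50)/100^2 = 0.5, kappa = 0.7
  r1 <- rep(c("x", "x", "y", "y"), c(40, 10, 5, 45))
  r2 <- rep(c("x", "y", "x", "y"), c(40, 10, 5, 45))
  k <- cohens_kappa(r1, r2)
  expect_equal(k$po, 0.85)
  expect_equal(k$pe, 0.5)
  expect_equal(k$kappa, 0.7)
  expect_true(k$ci[1] < 0.7 && k$ci[2] > 0.7)
  # independent uniform ratings: kappa near 0
  withr::with_seed(77, {
    a <- sample(LETTERS[1:4], 5000, replace = TRUE)
    b <- sample(LETTERS[1:4], 5000, replace = TRUE)
    expect_lt(abs(cohens_kappa(a, b)$kappa), 0.05)
  })
  expect_error(cohens_kappa(rep("A", 5), rep("A", 5)), "single shared category")
})

test_that("ICC(2,1) recovers its variance-components value", {
  expect_equal(icc_paired(c(1, 2, 3, 4), c(1, 2, 3, 4))$icc, 1)
  # symmetric noise with variance 5 per rating: ICC(2,1) -> 1/(1+5) = 1/6
  withr::with_seed(31, {
    subj <- rnorm(5000, sd = 1)
    l <- subj + rnorm(5000, sd = sqrt(5))
    r <- subj + rnorm(5000, sd = sqrt(5))
    expect_lt(abs(icc_paired(l, r)$icc - 1 / 6), 0.05)
    l2 <- rnorm(1000); r2 <- rnorm(1000)
    expect_lt(abs(icc_paired(l2, r2)$icc), 0.1)
  })
  expect_error(icc_paired(rep(1, 5), rep(1, 5)), "zero total variance")
  expect_error(icc_paired(1:2, 1:2), "at least 3")
})

test_that("ICC matches the closed form for a one-sided noise split", {
  # right = left + noise of variance 10: the two-way decomposition spreads
  # the error over both ratings (5 each), so ICC(2,1) -> 1/(1+5) = 1/6
  withr::with_seed(13, {
    subj <- rnorm(5000, sd = 1)
    l <- subj
    r <- subj + rnorm(5000, sd = sqrt(10))
    expect_lt(abs(icc_paired(l, r)$icc - 1 / 6), 0.05)
  })
})

test_that("auxiliary chi-squared and paired t behave on canonical tables", {
  # perfectly concordant 4x4 diagonal, n = 100: chi-squared = 3 * n = 300
  df <- data.frame(acr_mammo_reader1 = rep(LETTERS[1:4], 25),
                   acr_mri_reader1 = rep(LETTERS[1:4], 25))
  a <- auxiliary_tests(df)
  expect_equal(a$chi_squared$statistic, 300, tolerance = 1e-9)
  expect_lt(a$chi_squared$p_value, 0.001)
  # independence: 2x2 [[10,10],[10,10]] has statistic exactly 0
  df2 <- data.frame(
    acr_mammo_reader1 = rep(c("A", "A", "B", "B"), each = 10),
    acr_mri_reader1 = rep(c("A", "B", "A", "B"), each = 10))
  expect_equal(auxiliary_tests(df2)$chi_squared$statistic, 0)
  # identical paired vectors: t = 0, p = 1
  df3 <- data.frame(mean_pdff_breast_left = c(70, 80, 90),
                    mean_pdff_breast_right = c(70, 80, 90))
  pt_ <- auxiliary_tests(df3)$paired_t
  expect_equal(pt_$t, 0)
  expect_equal(pt_$p_value, 1)
})

test_that("Kruskal-Wallis type-I error is calibrated under the null", {
  # group sizes of a typical screening cohort stratified by ACR category
  sizes <- c(13, 52, 53, 20)
  g <- rep(LETTERS[1:4], sizes)
  withr::with_seed(2024, {
    rej <- mean(replicate(1000,
      kruskal_wallis_holm(rnorm(sum(sizes)), g)$p_global < 0.05))
  })
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})
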