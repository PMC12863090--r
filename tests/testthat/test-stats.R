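test_that("rank-sum: separation bounds, symmetry, and small-sample exact p", {
  r1 <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(abs(r1$effect$rank_biserial), 1)
  r2 <- rank_sum_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r2$effect$rank_biserial, 0)
  r3 <- rank_sum_test(c(1, 2), 3)
  expect_equal(r3$p_raw, 2 / 3)
  expect_error(rank_sum_test(c(1, 1), c(1, 1)), "degenerate")
})

test_that("exact rank-sum p-values match full enumeration for all n1+n2 <= 10", {
  withr::with_seed(7, {
    for (rep in 1:120) {
      n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
      vals <- sample(1000, n1 + n2) # tie-free
      x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
      expect_equal(rank_sum_test(x, y)$p_raw, enum_rank_sum_p(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("signed-rank: exact p-values, sign symmetry, and n = 1 edge", {
  s <- signed_rank_test(c(0.3, 1.1, 0.7, 2.2, 0.9))
  expect_equal(s$p_raw, 2 / 32)
  expect_equal(s$effect$rank_biserial, 1)
  sym <- signed_rank_test(c(-1.5, 1.5, -0.2, 0.2) + c(0, 1e-9, 0, 1e-9))
  expect_lt(abs(sym$effect$rank_biserial), 0.5)
  expect_equal(signed_rank_test(3.2)$p_raw, 1)
  expect_error(signed_rank_test(c(0, 0, 0)), "degenerate")
})

test_that("exact signed-rank p-values match sign-pattern enumeration", {
  withr::with_seed(17, {
    for (rep in 1:100) {
      d <- round(runif(sample(1:8, 1), -3, 3), 3)
      d <- d[d != 0]
      if (length(d) == 0 || anyDuplicated(abs(d))) next
      expect_equal(signed_rank_test(d)$p_raw, enum_signed_rank_p(d),
                   tolerance = 1e-12)
    }
  })
})

test_that("Pratt zero handling is available and returns a valid p", {
  p <- signed_rank_test(c(0, 0, 1, 2, -1, 3, 4, 2.5), zero_method = "pratt")
  expect_true(p$p_raw >= 0 && p$p_raw <= 1)
})

test_that("Fisher's exact test: identity table, enumeration oracle, Haldane OR", {
  f1 <- fisher_exact(matrix(c(10, 90, 10, 90), 2, byrow = TRUE))
  expect_equal(f1$p_raw, 1)
  expect_equal(f1$effect$sample_odds_ratio, 1)
  f2 <- fisher_exact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(f2$p_raw, 2 / 252)
  f3 <- fisher_exact(matrix(c(0, 10, 10, 0), 2, byrow = TRUE))
  expect_equal(f3$effect$sample_odds_ratio, (0.5 * 0.5) / (10.5 * 10.5))
  expect_error(fisher_exact(matrix(0, 2, 2)), "empty")
})

test_that("Fisher p-values match hypergeometric enumeration for all totals <= 10", {
  withr::with_seed(29, {
    for (rep in 1:150) {
      m <- matrix(sample(0:4, 4, replace = TRUE), 2)
      if (sum(m) == 0 || sum(m) > 10) next
      expect_equal(fisher_exact(m)$p_raw, enum_fisher_p(m), tolerance = 1e-9)
    }
  })
  # any table with identical rows has p = 1
  for (a in 1:3) for (b in 0:3) {
    if (a + b == 0) next
    expect_equal(fisher_exact(matrix(c(a, b, a, b), 2, byrow = TRUE))$p_raw, 1)
  }
})

test_that("McNemar: null center, exact binomial tail, chi-square switchover", {
  expect_equal(mcnemar_test(10, 10)$p_raw, 1)
  expect_equal(mcnemar_test(5, 0)$p_raw, 0.0625)
  expect_error(mcnemar_test(0, 0), "degenerate")
  withr::with_seed(41, {
    for (rep in 1:80) {
      b <- sample(0:12, 1); cc <- sample(0:12, 1)
      if (b + cc == 0) next
      expect_equal(mcnemar_test(b, cc)$p_raw, enum_mcnemar_p(b, cc),
                   tolerance = 1e-12)
    }
  })
  big <- mcnemar_test(80, 40)
  expect_equal(big$statistic, (abs(80 - 40) - 1)^2 / 120)
})

test_that("BH adjustment: hand-computed step-up, monotonicity, bounds", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.4, 5)), rep(0.4, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  withr::with_seed(3, {
    for (rep in 1:50) {
      p <- runif(sample(2:20, 1))
      adj <- bh_adjust(p)
      expect_true(all(adj >= p - 1e-12))
      ord <- order(p)
      expect_true(all(diff(adj[ord]) >= -1e-12))
    }
  })
})

test_that("proportion CIs clamp at the boundaries and are symmetric at 1/2", {
  expect_equal(unname(proportion_ci(0, 20)["low"]), 0)
  expect_equal(unname(proportion_ci(20, 20)["high"]), 1)
  ci <- proportion_ci(50, 100)
  expect_equal(unname(ci["low"] + ci["high"]), 1, tolerance = 1e-9)
  # matches the stated R reference implementation
  ref <- prop.test(13, 40)$conf.int
  expect_equal(unname(proportion_ci(13, 40)), c(ref[1], ref[2]))
})

test_that("Spearman correlation: monotone bounds and hand-ranked example", {
  expect_equal(spearman_corr(1:10, 1:10)$effect$rho, 1)
  expect_equal(spearman_corr(1:10, 10:1)$effect$rho, -1)
  expect_equal(spearman_corr(c(1, 2, 3), c(2, 1, 3))$effect$rho, 0.5)
  expect_error(spearman_corr(c(1, 1, 1), 1:3), "degenerate")
})

test_that("Poisson rate comparison reduces to the conditional binomial", {
  eq <- poisson_rate_test(10, 1000, 10, 1000)
  expect_equal(eq$p_raw, 1)
  expect_equal(eq$effect$rate_ratio, 1)
  z <- poisson_rate_test(0, 1000, 20, 1000)
  expect_equal(z$effect$rate_ratio, 0)
  expect_equal(z$ci$low, 0)
  expect_true(is.finite(z$ci$high) && z$ci$high > 0)
  t3 <- poisson_rate_test(30, 1000, 10, 1000)
  expect_equal(t3$p_raw, binom.test(30, 40, 0.5)$p.value)
  expect_equal(t3$effect$rate_ratio, 3)
  expect_error(poisson_rate_test(0, 10, 0, 10), "degenerate")
})

test_that("effect sizes: Cohen's d definition and 2x2 ratios", {
  x <- c(1, 2, 3, 4, 5); y <- x
  expect_equal(effect_sizes(x, y)$cohens_d, 0)
  # means one pooled SD apart
  withr::with_seed(19, {
    a <- rnorm(2000); b <- rnorm(2000)
    b <- (b - mean(b)) / sd(b)
    a <- (a - mean(a)) / sd(a) + 1
    d <- effect_sizes(a, b)$cohens_d
    expect_equal(d, 1, tolerance = 1e-6)
  })
  es <- effect_sizes_2x2(matrix(c(20, 80, 10, 90), 2, byrow = TRUE))
  expect_equal(es$risk_ratio, 2)
  expect_equal(es$odds_ratio, (20 * 90) / (80 * 10))
  expect_error(effect_sizes(rep(1, 5), rep(1, 5)), "pooled")
})

test_that("rank-sum test keeps its nominal size under a null of one distribution", {
  withr::with_seed(2024, {
    rejections <- 0L
    n_reps <- 400
    for (i in seq_len(n_reps)) {
      x <- rnorm(25); y <- rnorm(25)
      if (rank_sum_test(x, y)$p_raw < 0.05) rejections <- rejections + 1L
    }
    expect_gt(rejections / n_reps, 0.02)
    expect_lt(rejections / n_reps, 0.08)
  })
})
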