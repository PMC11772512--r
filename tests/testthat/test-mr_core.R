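test_that("Wald ratio arithmetic and null behaviour", {
  p <- make_pair(0.2, 0.01, 0.1, 0.05)
  res <- wald_ratio(p)
  expect_equal(res$beta, 0.5)
  expect_equal(res$se, 0.25)
  expect_equal(res$or, exp(0.5))

  p0 <- make_pair(0.2, 0.01, 0, 0.05)
  res0 <- wald_ratio(p0)
  expect_equal(res0$beta, 0)
  expect_equal(res0$pval, 1)

  expect_error(wald_ratio(make_pair(0, 0.01, 0.1, 0.05)), "ratio undefined")
  expect_error(wald_ratio(make_pair(c(1, 1), 0.01, 0.1, 0.05)),
               "exactly one SNP")
})

test_that("single-instrument recovery of a known causal effect", {
  # one strong instrument, true effect 0.4 at biobank-scale outcome se
  set.seed(88)
  ests <- replicate(500, {
    bx <- 0.15
    by <- rnorm(1, 0.4 * bx, 0.02)
    wald_ratio(make_pair(bx, 1e-8, by, 0.02))$beta
  })
  expect_lt(abs(mean(ests) - 0.4), 0.05)
})

test_that("IVW matches the hand-computed weighted mean and falls back to Wald", {
  p <- pair_from_ratios(c(0.5, 0.6, 0.45), c(0.2, 0.1, 0.05))
  res <- ivw(p)
  w <- 1 / c(0.2, 0.1, 0.05)^2
  expect_equal(res$beta, sum(w * c(0.5, 0.6, 0.45)) / sum(w),
               tolerance = 1e-12)
  expect_equal(res$beta, 0.4810, tolerance = 1e-4)
  # Q/(k-1) < 1 here, so the multiplicative inflation leaves the
  # fixed-effect standard error untouched
  expect_equal(res$se, sqrt(1 / sum(w)), tolerance = 1e-12)
  expect_equal(res$se, 0.04364, tolerance = 1e-4)

  # duplicated single SNP: IVW equals the single-SNP Wald ratio
  dup <- make_pair(c(0.2, 0.2), 0.01, c(0.1, 0.1), 0.05)
  expect_equal(ivw(dup)$beta, 0.5, tolerance = 1e-12)

  # one SNP: exact reduction to wald_ratio
  one <- make_pair(0.2, 0.01, 0.1, 0.05)
  expect_equal(ivw(one)$beta, wald_ratio(one)$beta)
  expect_equal(ivw(one)$se, wald_ratio(one)$se)

  # zero exposure effects are dropped with a warning
  mix <- make_pair(c(0, 0.2, 0.25), 0.01, c(0.1, 0.1, 0.12), 0.05)
  expect_warning(res_mix <- ivw(mix), "zero exposure effect")
  expect_equal(res_mix$n_snp, 2L)
})

test_that("MR-Egger recovers exact linear data and matches closed-form OLS", {
  # exact proportionality: slope = c, intercept = 0
  bx <- c(0.1, 0.2, 0.3, 0.4)
  p <- make_pair(bx, 0.01, 0.7 * bx, 0.05)
  res <- mr_egger(p)
  expect_equal(res$beta, 0.7, tolerance = 1e-9)
  expect_equal(res$egger_intercept, 0, tolerance = 1e-9)

  # equal weights: matches the closed-form OLS slope/intercept
  bx2 <- c(0.1, 0.25, 0.4)
  by2 <- c(0.03, 0.09, 0.11)
  res2 <- mr_egger(make_pair(bx2, 0.01, by2, 0.05))
  sxx <- sum((bx2 - mean(bx2))^2)
  slope <- sum((bx2 - mean(bx2)) * (by2 - mean(by2))) / sxx
  expect_equal(res2$beta, slope, tolerance = 1e-9)
  expect_equal(res2$egger_intercept, mean(by2) - slope * mean(bx2),
               tolerance = 1e-9)

  expect_warning(expect_null(mr_egger(make_pair(c(1, 2), 0.01, c(1, 2), 0.1))),
                 "not applicable")
})

test_that("MR-Egger recovers a planted directional-pleiotropy intercept", {
  set.seed(404)
  ints <- replicate(500, {
    bx <- runif(30, 0.05, 0.3)
    by <- rnorm(30, 0.3 * bx + 0.02, 0.02)
    mr_egger(make_pair(bx, 1e-8, by, 0.02))$egger_intercept
  })
  expect_lt(abs(mean(ints) - 0.02), 0.01)
})

test_that("weighted median interpolates the inverse-variance CDF", {
  # equal weights, three ratios: the middle one
  p <- pair_from_ratios(c(0.1, 0.5, 0.9), rep(0.1, 3))
  expect_equal(weighted_median(p, n_boot = 50)$beta, 0.5, tolerance = 1e-9)

  # dominant weight: the estimate equals the dominant ratio
  pdom <- pair_from_ratios(c(0.1, 0.5, 0.9), c(0.2, 0.02, 0.2))
  expect_equal(weighted_median(pdom, n_boot = 50)$beta, 0.5, tolerance = 1e-9)

  # random weights vs the brute-force interpolation oracle
  set.seed(31)
  for (i in 1:20) {
    r <- rnorm(7)
    s <- runif(7, 0.05, 0.5)
    got <- weighted_median(pair_from_ratios(r, s), n_boot = 2)$beta
    expect_equal(got, weighted_median_oracle(r, 1 / s^2), tolerance = 1e-9)
  }
})

test_that("weighted mode finds the dominant ratio cluster", {
  # degenerate cluster: common ratio, zero se
  pd <- pair_from_ratios(rep(0.3, 4), rep(0.1, 4))
  resd <- weighted_mode(pd, n_boot = 10)
  expect_equal(resd$beta, 0.3)
  expect_equal(resd$se, 0)

  # five-SNP cluster at 0.30 plus one outlier at 2.0
  pc <- pair_from_ratios(c(rep(0.3, 5), 2), rep(0.1, 6))
  expect_lt(abs(weighted_mode(pc, n_boot = 50)$beta - 0.3), 0.05)
})

test_that("weighted mode is more robust than IVW with 40% invalid instruments", {
  set.seed(606)
  bias <- replicate(300, {
    k <- 10
    bx <- runif(k, 0.1, 0.3)
    pleio <- c(rep(0, 6), rep(0.08, 4))  # 60% valid
    by <- rnorm(k, 0.3 * bx + pleio, 0.01)
    p <- make_pair(bx, 1e-8, by, 0.01)
    c(ivw = ivw(p)$beta, mode = weighted_mode(p, n_boot = 2)$beta)
  })
  expect_lt(abs(mean(bias["mode", ]) - 0.3), abs(mean(bias["ivw", ]) - 0.3))
})

test_that("Cochran's Q measures heterogeneity of the ratio estimates", {
  expect_equal(cochran_q(c(0.4, 0.4, 0.4), c(0.1, 0.2, 0.3), 0.4),
               list(q_stat = 0, q_pval = 1))
  q <- cochran_q(c(0, 1), c(0.5, 0.5), 0.5)
  expect_equal(q$q_stat, 2)
  expect_equal(q$q_pval, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(q$q_pval, 0.157, tolerance = 5e-3)
})

test_that("Q p-values are uniform for homogeneous instruments", {
  set.seed(99)
  p <- replicate(2000, {
    k <- 8
    bx <- rep(0.2, k)
    by <- rnorm(k, 0.5 * bx, 0.04)
    re_ratio <- by / bx
    se_ratio <- rep(0.04 / 0.2, k)
    w <- 1 / se_ratio^2
    beta <- sum(w * re_ratio) / sum(w)
    cochran_q(re_ratio, se_ratio, beta)$q_pval
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("leave-one-out re-estimates match IVW on each subset", {
  # identical SNPs: every re-estimate equals the full estimate
  pid <- make_pair(rep(0.2, 3), 0.01, rep(0.1, 3), 0.05)
  loo <- leave_one_out(pid)
  expect_true(all(abs(loo$beta - 0.5) < 1e-12))
  expect_false(any(loo$flagged))

  # each re-estimate is IVW on the complement (recomputation oracle)
  set.seed(13)
  p5 <- make_pair(runif(5, 0.1, 0.3), 0.01, rnorm(5, 0.06, 0.02), 0.02)
  loo5 <- leave_one_out(p5)
  for (i in 1:5) {
    sub <- make_pair(p5$beta_x[-i], p5$se_x[-i], p5$beta_y[-i], p5$se_y[-i])
    expect_equal(loo5$beta[i], ivw(sub)$beta, tolerance = 1e-12)
  }

  # a planted outlier strong enough to flip the pooled sign is flagged
  bx <- rep(0.2, 6)
  by <- c(rep(0.1, 5), -0.62)
  loo6 <- leave_one_out(make_pair(bx, 0.001, by, 0.01))
  expect_true(loo6$flagged[6])
  expect_false(any(loo6$flagged[1:5]))
})

test_that("BH adjustment matches the hand-computed step-up example", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(5)
  p <- runif(100)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 0)), ">")
})

test_that("odds-ratio rendering reproduces published confidence intervals", {
  # beta = 0 gives a unit OR with log-symmetric bounds
  ci0 <- or_ci(0, 0.1)
  expect_equal(ci0$or, 1)
  expect_equal(ci0$ci_low * ci0$ci_high, 1, tolerance = 1e-12)

  # the geometric mean of the computed bounds always equals the OR
  se <- (log(5.26) - log(1.653)) / (2 * qnorm(0.975))
  ci <- or_ci(log(2.949), se)
  expect_equal(sqrt(ci$ci_low * ci$ci_high), ci$or, tolerance = 1e-12)
  # published OR/CI pairs round-trip to their printed precision
  rec <- or_from_ci(1.653, 5.26)
  expect_equal(rec$or, 2.949, tolerance = 5e-4)
  # very wide published interval (risk-factor scale)
  rec2 <- or_from_ci(46.144, 2967.758)
  expect_equal(rec2$or, 370.060, tolerance = 5e-4)

  # p-value reconstruction from OR + CI (printed-digit precision)
  expect_equal(p_from_or_ci(27.842, 1.042, 743.623), 4.72e-2,
               tolerance = 5e-3)
  expect_equal(p_from_or_ci(2.933, 1.519, 5.664), 1.35e-3, tolerance = 5e-3)
  expect_equal(p_from_or_ci(1, 0.5, 2), 1)
  expect_error(p_from_or_ci(2, 3, 4), "bracket")
})

test_that("estimators are invariant to per-SNP sign flips", {
  set.seed(21)
  bx <- runif(6, 0.1, 0.3)
  by <- rnorm(6, 0.4 * bx, 0.02)
  p1 <- make_pair(bx, 0.01, by, 0.02)
  flip <- c(1, -1, 1, -1, -1, 1)
  p2 <- make_pair(bx * flip, 0.01, by * flip, 0.02)
  expect_equal(ivw(p2)$beta, ivw(p1)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(p2)$beta, mr_egger(p1)$beta, tolerance = 1e-12)
  expect_equal(weighted_median(p2, n_boot = 2)$beta,
               weighted_median(p1, n_boot = 2)$beta, tolerance = 1e-12)
  expect_equal(weighted_mode(p2, n_boot = 2)$beta,
               weighted_mode(p1, n_boot = 2)$beta, tolerance = 1e-12)
})

test_that("direction concordance is tracked across the estimator suite", {
  set.seed(55)
  bx <- runif(8, 0.1, 0.3)
  by <- rnorm(8, 0.5 * bx, 0.01)
  res <- mr_all_methods(make_pair(bx, 1e-8, by, 0.01), seed = 3,
                        n_boot = 100)
  expect_setequal(res$method, c("ivw", "egger", "weighted_median",
                                "weighted_mode"))
  expect_true(attr(res, "sign_concordant"))
})
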