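test_that("Cohen's d matches hand computation and is antisymmetric", {
  expect_equal(cohens_d(c(1, 2, 3), c(4, 5, 6)), -3.0)
  expect_equal(cohens_d(c(4, 5, 6), c(1, 2, 3)), 3.0)
  expect_equal(cohens_d(c(2, 4, 6), c(2, 4, 6)), 0)
  set.seed(1)
  a <- rnorm(20); b <- rnorm(25)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_warning(d <- cohens_d(c(1, 1), c(2, 2)), "infinity")
  expect_identical(d, -Inf)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "undefined")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("Mann-Whitney exact p agrees with full enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3)
  expect_equal(r$method, "exact")
  expect_equal(r$p, enumerate_mw_p(c(1, 2), c(3, 4)))
  # random no-tie cases, several sizes
  set.seed(42)
  for (k in 1:5) {
    a <- sample(seq(0, 1, length.out = 40), sample(3:6, 1))
    b <- sample(seq(2, 3, length.out = 40), sample(3:6, 1))
    expect_equal(mann_whitney_u(a, b)$p, enumerate_mw_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("identical samples give p = 1 and exact/approx modes agree", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  set.seed(7)
  for (k in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    pe <- mann_whitney_u(a, b, exact_max = 8)$p
    pa <- mann_whitney_u(a, b, exact_max = 0)$p
    expect_lt(abs(pe - pa), 0.02)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("subsampled test is seed-deterministic with coherent summaries", {
  set.seed(5)
  a <- rnorm(300); b <- rnorm(300)
  r1 <- subsampled_test(a, b, n_iter = 50, seed = 9)
  r2 <- subsampled_test(a, b, n_iter = 50, seed = 9)
  expect_identical(r1, r2)
  expect_length(r1$p_values, 50)
  expect_equal(r1$median_p, median(r1$p_values))
  expect_equal(r1$median_d, median(r1$d_values))
  expect_error(subsampled_test(rnorm(50), rnorm(300)), "at least")
})

test_that("subsampled test medians reflect the null and a 1-SD shift", {
  set.seed(11)
  meds_p <- numeric(20); meds_d <- numeric(20)
  for (k in 1:20) {
    a <- rnorm(1000); b <- rnorm(1000)
    r <- subsampled_test(a, b, n_iter = 100, seed = k)
    meds_p[k] <- r$median_p; meds_d[k] <- r$median_d
  }
  expect_gt(median(meds_p), 0.35)
  expect_lt(median(meds_p), 0.65)
  expect_lt(median(abs(meds_d)), 0.1)
  a <- rnorm(1000); b <- rnorm(1000) + 1
  r <- subsampled_test(a, b, n_iter = 100, seed = 1)
  expect_lt(r$median_p, 0.001)
  expect_lt(abs(abs(r$median_d) - 1), 0.25)
  expect_lt(r$median_d, 0)  # first minus second
})

test_that("covariate-adjusted contrasts recover a planted offset", {
  set.seed(21)
  n <- 150
  df <- data.frame(
    g = rep(c("1M", "10M", "18M"), each = n),
    area = rnorm(3 * n, 35, 5),
    brain_area = rep(c("M1", "S1"), length.out = 3 * n))
  df$y <- 40 - 18 * (df$g == "10M") - 21 * (df$g == "18M") +
    0.5 * df$area + rnorm(3 * n, 0, 10)
  res <- adjusted_group_contrasts(df, "y", "g", "area", "brain_area")
  expect_equal(nrow(res), 3)
  expect_true(all(c("mean_diff", "se", "t_stat", "cohens_d",
                    "p_tukey", "p_bonf") %in% names(res)))
  pair <- vapply(seq_len(nrow(res)), function(i)
    setequal(c(res$group_a[i], res$group_b[i]), c("1M", "10M")), logical(1))
  row <- res[pair, ]
  expect_equal(nrow(row), 1)
  expect_lt(abs(abs(row$mean_diff) - 18), 2 * row$se)
  # sign coherence of every contrast row
  expect_true(all(sign(res$mean_diff) == sign(res$t_stat)))
  expect_true(all(sign(res$mean_diff) == sign(res$cohens_d)))
  expect_true(all(res$p_bonf <= 1 & res$p_bonf >= res$p_tukey - 1e-9))
  expect_error(adjusted_group_contrasts(df, "y", "missing"), "not found")
})

test_that("multiplicity adjustments match hand computations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  # hand step-up: sorted (0.002, 0.03, 0.04) -> (0.006, 0.04, 0.04)
  expect_equal(bh_adjust(c(0.03, 0.002, 0.04)), c(0.04, 0.006, 0.04))
  expect_equal(bonferroni_adjust(0.4, family = 3), 1.0)
  expect_equal(bonferroni_adjust(c(0.01, 0.2), family = 3), c(0.03, 0.6))
})

test_that("GEE with singleton clusters reduces to OLS", {
  set.seed(31)
  x <- rnorm(60); y <- 1 + 0.7 * x + rnorm(60)
  f <- gee_fit(y, x, cluster = seq_along(y), working = "independence")
  ols <- lm(y ~ x)
  expect_lt(abs(f$slope - coef(ols)[2]), 1e-8)
  expect_lt(abs(f$intercept - coef(ols)[1]), 1e-8)
  # independence working correlation always matches pooled OLS points
  cl <- rep(1:10, each = 6)
  f2 <- gee_fit(y, x, cl, working = "independence")
  expect_lt(abs(f2$slope - coef(ols)[2]), 1e-8)
  expect_error(gee_slope(y, rep(1, 60), cl), "constant")
})

test_that("GEE recovers a clustered slope with near-nominal coverage", {
  set.seed(41)
  nrep <- 150
  est <- cover <- numeric(nrep)
  for (r in seq_len(nrep)) {
    cl <- rep(1:10, each = 50)
    u <- rnorm(10)
    x <- rnorm(500)
    y <- 0.5 * x + u[cl] + rnorm(500)  # intra-cluster correlation 0.5
    f <- gee_slope(y, x, cl)
    est[r] <- f$slope
    cover[r] <- abs(f$slope - 0.5) <= qt(0.975, f$df) * f$robust_se
  }
  expect_lt(abs(mean(est) - 0.5), 0.05)
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("GEE group contrast is near zero under exchangeable groups", {
  set.seed(51)
  cl <- rep(1:8, each = 40)
  y <- rnorm(320) + rnorm(8, 0, 0.3)[cl]
  g <- rep(c("IN", "PN"), 160)
  r <- gee_group_contrast(y, g, cl)
  expect_lt(abs(r$estimate), 3 * r$robust_se)
  expect_equal(r$levels, c("IN", "PN"))
  expect_error(gee_group_contrast(y, rep("IN", 320), cl), "2 levels")
})

test_that("Pearson correlation handles exact linear relations", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(x, rep(2, 5)), "constant")
  expect_error(pearson_r(1:2, 2:1), "at least 3")
})
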