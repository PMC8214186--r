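# brute-force oracle for Lin's coefficient: direct population moments
ccc_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my)) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

test_that("Lin concordance: perfect agreement, shift penalty, closed form", {
  x <- c(3.1, 4.7, 5.0, 6.2, 8.4)
  expect_equal(lin_ccc(x, x), 1)
  shifted <- lin_ccc(x, x + 10)
  expect_lt(shifted, 1)
  expect_equal(stats::cor(x, x + 10), 1)
  y <- c(2.9, 5.1, 4.6, 6.8, 7.9)
  expect_equal(lin_ccc(x, y), ccc_oracle(x, y), tolerance = 1e-12)
  expect_equal(lin_ccc(x, y), lin_ccc(y, x), tolerance = 1e-14)  # symmetric
})

test_that("|rho_c| <= |r| with equality only at matched location/scale", {
  set.seed(101)
  for (i in 1:25) {
    x <- rnorm(40, 10, 3)
    y <- 0.5 * x + rnorm(40, i / 5, 2)
    expect_lte(abs(lin_ccc(x, y)), abs(stats::cor(x, y)) + 1e-12)
  }
  x <- rnorm(100)
  expect_equal(lin_ccc(x, x), abs(stats::cor(x, x)), tolerance = 1e-12)
})

test_that("rho_c is invariant under a shared affine rescaling", {
  set.seed(7)
  x <- rnorm(30, 50, 5); y <- x + rnorm(30, 2, 3)
  expect_equal(lin_ccc(2.5 * x - 7, 2.5 * y - 7), lin_ccc(x, y),
               tolerance = 1e-12)
})

test_that("Bland-Altman bias and limits match the direct computation", {
  x <- c(10, 12, 9, 14, 11)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(unname(ba0$loa), c(0, 0))
  ba5 <- bland_altman(x, x + 5)
  expect_equal(ba5$bias, 5)
  expect_equal(unname(ba5$loa), c(5, 5))
  y <- c(11.2, 11.5, 10.1, 15.3, 10.6)
  ba <- bland_altman(x, y)
  d <- y - x
  expect_equal(ba$bias, mean(d), tolerance = 1e-14)
  expect_equal(unname(ba$loa),
               mean(d) + c(-1.96, 1.96) * stats::sd(d), tolerance = 1e-14)
  # limits span the bias symmetrically
  expect_equal(ba$loa[["upper"]] - ba$bias, ba$bias - ba$loa[["lower"]],
               tolerance = 1e-12)
})

test_that("limits of agreement cover ~95% of Gaussian differences", {
  set.seed(2024)
  ref <- rnorm(5000, 100, 10)
  test <- ref + rnorm(5000, 1, 4)
  ba <- bland_altman(ref, test)
  cover <- mean(ba$diffs >= ba$loa[1] & ba$diffs <= ba$loa[2])
  expect_equal(cover, 0.95, tolerance = 0.01)
})

test_that("percent error matches the elementwise definition", {
  pe <- percent_error(c(100, 100), c(100, 95))
  expect_equal(pe$per_pair, c(0, 5))
  expect_equal(pe$mean, 2.5)
  ref <- c(80, 120, 60, 150)
  tst <- c(84, 114, 66, 150)
  expect_equal(percent_error(ref, tst)$per_pair,
               100 * abs(tst - ref) / ref, tolerance = 1e-14)
  expect_equal(percent_error(ref, tst, signed = TRUE)$per_pair,
               100 * (tst - ref) / ref, tolerance = 1e-14)
  expect_warning(pe0 <- percent_error(c(0, 100), c(5, 95)), "zero reference")
  expect_equal(pe0$n_used, 1)
})

test_that("ICC: perfect repeats, pure noise, and the analytic variance ratio", {
  m <- cbind(1:10, 1:10)  # identical repeats, subjects differ
  expect_equal(icc_test_retest(m)$value, 1)

  set.seed(55)
  noise <- matrix(rnorm(400), 200, 2)  # no subject effect
  expect_equal(icc_test_retest(noise)$value, 0, tolerance = 0.12)

  coh <- simulate_agreement_cohort(n = 200, repeats = 2, subject_sd = 3,
                                   error_sd = 1, seed = 20)
  expect_equal(icc_test_retest(coh)$value, attr(coh, "true_icc"),
               tolerance = 0.05)
})

test_that("ICC mean squares agree with an aov decomposition oracle", {
  coh <- simulate_agreement_cohort(n = 30, repeats = 3, subject_sd = 2,
                                   error_sd = 1.5, seed = 31)
  long <- data.frame(y = as.vector(coh),
                     subj = factor(rep(seq_len(nrow(coh)), ncol(coh))),
                     rep = factor(rep(seq_len(ncol(coh)), each = nrow(coh))))
  ms <- summary(stats::aov(y ~ subj + rep, data = long))[[1]][, "Mean Sq"]
  r <- icc_test_retest(coh)
  expect_equal(r$msr, ms[1], tolerance = 1e-10)
  expect_equal(r$msc, ms[2], tolerance = 1e-10)
  expect_equal(r$mse, ms[3], tolerance = 1e-10)
})

test_that("ICC handles missing repeats listwise", {
  coh <- simulate_agreement_cohort(n = 50, seed = 3)
  coh[c(4, 9), 2] <- NA
  expect_warning(r <- icc_test_retest(coh), "dropped")
  expect_equal(r$n, 48)
  expect_error(icc_test_retest(coh[, 1, drop = FALSE]),
               class = "hs_invalid_input")
})

test_that("retention curves are exact on known confidence sets", {
  rc <- retention_curve(rep(1, 10), c(0, 0.5, 1))
  expect_equal(rc$retained, c(1, 1, 1))
  expect_equal(retention_curve(c(0.2, 0.6, 0.9), 0.5)$retained, 2 / 3)
  set.seed(77)
  u <- runif(10000)
  rc2 <- retention_curve(u, seq(0, 1, by = 0.1))
  expect_equal(rc2$retained, 1 - rc2$cutoff, tolerance = 0.02)
  expect_error(retention_curve(c(-0.1, 0.5)), class = "hs_invalid_input")
})

test_that("retention curve is monotone for arbitrary confidence vectors", {
  set.seed(88)
  for (i in 1:20) {
    conf <- runif(sample(5:200, 1))^sample(1:3, 1)
    rc <- retention_curve(conf, sort(runif(15)))
    expect_true(all(diff(rc$retained) <= 1e-12))
  }
})

test_that("agreement_report bundles consistent statistics", {
  set.seed(5)
  ref <- rnorm(40, 100, 10)
  tst <- ref + rnorm(40, 2, 4)
  rep <- agreement_report(ref, tst)
  expect_equal(rep$lin_ccc, ccc_oracle(ref, tst), tolerance = 1e-12)
  expect_lte(abs(rep$lin_ccc), abs(rep$pearson_r))
  expect_equal(rep$ba$bias, mean(tst - ref), tolerance = 1e-12)
  expect_equal(rep$n, 40)
  # a biased device lowers concordance but not correlation
  biased <- agreement_report(ref, ref + 15)
  expect_lt(biased$lin_ccc, 0.9)
  expect_equal(biased$pearson_r, 1, tolerance = 1e-12)
})
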