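test_that("paired t matches its closed form and handles degenerate input", {
  r <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-4)
  expect_equal(r$p, 2 * pt(-r$t, df = 2), tolerance = 1e-10)
  expect_equal(r$p, 0.0742, tolerance = 1e-3)
  # antisymmetric differences: mean zero, t = 0, p = 1
  x <- c(0.2, 0.5, 0.9, 1.4)
  r0 <- paired_t(x, rev(x))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_error(paired_t(x, x + 2), "degenerate")
  expect_error(paired_t(1:2, 2:3), "n >= 3")
})

test_that("Cohen's dz is the mean over the n-1 SD of differences", {
  expect_equal(cohens_dz(c(1, 2, 3)), 2)
  expect_equal(cohens_dz(c(4, 5, 6), c(3, 3, 3)), 2)
  set.seed(2)
  d <- rnorm(30)
  expect_equal(cohens_dz(d), mean(d) / sd(d))
  expect_error(cohens_dz(rep(1, 5)), "zero standard deviation")
})

test_that("BH FDR implements the step-up rule", {
  r <- fdr_bh(c(0.01, 0.02, 0.04, 0.05), alpha = 0.05)
  expect_true(all(r$reject))          # largest k with p(k) <= k*alpha/4 is 4
  expect_equal(fdr_bh(rep(1, 6))$reject, rep(FALSE, 6))
  expect_equal(fdr_bh(0.031)$q, 0.031)
  set.seed(3)
  p <- runif(40)
  r2 <- fdr_bh(p)
  expect_true(all(r2$q >= p))
  expect_equal(r2$q, p.adjust(p, "BH"))
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("the Anderson-Darling test is calibrated and powerful", {
  set.seed(4)
  rej <- mean(replicate(200, normality_ad(rnorm(5000))$p < 0.05))
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(rej - 0.05), 3 * se)
  rej_unif <- mean(replicate(50, normality_ad(runif(100))$p < 0.05))
  expect_gte(rej_unif, 0.9)
  expect_error(normality_ad(rep(2, 20)), "constant")
  expect_error(normality_ad(rnorm(5)), "n >= 8")
})

test_that("experience correlation recovers perfect and null relationships", {
  codes <- rep(1:3, each = 4)
  y <- 10 - 2 * codes
  r <- experience_correlation(y, codes)
  expect_equal(r$r, -1)
  # null: mean correlation across simulations is 0 within 3 SE
  set.seed(5)
  rs <- replicate(10000, cor(rep(1:3, each = 4), rnorm(12)))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)))
  # hand fixture matches the covariance formula
  yy <- c(3.1, 2.2, 2.8, 1.9, 1.2, 0.7)
  cc <- c(1, 1, 2, 2, 3, 3)
  brute <- sum((yy - mean(yy)) * (cc - mean(cc))) /
    sqrt(sum((yy - mean(yy))^2) * sum((cc - mean(cc))^2))
  expect_equal(experience_correlation(yy, cc)$r, brute)
  expect_length(r$ci, 2)
  expect_error(experience_correlation(rep(1, 5), rep(1, 5)), "constant")
})

test_that("analytic paired-t power matches its reference implementations", {
  expect_equal(power_paired_t(0, 30), 0.05, tolerance = 1e-10)
  expect_gt(power_paired_t(3, 30), 0.999)
  # cross-check against stats::power.t.test, which drops the far-tail
  # rejection mass (< 1e-3 at these effect sizes); we keep both tails
  for (dz in c(0.3, 0.5, 0.8)) {
    expect_equal(power_paired_t(dz, 25),
                 power.t.test(n = 25, delta = dz, sd = 1,
                              type = "paired")$power,
                 tolerance = 2e-3)
  }
  # Monte-Carlo oracle at dz = 0.5, n = 30
  set.seed(6)
  nrep <- 100000
  d <- matrix(rnorm(30 * nrep, mean = 0.5, sd = 1), nrow = 30)
  tstat <- colMeans(d) / (apply(d, 2, sd) / sqrt(30))
  mc <- mean(abs(tstat) > qt(0.975, 29))
  expect_equal(power_paired_t(0.5, 30), mc, tolerance = 0.01)
  # monotone in effect size and in sample size
  expect_true(all(diff(sapply(c(0.2, 0.4, 0.8, 1.6),
                              power_paired_t, n = 20)) > 0))
  expect_true(all(diff(sapply(c(5, 10, 40, 160),
                              function(n) power_paired_t(0.4, n))) > 0))
})

test_that("paired t holds its nominal type-I error rate", {
  set.seed(7)
  nrep <- 5000
  x <- matrix(rnorm(30 * nrep), nrow = 30)
  y <- matrix(rnorm(30 * nrep), nrow = 30)
  rej <- mean(vapply(seq_len(nrep), function(k)
    paired_t(x[, k], y[, k])$p < 0.05, logical(1)))
  se <- sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(rej - 0.05), 3 * se)
})

test_that("condition comparison assembles the full statistical battery", {
  set.seed(8)
  units <- c("SMN", "DMN", "VN", "ATN", "TPN")
  fake_mf <- function(shift_dmn = 0) {
    do.call(rbind, lapply(1:30, function(tr)
      data.frame(trial = tr, unit = units, metric = "flexibility",
                 value = 0.3 + rnorm(5, sd = 0.05) +
                   ifelse(units == "DMN", shift_dmn, 0))))
  }
  res <- compare_conditions(fake_mf(0.15), fake_mf(0), "flexibility")
  expect_setequal(res$unit, units)
  expect_true(all(res$q >= res$p))
  dmn <- res[res$unit == "DMN", ]
  expect_lt(dmn$q, 0.05)
  expect_identical(dmn$stars %in% c("*", "**", "***"), TRUE)
  expect_gt(dmn$dz, 1)
  expect_equal(dmn$n, 30)
  # aggregation pools repeated trials before pairing
  agg <- compare_conditions(fake_mf(0.15), fake_mf(0), "flexibility",
                            aggregate_by = rep(1:10, each = 3))
  expect_equal(agg$n[1], 10)
  expect_equal(significance_stars(c(0.3, 0.04, 0.009, 0.004)),
               c("", "*", "**", "***"))
})
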