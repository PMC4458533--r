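test_that("variance components match a hand-computed two-by-two ANOVA", {
  x <- matrix(c(1, 2, 3, 4), nrow = 2, byrow = TRUE)
  vc <- variance_components(x)
  # row means 1.5 / 3.5, grand mean 2.5: MS_B = 2*(1+1)/1 = 4, MS_W = 1/2
  expect_equal(vc$ms_between, 4)
  expect_equal(vc$ms_within, 0.5)
  expect_equal(vc$s2_within, 0.5)
  expect_equal(vc$s2_between, 1.75)
  expect_equal(vc$s2_ip, 2.25)
})

test_that("identical observations give zero variance components", {
  vc <- variance_components(matrix(7, nrow = 3, ncol = 4))
  expect_equal(vc$s2_within, 0)
  expect_equal(vc$s2_between, 0)
  expect_equal(vc$s2_ip, 0)
})

test_that("design errors are rejected", {
  expect_error(variance_components(matrix(1:4, nrow = 1)), "p >= 2")
  expect_error(variance_components(matrix(1:4, ncol = 1)), "n >= 2")
  x <- matrix(rnorm(12), nrow = 3); x[2, 3] <- NA
  expect_error(variance_components(x), "missing cells")
})

test_that("estimator agrees with a brute-force ANOVA oracle on small matrices", {
  # exhaustive sweep: every 2x2 matrix with integer entries in 0..3
  grids <- expand.grid(a = 0:3, b = 0:3, c = 0:3, d = 0:3)
  for (k in seq_len(nrow(grids))) {
    x <- matrix(as.numeric(grids[k, ]), nrow = 2)
    vc <- variance_components(x)
    or <- vc_oracle(x)
    expect_equal(vc$s2_within, or$s2_within, tolerance = 1e-12)
    expect_equal(vc$s2_between, or$s2_between, tolerance = 1e-12)
  }
  # random sweep over larger balanced shapes, including the aov route
  set.seed(401)
  for (rep in 1:60) {
    p <- sample(2:4, 1); n <- sample(2:4, 1)
    x <- matrix(sample(0:3, p * n, replace = TRUE) + 0, nrow = p)
    vc <- variance_components(x)
    or <- vc_oracle(x)
    expect_equal(vc$s2_within, or$s2_within, tolerance = 1e-12)
    expect_equal(vc$s2_between, or$s2_between, tolerance = 1e-12)
    if (vc$ms_within > 0 && vc$ms_between > 0) {
      d <- data.frame(y = as.vector(t(x)),
                      g = factor(rep(seq_len(p), each = n)))
      ms <- anova(stats::aov(y ~ g, data = d))$`Mean Sq`
      expect_equal(vc$ms_between, ms[1], tolerance = 1e-9)
      expect_equal(vc$ms_within, ms[2], tolerance = 1e-9)
    }
  }
})

test_that("variance components are consistent on large simulated designs", {
  # average the estimators over 50 independent p = 200 x n = 50 designs so
  # the Monte-Carlo error of the check is well below the 5% band
  set.seed(402)
  p <- 200L; n <- 50L
  sigma_b <- 2; sigma_w <- 3
  s2b <- s2w <- numeric(50)
  for (r in 1:50) {
    x <- matrix(rep(rnorm(p, 0, sigma_b), each = n) +
                rnorm(p * n, 0, sigma_w), nrow = p, byrow = TRUE)
    vc <- variance_components(x)
    s2b[r] <- vc$s2_between
    s2w[r] <- vc$s2_within
  }
  expect_lt(abs(mean(s2b) - 4) / 4, 0.05)
  expect_lt(abs(mean(s2w) - 9) / 9, 0.05)
})

test_that("tolerance limits reproduce the published table within print rounding", {
  # 11 of 12 published rows; the AFA 250 ng/mL row is anomalous (its printed
  # limits are inconsistent with the procedure that matches the other rows)
  tab <- rbind(summary_afa(), summary_ibr())
  anomalous <- tab$analyte == "AFA" & tab$nominal_conc == 250
  for (k in which(!anomalous)) {
    tol <- tolerance_interval(tab$bias_pct[k], tab$rsd_r_pct[k],
                              tab$rsd_ip_pct[k], p = 3, n = 4, beta = 0.95)
    expect_lt(abs(tol$tol_lower_pct - tab$published_tol_lower_pct[k]), 0.05)
    expect_lt(abs(tol$tol_upper_pct - tab$published_tol_upper_pct[k]), 0.05)
  }
})

test_that("a negative between/within variance ratio is not truncated", {
  # published RSD_IP < RSD_r: only the untruncated convention matches print
  tol <- tolerance_interval(7.63, 1.96, 1.89, p = 3, n = 4, beta = 0.95)
  expect_lt(tol$R, 0)
  expect_lt(abs(tol$tol_lower_pct - 3.28), 0.05)
  expect_lt(abs(tol$tol_upper_pct - 11.98), 0.05)
})

test_that("the R = 0 case matches its closed form", {
  s <- 3.2; bias <- 0; p <- 3L; n <- 4L; beta <- 0.95
  # independent closed form: R = 0 gives B^2 = 1 and
  # nu = 1 / ((1/n)^2/(p-1) + (1-1/n)/(p*n))
  nu <- 1 / ((1 / n)^2 / (p - 1) + (1 - 1 / n) / (p * n))
  k <- qt((1 + beta) / 2, floor(nu)) * sqrt(1 + 1 / (p * n))
  tol <- tolerance_interval(bias, s, s, p = p, n = n, beta = beta)
  expect_equal(tol$R, 0)
  expect_equal(tol$dof_int, as.integer(floor(nu)))
  expect_equal(tol$tol_upper_pct, k * s, tolerance = 1e-12)
  expect_equal(tol$tol_lower_pct, -k * s, tolerance = 1e-12)
})

test_that("tolerance limits are symmetric about the bias", {
  set.seed(403)
  for (rep in 1:50) {
    bias <- runif(1, -8, 8)
    rr <- runif(1, 0.5, 6)
    rip <- rr * runif(1, 0.95, 1.8)   # keeps n*R + 1 > 0 for n <= 4
    p <- sample(2:5, 1); n <- sample(2:4, 1)
    tol <- tolerance_interval(bias, rr, rip, p = p, n = n, beta = 0.95)
    expect_equal(bias - tol$tol_lower_pct, tol$tol_upper_pct - bias,
                 tolerance = 1e-9)
    expect_lte(tol$tol_lower_pct, bias)
    expect_gte(tol$tol_upper_pct, bias)
    expect_gte(tol$dof_int, 1L)
  }
})

test_that("the coverage factor increases strictly with beta", {
  betas <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  for (R_pair in list(c(2.1, 2.0), c(2.0, 2.0), c(2.0, 2.6))) {
    k <- vapply(betas, function(b)
      tolerance_interval(0, R_pair[1], R_pair[2], p = 3, n = 4, beta = b)$k_tol,
      numeric(1))
    expect_true(all(diff(k) > 0))
  }
})

test_that("invalid tolerance-interval inputs raise errors", {
  expect_error(tolerance_interval(0, 2, 2, p = 3, n = 4, beta = 1.2), "beta")
  expect_error(tolerance_interval(0, 2, 2, p = 3, n = 4, beta = 0), "beta")
  expect_error(tolerance_interval(0, 0, 2, p = 3, n = 4), "level_statistics")
  expect_error(tolerance_interval(0, 2, 2, p = 1, n = 4), "p >= 2")
})

test_that("strongly negative variance ratios fall back to R = 0 with warning", {
  # rsd_ip << rsd_r so that n*R + 1 <= 0 (only reachable from inconsistent
  # rounded summaries, not from raw data where n*R + 1 = MS_B/MS_W > 0)
  expect_warning(tol <- tolerance_interval(0, 10, 1, p = 3, n = 4), "R = 0")
  expect_equal(tol$R, 0)
})

test_that("level statistics handle exact and degenerate data", {
  mu <- 50
  x <- matrix(mu, nrow = 3, ncol = 4)
  ls <- level_statistics(x, mu)
  expect_equal(ls$bias_pct, 0)
  expect_equal(ls$rsd_r_pct, 0)
  expect_equal(ls$rsd_ip_pct, 0)
  expect_equal(c(ls$tol_lower_pct, ls$tol_upper_pct), c(0, 0))

  x2 <- matrix(mu * 1.05, nrow = 3, ncol = 4)
  ls2 <- level_statistics(x2, mu)
  expect_equal(ls2$bias_pct, 5, tolerance = 1e-12)
  expect_equal(ls2$rsd_r_pct, 0)
  expect_equal(c(ls2$tol_lower_pct, ls2$tol_upper_pct), c(5, 5),
               tolerance = 1e-12)

  # zero within-day but non-zero between-day variance: analytic limit
  x3 <- matrix(rep(c(49, 50, 51), each = 4), nrow = 3, byrow = TRUE)
  ls3 <- level_statistics(x3, mu)
  expect_equal(ls3$rsd_r_pct, 0)
  expect_gt(ls3$rsd_ip_pct, 0)
  expect_equal(ls3$dof_int, 2L)   # p - 1 at infinite variance ratio
  expect_true(is.finite(ls3$tol_lower_pct) && is.finite(ls3$tol_upper_pct))
})

test_that("level statistics recover the generating bias and precision", {
  set.seed(404)
  mu <- 75; delta <- 1; sigma_b <- 0.02 * mu; sigma_w <- 0.025 * mu
  p <- 3L; n <- 4L; B <- 1000L
  bias <- rsd_r2 <- numeric(B)
  for (b in seq_len(B)) {
    x <- matrix(mu * (1 + delta / 100) + rep(rnorm(p, 0, sigma_b), each = n) +
                rnorm(p * n, 0, sigma_w), nrow = p, byrow = TRUE)
    ls <- level_statistics(x, mu)
    bias[b] <- ls$bias_pct
    rsd_r2[b] <- ls$rsd_r_pct^2
  }
  expect_lt(abs(mean(bias) - 1.0), 0.1)
  expect_lt(abs(sqrt(mean(rsd_r2)) - 2.5), 0.1)
})

test_that("recovery statistics average per level, then overall", {
  rec <- data.frame(analyte = "AFA", level = rep(1:2, each = 3), series = 1:3,
                    area_extracted = c(860, 860, 860, 900, 900, 900),
                    area_reference = 1000)
  rs <- recovery_statistics(rec)
  expect_equal(rs$per_level$mean_recovery_pct, c(86, 90))
  expect_equal(rs$overall$mean_recovery_pct, 88)
  expect_equal(rs$overall$sd_recovery_pct, sd(c(86, 90)))

  all_equal <- data.frame(analyte = "AFA", level = rep(1:3, each = 2),
                          series = 1, area_extracted = 500,
                          area_reference = 500)
  rs2 <- recovery_statistics(all_equal)
  expect_equal(rs2$per_level$mean_recovery_pct, rep(100, 3))
  expect_equal(rs2$overall$sd_recovery_pct, 0)

  bad <- data.frame(analyte = "AFA", level = 1, series = 1,
                    area_extracted = 1, area_reference = 0)
  expect_error(recovery_statistics(bad), "reference")
})

test_that("simulated recovery data land near the generating yield", {
  pars <- default_simulation_params("afatinib", seed = 17L)
  sim <- simulate_responses(pars)
  rs <- recovery_statistics(sim$recovery_records)
  expect_equal(nrow(sim$recovery_records), 6L * 12L)  # 12 per level
  expect_gt(rs$overall$mean_recovery_pct, 85)
  expect_lt(rs$overall$mean_recovery_pct, 91)
})
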