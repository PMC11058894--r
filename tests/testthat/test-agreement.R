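test_that("OLS regression reproduces exact linear relationships", {
  x <- c(1, 2, 3, 4, 5)
  f1 <- ols_regression(x, x)
  expect_equal(c(f1$beta1, f1$beta0, f1$r_squared), c(1, 0, 1))
  f2 <- ols_regression(x, -2 * x + 3)
  expect_equal(c(f2$beta1, f2$beta0, f2$r_squared), c(-2, 3, 1))
  expect_error(ols_regression(rep(2, 5), x), "constant")
  expect_error(ols_regression(1:2, 1:2), "at least 3")
})

test_that("OLS matches the normal-equations oracle on random data", {
  withr::local_seed(101)
  for (rep in 1:50) {
    x <- stats::rnorm(50)
    y <- 0.7 * x + stats::rnorm(50, sd = 0.4)
    fit <- ols_regression(x, y)
    orc <- oracle_ols(x, y)
    expect_equal(fit$beta1, orc$beta1, tolerance = 1e-10)
    expect_equal(fit$beta0, orc$beta0, tolerance = 1e-10)
    expect_equal(fit$r_squared, orc$r_squared, tolerance = 1e-10)
  }
})

test_that("Bland-Altman limits are mean +/- 2 sample SD with pair-mean percentages", {
  d <- c(1.2, 0.8, 1.5, 1.1)
  ba0 <- bland_altman(d, d)
  expect_equal(c(ba0$mean_diff, ba0$loa_low, ba0$loa_high, ba0$mean_pct_diff),
               c(0, 0, 0, 0))
  ba1 <- bland_altman(d + 1, d)
  expect_equal(ba1$mean_diff, 1)
  expect_equal(ba1$loa_low, 1)
  expect_equal(ba1$loa_high, 1)
  expect_error(bland_altman(c(1, 2, -3), c(1, 2, 3)), "index 3")
})

test_that("Bland-Altman is antisymmetric and matches the two-pass oracle", {
  withr::local_seed(202)
  for (rep in 1:50) {
    a <- stats::rnorm(77, mean = 5)
    b <- stats::rnorm(77, mean = 5)
    ba <- bland_altman(a, b)
    orc <- oracle_bland_altman(a, b)
    expect_equal(ba$mean_diff, orc$mean_diff, tolerance = 1e-10)
    expect_equal(ba$loa_low, orc$loa_low, tolerance = 1e-10)
    expect_equal(ba$loa_high, orc$loa_high, tolerance = 1e-10)
    expect_equal(ba$mean_pct_diff, orc$mean_pct_diff, tolerance = 1e-10)
    rev <- bland_altman(b, a)
    expect_equal(rev$mean_diff, -ba$mean_diff, tolerance = 1e-12)
    expect_equal(rev$loa_low, -ba$loa_high, tolerance = 1e-12)
    expect_equal(rev$loa_high, -ba$loa_low, tolerance = 1e-12)
  }
})

test_that("the normal upper tail behaves like 1 - Phi", {
  expect_equal(normal_upper_tail(0), 0.5)
  z <- seq(-6, 6, by = 0.25)
  for (zz in z) {
    num <- stats::integrate(function(u) exp(-u^2 / 2) / sqrt(2 * pi),
                            zz, Inf, rel.tol = 1e-12)$value
    expect_equal(normal_upper_tail(zz), num, tolerance = 1e-8)
  }
  expect_equal(normal_upper_tail(-1.3), 1 - normal_upper_tail(1.3),
               tolerance = 1e-12)
  expect_error(normal_upper_tail(Inf), "finite")
})

test_that("Fisher r-to-z comparison gives the documented worked values", {
  expect_equal(fisher_rz_compare(0.5, 40, 0.5, 40)$z, 0)
  expect_equal(fisher_rz_compare(0.5, 40, 0.5, 40)$p_one_sided, 0.5)
  expect_equal(round(normal_upper_tail(1.43), 4), 0.0764)
  expect_equal(round(normal_upper_tail(1.58), 4), 0.0571)
  # antisymmetry in (r1, r2)
  a <- fisher_rz_compare(0.85, 77, 0.77, 77)
  b <- fisher_rz_compare(0.77, 77, 0.85, 77)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_equal(a$p_one_sided, 1 - b$p_one_sided, tolerance = 1e-12)
  # direct formula check
  z_manual <- (atanh(0.85) - atanh(0.77)) / sqrt(1 / 74 + 1 / 74)
  expect_equal(a$z, z_manual, tolerance = 1e-12)
  expect_error(fisher_rz_compare(1, 10, 0.5, 10), "inside")
  expect_error(fisher_rz_compare(0.5, 3, 0.5, 10), "exceed 3")
})

test_that("the dependent-correlation variant is sane", {
  same <- fisher_rz_compare(0.6, 50, 0.6, 50, method = "dependent", r12 = 0.8)
  expect_equal(same$z, 0)
  d <- fisher_rz_compare(0.85, 77, 0.77, 77, method = "dependent", r12 = 0.9)
  expect_true(is.finite(d$z))
  # shared variance makes the dependent test more powerful than independent
  expect_gt(abs(d$z), abs(fisher_rz_compare(0.85, 77, 0.77, 77)$z))
  expect_error(fisher_rz_compare(0.8, 50, 0.7, 50, method = "dependent"),
               "r12")
})

test_that("the paired t test matches the textbook formula", {
  sym <- c(-2, -1, 1, 2)
  r <- paired_t_test(sym, rep(0, 4))
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_two_sided, 1)
  big <- paired_t_test(rnorm(20, sd = 0.1) + 50, rnorm(20, sd = 0.1))
  expect_lt(big$p_two_sided, 0.001)
  expect_error(paired_t_test(c(1, 2, 3), c(0, 1, 2)), "zero-variance")
  withr::local_seed(303)
  for (rep in 1:50) {
    a <- stats::rnorm(30); b <- stats::rnorm(30)
    got <- paired_t_test(a, b)
    orc <- oracle_paired_t(a, b)
    expect_equal(got$t_stat, orc$t_stat, tolerance = 1e-10)
    expect_equal(got$p_two_sided, orc$p_two_sided, tolerance = 1e-10)
  }
})

test_that("association categories follow the R^2 bins with inclusive upper edges", {
  expect_equal(categorize_association(0.04), "weak")
  expect_equal(categorize_association(0.25), "weak")
  expect_equal(categorize_association(0.26), "moderate")
  expect_equal(categorize_association(0.5), "moderate")
  expect_equal(categorize_association(0.72), "strong")
  expect_equal(categorize_association(0.8), "strong")
  expect_equal(categorize_association(0.84), "very strong")
  expect_equal(categorize_association(1), "very strong")
  expect_error(categorize_association(1.2), "\\[0, 1\\]")
  expect_error(categorize_association(-0.1), "\\[0, 1\\]")
})

test_that("run_comparison assembles the full agreement panel", {
  tab <- make_paired_measurements(
    20, methods = list(lvvel = list(slope = 1, intercept = 0, sd = 0),
                       mvvel = list(slope = 0.9, intercept = 0.05, sd = 0.05)),
    seed = 5L)
  rep <- run_comparison(tab, list(c("lvvel", "echo"), "mvvel:echo",
                                  "mvvel:lvvel"))
  expect_s3_class(rep, "agreement_report")
  expect_equal(nrow(rep), 9)  # 3 pairs x 3 metrics
  exact <- dplyr::filter(rep, method == "lvvel", reference == "echo")
  expect_true(all(abs(exact$r_squared - 1) < 1e-12))
  expect_true(all(abs(exact$mean_diff) < 1e-12))
  expect_true(all(exact$category == "very strong"))
  # bit-stable across runs
  rep2 <- run_comparison(tab, list(c("lvvel", "echo"), "mvvel:echo",
                                   "mvvel:lvvel"))
  expect_identical(as.data.frame(rep), as.data.frame(rep2))
  expect_error(run_comparison(tab, list(c("nope", "echo"))), "unknown method")
})

test_that("missing cells are dropped pairwise for the affected pair only", {
  tab <- make_paired_measurements(
    12, methods = list(lvvel = list(slope = 1, intercept = 0, sd = 0.05),
                       mvvel = list(slope = 1, intercept = 0, sd = 0.05)),
    seed = 6L)
  tab$value[tab$method == "mvvel" & tab$metric == "ea" &
              tab$subject_id == 3] <- NA
  expect_message(
    rep <- run_comparison(tab, list("lvvel:echo", "mvvel:echo")),
    "dropped 1")
  n_lv <- dplyr::filter(rep, method == "lvvel", metric == "ea")$n
  n_mv <- dplyr::filter(rep, method == "mvvel", metric == "ea")$n
  expect_equal(n_lv, 12)
  expect_equal(n_mv, 11)
  expect_equal(dplyr::filter(rep, method == "mvvel", metric == "peak_e")$n, 12)
})
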