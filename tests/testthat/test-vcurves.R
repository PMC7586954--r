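test_that("evaluate_vc matches the Weibull PLC closed form at anchor points", {
  vc <- vulnerability_curve(b = 1.55, c = 0.75)
  expect_equal(evaluate_vc(vc, 0)$plc, 0)
  # psi = -b forces a unit exponent: PLC = 100 (1 - 1/e)
  expect_equal(evaluate_vc(vc, -1.55)$plc, 100 * (1 - exp(-1)),
               tolerance = 1e-12)
  # PLC = 50 at the closed-form P50
  expect_equal(evaluate_vc(vc, p50(vc))$plc, 50, tolerance = 1e-9)
  # ks scale needs ksmax
  expect_error(evaluate_vc(vc, -1, what = "ks"), "ksmax")
  vck <- vulnerability_curve(1.55, 0.75, ksmax = 2.55)
  expect_equal(evaluate_vc(vck, 0, what = "ks")$ks, 2.55)
  expect_error(evaluate_vc(vc, 0.5), "<= 0")
})

test_that("PLC is monotone in drying, bounded, and saturates", {
  set.seed(11)
  for (i in 1:20) {
    vc <- vulnerability_curve(b = runif(1, 0.1, 5), c = runif(1, 0.2, 4))
    psi <- seq(0, -30, length.out = 200)
    plc <- evaluate_vc(vc, psi)$plc
    expect_true(all(diff(plc) >= 0))       # nondecreasing as pressure falls
    expect_true(all(plc >= 0 & plc <= 100))
    expect_equal(plc[1], 0)
    expect_gt(evaluate_vc(vc, -1e6)$plc, 99.99)  # PLC -> 100 as psi -> -Inf
  }
})

test_that("p50 closed form agrees with bisection on evaluate_vc", {
  set.seed(42)
  for (i in 1:25) {
    vc <- vulnerability_curve(b = runif(1, 0.1, 5), c = runif(1, 0.2, 4))
    # independent oracle: bisection for PLC(psi) = 50
    root <- uniroot(function(p) evaluate_vc(vc, p)$plc - 50,
                    c(-1e4, -1e-12), tol = 1e-12)$root
    expect_equal(p50(vc), root, tolerance = 1e-9)
  }
  # exponential special case c = 1: P50 = -b ln 2
  expect_equal(p50(vulnerability_curve(2.3, 1)), -2.3 * log(2),
               tolerance = 1e-12)
})

test_that("p50 reproduces the measured stem and root values", {
  expect_lt(abs(p50(vulnerability_curve(1.55, 0.75)) - (-0.95)), 0.005)
  expect_lt(abs(p50(vulnerability_curve(0.29, 0.59)) - (-0.16)), 0.005)
})

test_that("fit_vc recovers parameters exactly from noiseless data", {
  psi <- c(0, -0.2, -0.5, -1, -1.5, -2, -3, -4)
  truth <- vulnerability_curve(1.55, 0.75)
  m <- data.frame(pressure_mpa = psi, plc = evaluate_vc(truth, psi)$plc)
  fit <- fit_vc(m)
  expect_true(fit$converged)
  expect_equal(fit$curve$b, 1.55, tolerance = 1e-6)
  expect_equal(fit$curve$c, 0.75, tolerance = 1e-6)
  expect_lt(fit$residual_sum_squares, 1e-10)
})

test_that("fit_vc recovers b within 15% from noisy generated data", {
  truth <- vulnerability_curve(1.55, 0.75, genotype = "species")
  m <- gen_vc_measurements(truth, sigma = 5, n_segments = 3, seed = 1)
  expect_equal(nrow(m), 18)
  fit <- fit_vc(m)
  expect_lt(abs(fit$curve$b - 1.55) / 1.55, 0.15)
})

test_that("fit_vc bias shrinks as the number of points grows", {
  truth <- vulnerability_curve(1.55, 0.75)
  mae <- sapply(c(10, 40, 160), function(n) {
    errs <- sapply(1:8, function(s) {
      psi <- -seq(0, 4, length.out = n)
      m <- gen_vc_measurements(truth, pressures = psi, sigma = 5,
                               n_segments = 1, seed = 100 + s)
      abs(fit_vc(m)$curve$b - 1.55)
    })
    mean(errs)
  })
  expect_lt(mae[3], mae[1])
})

test_that("fit_vc rejects degenerate inputs", {
  expect_error(fit_vc(data.frame(pressure_mpa = rep(-1, 5), plc = 1:5 * 10)),
               "same pressure")
  expect_error(fit_vc(data.frame(pressure_mpa = -(1:5), plc = rep(30, 5))),
               "zero variance")
  expect_error(fit_vc(data.frame(pressure_mpa = c(0, -1), plc = c(0, 40))),
               "at least")
})

test_that("ks-scale fit with known ksmax matches the plc-scale curve shape", {
  truth <- vulnerability_curve(0.8, 0.6, ksmax = 11.14)
  psi <- c(0, -0.1, -0.3, -0.6, -1, -1.5, -2.5, -4)
  ks <- evaluate_vc(truth, psi, what = "ks")$ks
  m_ks <- data.frame(pressure_mpa = psi, ks = ks)
  m_plc <- data.frame(pressure_mpa = psi, plc = 100 * (1 - ks / 11.14))
  fit_ks <- fit_vc(m_ks, scale = "ks", ksmax = 11.14)
  fit_plc <- fit_vc(m_plc, scale = "plc")
  expect_equal(fit_ks$curve$b, fit_plc$curve$b, tolerance = 1e-5)
  expect_equal(fit_ks$curve$c, fit_plc$curve$c, tolerance = 1e-5)
  # co-estimated ksmax also lands on the truth with clean data
  fit_co <- fit_vc(m_ks, scale = "ks")
  expect_equal(fit_co$curve$ksmax, 11.14, tolerance = 1e-4)
})

test_that("compare_vc_parameters matches hand-computed one-way ANOVA", {
  d <- data.frame(genotype = rep(c("g1", "g2"), each = 3),
                  b = c(1.0, 1.1, 0.9, 2.0, 2.1, 1.9))
  # textbook arithmetic as the oracle
  gm <- mean(d$b)
  ssb <- 3 * ((1 - gm)^2 + (2 - gm)^2)
  ssw <- sum((d$b - rep(c(1, 2), each = 3))^2)
  f_oracle <- (ssb / 1) / (ssw / 4)
  p_oracle <- pf(f_oracle, 1, 4, lower.tail = FALSE)
  cmp <- compare_vc_parameters(d, "b")
  expect_equal(cmp$results$b$F, f_oracle, tolerance = 1e-10)
  expect_equal(cmp$results$b$p_value, p_oracle, tolerance = 1e-10)
  expect_identical(cmp$results$b$flagged_pairs, "g2-g1")
})

test_that("compare_vc_parameters handles identical groups and outlier groups", {
  d0 <- data.frame(genotype = rep(c("a", "b", "c"), each = 3), b = rep(1, 9))
  cmp0 <- compare_vc_parameters(d0, "b")
  expect_equal(cmp0$results$b$F, 0)
  expect_length(cmp0$results$b$flagged_pairs, 0)

  set.seed(3)
  d1 <- data.frame(genotype = rep(c("a", "b", "c"), each = 4),
                   b = c(rnorm(4, 1, 0.05), rnorm(4, 1, 0.05),
                         rnorm(4, 3, 0.05)))
  cmp1 <- compare_vc_parameters(d1, "b")
  fl <- cmp1$results$b$flagged_pairs
  expect_setequal(fl, c("c-a", "c-b"))  # only pairs involving the outlier

  expect_error(compare_vc_parameters(data.frame(genotype = "a", b = 1)),
               "2 genotypes")
  expect_error(
    compare_vc_parameters(data.frame(genotype = c("a", "a", "b"),
                                     b = c(1, 2, 3))),
    "replicates")
})

test_that("VC measurement IO round-trips through delimited text", {
  truth <- vulnerability_curve(1.55, 0.75, ksmax = 2.55, genotype = "species")
  m <- gen_vc_measurements(truth, sigma = 2, seed = 5)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(m, path, row.names = FALSE)
  m2 <- read_vc_measurements(path)
  expect_equal(m2$plc, m$plc, tolerance = 1e-9)
  fit <- fit_vc(m2)
  rep_path <- tempfile(fileext = ".csv")
  rep <- write_vc_fits(fit, rep_path)
  expect_true(file.exists(rep_path))
  expect_equal(rep$b, fit$curve$b)
})
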