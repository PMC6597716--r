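test_that("the trade-off regression matches brute-force Pearson and OLS", {
  pts <- data.frame(enzyme = c("A", "B", "C"),
                    activity = 10^c(3, 2, 1), Tm_C = c(50, 70, 90))
  f <- fit_tradeoff(pts)
  expect_equal(abs(f$r), 1, tolerance = 1e-12)
  expect_equal(f$slope, -0.05, tolerance = 1e-12)

  set.seed(42)
  n <- 100
  Tm <- runif(n, 45, 95)
  act <- 10^(4 - 0.05 * Tm + rnorm(n, 0, 0.2))
  pts2 <- data.frame(enzyme = paste0("e", 1:n), activity = act, Tm_C = Tm)
  f2 <- fit_tradeoff(pts2)
  o <- ols_oracle(Tm, log10(act))
  expect_lt(rel_err(f2$slope, o$slope), 1e-10)
  expect_lt(rel_err(f2$r, pearson_oracle(Tm, log10(act))), 1e-10)
  se_slope <- summary(f2$lm)$coefficients["Tm", "Std. Error"]
  expect_lt(abs(f2$slope - (-0.05)), 2 * se_slope)

  # permutation invariance
  f2p <- fit_tradeoff(pts2[sample(n), ])
  expect_equal(f2p$slope, f2$slope)
  expect_equal(f2p$r, f2$r)
})

test_that("deviations measure escape from the trade-off line", {
  set.seed(7)
  n <- 20
  Tm <- seq(45, 95, length.out = n)
  pts <- data.frame(enzyme = paste0("wt", 1:n),
                    activity = 10^(4 - 0.05 * Tm + rnorm(n, 0, 0.1)),
                    Tm_C = Tm, group = "wild-type")
  f <- fit_tradeoff(pts)

  on_line <- data.frame(enzyme = "on",
                        activity = 10^(f$intercept + f$slope * 80),
                        Tm_C = 80)
  expect_equal(unname(deviation_from_line(f, on_line)), 0,
               tolerance = 1e-12)

  escaper <- data.frame(enzyme = "esc",
                        activity = 10^(f$intercept + f$slope * 85 + 1),
                        Tm_C = 85)
  expect_equal(unname(deviation_from_line(f, escaper)), 1,
               tolerance = 1e-12)

  # OLS residuals of the fitting set sum to zero
  expect_lt(abs(sum(deviation_from_line(f, pts))), 1e-10)
  expect_lt(abs(sum(residuals(f))), 1e-10)
})

test_that("the fit is equivariant under affine Tm rescaling", {
  set.seed(11)
  pts <- data.frame(enzyme = letters[1:10],
                    activity = 10^runif(10, 0, 3),
                    Tm_C = runif(10, 40, 95))
  f1 <- fit_tradeoff(pts)
  pts2 <- pts
  pts2$Tm_C <- 2 * pts$Tm_C + 10
  f2 <- fit_tradeoff(pts2)
  expect_equal(f2$slope, f1$slope / 2, tolerance = 1e-10)
  expect_equal(f2$r, f1$r, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_tradeoff(data.frame(enzyme = c("a", "b"),
                                       activity = c(1, 2),
                                       Tm_C = c(50, 60))),
               "at least 3")
  expect_error(fit_tradeoff(data.frame(enzyme = c("a", "b", "c"),
                                       activity = c(1, -2, 3),
                                       Tm_C = c(50, 60, 70))),
               "positive")
})
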