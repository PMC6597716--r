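test_that("fit_mm recovers noiseless parameters to machine precision", {
  tr <- truth_preset("thermophile-like")
  km <- truth_km(tr, 298.15)
  kcat <- truth_kcat(tr, 298.15)
  f <- fit_mm(simulate_titration(tr, 25, km * 2^seq(-2, 5), 1e-8))
  expect_true(f$converged)
  expect_lt(rel_err(f$kcat, kcat), 1e-7)
  expect_lt(rel_err(f$Km, km), 1e-7)
  expect_equal(unname(coef(f)), c(f$kcat, f$Km))
  expect_equal(predict(f)[1], f$Vmax * km / 4 / (f$Km + km / 4),
               tolerance = 1e-9)
})

test_that("degenerate titrations are rejected", {
  s <- kinetic_series("x", 25, "NAD", conc = c(1e-6, 1e-5),
                      velocity = c(1e-9, 2e-9), enzyme_conc = 1e-8)
  expect_error(fit_mm(s), "at least 5")
  s2 <- kinetic_series("x", 25, "NAD", conc = rep(1e-6, 6),
                       velocity = rep(1e-9, 6), enzyme_conc = 1e-8)
  expect_error(fit_mm(s2), "equal")
})

test_that("median Km recovery is within 5% at 1% noise", {
  tr <- truth_preset("thermophile-like")
  km <- truth_km(tr, 298.15)
  grid <- km * seq(0.2, 5, length.out = 8)
  kms <- vapply(1:100, function(seed) {
    fit_mm(simulate_titration(tr, 25, grid, 1e-8,
                              noise = noise_spec(0.01, seed)))$Km
  }, numeric(1))
  expect_lt(abs(stats::median(kms) - km) / km, 0.05)
})

test_that("fits are invariant to concentration unit rescaling", {
  tr <- truth_preset("thermophile-like")
  km <- truth_km(tr, 298.15)
  s <- simulate_titration(tr, 25, km * 2^seq(-2, 5), 1e-8,
                          noise = noise_spec(0.02, 11))
  f_M <- fit_mm(s)
  s_uM <- s
  s_uM$points$conc <- s$points$conc * 1e6
  f_uM <- fit_mm(s_uM)
  expect_equal(f_uM$kcat, f_M$kcat, tolerance = 1e-6)
  expect_equal(f_uM$Km, f_M$Km * 1e6, tolerance = 1e-4)
})

test_that("specific activity realises the unit definition", {
  # slope chosen so exactly 1 umol NADH/min forms in a 1 mL cuvette
  expect_equal(specific_activity(0.0622, volume = 1e-3, mass = 0.01), 1.0)
  expect_equal(specific_activity(0.0622, volume = 1e-3, mass = 0.02), 0.5)
  expect_error(specific_activity(-1, volume = 1e-3, mass = 1), "positive")
})

test_that("relative tables reproduce printed fold-changes at 2 s.f.", {
  t1 <- ipmdh_constants()
  t1 <- t1[t1$table == "T1", ]
  rel_k <- relative_table(stats::setNames(t1$kcat_per_s, t1$enzyme),
                          "TtIPMDH")
  expect_equal(rel_k$relative[rel_k$enzyme == "mut#9"], 9.5)
  expect_equal(rel_k$relative[rel_k$enzyme == "TtIPMDH"], 1.0)
  rel_km <- relative_table(stats::setNames(t1$Km_NAD_uM, t1$enzyme),
                           "TtIPMDH")
  expect_equal(rel_km$relative[rel_km$enzyme == "mut#28"], 250)
  expect_equal(rel_km$relative[rel_km$enzyme == "EcIPMDH"], 28)

  # ratio times reference reproduces the value within 2 s.f. rounding
  expect_equal(rel_km$relative * 2.2, t1$Km_NAD_uM, tolerance = 0.05)
  expect_error(relative_table(c(a = 1), "b"), "reference")
  expect_error(relative_table(c(a = 1, b = -2), "a"), "positive")
})

test_that("kcat fold-changes decrease with temperature for the mutants", {
  t2 <- ipmdh_constants()
  t2 <- t2[t2$table == "T2", ]
  fc <- fold_change_report(t2)
  expect_equal(unlist(fc$folds["mut9/21", ]), c(`25C` = 4.3 / 0.37,
                                                `40C` = 16 / 2.4,
                                                `70C` = 100 / 79))
  expect_equal(signif(unlist(fc$folds["mut9/21", ]), 2),
               c(`25C` = 12, `40C` = 6.7, `70C` = 1.3))
  expect_true(all(fc$decreasing[c("mut9/17", "mut9/21", "EcIPMDH")]))

  same <- data.frame(enzyme = rep(c("ref", "x"), 3),
                     temperature_C = rep(c(25, 40, 70), each = 2),
                     kcat_per_s = rep(c(1, 2), 3))
  fc_same <- fold_change_report(same, reference = "ref")
  expect_true(all(fc_same$decreasing))
  inc <- same
  inc$kcat_per_s <- c(1, 1, 1, 2, 1, 4)
  expect_false(fold_change_report(inc, reference = "ref")$decreasing[["x"]])
})
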