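printed_tt <- data.frame(T_K = c(25, 40, 70) + 273.15,
                         kcat = c(0.37, 2.4, 79),
                         Km = c(2.2e-6, 12e-6, 210e-6))

test_that("Eyring and binding free energies evaluate correctly", {
  k <- physical_constants()
  expect_equal(eyring_dg_act(k$k_B * 298.15 / k$h, 298.15), 0,
               tolerance = 1e-12)
  expect_equal(eyring_dg_act(0.37, 298.15), 75.485, tolerance = 1e-3)
  expect_equal(eyring_dg_act(13, 298.15), 66.663, tolerance = 1e-3)

  expect_equal(binding_dg(1, 298.15), 0)
  expect_equal(binding_dg(1, 298.15, "as_printed"), 0)
  expect_equal(binding_dg(2.2e-6, 298.15), -32.292, tolerance = 1e-3)
  expect_equal(binding_dg(62e-6, 298.15), -24.016, tolerance = 1e-3)
  expect_equal(binding_dg(2.2e-6, 298.15, "as_printed"), 32.292,
               tolerance = 1e-3)

  expect_equal(dg_total(75.485, -32.292), 43.193)
  expect_equal(dg_total(5, 0), 5)
  expect_error(eyring_dg_act(-1, 298.15), "positive")
  expect_error(binding_dg(0, 298.15), "positive")
})

test_that("regression enthalpies match a closed-form OLS oracle", {
  R <- physical_constants()$R

  arr <- arrhenius_dh_act(printed_tt[c("T_K", "kcat")])
  o <- ols_oracle(1 / printed_tt$T_K, log(printed_tt$kcat))
  expect_lt(rel_err(arr$slope, o$slope), 1e-10)
  expect_lt(rel_err(arr$dH_act, -R * o$slope - R * 298.15), 1e-10)
  expect_equal(arr$dH_act, 99.204, tolerance = 1e-3)

  vh <- vanthoff_dhm(printed_tt[c("T_K", "Km")])
  ov <- ols_oracle(1 / printed_tt$T_K, log(printed_tt$Km))
  expect_lt(rel_err(vh$dH_m, R * ov$slope), 1e-10)
  expect_equal(vh$dH_m, -86.065, tolerance = 1e-3)
  expect_equal(vanthoff_dhm(printed_tt[c("T_K", "Km")], "as_printed")$dH_m,
               86.065, tolerance = 1e-3)

  # formula limits for temperature-independent rates
  flat_k <- data.frame(T_K = c(298.15, 313.15, 343.15), kcat = 2)
  expect_equal(arrhenius_dh_act(flat_k)$dH_act, -R * 298.15,
               tolerance = 1e-9)
  flat_km <- data.frame(T_K = c(298.15, 313.15, 343.15), Km = 1e-5)
  expect_equal(vanthoff_dhm(flat_km)$dH_m, 0, tolerance = 1e-9)

  expect_error(arrhenius_dh_act(data.frame(T_K = 298.15, kcat = 1)),
               "at least 2")
  expect_warning(arrhenius_dh_act(data.frame(T_K = c(298.15, 343.15),
                                             kcat = c(1, 10))),
                 "2 temperatures")
})

test_that("round-trip through the generator recovers the truth enthalpies", {
  tr <- truth_preset("thermophile-like")
  T_K <- celsius_to_kelvin(c(25, 40, 55, 70))
  arr <- arrhenius_dh_act(data.frame(T_K = T_K, kcat = truth_kcat(tr, T_K)))
  # ln kcat is not exactly linear in 1/T (T prefactor); small curvature only
  expect_lt(abs(arr$dH_act - tr$dH_act), 0.5)
  vh <- vanthoff_dhm(data.frame(T_K = T_K, Km = truth_km(tr, T_K)))
  expect_lt(rel_err(vh$dH_m, tr$dHm), 1e-9)  # exactly linear by design
})

test_that("assembled profiles satisfy the conservation identities", {
  arr <- arrhenius_dh_act(printed_tt[c("T_K", "kcat")])
  vh <- vanthoff_dhm(printed_tt[c("T_K", "Km")])
  p <- assemble_profile(0.37, 2.2e-6, arr, vh, enzyme = "TtIPMDH")
  expect_lt(abs(p$dG_T - p$dG_act - p$dG_m), 1e-9)
  expect_lt(abs(p$dH_T - p$dH_act - p$dH_m), 1e-9)
  for (x in c("act", "m", "T"))
    expect_lt(abs(p[[paste0("mTdS_", x)]] -
                    (p[[paste0("dG_", x)]] - p[[paste0("dH_", x)]])), 1e-9)

  st <- profile_states(p)
  expect_equal(st$dG, c(0, p$dG_m, p$dG_T))

  zero <- assemble_profile(0.37, 2.2e-6, dH_act = 0, dH_m = 0)
  expect_equal(zero$mTdS_act, zero$dG_act)
  expect_equal(zero$mTdS_T, zero$dG_T)

  vh_printed <- vanthoff_dhm(printed_tt[c("T_K", "Km")], "as_printed")
  expect_error(assemble_profile(0.37, 2.2e-6, arr, vh_printed),
               "convention")
})

test_that("profile comparison is a metric and ranks the mutants with Ec", {
  tab <- ipmdh_constants()
  k <- tab[tab$table == "T2", ]
  profs <- lapply(split(k, k$enzyme), function(d) {
    d <- d[order(d$temperature_C), ]
    T_K <- celsius_to_kelvin(d$temperature_C)
    assemble_profile(
      d$kcat_per_s[1], d$Km_NAD_uM[1] * 1e-6,
      arrhenius_dh_act(data.frame(T_K = T_K, kcat = d$kcat_per_s)),
      vanthoff_dhm(data.frame(T_K = T_K, Km = d$Km_NAD_uM * 1e-6)),
      enzyme = d$enzyme[1])
  })
  cmp <- compare_profiles(unname(profs))
  D <- cmp$distance
  expect_true(isSymmetric(D))
  expect_true(all(D >= 0))
  expect_true(all(diag(D) == 0))
  expect_identical(compare_profiles(list(profs[[1]], profs[[1]]))
                   $distance[1, 2], 0)

  # engineered mutants resemble the mesophilic enzyme, not their parent
  expect_lt(D["mut9/21", "EcIPMDH"], D["mut9/21", "TtIPMDH"])
  expect_lt(D["mut9/17", "EcIPMDH"], D["mut9/17", "TtIPMDH"])
})
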