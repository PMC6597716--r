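test_that("truth_kcat follows the Eyring law and inverts the free energy", {
  k <- physical_constants()
  zero <- enzyme_truth("zero", dH_act = 0, dS_act = 0, dHm = 0, dSm = 0)
  # zero activation free energy leaves only the kB*T/h prefactor
  expect_equal(truth_kcat(zero, 298.15), k$k_B * 298.15 / k$h,
               tolerance = 1e-12)

  # a truth anchored at kcat(25 C) = 0.37/s maps back to 75.5 kJ/mol
  tr <- truth_preset("thermophile-like")
  expect_equal(truth_kcat(tr, 298.15), 0.37, tolerance = 1e-9)
  expect_equal(eyring_dg_act(truth_kcat(tr, 298.15), 298.15), 75.485,
               tolerance = 1e-3)

  # doubling kcat lowers the barrier by RT ln 2
  expect_equal(eyring_dg_act(1, 298.15) - eyring_dg_act(2, 298.15),
               k$R * 298.15 * log(2), tolerance = 1e-12)

  expect_error(truth_kcat(tr, -10), "positive")
  expect_true(all(truth_kcat(tr, celsius_to_kelvin(seq(0, 100))) > 0))
})

test_that("truth_km inverts binding_dg and worsens with T for exothermic binding", {
  tr <- truth_preset("thermophile-like")
  expect_equal(truth_km(tr, 298.15), 2.2e-6, tolerance = 1e-9)
  expect_equal(binding_dg(truth_km(tr, 298.15), 298.15), -32.292,
               tolerance = 1e-3)

  unit <- enzyme_truth("unit", 0, 0, dHm = 0, dSm = 0)
  expect_equal(truth_km(unit, 298.15), 1)  # dG_m = 0 is the 1 M standard state

  expect_lt(tr$dHm, 0)
  km <- truth_km(tr, celsius_to_kelvin(seq(0, 100, by = 5)))
  expect_true(all(diff(km) > 0))
  expect_true(all(km > 0))
  expect_error(truth_km(tr, 0), "positive")
})

test_that("simulate_titration obeys the rate law and is seed-reproducible", {
  tr <- truth_preset("thermophile-like")
  km <- truth_km(tr, 298.15)
  kcat <- truth_kcat(tr, 298.15)
  E <- 1e-8

  s <- simulate_titration(tr, 25, conc_grid = c(km, km * 1e6, km * 2^(0:3)),
                          enzyme_conc = E)
  expect_equal(s$points$velocity[1], kcat * E / 2, tolerance = 1e-12)
  expect_equal(s$points$velocity[2], kcat * E, tolerance = 1e-5)

  n17a <- simulate_titration(tr, 25, km * 2^(-2:5), E,
                             noise = noise_spec(0.05, 17))
  n17b <- simulate_titration(tr, 25, km * 2^(-2:5), E,
                             noise = noise_spec(0.05, 17))
  expect_identical(n17a$points, n17b$points)
  n18 <- simulate_titration(tr, 25, km * 2^(-2:5), E,
                            noise = noise_spec(0.05, 18))
  expect_false(identical(n17a$points, n18$points))

  expect_error(simulate_titration(tr, 25, numeric(0), E), "non-empty")
  expect_error(simulate_titration(tr, 25, c(1e-6, -1e-6), E), "positive")
})

test_that("simulate_melt has its midpoint at Tm and sharpens with dHvH", {
  tr <- enzyme_truth("m", 0, 0, 0, 0, Tm = 85, dHvH = 500,
                     baselines = c(1, 0, 0, 0))
  curve <- simulate_melt(tr, T_grid = seq(65, 105, by = 0.5))
  i <- which(curve$points$temperature_C == 85)
  expect_equal(curve$points$ellipticity[i], 0.5, tolerance = 1e-12)

  steep <- enzyme_truth("s", 0, 0, 0, 0, Tm = 85, dHvH = 1e5,
                        baselines = c(1, 0, 0, 0))
  sc <- simulate_melt(steep, T_grid = seq(65, 105, by = 0.5))
  expect_lt(abs(sc$points$ellipticity[sc$points$temperature_C == 84] - 1),
            1e-6)
  expect_lt(sc$points$ellipticity[sc$points$temperature_C == 86], 1e-6)

  expect_warning(simulate_melt(tr, T_grid = seq(20, 60, by = 2)),
                 "span")
})

test_that("toy structures realise the requested ligand distances exactly", {
  sites <- data.frame(chain = "A", resno = c(5, 12, 40),
                      resname = c("VAL", "HIS", "GLY"),
                      dist = c(5.0, 10.0, 1.2))
  pdb <- read_structure(make_toy_structure(sites))
  dm <- compute_distance_map(pdb)
  expect_equal(dm$min_dist[match(sites$resno, dm$resno)], sites$dist,
               tolerance = 0.011)

  # brute-force all-pairs oracle agrees with the vectorised distance map
  for (i in seq_len(nrow(sites))) {
    brute <- min(brute_res_lig_dist(pdb, "A", sites$resno[i], "IPM"),
                 brute_res_lig_dist(pdb, "A", sites$resno[i], "NAD"))
    expect_equal(dm$min_dist[dm$resno == sites$resno[i]], brute,
                 tolerance = 1e-9)
  }

  expect_error(make_toy_structure(
    data.frame(chain = "A", resno = c(1, 1), resname = "ALA", dist = 5)),
    "unique")
  expect_error(make_toy_structure(
    data.frame(chain = "A", resno = 1, resname = "ALA", dist = -2)),
    "positive")
})

test_that("fitted standard errors grow with the noise level", {
  tr <- truth_preset("thermophile-like")
  km <- truth_km(tr, 298.15)
  grid <- km * 2^seq(-2, 5, length.out = 8)
  mean_se <- vapply(c(0.01, 0.05, 0.1), function(sd) {
    ses <- vapply(1:50, function(seed) {
      f <- fit_mm(simulate_titration(tr, 25, grid, 1e-8,
                                     noise = noise_spec(sd, seed)))
      c(f$kcat_se, f$Km_se)
    }, numeric(2))
    rowMeans(ses)
  }, numeric(2))
  expect_true(all(diff(mean_se[1, ]) > 0))  # kcat SE
  expect_true(all(diff(mean_se[2, ]) > 0))  # Km SE
})
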