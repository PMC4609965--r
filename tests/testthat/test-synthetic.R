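test_that("dimer occupancy follows the quadratic equilibrium", {
  # hand oracle: cA = cB = 250 uM, kd = 250 uM -> (750 - sqrt(312500)) / 500
  f <- simulate_occupancy(250e-6, 250e-6, 250e-6, "exact_dimer")
  expect_equal(f, (750 - sqrt(312500)) / 500, tolerance = 1e-12)
  # no-binding limit
  expect_lt(simulate_occupancy(250e-6, 250e-6, 1e9, "exact_dimer"), 1e-6)
  # stoichiometric limit
  expect_equal(simulate_occupancy(250e-6, 250e-6, 1e-12, "exact_dimer"), 1,
               tolerance = 1e-4)
  expect_error(simulate_occupancy(250e-6, 250e-6, 0), class = "prekd_bad_param")
  # bounded by min(1, cB/cA)
  f2 <- simulate_occupancy(250e-6, 100e-6, 50e-6, "exact_dimer")
  expect_lte(f2, 100 / 250)
})

test_that("occupancy models agree in the excess-titrant limit", {
  kd <- 100e-6
  for (cB in c(50e-6, 250e-6, 1e-3)) {
    exact <- simulate_occupancy(kd / 1e4, cB, kd, "exact_dimer")
    hyp <- simulate_occupancy(kd / 1e4, cB, kd, "hyperbolic")
    expect_equal(exact, hyp, tolerance = 1e-3)
  }
})

test_that("true PRE rates localise to contact segments", {
  cfg <- scenario("homo", seed = 2)
  # no titrant: all zero
  expect_true(all(simulate_pre_truth(cfg, 0, site = 44)$gamma2_true == 0))
  tr <- simulate_pre_truth(cfg, 1, site = 44)
  nac <- region_map(cfg$visible_sequence)$regions$NAC
  for (rt in c(0.25, 0.75, 1.5)) {
    tt <- simulate_pre_truth(cfg, rt, site = 44)
    expect_true(all(tt$gamma2_true[nac[1]:nac[2]] == 0))
  }
  # inside segments positive, outside zero
  expect_true(all(tr$gamma2_true[36:44] > 0))
  expect_true(all(tr$gamma2_true[c(1:35, 45:123)] == 0))
  # hetero occupancy at matched ratio beats homo: kd 100 vs 500 uM
  f_het <- simulate_occupancy(250e-6, 250e-6, 100e-6, "exact_dimer")
  f_hom <- simulate_occupancy(250e-6, 250e-6, 500e-6, "exact_dimer")
  expect_gt(f_het, f_hom)
})

test_that("true PRE rates are nondecreasing in the titration ratio", {
  for (nm in c("homo", "hetero")) {
    cfg <- scenario(nm, seed = 4)
    mats <- vapply(cfg$ratios,
                   function(rt) simulate_pre_truth(cfg, rt, 44)$gamma2_true,
                   numeric(nchar(cfg$visible_sequence)))
    expect_true(all(apply(mats, 1, function(v) all(diff(v) >= -1e-12))))
  }
})

test_that("scenario truths encode the documented contact segments", {
  homo <- scenario("homo", seed = 1)
  expect_setequal(unique(homo$truth$residue[homo$truth$type == "specific"]),
                  124:140)
  expect_setequal(unique(homo$truth$residue[homo$truth$type == "nonspecific"]),
                  36:44)
  kds <- homo$truth$kd[homo$truth$type == "specific"]
  expect_true(all(kds >= 90e-6 & kds <= 1200e-6))
  het <- scenario("hetero", seed = 1)
  expect_setequal(unique(het$truth$residue[het$truth$type == "specific"]),
                  105:134)
  expect_true(all(het$truth$kd[het$truth$type == "specific"] >= 40e-6))
  expect_true(all(het$truth$kd[het$truth$type == "specific"] <= 350e-6))
  bb <- scenario("beta-beta", seed = 1)
  expect_equal(nrow(bb$truth), 0)
  expect_error(scenario("gamma-gamma"), "homo, hetero, beta-beta")
})

test_that("simulated peak tables are deterministic and exact when noiseless", {
  cfg <- scenario("homo", seed = 9, noise = 0)
  tabs <- simulate_peak_tables(cfg, 1, "para", site = 44)
  truth <- simulate_pre_truth(cfg, 1, site = 44)
  for (s in tabs[c(30, 38, 40, 128)]) {
    f <- fit_decay(s, noise = 0)
    r <- s$residue_index
    expect_equal(f$r2, cfg$baseline$r2[r] + truth$gamma2_true[r],
                 tolerance = 1e-7)
  }
  # same seed, identical tables; different seed differs
  cfg2 <- scenario("homo", seed = 10, noise = 0.02)
  a <- simulate_peak_tables(cfg2, 1, "dia", site = 11)
  b <- simulate_peak_tables(cfg2, 1, "dia", site = 11)
  expect_identical(a, b)
  c_ <- simulate_peak_tables(cfg2, 1, "dia", site = 11, seed = 999)
  expect_false(identical(a, c_))
  # prolines carry no peak
  expect_false(any(vapply(tabs, function(s) s$residue_index, integer(1)) %in%
                     which(strsplit(cfg$visible_sequence, "")[[1]] == "P")))
})

test_that("fast-path titrations carry truth and a clean zero point", {
  cfg <- scenario("hetero", seed = 21)
  sim <- simulate_titration(cfg, site = 44)
  set <- sim$set
  x0 <- set[set$x == 0, ]
  sig <- unique(set$gamma2_error)
  expect_true(all(abs(x0$gamma2) < 5 * sig))
  # truth record covers the configured segments
  expect_setequal(unique(sim$truth$residue[sim$truth$type == "specific"]),
                  105:134)
  # determinism
  sim2 <- simulate_titration(cfg, site = 44)
  expect_identical(sim$set$gamma2, sim2$set$gamma2)
})

test_that("full-path titration matches the fast path statistically", {
  cfg <- scenario("hetero", seed = 33)
  full <- simulate_titration(cfg, site = 44, path = "full")
  truth_last <- simulate_pre_truth(cfg, max(cfg$ratios), 44)
  last <- full$set[full$set$x == max(attr(full$set, "x_grid")), ]
  resid <- last$gamma2 - truth_last$gamma2_true[last$residue]
  # propagated-level agreement: residuals consistent with sigma_gamma
  sg <- propagated_sigma_gamma(cfg$titration_delays, cfg$noise)
  expect_lt(sd(resid), 3 * sg)
  expect_lt(abs(mean(resid)), 1)
})
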