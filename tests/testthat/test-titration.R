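test_that("binding model obeys its limiting values", {
  expect_equal(binding_model(0, 3, 40, 1e-4), 3)
  expect_equal(binding_model(1e-4, 0, 40, 1e-4), 20)      # half saturation
  expect_equal(binding_model(1e-4 * 1e6, 0, 40, 1e-4), 40, tolerance = 1e-4)
  expect_error(binding_model(1e-4, 0, 40, 0), class = "prekd_bad_param")
  expect_error(binding_model(-1e-6, 0, 40, 1e-4), class = "prekd_bad_param")
  # monotone nondecreasing when bound >= free
  x <- seq(0, 1e-3, length.out = 50)
  expect_true(all(diff(binding_model(x, 2, 35, 2e-4)) >= 0))
})

make_set <- function(values_by_residue, x = titration_x, sigma = 0.3) {
  profs <- lapply(seq_along(x), function(k) {
    make_pp(seq_along(values_by_residue),
            vapply(values_by_residue, function(v) v[k], numeric(1)),
            gamma2_error = sigma,
            sample = list(ratio = x[k] / 250e-6))
  })
  titration_set(profs, 250e-6)
}

test_that("residue selection applies a strict threshold at a grid point", {
  vals <- lapply(c(3, 20, 14.9, 15.0, 40), function(v)
    c(0, 0.2, 0.4, 0.6, 0.8, 1) * v)
  set <- make_set(vals)
  expect_equal(select_fittable_residues(set), c(2L, 5L))
  expect_equal(select_fittable_residues(set, threshold = 39.9), 5L)
  # all-weak set selects nothing
  expect_length(select_fittable_residues(set, threshold = 50), 0)
  # a point beyond the retained grid is an error
  expect_error(select_fittable_residues(set, point_index = 7),
               class = "prekd_bad_param")
  # designated ordinal on the grid
  expect_equal(select_fittable_residues(set, point_index = 5, threshold = 15),
               c(2L, 5L))
})

test_that("titration sets enforce their grid invariants", {
  p1 <- make_pp(1:4, rep(1, 4), sample = list(ratio = 0))
  p2 <- make_pp(1:4, rep(2, 4), sample = list(ratio = 0.5))
  expect_s3_class(titration_set(list(p2, p1), 250e-6), "titration_set")
  # missing x = 0 point
  p3 <- make_pp(1:4, rep(2, 4), sample = list(ratio = 1))
  expect_error(titration_set(list(p2, p3), 250e-6), class = "prekd_bad_param")
  # duplicate ratios
  expect_error(titration_set(list(p1, p2, p2), 250e-6),
               class = "prekd_bad_param")
  # residues missing at one point are dropped from the common grid
  p4 <- make_pp(1:3, rep(3, 3), sample = list(ratio = 1))
  set <- titration_set(list(p1, p2, p4), 250e-6)
  expect_equal(sort(unique(set$residue)), 1:3)
})

test_that("noiseless saturation data round-trip through the fitter", {
  for (kd in c(50e-6, 100e-6, 500e-6)) {
    y <- binding_model(titration_x, 1.5, 40, kd)
    f <- fit_titration(titration_x, y, sigma = 0.5)
    expect_equal(f$kd, kd, tolerance = 1e-6)
    expect_equal(f$gamma2_free, 1.5, tolerance = 1e-5)
    expect_equal(f$gamma2_bound, 40, tolerance = 1e-5)
    expect_false(f$flagged)
  }
})

test_that("degenerate titration profiles are flagged", {
  # straight line: kd diverges far beyond the sampled range
  y <- 0.02e6 * titration_x
  f <- fit_titration(titration_x, y, sigma = 0.5)
  expect_gt(f$kd, 10 * max(titration_x))
  expect_true(f$flagged)
  # all zeros: unidentifiable
  f0 <- fit_titration(titration_x, rep(0, 6), sigma = 0.5)
  expect_true(f0$flagged)
  expect_equal(f0$gamma2_free, 0, tolerance = 1e-6)
  expect_equal(f0$gamma2_bound, 0, tolerance = 1e-6)
  # too few points / bad errors
  expect_error(fit_titration(titration_x[1:3], c(0, 1, 2), 0.5),
               class = "prekd_too_few")
  expect_error(fit_titration(titration_x, rep(1, 6), 0), class = "prekd_bad_param")
})

test_that("estimates are invariant to a global error rescaling", {
  set.seed(31)
  y <- binding_model(titration_x, 0, 40, 1e-4) + rnorm(6, 0, 1)
  f1 <- fit_titration(titration_x, y, sigma = 1)
  f2 <- fit_titration(titration_x, y, sigma = 17)
  expect_equal(f1$kd, f2$kd, tolerance = 1e-6)
  expect_equal(f1$gamma2_bound, f2$gamma2_bound, tolerance = 1e-6)
  # heteroscedastic weights do matter in general, but the reduced
  # chi-square rescaling keeps errors comparable under global scaling
  expect_equal(f1$kd_se, f2$kd_se, tolerance = 1e-4)
})

test_that("saturation model never fits worse than its nested line", {
  set.seed(37)
  for (k in 1:20) {
    kd <- runif(1, 5e-4, 5e-3) # near-linear regime: line in the closure
    y <- binding_model(titration_x, 0, 30, kd) + rnorm(6, 0, 0.2)
    sat <- fit_titration(titration_x, y, sigma = 0.2)
    lin <- prekd:::fit_linear(titration_x, y, sigma = 0.2)
    # the bound gamma2_bound <= 500 truncates the exact linear limit, so a
    # small residual curvature term is tolerated on top of the line's fit
    expect_lte(sat$chisq, lin$chisq + 0.1)
  }
})

test_that("profile classification separates saturating from linear curves", {
  y_sat <- binding_model(titration_x, 0, 40, 1e-4)
  sat <- fit_titration(titration_x, y_sat, sigma = 0.3)
  lin <- prekd:::fit_linear(titration_x, y_sat, sigma = 0.3)
  expect_equal(classify_profile(sat, lin), "specific")
  y_lin <- 0.05e6 * titration_x
  sat2 <- fit_titration(titration_x, y_lin, sigma = 0.3)
  lin2 <- prekd:::fit_linear(titration_x, y_lin, sigma = 0.3)
  expect_equal(classify_profile(sat2, lin2), "nonspecific")
})

test_that("set-level fitting classifies and reports kd only where defined", {
  vals <- list(
    binding_model(titration_x, 0, 40, 1e-4),         # specific
    0.06e6 * titration_x,                            # nonspecific (linear)
    rep(0, 6))                                       # noninteracting
  set <- make_set(vals, sigma = 0.3)
  fits <- fit_titration_set(set)
  expect_equal(fits$classification,
               c("specific", "nonspecific", "noninteracting"))
  expect_equal(fits$kd[1], 1e-4, tolerance = 1e-4)
  expect_true(is.na(fits$kd[2]) && is.na(fits$kd[3]))
  # profile-likelihood interval brackets the estimate
  expect_lte(fits$kd_lo[1], fits$kd[1])
  expect_gte(fits$kd_hi[1], fits$kd[1])
})

test_that("kd identifiability degrades monotonically beyond the grid", {
  fracs <- vapply(c(5e-4, 2.5e-3, 5e-3, 1e-2), function(kd) {
    set.seed(7)
    mean(replicate(60, {
      y <- binding_model(titration_x, 0, 45, kd) + rnorm(6, 0, 1)
      sat <- fit_titration(titration_x, y, sigma = 1)
      lin <- prekd:::fit_linear(titration_x, y, sigma = 1)
      classify_profile(sat, lin) == "nonspecific"
    }))
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("group summaries report median and range of specific residues", {
  bf <- make_bf(1, "specific", 100e-6)
  gs <- group_summary(bf)
  expect_equal(gs$kd_median, 100e-6)
  expect_equal(c(gs$kd_min, gs$kd_max), c(100e-6, 100e-6))
  bf3 <- make_bf(1:4, c("specific", "specific", "specific", "nonspecific"),
                 c(90e-6, 500e-6, 1200e-6, NA))
  gs3 <- group_summary(bf3)
  expect_equal(gs3$kd_median, 500e-6)
  expect_equal(c(gs3$kd_min, gs3$kd_max), c(90e-6, 1200e-6))
  expect_equal(gs3$n, 3)
  expect_error(group_summary(make_bf(1:2, rep("nonspecific", 2))),
               class = "prekd_empty")
  expect_error(group_summary(bf3, residues = 10:20), class = "prekd_empty")
})

test_that("titration plots build", {
  vals <- list(binding_model(titration_x, 0, 40, 1e-4),
               binding_model(titration_x, 0, 35, 2e-4))
  set <- make_set(vals, sigma = 0.3)
  fits <- fit_titration_set(set)
  expect_s3_class(plot_titration(set, fits), "ggplot")
  expect_s3_class(plot_titration_surface(set), "ggplot")
})
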