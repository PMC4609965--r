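test_that("peak series enforce their invariants", {
  expect_s3_class(peak_series(1, c(0.012, 0.032, 0.104), c(3, 2, 1)),
                  "peak_series")
  expect_error(peak_series(1, c(0.012, 0.032), c(2, 1)), class = "prekd_bad_series")
  expect_error(peak_series(1, c(0.012, 0.032, 0.104), c(2, 1)),
               class = "prekd_bad_series")
  expect_error(peak_series(1, c(-0.01, 0.032, 0.104), c(3, 2, 1)),
               class = "prekd_bad_series")
  expect_error(peak_series(1, c(0.012, 0.012, 0.012), c(3, 2, 1)),
               class = "prekd_bad_series")
  s <- peak_series(7, standard_delays, exp(-10 * standard_delays))
  expect_equal(replicated_delays(s), c(0.012, 0.064))
})

test_that("replicate noise estimator matches hand arithmetic", {
  # identical replicates: zero noise
  s0 <- peak_series(1, c(0.012, 0.012, 0.064), c(100, 100, 60))
  expect_equal(estimate_intensity_noise(list(s0)), 0)
  # single pair (100, 102): |100-102|/2 / mean(101)
  s1 <- peak_series(1, c(0.012, 0.012, 0.064), c(100, 102, 60))
  expect_equal(estimate_intensity_noise(list(s1)), 1 / 101)
  # pooled over residues: RMS of the per-pair values
  s2 <- peak_series(2, c(0.012, 0.012, 0.064), c(200, 208, 60))
  expect_equal(estimate_intensity_noise(list(s1, s2)),
               sqrt(mean(c((1 / 101)^2, (4 / 204)^2))))
})

test_that("absence of replicate delays is a configuration error", {
  s <- peak_series(1, c(0.012, 0.032, 0.104), c(3, 2, 1))
  expect_error(estimate_intensity_noise(list(s)),
               class = "prekd_no_replicates")
  expect_error(estimate_intensity_noise(list(s)), "configuration")
})

test_that("noise estimator converges to its asymptote on simulated tables", {
  # pooled RMS half-difference of replicate pairs estimates sigma/sqrt(2)
  # under iid multiplicative Gaussian noise
  cfg <- scenario("homo", seed = 11, noise = 0.01)
  tabs <- simulate_peak_tables(cfg, 0, "dia", site = 44)
  expect_gte(length(tabs), 50)
  est <- estimate_intensity_noise(tabs)
  expect_lt(abs(est - 0.01 / sqrt(2)) / (0.01 / sqrt(2)), 0.15)
})

test_that("intensity tables round-trip through the reader", {
  d <- withr::local_tempdir()
  path <- file.path(d, "t.tsv")
  cfg <- scenario("beta-beta", seed = 3)
  tabs <- simulate_peak_tables(cfg, 1, "para", site = 44)[1:5]
  write_intensity_table(tabs, path)
  back <- read_intensity_table_meta(path)
  expect_length(back, 5)
  for (k in 1:5) {
    expect_equal(back[[k]]$residue_index, tabs[[k]]$residue_index)
    expect_equal(back[[k]]$delays, tabs[[k]]$delays, tolerance = 1e-9)
    expect_equal(back[[k]]$intensities, tabs[[k]]$intensities, tolerance = 1e-9)
  }
  expect_equal(back[[1]]$sample$label_site, 44L)
  expect_equal(back[[1]]$sample$arm, "para")
})

test_that("malformed intensity tables are rejected with row context", {
  d <- withr::local_tempdir()
  p <- file.path(d, "bad.tsv")
  writeLines(c("# delays: 0.012 0.032 0.104", "1\t10\t5\t2", "2\t9\txx\t2"), p)
  expect_error(read_intensity_table(p), "row 2")
  writeLines(c("# delays: 0.012 0.032 0.104", "1\t10\t5"), p)
  expect_error(read_intensity_table(p), "expected 3")
  writeLines(c("# delays: 0.012 0.032 0.104"), p)
  expect_error(read_intensity_table(p), class = "prekd_io")
  writeLines(c("1\t10\t5\t2"), p)
  expect_error(read_intensity_table(p), "delay schedule")
})

test_that("Sparky-style peak lists assemble into series", {
  d <- withr::local_tempdir()
  delays <- c(0.012, 0.032, 0.104)
  r2 <- c(A11 = 12, T44 = 20)
  for (k in seq_along(delays)) {
    writeLines(c(
      " Assignment         w1      w2   Data Height",
      sprintf("   A11N-HN    118.2   8.10   %.6e", 5e6 * exp(-12 * delays[k])),
      sprintf("   T44N-HN    110.9   8.45   %.6e", 3e6 * exp(-20 * delays[k]))),
      file.path(d, sprintf("pl%d.list", k)))
  }
  series <- read_sparky_peaks(file.path(d, sprintf("pl%d.list", 1:3)), delays)
  expect_length(series, 2)
  expect_equal(vapply(series, function(s) s$residue_index, integer(1)),
               c(11L, 44L))
  expect_equal(fit_decay(series[[2]])$r2, 20, tolerance = 1e-6)
})
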