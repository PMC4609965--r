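# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# closed-form log-linear estimate of the decay rate
loglin_r2 <- function(delays, intensities) {
  -unname(coef(lm(log(intensities) ~ delays))[2L])
}

# brute-force evaluation of the three significance clauses
filter_oracle <- function(x, floor = 8, mean_factor = 2) {
  m <- mean(x)
  q <- unname(quantile(x, 0.75, type = 7))
  vapply(x, function(v) v >= mean_factor * m && v > q && v >= floor,
         logical(1))
}

# the standard 10-delay schedule (s), with 12 ms and 64 ms duplicated
standard_delays <- c(12, 32, 104, 12, 124, 64, 48, 94, 64, 20) / 1000

# the titration design: 250 uM visible chain, ratios 0 - 1.5
titration_x <- c(0, 0.25, 0.5, 0.75, 1, 1.5) * 250e-6

# quick constructor for a relaxation profile from bare vectors
make_rp <- function(residue, r2, r2_error = 0, sample = list()) {
  out <- tibble::tibble(residue = as.integer(residue), r2 = r2,
                        r2_error = rep(r2_error, length.out = length(r2)),
                        amplitude = 100, fit_quality = 0)
  attr(out, "noise") <- 0
  attr(out, "sample") <- sample
  attr(out, "failures") <- tibble::tibble(residue = integer(),
                                          reason = character())
  class(out) <- c("relaxation_profile", class(out))
  out
}

# quick constructor for a pre_profile (bypasses the relaxation stage)
make_pp <- function(residue, gamma2, gamma2_error = 0.2, sample = list()) {
  prekd:::new_pre_profile(residue, gamma2,
                          rep(gamma2_error, length.out = length(gamma2)),
                          sample)
}

# quick binding_fit for summary-level tests
make_bf <- function(residue, classification, kd = NA_real_) {
  out <- tibble::tibble(residue = as.integer(residue),
                        classification = classification,
                        kd = kd)
  class(out) <- c("binding_fit", class(out))
  out
}
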