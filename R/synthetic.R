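#' Synthetic transient-dimer scenario configuration
#'
#' Builds the forward model behind the synthetic data: a two-state
#' fast-exchange transient dimer between an NMR-visible chain and a
#' spin-labelled (NMR-blind) chain. Contact segments on the visible chain
#' carry per-residue bound-state enhancement amplitudes and per-residue
#' dissociation constants; occupancy follows either the exact two-species
#' dimerisation equilibrium or its hyperbolic (excess-titrant) limit.
#' Per-residue baselines, amplitudes and constants are realised once, at
#' construction, under the configuration seed.
#'
#' Named default scenarios encode the canonical synuclein findings:
#' \describe{
#'   \item{`"homo"`}{alpha/alpha: N-terminal probes 11 and 44 contact the
#'     hot-spot segment 36--44 (nonspecific regime: K_D = 2.5 mM, far
#'     above the sampled concentrations, amplitude 150 s^-1) and the
#'     C-terminal segment 124--140 (specific: per-residue K_D log-normal
#'     with median 500 uM clamped to 90--1200 uM, amplitudes 30--60 s^-1).}
#'   \item{`"hetero"`}{alpha-MTSL / beta-visible: probes 11 and 44 contact
#'     the beta C-terminus 105--134 (specific: K_D median 100 uM clamped
#'     to 40--350 uM) plus an extremely weak N--N segment 37--41
#'     (amplitude 10 s^-1, nonspecific).}
#'   \item{`"beta-beta"`}{beta/beta: no contact segments at all.}
#' }
#'
#' @param name one of `"homo"`, `"hetero"`, `"beta-beta"`.
#' @param seed integer seed for all stochastic draws tied to this
#'   configuration.
#' @param noise relative (multiplicative) intensity noise.
#' @param occupancy_model `"exact_dimer"` or `"hyperbolic"`.
#' @param visible_concentration molar concentration of the visible chain.
#' @param ratios titrant : visible concentration ratios (must include 0).
#' @param delays relaxation delays (seconds) for contact-map experiments;
#'   the default is the standard 10-delay schedule with the 12 ms and
#'   64 ms points duplicated.
#' @param titration_delays delay schedule for titration experiments
#'   (6 points spanning 12--125 ms, first point duplicated).
#' @return object of class `scenario_config` with realised per-residue
#'   `truth` (site, residue, amplitude, kd, type) and `baseline`
#'   (residue, r2, i0) tables.
#' @export
#' @examples
#' cfg <- scenario("beta-beta", seed = 1)
#' cfg$spin_label_sites
scenario <- function(name = c("homo", "hetero", "beta-beta"), seed = 1L,
                     noise = 0.02,
                     occupancy_model = c("exact_dimer", "hyperbolic"),
                     visible_concentration = 250e-6,
                     ratios = c(0, 0.25, 0.5, 0.75, 1, 1.5),
                     delays = c(12, 32, 104, 12, 124, 64, 48, 94, 64, 20) / 1000,
                     titration_delays = c(12, 12, 35, 58, 81, 103, 125) / 1000) {
  if (!is.character(name) || !name[1L] %in% c("homo", "hetero", "beta-beta"))
    abort2(paste0("unknown scenario '", name[1L],
                  "'; valid names: homo, hetero, beta-beta"),
           "prekd_bad_scenario")
  name <- name[1L]
  occupancy_model <- match.arg(occupancy_model)
  alpha <- synuclein_sequence("alpha")
  beta <- synuclein_sequence("beta")
  if (name == "homo") {
    vis <- "alpha"; inv <- "alpha"; vseq <- alpha
    sites <- c(11L, 44L, 90L, 132L)
    segs <- tibble::tibble(
      site = rep(c(11L, 44L), each = 2L),
      start = rep(c(36L, 124L), 2L), end = rep(c(44L, 140L), 2L),
      type = rep(c("nonspecific", "specific"), 2L))
  } else if (name == "hetero") {
    vis <- "beta"; inv <- "alpha"; vseq <- beta
    sites <- c(11L, 44L, 90L, 132L)
    segs <- tibble::tibble(
      site = rep(c(11L, 44L), each = 2L),
      start = rep(c(37L, 105L), 2L), end = rep(c(41L, 134L), 2L),
      type = rep(c("weak", "specific"), 2L))
  } else {
    vis <- "beta"; inv <- "beta"; vseq <- beta
    sites <- c(11L, 44L, 80L, 134L)
    segs <- tibble::tibble(site = integer(), start = integer(),
                           end = integer(), type = character())
  }
  scenario_config(
    name = name, visible_species = vis, invisible_species = inv,
    visible_sequence = vseq,
    invisible_sequence = if (inv == "alpha") alpha else beta,
    spin_label_sites = sites, segments = segs, seed = seed, noise = noise,
    occupancy_model = occupancy_model,
    visible_concentration = visible_concentration, ratios = ratios,
    delays = delays, titration_delays = titration_delays)
}

#' @rdname scenario
#' @param visible_species,invisible_species species identifiers.
#' @param visible_sequence,invisible_sequence amino-acid strings.
#' @param spin_label_sites MTSL conjugation sites on the invisible chain.
#' @param segments tibble (`site`, `start`, `end`, `type`) of contact
#'   segments on the visible chain; `type` is `"specific"`,
#'   `"nonspecific"` or `"weak"`.
#' @export
scenario_config <- function(name, visible_species, invisible_species,
                            visible_sequence, invisible_sequence,
                            spin_label_sites, segments, seed = 1L,
                            noise = 0.02,
                            occupancy_model = c("exact_dimer", "hyperbolic"),
                            visible_concentration = 250e-6,
                            ratios = c(0, 0.25, 0.5, 0.75, 1, 1.5),
                            delays = c(12, 32, 104, 12, 124, 64, 48, 94, 64, 20) / 1000,
                            titration_delays = c(12, 12, 35, 58, 81, 103, 125) / 1000) {
  occupancy_model <- match.arg(occupancy_model)
  len <- nchar(visible_sequence)
  stopifnot(noise >= 0, visible_concentration > 0, all(ratios >= 0),
            0 %in% ratios, all(delays >= 0))
  if (nrow(segments) &&
      (any(segments$start < 1L) || any(segments$end > len) ||
       any(segments$start > segments$end)))
    abort2("contact segments must lie within the visible sequence",
           "prekd_bad_scenario")
  truth <- with_seed(derive_seed(seed, "truth"), realise_truth(segments))
  baseline <- with_seed(derive_seed(seed, "baseline"), tibble::tibble(
    residue = seq_len(len),
    r2 = runif(len, 10, 25),
    i0 = 1e6 * runif(len, 0.5, 1.5)))
  structure(list(
    name = name, visible_species = visible_species,
    invisible_species = invisible_species,
    visible_sequence = visible_sequence,
    invisible_sequence = invisible_sequence,
    spin_label_sites = as.integer(spin_label_sites), segments = segments,
    truth = truth, baseline = baseline, seed = as.integer(seed),
    noise = noise, occupancy_model = occupancy_model,
    visible_concentration = visible_concentration, ratios = sort(ratios),
    delays = delays, titration_delays = titration_delays),
    class = "scenario_config")
}

# realise per-residue amplitudes and dissociation constants for every
# contact segment; amplitudes taper linearly over the 3 edge residues
realise_truth <- function(segments) {
  if (!nrow(segments))
    return(tibble::tibble(site = integer(), residue = integer(),
                          amplitude = numeric(), kd = numeric(),
                          type = character()))
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    span <- seq(s$start, s$end)
    L <- length(span)
    pos <- seq_len(L)
    taper <- pmin(pos / 4, (L + 1 - pos) / 4, 1)
    amp <- switch(s$type,
      specific = runif(L, 30, 60),
      nonspecific = rep(150, L),
      weak = rep(10, L))
    kd <- switch(s$type,
      specific = {
        med <- if (s$end - s$start + 1L > 20L) 100e-6 else 500e-6
        lo <- if (med == 100e-6) 40e-6 else 90e-6
        hi <- if (med == 100e-6) 350e-6 else 1200e-6
        pmin(pmax(rlnorm(L, log(med), if (med == 100e-6) 0.5 else 0.45),
                  lo), hi)
      },
      nonspecific = rep(2.5e-3, L),
      weak = rep(2.5e-3, L))
    tibble::tibble(site = s$site, residue = span, amplitude = amp * taper,
                   kd = kd, type = s$type)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> '%s': %s (visible) / %s-MTSL, sites %s, %d contact segments, noise %.3g, occupancy %s\n",
              x$name, x$visible_species, x$invisible_species,
              paste(x$spin_label_sites, collapse = ","), nrow(x$segments),
              x$noise, x$occupancy_model))
  invisible(x)
}

#' Bound fraction of the visible chain in a two-species dimerisation
#'
#' For A (visible) + B (titrant) in equilibrium with dimer AB at
#' dissociation constant `kd`, the exact bound fraction of A is the
#' quadratic root
#' \deqn{f = \frac{(c_A + c_B + K_D) - \sqrt{(c_A + c_B + K_D)^2 -
#'   4 c_A c_B}}{2 c_A}}
#' The `"hyperbolic"` model is the excess-titrant limit
#' \eqn{f = c_B / (K_D + c_B)}, the form the titration fit assumes.
#'
#' @param c_visible,c_invisible concentrations (molar), >= 0;
#'   `c_invisible` may be a vector.
#' @param kd dissociation constant (molar), > 0.
#' @param model `"exact_dimer"` or `"hyperbolic"`.
#' @return bound fraction(s) in `[0, min(1, c_invisible / c_visible)]`.
#' @export
#' @examples
#' simulate_occupancy(250e-6, 250e-6, 250e-6, "exact_dimer") # 0.38196...
simulate_occupancy <- function(c_visible, c_invisible, kd,
                               model = c("exact_dimer", "hyperbolic")) {
  model <- match.arg(model)
  if (!is.numeric(kd) || any(kd <= 0))
    abort2("kd must be > 0", "prekd_bad_param")
  stopifnot(c_visible >= 0, all(c_invisible >= 0))
  if (model == "hyperbolic" || c_visible == 0)
    return(c_invisible / (kd + c_invisible))
  s <- c_visible + c_invisible + kd
  disc <- pmax(s^2 - 4 * c_visible * c_invisible, 0)
  (s - sqrt(disc)) / (2 * c_visible)
}

#' True per-residue PRE rates of a scenario at one titration point
#'
#' Fast-exchange population weighting: each residue's true
#' \eqn{\Gamma_2} is the bound fraction (at the residue's own K_D) times
#' its bound-state amplitude, summed over the contact segments covering
#' it; zero outside all segments.
#'
#' @param config a [scenario_config()].
#' @param ratio titrant : visible concentration ratio.
#' @param site spin-label site; default 44 when present, else the first
#'   configured site.
#' @return tibble (`residue`, `gamma2_true`) covering the full visible
#'   sequence.
#' @export
simulate_pre_truth <- function(config, ratio, site = NULL) {
  stopifnot(inherits(config, "scenario_config"), ratio >= 0)
  site <- site %||%
    if (44L %in% config$spin_label_sites) 44L else config$spin_label_sites[1L]
  len <- nchar(config$visible_sequence)
  out <- numeric(len)
  tr <- config$truth[config$truth$site == site, ]
  if (nrow(tr)) {
    f <- simulate_occupancy(config$visible_concentration,
                            ratio * config$visible_concentration,
                            tr$kd, config$occupancy_model)
    contrib <- f * tr$amplitude
    for (i in seq_len(nrow(tr)))
      out[tr$residue[i]] <- out[tr$residue[i]] + contrib[i]
  }
  tibble::tibble(residue = seq_len(len), gamma2_true = out)
}

# residues carrying an observable backbone amide peak (prolines have none)
observable_residues <- function(sequence) {
  which(strsplit(sequence, "")[[1L]] != "P")
}

#' Simulate peak-intensity decay tables for one sample
#'
#' Diamagnetic series decay at the per-residue baseline \eqn{R_2};
#' paramagnetic series at baseline plus the true \eqn{\Gamma_2} of the
#' titration point. Intensities are \eqn{I_0 e^{-R_2 t}} with
#' multiplicative Gaussian noise at the configured level; duplicated
#' delays receive independent noise. Prolines carry no amide peak and are
#' absent. Deterministic for a fixed seed.
#'
#' @param config a [scenario_config()].
#' @param ratio titrant : visible ratio of this sample.
#' @param arm `"para"` or `"dia"`.
#' @param site spin-label site.
#' @param delays delay schedule; defaults to `config$delays`.
#' @param seed RNG seed; defaults to a deterministic derivation from the
#'   configuration seed, the site, the ratio and the arm.
#' @return list of [peak_series()].
#' @export
simulate_peak_tables <- function(config, ratio, arm = c("para", "dia"),
                                 site = NULL, delays = NULL, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  arm <- match.arg(arm)
  site <- site %||%
    if (44L %in% config$spin_label_sites) 44L else config$spin_label_sites[1L]
  delays <- delays %||% config$delays
  seed <- seed %||% derive_seed(config$seed, site, ratio * 1000, arm)
  truth <- simulate_pre_truth(config, ratio, site)
  keep <- observable_residues(config$visible_sequence)
  meta <- list(visible_species = config$visible_species,
               invisible_species = config$invisible_species,
               label_site = site, ratio = ratio, arm = arm)
  label <- sprintf("%s(15N)/%s-%d-MTSL %s ratio %.2f",
                   config$visible_species, config$invisible_species, site,
                   arm, ratio)
  with_seed(seed, {
    lapply(keep, function(r) {
      r2 <- config$baseline$r2[r] +
        if (arm == "para") truth$gamma2_true[r] else 0
      mu <- config$baseline$i0[r] * exp(-r2 * delays)
      peak_series(r, delays,
                  mu * (1 + rnorm(length(delays), 0, config$noise)),
                  sample_label = label, sample = meta)
    })
  })
}

#' Run the full relaxation -> PRE path and assemble contact maps
#'
#' For every spin-label site of the scenario, simulates paramagnetic and
#' diamagnetic peak tables at the given mixing ratio, fits both
#' relaxation profiles (with the noise level estimated from the replicate
#' delays), computes the PRE profile with the significance filter, and
#' builds the multi-strip contact map.
#'
#' @param config a [scenario_config()].
#' @param ratio mixing ratio of the contact-map experiment (1 by
#'   default: equimolar visible and labelled chains).
#' @return a [build_contact_map()] object.
#' @export
simulate_contact_map <- function(config, ratio = 1) {
  stopifnot(inherits(config, "scenario_config"))
  profiles <- lapply(config$spin_label_sites, function(site) {
    para_tab <- simulate_peak_tables(config, ratio, "para", site = site)
    dia_tab <- simulate_peak_tables(config, ratio, "dia", site = site)
    compute_pre(fit_profile(para_tab), fit_profile(dia_tab))
  })
  rmap <- region_map(config$visible_sequence,
                     mtsl_sites = config$spin_label_sites)
  build_contact_map(profiles, rmap)
}

#' Propagated PRE-rate error of the mono-exponential fit
#'
#' Analytic error-propagation of the relative intensity noise through the
#' two-parameter decay fit and the paramagnetic-minus-diamagnetic
#' difference: \eqn{\sigma_{\Gamma_2} = \sigma_{rel}\sqrt{2 / S_{tt}}}
#' with \eqn{S_{tt} = \sum_i (t_i - \bar t)^2}.
#'
#' @param delays delay schedule in seconds.
#' @param noise relative intensity noise.
#' @return expected \eqn{\Gamma_2} standard error in s^-1.
#' @export
propagated_sigma_gamma <- function(delays, noise) {
  noise * sqrt(2 / sum((delays - mean(delays))^2))
}

# internal pre_profile constructor used by the fast titration path
new_pre_profile <- function(residue, gamma2, gamma2_error, sample) {
  out <- tibble::tibble(residue = as.integer(residue), gamma2 = gamma2,
                        gamma2_error = gamma2_error,
                        significant = FALSE)
  if (nrow(out) >= 4L) out$significant <- significance_filter(out$gamma2)
  attr(out, "sample") <- sample
  class(out) <- c("pre_profile", class(out))
  out
}

#' Simulate a PRE titration with its truth record
#'
#' One \eqn{\Gamma_2} profile per titration ratio, either through the
#' full relaxation -> PRE path (`path = "full"`: peak tables at the
#' titration delay schedule, decay fits, para-minus-dia differences) or
#' through the fast path (`path = "fast"`: Gaussian noise injected
#' directly on the true \eqn{\Gamma_2} with a standard deviation matching
#' the analytically propagated level, see [propagated_sigma_gamma()]).
#' Both paths are seeded and deterministic.
#'
#' @param config a [scenario_config()].
#' @param site spin-label site performing the titration (default 44).
#' @param path `"fast"` or `"full"`.
#' @param sigma_gamma per-point error for the fast path; default the
#'   propagated level.
#' @param seed RNG seed (default: derived from the configuration seed).
#' @return list with `set` (a [titration_set()]) and `truth` (tibble
#'   `residue`, `amplitude`, `kd`, `type` of the generating parameters).
#' @export
simulate_titration <- function(config, site = NULL, path = c("fast", "full"),
                               sigma_gamma = NULL, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  path <- match.arg(path)
  site <- site %||%
    if (44L %in% config$spin_label_sites) 44L else config$spin_label_sites[1L]
  seed <- seed %||% derive_seed(config$seed, site, "titration")
  ratios <- sort(config$ratios)
  keep <- observable_residues(config$visible_sequence)
  meta0 <- list(visible_species = config$visible_species,
                invisible_species = config$invisible_species,
                label_site = site)
  if (path == "fast") {
    sigma_gamma <- sigma_gamma %||%
      propagated_sigma_gamma(config$titration_delays, config$noise)
    profiles <- with_seed(seed, lapply(ratios, function(rt) {
      tr <- simulate_pre_truth(config, rt, site)
      g <- tr$gamma2_true[keep] + rnorm(length(keep), 0, sigma_gamma)
      new_pre_profile(keep, g, rep(sigma_gamma, length(keep)),
                      c(meta0, list(ratio = rt)))
    }))
  } else {
    profiles <- lapply(seq_along(ratios), function(k) {
      rt <- ratios[k]
      para <- simulate_peak_tables(config, rt, "para", site = site,
                                   delays = config$titration_delays,
                                   seed = derive_seed(seed, k, "para"))
      dia <- simulate_peak_tables(config, rt, "dia", site = site,
                                  delays = config$titration_delays,
                                  seed = derive_seed(seed, k, "dia"))
      compute_pre(fit_profile(para), fit_profile(dia))
    })
  }
  truth <- config$truth[config$truth$site == site,
                        c("residue", "amplitude", "kd", "type")]
  list(set = titration_set(profiles, config$visible_concentration,
                           ratios = ratios),
       truth = truth)
}
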