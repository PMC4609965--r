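#' Single-site saturation binding model for PRE titrations
#'
#' Under fast exchange the apparent PRE rate is the population-weighted
#' average of the free and bound states. With a single dimerisation site
#' and the spin-labelled (NMR-blind) species at concentration `x`, the
#' apparent rate follows the saturation isotherm
#' \deqn{\Gamma_2^{app}(x) = \Gamma_2^{free} +
#'   (\Gamma_2^{bound} - \Gamma_2^{free}) \frac{x}{K_D + x}}
#' where \eqn{\Gamma_2^{bound}} is the maximum observed saturation value.
#' The curve is monotone nondecreasing in `x` whenever
#' \eqn{\Gamma_2^{bound} \ge \Gamma_2^{free}}.
#'
#' @param x concentration of the spin-labelled species (molar), >= 0.
#' @param gamma2_free PRE rate of the free protein (s^-1).
#' @param gamma2_bound saturation PRE rate (s^-1).
#' @param kd dissociation constant (molar), > 0.
#' @return apparent PRE rate(s) in s^-1.
#' @export
#' @examples
#' binding_model(100e-6, 0, 40, 100e-6) # half saturation: 20
binding_model <- function(x, gamma2_free, gamma2_bound, kd) {
  if (!is.numeric(kd) || kd <= 0) abort2("kd must be > 0", "prekd_bad_param")
  if (any(x < 0)) abort2("x must be >= 0", "prekd_bad_param")
  gamma2_free + (gamma2_bound - gamma2_free) * x / (kd + x)
}

#' Assemble a titration set from per-ratio PRE profiles
#'
#' @param profiles list of `pre_profile` objects, one per titration point,
#'   each carrying `ratio` in its sample metadata (or `ratios` given
#'   explicitly, matched by position).
#' @param visible_concentration concentration of the NMR-visible chain
#'   (molar). The titrant concentration of each point is
#'   `ratio * visible_concentration`.
#' @param ratios dimensionless titration ratios; taken from profile
#'   metadata when `NULL`.
#' @param excluded optional tibble (`ratio`, `reason`) documenting points
#'   removed before analysis.
#' @return a `titration_set`: long tibble (`residue`, `x`, `gamma2`,
#'   `gamma2_error`) with attributes `x_grid`, `ratios`,
#'   `visible_concentration`, `excluded`. Only residues present at every
#'   retained titration point are kept (common grid).
#' @export
titration_set <- function(profiles, visible_concentration, ratios = NULL,
                          excluded = NULL) {
  stopifnot(length(profiles) >= 2L,
            all(vapply(profiles, inherits, logical(1), "pre_profile")),
            visible_concentration > 0)
  if (is.null(ratios))
    ratios <- vapply(profiles, function(p)
      as.numeric(attr(p, "sample")$ratio %||% NA_real_), numeric(1))
  if (anyNA(ratios))
    abort2("every profile needs a titration ratio", "prekd_metadata")
  ord <- order(ratios)
  profiles <- profiles[ord]; ratios <- ratios[ord]
  if (anyDuplicated(ratios))
    abort2("titration ratios must be distinct", "prekd_bad_param")
  if (!any(ratios == 0))
    abort2("the x = 0 (no titrant) point is required", "prekd_bad_param")
  x_grid <- ratios * visible_concentration
  long <- dplyr::bind_rows(lapply(seq_along(profiles), function(k) {
    p <- profiles[[k]]
    tibble::tibble(residue = p$residue, x = x_grid[k], gamma2 = p$gamma2,
                   gamma2_error = p$gamma2_error)
  }))
  counts <- table(long$residue)
  keep <- as.integer(names(counts)[counts == length(profiles)])
  long <- long[long$residue %in% keep, ]
  long <- dplyr::arrange(long, .data$residue, .data$x)
  attr(long, "x_grid") <- x_grid
  attr(long, "ratios") <- ratios
  attr(long, "visible_concentration") <- visible_concentration
  attr(long, "excluded") <- excluded %||%
    tibble::tibble(ratio = numeric(), reason = character())
  class(long) <- c("titration_set", class(long))
  long
}

#' @export
print.titration_set <- function(x, ...) {
  cat(sprintf("<titration_set> %d residues x %d points, visible chain %.3g M\n",
              length(unique(x$residue)), length(attr(x, "x_grid")),
              attr(x, "visible_concentration")))
  NextMethod()
}

#' Residues eligible for dissociation-constant fitting
#'
#' K_D fitting is restricted to residues whose PRE at a designated
#' titration point exceeds a threshold (strictly), by default 15 s^-1 at
#' the highest retained point. This mirrors the practice of fitting only
#' the residues with enough dynamic range to constrain the isotherm.
#'
#' @param set a [titration_set()].
#' @param threshold PRE threshold in s^-1 (strict inequality).
#' @param point_index 1-based ordinal of the titration point on the
#'   retained grid; default is the highest retained point.
#' @return integer vector of residue indices.
#' @export
select_fittable_residues <- function(set, threshold = 15, point_index = NULL) {
  stopifnot(inherits(set, "titration_set"))
  x_grid <- attr(set, "x_grid")
  point_index <- point_index %||% length(x_grid)
  if (point_index < 1L || point_index > length(x_grid))
    abort2(sprintf("point_index %d outside the retained grid (1..%d)",
                   point_index, length(x_grid)), "prekd_bad_param")
  at <- set[set$x == x_grid[point_index], ]
  sort(at$residue[at$gamma2 > threshold])
}

# weighted linear solve of (gamma2_free, gamma2_bound) at fixed kd; the
# model is linear in these two parameters, which makes profile-likelihood
# scans over kd exact and cheap.
chisq_at_kd <- function(x, y, sigma, kd) {
  u <- x / (kd + x)
  A <- cbind((1 - u) / sigma, u / sigma)
  b <- y / sigma
  fit <- tryCatch(qr.solve(A, b), error = function(e) c(0, 0))
  sum((b - A %*% fit)^2)
}

#' Fit the saturation isotherm to one residue's titration series
#'
#' Minimises the error-weighted sum of squares
#' \eqn{\sum_i [(\Gamma_{2,i} - \Gamma_2^{app}(x_i))/\sigma_i]^2} over the
#' three parameters \eqn{(\Gamma_2^{free}, \Gamma_2^{bound}, K_D)} by
#' Levenberg--Marquardt. Initialisation: \eqn{\Gamma_2^{free}} from the
#' x = 0 point, \eqn{\Gamma_2^{bound} = 2 \max \Gamma_2}, \eqn{K_D} at the
#' median titrant concentration. Box constraints keep \eqn{K_D \in}
#' (0, 1 M] and \eqn{\Gamma_2^{bound} \in} [0, 500 s^-1]. Parameter
#' uncertainties come from the covariance at the optimum scaled by the
#' reduced chi-square; the K_D confidence interval additionally comes from
#' a one-dimensional profile-likelihood scan (K_D fixed on a log grid, the
#' two linear parameters re-optimised exactly) at \eqn{\Delta\chi^2 = 1}.
#'
#' @param x titrant concentrations (molar), >= 4 points including 0.
#' @param gamma2 observed PRE rates (s^-1).
#' @param sigma per-point errors (s^-1), > 0. With `weighted = FALSE` the
#'   fit uses unit weights (estimates unchanged only if `sigma` is
#'   constant); errors are still scaled by the reduced chi-square.
#' @param weighted use the per-point errors as weights.
#' @param kd_max upper K_D bound (molar).
#' @param gb_max upper bound on `gamma2_bound` (s^-1).
#' @return list with the estimates, their standard errors, `kd_ci`
#'   (profile-likelihood interval), `chisq`, `n`, `converged`, `at_bound`
#'   and `flagged` (unidentifiable or boundary fits).
#' @export
fit_titration <- function(x, gamma2, sigma, weighted = TRUE,
                          kd_max = 1, gb_max = 500) {
  stopifnot(length(x) == length(gamma2), length(sigma) %in% c(1L, length(x)))
  if (length(x) < 4L)
    abort2("need at least 4 titration points", "prekd_too_few")
  if (any(sigma <= 0))
    abort2("errors must be > 0", "prekd_bad_param")
  sigma <- rep(sigma, length.out = length(x))
  w <- if (weighted) sigma else rep(1, length(x))
  kd_min <- 1e-9
  gf0 <- if (any(x == 0)) mean(gamma2[x == 0]) else min(gamma2)
  starts <- list(c(gf = gf0, gb = max(2 * max(gamma2), 1e-3),
                   kd = max(median(x[x > 0]), kd_min)))
  # second start in the near-linear limit (large kd, slope held fixed), so
  # flat-valley profiles are not left at a premature local stop
  lin0 <- fit_linear(x, gamma2, sigma, weighted = weighted)
  if (lin0$slope > 0) {
    kd0 <- min(0.5 * kd_max, max(0.9 * gb_max - gf0, 1) / lin0$slope)
    starts <- c(starts, list(c(gf = lin0$intercept,
                               gb = min(gb_max, lin0$intercept +
                                          lin0$slope * kd0),
                               kd = kd0)))
  }
  resfun <- function(p) (gamma2 - binding_model(x, p[1L], p[2L], p[3L])) / w
  fits <- lapply(starts, function(ini) minpack.lm::nls.lm(
    par = ini, fn = resfun,
    lower = c(-Inf, 0, kd_min), upper = c(Inf, gb_max, kd_max),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12)))
  fit <- fits[[which.min(vapply(fits, function(f) f$deviance, numeric(1)))]]
  p <- fit$par
  chisq <- sum(((gamma2 - binding_model(x, p[1L], p[2L], p[3L])) / sigma)^2)
  n <- length(x)
  dof <- max(1L, n - 3L)
  # covariance of the weighted problem, rescaled to the sigma scale and by
  # the reduced chi-square
  cov <- tryCatch({
    jac <- numericDeriv_jac(x, p, w)
    solve(crossprod(jac)) * (sum(resfun(p)^2) / dof)
  }, error = function(e) matrix(NA_real_, 3L, 3L))
  se <- sqrt(pmax(diag(cov), 0))
  at_bound <- p[3L] >= 0.99 * kd_max || p[3L] <= 2 * kd_min
  unident <- (p[2L] - p[1L]) <= 1e-6 * max(1, abs(p[2L]))
  # kd uncertainty exceeding the estimate itself (or an unusable
  # covariance) marks the constant as unconstrained by the sampled range
  ill_det <- chisq > .Machine$double.eps^0.5 &&
    (!is.finite(se[3L]) || se[3L] > p[3L])
  # a constant far beyond the sampled concentrations is indistinguishable
  # from a straight line within the data
  beyond_range <- p[3L] > 10 * max(x)
  converged <- fit$info %in% 1:3
  # profile likelihood for kd at delta chi-square = 1
  kd_ci <- c(NA_real_, NA_real_)
  if (converged && !unident) {
    grid <- exp(seq(log(max(kd_min, p[3L] / 1e3)),
                    log(min(kd_max, p[3L] * 1e3)), length.out = 121L))
    prof <- vapply(grid, function(k) chisq_at_kd(x, gamma2, sigma, k),
                   numeric(1))
    ok <- prof <= min(prof, chisq) + 1
    if (any(ok)) kd_ci <- range(c(grid[ok], p[3L]))
  }
  list(gamma2_free = unname(p[1L]), gamma2_bound = unname(p[2L]),
       kd = unname(p[3L]),
       gamma2_free_se = se[1L], gamma2_bound_se = se[2L], kd_se = se[3L],
       kd_ci = kd_ci, chisq = chisq, n = n, converged = converged,
       at_bound = at_bound,
       flagged = !converged || at_bound || unident || ill_det || beyond_range)
}

# analytic Jacobian of the weighted residuals w.r.t. (gf, gb, kd)
numericDeriv_jac <- function(x, p, w) {
  u <- x / (p[3L] + x)
  dgf <- -(1 - u) / w
  dgb <- -u / w
  dkd <- (p[2L] - p[1L]) * x / (p[3L] + x)^2 / w
  cbind(dgf, dgb, dkd)
}

# weighted straight-line fit (intercept + slope), the nonspecific
# comparison model
fit_linear <- function(x, gamma2, sigma, weighted = TRUE) {
  sigma <- rep(sigma, length.out = length(x))
  wts <- if (weighted) 1 / sigma^2 else rep(1, length(x))
  lf <- lm(gamma2 ~ x, weights = wts)
  pred <- stats::fitted(lf)
  list(intercept = unname(coef(lf)[1L]), slope = unname(coef(lf)[2L]),
       chisq = sum(((gamma2 - pred) / sigma)^2), n = length(x))
}

# small-sample-corrected information criterion for a weighted
# least-squares fit with known errors; chi-square plays the role of
# -2 log L up to a model-independent constant
aicc <- function(chisq, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  chisq + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Classify one titration profile
#'
#' Compares the three-parameter saturation model with a two-parameter
#' straight line by small-sample-corrected information criterion:
#' `"specific"` if the saturation model is favoured by at least `margin`
#' units and the fitted K_D is interior to its bounds (with
#' \eqn{\Gamma_2^{bound} > \Gamma_2^{free}}); `"nonspecific"` if the line
#' is favoured or the K_D estimate runs into a bound; `"noninteracting"`
#' is assigned by [fit_titration_set()] to residues that fail
#' [select_fittable_residues()].
#'
#' @param sat result of [fit_titration()].
#' @param lin result of the internal linear fit.
#' @param margin information-criterion margin (units of AICc).
#' @return `"specific"` or `"nonspecific"`.
#' @export
classify_profile <- function(sat, lin, margin = 2) {
  a_sat <- aicc(sat$chisq, 3L, sat$n)
  a_lin <- aicc(lin$chisq, 2L, lin$n)
  if (!sat$flagged && (a_lin - a_sat) >= margin &&
      sat$gamma2_bound > sat$gamma2_free) "specific" else "nonspecific"
}

#' Fit dissociation constants across a titration set
#'
#' Runs [select_fittable_residues()], fits the saturation and linear
#' models residue-by-residue to the selected residues, and classifies each
#' profile. Unselected residues are reported as `"noninteracting"`. The
#' `kd` column is populated only for residues classified `"specific"`
#' (elsewhere the constant is not defined); the raw saturation-model
#' estimate is kept in `kd_hat` for diagnostics.
#'
#' @param set a [titration_set()].
#' @param threshold,point_index selection rule, see
#'   [select_fittable_residues()].
#' @param margin model-selection margin in AICc units.
#' @param weighted weight the fit by per-point errors.
#' @return a `binding_fit` tibble, one row per residue of the set.
#' @export
fit_titration_set <- function(set, threshold = 15, point_index = NULL,
                              margin = 2, weighted = TRUE) {
  stopifnot(inherits(set, "titration_set"))
  selected <- select_fittable_residues(set, threshold, point_index)
  residues <- sort(unique(set$residue))
  rows <- lapply(residues, function(r) {
    d <- set[set$residue == r, ]
    base <- tibble::tibble(
      residue = r, classification = "noninteracting",
      kd = NA_real_, kd_se = NA_real_, kd_lo = NA_real_, kd_hi = NA_real_,
      kd_hat = NA_real_, gamma2_free = NA_real_, gamma2_free_se = NA_real_,
      gamma2_bound = NA_real_, gamma2_bound_se = NA_real_,
      chisq_sat = NA_real_, chisq_lin = NA_real_,
      aicc_sat = NA_real_, aicc_lin = NA_real_, flagged = FALSE)
    if (!(r %in% selected)) return(base)
    sat <- tryCatch(
      fit_titration(d$x, d$gamma2, d$gamma2_error, weighted = weighted),
      error = function(e) NULL)
    if (is.null(sat)) { base$flagged <- TRUE; return(base) }
    lin <- fit_linear(d$x, d$gamma2, d$gamma2_error, weighted = weighted)
    cls <- classify_profile(sat, lin, margin = margin)
    base$classification <- cls
    base$kd_hat <- sat$kd
    base$gamma2_free <- sat$gamma2_free
    base$gamma2_free_se <- sat$gamma2_free_se
    base$gamma2_bound <- sat$gamma2_bound
    base$gamma2_bound_se <- sat$gamma2_bound_se
    base$chisq_sat <- sat$chisq
    base$chisq_lin <- lin$chisq
    base$aicc_sat <- aicc(sat$chisq, 3L, sat$n)
    base$aicc_lin <- aicc(lin$chisq, 2L, lin$n)
    base$flagged <- sat$flagged
    if (cls == "specific") {
      base$kd <- sat$kd
      base$kd_se <- sat$kd_se
      base$kd_lo <- sat$kd_ci[1L]
      base$kd_hi <- sat$kd_ci[2L]
    }
    base
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "selected") <- selected
  attr(out, "x_grid") <- attr(set, "x_grid")
  class(out) <- c("binding_fit", class(out))
  out
}

#' Summarise dissociation constants over a residue group
#'
#' @param fits a `binding_fit` from [fit_titration_set()].
#' @param residues residue indices defining the group (`NULL` = all).
#' @return list with `n`, `kd_median`, `kd_min`, `kd_max` (molar), over
#'   residues classified `"specific"` in the group.
#' @export
#' @examples
#' \dontrun{group_summary(fits, residues = 124:140)}
group_summary <- function(fits, residues = NULL) {
  stopifnot(inherits(fits, "binding_fit"))
  d <- fits[fits$classification == "specific", ]
  if (!is.null(residues)) d <- d[d$residue %in% residues, ]
  if (!nrow(d))
    abort2("no residue classified 'specific' in the group", "prekd_empty")
  list(n = nrow(d), kd_median = median(d$kd), kd_min = min(d$kd),
       kd_max = max(d$kd))
}

#' Plot titration curves with their fitted isotherms
#'
#' @param set a [titration_set()].
#' @param fits optional `binding_fit`; fitted curves are drawn for
#'   residues classified specific.
#' @param residues residues to show (default: fittable residues).
#' @return a ggplot object.
#' @export
plot_titration <- function(set, fits = NULL, residues = NULL) {
  residues <- residues %||% select_fittable_residues(set)
  d <- set[set$residue %in% residues, ]
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x * 1e6, y = .data$gamma2,
                                        colour = factor(.data$residue))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$gamma2 - .data$gamma2_error,
                                        ymax = .data$gamma2 + .data$gamma2_error),
                           width = 0) +
    ggplot2::labs(x = "titrant concentration (µM)",
                  y = expression(Gamma[2] ~ (s^-1)), colour = "residue") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    sp <- fits[fits$classification == "specific" & fits$residue %in% residues, ]
    if (nrow(sp)) {
      xs <- seq(0, max(d$x), length.out = 100)
      curves <- dplyr::bind_rows(lapply(seq_len(nrow(sp)), function(i) {
        tibble::tibble(residue = sp$residue[i], x = xs,
                       gamma2 = binding_model(xs, sp$gamma2_free[i],
                                              sp$gamma2_bound[i], sp$kd[i]))
      }))
      gg <- gg + ggplot2::geom_line(
        data = curves, ggplot2::aes(x = .data$x * 1e6, y = .data$gamma2,
                                    colour = factor(.data$residue)))
    }
  }
  gg
}

#' Residue-by-ratio PRE surface
#'
#' Tile rendering of the titration surface (residue on x, titration ratio
#' on y, PRE rate as fill), the 2D analogue of the usual 3D titration
#' surface display.
#'
#' @param set a [titration_set()].
#' @param residues residues to include (default all).
#' @return a ggplot object.
#' @export
plot_titration_surface <- function(set, residues = NULL) {
  d <- if (is.null(residues)) set else set[set$residue %in% residues, ]
  ratios <- attr(set, "ratios")
  x_grid <- attr(set, "x_grid")
  d$ratio <- ratios[match(d$x, x_grid)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$residue, y = factor(.data$ratio),
                                  fill = .data$gamma2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(Gamma[2] ~ (s^-1))) +
    ggplot2::labs(x = "residue", y = "titrant : visible ratio") +
    ggplot2::theme_minimal()
}
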