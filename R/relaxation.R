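#' Fit a mono-exponential decay to one peak series
#'
#' Transverse relaxation series are modelled as
#' \eqn{I(t) = I_0 \exp(-R_2 t)} with two free parameters. Fitting
#' minimises relative residuals \eqn{(I_i - m_i)/m_i} by
#' Levenberg--Marquardt, matching the homoscedastic relative
#' (multiplicative) noise model used for replicate-based error estimation;
#' this also makes the fit exactly invariant under rescaling all
#' intensities. Initialisation comes from the log-linear closed form
#' (regression of \eqn{\log I} on \eqn{t}); replicate delay points enter as
#' independent observations.
#'
#' The rate uncertainty is the supplied relative noise level propagated
#' through the Gauss--Newton covariance of the relative residuals:
#' `r2_error = noise * sqrt(solve(crossprod(J))[2, 2])`. With `noise = 0`
#' the reported uncertainty is 0.
#'
#' @param series a [peak_series()].
#' @param noise relative intensity noise level (see
#'   [estimate_intensity_noise()]).
#' @return list with `r2` (s^-1), `r2_error` (s^-1), `amplitude`
#'   (intensity units), `fit_quality` (reduced chi-square when `noise > 0`,
#'   otherwise the summed squared relative residuals) and `converged`.
#' @export
#' @examples
#' s <- peak_series(1, c(0.012, 0.032, 0.104), 100 * exp(-15 * c(0.012, 0.032, 0.104)))
#' fit_decay(s)$r2
fit_decay <- function(series, noise = 0) {
  stopifnot(inherits(series, "peak_series"), noise >= 0)
  t <- series$delays
  i <- series$intensities
  pos <- i > 0
  if (sum(pos) < 2L || length(unique(t[pos])) < 2L)
    abort2("need >= 2 positive intensities at distinct delays to initialise",
           "prekd_fit_failed")
  ll <- lm(log(i[pos]) ~ t[pos])
  init <- c(i0 = exp(unname(coef(ll)[1L])), r2 = -unname(coef(ll)[2L]))
  resfun <- function(p) {
    m <- p[1L] * exp(-p[2L] * t)
    (i - m) / m
  }
  fit <- minpack.lm::nls.lm(
    par = init, fn = resfun,
    lower = c(.Machine$double.xmin, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  m <- p[1L] * exp(-p[2L] * t)
  # exact Jacobian of (I/m - 1): d/dI0 = -I/(m I0), d/dR2 = I t / m
  jac <- cbind(-i / (m * p[1L]), i * t / m)
  cov22 <- tryCatch(solve(crossprod(jac))[2L, 2L], error = function(e) NA_real_)
  rss <- sum(resfun(p)^2)
  n <- length(t)
  list(
    r2 = unname(p[2L]),
    r2_error = if (noise > 0 && is.finite(cov22) && cov22 >= 0)
      noise * sqrt(cov22) else if (noise == 0) 0 else NA_real_,
    amplitude = unname(p[1L]),
    fit_quality = if (noise > 0) rss / noise^2 / max(1L, n - 2L) else rss,
    converged = fit$info %in% 1:3 && is.finite(p[2L]))
}

#' Fit a per-residue relaxation profile
#'
#' Applies [fit_decay()] to every residue of one sample. Residues whose fit
#' fails (initialisation error, non-convergence, negative rate at the
#' optimum, or relative rate uncertainty above 100%) are recorded in the
#' `failures` attribute and are absent from the profile --- never reported
#' as zero. The pooled noise level is estimated from replicate delay points
#' unless supplied.
#'
#' @param series_collection list of [peak_series()], one per assigned
#'   residue of one sample.
#' @param noise relative intensity noise; if `NULL`, estimated from the
#'   collection's replicate points.
#' @param sample structured sample metadata (named list); defaults to the
#'   metadata of the first series.
#' @return a `relaxation_profile`: tibble with columns `residue`, `r2`,
#'   `r2_error`, `amplitude`, `fit_quality`; attributes `noise`, `sample`,
#'   `failures` (tibble of residue/reason).
#' @export
fit_profile <- function(series_collection, noise = NULL, sample = NULL) {
  if (inherits(series_collection, "peak_series"))
    series_collection <- list(series_collection)
  if (!length(series_collection))
    abort2("empty collection of peak series", "prekd_empty")
  stopifnot(all(vapply(series_collection, inherits, logical(1), "peak_series")))
  if (is.null(noise)) noise <- estimate_intensity_noise(series_collection)
  sample <- sample %||% series_collection[[1L]]$sample
  rows <- list(); fails <- list()
  for (s in series_collection) {
    res <- tryCatch(fit_decay(s, noise = noise), error = function(e) e)
    fail_reason <- NULL
    if (inherits(res, "error")) {
      fail_reason <- conditionMessage(res)
    } else if (!res$converged) {
      fail_reason <- "no convergence"
    } else if (res$r2 < 0) {
      fail_reason <- "negative rate at optimum"
    } else if (noise > 0 && (!is.finite(res$r2_error) || res$r2_error > abs(res$r2))) {
      fail_reason <- "relative rate uncertainty > 100%"
    }
    if (is.null(fail_reason)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        residue = s$residue_index, r2 = res$r2, r2_error = res$r2_error,
        amplitude = res$amplitude, fit_quality = res$fit_quality)
    } else {
      fails[[length(fails) + 1L]] <- tibble::tibble(
        residue = s$residue_index, reason = fail_reason)
    }
  }
  out <- if (length(rows)) dplyr::arrange(dplyr::bind_rows(rows), .data$residue)
         else tibble::tibble(residue = integer(), r2 = numeric(),
                             r2_error = numeric(), amplitude = numeric(),
                             fit_quality = numeric())
  attr(out, "noise") <- noise
  attr(out, "sample") <- sample
  attr(out, "failures") <- if (length(fails)) dplyr::bind_rows(fails)
    else tibble::tibble(residue = integer(), reason = character())
  class(out) <- c("relaxation_profile", class(out))
  out
}

#' @export
print.relaxation_profile <- function(x, ...) {
  cat(sprintf("<relaxation_profile> %d residues fitted, %d failed, noise %.4g\n",
              nrow(x), nrow(attr(x, "failures")), attr(x, "noise")))
  NextMethod()
}
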