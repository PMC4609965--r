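#' Compute an inter-chain PRE profile
#'
#' The PRE rate is the residue-specific difference of the \eqn{^1}H
#' \eqn{R_2} values of the paramagnetic and diamagnetic samples,
#' \eqn{\Gamma_2 = R_2^{para} - R_2^{dia}}, with the uncertainty propagated
#' in quadrature. Only residues fitted successfully in both arms appear in
#' the profile; residues broadened beyond detection or failing either fit
#' are absent.
#'
#' Sample metadata of the two profiles must agree on the visible species,
#' spin-label site and titration ratio (when present).
#'
#' @param para,dia `relaxation_profile` objects for the paramagnetic and
#'   diamagnetic (reduced) samples.
#' @param filter apply [significance_filter()] to fill the `significant`
#'   column (requires >= 4 residues; otherwise all `FALSE` with a warning).
#' @param ... thresholds passed on to [significance_filter()].
#' @return a `pre_profile`: tibble with columns `residue`, `gamma2`,
#'   `gamma2_error`, `significant`; sample metadata in attribute `sample`.
#' @export
compute_pre <- function(para, dia, filter = TRUE, ...) {
  stopifnot(inherits(para, "relaxation_profile"),
            inherits(dia, "relaxation_profile"))
  sp <- attr(para, "sample") %||% list()
  sd_ <- attr(dia, "sample") %||% list()
  for (key in c("visible_species", "invisible_species", "label_site", "ratio")) {
    if (!is.null(sp[[key]]) && !is.null(sd_[[key]]) &&
        !identical(sp[[key]], sd_[[key]]))
      abort2(sprintf("sample metadata mismatch on '%s' (%s vs %s)",
                     key, sp[[key]], sd_[[key]]), "prekd_metadata")
  }
  joined <- dplyr::inner_join(
    tibble::as_tibble(para)[, c("residue", "r2", "r2_error")],
    tibble::as_tibble(dia)[, c("residue", "r2", "r2_error")],
    by = "residue", suffix = c("_para", "_dia"))
  if (!nrow(joined))
    abort2("no residue fitted in both the paramagnetic and diamagnetic arm",
           "prekd_empty")
  out <- tibble::tibble(
    residue = joined$residue,
    gamma2 = joined$r2_para - joined$r2_dia,
    gamma2_error = sqrt(joined$r2_error_para^2 + joined$r2_error_dia^2))
  if (filter && nrow(out) >= 4L) {
    out$significant <- significance_filter(out$gamma2, ...)
  } else {
    if (filter) warning("fewer than 4 residues; significance not assessed")
    out$significant <- FALSE
  }
  meta <- sp
  for (nm in names(sd_)) if (is.null(meta[[nm]])) meta[[nm]] <- sd_[[nm]]
  attr(out, "sample") <- meta
  class(out) <- c("pre_profile", class(out))
  out
}

#' @export
print.pre_profile <- function(x, ...) {
  s <- attr(x, "sample") %||% list()
  cat(sprintf("<pre_profile> %d residues, %d significant%s\n",
              nrow(x), sum(x$significant),
              if (!is.null(s$label_site))
                sprintf(", spin label at %s", s$label_site) else ""))
  NextMethod()
}

#' Three-clause significance filter for PRE rates
#'
#' A residue's PRE is called significant only if all three clauses hold:
#' \eqn{\Gamma_2 \ge} `mean_factor` times the strip mean, \eqn{\Gamma_2 >}
#' the third quartile of the strip, and \eqn{\Gamma_2 \ge} the absolute
#' floor (8 s^-1 by default). Mean and quartile are computed over all
#' fitted residues of the strip; the quartile uses linear interpolation
#' between order statistics ([q3()]).
#'
#' @param x numeric vector of `gamma2` values, or a `pre_profile`.
#' @param floor absolute minimum PRE rate in s^-1.
#' @param mean_factor multiple of the strip mean required.
#' @return logical mask, one element per residue.
#' @export
#' @examples
#' significance_filter(c(rep(1, 9), 20))
significance_filter <- function(x, floor = 8, mean_factor = 2) {
  if (inherits(x, "pre_profile")) x <- x$gamma2
  x <- as.numeric(x)
  if (length(x) < 4L)
    abort2("significance filter needs at least 4 residues", "prekd_too_few")
  stopifnot(floor > 0, mean_factor > 0)
  x >= mean_factor * mean(x) & x > q3(x) & x >= floor
}
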