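`%||%` <- function(x, y) if (is.null(x)) y else x

abort2 <- function(msg, class) {
  stop(structure(class = c(class, "prekd_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Third quartile by linear interpolation between order statistics
#'
#' Convention used throughout the significance filter (R's default
#' `type = 7` quantile), stated explicitly so independent checks can match.
#'
#' @param x numeric vector.
#' @return the 0.75 quantile of `x`.
#' @keywords internal
q3 <- function(x) unname(quantile(x, 0.75, type = 7, names = FALSE))

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded simulation helpers do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# small, stable integer sub-seed so independent simulation arms get
# independent but reproducible streams; kept well below .Machine$integer.max
derive_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p) * 101
  }, numeric(1))
  as.integer((as.numeric(seed) + sum(round(parts * 7))) %% 2000000011)
}
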