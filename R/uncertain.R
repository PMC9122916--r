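#' Scalar values with standard uncertainty
#'
#' `uv()` creates a numeric vector that carries a standard uncertainty (one
#' standard deviation, same units as the value) alongside each value. All
#' derived quantities in the pipeline are expressed as `uv` objects so that
#' uncertainties propagate automatically through arithmetic:
#'
#' * sums and differences combine absolute uncertainties in quadrature,
#'   \eqn{sd = \sqrt{sd_a^2 + sd_b^2}};
#' * products and quotients combine relative uncertainties in quadrature,
#'   \eqn{sd/|x| = \sqrt{(sd_a/a)^2 + (sd_b/b)^2}};
#' * multiplication by an exact scalar scales the uncertainty linearly.
#'
#' A missing (`NA`) uncertainty marks a value whose spread is unknown; it is
#' treated as exact (sd 0) in propagation but printed without a `±` term.
#'
#' @param value numeric vector of central values.
#' @param sd numeric vector of non-negative standard uncertainties, recycled
#'   to the length of `value`. `NA` marks an unknown uncertainty.
#' @return An object of class `uv`.
#' @examples
#' r <- uv(5.67, 0.38)     # nmol l-1 d-1
#' a <- uv(2.50e4, 0.63e4) # copies ml-1
#' r / a                   # relative quadrature
#' @export
uv <- function(value, sd = NA_real_) {
  value <- as.numeric(value)
  sd <- rep_len(as.numeric(sd), length(value))
  if (any(!is.na(sd) & sd < 0)) {
    stop("standard uncertainty 'sd' must be non-negative", call. = FALSE)
  }
  structure(value, sd = sd, class = "uv")
}

#' @rdname uv
#' @param x object to test, coerce or extract from.
#' @export
is_uv <- function(x) inherits(x, "uv")

#' @rdname uv
#' @export
uv_value <- function(x) {
  if (is_uv(x)) as.numeric(unclass(x)) else as.numeric(x)
}

#' @rdname uv
#' @export
uv_sd <- function(x) {
  if (is_uv(x)) attr(x, "sd") else rep(NA_real_, length(x))
}

# coerce to uv, exact (sd 0) if plain numeric
as_uv <- function(x) {
  if (is_uv(x)) x else uv(x, 0)
}

#' @export
format.uv <- function(x, digits = 4, ...) {
  v <- uv_value(x)
  s <- uv_sd(x)
  ifelse(is.na(s),
    format(signif(v, digits), trim = TRUE, ...),
    paste0(
      format(signif(v, digits), trim = TRUE, ...), " ± ",
      format(signif(s, 2), trim = TRUE, ...)
    )
  )
}

#' @export
print.uv <- function(x, ...) {
  cat(format(x, ...), sep = "\n")
  invisible(x)
}

#' @export
`[.uv` <- function(x, i) uv(uv_value(x)[i], uv_sd(x)[i])

#' @export
c.uv <- function(...) {
  parts <- lapply(list(...), as_uv)
  uv(
    unlist(lapply(parts, uv_value)),
    unlist(lapply(parts, uv_sd))
  )
}

#' @export
Ops.uv <- function(e1, e2) {
  if (missing(e2)) { # unary + / -
    v <- get(.Generic)(uv_value(e1))
    return(uv(v, uv_sd(e1)))
  }
  v1 <- uv_value(e1); s1 <- uv_sd(e1); s1[is.na(s1)] <- 0
  v2 <- uv_value(e2); s2 <- uv_sd(e2); s2[is.na(s2)] <- 0
  v <- get(.Generic)(v1, v2)
  switch(.Generic,
    "+" = ,
    "-" = uv(v, sqrt(s1^2 + s2^2)),
    "*" = uv(v, abs(v) * sqrt(rel_err(v1, s1)^2 + rel_err(v2, s2)^2)),
    "/" = uv(v, abs(v) * sqrt(rel_err(v1, s1)^2 + rel_err(v2, s2)^2)),
    "^" = uv(v, abs(v * v2 * rel_err(v1, s1))), # exact exponent only
    # comparisons fall through on the central values
    v
  )
}

# relative error, 0 for an exact zero (0 +/- 0)
rel_err <- function(v, s) {
  out <- ifelse(v == 0 & s == 0, 0, s / abs(v))
  out[is.nan(out)] <- 0
  out
}

#' Mean of uncertain values with propagated uncertainty
#'
#' Averages a set of measurements that each carry a standard uncertainty.
#' Two spread estimates are available:
#'
#' * `"propagation"` (default): the uncertainty of the mean by quadrature of
#'   the input uncertainties, \eqn{\sqrt{\sum sd_i^2}/n} — the propagated
#'   standard error when each input's `sd` is its standard uncertainty.
#' * `"sample"`: the sample standard deviation of the central values,
#'   ignoring the per-value uncertainties — the empirical between-measurement
#'   spread.
#'
#' The two answer different questions (how well the mean is known vs. how
#' variable the measurements are) and can differ widely; see the package
#' vignette for when each is appropriate.
#'
#' @param x a `uv` vector (or plain numeric, treated as exact) of length >= 1.
#' @param method `"propagation"` or `"sample"`.
#' @return A length-1 `uv`.
#' @examples
#' rates <- uv(c(5.67, 4.61, 6.06, 7.72), c(0.38, 0.39, 0.37, 0.66))
#' uv_mean(rates)                    # propagated
#' uv_mean(rates, method = "sample") # between-replicate spread
#' @export
uv_mean <- function(x, method = c("propagation", "sample")) {
  method <- match.arg(method)
  x <- as_uv(x)
  n <- length(x)
  if (n == 0L) stop("cannot average an empty set of values", call. = FALSE)
  v <- uv_value(x)
  s <- uv_sd(x)
  s[is.na(s)] <- 0
  m <- mean(v)
  spread <- switch(method,
    propagation = sqrt(sum(s^2)) / n,
    sample = if (n == 1L) s else stats::sd(v)
  )
  uv(m, spread)
}
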