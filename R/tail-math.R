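#' Upper-tail proportion of the standard normal
#'
#' Proportion of a `N(0,1)` population retained by truncation at threshold
#' `x`, i.e. `1 - Phi(x)`. This is the "selected proportion" of classical
#' truncation-selection theory: every candidate whose standardized selection
#' criterion exceeds `x` is kept.
#'
#' @param x Numeric vector of standardized thresholds (standard-deviation
#'   units). Must be finite.
#' @return Numeric vector of selected proportions in `(0, 1)`.
#' @details Computed with the survival form `pnorm(x, lower.tail = FALSE)`,
#'   never as `1 - pnorm(x)`, so far-tail proportions retain full relative
#'   precision.
#' @seealso [threshold_for_proportion()] for the inverse,
#'   [selection_intensity()] for the mean of the retained tail.
#' @examples
#' upper_tail_proportion(0)      # 0.5
#' upper_tail_proportion(1.77)   # ~0.038
#' @export
upper_tail_proportion <- function(x) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    stop("`x` must be a finite numeric threshold", call. = FALSE)
  }
  stats::pnorm(x, lower.tail = FALSE)
}

#' Truncation threshold achieving a given selected proportion
#'
#' Inverse of [upper_tail_proportion()] on the scale of a normal selection
#' criterion with mean `mu` and standard deviation `sigma`: returns
#' `mu + sigma * qnorm(1 - alpha)`, the threshold above which a proportion
#' `alpha` of the population lies.
#'
#' @param alpha Selected proportion(s), strictly inside `(0, 1)`.
#' @param mu Mean of the selection criterion (default 0).
#' @param sigma Standard deviation of the selection criterion (default 1,
#'   must be positive).
#' @return Numeric vector of thresholds in trait units.
#' @examples
#' threshold_for_proportion(0.10)           # ~1.2816
#' threshold_for_proportion(0.5, mu = 3, sigma = 2)  # 3
#' @export
threshold_for_proportion <- function(alpha, mu = 0, sigma = 1) {
  check_proportion(alpha, "alpha")
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("`sigma` must be a positive finite number", call. = FALSE)
  }
  if (!is.numeric(mu) || any(!is.finite(mu))) {
    stop("`mu` must be finite", call. = FALSE)
  }
  mu + sigma * stats::qnorm(alpha, lower.tail = FALSE)
}

#' Selection intensity of truncation selection
#'
#' Mean of the upper-`alpha` tail of the standard normal,
#' `i(alpha) = phi(Phi^-1(1 - alpha)) / alpha`: the expected standardized
#' superiority of the selected candidates over the population mean. This is
#' the `i` of the breeder's equation `dG = b * sigma * i`.
#'
#' @param alpha Selected proportion(s) in `(0, 1)`.
#' @return Positive numeric vector, strictly decreasing in `alpha`, tending
#'   to 0 as `alpha -> 1`.
#' @details The ratio `phi(x)/alpha` is computed through survival functions
#'   and stays accurate over the entire representable range; only once
#'   `alpha` approaches the subnormal floor (`alpha < 1e-300`), where
#'   `phi(x)` itself degenerates, does the implementation fall back to the
#'   Mills-ratio asymptotic `i ~ x + 1/x` with `x = qnorm(1 - alpha)`.
#' @examples
#' selection_intensity(0.5)    # sqrt(2/pi) ~ 0.7979
#' selection_intensity(0.14)   # ~1.57
#' @export
selection_intensity <- function(alpha) {
  check_proportion(alpha, "alpha")
  x <- stats::qnorm(alpha, lower.tail = FALSE)
  out <- stats::dnorm(x) / alpha
  tiny <- alpha < 1e-300
  if (any(tiny)) out[tiny] <- x[tiny] + 1 / x[tiny]
  out
}

# shared validator: strict open-interval proportion
check_proportion <- function(p, name) {
  if (!is.numeric(p) || length(p) == 0L || any(!is.finite(p)) ||
      any(p <= 0) || any(p >= 1)) {
    stop(sprintf("`%s` must lie strictly within (0, 1)", name), call. = FALSE)
  }
  invisible(p)
}
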