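#' Parameters for GCA-based hybrid selection
#'
#' In hybrid breeding, lines from two genetically distant parent pools are
#' selected on predictors of their general combining ability (GCA), and the
#' complete factorial of crosses among the selected lines is advanced. GCA
#' values are deviations from the hybrid-population mean, so both selection
#' criteria are centered at zero; the pools may differ in the standard
#' deviation of the GCA criterion and in the regression slope of true GCA
#' on the criterion (1 for BLUPs).
#'
#' @param sigma1,sigma2 Standard deviations of the GCA selection criterion
#'   in the seed and pollen pool (trait units, positive).
#' @param b1,b2 Regression slopes of true GCA on the criterion (default 1,
#'   the BLUP case).
#' @param alpha_H Proportion of hybrids to retain from the full factorial,
#'   strictly inside `(0, 1)`.
#' @return An object of class `"hybrid_params"`.
#' @export
hybrid_params <- function(sigma1, sigma2, b1 = 1, b2 = 1, alpha_H) {
  for (nm in c("sigma1", "sigma2", "b1", "b2")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
      stop(sprintf("`%s` must be a positive number", nm), call. = FALSE)
    }
  }
  check_proportion(alpha_H, "alpha_H")
  structure(list(sigma1 = sigma1, sigma2 = sigma2, b1 = b1, b2 = b2,
                 alpha_H = alpha_H),
            class = "hybrid_params")
}

#' @export
print.hybrid_params <- function(x, ...) {
  cat(sprintf("<hybrid_params> sigma=(%.4g, %.4g) b=(%.4g, %.4g) alpha_H=%.4g\n",
              x$sigma1, x$sigma2, x$b1, x$b2, x$alpha_H))
  invisible(x)
}

#' Selection response of the hybrid factorial
#'
#' Expected gain of the factorial among GCA-selected lines over the
#' unselected factorial: the sum of the per-pool breeder's-equation
#' responses, `dG_Hyb = b1 sigma1 i(alpha(t1/sigma1)) +
#' b2 sigma2 i(alpha(t2/sigma2))`.
#'
#' @param t1,t2 Truncation thresholds applied to the GCA criterion in each
#'   pool (trait units).
#' @param params A [hybrid_params()] object.
#' @return Selection response in trait units.
#' @export
hybrid_response <- function(t1, t2, params) {
  stopifnot(inherits(params, "hybrid_params"),
            is.numeric(t1), length(t1) == 1L, is.finite(t1),
            is.numeric(t2), length(t2) == 1L, is.finite(t2))
  a1 <- upper_tail_proportion(t1 / params$sigma1)
  a2 <- upper_tail_proportion(t2 / params$sigma2)
  g1 <- if (a1 >= 1) 0 else params$b1 * params$sigma1 * selection_intensity(a1)
  g2 <- if (a2 >= 1) 0 else params$b2 * params$sigma2 * selection_intensity(a2)
  g1 + g2
}

#' Equal-proportion baseline for hybrid selection
#'
#' The conventional scheme: select the same proportion
#' `alpha_e = sqrt(alpha_H)` of lines from each pool, so the factorial of
#' selected-by-selected crosses has exactly the budgeted proportion
#' `alpha_H` of all possible hybrids.
#'
#' @param params A [hybrid_params()] object.
#' @return A `"hybrid_solution"` with `mode = "equal"`.
#' @export
equal_proportion_baseline <- function(params) {
  stopifnot(inherits(params, "hybrid_params"))
  a_e <- sqrt(params$alpha_H)
  t1 <- threshold_for_proportion(a_e, 0, params$sigma1)
  t2 <- threshold_for_proportion(a_e, 0, params$sigma2)
  new_hybrid_solution("equal", t1, t2, a_e, a_e, params)
}

#' Optimal per-pool selected proportions for hybrid selection
#'
#' Maximizes the factorial response subject to the hybrid budget
#' `alpha1 * alpha2 = alpha_H`. The Lagrange stationarity condition is
#' `b2 t2 - b1 t1 + dG1(t1) - dG2(t2) = 0`; substituting
#' `alpha2 = alpha_H / alpha1` makes this a one-dimensional root problem in
#' `alpha1`, solved by bracketed bisection/Brent iteration on
#' `alpha1 in [alpha_H (1 + eps), 1 - eps]` with `eps = 1e-12`. The result
#' is cross-checked against direct one-dimensional maximization; when the
#' pools are symmetric (`sigma1 b1 = sigma2 b2`) the stationary point is the
#' equal split `alpha1 = alpha2 = sqrt(alpha_H)`.
#'
#' More stringent selection concentrates in the pool with the larger
#' `sigma * b`: its optimal selected proportion falls below `sqrt(alpha_H)`.
#'
#' @param params A [hybrid_params()] object.
#' @return A `"hybrid_solution"` with `mode = "optimal"` (or
#'   `mode = "boundary"` if no interior stationary point exists and the
#'   optimum sits at `alpha2 = 1`, i.e. no selection in the weaker pool).
#' @examples
#' p <- hybrid_params(sigma1 = 1, sigma2 = 0.5, alpha_H = 0.01)
#' solve_optimal_hybrid(p)
#' @export
solve_optimal_hybrid <- function(params) {
  stopifnot(inherits(params, "hybrid_params"))
  aH <- params$alpha_H
  eps <- 1e-12
  station <- function(a1) {
    a2 <- aH / a1
    t1 <- params$sigma1 * stats::qnorm(a1, lower.tail = FALSE)
    t2 <- params$sigma2 * stats::qnorm(a2, lower.tail = FALSE)
    params$b2 * t2 - params$b1 * t1 +
      params$b1 * params$sigma1 * selection_intensity(a1) -
      params$b2 * params$sigma2 * selection_intensity(a2)
  }
  lo <- aH * (1 + eps)
  hi <- 1 - eps
  f_lo <- station(lo)
  f_hi <- station(hi)
  if (is.finite(f_lo) && is.finite(f_hi) && f_lo * f_hi < 0) {
    a1 <- stats::uniroot(station, c(lo, hi), tol = 1e-14)$root
    mode <- "optimal"
  } else {
    # no interior sign change: optimum on the boundary of the feasible box
    cand <- c(lo, hi)
    val <- vapply(cand, function(a1) {
      hybrid_response(params$sigma1 * stats::qnorm(a1, lower.tail = FALSE),
                      params$sigma2 * stats::qnorm(aH / a1, lower.tail = FALSE),
                      params)
    }, numeric(1))
    a1 <- cand[which.max(val)]
    mode <- "boundary"
  }
  a2 <- aH / a1
  t1 <- params$sigma1 * stats::qnorm(a1, lower.tail = FALSE)
  t2 <- params$sigma2 * stats::qnorm(a2, lower.tail = FALSE)
  new_hybrid_solution(mode, t1, t2, a1, a2, params)
}

#' Percent improvement of optimal over equal hybrid proportions
#'
#' `Psi_Hyb = 100 * (dG_Hyb(optimal) - dG_Hyb(equal)) / dG_Hyb(equal)`:
#' the relative gain in factorial response from selecting distinct
#' proportions in the two parent pools instead of the conventional equal
#' split. Zero when the pools are symmetric (`sigma1 b1 = sigma2 b2`).
#'
#' @param params A [hybrid_params()] object.
#' @param details If `TRUE`, return a list with both `"hybrid_solution"`
#'   objects alongside `psi_hyb`.
#' @return Percent improvement (scalar), or a list when `details = TRUE`.
#' @export
hybrid_percent_improvement <- function(params, details = FALSE) {
  eq <- equal_proportion_baseline(params)
  op <- solve_optimal_hybrid(params)
  psi <- 100 * (op$deltaG_hyb - eq$deltaG_hyb) / eq$deltaG_hyb
  if (details) list(psi_hyb = psi, equal = eq, optimal = op) else psi
}

new_hybrid_solution <- function(mode, t1, t2, alpha1, alpha2, params) {
  structure(
    list(mode = mode, t1 = t1, t2 = t2, alpha1 = alpha1, alpha2 = alpha2,
         deltaG_hyb = hybrid_response(t1, t2, params), params = params),
    class = "hybrid_solution"
  )
}

#' @export
print.hybrid_solution <- function(x, ...) {
  cat(sprintf(
    "<hybrid_solution> mode=%s alpha=(%.6g, %.6g) t=(%.4g, %.4g) dG_Hyb=%.6g\n",
    x$mode, x$alpha1, x$alpha2, x$t1, x$t2, x$deltaG_hyb))
  invisible(x)
}

#' @export
as.data.frame.hybrid_solution <- function(x, ...) {
  data.frame(mode = x$mode, alpha1 = x$alpha1, alpha2 = x$alpha2,
             t1 = x$t1, t2 = x$t2, deltaG_hyb = x$deltaG_hyb,
             stringsAsFactors = FALSE)
}
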