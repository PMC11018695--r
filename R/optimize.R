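#' Identical truncation threshold meeting the selection budget
#'
#' Finds the unique common threshold `t` with
#' `alpha_Tot(t, ..., t) = alpha_T`. Because the total selected proportion
#' is strictly decreasing in the threshold, the root is unique; it is
#' bracketed within `[min_k(mu_k - 10 sigma_k), max_k(mu_k + 10 sigma_k)]`
#' (tail mass beyond 10 SD is < 1e-23, far below any meaningful budget) and
#' solved by Brent's method with a Newton polish.
#'
#' @param scenario A [selection_scenario()].
#' @return A `"threshold_solution"`: list with `mode = "identical"`,
#'   `thresholds` (the common value repeated per set), `outcome`
#'   (a [total_response()]), `converged`, and `residual`
#'   (`|alpha_Tot - alpha_T|`).
#' @examples
#' sc <- selection_scenario(
#'   list(set_params("P1", 0.5, 0, 1, "BLUE", 0.36),
#'        set_params("P2", 0.5, 0, 1, "BLUE", 0.81)),
#'   alpha_T = 0.10)
#' solve_identical_threshold(sc)   # t ~ 1.77
#' @export
solve_identical_threshold <- function(scenario) {
  v <- scenario_vectors(scenario)
  aT <- scenario$alpha_T
  f <- function(t) sum(upper_tail_proportion((t - v$mu) / v$sigma) * v$pi) - aT
  lo <- min(v$mu - 10 * v$sigma)
  hi <- max(v$mu + 10 * v$sigma)
  t <- solve_decreasing_root(f, lo, hi,
                             fprime = function(t)
                               -sum(v$pi * stats::dnorm((t - v$mu) / v$sigma) / v$sigma))
  finish_solution("identical", rep(t, v$K), scenario)
}

#' Common threshold for all-BLUP scenarios
#'
#' For selection on BLUPs the regression of TGV on the criterion is 1 in
#' every set, so a single threshold applied to all candidates maximizes the
#' total response regardless of differences in means, variances, or
#' accuracies. This entry point solves the budget equation
#' `sum_k Phi((t* - mu_k)/sigma_k) pi_k = 1 - alpha_T` for that common
#' threshold; it is the identical-threshold solve restricted to BLUP
#' scenarios.
#'
#' @param scenario A [selection_scenario()] whose sets are all BLUP sets.
#' @return A `"threshold_solution"` with `mode = "blup_common"`.
#' @export
solve_blup_common_threshold <- function(scenario) {
  if (!all_blup(scenario)) {
    stop("all sets must use the BLUP criterion", call. = FALSE)
  }
  sol <- solve_identical_threshold(scenario)
  sol$mode <- "blup_common"
  sol
}

#' Optimal per-set thresholds under a fixed selection budget
#'
#' Maximizes the total selection response subject to
#' `alpha_Tot = alpha_T` via the Lagrange stationarity condition: at an
#' interior optimum the quantity `b_k (t_k - mu_k) + mu_k` — the expected
#' TGV of a candidate sitting exactly at the threshold — is equal across all
#' sets. Writing that common value as `s`, each threshold is
#' `t_k = mu_k + (s - mu_k)/b_k`, and `alpha_Tot` is strictly decreasing in
#' `s`, so the budget constraint reduces to a one-dimensional root problem
#' solved by bracketed Brent iteration with a Newton polish.
#'
#' For all-BLUP scenarios (`b_k = 1` for all `k`) the stationarity relation
#' forces equal thresholds, recovering the uniform-threshold optimality of
#' BLUP selection.
#'
#' @param scenario A [selection_scenario()].
#' @return A `"threshold_solution"` with `mode = "optimal"`.
#' @seealso [direct_constrained_maximize()] for the independent numerical
#'   cross-check, [percent_improvement()] for the gain over identical
#'   thresholds.
#' @examples
#' sc <- selection_scenario(
#'   list(set_params("P1", 0.5, 0, 1, "BLUE", 0.36),
#'        set_params("P2", 0.5, 0, 1, "BLUE", 0.81)),
#'   alpha_T = 0.10)
#' solve_optimal_thresholds(sc)   # t* ~ (2.65, 1.18)
#' @export
solve_optimal_thresholds <- function(scenario) {
  v <- scenario_vectors(scenario)
  aT <- scenario$alpha_T
  t_of_s <- function(s) v$mu + (s - v$mu) / v$b
  f <- function(s) {
    t <- t_of_s(s)
    sum(upper_tail_proportion((t - v$mu) / v$sigma) * v$pi) - aT
  }
  fp <- function(s) {
    t <- t_of_s(s)
    -sum(v$pi * stats::dnorm((t - v$mu) / v$sigma) / (v$sigma * v$b))
  }
  lo <- min(v$mu - 10 * v$b * v$sigma)
  hi <- max(v$mu + 10 * v$b * v$sigma)
  s <- solve_decreasing_root(f, lo, hi, fprime = fp)
  finish_solution("optimal", t_of_s(s), scenario)
}

#' Percent improvement of optimal over identical thresholds
#'
#' `Psi_Tot = 100 * (dG_Tot(optimal) - dG_Tot(identical)) /
#' dG_Tot(identical)`, the relative gain in total selection response from
#' tailoring thresholds to each set instead of applying one threshold to
#' all candidates. For all-BLUP scenarios this is zero up to solver
#' tolerance.
#'
#' @param scenario A [selection_scenario()].
#' @param details If `TRUE`, return a list with the two
#'   `"threshold_solution"` objects alongside `psi_tot`; otherwise (default)
#'   return the scalar percentage.
#' @return Percent improvement (scalar), or a list when `details = TRUE`.
#'   Errors if the identical-threshold response is not positive, since the
#'   ratio is then undefined.
#' @export
percent_improvement <- function(scenario, details = FALSE) {
  id <- solve_identical_threshold(scenario)
  op <- solve_optimal_thresholds(scenario)
  g_id <- id$outcome$deltaG_tot
  if (g_id <= 0) {
    stop("identical-threshold response is not positive; Psi_Tot undefined",
         call. = FALSE)
  }
  psi <- 100 * (op$outcome$deltaG_tot - g_id) / g_id
  if (details) list(psi_tot = psi, identical = id, optimal = op) else psi
}

#' Direct constrained maximization of the total response
#'
#' Numerical cross-check for [solve_optimal_thresholds()] that never uses
#' the stationarity condition: the budget constraint is enforced by
#' construction (the last set's selected proportion is
#' `(alpha_T - sum_{k<K} pi_k alpha_k) / pi_K`) and the total response is
#' maximized over the remaining free proportions — a grid-bracketed golden
#' section search for `K = 2`, Nelder-Mead from the identical-threshold
#' start for `K > 2`.
#'
#' @param scenario A [selection_scenario()].
#' @return A `"threshold_solution"` with `mode = "direct"`.
#' @export
direct_constrained_maximize <- function(scenario) {
  v <- scenario_vectors(scenario)
  aT <- scenario$alpha_T
  K <- v$K
  obj_alpha <- function(a) {   # a: per-set selected proportions, length K
    tot <- sum(a * v$pi)
    gam <- a * v$pi / tot
    sum(v$b * v$sigma * selection_intensity(a) * gam) +
      sum(v$mu * (gam - v$pi))
  }
  eps <- 1e-12
  if (K == 1L) {
    sol <- finish_solution("direct",
                           threshold_for_proportion(aT, v$mu, v$sigma),
                           scenario)
    return(sol)
  }
  if (K == 2L) {
    # feasible open interval for alpha_1 given alpha_2 in (0,1)
    lo <- max(eps, (aT - v$pi[2]) / v$pi[1] + eps)
    hi <- min(1 - eps, aT / v$pi[1] - eps)
    if (lo >= hi) stop("budget leaves no feasible interior proportions",
                       call. = FALSE)
    g <- function(a1) obj_alpha(c(a1, (aT - v$pi[1] * a1) / v$pi[2]))
    grid <- seq(lo, hi, length.out = 513)
    k <- which.max(vapply(grid, g, numeric(1)))
    br <- c(grid[max(k - 1L, 1L)], grid[min(k + 1L, length(grid))])
    opt <- stats::optimize(g, interval = br, maximum = TRUE, tol = 1e-12)
    a <- c(opt$maximum, (aT - v$pi[1] * opt$maximum) / v$pi[2])
  } else {
    # free sets 1..K-1 on logit scale, last set absorbs the budget
    id <- solve_identical_threshold(scenario)
    start <- stats::qlogis(pmin(pmax(id$outcome$sets$alpha[-K], eps), 1 - eps))
    pen <- function(p) {
      a_free <- stats::plogis(p)
      a_last <- (aT - sum(v$pi[-K] * a_free)) / v$pi[K]
      if (a_last <= eps || a_last >= 1 - eps) return(1e6 * (1 + abs(a_last)))
      -obj_alpha(c(a_free, a_last))
    }
    fit <- stats::optim(start, pen, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (fit$convergence != 0) {
      stop("direct maximization failed to converge (code ",
           fit$convergence, ")", call. = FALSE)
    }
    a_free <- stats::plogis(fit$par)
    a <- c(a_free, (aT - sum(v$pi[-K] * a_free)) / v$pi[K])
  }
  finish_solution("direct", threshold_for_proportion(a, v$mu, v$sigma),
                  scenario)
}

#' @export
print.threshold_solution <- function(x, ...) {
  cat(sprintf("<threshold_solution> mode=%s converged=%s residual=%.2e\n",
              x$mode, x$converged, x$residual))
  print(x$outcome)
  invisible(x)
}

#' @export
as.data.frame.threshold_solution <- function(x, ...) {
  out <- as.data.frame(x$outcome)
  out$mode <- x$mode
  out
}

# Brent root of a strictly decreasing function with optional Newton polish;
# extends the bracket if the sign change lies outside the initial one.
solve_decreasing_root <- function(f, lo, hi, fprime = NULL,
                                  tol = 1e-13, max_extend = 60L) {
  n <- 0L
  while (f(lo) < 0 && n < max_extend) { lo <- lo - (hi - lo); n <- n + 1L }
  n <- 0L
  while (f(hi) > 0 && n < max_extend) { hi <- hi + (hi - lo); n <- n + 1L }
  if (f(lo) < 0 || f(hi) > 0) {
    stop("root bracketing failed: budget not attainable in search range",
         call. = FALSE)
  }
  x <- stats::uniroot(f, c(lo, hi), tol = tol)$root
  if (!is.null(fprime)) {
    for (it in 1:8) {
      fx <- f(x)
      if (abs(fx) < 1e-14) break
      d <- fprime(x)
      if (!is.finite(d) || d == 0) break
      step <- fx / d
      x_new <- x - step
      if (!is.finite(x_new) || abs(f(x_new)) >= abs(fx)) break
      x <- x_new
    }
  }
  x
}

finish_solution <- function(mode, thresholds, scenario) {
  out <- total_response(thresholds, scenario)
  residual <- abs(out$alpha_tot - scenario$alpha_T)
  structure(
    list(mode = mode, thresholds = thresholds, outcome = out,
         converged = residual <= 1e-9, residual = residual),
    class = "threshold_solution"
  )
}
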