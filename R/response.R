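#' Total selected proportion under per-set thresholds
#'
#' Mixture of per-set upper-tail proportions weighted by the set
#' proportions: applying threshold `t_k` to set `k` whose selection
#' criterion is `N(mu_k, sigma_k^2)` retains `alpha((t_k - mu_k)/sigma_k)`
#' of that set, and `alpha_Tot = sum_k alpha_k * pi_k` of the combined pool.
#'
#' @param thresholds Numeric vector, one threshold per set (trait units).
#' @param scenario A [selection_scenario()].
#' @return The overall selected proportion.
#' @export
total_selected_proportion <- function(thresholds, scenario) {
  v <- scenario_vectors(scenario)
  check_thresholds(thresholds, v$K)
  a <- upper_tail_proportion((thresholds - v$mu) / v$sigma)
  sum(a * v$pi)
}

#' Post-selection composition of the selected fraction
#'
#' Proportion `gamma_k` of the selected candidates that originate from each
#' set: `gamma_k = alpha_k * pi_k / alpha_Tot`. These weights can deviate
#' grossly from the initial proportions `pi_k` when sets differ in mean,
#' criterion variance, or accuracy.
#'
#' @inheritParams total_selected_proportion
#' @return Named numeric vector `gamma` summing to 1.
#' @export
post_selection_composition <- function(thresholds, scenario) {
  v <- scenario_vectors(scenario)
  check_thresholds(thresholds, v$K)
  a <- upper_tail_proportion((thresholds - v$mu) / v$sigma)
  tot <- sum(a * v$pi)
  if (tot <= 0) {
    stop("degenerate selection: no candidates retained at these thresholds",
         call. = FALSE)
  }
  stats::setNames(a * v$pi / tot, v$label)
}

#' Within-set selection response (classical breeder's equation)
#'
#' Expected gain in mean TGV of the candidates selected from a single set,
#' `dG = b * sigma_sc * i(alpha)`, where `alpha` is the proportion of the
#' set above the threshold.
#'
#' @param t Truncation threshold, trait units.
#' @param set A [set_params()] object.
#' @return Selection response in trait units (0 in the no-selection limit
#'   `t -> -Inf`).
#' @export
within_set_response <- function(t, set) {
  stopifnot(inherits(set, "set_params"),
            is.numeric(t), length(t) == 1L, is.finite(t))
  ss <- derive_scale_and_slope(set)
  a <- upper_tail_proportion((t - set$mu) / ss$sigma_sc)
  if (a >= 1) return(0)           # guard: alpha -> 1 means no selection
  ss$b * ss$sigma_sc * selection_intensity(a)
}

#' Total selection response across all sets
#'
#' The multi-set extension of the breeder's equation: the expected gain in
#' mean TGV of the selected union over the unselected union,
#' `dG_Tot = sum_k dG_k * gamma_k + sum_k mu_k * (gamma_k - pi_k)`.
#' The first term weights the within-set responses by the post-selection
#' composition; the second accounts for the shift of that composition
#' toward sets with higher (or lower) means. The baseline is the
#' unselected-union mean `sum_k pi_k * mu_k`.
#'
#' @inheritParams total_selected_proportion
#' @return An object of class `"total_response"`: a list with `alpha_tot`,
#'   `deltaG_tot`, and a per-set data frame `sets` holding columns
#'   `label, t, alpha, intensity, deltaG, gamma`.
#' @examples
#' sc <- selection_scenario(
#'   list(set_params("P1", 0.5, 0, 1, "BLUE", 0.36),
#'        set_params("P2", 0.5, 0, 1, "BLUE", 0.81)),
#'   alpha_T = 0.10)
#' total_response(c(1.77, 1.77), sc)
#' @export
total_response <- function(thresholds, scenario) {
  v <- scenario_vectors(scenario)
  check_thresholds(thresholds, v$K)
  a <- upper_tail_proportion((thresholds - v$mu) / v$sigma)
  tot <- sum(a * v$pi)
  if (tot <= 0) {
    stop("degenerate selection: no candidates retained at these thresholds",
         call. = FALSE)
  }
  gam <- a * v$pi / tot
  i_k <- selection_intensity(a)
  dG <- v$b * v$sigma * i_k
  dG_tot <- sum(dG * gam) + sum(v$mu * (gam - v$pi))
  structure(
    list(alpha_tot = tot,
         deltaG_tot = dG_tot,
         sets = data.frame(label = v$label, t = thresholds, alpha = a,
                           intensity = i_k, deltaG = dG, gamma = gam,
                           stringsAsFactors = FALSE)),
    class = "total_response"
  )
}

#' @export
print.total_response <- function(x, ...) {
  cat(sprintf("<total_response> alpha_Tot=%.6g  dG_Tot=%.6g\n",
              x$alpha_tot, x$deltaG_tot))
  print(x$sets, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.total_response <- function(x, ...) {
  out <- x$sets
  out <- rbind(
    out,
    data.frame(label = "TOTAL", t = NA_real_, alpha = x$alpha_tot,
               intensity = NA_real_, deltaG = x$deltaG_tot, gamma = 1,
               stringsAsFactors = FALSE))
  out
}

#' Closed-form total response for BLUP sets at a common threshold
#'
#' For all-BLUP scenarios (slope `b = 1` in every set) the total response at
#' a common threshold `t*` collapses to
#' `dG_Tot = (1/alpha_Tot) * sum_k [sigma_k * phi(z_k) * pi_k
#'   + mu_k * pi_k * (alpha_k - alpha_Tot)]`
#' with `z_k = (t* - mu_k)/sigma_k`. Must agree with [total_response()]
#' evaluated at `(t*, ..., t*)` to numerical precision.
#'
#' @param t_star Common threshold, trait units.
#' @param scenario A [selection_scenario()] whose sets are all BLUP sets.
#' @return Total selection response in trait units.
#' @export
blup_total_response_closed_form <- function(t_star, scenario) {
  if (!all_blup(scenario)) {
    stop("closed form requires an all-BLUP scenario", call. = FALSE)
  }
  stopifnot(is.numeric(t_star), length(t_star) == 1L, is.finite(t_star))
  v <- scenario_vectors(scenario)
  z <- (t_star - v$mu) / v$sigma
  a <- upper_tail_proportion(z)
  tot <- sum(a * v$pi)
  if (tot <= 0) stop("degenerate selection at this threshold", call. = FALSE)
  (sum(v$sigma * stats::dnorm(z) * v$pi) +
      sum(v$mu * v$pi * (a - tot))) / tot
}

check_thresholds <- function(thresholds, K) {
  if (!is.numeric(thresholds) || length(thresholds) != K ||
      any(!is.finite(thresholds))) {
    stop(sprintf("`thresholds` must be %d finite value(s), one per set", K),
         call. = FALSE)
  }
  invisible(thresholds)
}
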