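#' Simulate candidates with the joint structure the theory assumes
#'
#' Draws `(SC, TGV)` pairs for every set of a scenario from the
#' conditional-normal generative model that underlies the analytic results:
#' the selection criterion is `SC ~ N(mu_k, sigma_k^2)` and, given the
#' criterion, `TGV | SC ~ N(mu_k + b_k (SC - mu_k), v_k)` with residual
#' variance `v_k = sigma_u^2 (1 - rho^2)` for BLUP sets and
#' `sigma_u^2 (1 - h2)` for BLUE sets. This encodes exactly the two
#' quantities the theory uses — the SC variance and the TGV-on-SC
#' regression — and by the law of total variance reproduces the marginal
#' genetic variance `sigma_u^2` in both cases.
#'
#' Each set draws from its own RNG substream, seeded deterministically from
#' the master seed, so adding a set never perturbs the criterion draws of
#' earlier sets (their draws form a common prefix).
#'
#' @param scenario A [selection_scenario()].
#' @param n_per_set Average number of candidates per set (integer >= 1):
#'   set `k` receives `round(K * n_per_set * pi_k)` candidates, so the
#'   realized pool composition matches the scenario proportions `pi_k`
#'   that the analytic mixture formulas weight by. With equal proportions
#'   every set gets exactly `n_per_set`.
#' @param seed Integer master seed.
#' @return A data frame with columns `set` (label), `sc`, `tgv`, carrying
#'   attributes `seed` and `n_per_set`.
#' @examples
#' sc <- selection_scenario(
#'   list(set_params("P1", 0.5, 0, 1, "BLUP", 0.6),
#'        set_params("P2", 0.5, 0, 1, "BLUP", 0.9)),
#'   alpha_T = 0.10)
#' pop <- simulate_candidates(sc, n_per_set = 1000, seed = 1)
#' head(pop)
#' @export
simulate_candidates <- function(scenario, n_per_set, seed) {
  v <- scenario_vectors(scenario)
  if (!is.numeric(n_per_set) || length(n_per_set) != 1L ||
      !is.finite(n_per_set) || n_per_set < 1 || n_per_set != round(n_per_set)) {
    stop("`n_per_set` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed)) {
    stop("`seed` must be an integer", call. = FALSE)
  }
  n_k <- pmax(1L, as.integer(round(v$K * n_per_set * v$pi)))
  parts <- vector("list", v$K)
  for (k in seq_len(v$K)) {
    n <- n_k[k]
    set.seed((as.numeric(seed) + k) %% .Machine$integer.max)
    sc <- stats::rnorm(n, v$mu[k], v$sigma[k])
    resid_var <- v$sigma_u[k]^2 *
      (1 - if (v$criterion[k] == "BLUP") v$accuracy[k]^2 else v$accuracy[k])
    tgv <- v$mu[k] + v$b[k] * (sc - v$mu[k]) +
      stats::rnorm(n, 0, sqrt(resid_var))
    parts[[k]] <- data.frame(set = v$label[k], sc = sc, tgv = tgv,
                             stringsAsFactors = FALSE)
  }
  pop <- do.call(rbind, parts)
  attr(pop, "seed") <- seed
  attr(pop, "n_per_set") <- n_k
  pop
}

#' Empirical counterparts of the analytic selection quantities
#'
#' Applies per-set thresholds to a simulated population and measures the
#' realized selected fraction, post-selection composition, and selection
#' response, for comparison with their closed-form values.
#'
#' @param population A data frame from [simulate_candidates()].
#' @param thresholds Numeric vector, one threshold per set (in scenario set
#'   order).
#' @param scenario The [selection_scenario()] the population was drawn from.
#' @return A list with `alpha_hat` (selected / total), `gamma_hat` (named
#'   per-set shares of the selected fraction), `deltaG_hat` (mean TGV of
#'   selected minus overall mean TGV), and `n_selected`.
#' @export
empirical_total_response <- function(population, thresholds, scenario) {
  v <- scenario_vectors(scenario)
  check_thresholds(thresholds, v$K)
  stopifnot(is.data.frame(population),
            all(c("set", "sc", "tgv") %in% names(population)))
  thr <- stats::setNames(thresholds, v$label)
  keep <- population$sc >= thr[population$set]
  n_sel <- sum(keep)
  if (n_sel == 0L) {
    stop("degenerate selection: no candidates exceed their threshold",
         call. = FALSE)
  }
  sel_sets <- factor(population$set[keep], levels = v$label)
  list(
    alpha_hat = n_sel / nrow(population),
    gamma_hat = stats::setNames(as.numeric(table(sel_sets)) / n_sel, v$label),
    deltaG_hat = mean(population$tgv[keep]) - mean(population$tgv),
    n_selected = n_sel
  )
}

#' Grid check that the solver's optimum is a maximum
#'
#' Sweeps constraint-respecting threshold combinations for a two-set
#' scenario — parameterized by the set-1 selected proportion, with set 2
#' absorbing the budget — evaluates the analytic total response on each,
#' and compares the grid argmax with [solve_optimal_thresholds()].
#'
#' @param scenario A two-set [selection_scenario()].
#' @param n_grid Number of grid points (>= 3).
#' @return A list with `solver` (the `"threshold_solution"`), `grid` (data
#'   frame of `t1, t2, deltaG_tot`), `grid_max`, `argmax` (row of the best
#'   grid point), and `ok` (`TRUE` when the solver response is at least the
#'   grid maximum minus 1e-9).
#' @export
empirical_optimality_check <- function(scenario, n_grid = 2001) {
  v <- scenario_vectors(scenario)
  if (v$K != 2L) stop("grid check is implemented for two-set scenarios",
                      call. = FALSE)
  stopifnot(n_grid >= 3)
  aT <- scenario$alpha_T
  eps <- 1e-9
  lo <- max(eps, (aT - v$pi[2]) / v$pi[1] + eps)
  hi <- min(1 - eps, aT / v$pi[1] - eps)
  a1 <- seq(lo, hi, length.out = n_grid)
  a2 <- (aT - v$pi[1] * a1) / v$pi[2]
  t1 <- threshold_for_proportion(a1, v$mu[1], v$sigma[1])
  t2 <- threshold_for_proportion(a2, v$mu[2], v$sigma[2])
  dG <- vapply(seq_along(a1), function(j)
    total_response(c(t1[j], t2[j]), scenario)$deltaG_tot, numeric(1))
  solver <- solve_optimal_thresholds(scenario)
  k <- which.max(dG)
  list(
    solver = solver,
    grid = data.frame(t1 = t1, t2 = t2, deltaG_tot = dG),
    grid_max = dG[k],
    argmax = data.frame(t1 = t1[k], t2 = t2[k], deltaG_tot = dG[k]),
    ok = solver$outcome$deltaG_tot >= dG[k] - 1e-9
  )
}
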