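#' Grid scan of the post-selection composition shift for BLUP selection
#'
#' For a family of two-set BLUP scenarios, computes the ratio
#' `gamma1* : pi1` — how much the share of set-1 candidates shrinks (or
#' grows) after selection with the optimal common BLUP threshold — over a
#' grid of the set-2 mean `mu2` and accuracy `rho2`.
#'
#' @param mu2 Numeric vector of set-2 means.
#' @param rho2 Numeric vector of set-2 prediction accuracies in `(0, 1]`.
#' @param pi1 Set-1 proportion.
#' @param alpha_T Total selected proportion.
#' @param mu1 Set-1 mean (default 0).
#' @param sigma_u Genetic standard deviation shared by both sets
#'   (default 1).
#' @param rho1 Set-1 accuracy (default 0.5).
#' @return Data frame with one row per grid point: `mu2, rho2, pi1,
#'   alpha_T, t_star, gamma1_star, ratio` (`ratio = gamma1_star / pi1`).
#' @export
scan_gamma_ratio <- function(mu2, rho2, pi1, alpha_T,
                             mu1 = 0, sigma_u = 1, rho1 = 0.5) {
  grid <- expand.grid(mu2 = mu2, rho2 = rho2, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(j) {
    sc <- selection_scenario(
      list(set_params("P1", pi1, mu1, sigma_u, "BLUP", rho1),
           set_params("P2", 1 - pi1, grid$mu2[j], sigma_u, "BLUP",
                      grid$rho2[j])),
      alpha_T)
    sol <- solve_blup_common_threshold(sc)
    g1 <- sol$outcome$sets$gamma[1]
    data.frame(mu2 = grid$mu2[j], rho2 = grid$rho2[j], pi1 = pi1,
               alpha_T = alpha_T, t_star = sol$thresholds[1],
               gamma1_star = g1, ratio = g1 / pi1)
  })
  do.call(rbind, rows)
}

#' Grid scan of the optimal-threshold improvement for BLUE selection
#'
#' For a family of two-set BLUE scenarios, computes `Psi_Tot` (percent gain
#' of optimal over identical thresholds) together with the set-1
#' post-selection share under each threshold policy, over a grid of the
#' set-2 mean `mu2` and root-heritability `h2` (so the set-2 heritability
#' is `h2^2`).
#'
#' @param mu2 Numeric vector of set-2 means.
#' @param h2 Numeric vector of set-2 root-heritabilities in `(0, 1]`.
#' @param pi1 Set-1 proportion.
#' @param alpha_T Total selected proportion.
#' @param mu1 Set-1 mean (default 0).
#' @param sigma_u Genetic standard deviation shared by both sets
#'   (default 1).
#' @param h1_sq Set-1 heritability (default 0.5).
#' @return Data frame with columns `mu2, h2, pi1, alpha_T, psi_tot,
#'   gamma1_star, gamma1_ident`.
#' @export
scan_psi_tot <- function(mu2, h2, pi1, alpha_T,
                         mu1 = 0, sigma_u = 1, h1_sq = 0.5) {
  grid <- expand.grid(mu2 = mu2, h2 = h2, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(j) {
    sc <- selection_scenario(
      list(set_params("P1", pi1, mu1, sigma_u, "BLUE", h1_sq),
           set_params("P2", 1 - pi1, grid$mu2[j], sigma_u, "BLUE",
                      grid$h2[j]^2)),
      alpha_T)
    res <- percent_improvement(sc, details = TRUE)
    data.frame(mu2 = grid$mu2[j], h2 = grid$h2[j], pi1 = pi1,
               alpha_T = alpha_T, psi_tot = res$psi_tot,
               gamma1_star = res$optimal$outcome$sets$gamma[1],
               gamma1_ident = res$identical$outcome$sets$gamma[1])
  })
  do.call(rbind, rows)
}

#' Grid scan of the hybrid-selection improvement over pool-variance ratios
#'
#' Computes `Psi_Hyb` and the optimal pool-1 selected proportion over a
#' grid of the criterion standard-deviation ratio `sigma2 : sigma1`
#' (pool 1 fixed at `sigma1 = 1`) for one or more hybrid budgets.
#'
#' @param ratio Numeric vector of `sigma2 / sigma1` values in `(0, 1]`.
#' @param alpha_H Numeric vector of hybrid budgets in `(0, 1)`.
#' @param b1,b2 Regression slopes of true GCA on the criterion (default 1).
#' @return Data frame with columns `ratio, alpha_H, psi_hyb, alpha1_opt,
#'   alpha1_over_equal` (`alpha1_opt / sqrt(alpha_H)`).
#' @export
scan_hybrid <- function(ratio, alpha_H, b1 = 1, b2 = 1) {
  grid <- expand.grid(ratio = ratio, alpha_H = alpha_H,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(j) {
    p <- hybrid_params(1, grid$ratio[j], b1, b2, grid$alpha_H[j])
    res <- hybrid_percent_improvement(p, details = TRUE)
    a1 <- res$optimal$alpha1
    data.frame(ratio = grid$ratio[j], alpha_H = grid$alpha_H[j],
               psi_hyb = res$psi_hyb, alpha1_opt = a1,
               alpha1_over_equal = a1 / sqrt(grid$alpha_H[j]))
  })
  do.call(rbind, rows)
}
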