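# Shared fixtures: the two contrasting worked scenarios (equal-proportion
# sets from one population with accuracies 0.6 / 0.9, selected on BLUEs or
# BLUPs) and random scenario generators for the property suites.

blue_example <- function(alpha_T = 0.10) {
  selection_scenario(
    list(set_params("P1", 0.5, 0, 1, "BLUE", 0.36),
         set_params("P2", 0.5, 0, 1, "BLUE", 0.81)),
    alpha_T = alpha_T)
}

blup_example <- function(alpha_T = 0.10) {
  selection_scenario(
    list(set_params("P1", 0.5, 0, 1, "BLUP", 0.6),
         set_params("P2", 0.5, 0, 1, "BLUP", 0.9)),
    alpha_T = alpha_T)
}

# mild selection on an inferior small set, stringent on a superior one;
# per-set selected proportions are stated, not solved
extreme_example <- function() {
  sets <- list(
    set_params("inferior", 0.2, 0, sigma_u = 0.6, "BLUE", 0.36),  # sigma_sc = 1
    set_params("superior", 0.8, 2, sigma_u = 1.8, "BLUE", 0.81))  # sigma_sc = 2
  scenario <- selection_scenario(sets, alpha_T = 0.1)  # alpha_T unused here
  thresholds <- c(
    threshold_for_proportion(0.45, 0, 1),
    threshold_for_proportion(0.0125, 2, 2))
  list(scenario = scenario, thresholds = thresholds)
}

random_scenario <- function(K = 2, criterion = c("BLUP", "BLUE"),
                            mixed = FALSE) {
  criterion <- match.arg(criterion)
  pi <- stats::runif(K, 0.1, 1)
  pi <- pi / sum(pi)
  sets <- lapply(seq_len(K), function(k) {
    crit <- if (mixed) sample(c("BLUP", "BLUE"), 1) else criterion
    set_params(paste0("S", k), pi[k],
               mu = stats::runif(1, -1.5, 1.5),
               sigma_u = stats::runif(1, 0.4, 2),
               criterion = crit,
               accuracy = stats::runif(1, 0.25, 0.95))
  })
  selection_scenario(sets, alpha_T = stats::runif(1, 0.02, 0.4))
}

expect_within_se <- function(observed, expected, se, n_se = 4,
                             label = "value") {
  expect_lt(abs(observed - expected), n_se * se,
            label = sprintf("%s |%.5g - %.5g| vs %g SE", label, observed,
                            expected, n_se))
}
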