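#' Population parameters of one candidate set
#'
#' A candidate set is a group of genotypes (a family, a population, a
#' prediction set, ...) whose selection criterion (SC) is normally
#' distributed with a common mean and variance and whose true genetic values
#' (TGVs) regress on the SC with a common slope. Two criterion types are
#' supported:
#'
#' * `"BLUP"` — shrunken predictions of the TGV with accuracy `rho`; the SC
#'   standard deviation is `rho * sigma_u` and the regression of TGV on SC
#'   equals 1.
#' * `"BLUE"` — phenotypic entry means with heritability `h2`; the SC
#'   standard deviation is `sigma_u / sqrt(h2)` and the regression of TGV on
#'   SC equals `h2`.
#'
#' @param label Character label for the set.
#' @param pi Proportion of this set in the combined candidate pool, strictly
#'   inside `(0, 1)` (proportions across a scenario must sum to 1).
#' @param mu Mean of the selection criterion, trait units.
#' @param sigma_u Genetic standard deviation of TGVs, trait units
#'   (positive).
#' @param criterion `"BLUP"` or `"BLUE"`.
#' @param accuracy Prediction accuracy `rho` for BLUP sets, heritability
#'   `h2` for BLUE sets; in `(0, 1]` either way.
#' @return An object of class `"set_params"`.
#' @seealso [selection_scenario()], [derive_scale_and_slope()]
#' @examples
#' set_params("P1", pi = 0.5, mu = 0, sigma_u = 1,
#'            criterion = "BLUE", accuracy = 0.36)
#' @export
set_params <- function(label, pi, mu, sigma_u,
                       criterion = c("BLUP", "BLUE"), accuracy) {
  criterion <- match.arg(criterion)
  stopifnot(is.character(label), length(label) == 1L)
  check_proportion(pi, "pi")
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu)) {
    stop("`mu` must be a finite number", call. = FALSE)
  }
  if (!is.numeric(sigma_u) || length(sigma_u) != 1L ||
      !is.finite(sigma_u) || sigma_u <= 0) {
    stop("`sigma_u` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(accuracy) || length(accuracy) != 1L ||
      !is.finite(accuracy) || accuracy <= 0 || accuracy > 1) {
    stop(sprintf("`accuracy` (%s) must lie in (0, 1]",
                 if (criterion == "BLUP") "rho" else "h2"), call. = FALSE)
  }
  structure(
    list(label = label, pi = pi, mu = mu, sigma_u = sigma_u,
         criterion = criterion, accuracy = accuracy),
    class = "set_params"
  )
}

#' @export
print.set_params <- function(x, ...) {
  ss <- derive_scale_and_slope(x)
  cat(sprintf(
    "<set_params> %s: pi=%.4g mu=%.4g sigma_u=%.4g %s(%s=%.4g) -> sigma_sc=%.4g b=%.4g\n",
    x$label, x$pi, x$mu, x$sigma_u, x$criterion,
    if (x$criterion == "BLUP") "rho" else "h2",
    x$accuracy, ss$sigma_sc, ss$b))
  invisible(x)
}

#' Selection-criterion scale and TGV-on-SC slope of a set
#'
#' Maps a set's criterion type and accuracy to the two quantities the
#' response formulas actually use: the standard deviation `sigma_sc` of the
#' selection criterion and the regression slope `b` of true genetic values
#' on the criterion.
#'
#' @param set A [set_params()] object.
#' @return A list with components `sigma_sc` and `b`:
#'   BLUP gives `(rho * sigma_u, 1)`, BLUE gives
#'   `(sigma_u / sqrt(h2), h2)`.
#' @examples
#' derive_scale_and_slope(
#'   set_params("P1", 0.5, 0, 1, "BLUE", accuracy = 0.36))
#' @export
derive_scale_and_slope <- function(set) {
  stopifnot(inherits(set, "set_params"))
  if (set$criterion == "BLUP") {
    list(sigma_sc = set$accuracy * set$sigma_u, b = 1.0)
  } else {
    h <- sqrt(set$accuracy)
    list(sigma_sc = set$sigma_u / h, b = set$accuracy)
  }
}

#' A multi-set truncation-selection scenario
#'
#' Bundles `K >= 1` candidate sets with the total selection budget
#' `alpha_T`, the fixed proportion of candidates to retain from the combined
#' pool.
#'
#' @param sets A list of [set_params()] objects (or a single one). Set
#'   proportions must sum to 1 (tolerance 1e-8); they are renormalized
#'   exactly.
#' @param alpha_T Total selected proportion, strictly inside `(0, 1)`.
#' @return An object of class `"selection_scenario"`.
#' @examples
#' sc <- selection_scenario(
#'   list(set_params("P1", 0.5, 0, 1, "BLUE", 0.36),
#'        set_params("P2", 0.5, 0, 1, "BLUE", 0.81)),
#'   alpha_T = 0.10)
#' sc
#' @export
selection_scenario <- function(sets, alpha_T) {
  if (inherits(sets, "set_params")) sets <- list(sets)
  if (!is.list(sets) || length(sets) < 1L ||
      !all(vapply(sets, inherits, logical(1), "set_params"))) {
    stop("`sets` must be a list of set_params objects", call. = FALSE)
  }
  check_proportion(alpha_T, "alpha_T")
  pis <- vapply(sets, `[[`, numeric(1), "pi")
  if (abs(sum(pis) - 1) > 1e-8) {
    stop(sprintf("set proportions must sum to 1 (got %.10g)", sum(pis)),
         call. = FALSE)
  }
  for (k in seq_along(sets)) sets[[k]]$pi <- pis[k] / sum(pis)
  structure(list(sets = sets, alpha_T = alpha_T),
            class = "selection_scenario")
}

#' @export
print.selection_scenario <- function(x, ...) {
  cat(sprintf("<selection_scenario> K=%d sets, alpha_T=%.4g\n",
              length(x$sets), x$alpha_T))
  for (s in x$sets) print(s)
  invisible(x)
}

#' @export
as.data.frame.selection_scenario <- function(x, ...) {
  do.call(rbind, lapply(x$sets, function(s) {
    ss <- derive_scale_and_slope(s)
    data.frame(label = s$label, pi = s$pi, mu = s$mu, sigma_u = s$sigma_u,
               criterion = s$criterion, accuracy = s$accuracy,
               sigma_sc = ss$sigma_sc, b = ss$b,
               stringsAsFactors = FALSE)
  }))
}

# internal: scenario -> parallel numeric vectors used by all formulas
scenario_vectors <- function(scenario) {
  stopifnot(inherits(scenario, "selection_scenario"))
  ss <- lapply(scenario$sets, derive_scale_and_slope)
  list(
    label = vapply(scenario$sets, `[[`, character(1), "label"),
    pi    = vapply(scenario$sets, `[[`, numeric(1), "pi"),
    mu    = vapply(scenario$sets, `[[`, numeric(1), "mu"),
    sigma_u = vapply(scenario$sets, `[[`, numeric(1), "sigma_u"),
    criterion = vapply(scenario$sets, `[[`, character(1), "criterion"),
    accuracy = vapply(scenario$sets, `[[`, numeric(1), "accuracy"),
    sigma = vapply(ss, `[[`, numeric(1), "sigma_sc"),
    b     = vapply(ss, `[[`, numeric(1), "b"),
    K     = length(scenario$sets)
  )
}

all_blup <- function(scenario) {
  all(vapply(scenario$sets, `[[`, character(1), "criterion") == "BLUP")
}

#' Read a selection scenario from CSV
#'
#' The CSV must have columns `label, pi, mu, sigma_u, criterion, accuracy`
#' with `criterion` in `{BLUP, BLUE}` and `accuracy` holding `rho` (BLUP) or
#' `h2` (BLUE). Lines starting with `#` are ignored.
#'
#' @param path Path to the CSV file.
#' @param alpha_T Total selected proportion (scalar; supplied separately
#'   from the per-set table).
#' @return A [selection_scenario()].
#' @seealso [write_scenario_csv()]
#' @export
read_scenario_csv <- function(path, alpha_T) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("label", "pi", "mu", "sigma_u", "criterion", "accuracy")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("scenario CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(seq_len(nrow(df)), function(k) {
    set_params(as.character(df$label[k]), df$pi[k], df$mu[k], df$sigma_u[k],
               toupper(df$criterion[k]), df$accuracy[k])
  })
  selection_scenario(sets, alpha_T)
}

#' Write a selection scenario to CSV
#'
#' @param scenario A [selection_scenario()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_csv <- function(scenario, path) {
  df <- as.data.frame(scenario)[, c("label", "pi", "mu", "sigma_u",
                                    "criterion", "accuracy")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
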