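---
title: "Truncation selection across multiple sets of genotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Truncation selection across multiple sets of genotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(truncsel)
```

## The problem

Breeding programs rarely select from a single homogeneous population. A
selection stage typically pools several *sets* of candidates — bi-parental
families, introgression populations, training versus prediction sets — that
differ in their mean performance, their genetic variance, and in how
accurately the selection criterion (SC) predicts each candidate's true
genetic value (TGV). When one threshold is applied to the pooled candidates,
the realized selected proportions, and hence the selection response, differ
across sets in ways the classical single-population breeder's equation does
not describe.

`truncsel` models this situation analytically. Each set $k$ contributes a
proportion $\pi_k$ of the candidate pool; its SC is normally distributed,
$N(\mu_k, \sigma_k^2)$, and the TGV regresses on the SC with slope $b_k$.
Two criterion types cover the standard cases:

* **BLUPs** (shrunken predictions with accuracy $\rho_k$):
  $\sigma_k = \rho_k \sigma_{u_k}$ and $b_k = 1$;
* **BLUEs** (phenotypic entry means with heritability $h_k^2$):
  $\sigma_k = \sigma_{u_k} / h_k$ and $b_k = h_k^2$,

where $\sigma_{u_k}$ is the genetic standard deviation of TGVs. Truncation
at threshold $t_k$ retains the proportion
$\alpha_k = 1 - \Phi\!\left(\frac{t_k - \mu_k}{\sigma_k}\right)$ of set $k$,
so the pool-level selected proportion is the mixture
$\alpha_{\mathrm{Tot}} = \sum_k \alpha_k \pi_k$, and the *post-selection
composition* is $\gamma_k = \alpha_k \pi_k / \alpha_{\mathrm{Tot}}$.

The total selection response combines the within-set breeder's equations
$\Delta G_k = b_k \sigma_k\, i_{\alpha_k}$ (with $i_\alpha$ the standard
normal selection intensity) with the composition shift:

$$
\Delta G_{\mathrm{Tot}}
 = \sum_k \Delta G_k\, \gamma_k + \sum_k \mu_k (\gamma_k - \pi_k).
$$

**Baseline convention.** $\Delta G_{\mathrm{Tot}}$ is the mean TGV of the
selected union minus the mean of the *unselected union*,
$\sum_k \pi_k \mu_k$. The formula above encodes this baseline implicitly; we
state it explicitly because the second (mean-shift) term can dominate: with
mild selection on an inferior set and stringent selection on a superior one,
$\Delta G_{\mathrm{Tot}}$ can be negative even though every within-set
response is positive.

All formulas are implemented for $K \ge 1$ sets; the two-set case is the
documented, example-backed configuration.

## Optimal thresholds under a fixed budget

The program-level budget fixes $\alpha_{\mathrm{Tot}} = \alpha_T$, but the
breeder may still split it across sets. Three policies are provided.

**Identical thresholds** (`solve_identical_threshold()`): one threshold for
all candidates. Since $\alpha_{\mathrm{Tot}}$ is strictly decreasing in the
threshold, the budget equation has a unique root, found by Brent iteration
on the bracket $[\min_k(\mu_k - 10\sigma_k),\, \max_k(\mu_k + 10\sigma_k)]$
(tail mass beyond 10 SD is below $10^{-23}$, far smaller than any practical
budget; the bracket auto-extends if ever needed) followed by a Newton
polish. Returned solutions satisfy
$|\alpha_{\mathrm{Tot}} - \alpha_T| \le 10^{-9}$; in practice residuals are
near machine precision.

**Optimal thresholds** (`solve_optimal_thresholds()`): maximize
$\Delta G_{\mathrm{Tot}}$ subject to the budget. The Lagrange stationarity
condition states that the *expected TGV of a candidate at the threshold*,
$s = b_k (t_k - \mu_k) + \mu_k$, is equal across sets — selection is optimal
exactly when the marginal candidate is equally good wherever it comes from.
We parameterize the whole threshold vector by this common score $s$,
$t_k = \mu_k + (s - \mu_k)/b_k$, along which $\alpha_{\mathrm{Tot}}$ is again
strictly decreasing, and solve the budget as a one-dimensional root problem.
This reduction is exact for any $K$ and inherits the uniqueness of the
interior solution. For all-BLUP scenarios ($b_k = 1$) the parameterization
forces equal thresholds — the uniform-threshold optimality of BLUP
selection. Because that property is then true *by construction* in this
solver, the package also proves it independently: the free constrained
maximizer (below) is shown in the test suite to land on the same response as
the common threshold across randomized BLUP scenarios.

**Direct constrained maximization** (`direct_constrained_maximize()`): an
independent numerical route that never uses stationarity. The budget is
enforced by construction — the last set's proportion absorbs
$(\alpha_T - \sum_{k<K} \pi_k \alpha_k)/\pi_K$ — and the response is
maximized over the free proportions: for $K = 2$ a 513-point grid brackets
the maximum before golden-section refinement (guarding against any
multimodality); for $K > 2$ Nelder-Mead runs from the identical-threshold
start on logit-transformed proportions. Agreement with the Lagrange solver
is better than $10^{-6}$ in $\Delta G_{\mathrm{Tot}}$ across randomized
scenario batteries. The two routes are kept strictly separate so that each
can serve as an oracle for the other; if they ever disagreed beyond that
tolerance the tests would fail rather than silently return the better one.

The benefit of tailoring thresholds is summarized by
$$
\Psi_{\mathrm{Tot}} = 100 \times
  \frac{\Delta G_{\mathrm{Tot}}(t^*) - \Delta G_{\mathrm{Tot}}(t^i)}
       {\Delta G_{\mathrm{Tot}}(t^i)},
$$
implemented in `percent_improvement()`. The ratio is undefined when the
identical-threshold response is not positive; the package raises an error in
that case rather than returning a sign-flipped percentage (the underlying
responses remain available via `details = TRUE`). This error contract is the
package's own choice for a case the theory leaves open.

### A worked contrast

Two equal sets from one population ($\mu = 0$, $\sigma_u = 1$), accuracies
$0.6$ and $0.9$, budget $\alpha_T = 0.10$:

```{r worked}
blue <- selection_scenario(
  list(set_params("P1", 0.5, 0, 1, "BLUE", 0.36),
       set_params("P2", 0.5, 0, 1, "BLUE", 0.81)), alpha_T = 0.10)
solve_identical_threshold(blue)
solve_optimal_thresholds(blue)
percent_improvement(blue)

blup <- selection_scenario(
  list(set_params("P1", 0.5, 0, 1, "BLUP", 0.6),
       set_params("P2", 0.5, 0, 1, "BLUP", 0.9)), alpha_T = 0.10)
solve_blup_common_threshold(blup)
```

For BLUEs the identical threshold leaves 14.5% of the attainable response on
the table (42.3% at $\alpha_T = 0.01$); for BLUPs the common threshold *is*
optimal and reaches the same maximum response.

## Hybrid GCA selection

In hybrid breeding, lines from two parent pools are selected on predicted
general combining ability (GCA; deviations from the hybrid-population mean,
so both criteria are centered at zero), and the complete factorial among
selected lines is advanced. With a fixed proportion $\alpha_H$ of hybrids to
keep, the per-pool proportions satisfy $\alpha_1 \alpha_2 = \alpha_H$; the
conventional choice is the equal split $\alpha^e = \sqrt{\alpha_H}$. The
factorial response is the sum of the per-pool breeder's equations, and the
stationarity condition for the optimal split is
$b_2 t_2 - b_1 t_1 + \Delta G_1(t_1) - \Delta G_2(t_2) = 0$.
`solve_optimal_hybrid()` substitutes $\alpha_2 = \alpha_H/\alpha_1$ and
root-solves this in $\alpha_1 \in [\alpha_H(1+\varepsilon), 1-\varepsilon]$
($\varepsilon = 10^{-12}$ interior guard; a boundary optimum — no selection
in the weaker pool — is returned with a flag rather than an error). Every
solution is cross-checked in the tests against direct one-dimensional
maximization.

When the pools differ in criterion variance or accuracy, the optimum
concentrates selection in the pool with larger $\sigma b$. At
$\sigma_2 : \sigma_1 = 0.5$ with $b = 1$, the package's exact optima give
$\Psi_{\mathrm{Hyb}} = 9.4\%$, $7.2\%$ and $6.4\%$ at
$\alpha_H = 0.25$, $0.01$ and $10^{-4}$: the improvement decreases toward
roughly 6% only in the stringent-selection limit, while the proportion
ratio $\alpha_1^o / \alpha^e$ falls below $0.25$ once $\alpha_H \le 0.01$.
These values are frozen in the test suite from two independent maximization
routes.

## Numerical choices

* **Tail arithmetic.** All tail probabilities go through survival functions
  (`pnorm(..., lower.tail = FALSE)`), never `1 - pnorm(...)`, preserving
  relative precision in the far tail. The selection intensity
  $i_\alpha = \varphi(\Phi^{-1}(1-\alpha))/\alpha$ is computed directly over
  the entire representable range; only below $\alpha = 10^{-300}$, where
  $\varphi$ itself reaches the subnormal floor and the ratio degenerates,
  does it switch to the Mills-ratio asymptotic $i \approx x + 1/x$. We
  deliberately place the switch at the floor rather than at a laxer point
  such as $10^{-12}$: at $\alpha = 10^{-12}$ the direct ratio is still
  exact to double precision while the asymptotic would introduce an error
  of order $2/x^3 \approx 5\times 10^{-3}$.
* **Root solving.** Budget equations use `uniroot` at tolerance $10^{-13}$
  plus up to eight Newton steps, giving residuals at machine precision;
  solutions report `converged` against the $10^{-9}$ contract.
* **Degenerate inputs.** Set proportions, budgets, and accuracies are
  validated to open/half-open intervals ($\pi_k, \alpha \in (0,1)$,
  $\rho, h^2 \in (0,1]$, $\sigma_u > 0$): boundary values make some formula
  degenerate (zero criterion variance, empty or all-in selection), and only
  interior cases are meaningful. Degenerate selection (no candidate
  retained) raises an error rather than returning `NaN`.
* **Tie-breaks.** Interior optima are unique by monotonicity along the
  stationarity manifold; no tie-breaking is needed.

## The Monte-Carlo oracle

`simulate_candidates()` draws the generative model the theory assumes,
set by set: $SC \sim N(\mu_k, \sigma_k^2)$ and
$TGV \mid SC \sim N(\mu_k + b_k (SC - \mu_k),\, v_k)$ with residual variance
$v_k = \sigma_{u_k}^2 (1-\rho_k^2)$ (BLUP) or $\sigma_{u_k}^2 (1-h_k^2)$
(BLUE). The conditional form was chosen over a joint bivariate draw because
it encodes exactly the two quantities the theory uses — the criterion
variance and the TGV-on-SC regression — and makes the residual-variance
formulas directly testable; the law of total variance then recovers the
marginal $\mathrm{Var}(TGV) = \sigma_{u_k}^2$ for both criterion types. Set
$k$ receives $\mathrm{round}(K \cdot n_{\mathrm{per\,set}} \cdot \pi_k)$
candidates so the realized pool composition matches the $\pi_k$ the mixture
formulas weight by. Per-set RNG substreams are seeded deterministically from
the master seed, so adding a set never perturbs earlier sets' criterion
draws.

`empirical_total_response()` measures $\hat\alpha$, $\hat\gamma$, and
$\Delta\hat G$ on a simulated population, and the test suite requires
agreement with the analytic formulas within four standard errors at
$n = 10^6$ candidates per set — a principled stochastic tolerance at any
problem size. `empirical_optimality_check()` additionally sweeps a
constraint-respecting threshold grid (2001 points for the documented
examples) and confirms the solver's optimum is the grid argmax.

**What the simulation does not emulate.** Candidates are i.i.d. within
sets: no pedigree or family structure, no linkage, no relationship between
the sets, no multi-stage or recurrent selection, and no uncertainty in the
population parameters themselves. Passing Monte-Carlo checks therefore
validates the algebra and the solvers under the model's assumptions; it
does not show that real breeding data, with unbalanced designs and related
candidates, follow the model. The theory is expected to hold approximately
under relaxed assumptions, but that is a conjecture to test on data, not a
property the simulations establish.

## Parameter-grid scans

`scan_gamma_ratio()`, `scan_psi_tot()`, and `scan_hybrid()` tabulate the
composition shift $\gamma_1^*/\pi_1$, the improvement
$\Psi_{\mathrm{Tot}}$, and the hybrid quantities over parameter grids — the
same machinery behind the package's contour-style analyses, emitted as
data frames (and CSVs via the CLI) because the quantities of record are
numeric. Scan defaults follow the documented baselines ($\mu_1 = 0$,
$\sigma_{u} = 1$, $\rho_1 = 0.5$ for the BLUP composition scan;
$h_1^2 = 0.5$ for the BLUE improvement scan, exposed as a parameter since
reasonable analyses may also use $h_1^2 = \sqrt{0.5}$).

## Command-line interface

The installed script (`system.file("cli", "truncsel.R", package =
"truncsel")`) is a two-line wrapper over `truncsel_cli()`, with verbs
`respond`, `optimize`, `blup-threshold`, `hybrid-optimize`, `scan`, and
`simulate`; scenarios are CSV tables, scan specifications are YAML files,
and outputs are CSVs with a header comment recording version, seed, and
parameters. Exit codes: 0 success, 2 invalid input, 3 solver failure.

## Problem sizes used in validation

The shipped validation uses desk-scale problems: closed-form worked
examples (two sets), randomized batteries of 50–200 scenarios for the
property checks, $10^6$ candidates per set for Monte-Carlo agreement, and
2001-point grids for optimality sweeps. All are the package's own choices,
large enough that four-standard-error bounds are tight (stochastic SEs
around $10^{-3}$) while the full suite runs in well under a minute.

## Known limitations

* Selecting exactly $k$ of $n$ candidates differs from truncation selection
  in finite samples; the equivalence is asymptotic, and no finite-$n$
  correction is implemented.
* Non-normal criterion distributions, covariances between sets, multi-trait
  indices, and optimum-contribution selection are out of scope.
* Partial ("triangle") factorials in hybrid selection are not modeled; the
  hybrid module covers the complete factorial only.
* Population parameters are taken as known; estimating them, and allocating
  resources between training and prediction sets, is left to the user.
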