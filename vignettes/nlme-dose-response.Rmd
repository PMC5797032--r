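---
title: "NLME dose-response association tests for high-throughput drug screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NLME dose-response association tests for high-throughput drug screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlmedrc)
```

## The problem

High-throughput drug screens expose a panel of cell lines to a dose ladder
of each drug and read out viability. The standard analysis fits each cell
line's dose-response curve (DRC) in isolation, extracts the midpoint — the
log10 IC50 — and tests that single number for association with a per-line
feature such as gene expression or mutation status. This discards two
things at once: the information that the other cell lines carry about any
one line's curve, and every feature of the curve other than the IC50
(asymptotes and slope).

`nlmedrc` implements the alternative: fit all cell lines of a drug jointly
with a nonlinear mixed-effects (NLME) model, and test associations either
through the model's per-line conditional IC50s or through an omnibus
likelihood-ratio statistic that is sensitive to *any* difference in curve
shape between two groups of cell lines.

## The model

Viability follows a four-parameter logistic (4PL) in log10 concentration
$x$:

$$y_{ij} = R + \frac{L - R}{1 + \exp\{(m + b_i - x_{ij})/s\}} +
\varepsilon_{ij}, \qquad b_i \sim N(0, \sigma_b^2), \quad
\varepsilon_{ij} \sim N(0, \sigma_e^2),$$

with $L$ the left (low-dose) asymptote, $R$ the right (high-dose)
asymptote, $m$ the population midpoint ("x-mid", the log10 IC50), and $s$
the scale. For inhibition curves $L > R$ and $s < 0$. Each cell line $i$
gets a scalar Gaussian random shift $b_i$ of its midpoint; all four curve
parameters are fixed effects. The per-line conditional midpoint is
$m + \hat b_i$ with $\hat b_i$ the conditional mode (BLUP), which is
shrunken towards $m$ relative to an independent per-line fit — this
shrinkage is what stabilises IC50 estimates on noisy lines.

The marginal likelihood integrates $b_i$ out per line. The package
evaluates that integral by a Laplace approximation at the conditional mode
(default) or adaptive Gauss–Hermite quadrature (`quadrature = "agq"`,
`nagq` nodes). The integrand is one-dimensional and close to Gaussian in
this model, so Laplace is accurate: the test suite compares it with
brute-force trapezoid integration (2001 points over ±6σ) on small
instances, and with 9-node quadrature, which agrees with brute force to
~1e-9 log-units.

### Numerical strategy

The six free parameters $(L, R, m, s, \log\sigma_b, \log\sigma_e)$ are
optimised by L-BFGS-B with box bounds (asymptotes in [−60, 250] %
viability, midpoint within ±2 log-units of the dose range, $s < 0$) and a
`parscale` of (50, 50, 0.5, 0.5, 1, 1) that evens out the conditioning gap
between asymptote and variance parameters. The gradient of the Laplace
objective is computed analytically in compiled code: the penalised
deviance term differentiates by the envelope identity (the inner mode is
stationary), and the log-determinant correction carries the third
derivative of the 4PL and the implicit derivative of the mode. The inner
mode search is a damped Newton iteration run to a tolerance far below the
outer optimiser's resolution. Starting values come from a pooled
least-squares 4PL fit (Levenberg–Marquardt) plus per-line half-response
crossings for the random-effect SD; this start was chosen over a
"median of individual fits" two-stage scheme because it is an order of
magnitude cheaper inside the permutation loop and markedly more robust
when the residual noise is very small, where a mediocre start can send the
optimiser into a degenerate step-function basin. A slope that collapses to
its boundary triggers one retry from the canonical slope, and reported
non-convergence triggers restarts and a differently-scaled quasi-Newton
polish before the fit is flagged.

## The three association tests

Given a two-level grouping of cell lines (for a continuous feature, the
median split of `median_split()`: strictly above the panel median is
"plus", ties go to "minus"):

* **Traditional IC50 test** (`traditional_ic50_table()` + `trad_assoc()`):
  each line fitted alone by bounded Levenberg–Marquardt least squares;
  Welch t-test (or Pearson correlation for continuous features) on the
  fitted midpoints.
* **NLME IC50 test** (`fit_nlme_pooled()` + `nlme_ic50_assoc()`): the same
  test applied to the conditional midpoints of the pooled fit. Because the
  pooled fit shares asymptotes and slope across lines, group differences in
  those parameters leak into the conditional midpoints — which is why this
  test also has power against non-IC50 curve differences.
* **Omnibus LR NLME test** (`omnibus_perm_test()`): compare the pooled fit
  over all lines with separate fits per group via
  $LLR = -2\,LL_{all} + 2(LL_{+} + LL_{-})$. The stratified model frees
  all four curve parameters and both variance components per group, so the
  statistic responds to any difference in curve shape. Significance comes
  from permuting the group labels across cell lines (a line's wells always
  move together, preserving within-line correlation), with
  $p = (1 + C)/(n + 1)$ where $C$ counts permuted statistics strictly
  exceeding the observed one; ties count against rejection. The pooled
  likelihood is computed once per dataset since label permutation cannot
  change it.

Two permutation-budget devices mirror screening practice. *Early
stopping*: once $C \ge \lfloor \alpha (n+1) \rfloor$ (5 at $n = 100$,
$\alpha = 0.05$) the p-value can no longer fall below $\alpha$ and the
loop stops. *Adaptive escalation*: an initial pass that ends with
$p \le \alpha$ is re-run from scratch with `adaptive_n` permutations
(default 9,999, minimum attainable p-value $10^{-4}$) on a fresh seed
stream — re-running rather than topping up keeps the reported p-value an
exact function of one recorded seed. A permutation whose stratified fit
fails to converge is counted as an exceedance, which can only make the
test conservative. Bonferroni correction (`bonferroni_adjust()`) handles
multiplicity across feature × drug tests.

## The simulator and what it does (not) emulate

`scenario_spec()`/`simulate_screen()` generate screens with the canonical
design: nine concentrations 0.02–10 µM in triplicate, per-line midpoints
drawn from $N(m_g, 0.3)$ around their group's value, group 1 curves at
$(L, R, m, s) = (100, 10, -0.5, -0.5)$, half the panel per group, and
expression intensities $N(8, 1)$ for over-expressers versus $N(3, 1)$ for
under-expressers. `scenario_grid()` enumerates the alternative scenarios
over the study levels ($L \in \{100, 90, 80, 70\}$,
$R \in \{10, 20, 30, 40\}$, $m \in \{-0.5, -0.4, -0.25, 0\}$,
$s \in \{-0.5, -0.4, -0.2\}$; 192 combinations in the full cross, 48 or 64
with one parameter held fixed).

Well noise is Gaussian with a constant SD of 10% viability at every dose —
a typical luminescence-assay replicate SD, chosen once as the stand-in for
per-dose empirical SDs that are not available, and deliberately not tuned.
Two consequences matter for interpreting the power tables. First, type-I
error is insensitive to this choice (the permutation test is exact under
label exchangeability for *any* noise model, and the t-tests only need
exchangeable per-line estimates), so the null rejection rates transfer to
real screens. Second, absolute power does depend on it: with clean
constant-10% noise the per-line traditional IC50 estimates are accurate,
so the traditional test is considerably stronger in midpoint-shift
scenarios (power ≈ 0.9 at a 0.5 log-unit shift, 50 lines) than it is on
screens with realistic heteroscedastic noise — the power *ordering* of the
tests and the blindness of the traditional test to asymptote/slope changes
are the transferable findings, not the absolute traditional-test power.
The simulator also does not model plate/edge effects, DMSO-control
normalisation noise, or truncation of viability at 0/100% (fits handle
excursions; truncating would bias asymptote estimates).

## Power harness

`estimate_power()` repeats simulate → median-split → test over `n_sims`
screens and reports the rejection rate at `alpha` (strict `p < alpha`,
consistent with the discreteness of the permutation p-value). Seeding is
nested — master seed → per-simulation seeds → per-permutation seeds — so
any single simulated dataset is reconstructible in isolation, and two
tests run with the same master seed score the *same* screens. A simulation
whose fits fail to converge is redrawn (up to 5 times, logged) rather than
silently dropped, keeping the denominator honest. `table2_summary()`
aggregates mean ± SD of power over a scenario grid.

Problem sizes used by the shipped checks: the per-line tests run at 100
simulations; the omnibus test at 50 simulations × 99 permutations; the
brute-force likelihood oracle on 3-line single-replicate toys; shrinkage
and diagnostics properties on 50- and 10-line screens. These sizes give
Monte-Carlo SEs of ~0.02–0.07 on rejection rates.

## Degenerate inputs and edge policies

Flat (zero-variance) response data return a non-converged individual fit
rather than an error; non-converged lines are omitted from the traditional
IC50 table and reported in its `failed` attribute. The drug filter
(`filter_drugs_by_min_viability()`) applies a strict `<` at the 20%
threshold to replicate-averaged viabilities. The NLME fitter requires at
least two cell lines, each with ≥ 4 distinct doses and ≥ 8 wells; the
omnibus test requires ≥ 2 lines per group. Variance components are
bounded below (σ_b ≥ 1e-6, σ_e ≥ 1e-3 on their natural scales) so the
shared-midpoint limit is reachable without divergence; at that limit the
marginal log-likelihood agrees with the pooled fixed-effects least-squares
log-likelihood to within optimiser tolerance (≈ 0.01 log-units on the test
case; exact agreement is unattainable because of the variance floor).

## Known limitations

Only the midpoint carries a random effect — between-line variation in
asymptotes or slope is absorbed by the residual and, in stratified fits,
by the group's fixed effects. Covariates cannot (yet) enter the NLME model
directly; associations are tested through grouping. The omnibus test as
implemented compares exactly two groups. p-values from the conditional-
midpoint t-test ignore the uncertainty of the variance components, as is
conventional; the permutation test does not. Permutation testing is
computationally dominant: one omnibus test costs roughly
`2 × n_perm` stratified NLME fits (tens of milliseconds each at 25 lines
per group on current hardware), which early stopping cuts sharply for
non-significant associations.

## A worked example

```{r example}
spec <- scenario_spec(n_lines = 50, group2 = fourpl(100, 10, -0.5, -0.2))
sim <- simulate_screen(spec, seed = 42)
groups <- median_split(sim$expression)

# traditional analysis: per-line IC50s, then a t-test
ic50s <- traditional_ic50_table(sim$screen)
trad_assoc(ic50s, groups, mode = "ttest")$p.value

# pooled NLME fit and the conditional-IC50 test
fit <- fit_nlme_pooled(sim$screen)
fit
nlme_ic50_assoc(fit, groups, mode = "ttest")$p.value

# omnibus permutation test: sensitive to the slope-only difference
omnibus_perm_test(sim$screen, groups = groups, n_perm = 99,
                  adaptive_n = NULL, seed = 1)
```

The two groups differ only in slope, so the IC50-based tests see (almost)
nothing while the omnibus statistic is large and its permutation p-value
small.
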