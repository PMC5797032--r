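#' Estimate type-I error or power of an association test by simulation
#'
#' Repeatedly simulates screens from a scenario, applies one of the three
#' association tests to each, and reports the rejection rate at level
#' `alpha`.  Under a null scenario (`group2 = group1`) this is the
#' empirical type-I error; under an alternative it is power.  The tests:
#'
#' * `"trad_ic50"` — Welch t-test of independently fitted per-line
#'   midpoints between over- and under-expressers ([traditional_ic50_table()]).
#' * `"nlme_ic50"` — the same t-test on conditional midpoints from the
#'   pooled NLME fit ([fit_nlme_pooled()]).
#' * `"omnibus_llr"` — the permutation LR test ([omnibus_perm_test()],
#'   run without adaptive escalation since only rejection at `alpha`
#'   matters here).
#'
#' Groups are formed by the median split of the simulated expression
#' values, mirroring how a real feature would be dichotomised.  Seeding is
#' nested (master seed -> per-simulation seeds -> per-permutation seeds) so
#' any single simulated dataset can be reconstructed in isolation.  A
#' simulation whose required fits fail to converge is redrawn (up to
#' `max_redraws` times, logged); a slot still failing counts as a
#' non-rejection.
#'
#' @param spec A [scenario_spec()].
#' @param test One of `"trad_ic50"`, `"nlme_ic50"`, `"omnibus_llr"`.
#' @param n_sims Number of simulated screens (default 100).
#' @param alpha Rejection level; rejection uses strict `p < alpha`.
#' @param seed Master seed.
#' @param n_perm Permutations per omnibus test (default 100).
#' @param quadrature,nagq Passed to the NLME fitter.
#' @return An object of class `"power_estimate"`: list with `scenario`,
#'   `test`, `n_sims`, `rejections`, `alpha`, `power`, `mc_se`, and `log`
#'   (per-simulation data frame of seed, p-value, redraws).
#' @export
estimate_power <- function(spec, test = c("trad_ic50", "nlme_ic50",
                                          "omnibus_llr"),
                           n_sims = 100L, alpha = 0.05, seed = NULL,
                           n_perm = 100L,
                           quadrature = c("laplace", "agq"), nagq = 9L,
                           max_redraws = 5L) {
  test <- match.arg(test)
  quadrature <- match.arg(quadrature)
  stopifnot(inherits(spec, "scenario_spec"))
  n_sims <- as.integer(n_sims)
  if (n_sims < 1L) stop("n_sims must be >= 1", call. = FALSE)
  seeds <- with_seed_opt(seed, {
    list(sim = sample.int(.Machine$integer.max, n_sims),
         perm = sample.int(.Machine$integer.max, n_sims))
  })
  log <- data.frame(sim = seq_len(n_sims), seed = seeds$sim,
                    p = NA_real_, redraws = 0L)
  rej <- 0L
  for (i in seq_len(n_sims)) {
    p <- NA_real_
    for (attempt in 0:max_redraws) {
      s_i <- child_seed(seeds$sim[i], attempt)
      sim <- simulate_screen(spec, seed = s_i)
      groups <- median_split(sim$expression)
      p <- tryCatch(
        apply_test(sim, groups, test, alpha = alpha, n_perm = n_perm,
                   perm_seed = child_seed(seeds$perm[i], attempt),
                   quadrature = quadrature, nagq = nagq),
        error = function(e) NA_real_)
      if (!is.na(p)) break
    }
    log$p[i] <- p
    log$redraws[i] <- attempt
    if (!is.na(p) && p < alpha) rej <- rej + 1L
  }
  power <- rej / n_sims
  structure(list(scenario = spec, test = test, n_sims = n_sims,
                 rejections = rej, alpha = alpha, power = power,
                 mc_se = sqrt(power * (1 - power) / n_sims), log = log),
            class = "power_estimate")
}

apply_test <- function(sim, groups, test, alpha, n_perm, perm_seed,
                       quadrature, nagq) {
  switch(test,
    trad_ic50 = {
      tab <- traditional_ic50_table(sim$screen)
      trad_assoc(tab, groups, mode = "ttest")$p.value
    },
    nlme_ic50 = {
      fit <- fit_nlme_pooled(sim$screen, quadrature = quadrature,
                             nagq = nagq)
      nlme_ic50_assoc(fit, groups, mode = "ttest")$p.value
    },
    omnibus_llr = {
      omnibus_perm_test(sim$screen, groups = groups, n_perm = n_perm,
                        alpha = alpha, adaptive_n = NULL, seed = perm_seed,
                        quadrature = quadrature, nagq = nagq)$p_value
    })
}

#' @export
print.power_estimate <- function(x, ...) {
  cat("Rejection rate of", x$test, "at alpha =", x$alpha, ":",
      format(x$power, digits = 3),
      sprintf("(%d/%d, MC se %.3f)\n", x$rejections, x$n_sims, x$mc_se))
  invisible(x)
}

#' Summarise power over a scenario grid
#'
#' Aggregates a collection of [estimate_power()] results (e.g. over a
#' [scenario_grid()] with one parameter held fixed) into the mean and SD
#' of power per test.
#'
#' @param estimates List of `"power_estimate"` objects.
#' @return Data frame with one row per test: `test`, `n_scenarios`,
#'   `mean_power`, `sd_power`.
#' @export
table2_summary <- function(estimates) {
  if (length(estimates) == 0L) stop("no estimates supplied", call. = FALSE)
  ok <- vapply(estimates, inherits, logical(1), what = "power_estimate")
  if (!all(ok)) stop("all elements must be power_estimate objects",
                     call. = FALSE)
  tests <- vapply(estimates, `[[`, character(1), "test")
  pw <- vapply(estimates, `[[`, numeric(1), "power")
  out <- do.call(rbind, lapply(unique(tests), function(tt) {
    v <- pw[tests == tt]
    data.frame(test = tt, n_scenarios = length(v), mean_power = mean(v),
               sd_power = if (length(v) > 1L) sd(v) else 0)
  }))
  rownames(out) <- NULL
  out
}
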