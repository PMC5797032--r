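test_that("Laplace and AGQ marginal likelihoods match brute-force integration", {
  for (seed in c(21, 22, 23)) {
    spec <- scenario_spec(n_lines = 4, replicates = 1, noise_sd = 10)
    sim <- simulate_screen(spec, seed = seed)
    scr <- sim$screen[sim$screen$cell_line %in% c("CL001", "CL002", "CL003"), ]
    ls <- unique(scr$cell_line)
    idx <- match(scr$cell_line, ls) - 1L
    ord <- order(idx)
    par <- c(100, 10, -0.5, -0.5, log(0.3), log(10))
    lap <- -nlmedrc:::nlme4pl_nll(par, scr$x[ord], scr$response[ord],
                                  idx[ord], 3L, 1L, 0, 0, numeric(0))
    gh <- nlmedrc:::gauss_hermite(9)
    agq <- -nlmedrc:::nlme4pl_nll(par, scr$x[ord], scr$response[ord],
                                  idx[ord], 3L, 9L, gh$z, gh$w, numeric(0))
    bf <- bf_marginal_loglik(100, 10, -0.5, -0.5, 0.3, 10, scr)
    expect_lt(abs(lap - bf), 0.05)
    expect_lt(abs(agq - bf), 1e-4)
  }
})

test_that("analytic gradient of the Laplace objective matches finite differences", {
  sim <- simulate_screen(scenario_spec(n_lines = 8), seed = 3)
  scr <- sim$screen
  ls <- unique(scr$cell_line)
  idx <- match(scr$cell_line, ls) - 1L
  ord <- order(idx)
  x <- scr$x[ord]; y <- scr$response[ord]; idx <- idx[ord]
  nll <- function(p) nlmedrc:::nlme4pl_nll(p, x, y, idx, 8L, 1L, 0, 0,
                                           numeric(0))
  for (par in list(c(100, 10, -0.5, -0.5, log(0.3), log(10)),
                   c(95, 20, -0.2, -0.8, log(0.1), log(6)))) {
    v <- nlmedrc:::nlme4pl_nll_grad(par, x, y, idx, 8L, numeric(0))
    expect_equal(v[1], nll(par))
    fd <- vapply(1:6, function(k) {
      h <- 1e-6 * max(1, abs(par[k])); e <- numeric(6); e[k] <- h
      (nll(par + e) - nll(par - e)) / (2 * h)
    }, numeric(1))
    expect_equal(v[-1], fd, tolerance = 1e-3)
  }
})

test_that("pooled fit recovers the generating model on a 50-line screen", {
  sim <- simulate_screen(scenario_spec(n_lines = 50), seed = 5)
  fit <- fit_nlme_pooled(sim$screen)
  expect_true(fit$converged)
  expect_equal(fit$n_lines, 50L)
  expect_equal(fit$n_obs, 1350L)
  f <- fit$fixed
  expect_lt(abs(f[["left"]] - 100), 10)
  expect_lt(abs(f[["right"]] - 10), 1)
  expect_lt(abs(f[["xmid"]] + 0.5), 0.05)
  expect_lt(abs(f[["scale"]] + 0.5), 0.05)
  expect_gt(fit$sd_xmid_re, 0.2)
  expect_lt(fit$sd_xmid_re, 0.4)
  expect_gt(fit$sd_resid, 9)
  expect_lt(fit$sd_resid, 11)
})

test_that("marginal loglik dominates the fixed-effects-only least-squares fit", {
  sim <- simulate_screen(scenario_spec(n_lines = 20), seed = 9)
  fit <- fit_nlme_pooled(sim$screen)
  d <- sim$screen
  ls <- minpack.lm::nlsLM(
    response ~ right + (left - right) / (1 + exp((xmid - x) / scale)),
    data = d, start = list(left = 100, right = 10, xmid = -0.5,
                           scale = -0.5))
  rss <- sum(resid(ls)^2)
  ll_ls <- -0.5 * nrow(d) * (log(2 * pi * rss / nrow(d)) + 1)
  expect_gt(fit$loglik, ll_ls - 0.05)
})

test_that("shared-midpoint near-noiseless screens collapse to the LS fit", {
  spec <- scenario_spec(n_lines = 4, noise_sd = 0.01, xmid_re_sd = 1e-9)
  sim <- simulate_screen(spec, seed = 2)
  fit <- fit_nlme_pooled(sim$screen)
  expect_true(fit$converged)
  expect_lt(fit$sd_xmid_re, 1e-3)
  # every conditional midpoint sits on the fixed effect
  expect_equal(unname(conditional_xmids(fit)),
               rep(fit$fixed[["xmid"]], 4), tolerance = 1e-3)
  d <- sim$screen
  ls <- minpack.lm::nlsLM(
    response ~ right + (left - right) / (1 + exp((xmid - x) / scale)),
    data = d, start = list(left = 100, right = 10, xmid = -0.5,
                           scale = -0.5))
  rss <- sum(resid(ls)^2)
  ll_ls <- -0.5 * nrow(d) * (log(2 * pi * rss / nrow(d)) + 1)
  expect_lt(abs(fit$loglik - ll_ls), 0.05)
})

test_that("conditional midpoints shrink towards the population value", {
  sim <- simulate_screen(scenario_spec(n_lines = 30), seed = 13)
  fit <- fit_nlme_pooled(sim$screen)
  cond <- conditional_xmids(fit)
  indiv <- traditional_ic50_table(sim$screen)
  common <- intersect(names(cond), names(indiv))
  expect_length(cond, 30)
  expect_lt(sd(cond[common]), sd(indiv[common]))
})

test_that("fits are deterministic and preconditions enforced", {
  sim <- simulate_screen(scenario_spec(n_lines = 6), seed = 4)
  f1 <- fit_nlme_pooled(sim$screen)
  f2 <- fit_nlme_pooled(sim$screen)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$line_xmid, f2$line_xmid)
  one <- sim$screen[sim$screen$cell_line == "CL001", ]
  expect_error(fit_nlme_pooled(one), "at least 2 cell lines")
})

test_that("residual diagnostics are calibrated under Gaussian noise", {
  n_ok <- 0L
  n_sims <- 30L
  for (k in seq_len(n_sims)) {
    sim <- simulate_screen(scenario_spec(n_lines = 10), seed = 100 + k)
    fit <- fit_nlme_pooled(sim$screen)
    dg <- residual_diagnostics(fit)
    expect_length(dg$residuals, fit$n_obs)
    expect_lt(abs(mean(dg$residuals)),
              3 * fit$sd_resid / sqrt(fit$n_obs))
    if (dg$p.value > 0.05) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 25L)  # ~95% expected under correct calibration
})
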