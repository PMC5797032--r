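test_that("noiseless 4PL data are recovered essentially exactly", {
  gen <- fourpl(100, 10, -0.5, -0.5)
  scr <- make_screen(list(CL1 = gen))
  fit <- fit_single_curve(scr)
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-8)
  expect_equal(unclass(fit$params), unclass(gen), tolerance = 1e-3)
})

test_that("fitted midpoint converts to the generating IC50", {
  gen <- fourpl(100, 10, 0, -0.5)
  fit <- fit_single_curve(make_screen(list(CL1 = gen)))
  expect_equal(ic50_concentration(fit$params), 1, tolerance = 1e-3)
})

test_that("flat data yield a non-converged fit, not an error", {
  scr <- make_screen(list(CL1 = fourpl(100, 10, -0.5, -0.5)))
  scr$response <- 100
  fit <- fit_single_curve(scr)
  expect_false(fit$converged)
  expect_null(fit$params)
})

test_that("precondition violations raise errors", {
  scr <- make_screen(list(CL1 = fourpl(100, 10, -0.5, -0.5)),
                     doses = c(0.1, 1, 10))
  expect_error(fit_single_curve(scr), "4 distinct")
  scr2 <- make_screen(list(CL1 = fourpl(100, 10, -0.5, -0.5)),
                      doses = c(0.1, 0.4, 1, 10), replicates = 1)
  expect_error(fit_single_curve(scr2), "8 observations")
})

test_that("refitting from the solution is a fixed point of the optimiser", {
  set.seed(7)
  scr <- make_screen(list(CL1 = fourpl(100, 10, -0.5, -0.5)), noise_sd = 8)
  fit <- fit_single_curve(scr)
  refit <- fit_single_curve(scr, init = fit$params)
  expect_equal(refit$rss, fit$rss, tolerance = 1e-6)
})

test_that("traditional IC50 table covers converged lines and drops failures", {
  set.seed(11)
  sim <- simulate_screen(scenario_spec(n_lines = 10), seed = 11)
  tab <- traditional_ic50_table(sim$screen)
  expect_length(tab, 10)
  expect_true(all(is.finite(tab)))

  flat <- sim$screen
  flat$response[flat$cell_line == "CL003"] <- 100
  tab2 <- traditional_ic50_table(flat)
  expect_false("CL003" %in% names(tab2))
  expect_true("CL003" %in% attr(tab2, "failed"))

  expect_error(traditional_ic50_table(sim$screen[0, ]), "empty")
  expect_error(traditional_ic50_table(sim$screen, drug = "nope"),
               "not present")
})

test_that("viability filter keeps drugs crossing strictly below threshold", {
  # hand-built table: replicate means at the top dose are 15 / 25 / 20
  mk <- function(drug, top_mean) {
    doses <- c(0.1, 0.4, 1, 10)
    means <- c(100, 80, 50, top_mean)
    data.frame(cell_line = "CL1", drug = drug,
               concentration_uM = rep(doses, each = 2),
               replicate = rep(1:2, 4),
               # replicates straddle the mean but average to it exactly
               response = rep(means, each = 2) + c(-2, 2))
  }
  scr <- dose_response_table(rbind(mk("kept", 15), mk("dropped", 25),
                                   mk("boundary", 20)))
  kept <- filter_drugs_by_min_viability(scr, threshold = 20)
  expect_setequal(kept, "kept")
})
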