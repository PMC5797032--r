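test_that("simulated screens have the specified layout", {
  spec <- scenario_spec(n_lines = 50)
  sim <- simulate_screen(spec, seed = 1)
  expect_equal(nrow(sim$screen), 50 * 3 * 9)
  expect_length(sim$expression, 50)
  expect_equal(sort(unique(table(sim$truth$group))), 25)
  expect_setequal(unique(sim$screen$concentration_uM),
                  c(0.02, 0.04, 0.1, 0.2, 0.4, 1, 2, 4, 10))
})

test_that("identical seeds reproduce the screen exactly", {
  spec <- scenario_spec(n_lines = 10)
  expect_identical(simulate_screen(spec, seed = 7),
                   simulate_screen(spec, seed = 7))
})

test_that("expression intensities follow the two group distributions", {
  spec <- scenario_spec(n_lines = 50, group2 = fourpl(100, 10, 0, -0.5))
  sim <- simulate_screen(spec, seed = 3)
  hi <- sim$expression[sim$truth$group == "group1"]
  lo <- sim$expression[sim$truth$group == "group2"]
  expect_length(hi, 25)
  expect_lt(abs(mean(hi) - 8), 3 / sqrt(25))
  expect_lt(abs(mean(lo) - 3), 3 / sqrt(25))
})

test_that("midpoint draws and well noise match the generating SDs", {
  spec <- scenario_spec(n_lines = 1000, replicates = 1)
  sim <- simulate_screen(spec, seed = 12)
  expect_gt(sd(sim$truth$xmid), 0.27)
  expect_lt(sd(sim$truth$xmid), 0.33)
  # residuals against the true per-line curves recover the noise SD
  tr <- sim$truth[match(sim$screen$cell_line, sim$truth$cell_line), ]
  mu <- tr$right + (tr$left - tr$right) /
    (1 + exp((tr$xmid - sim$screen$x) / tr$scale))
  expect_lt(abs(sd(sim$screen$response - mu) - 10), 1)
})

test_that("null scenario draws are unaffected by the group2 label", {
  base <- scenario_spec(n_lines = 10)
  same <- scenario_spec(n_lines = 10, group2 = fourpl(100, 10, -0.5, -0.5))
  expect_identical(simulate_screen(base, seed = 5),
                   simulate_screen(same, seed = 5))
})

test_that("scenario grid enumerates the study parameter levels", {
  expect_length(scenario_grid("left", 100), 4 * 4 * 3)
  expect_length(scenario_grid("scale", -0.5), 4 * 4 * 4)
  expect_length(scenario_grid(), 192)
  expect_length(scenario_grid(exclude = list(c(100, 10, -0.5, -0.5))), 191)
  expect_error(scenario_grid("slope", 1), "unknown parameter")
  expect_error(scenario_grid("left", 85), "study levels")
  g <- scenario_grid("right", 40)
  expect_true(all(vapply(g, function(s) s$group2[["right"]], numeric(1)) == 40))
  expect_true(all(vapply(g, function(s)
    identical(unclass(s$group1),
              unclass(fourpl(100, 10, -0.5, -0.5))), logical(1))))
})

test_that("invalid scenarios are rejected", {
  expect_error(scenario_spec(n_lines = 7), "even")
  expect_error(scenario_spec(doses = c(1, 1, 2)), "strictly increasing")
  expect_error(scenario_spec(noise_sd = c(1, 2)), "one value per dose")
})
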