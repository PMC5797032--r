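test_that("LLR combination and permutation p-value follow their formulas", {
  expect_equal(llr_from_loglik(-100, -40, -45), 30)
  expect_equal(perm_pvalue(0, 100), 1 / 101)
  expect_equal(perm_pvalue(100, 100), 1)
  expect_equal(perm_pvalue(0, 9999), 1e-4)
  expect_error(perm_pvalue(-1, 100))
  expect_error(perm_pvalue(5, 4))
  expect_error(perm_pvalue(0, 0))
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(rep(0.001, 345))[1], 0.345)
  expect_equal(bonferroni_adjust(c(0.5, 0.2, 0.9)), c(1, 0.6, 1))
  expect_identical(bonferroni_adjust(numeric(0)), numeric(0))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("traditional association matches the underlying stats tests", {
  v <- setNames(c(-1.2, -0.8, -0.5, -0.1, 0.3), paste0("CL", 1:5))
  out <- trad_assoc(v, v, mode = "pearson")
  expect_equal(out$estimate, 1)
  expect_lt(out$p.value, 1e-8)

  set.seed(1)
  ic <- setNames(rnorm(12), paste0("CL", 1:12))
  g <- setNames(rep(c("plus", "minus"), each = 6), paste0("CL", 1:12))
  out <- trad_assoc(ic, g, mode = "ttest")
  ref <- t.test(ic[g == "minus"], ic[g == "plus"])
  expect_equal(out$p.value, ref$p.value)
  expect_equal(abs(out$statistic), abs(unname(ref$statistic)))

  expect_error(trad_assoc(ic[1:2], setNames(rnorm(2), names(ic)[1:2]),
                          mode = "pearson"), "at least 3")
  expect_error(trad_assoc(setNames(rep(1, 5), paste0("CL", 1:5)),
                          setNames(rnorm(5), paste0("CL", 1:5))),
               "constant")
})

test_that("NLME association rejects constant conditional midpoints", {
  fake <- structure(list(converged = TRUE,
                         line_xmid = setNames(rep(-0.5, 6),
                                              paste0("CL", 1:6))),
                    class = "nlme_drc_fit")
  g <- setNames(rep(c("plus", "minus"), 3), paste0("CL", 1:6))
  expect_error(nlme_ic50_assoc(fake, g, mode = "ttest"), "constant")
})

test_that("group validation catches malformed assignments", {
  sim <- simulate_screen(scenario_spec(n_lines = 8), seed = 6)
  g <- median_split(sim$expression)
  bad <- g; bad[] <- "plus"
  expect_error(llr_statistic(sim$screen, groups = bad), "both groups")
  bad2 <- c(g, ZZZ = "plus")
  expect_error(llr_statistic(sim$screen, groups = bad2), "absent")
  expect_error(llr_statistic(sim$screen, groups = g[1:3]), "at least 2")
})

test_that("observed LLR separates true grouping from random relabelings", {
  spec <- scenario_spec(n_lines = 16, replicates = 2,
                        group2 = fourpl(100, 10, 0, -0.5))
  sim <- simulate_screen(spec, seed = 8)
  truth <- setNames(ifelse(sim$truth$group == "group1", "plus", "minus"),
                    sim$truth$cell_line)
  llr_true <- as.numeric(llr_statistic(sim$screen, groups = truth))
  expect_gt(llr_true, -1e-6)
  set.seed(99)
  llr_perm <- replicate(8, {
    g <- setNames(sample(unname(truth)), names(truth))
    as.numeric(llr_statistic(sim$screen, groups = g))
  })
  expect_gt(llr_true, median(llr_perm))
  expect_true(all(llr_perm > -1e-6))
})

test_that("omnibus permutation test is reproducible and self-consistent", {
  sim <- simulate_screen(scenario_spec(n_lines = 10, replicates = 2),
                         seed = 15)
  g <- median_split(sim$expression)
  r1 <- omnibus_perm_test(sim$screen, groups = g, n_perm = 30, seed = 5)
  r2 <- omnibus_perm_test(sim$screen, groups = g, n_perm = 30, seed = 5)
  expect_identical(r1, r2)
  expect_equal(r1$p_value, perm_pvalue(r1$exceed_count, r1$n_perm))
  expect_gte(r1$p_value, 1 / (r1$n_perm + 1))
})

test_that("early stopping halts once significance is out of reach", {
  # with n_perm = 100 and alpha = 0.05 the exceedance threshold is
  # floor(0.05 * 101) = 5: p is then at least 6/101 > 0.05
  expect_identical(floor(0.05 * 101), 5)
  expect_gt(perm_pvalue(5, 100), 0.05)
  expect_lt(perm_pvalue(4, 100), 0.05)

  sim <- simulate_screen(scenario_spec(n_lines = 10, replicates = 2),
                         seed = 16)
  g <- median_split(sim$expression)  # null: no true group difference
  r <- omnibus_perm_test(sim$screen, groups = g, n_perm = 100, seed = 21)
  if (r$stopped_early) {
    expect_equal(r$exceed_count, 5L)
    expect_lt(r$n_perm, 100L)
  }
  expect_false(r$escalated)
})

test_that("permutation level holds regardless of the noise scale", {
  for (noise in c(5, 20)) {
    rej <- 0L
    for (k in 1:15) {
      spec <- scenario_spec(n_lines = 8, replicates = 2, noise_sd = noise)
      sim <- simulate_screen(spec, seed = 400 + k)
      g <- median_split(sim$expression)
      r <- omnibus_perm_test(sim$screen, groups = g, n_perm = 19,
                             adaptive_n = NULL, seed = k)
      if (r$p_value < 0.05) rej <- rej + 1L
    }
    expect_lte(rej, 3L)  # Bin(15, 0.05): P(>3) < 0.006
  }
})
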