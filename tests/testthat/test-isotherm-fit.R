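test_that("noiseless direct curves recover K_d across the affinity range", {
  for (kd in c(10, 100, 1000, 1e4)) {
    fit <- fit_direct(direct_curve_noiseless(kd))
    expect_true(fit$converged)
    expect_equal(fit$kd, kd, tolerance = 5e-3)
    expect_equal(fit$amplitude, 100, tolerance = 1e-2)
    expect_equal(fit$baseline, 5, tolerance = 1e-2)
    expect_false(fit$low_confidence)
  }
})

test_that("a flat curve yields an amplitude interval containing zero", {
  x <- c(0, exp(seq(log(10), log(1e4), length.out = 11)))
  set.seed(3)
  cv <- titration_curve("direct_intensity", reporter = "L0",
                        fixed_concs = c(reporter = 50),
                        titrant_conc = x,
                        signal = 20 + rnorm(length(x), 0, 0.5))
  fit <- fit_direct(cv)
  expect_true(fit$amplitude_ci95[1] <= 0 || abs(fit$amplitude) < 3 * fit$resid_sd)
  pooled <- aggregate_replicates(c(fit$amplitude, -fit$amplitude, 0))
  expect_false(call_binding(pooled, fit$resid_sd)$bound)
})

test_that("truncated titrations are flagged low-confidence, not silently reported", {
  kd <- 5000
  x <- c(0, exp(seq(log(50), log(kd / 3), length.out = 9)))
  theta <- solve_binary_equilibrium(50, x, kd) / 50
  cv <- titration_curve("direct_intensity", reporter = "L0",
                        fixed_concs = c(reporter = 50),
                        titrant_conc = x, signal = 10 + 80 * theta)
  fit <- fit_direct(cv)
  expect_true(fit$low_confidence)
})

test_that("fits are invariant to the order points are supplied in", {
  cv <- direct_curve_noiseless(300)
  set.seed(11)
  perm <- sample(seq_along(cv$titrant_conc))
  cv_perm <- titration_curve("direct_intensity", reporter = "L0",
                             fixed_concs = c(reporter = 50),
                             titrant_conc = cv$titrant_conc[perm],
                             signal = cv$signal[perm])
  expect_identical(fit_direct(cv)$kd, fit_direct(cv_perm)$kd)
})

test_that("noiseless competition curves recover the shared-site fraction", {
  for (share in c(20, 50, 80, 95)) {
    sites <- two_site_system(c_bs1 = share, c_bs2 = 100 - share,
                             kd_l0 = 1000, kd_l1 = 300)
    cv <- competition_curve_noiseless(sites, kd_l1_design = 300)
    fit <- fit_competition(cv)
    st0 <- solve_competition_equilibrium(1000, 0, sites, "L0", "L1")
    truth <- 100 * st0$bound["BS1", "L0"] / sum(st0$bound[, "L0"])
    expect_true(fit$displaced)
    expect_equal(fit$percent_bs1, truth, tolerance = 2 / truth)
    # the %BS1 identity between the fitted plateaus
    expect_equal(fit$percent_bs1,
                 100 * (fit$f_start - fit$f_end) /
                   (fit$f_start - fit$f_background),
                 tolerance = 1e-8)
  }
})

test_that("a titration with no displacement is called unbound, like BTA on F and R", {
  panel <- make_reference_panel(5)
  curves <- simulate_assay(panel, "F", "tht_bta", noise_model(seed = 5))
  fits <- lapply(curves, fit_competition)
  disp <- vapply(fits, `[[`, numeric(1), "displacement")
  rsd <- sqrt(mean(vapply(fits, `[[`, numeric(1), "resid_sd")^2))
  call <- call_binding(aggregate_replicates(disp), rsd,
                       assay = "tht_bta", fibril = "F")
  expect_false(call$bound)
})

test_that("fibrils without reporter sites give no direct-assay binding call", {
  # R carries no AAR sites; the fitted amplitude must be indistinguishable
  # from zero at default noise
  panel <- make_reference_panel(9)
  curves <- simulate_assay(panel, "R", "aar_direct", noise_model(seed = 9))
  fits <- lapply(curves, fit_direct)
  amp <- vapply(fits, `[[`, numeric(1), "amplitude")
  rsd <- sqrt(mean(vapply(fits, `[[`, numeric(1), "resid_sd")^2))
  call <- call_binding(aggregate_replicates(amp), rsd,
                       assay = "aar_direct", fibril = "R")
  expect_false(call$bound)
})

test_that("replicate pooling reproduces the t-interval arithmetic", {
  agg <- aggregate_replicates(c(90, 100, 110))
  expect_equal(agg$mean, 100)
  halfwidth <- qt(0.975, 2) * 10 / sqrt(3)
  expect_equal(agg$ci95, c(100 - halfwidth, 100 + halfwidth))
  expect_equal(halfwidth, 24.84, tolerance = 1e-3)
  # identical replicates collapse to a zero-width interval
  agg0 <- aggregate_replicates(c(7, 7, 7))
  expect_equal(diff(agg0$ci95), 0)
  expect_error(aggregate_replicates(42), "at least 2")
})

test_that("95% replicate intervals cover the true K_d at the nominal rate", {
  panel <- make_reference_panel(1)
  truth <- panel$truth$MSA$kd_bs1[["AAR"]]
  hits <- 0
  n_sim <- 150
  for (s in 1:n_sim) {
    curves <- simulate_assay(panel, "MSA", "aar_direct", noise_model(seed = s))
    kd <- vapply(curves, function(cv) fit_direct(cv)$kd, numeric(1))
    ci <- aggregate_replicates(kd)$ci95
    hits <- hits + (ci[1] <= truth && truth <= ci[2])
  }
  expect_gte(hits / n_sim, 0.90)
})

test_that("degenerate competition input is rejected with a clear error", {
  x <- c(0, exp(seq(log(10), log(1e4), length.out = 9)))
  set.seed(2)
  cv <- titration_curve("competition", reporter = "L0", competitor = "L1",
                        fixed_concs = c(reporter = 1000, fibril = 500),
                        titrant_conc = x,
                        signal = rnorm(length(x), 0, 0.3), background = 0)
  expect_error(fit_competition(cv), "never bound")
  expect_error(titration_curve("competition", reporter = "L0",
                               fixed_concs = c(reporter = 1000),
                               titrant_conc = x, signal = seq_along(x)),
               "competitor")
  expect_error(titration_curve("direct_intensity", reporter = "L0",
                               fixed_concs = c(reporter = 50),
                               titrant_conc = 1:4, signal = 1:4),
               "5 points")
})
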