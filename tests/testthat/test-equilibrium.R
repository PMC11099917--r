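test_that("1:1 bound concentration matches the closed form and its limits", {
  # no ligand, no complex
  expect_identical(solve_binary_equilibrium(0, 500, 100), 0)
  # infinitely tight binding saturates all sites
  expect_equal(solve_binary_equilibrium(1000, 500, 1e-9), 500,
               tolerance = 1e-6)
  # equimolar at K_d: frozen value cross-checked against bisection
  expect_equal(solve_binary_equilibrium(100, 100, 100), 38.1966,
               tolerance = 1e-5)
  expect_equal(solve_binary_equilibrium(100, 100, 100),
               oracle_bound_11(100, 100, 100), tolerance = 1e-9)
  expect_error(solve_binary_equilibrium(-1, 10, 10), "must be")
  expect_error(solve_binary_equilibrium(10, 10, 0), "> 0")
})

test_that("quadratic solution agrees with bisection over a wide log-grid", {
  set.seed(42)
  for (i in 1:200) {
    l <- 10^runif(1, -3, 6)
    s <- 10^runif(1, -3, 6)
    k <- 10^runif(1, -3, 6)
    b <- solve_binary_equilibrium(l, s, k)
    expect_equal(b, oracle_bound_11(l, s, k), tolerance = 1e-9)
    expect_lte(b, min(l, s) * (1 + 1e-12))
  }
})

test_that("competition solver conserves mass and matches the reduced system", {
  sites <- two_site_system()
  # l1 = 0 reduces to the direct two-site problem (1-D oracle)
  st0 <- solve_competition_equilibrium(800, 0, sites, "L0", "L1")
  orc <- oracle_competition(800, 0,
                            conc = c(60, 40), kd0 = c(1000, 1000),
                            kd1 = c(300, Inf))
  expect_equal(sum(st0$bound[, "L0"]), sum(orc$bound[, 1]), tolerance = 1e-8)
  # conservation for both ligands
  st <- solve_competition_equilibrium(800, 450, sites, "L0", "L1")
  expect_lt(abs(st$free[["L0"]] + sum(st$bound[, "L0"]) - 800) / 800, 1e-8)
  expect_lt(abs(st$free[["L1"]] + sum(st$bound[, "L1"]) - 450) / 450, 1e-8)
  # per-class total bound never exceeds site concentration
  expect_lte(sum(st$bound["BS1", ]), 60 * (1 + 1e-10))
  expect_lte(sum(st$bound["BS2", ]), 40 * (1 + 1e-10))
})

test_that("excess competitor empties BS1 of reporter but not BS2", {
  # reporter in large excess, so freeing BS1-bound reporter barely perturbs
  # the free concentration and BS2 stays put
  sites <- two_site_system()
  st0 <- solve_competition_equilibrium(1e5, 0, sites, "L0", "L1")
  st_inf <- solve_competition_equilibrium(1e5, 1e10, sites, "L0", "L1")
  expect_lt(st_inf$bound["BS1", "L0"], 1e-3)
  expect_equal(st_inf$bound["BS2", "L0"], st0$bound["BS2", "L0"],
               tolerance = 1e-3)
})

test_that("identical site classes split bound reporter equally", {
  # two populations with identical L0 K_d and concentration
  sites_sym <- list(
    site_population("BS1", 50, c(L0 = 500, L1 = 100)),
    site_population("BS2", 50, c(L0 = 500))
  )
  st <- solve_competition_equilibrium(400, 0, sites_sym, "L0", "L1")
  expect_equal(st$bound["BS1", "L0"], st$bound["BS2", "L0"],
               tolerance = 1e-10)
})

test_that("reporter bound at BS1 and predicted intensity decrease with competitor", {
  sites <- two_site_system()
  l0_def <- ligand_def("L0", "reporter", "intensity", brightness_bound = 2)
  l1_grid <- c(0, 10, 50, 200, 1000, 5000, 5e4)
  bs1_bound <- numeric(0)
  intens <- numeric(0)
  for (l1 in l1_grid) {
    st <- solve_competition_equilibrium(800, l1, sites, "L0", "L1")
    bs1_bound <- c(bs1_bound, st$bound["BS1", "L0"])
    intens <- c(intens, predict_intensity(st, l0_def))
  }
  expect_true(all(diff(bs1_bound) <= 1e-9))
  expect_true(all(diff(intens) <= 1e-9))
})

test_that("signal lost at saturating competitor equals the initial BS1 share", {
  sites <- two_site_system(c_bs1 = 70, c_bs2 = 30)
  l0_def <- ligand_def("L0", "reporter", "intensity", brightness_bound = 1)
  st0 <- solve_competition_equilibrium(1000, 0, sites, "L0", "L1")
  st_inf <- solve_competition_equilibrium(1000, 1e9, sites, "L0", "L1")
  f0 <- predict_intensity(st0, l0_def)
  f_inf <- predict_intensity(st_inf, l0_def)
  share_bs1 <- st0$bound["BS1", "L0"] / sum(st0$bound[, "L0"])
  # BS2 re-equilibrates slightly as displaced reporter is freed, so the
  # identity holds to the size of that second-order effect
  expect_equal((f0 - f_inf) / f0, share_bs1, tolerance = 0.02)
})

test_that("intensity prediction sums bright bound reporter and ignores dark ligands", {
  sites <- list(site_population("BS1", 20, c(L0 = 1e-6, L1 = 1e-6)))
  st <- solve_competition_equilibrium(10, 5, sites, "L0", "L1")
  bright <- ligand_def("L0", "reporter", "intensity", brightness_bound = 5)
  dark <- ligand_def("L1", "competitor", "dark")
  total_bound_l0 <- sum(st$bound[, "L0"])
  expect_equal(predict_intensity(st, list(bright, dark)),
               5 * total_bound_l0, tolerance = 1e-8)
  # with nothing bound and dark free reporter the signal is zero
  empty <- solve_competition_equilibrium(0, 0, sites, "L0", "L1")
  expect_equal(predict_intensity(empty, list(bright, dark)), 0)
})

test_that("anisotropy interpolates between free and bound limits", {
  bta <- ligand_def("BTA", "reporter", "anisotropy",
                    r_free = 0.05, r_bound = 0.25)
  sites_none <- list(site_population("BS1", 100, c(other = 10)))
  st_free <- solve_direct_equilibrium(50, sites_none, "BTA")
  expect_equal(predict_anisotropy(st_free, bta), 0.05)
  sites_tight <- list(site_population("BS1", 1000, c(BTA = 1e-9)))
  st_bound <- solve_direct_equilibrium(50, sites_tight, "BTA")
  expect_equal(predict_anisotropy(st_bound, bta), 0.25, tolerance = 1e-6)
  # half bound -> midpoint
  st <- solve_direct_equilibrium(50, sites_tight, "BTA")
  st$bound[1, 1] <- 10
  st$free[["BTA"]] <- 10
  expect_equal(predict_anisotropy(st, bta), 0.15)
  # no ligand at all is undefined
  st_none <- solve_direct_equilibrium(0, sites_tight, "BTA")
  expect_error(predict_anisotropy(st_none, bta), "undefined")
})

test_that("competition solver matches the brute-force oracle on random systems", {
  set.seed(7)
  for (i in 1:60) {
    conc <- 10^runif(2, 0, 2.5)
    kd0 <- 10^runif(2, 0, 4)
    kd1 <- c(10^runif(1, 0, 4), Inf)
    l0 <- 10^runif(1, 0, 4)
    l1 <- 10^runif(1, 0, 4)
    sites <- list(site_population("BS1", conc[1], c(A = kd0[1], B = kd1[1])),
                  site_population("BS2", conc[2], c(A = kd0[2])))
    st <- solve_competition_equilibrium(l0, l1, sites, "A", "B")
    orc <- oracle_competition(l0, l1, conc, kd0, kd1)
    expect_lt(abs(st$free[["A"]] - orc$free[1]), 1e-8 * max(l0, 1))
    expect_lt(abs(sum(st$bound[, "B"]) - sum(orc$bound[, 2])),
              1e-8 * max(l1, 1))
  }
})

test_that("type constructors enforce their invariants", {
  expect_error(ligand_def("X", brightness_free = -1), ">= 0")
  expect_error(ligand_def("X", signal_mode = "anisotropy",
                          r_free = 0.3, r_bound = 0.2), "r_free")
  expect_error(site_population("BS1", -5, c(L0 = 10)), ">= 0")
  expect_error(site_population("BS1", 5, c(L0 = 0)), "> 0")
  ligs <- default_ligands()
  expect_error(
    fibril_model("bad", list(site_population("BS2", 10, c(OXI = 100))), ligs),
    "BS2"
  )
  # duplicate (class, signature) populations are rejected
  expect_error(
    fibril_model("dup", list(site_population("BS1", 10, c(ThT = 100)),
                             site_population("BS1", 20, c(ThT = 200)))),
    "one population"
  )
})
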