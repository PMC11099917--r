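# Shared fixtures built in code.

noiseless <- function(seed = 1L) {
  noise_model(sigma_rel = 0, sigma_abs = 0, sigma_abs_anisotropy = 0,
              replicates = 1L, seed = seed)
}

# Two-population test fibril: a BS1 class shared with the competitor and a
# reporter-only BS2 class.
two_site_system <- function(c_bs1 = 60, c_bs2 = 40,
                            kd_l0 = 1000, kd_l1 = 300) {
  list(
    site_population("BS1", c_bs1, c(L0 = kd_l0, L1 = kd_l1)),
    site_population("BS2", c_bs2, c(L0 = kd_l0))
  )
}

# Noise-free direct titration curve generated straight from the exact 1:1
# solution (independent of the simulator module).
direct_curve_noiseless <- function(kd, l_fix = 50, amplitude = 100,
                                   baseline = 5, n = 12) {
  x <- c(0, exp(seq(log(kd / 30), log(30 * kd), length.out = n)))
  theta <- solve_binary_equilibrium(l_fix, x, kd) / l_fix
  titration_curve("direct_intensity", reporter = "L0",
                  fixed_concs = c(reporter = l_fix),
                  titrant_conc = x, signal = baseline + amplitude * theta)
}

# Noise-free competition curve generated from the full two-site competition
# equilibrium (the model the fitter approximates with a 1:1 isotherm).
competition_curve_noiseless <- function(sites, kd_l1_design = 300,
                                        l0_total = 1000, n = 12) {
  x <- c(0, exp(seq(log(kd_l1_design / 30), log(30 * kd_l1_design),
                    length.out = n)))
  l0_def <- ligand_def("L0", "reporter", "intensity", brightness_bound = 1)
  y <- vapply(x, function(xi) {
    st <- solve_competition_equilibrium(l0_total, xi, sites, "L0", "L1")
    predict_intensity(st, l0_def)
  }, numeric(1))
  titration_curve("competition", reporter = "L0", competitor = "L1",
                  fixed_concs = c(reporter = l0_total, fibril = 500),
                  titrant_conc = x, signal = y, background = 0)
}
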