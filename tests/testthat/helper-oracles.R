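# Independent numerical oracles: plain bisection on the mass-balance
# residuals, sharing no code with the package solvers.

# 1:1 equilibrium: bisect on the bound concentration b in [0, min(L, S)]
# where the mass-action residual (L - b)(S - b) - kd * b is decreasing in b.
oracle_bound_11 <- function(l_total, s_total, kd, iters = 100) {
  if (l_total == 0 || s_total == 0) return(0)
  g <- function(b) (l_total - b) * (s_total - b) - kd * b
  lo <- 0
  hi <- min(l_total, s_total)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Two-ligand competition over site populations: nested bisection written
# from scratch. conc: site concentrations; kd0/kd1: per-site K_d for the two
# ligands (Inf = no binding). Returns free concentrations and per-site bound
# amounts for both ligands.
oracle_competition <- function(l0_total, l1_total, conc, kd0, kd1,
                               iters = 90) {
  site_bound <- function(f0, f1) {
    den <- 1 + ifelse(is.finite(kd0), f0 / kd0, 0) +
      ifelse(is.finite(kd1), f1 / kd1, 0)
    b0 <- ifelse(is.finite(kd0), conc * (f0 / kd0) / den, 0)
    b1 <- ifelse(is.finite(kd1), conc * (f1 / kd1) / den, 0)
    cbind(b0, b1)
  }
  free0_given <- function(f1) {
    if (l0_total == 0) return(0)
    g <- function(f0) f0 + sum(site_bound(f0, f1)[, 1]) - l0_total
    lo <- 0; hi <- l0_total
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  if (l1_total == 0) {
    f1 <- 0
  } else {
    g1 <- function(f1) f1 + sum(site_bound(free0_given(f1), f1)[, 2]) - l1_total
    lo <- 0; hi <- l1_total
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (g1(mid) > 0) hi <- mid else lo <- mid
    }
    f1 <- (lo + hi) / 2
  }
  f0 <- free0_given(f1)
  list(free = c(f0, f1), bound = site_bound(f0, f1))
}

# Textbook paired t-test: mean difference over its standard error.
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  list(t = t_stat, p = p)
}
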