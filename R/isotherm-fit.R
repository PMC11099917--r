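#' Construct a titration curve (one assay replicate)
#'
#' Holds one replicate of a binding titration: the titrant concentration
#' series, the fixed-component concentrations, and the observed signal
#' (fluorescence intensity in arbitrary units, or anisotropy). Points are
#' sorted by titrant concentration; fitting is therefore invariant to the
#' order in which points are supplied.
#'
#' In direct assays the fibril binding sites are titrated into a fixed
#' concentration of the reporter, so the signal tracks the bound fraction of
#' the reporter from 0 to 1. In competition assays the dark competitor (L1)
#' is titrated into a fixed mixture of fibril and reporter (L0).
#'
#' @param assay_kind `"direct_intensity"`, `"direct_anisotropy"` or
#'   `"competition"`.
#' @param reporter Reporter ligand name (L0).
#' @param competitor Competitor ligand name (L1); required for competition.
#' @param fixed_concs Named numeric vector of fixed concentrations in nM,
#'   e.g. `c(reporter = 1000, fibril = 500)`.
#' @param titrant_conc Titrant concentration series, nM (>= 0, no duplicates,
#'   at least 5 points).
#' @param signal Observed signal series, same length as `titrant_conc`.
#' @param replicate_id Replicate label.
#' @param background Optional signal of the free reporter with no fibril
#'   (used as the free-reporter reference in the %BS1 calculation).
#' @return An object of class `titration_curve`.
#' @export
titration_curve <- function(assay_kind = c("direct_intensity",
                                           "direct_anisotropy",
                                           "competition"),
                            reporter, competitor = NA_character_,
                            fixed_concs, titrant_conc, signal,
                            replicate_id = "r1", background = NULL) {
  assay_kind <- match.arg(assay_kind)
  if (length(titrant_conc) != length(signal)) {
    stop("titrant_conc and signal must have equal length", call. = FALSE)
  }
  if (length(titrant_conc) < 5) {
    stop("a titration needs at least 5 points", call. = FALSE)
  }
  if (any(titrant_conc < 0)) stop("titrant concentrations must be >= 0", call. = FALSE)
  ord <- order(titrant_conc)
  titrant_conc <- titrant_conc[ord]
  signal <- signal[ord]
  if (any(diff(titrant_conc) <= 0)) {
    stop("titrant series must be strictly increasing (no duplicate points)",
         call. = FALSE)
  }
  if (assay_kind == "competition" && (is.na(competitor) || !nzchar(competitor))) {
    stop("competition curves must name a competitor", call. = FALSE)
  }
  structure(
    list(assay_kind = assay_kind, reporter = reporter, competitor = competitor,
         fixed_concs = fixed_concs, titrant_conc = titrant_conc,
         signal = signal, replicate_id = replicate_id, background = background),
    class = "titration_curve"
  )
}

## Fraction of the fixed reporter bound when `sites` nM of binding sites are
## present (direct assays), or fraction of competitor-accessible sites
## occupied when `l1` nM competitor is present (competition assays). Both are
## the exact depletion-aware quadratic, not the free-ligand hyperbola.
theta_ligand_bound <- function(sites, l_fix, kd) {
  solve_binary_equilibrium(l_fix, sites, kd) / l_fix
}
theta_site_occupancy <- function(l1, s_tot, kd) {
  solve_binary_equilibrium(l1, s_tot, kd) / s_tot
}

## Shared least-squares driver: minpack.lm trust-region fits from a small
## deterministic grid of log-K_d starts, lowest RMSE wins.
run_multistart <- function(resid_fun, start_list, lower = NULL, upper = NULL) {
  best <- NULL
  for (st in start_list) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, fn = resid_fun, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  best
}

fit_se <- function(fit, n) {
  p <- length(fit$par)
  df <- max(n - p, 1)
  sigma2 <- fit$deviance / df
  vc <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  if (is.null(vc)) {
    ## singular information matrix: the parameters are unidentifiable from
    ## this curve, which is honestly reported as infinite uncertainty
    vc <- matrix(Inf, p, p, dimnames = list(names(fit$par), names(fit$par)))
  } else {
    dimnames(vc) <- list(names(fit$par), names(fit$par))
  }
  list(vcov = vc, df = df, sigma = sqrt(sigma2))
}

ci_from_se <- function(est, se, df) {
  if (is.na(se)) return(c(NA_real_, NA_real_))
  tq <- stats::qt(0.975, df)
  c(est - tq * se, est + tq * se)
}

#' Fit a direct titration to a 1:1 binding isotherm
#'
#' Least-squares fit of `signal = baseline + amplitude * theta` where `theta`
#' is the exact (depletion-aware) quadratic bound fraction of the fixed
#' reporter as fibril sites are titrated. For an intensity assay the baseline
#' is the free-reporter signal; for an anisotropy assay the baseline estimates
#' `r_free` and the amplitude `r_bound - r_free`.
#'
#' Three deterministic starts on a log-K_d grid are tried
#' (trust-region Levenberg-Marquardt, lowest RMSE wins). If the maximum
#' titrant concentration is below `K_d / 2` the fit is flagged low-confidence:
#' the plateau is unobserved and wide intervals are expected.
#'
#' @param curve A [titration_curve()] with `assay_kind` `"direct_intensity"`
#'   or `"direct_anisotropy"`.
#' @return An object of class `direct_fit`: fields `kd`, `amplitude`,
#'   `baseline`, `kd_ci95`, `amplitude_ci95`, `rmse`, `converged`,
#'   `low_confidence`, `replicate_id`.
#' @export
fit_direct <- function(curve) {
  stopifnot(inherits(curve, "titration_curve"))
  if (!curve$assay_kind %in% c("direct_intensity", "direct_anisotropy")) {
    stop("fit_direct needs a direct_intensity or direct_anisotropy curve",
         call. = FALSE)
  }
  x <- curve$titrant_conc
  y <- curve$signal
  if (length(x) < 5) stop("a titration needs at least 5 points", call. = FALSE)
  l_fix <- curve$fixed_concs[["reporter"]]
  if (is.null(l_fix) || !is.finite(l_fix) || l_fix <= 0) {
    stop("direct fit needs fixed_concs['reporter'] > 0", call. = FALSE)
  }

  resid_fun <- function(par) {
    th <- theta_ligand_bound(x, l_fix, exp(par[["log_kd"]]))
    y - (par[["baseline"]] + par[["amplitude"]] * th)
  }
  gm <- exp(mean(log(x[x > 0])))
  starts <- lapply(c(0.1, 1, 10) * gm, function(k0) {
    c(baseline = min(y), amplitude = max(y) - min(y), log_kd = log(k0))
  })
  fit <- run_multistart(resid_fun, starts)
  n <- length(y)
  if (is.null(fit)) {
    return(structure(list(kd = NA_real_, amplitude = NA_real_,
                          baseline = NA_real_, kd_ci95 = c(NA, NA),
                          amplitude_ci95 = c(NA, NA), rmse = NA_real_,
                          converged = FALSE, low_confidence = TRUE,
                          diagnostics = "all starts failed",
                          replicate_id = curve$replicate_id,
                          assay_kind = curve$assay_kind, n = n),
                     class = "direct_fit"))
  }
  se <- fit_se(fit, n)
  kd <- exp(fit$par[["log_kd"]])
  kd_ci <- exp(ci_from_se(fit$par[["log_kd"]],
                          sqrt(se$vcov["log_kd", "log_kd"]), se$df))
  amp_ci <- ci_from_se(fit$par[["amplitude"]],
                       sqrt(se$vcov["amplitude", "amplitude"]), se$df)
  structure(
    list(kd = kd, amplitude = fit$par[["amplitude"]],
         baseline = fit$par[["baseline"]],
         kd_ci95 = kd_ci, amplitude_ci95 = amp_ci,
         rmse = sqrt(fit$deviance / n),
         resid_sd = se$sigma,
         converged = fit$info %in% 1:4,
         low_confidence = max(x) < kd / 2,
         diagnostics = fit$message,
         replicate_id = curve$replicate_id,
         assay_kind = curve$assay_kind, n = n),
    class = "direct_fit"
  )
}

#' Fit a competition (displacement) titration
#'
#' Least-squares fit of
#' `signal = f_end + (f_start - f_end) * (1 - theta(l1; K_d_app))`,
#' where `theta` is the exact 1:1 bound fraction of the competitor-accessible
#' sites (depletion-aware; the accessible-site concentration is a fitted
#' parameter). The shared-site fraction is computed from the start and the
#' fitted limiting end fluorescence:
#' `percent_bs1 = 100 * (f_start - f_end) / (f_start - f_background)`.
#'
#' A curve is declared "no displacement" when the 95% CI of
#' `f_start - f_end` includes 0 or the displacement is smaller than three
#' residual standard deviations; the apparent competitor K_d is then reported
#' as `NA`.
#'
#' @param curve A [titration_curve()] with `assay_kind = "competition"`.
#' @param f_background Signal of the free reporter alone. Defaults to the
#'   curve's measured no-fibril `background` when present, else 0 (dark free
#'   reporter).
#' @param model `"auto"` (default: depletion-aware quadratic, falling back to
#'   its hyperbola limit unless the extra site-concentration parameter is
#'   supported by an F-test), `"depletion"`, or `"hyperbola"`. Replicates of
#'   one assay should be fitted with a common variant (see [fit_panel()]),
#'   since the two parameterisations report the apparent K_d on slightly
#'   different scales.
#' @return An object of class `competition_fit`: fields `kd_l1`, `f_start`,
#'   `f_end`, `f_background`, `percent_bs1`, `kd_ci95`, `percent_bs1_ci95`,
#'   `displacement` (`f_start - f_end`), `displacement_ci95`, `displaced`,
#'   `rmse`, `converged`, `replicate_id`.
#' @export
fit_competition <- function(curve, f_background = NULL,
                            model = c("auto", "depletion", "hyperbola")) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "titration_curve"))
  if (curve$assay_kind != "competition") {
    stop("fit_competition needs a competition curve", call. = FALSE)
  }
  x <- curve$titrant_conc
  y <- curve$signal
  if (length(x) < 5) stop("a titration needs at least 5 points", call. = FALSE)
  if (is.null(f_background)) {
    f_background <- if (!is.null(curve$background)) mean(curve$background) else 0
  }
  fib <- curve$fixed_concs[["fibril"]]
  s1_0 <- if (!is.null(fib) && is.finite(fib) && fib > 0) 0.2 * fib else 100
  n <- length(y)

  ## Depletion-aware model (accessible-site concentration s1 fitted) and its
  ## s1 -> 0 hyperbola limit. When the titrant far exceeds the sites the two
  ## coincide and s1 is unidentifiable, so the extra parameter is kept only
  ## if it reduces the residual sum of squares significantly (F-test, 5%).
  resid_dep <- function(par) {
    th <- theta_site_occupancy(x, exp(par[["log_s1"]]), exp(par[["log_kd"]]))
    y - (par[["f_end"]] + (par[["f_start"]] - par[["f_end"]]) * (1 - th))
  }
  resid_hyp <- function(par) {
    th <- x / (exp(par[["log_kd"]]) + x)
    y - (par[["f_end"]] + (par[["f_start"]] - par[["f_end"]]) * (1 - th))
  }
  pos <- x[x > 0]
  gm <- if (length(pos)) exp(mean(log(pos))) else 1
  starts_dep <- lapply(c(0.1, 1, 10) * gm, function(k0) {
    c(f_start = y[1], f_end = y[length(y)], log_kd = log(k0), log_s1 = log(s1_0))
  })
  starts_hyp <- lapply(c(0.1, 1, 10) * gm, function(k0) {
    c(f_start = y[1], f_end = y[length(y)], log_kd = log(k0))
  })
  ## f_start / f_end are anchored to the observed signal range (plus a
  ## margin): on a flat no-displacement curve the isotherm is unidentifiable
  ## and unbounded plateaus would otherwise run away.
  pad <- (max(y) - min(y)) + 0.05 * (abs(stats::median(y)) + 1)
  lo <- min(y) - pad
  hi <- max(y) + pad
  fit_dep <- if (model != "hyperbola") {
    run_multistart(resid_dep, starts_dep,
                   lower = c(lo, lo, -Inf, -Inf),
                   upper = c(hi, hi, Inf, Inf))
  }
  fit_hyp <- if (model != "depletion") {
    run_multistart(resid_hyp, starts_hyp,
                   lower = c(lo, lo, -Inf),
                   upper = c(hi, hi, Inf))
  }
  fit <- fit_hyp
  variant <- "hyperbola"
  if (model == "depletion") {
    fit <- fit_dep
    variant <- "depletion"
  } else if (model == "auto" && !is.null(fit_dep) && !is.null(fit_hyp) &&
             n > 4) {
    fstat <- (fit_hyp$deviance - fit_dep$deviance) /
      max(fit_dep$deviance / (n - 4), .Machine$double.xmin)
    if (is.finite(fstat) && fstat > stats::qf(0.95, 1, n - 4)) {
      fit <- fit_dep
      variant <- "depletion"
    }
  } else if (is.null(fit_hyp)) {
    fit <- fit_dep
    variant <- "depletion"
  }
  if (is.null(fit)) {
    return(structure(list(kd_l1 = NA_real_, f_start = NA_real_,
                          f_end = NA_real_, f_background = f_background,
                          percent_bs1 = NA_real_, kd_ci95 = c(NA, NA),
                          percent_bs1_ci95 = c(NA, NA),
                          displacement = NA_real_,
                          displacement_ci95 = c(NA, NA), displaced = NA,
                          displacement_observed = NA_real_,
                          variant = NA_character_,
                          model_deviances = c(depletion = NA_real_,
                                              hyperbola = NA_real_),
                          low_confidence = TRUE,
                          rmse = NA_real_, converged = FALSE,
                          diagnostics = "all starts failed",
                          replicate_id = curve$replicate_id, n = n),
                     class = "competition_fit"))
  }
  se <- fit_se(fit, n)
  f_start <- fit$par[["f_start"]]
  f_end <- fit$par[["f_end"]]
  if (is.finite(f_start) && f_start - f_background <= 3 * se$sigma) {
    stop("degenerate competition assay: start fluorescence does not exceed ",
         "the free-reporter background (reporter never bound)", call. = FALSE)
  }
  disp <- f_start - f_end
  v <- se$vcov
  disp_se <- sqrt(v["f_start", "f_start"] + v["f_end", "f_end"] -
                    2 * v["f_start", "f_end"])
  disp_ci <- ci_from_se(disp, disp_se, se$df)
  displaced <- is.finite(disp_ci[1]) && (disp_ci[1] > 0 || disp_ci[2] < 0) &&
    abs(disp) >= 3 * se$sigma
  pb <- 100 * disp / (f_start - f_background)
  pb <- min(max(pb, 0), 100)
  ## delta method for the %BS1 interval
  gs <- (f_end - f_background) / (f_start - f_background)^2
  ge <- -1 / (f_start - f_background)
  pb_se <- 100 * sqrt(max(
    gs^2 * v["f_start", "f_start"] + ge^2 * v["f_end", "f_end"] +
      2 * gs * ge * v["f_start", "f_end"], 0))
  pb_ci <- ci_from_se(pb, pb_se, se$df)
  kd <- exp(fit$par[["log_kd"]])
  kd_ci <- exp(ci_from_se(fit$par[["log_kd"]],
                          sqrt(v["log_kd", "log_kd"]), se$df))
  s1_hat <- if ("log_s1" %in% names(fit$par)) exp(fit$par[["log_s1"]]) else 0
  ## fraction of the limiting displacement realised at the largest titrant
  ## concentration actually measured: the basis for the binding call, so an
  ## extrapolated plateau far beyond the titration range cannot manufacture
  ## displacement evidence
  theta_max <- if (variant == "depletion") {
    theta_site_occupancy(max(x), s1_hat, kd)
  } else {
    max(x) / (kd + max(x))
  }
  structure(
    list(kd_l1 = if (displaced) kd else NA_real_,
         kd_l1_raw = kd,
         f_start = f_start, f_end = f_end, f_background = f_background,
         percent_bs1 = pb, kd_ci95 = kd_ci, percent_bs1_ci95 = pb_ci,
         displacement = disp, displacement_ci95 = disp_ci,
         displaced = displaced,
         displacement_observed = disp * theta_max,
         ## apparent K_d on the plain 1:1 isotherm scale (half-displacement
         ## point): the stable measure for cross-fibril comparisons
         kd_hyperbola = if (!is.null(fit_hyp)) {
           exp(fit_hyp$par[["log_kd"]])
         } else {
           NA_real_
         },
         variant = variant,
         model_deviances = c(
           depletion = if (!is.null(fit_dep)) fit_dep$deviance else NA_real_,
           hyperbola = if (!is.null(fit_hyp)) fit_hyp$deviance else NA_real_),
         low_confidence = max(x) < kd / 2,
         s1 = s1_hat,
         rmse = sqrt(fit$deviance / n), resid_sd = se$sigma,
         converged = fit$info %in% 1:4,
         diagnostics = fit$message,
         replicate_id = curve$replicate_id, n = n),
    class = "competition_fit"
  )
}

#' Pool replicate parameter estimates with a t-based 95% confidence interval
#'
#' Mean of the per-replicate estimates with
#' `CI = mean +/- t(0.975, n - 1) * sd / sqrt(n)`, mirroring reporting of
#' titration parameters as the average of at least three experimental
#' measurements with 95% confidence intervals.
#'
#' @param values Numeric vector of per-replicate parameter estimates
#'   (length >= 2).
#' @return A list with `mean`, `sd`, `se`, `n`, `ci95` (length-2 vector).
#' @examples
#' aggregate_replicates(c(90, 100, 110))  # 100 +/- 24.84
#' @export
aggregate_replicates <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) {
    stop("need at least 2 finite replicate estimates to form a confidence interval",
         call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  se <- s / sqrt(n)
  tq <- stats::qt(0.975, n - 1)
  list(mean = m, sd = s, se = se, n = n, ci95 = c(m - tq * se, m + tq * se))
}
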