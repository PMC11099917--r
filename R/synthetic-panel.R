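#' Replicate noise model for simulated titrations
#'
#' Gaussian measurement noise emulating plate-reader scatter across at least
#' three experimental measurements: each simulated signal is
#' `prediction * (1 + N(0, sigma_rel)) + N(0, sigma_abs)`. The absolute floor
#' is specified in intensity units; anisotropy curves use the separate
#' `sigma_abs_anisotropy` floor matched to the anisotropy dynamic range.
#'
#' @param sigma_rel Fractional signal noise (default 0.02).
#' @param sigma_abs Absolute noise floor, intensity units (default 0.5).
#' @param sigma_abs_anisotropy Absolute floor for anisotropy signals
#'   (default 0.002).
#' @param replicates Number of replicates (default 3).
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_rel = 0.02, sigma_abs = 0.5,
                        sigma_abs_anisotropy = 0.002,
                        replicates = 3L, seed = 1L) {
  stopifnot(sigma_rel >= 0, sigma_abs >= 0, sigma_abs_anisotropy >= 0,
            replicates >= 1)
  structure(list(sigma_rel = sigma_rel, sigma_abs = sigma_abs,
                 sigma_abs_anisotropy = sigma_abs_anisotropy,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "noise_model")
}

## Deterministic 31-bit polynomial string hash used to derive independent,
## reproducible RNG streams per (seed, fibril, assay). The multiplier keeps
## every intermediate product well inside exact double-precision integers.
hash31 <- function(...) {
  s <- paste(c(...), collapse = "\r")
  h <- 5381
  for (b in utf8ToInt(s)) {
    h <- (h * 1031 + b) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Base parameterisation of the eight-polymorph reference panel. K_d values
## (nM) are drawn around these bases subject to the qualitative profile:
## absent entry = no binding. Site concentrations are for 500 nM monomer.
panel_base_table <- function() {
  list(
    #          cA  cB   AAR   S5H   BTA
    F    = list(c_bs1 = 90, c_bs2 = 10, aar = 500,  s5h = NA,  bta = NA),
    R    = list(c_bs1 = 35, c_bs2 = 65, aar = NA,   s5h = NA,  bta = NA),
    f65  = list(c_bs1 = 95, c_bs2 = 5,  aar = 500,  s5h = NA,  bta = 600),
    f91  = list(c_bs1 = 85, c_bs2 = 15, aar = NA,   s5h = 800, bta = 600),
    f110 = list(c_bs1 = 40, c_bs2 = 60, aar = 500,  s5h = NA,  bta = 600),
    PD   = list(c_bs1 = 90, c_bs2 = 10, aar = 600,  s5h = 200, bta = 600),
    MSA  = list(c_bs1 = 88, c_bs2 = 12, aar = 250,  s5h = 800, bta = 600),
    DLB  = list(c_bs1 = 92, c_bs2 = 8,  aar = 1000, s5h = 700, bta = 600)
  )
}

## Assay-level titrant grids: a zero-titrant start point (anchoring the
## start fluorescence) plus 12 points log-spaced from K_d/30 to 30 K_d of
## the design (base) K_d of the relevant ligand. Direct assays titrate
## reporter-accessible fibril sites; competition assays titrate L1.
panel_grids <- function() {
  design_kd <- c(aar_direct = 500, tht_s5h = 400, tht_bta = 600,
                 tht_oxi = 500, tht_thr = 400, aar_tht = 1000,
                 bta_direct = 600, tht_direct = 1000)
  lapply(design_kd, function(k) {
    c(0, exp(seq(log(k / 30), log(30 * k), length.out = 12)))
  })
}

#' Generate the ground-truth eight-polymorph reference panel
#'
#' Builds eight [fibril_model()] objects (`F`, `R`, `f65`, `f91`, `f110`,
#' `PD`, `MSA`, `DLB`) whose site populations reproduce the qualitative
#' ligand profile of the panel: AAR binds all but R and f91; S5H displaces
#' ThT only from f91 and the PMCA-derived fibrils; BTA displaces ThT from all
#' but F and R; the ThT-site fraction shared with OXI is low for R and f110
#' and high otherwise, with f65 above f110; the apparent S5H K_d is lowest
#' for PD; and the AAR K_d is lower for MSA than for DLB (and distinct from
#' PD). Exact K_d magnitudes are drawn log-normally (sdlog 0.1) around fixed
#' bases in the 0.1-10 uM range, so that different seeds give the same
#' qualitative profile with different quantitative draws; the jitter is small
#' relative to the ordinal gaps so the orderings above hold for every seed.
#'
#' @param seed Integer seed for the parameter draws.
#' @return An object of class `panel_spec`: `fibrils` (named list of
#'   [fibril_model()]), `ligands`, `assays` (registry data.frame), `grids`
#'   (titrant series per assay), `fixed` (fixed concentrations), and `truth`
#'   (per-fibril ground-truth parameters, binding calls and shared-site
#'   fractions).
#' @export
make_reference_panel <- function(seed = 1L) {
  base <- panel_base_table()
  ligands <- default_ligands()
  registry <- assay_registry()
  grids <- panel_grids()

  fibrils <- list()
  truth <- list()
  with_seed(hash31("panel", seed), {
    for (nm in names(base)) {
      b <- base[[nm]]
      jit <- function(v, sdlog) v * exp(stats::rnorm(1, 0, sdlog))
      c_bs1 <- jit(b$c_bs1, 0.05)
      c_bs2 <- jit(b$c_bs2, 0.05)
      kd_bs1 <- c(ThT = jit(1000, 0.1), OXI = jit(500, 0.1), ThR = jit(400, 0.1))
      kd_bs2 <- c(ThT = kd_bs1[["ThT"]])
      if (!is.na(b$aar)) {
        aar_kd <- jit(b$aar, 0.1)
        kd_bs1[["AAR"]] <- aar_kd
        kd_bs2[["AAR"]] <- aar_kd
      }
      if (!is.na(b$s5h)) kd_bs1[["S5H"]] <- jit(b$s5h, 0.1)
      if (!is.na(b$bta)) kd_bs1[["BTA"]] <- jit(b$bta, 0.1)
      sites <- list(site_population("BS1", c_bs1, kd_bs1),
                    site_population("BS2", c_bs2, kd_bs2))
      fibrils[[nm]] <- fibril_model(nm, sites, ligands)
      truth[[nm]] <- list(
        c_bs1 = c_bs1, c_bs2 = c_bs2,
        kd_bs1 = kd_bs1, kd_bs2 = kd_bs2,
        percent_bs1 = 100 * c_bs1 / (c_bs1 + c_bs2),
        binds = c(AAR = !is.na(b$aar), S5H = !is.na(b$s5h),
                  BTA = !is.na(b$bta), OXI = TRUE, ThR = TRUE, ThT = TRUE)
      )
    }
  })

  structure(
    list(fibrils = fibrils, ligands = ligands, assays = registry,
         grids = grids,
         fixed = c(fibril_monomer = 500, reporter_competition = 1000,
                   reporter_direct = 100),
         seed = as.integer(seed), truth = truth),
    class = "panel_spec"
  )
}

## Concentration of sites on `model` accessible to `ligand` (finite K_d).
accessible_sites <- function(model, ligand) {
  sum(vapply(model$sites, function(s) {
    if (ligand %in% names(s$kd)) s$concentration else 0
  }, numeric(1)))
}

scale_sites <- function(model, factor) {
  lapply(model$sites, function(s) {
    site_population(s$site_class, s$concentration * factor, s$kd)
  })
}

#' Ground-truth shared-site fraction of a panel fibril
#'
#' The fraction (in percent) of bound reporter sitting on sites accessible to
#' the competitor, computed from the equilibrium solution at zero competitor.
#' This is the quantity the start/end-fluorescence calculation in
#' [fit_competition()] estimates.
#'
#' @param panel A `panel_spec`.
#' @param fibril Fibril name.
#' @param assay_id A competition assay id from the panel registry.
#' @return Percentage in `[0, 100]`.
#' @export
true_percent_bs1 <- function(panel, fibril, assay_id) {
  row <- panel$assays[panel$assays$assay_id == assay_id, ]
  if (nrow(row) != 1 || row$kind != "competition") {
    stop("assay_id must name a registered competition assay", call. = FALSE)
  }
  model <- panel$fibrils[[fibril]]
  if (is.null(model)) stop("unknown fibril: ", fibril, call. = FALSE)
  st <- solve_competition_equilibrium(
    panel$fixed[["reporter_competition"]], 0, model$sites,
    l0 = row$reporter, l1 = row$competitor)
  acc <- vapply(model$sites, function(s) row$competitor %in% names(s$kd),
                logical(1))
  b <- st$bound_by_population[, row$reporter]
  if (sum(b) <= 0) return(NA_real_)
  100 * sum(b[acc]) / sum(b)
}

forward_signal <- function(panel, fibril, assay_row, titrant) {
  model <- panel$fibrils[[fibril]]
  ligands <- panel$ligands
  rep_lig <- ligands[[assay_row$reporter]]
  if (assay_row$kind == "competition") {
    l0 <- panel$fixed[["reporter_competition"]]
    vapply(titrant, function(x) {
      st <- solve_competition_equilibrium(l0, x, model$sites,
                                          l0 = assay_row$reporter,
                                          l1 = assay_row$competitor)
      predict_intensity(st, ligands)
    }, numeric(1))
  } else {
    l_fix <- panel$fixed[["reporter_direct"]]
    acc <- accessible_sites(model, assay_row$reporter)
    vapply(titrant, function(x) {
      if (acc <= 0) {
        ## non-binder: the titrant axis is nominal, nothing ever binds
        st <- solve_direct_equilibrium(l_fix, model$sites, assay_row$reporter)
      } else {
        st <- solve_direct_equilibrium(l_fix, scale_sites(model, x / acc),
                                       assay_row$reporter)
      }
      if (assay_row$kind == "direct_anisotropy") {
        predict_anisotropy(st, rep_lig)
      } else {
        predict_intensity(st, rep_lig)
      }
    }, numeric(1))
  }
}

#' Simulate replicate titration curves for one fibril and assay
#'
#' Forward-models the assay with the exact equilibrium solvers and adds
#' Gaussian replicate noise:
#' `signal = prediction * (1 + N(0, sigma_rel)) + N(0, sigma_abs)`.
#' The RNG stream is derived deterministically from
#' `(noise$seed, fibril, assay_id)`, so the same seed gives byte-identical
#' curves and different assays are independent.
#'
#' For direct assays the titrant axis is the concentration of
#' reporter-accessible fibril binding sites (nM, proportional to the fibril
#' mass added) titrated into fixed reporter; for competition assays the
#' competitor is titrated into fixed fibril (500 nM monomer) plus reporter
#' (1000 nM).
#'
#' @param panel A `panel_spec` from [make_reference_panel()].
#' @param fibril Fibril name in the panel.
#' @param assay_id Assay id from the panel registry.
#' @param noise A [noise_model()].
#' @return List of [titration_curve()] objects, one per replicate.
#' @export
simulate_assay <- function(panel, fibril, assay_id, noise = noise_model()) {
  stopifnot(inherits(panel, "panel_spec"), inherits(noise, "noise_model"))
  if (!fibril %in% names(panel$fibrils)) {
    stop("unknown fibril: ", fibril, call. = FALSE)
  }
  row <- panel$assays[panel$assays$assay_id == assay_id, ]
  if (nrow(row) != 1) stop("unknown assay: ", assay_id, call. = FALSE)
  grid <- panel$grids[[assay_id]]
  pred <- forward_signal(panel, fibril, row, grid)
  s_abs <- if (row$kind == "direct_anisotropy") {
    noise$sigma_abs_anisotropy
  } else {
    noise$sigma_abs
  }
  fixed <- if (row$kind == "competition") {
    c(reporter = unname(panel$fixed[["reporter_competition"]]),
      fibril = unname(panel$fixed[["fibril_monomer"]]))
  } else {
    c(reporter = unname(panel$fixed[["reporter_direct"]]))
  }
  with_seed(hash31(noise$seed, fibril, assay_id), {
    lapply(seq_len(noise$replicates), function(r) {
      y <- pred * (1 + stats::rnorm(length(pred), 0, noise$sigma_rel)) +
        stats::rnorm(length(pred), 0, s_abs)
      titration_curve(
        assay_kind = row$kind, reporter = row$reporter,
        competitor = row$competitor, fixed_concs = fixed,
        titrant_conc = grid, signal = y,
        replicate_id = sprintf("r%d", r),
        background = 0
      )
    })
  })
}

#' Simulate a full titration dataset for a fibril panel
#'
#' Runs [simulate_assay()] for every (fibril, assay) combination and returns
#' the long-format titration table used by the CSV interface: one row per
#' (replicate, titrant point).
#'
#' @param panel A `panel_spec`.
#' @param noise A [noise_model()].
#' @param assays Character vector of assay ids; defaults to the four assays
#'   of the strain-typing protocol.
#' @param fibrils Fibril names; defaults to the whole panel.
#' @return A data.frame with columns `assay_id`, `fibril`, `assay_kind`,
#'   `reporter`, `competitor`, `fibril_conc_nM`, `reporter_conc_nM`,
#'   `titrant_nM`, `signal`, `replicate`.
#' @export
simulate_panel <- function(panel, noise = noise_model(),
                           assays = protocol_assays(),
                           fibrils = names(panel$fibrils)) {
  out <- list()
  for (fb in fibrils) {
    for (aid in assays) {
      row <- panel$assays[panel$assays$assay_id == aid, ]
      curves <- simulate_assay(panel, fb, aid, noise)
      for (cv in curves) {
        out[[length(out) + 1L]] <- data.frame(
          assay_id = aid, fibril = fb, assay_kind = cv$assay_kind,
          reporter = cv$reporter,
          competitor = if (is.na(row$competitor)) "" else row$competitor,
          fibril_conc_nM = if (cv$assay_kind == "competition")
            cv$fixed_concs[["fibril"]] else NA_real_,
          reporter_conc_nM = cv$fixed_concs[["reporter"]],
          titrant_nM = cv$titrant_conc, signal = cv$signal,
          replicate = cv$replicate_id,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' The four assays of the strain-typing protocol
#'
#' AAR direct titration, then ThT competition assays against S5H, BTA and
#' OXI: the minimal panel that distinguishes all eight fibril morphologies.
#'
#' @return Character vector of assay ids.
#' @export
protocol_assays <- function() {
  c("aar_direct", "tht_s5h", "tht_bta", "tht_oxi")
}
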