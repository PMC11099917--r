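#' Define a ligand used in fluorescence binding assays
#'
#' A ligand is either a reporter (the fluorescent species whose signal is
#' monitored, "L0" in a competition assay) or a competitor (a dark species
#' titrated to displace the reporter, "L1"). Solvatochromic reporters such as
#' thioflavin T (ThT) and AAR are read out by fluorescence intensity;
#' non-solvatochromic reporters such as BTA are read out by fluorescence
#' anisotropy.
#'
#' @param name Short ligand identifier, e.g. `"ThT"`, `"AAR"`, `"BTA"`,
#'   `"OXI"`, `"S5H"`, `"ThR"`.
#' @param role `"reporter"` or `"competitor"`.
#' @param signal_mode `"intensity"`, `"anisotropy"` or `"dark"`.
#' @param brightness_free,brightness_bound Fluorescence per unit concentration
#'   (arbitrary units / nM) of the free and bound ligand. For solvatochromic
#'   reporters `brightness_bound > brightness_free`.
#' @param r_free,r_bound Anisotropy of the free and bound states
#'   (dimensionless, anisotropy mode only); must satisfy
#'   `0 <= r_free <= r_bound <= 0.4`.
#' @return An object of class `ligand_def`.
#' @examples
#' tht <- ligand_def("ThT", "reporter", "intensity", brightness_bound = 1)
#' @export
ligand_def <- function(name,
                       role = c("reporter", "competitor"),
                       signal_mode = c("intensity", "anisotropy", "dark"),
                       brightness_free = 0,
                       brightness_bound = 0,
                       r_free = NA_real_,
                       r_bound = NA_real_) {
  role <- match.arg(role)
  signal_mode <- match.arg(signal_mode)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (brightness_free < 0 || brightness_bound < 0) {
    stop("brightness values must be >= 0", call. = FALSE)
  }
  if (signal_mode == "anisotropy") {
    if (is.na(r_free) || is.na(r_bound)) {
      stop("anisotropy-mode ligands need r_free and r_bound", call. = FALSE)
    }
    if (!(r_free >= 0 && r_free <= r_bound && r_bound <= 0.4)) {
      stop("require 0 <= r_free <= r_bound <= 0.4", call. = FALSE)
    }
  }
  structure(
    list(name = name, role = role, signal_mode = signal_mode,
         brightness_free = brightness_free, brightness_bound = brightness_bound,
         r_free = r_free, r_bound = r_bound),
    class = "ligand_def"
  )
}

#' Define a binding-site population on a fibril
#'
#' A fibril polymorph carries classes of small-molecule binding sites. In a
#' competition assay, BS1 denotes sites accessible to both the reporter L0 and
#' the competitor L1, and BS2 denotes sites accessible only to L0. A ligand
#' with no `kd` entry does not bind the population (dissociation constant
#' infinite).
#'
#' @param site_class `"BS1"` or `"BS2"`.
#' @param concentration Site concentration in nM (>= 0).
#' @param kd Named numeric vector of dissociation constants in nM
#'   (all > 0), names are ligand names.
#' @return An object of class `site_population`.
#' @export
site_population <- function(site_class = c("BS1", "BS2"), concentration, kd) {
  site_class <- match.arg(site_class)
  stopifnot(is.numeric(concentration), length(concentration) == 1L)
  if (concentration < 0) stop("site concentration must be >= 0", call. = FALSE)
  kd <- unlist(kd)
  if (length(kd) > 0 && (is.null(names(kd)) || any(!nzchar(names(kd))))) {
    stop("kd must be a named vector (ligand name -> K_d in nM)", call. = FALSE)
  }
  if (any(kd <= 0)) stop("all K_d must be > 0", call. = FALSE)
  structure(
    list(site_class = site_class, concentration = concentration, kd = kd),
    class = "site_population"
  )
}

#' Define a fibril polymorph as a collection of site populations
#'
#' Houses the per-polymorph ground truth used by the simulator: each fibril is
#' a named list of [site_population()] objects.
#'
#' @param name Polymorph label (`"F"`, `"R"`, `"f65"`, `"f91"`, `"f110"`,
#'   `"PD"`, `"MSA"`, `"DLB"`, or a synthetic label).
#' @param sites List of [site_population()] objects.
#' @param ligands Optional list of [ligand_def()] objects; when given, the
#'   constructor checks that no BS2 population carries a K_d entry for a
#'   competitor ligand.
#' @return An object of class `fibril_model`.
#' @export
fibril_model <- function(name, sites, ligands = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.list(sites) || length(sites) == 0 ||
      !all(vapply(sites, inherits, logical(1), "site_population"))) {
    stop("sites must be a non-empty list of site_population objects", call. = FALSE)
  }
  sig <- vapply(sites, function(s) {
    paste0(s$site_class, "|", paste(sort(names(s$kd)), collapse = ","))
  }, character(1))
  if (anyDuplicated(sig)) {
    stop("at most one population per (site_class, ligand signature)", call. = FALSE)
  }
  if (!is.null(ligands)) {
    comp <- vapply(ligands, function(l) l$name, character(1))[
      vapply(ligands, function(l) l$role == "competitor", logical(1))]
    for (s in sites) {
      if (s$site_class == "BS2" && any(names(s$kd) %in% comp)) {
        stop("a BS2 population cannot bind a competitor ligand", call. = FALSE)
      }
    }
  }
  structure(list(name = name, sites = sites), class = "fibril_model")
}

#' Exact bound concentration for a 1:1 binding equilibrium
#'
#' Solves the single-site mass balance
#' \eqn{b^2 - (L + S + K_d) b + L S = 0} for the physically meaningful root,
#' the exact (ligand-depletion aware) solution underlying a 1:1 binding
#' isotherm. The numerically stable form \eqn{b = 2LS / (p + \sqrt{p^2 - 4LS})}
#' with \eqn{p = L + S + K_d} avoids cancellation for tight binding.
#'
#' @param l_total Total ligand concentration, nM (vectorised).
#' @param s_total Total site concentration, nM.
#' @param kd Dissociation constant, nM (> 0).
#' @return Bound complex concentration in nM, `0 <= bound <= min(l_total, s_total)`.
#' @examples
#' solve_binary_equilibrium(100, 100, 100)  # 38.1966 nM
#' @export
solve_binary_equilibrium <- function(l_total, s_total, kd) {
  if (any(l_total < 0) || any(s_total < 0) || any(kd < 0)) {
    stop("concentrations and K_d must be >= 0", call. = FALSE)
  }
  if (any(kd == 0)) stop("K_d must be > 0", call. = FALSE)
  p <- l_total + s_total + kd
  disc <- p * p - 4 * l_total * s_total
  disc[disc < 0] <- 0  # guard tiny negative from roundoff
  b <- 2 * l_total * s_total / (p + sqrt(disc))
  pmin(b, pmin(l_total, s_total))
}

## Free-ligand concentration for one ligand binding several independent site
## populations: root of f + sum_i S_i f / (K_i + f) = total, monotone in f.
free_single_ligand <- function(l_total, conc, kd) {
  keep <- is.finite(kd) & conc > 0
  conc <- conc[keep]; kd <- kd[keep]
  if (l_total == 0) return(0)
  if (length(conc) == 0) return(l_total)
  resid <- function(f) f + sum(conc * f / (kd + f)) - l_total
  if (resid(l_total) <= 0) return(l_total)
  stats::uniroot(resid, lower = 0, upper = l_total,
                 tol = .Machine$double.eps^0.75 * max(l_total, 1))$root
}

site_matrices <- function(sites, ligand_names) {
  conc <- vapply(sites, `[[`, numeric(1), "concentration")
  kd <- vapply(ligand_names, function(nm) {
    vapply(sites, function(s) {
      if (nm %in% names(s$kd)) s$kd[[nm]] else Inf
    }, numeric(1))
  }, numeric(length(sites)))
  kd <- matrix(kd, nrow = length(sites),
               dimnames = list(NULL, ligand_names))
  list(conc = conc, kd = kd,
       class = vapply(sites, `[[`, character(1), "site_class"))
}

new_species_state <- function(free, bound_pop, sites, ligand_names) {
  cls <- vapply(sites, `[[`, character(1), "site_class")
  conc <- vapply(sites, `[[`, numeric(1), "concentration")
  classes <- unique(cls)
  bound <- matrix(0, nrow = length(classes), ncol = length(ligand_names),
                  dimnames = list(classes, ligand_names))
  occ <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    idx <- which(cls == cl)
    bound[cl, ] <- colSums(bound_pop[idx, , drop = FALSE])
    occ[[cl]] <- sum(bound_pop[idx, , drop = FALSE]) / max(sum(conc[idx]), .Machine$double.xmin)
  }
  structure(
    list(free = free, bound = bound, bound_by_population = bound_pop,
         occupancy = occ, site_class = cls, site_conc = conc),
    class = "species_state"
  )
}

competition_residual <- function(free, conc, kd, totals) {
  ## free, totals: length-2 (L0, L1); kd: n_sites x 2; conc: n_sites
  den <- 1 + (free[1] / kd[, 1]) + (free[2] / kd[, 2])
  bound <- cbind(conc * (free[1] / kd[, 1]) / den,
                 conc * (free[2] / kd[, 2]) / den)
  bound[!is.finite(bound)] <- 0
  list(resid = free + colSums(bound) - totals, bound = bound, den = den)
}

#' Solve a two-ligand competitive binding equilibrium
#'
#' Solves the coupled mass balances for a reporter (L0) and a competitor (L1)
#' over a set of independent site populations, with mutually exclusive
#' (competitive) occupancy within each population. The primary path is a
#' damped Newton iteration on log-transformed free concentrations with an
#' analytic Jacobian; if it fails to converge the solver falls back to nested
#' bisection (outer root-find on free L1, inner on free L0), which is
#' guaranteed for this monotone system.
#'
#' @param l0_total,l1_total Total concentrations of reporter and competitor, nM.
#' @param sites List of [site_population()] objects carrying per-ligand K_d
#'   entries; a missing entry means no binding.
#' @param l0,l1 Ligand names keying into the site K_d maps.
#' @param tol Convergence tolerance on the relative mass-balance residual.
#' @param maxit Maximum Newton iterations before falling back.
#' @return An object of class `species_state` with elements `free` (named
#'   vector, nM), `bound` (site-class x ligand matrix, nM),
#'   `bound_by_population`, and `occupancy` (per site class, in `[0, 1]`).
#' @export
solve_competition_equilibrium <- function(l0_total, l1_total, sites, l0, l1,
                                          tol = 1e-10, maxit = 100L) {
  if (l0_total < 0 || l1_total < 0) stop("totals must be >= 0", call. = FALSE)
  if (length(sites) == 0) stop("need at least one site population", call. = FALSE)
  sm <- site_matrices(sites, c(l0, l1))
  totals <- c(l0_total, l1_total)
  scale <- pmax(totals, 1)

  solved_free <- c(NA_real_, NA_real_)
  if (l0_total == 0 || l1_total == 0) {
    solved_free <- c(
      if (l0_total == 0) 0 else NA_real_,
      if (l1_total == 0) 0 else NA_real_
    )
    j <- which(totals > 0)
    for (k in j) {
      solved_free[k] <- free_single_ligand(totals[k], sm$conc, sm$kd[, k])
    }
    if (length(j) == 0) solved_free <- c(0, 0)
  } else {
    ## damped Newton on x = log(free)
    x <- log(totals)
    converged <- FALSE
    r <- competition_residual(exp(x), sm$conc, sm$kd, totals)
    for (it in seq_len(maxit)) {
      if (max(abs(r$resid) / scale) < tol) { converged <- TRUE; break }
      f <- exp(x)
      den2 <- r$den^2
      ## d resid_j / d f_k, then chain rule to log space (multiply by f_k)
      j11 <- 1 + sum(sm$conc / sm$kd[, 1] * (1 + f[2] / sm$kd[, 2]) / den2, na.rm = TRUE)
      j22 <- 1 + sum(sm$conc / sm$kd[, 2] * (1 + f[1] / sm$kd[, 1]) / den2, na.rm = TRUE)
      j12 <- -sum(sm$conc * (f[1] / sm$kd[, 1]) / sm$kd[, 2] / den2, na.rm = TRUE)
      j21 <- -sum(sm$conc * (f[2] / sm$kd[, 2]) / sm$kd[, 1] / den2, na.rm = TRUE)
      jac <- matrix(c(j11 * f[1], j12 * f[2], j21 * f[1], j22 * f[2]),
                    2, 2, byrow = TRUE)
      step <- tryCatch(solve(jac, -r$resid), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      ## damping: halve until the residual norm decreases
      lam <- 1
      ok <- FALSE
      for (h in 1:40) {
        xn <- x + lam * step
        rn <- competition_residual(exp(xn), sm$conc, sm$kd, totals)
        if (all(is.finite(rn$resid)) &&
            sum((rn$resid / scale)^2) < sum((r$resid / scale)^2)) {
          x <- xn; r <- rn; ok <- TRUE; break
        }
        lam <- lam / 2
      }
      if (!ok) break
    }
    if (converged) {
      solved_free <- exp(x)
    } else {
      ## nested bisection fallback: for fixed f1, f0 solves its own monotone
      ## mass balance; the outer residual in f1 changes sign on [0, l1_total]
      inner_f0 <- function(f1) {
        resid0 <- function(f0) {
          competition_residual(c(f0, f1), sm$conc, sm$kd, totals)$resid[1]
        }
        if (resid0(l0_total) <= 0) return(l0_total)
        stats::uniroot(resid0, lower = 0, upper = l0_total,
                       tol = .Machine$double.eps^0.75 * scale[1])$root
      }
      outer <- function(f1) {
        competition_residual(c(inner_f0(f1), f1), sm$conc, sm$kd, totals)$resid[2]
      }
      if (outer(l1_total) <= 0) {
        f1 <- l1_total
      } else {
        f1 <- stats::uniroot(outer, lower = 0, upper = l1_total,
                             tol = .Machine$double.eps^0.75 * scale[2])$root
      }
      solved_free <- c(inner_f0(f1), f1)
      r <- competition_residual(solved_free, sm$conc, sm$kd, totals)
      if (max(abs(r$resid) / scale) > 1e-6) {
        stop(sprintf(
          "competition solver did not converge (relative residuals %.3g, %.3g)",
          r$resid[1] / scale[1], r$resid[2] / scale[2]), call. = FALSE)
      }
    }
  }

  r <- competition_residual(solved_free, sm$conc, sm$kd, totals)
  bound_pop <- r$bound
  colnames(bound_pop) <- c(l0, l1)
  st <- new_species_state(stats::setNames(solved_free, c(l0, l1)),
                          bound_pop, sites, c(l0, l1))
  st
}

#' Solve a direct (single-ligand) binding equilibrium over site populations
#'
#' One-ligand specialisation of [solve_competition_equilibrium()]: the exact
#' two-site (or n-site) generalisation of the 1:1 mass balance.
#'
#' @param l_total Total ligand concentration, nM.
#' @param sites List of [site_population()] objects.
#' @param ligand Ligand name keying into the site K_d maps.
#' @return A `species_state` for the single ligand.
#' @export
solve_direct_equilibrium <- function(l_total, sites, ligand) {
  if (l_total < 0) stop("total must be >= 0", call. = FALSE)
  sm <- site_matrices(sites, ligand)
  f <- free_single_ligand(l_total, sm$conc, sm$kd[, 1])
  den <- 1 + f / sm$kd[, 1]
  bound <- matrix(sm$conc * (f / sm$kd[, 1]) / den, ncol = 1)
  bound[!is.finite(bound)] <- 0
  colnames(bound) <- ligand
  new_species_state(stats::setNames(f, ligand), bound, sites, ligand)
}

#' Predict observed fluorescence intensity from a solved binding state
#'
#' Total intensity is the sum over intensity-mode reporter ligands of
#' `brightness_bound * (bound at all site classes) + brightness_free * free`;
#' dark competitor ligands contribute nothing. Bound-state brightness is taken
#' to be identical across site classes (see the package vignette), which is
#' what makes the start/end-fluorescence calculation of the shared-site
#' fraction valid.
#'
#' @param state A `species_state`.
#' @param ligands A list of [ligand_def()] objects (or a single one).
#' @return Fluorescence in arbitrary units.
#' @export
predict_intensity <- function(state, ligands) {
  stopifnot(inherits(state, "species_state"))
  if (inherits(ligands, "ligand_def")) ligands <- list(ligands)
  total <- 0
  for (lg in ligands) {
    if (lg$signal_mode != "intensity") next
    if (!lg$name %in% colnames(state$bound)) next
    b <- sum(state$bound[, lg$name])
    f <- state$free[[lg$name]]
    total <- total + lg$brightness_bound * b + lg$brightness_free * f
  }
  total
}

#' Predict observed fluorescence anisotropy from a solved binding state
#'
#' Population-weighted anisotropy under the equal-quantum-yield assumption:
#' `r_obs = r_free + (r_bound - r_free) * f_bound`, with `f_bound` the bound
#' fraction of the ligand.
#'
#' @param state A `species_state`.
#' @param ligand An anisotropy-mode [ligand_def()].
#' @return Anisotropy (dimensionless).
#' @export
predict_anisotropy <- function(state, ligand) {
  stopifnot(inherits(state, "species_state"), inherits(ligand, "ligand_def"))
  if (ligand$signal_mode != "anisotropy") {
    stop("predict_anisotropy needs an anisotropy-mode ligand", call. = FALSE)
  }
  b <- sum(state$bound[, ligand$name])
  f <- state$free[[ligand$name]]
  if (b + f <= 0) {
    stop("anisotropy undefined: no ligand present (bound + free = 0)", call. = FALSE)
  }
  fb <- b / (b + f)
  ligand$r_free + (ligand$r_bound - ligand$r_free) * fb
}

#' @export
print.species_state <- function(x, ...) {
  cat("Binding equilibrium state\n")
  cat("  free (nM):", paste(sprintf("%s = %.4g", names(x$free), x$free),
                            collapse = ", "), "\n")
  cat("  bound (nM) by site class:\n")
  print(round(x$bound, 4))
  invisible(x)
}
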