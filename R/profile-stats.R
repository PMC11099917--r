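#' Binary binding call from pooled replicate fits
#'
#' A ligand is called "bound" when the pooled evidence (direct-assay
#' amplitude, or start-minus-end displacement for a competition assay) has a
#' 95% confidence interval excluding zero AND a magnitude of at least three
#' pooled residual standard deviations. Absence of a bar in a binding-panel
#' figure corresponds to `bound = FALSE`.
#'
#' @param pooled Pooled estimate from [aggregate_replicates()] of the
#'   per-replicate amplitude (direct) or displacement (competition).
#' @param resid_sd Pooled residual standard deviation of the fits.
#' @param assay Assay identifier (metadata).
#' @param fibril Fibril name (metadata).
#' @return An object of class `binding_call` with fields `assay`, `fibril`,
#'   `bound`, `evidence` (estimate, CI, residual SD) and `rule`.
#' @export
call_binding <- function(pooled, resid_sd, assay = NA_character_,
                         fibril = NA_character_) {
  if (is.null(pooled$ci95) || any(!is.finite(pooled$ci95))) {
    stop("binding call needs a pooled estimate with a finite confidence interval",
         call. = FALSE)
  }
  ci_excludes_zero <- pooled$ci95[1] > 0 || pooled$ci95[2] < 0
  big_enough <- abs(pooled$mean) >= 3 * resid_sd
  structure(
    list(assay = assay, fibril = fibril,
         bound = ci_excludes_zero && big_enough,
         evidence = list(estimate = pooled$mean, ci95 = pooled$ci95,
                         n = pooled$n, resid_sd = resid_sd),
         rule = "95% CI excludes 0 and |estimate| >= 3 * residual SD"),
    class = "binding_call"
  )
}

#' Two-sided paired t-test on replicate parameter estimates
#'
#' Compares a binding parameter (K_d or %BS1) between two fibrils, pairing
#' measurements by replicate index:
#' `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`, two-sided p.
#' Degenerate zero-variance differences with nonzero mean are flagged and the
#' p-value is floored at 1e-12 rather than reported as NaN; identical series
#' give `t = 0, p = 1`.
#'
#' @param values_a,values_b Equal-length numeric vectors (n >= 2), paired by
#'   replicate index.
#' @param alpha Significance level (default 0.05).
#' @param fibril_a,fibril_b Optional fibril names (metadata).
#' @param parameter Optional parameter label, e.g. `"kd"` or `"percent_bs1"`.
#' @return An object of class `paired_test_result` with fields `t_stat`,
#'   `p_value`, `n_pairs`, `significant`, `degenerate`.
#' @export
paired_t_test <- function(values_a, values_b, alpha = 0.05,
                          fibril_a = NA_character_, fibril_b = NA_character_,
                          parameter = NA_character_) {
  n <- length(values_a)
  if (n != length(values_b)) {
    stop("paired series must have equal length", call. = FALSE)
  }
  if (n < 2) stop("paired t-test needs at least 2 pairs", call. = FALSE)
  d <- values_a - values_b
  degenerate <- FALSE
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      t_stat <- 0
      p <- 1
    } else {
      degenerate <- TRUE
      t_stat <- sign(mean(d)) * Inf
      p <- 1e-12
    }
  } else {
    tt <- stats::t.test(values_a, values_b, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(
    list(fibril_a = fibril_a, fibril_b = fibril_b, parameter = parameter,
         t_stat = t_stat, p_value = p, n_pairs = n,
         significant = p < alpha, alpha = alpha, degenerate = degenerate),
    class = "paired_test_result"
  )
}

#' Holm correction for a list of paired test results
#'
#' The headline comparisons report raw paired-t p-values; this optional
#' helper applies Holm's step-down adjustment across a family of tests and
#' re-evaluates the significance flags.
#'
#' @param tests List of `paired_test_result` objects.
#' @param alpha Family significance level.
#' @return The list with `p_adjusted` added and `significant` recomputed.
#' @export
adjust_tests_holm <- function(tests, alpha = 0.05) {
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  padj <- stats::p.adjust(p, method = "holm")
  for (i in seq_along(tests)) {
    tests[[i]]$p_adjusted <- padj[i]
    tests[[i]]$significant <- padj[i] < alpha
  }
  tests
}

#' Assemble a per-fibril ligand binding profile
#'
#' Combines the binary binding calls of the four protocol assays with the
#' quantitative features (shared-site class for the ThT/OXI assay and
#' significance-backed K_d rank classes) into the feature vector consumed by
#' [classify()]. Ordinal features only assert orderings backed by significant
#' pairwise tests; pairs without significant differences are recorded as
#' indistinguishable (class `NA`).
#'
#' @param fibril Fibril name.
#' @param calls Named list of [call_binding()] results for the assays
#'   `aar_direct`, `tht_s5h`, `tht_bta`, `tht_oxi`.
#' @param oxi_bs1 Pooled %BS1 estimate for the ThT/OXI assay (or `NA`).
#' @param oxi_bs1_class `"high"`, `"low"` or `NA`.
#' @param s5h_kd_class,aar_kd_class `"lowest"`, `"other"` or `NA`.
#' @param kd Optional named vector of pooled K_d estimates (metadata).
#' @return An object of class `ligand_profile`.
#' @export
build_profile <- function(fibril, calls, oxi_bs1 = NA_real_,
                          oxi_bs1_class = NA_character_,
                          s5h_kd_class = NA_character_,
                          aar_kd_class = NA_character_,
                          kd = NULL) {
  required <- protocol_assays()
  missing <- setdiff(required, names(calls))
  if (length(missing) > 0) {
    stop("incomplete profile for ", fibril, ": missing assay(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  binary <- vapply(calls[required], `[[`, logical(1), "bound")
  structure(
    list(fibril = fibril,
         binary = binary,
         features = list(
           aar_bind = binary[["aar_direct"]],
           s5h_bind = binary[["tht_s5h"]],
           bta_bind = binary[["tht_bta"]],
           oxi_bind = binary[["tht_oxi"]],
           oxi_bs1_class = oxi_bs1_class,
           s5h_kd_class = s5h_kd_class,
           aar_kd_class = aar_kd_class
         ),
         oxi_bs1 = oxi_bs1, kd = kd, calls = calls),
    class = "ligand_profile"
  )
}

#' @export
print.ligand_profile <- function(x, ...) {
  cat("Ligand profile:", x$fibril, "\n")
  cat("  binary:",
      paste(sprintf("%s=%s", names(x$binary),
                    ifelse(x$binary, "+", "-")), collapse = " "), "\n")
  cat(sprintf("  OXI %%BS1: %.1f (%s)\n",
              x$oxi_bs1, x$features$oxi_bs1_class))
  cat("  S5H Kd class:", x$features$s5h_kd_class,
      "| AAR Kd class:", x$features$aar_kd_class, "\n")
  invisible(x)
}
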