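## Build titration_curve objects from the long-format titration table,
## one per (fibril, assay, replicate). Validates the schema and reports the
## offending rows by number.
curves_from_table <- function(df) {
  required <- c("assay_id", "fibril", "assay_kind", "reporter", "competitor",
                "fibril_conc_nM", "reporter_conc_nM", "titrant_nM", "signal",
                "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("titration table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("titration table is empty", call. = FALSE)
  if (any(!is.finite(df$titrant_nM))) {
    stop("non-numeric titrant_nM at row(s) ",
         paste(utils::head(which(!is.finite(df$titrant_nM)), 5), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$fibril, df$assay_id, df$replicate, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    sub <- df[rows, ]
    if (anyDuplicated(sub$titrant_nM)) {
      stop(sprintf(
        "duplicate titrant concentrations for fibril %s, assay %s, replicate %s (rows %s)",
        sub$fibril[1], sub$assay_id[1], sub$replicate[1],
        paste(utils::head(rows, 5), collapse = ", ")), call. = FALSE)
    }
    fixed <- c(reporter = sub$reporter_conc_nM[1])
    if (is.finite(sub$fibril_conc_nM[1])) {
      fixed[["fibril"]] <- sub$fibril_conc_nM[1]
    }
    comp <- sub$competitor[1]
    if (is.null(comp) || is.na(comp) || !nzchar(comp)) comp <- NA_character_
    out[[length(out) + 1L]] <- list(
      fibril = sub$fibril[1], assay_id = sub$assay_id[1],
      curve = titration_curve(
        assay_kind = sub$assay_kind[1], reporter = sub$reporter[1],
        competitor = comp, fixed_concs = fixed,
        titrant_conc = sub$titrant_nM, signal = sub$signal,
        replicate_id = as.character(sub$replicate[1]), background = 0)
    )
  }
  out
}

pooled_resid_sd <- function(fits) {
  s <- vapply(fits, function(f) f$resid_sd, numeric(1))
  sqrt(mean(s[is.finite(s)]^2))
}

## Fit all replicates of one (fibril, assay) and pool.
fit_assay_replicates <- function(fibril, assay_id, curves) {
  kind <- curves[[1]]$assay_kind
  if (length(curves) < 2) {
    stop(sprintf(
      "fibril %s, assay %s: %d replicate(s); at least 2 are needed to form confidence intervals",
      fibril, assay_id, length(curves)), call. = FALSE)
  }
  if (kind == "competition") {
    fits <- lapply(curves, fit_competition)
    ## choose the isotherm variant (depletion-aware vs hyperbola limit) once
    ## per assay with a pooled F-test over all replicates: the two variants
    ## report the apparent K_d on slightly different scales, so mixing them
    ## across replicates would inflate the replicate variance
    dev <- vapply(fits, `[[`, numeric(2), "model_deviances")
    n_rep <- length(fits)
    n_pt <- fits[[1]]$n
    variant <- "hyperbola"
    if (all(is.finite(dev)) && n_pt > 4) {
      df2 <- n_rep * (n_pt - 4)
      fstat <- ((sum(dev["hyperbola", ]) - sum(dev["depletion", ])) / n_rep) /
        max(sum(dev["depletion", ]) / df2, .Machine$double.xmin)
      if (is.finite(fstat) && fstat > stats::qf(0.95, n_rep, df2)) {
        variant <- "depletion"
      }
    }
    ## the apparent K_d used for cross-fibril comparisons is always the
    ## half-displacement point of the plain 1:1 isotherm, which is far more
    ## stable replicate-to-replicate than the depletion-variant K_d (whose
    ## correlation with the fitted site concentration inflates its variance)
    kd <- vapply(fits, `[[`, numeric(1), "kd_hyperbola")
    for (i in seq_along(fits)) {
      if (!identical(fits[[i]]$variant, variant)) {
        fits[[i]] <- fit_competition(curves[[i]], model = variant)
      }
    }
    ## the binding call rests on the fluorescence change realised over the
    ## measured titrant range; the fitted limiting plateau feeds %BS1
    disp <- vapply(fits, `[[`, numeric(1), "displacement_observed")
    pb <- vapply(fits, `[[`, numeric(1), "percent_bs1")
    rsd <- pooled_resid_sd(fits)
    pooled_disp <- aggregate_replicates(disp)
    call <- call_binding(pooled_disp, rsd, assay = assay_id, fibril = fibril)
    res <- list(fibril = fibril, assay_id = assay_id, kind = kind,
                fits = fits, call = call,
                evidence = pooled_disp, resid_sd = rsd,
                kd_replicates = kd,
                kd = if (call$bound) aggregate_replicates(kd) else NULL,
                percent_bs1_replicates = pb,
                percent_bs1 = if (call$bound) aggregate_replicates(pb) else NULL)
  } else {
    fits <- lapply(curves, fit_direct)
    amp <- vapply(fits, `[[`, numeric(1), "amplitude")
    kd <- vapply(fits, `[[`, numeric(1), "kd")
    rsd <- pooled_resid_sd(fits)
    pooled_amp <- aggregate_replicates(amp)
    call <- call_binding(pooled_amp, rsd, assay = assay_id, fibril = fibril)
    res <- list(fibril = fibril, assay_id = assay_id, kind = kind,
                fits = fits, call = call,
                evidence = pooled_amp, resid_sd = rsd,
                kd_replicates = kd,
                kd = if (call$bound) aggregate_replicates(kd) else NULL)
  }
  structure(res, class = "assay_result")
}

#' Fit every titration in a long-format dataset
#'
#' Fits each replicate curve (direct or competition, as flagged) and pools
#' the replicates per (fibril, assay): binary binding calls, pooled K_d and
#' %BS1 with t-based 95% confidence intervals.
#'
#' @param df Long-format titration table (see [simulate_panel()] /
#'   [read_titrations()]).
#' @return Nested list: `results[[fibril]][[assay_id]]` of class
#'   `assay_result`.
#' @export
fit_panel <- function(df) {
  items <- curves_from_table(df)
  key <- vapply(items, function(it) paste(it$fibril, it$assay_id, sep = "\r"),
                character(1))
  results <- list()
  for (k in unique(key)) {
    sel <- items[key == k]
    fb <- sel[[1]]$fibril
    aid <- sel[[1]]$assay_id
    results[[fb]][[aid]] <- fit_assay_replicates(fb, aid,
                                                 lapply(sel, `[[`, "curve"))
  }
  results
}

## Assign high/low shared-site classes across the panel: split the pooled
## %BS1 values at the largest gap, provided the fibrils adjacent to the gap
## differ significantly (paired t on per-replicate %BS1).
oxi_bs1_classes <- function(results, alpha) {
  fibs <- names(results)
  displaced <- fibs[vapply(fibs, function(fb) {
    r <- results[[fb]][["tht_oxi"]]
    !is.null(r) && isTRUE(r$call$bound)
  }, logical(1))]
  cls <- stats::setNames(rep(NA_character_, length(fibs)), fibs)
  if (length(displaced) < 2) return(cls)
  means <- vapply(displaced, function(fb) {
    results[[fb]][["tht_oxi"]]$percent_bs1$mean
  }, numeric(1))
  ord <- order(means)
  gaps <- diff(means[ord])
  g <- which.max(gaps)
  lo_fib <- displaced[ord][g]
  hi_fib <- displaced[ord][g + 1]
  tt <- paired_t_test(results[[lo_fib]][["tht_oxi"]]$percent_bs1_replicates,
                      results[[hi_fib]][["tht_oxi"]]$percent_bs1_replicates,
                      alpha = alpha, fibril_a = lo_fib, fibril_b = hi_fib,
                      parameter = "percent_bs1")
  if (!tt$significant) {
    cls[displaced] <- "high"
    return(cls)
  }
  cut <- (means[ord][g] + means[ord][g + 1]) / 2
  cls[displaced] <- ifelse(means[displaced] < cut, "low", "high")
  cls
}

## "lowest" rank class within a group: the member with the smallest pooled
## K_d, provided its per-replicate estimates are significantly lower than
## every other member's (paired t). Members of groups where the ordering is
## not significance-backed stay NA (indistinguishable).
lowest_kd_class <- function(results, members, assay_id, alpha) {
  cls <- stats::setNames(rep(NA_character_, length(members)), members)
  bound <- members[vapply(members, function(fb) {
    r <- results[[fb]][[assay_id]]
    !is.null(r) && isTRUE(r$call$bound)
  }, logical(1))]
  if (length(bound) < 2) return(cls)
  means <- vapply(bound, function(fb) mean(results[[fb]][[assay_id]]$kd_replicates),
                  numeric(1))
  cand <- bound[which.min(means)]
  others <- setdiff(bound, cand)
  sig <- vapply(others, function(fb) {
    tt <- paired_t_test(results[[cand]][[assay_id]]$kd_replicates,
                        results[[fb]][[assay_id]]$kd_replicates,
                        alpha = alpha, fibril_a = cand, fibril_b = fb,
                        parameter = "kd")
    tt$significant && tt$t_stat < 0
  }, logical(1))
  if (all(sig)) {
    cls[cand] <- "lowest"
    cls[others] <- "other"
  }
  cls
}

#' Build ligand profiles for a fitted fibril panel
#'
#' Turns pooled fit results into per-fibril feature vectors: binary binding
#' calls for the four protocol assays, the high/low shared-site class of the
#' ThT/OXI assay (largest significant gap across the panel), and K_d rank
#' classes computed within groups of fibrils sharing a binary profile (a
#' member is ranked "lowest" only when its per-replicate estimates are
#' significantly lower than every other group member's).
#'
#' @param results Nested fit results from [fit_panel()].
#' @param alpha Significance level for the backing paired t-tests.
#' @return Named list of `ligand_profile` objects.
#' @export
build_profiles <- function(results, alpha = 0.05) {
  fibs <- names(results)
  for (fb in fibs) {
    missing <- setdiff(protocol_assays(), names(results[[fb]]))
    if (length(missing) > 0) {
      stop("incomplete profile for ", fb, ": missing assay(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  oxi_cls <- oxi_bs1_classes(results, alpha)

  binkey <- vapply(fibs, function(fb) {
    paste(vapply(c("aar_direct", "tht_s5h", "tht_bta"), function(a) {
      results[[fb]][[a]]$call$bound
    }, logical(1)), collapse = "|")
  }, character(1))

  s5h_cls <- stats::setNames(rep(NA_character_, length(fibs)), fibs)
  aar_cls <- stats::setNames(rep(NA_character_, length(fibs)), fibs)
  for (k in unique(binkey)) {
    members <- fibs[binkey == k]
    s5h_k <- lowest_kd_class(results, members, "tht_s5h", alpha)
    s5h_cls[members] <- s5h_k
    rest <- members[is.na(s5h_k) | s5h_k != "lowest"]
    aar_cls[rest] <- lowest_kd_class(results, rest, "aar_direct", alpha)
  }

  profiles <- list()
  for (fb in fibs) {
    res <- results[[fb]]
    oxi <- res[["tht_oxi"]]
    kd <- c(
      AAR = if (!is.null(res[["aar_direct"]]$kd)) res[["aar_direct"]]$kd$mean else NA_real_,
      S5H = if (!is.null(res[["tht_s5h"]]$kd)) res[["tht_s5h"]]$kd$mean else NA_real_
    )
    profiles[[fb]] <- build_profile(
      fibril = fb,
      calls = lapply(res[protocol_assays()], `[[`, "call"),
      oxi_bs1 = if (!is.null(oxi$percent_bs1)) oxi$percent_bs1$mean else NA_real_,
      oxi_bs1_class = oxi_cls[[fb]],
      s5h_kd_class = s5h_cls[[fb]],
      aar_kd_class = aar_cls[[fb]],
      kd = kd
    )
  }
  profiles
}

#' Classify every profile of a panel
#'
#' @param profiles Named list of `ligand_profile` objects.
#' @param tree Decision tree (default [full_decision_tree()]).
#' @return A data.frame with columns `fibril`, `label`, `ambiguity`,
#'   `correct` (label equals the fibril's own name).
#' @export
classify_panel <- function(profiles, tree = full_decision_tree()) {
  rows <- lapply(profiles, function(p) {
    cl <- classify(p, tree)
    data.frame(fibril = p$fibril,
               label = cl$label,
               ambiguity = paste(cl$ambiguity, collapse = ","),
               correct = identical(cl$label, p$fibril),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run the full strain-typing pipeline on a simulated reference panel
#'
#' Generates the eight-polymorph ground-truth panel, simulates the four
#' protocol assays with replicate noise, fits every titration, builds ligand
#' profiles and classifies each fibril with the decision tree.
#'
#' @param seed Integer seed driving both the panel parameter draws and the
#'   replicate noise.
#' @param noise A [noise_model()]; its `seed` is overridden by `seed`.
#' @param alpha Significance level for profile statistics.
#' @return A list with `panel`, `data` (long titration table), `results`,
#'   `profiles`, `classification` (data.frame) and `all_correct`.
#' @export
run_strain_typing <- function(seed = 1L, noise = noise_model(), alpha = 0.05) {
  noise$seed <- as.integer(seed)
  panel <- make_reference_panel(seed)
  df <- simulate_panel(panel, noise)
  results <- fit_panel(df)
  profiles <- build_profiles(results, alpha = alpha)
  cls <- classify_panel(profiles)
  list(panel = panel, data = df, results = results, profiles = profiles,
       classification = cls, all_correct = all(cls$correct))
}
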