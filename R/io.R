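#' Run configuration for the command-line pipeline
#'
#' Captures everything a run depends on — seed, noise model, significance
#' level — so outputs can embed it verbatim together with a short content
#' hash and the package version (full reproducibility header).
#'
#' @param seed Integer seed.
#' @param noise A [noise_model()].
#' @param alpha Significance level.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, noise = noise_model(seed = seed),
                       alpha = 0.05) {
  noise$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), noise = noise, alpha = alpha),
            class = "run_config")
}

config_header <- function(config) {
  flat <- c(seed = config$seed, alpha = config$alpha,
            sigma_rel = config$noise$sigma_rel,
            sigma_abs = config$noise$sigma_abs,
            sigma_abs_anisotropy = config$noise$sigma_abs_anisotropy,
            replicates = config$noise$replicates)
  list(
    package = "fibrilprofiler",
    version = as.character(utils::packageVersion("fibrilprofiler")),
    config = as.list(flat),
    config_hash = sprintf("%08x", hash31(paste(names(flat), flat,
                                               collapse = ";")))
  )
}

#' Read a long-format titration CSV
#'
#' One row per (replicate, titrant point); see [simulate_panel()] for the
#' column schema. Schema violations are reported with the offending column
#' or row.
#'
#' @param path CSV file path.
#' @return A validated data.frame.
#' @export
read_titrations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  curves_from_table(df)  # full validation; discard curve objects
  df
}

#' Write a long-format titration CSV
#'
#' @param df Titration table (e.g. from [simulate_panel()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_titrations <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

results_to_list <- function(results) {
  lapply(results, function(per_fibril) {
    lapply(per_fibril, function(r) {
      out <- list(
        fibril = r$fibril, assay_id = r$assay_id, kind = r$kind,
        bound = r$call$bound,
        evidence = r$evidence[c("mean", "sd", "n", "ci95")],
        resid_sd = r$resid_sd,
        converged = all(vapply(r$fits, `[[`, logical(1), "converged"))
      )
      if (!is.null(r$kd)) out$kd <- r$kd[c("mean", "sd", "n", "ci95")]
      if (!is.null(r$percent_bs1)) {
        out$percent_bs1 <- r$percent_bs1[c("mean", "sd", "n", "ci95")]
      }
      out
    })
  })
}

profiles_to_list <- function(profiles) {
  lapply(profiles, function(p) {
    list(fibril = p$fibril, binary = as.list(p$binary),
         features = p$features, oxi_bs1 = p$oxi_bs1,
         kd = as.list(p$kd))
  })
}

#' Simulate a reference-panel dataset and write it to disk
#'
#' Writes the titration CSV and a ground-truth JSON (panel parameters plus
#' the reproducibility header) for downstream fitting and
#' parameter-recovery checks. Deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @param out_csv,out_truth Output paths.
#' @param assays Assays to simulate (default [protocol_assays()]).
#' @return Invisible list with the paths written.
#' @export
cmd_simulate <- function(config, out_csv, out_truth = NULL,
                         assays = protocol_assays()) {
  panel <- make_reference_panel(config$seed)
  df <- simulate_panel(panel, config$noise, assays = assays)
  write_titrations(df, out_csv)
  if (!is.null(out_truth)) {
    truth <- list(header = config_header(config), truth = panel$truth)
    jsonlite::write_json(truth, out_truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(csv = out_csv, truth = out_truth))
}

#' Fit a titration CSV and write pooled results as JSON
#'
#' @param config A [run_config()].
#' @param in_csv Input titration CSV.
#' @param out_json Output JSON path.
#' @return The nested fit results, invisibly.
#' @export
cmd_fit <- function(config, in_csv, out_json) {
  df <- read_titrations(in_csv)
  results <- fit_panel(df)
  payload <- list(header = config_header(config),
                  results = results_to_list(results))
  jsonlite::write_json(payload, out_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(results)
}

#' Build profiles from fit results and classify them
#'
#' Accepts either nested fit results (classifies after building profiles
#' with panel-level statistics) or a named list of feature lists (profiles
#' supplied directly, e.g. read back from JSON). Partial profiles yield
#' ambiguity sets, not errors.
#'
#' @param config A [run_config()].
#' @param results Nested fit results from [fit_panel()], or `NULL`.
#' @param profiles Named list of feature lists, used when `results` is `NULL`.
#' @param out_json Optional output path for the classification report.
#' @return The classification data.frame, invisibly.
#' @export
cmd_classify <- function(config, results = NULL, profiles = NULL,
                         out_json = NULL) {
  tree <- full_decision_tree()
  if (!is.null(results)) {
    profs <- build_profiles(results, alpha = config$alpha)
    cls <- classify_panel(profs, tree)
    prof_list <- profiles_to_list(profs)
  } else if (!is.null(profiles)) {
    rows <- lapply(names(profiles), function(nm) {
      cl <- classify(profiles[[nm]], tree)
      data.frame(fibril = nm,
                 label = cl$label,
                 ambiguity = paste(cl$ambiguity, collapse = ","),
                 correct = identical(cl$label, nm),
                 stringsAsFactors = FALSE)
    })
    cls <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    prof_list <- profiles
  } else {
    stop("cmd_classify needs fit results or profiles", call. = FALSE)
  }
  if (!is.null(out_json)) {
    payload <- list(header = config_header(config), profiles = prof_list,
                    classification = cls)
    jsonlite::write_json(payload, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(cls)
}

#' Run the minimal-assay-panel search and write the report
#'
#' @param config A [run_config()].
#' @param out_json Optional output path.
#' @return The `minimal_assay_set`, invisibly.
#' @export
cmd_search_panel <- function(config, out_json = NULL) {
  ms <- minimal_assay_search()
  if (!is.null(out_json)) {
    payload <- list(header = config_header(config),
                    assays = ms$assays, size = ms$size,
                    feasible = ms$feasible,
                    n_ligands = count_ligands(ms$assays),
                    certificate = lapply(ms$certificate, function(d) d))
    jsonlite::write_json(payload, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(ms)
}
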