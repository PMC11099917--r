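#' Default ligand toolkit
#'
#' The six-ligand toolkit used to probe fibril binding sites: thioflavin T
#' (ThT) and AAR are solvatochromic intensity reporters, BTA is a
#' non-solvatochromic reporter read out by fluorescence anisotropy (and used
#' as a dark competitor in the ThT channel), and OXI, S5H and thiazine red
#' (ThR) are dark competitors. Brightness values are nominal arbitrary
#' units/nM for simulation.
#'
#' @return Named list of [ligand_def()] objects.
#' @export
default_ligands <- function() {
  ligs <- list(
    ligand_def("ThT", "reporter", "intensity", brightness_free = 0,
               brightness_bound = 1),
    ligand_def("AAR", "reporter", "intensity", brightness_free = 0,
               brightness_bound = 1),
    ligand_def("BTA", "reporter", "anisotropy", r_free = 0.05, r_bound = 0.25),
    ligand_def("OXI", "competitor", "dark"),
    ligand_def("S5H", "competitor", "dark"),
    ligand_def("ThR", "competitor", "dark")
  )
  stats::setNames(ligs, vapply(ligs, `[[`, character(1), "name"))
}

#' Registry of binding assays
#'
#' The assays performed on the fibril panel, in the fixed registry order used
#' for lexicographic tie-breaking in the minimal-panel search (the AAR direct
#' assay first). The first six rows (`candidate = TRUE`) are the candidate
#' assays considered by [minimal_assay_search()]; the two trailing direct
#' assays are available to the simulator but carry no fixture evidence.
#'
#' @return A data.frame with columns `assay_id`, `kind`, `reporter`,
#'   `competitor`, `candidate`, `label`.
#' @export
assay_registry <- function() {
  data.frame(
    assay_id   = c("aar_direct", "tht_s5h", "tht_bta", "tht_oxi",
                   "tht_thr", "aar_tht", "bta_direct", "tht_direct"),
    kind       = c("direct_intensity", "competition", "competition",
                   "competition", "competition", "competition",
                   "direct_anisotropy", "direct_intensity"),
    reporter   = c("AAR", "ThT", "ThT", "ThT", "ThT", "AAR", "BTA", "ThT"),
    competitor = c(NA, "S5H", "BTA", "OXI", "ThR", "ThT", NA, NA),
    candidate  = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    label      = c("AAR direct", "ThT/S5H competition", "ThT/BTA competition",
                   "ThT/OXI competition", "ThT/ThR competition",
                   "AAR/ThT competition", "BTA direct (anisotropy)",
                   "ThT direct"),
    stringsAsFactors = FALSE
  )
}

#' Count the distinct ligands used by a set of assays
#'
#' Cardinality of the union of reporter and competitor ligand names over the
#' given assays.
#'
#' @param assays Character vector of assay ids.
#' @param registry Assay registry data.frame, by default [assay_registry()].
#' @return Integer count of distinct ligands.
#' @examples
#' count_ligands(c("aar_direct", "tht_s5h", "tht_bta", "tht_oxi"))  # 5
#' @export
count_ligands <- function(assays, registry = assay_registry()) {
  if (length(assays) == 0) return(0L)
  unknown <- setdiff(assays, registry$assay_id)
  if (length(unknown) > 0) {
    stop("unknown assay(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  rows <- registry[registry$assay_id %in% assays, ]
  length(unique(stats::na.omit(c(rows$reporter, rows$competitor))))
}
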