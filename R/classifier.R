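#' Reference ligand-profile table for the eight-polymorph panel
#'
#' The shipped fixture transcribing the reported discriminations for the
#' eight fibril morphologies: binary binding calls for each registered assay
#' (`NA` where no evidence is reported), the shared-site class of the ThT/OXI
#' assay, and the significance-backed K_d rank classes. Cell-level provenance
#' is in [reference_provenance()]; quantitative pairwise separations are in
#' [reference_separations()].
#'
#' @return A data.frame, one row per fibril.
#' @export
reference_profile_table <- function() {
  path <- system.file("extdata", "reference_profiles.tsv",
                      package = "fibrilprofiler", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  for (cl in grep("_bind$", names(tab), value = TRUE)) {
    tab[[cl]] <- as.logical(tab[[cl]])
  }
  tab
}

#' Cell-level provenance of the reference profile table
#'
#' Long-format annotation of every fixture cell: `observed` (directly
#' reported), `implied` (follows from the reported displacement pattern but
#' not individually asserted), `significant_difference` (backed by a reported
#' paired-test result) or `not_reported`.
#'
#' @return A data.frame with columns `fibril`, `field`, `value`, `basis`.
#' @export
reference_provenance <- function() {
  path <- system.file("extdata", "reference_provenance.tsv",
                      package = "fibrilprofiler", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Significance-backed quantitative separations in the reference fixture
#'
#' Fibril pairs distinguished by a reported significant quantitative
#' difference (K_d ordering or shared-site fraction) in a given assay. Pairs
#' without reported evidence are treated as not separable by that assay.
#'
#' @return A data.frame with columns `assay_id`, `fibril_a`, `fibril_b`,
#'   `basis`.
#' @export
reference_separations <- function() {
  path <- system.file("extdata", "reference_separations.tsv",
                      package = "fibrilprofiler", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Partition fibrils by identical binary binding vectors
#'
#' Groups the fibrils of a profile table by their bind/no-bind calls over the
#' chosen assays. Cells with no evidence (`NA`) are treated as
#' non-discriminating. The empty assay set yields a single group.
#'
#' @param table Profile table (as from [reference_profile_table()]).
#' @param assays Character vector of assay ids (their `<assay>_bind` columns
#'   must exist in `table`).
#' @return List of character vectors (groups of fibril names), in order of
#'   first appearance.
#' @export
partition_binary <- function(table, assays) {
  if (length(assays) == 0) {
    return(list(table$fibril))
  }
  cols <- paste0(assays, "_bind")
  unknown <- setdiff(cols, names(table))
  if (length(unknown) > 0) {
    stop("unknown assay column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keys <- apply(table[, cols, drop = FALSE], 1, function(v) {
    paste(ifelse(is.na(v), "?", as.character(v)), collapse = "|")
  })
  unname(lapply(unique(keys), function(k) table$fibril[keys == k]))
}

tree_leaf <- function(labels) {
  list(type = "leaf", labels = labels)
}
tree_node <- function(feature, branches, label = feature) {
  list(type = "test", feature = feature, branches = branches, label = label)
}

#' Decision tree from the binary (bind / no-bind) classification
#'
#' Reproduces the qualitative decision tree: AAR binding splits off R and
#' f91 (distinguished by S5H), S5H binding isolates the PMCA-derived fibrils
#' as a group, and BTA binding separates F from f65/f110. Its five leaves are
#' the five binary categories.
#'
#' @return A `decision_tree` object.
#' @export
binary_decision_tree <- function() {
  structure(
    tree_node("aar_bind", list(
      `FALSE` = tree_node("s5h_bind", list(
        `FALSE` = tree_leaf("R"),
        `TRUE` = tree_leaf("f91")
      ), label = "ThT/S5H competition"),
      `TRUE` = tree_node("s5h_bind", list(
        `TRUE` = tree_leaf(c("PD", "MSA", "DLB")),
        `FALSE` = tree_node("bta_bind", list(
          `FALSE` = tree_leaf("F"),
          `TRUE` = tree_leaf(c("f65", "f110"))
        ), label = "ThT/BTA competition")
      ), label = "ThT/S5H competition")
    ), label = "AAR direct"),
    class = "decision_tree"
  )
}

#' Decision tree distinguishing f65 and f110 by the shared-site fraction
#'
#' f65 and f110 share a binary profile; they are separated by the proportion
#' of ThT sites accessible to OXI (%BS1), high for f65 and significantly
#' lower for f110.
#'
#' @return A `decision_tree` object.
#' @export
bs1_decision_tree <- function() {
  structure(
    tree_node("oxi_bs1_class", list(
      high = tree_leaf("f65"),
      low = tree_leaf("f110")
    ), label = "ThT/OXI competition (%BS1)"),
    class = "decision_tree"
  )
}

#' Decision tree distinguishing the PMCA-derived fibrils by K_d
#'
#' PD is identified by its significantly lower apparent S5H K_d in the
#' ThT/S5H competition assay; MSA and DLB are then separated by the AAR
#' direct-assay K_d (lower for MSA).
#'
#' @return A `decision_tree` object.
#' @export
kd_decision_tree <- function() {
  structure(
    tree_node("s5h_kd_class", list(
      lowest = tree_leaf("PD"),
      other = tree_node("aar_kd_class", list(
        lowest = tree_leaf("MSA"),
        other = tree_leaf("DLB")
      ), label = "AAR direct (K_d)")
    ), label = "ThT/S5H competition (K_d)"),
    class = "decision_tree"
  )
}

#' Full two-stage decision tree for the eight-polymorph panel
#'
#' The binary tree with the quantitative subtrees grafted onto its two
#' ambiguous leaves: %BS1 for f65/f110 and the K_d tree for the
#' PMCA-derived fibrils. With all features present every profile reaches a
#' single polymorph label; with quantitative features withheld it returns the
#' five binary categories.
#'
#' @return A `decision_tree` object.
#' @export
full_decision_tree <- function() {
  tr <- binary_decision_tree()
  tr$branches$`TRUE`$branches$`TRUE` <- unclass(kd_decision_tree())
  tr$branches$`TRUE`$branches$`FALSE`$branches$`TRUE` <-
    unclass(bs1_decision_tree())
  tr
}

collect_labels <- function(node) {
  if (node$type == "leaf") return(node$labels)
  unique(unlist(lapply(node$branches, collect_labels)))
}

#' Classify a ligand profile with a decision tree
#'
#' Deterministic traversal. When a feature tested at a visited node is
#' missing (`NA`), traversal stops and the union of labels reachable from
#' that node is returned as the ambiguity set: partial profiles give partial
#' classifications, never errors.
#'
#' @param profile A [build_profile()] result, or a named list/vector of
#'   features (`aar_bind`, `s5h_bind`, `bta_bind`, `oxi_bs1_class`,
#'   `s5h_kd_class`, `aar_kd_class`).
#' @param tree A `decision_tree`; defaults to [full_decision_tree()].
#' @return A list of class `classification`: `label` (single label or `NA`),
#'   `ambiguity` (character vector of candidate labels), `path` (features
#'   tested, with the branch taken).
#' @export
classify <- function(profile, tree = full_decision_tree()) {
  feats <- if (inherits(profile, "ligand_profile")) profile$features
           else as.list(profile)
  node <- tree
  path <- character(0)
  while (node$type == "test") {
    val <- feats[[node$feature]]
    if (is.null(val) || length(val) != 1 || is.na(val)) {
      amb <- collect_labels(node)
      return(structure(list(label = if (length(amb) == 1) amb else NA_character_,
                            ambiguity = amb, path = path,
                            stopped_at = node$feature),
                       class = "classification"))
    }
    key <- as.character(val)
    if (!key %in% names(node$branches)) {
      amb <- collect_labels(node)
      return(structure(list(label = NA_character_, ambiguity = amb,
                            path = path, stopped_at = node$feature),
                       class = "classification"))
    }
    path <- c(path, sprintf("%s=%s", node$feature, key))
    node <- node$branches[[key]]
  }
  structure(
    list(label = if (length(node$labels) == 1) node$labels else NA_character_,
         ambiguity = node$labels, path = path, stopped_at = NA_character_),
    class = "classification"
  )
}

#' @export
print.classification <- function(x, ...) {
  if (!is.na(x$label)) {
    cat("Classified as:", x$label, "\n")
  } else {
    cat("Ambiguity set: {", paste(x$ambiguity, collapse = ", "), "}\n")
  }
  if (length(x$path)) cat("  path:", paste(x$path, collapse = " -> "), "\n")
  invisible(x)
}

## Does `assay` separate fibrils a and b under the fixture evidence rule:
## differing (non-NA) binary calls, or a listed significance-backed
## quantitative separation.
separates_pair <- function(table, separations, assay, a, b) {
  col <- paste0(assay, "_bind")
  va <- table[table$fibril == a, col]
  vb <- table[table$fibril == b, col]
  if (length(va) == 1 && length(vb) == 1 &&
      !is.na(va) && !is.na(vb) && va != vb) {
    return(TRUE)
  }
  any(separations$assay_id == assay &
        ((separations$fibril_a == a & separations$fibril_b == b) |
           (separations$fibril_a == b & separations$fibril_b == a)))
}

#' Exhaustive search for a minimal discriminating assay panel
#'
#' Enumerates assay subsets by increasing size (lexicographic within a size,
#' in registry order) and returns the first subset under which every pair of
#' fibrils is separated — by differing binary calls or by a
#' significance-backed quantitative difference recorded in the fixture. The
#' exhaustive enumeration is itself the minimality proof: all smaller
#' subsets have been checked and failed.
#'
#' @param table Profile table (default the shipped reference fixture).
#' @param candidates Candidate assay ids, in tie-break order (default the six
#'   registered candidate assays).
#' @param separations Quantitative separation table (default
#'   [reference_separations()]).
#' @return An object of class `minimal_assay_set`: `assays`, `size`,
#'   `feasible`, `certificate` (per assay, the fibril pairs it separates),
#'   and when infeasible `unseparated` (pairs no candidate separates) and
#'   `partition` (finest achievable grouping).
#' @export
minimal_assay_search <- function(table = reference_profile_table(),
                                 candidates = NULL,
                                 separations = reference_separations()) {
  if (is.null(candidates)) {
    reg <- assay_registry()
    candidates <- reg$assay_id[reg$candidate]
  }
  fibrils <- table$fibril
  if (length(fibrils) < 1) stop("profile table is empty", call. = FALSE)
  pairs <- if (length(fibrils) >= 2) {
    utils::combn(fibrils, 2, simplify = FALSE)
  } else {
    list()
  }

  sep_matrix <- matrix(FALSE, nrow = length(pairs), ncol = length(candidates),
                       dimnames = list(NULL, candidates))
  for (j in seq_along(candidates)) {
    for (i in seq_along(pairs)) {
      sep_matrix[i, j] <- separates_pair(table, separations, candidates[j],
                                         pairs[[i]][1], pairs[[i]][2])
    }
  }

  certificate_for <- function(subset) {
    lapply(stats::setNames(subset, subset), function(a) {
      idx <- which(sep_matrix[, a])
      if (length(idx) == 0) return(data.frame(fibril_a = character(0),
                                              fibril_b = character(0)))
      data.frame(fibril_a = vapply(pairs[idx], `[`, character(1), 1),
                 fibril_b = vapply(pairs[idx], `[`, character(1), 2))
    })
  }

  for (size in 0:length(candidates)) {
    subsets <- if (size == 0) list(character(0)) else {
      utils::combn(candidates, size, simplify = FALSE)
    }
    for (subset in subsets) {
      covered <- if (length(subset) == 0) {
        rep(FALSE, length(pairs))
      } else {
        apply(sep_matrix[, subset, drop = FALSE], 1, any)
      }
      if (length(pairs) == 0 || all(covered)) {
        return(structure(
          list(assays = subset, size = length(subset), feasible = TRUE,
               certificate = certificate_for(subset)),
          class = "minimal_assay_set"))
      }
    }
  }

  covered <- apply(sep_matrix, 1, any)
  unsep <- do.call(rbind, lapply(pairs[!covered], function(p) {
    data.frame(fibril_a = p[1], fibril_b = p[2])
  }))
  ## finest achievable partition: fibrils not separated by any candidate are
  ## merged (transitive closure of the unseparated relation)
  grp <- stats::setNames(seq_along(fibrils), fibrils)
  for (k in seq_len(nrow(unsep))) {
    ga <- grp[[unsep$fibril_a[k]]]
    gb <- grp[[unsep$fibril_b[k]]]
    grp[grp == gb] <- ga
  }
  part <- unname(lapply(unique(grp), function(g) names(grp)[grp == g]))
  structure(
    list(assays = candidates, size = length(candidates), feasible = FALSE,
         certificate = certificate_for(candidates),
         unseparated = unsep, partition = part),
    class = "minimal_assay_set"
  )
}

#' @export
print.minimal_assay_set <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("Minimal assay panel (size %d): %s\n", x$size,
                paste(x$assays, collapse = ", ")))
  } else {
    cat("No subset of the candidate assays separates all fibril pairs.\n")
    cat("Finest achievable partition:\n")
    for (g in x$partition) cat("  {", paste(g, collapse = ", "), "}\n")
  }
  invisible(x)
}

#' Export a decision tree in Graphviz DOT format
#'
#' @param tree A `decision_tree`.
#' @return A single DOT string (visualise with Graphviz `dot`).
#' @export
tree_to_dot <- function(tree) {
  lines <- c("digraph decision_tree {", "  node [shape=box];")
  counter <- new.env()
  counter$i <- 0L
  emit <- function(node) {
    counter$i <- counter$i + 1L
    id <- sprintf("n%d", counter$i)
    if (node$type == "leaf") {
      lines <<- c(lines, sprintf(
        "  %s [label=\"%s\", shape=ellipse];", id,
        paste(node$labels, collapse = ", ")))
    } else {
      lines <<- c(lines, sprintf("  %s [label=\"%s\"];", id, node$label))
      for (br in names(node$branches)) {
        child <- emit(node$branches[[br]])
        lines <<- c(lines, sprintf("  %s -> %s [label=\"%s\"];", id, child, br))
      }
    }
    id
  }
  emit(tree)
  paste(c(lines, "}"), collapse = "\n")
}
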