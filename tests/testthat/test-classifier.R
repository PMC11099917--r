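fixture_features <- function(row) {
  list(aar_bind = row$aar_direct_bind,
       s5h_bind = row$tht_s5h_bind,
       bta_bind = row$tht_bta_bind,
       oxi_bind = row$tht_oxi_bind,
       oxi_bs1_class = row$oxi_bs1_class,
       s5h_kd_class = row$s5h_kd_class,
       aar_kd_class = row$aar_kd_class)
}

test_that("three binary assays partition the panel into the five reported groups", {
  tab <- reference_profile_table()
  part <- partition_binary(tab, c("aar_direct", "tht_s5h", "tht_bta"))
  expect_length(part, 5)
  canon <- lapply(part, function(g) paste(sort(g), collapse = ","))
  expect_setequal(unlist(canon),
                  c("R", "f91", "F", "f110,f65", "DLB,MSA,PD"))
})

test_that("partitioning handles empty assay sets and degenerate tables", {
  tab <- reference_profile_table()
  expect_identical(partition_binary(tab, character(0)), list(tab$fibril))
  one <- tab[tab$fibril == "PD", ]
  expect_identical(partition_binary(one, c("aar_direct", "tht_s5h")),
                   list("PD"))
  expect_error(partition_binary(tab, "made_up"), "unknown assay")
})

test_that("adding assays only ever refines the binary partition", {
  tab <- reference_profile_table()
  assays <- c("aar_direct", "tht_s5h", "tht_bta", "tht_oxi")
  group_of <- function(part) {
    g <- rep(NA_integer_, nrow(tab))
    names(g) <- tab$fibril
    for (i in seq_along(part)) g[part[[i]]] <- i
    g
  }
  for (k in 1:(length(assays) - 1)) {
    coarse <- group_of(partition_binary(tab, assays[1:k]))
    fine <- group_of(partition_binary(tab, assays[1:(k + 1)]))
    # fibrils in different coarse groups never end up in the same fine group
    for (i in seq_len(nrow(tab))) for (j in seq_len(nrow(tab))) {
      if (coarse[i] != coarse[j]) expect_false(fine[i] == fine[j])
    }
  }
})

test_that("each fixture profile classifies to its own polymorph", {
  tab <- reference_profile_table()
  tree <- full_decision_tree()
  for (i in seq_len(nrow(tab))) {
    cl <- classify(fixture_features(tab[i, ]), tree)
    expect_identical(cl$label, tab$fibril[i])
  }
})

test_that("partial profiles give the smallest reachable ambiguity set", {
  # binary-only profiles collapse to the five binary categories
  tab <- reference_profile_table()
  tree <- full_decision_tree()
  sets <- character(0)
  for (i in seq_len(nrow(tab))) {
    f <- fixture_features(tab[i, ])
    f$oxi_bs1_class <- NA
    f$s5h_kd_class <- NA
    f$aar_kd_class <- NA
    cl <- classify(f, tree)
    sets <- c(sets, paste(sort(cl$ambiguity), collapse = ","))
  }
  expect_setequal(unique(sets), c("R", "f91", "F", "f110,f65", "DLB,MSA,PD"))
  # worked examples from the protocol
  expect_identical(classify(list(aar_bind = FALSE, s5h_bind = FALSE))$label, "R")
  expect_identical(
    classify(list(aar_bind = TRUE, s5h_bind = TRUE, s5h_kd_class = "lowest"))$label,
    "PD")
  expect_identical(
    classify(list(aar_bind = TRUE, s5h_bind = FALSE, bta_bind = TRUE,
                  oxi_bs1_class = "low"))$label,
    "f110")
  pmca <- classify(list(aar_bind = TRUE, s5h_bind = TRUE))
  expect_setequal(pmca$ambiguity, c("PD", "MSA", "DLB"))
  empty <- classify(list())
  expect_setequal(empty$ambiguity,
                  c("F", "R", "f65", "f91", "f110", "PD", "MSA", "DLB"))
})

test_that("the quantitative subtrees mirror the two-stage protocol", {
  expect_identical(classify(list(oxi_bs1_class = "high"),
                            bs1_decision_tree())$label, "f65")
  expect_identical(classify(list(s5h_kd_class = "other",
                                 aar_kd_class = "lowest"),
                            kd_decision_tree())$label, "MSA")
  binary_only <- classify(fixture_features(
    reference_profile_table()[3, ]), binary_decision_tree())
  expect_true(binary_only$label %in% c("f65", NA_character_) ||
                all(c("f65", "f110") %in% binary_only$ambiguity))
})

test_that("the minimal assay panel has size four and a verified certificate", {
  ms <- minimal_assay_search()
  expect_true(ms$feasible)
  expect_identical(ms$size, 4L)
  expect_identical(ms$assays,
                   c("aar_direct", "tht_s5h", "tht_bta", "tht_oxi"))
  # re-verify the certificate with a naive double loop over all pairs
  tab <- reference_profile_table()
  seps <- reference_separations()
  sep_by_subset <- function(a, b) {
    any(vapply(ms$assays, function(aid) {
      col <- paste0(aid, "_bind")
      va <- tab[tab$fibril == a, col]; vb <- tab[tab$fibril == b, col]
      bin <- !is.na(va) && !is.na(vb) && va != vb
      quant <- any(seps$assay_id == aid &
                     ((seps$fibril_a == a & seps$fibril_b == b) |
                        (seps$fibril_a == b & seps$fibril_b == a)))
      bin || quant
    }, logical(1)))
  }
  for (i in 1:(nrow(tab) - 1)) for (j in (i + 1):nrow(tab)) {
    expect_true(sep_by_subset(tab$fibril[i], tab$fibril[j]))
  }
  # certificate pairs are exactly the separated pairs per assay
  for (aid in ms$assays) {
    cert <- ms$certificate[[aid]]
    for (k in seq_len(nrow(cert))) {
      expect_true(sep_by_subset(cert$fibril_a[k], cert$fibril_b[k]))
    }
  }
})

test_that("degenerate tables are handled: duplicates infeasible, singletons trivial", {
  tab <- reference_profile_table()
  dup <- tab[c(1, 1), ]
  dup$fibril <- c("X1", "X2")
  ms <- minimal_assay_search(dup, separations = reference_separations()[0, ])
  expect_false(ms$feasible)
  expect_true(any(vapply(ms$partition, function(g) {
    setequal(g, c("X1", "X2"))
  }, logical(1))))
  single <- tab[1, ]
  ms1 <- minimal_assay_search(single)
  expect_true(ms1$feasible)
  expect_identical(ms1$size, 0L)
})

test_that("ligand counting takes the union of reporters and competitors", {
  expect_identical(count_ligands(c("aar_direct", "tht_s5h", "tht_bta",
                                   "tht_oxi")), 5L)
  expect_identical(count_ligands(character(0)), 0L)
  expect_identical(count_ligands(c("tht_s5h", "tht_oxi")), 3L)
  expect_error(count_ligands("bogus"), "unknown assay")
})

test_that("the decision tree exports readable DOT", {
  dot <- tree_to_dot(full_decision_tree())
  expect_match(dot, "^digraph")
  for (lab in c("AAR direct", "f65", "f110", "PD", "MSA", "DLB")) {
    expect_match(dot, lab, fixed = TRUE)
  }
})
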