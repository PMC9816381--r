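# Homolog retrieval and annotation transfer.

# a fixed little map: GluN2A pos p <-> GluN2B pos p+1 for p in 450..460,
# plus GluN1 pos p-10 <-> GluN2A pos p for 455..458
fixed_map <- function() {
  mk <- function(pos_a, pos_b, sub_a, sub_b) {
    glunmap:::new_alignment(
      tibble::tibble(pos_a = pos_a, aa_a = "G", pos_b = pos_b, aa_b = "G"),
      sub_a, sub_b,
      n_columns = length(pos_a), provenance = "structural", domain = "LBD"
    )
  }
  build_equivalence_map(list(
    mk(450:460, 451:461, "GluN2A", "GluN2B"),
    mk(445:448, 455:458, "GluN1", "GluN2A"),
    mk(445:448, 456:459, "GluN1", "GluN2B")
  ))
}

test_that("homologs require the same change at the equivalent position", {
  map <- fixed_map()
  db <- variant_db("GluN2B", 459, "G", "R", pathogenicity = "pathogenic")
  q <- tibble::tibble(subunit = "GluN2A", pos = 458L, ref_aa = "G", alt_aa = "R")
  hom <- find_homologs(q, map, db)
  expect_equal(nrow(hom), 1L)
  expect_equal(hom$subunit, "GluN2B")
  expect_equal(hom$pos, 459L)
  # same position, different ref: excluded
  db2 <- variant_db("GluN2B", 459, "A", "R")
  expect_equal(nrow(find_homologs(q, map, db2)), 0L)
  # same position, different alt: excluded
  db3 <- variant_db("GluN2B", 459, "G", "W")
  expect_equal(nrow(find_homologs(q, map, db3)), 0L)
  # unmapped position: no homologs
  q2 <- tibble::tibble(subunit = "GluN2A", pos = 999L, ref_aa = "G", alt_aa = "R")
  expect_equal(nrow(find_homologs(q2, map, db)), 0L)
})

test_that("homology is symmetric between the two variants", {
  map <- fixed_map()
  db <- variant_db(
    c("GluN2A", "GluN2B"), c(458, 459), c("G", "G"), c("R", "R"),
    pathogenicity = c("unannotated", "pathogenic")
  )
  va <- tibble::tibble(subunit = "GluN2A", pos = 458L, ref_aa = "G", alt_aa = "R")
  vb <- tibble::tibble(subunit = "GluN2B", pos = 459L, ref_aa = "G", alt_aa = "R")
  hom_ab <- find_homologs(va, map, db)
  hom_ba <- find_homologs(vb, map, db)
  expect_true(any(hom_ab$subunit == "GluN2B" & hom_ab$pos == 459))
  expect_true(any(hom_ba$subunit == "GluN2A" & hom_ba$pos == 458))
})

test_that("a pathogenic homolog transfers pathogenicity; classes move independently", {
  map <- fixed_map()
  db <- variant_db("GluN2B", 459, "G", "S",
    pathogenicity = "pathogenic", functional = "unannotated"
  )
  q <- tibble::tibble(subunit = "GluN2A", pos = 458L, ref_aa = "G", alt_aa = "S")
  pred <- predict_annotations(q, map, db)
  expect_equal(pred$status, "predicted")
  expect_equal(pred$predicted_pathogenicity, "pathogenic")
  expect_equal(pred$predicted_functional, "none")
  expect_equal(pred$functional_status, "homolog_unannotated")
  expect_equal(pred$n_homologs, 1L)
})

test_that("uncertain homologs never transfer and never appear as a call", {
  map <- fixed_map()
  db <- variant_db("GluN2B", 459, "G", "R", pathogenicity = "uncertain")
  q <- tibble::tibble(subunit = "GluN2A", pos = 458L, ref_aa = "G", alt_aa = "R")
  pred <- predict_annotations(q, map, db)
  expect_equal(pred$status, "homolog_unannotated")
  expect_equal(pred$predicted_pathogenicity, "none")
  # sweep: no prediction anywhere may carry class "uncertain"
  trio <- toy_trio(seed = 9)
  vdb <- toy_variant_db(trio$map, n_groups = 30, annotated_fraction = 0.6, seed = 9)
  all_pred <- annotate_database(vdb$db, trio$map)$predictions
  expect_false(any(all_pred$predicted_pathogenicity == "uncertain"))
  expect_false(any(all_pred$predicted_functional == "uncertain"))
})

test_that("disagreeing homologs give a conflict status and no call", {
  map <- fixed_map()
  # GluN1:445 <-> GluN2A:455 <-> GluN2B:456: plant opposite annotations on the ends
  db <- variant_db(
    c("GluN1", "GluN2B"), c(445, 456), c("G", "G"), c("R", "R"),
    pathogenicity = c("benign", "pathogenic")
  )
  q <- tibble::tibble(subunit = "GluN2A", pos = 455L, ref_aa = "G", alt_aa = "R")
  pred <- predict_annotations(q, map, db)
  expect_equal(pred$status, "conflict")
  expect_equal(pred$predicted_pathogenicity, "none")
  expect_equal(pred$n_homologs, 2L)
})

test_that("database-wide annotation is idempotent once predictions are accepted", {
  trio <- toy_trio(seed = 7)
  vdb <- toy_variant_db(trio$map, n_groups = 40, annotated_fraction = 0.5, seed = 7)
  first <- annotate_database(vdb$db, trio$map)
  accepted <- tibble::as_tibble(vdb$db)
  for (i in seq_len(nrow(first$predictions))) {
    p <- first$predictions[i, ]
    row <- accepted$subunit == p$subunit & accepted$pos == p$pos &
      accepted$ref_aa == p$ref_aa & accepted$alt_aa == p$alt_aa
    if (p$predicted_pathogenicity != "none" && p$new_pathogenicity) {
      accepted$pathogenicity[row] <- p$predicted_pathogenicity
    }
    if (p$predicted_functional != "none" && p$new_functional) {
      accepted$functional[row] <- p$predicted_functional
    }
  }
  accepted_db <- variant_db(
    accepted$subunit, accepted$pos, accepted$ref_aa, accepted$alt_aa,
    accepted$pathogenicity, accepted$functional, accepted$source
  )
  second <- annotate_database(accepted_db, trio$map)
  expect_equal(second$expansion$n_predicted_pathogenic, 0L)
  expect_equal(second$expansion$n_predicted_benign, 0L)
  expect_equal(second$expansion$n_vus_resolved, 0L)
  expect_equal(second$expansion$n_new_functional, 0L)
})

test_that("a saturated fixture doubles its pathogenic count (100% increase)", {
  # every unannotated variant has exactly one pathogenic homolog
  trio <- toy_trio(seed = 11)
  vdb <- toy_variant_db(trio$map,
    n_groups = 25, p_agree = 1, annotated_fraction = 1,
    p_pathogenic = 1, functional_fraction = 0, seed = 11
  )
  db <- tibble::as_tibble(vdb$db)
  # strip the annotation from the second member of every group
  led <- vdb$ledger
  for (g in seq_len(nrow(led))) {
    row <- db$subunit == led$subunit_b[g] & db$pos == led$pos_b[g]
    db$pathogenicity[row] <- "unannotated"
  }
  db <- variant_db(db$subunit, db$pos, db$ref_aa, db$alt_aa, db$pathogenicity, db$functional)
  res <- annotate_database(db, trio$map)
  expect_equal(res$expansion$n_predicted_pathogenic, 25L)
  expect_equal(res$expansion$pct_pathogenic_increase, 100)
})

test_that("a database with no homologous pairs yields zero predictions", {
  map <- fixed_map()
  db <- variant_db(
    c("GluN2A", "GluN2B"), c(458, 459), c("G", "G"), c("R", "W"), # different alts
    pathogenicity = c("unannotated", "pathogenic")
  )
  res <- annotate_database(db, map)
  expect_equal(res$expansion$n_predicted_pathogenic, 0L)
  expect_true(all(res$predictions$status %in% c("no_homolog", "homolog_unannotated")))
})
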