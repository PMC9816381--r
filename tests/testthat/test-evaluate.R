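# Grouping of equivalent-position variants, concordance, domain summary.

pair_map <- function() {
  # GluN2A p <-> GluN2B p+1 over 100..140; GluN1 p-15 joined in for 120..125
  mk <- function(pos_a, pos_b, sub_a, sub_b, aa_a = "G", aa_b = "G") {
    glunmap:::new_alignment(
      tibble::tibble(pos_a = pos_a, aa_a = aa_a, pos_b = pos_b, aa_b = aa_b),
      sub_a, sub_b,
      n_columns = length(pos_a), provenance = "structural", domain = "LBD"
    )
  }
  build_equivalence_map(list(
    mk(100:140, 101:141, "GluN2A", "GluN2B"),
    mk(105:110, 120:125, "GluN1", "GluN2A"),
    mk(105:110, 121:126, "GluN1", "GluN2B")
  ))
}

test_that("homologous, same-final and same-initial groups form per definition", {
  map <- pair_map()
  db <- variant_db(
    subunit = c("GluN2A", "GluN2B", "GluN1", "GluN2B", "GluN2A", "GluN2B", "GluN2B"),
    pos = c(103, 104, 105, 121, 130, 131, 131),
    ref_aa = c("G", "G", "K", "P", "A", "A", "A"),
    alt_aa = c("R", "R", "R", "R", "V", "S", "V"),
    pathogenicity = "pathogenic"
  )
  hom <- group_equivalent_variants(db, map, "homologous")
  # GluN2A 103 + GluN2B 104 (Gly->Arg) and GluN2A 130 + GluN2B 131 (Ala->Val)
  expect_equal(unique(hom$group_id), c(1L, 2L))
  expect_setequal(hom$pos, c(103L, 104L, 130L, 131L))
  sf <- group_equivalent_variants(db, map, "same_final")
  # GluN1 Lys105Arg + GluN2B Pro121Arg share the final residue, not the initial
  expect_equal(nrow(sf), 2L)
  expect_setequal(sf$ref_aa, c("K", "P"))
  si <- group_equivalent_variants(db, map, "same_initial")
  # GluN2A Ala130Val + GluN2B Ala131Ser/Val share Ala with two distinct alts
  expect_equal(length(unique(si$group_id)), 1L)
  expect_equal(nrow(si), 3L)
  # the three categories never share a (group of) comparison
  expect_equal(nrow(dplyr::inner_join(
    hom[, c("subunit", "pos", "ref_aa", "alt_aa")],
    sf[, c("subunit", "pos", "ref_aa", "alt_aa")],
    by = c("subunit", "pos", "ref_aa", "alt_aa")
  )), 0L)
})

test_that("variants at unmapped positions form no groups", {
  map <- pair_map()
  db <- variant_db(c("GluN2A", "GluN2B"), c(900, 901), c("G", "G"), c("R", "R"))
  for (cat in c("homologous", "same_final", "same_initial")) {
    expect_equal(nrow(group_equivalent_variants(db, map, cat)), 0L)
  }
})

test_that("concordance is 100% on all-agreeing groups and 0% on a planted clash", {
  map <- pair_map()
  agree <- variant_db(
    c("GluN2A", "GluN2B", "GluN2A", "GluN2B"), c(103, 104, 110, 111),
    c("G", "G", "G", "G"), c("R", "R", "W", "W"),
    pathogenicity = c("pathogenic", "pathogenic", "benign", "benign")
  )
  rep <- concordance(group_equivalent_variants(agree, map, "homologous"), "pathogenicity")
  expect_equal(rep$percent_coincident, 100)
  expect_equal(rep$n_groups, 2L)
  expect_equal(rep$n_variants, 4L)
  clash <- variant_db(
    c("GluN2A", "GluN2B"), c(103, 104), c("G", "G"), c("R", "R"),
    pathogenicity = c("pathogenic", "benign")
  )
  rep2 <- concordance(group_equivalent_variants(clash, map, "homologous"), "pathogenicity")
  expect_equal(rep2$percent_coincident, 0)
  expect_equal(nrow(attr(rep2, "discordant")), 2L)
})

test_that("uncertain members are discarded and thin groups leave the denominator", {
  map <- pair_map()
  db <- variant_db(
    c("GluN2A", "GluN2B", "GluN2A", "GluN2B"), c(103, 104, 110, 111),
    c("G", "G", "G", "G"), c("R", "R", "W", "W"),
    pathogenicity = c("pathogenic", "uncertain", "pathogenic", "pathogenic"),
    functional = c("LoF", "GoF", "unannotated", "unannotated")
  )
  groups <- group_equivalent_variants(db, map, "homologous")
  rep <- concordance(groups, "pathogenicity")
  expect_equal(rep$n_groups, 1L) # the uncertain-thinned group dropped out
  expect_equal(rep$percent_coincident, 100)
  # the uncertain member still counts for functional concordance: LoF vs GoF
  repf <- concordance(groups, "functional")
  expect_equal(repf$n_groups, 1L)
  expect_equal(repf$percent_coincident, 0)
})

test_that("complex is a first-class functional class and clashes with LoF", {
  map <- pair_map()
  db <- variant_db(
    c("GluN2A", "GluN2B"), c(103, 104), c("G", "G"), c("R", "R"),
    functional = c("complex", "LoF")
  )
  rep <- concordance(group_equivalent_variants(db, map, "homologous"), "functional")
  expect_equal(rep$percent_coincident, 0)
})

test_that("planted group counts give exact percentages (59/72 arithmetic)", {
  # 72 groups, 59 agreeing: percentage must come out at 81.94 (2 dp display)
  mk <- function(pos_a, pos_b) {
    glunmap:::new_alignment(
      tibble::tibble(pos_a = pos_a, aa_a = "A", pos_b = pos_b, aa_b = "A"),
      "GluN2A", "GluN2B",
      n_columns = length(pos_a), provenance = "structural", domain = "LBD"
    )
  }
  map <- build_equivalence_map(mk(1:72, 1:72))
  agree <- rep(c(TRUE, FALSE), c(59, 13))
  db <- variant_db(
    subunit = rep(c("GluN2A", "GluN2B"), 72),
    pos = rep(1:72, each = 2),
    ref_aa = "A", alt_aa = "V",
    pathogenicity = as.vector(rbind("pathogenic", ifelse(agree, "pathogenic", "benign")))
  )
  rep_ <- concordance(group_equivalent_variants(db, map, "homologous"), "pathogenicity")
  expect_equal(rep_$n_groups, 72L)
  expect_equal(rep_$n_coincident, 59L)
  expect_equal(glunmap:::round_half_up(rep_$percent_coincident, 2), 81.94)
})

test_that("concordance is invariant under member order permutation", {
  trio <- toy_trio(seed = 8)
  vdb <- toy_variant_db(trio$map, n_groups = 30, p_agree = 0.7, seed = 8)
  g <- group_equivalent_variants(vdb$db, trio$map, "homologous")
  base <- concordance(g, "pathogenicity")
  set.seed(1)
  perm <- g[sample(nrow(g)), ]
  again <- concordance(perm, "pathogenicity")
  expect_equal(again$n_coincident, base$n_coincident)
  expect_equal(again$percent_coincident, base$percent_coincident)
})

test_that("planted concordance p = 0.8 is recovered within 3 points (n = 200)", {
  trio <- toy_trio(n_residues = 320, noise_sigma = 0.2, seed = 11)
  vdb <- toy_variant_db(trio$map, n_groups = 200, p_agree = 0.8, seed = 11)
  g <- group_equivalent_variants(vdb$db, trio$map, "homologous")
  rep_ <- concordance(g, "pathogenicity")
  expect_equal(rep_$n_groups, 200L)
  expect_lt(abs(rep_$percent_coincident - 80), 3)
  # the report must reconcile exactly with the planted-truth ledger
  expect_equal(rep_$n_coincident, sum(vdb$ledger$agree_pathogenicity))
})

test_that("domain summary on identical structures reports 100% identity and zero RMSD", {
  trio <- toy_trio(n_residues = 60, noise_sigma = 0, seed = 14)
  doms <- toy_domains(60, trio$offsets)
  ds <- domain_summary(trio$chains, doms, pairs = list(c("GluN2A", "GluN2B")))
  ident_rows <- ds[!is.na(ds$identity_percent), ]
  expect_true(all(ident_rows$identity_percent == 100))
  expect_true(all(ds$rmsd[!is.na(ds$rmsd)] < 1e-6))
  expect_setequal(ds$domain, c("ATD", "ATD1", "ATD2", "LBD", "TMD"))
})
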