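# Chain models, structure reading, numbering and domain extraction.

make_toy_chain <- function(n = 10, subunit = "GluN1", pos = seq_len(n)) {
  chain_model(subunit, pos, rep(c("G", "A", "V", "L", "S"), length.out = n),
    cbind(seq_len(n), seq_len(n) %% 3, 0.5 * seq_len(n))
  )
}

test_that("chain model enforces its invariants", {
  expect_s3_class(make_toy_chain(), "glun_chain")
  expect_error(chain_model("GluN9", 1, "G", matrix(0, 1, 3)), "unknown subunit")
  expect_error(chain_model("GluN1", c(1, 1), c("G", "A"), matrix(0, 2, 3)), "strictly increasing")
  expect_error(chain_model("GluN1", c(2, 1), c("G", "A"), matrix(0, 2, 3)), "strictly increasing")
  expect_error(chain_model("GluN1", 1, "B", matrix(0, 1, 3)), "non-standard")
  expect_error(chain_model("GluN1", integer(), character()), "at least one")
})

test_that("a 10-residue single-chain PDB fixture reads as one chain of 10 sites", {
  ch <- make_toy_chain(10)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_chain_pdb(ch, path)
  got <- read_structure(path, subunit = "GluN1")
  expect_length(got, 1L)
  expect_equal(nrow(got$A), 10L)
  expect_equal(got$A$aa, ch$aa)
})

test_that("fixture-written PDB round-trips coordinates to fixed-width precision", {
  pair <- toy_structure_pair(n_residues = 30, noise_sigma = 0.4, seed = 9)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_chain_pdb(pair$chain_a, path)
  got <- read_structure(path, subunit = pair$chain_a$subunit[1])[[1]]
  expect_lt(max(abs(chain_coords(got) - chain_coords(pair$chain_a))), 1e-3)
  expect_identical(got$pos, pair$chain_a$pos)
})

test_that("unresolved residues come back as coordinate-absent sites via SEQRES", {
  ch <- make_toy_chain(12)
  df <- tibble::as_tibble(ch)
  df$x[5] <- NA; df$y[5] <- NA; df$z[5] <- NA # residue 5 unresolved
  ch2 <- glunmap:::as_chain(df)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_chain_pdb(ch2, path)
  got <- read_structure(path, subunit = "GluN1")[[1]]
  expect_equal(nrow(got), 12L) # all sites present
  expect_true(is.na(got$x[got$pos == 5]))
  expect_equal(sum(complete.cases(cbind(got$x, got$y, got$z))), 11L)
})

test_that("altloc picks highest occupancy and MSE reads as Met; junk residues drop", {
  lines <- c(
    "HEADER    SYNTHETIC TEST",
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       9.000   9.000   9.000  0.60  0.00           C",
    "ATOM      3  CA  MSE A   2       1.000   0.000   0.000  1.00  0.00           C",
    "HETATM    4  CA  XYZ A   3       2.000   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  ALA A   4       3.000   0.000   0.000  1.00  0.00           C",
    "END"
  )
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  expect_warning(got <- read_structure(path, subunit = "GluN1"), "non-standard")
  expect_equal(got$A$aa, c("G", "M", "A"))
  expect_equal(got$A$x[1], 9.0) # the 0.60-occupancy altloc won
})

test_that("unreadable files and empty chains are reported", {
  path <- withr::local_tempfile(fileext = ".pdb")
  expect_error(read_structure(path), "not found")
  writeLines(c("HEADER    JUNK", "END"), path)
  expect_error(read_structure(path, subunit = "GluN1"))
})

test_that("renumbering: identity, offset, inverse round trip, strict errors", {
  ch <- make_toy_chain(8)
  ident <- numbering_map(1:8, 1:8)
  expect_equal(renumber_chain(ch, ident)$pos, ch$pos)
  plus1 <- numbering_map(1:8, 2:9)
  shifted <- renumber_chain(ch, plus1)
  expect_equal(shifted$pos, ch$pos + 1L)
  back <- renumber_chain(shifted, invert_numbering_map(plus1))
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ch))
  partial <- numbering_map(1:5, 11:15)
  expect_error(renumber_chain(ch, partial), "unmapped construct position")
  loose <- renumber_chain(ch, partial, strict = FALSE)
  expect_equal(loose$pos, 11:15)
})

test_that("numbering maps derive from a near-identical orthologue alignment", {
  # orthologue differs by two substitutions and lacks the first two residues,
  # the rat-vs-human situation in miniature
  canonical <- "MSTWKLAGHEDVRKYLPQNMSTW"
  construct <- sub("^MS", "", canonical)
  construct <- sub("KYL", "RYL", construct)
  expect_warning(
    nmap <- numbering_map_from_alignment(construct, canonical),
    "differ between construct and canonical"
  )
  expect_equal(nmap$canonical_pos, nmap$construct_pos + 2L)
  expect_equal(sum(nmap$mismatch), 1L)
})

test_that("domain extraction returns exactly the in-range sites, idempotently", {
  ch <- make_toy_chain(10)
  doms <- domain_definition(
    rep("GluN1", 3), c("ATD1", "LBD", "LBD"), c(3L, 8L, 1L), c(5L, 9L, 1L)
  )
  atd <- extract_domain(ch, doms, "ATD1")
  expect_equal(atd$pos, 3:5)
  lbd <- extract_domain(ch, doms, "LBD") # discontinuous ranges
  expect_equal(lbd$pos, c(1L, 8L, 9L))
  expect_equal(
    tibble::as_tibble(extract_domain(atd, doms, "ATD1")),
    tibble::as_tibble(atd)
  )
  expect_error(extract_domain(ch, doms, "TMD"), "no ranges")
  doms2 <- domain_definition("GluN1", "TMD", 90L, 99L)
  expect_error(extract_domain(ch, doms2, "TMD"), "mismatch")
})

test_that("domain config JSON round-trips and rejects bad definitions", {
  doms <- toy_domains(60)
  path <- withr::local_tempfile(fileext = ".json")
  write_domain_config(doms, path)
  back <- read_domain_config(path)
  expect_equal(
    dplyr::arrange(tibble::as_tibble(back), subunit, domain, start),
    dplyr::arrange(tibble::as_tibble(doms), subunit, domain, start)
  )
  expect_error(domain_definition("GluN1", "KTD", 1, 5), "unknown domain")
  expect_error(domain_definition("GluN1", "LBD", 5, 2), "start <= end")
  expect_error(
    domain_definition(c("GluN1", "GluN1"), c("LBD", "LBD"), c(1, 3), c(4, 8)),
    "overlapping"
  )
})
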