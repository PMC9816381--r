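# Deterministic synthetic data: toy structure pairs with a known rigid
# transform and ground-truth residue correspondence, and toy variant
# databases with a planted annotation-agreement rate. Everything is
# reproducible from an explicit seed and never touches the global RNG
# stream of the caller.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# ideal alpha-helix trace: 100 degree twist and 1.5 Angstrom rise per
# residue, 2.3 Angstrom radius (canonical alpha-helix CA geometry)
helix_coords <- function(n, radius = 2.3, twist_deg = 100, rise = 1.5) {
  i <- seq_len(n) - 1L
  theta <- i * twist_deg * pi / 180
  cbind(radius * cos(theta), radius * sin(theta), rise * i)
}

# zigzag beta-strand-like trace: 3.3 A steps along x, alternating y offset
zigzag_coords <- function(n, step = 3.3, amplitude = 0.9) {
  i <- seq_len(n) - 1L
  cbind(step * i, amplitude * (i %% 2), rep(0, n))
}

random_rotation <- function() {
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  angle <- runif(1, 0, pi)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1], -axis[2], axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

random_sequence <- function(n) paste(sample(AA_ONE, n, replace = TRUE), collapse = "")

#' Generate a toy structure pair with known ground truth
#'
#' Chain B is a rigid transform of chain A plus isotropic Gaussian
#' coordinate noise and optional per-residue displacements; the true
#' correspondence is the identity on positions (with an optional offset on
#' B's numbering), stored as a ground-truth alignment alongside the chains.
#'
#' @param n_residues Number of residues (>= 4).
#' @param topology `"ideal_helix"` (100 degree twist / 1.5 Angstrom rise per
#'   residue) or `"zigzag_sheet"`.
#' @param noise_sigma Gaussian noise s.d. per coordinate, Angstrom.
#' @param displaced Named list `list(pos = offset_vector)` of extra
#'   displacements applied to chain B (position keys are A's numbering).
#' @param mutate_fraction Fraction of B residues whose amino acid is
#'   changed (sequence divergence without structural change).
#' @param offset_b Numbering offset of chain B relative to A.
#' @param subunit_a,subunit_b Subunit labels.
#' @param seed Integer seed; generation is reproducible from it.
#' @return List: `chain_a`, `chain_b` (`glun_chain`), `ground_truth` (a
#'   `glun_alignment` of the true correspondence), `rotation`,
#'   `translation` (the applied transform), and `spec` (the arguments).
#' @export
toy_structure_pair <- function(n_residues = 50, topology = c("ideal_helix", "zigzag_sheet"),
                               noise_sigma = 0, displaced = list(),
                               mutate_fraction = 0, offset_b = 0L,
                               subunit_a = "GluN2A", subunit_b = "GluN2B",
                               seed = 1L) {
  topology <- match.arg(topology)
  if (n_residues < 4L) abort("n_residues must be >= 4")
  with_seed(seed, {
    A <- switch(topology,
      ideal_helix = helix_coords(n_residues),
      zigzag_sheet = zigzag_coords(n_residues)
    )
    R <- random_rotation()
    t_vec <- runif(3, -20, 20)
    B <- sweep(A %*% t(R), 2, t_vec, "+")
    if (noise_sigma > 0) {
      B <- B + matrix(rnorm(3 * n_residues, sd = noise_sigma), ncol = 3)
    }
    for (p in names(displaced)) {
      i <- as.integer(p)
      B[i, ] <- B[i, ] + as.numeric(displaced[[p]])
    }
    seq_a <- strsplit(random_sequence(n_residues), "")[[1]]
    seq_b <- seq_a
    n_mut <- round(mutate_fraction * n_residues)
    if (n_mut > 0) {
      at <- sample(n_residues, n_mut)
      seq_b[at] <- vapply(seq_b[at], function(aa) sample(setdiff(AA_ONE, aa), 1), character(1))
    }
    pos_a <- seq_len(n_residues)
    pos_b <- pos_a + as.integer(offset_b)
    chain_a <- chain_model(subunit_a, pos_a, seq_a, A, source_label = "toy chain A")
    chain_b <- chain_model(subunit_b, pos_b, seq_b, B, source_label = "toy chain B")
    gt <- new_alignment(
      tibble(pos_a = pos_a, aa_a = seq_a, pos_b = pos_b, aa_b = seq_b),
      subunit_a, subunit_b,
      n_columns = n_residues, provenance = "structural"
    )
    list(
      chain_a = chain_a, chain_b = chain_b, ground_truth = gt,
      rotation = R, translation = t_vec,
      spec = list(
        n_residues = n_residues, topology = topology,
        noise_sigma = noise_sigma, displaced = displaced,
        mutate_fraction = mutate_fraction, offset_b = offset_b, seed = seed
      )
    )
  })
}

#' Generate a toy three-subunit system and its equivalence map
#'
#' Builds GluN1/GluN2A/GluN2B toy chains as rigid transforms of one scaffold
#' (with small numbering offsets so positions differ across subunits), runs
#' the real superposition + structural-alignment pipeline on the two pairs
#' involving GluN2A, plus GluN1-GluN2B, and assembles the equivalence map.
#'
#' @param n_residues Residues per chain.
#' @param noise_sigma Coordinate noise, Angstrom.
#' @param offsets Integer numbering offsets for the three subunits.
#' @param seed Integer seed.
#' @return List: `chains` (named list), `map` (`glun_map`), `sequences`
#'   (named character vector of full toy sequences), `offsets`.
#' @export
toy_trio <- function(n_residues = 60, noise_sigma = 0.2,
                     offsets = c(GluN1 = 0L, GluN2A = 3L, GluN2B = 5L),
                     seed = 1L) {
  chains <- with_seed(seed, {
    A <- helix_coords(n_residues)
    seq_chars <- strsplit(random_sequence(n_residues), "")[[1]]
    out <- list()
    for (s in GLUN_SUBUNITS) {
      R <- random_rotation()
      t_vec <- runif(3, -15, 15)
      X <- sweep(A %*% t(R), 2, t_vec, "+") +
        matrix(rnorm(3 * n_residues, sd = noise_sigma), ncol = 3)
      out[[s]] <- chain_model(
        s, seq_len(n_residues) + offsets[[s]], seq_chars, X,
        source_label = paste("toy", s)
      )
    }
    out
  })
  alns <- purrr::map(
    list(c("GluN1", "GluN2A"), c("GluN1", "GluN2B"), c("GluN2A", "GluN2B")),
    function(pr) align_domain(chains[[pr[1]]], chains[[pr[2]]])$alignment
  )
  map <- build_equivalence_map(alns)
  sequences <- vapply(chains, function(ch) {
    paste(c(rep("G", min(ch$pos) - 1L), ch$aa), collapse = "")
  }, character(1))
  list(chains = chains, map = map, sequences = sequences, offsets = offsets)
}

#' Generate a toy variant database with a planted agreement rate
#'
#' Plants homologous variant groups (same amino-acid change at equivalent
#' positions) on a map: each group is a pair of variants whose
#' pathogenicity (and, for a subset, functional) annotations agree with
#' probability `p_agree`. The planted truth is returned as a ledger so
#' downstream concordance and expansion reports can be reconciled against
#' it exactly.
#'
#' @param map A `glun_map` (toy or real).
#' @param n_groups Number of planted homologous groups (default 200).
#' @param p_agree Planted agreement rate: exactly `round(p_agree * n_groups)`
#'   groups (in seeded random order) get agreeing annotations, the rest get
#'   opposing ones, so the realized rate equals the nominal one up to
#'   rounding (default 1).
#' @param annotated_fraction Probability that each member carries a
#'   pathogenicity annotation at all (default 1; unannotated members are
#'   the natural targets for homology transfer).
#' @param p_pathogenic Class frequency of `pathogenic` vs `benign` among
#'   annotated members (default 0.5).
#' @param functional_fraction Fraction of groups that also carry functional
#'   annotations (default 0.5).
#' @param p_lof Class frequency of `LoF` vs `GoF` (default 0.5).
#' @param seed Integer seed.
#' @return List: `db` (`glun_variants`) and `ledger`, a tibble with one row
#'   per planted group (positions, change, planted classes and agreement
#'   flags, realized annotation status of each member).
#' @export
toy_variant_db <- function(map, n_groups = 200, p_agree = 1,
                           annotated_fraction = 1, p_pathogenic = 0.5,
                           functional_fraction = 0.5, p_lof = 0.5, seed = 1L) {
  classes <- position_classes(map)
  entries <- as_tibble(map) |>
    filter(.data$aa_a == .data$aa_b) |>
    left_join(classes, by = c(subunit_a = "subunit", pos_a = "pos")) |>
    distinct(.data$class_id, .keep_all = TRUE) # one group per equivalence class
  if (nrow(entries) < n_groups) {
    abort(sprintf(
      "map supports only %d identical-residue positions; %d groups requested",
      nrow(entries), n_groups
    ))
  }
  with_seed(seed, {
    picked <- entries[sample(nrow(entries), n_groups), , drop = FALSE]
    flip_path <- c(pathogenic = "benign", benign = "pathogenic")
    flip_fun <- c(LoF = "GoF", GoF = "LoF")
    # agreement flags are planted as an exact count in random order
    # (round(p * n) agreeing groups), so the realized agreement rate equals
    # the nominal rate up to rounding and recovery tests are sharp; the
    # ledger records the per-group realization either way
    n_agree <- round(p_agree * n_groups)
    agree_p_vec <- sample(rep(c(TRUE, FALSE), c(n_agree, n_groups - n_agree)))
    agree_f_vec <- sample(rep(c(TRUE, FALSE), c(n_agree, n_groups - n_agree)))
    rows <- list()
    ledger <- list()
    for (g in seq_len(n_groups)) {
      e <- picked[g, ]
      ref <- e$aa_a
      alt <- sample(setdiff(AA_ONE, ref), 1)
      ann1 <- runif(1) < annotated_fraction
      ann2 <- runif(1) < annotated_fraction
      class1 <- if (runif(1) < p_pathogenic) "pathogenic" else "benign"
      agree_p <- agree_p_vec[g]
      class2 <- if (agree_p) class1 else flip_path[[class1]]
      has_fun <- runif(1) < functional_fraction
      fun1 <- if (has_fun) (if (runif(1) < p_lof) "LoF" else "GoF") else "unannotated"
      agree_f <- agree_f_vec[g]
      fun2 <- if (has_fun) (if (agree_f) fun1 else flip_fun[[fun1]]) else "unannotated"
      rows[[length(rows) + 1L]] <- tibble(
        subunit = c(e$subunit_a, e$subunit_b),
        pos = c(e$pos_a, e$pos_b),
        ref_aa = ref, alt_aa = alt,
        pathogenicity = c(
          if (ann1) class1 else "unannotated",
          if (ann2) class2 else "unannotated"
        ),
        functional = c(
          if (ann1) fun1 else "unannotated",
          if (ann2) fun2 else "unannotated"
        ),
        source = "planted"
      )
      ledger[[length(ledger) + 1L]] <- tibble(
        group_id = g,
        subunit_a = e$subunit_a, pos_a = e$pos_a,
        subunit_b = e$subunit_b, pos_b = e$pos_b,
        ref_aa = ref, alt_aa = alt,
        annotated_1 = ann1, annotated_2 = ann2,
        class_1 = class1, class_2 = class2,
        agree_pathogenicity = agree_p,
        has_functional = has_fun, fun_1 = fun1, fun_2 = fun2,
        agree_functional = has_fun && agree_f
      )
    }
    list(db = new_variant_db(bind_rows(rows)), ledger = bind_rows(ledger))
  })
}

#' Toy domain definitions covering a 1..n toy chain
#'
#' Splits positions (plus per-subunit offsets) into ATD1/ATD2/LBD/TMD
#' blocks, with the LBD and TMD made sequence-discontinuous the way the
#' real domains are.
#'
#' @param n_residues Length of the toy chains (>= 24).
#' @param offsets Named integer offsets per subunit.
#' @return A `glun_domains` tibble.
#' @export
toy_domains <- function(n_residues = 60,
                        offsets = c(GluN1 = 0L, GluN2A = 3L, GluN2B = 5L)) {
  if (n_residues < 24L) abort("toy domains need n_residues >= 24")
  q <- n_residues %/% 6
  base <- tibble(
    domain = c("ATD1", "ATD2", "LBD", "TMD", "LBD", "TMD"),
    start = c(1L, q + 1L, 2L * q + 1L, 3L * q + 1L, 4L * q + 1L, 5L * q + 1L),
    end = c(q, 2L * q, 3L * q, 4L * q, 5L * q, n_residues)
  )
  purrr::map_dfr(names(offsets), function(s) {
    mutate(base,
      subunit = s,
      start = .data$start + offsets[[s]], end = .data$end + offsets[[s]]
    )
  }) |>
    (\(df) domain_definition(df$subunit, df$domain, df$start, df$end))()
}

#' Write a complete synthetic demo workspace
#'
#' Generates the toy trio, its sequences, domain definitions, a planted
#' variant table and the ground-truth ledger, and writes them under `dir`
#' as plain-text files (PDB, FASTA, JSON, TSV). This is the input set for
#' the end-to-end walkthrough: superpose, map, annotate, evaluate.
#'
#' @param dir Output directory (created if needed).
#' @param n_residues,noise_sigma,seed Passed to [toy_trio()].
#' @param n_groups,p_agree,annotated_fraction Passed to [toy_variant_db()].
#' @return Invisibly, a named list of the file paths written plus the
#'   in-memory objects (`trio`, `variants`).
#' @export
write_demo_workspace <- function(dir, n_residues = 60, noise_sigma = 0.2,
                                 n_groups = 25, p_agree = 1,
                                 annotated_fraction = 0.8, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trio <- toy_trio(n_residues = n_residues, noise_sigma = noise_sigma, seed = seed)
  paths <- list()
  for (s in names(trio$chains)) {
    paths[[paste0("pdb_", s)]] <-
      write_chain_pdb(trio$chains[[s]], file.path(dir, paste0(s, "_synthetic.pdb")))
  }
  paths$sequences <- write_fasta(trio$sequences, file.path(dir, "sequences_synthetic.fasta"))
  paths$domains <- write_domain_config(
    toy_domains(n_residues, trio$offsets), file.path(dir, "domains_synthetic.json")
  )
  paths$map <- write_equivalence_map(trio$map, file.path(dir, "equivalence_map.json"))
  vdb <- toy_variant_db(trio$map,
    n_groups = n_groups, p_agree = p_agree,
    annotated_fraction = annotated_fraction, seed = seed + 1L
  )
  paths$variants <- write_variant_table(vdb$db, file.path(dir, "variants_synthetic.tsv"))
  utils::write.table(vdb$ledger, file.path(dir, "planted_truth_ledger.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  paths$ledger <- file.path(dir, "planted_truth_ledger.tsv")
  invisible(list(paths = paths, trio = trio, variants = vdb))
}
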