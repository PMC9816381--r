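# Loader for the user-supplied experimental inputs (see
# inst/extdata/real/README.md). The toy-scale suite never needs these; the
# real-data checks use them when present.

real_data_dir <- function() {
  dir <- system.file("extdata", "real", package = "glunmap")
  if (dir == "") dir <- file.path("..", "..", "inst", "extdata", "real")
  dir
}

real_data_paths <- function() {
  dir <- real_data_dir()
  list(
    glun1_glun2a = file.path(dir, "6ira.cif"),
    glun1_glun2b = file.path(dir, "6whr.cif"),
    canonical = file.path(dir, "canonical.fasta"),
    domains = file.path(dir, "domains.json"),
    variants = file.path(dir, "variants.tsv")
  )
}

real_data_present <- function(need = c("glun1_glun2a", "glun1_glun2b", "canonical", "domains")) {
  all(vapply(real_data_paths()[need], file.exists, logical(1)))
}

# pick, per required subunit, the chain whose sequence best matches the
# canonical sequence, and renumber it into canonical numbering
load_real_chains <- function() {
  paths <- real_data_paths()
  seqs <- read_fasta(paths$canonical)
  chains <- list()
  assign_from <- function(structure_path, wanted) {
    parsed <- read_structure(structure_path, subunit = "GluN1")
    for (sub in wanted) {
      canonical <- seqs[[sub]]
      scores <- vapply(parsed, function(ch) {
        attr(global_align(chain_sequence_of(ch), canonical), "score")
      }, numeric(1))
      best <- parsed[[which.max(scores)]]
      construct_seq <- chain_sequence_of(best)
      nmap <- suppressWarnings(
        numbering_map_from_alignment(construct_seq, canonical)
      )
      # construct index -> author numbering of the structure
      author <- numbering_map(seq_len(nrow(best)), best$pos)
      full <- numbering_map(
        author$canonical_pos[match(nmap$construct_pos, author$construct_pos)],
        nmap$canonical_pos
      )
      df <- tibble::as_tibble(best)
      df$subunit <- sub
      chains[[sub]] <<- renumber_chain(
        chain_model(sub, best$pos, best$aa, cbind(best$x, best$y, best$z)),
        full,
        strict = FALSE
      )
    }
  }
  assign_from(paths$glun1_glun2a, c("GluN1", "GluN2A"))
  assign_from(paths$glun1_glun2b, "GluN2B")
  list(chains = chains, sequences = seqs)
}

chain_sequence_of <- function(ch) paste(ch$aa, collapse = "")
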