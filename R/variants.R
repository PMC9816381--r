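# Missense variant records and their pathogenicity / functional annotations.
# Protein-level only: genomic liftover, transcripts and truncating variants
# are out of scope (the transfer algorithm addresses missense changes).

GENE_TO_SUBUNIT <- c(
  GRIN1 = "GluN1", GRIN2A = "GluN2A", GRIN2B = "GluN2B",
  GluN1 = "GluN1", GluN2A = "GluN2A", GluN2B = "GluN2B"
)

# heterogeneous source vocabularies -> the package's enums
PATHOGENICITY_SYNONYMS <- c(
  "pathogenic" = "pathogenic", "likely pathogenic" = "pathogenic",
  "likely_pathogenic" = "pathogenic",
  "benign" = "benign", "likely benign" = "benign", "likely_benign" = "benign",
  "uncertain" = "uncertain", "uncertain significance" = "uncertain",
  "uncertain_significance" = "uncertain", "vus" = "uncertain",
  "unannotated" = "unannotated", "." = "unannotated", "na" = "unannotated"
)
FUNCTIONAL_SYNONYMS <- c(
  "lof" = "LoF", "loss-of-function" = "LoF", "loss of function" = "LoF",
  "gof" = "GoF", "gain-of-function" = "GoF", "gain of function" = "GoF",
  "complex" = "complex",
  "unannotated" = "unannotated", "." = "unannotated", "na" = "unannotated"
)

normalize_with <- function(x, table) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(table[key])
  out[is.na(x) | key == ""] <- "unannotated"
  out
}
normalize_pathogenicity <- function(x) normalize_with(x, PATHOGENICITY_SYNONYMS)
normalize_functional <- function(x) normalize_with(x, FUNCTIONAL_SYNONYMS)

#' Parse HGVS protein notation for a missense variant
#'
#' Accepts `p.(Gly459Arg)`, `p.Gly459Arg` and one-letter `p.G459R`, with an
#' optional `GENE:` prefix (`GRIN2B:p.(Gly459Arg)`) supplying the subunit.
#' Only missense substitutions are supported: stop (`Ter`/`*`), frameshift,
#' deletion/insertion and synonymous notation raise an unsupported-class
#' error.
#'
#' @param text HGVS-p string(s).
#' @param subunit Subunit for records without a gene prefix.
#' @return Tibble with columns `subunit`, `pos`, `ref_aa`, `alt_aa`
#'   (one-letter) and `hgvs_p` (normalized three-letter form).
#' @examples
#' parse_hgvs_p("p.(Gly459Arg)", subunit = "GluN2B")
#' @export
parse_hgvs_p <- function(text, subunit = NULL) {
  purrr::map_dfr(text, parse_hgvs_p_one, subunit = subunit)
}

parse_hgvs_p_one <- function(text, subunit = NULL) {
  raw <- trimws(text)
  body <- raw
  if (grepl(":", body, fixed = TRUE)) {
    gene <- sub(":.*$", "", body)
    body <- sub("^[^:]*:", "", body)
    subunit <- unname(GENE_TO_SUBUNIT[gene])
    if (is.na(subunit)) {
      abort(paste0("unknown gene/subunit prefix '", gene, "' in '", raw, "'"))
    }
  }
  if (is.null(subunit)) abort(paste0("no subunit given for '", raw, "'"))
  assert_subunit(subunit)
  body <- sub("^p\\.", "", body)
  body <- sub("^\\((.*)\\)$", "\\1", body)
  if (grepl("(Ter|\\*|fs|del|ins|dup|=)", body)) {
    abort(paste0(
      "unsupported variant class in '", raw,
      "': only missense substitutions are handled"
    ))
  }
  m3 <- stringr::str_match(body, "^([A-Za-z]{3})(\\d+)([A-Za-z]{3})$")
  m1 <- stringr::str_match(body, "^([A-Za-z])(\\d+)([A-Za-z])$")
  if (!is.na(m3[1, 1])) {
    ref <- aa_to_one(m3[1, 2]); alt <- aa_to_one(m3[1, 4]); pos <- as.integer(m3[1, 3])
  } else if (!is.na(m1[1, 1])) {
    ref <- toupper(m1[1, 2]); alt <- toupper(m1[1, 4]); pos <- as.integer(m1[1, 3])
    if (!is_standard_aa1(ref) || !is_standard_aa1(alt)) {
      abort(paste0("unknown residue code in '", raw, "'"))
    }
  } else {
    abort(paste0("cannot parse HGVS-p notation '", raw, "'"))
  }
  if (ref == alt) abort(paste0("self-substitution in '", raw, "' (not missense)"))
  tibble(
    subunit = subunit, pos = pos, ref_aa = ref, alt_aa = alt,
    hgvs_p = format_hgvs_p(ref, pos, alt)
  )
}

#' Format a missense variant in normalized HGVS-p notation
#'
#' @param ref_aa,alt_aa One-letter residue codes.
#' @param pos Canonical position.
#' @return `p.(RefPosAlt)` in three-letter codes, e.g. `p.(Gly459Arg)`.
#' @export
format_hgvs_p <- function(ref_aa, pos, alt_aa) {
  sprintf("p.(%s%d%s)", aa_to_three(ref_aa), as.integer(pos), aa_to_three(alt_aa))
}

new_variant_db <- function(df) {
  need <- c("subunit", "pos", "ref_aa", "alt_aa", "pathogenicity", "functional", "source")
  df <- as_tibble(df)[, need]
  df$pos <- as.integer(df$pos)
  if (any(df$ref_aa == df$alt_aa)) abort("self-substitution in variant table")
  if (!all(df$subunit %in% GLUN_SUBUNITS)) abort("unknown subunit in variant table")
  if (!all(df$pathogenicity %in% PATHOGENICITY_LEVELS)) abort("bad pathogenicity value")
  if (!all(df$functional %in% FUNCTIONAL_LEVELS)) abort("bad functional value")
  key <- paste(df$subunit, df$pos, df$ref_aa, df$alt_aa)
  if (anyDuplicated(key)) {
    dup <- df[key %in% key[duplicated(key)], , drop = FALSE] |>
      distinct(.data$subunit, .data$pos, .data$ref_aa, .data$alt_aa,
        .data$pathogenicity, .data$functional)
    if (nrow(dup) > length(unique(paste(dup$subunit, dup$pos, dup$ref_aa, dup$alt_aa)))) {
      abort("duplicate variant key with conflicting annotations")
    }
    df <- df[!duplicated(key), , drop = FALSE]
  }
  df <- arrange(df, .data$subunit, .data$pos, .data$ref_aa, .data$alt_aa)
  class(df) <- c("glun_variants", class(df))
  df
}

#' Build a variant database tibble
#'
#' @param subunit,pos,ref_aa,alt_aa Variant keys (one-letter residues).
#' @param pathogenicity,functional Annotation classes; free vocabulary is
#'   normalized (`"likely pathogenic"` -> `"pathogenic"`, `"VUS"` ->
#'   `"uncertain"`, `"."` -> `"unannotated"`, ...).
#' @param source Free-text provenance (default `"unspecified"`).
#' @return A `glun_variants` tibble keyed by
#'   (`subunit`, `pos`, `ref_aa`, `alt_aa`); duplicate keys with identical
#'   annotations are collapsed, conflicting ones are an error.
#' @export
variant_db <- function(subunit, pos, ref_aa, alt_aa,
                       pathogenicity = "unannotated",
                       functional = "unannotated",
                       source = "unspecified") {
  new_variant_db(tibble(
    subunit = subunit, pos = as.integer(pos),
    ref_aa = toupper(ref_aa), alt_aa = toupper(alt_aa),
    pathogenicity = normalize_pathogenicity(pathogenicity),
    functional = normalize_functional(functional),
    source = source
  ))
}

#' Read / write a variant annotation table (TSV)
#'
#' Tab-separated, UTF-8, header required with columns `gene`, `hgvs_p`,
#' `pathogenicity`, `functional` (optional `source`); `"."` marks a missing
#' annotation. Reading normalizes vocabulary and notation, so
#' write-then-read is the identity on normalized records.
#'
#' @param path TSV path.
#' @return `read_variant_table()` returns a `glun_variants` tibble.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path,
    sep = "\t", header = TRUE, quote = "",
    colClasses = "character", na.strings = NULL, fileEncoding = "UTF-8"
  )
  need <- c("gene", "hgvs_p", "pathogenicity", "functional")
  if (!all(need %in% names(df))) {
    abort(paste0(
      "variant table must have columns ", paste(need, collapse = ", ")
    ))
  }
  if (nrow(df) == 0L) {
    return(new_variant_db(tibble(
      subunit = character(), pos = integer(), ref_aa = character(),
      alt_aa = character(), pathogenicity = character(),
      functional = character(), source = character()
    )))
  }
  pat <- normalize_pathogenicity(df$pathogenicity)
  fun <- normalize_functional(df$functional)
  for (i in seq_len(nrow(df))) {
    if (is.na(pat[i])) abort(sprintf("row %d: unknown pathogenicity token '%s'", i, df$pathogenicity[i]))
    if (is.na(fun[i])) abort(sprintf("row %d: unknown functional token '%s'", i, df$functional[i]))
  }
  parsed <- parse_hgvs_p(paste0(df$gene, ":", df$hgvs_p))
  new_variant_db(tibble(
    subunit = parsed$subunit, pos = parsed$pos,
    ref_aa = parsed$ref_aa, alt_aa = parsed$alt_aa,
    pathogenicity = pat, functional = fun,
    source = if ("source" %in% names(df)) df$source else "unspecified"
  ))
}

#' @rdname read_variant_table
#' @param db A `glun_variants` tibble.
#' @export
write_variant_table <- function(db, path) {
  subunit_to_gene <- setNames(names(GENE_TO_SUBUNIT)[1:3], GLUN_SUBUNITS)
  out <- tibble(
    gene = subunit_to_gene[db$subunit],
    hgvs_p = format_hgvs_p(db$ref_aa, db$pos, db$alt_aa),
    pathogenicity = ifelse(db$pathogenicity == "unannotated", ".", db$pathogenicity),
    functional = ifelse(db$functional == "unannotated", ".", db$functional),
    source = db$source
  )
  utils::write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Check variant reference residues against canonical sequences
#'
#' @param db A `glun_variants` tibble.
#' @param sequences Named character vector of canonical sequences keyed by
#'   subunit.
#' @return Tibble of mismatching records with an `expected_aa` column; zero
#'   rows when every `ref_aa` matches its canonical residue.
#' @export
validate_against_sequence <- function(db, sequences) {
  missing <- setdiff(unique(db$subunit), names(sequences))
  if (length(missing)) {
    abort(paste0("no canonical sequence for: ", paste(missing, collapse = ", ")))
  }
  if (nrow(db) == 0L) {
    return(mutate(as_tibble(db), expected_aa = character()))
  }
  expected <- vapply(seq_len(nrow(db)), function(i) {
    substring(sequences[[db$subunit[i]]], db$pos[i], db$pos[i])
  }, character(1))
  out <- as_tibble(db)
  out$expected_aa <- expected
  out[expected != db$ref_aa | expected == "", , drop = FALSE]
}
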