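# Residue code tables shared across the package. Only the 20 standard amino
# acids are admitted; selenomethionine is folded into Met at parse time.

AA_THREE <- c(
  "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val"
)
AA_ONE <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)
names(AA_ONE) <- AA_THREE
AA_THREE_BY_ONE <- setNames(AA_THREE, AA_ONE)

#' Convert between one- and three-letter amino-acid codes
#'
#' Case-insensitive on input; three-letter output uses title case (`Gly`),
#' one-letter output is upper case. Only the 20 standard residues are
#' accepted.
#'
#' @param x Character vector of residue codes (all one-letter or all
#'   three-letter).
#' @return Character vector of the same length in the other convention.
#' @examples
#' aa_to_one("Gly")
#' aa_to_three("R")
#' @export
aa_to_one <- function(x) {
  key <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3)))
  out <- unname(AA_ONE[key])
  if (anyNA(out) || any(nchar(x) != 3L)) {
    bad <- unique(x[is.na(out) | nchar(x) != 3L])
    abort(paste0("unknown three-letter residue code: ", paste(bad, collapse = ", ")))
  }
  out
}

#' @rdname aa_to_one
#' @export
aa_to_three <- function(x) {
  out <- unname(AA_THREE_BY_ONE[toupper(x)])
  if (anyNA(out) || any(nchar(x) != 1L)) {
    bad <- unique(x[is.na(out) | nchar(x) != 1L])
    abort(paste0("unknown one-letter residue code: ", paste(bad, collapse = ", ")))
  }
  out
}

is_standard_aa1 <- function(x) x %in% AA_ONE

assert_sequence <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq) || nchar(seq) == 0L) {
    abort(paste0(what, " must be a single non-empty string"))
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!is_standard_aa1(chars))
  if (length(bad)) {
    abort(paste0(
      what, " contains non-standard letter '", chars[bad[1]],
      "' at position ", bad[1]
    ))
  }
  paste(chars, collapse = "")
}

# PDB residue names -> one-letter, MSE treated as MET.
PDB_AA3 <- setNames(AA_ONE, toupper(AA_THREE))
PDB_AA3[["MSE"]] <- "M"

pdb_resid_to_one <- function(x) unname(PDB_AA3[toupper(x)])
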