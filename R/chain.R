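# Chain models: one row per residue site, alpha-carbon coordinates in
# Angstrom, positions in canonical (full-length, signal peptide included)
# numbering. Structurally unresolved residues keep their row with NA
# coordinates so the sequence fallback can claim them later.

#' Construct a chain model
#'
#' A chain model is a tibble with one row per residue site: `subunit`, `pos`
#' (canonical 1-based position), `aa` (one-letter residue), and `x`, `y`, `z`
#' alpha-carbon coordinates in Angstrom (`NA` for unresolved sites).
#'
#' @param subunit One of `"GluN1"`, `"GluN2A"`, `"GluN2B"`.
#' @param pos Integer vector of canonical positions, strictly increasing.
#' @param aa One-letter residue codes (same length as `pos`).
#' @param xyz Numeric matrix with 3 columns (or `NULL` for a coordinate-free
#'   chain); rows may contain `NA` for unresolved residues.
#' @param source_label Free-text provenance, e.g. `"6IRA chain A"`.
#' @return A `glun_chain` tibble.
#' @examples
#' chain_model("GluN1", 1:3, c("G", "A", "V"), diag(3))
#' @export
chain_model <- function(subunit, pos, aa, xyz = NULL, source_label = "unknown") {
  assert_subunit(subunit)
  pos <- as.integer(pos)
  if (length(pos) == 0L) abort("chain must contain at least one residue")
  if (any(pos < 1L)) abort("canonical positions must be >= 1")
  if (is.unsorted(pos, strictly = TRUE)) {
    abort("canonical positions must be strictly increasing (and unique)")
  }
  aa <- toupper(aa)
  if (length(aa) != length(pos)) abort("pos and aa lengths differ")
  if (!all(is_standard_aa1(aa))) {
    abort(paste0(
      "non-standard residue(s) at position(s) ",
      paste(pos[!is_standard_aa1(aa)], collapse = ", ")
    ))
  }
  if (is.null(xyz)) {
    xyz <- matrix(NA_real_, nrow = length(pos), ncol = 3)
  }
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != length(pos) || ncol(xyz) != 3) {
    abort("xyz must be an n x 3 matrix matching pos")
  }
  out <- tibble(
    subunit = subunit, pos = pos, aa = aa,
    x = as.numeric(xyz[, 1]), y = as.numeric(xyz[, 2]), z = as.numeric(xyz[, 3])
  )
  attr(out, "source_label") <- source_label
  class(out) <- c("glun_chain", class(out))
  out
}

as_chain <- function(df, subunit = NULL, source_label = NULL) {
  chain_model(
    subunit %||% df$subunit[1],
    df$pos, df$aa, cbind(df$x, df$y, df$z),
    source_label %||% (attr(df, "source_label") %||% "unknown")
  )
}

chain_coords <- function(chain, resolved_only = TRUE) {
  m <- cbind(chain$x, chain$y, chain$z)
  rownames(m) <- chain$pos
  if (resolved_only) m <- m[stats::complete.cases(m), , drop = FALSE]
  m
}

chain_sequence <- function(chain) paste(chain$aa, collapse = "")

#' @export
print.glun_chain <- function(x, ...) {
  n_res <- sum(stats::complete.cases(cbind(x$x, x$y, x$z)))
  cat(sprintf(
    "<glun_chain> %s, %d sites (%d with coordinates), source: %s\n",
    x$subunit[1], nrow(x), n_res, attr(x, "source_label") %||% "unknown"
  ))
  NextMethod()
}

#' Read polymer chains from a PDB or mmCIF structure file
#'
#' Extracts one chain model per polymer chain, keeping alpha carbons only.
#' Alternate locations are resolved to the highest-occupancy conformer (ties:
#' first in file); `MSE` is read as methionine; other non-standard residues
#' are dropped with a warning. Chains without any alpha carbon are skipped
#' with a warning. Positions are the author residue numbers of the file; use
#' [renumber_chain()] to move to canonical numbering when they differ.
#'
#' @param path Path to a structure file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @param subunit Subunit label to assign, either a single value for all
#'   chains or a named vector `c(A = "GluN1", ...)` keyed by chain ID.
#'   Unnamed default is `"GluN1"` so toy files load without ceremony.
#' @param chains Optional character vector restricting which chain IDs to
#'   keep (e.g. the first protomer of a homodimeric pair).
#' @return Named list of `glun_chain` tibbles, one per chain ID.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           subunit = "GluN1", chains = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  if (!file.exists(path)) abort(paste0("structure file not found: ", path))
  parsed <- tryCatch(
    if (format == "cif") {
      bio3d::read.cif(path, rm.alt = FALSE)
    } else {
      bio3d::read.pdb(path, rm.alt = FALSE)
    },
    error = function(e) abort(paste0("cannot parse '", path, "': ", conditionMessage(e)))
  )
  atoms <- parsed$atom
  atoms <- atoms[atoms$elety == "CA" & atoms$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  chain_ids <- unique(atoms$chain)
  out <- list()
  for (cid in chain_ids) {
    ca <- atoms[atoms$chain == cid, , drop = FALSE]
    # resolve altlocs: highest occupancy, first on tie (file order is kept by split)
    ca <- do.call(rbind, lapply(split(ca, ca$resno), function(g) {
      g[which.max(replace(g$o, is.na(g$o), 1)), , drop = FALSE]
    }))
    ca <- ca[order(ca$resno), , drop = FALSE]
    aa1 <- pdb_resid_to_one(ca$resid)
    if (anyNA(aa1)) {
      warn(paste0(
        "chain ", cid, ": dropping non-standard residue(s) ",
        paste(unique(ca$resid[is.na(aa1)]), collapse = ", ")
      ))
      ca <- ca[!is.na(aa1), , drop = FALSE]
      aa1 <- aa1[!is.na(aa1)]
    }
    if (nrow(ca) == 0L) {
      warn(paste0("chain ", cid, " has no usable alpha carbons; skipped"))
      next
    }
    sub <- if (!is.null(names(subunit))) subunit[[cid]] else subunit[[1]]
    out[[cid]] <- chain_model(
      sub, ca$resno, aa1, cbind(ca$x, ca$y, ca$z),
      source_label = paste0(basename(path), " chain ", cid)
    )
  }
  if (length(out) == 0L) abort(paste0("no polymer chain with alpha carbons in ", path))
  # SEQRES-style entity sequence, when present, fills unresolved residues
  seqres <- parsed$seqres
  if (!is.null(seqres) && length(seqres)) {
    for (cid in names(out)) {
      entity <- pdb_resid_to_one(seqres[names(seqres) == cid])
      entity <- entity[!is.na(entity)]
      if (length(entity)) {
        # SEQRES has no numbering of its own: anchor it so it ends with the
        # last observed residue unless it already covers pos 1..n
        first_pos <- if (max(out[[cid]]$pos) <= length(entity)) {
          1L
        } else {
          max(out[[cid]]$pos) - length(entity) + 1L
        }
        filled <- try(
          suppressWarnings(fill_unresolved(
            out[[cid]], paste(entity, collapse = ""), first_pos = first_pos
          )),
          silent = TRUE
        )
        if (!inherits(filled, "try-error")) out[[cid]] <- filled
      }
    }
  }
  out
}

#' Add coordinate-absent sites for unresolved residues
#'
#' Given a chain whose rows cover only the structurally resolved residues and
#' the full sequence of the construct, inserts the missing positions as rows
#' with `NA` coordinates. The observed residues must occur in the sequence at
#' their stated positions (1-based over `sequence`); otherwise the chain is
#' returned unchanged with a warning.
#'
#' @param chain A `glun_chain`.
#' @param sequence Full-length sequence of the same numbering frame.
#' @param first_pos Position carried by the first letter of `sequence`
#'   (default 1); lets a SEQRES block of an offset-numbered construct be
#'   used directly.
#' @return A `glun_chain` covering positions
#'   `first_pos:(first_pos + nchar(sequence) - 1)`, unresolved sites with
#'   `NA` coordinates.
#' @export
fill_unresolved <- function(chain, sequence, first_pos = 1L) {
  sequence <- assert_sequence(sequence)
  seq_aa <- strsplit(sequence, "")[[1]]
  idx <- chain$pos - as.integer(first_pos) + 1L
  if (any(idx < 1L) || max(idx) > length(seq_aa) || !all(seq_aa[idx] == chain$aa)) {
    warn("observed residues do not match the supplied sequence; chain left as-is")
    return(chain)
  }
  missing_pos <- setdiff(
    seq.int(first_pos, length.out = length(seq_aa)), chain$pos
  )
  if (!length(missing_pos)) return(chain)
  extra <- tibble(
    subunit = chain$subunit[1], pos = as.integer(missing_pos),
    aa = seq_aa[missing_pos], x = NA_real_, y = NA_real_, z = NA_real_
  )
  all_rows <- arrange(bind_rows(as_tibble(chain), extra), .data$pos)
  as_chain(all_rows, source_label = attr(chain, "source_label"))
}

#' Write a chain model as a minimal PDB file
#'
#' Alpha-carbon-only PDB output (fixed-width ATOM records, 3 decimal places,
#' i.e. 1e-3 Angstrom precision). A SEQRES block covering every site —
#' including coordinate-absent ones — is emitted so that reading the file
#' back recovers unresolved residues. The header marks the file as synthetic.
#'
#' @param chain A `glun_chain`.
#' @param path Output path.
#' @param chain_id Single-character chain identifier.
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path, chain_id = "A") {
  lines <- c(
    "HEADER    SYNTHETIC TOY STRUCTURE",
    sprintf("TITLE     SYNTHETIC ALPHA-CARBON MODEL (%s)", chain$subunit[1]),
    "REMARK 999 GENERATED BY GLUNMAP FIXTURES - NOT AN EXPERIMENTAL STRUCTURE"
  )
  aa3 <- toupper(aa_to_three(chain$aa))
  n <- length(aa3)
  for (i in seq(1L, n, by = 13L)) {
    idx <- i:min(i + 12L, n)
    lines <- c(lines, sprintf(
      "SEQRES %3d %s %4d  %s", (i - 1L) %/% 13L + 1L, chain_id, n,
      paste(aa3[idx], collapse = " ")
    ))
  }
  resolved <- stats::complete.cases(cbind(chain$x, chain$y, chain$z))
  ser <- 0L
  for (i in which(resolved)) {
    ser <- ser + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      ser, aa3[i], chain_id, chain$pos[i], chain$x[i], chain$y[i], chain$z[i]
    ))
  }
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read canonical sequences from a FASTA file
#'
#' @param path FASTA path. Record names are truncated at the first
#'   whitespace; use subunit names (`GluN1`, ...) as identifiers.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(toupper(seqs), names(seqs))), path
  )
  invisible(path)
}
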