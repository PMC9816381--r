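# Construct-to-canonical numbering. Deposited constructs (and the rat GluN2B
# structure) do not use human canonical numbering; a numbering map is a
# strictly monotone partial function construct_pos -> canonical_pos.

#' Build a numbering map
#'
#' @param construct_pos,canonical_pos Equal-length integer vectors, both
#'   strictly increasing (order-consistent offset segments).
#' @return A tibble with columns `construct_pos`, `canonical_pos`.
#' @examples
#' numbering_map(1:10, 23:32) # uniform +22 offset
#' @export
numbering_map <- function(construct_pos, canonical_pos) {
  construct_pos <- as.integer(construct_pos)
  canonical_pos <- as.integer(canonical_pos)
  if (length(construct_pos) != length(canonical_pos)) {
    abort("construct_pos and canonical_pos lengths differ")
  }
  ord <- order(construct_pos)
  construct_pos <- construct_pos[ord]
  canonical_pos <- canonical_pos[ord]
  if (is.unsorted(construct_pos, strictly = TRUE) ||
    is.unsorted(canonical_pos, strictly = TRUE)) {
    abort("numbering map must be strictly increasing on both sides")
  }
  tibble(construct_pos = construct_pos, canonical_pos = canonical_pos)
}

#' Derive a numbering map from a pairwise sequence alignment
#'
#' Aligns the construct sequence to the canonical sequence globally and reads
#' the aligned columns off as a numbering map. Mismatched (non-identical)
#' aligned residues are kept but flagged, which is how a near-identical
#' orthologue (e.g. rat vs human GluN2B) is reconciled with human canonical
#' numbering.
#'
#' @param construct_seq,canonical_seq Amino-acid strings.
#' @param ... Passed to [global_align()] (scoring scheme).
#' @return A numbering map tibble with an extra logical column `mismatch`.
#' @export
numbering_map_from_alignment <- function(construct_seq, canonical_seq, ...) {
  aln <- global_align(construct_seq, canonical_seq, ...)
  out <- numbering_map(aln$pos_a, aln$pos_b)
  out$mismatch <- !aln$same_aa
  if (any(out$mismatch)) {
    warn(sprintf(
      "%d aligned position(s) differ between construct and canonical sequence (kept, flagged)",
      sum(out$mismatch)
    ))
  }
  out
}

#' Renumber a chain into canonical numbering
#'
#' @param chain A `glun_chain` in construct numbering.
#' @param map A numbering map from [numbering_map()].
#' @param strict If `TRUE` (default) an unmapped residue is an error; if
#'   `FALSE` unmapped residues are dropped.
#' @return The chain with `pos` rewritten to canonical numbering.
#' @export
renumber_chain <- function(chain, map, strict = TRUE) {
  hit <- match(chain$pos, map$construct_pos)
  if (anyNA(hit)) {
    if (strict) {
      abort(paste0(
        "unmapped construct position(s): ",
        paste(chain$pos[is.na(hit)], collapse = ", ")
      ))
    }
    chain <- chain[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  df <- as_tibble(chain)
  df$pos <- map$canonical_pos[hit]
  as_chain(df, source_label = attr(chain, "source_label"))
}

#' Invert a numbering map
#'
#' @param map A numbering map.
#' @return The canonical-to-construct map.
#' @export
invert_numbering_map <- function(map) {
  numbering_map(map$canonical_pos, map$construct_pos)
}
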