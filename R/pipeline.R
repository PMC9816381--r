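# High-level drivers tying the modules together: per-domain superposition of
# subunit pairs, assembly of the full equivalence map, and the standard
# report set.

#' Build the cross-subunit equivalence map from chains and domain ranges
#'
#' For each subunit pair, every domain block (ATD as its two sublobes when
#' `ATD1`/`ATD2` ranges are defined, else whole `ATD`; then `LBD` and `TMD`)
#' is extracted, superposed with iterative outlier rejection and read off as
#' a structural alignment. When canonical sequences are supplied, a global
#' sequence alignment of each pair provides the fallback for regions without
#' structural coverage (CTD, unresolved loops), subject to the minimum-run
#' guard of [build_equivalence_map()].
#'
#' @param chains Named list of `glun_chain` objects keyed by subunit, in
#'   canonical numbering.
#' @param domains A `glun_domains` definition.
#' @param sequences Optional named character vector of full canonical
#'   sequences (enables the sequence fallback).
#' @param pairs List of subunit pairs to align; defaults to all pairs
#'   present in `chains`.
#' @param cycles,reject_cutoff,pairing_cutoff Superposition and pairing
#'   parameters, see [superpose()] and [structural_alignment()].
#' @param min_fallback_run Passed to [build_equivalence_map()].
#' @return A `glun_map`.
#' @export
build_glun_map <- function(chains, domains, sequences = NULL, pairs = NULL,
                           cycles = 5L, reject_cutoff = 2.0,
                           pairing_cutoff = 4.0, min_fallback_run = 5L) {
  subunits <- names(chains)
  if (is.null(pairs)) pairs <- utils::combn(subunits, 2, simplify = FALSE)
  structural <- list()
  fallbacks <- list()
  for (pr in pairs) {
    a <- chains[[pr[1]]]; b <- chains[[pr[2]]]
    has_sublobes <- all(c("ATD1", "ATD2") %in%
      domains$domain[domains$subunit == a$subunit[1]])
    blocks <- c(if (has_sublobes) c("ATD1", "ATD2") else "ATD", "LBD", "TMD")
    for (d in blocks) {
      res <- align_domain(
        extract_domain(a, domains, d), extract_domain(b, domains, d),
        cycles = cycles, reject_cutoff = reject_cutoff,
        pairing_cutoff = pairing_cutoff, domain = d
      )
      structural[[length(structural) + 1L]] <- res$alignment
    }
    if (!is.null(sequences)) {
      fallbacks[[length(fallbacks) + 1L]] <- global_align(
        sequences[[pr[1]]], sequences[[pr[2]]],
        subunit_a = pr[1], subunit_b = pr[2]
      )
    }
  }
  build_equivalence_map(structural,
    sequence_fallback = fallbacks,
    min_fallback_run = min_fallback_run, domains = domains
  )
}
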