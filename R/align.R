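# Residue alignments: ordered pairs of positions across two chains, either
# from a global sequence alignment (Needleman-Wunsch) or read off a
# structural superposition. Both carry provenance so the equivalence map can
# give structure precedence over sequence.

new_alignment <- function(pairs, subunit_a, subunit_b, n_columns,
                          provenance = c("structural", "sequence"),
                          domain = NA_character_, score = NA_real_) {
  provenance <- match.arg(provenance)
  pairs <- as_tibble(pairs)
  if (nrow(pairs)) {
    if (is.unsorted(pairs$pos_a, strictly = TRUE) ||
      is.unsorted(pairs$pos_b, strictly = TRUE)) {
      abort("alignment pairs must be strictly increasing on both sides (no crossings)")
    }
  }
  pairs$same_aa <- pairs$aa_a == pairs$aa_b
  pairs$provenance <- provenance
  attr(pairs, "subunit_a") <- subunit_a
  attr(pairs, "subunit_b") <- subunit_b
  attr(pairs, "n_columns") <- as.integer(n_columns)
  attr(pairs, "domain") <- domain
  attr(pairs, "score") <- score
  class(pairs) <- c("glun_alignment", class(pairs))
  pairs
}

#' @export
print.glun_alignment <- function(x, ...) {
  st <- identity_stats(x)
  cat(sprintf(
    "<glun_alignment> %s vs %s (%s): %d pairs / %d columns, %d identical (%.2f%%)\n",
    attr(x, "subunit_a") %||% "?", attr(x, "subunit_b") %||% "?",
    x$provenance[1] %||% "?", nrow(x), attr(x, "n_columns"),
    st$identical_count, st$identity_percent
  ))
  NextMethod()
}

#' Global (Needleman-Wunsch) pairwise sequence alignment
#'
#' Optimal global alignment with affine gap penalties: a gap of length L
#' costs `gap_open + L * gap_extend`. Returns the aligned residue pairs with
#' 1-based positions into each input sequence; gap columns contribute to
#' `n_columns` (an attribute) but not to the pair list.
#'
#' @param seq_a,seq_b Amino-acid strings (standard 20-letter alphabet).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Gap penalties (positive costs; defaults 10 and
#'   0.5, the conventional protein-alignment defaults).
#' @param subunit_a,subunit_b Optional subunit labels carried as attributes.
#' @return A `glun_alignment` tibble with columns `pos_a`, `aa_a`, `pos_b`,
#'   `aa_b`, `same_aa`, `provenance` (= `"sequence"`); attributes
#'   `n_columns` and `score`.
#' @examples
#' global_align("GAVL", "GAL")
#' @export
global_align <- function(seq_a, seq_b, matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5,
                         subunit_a = NA_character_, subunit_b = NA_character_) {
  seq_a <- assert_sequence(seq_a, "seq_a")
  seq_b <- assert_sequence(seq_b, "seq_b")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global"
  )
  arow <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  brow <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- cumsum(arow != "-")
  ib <- cumsum(brow != "-")
  both <- arow != "-" & brow != "-"
  pairs <- tibble(
    pos_a = as.integer(ia[both]), aa_a = arow[both],
    pos_b = as.integer(ib[both]), aa_b = brow[both]
  )
  new_alignment(pairs, subunit_a, subunit_b,
    n_columns = length(arow), provenance = "sequence",
    score = Biostrings::score(pa)
  )
}

#' Read a residue alignment off a structural superposition
#'
#' Both chains must already be in the same coordinate frame (apply the
#' transform from [superpose()] first, or use [align_domain()] which does it
#' for you). Residues are paired by mutual nearest neighbour within
#' `pairing_cutoff` Angstrom, then reduced to the maximum-cardinality
#' non-crossing subset (longest increasing subsequence over partner
#' positions; ties broken towards the smaller summed distance), so the pair
#' list reads like a sequence alignment.
#'
#' @param a,b `glun_chain` tibbles in a common frame.
#' @param pairing_cutoff Maximum alpha-carbon distance for a pair (default
#'   4.0 Angstrom, about one residue spacing).
#' @param domain Optional domain label carried as an attribute.
#' @return A `glun_alignment` with `provenance = "structural"` and a
#'   `distance` column. `n_columns` counts paired plus unpaired structured
#'   residues (gap columns).
#' @export
structural_alignment <- function(a, b, pairing_cutoff = 4.0, domain = NA_character_) {
  A <- chain_coords(a); B <- chain_coords(b)
  if (nrow(A) == 0L || nrow(B) == 0L) abort("chain without structured residues")
  D <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  D[D < 0] <- 0
  D <- sqrt(D)
  nn_b <- apply(D, 1, which.min) # best partner in B for each A residue
  nn_a <- apply(D, 2, which.min)
  i <- seq_len(nrow(A))
  mutual <- nn_a[nn_b[i]] == i & D[cbind(i, nn_b[i])] <= pairing_cutoff
  if (!any(mutual)) abort("no residue pairs within pairing cutoff")
  cand <- tibble(
    ia = i[mutual], ib = nn_b[i][mutual],
    distance = D[cbind(i[mutual], nn_b[i][mutual])]
  ) |> arrange(.data$ia)
  keep <- lis_non_crossing(cand$ib, cand$distance)
  cand <- cand[keep, , drop = FALSE]
  pos_a_all <- as.integer(rownames(A)); pos_b_all <- as.integer(rownames(B))
  pairs <- tibble(
    pos_a = pos_a_all[cand$ia], aa_a = a$aa[match(pos_a_all[cand$ia], a$pos)],
    pos_b = pos_b_all[cand$ib], aa_b = b$aa[match(pos_b_all[cand$ib], b$pos)],
    distance = cand$distance
  )
  n_columns <- nrow(pairs) + (nrow(A) - nrow(pairs)) + (nrow(B) - nrow(pairs))
  new_alignment(pairs, a$subunit[1], b$subunit[1],
    n_columns = n_columns, provenance = "structural", domain = domain
  )
}

# Maximum-cardinality strictly-increasing subsequence of `values`; among
# equal-cardinality solutions prefer the smaller total `weight`. O(k^2) DP,
# returns the indices kept.
lis_non_crossing <- function(values, weight = rep(0, length(values))) {
  k <- length(values)
  if (k == 0L) return(integer())
  len <- rep(1L, k); wt <- weight; prev <- rep(0L, k)
  for (j in seq_len(k)) {
    for (i in seq_len(j - 1L)) {
      if (values[i] < values[j]) {
        cand_len <- len[i] + 1L
        cand_wt <- wt[i] + weight[j]
        if (cand_len > len[j] || (cand_len == len[j] && cand_wt < wt[j])) {
          len[j] <- cand_len; wt[j] <- cand_wt; prev[j] <- i
        }
      }
    }
  }
  best <- which(len == max(len))
  end <- best[which.min(wt[best])]
  out <- integer(len[end])
  pos <- len[end]
  while (end != 0L) {
    out[pos] <- end; pos <- pos - 1L; end <- prev[end]
  }
  out
}

#' Superpose one domain pair and derive its structural alignment
#'
#' Convenience wrapper: seeds the superposition from a global sequence
#' alignment of the two domain sequences, runs [superpose()] with iterative
#' rejection, transforms `a` into `b`'s frame and calls
#' [structural_alignment()].
#'
#' @inheritParams superpose
#' @inheritParams structural_alignment
#' @param ... Scoring options passed to [global_align()] for the seed.
#' @return List with elements `fit` (`glun_superposition`) and `alignment`
#'   (`glun_alignment`).
#' @export
align_domain <- function(a, b, cycles = 5L, reject_cutoff = 2.0,
                         pairing_cutoff = 4.0, domain = NA_character_, ...) {
  seed <- global_align(chain_sequence(a), chain_sequence(b), ...)
  pairing <- tibble(pos_a = a$pos[seed$pos_a], pos_b = b$pos[seed$pos_b])
  fit <- superpose(a, b, pairing = pairing, cycles = cycles, reject_cutoff = reject_cutoff)
  aln <- structural_alignment(apply_superposition(fit, a), b,
    pairing_cutoff = pairing_cutoff, domain = domain
  )
  list(fit = fit, alignment = aln)
}

#' Identity statistics of a residue alignment
#'
#' @param aln A `glun_alignment`.
#' @param denominator What to divide the identical-residue count by:
#'   `"columns"` (aligned pairs plus gap columns, the default), `"pairs"`
#'   (aligned pairs only), or `"domain_length"` (caller-supplied, e.g. the
#'   reference subunit's domain length).
#' @param domain_length Required when `denominator = "domain_length"`.
#' @return One-row tibble: `identical_count`, `denominator_n`,
#'   `identity_percent` (unrounded; display rounding is the caller's
#'   business), plus `identity_display` rounded half-up to 2 decimals.
#' @export
identity_stats <- function(aln, denominator = c("columns", "pairs", "domain_length"),
                           domain_length = NULL) {
  denominator <- match.arg(denominator)
  if (nrow(aln) == 0L) abort("empty alignment")
  ident <- sum(aln$same_aa)
  den <- switch(denominator,
    columns = attr(aln, "n_columns") %||% nrow(aln),
    pairs = nrow(aln),
    domain_length = domain_length %||% abort("domain_length required")
  )
  pct <- 100 * ident / den
  tibble(
    identical_count = ident, denominator_n = as.integer(den),
    identity_percent = pct,
    identity_display = round_half_up(pct, 2)
  )
}

# round half away from zero (display convention; R's round() is banker's)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Export an alignment as TSV (and optionally two-row aligned FASTA)
#'
#' @param aln A `glun_alignment`.
#' @param path Output TSV path (columns `pos_a`, `aa_a`, `pos_b`, `aa_b`,
#'   `distance`, `provenance`).
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(aln, path) {
  df <- as_tibble(aln)
  if (!"distance" %in% names(df)) df$distance <- NA_real_
  utils::write.table(
    df[, c("pos_a", "aa_a", "pos_b", "aa_b", "distance", "provenance")],
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
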