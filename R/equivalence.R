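# The cross-subunit equivalence map: for each unordered subunit pair, a
# partial bijection of canonical positions assembled from per-domain
# structural alignments, with sequence-alignment fallback for regions the
# crystals do not resolve (CTD, disordered loops). Structural entries take
# precedence over sequence entries.

map_columns <- c(
  "subunit_a", "pos_a", "aa_a", "subunit_b", "pos_b", "aa_b",
  "domain", "provenance"
)

canonical_pair_order <- function(sa, sb) {
  match(sa, GLUN_SUBUNITS) < match(sb, GLUN_SUBUNITS)
}

#' Assemble an equivalence map from residue alignments
#'
#' Takes per-domain structural alignments and whole-sequence (or regional)
#' sequence-alignment fallbacks, and builds one partial bijection of
#' canonical positions per subunit pair. Within a pair, a position claimed
#' by both a structural and a sequence entry keeps the structural one;
#' sequence-fallback pairs are only accepted inside runs of at least
#' `min_fallback_run` consecutive aligned columns, which suppresses spurious
#' single-residue matches in low-identity regions. Two entries of the same
#' provenance class that claim one position with different partners are a
#' hard error (conflicting alignments).
#'
#' @param structural List of `glun_alignment` objects with structural
#'   provenance (attributes `subunit_a`/`subunit_b` must be set; `domain`
#'   attribute is carried into the map).
#' @param sequence_fallback Optional list of sequence-provenance alignments
#'   used where structure is silent.
#' @param min_fallback_run Minimum run length of consecutive aligned columns
#'   for fallback pairs (default 5).
#' @param fallback_domain Domain label recorded for fallback entries whose
#'   position falls outside every structural domain (default `"CTD"`).
#' @param domains Optional `glun_domains` used to label fallback entries
#'   that fall inside a defined domain.
#' @return A `glun_map` tibble with columns `subunit_a`, `pos_a`, `aa_a`,
#'   `subunit_b`, `pos_b`, `aa_b`, `domain`, `provenance`; one row per
#'   equivalent position pair, subunits ordered GluN1 < GluN2A < GluN2B.
#' @export
build_equivalence_map <- function(structural, sequence_fallback = list(),
                                  min_fallback_run = 5L,
                                  fallback_domain = "CTD", domains = NULL) {
  if (inherits(structural, "glun_alignment")) structural <- list(structural)
  if (inherits(sequence_fallback, "glun_alignment")) {
    sequence_fallback <- list(sequence_fallback)
  }
  if (length(structural) + length(sequence_fallback) == 0L) {
    abort("at least one alignment is required")
  }
  rows_from <- function(aln, provenance) {
    sa <- attr(aln, "subunit_a"); sb <- attr(aln, "subunit_b")
    if (is.na(sa) || is.na(sb)) abort("alignment lacks subunit labels")
    df <- as_tibble(aln)
    df <- tibble(
      subunit_a = sa, pos_a = df$pos_a, aa_a = df$aa_a,
      subunit_b = sb, pos_b = df$pos_b, aa_b = df$aa_b,
      domain = attr(aln, "domain") %||% NA_character_,
      provenance = provenance
    )
    if (!canonical_pair_order(sa, sb)) {
      df <- tibble(
        subunit_a = df$subunit_b, pos_a = df$pos_b, aa_a = df$aa_b,
        subunit_b = df$subunit_a, pos_b = df$pos_a, aa_b = df$aa_a,
        domain = df$domain, provenance = df$provenance
      )
    }
    df
  }
  struct_rows <- purrr::map_dfr(structural, rows_from, provenance = "structural")
  fb_rows <- purrr::map_dfr(sequence_fallback, function(aln) {
    r <- rows_from(aln, "sequence")
    if (nrow(r) == 0L) return(r)
    # keep only runs of >= min_fallback_run consecutive aligned columns
    r <- arrange(r, .data$pos_a)
    run_break <- c(TRUE, diff(r$pos_a) != 1L | diff(r$pos_b) != 1L)
    run_id <- cumsum(run_break)
    r[run_id %in% which(tabulate(run_id) >= min_fallback_run), , drop = FALSE]
  })
  check_conflicts <- function(df, what) {
    dup_a <- df |>
      distinct(.data$subunit_a, .data$subunit_b, .data$pos_a, .data$pos_b) |>
      group_by(.data$subunit_a, .data$subunit_b, .data$pos_a) |>
      filter(n() > 1L) |> ungroup()
    dup_b <- df |>
      distinct(.data$subunit_a, .data$subunit_b, .data$pos_a, .data$pos_b) |>
      group_by(.data$subunit_a, .data$subunit_b, .data$pos_b) |>
      filter(n() > 1L) |> ungroup()
    bad <- bind_rows(dup_a, dup_b)
    if (nrow(bad)) {
      abort(paste0(
        "conflicting ", what, " alignments claim one position with different partners: ",
        paste(utils::head(sprintf(
          "%s:%d<->%s:%d", bad$subunit_a, bad$pos_a, bad$subunit_b, bad$pos_b
        ), 5), collapse = "; ")
      ))
    }
    df
  }
  empty_rows <- tibble(
    subunit_a = character(), pos_a = integer(), aa_a = character(),
    subunit_b = character(), pos_b = integer(), aa_b = character(),
    domain = character(), provenance = character()
  )
  if (ncol(struct_rows) == 0L) struct_rows <- empty_rows
  if (ncol(fb_rows) == 0L) fb_rows <- empty_rows
  struct_rows <- check_conflicts(distinct(struct_rows), "structural")
  fb_rows <- check_conflicts(distinct(fb_rows), "sequence")
  # structural precedence: drop fallback rows touching a structurally-claimed
  # position on either side of the same subunit pair
  if (nrow(fb_rows)) {
    fb_rows <- fb_rows |>
      anti_join(struct_rows, by = c("subunit_a", "subunit_b", "pos_a")) |>
      anti_join(struct_rows, by = c("subunit_a", "subunit_b", "pos_b"))
    if (nrow(fb_rows)) {
      fb_rows$domain <- label_domain(fb_rows, domains, fallback_domain)
    }
  }
  out <- bind_rows(struct_rows, fb_rows) |>
    arrange(.data$subunit_a, .data$subunit_b, .data$pos_a)
  class(out) <- c("glun_map", class(out))
  out
}

label_domain <- function(rows, domains, fallback_domain) {
  if (nrow(rows) == 0L) return(character())
  if (is.null(domains)) {
    return(ifelse(is.na(rows$domain), fallback_domain, rows$domain))
  }
  vapply(seq_len(nrow(rows)), function(i) {
    if (!is.na(rows$domain[i])) return(rows$domain[i])
    hit <- domains$subunit == rows$subunit_a[i] &
      domains$start <= rows$pos_a[i] & rows$pos_a[i] <= domains$end
    if (any(hit)) domains$domain[which(hit)[1]] else fallback_domain
  }, character(1))
}

#' @export
print.glun_map <- function(x, ...) {
  cat(sprintf(
    "<glun_map> %d equivalent position pairs across %d subunit pair(s)\n",
    nrow(x), nrow(distinct(as_tibble(x), .data$subunit_a, .data$subunit_b))
  ))
  NextMethod()
}

#' Look up the equivalent positions of one residue
#'
#' @param map A `glun_map`.
#' @param subunit Subunit of the query position.
#' @param pos Canonical position (integer, may be a vector).
#' @return Tibble with one row per partner: `subunit`, `pos`, `aa`,
#'   `domain`, `provenance`, plus the query columns `query_subunit`,
#'   `query_pos`. Zero rows when the position is unmapped.
#' @examples
#' # map_position(map, "GluN2B", 459)
#' @export
map_position <- function(map, subunit, pos) {
  assert_subunit(subunit)
  df <- as_tibble(map)
  fwd <- df |>
    filter(.data$subunit_a == subunit, .data$pos_a %in% pos) |>
    mutate(
      query_subunit = .data$subunit_a, query_pos = .data$pos_a,
      subunit = .data$subunit_b, pos = .data$pos_b, aa = .data$aa_b
    )
  rev <- df |>
    filter(.data$subunit_b == subunit, .data$pos_b %in% pos) |>
    mutate(
      query_subunit = .data$subunit_b, query_pos = .data$pos_b,
      subunit = .data$subunit_a, pos = .data$pos_a, aa = .data$aa_a
    )
  bind_rows(fwd, rev) |>
    select("query_subunit", "query_pos", "subunit", "pos", "aa", "domain", "provenance") |>
    arrange(.data$query_pos, .data$subunit)
}

#' Check composition consistency of the three-subunit map
#'
#' For every GluN1 position mapped to both GluN2A and GluN2B, composing
#' GluN1->GluN2A with GluN2A->GluN2B must land on the directly mapped
#' GluN1->GluN2B partner. Inconsistent triangles are reported, never
#' auto-repaired; by construction the GluN2A-GluN2B direct alignment (the
#' highest-identity pair) is the one the map keeps for that pair.
#'
#' @param map A `glun_map`.
#' @return Tibble of inconsistent triangles (`glun1_pos`, `glun2a_pos`,
#'   `glun2b_direct`, `glun2b_composed`); zero rows means fully consistent.
#' @export
check_three_way_consistency <- function(map) {
  df <- as_tibble(map)
  m12a <- df |> filter(.data$subunit_a == "GluN1", .data$subunit_b == "GluN2A")
  m12b <- df |> filter(.data$subunit_a == "GluN1", .data$subunit_b == "GluN2B")
  m2a2b <- df |> filter(.data$subunit_a == "GluN2A", .data$subunit_b == "GluN2B")
  tri <- m12a |>
    select(glun1_pos = "pos_a", glun2a_pos = "pos_b") |>
    inner_join(
      m12b |> select(glun1_pos = "pos_a", glun2b_direct = "pos_b"),
      by = "glun1_pos"
    ) |>
    left_join(
      m2a2b |> select(glun2a_pos = "pos_a", glun2b_composed = "pos_b"),
      by = "glun2a_pos"
    ) |>
    filter(is.na(.data$glun2b_composed) |
      .data$glun2b_composed != .data$glun2b_direct)
  tri
}

#' Serialize / read an equivalence map as JSON
#'
#' One JSON object per entry with keys `subunit_a`, `pos_a`, `aa_a`,
#' `subunit_b`, `pos_b`, `aa_b`, `domain`, `provenance`.
#'
#' @param map A `glun_map`.
#' @param path JSON path.
#' @return `write_equivalence_map()` returns `path` invisibly;
#'   `read_equivalence_map()` returns the `glun_map`.
#' @export
write_equivalence_map <- function(map, path) {
  jsonlite::write_json(as_tibble(map)[, map_columns], path,
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_equivalence_map
#' @export
read_equivalence_map <- function(path) {
  df <- as_tibble(jsonlite::fromJSON(path))
  if (!all(map_columns %in% names(df))) {
    abort("map JSON lacks required keys")
  }
  out <- df[, map_columns]
  out$pos_a <- as.integer(out$pos_a)
  out$pos_b <- as.integer(out$pos_b)
  out$domain <- as.character(out$domain)
  out <- arrange(out, .data$subunit_a, .data$subunit_b, .data$pos_a)
  class(out) <- c("glun_map", class(out))
  out
}

#' Cross-check map residues against canonical sequences
#'
#' @param map A `glun_map`.
#' @param sequences Named character vector of canonical sequences (names are
#'   subunit IDs).
#' @return Tibble of entries whose stored amino acid disagrees with the
#'   canonical sequence at that position; zero rows when clean.
#' @export
validate_map_sequences <- function(map, sequences) {
  df <- as_tibble(map)
  check_side <- function(subunit, pos, aa) {
    seq <- sequences[[subunit[1]]]
    if (is.null(seq)) return(rep(NA, length(pos)))
    substring(seq, pos, pos) != aa
  }
  bad_a <- unlist(purrr::map(
    split(seq_len(nrow(df)), df$subunit_a),
    function(i) i[which(check_side(df$subunit_a[i], df$pos_a[i], df$aa_a[i]))]
  ))
  bad_b <- unlist(purrr::map(
    split(seq_len(nrow(df)), df$subunit_b),
    function(i) i[which(check_side(df$subunit_b[i], df$pos_b[i], df$aa_b[i]))]
  ))
  df[sort(unique(c(bad_a, bad_b))), , drop = FALSE]
}
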