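# Computational evaluation: group variants that sit at equivalent positions,
# split the comparisons into the three categories (homologous; different
# initial / same final; same initial / different final), and measure how
# often their annotations coincide.

COMPARISON_CATEGORIES <- c("homologous", "same_final", "same_initial")

# Connected components of positions linked by the map (a position may be
# linked to one partner per other subunit). Returns tibble subunit/pos/class_id.
position_classes <- function(map) {
  df <- as_tibble(map)
  nodes <- unique(c(
    paste(df$subunit_a, df$pos_a, sep = ":"),
    paste(df$subunit_b, df$pos_b, sep = ":")
  ))
  parent <- seq_along(nodes)
  names(parent) <- nodes
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  a <- match(paste(df$subunit_a, df$pos_a, sep = ":"), nodes)
  b <- match(paste(df$subunit_b, df$pos_b, sep = ":"), nodes)
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  tibble(
    subunit = sub(":.*$", "", nodes),
    pos = as.integer(sub("^.*:", "", nodes)),
    class_id = match(roots, unique(roots))
  )
}

#' Group variants at equivalent positions by comparison category
#'
#' Variants are gathered over each equivalence class of positions and
#' grouped by the category's residue pattern:
#' * `homologous` — same reference and same alternate residue (a group is a
#'   pair or trio of the same amino-acid change across subunits);
#' * `same_final` — same alternate residue but at least two distinct
#'   reference residues in the group;
#' * `same_initial` — same reference residue but at least two distinct
#'   alternate residues.
#' Every group spans at least two variants from at least two subunits; the
#' three categories are disjoint by construction.
#'
#' @param db A `glun_variants` database.
#' @param map A `glun_map`.
#' @param category One of `"homologous"`, `"same_final"`, `"same_initial"`.
#' @return Tibble of group members: the variant columns plus `group_id`,
#'   `class_id` (equivalence class of positions) and `category`.
#' @export
group_equivalent_variants <- function(db, map, category = COMPARISON_CATEGORIES) {
  category <- match.arg(category)
  classes <- position_classes(map)
  members <- as_tibble(db) |>
    inner_join(classes, by = c("subunit", "pos"))
  if (nrow(members) == 0L) return(empty_groups(category))
  grouped <- switch(category,
    homologous = members |>
      group_by(.data$class_id, .data$ref_aa, .data$alt_aa),
    same_final = members |>
      group_by(.data$class_id, .data$alt_aa),
    same_initial = members |>
      group_by(.data$class_id, .data$ref_aa)
  )
  out <- grouped |>
    filter(n() >= 2L, dplyr::n_distinct(.data$subunit) >= 2L) |>
    ungroup()
  out <- switch(category,
    homologous = out,
    same_final = out |>
      group_by(.data$class_id, .data$alt_aa) |>
      filter(dplyr::n_distinct(.data$ref_aa) >= 2L) |>
      ungroup(),
    same_initial = out |>
      group_by(.data$class_id, .data$ref_aa) |>
      filter(dplyr::n_distinct(.data$alt_aa) >= 2L) |>
      ungroup()
  )
  if (nrow(out) == 0L) return(empty_groups(category))
  key <- switch(category,
    homologous = paste(out$class_id, out$ref_aa, out$alt_aa),
    same_final = paste(out$class_id, out$alt_aa),
    same_initial = paste(out$class_id, out$ref_aa)
  )
  out$group_id <- match(key, unique(key))
  out$category <- category
  arrange(out, .data$group_id, .data$subunit, .data$pos)
}

empty_groups <- function(category) {
  tibble(
    subunit = character(), pos = integer(), ref_aa = character(),
    alt_aa = character(), pathogenicity = character(), functional = character(),
    source = character(), class_id = integer(), group_id = integer(),
    category = character()
  )
}

#' Annotation concordance across equivalent-position groups
#'
#' A group is *coincident* when all its informative annotations agree.
#' For pathogenicity, `uncertain` and `unannotated` members are discarded
#' before comparison; for functional class only `unannotated` is discarded
#' (`complex` is a first-class value: complex vs LoF is discordant). Groups
#' left with fewer than two informative members drop out of the
#' denominator.
#'
#' @param groups Output of [group_equivalent_variants()].
#' @param annotation_kind `"pathogenicity"` or `"functional"`.
#' @return A `glun_concordance` object: a one-row summary tibble with
#'   `category`, `annotation_kind`, `n_groups`, `n_variants`,
#'   `n_coincident`, `percent_coincident`, and attributes `group_detail`
#'   (per-group tibble) and `discordant` (the discordant groups' members).
#' @export
concordance <- function(groups, annotation_kind = c("pathogenicity", "functional")) {
  annotation_kind <- match.arg(annotation_kind)
  drop_values <- if (annotation_kind == "pathogenicity") {
    c("uncertain", "unannotated")
  } else {
    "unannotated"
  }
  category <- if (nrow(groups)) groups$category[1] else NA_character_
  informative <- groups |>
    filter(!.data[[annotation_kind]] %in% drop_values) |>
    group_by(.data$group_id) |>
    filter(n() >= 2L) |>
    ungroup()
  detail <- informative |>
    group_by(.data$group_id) |>
    summarise(
      n_members = n(),
      classes = paste(sort(unique(.data[[annotation_kind]])), collapse = "/"),
      coincident = dplyr::n_distinct(.data[[annotation_kind]]) == 1L,
      .groups = "drop"
    )
  discordant <- informative |>
    filter(.data$group_id %in% detail$group_id[!detail$coincident])
  summary <- tibble(
    category = category, annotation_kind = annotation_kind,
    n_groups = nrow(detail),
    n_variants = nrow(informative),
    n_coincident = sum(detail$coincident),
    percent_coincident = if (nrow(detail)) 100 * sum(detail$coincident) / nrow(detail) else NA_real_
  )
  attr(summary, "group_detail") <- detail
  attr(summary, "discordant") <- discordant
  class(summary) <- c("glun_concordance", class(summary))
  summary
}

#' @export
print.glun_concordance <- function(x, ...) {
  cat(sprintf(
    "<glun_concordance> %s / %s: %d of %d groups coincident (%.2f%%), %d variants\n",
    x$category, x$annotation_kind, x$n_coincident, x$n_groups,
    x$percent_coincident, x$n_variants
  ))
  invisible(x)
}

#' Per-domain identity and RMSD summary for subunit pairs
#'
#' Reproduces the layout of the published per-domain conservation table:
#' for each subunit pair, the ATD sublobes are superposed independently
#' (two RMSD values) while identity is reported over the whole ATD, and the
#' discontinuous LBD and TMD are each superposed as one unit.
#'
#' @param chains Named list of `glun_chain` objects keyed by subunit, in
#'   canonical numbering.
#' @param domains A `glun_domains` definition covering those subunits.
#' @param pairs List of 2-element character vectors of subunits to compare;
#'   default: all pairs present.
#' @param identity_denominator Passed to [identity_stats()].
#' @param ... Superposition/pairing options passed to [align_domain()].
#' @return Tibble with one row per (pair, domain block): `subunit_a`,
#'   `subunit_b`, `domain`, `n_identical`, `denominator_n`,
#'   `identity_percent`, `rmsd` (NA for the whole-ATD identity row, whose
#'   RMSDs live on the ATD1/ATD2 rows).
#' @export
domain_summary <- function(chains, domains, pairs = NULL,
                           identity_denominator = "columns", ...) {
  subunits <- names(chains)
  if (is.null(pairs)) {
    pairs <- utils::combn(subunits, 2, simplify = FALSE)
  }
  purrr::map_dfr(pairs, function(pr) {
    a <- chains[[pr[1]]]; b <- chains[[pr[2]]]
    has_sublobes <- all(c("ATD1", "ATD2") %in% domains$domain[domains$subunit == a$subunit[1]])
    atd_parts <- if (has_sublobes) c("ATD1", "ATD2") else "ATD"
    blocks <- list()
    atd_alns <- list()
    for (d in atd_parts) {
      res <- align_domain(
        extract_domain(a, domains, d), extract_domain(b, domains, d),
        domain = d, ...
      )
      atd_alns[[d]] <- res$alignment
      blocks[[d]] <- tibble(domain = paste0("RMSD_", d), rmsd = res$fit$rmsd)
    }
    atd_ident <- combined_identity(atd_alns, identity_denominator)
    rows <- tibble(
      subunit_a = a$subunit[1], subunit_b = b$subunit[1],
      domain = "ATD",
      n_identical = atd_ident$identical_count,
      denominator_n = atd_ident$denominator_n,
      identity_percent = atd_ident$identity_percent,
      rmsd = NA_real_
    )
    for (d in atd_parts) {
      rows <- bind_rows(rows, tibble(
        subunit_a = a$subunit[1], subunit_b = b$subunit[1],
        domain = d, n_identical = NA_integer_, denominator_n = NA_integer_,
        identity_percent = NA_real_, rmsd = blocks[[d]]$rmsd
      ))
    }
    for (d in c("LBD", "TMD")) {
      res <- align_domain(
        extract_domain(a, domains, d), extract_domain(b, domains, d),
        domain = d, ...
      )
      st <- identity_stats(res$alignment, identity_denominator)
      rows <- bind_rows(rows, tibble(
        subunit_a = a$subunit[1], subunit_b = b$subunit[1],
        domain = d, n_identical = st$identical_count,
        denominator_n = st$denominator_n,
        identity_percent = st$identity_percent, rmsd = res$fit$rmsd
      ))
    }
    rows
  })
}

combined_identity <- function(alns, denominator) {
  ident <- sum(vapply(alns, function(a) sum(a$same_aa), integer(1)))
  den <- switch(denominator,
    columns = sum(vapply(alns, function(a) attr(a, "n_columns"), integer(1))),
    pairs = sum(vapply(alns, nrow, integer(1))),
    abort("combined identity supports denominators 'columns' and 'pairs'")
  )
  tibble(
    identical_count = ident, denominator_n = as.integer(den),
    identity_percent = 100 * ident / den
  )
}
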