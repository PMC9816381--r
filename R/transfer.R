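# Annotation transfer: a variant's homologs are the database variants with
# the SAME amino-acid change at a structurally equivalent position in
# another subunit. Pathogenicity and functional classes are extrapolated
# from homologs, each independently; uncertain/unannotated homolog values
# never transfer, and disagreement among homologs yields an explicit
# conflict rather than a call.

#' Find the homologous variants of a missense variant
#'
#' A homolog must satisfy all of: its position is equivalent to the query
#' position under the map, its reference residue equals the query reference,
#' and its alternate residue equals the query alternate. Variants at the
#' equivalent position with a different reference or alternate residue are
#' non-homologous and excluded (they carry no transferable information).
#'
#' @param variants Data frame with columns `subunit`, `pos`, `ref_aa`,
#'   `alt_aa` (e.g. one row of a `glun_variants` table or the output of
#'   [parse_hgvs_p()]).
#' @param map A `glun_map`.
#' @param db A `glun_variants` database to search.
#' @return Tibble of database records homologous to each query row, with
#'   query columns `query_subunit`, `query_pos`, `query_ref_aa`,
#'   `query_alt_aa` prepended.
#' @export
find_homologs <- function(variants, map, db) {
  variants <- as_tibble(variants)
  purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    eq <- map_position(map, v$subunit, v$pos)
    if (nrow(eq) == 0L) return(empty_homologs())
    hits <- as_tibble(db) |>
      inner_join(
        eq |> select(subunit = "subunit", pos = "pos"),
        by = c("subunit", "pos")
      ) |>
      filter(.data$ref_aa == v$ref_aa, .data$alt_aa == v$alt_aa)
    if (nrow(hits) == 0L) return(empty_homologs())
    bind_cols(
      tibble(
        query_subunit = v$subunit, query_pos = v$pos,
        query_ref_aa = v$ref_aa, query_alt_aa = v$alt_aa
      )[rep(1, nrow(hits)), ],
      hits
    )
  })
}

empty_homologs <- function() {
  tibble(
    query_subunit = character(), query_pos = integer(),
    query_ref_aa = character(), query_alt_aa = character(),
    subunit = character(), pos = integer(), ref_aa = character(),
    alt_aa = character(), pathogenicity = character(),
    functional = character(), source = character()
  )
}

transfer_class <- function(values, uninformative) {
  informative <- setdiff(unique(values), uninformative)
  if (length(informative) == 0L) {
    list(call = "none", status = "homolog_unannotated")
  } else if (length(informative) == 1L) {
    list(call = informative, status = "predicted")
  } else {
    list(call = "none", status = "conflict")
  }
}

#' Predict annotations for variants by homology transfer
#'
#' For each query variant, finds its annotated homologs and transfers the
#' pathogenicity and functional classes independently. Homologs annotated
#' `uncertain` or `unannotated` do not contribute; unanimous informative
#' homologs give a prediction; disagreeing ones give `conflict` and no call.
#' `uncertain` is never emitted as a transferred class.
#'
#' @inheritParams find_homologs
#' @return Tibble, one row per query variant: the query key, `hgvs_p`,
#'   `predicted_pathogenicity` / `predicted_functional` (`"none"` when no
#'   call), per-class statuses `pathogenicity_status` / `functional_status`,
#'   an overall `status` (`predicted` > `conflict` > `homolog_unannotated` >
#'   `no_homolog` by informativeness: conflict wins over predicted when
#'   either class conflicts), `n_homologs`, and a `supporting` list-column
#'   of the homolog records.
#' @export
predict_annotations <- function(variants, map, db) {
  variants <- as_tibble(variants)
  purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    hom <- find_homologs(v, map, db)
    if (nrow(hom) == 0L) {
      pat <- list(call = "none", status = "no_homolog")
      fun <- pat
      overall <- "no_homolog"
    } else {
      pat <- transfer_class(hom$pathogenicity, c("uncertain", "unannotated"))
      fun <- transfer_class(hom$functional, c("unannotated"))
      overall <- if (pat$status == "conflict" || fun$status == "conflict") {
        "conflict"
      } else if (pat$status == "predicted" || fun$status == "predicted") {
        "predicted"
      } else {
        "homolog_unannotated"
      }
    }
    tibble(
      subunit = v$subunit, pos = v$pos, ref_aa = v$ref_aa, alt_aa = v$alt_aa,
      hgvs_p = format_hgvs_p(v$ref_aa, v$pos, v$alt_aa),
      predicted_pathogenicity = pat$call,
      predicted_functional = fun$call,
      pathogenicity_status = pat$status,
      functional_status = fun$status,
      status = overall,
      n_homologs = nrow(hom),
      provenance = "inferred-by-homology",
      supporting = list(hom)
    )
  })
}

#' Apply the transfer algorithm database-wide
#'
#' Runs [predict_annotations()] over every variant whose pathogenicity is
#' `unannotated`/`uncertain` or whose functional class is `unannotated`,
#' and summarises the annotation expansion. Predictions are returned as a
#' separate table (provenance `"inferred-by-homology"`), never merged into
#' the observed annotations.
#'
#' @param db A `glun_variants` database.
#' @param map A `glun_map`.
#' @param pathogenic_baseline Denominator for the percent increase in
#'   pathogenic variants; defaults to the count of observed pathogenic
#'   records in `db`. Configurable because published percentages may use a
#'   subunit-restricted baseline.
#' @return List with `predictions` (tibble) and `expansion` (one-row
#'   tibble): `n_eligible`, `n_predicted_pathogenic`, `n_predicted_benign`,
#'   `n_vus_resolved`, `n_new_functional` (plus per-subunit functional
#'   counts), and percent changes `pct_pathogenic_increase`,
#'   `pct_vus_decrease`, `pct_functional_increase`.
#' @export
annotate_database <- function(db, map, pathogenic_baseline = NULL) {
  df <- as_tibble(db)
  eligible <- df |>
    filter(.data$pathogenicity %in% c("unannotated", "uncertain") |
      .data$functional == "unannotated")
  preds <- if (nrow(eligible)) {
    predict_annotations(eligible, map, db)
  } else {
    predict_annotations(df[0, ], map, db)
  }
  if (nrow(preds)) {
    preds <- preds |>
      left_join(
        df |> select("subunit", "pos", "ref_aa", "alt_aa",
          observed_pathogenicity = "pathogenicity",
          observed_functional = "functional"
        ),
        by = c("subunit", "pos", "ref_aa", "alt_aa")
      ) |>
      mutate(
        # a prediction only counts as new where the observation was silent
        new_pathogenicity = .data$pathogenicity_status == "predicted" &
          .data$observed_pathogenicity %in% c("unannotated", "uncertain"),
        new_functional = .data$functional_status == "predicted" &
          .data$observed_functional == "unannotated"
      )
  } else {
    preds$observed_pathogenicity <- character()
    preds$observed_functional <- character()
    preds$new_pathogenicity <- logical()
    preds$new_functional <- logical()
  }
  n_obs_pathogenic <- sum(df$pathogenicity == "pathogenic")
  n_obs_vus <- sum(df$pathogenicity == "uncertain")
  n_obs_functional <- sum(df$functional != "unannotated")
  baseline <- pathogenic_baseline %||% n_obs_pathogenic
  new_path <- preds$new_pathogenicity & preds$predicted_pathogenicity == "pathogenic"
  new_benign <- preds$new_pathogenicity & preds$predicted_pathogenicity == "benign"
  vus_resolved <- preds$new_pathogenicity & preds$observed_pathogenicity == "uncertain"
  fun_by_subunit <- vapply(
    GLUN_SUBUNITS,
    function(s) sum(preds$new_functional & preds$subunit == s), integer(1)
  )
  expansion <- tibble(
    n_eligible = nrow(eligible),
    n_predicted_pathogenic = sum(new_path),
    n_predicted_benign = sum(new_benign),
    n_vus_resolved = sum(vus_resolved),
    n_new_functional = sum(preds$new_functional),
    n_new_functional_GluN1 = fun_by_subunit[["GluN1"]],
    n_new_functional_GluN2A = fun_by_subunit[["GluN2A"]],
    n_new_functional_GluN2B = fun_by_subunit[["GluN2B"]],
    pathogenic_baseline = baseline,
    pct_pathogenic_increase = if (baseline > 0) 100 * sum(new_path) / baseline else NA_real_,
    pct_vus_decrease = if (n_obs_vus > 0) 100 * sum(vus_resolved) / n_obs_vus else NA_real_,
    pct_functional_increase = if (n_obs_functional > 0) {
      100 * sum(preds$new_functional) / n_obs_functional
    } else {
      NA_real_
    }
  )
  list(predictions = preds, expansion = expansion)
}
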