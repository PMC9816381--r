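# ggplot2 views of the main result types.

#' Plot per-pair distances of a structural alignment
#'
#' Post-superposition alpha-carbon distance along the alignment, coloured by
#' residue identity — a quick visual of where two subunits diverge.
#'
#' @param object A `glun_alignment` (structural provenance carries
#'   distances; sequence alignments plot identity only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glun_alignment <- function(object, ...) {
  df <- as_tibble(object)
  if (!"distance" %in% names(df)) df$distance <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_a, y = .data$distance)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$same_aa), size = 1) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d95f02"),
      name = "identical residue"
    ) +
    ggplot2::labs(
      x = sprintf("position in %s", attr(object, "subunit_a") %||% "chain A"),
      y = "CA–CA distance (Å)",
      title = sprintf(
        "%s vs %s structural alignment",
        attr(object, "subunit_a") %||% "A", attr(object, "subunit_b") %||% "B"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot retained-pair distances of a superposition fit
#'
#' @param object A `glun_superposition`.
#' @param ... Unused.
#' @return A ggplot object (histogram of post-fit pair distances is not
#'   recoverable from the fit alone, so this shows retained pairs and the
#'   fitted RMSD).
#' @export
autoplot.glun_superposition <- function(object, ...) {
  df <- tidy(object)
  df$idx <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_a, y = .data$pos_b)) +
    ggplot2::geom_point(size = 0.8, colour = "#2c7fb8") +
    ggplot2::labs(
      x = "position (chain A)", y = "position (chain B)",
      title = sprintf(
        "retained residue pairs (RMSD %.3f Å, %d pairs)",
        object$rmsd, object$n
      )
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of an equivalence map's coverage by domain and provenance
#'
#' @param object A `glun_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glun_map <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(pair = paste(.data$subunit_a, .data$subunit_b, sep = "–")) |>
    dplyr::count(.data$pair, .data$domain, .data$provenance)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$domain, y = .data$n, fill = .data$provenance
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(
      x = "domain", y = "equivalent position pairs",
      title = "equivalence map coverage"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a concordance report
#'
#' @param object A `glun_concordance`.
#' @param ... Unused.
#' @return A ggplot object showing coincident vs discordant group counts.
#' @export
autoplot.glun_concordance <- function(object, ...) {
  detail <- attr(object, "group_detail")
  df <- dplyr::count(detail, .data$coincident)
  df$outcome <- ifelse(df$coincident, "coincident", "discordant")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$n, fill = .data$outcome)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(coincident = "#1b9e77", discordant = "#d95f02")) +
    ggplot2::labs(
      x = NULL, y = "groups",
      title = sprintf(
        "%s concordance (%s): %.1f%% of %d groups",
        object$category, object$annotation_kind,
        object$percent_coincident, object$n_groups
      )
    ) +
    ggplot2::theme_minimal()
}
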