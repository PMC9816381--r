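# Topological domain definitions. A definition is a set of 1-based inclusive
# canonical-position intervals per (subunit, domain); LBD and TMD are
# discontinuous in sequence, the ATD is split into its two sublobes for
# superposition. Definitions are data (a JSON config), not code.

#' Construct a domain definition table
#'
#' @param subunit,domain,start,end Equal-length vectors; one row per
#'   interval. `domain` takes values in `ATD`, `ATD1`, `ATD2`, `LBD`, `TMD`,
#'   `CTD`; intervals are 1-based inclusive and must not overlap within one
#'   (subunit, domain).
#' @return A `glun_domains` tibble with columns `subunit`, `domain`,
#'   `start`, `end`.
#' @export
domain_definition <- function(subunit, domain, start, end) {
  out <- tibble(
    subunit = as.character(subunit), domain = as.character(domain),
    start = as.integer(start), end = as.integer(end)
  )
  if (!all(out$subunit %in% GLUN_SUBUNITS)) {
    abort("unknown subunit in domain definition")
  }
  if (!all(out$domain %in% GLUN_DOMAINS)) {
    abort(paste0(
      "unknown domain name(s): ",
      paste(setdiff(unique(out$domain), GLUN_DOMAINS), collapse = ", ")
    ))
  }
  if (any(out$start < 1L) || any(out$start > out$end)) {
    abort("intervals must satisfy 1 <= start <= end")
  }
  check <- out |>
    arrange(.data$subunit, .data$domain, .data$start) |>
    group_by(.data$subunit, .data$domain) |>
    summarise(ok = all(diff(.data$start) > 0) &&
      all(head(.data$end, -1) < tail(.data$start, -1)) || n() == 1L,
    .groups = "drop")
  if (!all(check$ok)) abort("overlapping intervals within one (subunit, domain)")
  class(out) <- c("glun_domains", class(out))
  out
}

#' Read / write domain definitions as JSON
#'
#' The JSON schema is a list of objects with keys `subunit`, `domain` and
#' `ranges` (a list of `[start, end]` 1-based inclusive pairs). The package
#' ships `inst/extdata/domains_synthetic_example.json`, a synthetic example
#' of the schema; real OPM-derived ranges are user-supplied data in the same
#' format.
#'
#' @param path JSON file path.
#' @return For `read_domain_config()`, a `glun_domains` tibble.
#' @export
read_domain_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- purrr::map_dfr(raw, function(entry) {
    ranges <- matrix(unlist(entry$ranges), ncol = 2, byrow = TRUE)
    tibble(
      subunit = entry$subunit, domain = entry$domain,
      start = as.integer(ranges[, 1]), end = as.integer(ranges[, 2])
    )
  })
  domain_definition(rows$subunit, rows$domain, rows$start, rows$end)
}

#' @rdname read_domain_config
#' @param domains A `glun_domains` tibble.
#' @export
write_domain_config <- function(domains, path) {
  entries <- domains |>
    group_by(.data$subunit, .data$domain) |>
    summarise(ranges = list(purrr::map2(.data$start, .data$end, c)), .groups = "drop")
  jsonlite::write_json(
    purrr::pmap(entries, function(subunit, domain, ranges) {
      list(subunit = subunit, domain = domain, ranges = ranges)
    }),
    path,
    auto_unbox = TRUE
  )
  invisible(path)
}

domain_positions <- function(domains, subunit, domain) {
  rows <- domains[domains$subunit == subunit & domains$domain == domain, , drop = FALSE]
  if (nrow(rows) == 0L) {
    abort(paste0("no ranges defined for ", subunit, " ", domain))
  }
  sort(unique(unlist(purrr::map2(rows$start, rows$end, seq))))
}

#' Extract the sites of one topological domain from a chain
#'
#' @param chain A `glun_chain` in canonical numbering.
#' @param domains A `glun_domains` tibble.
#' @param domain Domain name, e.g. `"LBD"`.
#' @return A `glun_chain` restricted to the domain's canonical positions,
#'   order preserved. Errors if no site falls inside the ranges (domain /
#'   structure mismatch).
#' @export
extract_domain <- function(chain, domains, domain) {
  keep <- domain_positions(domains, chain$subunit[1], domain)
  sub <- as_tibble(chain)[chain$pos %in% keep, , drop = FALSE]
  if (nrow(sub) == 0L) {
    abort(paste0(
      "no residues of ", chain$subunit[1], " fall in ", domain,
      " ranges: domain definition / structure mismatch"
    ))
  }
  out <- as_chain(sub, source_label = attr(chain, "source_label"))
  attr(out, "domain") <- domain
  out
}
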