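# Strict readers and writers for the package's external formats: long
# density CSV (date, taxon, guild, density), per-guild trait CSV, and the
# long-record view of a density panel.

#' Read a long-format density CSV
#'
#' Expects columns `date` (ISO 8601), `taxon`, `guild`
#' (`phyto`/`zoo`), `density` (individuals/ml, nonnegative).  Schema
#' violations fail fast with the offending line number (header = line 1).
#' Taxa named in `exclude_taxa` (e.g. unidentified or unnamed species
#' labels) are dropped before validation.
#'
#' @param path CSV path.
#' @param exclude_taxa Optional character vector of taxon labels to drop.
#' @return A records tibble (`date`, `taxon`, `guild`, `density`).
#' @export
read_density_csv <- function(path, exclude_taxa = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("date", "taxon", "guild", "density")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("density CSV lacks column(s): ", toString(miss)))
  }
  line_of <- function(i) i + 1L  # header occupies line 1
  if (!is.null(exclude_taxa)) {
    raw <- raw[!raw$taxon %in% exclude_taxa, , drop = FALSE]
  }
  date <- suppressWarnings(as.Date(raw$date))
  bad <- which(is.na(date))
  if (length(bad) > 0) {
    abort(sprintf("unparseable date at line %d: '%s'", line_of(bad[1]),
                  raw$date[bad[1]]))
  }
  bad <- which(is.na(raw$taxon) | !nzchar(raw$taxon))
  if (length(bad) > 0) {
    abort(sprintf("empty taxon at line %d", line_of(bad[1])))
  }
  bad <- which(!raw$guild %in% c("phyto", "zoo"))
  if (length(bad) > 0) {
    abort(sprintf("guild must be 'phyto' or 'zoo' at line %d (got '%s')",
                  line_of(bad[1]), raw$guild[bad[1]]))
  }
  density <- suppressWarnings(as.numeric(raw$density))
  bad <- which(is.na(density))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric density at line %d: '%s'", line_of(bad[1]),
                  raw$density[bad[1]]))
  }
  bad <- which(density < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative density at line %d", line_of(bad[1])))
  }
  tibble(date = date, taxon = raw$taxon, guild = raw$guild,
         density = density)
}

#' Write records / a panel to the long density CSV format
#'
#' @param records A records tibble (or use [panel_to_records()] first).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_density_csv <- function(records, path) {
  records <- validate_records(records)
  readr::write_csv(records, path)
  invisible(path)
}

#' Long-record view of a density panel
#'
#' Inverse of [monthly_mean()] for gap-free panels: one record per
#' (month, taxon), dated on the first of the month, so synthetic panels
#' round-trip through the public CSV entry points.
#'
#' @param panel A [new_density_panel()].
#' @return Records tibble (`date`, `taxon`, `guild`, `density`).
#' @export
panel_to_records <- function(panel) {
  g <- panel_guilds(panel)
  long <- tidyr::pivot_longer(as_tibble(panel), -"month",
                              names_to = "taxon", values_to = "density")
  long <- long[!is.na(long$density), , drop = FALSE]
  tibble(date = long$month, taxon = long$taxon,
         guild = unname(g[long$taxon]), density = long$density)
}

#' Read a per-guild trait CSV into a fuzzy trait matrix
#'
#' The file must carry a `taxon` column plus the guild's `block.category`
#' fuzzy columns and numeric trait columns (the layout written by
#' [write_trait_csv()] and produced by [generate_trait_table()]).
#'
#' @param path CSV path.
#' @param guild `"phyto"` or `"zoo"` (selects the expected schema).
#' @param schema Optional explicit block schema overriding the guild's.
#' @return A `fuzzy_trait_matrix`.
#' @export
read_trait_csv <- function(path, guild = c("phyto", "zoo"), schema = NULL) {
  guild <- arg_match(guild)
  schema <- schema %||% guild_trait_schema(guild)
  raw <- readr::read_csv(path, col_types = readr::cols(
    taxon = "c", .default = "d"), progress = FALSE)
  if (!"taxon" %in% names(raw)) abort("trait CSV lacks a `taxon` column")
  new_fuzzy_trait_matrix(raw, schema)
}

#' @rdname read_trait_csv
#' @param traits A `fuzzy_trait_matrix`.
#' @export
write_trait_csv <- function(traits, path) {
  readr::write_csv(as_tibble(traits), path)
  invisible(path)
}
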