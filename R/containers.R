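# Core containers: density panels (month x taxon tibbles with a guild map)
# and metric series (one named monthly scalar series with transform flags).

#' Construct a density panel
#'
#' A density panel is a wide tibble with a `month` column (first-of-month
#' `Date`, strictly increasing, consecutive calendar months) and one column of
#' mean densities (individuals/ml) per taxon, plus a guild map attribute
#' assigning every taxon to `"phyto"` or `"zoo"`.  Missing months (no sampling
#' at all) hold `NA`, never zero.
#'
#' @param tbl Tibble with a `month` column and numeric taxon columns.
#' @param guilds Named character vector mapping taxon names to
#'   `"phyto"`/`"zoo"`.
#' @return A `density_panel` tibble.
#' @export
new_density_panel <- function(tbl, guilds) {
  tbl <- as_tibble(tbl)
  if (!"month" %in% names(tbl)) abort("panel needs a `month` column")
  tbl$month <- as.Date(tbl$month)
  taxa <- setdiff(names(tbl), "month")
  if (length(taxa) == 0) abort("panel needs at least one taxon column")
  if (anyDuplicated(tbl$month)) abort("duplicate months in panel")
  if (is.unsorted(tbl$month, strictly = TRUE)) {
    tbl <- arrange(tbl, .data$month)
  }
  missing_guild <- setdiff(taxa, names(guilds))
  if (length(missing_guild) > 0) {
    abort(paste0("taxa without a guild: ", toString(head(missing_guild, 5))))
  }
  bad <- !guilds[taxa] %in% c("phyto", "zoo")
  if (any(bad)) abort("guilds must be 'phyto' or 'zoo'")
  vals <- as.matrix(tbl[taxa])
  if (any(vals < 0, na.rm = TRUE)) abort("densities must be >= 0")
  structure(tbl, guilds = guilds[taxa],
            class = c("density_panel", class(tbl)))
}

#' @export
print.density_panel <- function(x, ...) {
  g <- attr(x, "guilds")
  cat(sprintf("<density_panel> %d months x %d taxa (%d phyto, %d zoo)\n",
              nrow(x), length(g), sum(g == "phyto"), sum(g == "zoo")))
  NextMethod()
}

# month x taxon numeric matrix (rownames = ISO month)
panel_matrix <- function(panel, taxa = NULL) {
  taxa <- taxa %||% setdiff(names(panel), "month")
  m <- as.matrix(as.data.frame(panel)[, taxa, drop = FALSE])
  rownames(m) <- format(panel$month, "%Y-%m-%d")
  m
}

#' Guild map of a density panel
#'
#' @param panel A [new_density_panel()].
#' @return Named character vector mapping each taxon to `"phyto"`/`"zoo"`.
#' @export
panel_guilds <- function(panel) attr(panel, "guilds")

# subset taxon columns, keeping the guild map in step
panel_subset <- function(panel, taxa) {
  g <- panel_guilds(panel)[taxa]
  new_density_panel(as_tibble(panel)[c("month", taxa)], g)
}

#' Construct a metric series
#'
#' A metric series is a tibble with columns `month` (Date) and `value`
#' (numeric), carrying the metric's name and an ordered record of the
#' transforms applied to it (`"detrended"`, `"deseasonalized"`, `"scaled"`).
#' An optional logical `interpolated` column flags gap-filled points.
#'
#' @param month Date vector of consecutive months.
#' @param value Numeric values (may contain `NA`).
#' @param metric Name of the metric.
#' @param transforms Character vector of transforms already applied.
#' @param interpolated Optional logical vector flagging interpolated points.
#' @return A `metric_series` tibble.
#' @export
metric_series <- function(month, value, metric = "metric",
                          transforms = character(), interpolated = NULL) {
  month <- as.Date(month)
  if (length(month) != length(value)) abort("month/value length mismatch")
  tbl <- tibble(month = month, value = as.numeric(value))
  if (!is.null(interpolated)) tbl$interpolated <- interpolated
  structure(tbl, metric = metric, transforms = transforms,
            class = c("metric_series", class(tbl)))
}

#' @export
print.metric_series <- function(x, ...) {
  tr <- attr(x, "transforms")
  cat(sprintf("<metric_series> %s (%d months%s)\n", attr(x, "metric"),
              nrow(x),
              if (length(tr)) paste0("; ", paste(tr, collapse = " > "))
              else ""))
  NextMethod()
}

# rebuild a metric_series from a template with new values / extra transforms
ms_update <- function(series, value, add_transform = NULL) {
  metric_series(series$month, value, metric = attr(series, "metric"),
                transforms = c(attr(series, "transforms"), add_transform),
                interpolated = series[["interpolated"]])
}

# accept metric_series or any data frame with month + value
as_metric_series <- function(x, metric = "metric") {
  if (inherits(x, "metric_series")) return(x)
  if (is.data.frame(x) && all(c("month", "value") %in% names(x))) {
    return(metric_series(x$month, x$value, metric = metric))
  }
  if (is.numeric(x)) {
    return(metric_series(month_seq("2000-01-01", length(x)), x,
                         metric = metric))
  }
  abort("expected a metric_series, a data frame with month/value, or a numeric vector")
}

has_transform <- function(series, what) what %in% attr(series, "transforms")
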