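# Standardization of raw sample records into monthly density panels, and the
# stationarity transforms (linear detrend, additive seasonal removal,
# z-scaling) applied to every metric series before association analyses.

#' Fill unrecorded taxa with zero-density records
#'
#' A taxon not recorded on a sampling date is taken to have density zero on
#' that date: for every (sampling date x known taxon) pair absent from the
#' input a zero record is added.  Existing records are unchanged; the
#' operation is idempotent.  Months that were never sampled gain nothing
#' here — absence of a whole sampling date stays missing downstream.
#'
#' @param records Tibble with columns `date`, `taxon`, `guild`, `density`.
#' @return Records tibble completed over the date x taxon grid.
#' @export
fill_unrecorded_with_zero <- function(records) {
  records <- validate_records(records)
  if (nrow(records) == 0) abort("no records to fill")
  guild_map <- distinct(records, .data$taxon, .data$guild)
  if (anyDuplicated(guild_map$taxon)) {
    abort("a taxon appears with more than one guild")
  }
  full <- tidyr::expand_grid(date = sort(unique(records$date)),
                             taxon = guild_map$taxon)
  out <- left_join(full, records, by = c("date", "taxon"))
  out$density[is.na(out$density)] <- 0
  out <- select(out, -"guild")
  out <- left_join(out, guild_map, by = "taxon")
  arrange(out[c("date", "taxon", "guild", "density")], .data$date,
          .data$taxon)
}

validate_records <- function(records) {
  records <- as_tibble(records)
  need <- c("date", "taxon", "guild", "density")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("records lack column(s): ", toString(miss)))
  }
  records$date <- as.Date(records$date)
  if (anyNA(records$date)) abort("unparseable dates in records")
  if (any(!nzchar(records$taxon))) abort("empty taxon names")
  if (any(records$density < 0, na.rm = TRUE)) {
    abort("negative densities in records")
  }
  records
}

#' Average records to a monthly density panel
#'
#' Each panel cell is the arithmetic mean of the taxon's densities over the
#' sampling dates within that calendar month.  The panel index is the full
#' consecutive month range; calendar months with no sampling at all are
#' `NA` (missing), never zero.
#'
#' @param records Zero-filled records (see [fill_unrecorded_with_zero()]).
#' @return A [new_density_panel()].
#' @export
monthly_mean <- function(records) {
  records <- validate_records(records)
  guild_map <- distinct(records, .data$taxon, .data$guild)
  monthly <- records |>
    mutate(month = lubridate::floor_date(.data$date, "month")) |>
    group_by(.data$month, .data$taxon) |>
    summarise(density = mean(.data$density), .groups = "drop")
  m0 <- min(monthly$month); m1 <- max(monthly$month)
  span <- (lubridate::year(m1) - lubridate::year(m0)) * 12 +
    (lubridate::month(m1) - lubridate::month(m0)) + 1
  months <- month_seq(m0, span)
  wide <- tidyr::pivot_wider(monthly, names_from = "taxon",
                             values_from = "density")
  wide <- left_join(tibble(month = months), wide, by = "month")
  new_density_panel(wide, setNames(guild_map$guild, guild_map$taxon))
}

#' Drop taxa whose monthly series is almost all zeros
#'
#' Removes taxa whose series contains strictly more than
#' `max_zero_fraction` zeros (fraction computed over non-missing months);
#' survivors keep their order.  Exactly at the threshold a taxon is
#' retained.
#'
#' @param panel A [new_density_panel()].
#' @param max_zero_fraction Threshold in `[0, 1)`; default 0.99.
#' @return The filtered panel.
#' @export
filter_sparse_taxa <- function(panel, max_zero_fraction = 0.99) {
  check_number(max_zero_fraction, "max_zero_fraction", lower = 0, upper = 1,
               open_upper = TRUE)
  taxa <- setdiff(names(panel), "month")
  zf <- vapply(taxa, function(tx) {
    v <- panel[[tx]]
    mean(v[!is.na(v)] == 0)
  }, numeric(1))
  keep <- taxa[is.finite(zf) & zf <= max_zero_fraction]
  if (length(keep) == 0) {
    abort("all taxa exceed the zero-fraction threshold; panel unusable")
  }
  panel_subset(panel, keep)
}

#' Remove a linear trend from a metric series
#'
#' Ordinary least-squares residuals on the month index; missing values stay
#' missing and the `detrended` flag is recorded.
#'
#' @param series A [metric_series()] (or data frame with `month`, `value`).
#' @return Detrended `metric_series`.
#' @export
linear_detrend <- function(series) {
  series <- as_metric_series(series)
  ok <- !is.na(series$value)
  if (sum(ok) < 3) abort("need at least 3 non-missing values to detrend")
  t_idx <- seq_len(nrow(series))
  fit <- lm(value ~ t_idx, data = tibble(value = series$value,
                                         t_idx = t_idx),
            na.action = na.exclude)
  ms_update(series, as.numeric(residuals(fit)), "detrended")
}

#' Remove the additive seasonal component from a detrended series
#'
#' The seasonal estimate is the mean of the detrended values for each of the
#' 12 calendar months across all years, centred so the 12 means sum to zero;
#' the matching month's centred mean is subtracted from each value.
#'
#' @param series A detrended [metric_series()] spanning at least 24 months.
#' @return Deseasonalized `metric_series`.
#' @export
deseasonalize <- function(series) {
  series <- as_metric_series(series)
  if (nrow(series) < 24) abort("need at least 24 months to deseasonalize")
  if (!has_transform(series, "detrended")) {
    abort("deseasonalize() expects a detrended series; call linear_detrend() first")
  }
  moy <- month_of_year(series$month)
  means <- vapply(1:12, function(m) {
    v <- series$value[moy == m]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  if (anyNA(means)) {
    abort(sprintf("calendar month(s) entirely missing: %s",
                  toString(month.abb[which(is.na(means))])))
  }
  centred <- means - mean(means)
  ms_update(series, series$value - centred[moy], "deseasonalized")
}

#' Scale a metric series to zero mean and unit variance
#'
#' Uses the sample (n - 1) standard deviation over non-missing entries.
#'
#' @param series A [metric_series()].
#' @return Scaled `metric_series` (flag `scaled`).
#' @export
zscale <- function(series) {
  series <- as_metric_series(series)
  v <- series$value
  ok <- !is.na(v)
  if (length(unique(v[ok])) < 2) abort("zero variance; cannot scale")
  s <- sd(v[ok])
  ms_update(series, (v - mean(v[ok])) / s, "scaled")
}

#' Detrend, deseasonalize and scale in the standard order
#'
#' Convenience composition applied to every state and functional diversity
#' series before cross-correlation and cross mapping: linear detrend, then
#' additive seasonal removal on the residuals, then z-scaling.
#'
#' @param series A [metric_series()].
#' @param deseason Set `FALSE` to skip the seasonal step (series shorter
#'   than 24 months).
#' @return Transformed `metric_series`.
#' @export
standardize_series <- function(series, deseason = TRUE) {
  out <- linear_detrend(series)
  if (deseason) out <- deseasonalize(out)
  zscale(out)
}

#' Linearly interpolate internal gaps in a metric series
#'
#' Used only where a downstream consumer (delay embedding) needs a gap-free
#' grid.  Interpolated points are flagged in the `interpolated` column;
#' leading/trailing missing values are left missing.
#'
#' @param series A [metric_series()].
#' @param max_gap Longest internal run of missing months to fill.
#' @return `metric_series` with gaps filled and flagged.
#' @export
interpolate_gaps <- function(series, max_gap = Inf) {
  series <- as_metric_series(series)
  v <- series$value
  filled <- zoo::na.approx(v, x = seq_along(v), na.rm = FALSE,
                           maxgap = max_gap)
  out <- ms_update(series, filled)
  out$interpolated <- is.na(v) & !is.na(filled)
  out
}
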