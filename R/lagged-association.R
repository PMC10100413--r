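# Lagged cross-correlation profiles with red-noise surrogate envelopes and
# Lag0 / LagX significance classification.
#
# Sign convention (used throughout the package): the statistic at lag k is
# cor(x_{t+k}, y_t).  A NEGATIVE k therefore means x's earlier values align
# with y's present values — x (functional diversity) moves before y (state).
# A positive k means x lags y.

ccf_at_lag <- function(xv, yv, k, min_overlap = 10) {
  t_len <- length(xv)
  if (k >= 0) {
    xs <- xv[(1 + k):t_len]; ys <- yv[seq_len(t_len - k)]
  } else {
    xs <- xv[seq_len(t_len + k)]; ys <- yv[(1 - k):t_len]
  }
  ok <- !is.na(xs) & !is.na(ys)
  if (sum(ok) < min_overlap) return(NA_real_)
  if (sd(xs[ok]) == 0 || sd(ys[ok]) == 0) return(NA_real_)
  cor(xs[ok], ys[ok])
}

align_pair <- function(x, y) {
  x <- as_metric_series(x, "x"); y <- as_metric_series(y, "y")
  common <- intersect(x$month, y$month)
  if (length(common) < 24) abort("series overlap too short (< 24 months)")
  common <- sort(as.Date(common, origin = "1970-01-01"))
  list(x = x$value[match(common, x$month)],
       y = y$value[match(common, y$month)], month = common)
}

#' Lagged cross-correlation profile of two series
#'
#' Pearson correlation of `x_{t+k}` with `y_t` for every lag `k` in
#' `[-max_lag, max_lag]` over the pairwise-complete overlap.  Negative lags
#' mean `x` moves earlier than `y`.  Lags with fewer than `min_overlap`
#' complete pairs are `NA`.  Both series should be detrended,
#' deseasonalized and scaled first (a warning is issued otherwise when the
#' inputs carry transform flags).
#'
#' @param x,y [metric_series()] (or data frames with `month`/`value`).
#' @param max_lag Maximum |lag| in months (default 60).
#' @param min_overlap Minimum complete pairs per lag.
#' @return Tibble with columns `lag`, `statistic`.
#' @export
cross_correlation <- function(x, y, max_lag = 60, min_overlap = 10) {
  check_count(max_lag, "max_lag", min = 1)
  for (s in list(x, y)) {
    if (inherits(s, "metric_series") && !has_transform(s, "scaled")) {
      warn("series is not flagged as scaled; standardize_series() is the usual precursor")
      break
    }
  }
  p <- align_pair(x, y)
  if (length(p$x) < 3 * max_lag) {
    warn(sprintf("overlap (%d) is below the recommended 3 * max_lag = %d",
                 length(p$x), 3 * max_lag))
  }
  lags <- -max_lag:max_lag
  tibble(lag = lags,
         statistic = vapply(lags, function(k) {
           ccf_at_lag(p$x, p$y, k, min_overlap)
         }, numeric(1)))
}

#' Per-lag null envelope from a surrogate ensemble
#'
#' Computes the full lag profile of every surrogate against `y` and returns
#' the per-lag empirical 2.5%/97.5% quantiles, plus the ensemble
#' distribution of each surrogate's strongest |r| across lags (the null for
#' the selection-corrected LagX test).
#'
#' @param ensemble A [red_noise_surrogates()] ensemble standing in for `x`.
#' @param y The partner series (same time grid).
#' @param max_lag Maximum |lag| in months.
#' @param probs Lower/upper envelope probabilities.
#' @param min_overlap Minimum complete pairs per lag.
#' @return List with `envelope` (tibble `lag`, `lower`, `upper`) and
#'   `max_abs` (numeric vector, one strongest-|r| per surrogate).
#' @export
null_envelope <- function(ensemble, y, max_lag = 60,
                          probs = c(0.025, 0.975), min_overlap = 10) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  y <- as_metric_series(y, "y")
  yv <- y$value
  t_len <- length(yv)
  if (ensemble$t_len != t_len) {
    abort("ensemble and y differ in length")
  }
  if (ensemble$n < 200) {
    warn("fewer than 200 surrogates: envelope quantiles will be unstable")
  }
  s_mat <- ensemble$matrix   # n x T
  lags <- -max_lag:max_lag
  prof <- matrix(NA_real_, ensemble$n, length(lags))
  for (li in seq_along(lags)) {
    k <- lags[li]
    if (k >= 0) {
      xi <- (1 + k):t_len; yi <- seq_len(t_len - k)
    } else {
      xi <- seq_len(t_len + k); yi <- (1 - k):t_len
    }
    ys <- yv[yi]
    ok <- !is.na(ys)
    if (sum(ok) < min_overlap || sd(ys[ok]) == 0) next
    prof[, li] <- suppressWarnings(
      as.numeric(cor(t(s_mat[, xi[ok], drop = FALSE]), ys[ok])))
  }
  env <- tibble(
    lag = lags,
    lower = apply(prof, 2, function(v) {
      if (all(is.na(v))) NA_real_ else quantile(v, probs[1], na.rm = TRUE)
    }),
    upper = apply(prof, 2, function(v) {
      if (all(is.na(v))) NA_real_ else quantile(v, probs[2], na.rm = TRUE)
    }))
  max_abs <- apply(abs(prof), 1, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
  list(envelope = env, max_abs = max_abs)
}

strongest_lag_of <- function(lags, stat) {
  a <- abs(stat)
  if (all(is.na(a))) return(NA_integer_)
  best <- which(a == max(a, na.rm = TRUE))
  # deterministic tie-break: smallest |lag|, negative before positive
  best <- best[order(abs(lags[best]), lags[best])]
  best[1]
}

#' Classify a series pair against its red-noise null
#'
#' Builds the observed lag profile, the per-lag surrogate envelope, and the
#' two significance calls: `lag0_significant` (the observed lag-0
#' correlation falls outside its per-lag 2.5%/97.5% band) and
#' `strongest_significant` (the observed strongest |r| across lags exceeds
#' the 95th percentile of the surrogate strongest-|r| distribution — the
#' selection-corrected LagX test; set `multiplicity = "per_lag"` to compare
#' against the per-lag band at the strongest lag instead).
#'
#' @inheritParams cross_correlation
#' @param ensemble A [red_noise_surrogates()] ensemble for `x`.
#' @param probs Envelope probabilities.
#' @param multiplicity `"max"` (default, conservative) or `"per_lag"`.
#' @return A `lag_profile` tibble (`lag`, `statistic`, `null_lower`,
#'   `null_upper`, `outside`) with attributes `lag0_significant`,
#'   `strongest_lag`, `strongest_value`, `strongest_significant`,
#'   `strongest_threshold`.
#' @export
classify_lagged_correlation <- function(x, y, ensemble, max_lag = 60,
                                        probs = c(0.025, 0.975),
                                        min_overlap = 10,
                                        multiplicity = c("max", "per_lag")) {
  multiplicity <- arg_match(multiplicity)
  obs <- suppressWarnings(
    cross_correlation(x, y, max_lag = max_lag, min_overlap = min_overlap))
  nul <- null_envelope(ensemble, y, max_lag = max_lag, probs = probs,
                       min_overlap = min_overlap)
  tbl <- left_join(obs, rename(nul$envelope, null_lower = "lower",
                               null_upper = "upper"), by = "lag")
  tbl$outside <- !is.na(tbl$statistic) &
    (tbl$statistic < tbl$null_lower | tbl$statistic > tbl$null_upper)
  i0 <- which(tbl$lag == 0)
  ibest <- strongest_lag_of(tbl$lag, tbl$statistic)
  thr <- quantile(nul$max_abs, 0.95, na.rm = TRUE)
  # the max-|r| null threshold dominates every single-lag band by design
  strongest_sig <- if (is.na(ibest)) FALSE else if (multiplicity == "max") {
    abs(tbl$statistic[ibest]) > thr
  } else {
    tbl$outside[ibest]
  }
  structure(tbl,
            lag0_significant = isTRUE(tbl$outside[i0]),
            strongest_lag = if (is.na(ibest)) NA_integer_
            else tbl$lag[ibest],
            strongest_value = if (is.na(ibest)) NA_real_
            else tbl$statistic[ibest],
            strongest_significant = isTRUE(strongest_sig),
            strongest_threshold = unname(thr),
            statistic_type = "pearson_r",
            class = c("lag_profile", class(tbl)))
}

#' Tidiers for lag profiles and surrogate ensembles
#'
#' `tidy()` returns the per-lag table; `glance()` returns a one-row summary
#' (lag-0 value and flag, strongest lag/value/flag).
#'
#' @param x A `lag_profile` or `surrogate_ensemble`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lag_profile
#' @export
tidy.lag_profile <- function(x, ...) as_tibble(x)

#' @rdname tidy.lag_profile
#' @method glance lag_profile
#' @export
glance.lag_profile <- function(x, ...) {
  i0 <- which(x$lag == 0)
  tibble(lag0_statistic = x$statistic[i0],
         lag0_significant = attr(x, "lag0_significant"),
         strongest_lag = attr(x, "strongest_lag"),
         strongest_value = attr(x, "strongest_value"),
         strongest_significant = attr(x, "strongest_significant"))
}
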