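# Five system-state series computed from a monthly density panel:
# community composition (PC1 scores), log total density, windowed Fisher
# information, windowed log multivariate variability index, and the log
# zooplankton:phytoplankton density ratio.

#' Community composition as first principal component scores
#'
#' Each taxon series is centred and scaled (correlation-matrix PCA, so
#' high-density taxa do not dominate) and the month scores on the first
#' component are returned.  The sign is fixed so that the loading-weighted
#' mean density correlates non-negatively with the scores.  Months with any
#' missing density give missing scores; constant taxa are dropped with a
#' message.
#'
#' @param panel A [new_density_panel()] with >= 2 taxa and >= 3 months.
#' @return A [metric_series()] named `"community"`.
#' @export
community_pc1 <- function(panel) {
  mat <- panel_matrix(panel)
  if (ncol(mat) < 2) abort("need at least 2 taxa")
  complete <- rowSums(is.na(mat)) == 0
  if (sum(complete) < 3) abort("need at least 3 complete months")
  x <- mat[complete, , drop = FALSE]
  sds <- apply(x, 2, sd)
  if (all(sds == 0)) abort("degenerate panel: all taxa constant")
  if (any(sds == 0)) {
    inform(sprintf("dropping %d constant taxa from PCA", sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1]
  weighted <- as.numeric(x %*% pc$rotation[, 1])
  if (isTRUE(cor(weighted, scores) < 0)) scores <- -scores
  out <- rep(NA_real_, nrow(mat))
  out[complete] <- scores
  metric_series(panel$month, out, metric = "community")
}

#' Log total plankton density
#'
#' Natural log of the per-month density sum across all taxa of both guilds.
#' If any monthly sum is zero, half the smallest positive sum is added as an
#' offset before logging (otherwise the log is exact).
#'
#' @param panel A [new_density_panel()].
#' @return A [metric_series()] named `"density"`.
#' @export
total_density <- function(panel) {
  mat <- panel_matrix(panel)
  sums <- rowSums(mat)
  metric_series(panel$month, log_with_offset(sums), metric = "density")
}

#' Windowed Fisher information of the community
#'
#' Within each sliding window the multivariate monthly observations are
#' grouped into discrete system states: two months share a state when every
#' taxon's values differ by less than `bin_tolerance` times that taxon's
#' measurement scale (the standard deviation of the taxon's full series,
#' computed once so the binning is independent of the ordering of months).
#' With `p_s` the fraction of window months in state `s`, states ordered by
#' first occurrence, and `q_s = sqrt(p_s)`,
#' `FI = 4 * sum_s (q_s - q_{s+1})^2` including the boundary terms
#' `q_0 = q_{m+1} = 0`.  A window occupying a single state gives FI = 8
#' (maximal order/stability); a window in which every month is its own
#' state gives `8/window`, approaching 0.  The value is assigned to the
#' window's final month; windows containing missing months give `NA`.
#'
#' @param panel A [new_density_panel()].
#' @param window_months Sliding window length (>= 8; default 48).
#' @param step Months between evaluated windows (default 1).
#' @param bin_tolerance Relative state-size multiplier (default 0.5).
#' @return A [metric_series()] named `"fi"`.
#' @export
fisher_information <- function(panel, window_months = 48, step = 1,
                               bin_tolerance = 0.5) {
  check_count(window_months, "window_months", min = 8)
  check_count(step, "step", min = 1)
  check_number(bin_tolerance, "bin_tolerance", lower = 0, open_lower = TRUE)
  mat <- panel_matrix(panel)
  n <- nrow(mat)
  if (window_months > n) abort("window longer than the series")
  # order-free measurement scale per taxon, fixed across windows
  scale <- apply(mat, 2, sd, na.rm = TRUE)
  scale[!is.finite(scale) | scale == 0] <-
    max(c(scale[is.finite(scale) & scale > 0], 1e-12))
  tol <- bin_tolerance * scale
  out <- rep(NA_real_, n)
  ends <- seq(window_months, n, by = step)
  for (e in ends) {
    win <- mat[(e - window_months + 1):e, , drop = FALSE]
    if (anyNA(win)) next
    out[e] <- fi_window(win, tol)
  }
  metric_series(panel$month, out, metric = "fi")
}

# FI of one gap-free window (months x taxa); tol = absolute per-taxon widths
fi_window <- function(win, tol) {
  w <- nrow(win)
  # greedy first-occurrence state assignment
  centers <- matrix(win[1, ], nrow = 1)
  counts <- 1L
  if (w > 1) {
    for (i in 2:w) {
      assigned <- FALSE
      for (s in seq_len(nrow(centers))) {
        if (all(abs(win[i, ] - centers[s, ]) < tol)) {
          counts[s] <- counts[s] + 1L
          assigned <- TRUE
          break
        }
      }
      if (!assigned) {
        centers <- rbind(centers, win[i, ])
        counts <- c(counts, 1L)
      }
    }
  }
  q <- sqrt(counts / w)
  4 * sum(diff(c(0, q, 0))^2)
}

#' Windowed multivariate variability index (log scale)
#'
#' For each sliding window the covariance matrix of the taxon series is
#' formed and `MVI = sqrt(largest eigenvalue)` computed; the natural log of
#' MVI is assigned to the window's final month.  Windows containing missing
#' values give `NA`.  The covariance matrix may be singular (window shorter
#' than the number of taxa); the dominant eigenvalue is still defined.
#'
#' @param panel A [new_density_panel()].
#' @param window_months Window length (default 12).
#' @return A [metric_series()] named `"mvi"`.
#' @export
mvi <- function(panel, window_months = 12) {
  check_count(window_months, "window_months", min = 2)
  mat <- panel_matrix(panel)
  n <- nrow(mat)
  if (window_months > n) abort("window longer than the series")
  raw <- rep(NA_real_, n)
  for (e in window_months:n) {
    win <- mat[(e - window_months + 1):e, , drop = FALSE]
    if (anyNA(win)) next
    cv <- stats::cov(win)
    lam <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values[1]
    raw[e] <- sqrt(max(lam, 0))
  }
  vals <- rep(NA_real_, n)
  ok <- !is.na(raw)
  if (any(ok) && any(raw[ok] > 0)) vals[ok] <- log_with_offset(raw[ok])
  metric_series(panel$month, vals, metric = "mvi")
}

#' Log zooplankton:phytoplankton density ratio
#'
#' Natural log of the monthly ratio of summed zooplankton to summed
#' phytoplankton densities.  If any monthly guild sum is zero, each guild's
#' sums are offset by half their smallest positive value before forming the
#' ratio; otherwise the ratio is exact.
#'
#' @param panel A [new_density_panel()] containing both guilds.
#' @return A [metric_series()] named `"zp_ratio"`.
#' @export
trophic_ratio <- function(panel) {
  g <- panel_guilds(panel)
  zoo_taxa <- names(g)[g == "zoo"]
  phy_taxa <- names(g)[g == "phyto"]
  if (length(zoo_taxa) == 0 || length(phy_taxa) == 0) {
    abort("panel must contain both guilds")
  }
  zs <- rowSums(panel_matrix(panel, zoo_taxa))
  ps <- rowSums(panel_matrix(panel, phy_taxa))
  needs_offset <- any(zs == 0, na.rm = TRUE) || any(ps == 0, na.rm = TRUE)
  if (needs_offset) {
    vals <- log_with_offset(zs) - log_with_offset(ps)
  } else {
    vals <- log(zs / ps)
  }
  metric_series(panel$month, vals, metric = "zp_ratio")
}

#' All five state metrics of a panel
#'
#' @param panel A [new_density_panel()].
#' @param fi_window,fi_step,fi_tolerance Fisher information knobs (see
#'   [fisher_information()]).
#' @param mvi_window MVI window length (see [mvi()]).
#' @return A `state_metric_set` tibble: `month`, `community`, `density`,
#'   `fi`, `mvi`, `zp_ratio`.
#' @export
#' @examples
#' sim <- simulate_community(community_sim_config(n_months = 60, seed = 3))
#' head(state_metrics(sim$panel, fi_window = 24))
state_metrics <- function(panel, fi_window = 48, fi_step = 1,
                          fi_tolerance = 0.5, mvi_window = 12) {
  out <- tibble(
    month = panel$month,
    community = community_pc1(panel)$value,
    density = total_density(panel)$value,
    fi = fisher_information(panel, fi_window, fi_step, fi_tolerance)$value,
    mvi = mvi(panel, mvi_window)$value,
    zp_ratio = trophic_ratio(panel)$value)
  structure(out, class = c("state_metric_set", class(out)))
}
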