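# Seeded generators: lake-like community panels, coupled logistic maps with
# known causal structure, and lag-injected red-noise pairs.  These define the
# study conditions under which the pipeline is exercised and validated.

#' Configuration for the community simulator
#'
#' Defaults describe a desk-scale lake: 18 phytoplankton and 6 zooplankton
#' taxa observed monthly for 396 months (33 years, the median monitoring
#' length of long-running lake programmes), seasonal log-amplitude 0.8,
#' red-noise persistence 0.45, noise sd 0.6 on the log scale, and 15%
#' zero inflation.
#'
#' @param n_phyto,n_zoo Number of taxa per guild (`n_phyto >= 12`,
#'   `n_zoo >= 4` mirror observed lake panels at desk scale).
#' @param n_months Series length in months (>= 24).
#' @param season_amplitude Maximum seasonal amplitude on the log-density
#'   scale (per-taxon amplitudes are drawn in `[0.5, 1.5] *` this value).
#' @param ar_coefficient Lag-1 autocorrelation of the log-density noise,
#'   in (-1, 1).
#' @param noise_sd Stationary standard deviation of the log-density noise.
#' @param regime_shift_month Optional month index after which designated taxa
#'   shift their mean log-density.
#' @param regime_shift_magnitude Additive shift in mean log-density applied
#'   after `regime_shift_month`.
#' @param zero_inflation Probability in `[0, 1)` that an observation is
#'   replaced by a true zero.
#' @param seed Integer seed; expanded into per-stream child seeds.
#' @return A validated `community_sim_config` list.
#' @export
community_sim_config <- function(n_phyto = 18, n_zoo = 6, n_months = 396,
                                 season_amplitude = 0.8,
                                 ar_coefficient = 0.45, noise_sd = 0.6,
                                 regime_shift_month = NULL,
                                 regime_shift_magnitude = 0,
                                 zero_inflation = 0.15, seed = 1) {
  check_count(n_phyto, "n_phyto", min = 2)
  check_count(n_zoo, "n_zoo", min = 2)
  check_count(n_months, "n_months", min = 24)
  check_number(season_amplitude, "season_amplitude", lower = 0)
  check_number(ar_coefficient, "ar_coefficient", lower = -1, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0, open_lower = TRUE)
  if (!is.null(regime_shift_month)) {
    check_count(regime_shift_month, "regime_shift_month", min = 2)
    if (regime_shift_month >= n_months) {
      abort("`regime_shift_month` must fall inside the series")
    }
  }
  check_number(regime_shift_magnitude, "regime_shift_magnitude")
  check_number(zero_inflation, "zero_inflation", lower = 0, upper = 1,
               open_upper = TRUE)
  check_count(seed, "seed", min = 0)
  structure(list(n_phyto = as.integer(n_phyto), n_zoo = as.integer(n_zoo),
                 n_months = as.integer(n_months),
                 season_amplitude = season_amplitude,
                 ar_coefficient = ar_coefficient, noise_sd = noise_sd,
                 regime_shift_month = regime_shift_month,
                 regime_shift_magnitude = regime_shift_magnitude,
                 zero_inflation = zero_inflation, seed = as.integer(seed)),
            class = "community_sim_config")
}

# stationary AR(1) noise matrix (n_months x n_taxa), unit handled by caller
ar1_noise <- function(n_months, n_taxa, r, sd) {
  innov <- matrix(rnorm(n_months * n_taxa), n_months, n_taxa)
  innov <- innov * sd * sqrt(1 - r^2)
  init <- rnorm(n_taxa, sd = sd)   # draw x_0 from the stationary law
  out <- innov
  if (n_months >= 1) {
    out <- apply(rbind(r * init, innov), 2, function(a) {
      as.numeric(stats::filter(a, r, method = "recursive"))
    })[-1, , drop = FALSE]
  }
  out
}

#' Simulate a lake-like plankton community panel with traits
#'
#' Per-taxon monthly density is `exp(level + seasonal sinusoid + AR(1)
#' noise)`, with true zeros injected by Bernoulli masking and an optional
#' multiplicative regime shift (additive on the log scale) applied to a
#' designated subset of taxa (the first half of each guild).
#'
#' @param config A [community_sim_config()].
#' @return A list with elements `panel` (a [new_density_panel()] tibble),
#'   `traits` (named list of phyto/zoo trait tibbles from
#'   [generate_trait_table()]), and `shifted_taxa` (character vector).
#' @export
#' @examples
#' sim <- simulate_community(community_sim_config(n_months = 48, seed = 7))
#' dim(sim$panel)
simulate_community <- function(config = community_sim_config()) {
  if (!inherits(config, "community_sim_config")) {
    config <- do.call(community_sim_config, as.list(config))
  }
  n <- config$n_months
  taxa_phy <- sprintf("phy_%02d", seq_len(config$n_phyto))
  taxa_zoo <- sprintf("zoo_%02d", seq_len(config$n_zoo))
  taxa <- c(taxa_phy, taxa_zoo)
  n_taxa <- length(taxa)
  guilds <- setNames(rep(c("phyto", "zoo"),
                         c(config$n_phyto, config$n_zoo)), taxa)

  set.seed(child_seed(config$seed, "community/levels"))
  level <- rnorm(n_taxa, mean = 2, sd = 1)
  amp <- config$season_amplitude * runif(n_taxa, 0.5, 1.5)
  phase <- runif(n_taxa, 0, 12)

  set.seed(child_seed(config$seed, "community/noise"))
  noise <- ar1_noise(n, n_taxa, config$ar_coefficient, config$noise_sd)

  t_idx <- seq_len(n)
  seasonal <- vapply(seq_len(n_taxa), function(j) {
    amp[j] * sin(2 * pi * (t_idx + phase[j]) / 12)
  }, numeric(n))

  logd <- matrix(level, n, n_taxa, byrow = TRUE) + seasonal + noise

  shifted <- c(taxa_phy[seq_len(ceiling(config$n_phyto / 2))],
               taxa_zoo[seq_len(ceiling(config$n_zoo / 2))])
  if (!is.null(config$regime_shift_month)) {
    after <- t_idx > config$regime_shift_month
    logd[after, taxa %in% shifted] <-
      logd[after, taxa %in% shifted] + config$regime_shift_magnitude
  }
  dens <- exp(logd)

  if (config$zero_inflation > 0) {
    set.seed(child_seed(config$seed, "community/zeros"))
    mask <- matrix(rbinom(n * n_taxa, 1, config$zero_inflation),
                   n, n_taxa) == 1
    dens[mask] <- 0
  }

  colnames(dens) <- taxa
  panel <- new_density_panel(
    tibble(month = month_seq("1990-01-01", n), !!!as.data.frame(dens)),
    guilds)
  traits <- list(
    phyto = generate_trait_table(config$n_phyto, "phyto",
                                 seed = child_seed(config$seed,
                                                   "traits/phyto"),
                                 taxa = taxa_phy),
    zoo = generate_trait_table(config$n_zoo, "zoo",
                               seed = child_seed(config$seed, "traits/zoo"),
                               taxa = taxa_zoo))
  list(panel = panel, traits = traits, shifted_taxa = shifted,
       config = config)
}

#' Configuration for the coupled logistic map pair
#'
#' A two-species discrete logistic system with asymmetric coupling, the
#' standard benchmark for cross-mapping causality: `beta_xy` is the effect of
#' y on x and `beta_yx` the effect of x on y.
#'
#' @param r_x,r_y Growth rates.
#' @param beta_xy Effect of `y` on `x` (so `y` causes `x` when nonzero).
#' @param beta_yx Effect of `x` on `y`.
#' @param n_steps Steps returned after burn-in.
#' @param burn_in Discarded initial steps.
#' @param seed Integer seed (random interior initial conditions).
#' @return A validated `coupled_logistic_config` list.
#' @export
coupled_logistic_config <- function(r_x = 3.8, r_y = 3.5, beta_xy = 0.02,
                                    beta_yx = 0.32, n_steps = 1000,
                                    burn_in = 100, seed = 1) {
  check_number(r_x, "r_x", lower = 0, open_lower = TRUE)
  check_number(r_y, "r_y", lower = 0, open_lower = TRUE)
  check_number(beta_xy, "beta_xy")
  check_number(beta_yx, "beta_yx")
  check_count(n_steps, "n_steps", min = 10)
  check_count(burn_in, "burn_in", min = 0)
  check_count(seed, "seed", min = 0)
  structure(list(r_x = r_x, r_y = r_y, beta_xy = beta_xy, beta_yx = beta_yx,
                 n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
                 seed = as.integer(seed)),
            class = "coupled_logistic_config")
}

#' Simulate a coupled logistic map pair with known causal structure
#'
#' Iterates `x(t+1) = x(t) (r_x - r_x x(t) - beta_xy y(t))` and
#' `y(t+1) = y(t) (r_y - r_y y(t) - beta_yx x(t))`, discarding `burn_in`
#' steps.  Trajectories that leave `(0, 1)` raise an error naming the step.
#'
#' @param config A [coupled_logistic_config()].
#' @return Tibble with columns `time`, `x`, `y`.
#' @export
#' @examples
#' head(simulate_coupled_logistic(coupled_logistic_config(n_steps = 50)))
simulate_coupled_logistic <- function(config = coupled_logistic_config()) {
  if (!inherits(config, "coupled_logistic_config")) {
    config <- do.call(coupled_logistic_config, as.list(config))
  }
  set.seed(child_seed(config$seed, "coupled_logistic"))
  total <- config$n_steps + config$burn_in
  x <- numeric(total); y <- numeric(total)
  x[1] <- runif(1, 0.2, 0.8); y[1] <- runif(1, 0.2, 0.8)
  for (t in seq_len(total - 1)) {
    x[t + 1] <- x[t] * (config$r_x - config$r_x * x[t] -
                          config$beta_xy * y[t])
    y[t + 1] <- y[t] * (config$r_y - config$r_y * y[t] -
                          config$beta_yx * x[t])
    if (!is.finite(x[t + 1]) || !is.finite(y[t + 1]) ||
        x[t + 1] <= 0 || x[t + 1] >= 1 || y[t + 1] <= 0 || y[t + 1] >= 1) {
      abort(sprintf(
        "coupled logistic map diverged outside (0,1) at step %d; reduce growth rates or coupling",
        t + 1))
    }
  }
  keep <- seq.int(config$burn_in + 1, total)
  tibble(time = seq_along(keep), x = x[keep], y = y[keep])
}

#' Simulate a red-noise pair with an injected lag
#'
#' The base series is stationary AR(1) red noise; the partner is the base
#' shifted by `k` months plus white observation noise, so the partner lags
#' the base by `k` (positive `k` = partner later).  Returned aligned on a
#' common index as `x` (the shifted partner) and `y` (the base), so that the
#' strongest cross-correlation lag of `(x, y)` under this package's sign
#' convention recovers `k`.
#'
#' @param k Signed lag in months (`|k| < n/4`).
#' @param noise_sd Standard deviation of the white noise added to the
#'   partner.
#' @param n Length of the returned pair.
#' @param seed Integer seed.
#' @param ar Autocorrelation of the base red noise.
#' @return Tibble with columns `month`, `x` (partner), `y` (base).
#' @export
simulate_lagged_pair <- function(k, noise_sd = 0, n = 480, seed = 1,
                                 ar = 0.6) {
  check_count(n, "n", min = 24)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (!is.numeric(k) || length(k) != 1 || k != floor(k)) {
    abort("`k` must be a single integer lag")
  }
  if (abs(k) >= n / 4) abort("|k| too large for the series length n")
  set.seed(child_seed(seed, "lagged_pair"))
  pad <- abs(k)
  base <- as.numeric(ar1_noise(n + 2 * pad, 1, ar, 1))
  idx <- seq_len(n) + pad
  y <- base[idx]
  x <- base[idx - k] + if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
  tibble(month = month_seq("1990-01-01", n), x = x, y = y)
}
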