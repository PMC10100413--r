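# Small in-code fixtures shared across the suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

months_from <- function(n, start = "1990-01-01") {
  seq(as.Date(start), by = "month", length.out = n)
}

# wide panel from a month x taxon matrix; all phyto unless guilds given
make_panel <- function(mat, guilds = NULL, start = "1990-01-01") {
  taxa <- colnames(mat) %||% paste0("t", seq_len(ncol(mat)))
  colnames(mat) <- taxa
  guilds <- guilds %||% setNames(rep("phyto", length(taxa)), taxa)
  new_density_panel(
    tibble::tibble(month = months_from(nrow(mat), start),
                   !!!as.data.frame(mat)),
    guilds)
}

make_series <- function(values, start = "1990-01-01",
                        transforms = character()) {
  metric_series(months_from(length(values), start), values,
                transforms = transforms)
}

# a trait_space built directly from coordinates (for geometry oracles)
make_space <- function(coords, taxa = NULL) {
  coords <- as.matrix(coords)
  taxa <- taxa %||% paste0("t", seq_len(nrow(coords)))
  rownames(coords) <- taxa
  structure(list(coords = coords, eig = rep(1, ncol(coords)),
                 m = ncol(coords), taxa = taxa),
            class = "trait_space")
}

# a ccm_lag_profile with prescribed optimum/significance (for rule tests)
make_ccm_profile <- function(opt_tp, significant, tp_range = -30:30,
                             skill = 0.5) {
  skills <- rep(0.1, length(tp_range))
  skills[match(opt_tp, tp_range)] <- skill
  structure(tibble::tibble(tp = as.integer(tp_range), skill = skills),
            E = 2, direction = "test", optimal_tp = as.integer(opt_tp),
            optimal_skill = skill, null_q95 = 0.3,
            significant = significant, n_surrogates = 0,
            class = c("ccm_lag_profile", "tbl_df", "tbl", "data.frame"))
}

# independent standardized red-noise series (via the lagged-pair base)
red_noise_series <- function(n, seed, ar = 0.6) {
  base <- simulate_lagged_pair(k = 0, noise_sd = 0, n = n, seed = seed,
                               ar = ar)$y
  make_series(base, transforms = c("detrended", "deseasonalized", "scaled"))
}
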