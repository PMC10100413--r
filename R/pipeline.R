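# End-to-end orchestration: configuration, the full
# simulate/ingest -> preprocess -> state metrics -> functional diversity ->
# cross-correlation -> CCM -> classification pipeline, and result writers.

#' Build a full analysis configuration
#'
#' All knobs default to the analysis' canonical values: +/-60 month lag
#' grid, 10,000 surrogates, 2.5%/97.5% correlation envelopes, 95th-quantile
#' cross-map significance, 10-dimensional trait space cap, and the 0.99
#' zero-fraction taxon filter.  `profile = "smoke"` switches to a fast
#' profile (200 surrogates, +/-24 month lags) for continuous testing.
#'
#' @param simulation A [community_sim_config()] (ignored when
#'   `density_csv` given).
#' @param density_csv,trait_csv Optional input paths (long density CSV and
#'   per-guild trait CSVs as `c(phyto = ..., zoo = ...)`).
#' @param max_zero_fraction Sparse-taxon filter threshold.
#' @param fi_window,fi_step,fi_tolerance,mvi_window State-metric knobs.
#' @param fd_max_dim,fd_correction Trait-space knobs.
#' @param max_lag Cross-correlation lag bound (months).
#' @param n_surrogates Surrogates for both null models.
#' @param envelope_probs Cross-correlation envelope probabilities.
#' @param multiplicity LagX multiplicity handling (see
#'   [classify_lagged_correlation()]).
#' @param E_range,tau,tp_max,ccm_samples,ccm_surrogate CCM knobs.
#' @param as_printed Use the variance-inflating surrogate recurrence (see
#'   [red_noise_surrogates()]).
#' @param synchrony_band Paired-lag synchrony half-window (months).
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @param profile `"full"` or `"smoke"`.
#' @return An `analysis_config` list that round-trips through YAML.
#' @export
analysis_config <- function(simulation = community_sim_config(),
                            density_csv = NULL, trait_csv = NULL,
                            max_zero_fraction = 0.99,
                            fi_window = 48, fi_step = 1, fi_tolerance = 0.5,
                            mvi_window = 12,
                            fd_max_dim = 10, fd_correction = "cailliez",
                            max_lag = 60, n_surrogates = 10000,
                            envelope_probs = c(0.025, 0.975),
                            multiplicity = "max",
                            E_range = 1:10, tau = 1, tp_max = 60,
                            ccm_samples = 100,
                            ccm_surrogate = "predictor",
                            as_printed = FALSE, synchrony_band = 12,
                            seed = 1, out_dir = NULL,
                            profile = c("full", "smoke")) {
  profile <- arg_match(profile)
  if (profile == "smoke") {
    n_surrogates <- min(n_surrogates, 200)
    max_lag <- min(max_lag, 24)
    tp_max <- min(tp_max, 24)
  }
  structure(list(
    simulation = if (is.null(density_csv)) unclass(simulation) else NULL,
    input = list(density_csv = density_csv, trait_csv = trait_csv),
    preprocessing = list(max_zero_fraction = max_zero_fraction),
    state = list(fi_window = fi_window, fi_step = fi_step,
                 fi_tolerance = fi_tolerance, mvi_window = mvi_window),
    fd = list(max_dim = fd_max_dim, correction = fd_correction),
    association = list(max_lag = max_lag, n_surrogates = n_surrogates,
                       envelope_probs = envelope_probs,
                       multiplicity = multiplicity),
    ccm = list(E_range = E_range, tau = tau, tp_max = tp_max,
               n_samples = ccm_samples, n_surrogates = n_surrogates,
               surrogate = ccm_surrogate, as_printed = as_printed,
               synchrony_band = synchrony_band),
    seed = as.integer(seed), out_dir = out_dir, profile = profile),
    class = "analysis_config")
}

#' Read/write an analysis configuration as YAML
#'
#' @param config An [analysis_config()].
#' @param path YAML file path.
#' @return `read_analysis_config()` returns the config; the writer returns
#'   `path` invisibly.
#' @export
write_analysis_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- analysis_config(
    simulation = if (!is.null(raw$simulation)) {
      do.call(community_sim_config, raw$simulation)
    } else {
      community_sim_config()
    },
    density_csv = raw$input$density_csv, trait_csv = raw$input$trait_csv,
    max_zero_fraction = raw$preprocessing$max_zero_fraction,
    fi_window = raw$state$fi_window, fi_step = raw$state$fi_step,
    fi_tolerance = raw$state$fi_tolerance,
    mvi_window = raw$state$mvi_window,
    fd_max_dim = raw$fd$max_dim, fd_correction = raw$fd$correction,
    max_lag = raw$association$max_lag,
    n_surrogates = raw$association$n_surrogates,
    envelope_probs = unlist(raw$association$envelope_probs),
    multiplicity = raw$association$multiplicity,
    E_range = unlist(raw$ccm$E_range), tau = raw$ccm$tau,
    tp_max = raw$ccm$tp_max, ccm_samples = raw$ccm$n_samples,
    ccm_surrogate = raw$ccm$surrogate, as_printed = raw$ccm$as_printed,
    synchrony_band = raw$ccm$synchrony_band,
    seed = raw$seed, out_dir = raw$out_dir, profile = raw$profile)
  cfg
}

fd_metric_names <- c("fric", "fdis", "feve")
state_metric_names <- c("community", "density", "fi", "mvi", "zp_ratio")

#' Run the full lead-lag analysis
#'
#' Simulates (or ingests) a monthly plankton panel, computes the five state
#' metrics and six functional diversity series (3 metrics x 2 guilds),
#' standardizes every series (detrend, deseasonalize, z-scale), then runs
#' the lagged cross-correlation test against red-noise surrogates for all
#' 30 FD x state pairs and lagged CCM in both directions (60 mappings) with
#' paired-lag direction classification.
#'
#' @param config An [analysis_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A `planklag_results` list: `panel`, `series` (standardized
#'   metric series), `associations` (30 rows), `ccm` (60 rows),
#'   `classifications` (30 rows), `manifest`.  If `config$out_dir` is set,
#'   tables are also written there (see [write_results()]).
#' @export
#' @examples
#' \dontrun{
#' cfg <- analysis_config(simulation = community_sim_config(n_months = 120),
#'                        profile = "smoke")
#' res <- run_full_analysis(cfg, seed = 1)
#' res$associations
#' }
run_full_analysis <- function(config = analysis_config(), seed = NULL) {
  seed <- as.integer(seed %||% config$seed)
  manifest <- list(seed = seed, config_hash = rlang::hash(unclass(config)),
                   package_version = as.character(utils::packageVersion("planklag")),
                   stages = character())
  bundle <- list(config = config, manifest = manifest)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      bundle$manifest$failed_stage <<- name
      bundle$manifest$error <<- conditionMessage(e)
      if (!is.null(config$out_dir)) {
        try(write_results(bundle, config$out_dir), silent = TRUE)
      }
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    bundle$manifest$stages <<- c(bundle$manifest$stages, name)
    res
  }

  # --- input -----------------------------------------------------------
  inputs <- stage("input", {
    if (!is.null(config$input$density_csv)) {
      records <- read_density_csv(config$input$density_csv)
      panel <- monthly_mean(fill_unrecorded_with_zero(records))
      traits <- purrr::imap(config$input$trait_csv, function(p, g) {
        read_trait_csv(p, guild = g)
      })
      list(panel = panel, traits = traits)
    } else {
      sim_cfg <- do.call(community_sim_config,
                         c(config$simulation[setdiff(names(config$simulation),
                                                     "seed")],
                           list(seed = child_seed(seed, "simulation"))))
      simulate_community(sim_cfg)
    }
  })
  bundle$panel <- stage("preprocess", {
    filter_sparse_taxa(inputs$panel,
                       config$preprocessing$max_zero_fraction)
  })

  # --- metric series ---------------------------------------------------
  state_raw <- stage("state_metrics", {
    sm <- state_metrics(bundle$panel, fi_window = config$state$fi_window,
                        fi_step = config$state$fi_step,
                        fi_tolerance = config$state$fi_tolerance,
                        mvi_window = config$state$mvi_window)
    bundle$state_metrics <- sm
    purrr::map(set_names(state_metric_names), function(m) {
      metric_series(sm$month, sm[[m]], metric = m)
    })
  })
  fd_raw <- stage("functional_diversity", {
    guilds <- c("phyto", "zoo")
    out <- list()
    for (g in guilds) {
      traits <- inputs$traits[[g]]
      pg <- panel_guilds(bundle$panel)
      keep <- intersect(traits$taxon,
                        names(pg)[pg == g])
      d <- gower_dissimilarity(traits)
      space <- embed_trait_space(d[keep, keep, drop = FALSE],
                                 max_dim = config$fd$max_dim,
                                 correction = config$fd$correction)
      fds <- fd_series(panel_subset(bundle$panel, keep), space, guild = g)
      bundle$fd_series[[g]] <- fds
      for (m in fd_metric_names) {
        out[[paste(g, m, sep = "_")]] <-
          metric_series(fds$month, fds[[m]], metric = m)
      }
    }
    out
  })

  series <- stage("standardize", {
    purrr::map(c(state_raw, fd_raw), standardize_series)
  })
  bundle$series <- series

  # --- lagged cross-correlation ---------------------------------------
  bundle$associations <- stage("cross_correlation", {
    rows <- list()
    for (g in c("phyto", "zoo")) {
      for (fm in fd_metric_names) {
        fd_s <- series[[paste(g, fm, sep = "_")]]
        ens <- red_noise_surrogates(
          fd_s, n = config$association$n_surrogates,
          seed = child_seed(seed, paste0("ccf_surr/", g, "/", fm)),
          as_printed = config$ccm$as_printed)
        for (sm in state_metric_names) {
          prof <- classify_lagged_correlation(
            fd_s, series[[sm]], ens,
            max_lag = config$association$max_lag,
            probs = config$association$envelope_probs,
            multiplicity = config$association$multiplicity)
          rows[[length(rows) + 1]] <- dplyr::bind_cols(
            tibble(guild = g, fd_metric = fm, state_metric = sm),
            glance(prof))
        }
      }
    }
    dplyr::bind_rows(rows)
  })

  # --- lagged CCM, both directions ------------------------------------
  ccm_out <- stage("ccm", {
    tp_range <- -config$ccm$tp_max:config$ccm$tp_max
    e_cache <- purrr::map(series, function(s) {
      tryCatch(select_E(s, E_range = config$ccm$E_range,
                        tau = config$ccm$tau),
               error = function(e) NA_integer_)
    })
    rows <- list()
    cls <- list()
    for (g in c("phyto", "zoo")) {
      for (fm in fd_metric_names) {
        fd_key <- paste(g, fm, sep = "_")
        fd_s <- interpolate_gaps(series[[fd_key]])
        for (sm in state_metric_names) {
          st_s <- interpolate_gaps(series[[sm]])
          pair_seed <- child_seed(seed, paste("ccm", g, fm, sm, sep = "/"))
          fwd <- lagged_ccm(fd_s, st_s, E = e_cache[[fd_key]],
                            tau = config$ccm$tau, tp_range = tp_range,
                            n_surrogates = config$ccm$n_surrogates,
                            seed = pair_seed,
                            surrogate = config$ccm$surrogate,
                            direction = sprintf("%s_%s xmap %s", g, fm, sm))
          rev <- lagged_ccm(st_s, fd_s, E = e_cache[[sm]],
                            tau = config$ccm$tau, tp_range = tp_range,
                            n_surrogates = config$ccm$n_surrogates,
                            seed = child_seed(pair_seed, "reverse"),
                            surrogate = config$ccm$surrogate,
                            direction = sprintf("%s xmap %s_%s", sm, g, fm))
          pair <- classify_pair(fwd, rev, band = config$ccm$synchrony_band)
          meta <- tibble(guild = g, fd_metric = fm, state_metric = sm)
          rows[[length(rows) + 1]] <- dplyr::bind_cols(meta, glance(fwd))
          rows[[length(rows) + 1]] <- dplyr::bind_cols(meta, glance(rev))
          cls[[length(cls) + 1]] <- dplyr::bind_cols(
            meta,
            tibble(classification = pair$classification,
                   forward_tp = pair$forward$optimal_tp,
                   reverse_tp = pair$reverse$optimal_tp,
                   forward_significant = pair$forward$significant,
                   reverse_significant = pair$reverse$significant))
        }
      }
    }
    list(ccm = dplyr::bind_rows(rows), classifications = dplyr::bind_rows(cls))
  })
  bundle$ccm <- ccm_out$ccm
  bundle$classifications <- ccm_out$classifications

  bundle$manifest$stages <- c(bundle$manifest$stages, "done")
  if (!is.null(config$out_dir)) write_results(bundle, config$out_dir)
  structure(bundle, class = "planklag_results")
}

#' @export
print.planklag_results <- function(x, ...) {
  cat(sprintf(
    "<planklag_results> %d association rows, %d CCM rows, %d pair classifications\n",
    NROW(x$associations), NROW(x$ccm), NROW(x$classifications)))
  invisible(x)
}

#' Write the result bundle to a directory
#'
#' Emits `associations.tsv`, `ccm.tsv`, `classifications.tsv`,
#' `state_metrics.csv`, `fd_phyto.csv`/`fd_zoo.csv`, and `manifest.json`.
#'
#' @param bundle A [run_full_analysis()] result (possibly partial).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(bundle$associations)) {
    readr::write_tsv(bundle$associations, file.path(dir, "associations.tsv"))
    jsonlite::write_json(bundle$associations,
                         file.path(dir, "associations.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(bundle$ccm)) {
    readr::write_tsv(bundle$ccm, file.path(dir, "ccm.tsv"))
    jsonlite::write_json(bundle$ccm, file.path(dir, "ccm.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(bundle$classifications)) {
    readr::write_tsv(bundle$classifications,
                     file.path(dir, "classifications.tsv"))
  }
  if (!is.null(bundle$state_metrics)) {
    readr::write_csv(as_tibble(bundle$state_metrics),
                     file.path(dir, "state_metrics.csv"))
  }
  for (g in names(bundle$fd_series)) {
    readr::write_csv(as_tibble(bundle$fd_series[[g]]),
                     file.path(dir, paste0("fd_", g, ".csv")))
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
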