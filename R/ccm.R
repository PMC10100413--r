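# Empirical dynamic modelling: delay embedding, simplex forecasting,
# embedding-dimension selection, convergent cross mapping over library
# sizes, lagged CCM over a signed prediction-offset grid with red-noise
# surrogate significance, and paired-lag causality-direction
# classification.

series_values <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  as_metric_series(x)$value
}

#' Delay-embed a series
#'
#' Builds the delay vectors `(x_t, x_{t-tau}, ..., x_{t-(E-1) tau})` for
#' every `t` where all components are observed.
#'
#' @param x Numeric vector or [metric_series()] (gap-free on its evaluation
#'   range; see [interpolate_gaps()]).
#' @param E Embedding dimension (>= 1).
#' @param tau Lag step in months (default 1).
#' @return List with `coords` (rows = delay vectors), `time` (the `t` of
#'   each row), `E`, `tau`.
#' @export
delay_embed <- function(x, E, tau = 1) {
  v <- series_values(x)
  check_count(E, "E", min = 1)
  check_count(tau, "tau", min = 1)
  t_len <- length(v)
  first <- (E - 1) * tau + 1
  if (first > t_len) abort("series too short for this embedding")
  times <- first:t_len
  coords <- vapply(0:(E - 1), function(j) v[times - j * tau],
                   numeric(length(times)))
  coords <- matrix(coords, ncol = E)
  ok <- rowSums(is.na(coords)) == 0
  coords <- coords[ok, , drop = FALSE]
  times <- times[ok]
  if (nrow(coords) < E + 2) {
    abort("fewer than E + 2 usable delay vectors")
  }
  list(coords = coords, time = as.integer(times), E = as.integer(E),
       tau = as.integer(tau))
}

# target value aligned with each embedding row: b[time + tp] (NA off-range)
embed_target <- function(emb, b, tp) {
  idx <- emb$time + tp
  out <- rep(NA_real_, length(idx))
  ok <- idx >= 1 & idx <= length(b)
  out[ok] <- b[idx[ok]]
  out
}

default_exclusion <- function(emb, tp) max(emb$tau * emb$E, abs(tp))

# core prediction: simplex forecast of `target` from `emb` using `lib` rows
simplex_predict <- function(emb, target, lib, pred, n_neighbors = emb$E + 1,
                            exclusion = default_exclusion(emb, 0)) {
  cpp_simplex_predict(emb$coords, emb$time, target, as.integer(lib),
                      as.integer(pred), as.integer(n_neighbors),
                      as.integer(exclusion))
}

skill_cor <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  if (sum(ok) < 5) return(NA_real_)
  if (sd(obs[ok]) == 0 || sd(pred[ok]) == 0) return(NA_real_)
  cor(pred[ok], obs[ok])
}

#' Leave-one-out simplex forecast skill of a series
#'
#' Each delay vector's `E + 1` nearest neighbours (excluding temporally
#' adjacent points within the Theiler window `max(tau * E, |tp|)`) predict
#' the value `tp` steps ahead; skill is the Pearson correlation between
#' predictions and observations.
#'
#' @inheritParams delay_embed
#' @param tp Prediction offset (default 1 step ahead).
#' @param exclusion Temporal exclusion radius; defaults to the Theiler
#'   window above.
#' @return Forecast skill (Pearson rho).
#' @export
simplex_skill <- function(x, E, tp = 1, tau = 1, exclusion = NULL) {
  v <- series_values(x)
  if (sd(v, na.rm = TRUE) == 0) abort("constant series: forecast skill undefined")
  emb <- delay_embed(v, E, tau)
  target <- embed_target(emb, v, tp)
  valid <- which(is.finite(target))
  if (length(valid) < E + 2) abort("too few usable forecasts")
  exclusion <- exclusion %||% default_exclusion(emb, tp)
  pred <- simplex_predict(emb, target, lib = valid, pred = valid,
                          exclusion = exclusion)
  skill <- skill_cor(pred, target[valid])
  if (is.na(skill)) abort("forecast skill undefined (zero variance)")
  skill
}

#' Choose the embedding dimension by simplex forecasting
#'
#' Returns the `E` in `E_range` maximizing one-step simplex skill; ties go
#' to the smallest `E`.  Chosen once per series (on its detrended form) and
#' reused across prediction offsets.
#'
#' @inheritParams simplex_skill
#' @param E_range Candidate dimensions (default 1:10).
#' @return The selected integer `E`.
#' @export
select_E <- function(x, E_range = 1:10, tp = 1, tau = 1) {
  skills <- vapply(E_range, function(e) {
    tryCatch(simplex_skill(x, e, tp = tp, tau = tau),
             error = function(err) NA_real_)
  }, numeric(1))
  if (all(is.na(skills))) abort("simplex skill undefined for every E")
  E_range[which.max(skills)]   # which.max takes the first (smallest E) tie
}

geometric_library_grid <- function(l_min, l_max, n_sizes = 8) {
  sizes <- unique(round(exp(seq(log(l_min), log(l_max),
                                length.out = n_sizes))))
  sizes[sizes >= l_min & sizes <= l_max]
}

#' Convergent cross-map skill across library sizes
#'
#' Uses the delay-embedded manifold of `predictor` (series A) to cross-map
#' `target` (series B) at offset `tp` — the test of B's causal influence on
#' A.  For each library size, `n_samples` random without-replacement
#' subsets of A's delay vectors form the library; at the maximum size the
#' full library is used once.  Skill is the mean Pearson correlation
#' between cross-mapped predictions and observations.
#'
#' @param predictor,target Numeric vectors or [metric_series()] on a common
#'   monthly grid.
#' @param E Embedding dimension for `predictor` (see [select_E()]).
#' @param tp Signed prediction offset in months.
#' @param tau Embedding lag step.
#' @param library_sizes Increasing library sizes; default geometric grid
#'   from `E + 2` to the full library.
#' @param n_samples Random libraries per size (default 100).
#' @param seed Integer seed for the library sampling.
#' @param direction Label stored on the result (e.g. `"fd xmap state"`).
#' @return A `ccm_fit`: tibble of skills per library size plus sampling
#'   detail, `convergent` flag (see [convergence_test()]).
#' @export
ccm_skill <- function(predictor, target, E, tp = 0, tau = 1,
                      library_sizes = NULL, n_samples = 100, seed = 1,
                      direction = "A xmap B") {
  a <- series_values(predictor)
  b <- series_values(target)
  if (length(a) != length(b)) abort("series must share one time grid")
  emb <- delay_embed(a, E, tau)
  tgt <- embed_target(emb, b, tp)
  valid <- which(is.finite(tgt))
  l_max <- length(valid)
  if (l_max < E + 2) abort("too few usable vectors for cross mapping")
  library_sizes <- library_sizes %||% geometric_library_grid(E + 2, l_max)
  library_sizes <- sort(unique(pmin(library_sizes, l_max)))
  skipped <- library_sizes < E + 2
  if (any(skipped)) {
    warn(sprintf("skipping library sizes < E + 2: %s",
                 toString(library_sizes[skipped])))
    library_sizes <- library_sizes[!skipped]
  }
  exclusion <- default_exclusion(emb, tp)
  set.seed(child_seed(seed, "ccm_library_sampling"))

  sample_skills <- purrr::map(library_sizes, function(L) {
    if (L >= l_max) {
      pred <- simplex_predict(emb, tgt, lib = valid, pred = valid,
                              exclusion = exclusion)
      return(skill_cor(pred, tgt[valid]))
    }
    vapply(seq_len(n_samples), function(s) {
      lib <- valid[sample.int(l_max, L)]
      pred <- simplex_predict(emb, tgt, lib = lib, pred = valid,
                              exclusion = exclusion)
      skill_cor(pred, tgt[valid])
    }, numeric(1))
  })
  skills <- tibble(library_size = library_sizes,
                   skill = vapply(sample_skills, function(s) {
                     mean(s, na.rm = TRUE)
                   }, numeric(1)),
                   n_samples = vapply(sample_skills, length, integer(1)))
  fit <- structure(
    list(direction = direction, E = emb$E, tau = emb$tau, tp = as.integer(tp),
         library_sizes = library_sizes, skills = skills,
         sample_skills_min = sample_skills[[1]],
         skill_max = skills$skill[nrow(skills)], n_valid = l_max,
         seed = as.integer(seed)),
    class = "ccm_fit")
  fit$convergent <- tryCatch(convergence_test(fit),
                             error = function(e) NA)
  fit
}

#' @export
print.ccm_fit <- function(x, ...) {
  cat(sprintf("<ccm_fit> %s | E = %d, tp = %+d | skill %.3f at L = %d | convergent: %s\n",
              x$direction, x$E, x$tp, x$skill_max,
              max(x$library_sizes), format(x$convergent)))
  invisible(x)
}

#' Test convergence of a cross-map skill curve
#'
#' Convergent iff the skill at the largest library size exceeds the 95th
#' percentile of the sampled skills at the smallest size by at least
#' `margin` — skill must genuinely improve as the library grows, the
#' namesake criterion of convergent cross mapping.
#'
#' @param fit A [ccm_skill()] result with >= 2 library sizes and >= 20
#'   samples at the smallest.
#' @param margin Minimum improvement (default 0.05).
#' @return Logical flag.
#' @export
convergence_test <- function(fit, margin = 0.05) {
  stopifnot(inherits(fit, "ccm_fit"))
  if (length(fit$library_sizes) < 2) {
    abort("need at least 2 library sizes to test convergence")
  }
  if (length(fit$sample_skills_min) < 20) {
    abort("need >= 20 samples at the smallest library size")
  }
  q95 <- quantile(fit$sample_skills_min, 0.95, na.rm = TRUE)
  isTRUE(fit$skill_max > q95 && (fit$skill_max - q95) >= margin)
}

#' @rdname tidy.lag_profile
#' @method tidy ccm_fit
#' @export
tidy.ccm_fit <- function(x, ...) x$skills

#' @rdname tidy.lag_profile
#' @method glance ccm_fit
#' @export
glance.ccm_fit <- function(x, ...) {
  tibble(direction = x$direction, E = x$E, tp = x$tp,
         skill_max = x$skill_max,
         library_max = max(x$library_sizes), convergent = x$convergent)
}

# Max-over-offsets cross-map skill of one (surrogate) predictor series:
# neighbours are computed once with a fixed exclusion radius covering the
# whole offset grid, then every tp reuses them, so the selection-corrected
# null costs barely more than a single-offset evaluation.
max_skill_over_tps <- function(a, b, E, tau, tp_range) {
  emb <- tryCatch(delay_embed(a, E, tau), error = function(e) NULL)
  if (is.null(emb)) return(NA_real_)
  exclusion <- max(emb$tau * emb$E, max(abs(tp_range)))
  nb <- cpp_simplex_neighbors(emb$coords, emb$time, emb$E + 1L,
                              as.integer(exclusion))
  cpp_max_skill_over_tps(nb$idx, nb$weight, emb$time, as.numeric(b),
                         as.integer(tp_range))
}

# full-library cross-map skill for one tp (embedding reused by the caller)
ccm_full_skill_at <- function(emb, b, tp) {
  tgt <- embed_target(emb, b, tp)
  valid <- which(is.finite(tgt))
  if (length(valid) < emb$E + 2) return(NA_real_)
  pred <- simplex_predict(emb, tgt, lib = valid, pred = valid,
                          exclusion = default_exclusion(emb, tp))
  skill_cor(pred, tgt[valid])
}

#' Lagged convergent cross mapping over a prediction-offset grid
#'
#' Full-library cross-map skill of `predictor` onto `target` for every
#' offset `tp` in `tp_range`; the optimal `tp` is the skill argmax (ties:
#' smallest |tp|, negative first), with a plateau correction for the
#' right-censoring induced by the embedding (see the methods vignette).
#' Significance is selection-corrected: because the observed statistic is
#' a maximum over the whole offset grid, each red-noise surrogate
#' (substituted for the predictor, or for both series with
#' `surrogate = "both"`) contributes its own maximum-over-offsets skill
#' to the null, and the observed optimal skill must exceed the 95th
#' percentile of those maxima.  Judging the observed maximum against a
#' single-offset null would be anti-conservative (roughly half of
#' independent red-noise pairs would flag as causal).
#'
#' @inheritParams ccm_skill
#' @param tp_range Signed offsets (default -60:60 months).
#' @param n_surrogates Surrogate count for the null (default 1000).
#' @param surrogate Which series the surrogates replace.
#' @param ar Optional AR(1) coefficient for the surrogates (estimated when
#'   `NULL`).
#' @return A `ccm_lag_profile` tibble (`tp`, `skill`) with attributes
#'   `optimal_tp`, `optimal_skill`, `significant`, `null_q95`, `E`,
#'   `direction`.
#' @export
lagged_ccm <- function(predictor, target, E = NULL, tau = 1,
                       tp_range = -60:60, n_surrogates = 1000, seed = 1,
                       surrogate = c("predictor", "both"), ar = NULL,
                       direction = "A xmap B") {
  surrogate <- arg_match(surrogate)
  a <- series_values(predictor)
  b <- series_values(target)
  if (length(a) != length(b)) abort("series must share one time grid")
  E <- E %||% select_E(a, tau = tau)
  emb <- delay_embed(a, E, tau)
  skills <- vapply(tp_range, function(tp) ccm_full_skill_at(emb, b, tp),
                   numeric(1))
  if (all(is.na(skills))) abort("cross-map skill undefined at every tp")
  best <- which(skills == max(skills, na.rm = TRUE))
  ibest <- best[order(abs(tp_range[best]), tp_range[best])][1]
  # Plateau correction: a delay vector carries the predictor's E-1 past
  # values, so when B is a lagged copy of A the skill is near-maximal on
  # the whole plateau [k - (E-1), k].  Walk right from the argmax over
  # near-ties (within plateau_tol, at most E-1 steps) to report the
  # plateau's upper edge - the true alignment lag.
  plateau_tol <- 0.03
  peak <- skills[ibest]
  window <- ibest + seq_len(E - 1)
  window <- window[window <= length(skills)]
  near <- window[!is.na(skills[window]) & skills[window] >= peak - plateau_tol]
  if (length(near) > 0) ibest <- max(near)
  opt_tp <- tp_range[ibest]
  opt_skill <- skills[ibest]

  null_skills <- rep(NA_real_, n_surrogates)
  if (n_surrogates > 0) {
    ens_a <- red_noise_surrogates(metric_series(
      month_seq("1990-01-01", length(a)), a), n = n_surrogates,
      seed = child_seed(seed, "ccm_null_a"), r = ar)
    ens_b <- if (surrogate == "both") {
      red_noise_surrogates(metric_series(
        month_seq("1990-01-01", length(b)), b), n = n_surrogates,
        seed = child_seed(seed, "ccm_null_b"), r = ar)
    } else {
      NULL
    }
    for (s in seq_len(n_surrogates)) {
      sa <- ens_a$matrix[s, ]
      sb <- if (is.null(ens_b)) b else ens_b$matrix[s, ]
      null_skills[s] <- max_skill_over_tps(sa, sb, E, tau, tp_range)
    }
  }
  q95 <- if (all(is.na(null_skills))) NA_real_
  else quantile(null_skills, 0.95, na.rm = TRUE)
  structure(tibble(tp = as.integer(tp_range), skill = skills),
            E = E, direction = direction,
            optimal_tp = as.integer(opt_tp), optimal_skill = opt_skill,
            null_q95 = unname(q95),
            significant = isTRUE(opt_skill > q95),
            n_surrogates = n_surrogates,
            class = c("ccm_lag_profile", "tbl_df", "tbl", "data.frame"))
}

#' @rdname tidy.lag_profile
#' @method glance ccm_lag_profile
#' @export
glance.ccm_lag_profile <- function(x, ...) {
  tibble(direction = attr(x, "direction"), E = attr(x, "E"),
         optimal_tp = attr(x, "optimal_tp"),
         optimal_skill = attr(x, "optimal_skill"),
         null_q95 = attr(x, "null_q95"),
         significant = attr(x, "significant"))
}

#' Classify the causal direction of a forward/reverse cross-mapping pair
#'
#' `forward` is the functional-diversity-manifold mapping (`FD xmap
#' state`, testing state's influence on FD) and `reverse` the state-manifold
#' mapping.  Precedence: (1) if neither mapping is significant the pair is
#' `"none"`; (2) if the pairing line crosses zero — the two optimal offsets
#' have strictly opposite signs — the variable with the negative offset
#' leads (`"FD-leads"` / `"state-leads"`); (3) otherwise offsets both
#' within the +/- `band` months synchrony window are `"synchronous"`, and
#' same-side offsets beyond it are `"bidirectional-equal"`.
#'
#' @param forward,reverse `ccm_lag_profile` results on the same `tp` grid.
#' @param band Synchrony half-window in months (default 12).
#' @return A `causal_pair_summary` list: `classification`, `forward`,
#'   `reverse` (their [glance()] rows).
#' @export
classify_pair <- function(forward, reverse, band = 12) {
  stopifnot(inherits(forward, "ccm_lag_profile"),
            inherits(reverse, "ccm_lag_profile"))
  if (!identical(forward$tp, reverse$tp)) {
    abort("forward and reverse profiles must share the tp grid")
  }
  f_tp <- attr(forward, "optimal_tp")
  r_tp <- attr(reverse, "optimal_tp")
  f_sig <- attr(forward, "significant")
  r_sig <- attr(reverse, "significant")
  classification <- if (!f_sig && !r_sig) {
    "none"
  } else if (f_tp < 0 && r_tp > 0) {
    "FD-leads"
  } else if (f_tp > 0 && r_tp < 0) {
    "state-leads"
  } else if (abs(f_tp) <= band && abs(r_tp) <= band) {
    "synchronous"
  } else {
    "bidirectional-equal"
  }
  structure(list(classification = classification,
                 forward = glance(forward), reverse = glance(reverse),
                 band = band),
            class = "causal_pair_summary")
}

#' @export
print.causal_pair_summary <- function(x, ...) {
  cat(sprintf("<causal_pair_summary> %s (forward tp %+d%s, reverse tp %+d%s)\n",
              x$classification,
              x$forward$optimal_tp, if (x$forward$significant) "*" else "",
              x$reverse$optimal_tp, if (x$reverse$significant) "*" else ""))
  invisible(x)
}
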