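logistic_pair <- function(seed = 2, n = 500, beta_yx = 0.32) {
  simulate_coupled_logistic(coupled_logistic_config(
    beta_xy = 0, beta_yx = beta_yx, n_steps = n, seed = seed))
}

test_that("delay embedding produces the expected vectors", {
  v <- 1:10
  e1 <- delay_embed(v, E = 1)
  expect_equal(as.numeric(e1$coords), v)
  e3 <- delay_embed(v, E = 3, tau = 1)
  expect_equal(nrow(e3$coords), 8)
  expect_equal(e3$coords[1, ], c(3, 2, 1))
  e22 <- delay_embed(v, E = 2, tau = 2)
  expect_equal(nrow(e22$coords), 8)
  expect_equal(e22$coords[1, ], c(3, 1))
  # rows containing missing values are dropped
  v[5] <- NA
  em <- delay_embed(v, E = 2)
  expect_false(any(is.na(em$coords)))
  expect_error(delay_embed(1:4, E = 4), "usable|short")
})

test_that("simplex forecasting separates deterministic from random series", {
  cl <- logistic_pair(seed = 41, n = 500)
  expect_gt(simplex_skill(cl$x, E = 2), 0.95)
  # noiseless periodic series are almost perfectly predictable
  per <- sin(2 * pi * (1:200) / 12)
  expect_gt(simplex_skill(per, E = 2), 0.99)
  set.seed(42)
  expect_lt(abs(simplex_skill(rnorm(500), E = 3)), 0.15)
  expect_error(simplex_skill(rep(1, 50), E = 2), "constant")
})

test_that("embedding dimension selection is deterministic and sensible", {
  cl <- logistic_pair(seed = 43, n = 400)
  e <- select_E(cl$x)
  expect_true(e %in% 1:3)
  expect_identical(select_E(cl$x), e)
  ar <- as.numeric(arima.sim(list(ar = 0.6), 400))
  expect_identical(select_E(ar), select_E(ar))
})

test_that("cross mapping detects the causal direction on the coupled logistic pair", {
  cl <- logistic_pair(seed = 44, n = 1000)
  # x drives y, so y's manifold predicts x ("y xmap x" tests x -> y)
  true_dir <- ccm_skill(cl$y, cl$x, E = 2, seed = 1,
                        direction = "y xmap x")
  false_dir <- ccm_skill(cl$x, cl$y, E = 2, seed = 1,
                         direction = "x xmap y")
  expect_gt(true_dir$skill_max - false_dir$skill_max, 0.3)
  expect_true(true_dir$convergent)
  # self-map approaches perfection at full library
  self <- ccm_skill(cl$x, cl$x, E = 2, tp = 0, seed = 1)
  expect_gt(self$skill_max, 0.99)
  # library sizes increase and skills stay in [-1, 1]
  expect_true(all(diff(true_dir$library_sizes) > 0))
  expect_true(all(abs(true_dir$skills$skill) <= 1))
})

test_that("cross-map skill is invariant to affine rescaling of both series", {
  cl <- logistic_pair(seed = 45, n = 300)
  base <- ccm_skill(cl$y, cl$x, E = 2, seed = 2)
  scaled <- ccm_skill(5 * cl$y - 2, -3 * cl$x + 10, E = 2, seed = 2)
  expect_equal(abs(scaled$skill_max), abs(base$skill_max),
               tolerance = 1e-10)
})

test_that("convergence testing accepts causal pairs and rejects independent ones", {
  causal <- ccm_skill(logistic_pair(seed = 46, n = 800)$y,
                      logistic_pair(seed = 46, n = 800)$x, E = 2, seed = 3)
  expect_true(convergence_test(causal))

  ia <- logistic_pair(seed = 47, n = 800, beta_yx = 0)
  indep <- ccm_skill(ia$y, ia$x, E = 2, seed = 4)
  expect_false(convergence_test(indep))

  # flat skill curve from structureless data
  set.seed(48)
  flat <- ccm_skill(rnorm(300), rnorm(300), E = 2, seed = 5)
  expect_false(convergence_test(flat))
})

test_that("lagged CCM recovers injected shifts and self-maps at zero", {
  base <- red_noise_series(480, seed = 49)
  a <- base$value
  k <- -7
  b <- a[((seq_len(480) - 1 - k) %% 480) + 1]   # b_t = a_{t-k}, circular
  lp <- lagged_ccm(a, b, E = 3, tp_range = -20:20, n_surrogates = 0)
  expect_lte(abs(attr(lp, "optimal_tp") - k), 1)

  self <- lagged_ccm(a, a, E = 3, tp_range = -5:5, n_surrogates = 0)
  expect_equal(attr(self, "optimal_tp"), 0L)

  # surrogate significance: a strongly coupled pair is detected
  pair <- simulate_lagged_pair(k = -12, noise_sd = 0.25, n = 480, seed = 50)
  lps <- lagged_ccm(pair$y, pair$x, tp_range = -20:20, n_surrogates = 100,
                    seed = 6)
  expect_lte(abs(attr(lps, "optimal_tp") - (-12)), 1)
  expect_true(attr(lps, "significant"))
  g <- glance(lps)
  expect_true(all(c("optimal_tp", "optimal_skill", "significant") %in%
                    names(g)))
})

test_that("paired-lag classification follows the precedence rules", {
  case <- function(f_tp, r_tp, f_sig = TRUE, r_sig = TRUE) {
    classify_pair(make_ccm_profile(f_tp, f_sig),
                  make_ccm_profile(r_tp, r_sig))$classification
  }
  expect_equal(case(-5, 5), "FD-leads")
  expect_equal(case(5, -5), "state-leads")
  expect_equal(case(0, 0), "synchronous")
  expect_equal(case(-3, -3), "synchronous")
  expect_equal(case(-30, -30), "bidirectional-equal")
  expect_equal(case(-5, 5, FALSE, FALSE), "none")
  expect_equal(case(8, 11), "synchronous")
  expect_equal(case(14, 20), "bidirectional-equal")
  # crossing takes precedence over the synchrony band
  expect_equal(case(-2, 2), "FD-leads")
  expect_error(classify_pair(make_ccm_profile(0, TRUE, tp_range = -5:5),
                             make_ccm_profile(0, TRUE, tp_range = -6:6)),
               "grid")
})

test_that("lagged-CCM surrogate significance stays rare on independent pairs", {
  hits <- 0
  n_rep <- 25
  for (i in seq_len(n_rep)) {
    x <- red_noise_series(300, seed = 8000 + i)$value
    y <- red_noise_series(300, seed = 8800 + i)$value
    lp <- lagged_ccm(x, y, E = 2, tp_range = -10:10, n_surrogates = 100,
                     seed = i)
    hits <- hits + isTRUE(attr(lp, "significant"))
  }
  expect_lte(hits / n_rep, 0.2)
})

test_that("cross-map skill grows with library size for causal pairs", {
  cl <- logistic_pair(seed = 51, n = 800)
  fit <- ccm_skill(cl$y, cl$x, E = 2, seed = 7)
  sk <- fit$skills$skill
  expect_gt(cor(seq_along(sk), sk, method = "spearman"), 0.8)
  expect_gt(sk[length(sk)], sk[1])
})
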