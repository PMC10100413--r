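test_that("total density and trophic ratio follow exact logs on positive panels", {
  m <- cbind(a = c(10, 5), b = c(90, 5))
  g <- c(a = "phyto", b = "zoo")
  panel <- make_panel(m, g)
  expect_equal(total_density(panel)$value, log(c(100, 10)),
               tolerance = 1e-12)
  expect_equal(trophic_ratio(panel)$value, c(log(90 / 10), 0),
               tolerance = 1e-12)
  # single taxon: log of its own density
  solo <- make_panel(cbind(a = c(2, 7)))
  expect_equal(total_density(solo)$value, log(c(2, 7)), tolerance = 1e-12)
  # scale invariance of the ratio
  doubled <- make_panel(2 * m, g)
  expect_equal(trophic_ratio(doubled)$value, trophic_ratio(panel)$value,
               tolerance = 1e-12)
})

test_that("zero months use the documented half-minimum offset", {
  panel <- make_panel(cbind(a = c(0, 4, 10)))
  # sums {0, 4, 10}: eps = 2
  expect_equal(total_density(panel)$value, log(c(0, 4, 10) + 2),
               tolerance = 1e-12)
})

test_that("community PC1 matches the correlation-matrix eigen oracle", {
  set.seed(11)
  base <- abs(rnorm(40, 10, 2))
  # two perfectly correlated taxa: scores proportional to either series
  panel <- make_panel(cbind(a = base, b = 2 * base))
  sc <- community_pc1(panel)$value
  expect_equal(abs(cor(sc, base)), 1, tolerance = 1e-10)

  # two noisy taxa: PC1 variance share equals the top eigenvalue of the
  # 2x2 correlation matrix (independent eigen oracle)
  x1 <- abs(rnorm(200, 10)); x2 <- abs(rnorm(200, 10))
  p2 <- make_panel(cbind(a = x1, b = x2))
  sc2 <- community_pc1(p2)$value
  lam1 <- eigen(cor(cbind(x1, x2)))$values[1]
  expect_equal(var(sc2), lam1, tolerance = 1e-8)

  # negating the inputs cannot change association magnitudes
  sc_neg <- community_pc1(make_panel(cbind(a = max(x1) - x1 + 1,
                                           b = max(x2) - x2 + 1)))$value
  expect_equal(abs(cor(sc_neg, sc2)), 1, tolerance = 1e-8)
  expect_error(community_pc1(make_panel(cbind(a = rep(1, 10),
                                              b = rep(2, 10)))),
               "degenerate")
})

test_that("Fisher information hits its analytic limits", {
  const <- make_panel(matrix(5, 60, 3,
                             dimnames = list(NULL, paste0("t", 1:3))))
  fi <- fisher_information(const, window_months = 48)
  expect_equal(fi$value[48], 8, tolerance = 1e-12)
  expect_true(all(is.na(fi$value[1:47])))

  # continuous noise proliferates states: FI far below the ordered ceiling
  set.seed(4)
  noisy <- make_panel(matrix(exp(rnorm(240 * 4)), 240, 4,
                             dimnames = list(NULL, paste0("t", 1:4))))
  expect_lt(mean(fisher_information(noisy, 48)$value, na.rm = TRUE), 2)

  expect_error(fisher_information(const, window_months = 120), "window")
})

test_that("Fisher information is invariant to uniform rescaling and detects order", {
  set.seed(5)
  lv <- matrix(rnorm(120 * 3, sd = 0.3), 120, 3) + rep(c(0, 3), each = 60)
  colnames(lv) <- paste0("t", 1:3)
  p <- make_panel(exp(lv))
  p_scaled <- make_panel(exp(lv) * 1000)
  expect_equal(fisher_information(p, 24)$value,
               fisher_information(p_scaled, 24)$value, tolerance = 1e-10)

  ok <- 0
  for (i in 1:20) {
    sh <- sample(120)
    p_sh <- make_panel(exp(lv[sh, , drop = FALSE]))
    f_ord <- mean(fisher_information(p, 24)$value, na.rm = TRUE)
    f_sh <- mean(fisher_information(p_sh, 24)$value, na.rm = TRUE)
    ok <- ok + (f_ord > f_sh)
  }
  expect_gte(ok, 18)
})

test_that("MVI matches analytic and brute-force eigenvalues", {
  # Gram-Schmidt: two centred, unit-variance, exactly uncorrelated series,
  # so the window covariance is the identity and log MVI = 0
  set.seed(6)
  v1 <- rnorm(12); v1 <- (v1 - mean(v1)) / sd(v1)
  v2 <- rnorm(12); v2 <- v2 - mean(v2)
  v2 <- v2 - sum(v1 * v2) / sum(v1 * v1) * v1
  v2 <- v2 / sd(v2)
  shift <- abs(min(c(v1, v2))) + 1
  panel <- make_panel(cbind(a = v1 + shift, b = v2 + shift))
  v <- mvi(panel, window_months = 12)$value
  expect_equal(v[12], 0, tolerance = 1e-10)

  # perfectly correlated unit-variance pair: eigenvalue 2
  p2 <- make_panel(cbind(a = v1 + shift, b = v1 + shift))
  expect_equal(mvi(p2, 12)$value[12], log(sqrt(2)), tolerance = 1e-10)

  # brute-force characteristic-polynomial oracle on random 2x2 windows
  for (i in 1:10) {
    m <- matrix(abs(rnorm(24, 10)), 12, 2,
                dimnames = list(NULL, c("a", "b")))
    cv <- cov(m)
    tr <- cv[1, 1] + cv[2, 2]
    dt <- cv[1, 1] * cv[2, 2] - cv[1, 2]^2
    lam <- (tr + sqrt(tr^2 - 4 * dt)) / 2
    expect_equal(mvi(make_panel(m), 12)$value[12], log(sqrt(lam)),
                 tolerance = 1e-10)
  }

  # Rayleigh bound: MVI^2 >= max per-taxon variance
  m <- matrix(abs(rnorm(60, 10, 3)), 20, 3,
              dimnames = list(NULL, paste0("t", 1:3)))
  val <- mvi(make_panel(m), 20)$value[20]
  expect_gte(exp(val)^2 + 1e-10, max(apply(m, 2, var)))
})

test_that("state metrics are invariant to taxon ordering", {
  set.seed(8)
  m <- matrix(abs(rnorm(200, 20, 5)), 40, 5,
              dimnames = list(NULL, paste0("t", 1:5)))
  g <- setNames(c("phyto", "phyto", "phyto", "zoo", "zoo"), colnames(m))
  p1 <- make_panel(m, g)
  p2 <- make_panel(m[, 5:1], g[5:1])
  expect_equal(total_density(p1)$value, total_density(p2)$value,
               tolerance = 1e-12)
  expect_equal(trophic_ratio(p1)$value, trophic_ratio(p2)$value,
               tolerance = 1e-12)
  expect_equal(mvi(p1, 12)$value, mvi(p2, 12)$value, tolerance = 1e-10)
  expect_equal(abs(community_pc1(p1)$value), abs(community_pc1(p2)$value),
               tolerance = 1e-8)
  expect_equal(fisher_information(p1, 12)$value,
               fisher_information(p2, 12)$value, tolerance = 1e-10)
})

test_that("state metrics show no drift on stationary synthetic panels", {
  n_ok <- 0; n_tot <- 0
  for (i in 1:12) {
    sim <- simulate_community(community_sim_config(
      n_phyto = 8, n_zoo = 4, n_months = 240, ar_coefficient = 0.2,
      zero_inflation = 0, seed = 400 + i))
    sm <- state_metrics(sim$panel, fi_window = 24)
    for (m in c("community", "density", "fi", "mvi", "zp_ratio")) {
      v <- sm[[m]]
      t_idx <- seq_along(v)[!is.na(v)]
      v <- v[!is.na(v)]
      if (sd(v) == 0) next
      fit <- summary(lm(v ~ t_idx))
      r1 <- cor(head(residuals(lm(v ~ t_idx)), -1),
                tail(residuals(lm(v ~ t_idx)), -1))
      infl <- sqrt(max((1 + r1) / (1 - r1), 1))   # AR-adjusted slope se
      t_adj <- abs(fit$coefficients[2, "t value"]) / infl
      n_tot <- n_tot + 1
      n_ok <- n_ok + (t_adj < 1.96)
    }
  }
  expect_gte(n_ok / n_tot, 0.9)
})
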