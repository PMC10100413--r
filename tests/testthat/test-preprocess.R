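records_fixture <- function() {
  tibble::tibble(
    date = as.Date(c("2000-01-05", "2000-01-05", "2000-02-03")),
    taxon = c("a", "b", "a"),
    guild = c("phyto", "zoo", "phyto"),
    density = c(1, 2, 3))
}

test_that("zero-filling completes the date x taxon grid and is idempotent", {
  filled <- fill_unrecorded_with_zero(records_fixture())
  expect_equal(nrow(filled), 4)
  missing_pair <- dplyr::filter(filled, date == as.Date("2000-02-03"),
                                taxon == "b")
  expect_equal(missing_pair$density, 0)
  expect_equal(missing_pair$guild, "zoo")
  expect_identical(fill_unrecorded_with_zero(filled), filled)

  # complete grid passes through unchanged
  complete <- fill_unrecorded_with_zero(records_fixture())
  expect_identical(fill_unrecorded_with_zero(complete), complete)
  expect_error(fill_unrecorded_with_zero(records_fixture()[0, ]), "empty|no records")

  # brute-force grid count: 12 dates x 10 taxa with 50 records -> 70 zeros
  set.seed(1)
  grid <- tidyr::expand_grid(date = as.Date("2000-01-01") + 0:11 * 7,
                             taxon = paste0("t", 1:10))
  some <- grid[sample(nrow(grid), 50), ]
  some$guild <- "phyto"; some$density <- 1
  out <- fill_unrecorded_with_zero(some)
  expect_equal(nrow(out), 120)
  expect_equal(sum(out$density == 0), 70)
})

test_that("monthly means average within months and mark unsampled months missing", {
  rec <- tibble::tibble(
    date = as.Date(c("2000-01-04", "2000-01-20", "2000-03-07", "2000-03-09",
                     "2000-03-30")),
    taxon = "a", guild = "phyto",
    density = c(4, 6, 0, 0, 9))
  rec <- dplyr::bind_rows(rec, dplyr::mutate(rec, taxon = "b",
                                             density = density + 1))
  panel <- monthly_mean(rec)
  expect_equal(panel$a[1], 5)          # mean(4, 6)
  expect_true(is.na(panel$a[2]))       # February never sampled
  expect_equal(panel$a[3], 3)          # mean(0, 0, 9)
  # taxon reordering commutes
  panel2 <- monthly_mean(rec[order(rev(rec$taxon)), ])
  expect_equal(panel2$a, panel$a)
  expect_equal(panel2$b, panel$b)
})

test_that("sparse-taxon filter applies a strict zero-fraction threshold", {
  m <- cbind(dense = rep(1, 1000),
             sparse995 = c(rep(1, 5), rep(0, 995)),
             boundary = NA)
  m[, "boundary"] <- c(rep(1, 10), rep(0, 990))   # exactly 99%
  panel <- make_panel(m)
  kept <- filter_sparse_taxa(panel, 0.99)
  expect_setequal(setdiff(names(kept), "month"), c("dense", "boundary"))

  hundred <- make_panel(cbind(edge = c(1, rep(0, 99))))
  expect_equal(setdiff(names(filter_sparse_taxa(hundred, 0.99)), "month"),
               "edge")
  all_sparse <- make_panel(cbind(z = rep(0, 100)))
  expect_error(filter_sparse_taxa(all_sparse), "unusable")

  # property: never removes a taxon at or below the threshold
  set.seed(7)
  for (i in 1:20) {
    zf <- runif(5)
    cols <- sapply(zf, function(f) {
      v <- rep(1, 200); v[seq_len(floor(200 * f))] <- 0; sample(v)
    })
    colnames(cols) <- paste0("t", 1:5)
    pan <- make_panel(cols)
    thr <- runif(1, 0.3, 0.99)
    kept <- tryCatch(filter_sparse_taxa(pan, thr), error = function(e) NULL)
    frac <- colMeans(cols == 0)
    should_keep <- names(frac)[frac <= thr]
    if (!is.null(kept)) {
      expect_true(all(should_keep %in% names(kept)))
    } else {
      expect_length(should_keep, 0)
    }
  }
})

test_that("linear detrending matches closed-form OLS and is idempotent", {
  ramp <- make_series(1:60)
  expect_equal(linear_detrend(ramp)$value, rep(0, 60), tolerance = 1e-10)
  flat <- make_series(rep(4, 60))
  expect_equal(linear_detrend(flat)$value, rep(0, 60), tolerance = 1e-10)

  # oracle: hand OLS on ramp + sinusoid
  t_idx <- 1:120
  y <- 0.3 * t_idx + sin(2 * pi * t_idx / 12)
  b <- sum((t_idx - mean(t_idx)) * (y - mean(y))) / sum((t_idx - mean(t_idx))^2)
  a <- mean(y) - b * mean(t_idx)
  expected <- y - (a + b * t_idx)
  got <- linear_detrend(make_series(y))
  expect_equal(got$value, expected, tolerance = 1e-8)
  expect_true("detrended" %in% attr(got, "transforms"))
  # idempotence
  expect_equal(linear_detrend(got)$value, got$value, tolerance = 1e-8)

  # missing values stay missing
  y[5] <- NA
  expect_true(is.na(linear_detrend(make_series(y))$value[5]))
  expect_error(linear_detrend(make_series(c(1, 2, NA, NA))), "3 non-missing")
})

test_that("seasonal removal subtracts centred calendar-month means", {
  t_idx <- 1:120
  seasonal <- sin(2 * pi * t_idx / 12)
  s <- make_series(seasonal, transforms = "detrended")
  out <- deseasonalize(s)
  expect_lt(max(abs(out$value)), 1e-8)

  # white noise: every calendar month of the output has the same mean
  set.seed(2)
  wn <- deseasonalize(make_series(rnorm(240), transforms = "detrended"))
  mm <- tapply(wn$value, format(wn$month, "%m"), mean)
  expect_lt(diff(range(mm)), 1e-10)

  # idempotence
  expect_equal(deseasonalize(wn)$value, wn$value, tolerance = 1e-8)

  # requires the detrended flag and all 12 calendar months
  expect_error(deseasonalize(make_series(rnorm(120))), "detrended")
  gap <- make_series(rnorm(60), transforms = "detrended")
  gap$value[format(gap$month, "%m") == "06"] <- NA
  expect_error(deseasonalize(gap), "Jun")
})

test_that("z-scaling uses the sample (n-1) standard deviation", {
  out <- zscale(make_series(c(0, 2)))
  expect_equal(out$value, c(-1, 1) / sqrt(2), tolerance = 1e-10)
  set.seed(3)
  s <- zscale(make_series(rnorm(50, 5, 3)))
  expect_equal(mean(s$value), 0, tolerance = 1e-10)
  expect_equal(var(s$value), 1, tolerance = 1e-10)
  expect_equal(zscale(s)$value, s$value, tolerance = 1e-8)  # idempotent
  expect_error(zscale(make_series(rep(1, 10))), "variance")
})

test_that("gap interpolation fills and flags internal gaps only", {
  v <- c(1, 2, NA, 4, NA, NA, 7, NA)
  out <- interpolate_gaps(make_series(v))
  expect_equal(out$value[3], 3)
  expect_equal(out$value[5:6], c(5, 6))
  expect_true(is.na(out$value[8]))     # trailing gap stays missing
  expect_equal(which(out$interpolated), c(3, 5, 6))
})
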