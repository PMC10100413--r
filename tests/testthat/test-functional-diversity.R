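simple_schema <- function() {
  list(trait_block("size", "fuzzy", c("small", "medium", "large")),
       trait_block("colonial", "fuzzy", c("colonial", "not_colonial")),
       trait_block("carbon", "numeric"))
}

test_that("fuzzy coding turns species records into affinity fractions", {
  schema <- list(
    trait_block("cell_length", "fuzzy",
                c("<=10", ">10-25", ">25-100", ">100")),
    trait_block("colonial", "fuzzy", c("colonial", "not_colonial")))
  sp <- tibble::tibble(
    taxon = c("g1", "g1", "g2", "g3", "g3", "g3", "g3"),
    cell_length = c("<=10", ">10-25", ">100", "<=10", "<=10", ">10-25",
                    "<=10"),
    colonial = c("colonial", "colonial", "not_colonial", "colonial",
                 "colonial", "colonial", "not_colonial"))
  out <- fuzzy_code(sp, schema)
  g1 <- out[out$taxon == "g1", ]
  expect_equal(as.numeric(g1[paste0("cell_length.",
                                    c("<=10", ">10-25", ">25-100", ">100"))]),
               c(0.5, 0.5, 0, 0))
  # single-species taxon is one-hot
  g2 <- out[out$taxon == "g2", ]
  expect_equal(as.numeric(g2[["cell_length.>100"]]), 1)
  # 4 species, 3 colonial
  g3 <- out[out$taxon == "g3", ]
  expect_equal(as.numeric(g3[c("colonial.colonial",
                               "colonial.not_colonial")]), c(0.75, 0.25))
})

test_that("fuzzy coding lists and excludes taxa with no trait data", {
  schema <- list(trait_block("size", "fuzzy", c("s", "l")))
  sp <- tibble::tibble(taxon = c("a", "b"), size = c("s", NA))
  expect_message(out <- fuzzy_code(sp, schema), "b")
  expect_equal(out$taxon, "a")
  expect_equal(attr(out, "excluded"), "b")
})

test_that("Gower dissimilarity matches its definition and a brute-force oracle", {
  schema <- list(trait_block("size", "fuzzy", c("s", "l")),
                 trait_block("num", "numeric"))
  # identical rows -> 0; numeric endpoints + identical fuzzy -> 0.5
  tr <- tibble::tibble(taxon = c("a", "b", "c"),
                       size.s = c(1, 1, 0), size.l = c(0, 0, 1),
                       num = c(0, 10, 10))
  tr <- planklag:::new_fuzzy_trait_matrix(tr, schema)
  d <- gower_dissimilarity(tr)
  expect_equal(d["a", "b"], 0.5, tolerance = 1e-12)  # (0 + 1)/2
  expect_equal(d["b", "c"], 0.5, tolerance = 1e-12)  # (1 + 0)/2
  expect_equal(d["a", "c"], 1, tolerance = 1e-12)    # disjoint + endpoints
  expect_equal(diag(unclass(d)), setNames(rep(0, 3), c("a", "b", "c")))

  # disjoint one-hot categories in every block -> 1
  tr2 <- planklag:::new_fuzzy_trait_matrix(
    tibble::tibble(taxon = c("a", "b"), size.s = c(1, 0), size.l = c(0, 1),
                   num = c(0, 1)),
    schema)
  expect_equal(gower_dissimilarity(tr2)["a", "b"], 1, tolerance = 1e-12)

  # brute-force per-pair loop on random fuzzy tables
  set.seed(10)
  for (rep in 1:5) {
    n <- 8
    aff1 <- t(apply(matrix(rgamma(n * 3, 1), n), 1, function(v) v / sum(v)))
    aff2 <- t(apply(matrix(rgamma(n * 2, 1), n), 1, function(v) v / sum(v)))
    num <- runif(n)
    tab <- tibble::tibble(taxon = paste0("t", 1:n),
                          size.small = aff1[, 1], size.medium = aff1[, 2],
                          size.large = aff1[, 3],
                          colonial.colonial = aff2[, 1],
                          colonial.not_colonial = aff2[, 2],
                          carbon = num)
    tab <- planklag:::new_fuzzy_trait_matrix(tab, simple_schema())
    d <- gower_dissimilarity(tab)
    rng <- diff(range(num))
    for (i in 1:n) for (j in 1:n) {
      manual <- mean(c(sum(abs(aff1[i, ] - aff1[j, ])) / 2,
                       sum(abs(aff2[i, ] - aff2[j, ])) / 2,
                       abs(num[i] - num[j]) / rng))
      expect_equal(d[i, j], manual, tolerance = 1e-12)
    }
    expect_true(isSymmetric(unclass(d)))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("trait-space embedding reproduces Euclidean geometry", {
  # 3 equidistant taxa: equilateral triangle in 2 dims
  d3 <- matrix(1, 3, 3) - diag(3)
  rownames(d3) <- colnames(d3) <- c("a", "b", "c")
  sp3 <- embed_trait_space(d3)
  expect_lte(sp3$m, 2)
  dd <- as.matrix(dist(sp3$coords))
  off <- dd[upper.tri(dd)]
  expect_lt(diff(range(off)), 1e-8)

  # Euclidean input distances: exact round-trip
  set.seed(12)
  pts <- matrix(rnorm(7 * 3), 7, 3)
  d7 <- as.matrix(dist(pts))
  rownames(d7) <- colnames(d7) <- paste0("t", 1:7)
  sp7 <- embed_trait_space(d7 / max(d7))
  rec <- as.matrix(dist(sp7$coords)) * max(d7)
  expect_equal(rec, d7, tolerance = 1e-8, ignore_attr = TRUE)

  # rank bound and degenerate input
  sp5 <- embed_trait_space(d7[1:5, 1:5] / max(d7), max_dim = 10)
  expect_lte(sp5$m, 4)
  expect_error(embed_trait_space(d7[1:2, 1:2]), "3 taxa")
})

test_that("FRic equals analytic hull volume ratios and is hull-monotone", {
  square <- make_space(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  expect_equal(fric(square, c("t1", "t2", "t3")), 0.5, tolerance = 1e-10)
  expect_equal(fric(square, square$taxa), 1, tolerance = 1e-12)
  # degenerate (collinear) present set: flagged missing, not zero
  line <- make_space(rbind(c(0, 0), c(1, 0), c(2, 0), c(0, 1)))
  expect_true(is.na(fric(line, c("t1", "t2", "t3"))))

  # unnormalized hull volume never decreases when taxa are added
  set.seed(13)
  pts <- matrix(rnorm(20), 10, 2)
  v_sub <- hull_volume(pts[1:6, ])
  v_all <- hull_volume(pts)
  expect_gte(v_all, v_sub)
})

test_that("hull volumes delegate correctly in three or more dimensions", {
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(hull_volume(tetra), 1 / 6, tolerance = 1e-10)
  cube4 <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  expect_equal(hull_volume(cube4), 1, tolerance = 1e-10)
  # degenerate: coplanar points in 3 dims
  flat <- cbind(matrix(rnorm(10), 5, 2), 0)
  expect_true(is.na(hull_volume(flat)))
})

test_that("FDis matches analytic cases and is rigid-motion invariant", {
  two <- make_space(rbind(c(0, 0), c(3, 4)))       # distance 5
  expect_equal(fdis(two, c(t1 = 1, t2 = 1)), 2.5, tolerance = 1e-12)
  expect_equal(fdis(two, c(t1 = 7, t2 = 0)), 0)
  expect_equal(fdis(two, c(t1 = 2, t2 = 2)),
               fdis(two, c(t1 = 200, t2 = 200)), tolerance = 1e-12)

  set.seed(14)
  pts <- matrix(rnorm(12), 6, 2)
  w <- setNames(runif(6, 0.1, 2), paste0("t", 1:6))
  base <- fdis(make_space(pts), w)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(pts %*% rot, 2, c(3, -1), "+")
  expect_equal(fdis(make_space(moved), w), base, tolerance = 1e-10)
})

test_that("FEve matches analytic and exhaustive spanning-tree oracles", {
  # equally spaced collinear taxa, equal abundance: perfect evenness
  coll <- make_space(cbind(0:4, 0))
  expect_equal(feve(coll, setNames(rep(1, 5), coll$taxa)), 1,
               tolerance = 1e-12)
  # one branch dominating: bounded below by 0
  skew <- make_space(cbind(c(0, 1e-9, 1), 0))
  v <- feve(skew, setNames(rep(1, 3), skew$taxa))
  expect_gte(v, 0)
  expect_lt(v, 0.01)
  expect_true(is.na(feve(coll, setNames(c(1, 1, 0, 0, 0), coll$taxa))))

  # exhaustive MST oracle on 5 random points: enumerate all edge subsets
  set.seed(15)
  for (rep in 1:3) {
    pts <- matrix(rnorm(10), 5, 2)
    w <- runif(5, 0.5, 2)
    dm <- as.matrix(dist(pts))
    edges <- t(combn(5, 2))
    best <- NULL; best_w <- Inf
    for (sub in combn(nrow(edges), 4, simplify = FALSE)) {
      g <- matrix(0, 5, 5)
      for (e in sub) g[edges[e, 1], edges[e, 2]] <-
          g[edges[e, 2], edges[e, 1]] <- 1
      # connectivity check via reachability
      reach <- (diag(5) + g) %*% (diag(5) + g) %*% (diag(5) + g) %*%
        (diag(5) + g)
      if (all(reach > 0)) {
        tw <- sum(dm[edges[sub, , drop = FALSE]])
        if (tw < best_w) { best_w <- tw; best <- sub }
      }
    }
    ew <- apply(edges[best, ], 1, function(ij) {
      dm[ij[1], ij[2]] / (w[ij[1]] + w[ij[2]])
    })
    pew <- ew / sum(ew)
    thr <- 1 / 4
    oracle <- (sum(pmin(pew, thr)) - thr) / (1 - thr)
    expect_equal(feve(make_space(pts), setNames(w, paste0("t", 1:5))),
                 oracle, tolerance = 1e-10)
    expect_gte(oracle, 0); expect_lte(oracle, 1)
  }

  # uniform abundance scaling leaves FEve unchanged
  pts <- matrix(rnorm(12), 6, 2)
  w <- setNames(runif(6, 0.1, 3), paste0("t", 1:6))
  expect_equal(feve(make_space(pts), w), feve(make_space(pts), 10 * w),
               tolerance = 1e-12)
})

test_that("monthly FD series honour presence and precondition rules", {
  space <- make_space(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
                      taxa = paste0("t", 1:4))
  m <- rbind(c(1, 1, 1, 1),     # all present equal: FRic = 1
             c(2, 0, 0, 0),     # one taxon: FDis 0, FRic/FEve NA
             c(1, 1, 1, 1))
  colnames(m) <- paste0("t", 1:4)
  panel <- make_panel(m)
  fds <- fd_series(panel, space)
  expect_equal(fds$fric[1], 1, tolerance = 1e-10)
  expect_equal(fds$fdis[2], 0)
  expect_true(is.na(fds$fric[2]) && is.na(fds$feve[2]))
  # constant panel rows give constant series
  expect_equal(fds$fric[3], fds$fric[1], tolerance = 1e-12)
  expect_equal(fds$feve[3], fds$feve[1], tolerance = 1e-12)
  # panel taxa must be a subset of the space
  bad <- make_panel(cbind(zzz = c(1, 2, 1)))
  expect_error(fd_series(bad, space), "missing from trait space")
})
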