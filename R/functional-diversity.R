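# Functional diversity: mixed-type (fuzzy/numeric) Gower dissimilarity,
# principal-coordinates trait space with capped dimension, and the three
# community metrics FRic (convex-hull volume share), FDis (abundance-weighted
# dispersion) and FEve (minimum-spanning-tree evenness), evaluated monthly.

#' Gower dissimilarity for fuzzy-coded trait matrices
#'
#' Per trait block: numeric traits contribute `|x_i - x_j| / range`; fuzzy
#' blocks contribute half the Manhattan distance between affinity vectors
#' (which lies in `[0, 1]` because each row sums to 1).  The overall
#' dissimilarity is the block-weight-weighted mean over blocks where both
#' taxa have data; a pair with no shared blocks is an error.
#'
#' @param traits A `fuzzy_trait_matrix` (see [fuzzy_code()],
#'   [generate_trait_table()]).
#' @param schema Block schema; defaults to the one attached to `traits`.
#' @return A symmetric `dissimilarity_matrix` with zero diagonal and values
#'   in `[0, 1]`, dimnames = taxa.
#' @export
#' @examples
#' tr <- generate_trait_table(5, "zoo", seed = 2)
#' gower_dissimilarity(tr)[1:3, 1:3]
gower_dissimilarity <- function(traits, schema = NULL) {
  schema <- schema %||% trait_schema(traits)
  traits <- as_tibble(traits)
  n <- nrow(traits)
  if (n < 2) abort("need at least 2 taxa")
  taxa <- traits$taxon %||% paste0("t", seq_len(n))

  num <- matrix(0, n, n)
  wsum <- matrix(0, n, n)
  for (b in schema) {
    cols <- block_columns(b)
    x <- as.matrix(traits[cols])
    if (b$type == "numeric") {
      v <- x[, 1]
      avail <- outer(!is.na(v), !is.na(v), `&`)
      rng <- diff(range(v, na.rm = TRUE))
      d <- if (is.finite(rng) && rng > 0) {
        abs(outer(v, v, `-`)) / rng
      } else {
        matrix(0, n, n)
      }
      d[!avail] <- 0
    } else {
      ok <- rowSums(is.na(x)) == 0
      avail <- outer(ok, ok, `&`)
      x0 <- x
      x0[is.na(x0)] <- 0
      # half Manhattan distance between affinity rows
      d <- matrix(0, n, n)
      for (j in seq_len(ncol(x0))) {
        d <- d + abs(outer(x0[, j], x0[, j], `-`))
      }
      d <- d / 2
      d[!avail] <- 0
    }
    num <- num + b$weight * d * avail
    wsum <- wsum + b$weight * avail
  }
  if (any(wsum == 0 & row(wsum) != col(wsum))) {
    abort("some taxon pairs share no trait blocks with data")
  }
  out <- num / wsum
  diag(out) <- 0
  out <- (out + t(out)) / 2
  out <- pmin(pmax(out, 0), 1)
  dimnames(out) <- list(taxa, taxa)
  structure(out, class = c("dissimilarity_matrix", "matrix", "array"))
}

#' Embed a dissimilarity matrix in a low-dimensional trait space
#'
#' Principal coordinates analysis with a Cailliez additive correction for
#' negative eigenvalues (disable with `correction = "none"`).  The retained
#' dimension is `min(max_dim, n_taxa - 1, number of positive eigenvalues)`;
#' capping at 10 axes avoids the degenerate convex-hull estimates that
#' high-dimensional FRic computations are prone to.
#'
#' @param d A `dissimilarity_matrix` (or symmetric matrix / `dist`).
#' @param max_dim Maximum number of retained axes (default 10).
#' @param correction `"cailliez"` (default) or `"none"`.
#' @return A `trait_space` list: `coords` (taxa x m), `eig`, `m`, `taxa`.
#' @export
embed_trait_space <- function(d, max_dim = 10,
                              correction = c("cailliez", "none")) {
  correction <- arg_match(correction)
  check_count(max_dim, "max_dim", min = 1)
  m0 <- as.matrix(d)
  n <- nrow(m0)
  if (n < 3) abort("need at least 3 taxa for a usable trait space")
  taxa <- rownames(m0) %||% paste0("t", seq_len(n))
  pc <- ape::pcoa(stats::as.dist(m0),
                  correction = if (correction == "cailliez") "cailliez"
                  else "none")
  if (!is.null(pc$vectors.cor)) {
    coords <- pc$vectors.cor
    eig <- pc$values$Corr_eig
  } else {
    coords <- pc$vectors
    eig <- pc$values$Eigenvalues
  }
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  m <- min(max_dim, n - 1, n_pos, ncol(coords))
  coords <- coords[, seq_len(m), drop = FALSE]
  rownames(coords) <- taxa
  colnames(coords) <- paste0("axis", seq_len(m))
  structure(list(coords = coords, eig = eig, m = m, taxa = taxa),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat(sprintf("<trait_space> %d taxa embedded in %d axes\n",
              length(x$taxa), x$m))
  invisible(x)
}

# ---- convex hull volumes ----------------------------------------------------

# 2-D polygon area by the shoelace formula on the hull vertex cycle
shoelace_area <- function(pts) {
  h <- grDevices::chull(pts)
  if (length(h) < 3) return(0)
  p <- pts[h, , drop = FALSE]
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

find_python <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  abort("no `python` interpreter found on PATH (needed for >2-D convex hulls)")
}

# Batched d>=3 hull volumes through the system SciPy/Qhull bindings.
# `point_sets` is a list of numeric matrices; returns one volume (or NA for
# degenerate sets) per element.
qhull_volumes <- function(point_sets) {
  if (length(point_sets) == 0) return(numeric(0))
  script <- system.file("python", "hull_volume.py", package = "planklag")
  if (script == "") abort("hull_volume.py not found in the installed package")
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  payload <- purrr::map(point_sets, function(p) {
    apply(unname(as.matrix(p)), 1, as.numeric, simplify = FALSE)
  })
  jsonlite::write_json(payload, infile, digits = NA)
  status <- system2(find_python(), c(script, infile, outfile),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(outfile)) {
    abort("Qhull helper failed; check that SciPy is available to `python`")
  }
  out <- jsonlite::read_json(outfile, simplifyVector = TRUE)
  vapply(out, function(v) if (is.null(v) || is.na(v)) NA_real_ else
    as.numeric(v), numeric(1))
}

#' Convex hull volume of a point set
#'
#' Exact in 1-D (range length) and 2-D (shoelace on the hull cycle);
#' delegates to Qhull (via the system SciPy) for 3 or more dimensions.
#' Degenerate sets (fewer than `d + 1` points, or affinely dependent points)
#' return `NA`, never zero.
#'
#' @param points Numeric matrix (points x dimensions).
#' @return Hull volume, or `NA_real_` when degenerate.
#' @export
hull_volume <- function(points) {
  points <- as.matrix(points)
  d <- ncol(points)
  if (nrow(points) < d + 1) return(NA_real_)
  if (d == 1) {
    v <- diff(range(points[, 1]))
    return(if (v > 0) v else NA_real_)
  }
  if (d == 2) {
    v <- shoelace_area(points)
    return(if (v > 0) v else NA_real_)
  }
  qhull_volumes(list(points))[[1]]
}

# Batched front-end used by fd_series: computes many hull volumes with one
# subprocess call for all >=3-D sets.
hull_volumes <- function(point_sets) {
  dims <- vapply(point_sets, ncol, integer(1))
  out <- rep(NA_real_, length(point_sets))
  low <- which(dims <= 2)
  if (length(low) > 0) {
    out[low] <- vapply(point_sets[low], hull_volume, numeric(1))
  }
  high <- which(dims >= 3)
  if (length(high) > 0) {
    ok <- vapply(point_sets[high], function(p) nrow(p) > ncol(p),
                 logical(1))
    if (any(ok)) {
      out[high[ok]] <- qhull_volumes(point_sets[high[ok]])
    }
  }
  out
}

# ---- the three FD metrics ---------------------------------------------------

resolve_present <- function(space, present) {
  if (is.character(present)) {
    miss <- setdiff(present, space$taxa)
    if (length(miss) > 0) {
      abort(paste0("taxa not in trait space: ", toString(head(miss, 5))))
    }
    match(present, space$taxa)
  } else if (is.logical(present)) {
    which(present)
  } else {
    as.integer(present)
  }
}

#' Functional richness of a community subset
#'
#' Convex hull volume of the present taxa's coordinates, in
#' `m_eff = min(m, S_present - 1)` leading axes, divided by the hull volume
#' of all taxa in the same `m_eff` axes, so `FRic` is in `[0, 1]` and
#' comparable across months.  Degenerate hulls yield `NA`.
#'
#' @param space A [embed_trait_space()] result.
#' @param present Taxon names, indices, or logical vector.
#' @return FRic in `[0, 1]`, or `NA_real_`.
#' @export
fric <- function(space, present) {
  idx <- resolve_present(space, present)
  s <- length(idx)
  if (s < 2) return(NA_real_)
  m_eff <- min(space$m, s - 1)
  sub <- space$coords[idx, seq_len(m_eff), drop = FALSE]
  all_pts <- space$coords[, seq_len(m_eff), drop = FALSE]
  v_present <- hull_volume(sub)
  v_all <- hull_volume(all_pts)
  if (is.na(v_present) || is.na(v_all) || v_all == 0) return(NA_real_)
  v_present / v_all
}

#' Functional dispersion of a community
#'
#' Abundance-weighted mean distance of present taxa to their weighted
#' centroid in the full trait space.  A single present taxon has FDis 0 by
#' definition; FDis is invariant to uniform weight scaling and to rigid
#' motions of the space.
#'
#' @param space A [embed_trait_space()] result.
#' @param abundances Nonnegative weights, named by taxon or aligned with
#'   `space$taxa`.
#' @return FDis (>= 0), or `NA_real_` if no taxon has positive weight.
#' @export
fdis <- function(space, abundances) {
  w <- align_weights(space, abundances)
  if (sum(w, na.rm = TRUE) <= 0) return(NA_real_)
  keep <- which(!is.na(w) & w > 0)
  if (length(keep) == 1) return(0)
  x <- space$coords[keep, , drop = FALSE]
  wk <- w[keep]
  centroid <- colSums(x * wk) / sum(wk)
  dists <- sqrt(rowSums((x - matrix(centroid, nrow(x), ncol(x),
                                    byrow = TRUE))^2))
  sum(wk * dists) / sum(wk)
}

#' Functional evenness of a community
#'
#' Regularity of abundance along the minimum spanning tree of present taxa:
#' branch weights `EW_l = dist(i, j) / (w_i + w_j)` are normalized to
#' `PEW_l`, and `FEve = (sum(min(PEW_l, 1/(S-1))) - 1/(S-1)) /
#' (1 - 1/(S-1))`, in `[0, 1]`.  Needs at least 3 taxa with positive
#' abundance.
#'
#' @inheritParams fdis
#' @return FEve in `[0, 1]`, or `NA_real_` when `S < 3`.
#' @export
feve <- function(space, abundances) {
  w <- align_weights(space, abundances)
  keep <- which(!is.na(w) & w > 0)
  s <- length(keep)
  if (s < 3) return(NA_real_)
  x <- space$coords[keep, , drop = FALSE]
  wk <- w[keep]
  d <- as.matrix(stats::dist(x))
  tree <- vegan::spantree(stats::as.dist(d))
  i <- 2:s
  j <- tree$kid
  ew <- d[cbind(i, j)] / (wk[i] + wk[j])
  if (sum(ew) == 0) return(NA_real_)
  pew <- ew / sum(ew)
  thr <- 1 / (s - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

align_weights <- function(space, abundances) {
  if (!is.null(names(abundances))) {
    w <- rep(0, length(space$taxa))
    names(w) <- space$taxa
    common <- intersect(names(abundances), space$taxa)
    w[common] <- abundances[common]
    w
  } else {
    if (length(abundances) != length(space$taxa)) {
      abort("unnamed `abundances` must align with space$taxa")
    }
    as.numeric(abundances)
  }
}

#' Monthly functional diversity series for a guild
#'
#' For every month of the panel, taxa with strictly positive density are
#' "present"; FRic/FDis/FEve are evaluated with the month's densities as
#' weights.  Months failing a metric's preconditions (too few present taxa,
#' degenerate hulls, unsampled months) yield `NA` for that metric.  FRic
#' hull volumes are batched into a single Qhull call.
#'
#' @param panel A [new_density_panel()] (only taxa present in `space` are
#'   used; panel taxa must be a subset of the space's taxa).
#' @param space A [embed_trait_space()] built from the same guild's traits.
#' @param guild Optional `"phyto"`/`"zoo"` filter applied to the panel's
#'   guild map.
#' @return An `fd_series` tibble: `month`, `fric`, `fdis`, `feve`, with the
#'   guild recorded as an attribute.
#' @export
fd_series <- function(panel, space, guild = NULL) {
  taxa <- setdiff(names(panel), "month")
  if (!is.null(guild)) {
    g <- panel_guilds(panel)
    taxa <- taxa[g[taxa] == guild]
  }
  if (length(taxa) == 0) abort("no panel taxa for this guild")
  miss <- setdiff(taxa, space$taxa)
  if (length(miss) > 0) {
    abort(paste0("panel taxa missing from trait space: ",
                 toString(head(miss, 5))))
  }
  mat <- panel_matrix(panel, taxa)
  n_m <- nrow(mat)

  fric_sets <- vector("list", n_m)
  denom_dims <- integer(n_m)
  fdis_v <- feve_v <- rep(NA_real_, n_m)
  for (i in seq_len(n_m)) {
    dens <- mat[i, ]
    if (all(is.na(dens))) next
    w <- setNames(ifelse(is.na(dens), 0, dens), taxa)
    fdis_v[i] <- fdis(space, w)
    feve_v[i] <- feve(space, w)
    present <- names(w)[w > 0]
    s <- length(present)
    if (s >= 2) {
      m_eff <- min(space$m, s - 1)
      fric_sets[[i]] <- space$coords[match(present, space$taxa),
                                     seq_len(m_eff), drop = FALSE]
      denom_dims[i] <- m_eff
    }
  }

  todo <- which(!vapply(fric_sets, is.null, logical(1)))
  fric_v <- rep(NA_real_, n_m)
  if (length(todo) > 0) {
    dims_needed <- sort(unique(denom_dims[todo]))
    denom_sets <- purrr::map(dims_needed, function(mm) {
      space$coords[, seq_len(mm), drop = FALSE]
    })
    vols <- hull_volumes(c(fric_sets[todo], denom_sets))
    v_num <- vols[seq_along(todo)]
    v_den <- setNames(vols[length(todo) + seq_along(dims_needed)],
                      dims_needed)
    denom <- v_den[as.character(denom_dims[todo])]
    val <- v_num / denom
    val[!is.finite(val)] <- NA_real_
    fric_v[todo] <- val
  }

  structure(tibble(month = panel$month, fric = fric_v, fdis = fdis_v,
                   feve = feve_v),
            guild = guild, class = c("fd_series", "tbl_df", "tbl", "data.frame"))
}
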