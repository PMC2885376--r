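#' NSC transform under imposed row weights
#'
#' Co-inertia analysis requires the two coupled tables to share one row
#' metric. This transform recomputes the NSC centring of a non-negative
#' table under externally supplied row weights `d` (typically the gene
#' masses of the expression table): row profiles `q_ij = P_ij / rho_i` are
#' taken from the table's own masses, the column reference
#' `gamma'_j = sum_i d_i q_ij` is recomputed under `d`, and
#' `Z_ij = c * (q_ij - gamma'_j)`. Every column is then `d`-centred by
#' construction.
#'
#' @param raw_table Non-negative matrix or `gene_id`-tibble (rows must carry
#'   the same identifiers, in the same order, as `row_weights`).
#' @param row_weights Named positive weights summing to 1 (names are row
#'   identifiers); an unnamed vector is matched by position.
#' @return A [weighted_table()] with `row_weights = d` and uniform column
#'   weights `1/c`.
#' @export
impose_row_weights <- function(raw_table, row_weights) {
  m <- as_nonneg_matrix(raw_table)
  d <- as.numeric(row_weights)
  if (length(d) != nrow(m)) {
    stop_miract("row_weights length does not match table rows", "shape")
  }
  if (!is.null(names(row_weights))) {
    mism <- which(names(row_weights) != rownames(m))
    if (length(mism) > 0) {
      stop_miract(sprintf(
        "row id mismatch at position %d: table '%s' vs weights '%s'",
        mism[1], rownames(m)[mism[1]], names(row_weights)[mism[1]]), "ids")
    }
  }
  if (any(d <= 0)) stop_miract("imposed row weights must be > 0", "weights")
  if (abs(sum(d) - 1) > 1e-8) {
    stop_miract("imposed row weights must sum to 1", "weights")
  }
  d <- d / sum(d)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    stop_miract(sprintf("row '%s' has zero sum", rownames(m)[rs == 0][1]),
                "zero_row")
  }
  q <- m / rs
  gamma_prime <- colSums(q * d)
  cc <- ncol(m)
  Z <- cc * sweep(q, 2, gamma_prime, `-`)
  weighted_table(Z, row_weights = d, col_weights = rep(1 / cc, cc))
}

#' Condense a weighted table to group centroids (between-group analysis)
#'
#' Replaces the sample columns of a weighted table by their group centroids:
#' each group column is the column-weighted mean of its samples' `Z`
#' columns, with group weight equal to the summed sample weights. The
#' condensed table is then centred by the weighted grand centroid, so `k`
#' groups yield at most `k - 1` non-null axes. Decomposing the condensed
#' table is between-group analysis: the ordination of group differences
#' rather than individual samples, maximising between-group variance.
#'
#' @param wt A [weighted_table()] whose columns are samples.
#' @param groups Data frame (`sample_id`, `group`) covering every column.
#' @return A [weighted_table()] whose columns are groups, `col_weights` the
#'   group weights; row weights unchanged.
#' @export
between_group_condense <- function(wt, groups) {
  stopifnot(inherits(wt, "weighted_table"))
  mg <- match_groups(groups, wt$col_ids, min_groups = 1L)
  lv <- mg$levels
  B <- matrix(0, nrow(wt$Z), length(lv), dimnames = list(wt$row_ids, lv))
  w_g <- numeric(length(lv))
  for (k in seq_along(lv)) {
    j <- which(mg$labels == lv[k])
    w_g[k] <- sum(wt$col_weights[j])
    B[, k] <- (wt$Z[, j, drop = FALSE] %*% wt$col_weights[j]) / w_g[k]
  }
  centroid <- B %*% w_g / sum(w_g)
  B <- B - centroid[, rep(1, length(lv)), drop = FALSE]
  weighted_table(B, row_weights = wt$row_weights, col_weights = w_g / sum(w_g) * sum(wt$col_weights))
}

#' Co-inertia analysis of two weighted tables
#'
#' Finds pairs of axes, one in each table's column space, whose projections
#' of the shared rows (genes) are maximally covariant. With
#' `W = Z_X' D_r Z_Y` the cross table, the decomposition is the SVD of
#' `D_cX^{1/2} W D_cY^{1/2}`: the singular values `s_k` are the successive
#' maximal covariances, the axes are the back-transformed singular vectors
#' (orthonormal under each table's column metric), and the RV coefficient
#' summarises the global association in `[0, 1]`.
#'
#' @param tabX,tabY [weighted_table()]s with identical row identifiers and
#'   row weights (within `1e-10`).
#' @param n_axes Number of axis pairs to retain.
#' @return An object of class `"coinertia"`: singular covariances `s` (the
#'   retained `s_k`), `axes_X`, `axes_Y`, display coordinates `display_X`,
#'   `display_Y` (axes scaled by `sqrt(s_k)`), row projections
#'   `gene_coords_X`, `gene_coords_Y`, the coefficient `rv`, the retained
#'   axis count `n_axes` and the effective `rank`.
#' @export
coinertia <- function(tabX, tabY, n_axes = 2L) {
  stopifnot(inherits(tabX, "weighted_table"), inherits(tabY, "weighted_table"))
  check_shared_rows(tabX, tabY)
  n_axes <- as.integer(n_axes)
  kmax <- min(ncol(tabX$Z), ncol(tabY$Z))
  if (n_axes < 1) stop_miract("n_axes must be >= 1", "args")
  n_axes <- min(n_axes, kmax)

  scX <- sqrt(tabX$col_weights); scY <- sqrt(tabY$col_weights)
  W <- crossprod(tabX$Z, tabX$row_weights * tabY$Z)
  M <- (scX * W) %*% diag(scY, length(scY))
  dec <- svd(M)
  s_all <- dec$d
  keep <- seq_len(n_axes)
  s <- s_all[keep]

  axes_X <- dec$u[, keep, drop = FALSE] / scX
  axes_Y <- dec$v[, keep, drop = FALSE] / scY
  # orient each pair jointly (covariance sign preserved): largest-|loading|
  # entry on the X side positive
  for (j in seq_along(keep)) {
    i <- which.max(abs(axes_X[, j]))
    if (axes_X[i, j] < 0) {
      axes_X[, j] <- -axes_X[, j]
      axes_Y[, j] <- -axes_Y[, j]
    }
  }
  ax_names <- paste0("Axis", seq_along(keep))
  dimnames(axes_X) <- list(tabX$col_ids, ax_names)
  dimnames(axes_Y) <- list(tabY$col_ids, ax_names)
  gene_coords_X <- tabX$Z %*% (axes_X * tabX$col_weights)
  gene_coords_Y <- tabY$Z %*% (axes_Y * tabY$col_weights)
  dimnames(gene_coords_X) <- list(tabX$row_ids, ax_names)
  dimnames(gene_coords_Y) <- list(tabY$row_ids, ax_names)

  rank <- if (s_all[1] <= 1e-24) 0L else sum(s >= 1e-9 * s_all[1])

  structure(list(
    s = s, s_all = s_all,
    axes_X = axes_X, axes_Y = axes_Y,
    display_X = sweep(axes_X, 2, sqrt(s), `*`),
    display_Y = sweep(axes_Y, 2, sqrt(s), `*`),
    gene_coords_X = gene_coords_X, gene_coords_Y = gene_coords_Y,
    rv = rv_from_tables(tabX, tabY, s_all),
    n_axes = length(keep), rank = rank,
    inertia_X = total_inertia(tabX), inertia_Y = total_inertia(tabY),
    tabX = tabX, tabY = tabY),
    class = "coinertia")
}

# rows must agree in id and weight; report the first discrepancy
check_shared_rows <- function(tabX, tabY) {
  if (length(tabX$row_ids) != length(tabY$row_ids)) {
    stop_miract("tables have different numbers of rows", "rows")
  }
  mism <- which(tabX$row_ids != tabY$row_ids)
  if (length(mism) > 0) {
    stop_miract(sprintf("row id mismatch at position %d: '%s' vs '%s'",
                        mism[1], tabX$row_ids[mism[1]], tabY$row_ids[mism[1]]),
                "rows")
  }
  dw <- which(abs(tabX$row_weights - tabY$row_weights) > 1e-10)
  if (length(dw) > 0) {
    stop_miract(sprintf(
      "row weight mismatch for '%s': %.12g vs %.12g (co-inertia needs a shared row metric)",
      tabX$row_ids[dw[1]], tabX$row_weights[dw[1]], tabY$row_weights[dw[1]]),
      "rows")
  }
  invisible(TRUE)
}

# RV from precomputed cross singular values and the two tables' self products
rv_from_tables <- function(tabX, tabY, s_all) {
  nx <- self_product_fnorm2(tabX)
  ny <- self_product_fnorm2(tabY)
  if (nx <= 0 || ny <= 0) return(NA_real_)
  sum(s_all^2) / sqrt(nx * ny)
}

# squared Frobenius norm of D_c^{1/2} Z' D_r Z D_c^{1/2}
self_product_fnorm2 <- function(wt) {
  sc <- sqrt(wt$col_weights)
  K <- crossprod(wt$Z, wt$row_weights * wt$Z)
  K <- (sc * K) %*% diag(sc, length(sc))
  sum(K^2)
}

#' RV coefficient between two weighted tables
#'
#' Global association in `[0, 1]` between two tables sharing rows and row
#' weights: the total co-inertia normalised by the tables' own inertia
#' operators. Equals 1 when the two tables are identical up to positive
#' scaling of `Z`.
#'
#' @inheritParams coinertia
#' @return A scalar in `[0, 1]`.
#' @export
rv_coefficient <- function(tabX, tabY) {
  check_shared_rows(tabX, tabY)
  nx <- self_product_fnorm2(tabX)
  ny <- self_product_fnorm2(tabY)
  if (nx <= 0 || ny <= 0) {
    stop_miract("RV is undefined for a table with zero total inertia",
                "zero_total")
  }
  scX <- sqrt(tabX$col_weights); scY <- sqrt(tabY$col_weights)
  W <- crossprod(tabX$Z, tabX$row_weights * tabY$Z)
  M <- (scX * W) %*% diag(scY, length(scY))
  sum(M^2) / sqrt(nx * ny)
}

#' Unsupervised co-inertia of expression and target tables
#'
#' The exploratory pipeline: align both tables on shared genes, NSC-centre
#' the expression table, centre the target table under the same gene masses,
#' and couple the pair by [coinertia()]. On the resulting display, sample
#' points and miRNA points share axes; a miRNA plotted opposite a sample
#' group (through the origin) is inferred active in that group, because its
#' predicted targets are down-regulated there.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param targets Target count tibble from [build_target_table()].
#' @param n_axes Number of axis pairs to retain (default 2, for plotting).
#' @param row_weights `"expression"` (default) imposes the expression-derived
#'   gene masses on both tables; `"uniform"` recomputes both centrings under
#'   equal gene weights `1/g`.
#' @return A `"coinertia"` object whose `display_X` rows are samples and
#'   `display_Y` rows are miRNAs, with a `source_label` field.
#' @export
unsupervised_cia <- function(expr, targets, n_axes = 2L,
                             row_weights = c("expression", "uniform")) {
  row_weights <- match.arg(row_weights)
  al <- align_tables(expr, targets)
  wts <- coupling_tables(al, row_weights)
  res <- coinertia(wts$X, wts$Y, n_axes = n_axes)
  res$source_label <- al$source_label
  miract_log("unsupervised_cia [%s]: rv = %.4f", al$source_label, res$rv)
  res
}

# build the two weighted tables of a coupling under the chosen row metric
coupling_tables <- function(al, row_weights) {
  em <- expr_values(al$expression)
  tm <- target_values(al$targets)
  if (row_weights == "uniform") {
    d <- rep(1 / nrow(em), nrow(em))
    names(d) <- rownames(em)
    X <- impose_row_weights(em, d)
    Y <- impose_row_weights(tm, d)
  } else {
    X <- nsc_transform(em)
    d <- X$row_weights
    names(d) <- X$row_ids
    Y <- impose_row_weights(tm, d)
  }
  list(X = X, Y = Y)
}

#' Supervised co-inertia (between-group coupling)
#'
#' The discriminant pipeline behind the per-program miRNA rankings: the
#' expression NSC is condensed to group centroids ([between_group_condense()])
#' before coupling, so the first co-inertia axis is the direction that best
#' separates the pre-assigned groups, paired with the miRNA axis of maximal
#' covariance. With two groups the condensed table has a single non-null
#' axis, so the result is one ranked vector of miRNA coordinates. Axis 1 is
#' oriented so the target group's coordinate is positive; active miRNAs then
#' sit at the negative end (their targets are down-regulated in the target
#' group).
#'
#' @inheritParams unsupervised_cia
#' @param groups Data frame (`sample_id`, `group`) covering every sample;
#'   at least two non-empty groups.
#' @param target_group The group whose active miRNAs are sought.
#' @return An object of class `"supervised_cia"`: the underlying
#'   `"coinertia"` fit, `target_group`, oriented `group_coords` and
#'   `mirna_coords` (axis-1 loadings) and the `source_label`.
#' @seealso [rank_mirnas()], [consensus()]
#' @export
supervised_cia <- function(expr, targets, groups, target_group,
                           row_weights = c("expression", "uniform")) {
  row_weights <- match.arg(row_weights)
  al <- align_tables(expr, targets)
  sample_ids <- setdiff(names(al$expression), "gene_id")
  mg <- match_groups(groups, sample_ids, min_groups = 2L)
  if (!target_group %in% mg$levels) {
    stop_miract(sprintf("target group '%s' not among assigned groups (%s)",
                        target_group, paste(mg$levels, collapse = ", ")),
                "groups")
  }
  wts <- coupling_tables(al, row_weights)
  condensed <- between_group_condense(wts$X, groups)
  n_axes <- max(1L, length(mg$levels) - 1L)
  res <- coinertia(condensed, wts$Y, n_axes = n_axes)

  if (res$rank == 0) {
    warn("[miract] group centroids are indistinguishable: singular covariance is 0 and the ranking is meaningless")
  }
  gc <- res$axes_X[, 1]
  if (gc[target_group] < 0) {
    res$axes_X[, 1] <- -res$axes_X[, 1]
    res$axes_Y[, 1] <- -res$axes_Y[, 1]
    res$display_X[, 1] <- -res$display_X[, 1]
    res$display_Y[, 1] <- -res$display_Y[, 1]
    res$gene_coords_X[, 1] <- -res$gene_coords_X[, 1]
    res$gene_coords_Y[, 1] <- -res$gene_coords_Y[, 1]
  }
  structure(list(coinertia = res, target_group = target_group,
                 group_coords = res$axes_X[, 1],
                 mirna_coords = res$axes_Y[, 1],
                 groups = mg$levels,
                 source_label = al$source_label),
            class = "supervised_cia")
}

#' @export
print.coinertia <- function(x, ...) {
  cat(sprintf("Co-inertia analysis: %d axis pair(s), rv = %.4f\n",
              x$n_axes, x$rv))
  cat("Singular covariances:", format(signif(x$s, 6)), "\n")
  invisible(x)
}

#' @export
print.supervised_cia <- function(x, ...) {
  cat(sprintf(
    "Supervised co-inertia (%s), target group '%s', s1 = %.6g\n",
    x$source_label, x$target_group, x$coinertia$s[1]))
  cat("Group coordinates:\n")
  print(round(x$group_coords, 4))
  invisible(x)
}

#' Export a co-inertia result to TSV files
#'
#' Writes `covariances.tsv` (axis, s, s squared, fraction of the total),
#' sample/group coordinates, miRNA coordinates, the two gene projections and
#' a `summary.tsv` (rv, inertias, axis count) into a directory.
#'
#' @param x A `"coinertia"` or `"supervised_cia"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_coinertia <- function(x, dir) {
  sup <- inherits(x, "supervised_cia")
  res <- if (sup) x$coinertia else x
  stopifnot(inherits(res, "coinertia"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tibble(axis = seq_along(res$s), s = res$s, s2 = res$s^2,
                          fraction = res$s^2 / sum(res$s_all^2)),
                   file.path(dir, "covariances.tsv"), progress = FALSE)
  xfile <- if (sup) "groups_coords.tsv" else "samples_coords.tsv"
  xid <- if (sup) "group" else "sample_id"
  coords_tsv(res$display_X, xid, file.path(dir, xfile))
  coords_tsv(res$display_Y, "mirna_id", file.path(dir, "mirna_coords.tsv"))
  coords_tsv(res$gene_coords_X, "gene_id", file.path(dir, "gene_coords_X.tsv"))
  coords_tsv(res$gene_coords_Y, "gene_id", file.path(dir, "gene_coords_Y.tsv"))
  readr::write_tsv(tibble(rv = res$rv, inertia_X = res$inertia_X,
                          inertia_Y = res$inertia_Y, n_axes = res$n_axes),
                   file.path(dir, "summary.tsv"), progress = FALSE)
  invisible(dir)
}
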