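#' Weighted table (duality-diagram triple)
#'
#' The common currency of every ordination here: a centred, transformed
#' numeric table `Z` together with strictly positive row weights (summing to
#' 1) and column weights. Non-symmetric correspondence analysis, the
#' between-group condensation and co-inertia analysis all operate on this
#' triple.
#'
#' @param Z Numeric matrix (rows x columns) of centred transformed values.
#' @param row_weights Positive reals summing to 1 (row masses).
#' @param col_weights Positive reals (column metric); uniform `1/c` for a
#'   fresh NSC, group proportions after condensation.
#' @param row_ids,col_ids Identifiers; default to `dimnames(Z)`.
#' @return An object of class `"weighted_table"`.
#' @export
weighted_table <- function(Z, row_weights, col_weights,
                           row_ids = rownames(Z), col_ids = colnames(Z)) {
  Z <- as.matrix(Z)
  if (length(row_weights) != nrow(Z) || length(col_weights) != ncol(Z)) {
    stop_miract("weight lengths must match table dimensions", "shape")
  }
  if (any(row_weights <= 0) || any(col_weights <= 0)) {
    stop_miract("row and column weights must be strictly positive", "weights")
  }
  if (abs(sum(row_weights) - 1) > 1e-12) {
    stop_miract("row weights must sum to 1", "weights")
  }
  dimnames(Z) <- list(row_ids, col_ids)
  structure(list(Z = Z, row_ids = row_ids, col_ids = col_ids,
                 row_weights = as.numeric(row_weights),
                 col_weights = as.numeric(col_weights)),
            class = "weighted_table")
}

#' @export
print.weighted_table <- function(x, ...) {
  cat(sprintf("Weighted table: %d rows x %d columns, total inertia %.6g\n",
              nrow(x$Z), ncol(x$Z), total_inertia(x)))
  invisible(x)
}

# coerce an input to the nonnegative numeric matrix the transforms expect
as_nonneg_matrix <- function(table) {
  if (inherits(table, "data.frame")) {
    m <- if ("gene_id" %in% names(table)) {
      v <- as.matrix(table[, setdiff(names(table), "gene_id"), drop = FALSE])
      rownames(v) <- table$gene_id
      v
    } else {
      as.matrix(table)
    }
  } else {
    m <- as.matrix(table)
  }
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("col", seq_len(ncol(m)))
  if (any(m < 0)) stop_miract("table has negative entries", "negative")
  if (sum(m) <= 0) stop_miract("table has zero grand total", "zero_total")
  m
}

#' Non-symmetric correspondence transform
#'
#' Centres a non-negative table for non-symmetric correspondence analysis
#' (NSC): with `P` the table divided by its grand total, row masses
#' `rho_i = sum_j P_ij` and column masses `gamma_j = sum_i P_ij`, the
#' transformed value is `Z_ij = c * (P_ij / rho_i - gamma_j)` where `c` is
#' the number of columns. Row weights are the masses `rho`, column weights
#' are uniform `1/c`. Under these metrics the total inertia equals `c` times
#' the numerator of the Goodman-Kruskal tau predictability index: NSC
#' decomposes how much better the column category can be predicted once the
#' row (gene) is known.
#'
#' @param table Non-negative numeric matrix, or a tibble whose first column
#'   `gene_id` holds row identifiers (an expression matrix or target table).
#' @return A [weighted_table()].
#' @export
#' @examples
#' nsc_transform(matrix(c(2, 0, 0, 2), 2, dimnames = list(c("a", "b"), c("x", "y"))))
nsc_transform <- function(table) {
  m <- as_nonneg_matrix(table)
  P <- m / sum(m)
  rho <- rowSums(P)
  gamma <- colSums(P)
  if (any(rho == 0)) {
    stop_miract(sprintf("row '%s' has zero sum", rownames(m)[rho == 0][1]),
                "zero_row")
  }
  if (any(gamma == 0)) {
    stop_miract(sprintf("column '%s' has zero sum", colnames(m)[gamma == 0][1]),
                "zero_col")
  }
  cc <- ncol(m)
  Z <- cc * (P / rho - matrix(gamma, nrow(m), cc, byrow = TRUE))
  weighted_table(Z, row_weights = rho, col_weights = rep(1 / cc, cc))
}

#' Total inertia of a weighted table
#'
#' The weighted sum of squares `sum_i rho_i sum_j gamma_j Z_ij^2`, i.e. the
#' trace of the duality-diagram operator. It equals the sum of all
#' eigenvalues of the full decomposition.
#'
#' @param wt A [weighted_table()].
#' @return A non-negative scalar.
#' @export
total_inertia <- function(wt) {
  stopifnot(inherits(wt, "weighted_table"))
  sum(wt$row_weights * (wt$Z^2 %*% wt$col_weights))
}

#' Weighted generalized singular decomposition
#'
#' The ordination engine behind NSC, the between-group analysis and
#' co-inertia: decomposes a [weighted_table()] by the SVD of
#' `A = D_r^{1/2} Z D_c^{1/2}`. Eigenvalues are the squared singular values;
#' column axes are `D_c`-orthonormal; row coordinates are the `Z D_c`
#' projections (principal coordinates with `D_r`-weighted variance
#' `lambda_k`); column coordinates are the axes scaled by `sqrt(lambda_k)`.
#'
#' Axes whose eigenvalue falls below `tol * lambda_1` are discarded. Each
#' retained axis is oriented so that its largest-magnitude loading is
#' positive (a display convention only; supervised ranking re-orients by the
#' target group).
#'
#' @param wt A [weighted_table()].
#' @param n_axes Maximum number of axes to retain.
#' @param tol Relative eigenvalue tolerance for the rank cut.
#' @return An object of class `"ordination"`: `eigenvalues`, `col_axes`,
#'   `row_coords`, `col_coords`, `rank`, and the `source` table.
#' @export
weighted_decomposition <- function(wt, n_axes = 2L, tol = 1e-9) {
  stopifnot(inherits(wt, "weighted_table"))
  if (tol <= 0) stop_miract("tol must be > 0", "args")
  r <- nrow(wt$Z); cc <- ncol(wt$Z)
  if (n_axes < 1 || n_axes > min(r, cc)) {
    stop_miract(sprintf("n_axes must be between 1 and %d", min(r, cc)), "args")
  }
  sr <- sqrt(wt$row_weights)
  sc <- sqrt(wt$col_weights)
  A <- wt$Z * sr
  A <- sweep(A, 2, sc, `*`)
  dec <- svd(A)
  lambda <- dec$d^2
  # an effectively null table (e.g. proportional rows) has rank 0; the 1e-24
  # absolute floor is squared-singular-value scale for Z entries of order 1
  keep <- if (lambda[1] <= 1e-24) integer(0) else {
    which(lambda >= tol * lambda[1])
  }
  keep <- head(keep, n_axes)
  k <- length(keep)
  if (k == 0) {
    return(structure(list(
      eigenvalues = numeric(0),
      col_axes = matrix(0, cc, 0, dimnames = list(wt$col_ids, NULL)),
      row_coords = matrix(0, r, 0, dimnames = list(wt$row_ids, NULL)),
      col_coords = matrix(0, cc, 0, dimnames = list(wt$col_ids, NULL)),
      rank = 0L, source = wt), class = "ordination"))
  }
  lambda <- lambda[keep]
  axes <- dec$v[, keep, drop = FALSE] / sc
  # orient: largest |loading| positive, per axis
  for (j in seq_len(k)) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  row_coords <- wt$Z %*% (axes * wt$col_weights)
  col_coords <- sweep(axes, 2, sqrt(lambda), `*`)
  ax_names <- paste0("Axis", seq_len(k))
  dimnames(axes) <- list(wt$col_ids, ax_names)
  dimnames(row_coords) <- list(wt$row_ids, ax_names)
  dimnames(col_coords) <- list(wt$col_ids, ax_names)
  structure(list(eigenvalues = lambda, col_axes = axes,
                 row_coords = row_coords, col_coords = col_coords,
                 rank = as.integer(k), source = wt),
            class = "ordination")
}

#' Non-symmetric correspondence analysis
#'
#' Composition of [nsc_transform()] and [weighted_decomposition()]: the
#' single-table ordination applied to each side of the coupling.
#'
#' @inheritParams nsc_transform
#' @inheritParams weighted_decomposition
#' @return An `"ordination"` object.
#' @export
nsc <- function(table, n_axes = 2L, tol = 1e-9) {
  wt <- nsc_transform(table)
  n_axes <- min(n_axes, nrow(wt$Z), ncol(wt$Z))
  weighted_decomposition(wt, n_axes = n_axes, tol = tol)
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("NSC ordination: rank %d, total inertia %.6g\n", x$rank,
              total_inertia(x$source)))
  if (x$rank > 0) {
    cat("Eigenvalues:", format(signif(x$eigenvalues, 6)), "\n")
  }
  invisible(x)
}

#' Export an ordination to TSV files
#'
#' Writes `eigenvalues.tsv`, `row_coords.tsv` and `col_coords.tsv` into a
#' directory (identifiers in the first column, axes `Axis1..AxisK`).
#'
#' @param ord An `"ordination"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ordination <- function(ord, dir) {
  stopifnot(inherits(ord, "ordination"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tibble(axis = seq_along(ord$eigenvalues),
                          eigenvalue = ord$eigenvalues),
                   file.path(dir, "eigenvalues.tsv"), progress = FALSE)
  coords_tsv(ord$row_coords, "row_id", file.path(dir, "row_coords.tsv"))
  coords_tsv(ord$col_coords, "col_id", file.path(dir, "col_coords.tsv"))
  invisible(dir)
}

# write a coordinate matrix as id + AxisK columns
coords_tsv <- function(m, id_name, path) {
  df <- tibble(!!id_name := rownames(m))
  if (ncol(m) > 0) df <- dplyr::bind_cols(df, as_tibble(m))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
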