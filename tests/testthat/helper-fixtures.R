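# Fixture builders and independent oracles shared across the suite.
# Oracles deliberately use a different numerical route (dense symmetric
# eigendecompositions, explicit loops) than the package (LAPACK SVD).

# random strictly-positive-margin nonnegative table
random_table <- function(r, c, max_count = 9) {
  m <- matrix(sample.int(max_count + 1, r * c, replace = TRUE) - 1, r, c)
  m[cbind(seq_len(r), sample.int(c, r, replace = TRUE))] <-
    m[cbind(seq_len(r), sample.int(c, r, replace = TRUE))] + 1
  for (j in which(colSums(m) == 0)) m[sample.int(r, 1), j] <- 1
  dimnames(m) <- list(paste0("g", seq_len(r)), paste0("s", seq_len(c)))
  m
}

# expression tibble from a matrix
expr_tbl <- function(m) {
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

# target tibble from a count matrix
target_tbl <- function(m, label = "prog") {
  out <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                          tibble::as_tibble(m, .name_repair = "minimal"))
  attr(out, "source_label") <- label
  out
}

# eigenvalues of the duality-diagram operator by dense symmetric eigensolve
oracle_eigenvalues <- function(wt) {
  sc <- sqrt(wt$col_weights)
  S <- crossprod(wt$Z, wt$row_weights * wt$Z)      # Z' D_r Z
  S <- (sc * S) * rep(sc, each = length(sc))       # D_c^{1/2} . D_c^{1/2}
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sort(pmax(ev, 0), decreasing = TRUE)
}

# singular covariances of a coupling: the scaled cross table is formed
# explicitly, entry by entry, then decomposed densely
oracle_coinertia_s <- function(tabX, tabY) {
  cx <- ncol(tabX$Z); cy <- ncol(tabY$Z)
  M <- matrix(0, cx, cy)
  for (j in seq_len(cx)) {
    for (k in seq_len(cy)) {
      M[j, k] <- sqrt(tabX$col_weights[j]) * sqrt(tabY$col_weights[k]) *
        sum(tabX$row_weights * tabX$Z[, j] * tabY$Z[, k])
    }
  }
  svd(M, nu = 0, nv = 0)$d
}

# covariance of the row projections of one D_c-unit axis pair
axis_pair_covariance <- function(tabX, tabY, bx, by) {
  fx <- tabX$Z %*% (tabX$col_weights * bx)
  fy <- tabY$Z %*% (tabY$col_weights * by)
  sum(tabX$row_weights * fx * fy)
}

# normalise a vector to unit norm under a diagonal metric
unit_under <- function(b, w) b / sqrt(sum(w * b^2))

# write lines to a temp TSV and return the path
tsv_fixture <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
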