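test_that("imposing a table's own masses reproduces its NSC transform", {
  set.seed(5)
  for (rep in 1:10) {
    m <- random_table(6, 4)
    wt <- nsc_transform(m)
    d <- wt$row_weights
    names(d) <- wt$row_ids
    wt2 <- impose_row_weights(m, d)
    expect_lt(max(abs(wt$Z - wt2$Z)), 1e-12)
    # centring identity under the imposed weights
    expect_lt(max(abs(colSums(d * wt2$Z))), 1e-10)
  }
})

test_that("imposed-weight transform matches direct recomputation on a 3x2 toy", {
  m <- matrix(c(2, 1, 1, 2, 3, 1), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("x", "y")))
  d <- c(g1 = 0.5, g2 = 0.25, g3 = 0.25)
  wt <- impose_row_weights(m, d)
  q <- m / rowSums(m)
  gp <- colSums(q * d)
  expect_equal(unname(wt$Z), unname(2 * sweep(q, 2, gp)), tolerance = 1e-14)
  expect_equal(wt$row_weights, unname(d))
  expect_lt(max(abs(colSums(d * wt$Z))), 1e-12)

  # validation: id mismatch and bad weights are refused
  expect_error(impose_row_weights(m, c(g1 = 0.5, gX = 0.25, g3 = 0.25)),
               class = "miract_error_ids")
  expect_error(impose_row_weights(m, c(g1 = 1, g2 = -0.5, g3 = 0.5)),
               class = "miract_error_weights")
})

test_that("group condensation averages columns and centres by the grand centroid", {
  set.seed(17)
  wt <- nsc_transform(random_table(6, 4))
  groups <- tibble::tibble(sample_id = wt$col_ids,
                           group = c("A", "A", "B", "B"))
  cond <- between_group_condense(wt, groups)
  overall <- rowSums(sweep(wt$Z, 2, wt$col_weights, `*`))
  for (g in c("A", "B")) {
    j <- which(groups$group == g)
    expected <- rowMeans(wt$Z[, j]) - overall / sum(wt$col_weights)
    expect_lt(max(abs(cond$Z[, g] - expected)), 1e-12)
  }
  expect_equal(cond$col_weights, c(0.5, 0.5))

  # singleton groups give the grand-centroid-centred original table
  single <- tibble::tibble(sample_id = wt$col_ids, group = wt$col_ids)
  cond1 <- between_group_condense(wt, single)
  expect_lt(max(abs(cond1$Z - (wt$Z - overall / sum(wt$col_weights)))), 1e-12)

  # one group only: all zeros
  one <- tibble::tibble(sample_id = wt$col_ids, group = "all")
  expect_lt(max(abs(between_group_condense(wt, one)$Z)), 1e-12)

  # unassigned column is an error
  expect_error(between_group_condense(wt, groups[-1, ]),
               class = "miract_error_groups")
})

test_that("between-group inertia never exceeds total inertia", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(4:8, 1)
    wt <- nsc_transform(random_table(sample(5:9, 1), n))
    groups <- tibble::tibble(
      sample_id = wt$col_ids,
      group = paste0("G", sample.int(3, n, replace = TRUE)))
    cond <- between_group_condense(wt, groups)
    expect_lte(total_inertia(cond), total_inertia(wt) + 1e-10)
  }
})

test_that("self-coupling reproduces the single-table spectrum with RV = 1", {
  set.seed(29)
  for (rep in 1:10) {
    wt <- nsc_transform(random_table(7, 4))
    ord <- weighted_decomposition(wt, n_axes = 4, tol = 1e-14)
    co <- coinertia(wt, wt, n_axes = 4)
    k <- length(ord$eigenvalues)
    expect_lt(max(abs(co$s[seq_len(k)] - ord$eigenvalues)), 1e-10)
    expect_equal(co$rv, 1, tolerance = 1e-10)
  }
})

test_that("singular covariances match the explicit brute-force oracle", {
  set.seed(37)
  for (rep in 1:20) {
    base <- random_table(8, 3)
    other <- random_table(8, 4)
    rownames(other) <- rownames(base)
    X <- nsc_transform(base)
    d <- X$row_weights
    names(d) <- X$row_ids
    Y <- impose_row_weights(other, d)
    co <- coinertia(X, Y, n_axes = 3)
    expect_lt(max(abs(co$s_all - oracle_coinertia_s(X, Y))), 1e-10)

    # permuting Y's columns (with weights) leaves the totals unchanged
    perm <- sample(ncol(Y$Z))
    Yp <- weighted_table(Y$Z[, perm], row_weights = Y$row_weights,
                         col_weights = Y$col_weights[perm])
    cop <- coinertia(X, Yp, n_axes = 3)
    expect_equal(sum(cop$s_all^2), sum(co$s_all^2), tolerance = 1e-12)
    expect_equal(cop$rv, co$rv, tolerance = 1e-12)
  }
})

test_that("the first axis pair dominates random unit axis pairs in covariance", {
  set.seed(43)
  base <- random_table(10, 4)
  other <- random_table(10, 5)
  rownames(other) <- rownames(base)
  X <- nsc_transform(base)
  d <- X$row_weights; names(d) <- X$row_ids
  Y <- impose_row_weights(other, d)
  co <- coinertia(X, Y, n_axes = 1)
  best <- axis_pair_covariance(X, Y, co$axes_X[, 1], co$axes_Y[, 1])
  expect_equal(abs(best), co$s[1], tolerance = 1e-10)
  for (i in 1:1000) {
    bx <- unit_under(rnorm(4), X$col_weights)
    by <- unit_under(rnorm(5), Y$col_weights)
    expect_lte(axis_pair_covariance(X, Y, bx, by)^2, co$s[1]^2 + 1e-12)
  }
})

test_that("coupling validates its shared row metric", {
  set.seed(47)
  X <- nsc_transform(random_table(6, 3))
  other <- random_table(6, 4)
  rownames(other) <- X$row_ids
  d <- X$row_weights; names(d) <- X$row_ids
  Y <- impose_row_weights(other, d)
  Ybadw <- weighted_table(Y$Z, row_weights = rev(Y$row_weights),
                          col_weights = Y$col_weights,
                          row_ids = Y$row_ids, col_ids = Y$col_ids)
  expect_error(coinertia(X, Ybadw, 2), class = "miract_error_rows")
  Ybadid <- weighted_table(Y$Z, row_weights = Y$row_weights,
                           col_weights = Y$col_weights,
                           row_ids = rev(Y$row_ids), col_ids = Y$col_ids)
  expect_error(coinertia(X, Ybadid, 2), "mismatch",
               class = "miract_error_rows")

  # consistent row permutation of both tables is irrelevant
  co <- coinertia(X, Y, n_axes = 2)
  perm <- sample(6)
  Xp <- weighted_table(X$Z[perm, ], X$row_weights[perm], X$col_weights)
  Yp <- weighted_table(Y$Z[perm, ], Y$row_weights[perm], Y$col_weights)
  cop <- coinertia(Xp, Yp, n_axes = 2)
  expect_equal(cop$s, co$s, tolerance = 1e-12)
  expect_equal(cop$rv, co$rv, tolerance = 1e-12)
})

test_that("RV is 1 for self, scale-invariant, and refuses null tables", {
  set.seed(53)
  X <- nsc_transform(random_table(6, 4))
  expect_equal(rv_coefficient(X, X), 1, tolerance = 1e-12)
  Y <- weighted_table(3.7 * X$Z, X$row_weights, X$col_weights)
  expect_equal(rv_coefficient(X, Y), 1, tolerance = 1e-12)
  s <- oracle_coinertia_s(X, Y)
  nx <- sum(oracle_coinertia_s(X, X)^2) # self cross-product Frobenius
  ny <- sum(oracle_coinertia_s(Y, Y)^2)
  expect_equal(rv_coefficient(X, Y), sum(s^2) / sqrt(nx * ny),
               tolerance = 1e-10)
  Z0 <- weighted_table(matrix(0, 6, 4), X$row_weights, X$col_weights,
                       row_ids = X$row_ids, col_ids = X$col_ids)
  expect_error(rv_coefficient(X, Z0), class = "miract_error_zero_total")
})

test_that("the unsupervised pipeline is self-consistent and alignment-invariant", {
  set.seed(59)
  m <- random_table(12, 5) + 1
  expr <- expr_tbl(m)
  # identical structure on both sides couples perfectly
  res <- unsupervised_cia(expr, target_tbl(m, "self"), n_axes = 2)
  expect_equal(res$rv, 1, tolerance = 1e-8)

  tm <- random_table(12, 4)
  rownames(tm) <- rownames(m)
  res1 <- unsupervised_cia(expr, target_tbl(tm, "p"), n_axes = 2)
  shuffle <- sample(12)
  res2 <- unsupervised_cia(expr, target_tbl(tm[shuffle, ], "p"), n_axes = 2)
  expect_equal(res2$s, res1$s, tolerance = 1e-10)
  expect_equal(res2$display_Y, res1$display_Y, tolerance = 1e-10)
  expect_equal(res2$rv, res1$rv, tolerance = 1e-12)
})

test_that("supervised coupling yields one oriented axis for two groups", {
  sim <- simulate_dataset(g = 120, n_per_group = 4, m = 10, n_active = 2,
                          delta = 0.6, seed = 4)
  fit <- supervised_cia(sim$expression, sim$targets, sim$groups, "A")
  expect_equal(fit$coinertia$n_axes, 1L)
  expect_equal(fit$coinertia$rank, 1L)
  expect_gt(fit$group_coords["A"], 0)

  # swapping the target group negates the orientation, coordinates mirror
  fitB <- supervised_cia(sim$expression, sim$targets, sim$groups, "B")
  expect_gt(fitB$group_coords["B"], 0)
  expect_equal(fitB$mirna_coords, -fit$mirna_coords, tolerance = 1e-10)

  # relabelling the groups has no effect beyond the labels
  g2 <- sim$groups
  g2$group <- ifelse(g2$group == "A", "case", "control")
  fit2 <- supervised_cia(sim$expression, sim$targets, g2, "case")
  expect_equal(unname(fit2$mirna_coords), unname(fit$mirna_coords),
               tolerance = 1e-10)

  expect_error(supervised_cia(sim$expression, sim$targets, sim$groups, "Z"),
               class = "miract_error_groups")
})

test_that("indistinguishable group centroids degrade with a warning", {
  set.seed(61)
  # identical expression in both groups: centroids coincide exactly
  m <- matrix(rep(c(4, 2, 7, 5), 4), 4, 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  tm <- random_table(4, 3)
  rownames(tm) <- rownames(m)
  groups <- tibble::tibble(sample_id = colnames(m),
                           group = c("A", "B", "A", "B"))
  expect_warning(
    fit <- supervised_cia(expr_tbl(m), target_tbl(tm), groups, "A"),
    "indistinguishable")
  expect_equal(fit$coinertia$rank, 0L)
  expect_error(rank_mirnas(fit), class = "miract_error_degenerate")
})
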