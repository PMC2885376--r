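#' Simulate a paired expression / target-site dataset with planted miRNA activity
#'
#' Generates the two coupled tables the method consumes, with known truth:
#' a genes x miRNAs table of predicted target-site counts and a two-group
#' genes x samples log2-scale expression matrix in which the predicted
#' targets of a chosen set of "active" miRNAs are down-regulated in group
#' `"A"`, in proportion to their site count (a linear dose-response, the
#' simplest mechanism consistent with miRNA-directed mRNA degradation).
#'
#' Site counts are `Bernoulli(p_target) * (1 + Poisson(max(lambda_sites - 1, 0)))`
#' per (gene, miRNA) cell; expression is
#' `baseline_g + noise - delta * (active site load)` for group-A samples,
#' with `baseline_g ~ Normal(baseline_mean, baseline_sd)` and
#' `noise ~ Normal(0, sigma)`, floored at 0. Gene rows (and miRNA columns)
#' that would violate the positivity invariants are redrawn. All randomness
#' derives from `seed`; the draw order is fixed (counts by gene row, zero-row
#' redraws, zero-column redraws, baselines, noise), so an identical seed
#' yields a bit-identical dataset.
#'
#' @param g Number of genes.
#' @param n_per_group Samples per group (groups `"A"` and `"B"`).
#' @param m Number of miRNAs.
#' @param n_active Number of active (planted) miRNAs; the first `n_active`
#'   miRNA ids are active.
#' @param lambda_sites Mean site count of a targeted (gene, miRNA) pair.
#' @param p_target Probability that a (gene, miRNA) pair has any sites.
#' @param baseline_mean,baseline_sd Gene baseline distribution, log2 units.
#' @param delta Down-regulation per target site in group A, log2 units
#'   (`>= 0`; 0 gives a null dataset).
#' @param sigma Residual noise standard deviation, log2 units.
#' @param seed Integer seed; the only source of randomness.
#' @return A list of class `"mirna_simulation"`: `expression` (tibble),
#'   `targets` (target-count tibble, `source_label` `"simulated"`), `groups`
#'   (tibble `sample_id`, `group`), `truth` (active miRNA ids) and `config`.
#' @export
#' @examples
#' sim <- simulate_dataset(g = 60, m = 8, n_active = 2, seed = 1)
#' sim$truth
simulate_dataset <- function(g = 500, n_per_group = 6, m = 30, n_active = 3,
                             lambda_sites = 1.3, p_target = 0.1,
                             baseline_mean = 8, baseline_sd = 1.5,
                             delta = 0.5, sigma = 0.5, seed = 1) {
  if (g < 1 || n_per_group < 1 || m < 1 || n_active < 1) {
    stop_miract("g, n_per_group, m and n_active must all be >= 1", "args")
  }
  if (n_active > m) stop_miract("n_active cannot exceed m", "args")
  if (delta < 0) stop_miract("delta must be >= 0", "args")
  if (sigma <= 0) stop_miract("sigma must be > 0", "args")
  if (p_target <= 0 || p_target > 1) {
    stop_miract("p_target must be in (0, 1]", "args")
  }
  cfg <- list(g = g, n_per_group = n_per_group, m = m, n_active = n_active,
              lambda_sites = lambda_sites, p_target = p_target,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              delta = delta, sigma = sigma, seed = seed)
  gene_ids <- sprintf("gene%04d", seq_len(g))
  mirna_ids <- sprintf("miR-%03d", seq_len(m))
  sample_ids <- c(paste0("A_", seq_len(n_per_group)),
                  paste0("B_", seq_len(n_per_group)))
  group <- rep(c("A", "B"), each = n_per_group)
  lam <- max(lambda_sites - 1, 0)

  withr::local_seed(seed)
  draw_row <- function() {
    hit <- runif(m) < p_target
    counts <- integer(m)
    counts[hit] <- 1L + rpois(sum(hit), lam)
    counts
  }
  C <- matrix(0L, g, m, dimnames = list(gene_ids, mirna_ids))
  for (i in seq_len(g)) C[i, ] <- draw_row()
  for (i in which(rowSums(C) == 0)) {
    repeat {
      C[i, ] <- draw_row()
      if (sum(C[i, ]) > 0) break
    }
  }
  for (j in which(colSums(C) == 0)) {
    repeat {
      hit <- runif(g) < p_target
      col <- integer(g)
      col[hit] <- 1L + rpois(sum(hit), lam)
      if (sum(col) > 0) { C[, j] <- col; break }
    }
  }

  active <- mirna_ids[seq_len(n_active)]
  load_a <- C[, active, drop = FALSE] %*% rep(1, n_active)
  baseline <- rnorm(g, baseline_mean, baseline_sd)
  X <- baseline + matrix(rnorm(g * 2 * n_per_group, 0, sigma), g)
  X[, group == "A"] <- X[, group == "A"] - delta * as.vector(load_a)
  X[X < 0] <- 0
  # a fully-silent gene row breaks the NSC row masses; re-noise such rows
  for (i in which(rowSums(X) == 0)) {
    repeat {
      X[i, ] <- baseline[i] + rnorm(2 * n_per_group, 0, sigma)
      X[i, group == "A"] <- X[i, group == "A"] - delta * load_a[i]
      X[i, ][X[i, ] < 0] <- 0
      if (sum(X[i, ]) > 0) break
    }
  }
  dimnames(X) <- list(gene_ids, sample_ids)

  expression <- dplyr::bind_cols(tibble(gene_id = gene_ids),
                                 as_tibble(X, .name_repair = "minimal"))
  targets <- dplyr::bind_cols(tibble(gene_id = gene_ids),
                              as_tibble(C, .name_repair = "minimal"))
  attr(targets, "source_label") <- "simulated"
  structure(list(expression = expression, targets = targets,
                 groups = tibble(sample_id = sample_ids, group = group),
                 truth = active, config = cfg),
            class = "mirna_simulation")
}

#' @export
print.mirna_simulation <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic dataset: %d genes x %d samples (2 groups), %d miRNAs (%d active), delta = %g\n",
    cfg$g, 2 * cfg$n_per_group, cfg$m, cfg$n_active, cfg$delta))
  invisible(x)
}

#' Perturb a target-count table into a pseudo prediction program
#'
#' Emulates the disagreement between target-prediction programs: each
#' (gene, miRNA) cell is independently toggled with probability `flip_rate`
#' (a non-zero count becomes 0, a zero becomes 1). A row or column driven to
#' an all-zero sum has one of its toggles reverted, preserving the table
#' invariants. Deterministic given `seed`.
#'
#' @param targets Target count tibble.
#' @param flip_rate Per-cell toggle probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A target count tibble; `source_label` gains a
#'   `"_flip<rate>_s<seed>"` suffix.
#' @export
perturb_target_table <- function(targets, flip_rate, seed = 1) {
  if (flip_rate < 0 || flip_rate >= 1) {
    stop_miract("flip_rate must be in [0, 1)", "args")
  }
  C <- target_values(targets)
  if (flip_rate > 0) {
    withr::local_seed(seed)
    flip <- matrix(runif(length(C)) < flip_rate, nrow(C))
    C2 <- C
    C2[flip & C > 0] <- 0
    C2[flip & C == 0] <- 1
    # restore any row/column flattened to zero by reverting one toggle
    for (i in which(rowSums(C2) == 0)) {
      j <- which(flip[i, ] & C[i, ] > 0)[1]
      C2[i, j] <- C[i, j]
      flip[i, j] <- FALSE
    }
    for (j in which(colSums(C2) == 0)) {
      i <- which(flip[, j] & C[, j] > 0)[1]
      C2[i, j] <- C[i, j]
      flip[i, j] <- FALSE
    }
    C <- C2
  }
  out <- dplyr::bind_cols(tibble(gene_id = rownames(C)),
                          as_tibble(C, .name_repair = "minimal"))
  attr(out, "source_label") <- sprintf("%s_flip%g_s%d", target_label(targets),
                                       flip_rate, as.integer(seed))
  out
}

#' Derive a family of pseudo prediction programs from one simulation
#'
#' Convenience wrapper used throughout validation: perturbs the simulated
#' target table `n_programs` times with distinct seeds, yielding the
#' per-program tables a real analysis would obtain from different
#' prediction databases.
#'
#' @param sim A `"mirna_simulation"`.
#' @param n_programs Number of pseudo programs.
#' @param flip_rate Per-cell toggle probability for each program.
#' @return Named list of target count tibbles.
#' @export
simulate_programs <- function(sim, n_programs = 5, flip_rate = 0.1) {
  stopifnot(inherits(sim, "mirna_simulation"))
  seeds <- sim$config$seed * 1000L + seq_len(n_programs)
  out <- purrr::map(seeds, function(s) {
    tt <- perturb_target_table(sim$targets, flip_rate, seed = s)
    attr(tt, "source_label") <- sprintf("program%d", s - sim$config$seed * 1000L)
    tt
  })
  names(out) <- purrr::map_chr(out, target_label)
  out
}
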