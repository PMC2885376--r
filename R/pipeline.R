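#' @name runners
#' @rdname runners
#' @title End-to-end pipeline runners
#'
#' @description
#' The file-in / file-out layer used by the `miract` command line: each
#' runner reads TSV inputs (or accepts in-memory tibbles), executes the
#' corresponding analysis and writes the standard TSV outputs (plus a
#' best-effort plot image) into an output directory. Outputs are
#' deterministic: rerunning on identical inputs yields byte-identical
#' tables.
#'
#' * `run_cia()` - unsupervised co-inertia per target table
#'   (`covariances.tsv`, `samples_coords.tsv`, `mirna_coords.tsv`, gene
#'   projections, `summary.tsv`, `cia_plot.png`).
#' * `run_supervised()` - supervised co-inertia + ranking per target table
#'   (`ranked_<label>.tsv`), then the cross-program consensus
#'   (`consensus.tsv`). With a single target table the ranked list is still
#'   written but the consensus step is refused.
#' * `run_simulate()` - writes a synthetic dataset (`expression.tsv`,
#'   `groups.tsv`, `truth.tsv`, one `targets_<label>.tsv` per pseudo
#'   program).
#'
#' @param expression Expression tibble or path to an expression TSV.
#' @param targets A target table/path, or a (named) list of them - one per
#'   prediction program.
#' @param groups Group tibble or path (`sample_id`, `group`).
#' @param target_group Group whose active miRNAs are sought.
#' @param out_dir Output directory, created if needed.
#' @param n_axes Axis pairs for the unsupervised display.
#' @param k,min_programs Consensus parameters (top-`k`, support filter).
#' @param allow_shift Passed to [read_expression_matrix()].
#' @param row_weights Row-metric mode, see [unsupervised_cia()].
#' @param n_programs,flip_rate Pseudo-program family for `run_simulate()`.
#' @param seed Simulation seed.
#' @param ... Passed to [simulate_dataset()].
#' @return The output directory, invisibly; `run_supervised()` returns the
#'   consensus table invisibly when computed.
NULL

# accept a path or an in-memory tibble
as_expression <- function(x, allow_shift = FALSE) {
  if (is.character(x)) read_expression_matrix(x, allow_shift = allow_shift)
  else { validate_expression(as_tibble(x)); as_tibble(x) }
}

as_target_list <- function(targets) {
  if (!is.list(targets) || inherits(targets, "data.frame")) {
    targets <- list(targets)
  }
  out <- purrr::imap(targets, function(t, i) {
    fallback <- if (is.character(i) && nzchar(i)) i else paste0("program", i)
    if (is.character(t)) {
      lbl <- if (is.character(i) && nzchar(i)) i else
        sub("^targets_", "", sub("\\.tsv$", "", basename(t)))
      build_target_table(read_target_records(t), source_label = lbl)
    } else {
      t <- as_tibble(t)
      attr(t, "source_label") <- target_label(t, fallback)
      t
    }
  })
  names(out) <- purrr::map_chr(out, target_label)
  if (anyDuplicated(names(out))) {
    stop_miract("duplicate target table labels", "ids")
  }
  out
}

as_groups <- function(x) {
  if (is.character(x)) read_groups(x) else as_tibble(x)
}

#' @rdname runners
#' @export
run_cia <- function(expression, targets, groups = NULL, out_dir,
                    n_axes = 2L, allow_shift = FALSE,
                    row_weights = c("expression", "uniform")) {
  row_weights <- match.arg(row_weights)
  expr <- as_expression(expression, allow_shift)
  tabs <- as_target_list(targets)
  grp <- if (!is.null(groups)) as_groups(groups) else NULL
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (lbl in names(tabs)) {
    res <- unsupervised_cia(expr, tabs[[lbl]], n_axes = n_axes,
                            row_weights = row_weights)
    sub <- if (length(tabs) > 1) file.path(out_dir, lbl) else out_dir
    write_coinertia(res, sub)
    miract_log("cia [%s]: rv = %.4f, inertia X = %.4g, Y = %.4g", lbl,
               res$rv, res$inertia_X, res$inertia_Y)
    save_plot_quietly(autoplot(res, groups = grp),
                      file.path(sub, "cia_plot.png"))
  }
  invisible(out_dir)
}

#' @rdname runners
#' @export
run_supervised <- function(expression, targets, groups, target_group,
                           out_dir, k = 20L, min_programs = 2L,
                           allow_shift = FALSE,
                           row_weights = c("expression", "uniform")) {
  row_weights <- match.arg(row_weights)
  expr <- as_expression(expression, allow_shift)
  tabs <- as_target_list(targets)
  grp <- as_groups(groups)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lists <- purrr::map(tabs, function(tt) {
    fit <- supervised_cia(expr, tt, grp, target_group,
                          row_weights = row_weights)
    rl <- rank_mirnas(fit)
    write_ranked_list(rl, file.path(out_dir,
                                    paste0("ranked_", attr(rl, "program"),
                                           ".tsv")))
    rl
  })
  if (length(lists) < 2) {
    stop_miract(paste0(
      "consensus needs ranked lists from >= 2 prediction programs; ",
      "only one target table was given (its ranked list has been written)"),
      "args")
  }
  cons <- consensus(lists, k = k, min_programs = min_programs)
  write_consensus(cons, file.path(out_dir, "consensus.tsv"))
  invisible(cons)
}

#' @rdname runners
#' @export
run_simulate <- function(out_dir, n_programs = 5, flip_rate = 0.1, seed = 1,
                         ...) {
  sim <- simulate_dataset(seed = seed, ...)
  progs <- simulate_programs(sim, n_programs = n_programs,
                             flip_rate = flip_rate)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(sim$expression, file.path(out_dir, "expression.tsv"))
  readr::write_tsv(sim$groups, file.path(out_dir, "groups.tsv"),
                   progress = FALSE)
  readr::write_tsv(tibble(mirna_id = sim$truth),
                   file.path(out_dir, "truth.tsv"), progress = FALSE)
  for (lbl in names(progs)) {
    write_target_records(progs[[lbl]],
                         file.path(out_dir, paste0("targets_", lbl, ".tsv")))
  }
  invisible(out_dir)
}

#' Write a target count table as long-format records
#'
#' Serialises a gene x miRNA count table back to the long 3-column record
#' format [read_target_records()] reads, one line per non-zero cell.
#'
#' @param targets Target count tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_target_records <- function(targets, path) {
  m <- target_values(targets)
  nz <- which(m > 0, arr.ind = TRUE)
  nz <- nz[order(nz[, "col"], nz[, "row"]), , drop = FALSE]
  rec <- tibble(mirna_id = colnames(m)[nz[, "col"]],
                gene_id = rownames(m)[nz[, "row"]],
                site_count = as.integer(m[nz]))
  readr::write_tsv(rec, path, progress = FALSE)
  invisible(path)
}

# plotting is best-effort: a headless device failure must not sink a run
save_plot_quietly <- function(plot, path, width = 9, height = 4.5) {
  tryCatch(
    suppressMessages(ggplot2::ggsave(path, plot = plot, width = width,
                                     height = height, dpi = 120)),
    error = function(e) {
      warn(sprintf("[miract] could not render plot '%s': %s", path,
                   conditionMessage(e)))
    })
  invisible(path)
}
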