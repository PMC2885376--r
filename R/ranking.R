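#' Construct a ranked miRNA list
#'
#' Lightweight constructor/validator for the per-program ranked list: a
#' tibble of (`mirna_id`, `rank`) rows, optionally with the axis
#' `coordinate`, labelled by the prediction program and the target group.
#' Ranks need not be complete (a published top-K excerpt is a valid list);
#' miRNA identifiers must be unique within a list.
#'
#' @param x Data frame with columns `mirna_id` and `rank` (and optionally
#'   `coordinate`).
#' @param program Label of the prediction program the list came from.
#' @param target_group The group the ranking is relative to.
#' @return A tibble of class `"ranked_list"` with attributes `program` and
#'   `target_group`.
#' @export
ranked_list <- function(x, program, target_group = NA_character_) {
  x <- as_tibble(x)
  if (!all(c("mirna_id", "rank") %in% names(x))) {
    stop_miract("a ranked list needs columns mirna_id and rank", "parse")
  }
  if (anyDuplicated(x$mirna_id)) {
    stop_miract(sprintf("duplicate miRNA '%s' in ranked list",
                        x$mirna_id[duplicated(x$mirna_id)][1]), "ids")
  }
  if (any(x$rank < 1 | x$rank != round(x$rank))) {
    stop_miract("ranks must be positive integers", "parse")
  }
  x <- dplyr::arrange(x, .data$rank)
  structure(x, class = c("ranked_list", class(tibble())),
            program = program, target_group = target_group)
}

#' Rank miRNAs along a supervised co-inertia axis
#'
#' Orders miRNAs by their axis-1 coordinate, most negative first: with the
#' target group oriented positive, the miRNAs at the opposite end of the
#' axis are the ones whose predicted targets are down-regulated in the
#' target group, i.e. the miRNAs inferred active there. Ties in coordinate
#' break lexicographically by miRNA id, ascending; ranks run 1..m.
#'
#' @param result A `"supervised_cia"` object.
#' @return A `"ranked_list"` tibble with columns `mirna_id`, `coordinate`,
#'   `rank`.
#' @export
rank_mirnas <- function(result) {
  stopifnot(inherits(result, "supervised_cia"))
  if (result$coinertia$rank == 0) {
    stop_miract(
      "the supervised axis is null (indistinguishable group centroids); no meaningful ranking exists",
      "degenerate")
  }
  co <- result$mirna_coords
  ord <- order(co, names(co), method = "radix")
  out <- tibble(mirna_id = names(co)[ord], coordinate = unname(co)[ord],
                rank = seq_along(co))
  ranked_list(out, program = result$source_label,
              target_group = result$target_group)
}

#' Consensus of ranked miRNA lists across prediction programs
#'
#' Prediction programs disagree, so a miRNA is only trusted when several
#' programs rank it highly: for each miRNA the ranks at or below `k` are
#' collected across programs, miRNAs supported by at least `min_programs`
#' such ranks are kept, and the consensus score is the arithmetic mean of
#' the collected ranks (ranks beyond `k`, like absences, contribute
#' nothing). Rows are sorted by average rank ascending, ties broken by more
#' supporting programs, then by miRNA id.
#'
#' @param lists A list of two or more [ranked_list()]s (or data frames with
#'   `mirna_id` and `rank`); names of the list are used as program labels
#'   when a list carries no `program` attribute. All lists must target the
#'   same group.
#' @param k Top-rank cutoff: only ranks `<= k` count (default 20).
#' @param min_programs Minimum number of supporting programs (default 2).
#' @return A tibble of class `"consensus_table"`: `mirna_id`, one rank
#'   column per program (`NA` when the miRNA is absent or beyond `k`),
#'   `average_rank`, `n_programs`.
#' @export
consensus <- function(lists, k = 20L, min_programs = 2L) {
  if (!is.list(lists) || inherits(lists, "data.frame")) {
    stop_miract("lists must be a list of ranked lists", "args")
  }
  if (length(lists) < 2) {
    stop_miract("consensus needs at least 2 ranked lists", "args")
  }
  if (k < 1) stop_miract("k must be >= 1", "args")
  if (min_programs < 2) stop_miract("min_programs must be >= 2", "args")
  programs <- purrr::imap_chr(lists, function(l, i) {
    p <- attr(l, "program")
    if (!is.null(p) && !is.na(p)) as.character(p)
    else if (is.character(i) && nzchar(i)) i
    else paste0("program", i)
  })
  if (anyDuplicated(programs)) {
    stop_miract("duplicate program labels among the input lists", "ids")
  }
  tg <- unique(stats::na.omit(purrr::map_chr(
    lists, function(l) attr(l, "target_group") %||% NA_character_)))
  if (length(tg) > 1) {
    stop_miract(sprintf("lists target different groups: %s",
                        paste(tg, collapse = ", ")), "groups")
  }

  long <- purrr::map2_dfr(lists, programs, function(l, p) {
    l <- as_tibble(l)
    if (anyDuplicated(l$mirna_id)) {
      stop_miract(sprintf("duplicate miRNA '%s' in list '%s'",
                          l$mirna_id[duplicated(l$mirna_id)][1], p), "ids")
    }
    tibble(mirna_id = l$mirna_id, program = p, rank = as.numeric(l$rank))
  })
  top <- dplyr::filter(long, .data$rank <= k)
  agg <- top |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(average_rank = mean(.data$rank),
                     n_programs = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_programs >= min_programs)
  wide <- top |>
    dplyr::filter(.data$mirna_id %in% agg$mirna_id) |>
    tidyr::pivot_wider(names_from = "program", values_from = "rank")
  # keep a column for every program, even one contributing no consensus rank
  for (p in setdiff(programs, names(wide))) wide[[p]] <- NA_real_
  out <- wide[, c("mirna_id", programs), drop = FALSE] |>
    dplyr::left_join(agg, by = "mirna_id") |>
    dplyr::arrange(.data$average_rank, dplyr::desc(.data$n_programs),
                   .data$mirna_id)
  structure(out, class = c("consensus_table", class(tibble())),
            k = as.integer(k), min_programs = as.integer(min_programs),
            target_group = if (length(tg) == 1) tg else NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a wide table of per-program ranks as partial ranked lists
#'
#' Reads a TSV whose first column is `mirna_id` and whose remaining columns
#' each hold one prediction program's rank for that miRNA (blank when the
#' miRNA is absent or beyond the program's reported cutoff) and splits it
#' into one partial [ranked_list()] per program, ready for [consensus()].
#' This is the format of published top-K consensus excerpts; the package
#' ships three such tables under `inst/extdata` (miRNAs associated with
#' papillary thyroid carcinoma, and with LPS-treated wild-type and
#' MAL-knockout mouse macrophages, as ranked by five target-prediction
#' programs).
#'
#' @param path Path to the wide TSV.
#' @param target_group Optional group label to attach to every list.
#' @return Named list of `"ranked_list"` tibbles, one per program column.
#' @examples
#' p <- system.file("extdata", "ptc_program_ranks.tsv", package = "miract")
#' consensus(read_program_ranks(p), k = 20, min_programs = 2)
#' @export
read_program_ranks <- function(path, target_group = NA_character_) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    mirna_id = "c", .default = "d"), progress = FALSE)
  programs <- setdiff(names(wide), "mirna_id")
  out <- purrr::map(programs, function(p) {
    d <- wide[!is.na(wide[[p]]), c("mirna_id", p)]
    names(d) <- c("mirna_id", "rank")
    ranked_list(d, program = p, target_group = target_group)
  })
  names(out) <- programs
  out
}

#' Format consensus average ranks for display
#'
#' Average ranks are reported to two decimals with round-half-to-even, the
#' convention used in the exported tables; the `average_rank` column itself
#' keeps full precision.
#'
#' @param x A `"consensus_table"`.
#' @return Character vector of formatted averages.
#' @export
format_average_rank <- function(x) {
  formatC(round(x$average_rank, 2), format = "fg", digits = 8)
}

#' Write a ranked list to TSV
#'
#' @param x A `"ranked_list"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Write a consensus table to TSV
#'
#' The machine twin of a published consensus table: one column per program
#' (empty cell when the miRNA is absent or ranked beyond the cutoff),
#' average rank (two decimals, round-half-to-even) and the number of
#' supporting programs.
#'
#' @param x A `"consensus_table"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(x, path) {
  out <- as_tibble(x)
  out$average_rank <- round(out$average_rank, 2)
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @export
print.consensus_table <- function(x, ...) {
  cat(sprintf("Consensus over %d program column(s), top-%d rule, >= %d programs\n",
              sum(!names(x) %in% c("mirna_id", "average_rank", "n_programs")),
              attr(x, "k"), attr(x, "min_programs")))
  NextMethod()
}
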