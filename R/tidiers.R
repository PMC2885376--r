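#' Tidy an ordination
#'
#' Returns one row per (item, axis): row or column coordinates in long
#' format, broom-style.
#'
#' @param x An `"ordination"` object.
#' @param which `"rows"` (principal row coordinates) or `"cols"` (column
#'   coordinates).
#' @param ... Unused.
#' @return A tibble with columns `id`, `axis`, `coordinate`.
#' @export
tidy.ordination <- function(x, which = c("rows", "cols"), ...) {
  which <- match.arg(which)
  m <- if (which == "rows") x$row_coords else x$col_coords
  coords_long(m)
}

coords_long <- function(m, id_name = "id") {
  if (ncol(m) == 0) {
    return(tibble(!!id_name := rownames(m))[0, ] |>
             dplyr::mutate(axis = integer(0), coordinate = numeric(0)))
  }
  as_tibble(m, rownames = id_name) |>
    tidyr::pivot_longer(-dplyr::all_of(id_name), names_to = "axis",
                        values_to = "coordinate") |>
    dplyr::mutate(axis = as.integer(sub("Axis", "", .data$axis)))
}

#' Glance at an ordination
#'
#' @param x An `"ordination"` object.
#' @param ... Unused.
#' @return One-row tibble: `rank`, `total_inertia`, `lambda1`,
#'   `prop_axis1` (share of inertia on the first axis).
#' @export
glance.ordination <- function(x, ...) {
  ti <- total_inertia(x$source)
  tibble(rank = x$rank, total_inertia = ti,
         lambda1 = if (x$rank > 0) x$eigenvalues[1] else 0,
         prop_axis1 = if (x$rank > 0 && ti > 0) x$eigenvalues[1] / ti else NA_real_)
}

#' Tidy a co-inertia result
#'
#' @param x A `"coinertia"` object.
#' @param which Which coordinates to return: `"samples"` (display
#'   coordinates of table X's columns), `"mirnas"` (table Y's columns) or
#'   `"genes"` (the shared-row projections in both spaces).
#' @param ... Unused.
#' @return A long tibble of coordinates; for `"genes"` a column `space`
#'   distinguishes the two projections.
#' @export
tidy.coinertia <- function(x, which = c("samples", "mirnas", "genes"), ...) {
  which <- match.arg(which)
  if (which == "samples") return(coords_long(x$display_X, "sample_id"))
  if (which == "mirnas") return(coords_long(x$display_Y, "mirna_id"))
  dplyr::bind_rows(
    dplyr::mutate(coords_long(x$gene_coords_X, "gene_id"), space = "X"),
    dplyr::mutate(coords_long(x$gene_coords_Y, "gene_id"), space = "Y"))
}

#' Glance at a co-inertia result
#'
#' @param x A `"coinertia"` object.
#' @param ... Unused.
#' @return One-row tibble: `rv`, `s1`, `total_coinertia` (sum of squared
#'   covariances), `inertia_X`, `inertia_Y`, `n_axes`.
#' @export
glance.coinertia <- function(x, ...) {
  tibble(rv = x$rv, s1 = x$s[1], total_coinertia = sum(x$s_all^2),
         inertia_X = x$inertia_X, inertia_Y = x$inertia_Y, n_axes = x$n_axes)
}

#' Tidy a supervised co-inertia result
#'
#' @param x A `"supervised_cia"` object.
#' @param ... Unused.
#' @return A tibble of miRNA axis-1 coordinates (`mirna_id`, `coordinate`),
#'   most negative (most associated with the target group) first.
#' @export
tidy.supervised_cia <- function(x, ...) {
  as_tibble(rank_mirnas(x))
}

#' Glance at a supervised co-inertia result
#'
#' @param x A `"supervised_cia"` object.
#' @param ... Unused.
#' @return One-row tibble: `target_group`, `s1`, `rv`, `n_groups`,
#'   `program`.
#' @export
glance.supervised_cia <- function(x, ...) {
  tibble(target_group = x$target_group, s1 = x$coinertia$s[1],
         rv = x$coinertia$rv, n_groups = length(x$groups),
         program = x$source_label)
}
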