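#' Read a gene expression matrix from TSV
#'
#' Reads a tab-separated expression table whose first column (`gene_id`)
#' holds gene identifiers and whose remaining columns hold one numeric
#' expression profile per sample (typically log2 intensities). The table is
#' validated for the downstream ordination: identifiers must be unique, every
#' entry non-negative, and every gene must have a positive total.
#'
#' Non-symmetric correspondence analysis operates on non-negative tables, so
#' negative entries are rejected by default. Two-colour log-intensities can
#' dip below zero; setting `allow_shift = TRUE` subtracts the global minimum
#' from every entry (making the smallest value 0) and emits a warning instead.
#'
#' @param path Path to a UTF-8 TSV file. Header row: `gene_id` followed by
#'   sample identifiers; body numeric with `.` decimal separator.
#' @param allow_shift If `TRUE`, a table containing negatives is shifted so
#'   its global minimum becomes zero (with a warning) rather than rejected.
#' @return A tibble with column `gene_id` and one numeric column per sample.
#' @seealso [write_expression_matrix()], [collapse_probes()], [align_tables()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), tf)
#' read_expression_matrix(tf)
read_expression_matrix <- function(path, allow_shift = FALSE) {
  if (!file.exists(path)) {
    stop_miract(sprintf("expression file not found: '%s'", path), "io")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 3) {
    stop_miract("expression TSV needs a gene_id column and at least 2 samples",
                "parse")
  }
  gene_ids <- as.character(raw[[1]])
  sample_ids <- names(raw)[-1]
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_miract(sprintf(
      "non-numeric expression value '%s' at gene '%s', sample '%s'",
      body[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]),
      "parse")
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop_miract(sprintf("missing expression value at gene '%s', sample '%s'",
                        gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]), "parse")
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  num <- shift_nonnegative(num, allow_shift)
  out <- tibble(gene_id = gene_ids)
  out <- dplyr::bind_cols(out, as_tibble(num, .name_repair = "minimal"))
  validate_expression(out)
  out
}

# enforce non-negativity, optionally by a global shift (two-colour data)
shift_nonnegative <- function(num, allow_shift) {
  mn <- min(num)
  if (mn < 0) {
    if (!allow_shift) {
      bad <- which(num == mn, arr.ind = TRUE)[1, ]
      stop_miract(sprintf(
        "negative expression value %g at gene '%s', sample '%s' (set allow_shift = TRUE to shift the table)",
        mn, rownames(num)[bad[1]], colnames(num)[bad[2]]), "negative")
    }
    warn(sprintf(
      "[miract] expression table contains negatives; shifted all values by %g so the minimum is 0",
      -mn))
    num <- num - mn
  }
  num
}

# shared invariant checks for an expression tibble
validate_expression <- function(expr) {
  gene_ids <- expr$gene_id
  if (anyDuplicated(gene_ids)) {
    stop_miract(sprintf("duplicate gene identifier '%s'",
                        gene_ids[duplicated(gene_ids)][1]), "ids")
  }
  if (anyDuplicated(names(expr))) {
    stop_miract(sprintf("duplicate sample identifier '%s'",
                        names(expr)[duplicated(names(expr))][1]), "ids")
  }
  m <- expr_values(expr)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop_miract("need at least 2 genes and 2 samples", "shape")
  }
  if (min(m) < 0) {
    stop_miract("expression matrix has negative entries", "negative")
  }
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    stop_miract(sprintf("gene '%s' has zero total expression",
                        gene_ids[which(rs <= 0)[1]]), "zero_row")
  }
  invisible(expr)
}

# numeric matrix view of an expression tibble (genes x samples)
expr_values <- function(expr) {
  m <- as.matrix(expr[, setdiff(names(expr), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: round-tripping preserves values and
#' identifier order.
#'
#' @param expr Expression tibble (`gene_id` + numeric sample columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Collapse probe-level expression to gene level
#'
#' Microarray platforms measure probes, not genes. Probes annotated to more
#' than one gene are discarded as ambiguous; probes absent from the map are
#' dropped (the count is logged); where several probes remain for one gene
#' their rows are averaged arithmetically, per sample. Genes appear in the
#' order of their first surviving probe.
#'
#' @param probe_expr Probe-level expression tibble (`gene_id` column holds
#'   probe identifiers).
#' @param probe_map Data frame with columns `probe_id` and `gene_id`; a probe
#'   mapping to several genes occupies several rows.
#' @return Gene-level expression tibble.
#' @export
collapse_probes <- function(probe_expr, probe_map) {
  probe_map <- as_tibble(probe_map)
  if (!all(c("probe_id", "gene_id") %in% names(probe_map))) {
    stop_miract("probe_map needs columns probe_id and gene_id", "parse")
  }
  probe_map <- dplyr::distinct(probe_map, .data$probe_id, .data$gene_id)
  multi <- probe_map |>
    dplyr::count(.data$probe_id) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::pull(.data$probe_id)
  map1 <- dplyr::filter(probe_map, !.data$probe_id %in% multi)

  probes <- probe_expr$gene_id
  n_unmapped <- sum(!probes %in% probe_map$probe_id)
  if (n_unmapped > 0) {
    miract_log("collapse_probes: dropped %d probe(s) absent from the map",
               n_unmapped)
  }
  keep <- probes %in% map1$probe_id
  if (!any(keep)) {
    stop_miract("no probe survives the probe map filter", "empty")
  }
  m <- expr_values(probe_expr)[keep, , drop = FALSE]
  gene_of <- map1$gene_id[match(rownames(m), map1$probe_id)]
  gene_order <- unique(gene_of)
  sums <- rowsum(m, group = gene_of, reorder = FALSE)
  counts <- as.vector(table(factor(gene_of, levels = rownames(sums))))
  means <- sums / counts
  out <- tibble(gene_id = rownames(means))
  out <- dplyr::bind_cols(out, as_tibble(means, .name_repair = "minimal"))
  out[match(gene_order, out$gene_id), , drop = FALSE]
}

#' Read miRNA target-prediction records
#'
#' Parses a long-format prediction file: one line per predicted miRNA-gene
#' interaction, columns `mirna_id`, `gene_id` and optionally `site_count`
#' (number of predicted target sites in the gene's 3'UTR; defaults to 1).
#' Lines starting with `#` are skipped; a header line naming the columns is
#' recognised and skipped too.
#'
#' @param path Path to a 2- or 3-column TSV.
#' @return A tibble with columns `mirna_id`, `gene_id`, `site_count`.
#' @seealso [build_target_table()]
#' @export
read_target_records <- function(path) {
  if (!file.exists(path)) {
    stop_miract(sprintf("target file not found: '%s'", path), "io")
  }
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) > 0 && startsWith(lines[1], "mirna_id")) {
    lines <- lines[-1]
    line_no <- line_no[-1]
  }
  if (length(lines) == 0) {
    stop_miract("no target records in file", "empty")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2 | nf > 3)) {
    stop_miract(sprintf("line %d: expected 2 or 3 tab-separated fields",
                        line_no[which(nf < 2 | nf > 3)[1]]), "parse")
  }
  mirna <- vapply(fields, `[[`, "", 1)
  gene <- vapply(fields, `[[`, "", 2)
  count_chr <- vapply(fields, function(f) if (length(f) >= 3) f[[3]] else "1",
                      "")
  count <- suppressWarnings(as.numeric(count_chr))
  bad <- which(is.na(count) | count < 1 | count != round(count))
  if (length(bad) > 0) {
    stop_miract(sprintf("line %d: site_count '%s' is not a positive integer",
                        line_no[bad[1]], count_chr[bad[1]]), "parse")
  }
  tibble(mirna_id = mirna, gene_id = gene, site_count = as.integer(count))
}

#' Build a gene x miRNA target-site count table
#'
#' Aggregates long-format target records into the frequency table of
#' predicted target sites per gene that the coupling consumes: rows are
#' genes, columns are miRNAs, cells the summed site counts. Row and column
#' order follow first appearance in the record stream, so the construction is
#' order-insensitive only up to a consistent reindexing.
#'
#' @param records Tibble of records as returned by [read_target_records()].
#' @param source_label Name of the prediction program the records came from
#'   (kept as the table's `source_label` attribute and used to label ranked
#'   lists downstream).
#' @param binarize If `TRUE` every (gene, miRNA) pair with at least one site
#'   contributes 1 instead of its summed site count. Programs reporting
#'   multiple sites per gene (e.g. miRanda-style output) can be flattened to
#'   presence/absence this way.
#' @return A tibble with column `gene_id` and one integer column per miRNA,
#'   `source_label` attribute set. Every row and column sum is at least 1 by
#'   construction.
#' @export
build_target_table <- function(records, source_label = "targets",
                               binarize = FALSE) {
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    stop_miract("empty target record list", "empty")
  }
  if (!all(c("mirna_id", "gene_id") %in% names(records))) {
    stop_miract("records need columns mirna_id and gene_id", "parse")
  }
  if (!"site_count" %in% names(records)) {
    records$site_count <- 1L
  }
  if (any(records$site_count < 1)) {
    stop_miract("site_count must be >= 1", "parse")
  }
  gene_lv <- unique(records$gene_id)
  mirna_lv <- unique(records$mirna_id)
  counts <- matrix(0, nrow = length(gene_lv), ncol = length(mirna_lv),
                   dimnames = list(gene_lv, mirna_lv))
  idx <- cbind(match(records$gene_id, gene_lv),
               match(records$mirna_id, mirna_lv))
  for (k in seq_len(nrow(records))) {
    counts[idx[k, 1], idx[k, 2]] <- counts[idx[k, 1], idx[k, 2]] +
      records$site_count[k]
  }
  if (binarize) counts <- (counts > 0) * 1
  out <- tibble(gene_id = gene_lv)
  out <- dplyr::bind_cols(out, as_tibble(counts, .name_repair = "minimal"))
  attr(out, "source_label") <- source_label
  out
}

# numeric matrix view of a target table (genes x miRNAs)
target_values <- function(targets) {
  m <- as.matrix(targets[, setdiff(names(targets), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- targets$gene_id
  m
}

# source_label attribute with a fallback (attributes are lost by many verbs)
target_label <- function(targets, default = "targets") {
  lbl <- attr(targets, "source_label")
  if (is.null(lbl)) default else lbl
}

#' Align an expression matrix and a target table on shared genes
#'
#' Restricts both tables to the genes present in both, in
#' expression-matrix order (the authoritative gene order downstream).
#' miRNA columns whose site total drops to zero on the shared gene set are
#' removed with a warning. The analysis is refused when fewer than 3 genes
#' are shared.
#'
#' @param expr Expression tibble.
#' @param targets Target count tibble from [build_target_table()].
#' @return A list of class `"aligned_tables"` with elements `expression`,
#'   `targets`, `n_shared` and `source_label`.
#' @export
align_tables <- function(expr, targets) {
  validate_expression(expr)
  shared <- intersect(expr$gene_id, targets$gene_id)
  if (length(shared) < 3) {
    stop_miract(sprintf(
      "only %d gene(s) shared between expression and target tables; need >= 3",
      length(shared)), "alignment")
  }
  expr2 <- expr[expr$gene_id %in% shared, , drop = FALSE]
  targets2 <- targets[match(expr2$gene_id, targets$gene_id), , drop = FALSE]
  tm <- target_values(targets2)
  zero_col <- colSums(tm) == 0
  if (any(zero_col)) {
    warn(sprintf(
      "[miract] dropped %d miRNA column(s) with no target sites on the %d shared genes: %s",
      sum(zero_col), length(shared),
      paste(colnames(tm)[zero_col], collapse = ", ")))
    targets2 <- targets2[, c(TRUE, !zero_col), drop = FALSE]
  }
  miract_log("align_tables: %d shared genes, %d miRNAs retained",
             length(shared), ncol(targets2) - 1L)
  structure(list(expression = expr2, targets = targets2,
                 n_shared = length(shared),
                 source_label = target_label(targets)),
            class = "aligned_tables")
}

#' @export
print.aligned_tables <- function(x, ...) {
  cat(sprintf(
    "Aligned tables (%s): %d shared genes, %d samples, %d miRNAs\n",
    x$source_label, x$n_shared, ncol(x$expression) - 1L,
    ncol(x$targets) - 1L))
  invisible(x)
}

#' Read a sample-to-group assignment
#'
#' @param path 2-column TSV (`sample_id`, `group`); a header line naming the
#'   columns is recognised.
#' @return Tibble with columns `sample_id` and `group`.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) {
    stop_miract(sprintf("group file not found: '%s'", path), "io")
  }
  g <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(g))) {
    g <- readr::read_tsv(path, col_names = c("sample_id", "group"),
                         col_types = "cc", progress = FALSE)
  }
  g
}

# validate a group assignment against a set of sample ids; returns the
# group factor in sample order plus the ordered distinct labels
match_groups <- function(groups, sample_ids, min_groups = 2L) {
  groups <- as_tibble(groups)
  missing <- setdiff(sample_ids, groups$sample_id)
  if (length(missing) > 0) {
    stop_miract(sprintf("sample '%s' has no group assignment", missing[1]),
                "groups")
  }
  lab <- groups$group[match(sample_ids, groups$sample_id)]
  levels <- unique(groups$group)
  present <- unique(lab)
  if (length(present) < min_groups) {
    stop_miract(sprintf("need >= %d non-empty groups, found %d", min_groups,
                        length(present)), "groups")
  }
  list(labels = lab, levels = levels[levels %in% present])
}
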