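#' Classify cell lines as resistant or sensitive by the SD rule
#'
#' Cell lines whose log10 GI50 is at least `multiplier` sample standard
#' deviations above the per-drug mean are resistant (more drug is needed for
#' 50% growth inhibition); those at least `multiplier` SDs below the mean
#' are sensitive. Mean and SD (n-1 denominator) are computed over present
#' values only; cell lines with missing GI50 are excluded from the
#' calculation and from both groups.
#'
#' @param gi50_row Named numeric vector of log10 GI50 values for one drug.
#' @param multiplier SD multiplier (default 0.8).
#' @param drug_id Optional drug identifier stored in the result.
#' @return A list of class `"sensitivity_groups"` with elements `drug_id`,
#'   `resistant`, `sensitive` (cell identifier vectors), `rule`,
#'   `threshold_used`, `mean_gi50`, `sd_gi50`, `n_used`; or `NULL` (with a
#'   message) when fewer than 3 values are present.
#' @export
classify_by_sd <- function(gi50_row, multiplier = 0.8, drug_id = NA_character_) {
  stopifnot(multiplier >= 0)
  vals <- gi50_row[is.finite(gi50_row)]
  if (length(vals) < 3L) {
    .msg("drug ", drug_id, " skipped: only ", length(vals),
         " present GI50 values (need >= 3 for the SD rule)")
    return(NULL)
  }
  m <- mean(vals)
  s <- stats::sd(vals)
  res <- vals >= m + multiplier * s
  sen <- vals <= m - multiplier * s
  # a cell can satisfy both only at the degenerate threshold 0 (SD 0 or
  # multiplier 0, value at the mean); such cells stay unassigned so the
  # groups are always disjoint
  both <- res & sen
  structure(list(drug_id = drug_id,
                 resistant = names(vals)[res & !both],
                 sensitive = names(vals)[sen & !both],
                 rule = "sd",
                 threshold_used = multiplier,
                 mean_gi50 = m,
                 sd_gi50 = s,
                 n_used = length(vals)),
            class = "sensitivity_groups")
}

#' Classify cell lines as resistant or sensitive by the fold-change rule
#'
#' A cell line whose GI50 is at least `fold`-fold above the average GI50
#' for the drug is resistant; at least `fold`-fold below, sensitive.
#' Applied on the log10 scale: `|log10 GI50 - mean(log10 GI50)| >=
#' log10(fold)`, i.e. fold change relative to the geometric-mean GI50.
#'
#' @param gi50_row Named numeric vector of log10 GI50 values for one drug.
#' @param fold Fold-change threshold, must exceed 1 (default 6).
#' @param drug_id Optional drug identifier.
#' @return A `"sensitivity_groups"` list (see [classify_by_sd()]); `NULL`
#'   with a message when fewer than 2 values are present.
#' @export
classify_by_fold <- function(gi50_row, fold = 6, drug_id = NA_character_) {
  if (!is.finite(fold) || fold <= 1) stop("fold threshold must be > 1")
  vals <- gi50_row[is.finite(gi50_row)]
  if (length(vals) < 2L) {
    .msg("drug ", drug_id, " skipped: only ", length(vals),
         " present GI50 values (need >= 2 for the fold rule)")
    return(NULL)
  }
  m <- mean(vals)
  thr <- log10(fold)
  structure(list(drug_id = drug_id,
                 resistant = names(vals)[vals - m >= thr],
                 sensitive = names(vals)[m - vals >= thr],
                 rule = "fold",
                 threshold_used = fold,
                 mean_gi50 = m,
                 sd_gi50 = NA_real_,
                 n_used = length(vals)),
            class = "sensitivity_groups")
}

#' Keep drugs with enough cell lines in both sensitivity groups
#'
#' @param groups List of `"sensitivity_groups"` (NULL entries are dropped).
#' @param min_size Minimum size required of both the resistant and the
#'   sensitive group (default 6).
#' @return The filtered list; counts kept/dropped are reported via
#'   `message()`.
#' @export
filter_drugs <- function(groups, min_size = 6L) {
  groups <- Filter(Negate(is.null), groups)
  keep <- vapply(groups, function(g) {
    length(g$resistant) >= min_size && length(g$sensitive) >= min_size
  }, logical(1L))
  .msg("drug filter (>= ", min_size, " per group): kept ", sum(keep),
       " of ", length(groups), " drugs")
  groups[keep]
}

#' Rank cell lines by one gene's expression into high and low groups
#'
#' Cells are sorted by the gene's expression in descending order, ties
#' broken by cell identifier (lexicographic) so the partition is
#' deterministic; the first `k` cells form the high-expression group and
#' the last `k` the low-expression group.
#'
#' @param expr Genes x cells numeric matrix (or `"expression_set"`).
#' @param gene_id Gene to rank by; unknown gene is an error.
#' @param k Group size; `2 * k` must not exceed the number of cells.
#' @return List with character vectors `high` and `low`.
#' @export
rank_cells_by_gene <- function(expr, gene_id, k = 15L) {
  values <- if (is.list(expr)) expr$values else expr
  if (!gene_id %in% rownames(values)) {
    stop("unknown gene: ", gene_id)
  }
  n <- ncol(values)
  if (2L * k > n) stop("2*k exceeds the number of cells (", n, ")")
  v <- values[gene_id, ]
  ord <- order(-v, colnames(values), method = "radix")
  ids <- colnames(values)[ord]
  list(high = ids[seq_len(k)], low = ids[seq.int(n - k + 1L, n)])
}

#' Compare drug response between two cell groups
#'
#' Tests whether the mean log10 GI50 differs between two groups of cell
#' lines (e.g. high versus low expressors of a metastasis suppressor gene)
#' using the same equal-variance two-sample t engine as the per-gene
#' signatures.
#'
#' @param high,low Character vectors of cell identifiers.
#' @param gi50_row Named numeric log10 GI50 vector for one drug.
#' @param var_equal Equal-variance Student t (default) or Welch.
#' @return List with `delta_mean` (mean GI50 high minus low), `p`, and the
#'   group sizes used; `NULL` with a message when either group has fewer
#'   than 2 present values.
#' @export
compare_group_response <- function(high, low, gi50_row, var_equal = TRUE) {
  a <- gi50_row[intersect(high, names(gi50_row))]
  b <- gi50_row[intersect(low, names(gi50_row))]
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    .msg("group response comparison skipped: fewer than 2 present GI50 ",
         "values in a group")
    return(NULL)
  }
  res <- .row_t_stats(matrix(c(a, b), nrow = 1L),
                      seq_along(a), length(a) + seq_along(b),
                      var_equal = var_equal)
  list(delta_mean = res$mean_diff[1L], p = res$p[1L],
       n_high = length(a), n_low = length(b))
}
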