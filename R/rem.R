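#' Build a drug-specific response engineering module (REM)
#'
#' The resistance-minus-sensitive signature for one drug: the set of genes
#' that satisfy both REM criteria, (i) expression differs significantly
#' between resistant and sensitive cell lines (two-sample t-test,
#' `p < alpha`), and (ii) expression correlates significantly with log10
#' GI50 across the grouped cells (Pearson by default, `p < alpha`).
#' `v_rem = s * (1 - p)` is signed resistant-minus-sensitive: positive
#' values mean higher expression in resistant cells.
#'
#' @param expr Genes x cells numeric matrix (or `"expression_set"`) whose
#'   columns are cell-line identifiers.
#' @param groups A `"sensitivity_groups"` object (see [classify_by_sd()]).
#' @param gi50_row Named numeric log10 GI50 vector for the drug.
#' @param alpha Significance threshold applied to both criteria
#'   (default 0.05).
#' @param min_group_size Minimum resistant and sensitive group size
#'   (default 6); smaller groups are a hard error.
#' @param cor_method `"pearson"` (default) or `"spearman"` for
#'   criterion (ii).
#' @param cor_cells `"grouped"` (default; union of the two groups) or
#'   `"all"` (every cell with both expression and GI50 present).
#' @param var_equal Equal-variance t-test (default) or Welch.
#' @return A list of class `"rem"`: `drug_id`, `genes` (data.frame with
#'   `gene_id`, `v_rem`, `r_gi50`, `p_gi50`, plus the criterion-(i) `p_group`
#'   and `q_group` reported for transparency), `n_resistant`, `n_sensitive`,
#'   `alpha`, `stats` (the same columns for every tested gene, with a
#'   logical `in_rem`). An empty REM is valid and reported with a message.
#' @export
build_rem <- function(expr, groups, gi50_row, alpha = 0.05,
                      min_group_size = 6L,
                      cor_method = c("pearson", "spearman"),
                      cor_cells = c("grouped", "all"),
                      var_equal = TRUE) {
  cor_method <- match.arg(cor_method)
  cor_cells <- match.arg(cor_cells)
  values <- if (is.list(expr)) expr$values else expr
  res_cells <- intersect(groups$resistant, colnames(values))
  sen_cells <- intersect(groups$sensitive, colnames(values))
  if (length(res_cells) < min_group_size ||
      length(sen_cells) < min_group_size) {
    stop("drug ", groups$drug_id, ": needs at least ", min_group_size,
         " resistant and sensitive cell lines with expression (got ",
         length(res_cells), " and ", length(sen_cells), ")")
  }
  tt <- two_group_test(values, res_cells, sen_cells, var_equal = var_equal)

  cells <- if (cor_cells == "grouped") {
    c(res_cells, sen_cells)
  } else {
    intersect(colnames(values), names(gi50_row)[is.finite(gi50_row)])
  }
  g <- gi50_row[cells]
  if (any(!is.finite(g))) {
    stop("drug ", groups$drug_id, ": missing GI50 for grouped cell(s) ",
         paste(cells[!is.finite(g)], collapse = ", "))
  }
  x <- values[tt$gene_id, cells, drop = FALSE]
  ok <- rowSums(is.na(x)) == 0L
  tt <- tt[ok, , drop = FALSE]
  x <- x[ok, , drop = FALSE]
  ct <- .row_cor_test(x, g, method = cor_method)

  stats_tab <- data.frame(gene_id = tt$gene_id,
                          v_rem = v_statistic(tt$p, tt$s),
                          r_gi50 = ct$r,
                          p_gi50 = ct$p,
                          p_group = tt$p,
                          q_group = as.numeric(storey_qvalues(tt$p)),
                          row.names = NULL, stringsAsFactors = FALSE)
  in_rem <- stats_tab$p_group < alpha &
    !is.na(stats_tab$p_gi50) & stats_tab$p_gi50 < alpha
  stats_tab$in_rem <- in_rem
  if (!any(in_rem)) {
    .msg("drug ", groups$drug_id, ": empty REM at alpha = ", alpha)
  }
  structure(list(drug_id = groups$drug_id,
                 genes = stats_tab[in_rem,
                                   c("gene_id", "v_rem", "r_gi50", "p_gi50",
                                     "p_group", "q_group"),
                                   drop = FALSE],
                 n_resistant = length(res_cells),
                 n_sensitive = length(sen_cells),
                 alpha = alpha,
                 cor_method = cor_method,
                 cor_cells = cor_cells,
                 stats = stats_tab),
            class = "rem")
}

#' Pair a REM's v values with a signature's v values
#'
#' Produces the ordered `(v_rem, v_sig)` pairs over the genes shared by a
#' REM and a signature (e.g. an induction signature), in the REM's stable
#' gene order. Missing genes are dropped with a message reporting the count.
#'
#' @param rem A `"rem"` object from [build_rem()].
#' @param signature Signature data.frame with `gene_id` and `v` columns.
#' @return Data.frame with columns `gene_id`, `v_rem`, `v_sig`.
#' @export
rem_v_vector <- function(rem, signature) {
  if (nrow(rem$genes) == 0L) {
    stop("drug ", rem$drug_id, ": REM is empty")
  }
  idx <- match(rem$genes$gene_id, signature$gene_id)
  missing <- is.na(idx)
  if (all(missing)) {
    stop("drug ", rem$drug_id,
         ": no REM genes present in the signature")
  }
  if (any(missing)) {
    .msg("drug ", rem$drug_id, ": ", sum(missing),
         " REM gene(s) absent from the signature, dropped")
  }
  data.frame(gene_id = rem$genes$gene_id[!missing],
             v_rem = rem$genes$v_rem[!missing],
             v_sig = signature$v[idx[!missing]],
             row.names = NULL, stringsAsFactors = FALSE)
}
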