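#' Correlate an induction signature with a drug REM
#'
#' Pearson correlation of the paired v values with two-sided significance
#' from the t-transform. A significant negative correlation means the
#' induction opposes the resistance signature, so inducing the factor is
#' predicted to sensitize resistant cells to the drug; a significant
#' positive correlation predicts sensitization on repression instead.
#'
#' @param paired Data.frame with columns `v_rem` and `v_sig` (see
#'   [rem_v_vector()]); at least 3 pairs.
#' @param alpha Significance threshold for a call (default 0.001).
#' @param drug_id,factor_id Optional labels carried into the result.
#' @return A list of class `"comparison_result"`: `drug_id`, `factor_id`,
#'   `n_genes`, `r`, `p_r`, `call` (one of
#'   `"predict_sensitization_on_induction"`,
#'   `"predict_sensitization_on_repression"`, `"no_call"`). Zero variance in
#'   either vector yields `r = NA` and `no_call` with a message.
#' @export
correlate_signatures <- function(paired, alpha = 0.001,
                                 drug_id = NA_character_,
                                 factor_id = NA_character_) {
  if (nrow(paired) < 3L) stop("need at least 3 (v_rem, v_sig) pairs")
  out <- list(drug_id = drug_id, factor_id = factor_id,
              n_genes = nrow(paired), r = NA_real_, p_r = NA_real_,
              call = "no_call")
  if (stats::sd(paired$v_rem) == 0 || stats::sd(paired$v_sig) == 0) {
    .msg("correlation undefined (zero variance in a v-vector): no call")
    class(out) <- "comparison_result"
    return(out)
  }
  ct <- .cor_test_pair(paired$v_sig, paired$v_rem)
  out$r <- ct$r
  out$p_r <- ct$p
  if (is.finite(ct$p) && ct$p < alpha) {
    out$call <- if (ct$r < 0) {
      "predict_sensitization_on_induction"
    } else {
      "predict_sensitization_on_repression"
    }
  }
  class(out) <- "comparison_result"
  out
}

#' Screen a factor's induction signature against many drug REMs
#'
#' @param induction An induction signature: either the list returned by
#'   [induction_signature()] or its `signature` data.frame.
#' @param rems List of `"rem"` objects.
#' @param alpha Significance threshold for calls (default 0.001).
#' @param factor_id Label for the factor.
#' @return Data.frame with one row per comparable REM (columns `factor_id`,
#'   `drug_id`, `n_genes`, `r`, `p_r`, `call`), sorted by `r` ascending so
#'   the strongest anti-correlations come first. REMs with no genes in the
#'   signature are skipped with a message.
#' @export
screen_factor <- function(induction, rems, alpha = 0.001,
                          factor_id = "factor") {
  if (length(rems) < 1L) stop("need at least one REM")
  sig <- if (is.data.frame(induction)) induction else induction$signature
  rows <- lapply(rems, function(rem) {
    paired <- tryCatch(rem_v_vector(rem, sig), error = function(e) {
      .msg("drug ", rem$drug_id, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(paired)) return(NULL)
    if (nrow(paired) < 3L) {
      .msg("drug ", rem$drug_id, " skipped: only ", nrow(paired),
           " gene(s) shared with the signature (need >= 3)")
      return(NULL)
    }
    res <- correlate_signatures(paired, alpha = alpha,
                                drug_id = rem$drug_id,
                                factor_id = factor_id)
    data.frame(factor_id = factor_id, drug_id = rem$drug_id,
               n_genes = res$n_genes, r = res$r, p_r = res$p_r,
               call = res$call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(factor_id = character(), drug_id = character(),
                      n_genes = integer(), r = numeric(), p_r = numeric(),
                      call = character(), stringsAsFactors = FALSE))
  }
  out[order(out$r, out$drug_id), , drop = FALSE]
}

#' Two-dimensional unsupervised hierarchical clustering of a matrix
#'
#' Average-linkage agglomerative clustering on both axes with the
#' uncentered-correlation distance `1 - sum(xy) / sqrt(sum(x^2) sum(y^2))`
#' (the convention of the classic microarray clustering tools). Missing
#' entries are permitted; distances use pairwise-complete entries, and a
#' row or column sharing fewer than 2 complete entries with every other is
#' dropped with a message. Leaf order is deterministic for a given input.
#'
#' @param m Numeric matrix with unique dimnames, at least 2 x 2 (a
#'   dose-response or expression matrix).
#' @return A list of class `"cluster_view"`: `row_order`, `col_order`
#'   (label permutations), `row_hclust`, `col_hclust`, and `matrix` (the
#'   input reordered; values preserved).
#' @export
cluster_heatmap <- function(m) {
  if (is.list(m)) m <- m$values
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need at least 2 rows and 2 columns")
  rows <- .drop_disconnected(m, "row")
  m <- m[rows, , drop = FALSE]
  cols <- .drop_disconnected(t(m), "column")
  m <- m[, cols, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("fewer than 2 connected rows/columns remain after dropping")
  }
  hr <- stats::hclust(.uncentered_dist(m), method = "average")
  hc <- stats::hclust(.uncentered_dist(t(m)), method = "average")
  ro <- rownames(m)[hr$order]
  co <- colnames(m)[hc$order]
  structure(list(row_order = ro, col_order = co,
                 row_hclust = hr, col_hclust = hc,
                 matrix = m[ro, co, drop = FALSE]),
            class = "cluster_view")
}

#' Plot a clustered heatmap
#'
#' Renders the reordered matrix of a [cluster_heatmap()] result with
#' missing entries in white.
#'
#' @param x A `"cluster_view"` object.
#' @param col Color palette for present values.
#' @param main Plot title.
#' @param ... Further arguments passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.cluster_view <- function(x, col = grDevices::hcl.colors(64, "Blue-Red"),
                              main = "", ...) {
  m <- x$matrix
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                  col = col, axes = FALSE, xlab = "", ylab = "",
                  main = main, useRaster = FALSE, ...)
  invisible(x)
}

# Uncentered-correlation distance between the rows of m, with
# pairwise-complete handling of missing values, fully vectorized:
# shared-entry cross products via masked matrix multiplication.
.uncentered_dist <- function(m) {
  w <- !is.na(m)
  x <- m
  x[!w] <- 0
  x2 <- x^2
  cross <- tcrossprod(x)
  sx2 <- tcrossprod(x2, w * 1)     # sum of x^2 over entries shared with y
  sy2 <- t(sx2)
  denom <- sqrt(sx2 * sy2)
  r <- ifelse(denom > 0, cross / denom, 0)
  d <- 1 - r
  d[d < 0] <- 0
  diag(d) <- 0
  stats::as.dist(d)
}

.drop_disconnected <- function(m, axis) {
  w <- (!is.na(m)) * 1
  overlap <- tcrossprod(w)
  diag(overlap) <- 0
  ok <- apply(overlap, 1L, max) >= 2
  if (!all(ok)) {
    .msg(sum(!ok), " ", axis, "(s) dropped: fewer than 2 ",
         "pairwise-complete entries with every other ", axis)
  }
  rownames(m)[ok]
}
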