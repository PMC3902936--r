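#' Per-gene two-group test on an expression matrix
#'
#' Student's equal-variance two-sample t-test (Welch selectable) for every
#' gene between two sample groups. The sign `s` is the sign of
#' `mean(group_a) - mean(group_b)`. Genes with missing values among the
#' samples used are dropped from the contrast with a message. Degenerate
#' genes: zero pooled variance with equal means gives `p = 1, s = 0`; zero
#' variance with unequal means gives the smallest representable positive p.
#'
#' @param expr Genes x samples numeric matrix (or `"expression_set"`).
#' @param group_a,group_b Character vectors of column (sample) identifiers;
#'   at least 2 each.
#' @param var_equal Equal-variance Student t (default `TRUE`) or Welch.
#' @return A data.frame with columns `gene_id`, `mean_diff`, `s`, `p`.
#' @export
two_group_test <- function(expr, group_a, group_b, var_equal = TRUE) {
  values <- if (is.list(expr)) expr$values else expr
  missing_cols <- setdiff(c(group_a, group_b), colnames(values))
  if (length(missing_cols) > 0L) {
    stop("unknown sample(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- values[, c(group_a, group_b), drop = FALSE]
  ok <- rowSums(is.na(x)) == 0L
  if (!all(ok)) {
    .msg(sum(!ok), " gene(s) dropped from contrast (missing values)")
    x <- x[ok, , drop = FALSE]
  }
  res <- .row_t_stats(x, seq_along(group_a),
                      length(group_a) + seq_along(group_b),
                      var_equal = var_equal)
  data.frame(gene_id = rownames(x), mean_diff = res$mean_diff,
             s = as.integer(res$s), p = res$p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signed differential statistic v
#'
#' `v = s * (1 - p)`: the extent to which a gene is up- (`v > 0`) or
#' down-regulated (`v < 0`) in the first group relative to the second, with
#' maximal and minimal values 1 and -1 as `p` approaches 0 and `v = 0` when
#' there is no evidence (`p = 1`) or no direction (`s = 0`).
#'
#' @param p P-value(s) in (0, 1].
#' @param s Sign(s) in \{-1, 0, +1\}.
#' @return Numeric vector of v values in \[-1, 1\].
#' @export
v_statistic <- function(p, s) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p must lie in (0, 1]")
  }
  if (!all(s %in% c(-1, 0, 1))) stop("s must be in {-1, 0, +1}")
  s * (1 - p)
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0, 0.05, ..., 0.90
#' with a natural-cubic-spline fit extrapolated to lambda = 1 (clipped to
#' (0, 1\]), then computes `q_i = min over p_j >= p_i of pi0 * m * p_j /
#' rank(p_j)`. With fewer than 100 p-values the spline is unstable, so
#' pi0 = 1 is used (equivalent to Benjamini-Hochberg) with a message.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param pi0 Optional fixed pi0 override (e.g. 1 for BH-equivalent
#'   q-values); default `NULL` estimates it.
#' @return Numeric vector of q-values, same order as the input; the pi0
#'   used is attached as attribute `"pi0"`.
#' @export
storey_qvalues <- function(p_values, pi0 = NULL) {
  p <- p_values
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100L) {
      .msg("fewer than 100 p-values: using conservative pi0 = 1")
      pi0 <- 1
    } else {
      lambda <- seq(0, 0.90, by = 0.05)
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1L))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = 1)$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  } else {
    stopifnot(pi0 > 0, pi0 <= 1)
  }
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  ranks <- m:1L  # rank of each sorted p, largest first
  q[ord] <- cummin(pi0 * m * p[ord] / ranks)
  q <- pmin(q, 1)
  attr(q, "pi0") <- pi0
  q
}

#' Build the full signed signature for a two-group contrast
#'
#' Convenience wrapper combining [two_group_test()], [storey_qvalues()] and
#' [v_statistic()] into the per-gene table used throughout the pipeline.
#'
#' @inheritParams two_group_test
#' @param contrast_id Label stored as attribute `"contrast_id"`.
#' @return Data.frame with columns `gene_id`, `mean_diff`, `s`, `p`, `q`,
#'   `v` (sign convention: positive = higher in `group_a`).
#' @export
build_signature <- function(expr, group_a, group_b,
                            contrast_id = NA_character_, var_equal = TRUE) {
  tab <- two_group_test(expr, group_a, group_b, var_equal = var_equal)
  tab$q <- as.numeric(storey_qvalues(tab$p))
  tab$v <- v_statistic(tab$p, tab$s)
  attr(tab, "contrast_id") <- contrast_id
  tab
}

#' Induction signature: induced versus control contrast
#'
#' Builds the full v signature of an induction experiment (sign convention:
#' positive v = up-regulated after induction) and reports how many genes
#' pass the differential-expression filter `p < alpha` and `q < fdr_max`,
#' split by direction.
#'
#' @param expr Genes x samples matrix or `"expression_set"`.
#' @param control,induced Character vectors of replicate column names
#'   (at least 2 each).
#' @param alpha Per-gene p threshold (default 0.01).
#' @param fdr_max Maximum q-value (default 0.10).
#' @param contrast_id Label for the signature.
#' @inheritParams two_group_test
#' @return List with `signature` (data.frame as [build_signature()]),
#'   `n_up`, `n_down`, and `contrast_id`.
#' @export
induction_signature <- function(expr, control, induced, alpha = 0.01,
                                fdr_max = 0.10,
                                contrast_id = "induction",
                                var_equal = TRUE) {
  if (length(control) < 2L || length(induced) < 2L) {
    stop("need at least 2 replicates per arm")
  }
  sig <- build_signature(expr, group_a = induced, group_b = control,
                         contrast_id = contrast_id, var_equal = var_equal)
  pass <- sig$p < alpha & sig$q < fdr_max
  list(signature = sig,
       n_up = sum(pass & sig$s > 0),
       n_down = sum(pass & sig$s < 0),
       contrast_id = contrast_id)
}

#' Chi-square test of a gene set against the random-set expectation
#'
#' Counts how many members of a candidate gene set are differentially
#' expressed (`p < alpha`) in a signature, estimates the random expectation
#' as the mean count over `n_random` same-size gene sets drawn uniformly
#' without replacement from all profiled genes, and compares observed to
#' expected with a 1-df chi-square on the \{differential, non-differential\}
#' split. A two-sided exact binomial test with success probability
#' `expected / k` is reported as a cross-check.
#'
#' @param signature Signature data.frame with columns `gene_id` and `p`
#'   (e.g. from [build_signature()]).
#' @param gene_set A gene set (list with `name`, `genes`) or a character
#'   vector of gene identifiers.
#' @param alpha Differential-expression threshold (default 0.05).
#' @param n_random Number of random sets (default 10).
#' @param seed Integer seed for the random draws (the caller's RNG state is
#'   restored afterwards).
#' @return List of class `"gene_set_null_result"`: `set_name`,
#'   `set_size` (members found in the signature), `observed_count`,
#'   `expected_count`, `n_random_sets`, `chi2`, `p_chi2`, `p_binom`,
#'   `unreliable` (TRUE when an expected cell is below 1), `min_p_member`.
#' @export
gene_set_null_test <- function(signature, gene_set, alpha = 0.05,
                               n_random = 10L, seed = 1L) {
  stopifnot(n_random >= 1L)
  genes <- if (is.list(gene_set)) gene_set$genes else gene_set
  set_name <- if (is.list(gene_set)) gene_set$name else NA_character_
  all_genes <- signature$gene_id
  present <- intersect(genes, all_genes)
  dropped <- length(genes) - length(present)
  if (dropped > 0L) {
    .msg("gene set '", set_name, "': ", dropped,
         " member(s) absent from the signature, dropped")
  }
  if (length(present) == 0L) {
    stop("gene set has no members among the profiled genes")
  }
  k <- length(present)
  hit <- stats::setNames(signature$p < alpha, all_genes)
  observed <- sum(hit[present])
  expected <- .with_seed(seed, {
    mean(vapply(seq_len(n_random), function(i) {
      sum(hit[sample(all_genes, k)])
    }, numeric(1L)))
  })
  if (expected <= 0 || expected >= k) {
    chi2 <- if (observed == expected) 0 else Inf
    p_chi2 <- if (observed == expected) 1 else 0
    unreliable <- TRUE
  } else {
    chi2 <- (observed - expected)^2 / expected +
      (observed - expected)^2 / (k - expected)
    p_chi2 <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    unreliable <- expected < 1 || (k - expected) < 1
  }
  p_binom <- if (expected > 0 && expected < k) {
    stats::binom.test(observed, k, p = expected / k)$p.value
  } else {
    NA_real_
  }
  structure(list(set_name = set_name, set_size = k,
                 observed_count = observed, expected_count = expected,
                 n_random_sets = as.integer(n_random),
                 chi2 = chi2, p_chi2 = p_chi2, p_binom = p_binom,
                 unreliable = unreliable,
                 min_p_member = min(signature$p[match(present, all_genes)])),
            class = "gene_set_null_result")
}
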