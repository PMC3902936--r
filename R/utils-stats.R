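# Internal vectorized statistical engines shared across modules.

# Row-wise two-sample t statistics on a genes x samples matrix.
# Equal-variance (Student) by default; Welch via var_equal = FALSE.
# Degenerate rows: zero pooled variance with equal means -> p = 1, s = 0;
# zero variance with unequal means -> p = smallest positive double.
.row_t_stats <- function(x, a_cols, b_cols, var_equal = TRUE) {
  xa <- x[, a_cols, drop = FALSE]
  xb <- x[, b_cols, drop = FALSE]
  na <- ncol(xa)
  nb <- ncol(xb)
  if (na < 2L || nb < 2L) {
    stop("two-group test requires at least 2 samples per group (got ",
         na, " and ", nb, ")")
  }
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  d <- ma - mb
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep.int(na + nb - 2, nrow(x))
  } else {
    se2a <- va / na
    se2b <- vb / nb
    se <- sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
    df[!is.finite(df)] <- na + nb - 2
  }
  t <- d / se
  p <- 2 * stats::pt(-abs(t), df)
  zero_var <- se == 0
  if (any(zero_var)) {
    flat <- zero_var & d == 0
    p[flat] <- 1
    p[zero_var & !flat] <- .Machine$double.xmin
    t[flat] <- 0
  }
  s <- sign(d)
  s[zero_var & d == 0] <- 0
  list(p = p, s = s, mean_diff = d, t = t, df = df)
}

# Row-wise Pearson (or Spearman, by pre-ranking) correlation of each row of
# x against the vector y, with the two-sided p-value from the t-transform
# t = r * sqrt((n-2)/(1-r^2)).
.row_cor_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(y)
  if (ncol(x) != n) stop("ncol(x) must equal length(y)")
  if (n < 3L) stop("correlation test requires at least 3 observations")
  if (method == "spearman") {
    x <- t(apply(x, 1L, rank))
    y <- rank(y)
  }
  xc <- x - rowMeans(x)
  yc <- y - mean(y)
  denom <- sqrt(rowSums(xc^2) * sum(yc^2))
  r <- as.vector(xc %*% yc) / denom
  r[denom == 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  list(r = r, p = p, n = n)
}

# Pearson correlation of two vectors with the t-transform p-value.
.cor_test_pair <- function(x, y) {
  n <- length(x)
  res <- .row_cor_test(matrix(x, nrow = 1L), y)
  list(r = res$r[1L], p = res$p[1L], n = n)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so seeded helpers do not perturb the
# global stream.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.msg <- function(...) message("[remsig] ", ...)
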