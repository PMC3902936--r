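test_that("two-group test matches stats::t.test and handles degeneracy", {
  m <- rand_expr(50, sprintf("s%d", 1:10), seed = 3)
  a <- colnames(m)[1:5]
  b <- colnames(m)[6:10]
  res <- two_group_test(m, a, b)
  # independent oracle: per-gene stats::t.test
  for (i in c(1, 17, 50)) {
    tt <- t.test(m[i, a], m[i, b], var.equal = TRUE)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$mean_diff[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
  }
  w <- two_group_test(m, a, b, var_equal = FALSE)
  for (i in c(2, 31)) {
    tw <- t.test(m[i, a], m[i, b])
    expect_equal(w$p[i], tw$p.value, tolerance = 1e-12)
  }

  # identical groups: p = 1, s = 0
  flat <- matrix(1, 2, 6, dimnames = list(c("g1", "g2"), sprintf("s%d", 1:6)))
  fres <- two_group_test(flat, sprintf("s%d", 1:3), sprintf("s%d", 4:6))
  expect_equal(fres$p, c(1, 1))
  expect_equal(fres$s, c(0L, 0L))

  # zero variance with unequal means: smallest representable positive p
  flat2 <- flat
  flat2[1, 4:6] <- 2
  zres <- two_group_test(flat2, sprintf("s%d", 1:3), sprintf("s%d", 4:6))
  expect_equal(zres$p[1], .Machine$double.xmin)
  expect_equal(zres$s[1], -1L)

  expect_error(two_group_test(m, a, "sX"), "sX")
})

test_that("equal-variance t equals Welch when sample variances are equal", {
  set.seed(5)
  a_vals <- rnorm(6)
  m <- matrix(c(a_vals, a_vals + 1.3), 1, 12,
              dimnames = list("g", sprintf("s%d", 1:12)))
  st <- two_group_test(m, sprintf("s%d", 1:6), sprintf("s%d", 7:12))
  we <- two_group_test(m, sprintf("s%d", 1:6), sprintf("s%d", 7:12),
                       var_equal = FALSE)
  expect_equal(st$p, we$p, tolerance = 1e-10)
})

test_that("t-test agrees with the exhaustive 3v3 permutation oracle", {
  # frozen example: permutation p = 2/20 (only the two extreme assignments)
  a <- c(5, 6, 7); b <- c(1, 2, 3)
  expect_equal(perm_t_pvalue_3v3(a, b), 0.10)
  m <- matrix(c(a, b), 1, 6, dimnames = list("g", sprintf("s%d", 1:6)))
  res <- two_group_test(m, sprintf("s%d", 1:3), sprintf("s%d", 4:6))
  expect_equal(res$p, 2 * pt(-4 / sqrt(2 / 3), df = 4), tolerance = 1e-12)
  expect_lt(res$p, 0.05)

  # rank agreement across random instances
  set.seed(21)
  p_t <- p_perm <- numeric(40)
  for (i in 1:40) {
    x <- rnorm(3, i %% 3, 1); y <- rnorm(3)
    mi <- matrix(c(x, y), 1, 6, dimnames = list("g", sprintf("s%d", 1:6)))
    p_t[i] <- two_group_test(mi, sprintf("s%d", 1:3), sprintf("s%d", 4:6))$p
    p_perm[i] <- perm_t_pvalue_3v3(x, y)
  }
  expect_gt(cor(rank(p_t), rank(p_perm)), 0.9)
})

test_that("v = s(1-p) with bounds, zeros, and exact group-swap antisymmetry", {
  expect_equal(v_statistic(1, 1), 0)
  expect_equal(v_statistic(0.05, 1), 0.95)
  expect_equal(v_statistic(1e-12, -1), -(1 - 1e-12))
  expect_equal(v_statistic(0.3, 0), 0)
  expect_error(v_statistic(0, 1), "0, 1")
  expect_error(v_statistic(1.2, 1), "0, 1")
  expect_error(v_statistic(0.5, 2), "s must be")

  m <- rand_expr(200, sprintf("s%d", 1:12), seed = 9)
  a <- colnames(m)[1:6]; b <- colnames(m)[7:12]
  ab <- two_group_test(m, a, b)
  ba <- two_group_test(m, b, a)
  expect_identical(ab$p, ba$p)           # p preserved exactly
  expect_identical(ab$s, -ba$s)          # sign flips
  expect_identical(v_statistic(ab$p, ab$s), -v_statistic(ba$p, ba$s))
  expect_true(all(abs(v_statistic(ab$p, ab$s)) <= 1))
})

test_that("Storey-Tibshirani q-values: BH equivalence, monotonicity, extremes", {
  set.seed(13)
  p <- runif(2000)
  q_bh_oracle <- p.adjust(p, method = "BH")
  q1 <- storey_qvalues(p, pi0 = 1)
  expect_equal(as.numeric(q1), q_bh_oracle, tolerance = 1e-10)

  q <- storey_qvalues(p)
  pi0 <- attr(q, "pi0")
  expect_true(pi0 > 0 && pi0 <= 1)
  # pi0*p <= q <= pi0*m*p/rank, and q monotone in p (stable on ties)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
  expect_true(all(q[ord] <= pi0 * length(p) * p[ord] / seq_along(p) + 1e-12))
  expect_true(all(q >= pi0 * p - 1e-12))

  # extreme case: all p identical and tiny
  q_small <- storey_qvalues(rep(1e-6, 1000), pi0 = 1)
  expect_true(all(abs(q_small - 1e-6) < 1e-18))

  # fewer than 100 p-values falls back to pi0 = 1 with a message
  expect_message(qf <- storey_qvalues(runif(50)), "pi0 = 1")
  expect_equal(attr(qf, "pi0"), 1)

  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("induction signature recovers planted up/down counts and nulls", {
  cols <- c(sprintf("ctrl_%d", 1:3), sprintf("ind_%d", 1:3))
  # 400 genes keep the expected null leakage through the p/q filter (~2
  # genes) small next to the planted groups
  n_genes <- 400
  m <- rand_expr(n_genes, cols, seed = 31)
  # plant 150 up, 30 down in the induced arm; effect 7 gives ~0.98 power
  # for a 3v3 Student t at p < 0.01 (noncentrality 7/sqrt(2/3), df 4), so
  # planted counts are recoverable within 10%
  m[1:150, 4:6] <- m[1:150, 4:6] + 7
  m[151:180, 4:6] <- m[151:180, 4:6] - 7
  res <- induction_signature(m, control = cols[1:3], induced = cols[4:6],
                             alpha = 0.01, fdr_max = 0.10)
  expect_lt(abs(res$n_up - 150) / 150, 0.10)
  expect_lt(abs(res$n_down - 30) / 30, 0.10)
  expect_true(all(res$signature$v[1:150][res$signature$p[1:150] < 0.01] > 0))

  # control == induced columns: nothing passes
  dup <- cbind(m[, 1:3], m[, 1:3])
  colnames(dup) <- cols
  res0 <- induction_signature(dup, cols[1:3], cols[4:6])
  expect_equal(res0$n_up + res0$n_down, 0L)

  # null experiment: passing fraction at alpha = 0.01 stays small
  null_m <- rand_expr(5000, cols, seed = 77)
  rn <- induction_signature(null_m, cols[1:3], cols[4:6], alpha = 0.01)
  expect_lt((rn$n_up + rn$n_down) / 5000, 0.02)

  expect_error(induction_signature(m, cols[1], cols[4:6]), "2 replicates")
})

test_that("gene-set chi-square null test: determinism, signal, edge cases", {
  set.seed(17)
  sig <- data.frame(gene_id = sprintf("g%04d", 1:2000), p = runif(2000))
  gs <- list(name = "set", genes = sig$gene_id[sample(2000, 36)])
  r1 <- gene_set_null_test(sig, gs, alpha = 0.05, n_random = 10, seed = 4)
  r2 <- gene_set_null_test(sig, gs, alpha = 0.05, n_random = 10, seed = 4)
  expect_identical(r1$expected_count, r2$expected_count)
  expect_identical(r1$p_chi2, r2$p_chi2)
  expect_lte(r1$observed_count, r1$set_size)
  expect_gte(r1$expected_count, 0)

  # the seeded draws must not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  invisible(gene_set_null_test(sig, gs, seed = 9))
  expect_identical(rnorm(1), before)

  # a fully significant set against a null background is detected
  sig2 <- sig
  sig2$p[match(gs$genes, sig2$gene_id)] <- 1e-4
  rs <- gene_set_null_test(sig2, gs, alpha = 0.05, n_random = 10, seed = 4)
  expect_lt(rs$p_chi2, 0.001)
  expect_lt(rs$p_binom, 0.001)
  expect_equal(rs$observed_count, 36)

  # members absent from the signature are dropped with a message
  gs_mixed <- list(name = "mix", genes = c(gs$genes[1:5], "absent1", "absent2"))
  expect_message(rm5 <- gene_set_null_test(sig, gs_mixed, seed = 1),
                 "2 member\\(s\\) absent")
  expect_equal(rm5$set_size, 5L)

  expect_error(gene_set_null_test(sig, list(name = "none", genes = "zzz"),
                                  seed = 1),
               "no members")
})
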