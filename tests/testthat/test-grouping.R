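test_that("SD-rule classification matches hand arithmetic on 10 values", {
  # values: mean -6.0, sample SD sqrt(10/9); cutoff 0.8*SD ~ 0.843
  row <- gi50_row(c(-8, -7, -6, -6, -6, -6, -6, -6, -5, -4))
  g <- classify_by_sd(row, 0.8, drug_id = "d")
  expect_s3_class(g, "sensitivity_groups")
  expect_equal(g$mean_gi50, -6)
  expect_equal(g$sd_gi50, sqrt(10 / 9))
  expect_setequal(g$resistant, names(row)[row %in% c(-5, -4)])
  expect_setequal(g$sensitive, names(row)[row %in% c(-8, -7)])
  expect_length(intersect(g$resistant, g$sensitive), 0L)
})

test_that("SD-rule degenerate cases behave as documented", {
  # all equal -> SD 0 -> both groups empty
  g <- classify_by_sd(gi50_row(rep(-6, 8)), 0.8)
  expect_length(g$resistant, 0L)
  expect_length(g$sensitive, 0L)

  # multiplier 0 -> every non-mean cell lands in exactly one group
  row <- gi50_row(c(-7, -6.5, -6, -5.5, -5))
  g0 <- classify_by_sd(row, 0)
  expect_setequal(c(g0$resistant, g0$sensitive),
                  names(row)[row != mean(row)])
  expect_length(intersect(g0$resistant, g0$sensitive), 0L)

  # fewer than 3 present values -> drug skipped with a logged reason
  expect_message(res <- classify_by_sd(gi50_row(c(-6, NA, NA)), 0.8),
                 "skipped")
  expect_null(res)

  # missing values excluded from mean/SD and from the groups
  row_na <- gi50_row(c(-8, -7, -6, -6, -6, -6, -6, -6, -5, -4, NA))
  gna <- classify_by_sd(row_na, 0.8)
  expect_equal(gna$mean_gi50, -6)
  expect_equal(gna$n_used, 10L)
  expect_false("c11" %in% c(gna$resistant, gna$sensitive))
})

test_that("fold-rule classification works on the log10 scale", {
  # mean log10 = -6.0; cell at -5.2 is 10^0.8 ~ 6.31-fold above -> resistant;
  # cell at -5.7 is 10^0.3 ~ 2-fold -> unassigned
  row <- gi50_row(c(-6.8, -6.3, -6.0, -6.0, -5.7, -5.2))
  expect_equal(mean(row), -6.0)
  g <- classify_by_fold(row, fold = 6)
  expect_true("c06" %in% g$resistant)   # -5.2
  expect_false("c05" %in% c(g$resistant, g$sensitive))  # -5.7

  # fold just above 1 assigns every cell away from the mean
  g1 <- classify_by_fold(row, fold = 1 + 1e-9)
  expect_setequal(c(g1$resistant, g1$sensitive),
                  names(row)[row != mean(row)])
  expect_length(intersect(g1$resistant, g1$sensitive), 0L)

  expect_error(classify_by_fold(row, fold = 1), "> 1")
  expect_error(classify_by_fold(row, fold = 0.5), "> 1")
})

test_that("SD and fold rules never put a cell on opposite sides", {
  for (seed in 1:20) {
    set.seed(seed)
    row <- gi50_row(rnorm(60, -6, 0.6))
    gs <- classify_by_sd(row, 0.8)
    gf <- classify_by_fold(row, 1.5)
    expect_length(intersect(gs$resistant, gf$sensitive), 0L)
    expect_length(intersect(gs$sensitive, gf$resistant), 0L)
  }
})

test_that("drug filter keeps exactly the drugs with both groups large enough", {
  mk <- function(nr, ns, id) {
    structure(list(drug_id = id,
                   resistant = sprintf("r%d", seq_len(nr)),
                   sensitive = sprintf("s%d", seq_len(ns)),
                   rule = "sd", threshold_used = 0.8,
                   mean_gi50 = -6, sd_gi50 = 1, n_used = 60),
              class = "sensitivity_groups")
  }
  groups <- list(mk(7, 6, "a"), mk(6, 5, "b"), mk(12, 12, "c"), NULL)
  expect_message(kept <- filter_drugs(groups, 6), "kept 2 of 3")
  expect_equal(vapply(kept, `[[`, character(1), "drug_id"), c("a", "c"))
  expect_message(all1 <- filter_drugs(groups, 1))
  expect_length(all1, 3L)
  expect_message(none <- filter_drugs(list(), 6))
  expect_length(none, 0L)
})

test_that("expression ranking partitions cells deterministically", {
  cells <- sprintf("c%02d", 1:60)
  m <- matrix(0, 2, 60, dimnames = list(c("gA", "gB"), cells))
  m["gA", ] <- 1:60
  ranked <- rank_cells_by_gene(m, "gA", k = 15)
  expect_setequal(ranked$high, cells[46:60])
  expect_setequal(ranked$low, cells[1:15])

  # all-equal expression: groups are determined purely by identifier order
  tie <- rank_cells_by_gene(m, "gB", k = 15)
  expect_equal(tie$high, cells[1:15])
  expect_equal(tie$low, cells[46:60])

  # k = n/2 partitions every cell
  half <- rank_cells_by_gene(m, "gA", k = 30)
  expect_setequal(c(half$high, half$low), cells)

  expect_error(rank_cells_by_gene(m, "nope", 5), "unknown gene")
  expect_error(rank_cells_by_gene(m, "gA", 31), "exceeds")
})

test_that("group response comparison detects planted GI50 shifts", {
  cells <- sprintf("c%02d", 1:30)
  set.seed(7)
  row <- gi50_row(c(rnorm(15, -6 + 3 * 0.5, 0.5), rnorm(15, -6, 0.5)), cells)
  res <- compare_group_response(cells[1:15], cells[16:30], row)
  expect_true(res$p < 0.01)
  expect_true(res$delta_mean > 0)

  # identical values in both groups: delta 0, p = 1
  flat <- gi50_row(rep(c(-6, -5.5), 10), sprintf("c%02d", 1:20))
  same <- compare_group_response(sprintf("c%02d", 1:10),
                                 sprintf("c%02d", 11:20), flat)
  expect_equal(same$delta_mean, 0)
  expect_equal(same$p, 1)

  # a group with fewer than 2 present values is skipped
  row2 <- gi50_row(c(-6, NA, -5, -6, -7), sprintf("c%02d", 1:5))
  expect_message(skip <- compare_group_response(c("c01", "c02"),
                                                c("c03", "c04", "c05"), row2),
                 "skipped")
  expect_null(skip)
})

test_that("SD classification tails approach the Gaussian expectation", {
  set.seed(11)
  row <- gi50_row(rnorm(10000, -6, 0.5), sprintf("c%05d", 1:10000))
  g <- classify_by_sd(row, 0.8)
  expected <- 1 - pnorm(0.8)  # ~0.2119 per tail
  expect_lt(abs(length(g$resistant) / 10000 - expected), 0.02)
  expect_lt(abs(length(g$sensitive) / 10000 - expected), 0.02)
})
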