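# Shared fixture builders; all fixtures are generated in code.

# Small named GI50 row.
gi50_row <- function(values, cells = sprintf("c%02d", seq_along(values))) {
  stats::setNames(values, cells)
}

# Random genes x samples matrix with unique dimnames.
rand_expr <- function(n_genes, samples, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * length(samples), 0, sd), n_genes, length(samples),
         dimnames = list(sprintf("g%04d", seq_len(n_genes)), samples))
}

# Write a drugs x cells (or genes x samples) matrix as the TSV dialect the
# readers expect; returns the path.
write_matrix_tsv <- function(m, id_col = "drug_id",
                             path = tempfile(fileext = ".tsv")) {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  path
}

# Exhaustive two-sided permutation p-value for a 3v3 equal-variance t-test:
# the proportion of the 20 group assignments with |t| at least as extreme.
perm_t_pvalue_3v3 <- function(a, b) {
  vals <- c(a, b)
  combs <- combn(6, 3)
  tstat <- function(ia) {
    x <- vals[ia]; y <- vals[-ia]
    sp <- sqrt((2 * var(x) + 2 * var(y)) / 4)
    (mean(x) - mean(y)) / (sp * sqrt(2 / 3))
  }
  t_obs <- tstat(1:3)
  t_all <- apply(combs, 2, tstat)
  mean(abs(t_all) >= abs(t_obs) - 1e-12)
}

# Planted one-drug REM benchmark scenario: 60 cells, 12v12 planted groups
# with a modest (0.25 SD) GI50 tail shift so the two REM criteria carry
# complementary information, planted genes with group effect `effect` and
# GI50 coupling 1.5.
rem_scenario <- function(seed, n_genes = 5000, n_planted = 200, effect = 2) {
  dr <- generate_dose_response(n_drugs = 1, n_cells = 60,
                               tail_fraction = 0.2, tail_shift = 0.25,
                               seed = seed)
  ex <- generate_expression(n_genes = n_genes, dose = dr$gi50,
                            truth = dr$truth, n_planted = n_planted,
                            effect = effect, sigma = 1,
                            gi50_coupling = 1.5, seed = seed + 10000)
  list(dose = dr$gi50, truth = ex$truth, values = ex$values,
       drug_id = names(ex$truth$drugs)[1])
}
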