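# remsig

Drug-response signature matching for predicting engineered reversal of
chemoresistance in cancer cell lines.

## The problem

Large cell-line screens (NCI-60 style) report, for each drug, a log10 GI50
per cell line — the concentration giving 50% growth inhibition — together
with the lines' transcriptomes. `remsig` asks: *which genes, if induced or
repressed, would push a resistant cell's transcriptome toward the
sensitive state?* It is aimed at computational pharmacogenomics work on
candidate resistance-reversal factors such as metastasis suppressor genes.

The pipeline:

1. **Sensitivity grouping** — per drug, cell lines with
   GI50 ≥ mean + 0.8·SD are *resistant*, ≤ mean − 0.8·SD *sensitive*
   (a ≥ 6-fold-change rule relative to the geometric-mean GI50 is also
   provided); only drugs with ≥ 6 lines in both groups are analyzed.
2. **Signed signatures** — per gene, a Student two-sample t-test between
   the groups gives p and the direction s, combined into
   `v = s·(1 − p) ∈ [−1, 1]` (positive = higher in resistant);
   Storey–Tibshirani q-values control the FDR.
3. **Response engineering module (REM)** — the drug's
   resistance-minus-sensitive signature: genes that both (i) differ
   between the groups (p < α) and (ii) correlate with GI50 across the
   grouped cells (Pearson t-transform, p < α).
4. **Signature comparison** — an induction signature (v-vector of an
   induced-vs-control contrast) is correlated with the REM over the REM
   genes; a significant negative r predicts sensitization on induction.
   Candidate gene sets can also be tested per drug against the mean count
   of differential genes in 10 random same-size sets (1-df chi-square).

A synthetic-data module generates NCI-60-style dose–response and
expression matrices with planted, recorded ground truth (group labels,
planted REM genes, target induction correlation) so every stage is
verifiable offline. See `vignettes/rem-workflow.Rmd` for the model,
parameter defaults, and design choices.

## Worked example

```r
library(remsig)

dr <- generate_dose_response(n_drugs = 20, n_cells = 60, seed = 7)
ex <- generate_expression(n_genes = 1000, dose = dr$gi50, truth = dr$truth,
                          n_planted = 100, seed = 8)

groups <- classify_by_sd(dr$gi50["D0001", ], 0.8, drug_id = "D0001")
length(groups$resistant)   # 10
length(groups$sensitive)   # 11

rem <- build_rem(ex$values, groups, dr$gi50["D0001", ], alpha = 0.05)
nrow(rem$genes)            # 38
head(rem$genes[, c("gene_id", "v_rem", "r_gi50", "p_gi50")], 3)
#    gene_id v_rem     r_gi50       p_gi50
# 1   G00001    -1 -0.9752566 6.500853e-14
# 21  G00021     1  0.9688916 5.580681e-13
# 41  G00041     1  0.9740412 1.020362e-13

ind <- generate_induction_experiment(
  setNames(rem$genes$v_rem, rem$genes$gene_id),
  target_correlation = -0.85, seed = 9)
isig <- induction_signature(ind$values, ind$control, ind$induced)
res <- correlate_signatures(rem_v_vector(rem, isig$signature))
round(res$r, 3)            # -0.818
signif(res$p_r, 3)         # 3.7e-10
res$call                   # "predict_sensitization_on_induction"
```

The 21 classified lines are the drug's GI50 tails; the 38 REM genes passed
both criteria, with `v_rem` near ±1 (strong group difference) and `r_gi50`
their GI50 correlation. The induction experiment was generated to oppose
the REM at population correlation −0.85; the measured v-vector correlation
−0.818 (p ≈ 4e−10) is significantly negative, so induction of this factor
is predicted to sensitize resistant cells.

`run_pipeline()` orchestrates all stages from files to a directory of TSV
tables plus a JSON summary and is byte-identical across repeated runs with
a fixed seed; `inst/scripts/remsig-cli.R` exposes the stages as shell
subcommands (`simulate`, `classify`, `signature`, `rem`, `geneset-test`,
`compare`, `run`).

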