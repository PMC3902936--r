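#' Run the end-to-end drug-response re-engineering pipeline
#'
#' Orchestrates every stage: classify cell lines per drug, filter drugs by
#' group size, build per-drug resistant-versus-sensitive signatures and
#' REMs, test candidate gene sets against the random-set null, and — when
#' an induction experiment is supplied — compare the induction signature
#' against every REM. All outputs are tab-delimited tables plus a
#' machine-readable JSON summary; identical inputs, configuration and seed
#' produce byte-identical outputs.
#'
#' @param dose_path Path to the drugs x cells log10 GI50 matrix.
#' @param expr_path Path to the genes x cells expression matrix (columns
#'   must be cell identifiers matching the dose matrix).
#' @param out_dir Output directory (created if needed).
#' @param gene_set_path Optional GMT file of candidate gene sets.
#' @param induction_path Optional genes x replicates expression matrix for
#'   an induction experiment.
#' @param induction_label_path Label file for the induction samples; labels
#'   must be `control` / `induced`. Required with `induction_path`.
#' @param config A [run_config()] object.
#' @return Invisibly, a list with the in-memory stage results (`groups`,
#'   `signatures`, `rems`, `geneset_tests`, `comparisons`, `summary`).
#' @export
run_pipeline <- function(dose_path, expr_path, out_dir,
                         gene_set_path = NULL,
                         induction_path = NULL,
                         induction_label_path = NULL,
                         config = run_config()) {
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  dose <- stage("read_dose_response", read_dose_response(dose_path))
  expr <- stage("read_expression", read_expression(expr_path))
  gene_sets <- if (!is.null(gene_set_path)) {
    stage("read_gene_sets", read_gene_sets(gene_set_path))
  }

  # -- classification ------------------------------------------------------
  groups <- stage("classify", {
    lapply(rownames(dose), function(d) {
      row <- dose[d, ]
      if (config$classification_rule == "sd") {
        classify_by_sd(row, config$sd_multiplier, drug_id = d)
      } else {
        classify_by_fold(row, config$fold_threshold, drug_id = d)
      }
    })
  })
  groups <- Filter(Negate(is.null), groups)
  group_rows <- do.call(rbind, lapply(groups, function(g) {
    n <- length(g$resistant) + length(g$sensitive)
    if (n == 0L) return(NULL)
    data.frame(drug_id = g$drug_id,
               cell_id = c(g$resistant, g$sensitive),
               group = rep(c("resistant", "sensitive"),
                           c(length(g$resistant), length(g$sensitive))),
               rule = g$rule, threshold = g$threshold_used,
               stringsAsFactors = FALSE)
  }))
  .write_tsv(group_rows, file.path(out_dir, "groups.tsv"))

  kept <- stage("filter_drugs", filter_drugs(groups, config$min_group_size))

  # -- per-drug signatures and REMs ---------------------------------------
  values <- expr$values
  sig_list <- list()
  rem_list <- list()
  stage("signatures_and_rems", {
    for (g in kept) {
      res_cells <- intersect(g$resistant, colnames(values))
      sen_cells <- intersect(g$sensitive, colnames(values))
      if (length(res_cells) < config$min_group_size ||
          length(sen_cells) < config$min_group_size) {
        .msg("drug ", g$drug_id,
             " dropped: too few grouped cells with expression")
        next
      }
      sig <- build_signature(values, res_cells, sen_cells,
                             contrast_id = g$drug_id)
      rem <- build_rem(values, g, dose[g$drug_id, ],
                       alpha = config$alpha_gene,
                       min_group_size = config$min_group_size)
      sig_list[[g$drug_id]] <- sig
      rem_list[[g$drug_id]] <- rem
    }
  })
  sig_rows <- do.call(rbind, lapply(names(sig_list), function(d) {
    cbind(data.frame(drug_id = d, stringsAsFactors = FALSE), sig_list[[d]])
  }))
  .write_tsv(sig_rows, file.path(out_dir, "signatures.tsv"))
  rem_rows <- do.call(rbind, lapply(rem_list, function(r) {
    if (nrow(r$genes) == 0L) return(NULL)
    cbind(data.frame(drug_id = r$drug_id, stringsAsFactors = FALSE),
          r$genes[, c("gene_id", "v_rem", "r_gi50", "p_gi50")],
          data.frame(n_resistant = r$n_resistant,
                     n_sensitive = r$n_sensitive))
  }))
  .write_tsv(rem_rows, file.path(out_dir, "rems.tsv"))

  # -- gene-set null tests -------------------------------------------------
  gs_rows <- NULL
  if (!is.null(gene_sets) && length(gene_sets) > 0L) {
    gs_rows <- stage("geneset_test", {
      rows <- list()
      i <- 0L
      for (d in names(sig_list)) {
        for (gs in gene_sets) {
          i <- i + 1L
          res <- gene_set_null_test(sig_list[[d]], gs,
                                    alpha = config$alpha_gene,
                                    n_random = config$n_random_sets,
                                    seed = (config$seed + i) %% .Machine$integer.max)
          rows[[i]] <- data.frame(drug_id = d, set_name = res$set_name,
                                  set_size = res$set_size,
                                  observed = res$observed_count,
                                  expected = res$expected_count,
                                  chi2 = res$chi2, p_chi2 = res$p_chi2,
                                  p_binom = res$p_binom,
                                  unreliable = res$unreliable,
                                  min_p_member = res$min_p_member,
                                  stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
    .write_tsv(gs_rows, file.path(out_dir, "geneset_tests.tsv"))
  }

  # -- induction comparison ------------------------------------------------
  cmp_rows <- NULL
  ind <- NULL
  if (!is.null(induction_path)) {
    cmp_rows <- stage("compare", {
      if (is.null(induction_label_path)) {
        stop("induction_label_path is required with induction_path")
      }
      ie <- read_expression(induction_path, induction_label_path)
      ctrl <- names(ie$labels)[ie$labels == "control"]
      indc <- names(ie$labels)[ie$labels == "induced"]
      ind <- induction_signature(ie$values, ctrl, indc,
                                  alpha = config$alpha_induction,
                                  fdr_max = config$fdr_max)
      screen_factor(ind, rem_list, alpha = config$alpha_call)
    })
    .write_tsv(cmp_rows, file.path(out_dir, "comparisons.tsv"))
  }

  # -- summary -------------------------------------------------------------
  summary <- list(
    config = unclass(config),
    n_drugs = nrow(dose),
    n_cells = ncol(dose),
    n_genes = nrow(values),
    n_drugs_classified = length(groups),
    n_drugs_kept = length(kept),
    n_drugs_analyzed = length(sig_list),
    rem_sizes = vapply(rem_list, function(r) nrow(r$genes), integer(1L)),
    geneset_significant = if (!is.null(gs_rows)) {
      sum(gs_rows$p_chi2 < 0.05)
    } else {
      NULL
    },
    induction = if (!is.null(ind)) {
      list(n_up = ind$n_up, n_down = ind$n_down)
    } else {
      NULL
    },
    n_calls = if (!is.null(cmp_rows)) {
      sum(cmp_rows$call != "no_call")
    } else {
      NULL
    })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(groups = groups, signatures = sig_list, rems = rem_list,
                 geneset_tests = gs_rows, comparisons = cmp_rows,
                 summary = summary))
}

.write_tsv <- function(df, path) {
  if (is.null(df) || nrow(df) == 0L) {
    writeLines(character(0L), path)
    return(invisible(path))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
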