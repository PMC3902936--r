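#' Run configuration for the end-to-end pipeline
#'
#' Bundles every threshold used by the pipeline stages. Defaults follow the
#' analysis conventions of the NCI-60 style screen: cell lines at least
#' 0.8 SD above/below the per-drug mean log10 GI50 are resistant/sensitive,
#' drugs need at least six cell lines in each group, induction signatures
#' are filtered at P < 0.01 and FDR < 10%, and the gene-set null uses 10
#' random same-size sets.
#'
#' @param classification_rule `"sd"` (mean +/- multiplier * SD on log10 GI50)
#'   or `"fold"` (fold change relative to the geometric-mean GI50).
#' @param sd_multiplier SD multiplier for the `"sd"` rule.
#' @param fold_threshold Fold-change threshold for the `"fold"` rule (> 1).
#' @param min_group_size Minimum resistant and sensitive group size per drug.
#' @param alpha_gene Per-gene significance threshold for REM construction.
#' @param alpha_induction Per-gene p threshold for the induction signature.
#' @param fdr_max Maximum q-value for the induction signature filter.
#' @param n_random_sets Number of random gene sets for the chi-square null.
#' @param rank_group_size Group size for expression-ranked high/low cells.
#' @param alpha_call Significance threshold for sensitization calls.
#' @param seed Integer seed controlling all pipeline randomness.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(classification_rule = c("sd", "fold"),
                       sd_multiplier = 0.8,
                       fold_threshold = 6,
                       min_group_size = 6L,
                       alpha_gene = 0.05,
                       alpha_induction = 0.01,
                       fdr_max = 0.10,
                       n_random_sets = 10L,
                       rank_group_size = 15L,
                       alpha_call = 0.001,
                       seed = 1L) {
  cfg <- list(classification_rule = match.arg(classification_rule),
              sd_multiplier = as.numeric(sd_multiplier),
              fold_threshold = as.numeric(fold_threshold),
              min_group_size = as.integer(min_group_size),
              alpha_gene = as.numeric(alpha_gene),
              alpha_induction = as.numeric(alpha_induction),
              fdr_max = as.numeric(fdr_max),
              n_random_sets = as.integer(n_random_sets),
              rank_group_size = as.integer(rank_group_size),
              alpha_call = as.numeric(alpha_call),
              seed = as.integer(seed))
  stopifnot(cfg$sd_multiplier > 0, cfg$fold_threshold > 1,
            cfg$min_group_size >= 2L, cfg$n_random_sets >= 1L,
            cfg$rank_group_size >= 1L,
            cfg$alpha_gene > 0, cfg$alpha_gene < 1,
            cfg$alpha_induction > 0, cfg$alpha_induction < 1,
            cfg$alpha_call > 0, cfg$alpha_call < 1,
            cfg$fdr_max > 0, cfg$fdr_max <= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a flat `key: value` text file
#'
#' Unknown keys are an error; omitted keys take their [run_config()]
#' defaults.
#'
#' @param path Path to the configuration file.
#' @return A `"run_config"` list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1L), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = ":"),
                        character(1L)))
  known <- names(formals(run_config))
  bad <- setdiff(keys, known)
  if (length(bad) > 0L) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  args <- stats::setNames(as.list(vals), keys)
  numeric_keys <- setdiff(known, "classification_rule")
  for (k in intersect(names(args), numeric_keys)) {
    args[[k]] <- as.numeric(args[[k]])
  }
  do.call(run_config, args)
}

#' Write a run configuration as flat `key: value` text
#'
#' @param config A `"run_config"` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  writeLines(sprintf("%s: %s", names(config),
                     vapply(config, format, character(1L))), path)
  invisible(path)
}
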