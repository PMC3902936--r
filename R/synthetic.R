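# Synthetic NCI-60-style data with planted, recorded ground truth.
# Every generator is deterministic given its seed, and the returned
# planted-truth object is sufficient to score downstream stages without
# re-running generation.

#' Generate a dose-response matrix with planted resistant/sensitive tails
#'
#' Per drug, core cell lines draw log10 GI50 from Normal(mu_d, sigma_d);
#' `ceiling(tail_fraction * n_cells)` cells are shifted up by
#' `tail_shift * sigma_d` (planted resistant) and the same number down
#' (planted sensitive). Per-drug means are drawn around a typical
#' micromolar potency (`gi50_mean` on the log10 molar scale) and per-drug
#' SDs uniformly from `gi50_sd_range`, so all planted structure is
#' scale-free in SD units.
#'
#' @param n_drugs,n_cells Matrix dimensions.
#' @param tail_fraction Fraction of cells per planted tail, in (0, 0.5).
#' @param tail_shift Tail shift in per-drug SD units (>= 0).
#' @param seed Integer seed.
#' @param gi50_mean,gi50_mean_sd Mean and SD of the per-drug mean log10
#'   GI50.
#' @param gi50_sd_range Range of the per-drug SD of log10 GI50.
#' @return List with `gi50` (drugs x cells numeric matrix) and `truth`, a
#'   `"planted_truth"` list recording per-drug resistant/sensitive cells,
#'   mu, sigma, and all generator parameters.
#' @export
generate_dose_response <- function(n_drugs = 200L, n_cells = 60L,
                                   tail_fraction = 0.15, tail_shift = 3,
                                   seed = 1L,
                                   gi50_mean = -6, gi50_mean_sd = 1,
                                   gi50_sd_range = c(0.3, 0.7)) {
  stopifnot(n_drugs >= 1L, n_cells >= 2L,
            tail_fraction > 0, tail_fraction < 0.5, tail_shift >= 0)
  k <- ceiling(tail_fraction * n_cells)
  if (n_cells < 2L * k) {
    stop("infeasible sizes: n_cells (", n_cells,
         ") < 2 * planted tail size (", k, ")")
  }
  drug_ids <- sprintf("D%04d", seq_len(n_drugs))
  cell_ids <- sprintf("C%02d", seq_len(n_cells))
  gi50 <- matrix(NA_real_, n_drugs, n_cells,
                 dimnames = list(drug_ids, cell_ids))
  drugs <- vector("list", n_drugs)
  names(drugs) <- drug_ids
  .with_seed(seed, {
    mu <- stats::rnorm(n_drugs, gi50_mean, gi50_mean_sd)
    sigma <- stats::runif(n_drugs, gi50_sd_range[1L], gi50_sd_range[2L])
    for (d in seq_len(n_drugs)) {
      vals <- stats::rnorm(n_cells, mu[d], sigma[d])
      tails <- sample(n_cells, 2L * k)
      res <- tails[seq_len(k)]
      sen <- tails[k + seq_len(k)]
      vals[res] <- vals[res] + tail_shift * sigma[d]
      vals[sen] <- vals[sen] - tail_shift * sigma[d]
      gi50[d, ] <- vals
      drugs[[d]] <- list(resistant = cell_ids[sort(res)],
                         sensitive = cell_ids[sort(sen)],
                         mu = mu[d], sigma = sigma[d])
    }
  })
  truth <- structure(list(cells = cell_ids, drugs = drugs,
                          planted_genes = NULL,
                          params = list(n_drugs = n_drugs, n_cells = n_cells,
                                        tail_fraction = tail_fraction,
                                        tail_shift = tail_shift,
                                        gi50_mean = gi50_mean,
                                        gi50_mean_sd = gi50_mean_sd,
                                        gi50_sd_range = gi50_sd_range,
                                        seed = seed)),
                     class = "planted_truth")
  list(gi50 = gi50, truth = truth)
}

#' Generate an expression matrix with planted drug-response genes
#'
#' Background genes are iid Normal(0, `sigma`) per cell. Each planted gene
#' is assigned a drug (cycling through the planted drugs) and a random
#' sign, and receives (i) a mean shift of `sign * effect` in that drug's
#' planted-resistant cells and (ii) a GI50-tracking component
#' `sign * gi50_coupling * z_c`, where `z_c = (gi50 - mu_d) / sigma_d` is
#' the cell's GI50 deviation for the drug in SD units — so planted genes
#' are discoverable by both REM criteria (group difference and GI50
#' correlation).
#'
#' @param n_genes Number of genes.
#' @param dose Drugs x cells GI50 matrix from [generate_dose_response()].
#' @param truth The matching `"planted_truth"` object.
#' @param n_planted Number of planted genes (first `n_planted` rows).
#' @param effect Group mean shift in expression units.
#' @param sigma Background expression SD.
#' @param gi50_coupling Slope of the GI50-tracking component per GI50 SD.
#' @param seed Integer seed.
#' @return List with `values` (genes x cells matrix) and `truth` (input
#'   truth with a `planted_genes` data.frame added: `gene_id`, `drug_id`,
#'   `sign`, `effect`, `gi50_coupling`).
#' @export
generate_expression <- function(n_genes = 2000L, dose, truth,
                                n_planted = 0L, effect = 2, sigma = 1,
                                gi50_coupling = 1.5, seed = 1L) {
  stopifnot(n_planted <= n_genes, n_planted >= 0L)
  cells <- truth$cells
  if (!all(cells %in% colnames(dose))) {
    stop("truth references cells absent from the dose-response matrix: ",
         paste(setdiff(cells, colnames(dose)), collapse = ", "))
  }
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  drug_ids <- names(truth$drugs)
  planted <- NULL
  values <- .with_seed(seed, {
    x <- matrix(stats::rnorm(n_genes * length(cells), 0, sigma),
                n_genes, length(cells),
                dimnames = list(gene_ids, cells))
    if (n_planted > 0L) {
      assigned <- drug_ids[((seq_len(n_planted) - 1L) %% length(drug_ids)) + 1L]
      sgn <- sample(c(-1, 1), n_planted, replace = TRUE)
      for (i in seq_len(n_planted)) {
        d <- assigned[i]
        info <- truth$drugs[[d]]
        z <- (dose[d, cells] - info$mu) / info$sigma
        shift <- gi50_coupling * z
        shift[cells %in% info$resistant] <-
          shift[cells %in% info$resistant] + effect
        x[i, ] <- x[i, ] + sgn[i] * shift
      }
      planted <- data.frame(gene_id = gene_ids[seq_len(n_planted)],
                            drug_id = assigned, sign = sgn,
                            effect = effect,
                            gi50_coupling = gi50_coupling,
                            stringsAsFactors = FALSE)
    }
    x
  })
  truth$planted_genes <- planted
  truth$params$expression <- list(n_genes = n_genes, n_planted = n_planted,
                                  effect = effect, sigma = sigma,
                                  gi50_coupling = gi50_coupling,
                                  seed = seed)
  list(values = values, truth = truth)
}

#' Generate a replicated induction experiment with a target REM correlation
#'
#' Builds per-gene induced-minus-control mean shifts whose population
#' correlation with a REM v-vector equals `target_correlation`:
#' `delta = rho * v_rem + sqrt(1 - rho^2) * sd(v_rem) * eps` with iid
#' standard-normal `eps`, then rescaled to SD `shift_scale`. Control and
#' induced replicate columns are emitted with iid Normal(0, `noise`)
#' within-arm variation around 0 and `delta` respectively.
#'
#' @param v_rem Named numeric vector of REM v values (gene order defines
#'   the output row order).
#' @param target_correlation Target population correlation in \[-1, 1\].
#' @param n_replicates Replicates per arm (>= 2; a t-test is undefined
#'   below that).
#' @param noise Within-arm SD of the replicate noise.
#' @param shift_scale SD of the rescaled shift vector.
#' @param seed Integer seed.
#' @return List with `values` (genes x 2*n_replicates matrix; columns
#'   `ctrl_*` then `ind_*`), `control`, `induced` (column name vectors),
#'   `labels` (named character vector), `shifts` (the planted delta), and
#'   `target_correlation`.
#' @export
generate_induction_experiment <- function(v_rem, target_correlation,
                                          n_replicates = 3L, noise = 0.5,
                                          shift_scale = 1, seed = 1L) {
  rho <- target_correlation
  if (!is.finite(rho) || abs(rho) > 1) {
    stop("target_correlation must lie in [-1, 1]")
  }
  if (n_replicates < 2L) stop("need at least 2 replicates per arm")
  n <- length(v_rem)
  gene_ids <- if (is.null(names(v_rem))) {
    sprintf("G%05d", seq_len(n))
  } else {
    names(v_rem)
  }
  ctrl <- sprintf("ctrl_%d", seq_len(n_replicates))
  ind <- sprintf("ind_%d", seq_len(n_replicates))
  out <- .with_seed(seed, {
    eps <- stats::rnorm(n)
    delta <- rho * v_rem + sqrt(1 - rho^2) * stats::sd(v_rem) * eps
    if (stats::sd(delta) > 0) {
      delta <- delta / stats::sd(delta) * shift_scale
    }
    m <- matrix(stats::rnorm(n * 2L * n_replicates, 0, noise),
                n, 2L * n_replicates,
                dimnames = list(gene_ids, c(ctrl, ind)))
    m[, ind] <- m[, ind] + delta
    list(values = m, shifts = stats::setNames(as.numeric(delta), gene_ids))
  })
  list(values = out$values, control = ctrl, induced = ind,
       labels = stats::setNames(rep(c("control", "induced"),
                                    each = n_replicates),
                                c(ctrl, ind)),
       shifts = out$shifts, target_correlation = rho)
}

#' Write a planted-truth object as structured text (JSON)
#'
#' @param truth A `"planted_truth"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_planted_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a planted-truth object written by [write_planted_truth()]
#'
#' @param path Path to the JSON truth file.
#' @return A `"planted_truth"` list.
#' @export
read_planted_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$drugs <- lapply(truth$drugs, function(d) {
    list(resistant = as.character(d$resistant),
         sensitive = as.character(d$sensitive),
         mu = as.numeric(d$mu), sigma = as.numeric(d$sigma))
  })
  structure(truth, class = "planted_truth")
}

#' Sensitivity groups from planted truth
#'
#' Wraps a drug's planted resistant/sensitive labels as a
#' `"sensitivity_groups"` object so downstream stages (e.g. [build_rem()])
#' can be scored directly against the generator's ground truth.
#'
#' @param truth A `"planted_truth"` object.
#' @param drug_id Drug identifier present in `truth`.
#' @return A `"sensitivity_groups"` list with rule `"planted"`.
#' @export
planted_groups <- function(truth, drug_id) {
  info <- truth$drugs[[drug_id]]
  if (is.null(info)) stop("unknown drug in truth: ", drug_id)
  structure(list(drug_id = drug_id,
                 resistant = info$resistant,
                 sensitive = info$sensitive,
                 rule = "planted",
                 threshold_used = NA_real_,
                 mean_gi50 = info$mu,
                 sd_gi50 = info$sigma,
                 n_used = length(truth$cells)),
            class = "sensitivity_groups")
}
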