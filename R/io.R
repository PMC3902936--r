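#' Read a drugs x cell-lines dose-response matrix
#'
#' Reads a tab- or comma-delimited matrix of log10 GI50 values (molar scale)
#' with drug identifiers in the first column and cell-line identifiers in the
#' header row. Empty fields and `"NA"` mark missing GI50 measurements; they
#' are kept as `NA` and never imputed. Input ordering is preserved.
#'
#' @param path Path to the delimited file.
#' @return A numeric matrix (drugs in rows, cell lines in columns) with
#'   unique dimnames; missing entries are `NA`.
#' @seealso [write_dose_response()], [read_expression()]
#' @export
read_dose_response <- function(path) {
  m <- .read_delim_matrix(path, what = "dose-response")
  if (nrow(m) < 1L || ncol(m) < 2L) {
    stop("dose-response matrix needs at least 1 drug and 2 cell lines")
  }
  m
}

#' Write a dose-response matrix
#'
#' @param x Numeric matrix as returned by [read_dose_response()].
#' @param path Output path; tab-delimited, `NA` for missing entries.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(x, path) {
  .write_delim_matrix(x, path, id_col = "drug_id")
}

#' Read a genes x samples expression matrix
#'
#' Reads a delimited expression matrix (assumed already on a log scale;
#' no normalization is performed) with gene identifiers in the first column
#' and sample identifiers in the header. An optional two-column, headerless
#' label file maps samples to group labels (e.g. cell line, or
#' control/induced arm).
#'
#' Missing expression values are tolerated on load; analysis functions drop
#' genes with missing values among the samples a contrast uses (see
#' [two_group_test()]).
#'
#' @param path Path to the expression matrix.
#' @param label_path Optional path to a two-column (sample, label) file.
#' @return A list of class `"expression_set"` with elements `values`
#'   (numeric matrix) and `labels` (named character vector or `NULL`).
#' @export
read_expression <- function(path, label_path = NULL) {
  m <- .read_delim_matrix(path, what = "expression")
  if (nrow(m) < 2L) stop("expression matrix needs at least 2 genes")
  labels <- NULL
  if (!is.null(label_path)) {
    lab <- utils::read.table(label_path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "",
                             comment.char = "")
    if (ncol(lab) < 2L) stop("label file must have two columns (sample, label)")
    unknown <- setdiff(lab[[1L]], colnames(m))
    if (length(unknown) > 0L) {
      stop("label file references unknown sample(s): ",
           paste(unknown, collapse = ", "))
    }
    labels <- stats::setNames(lab[[2L]], lab[[1L]])
  }
  structure(list(values = m, labels = labels), class = "expression_set")
}

#' Write an expression matrix (and optional sample labels)
#'
#' @param x An `"expression_set"` (list with `values`, `labels`) or a bare
#'   numeric matrix.
#' @param path Output path for the matrix.
#' @param label_path Optional output path for the sample-label table.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, label_path = NULL) {
  values <- if (is.list(x)) x$values else x
  .write_delim_matrix(values, path, id_col = "gene_id")
  if (!is.null(label_path)) {
    labels <- if (is.list(x)) x$labels else NULL
    if (is.null(labels)) stop("no sample labels to write")
    utils::write.table(data.frame(names(labels), unname(labels)),
                       label_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate members within a set are dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @return A list of gene sets, each a list with elements `name`,
#'   `description` and `genes`. An empty file yields an empty list.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      ndup <- length(genes) - length(unique(genes))
      warning("gene set '", fields[[1L]], "': dropped ", ndup,
              " duplicate member(s)", call. = FALSE)
      genes <- unique(genes)
    }
    if (length(genes) == 0L) stop("GMT line ", i, " defines an empty set")
    sets[[i]] <- list(name = fields[[1L]], description = fields[[2L]],
                      genes = genes)
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets List of gene sets as returned by [read_gene_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# Shared delimited-matrix reader: first column ids, header row ids;
# auto-detects tab vs comma; "" and "NA" are missing; duplicate ids and
# non-numeric cells are hard errors naming the offender.
.read_delim_matrix <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate row identifier(s) in ", what, " matrix: ",
         paste(unique(dup), collapse = ", "))
  }
  col_ids <- colnames(df)[-1L]
  dupc <- col_ids[duplicated(col_ids)]
  if (length(dupc) > 0L) {
    stop("duplicate column identifier(s) in ", what, " matrix: ",
         paste(unique(dupc), collapse = ", "))
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  miss <- raw == "" | raw == "NA"
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(num) & !miss, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-numeric value '", raw[bad[1L, , drop = FALSE]],
         "' in ", what, " matrix at row '", ids[bad[1L, 1L]],
         "', column '", col_ids[bad[1L, 2L]], "'")
  }
  num[miss] <- NA_real_
  if (any(is.infinite(num))) {
    stop("non-finite value in ", what, " matrix")
  }
  dimnames(num) <- list(ids, col_ids)
  num
}

.write_delim_matrix <- function(x, path, id_col) {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
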