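#' Write an expression dataset to TSV files
#'
#' Writes `<path>_expression.tsv` (first column `gene_id`, one column per
#' sample) and `<path>_phenotype.tsv` (columns `sample_id, group, stage,
#' batch`; stage of normal samples encoded `NA`). UTF-8, LF line endings.
#' `read_dataset(write_dataset(ds, p))` reproduces the matrix to 1e-12 and
#' all labels exactly.
#'
#' @param ds an `expr_dataset`.
#' @param path file-path prefix.
#' @return (invisibly) the two file paths written.
#' @export
write_dataset <- function(ds, path) {
  validate_expr_dataset(ds)
  expr_path <- paste0(path, "_expression.tsv")
  pheno_path <- paste0(path, "_phenotype.tsv")
  expr_tbl <- dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(ds$exprs)),
    tibble::as_tibble(ds$exprs))
  readr::write_tsv(expr_tbl, expr_path)
  readr::write_tsv(ds$pheno, pheno_path)
  invisible(c(expression = expr_path, phenotype = pheno_path))
}

#' Read an expression dataset from TSV files
#'
#' Counterpart of [write_dataset()]. Malformed input (ragged rows, duplicate
#' gene or sample ids, phenotype/matrix sample mismatch) raises a parse error
#' identifying the offending line or id.
#'
#' @param path file-path prefix used by [write_dataset()].
#' @return an `expr_dataset` (without planted-truth annotations).
#' @export
read_dataset <- function(path) {
  expr_path <- paste0(path, "_expression.tsv")
  pheno_path <- paste0(path, "_phenotype.tsv")
  expr_tbl <- readr::read_tsv(expr_path, show_col_types = FALSE,
                              progress = FALSE)
  stop_on_parse_problems(expr_tbl, expr_path)
  pheno <- readr::read_tsv(pheno_path, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  stop_on_parse_problems(pheno, pheno_path)

  if (!identical(names(expr_tbl)[1], "gene_id")) {
    abort(sprintf("%s: first column must be `gene_id`", expr_path),
          class = "stagenet_parse_error")
  }
  need <- c("sample_id", "group", "stage", "batch")
  if (!all(need %in% names(pheno))) {
    abort(sprintf("%s: missing column(s) %s", pheno_path,
                  paste(setdiff(need, names(pheno)), collapse = ", ")),
          class = "stagenet_parse_error")
  }
  if (anyDuplicated(expr_tbl$gene_id)) {
    dup <- unique(expr_tbl$gene_id[duplicated(expr_tbl$gene_id)])
    abort(sprintf("%s: duplicate gene id(s): %s", expr_path,
                  paste(dup, collapse = ", ")),
          class = "stagenet_parse_error")
  }
  X <- as.matrix(expr_tbl[, -1])
  if (!is.numeric(X)) {
    abort(sprintf("%s: non-numeric expression values", expr_path),
          class = "stagenet_parse_error")
  }
  rownames(X) <- expr_tbl$gene_id

  missing_pheno <- setdiff(colnames(X), pheno$sample_id)
  if (length(missing_pheno)) {
    abort(sprintf("%s: sample(s) missing from phenotype: %s", pheno_path,
                  paste(missing_pheno, collapse = ", ")),
          class = "stagenet_parse_error")
  }
  extra_pheno <- setdiff(pheno$sample_id, colnames(X))
  if (length(extra_pheno)) {
    abort(sprintf("%s: phenotype sample(s) absent from matrix: %s",
                  pheno_path, paste(extra_pheno, collapse = ", ")),
          class = "stagenet_parse_error")
  }
  pheno <- pheno[match(colnames(X), pheno$sample_id), ]
  ds <- new_expr_dataset(exprs = X, pheno = pheno)
  validate_expr_dataset(ds)
  ds
}

stop_on_parse_problems <- function(tbl, path) {
  probs <- readr::problems(tbl)
  if (nrow(probs)) {
    abort(sprintf("%s: parse problem at line %d: %s", path,
                  probs$row[1], probs$expected[1]),
          class = "stagenet_parse_error")
  }
  invisible(tbl)
}

#' Read gene sets in GMT format
#'
#' GMT lines are `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return a named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    abort(sprintf("%s: GMT line %d has fewer than 3 fields", path, bad[1]),
          class = "stagenet_parse_error")
  }
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, "", 1L))
}
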