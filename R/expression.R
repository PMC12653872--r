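#' Expression matrix container
#'
#' A light S3 container for a genes-by-samples expression matrix with
#' tumor/normal group labels and a platform kind.  Counts cohorts hold
#' non-negative integer counts; intensity cohorts hold log2-scale values.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param groups character or factor of length `ncol(values)` with levels
#'   `tumor` and `normal`.
#' @param platform one of `"counts"`, `"intensity"`, `"logcpm"`.
#' @return an object of class `tmr_expr`.
#' @export
expression_matrix <- function(values, groups,
                              platform = c("counts", "intensity", "logcpm")) {
  platform <- match.arg(platform)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames")
  if (length(groups) != ncol(values))
    stop("`groups` must have one label per sample")
  groups <- as.character(groups)
  if (!all(groups %in% c("tumor", "normal")))
    stop("group labels must be 'tumor' or 'normal'")
  if (platform == "counts") {
    if (any(values < 0)) stop("counts matrix must be non-negative")
  }
  if (anyDuplicated(rownames(values)))
    values <- consolidate_duplicates(values)
  structure(
    list(values = values, genes = rownames(values),
         samples = colnames(values), groups = groups, platform = platform),
    class = "tmr_expr")
}

#' @export
print.tmr_expr <- function(x, ...) {
  cat(sprintf("<tmr_expr> %d genes x %d samples [%s], %d tumor / %d normal\n",
              nrow(x$values), ncol(x$values), x$platform,
              sum(x$groups == "tumor"), sum(x$groups == "normal")))
  invisible(x)
}

#' @export
dim.tmr_expr <- function(x) dim(x$values)

#' Write an expression cohort to TSV
#'
#' Emits the matrix as a tab-separated file (first column `gene`, header row
#' of sample ids) and a two-column sample sheet (`sample`, `group`).
#'
#' @param mat a [expression_matrix()] object.
#' @param path output TSV path for the matrix.
#' @param sample_sheet output path for the sample sheet; defaults to
#'   `<path>` with a `.samples.tsv` suffix.
#' @return invisibly, the two paths written.
#' @export
write_expression <- function(mat, path, sample_sheet = NULL) {
  stopifnot(inherits(mat, "tmr_expr"))
  sample_sheet <- sample_sheet %||% sub("(\\.tsv)?$", ".samples.tsv", path)
  df <- data.frame(gene = mat$genes, mat$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = mat$samples, group = mat$groups),
              sample_sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = path, samples = sample_sheet))
}

#' Read an expression cohort from TSV
#'
#' Counterpart of [write_expression()].  Duplicate gene ids are consolidated
#' by keeping the row that agrees most often with the per-cell statistical
#' mode of its duplicate group (first row on ties).
#'
#' @param path TSV matrix path (first column gene id, header of sample ids).
#' @param sample_sheet two-column sample sheet path.
#' @param platform platform kind of the cohort.
#' @return a [expression_matrix()] object.
#' @export
read_expression <- function(path, sample_sheet,
                            platform = c("counts", "intensity", "logcpm")) {
  platform <- match.arg(platform)
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  sheet <- read.delim(sample_sheet)
  groups <- setNames(as.character(sheet$group), sheet$sample)[colnames(m)]
  expression_matrix(m, groups, platform)
}
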