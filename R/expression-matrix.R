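#' Construct an expression matrix with sample metadata
#'
#' Bundles a probes x samples intensity matrix with its sample sheet
#' (genotype, condition, replicate) and a scale flag. This is the container
#' every pipeline stage passes along; all readers and the simulator return
#' one.
#'
#' @param values Numeric matrix, probes in rows, samples in columns. Row
#'   names are probe identifiers, column names sample identifiers.
#' @param samples Data frame with columns `sample_id`, `genotype`,
#'   `condition` (one of `"control"`, `"stressed"`) and `replicate`
#'   (integer >= 1), one row per column of `values`, in column order.
#' @param scale Either `"linear"` (raw intensities) or `"log2"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `samples` and `scale`.
#' @export
expression_matrix <- function(values, samples, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry probe row names and sample column names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate probe id: ", dup[[1L]])
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must all be finite")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  needed <- c("sample_id", "genotype", "condition", "replicate")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols))
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("sample sheet has ", nrow(samples), " rows but matrix has ",
         ncol(values), " columns")
  if (!identical(as.character(samples$sample_id), colnames(values)))
    stop("sample sheet rows must match matrix columns in order")
  bad_cond <- setdiff(unique(samples$condition), c("control", "stressed"))
  if (length(bad_cond))
    stop("unknown condition label: ", bad_cond[[1L]])
  samples$replicate <- as.integer(samples$replicate)
  if (anyNA(samples$replicate) || any(samples$replicate < 1L))
    stop("replicate indices must be integers >= 1")
  structure(list(values = values, samples = samples, scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " probes x ",
      ncol(x$values), " samples (", x$scale, " scale)\n", sep = "")
  tab <- table(x$samples$condition)
  cat("  conditions:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  genotypes: ", length(unique(x$samples$genotype)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset the sample columns of an expression matrix
#'
#' @param x An `expression_matrix`.
#' @param j Column index (logical, integer or sample-id character vector).
#' @return An `expression_matrix` with the selected columns and their
#'   sample-sheet rows; probe values are untouched.
#' @keywords internal
#' @export
subset_samples <- function(x, j) {
  stopifnot(inherits(x, "expression_matrix"))
  if (is.character(j)) j <- match(j, colnames(x$values))
  vals <- x$values[, j, drop = FALSE]
  expression_matrix(vals, x$samples[j, , drop = FALSE], scale = x$scale)
}

#' Read an expression matrix and its sample sheet from TSV files
#'
#' The expression file is tab-separated with a header row of sample ids and
#' probe ids in the first column. The sample sheet must register every
#' sample column with its genotype, condition and replicate; genotype and
#' condition are never inferred from column names. An optional `scale`
#' column in the sheet (all rows equal, `"linear"` or `"log2"`) sets the
#' scale flag; the default is linear intensities.
#'
#' @param path Path to the expression TSV.
#' @param sample_sheet Path to the sample-sheet TSV with columns
#'   `sample_id`, `genotype`, `condition`, `replicate` and optionally
#'   `scale`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, sample_sheet) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L)
    stop("expression file needs a probe-id column plus >=1 sample column")
  probes <- raw[[1L]]
  dup <- probes[duplicated(probes)]
  if (length(dup))
    stop("duplicate probe id: ", dup[[1L]])
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric expression cell at probe ", probes[bad[[1L]]],
         ", sample ", colnames(cells)[bad[[2L]]])
  }
  dimnames(num) <- list(probes, colnames(cells))

  sheet <- utils::read.delim(sample_sheet, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("sample_id", "genotype", "condition", "replicate")
  missing_cols <- setdiff(needed, names(sheet))
  if (length(missing_cols))
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  unregistered <- setdiff(colnames(num), sheet$sample_id)
  if (length(unregistered))
    stop("unregistered sample ", unregistered[[1L]])
  sheet <- sheet[match(colnames(num), sheet$sample_id), , drop = FALSE]
  scale <- "linear"
  if ("scale" %in% names(sheet)) {
    sc <- unique(sheet$scale)
    if (length(sc) != 1L)
      stop("sample sheet `scale` column must be constant")
    scale <- sc
  }
  expression_matrix(num, sheet[, needed], scale = scale)
}

#' Write an expression matrix and sample sheet to TSV files
#'
#' Inverse of [read_expression_matrix()]; a read-write-read round trip is
#' value-identical (values are printed at full precision).
#'
#' @param x An `expression_matrix`.
#' @param path Output path for the expression TSV.
#' @param sheet_path Output path for the sample sheet (includes the scale
#'   flag); omit to skip writing the sheet.
#' @return Invisibly, `x`.
#' @export
write_expression_matrix <- function(x, path, sheet_path = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(probe_id = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sheet_path)) {
    sheet <- x$samples
    sheet$scale <- x$scale
    utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}
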