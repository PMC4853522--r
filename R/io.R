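#' Read a genotype x trait table
#'
#' Rows are genotypes (first column), columns are morpho-physiological
#' traits. Empty cells or `NA` mark missing measurements and are kept as
#' `NA`, never imputed.
#'
#' @param path Path to a TSV with genotypes in the first column and one
#'   column per trait.
#' @return A `trait_table`: a data frame of trait values with genotype row
#'   names.
#' @export
read_trait_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (ncol(raw) < 2L)
    stop("trait file needs a genotype column plus >=1 trait column")
  genotypes <- as.character(raw[[1L]])
  dup <- genotypes[duplicated(genotypes)]
  if (length(dup))
    stop("duplicate genotype row: ", dup[[1L]])
  values <- raw[, -1L, drop = FALSE]
  for (trait in names(values)) {
    v <- suppressWarnings(as.numeric(values[[trait]]))
    if (all(is.na(v)))
      stop("trait column with no non-missing values: ", trait)
    if (any(is.na(v) & !is.na(values[[trait]])))
      stop("non-numeric trait value in column ", trait)
    values[[trait]] <- v
  }
  rownames(values) <- genotypes
  trait_table(values)
}

#' @rdname read_trait_table
#' @param values Data frame of numeric trait columns with genotype row
#'   names (used to build a table programmatically).
#' @export
trait_table <- function(values) {
  values <- as.data.frame(values)
  if (is.null(rownames(values)))
    stop("trait table needs genotype row names")
  if (!all(vapply(values, is.numeric, logical(1L))))
    stop("all trait columns must be numeric")
  if (any(vapply(values, function(v) all(is.na(v)), logical(1L))))
    stop("trait column with no non-missing values")
  inf <- vapply(values, function(v) any(is.infinite(v)), logical(1L))
  if (any(inf))
    stop("non-finite trait value in column ", names(values)[inf][[1L]])
  class(values) <- c("trait_table", "data.frame")
  values
}

#' Write a trait table to TSV
#' @param x A `trait_table`.
#' @param path Output path.
#' @return Invisibly, `x`.
#' @export
write_trait_table <- function(x, path) {
  df <- data.frame(genotype = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Parse rice RAP-DB locus identifiers
#'
#' RAP-DB identifiers follow `Os<chromosome>g<locus>` with a two-digit
#' chromosome (01-12) and a seven-digit locus number, e.g. `Os09g0286400`
#' sits on chromosome 9. Parsing is strict and case-sensitive; malformed
#' identifiers raise an error naming the offending string.
#'
#' @param locus_id Character vector of identifiers.
#' @return A data frame with columns `locus_id`, `chromosome` (integer
#'   1-12) and `locus_number` (integer).
#' @seealso [format_rap_locus()] for the inverse, and
#'   [chromosome_distribution()] for a tolerant tally.
#' @export
parse_rap_locus <- function(locus_id) {
  locus_id <- as.character(locus_id)
  ok <- grepl("^Os(0[1-9]|1[0-2])g[0-9]{7}$", locus_id)
  if (!all(ok))
    stop("malformed RAP locus id: ", locus_id[!ok][[1L]])
  data.frame(locus_id = locus_id,
             chromosome = as.integer(substr(locus_id, 3L, 4L)),
             locus_number = as.integer(substr(locus_id, 6L, 12L)),
             stringsAsFactors = FALSE)
}

#' @rdname parse_rap_locus
#' @param chromosome Integer vector in 1-12.
#' @param locus_number Integer vector (seven digits when formatted).
#' @export
format_rap_locus <- function(chromosome, locus_number) {
  if (any(chromosome < 1L | chromosome > 12L))
    stop("chromosome must lie in 1-12")
  sprintf("Os%02dg%07d", as.integer(chromosome), as.integer(locus_number))
}

#' Read a GO annotation table
#'
#' Accepts either a plain TSV with columns gene, term and optionally
#' namespace and label (assumed pre-propagated to ancestor terms), or a
#' GAF 2.x file (comment lines starting with `!`, 17 columns; gene from
#' column 2, term from column 5, namespace from the aspect code in column
#' 9).
#'
#' @param path Path to the annotation file.
#' @return A `go_annotation`: a data frame with columns `gene`, `term`,
#'   `namespace`, `label`, one row per gene-term pair (deduplicated).
#' @export
read_go_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  is_gaf <- startsWith(first, "!")
  if (is_gaf) {
    raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                             comment.char = "!", stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(raw) != 17L)
      stop("GAF file must have 17 columns, found ", ncol(raw))
    aspect <- c(P = "biological_process", F = "molecular_function",
                C = "cellular_component")[raw[[9L]]]
    ann <- data.frame(gene = raw[[2L]], term = raw[[5L]],
                      namespace = unname(aspect), label = raw[[10L]],
                      stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!all(c("gene", "term") %in% names(raw)))
      stop("GO annotation TSV needs columns `gene` and `term`")
    ann <- data.frame(gene = raw$gene, term = raw$term,
                      namespace = if ("namespace" %in% names(raw))
                        raw$namespace else "molecular_function",
                      label = if ("label" %in% names(raw)) raw$label
                      else raw$term,
                      stringsAsFactors = FALSE)
  }
  ann <- ann[!duplicated(ann[c("gene", "term")]), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("go_annotation", "data.frame")
  ann
}

#' Read a RAP-to-MSU identifier mapping
#'
#' @param path TSV with two columns: RAP-DB id, MSU (TIGR) id. A header is
#'   optional (detected when the first line does not look like an id pair).
#'   Identical duplicate rows are collapsed; conflicting duplicate keys are
#'   an error.
#' @return An `id_mapping`: a named character vector (names = RAP ids,
#'   values = MSU ids).
#' @export
read_id_mapping <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L)
    stop("mapping file needs two columns (RAP id, MSU id)")
  if (nrow(raw) && !grepl("^Os", raw[[1L]][[1L]]))
    raw <- raw[-1L, , drop = FALSE]
  raw <- raw[!duplicated(raw[1:2]), , drop = FALSE]
  dup <- raw[[1L]][duplicated(raw[[1L]])]
  if (length(dup))
    stop("conflicting duplicate mapping key: ", dup[[1L]])
  bad <- !grepl("^LOC_Os[0-9]{2}g[0-9]{5}$", raw[[2L]])
  if (any(bad))
    stop("MSU id does not match LOC_Os##g##### pattern: ",
         raw[[2L]][bad][[1L]])
  mapping <- stats::setNames(raw[[2L]], raw[[1L]])
  class(mapping) <- "id_mapping"
  mapping
}

#' Read a protein-interaction edge list
#'
#' @param path TSV with two or three columns: node, node, optional
#'   confidence weight. A header row is detected by a non-numeric third
#'   column value or the literal names node_a/node_b. Self-edges are
#'   dropped (with a message stating how many) and duplicate unordered
#'   pairs collapsed, keeping the first confidence seen.
#' @return An `interaction_edges` data frame with columns `node_a`,
#'   `node_b` and `confidence` (NA when absent).
#' @export
read_interaction_edges <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!ncol(raw) %in% c(2L, 3L))
    stop("edge list needs two or three columns, found ", ncol(raw))
  if (nrow(raw) && raw[[1L]][[1L]] %in% c("node_a", "node", "source"))
    raw <- raw[-1L, , drop = FALSE]
  conf <- if (ncol(raw) == 3L) suppressWarnings(as.numeric(raw[[3L]]))
          else rep(NA_real_, nrow(raw))
  interaction_edges(raw[[1L]], raw[[2L]], conf)
}

#' @rdname read_interaction_edges
#' @param node_a,node_b Character vectors of endpoints.
#' @param confidence Optional numeric weights.
#' @export
interaction_edges <- function(node_a, node_b, confidence = NULL) {
  if (is.null(confidence)) confidence <- rep(NA_real_, length(node_a))
  self <- node_a == node_b
  if (any(self))
    message("dropped ", sum(self), " self-edge(s)")
  df <- data.frame(node_a = node_a[!self], node_b = node_b[!self],
                   confidence = confidence[!self],
                   stringsAsFactors = FALSE)
  # canonical orientation so duplicate unordered pairs collapse
  flip <- df$node_a > df$node_b
  tmp <- df$node_a[flip]; df$node_a[flip] <- df$node_b[flip]
  df$node_b[flip] <- tmp
  df <- df[!duplicated(df[c("node_a", "node_b")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interaction_edges", "data.frame")
  df
}

#' Write a significant-gene table to TSV
#'
#' One row per selected probe with its fold score d and q-value (%), both
#' printed to two decimals, sorted by decreasing |d| with lexicographic
#' probe-id tie-break.
#'
#' @param result A `significant_gene_set` from [select_significant()].
#' @param path Output path.
#' @param annotation Optional named character vector of per-probe
#'   functional annotations.
#' @return Invisibly, the data frame written.
#' @export
write_significant_table <- function(result, path, annotation = NULL) {
  stopifnot(inherits(result, "significant_gene_set"))
  df <- as.data.frame(result)
  ord <- order(-abs(df$d), df$probe_id)
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  out <- data.frame(
    probe_name = df$probe_id,
    annotation = if (is.null(annotation)) rep("", n) else
      ifelse(is.na(annotation[df$probe_id]), "", annotation[df$probe_id]),
    fold_score_d = sprintf("%.2f", df$d),
    q_value_percent = sprintf("%.2f", df$q),
    direction = df$direction,
    trait = rep(attr(result, "trait") %||% "", n),
    condition = rep(attr(result, "condition") %||% "", n),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
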