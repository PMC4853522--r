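#' Quantile-normalize an expression matrix
#'
#' Forces every sample column onto the common reference distribution given
#' by the row-wise mean of the column-wise sorted data. Tied values within
#' a column receive the mean of the reference values at their tied ranks,
#' so the operation is deterministic and idempotent.
#'
#' @param x An [expression_matrix()] with at least two samples.
#' @return An `expression_matrix` of the same shape and scale flag.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  vals <- x$values
  if (ncol(vals) < 2L)
    stop("quantile normalization needs >=2 samples")
  if (anyNA(vals))
    stop("NaN/NA in expression values")
  ref <- rowMeans(apply(vals, 2L, sort, method = "radix"))
  out <- vals
  for (j in seq_len(ncol(vals))) {
    o <- order(vals[, j], method = "radix")
    xs <- vals[o, j]
    grp <- cumsum(c(TRUE, xs[-1L] != xs[-length(xs)]))
    out[o, j] <- stats::ave(ref, grp)
  }
  expression_matrix(out, x$samples, scale = x$scale)
}

#' Log2-transform a linear-scale expression matrix
#'
#' @param x An [expression_matrix()] flagged `linear`. If already on log2
#'   scale the matrix is returned unchanged with a warning.
#' @param pseudocount Non-negative constant added before taking logs
#'   (default 0; required > 0 when zeros are present).
#' @return The matrix with values `log2(value + pseudocount)` and scale
#'   flag `log2`.
#' @export
log2_transform <- function(x, pseudocount = 0) {
  stopifnot(inherits(x, "expression_matrix"), pseudocount >= 0)
  if (x$scale == "log2") {
    warning("matrix already on log2 scale; returning unchanged")
    return(x)
  }
  if (any(x$values + pseudocount <= 0))
    stop("non-positive value with pseudocount ", pseudocount,
         "; increase the pseudocount")
  expression_matrix(log2(x$values + pseudocount), x$samples, scale = "log2")
}

#' Split an expression matrix into control and stressed halves
#'
#' The two conditions are analyzed separately throughout; this partitions
#' the sample columns by the sample sheet's condition label, preserving
#' probe order.
#'
#' @param x An [expression_matrix()] containing both conditions, each with
#'   at least 4 samples (fewer would make the permutation null vacuous).
#' @return A list with elements `control` and `stressed`.
#' @export
split_by_condition <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  out <- lapply(c(control = "control", stressed = "stressed"), function(cond) {
    j <- which(x$samples$condition == cond)
    if (length(j) < 4L)
      stop("condition ", cond, " has ", length(j),
           " samples; >=4 required")
    subset_samples(x, j)
  })
  out
}

#' Weight a trait onto the [0, 1] scale across genotypes
#'
#' Maps per-genotype raw trait values to comparable responses: `minmax`
#' sets `(v - min)/(max - min)` so the extreme genotypes land exactly on 0
#' and 1; `rank` maps average ranks to `(rank - 1)/(G - 1)`. Genotypes
#' with missing values receive `NA` and are excluded downstream.
#'
#' @param traits A `trait_table`.
#' @param trait Name of the trait column to weight.
#' @param method `"minmax"` (default) or `"rank"`.
#' @return Named numeric vector of weights per genotype, `NA` for
#'   genotypes missing the trait.
#' @export
weight_trait <- function(traits, trait, method = c("minmax", "rank")) {
  method <- match.arg(method)
  stopifnot(inherits(traits, "trait_table"))
  if (!trait %in% names(traits))
    stop("unknown trait: ", trait)
  v <- stats::setNames(traits[[trait]], rownames(traits))
  obs <- v[!is.na(v)]
  if (length(obs) < 2L)
    stop("trait ", trait, " has fewer than 2 genotypes with values")
  if (max(obs) == min(obs))
    stop("degenerate trait ", trait, ": all values equal")
  w <- rep(NA_real_, length(v))
  names(w) <- names(v)
  if (method == "minmax") {
    w[names(obs)] <- (obs - min(obs)) / (max(obs) - min(obs))
  } else {
    r <- rank(obs, ties.method = "average")
    w[names(obs)] <- (r - 1) / (length(obs) - 1)
  }
  attr(w, "method") <- method
  w
}

#' Build the per-sample quantitative response for one trait
#'
#' Assigns every sample column the weighted trait value of its genotype
#' (replicates share their genotype's value verbatim). Columns belonging
#' to genotypes without a weight are dropped with a message; probe values
#' are never altered.
#'
#' @param x An [expression_matrix()] (typically one condition,
#'   preprocessed).
#' @param weights Named per-genotype weights from [weight_trait()]; `NA`
#'   marks exclusion.
#' @param trait Trait name carried along for reporting.
#' @return A `weighted_response`: list with the column-filtered matrix
#'   `expr`, per-sample response `y`, its mean `ybar`, the `trait`,
#'   `method` and `condition` tags, and `n_dropped`.
#' @export
build_response_design <- function(x, weights, trait = "trait") {
  stopifnot(inherits(x, "expression_matrix"))
  g <- x$samples$genotype
  unknown <- setdiff(unique(g), names(weights))
  if (length(unknown))
    stop("genotype without a trait weight or exclusion flag: ",
         unknown[[1L]])
  y <- unname(weights[g])
  keep <- !is.na(y)
  if (!any(keep))
    stop("all genotypes excluded for trait ", trait)
  if (any(!keep))
    message("dropped ", sum(!keep),
            " sample column(s) of genotypes missing trait ", trait)
  expr <- subset_samples(x, which(keep))
  y <- y[keep]
  if (length(unique(y)) < 2L)
    stop("fewer than 2 distinct response values for trait ", trait)
  conds <- unique(expr$samples$condition)
  structure(list(expr = expr,
                 y = stats::setNames(y, expr$samples$sample_id),
                 ybar = mean(y),
                 trait = trait,
                 method = attr(weights, "method") %||% "minmax",
                 condition = if (length(conds) == 1L) conds else "mixed",
                 n_dropped = sum(!keep)),
            class = "weighted_response")
}
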