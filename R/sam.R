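#' Quantitative-response SAM scores
#'
#' Regresses each probe's expression on the weighted trait response and
#' forms the SAM statistic `d = r/(s + s0)`, where `r` is the least-squares
#' slope and `s` its standard error. Probes with zero variance get
#' `r = s = d = 0`.
#'
#' For probe i with expression `x_ij` over samples j and response `y_j`:
#' `r_i = sum_j x_ij (y_j - ybar) / sum_j (y_j - ybar)^2`, and
#' `s_i = sqrt(RSS_i / (n - 2)) / sqrt(sum_j (y_j - ybar)^2)` with `RSS_i`
#' the residual sum of squares from the intercept + slope fit.
#'
#' @param response A `weighted_response` from [build_response_design()]
#'   (carries the matrix and the per-sample y).
#' @param s0 Fudge factor, a non-negative constant added to every `s_i`
#'   (see [estimate_s0()]).
#' @param y Optional replacement response vector (same length as the
#'   samples) used internally for permutations.
#' @return A `sam_scores` object: list with vectors `r`, `s`, `d`, scalar
#'   `s0`, and `probe_ids`.
#' @export
compute_regression_scores <- function(response, s0 = 0, y = NULL) {
  stopifnot(inherits(response, "weighted_response"), s0 >= 0)
  X <- response$expr$values
  if (is.null(y)) y <- unname(response$y)
  n <- length(y)
  if (n < 4L)
    stop("need >=4 samples, got ", n)
  if (length(unique(y)) < 2L)
    stop("all response values equal")
  yc <- y - mean(y)
  syy <- sum(yc^2)
  r <- drop(X %*% yc) / syy
  xc <- X - rowMeans(X)
  sxx <- rowSums(xc^2)
  rss <- pmax(sxx - r^2 * syy, 0)
  s <- sqrt(rss / (n - 2)) / sqrt(syy)
  zero <- sxx == 0
  r[zero] <- 0
  s[zero] <- 0
  d <- r / (s + s0)
  d[s + s0 == 0 & r == 0] <- 0
  structure(list(r = unname(r), s = unname(s), d = unname(d), s0 = s0,
                 probe_ids = rownames(X)),
            class = "sam_scores")
}

#' Estimate the SAM fudge factor s0
#'
#' Searches candidate percentiles 0, 5, ..., 100 of the standard-error
#' distribution. For each candidate `s0 = quantile(s, alpha)` the scores
#' `d = r/(s + s0)` are binned into up to 100 equal-count bins by `s`; the
#' dispersion of each bin is `1.4826 x MAD`, and the candidate minimizing
#' the coefficient of variation of these bin dispersions is chosen. This
#' stabilizes scores of low-variance probes without over-shrinking the
#' rest.
#'
#' @param r Per-probe slopes.
#' @param s Per-probe slope standard errors (same length).
#' @return List with `s0` (always an exact percentile of `s`) and
#'   `percentile` (the chosen alpha, in 0-100). With fewer than two
#'   distinct `s` values, falls back to `s0 = median(s)` with a warning.
#' @export
estimate_s0 <- function(r, s) {
  stopifnot(length(r) == length(s))
  if (length(unique(s)) < 2L) {
    warning("fewer than 2 distinct s values; falling back to s0 = median(s)")
    return(list(s0 = stats::median(s), percentile = 50))
  }
  alphas <- seq(0, 100, by = 5)
  cand <- stats::quantile(s, alphas / 100, names = FALSE, type = 7)
  nbins <- min(100L, max(2L, floor(length(s) / 2)))
  breaks <- unique(stats::quantile(s, seq(0, 1, length.out = nbins + 1L),
                                   names = FALSE))
  bin <- cut(s, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    spread <- tapply(d, bin, stats::mad)  # mad() constant = 1.4826
    spread <- spread[is.finite(spread)]
    if (length(spread) < 2L || mean(spread) == 0) return(Inf)
    stats::sd(spread) / mean(spread)
  }, numeric(1L))
  best <- which.min(cv)
  list(s0 = cand[[best]], percentile = alphas[[best]], cv = unname(cv))
}

# All distinct permutations of a (possibly tied) value vector, one per
# column. Only called for small counts, guarded by the caller.
distinct_permutations <- function(y) {
  rec <- function(vals) {
    if (length(vals) == 1L) return(list(vals))
    out <- list()
    for (v in unique(vals)) {
      rest <- vals[-match(v, vals)]
      out <- c(out, lapply(rec(rest), function(p) c(v, p)))
    }
    out
  }
  perms <- rec(sort(y))
  matrix(unlist(perms), nrow = length(y))
}

n_distinct_permutations <- function(y) {
  counts <- table(y)
  exp(lgamma(length(y) + 1) - sum(lgamma(counts + 1)))
}

#' Permutation null distribution of SAM scores
#'
#' Permutes the response values uniformly at random across sample columns
#' (plain sample-label permutation; replicate ties in y are allowed in the
#' permuted vectors) and recomputes `d` with the fudge factor fixed at its
#' observed-data estimate. When the number of distinct permutations of y
#' does not exceed `B`, all of them are enumerated instead and the null is
#' exact (a message is emitted).
#'
#' @param response A `weighted_response`.
#' @param s0 Fudge factor from the observed data.
#' @param B Number of permutations (default 100, minimum 10).
#' @param seed Integer seed for the permutation draws.
#' @param blocks `"samples"` (default) permutes the response across
#'   individual sample columns; `"genotype"` permutes whole genotype
#'   blocks (each genotype's replicates move together), a coarser null
#'   that respects replicate structure.
#' @return A `permutation_null` object: list with `dstar` (probes x B
#'   matrix of permuted scores), `dbar` (expected order statistics: the
#'   mean over permutations of the k-th smallest score), `B`, `exact`
#'   flag, `seed`, `blocks`, and `perm` (the permuted response vectors,
#'   one column per permutation).
#' @export
permutation_null <- function(response, s0, B = 100L, seed = 1L,
                             blocks = c("samples", "genotype")) {
  stopifnot(inherits(response, "weighted_response"))
  blocks <- match.arg(blocks)
  if (B < 10L)
    stop("B must be >= 10")
  y <- unname(response$y)
  if (blocks == "genotype") {
    g <- response$expr$samples$genotype
    yg <- tapply(y, g, unique)
    if (any(lengths(yg) != 1L))
      stop("block permutation requires one response value per genotype")
    base <- vapply(yg, `[[`, numeric(1L), 1L)
  } else {
    base <- y
  }
  n_exact <- n_distinct_permutations(base)
  exact <- n_exact <= B
  if (exact) {
    message("enumerating all ", round(n_exact),
            " distinct permutations (exact null)")
    perm <- distinct_permutations(base)
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    perm <- vapply(seq_len(B), function(b) sample(base),
                   numeric(length(base)))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  if (blocks == "genotype")
    perm <- perm[match(g, names(yg)), , drop = FALSE]
  X <- response$expr$values
  yc <- sweep(perm, 2L, colMeans(perm))
  syy <- colSums(yc^2)
  R <- sweep(X %*% yc, 2L, syy, "/")
  xc <- X - rowMeans(X)
  sxx <- rowSums(xc^2)
  n <- length(y)
  rss <- pmax(sxx - sweep(R^2, 2L, syy, "*"), 0)
  S <- sweep(sqrt(rss / (n - 2)), 2L, sqrt(syy), "/")
  zero <- sxx == 0
  R[zero, ] <- 0
  S[zero, ] <- 0
  dstar <- R / (S + s0)
  dstar[S + s0 == 0 & R == 0] <- 0
  dimnames(dstar) <- NULL
  dbar <- rowMeans(apply(dstar, 2L, sort, method = "radix"))
  structure(list(dstar = dstar, dbar = dbar, B = ncol(dstar),
                 exact = exact, seed = seed, blocks = blocks,
                 perm = perm),
            class = "permutation_null")
}

count_ge <- function(sorted, cut) {
  if (!is.finite(cut) && cut > 0) return(0L)
  length(sorted) - findInterval(cut, sorted, left.open = TRUE)
}
count_le <- function(sorted, cut) {
  if (!is.finite(cut) && cut < 0) return(0L)
  findInterval(cut, sorted)
}

#' Permutation FDR table and per-probe q-values
#'
#' Walks the sorted observed scores against the expected order statistics
#' of the permutation null. For each threshold delta, the walk moves down
#' from the largest observed score while `d_(k) - dbar_(k) >= delta` (the
#' upper cut is the smallest score reached) and up from the smallest while
#' `dbar_(k) - d_(k) >= delta` (the lower cut is the largest score
#' reached); probes outside the cuts are called, so each called block is
#' contiguous in d and q-values are monotone in |d| on each side. False calls are counted per permutation at the same
#' cuts and summarized by the median (or the 90th percentile). The null
#' proportion `pi0` is estimated from the fraction of observed scores
#' inside the interquartile band of all permuted scores, and
#' `FDR(delta) = 100 * pi0 * false / max(1, called)` (percent). A probe's
#' q-value is the smallest FDR over all deltas at which it is called;
#' probes never called get q = 100.
#'
#' @param scores A `sam_scores` object.
#' @param null A `permutation_null` from the same matrix/response.
#' @param delta_grid Increasing non-negative thresholds; default 200
#'   evenly spaced values from 0 to `max |d_(k) - dbar_(k)|`.
#' @param false_summary Summary of per-permutation false-call counts:
#'   `"median"` (default) or `"q90"` (the 90th percentile, which is more
#'   conservative at extreme cuts where the median count collapses to
#'   zero).
#' @return List with `table` (data frame: delta, cut_lower, cut_upper,
#'   called, false_calls, pi0, fdr_percent) and `q` (named per-probe
#'   q-values in percent).
#' @export
fdr_and_qvalues <- function(scores, null, delta_grid = NULL,
                            false_summary = c("median", "q90")) {
  stopifnot(inherits(scores, "sam_scores"),
            inherits(null, "permutation_null"))
  false_summary <- match.arg(false_summary)
  d <- scores$d
  m <- length(d)
  ord <- order(d)
  ds <- d[ord]
  dbar <- null$dbar
  stopifnot(length(dbar) == m)
  gap <- ds - dbar
  if (is.null(delta_grid))
    delta_grid <- seq(0, max(abs(gap)), length.out = 200L)
  if (!length(delta_grid))
    stop("empty delta grid")
  band <- stats::quantile(null$dstar, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, sum(d >= band[[1L]] & d <= band[[2L]]) / (0.5 * m))
  perm_sorted <- apply(null$dstar, 2L, sort, method = "radix")
  summarize <- if (false_summary == "median") stats::median else
    function(x) stats::quantile(x, 0.9, names = FALSE, type = 7)

  q <- rep(100, m)
  rows <- lapply(delta_grid, function(delta) {
    # walk inward from each extreme while the observed-vs-expected gap
    # stays >= delta; the cut is the innermost observed d reached
    below <- which(gap < delta)
    cut_up <- if (!length(below)) ds[[1L]] else
      if (max(below) == m) Inf else ds[[max(below) + 1L]]
    above <- which(-gap < delta)
    cut_lo <- if (!length(above)) ds[[m]] else
      if (min(above) == 1L) -Inf else ds[[min(above) - 1L]]
    called_mask <- d >= cut_up | d <= cut_lo
    called <- sum(called_mask)
    false_b <- vapply(seq_len(ncol(perm_sorted)), function(b)
      count_ge(perm_sorted[, b], cut_up) + count_le(perm_sorted[, b], cut_lo),
      numeric(1L))
    fc <- summarize(false_b)
    fdr <- min(100, 100 * pi0 * fc / max(1, called))
    if (called == 0L) fdr <- 0
    q[called_mask] <<- pmin(q[called_mask], fdr)
    data.frame(delta = delta, cut_lower = cut_lo, cut_upper = cut_up,
               called = called, false_calls = fc, pi0 = pi0,
               fdr_percent = fdr)
  })
  tab <- do.call(rbind, rows)
  names(q) <- scores$probe_ids
  list(table = tab, q = q)
}

#' Select significant probes at combined FDR and score thresholds
#'
#' Keeps probes with `q <= max_fdr_percent` and `|d| >= min_abs_d`
#' (defaults: 5% FDR and 2-fold score), partitioned by the sign of d into
#' positively and negatively expressed lists.
#'
#' @param scores A `sam_scores` object.
#' @param q Per-probe q-values (percent) from [fdr_and_qvalues()].
#' @param max_fdr_percent Maximum q-value, in percent (default 5).
#' @param min_abs_d Minimum absolute score (default 2).
#' @param trait,condition Tags recorded on the result.
#' @return A `significant_gene_set`: data frame with columns `probe_id`,
#'   `d`, `q`, `direction`, with the thresholds and tags as attributes.
#' @export
select_significant <- function(scores, q, max_fdr_percent = 5,
                               min_abs_d = 2, trait = NA_character_,
                               condition = NA_character_) {
  stopifnot(inherits(scores, "sam_scores"))
  keep <- q <= max_fdr_percent & abs(scores$d) >= min_abs_d
  df <- data.frame(probe_id = scores$probe_ids[keep],
                   d = scores$d[keep],
                   q = unname(q[keep]),
                   direction = ifelse(scores$d[keep] > 0,
                                      "positive", "negative"),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("significant_gene_set", "data.frame"),
            trait = trait, condition = condition,
            thresholds = list(max_fdr_percent = max_fdr_percent,
                              min_abs_d = min_abs_d))
}

#' Run the full quantitative-response SAM analysis for one trait
#'
#' Composes trait weighting, response design, score computation (with the
#' fudge factor estimated from the observed data and reused for every
#' permutation), the permutation null, FDR/q-value estimation and
#' combined-threshold selection.
#'
#' @param x A preprocessed (normalized, log2) [expression_matrix()] for a
#'   single condition.
#' @param traits A `trait_table`.
#' @param trait Trait column name.
#' @param B Number of permutations (default 100).
#' @param seed Integer seed for the permutation draws.
#' @param weighting `"minmax"` or `"rank"` trait weighting.
#' @param max_fdr_percent,min_abs_d Selection thresholds (defaults 5, 2).
#' @param false_summary Passed to [fdr_and_qvalues()].
#' @param blocks Passed to [permutation_null()] (`"samples"` or
#'   `"genotype"`).
#' @return A `trait_sam_result`: list with `significant`, `fdr_table`,
#'   `q`, `scores`, `null`, `response` and the `s0` estimate.
#' @export
run_trait_sam <- function(x, traits, trait, B = 100L, seed = 1L,
                          weighting = c("minmax", "rank"),
                          max_fdr_percent = 5, min_abs_d = 2,
                          false_summary = c("median", "q90"),
                          blocks = c("samples", "genotype")) {
  weighting <- match.arg(weighting)
  w <- weight_trait(traits, trait, method = weighting)
  response <- build_response_design(x, w, trait = trait)
  raw <- compute_regression_scores(response, s0 = 0)
  s0_fit <- estimate_s0(raw$r, raw$s)
  scores <- compute_regression_scores(response, s0 = s0_fit$s0)
  null <- permutation_null(response, s0 = s0_fit$s0, B = B, seed = seed,
                           blocks = match.arg(blocks))
  fq <- fdr_and_qvalues(scores, null, false_summary = false_summary)
  sig <- select_significant(scores, fq$q, max_fdr_percent = max_fdr_percent,
                            min_abs_d = min_abs_d, trait = trait,
                            condition = response$condition)
  structure(list(significant = sig, fdr_table = fq$table, q = fq$q,
                 scores = scores, null = null, response = response,
                 s0 = s0_fit),
            class = "trait_sam_result")
}

#' @export
print.trait_sam_result <- function(x, ...) {
  sig <- x$significant
  cat("trait_sam_result: trait=", attr(sig, "trait"),
      " condition=", attr(sig, "condition"), "\n", sep = "")
  cat("  s0=", signif(x$s0$s0, 4), " (percentile ", x$s0$percentile,
      "), B=", x$null$B, if (x$null$exact) " (exact)", "\n", sep = "")
  cat("  selected: ", sum(sig$direction == "positive"), " positive, ",
      sum(sig$direction == "negative"), " negative\n", sep = "")
  invisible(x)
}

#' Run SAM for every trait in both conditions
#'
#' Loops [run_trait_sam()] over all trait columns and the control and
#' stressed halves of the matrix, and tallies positive/negative counts per
#' trait and condition.
#'
#' @param x A preprocessed [expression_matrix()] containing both
#'   conditions.
#' @param traits A `trait_table` (interrogates both conditions with the
#'   same trait values, which is the study-design pairing unless a second
#'   table is supplied).
#' @param traits_control Optional separate `trait_table` for the control
#'   condition.
#' @param ... Passed to [run_trait_sam()] (B, seed, weighting,
#'   thresholds).
#' @return List with `counts` (data frame: trait, condition, n_positive,
#'   n_negative) and `results` (named list of `trait_sam_result`, names
#'   `<trait>.<condition>`).
#' @export
run_all_traits <- function(x, traits, traits_control = NULL, ...) {
  halves <- split_by_condition(x)
  trait_names <- names(traits)
  results <- list()
  rows <- list()
  for (cond in names(halves)) {
    tt <- if (cond == "control" && !is.null(traits_control))
      traits_control else traits
    for (trait in trait_names) {
      res <- run_trait_sam(halves[[cond]], tt, trait, ...)
      key <- paste(trait, cond, sep = ".")
      results[[key]] <- res
      sig <- res$significant
      rows[[key]] <- data.frame(
        trait = trait, condition = cond,
        n_positive = sum(sig$direction == "positive"),
        n_negative = sum(sig$direction == "negative"),
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  list(counts = counts, results = results)
}
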