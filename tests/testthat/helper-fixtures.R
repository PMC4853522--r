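# Builders for small in-code fixtures shared across tests.

# Expression matrix with g genotypes x r replicates for one condition
# (or both when conditions = c("control", "stressed")).
make_expr <- function(values, genotypes, replicates = 1L,
                      conditions = "stressed", scale = "log2") {
  n <- length(genotypes) * replicates * length(conditions)
  stopifnot(ncol(values) == n)
  sheet <- expand.grid(replicate = seq_len(replicates),
                       genotype = genotypes, condition = conditions,
                       stringsAsFactors = FALSE)
  sheet$sample_id <- sprintf("%s_%s_r%d", sheet$genotype,
                             substr(sheet$condition, 1, 3),
                             sheet$replicate)
  sheet <- sheet[, c("sample_id", "genotype", "condition", "replicate")]
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  colnames(values) <- sheet$sample_id
  expression_matrix(values, sheet, scale = scale)
}

# A weighted_response built directly from a matrix and per-sample y
# (bypasses trait weighting; y must be constant within genotype here, so
# each sample is its own genotype when values differ arbitrarily).
make_response <- function(values, y, condition = "stressed") {
  expr <- make_expr(values, genotypes = paste0("g", seq_along(y)),
                    conditions = condition)
  w <- stats::setNames(y, paste0("g", seq_along(y)))
  build_response_design(expr, w, trait = "trait")
}

# Independent per-probe least-squares oracle via lm().
lm_oracle <- function(values, y) {
  fits <- apply(values, 1L, function(x) {
    fit <- summary(stats::lm(x ~ y))
    co <- stats::coef(fit)
    if (nrow(co) < 2L) c(r = 0, s = 0)     # constant probe
    else c(r = co[2L, 1L], s = co[2L, 2L])
  })
  list(r = unname(fits["r", ]), s = unname(fits["s", ]))
}

# All permutations of seq_len(n) as a list (independent of the package's
# distinct-permutation enumerator).
index_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in index_permutations(n - 1L))
    for (pos in seq_len(n))
      out <- c(out, list(append(sub, n, after = pos - 1L)))
  out
}

# The 60 rice RAP-DB locus ids of the ion homeostasis/transport gene set
# used as realistic identifier fixtures.
tableT2_ids <- c(
  "Os01g0557500", "Os01g0645200", "Os05g0382200", "Os06g0152200",
  "Os06g0701600", "Os08g0503700", "Os09g0286400", "Os09g0299400",
  "Os09g0484900", "Os10g0436900", "Os11g0648000", "Os12g0170300",
  "Os12g0641100", "Os01g0210700", "Os01g0369300", "Os01g0648000",
  "Os01g0696100", "Os01g0932500", "Os02g0519100", "Os02g0612700",
  "Os03g0337500", "Os03g0575200", "Os03g0656500", "Os04g0401700",
  "Os04g0682800", "Os06g0625900", "Os06g0671000", "Os07g0102100",
  "Os07g0669700", "Os01g0678500", "Os01g0908500", "Os02g0138900",
  "Os02g0720700", "Os04g0605500", "Os04g0653200", "Os05g0594200",
  "Os03g0150800", "Os03g0161200", "Os03g0195800", "Os03g0838400",
  "Os04g0185600", "Os05g0477800", "Os08g0155400", "Os08g0406400",
  "Os09g0240500", "Os10g0444600", "Os01g0588200", "Os01g0704100",
  "Os01g0975900", "Os02g0117500", "Os02g0255000", "Os02g0823100",
  "Os03g0129100", "Os03g0758300", "Os04g0643600", "Os05g0231700",
  "Os06g0527400", "Os08g0555000", "Os09g0541000", "Os12g0639800")
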