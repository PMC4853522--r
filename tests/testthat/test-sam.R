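test_that("slopes and standard errors match the per-probe lm oracle", {
  set.seed(10)
  for (rep in 1:10) {
    m <- sample(5:20, 1); n <- sample(4:12, 1)
    vals <- matrix(rnorm(m * n, 8, 2), nrow = m)
    y <- round(runif(n), 2)
    if (length(unique(y)) < 2) y[1] <- y[1] + 0.5
    resp <- make_response(vals, y)
    sc <- compute_regression_scores(resp, s0 = 0.3)
    oracle <- lm_oracle(vals, y)
    expect_lt(max(abs(sc$r - oracle$r)), 1e-10)
    expect_lt(max(abs(sc$s - oracle$s)), 1e-10)
    expect_identical(sc$d, sc$r / (sc$s + 0.3))
  }
})

test_that("perfect-fit and constant probes get the stated scores", {
  y <- c(0, 0.25, 0.5, 1)
  vals <- rbind(y,              # x = y exactly: slope 1, zero residual
                rep(3, 4))      # constant probe
  resp <- make_response(vals, y)
  sc <- compute_regression_scores(resp, s0 = 1)
  expect_equal(sc$r[1], 1)
  expect_equal(sc$s[1], 0)
  expect_equal(sc$d[1], 1)     # d = 1/(0+1)
  expect_identical(sc$r[2], 0)
  expect_identical(sc$d[2], 0)
})

test_that("scores respond to scaling, column order and response sign as they must", {
  set.seed(11)
  vals <- matrix(rnorm(30 * 8, 8, 2), nrow = 30)
  y <- c(0, 0.1, 0.3, 0.4, 0.6, 0.7, 0.9, 1)
  resp <- make_response(vals, y)
  sc <- compute_regression_scores(resp, s0 = 0)

  # scale equivariance: x -> c*x multiplies r and s by c, d unchanged (s0=0)
  resp_c <- make_response(3.7 * vals, y)
  sc_c <- compute_regression_scores(resp_c, s0 = 0)
  expect_equal(sc_c$r, 3.7 * sc$r)
  expect_equal(sc_c$s, 3.7 * sc$s)
  expect_equal(sc_c$d, sc$d)

  # permutation invariance: reordering columns with their responses
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  resp_p <- make_response(vals[, perm], y[perm])
  sc_p <- compute_regression_scores(resp_p, s0 = 0)
  expect_equal(sc_p$d, sc$d)

  # sign symmetry: negating the response negates r and d
  resp_n <- make_response(vals, -y)
  sc_n <- compute_regression_scores(resp_n, s0 = 0)
  expect_equal(sc_n$r, -sc$r)
  expect_equal(sc_n$d, -sc$d)

  expect_error(compute_regression_scores(make_response(vals[, 1:3],
                                                       y[1:3])),
               ">=4 samples")
})

test_that("s0 search picks a percentile that stabilizes small-s inflation", {
  set.seed(12)
  # heavy small-s inflation: d = r/s explodes where s is tiny
  s <- rchisq(500, 3) / 10
  r <- rnorm(500) * (s + 0.2)
  fit <- estimate_s0(r, s)
  expect_gt(fit$s0, 0)
  expect_true(any(abs(fit$s0 -
                        quantile(s, seq(0, 1, 0.05), names = FALSE)) <
                    1e-12))
  # exhaustive grid oracle over the same candidates
  alphas <- seq(0, 100, by = 5)
  nbins <- min(100L, max(2L, floor(length(s) / 2)))
  breaks <- unique(quantile(s, seq(0, 1, length.out = nbins + 1),
                            names = FALSE))
  bin <- cut(s, breaks, include.lowest = TRUE, labels = FALSE)
  cv_oracle <- sapply(quantile(s, alphas / 100, names = FALSE),
                      function(s0) {
                        sp <- tapply(r / (s + s0), bin, mad)
                        sd(sp) / mean(sp)
                      })
  expect_equal(fit$cv, unname(cv_oracle))
  expect_lte(fit$cv[match(fit$percentile, alphas)], cv_oracle[1])

  # all s equal: fallback to the median with a warning
  expect_warning(flat <- estimate_s0(rnorm(50), rep(2, 50)),
                 "fewer than 2 distinct s")
  expect_identical(flat$s0, 2)
})

test_that("tiny designs enumerate the exact permutation null", {
  set.seed(13)
  vals <- matrix(rnorm(12 * 4), nrow = 12)
  y <- c(0, 0.2, 0.7, 1)
  resp <- make_response(vals, y)
  expect_message(null <- permutation_null(resp, s0 = 0.1, B = 100,
                                          seed = 1),
                 "24 distinct permutations")
  expect_true(null$exact)
  expect_identical(ncol(null$dstar), 24L)

  # brute-force oracle: all 24 index permutations, scores via lm
  perms <- index_permutations(4L)
  d_oracle <- sapply(perms, function(p) {
    o <- lm_oracle(vals, y[p])
    o$r / (o$s + 0.1)
  })
  sort_cols <- apply(d_oracle, 2, sort)
  expect_equal(null$dbar, rowMeans(sort_cols), tolerance = 1e-12)
  # every enumerated column appears among the oracle's columns
  key <- function(m) sort(apply(round(m, 9), 2, paste, collapse = ","))
  expect_identical(key(null$dstar), key(d_oracle))
})

test_that("Monte-Carlo null is seed-deterministic and centered for pure noise", {
  set.seed(14)
  vals <- matrix(rnorm(80 * 10), nrow = 80)
  y <- seq(0, 1, length.out = 10)
  resp <- make_response(vals, y)
  a <- permutation_null(resp, s0 = 0.05, B = 50, seed = 42)
  b <- permutation_null(resp, s0 = 0.05, B = 50, seed = 42)
  expect_identical(a$dstar, b$dstar)
  expect_false(a$exact)
  # mean of expected order statistics within MC error of 0 for noise
  se <- sd(a$dbar) / sqrt(length(a$dbar))
  expect_lt(abs(mean(a$dbar)), max(3 * se, 0.2))
  expect_error(permutation_null(resp, s0 = 0, B = 5), "B must be >= 10")
})

test_that("genotype-block permutations move replicates together", {
  sim <- generate_dataset(sim_config(n_probes = 30, spike_fraction = 0,
                                     seed = 25))
  norm <- log2_transform(quantile_normalize(sim$expression))
  str <- split_by_condition(norm)$stressed
  w <- weight_trait(sim$traits, "shoot_K")
  resp <- build_response_design(str, w, "shoot_K")
  null <- permutation_null(resp, s0 = 0.1, B = 20, seed = 3,
                           blocks = "genotype")
  expect_identical(ncol(null$dstar), 20L)
  g <- resp$expr$samples$genotype
  within_block <- apply(null$perm, 2, function(p)
    all(tapply(p, g, function(v) length(unique(v))) == 1L))
  expect_true(all(within_block))
  expect_identical(null$dstar,
                   permutation_null(resp, 0.1, B = 20, seed = 3,
                                    blocks = "genotype")$dstar)
  # sample-level permutation differs from the block null
  samp <- permutation_null(resp, s0 = 0.1, B = 20, seed = 3)
  expect_false(identical(null$dstar, samp$dstar))
})

test_that("FDR table and q-values agree with a direct recomputation", {
  set.seed(15)
  sim <- generate_dataset(sim_config(n_probes = 150,
                                     spiked_traits = "shoot_Na",
                                     spike_fraction = 0.05, seed = 31))
  norm <- log2_transform(quantile_normalize(sim$expression))
  str <- split_by_condition(norm)$stressed
  w <- weight_trait(sim$traits, "shoot_Na")
  resp <- build_response_design(str, w, "shoot_Na")
  sc0 <- compute_regression_scores(resp, 0)
  s0 <- estimate_s0(sc0$r, sc0$s)$s0
  sc <- compute_regression_scores(resp, s0)
  null <- permutation_null(resp, s0, B = 40, seed = 7)
  fq <- fdr_and_qvalues(sc, null)

  # naive re-derivation of every table row from the definitions
  d <- sc$d; ds <- sort(d); dbar <- null$dbar; m <- length(d)
  band <- quantile(null$dstar, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, sum(d >= band[1] & d <= band[2]) / (0.5 * m))
  q_naive <- rep(100, m)
  for (i in seq_len(nrow(fq$table))) {
    delta <- fq$table$delta[i]
    # explicit inward walks, written independently of the implementation
    k <- m
    while (k >= 1 && ds[k] - dbar[k] >= delta) k <- k - 1
    cut_up <- if (k == m) Inf else ds[k + 1]
    k <- 1
    while (k <= m && dbar[k] - ds[k] >= delta) k <- k + 1
    cut_lo <- if (k == 1) -Inf else ds[k - 1]
    called <- d >= cut_up | d <= cut_lo
    false_b <- apply(null$dstar, 2,
                     function(col) sum(col >= cut_up) + sum(col <= cut_lo))
    fdr <- min(100, 100 * pi0 * median(false_b) / max(1, sum(called)))
    if (!any(called)) fdr <- 0
    expect_equal(fq$table$cut_upper[i], cut_up)
    expect_equal(fq$table$cut_lower[i], cut_lo)
    expect_identical(fq$table$called[i], sum(called))
    expect_equal(fq$table$fdr_percent[i], fdr)
    q_naive[called] <- pmin(q_naive[called], fdr)
  }
  expect_equal(unname(fq$q), q_naive)

  # q ordering: on one side, a larger |d| never has a larger q
  for (side in list(d > 0, d < 0)) {
    dd <- d[side]; qq <- fq$q[side]
    o <- order(abs(dd), decreasing = TRUE)
    expect_true(all(diff(qq[o]) >= -1e-12))
  }
  expect_error(fdr_and_qvalues(sc, null, delta_grid = numeric(0)),
               "empty delta grid")
})

test_that("an unreachable delta calls nothing and reports FDR 0, q 100", {
  set.seed(16)
  vals <- matrix(rnorm(40 * 8), nrow = 40)
  resp <- make_response(vals, seq(0, 1, length.out = 8))
  sc <- compute_regression_scores(resp, 0.1)
  null <- permutation_null(resp, 0.1, B = 20, seed = 1)
  fq <- fdr_and_qvalues(sc, null, delta_grid = c(1e9))
  expect_identical(fq$table$called, 0L)
  expect_identical(fq$table$fdr_percent, 0)
  expect_true(all(fq$q == 100))
})

test_that("combined selection applies both thresholds with directions", {
  scores <- structure(list(r = 1:3, s = rep(0.1, 3), s0 = 0,
                           d = c(2.25, -3.65, 1.5),
                           probe_ids = c("pA", "pB", "pC")),
                      class = "sam_scores")
  q <- c(pA = 2.34, pB = 0.71, pC = 1)
  sig <- select_significant(scores, q)
  expect_setequal(sig$probe_id, c("pA", "pB"))
  expect_identical(sig$direction[sig$probe_id == "pA"], "positive")
  expect_identical(sig$direction[sig$probe_id == "pB"], "negative")
  expect_false("pC" %in% sig$probe_id)   # |d| = 1.5 < 2 despite q = 1%
})

test_that("the per-trait driver recovers directional spikes and loops cleanly", {
  sim <- generate_dataset(sim_config(n_probes = 400,
                                     spiked_traits = "shoot_Na",
                                     spike_fraction = 0.025, seed = 17))
  norm <- log2_transform(quantile_normalize(sim$expression))
  str <- split_by_condition(norm)$stressed
  res <- run_trait_sam(str, sim$traits, "shoot_Na", B = 60, seed = 2)
  truth <- sim$truth
  idx <- match(truth$probe_id, res$scores$probe_ids)
  sgn <- ifelse(truth$direction == "positive", 1, -1)
  # every spike reaches q <= 5% with the right sign
  q_recall <- mean(res$q[idx] <= 5 & sign(res$scores$d[idx]) == sgn)
  expect_gte(q_recall, 0.9)
  # spikes at 4 sigma and above also clear the combined |d| >= 2 rule
  strong <- abs(truth$beta) >= 2
  hit <- merge(truth[strong, ], res$significant, by = "probe_id")
  expect_gte(sum(hit$direction.x == hit$direction.y) / sum(strong), 0.8)

  # null data, any trait: near-zero selections under the combined rule
  null_sim <- generate_dataset(sim_config(n_probes = 400,
                                          spike_fraction = 0, seed = 18))
  null_norm <- log2_transform(quantile_normalize(null_sim$expression))
  null_str <- split_by_condition(null_norm)$stressed
  null_res <- run_trait_sam(null_str, null_sim$traits, "root_K",
                            B = 60, seed = 2)
  expect_lte(nrow(null_res$significant), 2L)
})

test_that("looping all traits over both conditions yields 28 result sets", {
  sim <- generate_dataset(sim_config(n_probes = 60, spike_fraction = 0,
                                     seed = 19))
  norm <- log2_transform(quantile_normalize(sim$expression))
  out <- run_all_traits(norm, sim$traits, B = 10, seed = 1)
  expect_identical(nrow(out$counts), 28L)
  expect_identical(length(out$results), 28L)
  expect_setequal(unique(out$counts$condition), c("control", "stressed"))
  expect_identical(length(unique(out$counts$trait)), 14L)
})
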