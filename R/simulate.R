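#' Default genotype panel and trait names for simulation
#'
#' Eight diverse rice genotypes (landraces, cultivars, high-yielding
#' varieties and wild species) and fourteen salinity-relevant
#' morpho-physiological traits emulate the study design the package
#' targets.
#' @keywords internal
default_genotypes <- function() {
  c("Pokkali", "PSBRc50", "IR58", "BRRIdhan29",
    "Banikat", "Nipponbare", "O_latifolia", "O_rufipogon")
}

#' @keywords internal
default_traits <- function() {
  c("shoot_Na", "root_Na", "shoot_K", "root_K", "shoot_Na_K", "root_Na_K",
    "shoot_Cl", "root_Cl", "biomass", "shoot_length", "root_length",
    "shoot_dry_weight", "root_dry_weight", "water_content")
}

#' Simulation configuration
#'
#' Parameters of the synthetic study: a probes x samples one-color
#' intensity matrix over `genotypes x conditions x replicates` columns,
#' per-genotype trait values, and trait-linked spike-in probes whose log2
#' expression rises (or falls) linearly with the weighted trait value of
#' the sample's genotype.
#'
#' @param n_probes Number of probes (>= 10; default 2000, a scaled-down
#'   44K array).
#' @param genotypes Genotype labels (default: the eight-genotype panel).
#' @param replicates Replicates per genotype per condition (default 3,
#'   giving 8 x 2 x 3 = 48 samples).
#' @param traits Trait names (default: 14 morpho-physiological traits).
#' @param spike_fraction Fraction of probes spiked per trait and
#'   direction (default 0.005); spike sets are disjoint across all
#'   trait/direction pairs. 0 disables spikes.
#' @param spiked_traits Traits receiving spikes (default: all).
#' @param beta_mean,beta_sd Mean and sd of the |effect size| on the log2
#'   scale (default 2 and 0.25; the response spans [0,1], so beta is the
#'   full log2 expression range across genotypes).
#' @param mu_mean,mu_sd Baseline per-probe log2 intensity distribution
#'   (default 8 and 1.5).
#' @param sigma Replicate noise sd on the log2 scale (default 0.5, > 0).
#' @param trait_mean,trait_sd Per-genotype raw trait value distribution
#'   (default 100 and 25).
#' @param trait_noise_sd Optional extra noise on trait values (default 0),
#'   a knob for trait/expression growth-condition mismatch.
#' @param spike_in_control If `FALSE` (default) control-condition columns
#'   carry no spike effect, mirroring the far weaker constitutive
#'   response.
#' @param seed Master seed; every generator derives its own substream.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_probes = 2000L,
                       genotypes = default_genotypes(),
                       replicates = 3L,
                       traits = default_traits(),
                       spike_fraction = 0.005,
                       spiked_traits = traits,
                       beta_mean = 2, beta_sd = 0.25,
                       mu_mean = 8, mu_sd = 1.5,
                       sigma = 0.5,
                       trait_mean = 100, trait_sd = 25,
                       trait_noise_sd = 0,
                       spike_in_control = FALSE,
                       seed = 1L) {
  if (n_probes < 10L) stop("n_probes must be >= 10")
  if (replicates < 2L) stop("replicates must be >= 2")
  if (sigma <= 0) stop("sigma must be > 0")
  if (spike_fraction < 0) stop("spike_fraction must be >= 0")
  if (spike_fraction > 0 && spike_fraction * n_probes < 1)
    stop("spike_fraction x n_probes < 1: no spike can be placed")
  n_sets <- 2L * length(spiked_traits)
  if (spike_fraction * n_sets > 1)
    stop("spike sets exceed the probe pool; lower spike_fraction")
  structure(list(n_probes = as.integer(n_probes), genotypes = genotypes,
                 conditions = c("control", "stressed"),
                 replicates = as.integer(replicates), traits = traits,
                 spike_fraction = spike_fraction,
                 spiked_traits = spiked_traits,
                 beta_mean = beta_mean, beta_sd = beta_sd,
                 mu_mean = mu_mean, mu_sd = mu_sd, sigma = sigma,
                 trait_mean = trait_mean, trait_sd = trait_sd,
                 trait_noise_sd = trait_noise_sd,
                 spike_in_control = spike_in_control,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic expression study
#'
#' Draws per-genotype trait values, assigns disjoint spike-in probe sets
#' per trait and direction, and emits a linear-scale intensity matrix in
#' which a spiked probe i for trait t follows
#' `log2 x_ij = mu_i + beta_i * y_g(j) + eps_ij`, with `y_g` the
#' genotype's min-max-weighted trait value, `eps ~ N(0, sigma^2)`, and
#' `beta = 0` for all other probes (and, by default, for all control
#' columns). The matrix is emitted on the linear scale so the log2
#' preprocessing step is exercised downstream.
#'
#' @param config A [sim_config()].
#' @return List with `expression` (an [expression_matrix()], linear
#'   scale), `traits` (a `trait_table`), and `truth` (data frame:
#'   probe_id, trait, direction, beta) listing the spiked probes.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "expression"))
  n <- config$n_probes
  G <- length(config$genotypes)

  chr <- sample(1:12, n, replace = TRUE)
  num <- sample(1000000:9999999, n)  # unique locus numbers -> unique ids
  probe_ids <- format_rap_locus(chr, num)

  tvals <- matrix(stats::rnorm(G * length(config$traits),
                               config$trait_mean, config$trait_sd),
                  nrow = G,
                  dimnames = list(config$genotypes, config$traits))
  if (config$trait_noise_sd > 0)
    tvals <- tvals + stats::rnorm(length(tvals), 0, config$trait_noise_sd)
  for (t in seq_len(ncol(tvals)))  # degenerate traits cannot be weighted
    if (max(tvals[, t]) == min(tvals[, t]))
      stop("degenerate trait drawn: all genotypes equal for ",
           colnames(tvals)[t])
  traits <- trait_table(as.data.frame(tvals))

  k <- round(config$spike_fraction * n)
  truth <- data.frame(probe_id = character(0), trait = character(0),
                      direction = character(0), beta = numeric(0),
                      stringsAsFactors = FALSE)
  beta <- matrix(0, nrow = n, ncol = length(config$traits),
                 dimnames = list(probe_ids, config$traits))
  if (k > 0) {
    sets <- expand.grid(trait = config$spiked_traits,
                        direction = c("positive", "negative"),
                        stringsAsFactors = FALSE)
    pool <- sample(n, k * nrow(sets))
    for (i in seq_len(nrow(sets))) {
      idx <- pool[((i - 1L) * k + 1L):(i * k)]
      sgn <- if (sets$direction[i] == "positive") 1 else -1
      b <- sgn * pmax(stats::rnorm(k, config$beta_mean, config$beta_sd),
                      0.1)
      beta[idx, sets$trait[i]] <- b
      truth <- rbind(truth, data.frame(probe_id = probe_ids[idx],
                                       trait = sets$trait[i],
                                       direction = sets$direction[i],
                                       beta = b,
                                       stringsAsFactors = FALSE))
    }
  }

  samples <- expand.grid(replicate = seq_len(config$replicates),
                         genotype = config$genotypes,
                         condition = config$conditions,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("genotype", "condition", "replicate")]
  samples$sample_id <- sprintf("%s_%s_r%d",
                               samples$genotype,
                               ifelse(samples$condition == "control",
                                      "ctl", "str"),
                               samples$replicate)
  samples <- samples[, c("sample_id", "genotype", "condition", "replicate")]

  y <- apply(tvals, 2L, function(v) (v - min(v)) / (max(v) - min(v)))
  rownames(y) <- config$genotypes
  mu <- stats::rnorm(n, config$mu_mean, config$mu_sd)
  effect <- matrix(0, nrow = n, ncol = nrow(samples))
  active <- samples$condition == "stressed" | config$spike_in_control
  if (any(active) && k > 0) {
    # summed over traits; spike sets are disjoint so at most one term
    yg <- y[samples$genotype[active], , drop = FALSE]
    effect[, active] <- beta %*% t(yg)
  }
  log2x <- mu + effect +
    matrix(stats::rnorm(n * nrow(samples), 0, config$sigma), nrow = n)
  values <- 2^log2x
  dimnames(values) <- list(probe_ids, samples$sample_id)

  list(expression = expression_matrix(values, samples, scale = "linear"),
       traits = traits, truth = truth, config = config)
}

#' Generate a GO annotation with a planted enriched term
#'
#' Annotates every probe to one or more random background terms and plants
#' one designated term that covers a fixed fraction of the spiked probes
#' and a (much lower) fraction of the background, so enrichment analysis
#' has a known positive.
#'
#' @param truth Spike registry from [generate_dataset()] (probes of all
#'   traits pooled).
#' @param probe_ids All probe ids (the annotation background).
#' @param n_terms Number of random background terms (default 40).
#' @param terms_per_gene Terms drawn per gene (default 2).
#' @param spiked_rate Fraction of spiked probes annotated to the planted
#'   term (default 0.8).
#' @param background_rate Fraction of non-spiked probes annotated to the
#'   planted term (default 0.02). Setting `spiked_rate = background_rate`
#'   makes the planted term null.
#' @param min_spiked Minimum number of spiked probes required (default 5).
#' @param seed Master seed (the GO substream is derived from it).
#' @return A `go_annotation` data frame; the planted term id is
#'   `GO:9999999` with attribute `planted_term`.
#' @export
generate_go_annotation <- function(truth, probe_ids, n_terms = 40L,
                                   terms_per_gene = 2L, spiked_rate = 0.8,
                                   background_rate = 0.02, min_spiked = 5L,
                                   seed = 1L) {
  spiked <- unique(truth$probe_id)
  if (length(spiked) < min_spiked)
    stop("need at least ", min_spiked, " spiked probes, got ",
         length(spiked))
  set.seed(derive_seed(seed, "go"))
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  ns <- sample(c("biological_process", "molecular_function"), n_terms,
               replace = TRUE)
  gene <- rep(probe_ids, each = terms_per_gene)
  term <- unlist(lapply(probe_ids, function(g)
    sample(terms, terms_per_gene)))
  ann <- data.frame(gene = gene, term = term,
                    namespace = ns[match(term, terms)],
                    label = term, stringsAsFactors = FALSE)

  planted <- "GO:9999999"
  bg <- setdiff(probe_ids, spiked)
  hit_spiked <- sample(spiked, round(spiked_rate * length(spiked)))
  hit_bg <- sample(bg, round(background_rate * length(bg)))
  ann <- rbind(ann, data.frame(gene = c(hit_spiked, hit_bg),
                               term = planted,
                               namespace = "molecular_function",
                               label = "planted trait-response term",
                               stringsAsFactors = FALSE))
  ann <- ann[!duplicated(ann[c("gene", "term")]), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("go_annotation", "data.frame")
  attr(ann, "planted_term") <- planted
  ann
}

#' Generate a random interactome with an optional planted hub
#'
#' Draws a simple undirected random graph over the probe ids. If a hub is
#' requested, one node (by default the first spiked probe supplied) is
#' first wired to `hub_degree` distinct neighbors; remaining edges are
#' sampled uniformly from the untouched pairs. No self-edges or duplicate
#' pairs are produced.
#'
#' @param probe_ids Node labels (>= 2).
#' @param n_edges Total number of edges (must not exceed the simple-graph
#'   maximum `n*(n-1)/2`).
#' @param hub Optional node label to plant as a hub.
#' @param hub_degree Degree of the planted hub (default 0 = none).
#' @param seed Master seed (interactome substream derived from it).
#' @return An `interaction_edges` data frame with attribute `hub`.
#' @export
generate_interactome <- function(probe_ids, n_edges, hub = NULL,
                                 hub_degree = 0L, seed = 1L) {
  n <- length(probe_ids)
  if (n < 2L) stop("need >= 2 probes")
  max_edges <- n * (n - 1) / 2
  if (n_edges > max_edges)
    stop("requested ", n_edges, " edges > simple-graph maximum ",
         max_edges)
  if (hub_degree > 0L && is.null(hub))
    stop("hub_degree > 0 requires a hub node")
  if (hub_degree > n - 1L)
    stop("hub degree cannot exceed n - 1")
  set.seed(derive_seed(seed, "interactome"))
  a <- character(0); b <- character(0)
  if (hub_degree > 0L) {
    nb <- sample(setdiff(probe_ids, hub), hub_degree)
    a <- rep(hub, hub_degree); b <- nb
  }
  key <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "\t")
  used <- key(a, b)
  need <- n_edges - length(a)
  if (need < 0) stop("n_edges smaller than planted hub degree")
  # filler edges avoid the hub so its planted degree is exact
  pool <- if (hub_degree > 0L) setdiff(probe_ids, hub) else probe_ids
  np <- length(pool)
  if (need > np * (np - 1) / 2)
    stop("requested edges exceed the simple-graph maximum off the hub")
  while (need > 0) {
    u <- pool[sample(np, 2 * need, replace = TRUE)]
    v <- pool[sample(np, 2 * need, replace = TRUE)]
    ok <- u != v & !duplicated(key(u, v)) & !(key(u, v) %in% used)
    u <- u[ok][seq_len(min(need, sum(ok)))]
    v <- v[ok][seq_len(min(need, sum(ok)))]
    a <- c(a, u); b <- c(b, v)
    used <- c(used, key(u, v))
    need <- n_edges - length(a)
  }
  edges <- suppressMessages(interaction_edges(a, b))
  attr(edges, "hub") <- hub
  edges
}
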