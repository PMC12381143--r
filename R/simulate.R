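#' Configuration for the synthetic spatial multi-omics generator
#'
#' Defines the study conditions the generator emulates: a four-stratum
#' (or three-subregion) microdissection design with paired RNA-seq counts
#' and DIA-style protein log2 intensities, planted per-compartment
#' enrichments, per-gene mRNA-protein coupling classes, abundance-linked
#' missingness, half-lives anti-correlated with coupling, and a paired
#' sorted/unsorted (P3/P2) fraction experiment with planted contaminants.
#'
#' @param n_genes Number of genes (features shared by both molecule levels).
#' @param compartments Compartment labels; default the four CA1 strata.
#' @param n_replicates Biological replicates per compartment (default 7,
#'   the tissue design; the sorting design in the source study used 5).
#' @param enriched_fraction Fraction of genes planted as mRNA-enriched in
#'   each compartment (recycled across compartments).
#' @param effect_lfc Planted log2 fold change of enrichment.
#' @param nb_dispersion_log_mean,nb_dispersion_log_sd Log-normal
#'   parameters of the gene-wise negative-binomial dispersion.
#' @param size_factor_log_sd SD of log size factors (geometric mean 1).
#' @param base_log_mean,base_log_sd Log-normal parameters of baseline
#'   count means.
#' @param coupling_fractions Named vector `(positive, negative, null)`
#'   giving the gene fractions with planted mRNA-protein profile
#'   correlation +1, -1 and 0; must sum to at most 1 (remainder null).
#' @param protein_base_mean,protein_base_sd Normal parameters of baseline
#'   protein log2 intensity.
#' @param population_correlation Correlation between baseline log2
#'   protein intensity and baseline log2 mRNA abundance across genes
#'   (the modest population-level mRNA-protein correlation of neural
#'   tissue; default 0.35).
#' @param protein_noise_sd Replicate noise SD of protein log2 intensities.
#' @param missing_rate Overall missing-value rate for intensities;
#'   realized intensity-dependently (lowest tercile twice as likely).
#' @param halflife_base_hours Geometric-mean protein half-life in hours.
#' @param halflife_coupling_slope Log-scale slope linking half-life to the
#'   coupling coefficient; positive values make positively coupled genes
#'   stochastically shorter-lived.
#' @param halflife_log_sd Log-normal noise SD of half-lives.
#' @param contaminant_fraction Fraction of features planted as sorting
#'   contaminants.
#' @param contaminant_lfc Planted log2 shift of contaminants in the P2
#'   (unsorted) relative to the P3 (sorted) fraction.
#' @param translatome_neuropil_prob,translatome_soma_prob Baseline label
#'   probabilities for the translatome reference (remainder `unbiased`).
#' @param seed Default seed for the generator.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L,
                       compartments = c("SO", "SP", "SR", "SLM"),
                       n_replicates = 7L,
                       enriched_fraction = 0.1,
                       effect_lfc = 1.0,
                       nb_dispersion_log_mean = log(0.05),
                       nb_dispersion_log_sd = 0.5,
                       size_factor_log_sd = 0.15,
                       base_log_mean = log(150),
                       base_log_sd = 1.2,
                       coupling_fractions = c(positive = 0.2, negative = 0.15, null = 0.65),
                       protein_base_mean = 20,
                       protein_base_sd = 2,
                       population_correlation = 0.35,
                       protein_noise_sd = 0.25,
                       missing_rate = 0.05,
                       halflife_base_hours = 192,
                       halflife_coupling_slope = 0.5,
                       halflife_log_sd = 0.3,
                       contaminant_fraction = 0.1,
                       contaminant_lfc = 2.0,
                       translatome_neuropil_prob = 0.2,
                       translatome_soma_prob = 0.4,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), compartments = as.character(compartments),
    n_replicates = as.integer(n_replicates),
    enriched_fraction = rep_len(enriched_fraction, length(compartments)),
    effect_lfc = effect_lfc,
    nb_dispersion_log_mean = nb_dispersion_log_mean,
    nb_dispersion_log_sd = nb_dispersion_log_sd,
    size_factor_log_sd = size_factor_log_sd,
    base_log_mean = base_log_mean, base_log_sd = base_log_sd,
    coupling_fractions = coupling_fractions,
    protein_base_mean = protein_base_mean, protein_base_sd = protein_base_sd,
    population_correlation = population_correlation,
    protein_noise_sd = protein_noise_sd,
    missing_rate = missing_rate,
    halflife_base_hours = halflife_base_hours,
    halflife_coupling_slope = halflife_coupling_slope,
    halflife_log_sd = halflife_log_sd,
    contaminant_fraction = contaminant_fraction,
    contaminant_lfc = contaminant_lfc,
    translatome_neuropil_prob = translatome_neuropil_prob,
    translatome_soma_prob = translatome_soma_prob,
    seed = as.integer(seed)
  )
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (length(cfg$compartments) < 2L) stop("need >= 2 compartments", call. = FALSE)
  if (cfg$n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  fr <- c(cfg$enriched_fraction, cfg$missing_rate, cfg$contaminant_fraction,
          cfg$coupling_fractions, cfg$translatome_neuropil_prob,
          cfg$translatome_soma_prob)
  if (any(fr < 0 | fr > 1)) stop("all fractions/rates must lie in [0, 1]", call. = FALSE)
  if (sum(cfg$coupling_fractions[c("positive", "negative")]) > 1 + 1e-12) {
    stop("coupling fractions sum above 1", call. = FALSE)
  }
  if (cfg$translatome_neuropil_prob + cfg$translatome_soma_prob > 1 + 1e-12) {
    stop("translatome label probabilities sum above 1", call. = FALSE)
  }
  if (!all(is.finite(c(cfg$effect_lfc, cfg$contaminant_lfc)))) {
    stop("effect sizes must be finite", call. = FALSE)
  }
  if (abs(cfg$population_correlation) > 1) {
    stop("population_correlation must lie in [-1, 1]", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

std_profile <- function(x) {
  s <- stats::sd(x)
  if (s < 1e-12) return(NULL)
  (x - mean(x)) / s
}

random_unit_profile <- function(k) {
  repeat {
    z <- stats::rnorm(k)
    s <- std_profile(z)
    if (!is.null(s)) return(s)
  }
}

#' Simulate the paired tissue transcriptome/proteome experiment
#'
#' RNA counts are negative-binomial with per-sample size factors and a
#' planted per-compartment log2 enrichment for a configured fraction of
#' genes. Protein log2 intensities follow a compartment profile built so
#' that the expected correlation between a gene's mRNA and protein
#' compartment profiles equals the planted coupling coefficient
#' (+1, -1 or 0 by class), with replicate noise and intensity-dependent
#' missingness. The truth record enables recovery testing downstream.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List with `rna` and `protein` ([omics_matrix()] objects) and
#'   `truth` (list with per-gene data frame `genes`, the planted mRNA
#'   profile matrix `mrna_profile`, protein profile `protein_profile`,
#'   and the true `size_factors`).
#' @export
simulate_spatial_omics <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  comps <- config$compartments
  k <- length(comps)
  n <- config$n_genes
  genes <- sprintf("gene%05d", seq_len(n))

  base_mean <- stats::rlnorm(n, config$base_log_mean, config$base_log_sd)
  alpha <- stats::rlnorm(n, config$nb_dispersion_log_mean, config$nb_dispersion_log_sd)

  # planted mRNA enrichment: disjoint gene blocks per compartment
  enriched_comp <- rep(NA_character_, n)
  pool <- sample.int(n)
  offset <- 0L
  for (i in seq_along(comps)) {
    n_c <- stats::rbinom(1L, n, config$enriched_fraction[i])
    n_c <- min(n_c, length(pool) - offset)
    if (n_c > 0) {
      enriched_comp[pool[offset + seq_len(n_c)]] <- comps[i]
      offset <- offset + n_c
    }
  }
  beta <- matrix(0, n, k, dimnames = list(genes, comps))
  for (i in seq_along(comps)) {
    beta[which(enriched_comp == comps[i]), i] <- config$effect_lfc
  }

  # coupling classes and protein compartment profiles
  cls <- sample(rep(c("positive", "negative", "null"),
                    times = c(round(n * config$coupling_fractions[["positive"]]),
                              round(n * config$coupling_fractions[["negative"]]),
                              n - round(n * config$coupling_fractions[["positive"]]) -
                                round(n * config$coupling_fractions[["negative"]]))))
  rho <- c(positive = 1, negative = -1, null = 0)[cls]
  # A profile correlation is only defined for spatially varying mRNAs:
  # coupled genes without a planted enrichment block receive a random
  # compartment profile of the same amplitude on the mRNA side, which the
  # protein construction below then tracks with correlation rho.
  flat <- rowSums(beta != 0) == 0
  for (g in which(flat & rho != 0)) {
    beta[g, ] <- config$effect_lfc * random_unit_profile(k)
  }
  gamma <- matrix(0, n, k, dimnames = list(genes, comps))
  amplitude <- config$effect_lfc
  for (g in seq_len(n)) {
    z <- std_profile(beta[g, ])
    if (is.null(z)) z <- random_unit_profile(k)
    e <- random_unit_profile(k)
    gamma[g, ] <- amplitude * (rho[g] * z + sqrt(1 - rho[g]^2) * e)
  }

  # samples: compartments x replicates
  meta <- expand.grid(replicate = seq_len(config$n_replicates),
                      compartment = comps, stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = sprintf("%s_r%d", meta$compartment, meta$replicate),
                     compartment = meta$compartment, replicate = meta$replicate,
                     fraction = "tissue", stringsAsFactors = FALSE)
  sf <- exp(stats::rnorm(nrow(meta), 0, config$size_factor_log_sd))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- meta$sample_id

  ci <- match(meta$compartment, comps)
  mu <- base_mean * 2^beta[, ci, drop = FALSE]
  mu <- sweep(mu, 2, sf, `*`)
  counts <- matrix(stats::rnbinom(n * nrow(meta), mu = mu, size = rep(1 / alpha, nrow(meta))),
                   nrow = n, dimnames = list(genes, meta$sample_id))
  rna <- omics_matrix(counts, "rna_counts", meta)

  # baseline protein abundance is partially coupled to baseline mRNA
  # abundance, reproducing the modest population-level mRNA-protein
  # correlation seen in neural tissue
  rp <- config$population_correlation
  lb <- log2(base_mean)
  prot_base <- config$protein_base_mean + config$protein_base_sd *
    (rp * (lb - mean(lb)) / stats::sd(lb) + sqrt(1 - rp^2) * stats::rnorm(n))
  y <- prot_base + gamma[, ci, drop = FALSE] +
    matrix(stats::rnorm(n * nrow(meta), 0, config$protein_noise_sd), n)
  dimnames(y) <- list(genes, meta$sample_id)
  y <- inject_mnar_missing(y, config$missing_rate)
  protein <- omics_matrix(y, "protein_log2", meta)

  prot_dev <- gamma - rowMeans(gamma)
  prot_enr <- apply(prot_dev, 1, function(d) {
    j <- which.max(d)
    if (d[j] >= 0.5 * config$effect_lfc) comps[j] else NA_character_
  })
  truth <- list(
    genes = data.frame(
      gene = genes,
      mrna_enriched_compartment = enriched_comp,
      mrna_sign = ifelse(is.na(enriched_comp), NA_integer_, 1L),
      protein_enriched_compartment = prot_enr,
      coupling_class = unname(cls),
      rho = unname(rho),
      stringsAsFactors = FALSE
    ),
    mrna_profile = beta,
    protein_profile = gamma,
    size_factors = sf
  )
  list(rna = rna, protein = protein, truth = truth)
}

# MNAR-lite missingness: overall rate preserved, lowest-intensity tercile
# twice as likely missing as the rest (2r' vs r', (1/3)2r' + (2/3)r' = rate).
inject_mnar_missing <- function(y, rate) {
  if (rate <= 0) return(y)
  r_hi <- 0.75 * rate
  r_lo <- 1.5 * rate
  cut <- stats::quantile(y, 1 / 3, na.rm = TRUE)
  p <- ifelse(y <= cut, r_lo, r_hi)
  y[stats::runif(length(y)) < p] <- NA_real_
  y
}

#' Simulate the sorted-vs-unsorted (P3/P2) synaptosome experiment
#'
#' Each compartment contributes paired P2 (unsorted control) and P3
#' (sorted) samples. Planted contaminant features are shifted by
#' `contaminant_lfc` log2 units upward in P2 relative to P3; all other
#' features carry symmetric noise. Compartment enrichments are planted
#' as in [simulate_spatial_omics()], so a synaptic one-vs-rest analysis
#' on the filtered P3 samples can be benchmarked.
#'
#' @inheritParams simulate_spatial_omics
#' @return List with `protein`, `rna` (both containing P2 and P3
#'   samples) and `truth` (per-feature contaminant flag, planted
#'   compartment enrichment, and true size factors for the RNA libraries).
#' @export
simulate_sorting_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed + 1L)
  comps <- config$compartments
  n <- config$n_genes
  genes <- sprintf("gene%05d", seq_len(n))

  contaminant <- rep(FALSE, n)
  n_cont <- round(n * config$contaminant_fraction)
  if (n_cont > 0) contaminant[sample.int(n, n_cont)] <- TRUE

  enriched_comp <- rep(NA_character_, n)
  pool <- sample(which(!contaminant))
  offset <- 0L
  for (i in seq_along(comps)) {
    n_c <- stats::rbinom(1L, n, config$enriched_fraction[i])
    n_c <- min(n_c, length(pool) - offset)
    if (n_c > 0) {
      enriched_comp[pool[offset + seq_len(n_c)]] <- comps[i]
      offset <- offset + n_c
    }
  }
  beta <- matrix(0, n, length(comps), dimnames = list(genes, comps))
  for (i in seq_along(comps)) {
    beta[which(enriched_comp == comps[i]), i] <- config$effect_lfc
  }

  meta <- expand.grid(replicate = seq_len(config$n_replicates),
                      fraction = c("P2", "P3"), compartment = comps,
                      stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = sprintf("%s_%s_r%d", meta$compartment, meta$fraction, meta$replicate),
    compartment = meta$compartment, replicate = meta$replicate,
    fraction = meta$fraction, stringsAsFactors = FALSE)
  ci <- match(meta$compartment, comps)
  p2 <- meta$fraction == "P2"

  # protein log2 intensities
  prot_base <- stats::rnorm(n, config$protein_base_mean, config$protein_base_sd)
  shift <- outer(ifelse(contaminant, config$contaminant_lfc, 0), as.numeric(p2))
  y <- prot_base + beta[, ci, drop = FALSE] + shift +
    matrix(stats::rnorm(n * nrow(meta), 0, config$protein_noise_sd), n)
  dimnames(y) <- list(genes, meta$sample_id)
  y <- inject_mnar_missing(y, config$missing_rate)
  protein <- omics_matrix(y, "protein_log2", meta)

  # RNA counts from the sorted libraries
  base_mean <- stats::rlnorm(n, config$base_log_mean, config$base_log_sd)
  alpha <- stats::rlnorm(n, config$nb_dispersion_log_mean, config$nb_dispersion_log_sd)
  sf <- exp(stats::rnorm(nrow(meta), 0, config$size_factor_log_sd))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- meta$sample_id
  mu <- base_mean * 2^(beta[, ci, drop = FALSE] + shift)
  mu <- sweep(mu, 2, sf, `*`)
  counts <- matrix(stats::rnbinom(n * nrow(meta), mu = mu, size = rep(1 / alpha, nrow(meta))),
                   nrow = n, dimnames = list(genes, meta$sample_id))
  rna <- omics_matrix(counts, "rna_counts", meta)

  truth <- list(
    genes = data.frame(gene = genes, contaminant = contaminant,
                       enriched_compartment = enriched_comp,
                       stringsAsFactors = FALSE),
    size_factors = sf
  )
  list(protein = protein, rna = rna, truth = truth)
}

#' Simulate the gene-level reference tables and gene sets
#'
#' Half-lives are log-normal with log-mean decreasing in the planted
#' coupling coefficient, so positively coupled genes are stochastically
#' shorter-lived. Translatome labels are drawn with the neuropil
#' probability raised for genes whose planted mRNA and protein
#' enrichment both fall in the most distal compartment. Gene sets
#' comprise each planted enrichment block as one set plus random decoys,
#' and each gene receives a random 100-600 aa protein sequence.
#'
#' @param config A [sim_config()].
#' @param truth Truth record from [simulate_spatial_omics()].
#' @param seed Integer seed.
#' @param n_decoy_sets,decoy_set_size Decoy gene-set layout in the GMT.
#' @return List with `half_life`, `translatome`, `sequences` (as in
#'   [read_reference_tables()]) and `gene_sets` (a `gene_set_collection`).
#' @export
simulate_reference_tables <- function(config, truth, seed = config$seed,
                                      n_decoy_sets = 10L, decoy_set_size = 50L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed + 2L)
  g <- truth$genes
  n <- nrow(g)
  comps <- config$compartments
  distal <- comps[length(comps)]

  half_life <- exp(log(config$halflife_base_hours) -
                     config$halflife_coupling_slope * g$rho +
                     stats::rnorm(n, 0, config$halflife_log_sd))
  names(half_life) <- g$gene

  co_distal <- !is.na(g$mrna_enriched_compartment) &
    !is.na(g$protein_enriched_compartment) &
    g$mrna_enriched_compartment == distal &
    g$protein_enriched_compartment == distal
  p_base <- c(soma = config$translatome_soma_prob,
              neuropil = config$translatome_neuropil_prob)
  p_base <- c(p_base, unbiased = 1 - sum(p_base))
  p_distal <- c(soma = 0.05, neuropil = 0.75, unbiased = 0.20)
  translatome <- vapply(seq_len(n), function(i) {
    p <- if (co_distal[i]) p_distal else p_base
    sample(names(p), 1L, prob = p)
  }, character(1))
  names(translatome) <- g$gene

  sets <- list()
  for (cc in comps) {
    members <- g$gene[!is.na(g$mrna_enriched_compartment) &
                        g$mrna_enriched_compartment == cc]
    if (length(members)) {
      sets[[paste0("planted_", cc)]] <- list(
        description = paste("planted mRNA enrichment block", cc), genes = members)
    }
  }
  for (i in seq_len(n_decoy_sets)) {
    sets[[sprintf("decoy_%02d", i)]] <- list(
      description = "random decoy set",
      genes = sample(g$gene, min(decoy_set_size, n)))
  }
  class(sets) <- "gene_set_collection"

  lens <- sample(100:600, n, replace = TRUE)
  sequences <- vapply(lens, function(L) {
    paste(sample(aa_alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
  names(sequences) <- g$gene

  list(half_life = half_life, translatome = translatome,
       sequences = sequences, gene_sets = sets)
}
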