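test_that("the generator is deterministic given (config, seed)", {
  cfg <- sim_config(n_genes = 150, n_replicates = 3)
  a <- simulate_spatial_omics(cfg, seed = 5)
  b <- simulate_spatial_omics(cfg, seed = 5)
  expect_identical(a$rna$values, b$rna$values)
  expect_identical(a$protein$values, b$protein$values)
  expect_identical(a$truth$genes, b$truth$genes)
  d <- simulate_spatial_omics(cfg, seed = 6)
  expect_false(identical(a$rna$values, d$rna$values))

  s1 <- simulate_sorting_experiment(cfg, seed = 5)
  s2 <- simulate_sorting_experiment(cfg, seed = 5)
  expect_identical(s1$protein$values, s2$protein$values)
  r1 <- simulate_reference_tables(cfg, a$truth, seed = 5)
  r2 <- simulate_reference_tables(cfg, a$truth, seed = 5)
  expect_identical(r1$half_life, r2$half_life)
  expect_identical(r1$sequences, r2$sequences)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(compartments = "SO"), "compartments")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(missing_rate = 1.2), "fractions")
  expect_error(sim_config(coupling_fractions = c(positive = 0.7, negative = 0.5, null = 0)),
               "sum above 1")
})

test_that("full coupling with vanishing noise yields near-perfect profile correlations", {
  cfg <- sim_config(n_genes = 120, n_replicates = 5,
                    coupling_fractions = c(positive = 1, negative = 0, null = 0),
                    protein_noise_sd = 1e-3, missing_rate = 0,
                    nb_dispersion_log_mean = log(0.005), base_log_mean = log(5000),
                    base_log_sd = 0.3)
  sim <- simulate_spatial_omics(cfg, seed = 2)
  rna_means <- compartment_means(log2(sim$rna$values + 1), meta = sim$rna$meta)
  prot_means <- compartment_means(sim$protein)
  r <- vapply(seq_len(nrow(rna_means)),
              function(i) stats::cor(rna_means[i, ], prot_means[i, ]), numeric(1))
  expect_true(all(r >= 0.9))
})

test_that("planted enrichment counts stay inside the binomial 99% interval", {
  cfg <- sim_config(n_genes = 2000, enriched_fraction = 0.1, effect_lfc = 1)
  sim <- simulate_spatial_omics(cfg, seed = 3)
  n_so <- sum(sim$truth$genes$mrna_enriched_compartment == "SO", na.rm = TRUE)
  bounds <- stats::qbinom(c(0.005, 0.995), 2000, 0.1)
  expect_gte(n_so, bounds[1])
  expect_lte(n_so, bounds[2])
})

test_that("NB marginal moments match the configured dispersion model", {
  cfg <- sim_config(n_genes = 1000, n_replicates = 7, enriched_fraction = 0,
                    effect_lfc = 0, size_factor_log_sd = 0)
  sim <- simulate_spatial_omics(cfg, seed = 4)
  k <- sim$rna$values
  mu <- rowMeans(k)
  v <- apply(k, 1, stats::var)
  # the median observed-to-expected variance ratio (expected mu + alpha*mu^2
  # at the configured geometric-mean dispersion) screens the NB marginals
  ratio <- v / (mu + exp(cfg$nb_dispersion_log_mean) * mu^2)
  expect_gt(stats::median(ratio[mu > 50]), 0.7)
  expect_lt(stats::median(ratio[mu > 50]), 1.4)
  # and the gene-wise moment dispersions track the planted log-normal spread
  alpha_implied <- (v - mu) / mu^2
  keep <- mu > 200 & alpha_implied > 0
  expect_lt(abs(stats::median(log(alpha_implied[keep])) - cfg$nb_dispersion_log_mean), 0.35)
})

test_that("sorting experiment plants contaminant shifts only when asked", {
  cfg0 <- sim_config(n_genes = 200, n_replicates = 4, contaminant_fraction = 0)
  s0 <- simulate_sorting_experiment(cfg0, seed = 1)
  expect_false(any(s0$truth$genes$contaminant))

  cfg <- sim_config(n_genes = 200, n_replicates = 4, contaminant_fraction = 0.2,
                    contaminant_lfc = 5, protein_noise_sd = 0.05,
                    effect_lfc = 0, enriched_fraction = 0, missing_rate = 0)
  s <- simulate_sorting_experiment(cfg, seed = 1)
  p2 <- s$protein$meta$fraction == "P2"
  diff <- rowMeans(s$protein$values[, p2]) - rowMeans(s$protein$values[, !p2])
  cont <- s$truth$genes$contaminant
  # at an extreme planted effect, every contaminant separates from every
  # non-contaminant by mean shift
  expect_gt(min(diff[cont]), max(diff[!cont]))
})

test_that("half-life coupling direction and gene-set layout are as planted", {
  cfg <- sim_config(n_genes = 500)
  sim <- simulate_spatial_omics(cfg, seed = 7)
  refs <- simulate_reference_tables(cfg, sim$truth, seed = 7)
  g <- sim$truth$genes
  hl <- refs$half_life[g$gene]
  expect_lt(stats::median(hl[g$rho == 1]), stats::median(hl[g$rho == -1]))

  # slope 0: no systematic difference (two-sided rank test across seeds)
  cfg0 <- sim_config(n_genes = 500, halflife_coupling_slope = 0)
  pvals <- vapply(1:5, function(sd) {
    simx <- simulate_spatial_omics(cfg0, seed = sd)
    refx <- simulate_reference_tables(cfg0, simx$truth, seed = sd)
    gx <- simx$truth$genes
    hlx <- refx$half_life[gx$gene]
    stats::wilcox.test(hlx[gx$rho == 1], hlx[gx$rho == -1])$p.value
  }, numeric(1))
  expect_gt(sum(pvals > 0.01), 3)

  # planted sets contain exactly the planted genes; decoys only overlap by chance
  sets <- refs$gene_sets
  planted_names <- grep("^planted_", names(sets), value = TRUE)
  for (nm in planted_names) {
    cc <- sub("planted_", "", nm)
    expect_setequal(sets[[nm]]$genes,
                    g$gene[!is.na(g$mrna_enriched_compartment) &
                             g$mrna_enriched_compartment == cc])
  }
  # sequences: valid lengths and alphabet
  lens <- nchar(refs$sequences)
  expect_true(all(lens >= 100 & lens <= 600))
  expect_false(any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", refs$sequences)))
})

test_that("intensity-dependent missingness doubles in the lowest tercile", {
  cfg <- sim_config(n_genes = 3000, n_replicates = 7, missing_rate = 0.1,
                    effect_lfc = 0, enriched_fraction = 0)
  sim <- simulate_spatial_omics(cfg, seed = 8)
  y <- sim$protein$values
  overall <- mean(is.na(y))
  expect_gt(overall, 0.08); expect_lt(overall, 0.12)
  # reconstruct intensity from row means to locate the low tercile
  approx_level <- matrix(rowMeans(y, na.rm = TRUE), nrow(y), ncol(y))
  cutv <- stats::quantile(approx_level, 1 / 3)
  low <- approx_level <= cutv
  expect_gt(mean(is.na(y[low])) / mean(is.na(y[!low])), 1.5)
})
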