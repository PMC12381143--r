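test_that("valid-value filtering matches hand enumeration", {
  v <- matrix(rnorm(30, 20), 5, 6,
              dimnames = list(sprintf("p%d", 1:5), sprintf("s%d", 1:6)))
  # craft missingness: p1 complete; p2 missing everywhere in group B;
  # p3 one value per group; p4 missing 2 of 3 in A; p5 all missing
  v[2, 4:6] <- NA
  v[3, c(1, 2, 4, 5)] <- NA
  v[4, c(1, 2)] <- NA
  v[5, ] <- NA
  meta <- make_meta(colnames(v), rep(c("SO", "SP"), each = 3), rep(1:3, 2))
  om <- omics_matrix(v, "protein_log2", meta)
  grp <- stats::setNames(rep(c("A", "B"), each = 3), colnames(v))
  kept1 <- rownames(filter_valid_values(om, grp, min_quant = 1)$values)
  expect_identical(kept1, c("p1", "p3", "p4"))
  kept2 <- rownames(filter_valid_values(om, grp, min_quant = 2)$values)
  expect_identical(kept2, "p1")
  # pooled mode
  keptp <- rownames(filter_valid_values(om, grp, min_quant = 3, by_contrast = FALSE)$values)
  expect_identical(keptp, c("p1", "p2", "p4"))
  # no missing values: identity on the contrast samples
  full <- random_protein_matrix(n_feat = 10, n_rep = 2, seed = 1)
  grp2 <- stats::setNames(full$meta$compartment, full$meta$sample_id)
  expect_identical(dim(filter_valid_values(full, grp2)), dim(full))
  expect_error(filter_valid_values(om, grp[0]), "group")
})

test_that("NB Wald test returns an exact null on identical groups", {
  v <- matrix(rep(c(10, 25, 40, 13), times = 6), 4,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:6)))
  meta <- make_meta(colnames(v), rep(c("SO", "SP"), each = 3), rep(1:3, 2))
  om <- omics_matrix(v, "rna_counts", meta)
  grp <- factor(meta$compartment, levels = c("SO", "SP"))
  names(grp) <- meta$sample_id
  de <- nb_wald_de(om, grp, size_factors = stats::setNames(rep(1, 6), colnames(v)))
  expect_equal(de$log2fc, rep(0, 4), tolerance = 1e-8)
  expect_equal(de$pvalue, rep(1, 4), tolerance = 1e-8)
  expect_false(any(de$untestable))
})

test_that("NB Wald matches the two-sample Poisson statistic at large counts", {
  set.seed(2)
  y1 <- rpois(4, 6000); y2 <- rpois(4, 9000)
  m <- matrix(c(y1, y2), 1, dimnames = list("g1", sprintf("s%d", 1:8)))
  meta <- make_meta(colnames(m), rep(c("SO", "SP"), each = 4), rep(1:4, 2))
  om <- omics_matrix(m, "rna_counts", meta)
  grp <- factor(meta$compartment, levels = c("SO", "SP")); names(grp) <- meta$sample_id
  de <- nb_wald_de(om, grp, size_factors = stats::setNames(rep(1, 8), colnames(m)),
                   use_replicate = FALSE)
  z_pois <- log(sum(y2) / sum(y1)) / sqrt(1 / sum(y1) + 1 / sum(y2))
  expect_equal(de$stat, z_pois, tolerance = 0.02)
  # all-zero gene is flagged untestable, not dropped
  m0 <- rbind(m, g0 = rep(0L, 8))
  om0 <- omics_matrix(m0, "rna_counts", meta)
  de0 <- nb_wald_de(om0, grp, size_factors = stats::setNames(rep(1, 8), colnames(m0)),
                    use_replicate = FALSE)
  expect_identical(nrow(de0), 2L)
  expect_true(de0$untestable[de0$feature == "g0"])
})

test_that("NB Wald fold changes agree with DESeq2 on simulated data", {
  cfg <- sim_config(n_genes = 250, n_replicates = 5, missing_rate = 0)
  sim <- simulate_spatial_omics(cfg, seed = 12)
  ids <- sim$rna$meta$sample_id[sim$rna$meta$compartment %in% c("SO", "SLM")]
  two <- subset_omics(sim$rna, samples = ids)
  grp <- factor(two$meta$compartment, levels = c("SO", "SLM"))
  names(grp) <- two$meta$sample_id
  mine <- nb_wald_de(two, grp, use_replicate = FALSE)

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = matrix(as.integer(two$values), nrow(two$values),
                         dimnames = dimnames(two$values)),
      colData = data.frame(condition = grp), design = ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds, contrast = c("condition", "SLM", "SO"))
  })
  ok <- !mine$untestable & !is.na(ref$log2FoldChange)
  expect_gt(stats::cor(mine$log2fc[ok], ref$log2FoldChange[ok]), 0.99)
  expect_gt(stats::cor(rank(mine$pvalue[ok]), rank(ref$pvalue[ok])), 0.95)
})

test_that("moderated t collapses to known limits", {
  # identical group values (same residuals in both groups): t = 0, p = 1
  set.seed(3)
  noise <- matrix(rnorm(12, 0, 0.3), 3, 4)
  v <- cbind(20 + noise, 20 + noise)
  dimnames(v) <- list(sprintf("p%d", 1:3), sprintf("s%d", 1:8))
  meta <- make_meta(colnames(v), rep(c("SO", "SP"), each = 4), rep(1:4, 2))
  om <- omics_matrix(v, "protein_log2", meta)
  grp <- factor(meta$compartment, levels = c("SO", "SP")); names(grp) <- meta$sample_id
  de <- moderated_lm_de(om, grp, use_replicate = FALSE)
  expect_equal(de$log2fc, rep(0, 3), tolerance = 1e-10)
  expect_equal(de$pvalue, rep(1, 3), tolerance = 1e-10)

  # equal residual variances: d0 -> Inf and t equals the common-variance z test
  set.seed(4)
  n_prot <- 60
  base <- rnorm(n_prot, 20, 1)
  resid_pattern <- rnorm(8, 0, 0.4)
  v2 <- outer(base, rep(1, 8)) + outer(rep(1, n_prot), resid_pattern)
  dimnames(v2) <- list(sprintf("q%02d", 1:n_prot), sprintf("s%d", 1:8))
  om2 <- omics_matrix(v2, "protein_log2", meta)
  de2 <- moderated_lm_de(om2, grp, use_replicate = FALSE)
  expect_true(is.infinite(de2$prior_df[1]))
  s2 <- de2$prior_var[1]
  z_expect <- de2$log2fc / sqrt(s2 * (1 / 4 + 1 / 4))
  expect_equal(de2$stat, z_expect, tolerance = 1e-8)
})

test_that("variance prior estimation matches limma's squeezeVar", {
  set.seed(5)
  d0 <- 6; s0 <- 0.08; dg <- 8
  s2 <- s0 * d0 / rchisq(3000, d0) * rchisq(3000, dg) / dg
  mine <- stratomics:::fit_variance_prior(s2, rep(dg, 3000))
  ref <- limma::squeezeVar(s2, df = dg)
  expect_equal(mine$d0, ref$df.prior, tolerance = 0.05)
  expect_equal(mine$s0sq, ref$var.prior, tolerance = 0.05)
  # and recovers the generating parameters to within 20%
  expect_lt(abs(mine$d0 - d0) / d0, 0.2)
  expect_lt(abs(mine$s0sq - s0) / s0, 0.2)
})

test_that("BH adjustment matches hand computation and propagates NA", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.05)), c(0.015, 0.05, 0.05))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- c(0.01, NA, 0.3)
  expect_true(is.na(bh_adjust(p)[2]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation invariance and q >= p
  set.seed(6)
  p <- runif(50)
  q <- bh_adjust(p)
  o <- sample(50)
  expect_equal(bh_adjust(p[o]), q[o])
  expect_true(all(q >= p))
  expect_equal(q, manual_bh(p))
})

test_that("enrichment calls respect scheme semantics and antisymmetry", {
  de_pair <- function(label, feats, lfc, q) {
    data.frame(feature = feats, contrast = label, base_mean = 1,
               log2fc = lfc, se = 0.1, stat = lfc / 0.1, pvalue = q, padj = q,
               dispersion = 0.01, untestable = FALSE, stringsAsFactors = FALSE)
  }
  # feature significant against only one of two others: no pairwise call
  de_list <- list(
    CA1_vs_CA23 = de_pair("CA1_vs_CA23", c("f1", "f2"), c(0.5, 0.5), c(0.005, 0.005)),
    CA1_vs_DG   = de_pair("CA1_vs_DG",   c("f1", "f2"), c(0.5, 0.01), c(0.005, 0.5)),
    CA23_vs_DG  = de_pair("CA23_vs_DG",  c("f1", "f2"), c(0, 0), c(1, 1))
  )
  calls <- call_enrichment(de_list, "pairwise_intersection", "protein",
                           lfc_min = 0.1, alpha = 0.01)
  ca1 <- calls[calls$compartment == "CA1" & calls$direction == "enriched", ]
  expect_identical(ca1$feature, "f1")
  expect_false("f2" %in% ca1$feature)
  # flipped-label contrasts are handled by sign reversal: f1 depleted in CA23
  ca23 <- calls[calls$compartment == "CA23", ]
  expect_true(all(ca23$direction != "enriched" | ca23$feature != "f1"))

  # one-vs-rest: single contrast drives the call
  ovr <- list(SO = de_pair("SO_vs_rest", c("f1", "f2", "f3"),
                           c(0.5, -0.5, 0.05), c(0.005, 0.005, 0.001)))
  c2 <- call_enrichment(ovr, "one_vs_rest", "mrna", lfc_min = 0.1, alpha = 0.01)
  expect_identical(c2$feature[c2$direction == "enriched"], "f1")
  expect_identical(c2$feature[c2$direction == "depleted"], "f2")
  # |lfc| below threshold is never called even when highly significant
  expect_false("f3" %in% c2$feature)
  # antisymmetry: no feature is both enriched and depleted in one compartment
  key <- paste(c2$feature, c2$compartment)
  expect_false(any(duplicated(key)))
})
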