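test_that("population correlation behaves on exact and hand-computed inputs", {
  comps <- c("SO", "SP", "SR", "SLM")
  rna <- matrix(rnorm(40, 10), 10, 4, dimnames = list(sprintf("g%d", 1:10), comps))
  # protein = mRNA + constant: r = 1 in every scope
  out <- population_correlation(rna, rna + 3)
  expect_equal(out$r, rep(1, 5))
  # protein = -mRNA: r = -1
  out2 <- population_correlation(rna, -rna)
  expect_equal(out2$r, rep(-1, 5))
  # hand computation: cov terms 6.5, sds sqrt(5), sqrt(8.75)
  x <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(letters[1:4], "SO"))
  y <- matrix(c(1, 2, 3, 5), 4, 1, dimnames = list(letters[1:4], "SO"))
  out3 <- population_correlation(x, y)
  expect_equal(out3$r[out3$scope == "SO"], 6.5 / (sqrt(5) * sqrt(8.75)),
               tolerance = 1e-10)
  # fewer than 3 complete pairs is flagged
  y2 <- y; y2[1:2, 1] <- NA
  out4 <- population_correlation(x, y2)
  expect_true(out4$flagged[out4$scope == "SO"])
})

test_that("profile correlation classification thresholds are honored", {
  comps <- c("SO", "SP", "SR", "SLM")
  set.seed(1)
  rna <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(sprintf("g%02d", 1:20), comps))
  # identical profiles: positive class with r = 1
  out <- profile_correlation_classify(rna, rna + 2)
  expect_true(all(out$records$class == "positive"))
  expect_equal(out$records$r, rep(1, 20), tolerance = 1e-12)
  # strictly monotone profile vs its reverse: negative class
  mono <- matrix(c(1, 2, 3, 4), 1, dimnames = list("g1", comps))
  revp <- matrix(c(4, 3, 2, 1), 1, dimnames = list("g1", comps))
  out2 <- profile_correlation_classify(mono, revp)
  expect_identical(out2$records$class, "negative")
  # zero-variance profile: class neither, r undefined, flagged
  flat <- matrix(2, 1, 4, dimnames = list("g1", comps))
  out3 <- profile_correlation_classify(flat, mono)
  expect_identical(out3$records$class, "neither")
  expect_true(is.na(out3$records$r) && out3$records$flagged)
  # class counts monotone in thresholds: loosening r_pos grows the class
  prot <- rna + matrix(rnorm(80, 0, 0.8), 20, 4)
  strict <- profile_correlation_classify(rna, prot, r_pos = 0.95)
  loose <- profile_correlation_classify(rna, prot, r_pos = 0.6)
  expect_gte(loose$summary$positive, strict$summary$positive)
  # genes absent on one side are counted, not silently dropped
  out4 <- profile_correlation_classify(rna[1:10, ], prot)
  expect_identical(out4$n_skipped, 10L)
})

test_that("fold-change z-scores standardize each row", {
  m <- matrix(c(1, 2, 3, 4), 1, dimnames = list("g1", c("SO", "SP", "SR", "SLM")))
  z <- zscore_fold_changes(m)$z
  expect_equal(unname(z[1, ]), c(-1.1619, -0.3873, 0.3873, 1.1619), tolerance = 1e-4)
  # constant rows become zero and are flagged
  m2 <- rbind(m, g2 = rep(5, 4))
  out <- zscore_fold_changes(m2)
  expect_equal(unname(out$z["g2", ]), rep(0, 4))
  expect_true(out$flagged_constant[["g2"]])
  expect_false(out$flagged_constant[["g1"]])
  # every non-degenerate row has mean 0 and sd 1
  set.seed(2)
  big <- matrix(rnorm(200), 50, 4,
                dimnames = list(sprintf("g%02d", 1:50), c("SO", "SP", "SR", "SLM")))
  zb <- zscore_fold_changes(big)$z
  expect_equal(unname(rowMeans(zb)), rep(0, 50), tolerance = 1e-10)
  expect_equal(unname(apply(zb, 1, sd)), rep(1, 50), tolerance = 1e-10)
  expect_error(zscore_fold_changes(big[, 1, drop = FALSE]), ">= 2")
  # per-set long distributions cover exactly the member genes present
  sets <- structure(list(S1 = list(description = "d", genes = c("g01", "g02", "gZZ"))),
                    class = "gene_set_collection")
  sd_out <- zscore_fold_changes(big, sets)$set_distributions
  expect_setequal(unique(sd_out$gene), c("g01", "g02"))
  expect_identical(nrow(sd_out), 8L)
})

test_that("Kruskal-Wallis/Dunn matches hand values and independent recomputation", {
  # hand example: ranks 1.5 / 3.5 / 5.5 -> H = 4.5714, p = exp(-H/2)
  kt <- kruskal_dunn_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(kt$H, 32 / 7, tolerance = 1e-10)
  expect_equal(kt$p, exp(-(32 / 7) / 2), tolerance = 1e-10)
  expect_identical(kt$df, 2L)
  # identical value multisets across groups: H = 0, all Z = 0
  kt0 <- kruskal_dunn_test(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(kt0$H, 0, tolerance = 1e-12)
  expect_equal(kt0$dunn$Z, rep(0, 3), tolerance = 1e-12)
  # oracle equivalence on random tied inputs
  set.seed(3)
  for (i in 1:25) {
    v <- sample(1:6, 12, replace = TRUE)  # heavy ties
    g <- sample(rep(c("a", "b", "c"), each = 4))
    kk <- kruskal_dunn_test(v, g)
    expect_equal(kk$H, manual_kw_H(v, g), tolerance = 1e-10)
    expect_equal(kk$dunn$Z[kk$dunn$comparison == "a vs b"],
                 unname(manual_dunn_z(v, g, "a", "b")), tolerance = 1e-10)
  }
  # Bonferroni adjustment is p * m capped at 1
  expect_equal(kt$dunn$p_adjusted, pmin(1, kt$dunn$p * 3))
  expect_error(kruskal_dunn_test(1:3, c("a", "a", "b")), "n >= 2")
})

test_that("half-life group test joins by gene and orders classes as planted", {
  records <- data.frame(
    gene = sprintf("g%02d", 1:30),
    r = c(rep(0.95, 10), rep(-0.95, 10), rep(0, 10)),
    n_profile_points = 4,
    class = rep(c("positive", "negative", "neither"), each = 10),
    flagged = FALSE, stringsAsFactors = FALSE)
  set.seed(4)
  hl <- c(rlnorm(10, log(50), 0.1), rlnorm(10, log(400), 0.1), rlnorm(10, log(150), 0.1))
  refs <- list(half_life = stats::setNames(hl, records$gene))
  out <- halflife_group_test(records, refs)
  expect_identical(out$n_mapped, 30L)
  expect_lt(out$medians$positive, out$medians$negative)
  expect_lt(out$test$p, 0.01)
  zpn <- out$test$dunn$Z[out$test$dunn$comparison == "positive vs negative"]
  expect_lt(zpn, 0)  # shorter half-lives rank lower
  # genes without half-life entries are excluded from the join count
  refs2 <- list(half_life = refs$half_life[1:20])
  expect_identical(halflife_group_test(records, refs2)$n_mapped, 20L)
})

test_that("co-enrichment cross-tab matches manual enumeration", {
  call_df <- function(feats, comps, molecule) {
    data.frame(feature = feats, molecule = molecule, compartment = comps,
               direction = "enriched", contrasts = "x", stringsAsFactors = FALSE)
  }
  # 12-gene fixture with one multi-compartment mRNA call (g1 in SP and SLM)
  mrna <- call_df(c("g1", "g1", "g2", "g3", "g4", "g5"),
                  c("SP", "SLM", "SP", "SO", "SLM", "SR"), "mrna")
  prot <- call_df(c("g1", "g2", "g3", "g4", "g6"),
                  c("SLM", "SLM", "SO", "SLM", "SP"), "protein")
  tr <- c(g1 = "neuropil", g2 = "soma", g4 = "neuropil")
  out <- co_enrichment_map(mrna, prot, tr)
  # manual enumeration: (SP,SLM): g1,g2; (SLM,SLM): g1,g4; (SO,SO): g3
  expect_identical(out$n_genes[out$mrna_compartment == "SP" &
                                 out$prot_compartment == "SLM"], 2L)
  expect_identical(out$genes[out$mrna_compartment == "SLM" &
                               out$prot_compartment == "SLM"], "g1;g4")
  expect_identical(out$n_genes[out$mrna_compartment == "SO" &
                                 out$prot_compartment == "SO"], 1L)
  expect_identical(nrow(out), 3L)
  # translatome proportions sum to 1 over labeled genes
  sums <- rowSums(out[, c("prop_soma", "prop_neuropil", "prop_unbiased")])
  expect_equal(sums[out$n_labeled > 0], rep(1, sum(out$n_labeled > 0)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # (SP, SLM): g1 neuropil + g2 soma
  sp_slm <- out[out$mrna_compartment == "SP" & out$prot_compartment == "SLM", ]
  expect_equal(sp_slm$prop_soma, 0.5)
  expect_equal(sp_slm$prop_neuropil, 0.5)
  # mixed schemes are rejected
  bad <- call_df("g9", "CA1", "protein")
  expect_error(co_enrichment_map(mrna, bad, tr), "scheme")
})

test_that("proportions follow the labeled-gene arithmetic", {
  mrna <- data.frame(feature = sprintf("g%02d", 1:10), molecule = "mrna",
                     compartment = "SLM", direction = "enriched",
                     contrasts = "x", stringsAsFactors = FALSE)
  prot <- mrna; prot$molecule <- "protein"
  tr <- stats::setNames(c(rep("neuropil", 4), "soma", rep("unbiased", 5)),
                        sprintf("g%02d", 1:10))
  out <- co_enrichment_map(mrna, prot, tr)
  expect_equal(out$prop_neuropil, 0.4)
  expect_equal(out$prop_soma, 0.1)
  expect_equal(out$prop_unbiased, 0.5)
})
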