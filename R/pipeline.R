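#' Configuration for a full pipeline run
#'
#' Bundles the synthetic-data conditions with the analysis thresholds:
#' tissue-track significance `alpha_tissue = 0.01` and synaptosome-track
#' `alpha_synapto = 0.05`, the enrichment fold-change floor
#' `lfc_min = 0.1`, correlation-class thresholds `r_pos/r_neg = +/-0.9`,
#' ORA FDR cutoff 0.05, and PLS-DA cross-validation settings (3-fold,
#' 15 repeats by default).
#'
#' @param sim A [sim_config()] (or a list of overrides for its
#'   defaults).
#' @param scheme Tissue contrast scheme, `"one_vs_rest"` (default for
#'   strata) or `"pairwise"` (with calls intersected across pairs, the
#'   subregion convention).
#' @param alpha_tissue,alpha_synapto Adjusted-p thresholds per track.
#' @param lfc_min Minimum absolute log2 fold change for enrichment.
#' @param r_pos,r_neg Profile-correlation class thresholds.
#' @param fdr_cutoff ORA significance threshold.
#' @param plsda_k,plsda_repeats,plsda_a_max PLS-DA CV settings.
#' @param seed Master seed; every stochastic stage derives from it.
#' @return A validated `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       scheme = c("one_vs_rest", "pairwise"),
                       alpha_tissue = 0.01, alpha_synapto = 0.05,
                       lfc_min = 0.1, r_pos = 0.9, r_neg = -0.9,
                       fdr_cutoff = 0.05,
                       plsda_k = 3L, plsda_repeats = 15L, plsda_a_max = 5L,
                       seed = 1L) {
  scheme <- match.arg(scheme)
  if (is.list(sim) && !inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  stopifnot(inherits(sim, "sim_config"))
  if (any(c(alpha_tissue, alpha_synapto, fdr_cutoff) <= 0) ||
      any(c(alpha_tissue, alpha_synapto, fdr_cutoff) > 1)) {
    stop("significance thresholds must lie in (0, 1]", call. = FALSE)
  }
  if (lfc_min < 0) stop("lfc_min must be non-negative", call. = FALSE)
  if (r_neg >= r_pos) stop("r_neg must be below r_pos", call. = FALSE)
  structure(list(sim = sim, scheme = scheme,
                 alpha_tissue = alpha_tissue, alpha_synapto = alpha_synapto,
                 lfc_min = lfc_min, r_pos = r_pos, r_neg = r_neg,
                 fdr_cutoff = fdr_cutoff,
                 plsda_k = as.integer(plsda_k),
                 plsda_repeats = as.integer(plsda_repeats),
                 plsda_a_max = as.integer(plsda_a_max),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full integration pipeline on a synthetic bundle
#'
#' Executes the complete analysis: simulation; count normalization and
#' NB Wald differential enrichment with enrichment calls; protein rlr
#' normalization and moderated-t enrichment; the sorted/unsorted
#' contaminant track (P3-vs-P2 tests, contaminant list, filtering,
#' synaptic one-vs-rest tests, PLS-DA with VIP scores); and the
#' integration track (iBAQ, population and profile correlations,
#' half-life rank tests, co-enrichment with translatome proportions,
#' z-scored fold-change gene-set distributions, ORA). All stages are
#' pure functions of (config, seed); reruns are byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, all product tables and
#'   a manifest are written via [write_results_bundle()].
#' @return A list of stage products plus a `summary` element of headline
#'   counts and statistics.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  sim_cfg <- config$sim
  call_scheme <- if (config$scheme == "pairwise") "pairwise_intersection" else "one_vs_rest"

  # --- simulate ------------------------------------------------------------
  tissue <- simulate_spatial_omics(sim_cfg, seed = config$seed)
  refs <- simulate_reference_tables(sim_cfg, tissue$truth, seed = config$seed)
  sorting <- simulate_sorting_experiment(sim_cfg, seed = config$seed)

  # --- tissue track: RNA ---------------------------------------------------
  sf <- median_ratio_size_factors(tissue$rna)
  rna_lognorm <- log2(sf$normalized + 1)
  rna_de <- de_compartments(tissue$rna, scheme = config$scheme)
  mrna_calls <- call_enrichment(rna_de, scheme = call_scheme, molecule = "mrna",
                                lfc_min = config$lfc_min, alpha = config$alpha_tissue)

  # --- tissue track: protein ----------------------------------------------
  prot_norm <- rlr_normalize(tissue$protein)
  prot_de <- de_compartments(prot_norm, scheme = config$scheme)
  prot_calls <- call_enrichment(prot_de, scheme = call_scheme, molecule = "protein",
                                lfc_min = config$lfc_min, alpha = config$alpha_tissue)

  # --- synaptosome track ---------------------------------------------------
  prot_fraction_de <- de_fractions(sorting$protein)
  rna_fraction_de <- de_fractions(sorting$rna)
  contaminants_protein <- build_contaminant_list(prot_fraction_de,
                                                 alpha = config$alpha_synapto,
                                                 lfc_min = config$lfc_min)
  contaminants_rna <- build_contaminant_list(rna_fraction_de,
                                             alpha = config$alpha_synapto,
                                             lfc_min = config$lfc_min)
  p3_ids <- sorting$protein$meta$sample_id[sorting$protein$meta$fraction == "P3"]
  prot_p3 <- subset_omics(sorting$protein, samples = p3_ids)
  prot_p3 <- suppressMessages(apply_contaminant_filter(prot_p3, contaminants_protein))
  synaptic_de <- de_compartments(prot_p3, scheme = "one_vs_rest")
  synaptic_calls <- call_enrichment(synaptic_de, scheme = "one_vs_rest",
                                    molecule = "protein",
                                    lfc_min = config$lfc_min,
                                    alpha = config$alpha_synapto)

  complete <- rowSums(is.na(prot_p3$values)) == 0
  Xp <- t(prot_p3$values[complete, , drop = FALSE])
  pls_labels <- factor(prot_p3$meta$compartment)
  a_max <- min(config$plsda_a_max, nrow(Xp) - 2L, qr(scale(Xp))$rank)
  pls_cv <- cross_validate_plsda(Xp, pls_labels, k = config$plsda_k,
                                 repeats = config$plsda_repeats,
                                 A_max = a_max, seed = config$seed)
  pls_fit <- fit_plsda(Xp, pls_labels, A = pls_cv$chosen_A)
  vip <- vip_scores(pls_fit)

  # --- integration track ---------------------------------------------------
  pep_counts <- peptide_count_table(refs$sequences)
  ibaq <- ibaq_transform(prot_norm, pep_counts)
  rna_means <- compartment_means(rna_lognorm, meta = tissue$rna$meta)
  ibaq_means <- compartment_means(ibaq)
  pop_cor <- population_correlation(rna_means, ibaq_means)
  prof <- profile_correlation_classify(rna_means, ibaq_means,
                                       r_pos = config$r_pos, r_neg = config$r_neg)
  halflife <- halflife_group_test(prof, refs)
  co_map <- co_enrichment_map(mrna_calls, prot_calls, refs$translatome)

  comps <- sim_cfg$compartments
  if (config$scheme == "one_vs_rest") {
    lfc_mat <- vapply(comps, function(cc) {
      de <- rna_de[[cc]]
      stats::setNames(de$log2fc, de$feature)[rownames(rna_lognorm)]
    }, numeric(nrow(rna_lognorm)))
    zdist <- zscore_fold_changes(lfc_mat, refs$gene_sets)
  } else {
    zdist <- NULL
  }

  background <- rownames(tissue$rna$values)
  ora <- do.call(rbind, lapply(comps, function(cc) {
    q <- mrna_calls$feature[mrna_calls$compartment == cc &
                              mrna_calls$direction == "enriched"]
    if (length(q) < 1L) return(NULL)
    res <- suppressMessages(ora_hypergeometric(q, background, refs$gene_sets,
                                               fdr_cutoff = config$fdr_cutoff))
    if (nrow(res)) cbind(query_compartment = cc, res) else NULL
  }))

  summary <- list(
    n_genes = sim_cfg$n_genes,
    n_mrna_enriched_calls = sum(mrna_calls$direction == "enriched"),
    n_protein_enriched_calls = sum(prot_calls$direction == "enriched"),
    n_contaminants_protein = nrow(contaminants_protein),
    n_contaminants_rna = nrow(contaminants_rna),
    n_synaptic_enriched_calls = sum(synaptic_calls$direction == "enriched"),
    correlation_classes = prof$summary,
    halflife_H = halflife$test$H,
    halflife_p = halflife$test$p,
    plsda_chosen_A = pls_cv$chosen_A,
    plsda_cv_accuracy = max(pls_cv$table$mean_accuracy),
    n_ora_significant = if (is.null(ora)) 0L else sum(ora$significant)
  )

  result <- list(
    config = config, tissue = tissue, refs = refs, sorting = sorting,
    size_factors = sf$size_factors, rna_lognorm = rna_lognorm,
    rna_de = rna_de, mrna_calls = mrna_calls,
    prot_norm = prot_norm, prot_de = prot_de, prot_calls = prot_calls,
    prot_fraction_de = prot_fraction_de, rna_fraction_de = rna_fraction_de,
    contaminants_protein = contaminants_protein, contaminants_rna = contaminants_rna,
    synaptic_de = synaptic_de, synaptic_calls = synaptic_calls,
    pls_cv = pls_cv, pls_fit = pls_fit, vip = vip,
    ibaq = ibaq, population_correlation = pop_cor, profile_classes = prof,
    halflife_test = halflife, co_enrichment = co_map, zscore = zdist,
    ora = ora, summary = summary
  )

  if (!is.null(out_dir)) {
    products <- list(
      rna_counts = tissue$rna, protein_log2 = tissue$protein,
      size_factors = data.frame(sample_id = names(sf$size_factors),
                                size_factor = unname(sf$size_factors)),
      mrna_de = do.call(rbind, rna_de), protein_de = do.call(rbind, prot_de),
      mrna_enrichment_calls = mrna_calls, protein_enrichment_calls = prot_calls,
      contaminants_protein = as.data.frame(contaminants_protein),
      contaminants_rna = as.data.frame(contaminants_rna),
      synaptic_de = do.call(rbind, synaptic_de),
      synaptic_enrichment_calls = synaptic_calls,
      plsda_cv = pls_cv$table, vip_scores = vip,
      population_correlation = pop_cor,
      correlation_records = prof$records,
      dunn_tests = halflife$test$dunn,
      co_enrichment = co_map
    )
    if (!is.null(ora)) products$ora <- ora
    cfg_json <- config
    cfg_json$sim <- unclass(cfg_json$sim)
    write_results_bundle(products, out_dir, config = unclass(cfg_json),
                         seed = config$seed)
  }
  result
}
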