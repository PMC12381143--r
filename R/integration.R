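#' Population-level mRNA-protein abundance correlation
#'
#' Pearson correlation between gene-level mean mRNA abundance (log2
#' normalized counts) and mean protein abundance (log2 iBAQ), computed
#' within each compartment and across all compartments (per-gene grand
#' mean over compartment means). Only genes with complete observations
#' on both sides of a scope enter that scope's correlation.
#'
#' @param rna_abund Gene x compartment matrix of mean log2 normalized
#'   counts (see [compartment_means()]).
#' @param prot_abund Gene x compartment matrix of mean log2 iBAQ values.
#' @return Data frame with `scope` (compartment or `"all"`), `r` and
#'   `n_pairs`; scopes with fewer than 3 complete pairs report `NA` with
#'   `flagged = TRUE`.
#' @export
population_correlation <- function(rna_abund, prot_abund) {
  shared <- intersect(rownames(rna_abund), rownames(prot_abund))
  comps <- intersect(colnames(rna_abund), colnames(prot_abund))
  if (length(comps) < 1L) stop("no shared compartments", call. = FALSE)
  rna <- rna_abund[shared, comps, drop = FALSE]
  prot <- prot_abund[shared, comps, drop = FALSE]
  one_scope <- function(x, y, scope) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) {
      data.frame(scope = scope, r = NA_real_, n_pairs = sum(ok), flagged = TRUE)
    } else {
      data.frame(scope = scope, r = stats::cor(x[ok], y[ok]), n_pairs = sum(ok),
                 flagged = FALSE)
    }
  }
  rows <- lapply(comps, function(cc) one_scope(rna[, cc], prot[, cc], cc))
  rows[[length(rows) + 1L]] <- one_scope(rowMeans(rna), rowMeans(prot), "all")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify genes by mRNA-protein profile correlation across compartments
#'
#' Per shared gene, the Pearson correlation of its mean mRNA profile and
#' mean protein profile across the compartments (typically the 4 CA1
#' strata) is computed and thresholded into `positive` (`r >= r_pos`),
#' `negative` (`r <= r_neg`) or `neither`. Profiles with zero variance on
#' either side yield an undefined `r` and class `neither`, flagged.
#'
#' @param rna_means,prot_means Gene x compartment matrices of means over
#'   replicates (matching column order; log2 scale).
#' @param r_pos,r_neg Class thresholds (defaults +0.9 / -0.9).
#' @return List with `records` (data frame `gene`, `r`,
#'   `n_profile_points`, `class`, `flagged`), `summary` (class counts)
#'   and `n_skipped` (genes absent from one side).
#' @export
profile_correlation_classify <- function(rna_means, prot_means,
                                         r_pos = 0.9, r_neg = -0.9) {
  if (r_neg >= r_pos) stop("r_neg must be below r_pos", call. = FALSE)
  comps <- intersect(colnames(rna_means), colnames(prot_means))
  if (length(comps) < 3L) stop("need >= 3 shared compartments for a profile correlation",
                               call. = FALSE)
  shared <- intersect(rownames(rna_means), rownames(prot_means))
  n_skipped <- length(union(rownames(rna_means), rownames(prot_means))) - length(shared)
  rna <- rna_means[shared, comps, drop = FALSE]
  prot <- prot_means[shared, comps, drop = FALSE]
  r <- flagged <- rep(NA, length(shared))
  for (i in seq_along(shared)) {
    x <- rna[i, ]; y <- prot[i, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) < 1e-12 || stats::sd(y[ok]) < 1e-12) {
      r[i] <- NA_real_; flagged[i] <- TRUE
    } else {
      r[i] <- stats::cor(x[ok], y[ok]); flagged[i] <- FALSE
    }
  }
  cls <- ifelse(is.na(r), "neither",
                ifelse(r >= r_pos, "positive",
                       ifelse(r <= r_neg, "negative", "neither")))
  records <- data.frame(gene = shared, r = as.numeric(r),
                        n_profile_points = length(comps), class = cls,
                        flagged = as.logical(flagged), stringsAsFactors = FALSE)
  summary <- table(factor(cls, levels = c("positive", "negative", "neither")))
  list(records = records, summary = as.list(summary), n_skipped = n_skipped)
}

#' Row-wise z-scores of log2 fold changes across compartments
#'
#' For each gene, subtracts the mean fold change across compartments and
#' divides by the (sample, ddof = 1) standard deviation — the
#' standardization underlying ridge-plot distributions of gene-set fold
#' changes. Constant rows become all zero and are flagged.
#'
#' @param lfc Gene x compartment matrix of log2 fold changes (>= 2
#'   columns).
#' @param gene_sets Optional `gene_set_collection`; when given, a long
#'   data frame of per-set z-score distributions is returned alongside.
#' @return List with `z` (matrix), `flagged_constant` (logical vector)
#'   and, when requested, `set_distributions` (`set`, `gene`,
#'   `compartment`, `z`).
#' @export
zscore_fold_changes <- function(lfc, gene_sets = NULL) {
  if (!is.matrix(lfc) || ncol(lfc) < 2L) {
    stop("fold-change matrix needs >= 2 compartment columns", call. = FALSE)
  }
  mu <- rowMeans(lfc)
  sdv <- apply(lfc, 1, stats::sd)
  flagged <- sdv < 1e-12
  z <- (lfc - mu) / ifelse(flagged, 1, sdv)
  z[flagged, ] <- 0
  out <- list(z = z, flagged_constant = stats::setNames(flagged, rownames(lfc)))
  if (!is.null(gene_sets)) {
    rows <- list()
    for (nm in names(gene_sets)) {
      members <- intersect(gene_sets[[nm]]$genes, rownames(z))
      if (!length(members)) next
      sub <- z[members, , drop = FALSE]
      rows[[nm]] <- data.frame(
        set = nm,
        gene = rep(members, times = ncol(sub)),
        compartment = rep(colnames(sub), each = length(members)),
        z = as.vector(sub), stringsAsFactors = FALSE)
    }
    out$set_distributions <- if (length(rows)) do.call(rbind, rows) else
      data.frame(set = character(0), gene = character(0),
                 compartment = character(0), z = numeric(0))
    rownames(out$set_distributions) <- NULL
  }
  out
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H (via `stats::kruskal.test`) followed by
#' Dunn's pairwise z statistics on the pooled ranks with the tie
#' correction `sum(t^3 - t)`, two-sided normal p-values and Bonferroni
#' adjustment over the pairwise comparisons.
#'
#' For very small groups, where the chi-square reference for H is a
#' rough approximation, `p_method = "permutation"` additionally computes
#' a label-permutation p-value for H (Monte-Carlo, `n_perm` draws).
#'
#' @param values Numeric vector of observations.
#' @param groups Factor/character of group labels (same length).
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Monte-Carlo permutations when `p_method = "permutation"`.
#' @param perm_seed Seed for the permutation draw.
#' @return A `rank_test_result`: list with `H`, `df`, `p`, `n` (group
#'   sizes) and `dunn` (data frame `comparison`, `Z`, `p`, `p_adjusted`);
#'   with `p_method = "permutation"` also `p_permutation`.
#' @export
kruskal_dunn_test <- function(values, groups, p_method = c("chisq", "permutation"),
                              n_perm = 10000L, perm_seed = 1L) {
  p_method <- match.arg(p_method)
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2L)) stop("every group needs n >= 2", call. = FALSE)
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  rk <- rank(values)
  rbar <- tapply(rk, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  var_core <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  levs <- levels(groups)
  prs <- utils::combn(levs, 2, simplify = FALSE)
  dunn <- do.call(rbind, lapply(prs, function(pr) {
    ni <- sizes[[pr[1]]]; nj <- sizes[[pr[2]]]
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) / sqrt(var_core * (1 / ni + 1 / nj))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(comparison = paste(pr, collapse = " vs "), Z = z, p = p,
               stringsAsFactors = FALSE)
  }))
  dunn$p_adjusted <- pmin(1, dunn$p * nrow(dunn))
  rownames(dunn) <- NULL
  out <- list(H = unname(kw$statistic), df = unname(kw$parameter),
              p = kw$p.value, n = as.list(sizes), dunn = dunn)
  if (p_method == "permutation") {
    H_obs <- out$H
    set.seed(perm_seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      Hb <- suppressWarnings(stats::kruskal.test(values, sample(groups))$statistic)
      if (Hb >= H_obs - 1e-12) hits <- hits + 1L
    }
    out$p_permutation <- (hits + 1) / (n_perm + 1)
  }
  structure(out, class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4f, df = %d, p = %.4g\n",
              x$H, x$df, x$p))
  print(x$dunn, row.names = FALSE)
  invisible(x)
}

#' Protein half-life comparison across correlation classes
#'
#' Joins correlation records to the gene-level half-life reference and
#' compares half-lives across the groups `all` (every mapped gene),
#' `positive` and `negative` with [kruskal_dunn_test()]. The `all` group
#' deliberately overlaps the class groups (its members re-enter the
#' pooled ranking), mirroring the three-box comparison convention; the
#' groups are therefore not independent.
#'
#' @param records Correlation records from
#'   [profile_correlation_classify()] (`$records` or the list itself).
#' @param reference Reference tables with a `half_life` element (named
#'   numeric, hours).
#' @param groups Which groups to compare (default
#'   `c("all", "positive", "negative")`).
#' @return List with `test` (a `rank_test_result`), `n_mapped` (genes
#'   joined to a half-life) and `medians` (named list of group medians).
#' @export
halflife_group_test <- function(records, reference,
                                groups = c("all", "positive", "negative")) {
  if (is.list(records) && !is.data.frame(records) && !is.null(records$records)) {
    records <- records$records
  }
  hl <- reference$half_life
  if (is.null(hl)) stop("reference tables lack half-lives", call. = FALSE)
  mapped <- records[records$gene %in% names(hl), , drop = FALSE]
  if (!nrow(mapped)) stop("no gene maps to a half-life", call. = FALSE)
  mapped$half_life <- hl[mapped$gene]
  vals <- list()
  for (g in groups) {
    vals[[g]] <- if (g == "all") mapped$half_life else
      mapped$half_life[mapped$class == g]
  }
  values <- unlist(vals, use.names = FALSE)
  labels <- rep(names(vals), lengths(vals))
  test <- kruskal_dunn_test(values, factor(labels, levels = groups))
  list(test = test, n_mapped = nrow(mapped),
       medians = lapply(vals, stats::median))
}

#' Cross-tabulate mRNA and protein enrichment sites with translatome labels
#'
#' Genes enriched (direction `enriched`) at both molecule levels are
#' placed into `(mRNA compartment, protein compartment)` cells; genes
#' enriched in several compartments contribute to every applicable cell.
#' Within each cell, the proportions of translatome labels (`soma`,
#' `neuropil`, `unbiased`) are computed over the labeled genes, with
#' unlabeled genes counted separately.
#'
#' @param mrna_calls,prot_calls `EnrichmentCall` data frames (see
#'   [call_enrichment()]) from the same compartment scheme.
#' @param translatome Optional named character vector of gene labels
#'   (or reference tables list with a `translatome` element).
#' @return Data frame with one row per occupied cell: `mrna_compartment`,
#'   `prot_compartment`, `n_genes`, `genes` (';'-joined), and — when a
#'   translatome is supplied — `n_labeled`, `prop_soma`, `prop_neuropil`,
#'   `prop_unbiased`, `n_unlabeled`.
#' @export
co_enrichment_map <- function(mrna_calls, prot_calls, translatome = NULL) {
  if (is.list(translatome) && !is.null(translatome$translatome)) {
    translatome <- translatome$translatome
  }
  me <- mrna_calls[mrna_calls$direction == "enriched", , drop = FALSE]
  pe <- prot_calls[prot_calls$direction == "enriched", , drop = FALSE]
  comps <- unique(c(me$compartment, pe$compartment))
  scheme_hits <- vapply(compartment_schemes, function(s) all(comps %in% s), logical(1))
  if (length(comps) && !any(scheme_hits)) {
    stop("mRNA and protein calls mix compartment schemes", call. = FALSE)
  }
  joined <- merge(me[, c("feature", "compartment")],
                  pe[, c("feature", "compartment")],
                  by = "feature", suffixes = c("_mrna", "_prot"))
  if (!nrow(joined)) {
    return(data.frame(mrna_compartment = character(0),
                      prot_compartment = character(0),
                      n_genes = integer(0), genes = character(0),
                      stringsAsFactors = FALSE))
  }
  cells <- split(joined$feature,
                 list(mrna = joined$compartment_mrna,
                      prot = joined$compartment_prot), drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(names(cells), function(key) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    genes <- sort(unique(cells[[key]]))
    row <- data.frame(mrna_compartment = parts[1], prot_compartment = parts[2],
                      n_genes = length(genes),
                      genes = paste(genes, collapse = ";"),
                      stringsAsFactors = FALSE)
    if (!is.null(translatome)) {
      lab <- translatome[genes]
      labeled <- lab[!is.na(lab)]
      row$n_labeled <- length(labeled)
      for (ll in c("soma", "neuropil", "unbiased")) {
        row[[paste0("prop_", ll)]] <-
          if (length(labeled)) mean(labeled == ll) else NA_real_
      }
      row$n_unlabeled <- length(genes) - length(labeled)
    }
    row
  }))
  out <- out[order(out$mrna_compartment, out$prot_compartment), , drop = FALSE]
  rownames(out) <- NULL
  out
}
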