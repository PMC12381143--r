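#' Differential tests of sorted (P3) versus unsorted (P2) fractions
#'
#' Runs the P3-vs-P2 comparison separately within each compartment, with
#' the molecule-appropriate test (NB Wald for counts, moderated linear
#' model for intensities). Reported log2 fold changes are P3 relative to
#' P2, so contaminants carried by the unsorted fraction appear negative.
#'
#' @param mat An [omics_matrix()] containing `P2` and `P3` fraction
#'   samples for each compartment.
#' @param min_quant Valid-value threshold per group (intensities only).
#' @return Named list (by compartment) of `DEResult` data frames.
#' @export
de_fractions <- function(mat, min_quant = 1L) {
  stopifnot(inherits(mat, "omics_matrix"))
  if (!all(c("P2", "P3") %in% mat$meta$fraction)) {
    stop("matrix must contain P2 and P3 fraction samples", call. = FALSE)
  }
  comps <- unique(mat$meta$compartment)
  out <- list()
  for (cc in comps) {
    ids <- mat$meta$sample_id[mat$meta$compartment == cc]
    sub <- subset_omics(mat, samples = ids)
    grp <- factor(sub$meta$fraction, levels = c("P2", "P3"))
    names(grp) <- sub$meta$sample_id
    lab <- paste0("P3_vs_P2@", cc)
    if (mat$kind == "rna_counts") {
      out[[cc]] <- nb_wald_de(sub, grp, contrast_label = lab)
    } else {
      subf <- filter_valid_values(sub, grp, min_quant = min_quant)
      out[[cc]] <- moderated_lm_de(subf, grp, contrast_label = lab)
    }
  }
  out
}

#' Compile the sorting-contaminant list
#'
#' A feature is listed as a contaminant when it is significantly enriched
#' in the unsorted (P2) fraction — `q < alpha` and `log2fc(P3/P2) <=
#' -lfc_min` — in any compartment (union semantics). Every listed feature
#' carries the provenance of the compartment contrasts that flagged it.
#'
#' @param p3_vs_p2_de Named list of P3-vs-P2 `DEResult` data frames per
#'   compartment (see [de_fractions()]).
#' @param alpha Adjusted-p threshold (default 0.05, the synaptosome
#'   convention).
#' @param lfc_min Minimum magnitude of the P2-direction log2 fold change.
#' @return A `contaminant_list`: data frame `feature`, `compartments`
#'   (provenance, ';'-joined), `min_padj`.
#' @export
build_contaminant_list <- function(p3_vs_p2_de, alpha = 0.05, lfc_min = 0.1) {
  if (!length(p3_vs_p2_de)) stop("no P3-vs-P2 results supplied", call. = FALSE)
  hits <- list()
  for (cc in names(p3_vs_p2_de)) {
    de <- p3_vs_p2_de[[cc]]
    sel <- !is.na(de$padj) & de$padj < alpha & de$log2fc <= -lfc_min
    if (any(sel)) {
      hits[[cc]] <- data.frame(feature = de$feature[sel], compartment = cc,
                               padj = de$padj[sel], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    out <- data.frame(feature = character(0), compartments = character(0),
                      min_padj = numeric(0), stringsAsFactors = FALSE)
  } else {
    all_hits <- do.call(rbind, hits)
    out <- do.call(rbind, lapply(split(all_hits, all_hits$feature), function(d) {
      data.frame(feature = d$feature[1],
                 compartments = paste(sort(d$compartment), collapse = ";"),
                 min_padj = min(d$padj), stringsAsFactors = FALSE)
    }))
    out <- out[order(out$feature), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("contaminant_list", class(out))
  out
}

#' Remove listed contaminant features from a matrix
#'
#' Listed features are removed from all compartments; the remaining
#' feature order is preserved. Filtering is idempotent.
#'
#' @param mat An [omics_matrix()].
#' @param list A `contaminant_list` from [build_contaminant_list()].
#' @return The filtered [omics_matrix()].
#' @export
apply_contaminant_filter <- function(mat, list) {
  stopifnot(inherits(mat, "omics_matrix"))
  drop <- intersect(rownames(mat$values), list$feature)
  keep <- setdiff(rownames(mat$values), drop)
  message(length(drop), " contaminant feature(s) removed; ", length(keep), " remain")
  subset_omics(mat, features = keep)
}
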