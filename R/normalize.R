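#' Median-of-ratios size factors for a count matrix
#'
#' The classical median-of-ratios estimator: the reference abundance of a
#' gene is its geometric mean across samples (computed over genes with
#' all-positive counts), and a sample's size factor is the median of its
#' count-to-reference ratios. Factors are rescaled to unit geometric mean
#' so the overall scale is identified.
#'
#' @param counts An [omics_matrix()] of kind `rna_counts`, or a plain
#'   non-negative numeric matrix (e.g. already-normalized counts, for
#'   fixed-point checks).
#' @return List with `size_factors` (named numeric, geometric mean 1) and
#'   `normalized` (matrix of counts divided by their size factor).
#' @export
median_ratio_size_factors <- function(counts) {
  if (inherits(counts, "omics_matrix")) {
    if (counts$kind != "rna_counts") stop("size factors require a count matrix", call. = FALSE)
    k <- counts$values
  } else {
    if (!is.matrix(counts) || !is.numeric(counts) || any(counts < 0) || anyNA(counts)) {
      stop("size factors require a complete non-negative matrix", call. = FALSE)
    }
    k <- counts
  }
  pos <- rowSums(k > 0) == ncol(k)
  if (!any(pos)) stop("no gene with positive counts in every sample", call. = FALSE)
  logk <- log(k[pos, , drop = FALSE])
  log_ref <- rowMeans(logk)
  log_sf <- apply(logk - log_ref, 2, stats::median)
  log_sf <- log_sf - mean(log_sf)
  sf <- exp(log_sf)
  names(sf) <- colnames(k)
  list(size_factors = sf, normalized = sweep(k, 2, sf, `/`))
}

#' Robust-linear-regression (rlr) normalization of log2 intensities
#'
#' Each sample is regressed on the per-feature median reference profile
#' (pairwise-complete) by Huber M-estimation (tuning constant 1.345, up
#' to 50 IRLS iterations), and the fitted affine map is inverted:
#' `x' = (x - a) / b`. Removes per-sample shift and scale effects while
#' down-weighting outlying features; missing cells stay missing.
#'
#' @param logmat An [omics_matrix()] of kind `protein_log2`.
#' @return A normalized [omics_matrix()] of the same shape and kind.
#' @export
rlr_normalize <- function(logmat) {
  stopifnot(inherits(logmat, "omics_matrix"))
  if (logmat$kind != "protein_log2") stop("rlr normalization expects log2 intensities", call. = FALSE)
  x <- logmat$values
  ref <- apply(x, 1, stats::median, na.rm = TRUE)
  out <- x
  for (j in seq_len(ncol(x))) {
    ok <- !is.na(x[, j]) & !is.na(ref)
    if (sum(ok) < 3) {
      stop("sample ", colnames(x)[j], ": fewer than 3 features for rlr fit", call. = FALSE)
    }
    cf <- huber_affine_fit(ref[ok], x[ok, j], sample_id = colnames(x)[j])
    out[, j] <- (x[, j] - cf[1]) / cf[2]
  }
  omics_matrix(out, logmat$kind, logmat$meta)
}

# Huber regression y ~ a + b r; exact fits (zero residual scale, where the
# MAD scale estimate degenerates) fall back to OLS, which coincides with
# the Huber solution there.
huber_affine_fit <- function(r, y, k = 1.345, maxit = 50L, sample_id = "?") {
  ols <- stats::lm.fit(cbind(1, r), y)
  if (max(abs(ols$residuals)) < 1e-10) {
    cf <- ols$coefficients
  } else {
    fit <- tryCatch(
      MASS::rlm(y ~ r, psi = MASS::psi.huber, k = k, maxit = maxit),
      error = function(e) stop("rlr fit failed for sample ", sample_id, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    if (!fit$converged) {
      stop("rlr fit did not converge for sample ", sample_id, call. = FALSE)
    }
    cf <- stats::coef(fit)
  }
  if (!is.finite(cf[2]) || cf[2] <= 0) {
    stop("non-positive rlr slope for sample ", sample_id, call. = FALSE)
  }
  unname(cf)
}

#' Count theoretical tryptic peptides of a protein (Trypsin/P)
#'
#' Cleaves after every K or R, including when followed by proline
#' (the Trypsin/P rule used to build DIA spectral libraries), optionally
#' rejoining up to `missed_cleavages` adjacent fragments, and counts the
#' distinct fragments whose length falls in `[min_len, max_len]`. This is
#' the divisor of the iBAQ transformation.
#'
#' @param seq Amino-acid sequence (case-insensitive).
#' @param min_len,max_len Peptide length bounds (default 7-35).
#' @param missed_cleavages Maximum internal cleavage sites skipped.
#' @return Integer count of distinct in-range peptides.
#' @export
count_tryptic_peptides <- function(seq, min_len = 7L, max_len = 35L,
                                   missed_cleavages = 0L) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  s <- toupper(seq)
  s <- sub("\\*$", "", s)
  chars <- strsplit(s, "")[[1]]
  if (any(!chars %in% aa_alphabet)) stop("invalid amino-acid character", call. = FALSE)
  cut_after <- which(chars %in% c("K", "R"))
  bounds <- unique(c(0L, cut_after, length(chars)))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  n_frag <- length(starts)
  peptides <- character(0)
  for (i in seq_len(n_frag)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > n_frag) break
      len <- ends[j] - starts[i] + 1L
      if (len >= min_len && len <= max_len) {
        peptides <- c(peptides, substr(s, starts[i], ends[j]))
      }
    }
  }
  length(unique(peptides))
}

#' Theoretical peptide counts for a set of protein sequences
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @inheritParams count_tryptic_peptides
#' @return Named integer vector of peptide counts.
#' @export
peptide_count_table <- function(sequences, min_len = 7L, max_len = 35L,
                                missed_cleavages = 0L) {
  vapply(sequences, count_tryptic_peptides, integer(1),
         min_len = min_len, max_len = max_len,
         missed_cleavages = missed_cleavages)
}

#' iBAQ transformation of protein intensities
#'
#' Divides each protein's linear-scale intensity by its theoretical
#' tryptic peptide count; log2 inputs are de-logged, divided, and
#' re-logged. Proteins with a zero peptide count become missing with a
#' warning.
#'
#' @param intensity An [omics_matrix()] of kind `protein_log2` (log2
#'   scale) or `protein_ibaq`/linear values are not accepted.
#' @param counts Named integer vector of theoretical peptide counts
#'   covering every protein in `intensity` (see [peptide_count_table()]).
#' @return An [omics_matrix()] of kind `protein_ibaq` (log2 iBAQ).
#' @export
ibaq_transform <- function(intensity, counts) {
  stopifnot(inherits(intensity, "omics_matrix"))
  if (intensity$kind != "protein_log2") {
    stop("iBAQ transformation expects log2 intensities", call. = FALSE)
  }
  prot <- rownames(intensity$values)
  miss <- setdiff(prot, names(counts))
  if (length(miss)) {
    stop("no peptide count for protein(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  cnt <- counts[prot]
  zero <- cnt == 0
  lin <- 2^intensity$values
  ibaq <- lin / cnt
  if (any(zero)) {
    warning(sum(zero), " protein(s) with zero theoretical peptides set to missing")
    ibaq[zero, ] <- NA_real_
  }
  omics_matrix(log2(ibaq), "protein_ibaq", intensity$meta)
}
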