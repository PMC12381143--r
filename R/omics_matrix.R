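#' Feature-by-sample abundance matrix with sample metadata
#'
#' The central container of the package: a numeric matrix of abundances
#' (RNA counts, protein log2 intensities, or log2 iBAQ values) whose columns
#' are described by a sample metadata table (compartment, replicate,
#' fraction). Counts must be complete non-negative integers; intensity
#' matrices may contain missing values (`NA`).
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#'   Row names are feature (gene symbol) identifiers, column names are
#'   sample identifiers; both must be unique.
#' @param kind One of `"rna_counts"`, `"protein_log2"`, `"protein_ibaq"`.
#' @param meta Data frame with one row per sample and columns `sample_id`,
#'   `compartment`, `replicate`, `fraction`. Compartments must all belong to
#'   a single scheme: subregions (`CA1`, `CA23`, `DG`) or CA1 strata
#'   (`SO`, `SP`, `SR`, `SLM`). Fractions are `tissue`, `P2` or `P3`.
#'
#' @return An object of class `omics_matrix`: a list with elements
#'   `values`, `kind` and `meta` (`meta` re-ordered to match the columns).
#' @export
omics_matrix <- function(values, kind = c("rna_counts", "protein_log2", "protein_ibaq"),
                         meta) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop("`values` must have row (feature) and column (sample) names", call. = FALSE)
  }
  if (anyDuplicated(fid)) stop("duplicate feature ids", call. = FALSE)
  if (anyDuplicated(sid)) stop("duplicate sample ids", call. = FALSE)
  if (kind == "rna_counts") {
    if (anyNA(values)) stop("count matrices must not contain missing values", call. = FALSE)
    if (any(values < 0)) stop("counts must be non-negative", call. = FALSE)
    if (any(abs(values - round(values)) > 1e-8)) {
      stop("counts must be integers", call. = FALSE)
    }
    storage.mode(values) <- "double"
  }
  meta <- validate_sample_meta(meta, sid)
  structure(list(values = values, kind = kind, meta = meta),
            class = "omics_matrix")
}

compartment_schemes <- list(
  subregion = c("CA1", "CA23", "DG"),
  strata    = c("SO", "SP", "SR", "SLM")
)

validate_sample_meta <- function(meta, sample_ids) {
  req <- c("sample_id", "compartment", "replicate", "fraction")
  if (!is.data.frame(meta) || !all(req %in% names(meta))) {
    stop("`meta` must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  meta <- as.data.frame(meta)[, req]
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata", call. = FALSE)
  missing_meta <- setdiff(sample_ids, meta$sample_id)
  if (length(missing_meta)) {
    stop("samples absent from metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  comp <- unique(as.character(meta$compartment))
  scheme_hits <- vapply(compartment_schemes, function(s) all(comp %in% s), logical(1))
  if (!any(scheme_hits)) {
    stop("compartments must all come from one scheme (",
         paste(vapply(compartment_schemes, paste, "", collapse = "/"),
               collapse = " or "), "); got: ",
         paste(comp, collapse = ", "), call. = FALSE)
  }
  if (!all(meta$fraction %in% c("tissue", "P2", "P3"))) {
    stop("fraction must be one of tissue, P2, P3", call. = FALSE)
  }
  rep_num <- suppressWarnings(as.integer(meta$replicate))
  if (anyNA(rep_num) || any(rep_num < 1)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  meta$replicate <- rep_num
  meta$compartment <- as.character(meta$compartment)
  meta$fraction <- as.character(meta$fraction)
  meta$sample_id <- as.character(meta$sample_id)
  meta
}

#' Identify the compartment scheme of an omics matrix
#'
#' @param x An `omics_matrix`.
#' @return `"subregion"` or `"strata"`.
#' @export
compartment_scheme <- function(x) {
  comp <- unique(x$meta$compartment)
  for (nm in names(compartment_schemes)) {
    if (all(comp %in% compartment_schemes[[nm]])) return(nm)
  }
  stop("unrecognized compartment labels", call. = FALSE)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> kind=%s, %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  cat("compartments:", paste(unique(x$meta$compartment), collapse = ", "), "\n")
  cat("fractions:   ", paste(unique(x$meta$fraction), collapse = ", "), "\n")
  n_na <- sum(is.na(x$values))
  if (n_na) cat(sprintf("missing cells: %d (%.1f%%)\n", n_na,
                        100 * n_na / length(x$values)))
  invisible(x)
}

#' Subset an omics matrix by features and/or samples
#'
#' @param x An `omics_matrix`.
#' @param features Character vector of feature ids to keep (default all).
#' @param samples Character vector of sample ids to keep (default all).
#' @return A new `omics_matrix`.
#' @export
subset_omics <- function(x, features = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(features)) {
    miss <- setdiff(features, rownames(v))
    if (length(miss)) stop("unknown features: ", paste(utils::head(miss, 5), collapse = ", "),
                           call. = FALSE)
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(v))
    if (length(miss)) stop("unknown samples: ", paste(utils::head(miss, 5), collapse = ", "),
                           call. = FALSE)
    v <- v[, samples, drop = FALSE]
  }
  omics_matrix(v, x$kind, x$meta[x$meta$sample_id %in% colnames(v), , drop = FALSE])
}

#' Per-gene compartment means of an abundance matrix
#'
#' Averages samples within each compartment (replicates collapse), using only
#' non-missing values. Used for profile correlations and population
#' correlations, where the per-stratum mean abundance is the unit of analysis.
#'
#' @param x An `omics_matrix`, or a plain numeric matrix (then `meta`
#'   must be supplied).
#' @param min_obs Minimum non-missing replicate values for a mean to be
#'   reported; compartment means based on fewer observations become `NA`.
#' @param meta Sample metadata data frame when `x` is a plain matrix.
#' @return Numeric matrix, features x compartments.
#' @export
compartment_means <- function(x, min_obs = 1L, meta = NULL) {
  if (inherits(x, "omics_matrix")) {
    meta <- x$meta
    x <- list(values = x$values, meta = meta)
  } else {
    if (is.null(meta)) stop("`meta` required for a plain matrix", call. = FALSE)
    meta <- validate_sample_meta(meta, colnames(x))
    x <- list(values = x, meta = meta)
  }
  comp <- x$meta$compartment
  levels <- unique(comp)
  out <- vapply(levels, function(cc) {
    sub <- x$values[, comp == cc, drop = FALSE]
    n_ok <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    m[n_ok < min_obs] <- NA_real_
    m
  }, numeric(nrow(x$values)))
  out <- matrix(out, nrow = nrow(x$values),
                dimnames = list(rownames(x$values), levels))
  out
}
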