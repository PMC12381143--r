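#' Hypergeometric overrepresentation analysis against a custom background
#'
#' One-sided hypergeometric (equivalently one-sided Fisher) test of each
#' gene set's overlap with the query, against a background of all genes
#' identified in the experiment. Query genes outside the background are
#' dropped (and counted); sets are intersected with the background and
#' skipped below `min_set`. P-values are BH-adjusted across tested sets.
#'
#' @param query Character vector of genes of interest (duplicates
#'   ignored).
#' @param background Character vector: the gene universe.
#' @param sets A `gene_set_collection` (see [read_gene_sets_gmt()]).
#' @param fdr_cutoff Significance threshold on the BH-adjusted p.
#' @param min_set Minimum in-background set size to test.
#' @return Data frame with one row per tested set: `set`, `K` (set size
#'   in background), `n` (query size), `x` (overlap), `N` (background
#'   size), `p`, `q`, `significant`, `overlap_genes` (';'-joined), plus
#'   attribute `n_query_dropped`.
#' @export
ora_hypergeometric <- function(query, background, sets,
                               fdr_cutoff = 0.05, min_set = 3L) {
  query <- unique(query)
  background <- unique(background)
  n_dropped <- sum(!query %in% background)
  if (n_dropped) {
    message(n_dropped, " query gene(s) outside background dropped")
  }
  query <- intersect(query, background)
  if (!length(query)) stop("empty query after intersecting with background", call. = FALSE)
  N <- length(background)
  n <- length(query)
  rows <- list()
  for (nm in names(sets)) {
    members <- intersect(unique(sets[[nm]]$genes), background)
    K <- length(members)
    if (K < min_set) next
    hit <- intersect(query, members)
    x <- length(hit)
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    rows[[nm]] <- data.frame(set = nm, K = K, n = n, x = x, N = N, p = p,
                             overlap_genes = paste(sort(hit), collapse = ";"),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(set = character(0), K = integer(0), n = integer(0),
                      x = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0),
                      overlap_genes = character(0), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out$q <- bh_adjust(out$p)
    out$significant <- out$q < fdr_cutoff
    out <- out[order(out$p, out$set),
               c("set", "K", "n", "x", "N", "p", "q", "significant", "overlap_genes")]
    rownames(out) <- NULL
  }
  attr(out, "n_query_dropped") <- n_dropped
  out
}
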