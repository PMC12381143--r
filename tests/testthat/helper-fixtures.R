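# Shared fixture builders: everything is generated in code at test time.

make_meta <- function(sample_ids, compartment, replicate = NULL, fraction = "tissue") {
  if (is.null(replicate)) replicate <- stats::ave(seq_along(sample_ids),
                                                  compartment, FUN = seq_along)
  data.frame(sample_id = sample_ids, compartment = compartment,
             replicate = replicate, fraction = fraction,
             stringsAsFactors = FALSE)
}

toy_count_matrix <- function() {
  m <- matrix(c(10, 100, 20, 200), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  omics_matrix(m, "rna_counts",
               make_meta(c("s1", "s2"), c("SO", "SO"), 1:2))
}

# strata design: n_rep replicates per stratum, optional group effect on
# the first `n_eff` features in the last stratum
random_protein_matrix <- function(n_feat = 40, n_rep = 4, noise = 0.3,
                                  n_eff = 0, effect = 2, seed = 1) {
  set.seed(seed)
  comps <- c("SO", "SP", "SR", "SLM")
  meta <- make_meta(sprintf("%s_r%d", rep(comps, each = n_rep), rep(1:n_rep, 4)),
                    rep(comps, each = n_rep), rep(1:n_rep, 4))
  base <- stats::rnorm(n_feat, 20, 2)
  v <- matrix(stats::rnorm(n_feat * nrow(meta), 0, noise), n_feat) + base
  if (n_eff > 0) {
    v[seq_len(n_eff), meta$compartment == "SLM"] <-
      v[seq_len(n_eff), meta$compartment == "SLM"] + effect
  }
  dimnames(v) <- list(sprintf("p%03d", seq_len(n_feat)), meta$sample_id)
  omics_matrix(v, "protein_log2", meta)
}

# independent rank-based Kruskal-Wallis H (tie-corrected), used as an
# oracle against the package implementation
manual_kw_H <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  rk <- rank(values)
  num <- 12 / (N * (N + 1)) *
    sum(tapply(rk, groups, function(r) length(r) * (mean(r) - (N + 1) / 2)^2))
  ties <- table(values)
  num / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# independent Dunn z for one pair, tie-corrected
manual_dunn_z <- function(values, groups, a, b) {
  groups <- factor(groups)
  N <- length(values)
  rk <- rank(values)
  rbar <- tapply(rk, groups, mean)
  ties <- table(values)
  varc <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  ni <- sum(groups == a); nj <- sum(groups == b)
  (rbar[[a]] - rbar[[b]]) / sqrt(varc * (1 / ni + 1 / nj))
}

# independent BH implementation from the step-up definition
manual_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# brute-force hypergeometric upper tail by enumerating all query draws
brute_force_ora_p <- function(N, K, n, x_obs) {
  universe <- seq_len(N)
  in_set <- universe <= K
  draws <- utils::combn(universe, n)
  mean(colSums(matrix(in_set[draws], nrow = n)) >= x_obs)
}

# separable strata-like classification data with planted features
sep_strata_data <- function(n_rep = 7, n_feat = 40, n_planted = 8,
                            effect = 2, noise = 0.3, seed = 9) {
  set.seed(seed)
  labs <- rep(c("SO", "SP", "SR", "SLM"), each = n_rep)
  X <- matrix(stats::rnorm(4 * n_rep * n_feat, 0, noise), 4 * n_rep)
  colnames(X) <- paste0("f", seq_len(n_feat))
  for (i in seq_len(n_planted)) {
    X[, i] <- X[, i] + effect * (as.integer(factor(labs)) == (i %% 4) + 1)
  }
  list(X = X, labels = labs, planted = paste0("f", seq_len(n_planted)))
}
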