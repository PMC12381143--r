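#' Valid-value filtering for a contrast
#'
#' Retains features with at least `min_quant` non-missing values in each
#' group of the contrast (the "filter by contrast" convention of DIA
#' proteomics pipelines); with `by_contrast = FALSE` the requirement is
#' `min_quant` non-missing values across all samples pooled.
#'
#' @param mat An [omics_matrix()].
#' @param groups Named character/factor vector assigning each sample of
#'   the contrast to a group; samples not named are ignored.
#' @param min_quant Minimum non-missing values required.
#' @param by_contrast Require the minimum in each group (`TRUE`) or
#'   overall (`FALSE`).
#' @return The filtered [omics_matrix()] restricted to the contrast's
#'   samples.
#' @export
filter_valid_values <- function(mat, groups, min_quant = 1L, by_contrast = TRUE) {
  stopifnot(inherits(mat, "omics_matrix"))
  groups <- groups[!is.na(groups)]
  samples <- names(groups)
  if (is.null(samples) || !all(samples %in% colnames(mat$values))) {
    stop("`groups` must be named by sample ids present in the matrix", call. = FALSE)
  }
  g <- factor(as.character(groups))
  if (any(table(g) == 0) || nlevels(g) < 1) stop("empty group in contrast", call. = FALSE)
  v <- mat$values[, samples, drop = FALSE]
  if (by_contrast) {
    keep <- Reduce(`&`, lapply(levels(g), function(l) {
      rowSums(!is.na(v[, g == l, drop = FALSE])) >= min_quant
    }))
  } else {
    keep <- rowSums(!is.na(v)) >= min_quant
  }
  subset_omics(mat, features = rownames(v)[keep], samples = samples)
}

# ---- negative binomial Wald test ------------------------------------------

# Gene-wise method-of-moments dispersion on normalized counts, a robust
# a1/mu + a0 trend across genes, and a geometric-mean shrink of the two
# (trend-only when the gene-wise estimate sits at the 1e-8 floor).
# The gene-wise moment estimate uses residual variance around the fitted
# design (so planted group effects do not masquerade as dispersion) and
# subtracts the size-factor-scaled Poisson term mean(1/s) * mu.
estimate_dispersions <- function(k, sf, X = NULL, floor = 1e-8) {
  q <- sweep(k, 2, sf, `/`)
  mu <- rowMeans(q)
  if (is.null(X)) {
    v <- apply(q, 1, stats::var)
  } else {
    qrX <- qr(X)
    resid <- t(qr.resid(qrX, t(q)))
    dfres <- max(ncol(q) - qrX$rank, 1L)
    v <- rowSums(resid^2) / dfres
  }
  xim <- mean(1 / sf)
  alpha_gene <- pmax((v - xim * mu) / mu^2, floor)
  alpha_gene[!is.finite(alpha_gene) | mu <= 0] <- floor
  # the geometric-mean combination below averages log(alpha); correct the
  # downward log-scale bias of the chi-square variance estimate,
  # E[log v] - log E[v] = digamma(d/2) - log(d/2)
  dfres_c <- if (is.null(X)) ncol(q) - 1L else max(ncol(q) - qr(X)$rank, 1L)
  log_bias <- log(dfres_c / 2) - digamma(dfres_c / 2)
  fit_ok <- mu > 0 & alpha_gene > floor
  if (sum(fit_ok) >= 10) {
    tf <- tryCatch(
      MASS::rlm(alpha_gene[fit_ok] ~ I(1 / mu[fit_ok]), maxit = 50),
      error = function(e) NULL
    )
    if (!is.null(tf)) {
      a0 <- max(stats::coef(tf)[1], floor)
      a1 <- max(stats::coef(tf)[2], 0)
    } else {
      a0 <- stats::median(alpha_gene[fit_ok]); a1 <- 0
    }
  } else {
    a0 <- max(stats::median(alpha_gene), floor); a1 <- 0
  }
  alpha_trend <- pmax(a1 / pmax(mu, 1e-8) + a0, floor)
  alpha <- exp((log(alpha_gene) + log_bias + log(alpha_trend)) / 2)
  alpha[alpha_gene <= floor] <- alpha_trend[alpha_gene <= floor]
  list(alpha = alpha, alpha_gene = alpha_gene, alpha_trend = alpha_trend,
       base_mean = mu, trend_coef = c(a0 = a0, a1 = a1))
}

# IRLS fit of a negative-binomial GLM with log link, known dispersion
# alpha and offset log(sf). Returns the coefficient vector and its
# covariance (X'WX)^{-1}.
nb_irls <- function(y, X, offset, alpha, maxit = 100L, tol = 1e-8) {
  mu <- pmax(y, 0.5)
  beta <- rep(0, ncol(X))
  eta <- log(mu)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- mu / (1 + alpha * mu)
    z <- eta - offset + (y - mu) / mu
    xtwx <- crossprod(X, w * X)
    fit <- tryCatch(solve(xtwx, crossprod(X, w * z)), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    delta <- max(abs(fit - beta))
    beta <- drop(fit)
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    if (delta < tol) { converged <- TRUE; break }
  }
  w <- mu / (1 + alpha * mu)
  cov <- tryCatch(solve(crossprod(X, w * X)), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  list(beta = beta, cov = cov, converged = converged, iter = it)
}

#' Negative-binomial Wald differential enrichment test for counts
#'
#' Per gene: method-of-moments dispersion on size-factor-normalized
#' counts, a robust `a1/mu + a0` dispersion trend across genes, a
#' geometric-mean shrink of gene-wise and trend values, then a
#' negative-binomial GLM (log link, offset `log(s_j)`) with a two-level
#' group factor and an additive replicate blocking factor, fit by IRLS.
#' The Wald statistic `z = beta/SE` for the group coefficient is referred
#' to a standard normal (two-sided) and BH-adjusted across tested genes.
#'
#' @param counts An [omics_matrix()] of kind `rna_counts` (all samples of
#'   the contrast).
#' @param group Factor (or named vector over the samples) with exactly two
#'   levels; the reported log2 fold change is level 2 relative to level 1.
#' @param size_factors Optional named size factors; computed by
#'   [median_ratio_size_factors()] when `NULL`.
#' @param contrast_label Label stored in the result's `contrast` column.
#' @param use_replicate Include the replicate blocking factor (default
#'   TRUE when >1 replicate level is present).
#' @return A `DEResult` data frame: `feature`, `contrast`, `base_mean`,
#'   `log2fc`, `se`, `stat`, `pvalue`, `padj`, `dispersion`, `untestable`.
#' @export
nb_wald_de <- function(counts, group, size_factors = NULL,
                       contrast_label = NULL, use_replicate = TRUE) {
  stopifnot(inherits(counts, "omics_matrix"))
  if (counts$kind != "rna_counts") stop("nb_wald_de expects counts", call. = FALSE)
  k <- counts$values
  if (!is.null(names(group))) group <- group[colnames(k)]
  group <- droplevels(factor(group))
  if (nlevels(group) != 2L) stop("group must have exactly two levels", call. = FALSE)
  if (any(table(group) < 2L)) stop("need >= 2 samples per group", call. = FALSE)
  if (is.null(size_factors)) {
    size_factors <- median_ratio_size_factors(counts)$size_factors
  }
  sf <- size_factors[colnames(k)]
  if (anyNA(sf)) stop("size factors missing for some samples", call. = FALSE)
  repf <- factor(counts$meta$replicate)
  X <- if (use_replicate && nlevels(repf) > 1L) {
    stats::model.matrix(~ group + repf)
  } else {
    stats::model.matrix(~ group)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  disp <- estimate_dispersions(k, sf, X)
  gi <- match("group", substr(colnames(X), 1, 5))
  offset <- log(sf)
  n <- nrow(k)
  log2fc <- se <- stat <- pvalue <- rep(NA_real_, n)
  untestable <- rep(FALSE, n)
  ln2 <- log(2)
  for (g in seq_len(n)) {
    y <- k[g, ]
    if (all(y == 0)) { untestable[g] <- TRUE; next }
    fit <- nb_irls(y, X, offset, disp$alpha[g])
    if (is.null(fit) || !fit$converged) { untestable[g] <- TRUE; next }
    b <- fit$beta[gi]
    s <- sqrt(fit$cov[gi, gi])
    if (!is.finite(s) || s <= 0) { untestable[g] <- TRUE; next }
    log2fc[g] <- b / ln2
    se[g] <- s / ln2
    stat[g] <- b / s
    pvalue[g] <- 2 * stats::pnorm(-abs(stat[g]))
  }
  padj <- rep(NA_real_, n)
  padj[!untestable] <- bh_adjust(pvalue[!untestable])
  if (is.null(contrast_label)) {
    contrast_label <- paste0(levels(group)[2], "_vs_", levels(group)[1])
  }
  data.frame(feature = rownames(k), contrast = contrast_label,
             base_mean = disp$base_mean, log2fc = log2fc, se = se,
             stat = stat, pvalue = pvalue, padj = padj,
             dispersion = disp$alpha, untestable = untestable,
             stringsAsFactors = FALSE, row.names = NULL)
}

# ---- empirical-Bayes moderated linear model -------------------------------

# Solve trigamma(x) = y by Newton iteration (y > 0).
trigamma_inverse <- function(y, maxit = 75L, tol = 1e-10) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(maxit)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < tol) break
  }
  x
}

# Moment-matched scaled inverse-chi-square prior for residual variances:
# match mean and variance of log(s^2) via digamma/trigamma identities.
fit_variance_prior <- function(s2, df) {
  ok <- df > 0 & is.finite(s2) & s2 > 0
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2L) stop("fewer than 2 proteins with positive residual df", call. = FALSE)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- exp(emean)
  }
  list(d0 = d0, s0sq = s0sq)
}

#' Empirical-Bayes moderated linear-model test for log2 intensities
#'
#' Per protein: ordinary least squares on the available (non-missing)
#' values with group and replicate factors; residual variances are
#' shrunk toward a scaled inverse-chi-square prior whose parameters
#' `(d0, s0^2)` are estimated by matching the first two moments of
#' `log s^2` (digamma/trigamma inversion). The moderated t statistic for
#' the group coefficient has `d0 + d_g` degrees of freedom; p-values are
#' two-sided and BH-adjusted.
#'
#' @param logmat An [omics_matrix()] of log2 intensities, valid-value
#'   filtered for the contrast (see [filter_valid_values()]).
#' @inheritParams nb_wald_de
#' @return A `DEResult` data frame with columns `feature`, `contrast`,
#'   `base_mean`, `log2fc`, `se`, `stat`, `pvalue`, `padj`, `df`,
#'   `prior_df`, `prior_var`, `untestable`.
#' @export
moderated_lm_de <- function(logmat, group, contrast_label = NULL,
                            use_replicate = TRUE) {
  stopifnot(inherits(logmat, "omics_matrix"))
  if (!logmat$kind %in% c("protein_log2", "protein_ibaq")) {
    stop("moderated_lm_de expects log-scale intensities", call. = FALSE)
  }
  x <- logmat$values
  if (!is.null(names(group))) group <- group[colnames(x)]
  group <- droplevels(factor(group))
  if (nlevels(group) != 2L) stop("group must have exactly two levels", call. = FALSE)
  repf <- factor(logmat$meta$replicate)
  X <- if (use_replicate && nlevels(repf) > 1L) {
    stats::model.matrix(~ group + repf)
  } else {
    stats::model.matrix(~ group)
  }
  gi <- 2L  # group coefficient
  n <- nrow(x)
  beta <- s2 <- vc <- rep(NA_real_, n)
  df <- rep(0, n)
  untestable <- rep(FALSE, n)
  for (g in seq_len(n)) {
    obs <- !is.na(x[g, ])
    if (length(unique(group[obs])) < 2L) { untestable[g] <- TRUE; next }
    Xg <- X[obs, , drop = FALSE]
    keep <- qr(Xg)$rank
    fit <- stats::lm.fit(Xg, x[g, obs])
    cf <- fit$coefficients
    if (is.na(cf[gi])) { untestable[g] <- TRUE; next }
    used <- !is.na(cf)
    Xu <- Xg[, used, drop = FALSE]
    xtxi <- tryCatch(chol2inv(chol(crossprod(Xu))), error = function(e) NULL)
    if (is.null(xtxi)) { untestable[g] <- TRUE; next }
    gi_u <- sum(used[seq_len(gi)])
    beta[g] <- cf[gi]
    df[g] <- sum(obs) - sum(used)
    rss <- sum(fit$residuals^2)
    s2[g] <- if (df[g] > 0) rss / df[g] else NA_real_
    vc[g] <- xtxi[gi_u, gi_u]
  }
  tested <- !untestable
  prior <- fit_variance_prior(s2[tested], df[tested])
  d0 <- prior$d0; s0sq <- prior$s0sq
  s2_use <- s2
  zero_df <- tested & df == 0
  if (any(zero_df)) {
    warning(sum(zero_df), " protein(s) with zero residual df use the prior variance only")
    s2_use[zero_df] <- 0
  }
  s2_mod <- if (is.finite(d0)) (d0 * s0sq + df * ifelse(is.na(s2_use), 0, s2_use)) / (d0 + df)
            else rep(s0sq, n)
  stat <- beta / sqrt(s2_mod * vc)
  dft <- d0 + df
  pvalue <- 2 * stats::pt(-abs(stat), df = pmin(dft, 1e12))
  pvalue[untestable] <- NA_real_
  stat[untestable] <- NA_real_
  padj <- rep(NA_real_, n)
  padj[tested] <- bh_adjust(pvalue[tested])
  if (is.null(contrast_label)) {
    contrast_label <- paste0(levels(group)[2], "_vs_", levels(group)[1])
  }
  data.frame(feature = rownames(x), contrast = contrast_label,
             base_mean = rowMeans(x, na.rm = TRUE), log2fc = beta,
             se = sqrt(s2_mod * vc), stat = stat, pvalue = pvalue, padj = padj,
             df = df, prior_df = d0, prior_var = s0sq,
             untestable = untestable, stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment with input validation
#'
#' Thin validating wrapper over `stats::p.adjust(method = "BH")`;
#' `NA` entries propagate unchanged.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Vector of BH-adjusted q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

# ---- contrast schemes and enrichment calls --------------------------------

#' Run all compartment contrasts of a scheme
#'
#' `one_vs_rest` compares each compartment against the pooled remaining
#' compartments; `pairwise` compares every unordered compartment pair.
#' Counts are tested with [nb_wald_de()] (shared size factors across
#' contrasts); intensities are valid-value filtered per contrast and
#' tested with [moderated_lm_de()].
#'
#' @param mat An [omics_matrix()].
#' @param scheme `"one_vs_rest"` or `"pairwise"`.
#' @param min_quant Valid-value threshold per group (intensities only).
#' @return Named list of `DEResult` data frames; `one_vs_rest` names are
#'   compartments, `pairwise` names are `A_vs_B` labels.
#' @export
de_compartments <- function(mat, scheme = c("one_vs_rest", "pairwise"),
                            min_quant = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(mat, "omics_matrix"))
  comps <- unique(mat$meta$compartment)
  if (length(comps) < 2L) stop("need >= 2 compartments", call. = FALSE)
  is_counts <- mat$kind == "rna_counts"
  sf <- if (is_counts) median_ratio_size_factors(mat)$size_factors else NULL
  out <- list()
  if (scheme == "one_vs_rest") {
    for (cc in comps) {
      grp <- factor(ifelse(mat$meta$compartment == cc, cc, "rest"),
                    levels = c("rest", cc))
      names(grp) <- mat$meta$sample_id
      lab <- paste0(cc, "_vs_rest")
      if (is_counts) {
        out[[cc]] <- nb_wald_de(mat, grp, size_factors = sf, contrast_label = lab)
      } else {
        sub <- filter_valid_values(mat, grp, min_quant = min_quant)
        out[[cc]] <- moderated_lm_de(sub, grp, contrast_label = lab)
      }
    }
  } else {
    prs <- utils::combn(comps, 2, simplify = FALSE)
    for (pr in prs) {
      sel <- mat$meta$compartment %in% pr
      ids <- mat$meta$sample_id[sel]
      sub <- subset_omics(mat, samples = ids)
      grp <- factor(sub$meta$compartment, levels = c(pr[2], pr[1]))
      names(grp) <- sub$meta$sample_id
      lab <- paste0(pr[1], "_vs_", pr[2])
      if (is_counts) {
        out[[lab]] <- nb_wald_de(sub, grp, size_factors = sf[ids], contrast_label = lab)
      } else {
        subf <- filter_valid_values(sub, grp, min_quant = min_quant)
        out[[lab]] <- moderated_lm_de(subf, grp, contrast_label = lab)
      }
    }
  }
  attr(out, "scheme") <- scheme
  attr(out, "compartments") <- comps
  out
}

#' Call significant compartment enrichment from DE results
#'
#' `one_vs_rest`: a feature is enriched in a compartment when its single
#' contrast has `q < alpha` and `log2fc >= lfc_min` (depleted with
#' `log2fc <= -lfc_min`). `pairwise_intersection`: enrichment requires
#' `q < alpha` and `log2fc >= lfc_min` against every other compartment.
#'
#' @param de_list A list from [de_compartments()] (or equivalently
#'   structured).
#' @param scheme `"one_vs_rest"` or `"pairwise_intersection"`.
#' @param molecule `"mrna"` or `"protein"`, recorded in the calls.
#' @param lfc_min Minimum absolute log2 fold change (default 0.1).
#' @param alpha Adjusted-p significance threshold (0.01 tissue
#'   convention; 0.05 for synaptosome comparisons).
#' @return `EnrichmentCall` data frame: `feature`, `molecule`,
#'   `compartment`, `direction`, `contrasts`.
#' @export
call_enrichment <- function(de_list, scheme = c("one_vs_rest", "pairwise_intersection"),
                            molecule = c("mrna", "protein"),
                            lfc_min = 0.1, alpha = 0.01) {
  scheme <- match.arg(scheme)
  molecule <- match.arg(molecule)
  calls <- list()
  add_call <- function(features, compartment, direction, contrasts) {
    if (!length(features)) return()
    calls[[length(calls) + 1L]] <<- data.frame(
      feature = features, molecule = molecule, compartment = compartment,
      direction = direction, contrasts = paste(contrasts, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (scheme == "one_vs_rest") {
    for (cc in names(de_list)) {
      de <- de_list[[cc]]
      sig <- !is.na(de$padj) & de$padj < alpha
      add_call(de$feature[sig & de$log2fc >= lfc_min], cc, "enriched", de$contrast[1])
      add_call(de$feature[sig & de$log2fc <= -lfc_min], cc, "depleted", de$contrast[1])
    }
  } else {
    labs <- names(de_list)
    prs <- strsplit(labs, "_vs_", fixed = TRUE)
    comps <- unique(unlist(prs))
    if (length(comps) < 2L) stop("pairwise scheme needs >= 2 compartments", call. = FALSE)
    for (cc in comps) {
      others <- setdiff(comps, cc)
      per_dir <- list(enriched = NULL, depleted = NULL)
      used <- character(0)
      ok <- TRUE
      for (oo in others) {
        i <- match(paste0(cc, "_vs_", oo), labs)
        flip <- FALSE
        if (is.na(i)) { i <- match(paste0(oo, "_vs_", cc), labs); flip <- TRUE }
        if (is.na(i)) { ok <- FALSE; break }
        de <- de_list[[i]]
        lfc <- if (flip) -de$log2fc else de$log2fc
        sig <- !is.na(de$padj) & de$padj < alpha
        enr <- de$feature[sig & lfc >= lfc_min]
        dep <- de$feature[sig & lfc <= -lfc_min]
        per_dir$enriched <- if (is.null(per_dir$enriched)) enr else intersect(per_dir$enriched, enr)
        per_dir$depleted <- if (is.null(per_dir$depleted)) dep else intersect(per_dir$depleted, dep)
        used <- c(used, de$contrast[1])
      }
      if (!ok) stop("missing contrast for compartment ", cc, call. = FALSE)
      add_call(per_dir$enriched, cc, "enriched", used)
      add_call(per_dir$depleted, cc, "depleted", used)
    }
  }
  if (!length(calls)) {
    return(data.frame(feature = character(0), molecule = character(0),
                      compartment = character(0), direction = character(0),
                      contrasts = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
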