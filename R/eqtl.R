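# Additive-model cis-eQTL scan: cis pairing, per-pair ordinary least
# squares with sex/population covariates, joint BH-FDR, and the
# genotype-randomization significance check.
#
# The per-pair fit is computed by residualizing expression and dosage
# against the covariate design (Frisch-Waugh), which is algebraically
# identical to the full OLS fit of y on [intercept, dosage, covariates];
# standard errors use the full-model residual degrees of freedom. Pairs
# with missing dosages fall back to a direct QR fit on the complete
# samples.

#' Build cis (variant, gene) pairs
#'
#' A pair is included iff variant and gene are on the same chromosome and
#' the minimum distance between the variant locus and the gene interval is
#' strictly below `max_distance` (variants inside a gene get distance 0).
#' Deletion-coded variants use their full interval, point insertions a 1-bp
#' locus.
#'
#' @param tevs Variant tibble.
#' @param genes Gene tibble.
#' @param max_distance Cis window in bp (default 1 Mbp).
#' @return Tibble `variant_id`, `gene_id`, `distance`.
#' @export
build_cis_pairs <- function(tevs, genes, max_distance = 1e6) {
  if (nrow(tevs) == 0 || nrow(genes) == 0) {
    return(tibble::tibble(variant_id = character(0), gene_id = character(0),
                          distance = numeric(0)))
  }
  loci <- tev_loci(tevs)
  gr_v <- as_granges0(loci)
  gr_g <- as_granges0(genes)
  hits <- GenomicRanges::findOverlaps(gr_v, gr_g, maxgap = max_distance - 1)
  if (length(hits) == 0) {
    return(tibble::tibble(variant_id = character(0), gene_id = character(0),
                          distance = numeric(0)))
  }
  d <- GenomicRanges::distance(gr_v[S4Vectors::queryHits(hits)],
                               gr_g[S4Vectors::subjectHits(hits)])
  out <- tibble::tibble(
    variant_id = loci$variant_id[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    distance = as.numeric(d)
  )
  dplyr::distinct(out[out$distance < max_distance, , drop = FALSE])
}

# Covariate design matrix: intercept, male indicator (if both sexes
# present), K-1 population indicators (if >= 2 populations).
covariate_design <- function(samples) {
  n <- nrow(samples)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(samples$sex) && dplyr::n_distinct(samples$sex) > 1) {
    X <- cbind(X, sex_male = as.numeric(samples$sex == "male"))
  }
  if (!is.null(samples$population) && dplyr::n_distinct(samples$population) > 1) {
    pop <- factor(samples$population)
    P <- stats::model.matrix(~pop)[, -1, drop = FALSE]
    X <- cbind(X, P)
  }
  X
}

#' Fit the additive model for one (expression, dosage) pair
#'
#' Ordinary least squares of `y` on `[intercept, g, sex dummy, population
#' dummies]`; `t = beta / SE(beta)` with p from the t distribution on
#' `n_used - #coefficients` degrees of freedom. Samples with missing dosage
#' or expression are dropped. A dosage that is constant after removal skips
#' the pair with reason `"monomorphic"`; a rank-deficient design skips with
#' `"collinear"`. A zero-residual fit reports `p = 0` with `perfect_fit =
#' TRUE`.
#'
#' @param y Numeric expression vector.
#' @param g Numeric dosage vector (0/1/2, `NA` = missing).
#' @param covariates Optional data frame with `sex` and/or `population`
#'   columns, same length as `y`.
#' @return One-row tibble: `n_used`, `beta`, `se`, `statistic`, `p_value`,
#'   `df`, `perfect_fit`, `skipped`, `skip_reason`.
#' @export
fit_additive_model <- function(y, g, covariates = NULL) {
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]
  g <- g[keep]
  C <- if (is.null(covariates)) {
    matrix(1, length(y), 1)
  } else {
    covariate_design(covariates[keep, , drop = FALSE])
  }
  fit <- ols_pair(y, g, C)
  tibble::as_tibble(fit)
}

# Full OLS of y on cbind(C, g); returns the g coefficient's stats.
ols_pair <- function(y, g, C) {
  skip <- function(reason) {
    list(n_used = length(y), beta = NA_real_, se = NA_real_,
         statistic = NA_real_, p_value = NA_real_, df = NA_real_,
         perfect_fit = FALSE, skipped = TRUE, skip_reason = reason)
  }
  n <- length(y)
  if (length(unique(g)) < 2) return(skip("monomorphic"))
  X <- cbind(C, g = g)
  p <- ncol(X)
  if (n <= p + 1) return(skip("insufficient_samples"))
  qx <- qr(X)
  if (qx$rank < p) return(skip("collinear"))
  res <- qr.resid(qx, y)
  beta_all <- qr.coef(qx, y)
  rss <- sum(res^2)
  df <- n - p
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  piv <- qx$pivot
  var_unscaled <- numeric(p)
  var_unscaled[piv] <- diag(xtx_inv)
  beta <- unname(beta_all[p])
  tss <- sum(y^2)
  perfect <- rss <= 1e-12 * max(tss, 1)
  se <- sqrt(rss / df * var_unscaled[p])
  if (perfect) {
    statistic <- sign(beta) * Inf
    p_value <- 0
  } else {
    statistic <- beta / se
    p_value <- 2 * stats::pt(-abs(statistic), df)
  }
  list(n_used = n, beta = beta, se = se, statistic = statistic,
       p_value = p_value, df = df, perfect_fit = perfect,
       skipped = FALSE, skip_reason = NA_character_)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH over one family of p-values, returned in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    rlang::abort("All p-values must lie in [0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

# Vectorized scan core shared by run_scan() and permutation_validation().
# RY: genes x n covariate-residualized expression; qrC: QR of covariate
# design; G: variants x n dosage matrix; groups: list mapping variant row
# -> integer indices into `pairs`. Returns p-values (NA where skipped) and
# per-pair stats when `full = TRUE`.
scan_core <- function(Y, RY, qrC, G, pairs, gene_rows, groups, full = FALSE) {
  n <- ncol(G)
  p_cov <- qrC$rank
  df_full <- n - p_cov - 1
  m <- nrow(pairs)
  p_value <- rep(NA_real_, m)
  skip_reason <- rep(NA_character_, m)
  beta <- se <- statistic <- rep(NA_real_, m)
  n_used <- rep(n, m)
  perfect <- rep(FALSE, m)
  ry_ss <- rowSums(RY^2)
  for (v in names(groups)) {
    idx <- groups[[v]]
    g <- G[v, ]
    gi <- gene_rows[idx]
    miss <- is.na(g)
    if (!any(miss)) {
      gu <- unique(g)
      if (length(gu) < 2) { skip_reason[idx] <- "monomorphic"; next }
      rg <- qr.resid(qrC, g)
      sgg <- sum(rg^2)
      if (sgg < 1e-10 * n) { skip_reason[idx] <- "collinear"; next }
      b <- as.vector(RY[gi, , drop = FALSE] %*% rg) / sgg
      rss <- pmax(ry_ss[gi] - b^2 * sgg, 0)
      pf <- rss <= 1e-12 * pmax(ry_ss[gi], 1)
      s <- sqrt(rss / df_full / sgg)
      t <- b / s
      pv <- 2 * stats::pt(-abs(t), df_full)
      t[pf] <- sign(b[pf]) * Inf
      pv[pf] <- 0
      beta[idx] <- b; se[idx] <- s; statistic[idx] <- t
      p_value[idx] <- pv; perfect[idx] <- pf
    } else {
      keep <- !miss
      for (j in seq_along(idx)) {
        y <- Y[gi[j], keep]
        fit <- ols_pair(y, g[keep], covariate_design_cache(qrC, keep))
        n_used[idx[j]] <- fit$n_used
        beta[idx[j]] <- fit$beta; se[idx[j]] <- fit$se
        statistic[idx[j]] <- fit$statistic; p_value[idx[j]] <- fit$p_value
        perfect[idx[j]] <- fit$perfect_fit
        skip_reason[idx[j]] <- fit$skip_reason
      }
    }
  }
  if (full) {
    list(p_value = p_value, beta = beta, se = se, statistic = statistic,
         n_used = n_used, perfect = perfect, skip_reason = skip_reason)
  } else {
    list(p_value = p_value, skip_reason = skip_reason)
  }
}

# Rebuild the covariate design rows for a complete-sample subset from the
# full QR (the design columns are recoverable as Q %*% R).
covariate_design_cache <- function(qrC, keep) {
  C_full <- qr.X(qrC)
  C_full[keep, , drop = FALSE]
}

#' Run the cis-eQTL scan
#'
#' Fits every cis pair with the additive covariate model, applies BH-FDR
#' jointly across all tested pairs, and flags associations with
#' `q <= fdr_threshold`. Pairs skipped as monomorphic / collinear /
#' underpowered are excluded from the BH family and reported in the
#' `skipped` attribute.
#'
#' @param pairs Cis pairs from [build_cis_pairs()].
#' @param expression Expression tibble (aligned; see [align_samples()]).
#' @param tevs Variant tibble (aligned).
#' @param samples Sample metadata tibble (aligned).
#' @param fdr_threshold Significance threshold on BH q (default 0.05).
#' @param log2_transform Fit on `log2(x + 1)`-transformed expression.
#' @return A `tev_scan` tibble: one row per tested pair with `variant_id`,
#'   `gene_id`, `distance`, `n_used`, `beta`, `se`, `statistic`, `p_value`,
#'   `q_value`, `significant`, `perfect_fit`. Attributes: `skipped`
#'   (tibble of skipped pairs with reasons), `fdr_threshold`, `n_samples`.
#' @export
run_scan <- function(pairs, expression, tevs, samples, fdr_threshold = 0.05,
                     log2_transform = FALSE) {
  ctx <- scan_context(pairs, expression, tevs, samples, log2_transform)
  if (nrow(ctx$pairs) == 0) {
    rlang::warn("No testable cis pairs.")
    out <- tibble::tibble(variant_id = character(0), gene_id = character(0),
                          distance = numeric(0), n_used = integer(0),
                          beta = numeric(0), se = numeric(0),
                          statistic = numeric(0), p_value = numeric(0),
                          q_value = numeric(0), significant = logical(0),
                          perfect_fit = logical(0))
    return(new_tev_scan(out, ctx$pairs[0, ], fdr_threshold, 0L))
  }
  res <- scan_core(ctx$Y, ctx$RY, ctx$qrC, ctx$G, ctx$pairs, ctx$gene_rows,
                   ctx$groups, full = TRUE)
  tested <- is.na(res$skip_reason)
  out <- ctx$pairs
  out$n_used <- res$n_used
  out$beta <- res$beta
  out$se <- res$se
  out$statistic <- res$statistic
  out$p_value <- res$p_value
  out$perfect_fit <- res$perfect
  skipped <- out[!tested, c("variant_id", "gene_id", "distance")]
  skipped$reason <- res$skip_reason[!tested]
  out <- out[tested, , drop = FALSE]
  out$q_value <- if (nrow(out) > 0) bh_adjust(out$p_value) else numeric(0)
  out$significant <- out$q_value <= fdr_threshold
  out <- out[, c("variant_id", "gene_id", "distance", "n_used", "beta", "se",
                 "statistic", "p_value", "q_value", "significant", "perfect_fit")]
  new_tev_scan(out, skipped, fdr_threshold, ncol(ctx$G))
}

new_tev_scan <- function(out, skipped, fdr_threshold, n_samples) {
  out <- tibble::as_tibble(out)
  attr(out, "skipped") <- tibble::as_tibble(skipped)
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "n_samples") <- n_samples
  class(out) <- c("tev_scan", class(out))
  out
}

# Precompute the aligned matrices, covariate QR and pair grouping.
scan_context <- function(pairs, expression, tevs, samples, log2_transform = FALSE) {
  common <- samples$sample_id[samples$sample_id %in% names(expression)]
  tev_samples <- if (nrow(tevs) > 0) names(tevs$dosages[[1]]) else character(0)
  common <- common[common %in% tev_samples]
  if (length(common) == 0 && nrow(pairs) > 0) {
    rlang::abort("No samples shared between expression, genotypes and metadata.")
  }
  samples <- samples[match(common, samples$sample_id), , drop = FALSE]
  pairs <- pairs[pairs$variant_id %in% tevs$variant_id &
                   pairs$gene_id %in% expression$gene_id, , drop = FALSE]
  Y <- as.matrix(expression[, common, drop = FALSE])
  rownames(Y) <- expression$gene_id
  if (log2_transform) Y <- log2(Y + 1)
  G <- dosage_matrix(tevs, common)
  C <- covariate_design(samples)
  qrC <- qr(C)
  RY <- t(qr.resid(qrC, t(Y)))
  gene_rows <- match(pairs$gene_id, rownames(Y))
  groups <- split(seq_len(nrow(pairs)), pairs$variant_id)
  list(pairs = pairs, Y = Y, RY = RY, qrC = qrC, G = G,
       gene_rows = gene_rows, groups = groups, samples = samples)
}

#' Genotype-randomization validation of the scan
#'
#' Re-runs the full scan `R` times with each variant's dosage vector
#' independently permuted across samples (expression and covariates
#' untouched) and compares the observed number of significant associations
#' with the randomized counts: `z = (observed - mean) / sd` (sample sd) and
#' `empirical p = (1 + #replicates >= observed) / (1 + R)`.
#'
#' @inheritParams run_scan
#' @param R Number of randomizations (default 100).
#' @param seed Seed for the permutations.
#' @return A `tev_perm` list: `observed`, `replicates`, `mean`, `sd`, `z`,
#'   `empirical_p`, `R`, `degenerate_sd` flag.
#' @export
permutation_validation <- function(pairs, expression, tevs, samples, R = 100,
                                   fdr_threshold = 0.05, seed = 1,
                                   log2_transform = FALSE) {
  if (R < 2) rlang::abort("`R` must be at least 2.")
  ctx <- scan_context(pairs, expression, tevs, samples, log2_transform)
  observed_scan <- run_scan(pairs, expression, tevs, samples, fdr_threshold,
                            log2_transform)
  observed <- sum(observed_scan$significant)
  n <- ncol(ctx$G)
  count_significant <- function(G) {
    res <- scan_core(ctx$Y, ctx$RY, ctx$qrC, G, ctx$pairs, ctx$gene_rows,
                     ctx$groups, full = FALSE)
    pv <- res$p_value[is.na(res$skip_reason)]
    if (length(pv) == 0) return(0L)
    sum(bh_adjust(pv) <= fdr_threshold)
  }
  replicates <- withr::with_seed(derive_seed(seed, 8L), {
    vapply(seq_len(R), function(r) {
      Gp <- ctx$G
      for (i in seq_len(nrow(Gp))) Gp[i, ] <- Gp[i, sample.int(n)]
      count_significant(Gp)
    }, integer(1))
  })
  m <- mean(replicates)
  s <- stats::sd(replicates)
  out <- list(
    observed = observed,
    replicates = replicates,
    mean = m,
    sd = s,
    z = safe_z(observed, m, s),
    empirical_p = empirical_p(observed, replicates),
    R = R,
    degenerate_sd = s == 0
  )
  class(out) <- "tev_perm"
  out
}

#' @export
print.tev_scan <- function(x, ...) {
  cat(sprintf("cis-eQTL scan: %d tested pairs, %d significant (q <= %g), %d skipped\n",
              nrow(x), sum(x$significant), attr(x, "fdr_threshold"),
              nrow(attr(x, "skipped"))))
  NextMethod()
}

#' @export
print.tev_perm <- function(x, ...) {
  cat(sprintf(
    "Genotype-randomization validation: observed %d significant vs null mean %.1f (sd %.2f), z = %.2f, empirical p = %.3g (R = %d)\n",
    x$observed, x$mean, x$sd, x$z, x$empirical_p, x$R))
  invisible(x)
}

#' @rdname run_scan
#' @param x A `tev_scan`.
#' @param ... Unused.
#' @method tidy tev_scan
#' @export
tidy.tev_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "tev_scan")
  attr(out, "skipped") <- NULL
  attr(out, "fdr_threshold") <- NULL
  attr(out, "n_samples") <- NULL
  tibble::as_tibble(out)
}

#' @rdname run_scan
#' @method glance tev_scan
#' @export
glance.tev_scan <- function(x, ...) {
  sk <- attr(x, "skipped")
  tibble::tibble(
    n_tested = nrow(x),
    n_significant = sum(x$significant),
    n_skipped = nrow(sk),
    n_monomorphic = sum(sk$reason == "monomorphic"),
    n_collinear = sum(sk$reason == "collinear"),
    fdr_threshold = attr(x, "fdr_threshold"),
    n_samples = attr(x, "n_samples")
  )
}

#' @rdname permutation_validation
#' @param x A `tev_perm`.
#' @param ... Unused.
#' @method tidy tev_perm
#' @export
tidy.tev_perm <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$replicates),
                 n_significant = x$replicates)
}

#' @rdname permutation_validation
#' @method glance tev_perm
#' @export
glance.tev_perm <- function(x, ...) {
  tibble::tibble(observed = x$observed, null_mean = x$mean, null_sd = x$sd,
                 z = x$z, empirical_p = x$empirical_p, R = x$R,
                 degenerate_sd = x$degenerate_sd)
}
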