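test_that("cis pairing uses interval distance with a strict 1 Mbp bound", {
  tevs <- make_tevs(c("v1", "v2", "v3"), "chr1", c(100000, 1600001, 550000),
                    c("Alu", "Alu", "SVA"),
                    replicate(3, c(S1 = 1L), simplify = FALSE))
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", start = 500000, end = 600000,
    strand = "+", biotype = "protein_coding",
    substructure = list(tibble::tibble(feature = character(0),
                                       start = numeric(0), end = numeric(0))))
  pairs <- build_cis_pairs(tevs, genes)
  expect_equal(pairs$distance[pairs$variant_id == "v1"], 400000)
  # v2 sits exactly 1,000,000 bp beyond the gene end: excluded (strict below)
  expect_false("v2" %in% pairs$variant_id)
  expect_equal(pairs$distance[pairs$variant_id == "v3"], 0)
  # nudge one bp closer and the pair appears at 999,999
  tevs$pos[2] <- 1600000L
  pairs2 <- build_cis_pairs(tevs, genes)
  expect_equal(pairs2$distance[pairs2$variant_id == "v2"], 999999)
})

test_that("deletion-coded variants pair via their full interval", {
  tevs <- make_tevs("d1", "chr1", 100001, "Alu", list(c(S1 = 1L)),
                    deletion_coded = TRUE, length = 5000L)
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", start = 1.1e6, end = 1.2e6,
    strand = "+", biotype = "other", substructure = list(tibble::tibble()))
  # interval end at 105,000 -> distance 995,000; a point locus would be cis too,
  # but at 1,004,999 the interval is cis while the point (distance 999,999+5,000)
  # would not be
  p <- build_cis_pairs(tevs, genes)
  expect_equal(p$distance, 1.1e6 - (1e5 + 5000))
  tevs$pos[1] <- 104001L
  p2 <- build_cis_pairs(tevs, genes)
  expect_equal(p2$distance, 1.1e6 - (104000 + 5000))
})

test_that("the additive fit matches a closed-form normal-equations oracle", {
  set.seed(301)
  for (i in 1:50) {
    n <- sample(15:50, 1)
    covs <- data.frame(sex = sample(c("male", "female"), n, replace = TRUE),
                       population = sample(c("P1", "P2", "P3"), n, replace = TRUE))
    g <- sample(0:2, n, replace = TRUE)
    if (length(unique(g)) < 2) next
    y <- rnorm(n, 5 + 0.5 * g)
    fit <- fit_additive_model(y, g, covs)
    X <- cbind(1, as.numeric(covs$sex == "male"),
               stats::model.matrix(~factor(covs$population))[, -1, drop = FALSE], g)
    if (qr(X)$rank < ncol(X)) next
    oracle <- ols_oracle(y, X)
    expect_equal(fit$beta, oracle$beta, tolerance = 1e-8)
    expect_equal(fit$se, oracle$se, tolerance = 1e-8)
    expect_equal(fit$statistic, oracle$t, tolerance = 1e-8)
    expect_equal(fit$p_value, oracle$p, tolerance = 1e-8)
    expect_equal(fit$df, oracle$df)
  }
})

test_that("degenerate pairs are skipped with reasons; perfect fits flagged", {
  y <- 3 + 2 * c(0, 0, 1, 1, 2, 2, 1, 0)
  fit <- fit_additive_model(y, c(0, 0, 1, 1, 2, 2, 1, 0))
  expect_equal(fit$beta, 2)
  expect_true(fit$perfect_fit)
  expect_equal(fit$p_value, 0)
  mono <- fit_additive_model(rnorm(10), rep(1, 10))
  expect_true(mono$skipped)
  expect_equal(mono$skip_reason, "monomorphic")
  # dosage identical to the sex dummy: collinear design
  covs <- data.frame(sex = rep(c("male", "female"), each = 5),
                     population = rep("P", 10))
  col <- fit_additive_model(rnorm(10), rep(c(1, 0), each = 5), covs)
  expect_true(col$skipped)
  expect_equal(col$skip_reason, "collinear")
  # missing dosages are dropped before fitting
  g <- c(NA, 0, 1, 2, 0, 1, 2, 0, 1, 2)
  fit_na <- fit_additive_model(rnorm(10), g)
  expect_equal(fit_na$n_used, 9)
})

test_that("BH adjustment equals the direct step-up definition", {
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)  # m = 1: q = p
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(99)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_direct(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_equal(order(q[order(p)]), seq_along(p))  # monotone in p order
  }
})

test_that("the scan matches per-pair fits, including with missing dosages", {
  cfg <- small_config(seed = 21, missing_rate = 0.05)
  b <- sim_bundle(cfg)
  tevs_f <- suppressMessages(filter_by_carriers(b$tevs, 3))
  pairs <- build_cis_pairs(tevs_f, b$genes)
  scan <- run_scan(pairs, b$expression, tevs_f, b$cohort)
  expect_true(all(scan$p_value >= 0 & scan$p_value <= 1))
  expect_true(all(scan$q_value >= scan$p_value - 1e-12))
  expect_equal(scan$significant, scan$q_value <= 0.05)
  # spot-check rows (with and without missing dosage) against the direct fit
  G <- dosage_matrix(tevs_f, b$cohort$sample_id)
  has_na <- rowSums(is.na(G)) > 0
  pick <- c(which(scan$variant_id %in% rownames(G)[has_na])[1],
            which(scan$variant_id %in% rownames(G)[!has_na])[1])
  for (i in pick[!is.na(pick)]) {
    y <- as.numeric(b$expression[b$expression$gene_id == scan$gene_id[i], -1])
    fit <- fit_additive_model(y, G[scan$variant_id[i], ],
                              b$cohort[, c("sex", "population")])
    expect_equal(scan$beta[i], fit$beta, tolerance = 1e-8)
    expect_equal(scan$se[i], fit$se, tolerance = 1e-8)
    expect_equal(scan$p_value[i], fit$p_value, tolerance = 1e-8)
  }
})

test_that("jointly permuting the sample order of all inputs leaves results unchanged", {
  cfg <- small_config(seed = 23)
  b <- sim_bundle(cfg)
  tevs_f <- suppressMessages(filter_by_carriers(b$tevs, 3))
  pairs <- build_cis_pairs(tevs_f, b$genes)
  scan1 <- run_scan(pairs, b$expression, tevs_f, b$cohort)
  perm <- sample(nrow(b$cohort))
  cohort2 <- b$cohort[perm, ]
  expr2 <- b$expression[, c("gene_id", cohort2$sample_id)]
  tevs2 <- tevs_f
  tevs2$dosages <- lapply(tevs_f$dosages, function(d) d[cohort2$sample_id])
  scan2 <- run_scan(pairs, expr2, tevs2, cohort2)
  expect_equal(tidy(scan1), tidy(scan2), tolerance = 1e-10)
})

test_that("planted effects are recovered and genotype randomization separates them", {
  cfg <- small_config(seed = 25, n_samples = 100L, n_planted = 5L,
                      planted_beta = 2, noise_sd = 1)
  b <- sim_bundle(cfg)
  tevs_f <- suppressMessages(filter_by_carriers(b$tevs, 3))
  pairs <- build_cis_pairs(tevs_f, b$genes)
  scan <- run_scan(pairs, b$expression, tevs_f, b$cohort)
  hits <- dplyr::inner_join(tidy(scan), b$planted, by = c("variant_id", "gene_id"),
                            suffix = c("", "_true"))
  expect_gte(sum(hits$significant), 4)
  expect_true(all(abs(hits$beta - hits$beta_true) < 3 * hits$se + 1e-9))
  perm <- permutation_validation(pairs, b$expression, tevs_f, b$cohort,
                                 R = 20, seed = 25)
  expect_gt(perm$z, 3)
  expect_equal(length(perm$replicates), 20)
  expect_equal(perm$empirical_p,
               (1 + sum(perm$replicates >= perm$observed)) / 21)
  # glance/tidy accessors agree with the object
  expect_equal(glance(perm)$observed, perm$observed)
  expect_equal(nrow(tidy(perm)), 20)
})

test_that("a single-pair family reduces BH to the raw p-value", {
  cfg <- small_config(seed = 27)
  b <- sim_bundle(cfg)
  tevs_f <- suppressMessages(filter_by_carriers(b$tevs, 3))
  pairs <- build_cis_pairs(tevs_f, b$genes)[1, ]
  scan <- run_scan(pairs, b$expression, tevs_f, b$cohort)
  expect_equal(scan$q_value, scan$p_value)
})
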