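make_gene <- function(gene_id, chrom, start, end, strand = "+",
                      biotype = "protein_coding", substructure = NULL) {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, start = start, end = end,
    strand = strand, biotype = biotype,
    substructure = list(substructure %||% tibble::tibble(
      feature = character(0), start = numeric(0), end = numeric(0))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("orientation concordance classifies by host-gene strand", {
  genes <- dplyr::bind_rows(
    make_gene("gp", "c1", 1e6, 2e6, "+"),
    make_gene("gm", "c1", 3e6, 4e6, "-"),
    make_gene("gm2", "c1", 3.5e6, 4.5e6, "+"))
  tevs <- make_tevs(
    c("a_conc", "a_disc", "a_both", "a_inter", "a_unk", "s_disc"),
    "c1", c(1.5e6, 3.2e6, 3.8e6, 5e6, 1.2e6, 3.1e6),
    c("Alu", "Alu", "Alu", "Alu", "Alu", "SVA"),
    replicate(6, c(S1 = 1L), simplify = FALSE),
    strand = c("+", "+", "-", "+", "unknown", "+"))
  res <- orientation_concordance(tevs, genes)
  alu <- res$by_class[res$by_class$te_class == "Alu", ]
  # a_conc concordant; a_disc discordant; a_both overlaps both strands ->
  # counted once as concordant; a_inter intergenic (excluded); a_unk unoriented
  expect_equal(alu$concordant, 2)
  expect_equal(alu$discordant, 1)
  expect_equal(alu$unoriented, 1)
  expect_equal(alu$n_intragenic, 3)
  sva <- res$by_class[res$by_class$te_class == "SVA", ]
  expect_equal(c(sva$concordant, sva$discordant), c(0, 1))
  expect_equal(nrow(res$tests), 1)
  expect_equal(tidy(res), res$by_class)
})

test_that("two-sided Fisher p-values match direct hypergeometric summation", {
  # identical proportions: p = 1
  even <- class_contribution_test(tibble::tibble(
    te_class = c("Alu", "L1"), total = c(20, 20), significant = c(10, 10)))
  expect_gte(even$p_value, 0.99)
  # the fully separated 5/0 vs 0/5 table
  sep <- orientation_tab <- tibble::tibble(
    te_class = c("A", "B"), total = c(5, 5), significant = c(5, 0))
  expect_equal(class_contribution_test(sep)$p_value, 2 / 252, tolerance = 1e-12)
  # random tables against the oracle
  set.seed(17)
  for (i in 1:100) {
    tab <- matrix(sample(0:30, 4, replace = TRUE), 2)
    expect_equal(stats::fisher.test(tab)$p.value,
                 fisher_oracle(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-10)
  }
  expect_error(class_contribution_test(tibble::tibble(
    te_class = "A", total = 2, significant = 5)), "exceed")
})

test_that("class contribution detects the SVA excess in catalog-scale counts", {
  counts <- tibble::tibble(te_class = c("Alu", "L1", "SVA"),
                           total = c(7208, 935, 406),
                           significant = c(267, 21, 35))
  res <- class_contribution_test(counts)
  sva_alu <- res$p_value[res$class_a == "Alu" & res$class_b == "SVA"]
  sva_l1 <- res$p_value[res$class_a == "L1" & res$class_b == "SVA"]
  expect_lt(sva_alu, 1e-4)
  expect_lt(sva_l1, 1e-4)
})

test_that("context classification applies UTR-over-exon precedence and partitions", {
  sub <- tibble::tibble(
    feature = c("five_prime_utr", "exon", "intron", "exon", "three_prime_utr"),
    start = c(0, 100, 300, 600, 900) + 1e6,
    end = c(100, 300, 600, 900, 1000) + 1e6)
  genes <- make_gene("g1", "c1", 1e6, 1e6 + 1000, "+", substructure = sub)
  tevs <- make_tevs(
    c("in_utr3", "in_utr5", "in_exon", "in_intron", "inter", "span_utr3"),
    "c1", c(1e6 + 950, 1e6 + 50, 1e6 + 200, 1e6 + 400, 5e6, 1e6 + 850),
    rep("Alu", 6), replicate(6, c(S1 = 1L), simplify = FALSE),
    deletion_coded = c(rep(FALSE, 5), TRUE), length = rep(200L, 6))
  ctx <- classify_context(tevs, genes)
  expect_equal(as.character(ctx$context),
               c("three_prime_utr", "five_prime_utr", "exon", "intron",
                 "intergenic", "three_prime_utr"))
  # labels partition the set
  expect_equal(sum(table(ctx$context)), nrow(tevs))
})

test_that("context enrichment flags a planted 3'UTR skew", {
  set.seed(41)
  sub <- tibble::tibble(
    feature = c("exon", "intron", "three_prime_utr"),
    start = c(0, 2e5, 8e5) + 1e6, end = c(2e5, 8e5, 1e6) + 1e6)
  genes <- make_gene("g1", "c1", 1e6, 2e6, "+", substructure = sub)
  mk <- function(n, utr_frac, prefix) {
    in_utr <- runif(n) < utr_frac
    pos <- ifelse(in_utr, 1e6 + 8e5 + floor(runif(n) * 2e5),
                  3e6 + floor(runif(n) * 1e6))
    make_tevs(paste0(prefix, seq_len(n)), "c1", pos, "Alu",
              replicate(n, c(S1 = 1L), simplify = FALSE))
  }
  subset_tevs <- mk(300, 0.30, "s")
  background <- mk(3000, 0.05, "b")
  res <- context_enrichment(subset_tevs, background, genes)
  utr3 <- res[res$context == "three_prime_utr", ]
  expect_gt(utr3$log2_ratio, 0)
  expect_lt(utr3$p_value, 1e-3)
})

test_that("regulatory enrichment calls a constructed spike and flags degenerate cells", {
  sizes <- c(c1 = 1e7)
  reg <- tibble::tibble(chrom = "c1", start = seq(0, 9e6, by = 1e6),
                        end = seq(0, 9e6, by = 1e6) + 1e5)  # 10% of genome
  set.seed(53)
  inside <- sample(seq_len(nrow(reg)), 60, replace = TRUE)
  tevs <- make_tevs(sprintf("sva%02d", 1:60), "c1",
                    reg$start[inside] + 50 + seq_len(60) %% 40,
                    rep("SVA", 60), replicate(60, c(S1 = 1L), simplify = FALSE))
  res <- regulatory_enrichment(tevs, reg, sizes, R = 50, seed = 2)
  sva_reg <- res[res$te_class == "SVA" & res$region == "regulatory", ]
  expect_gt(sva_reg$z, 3)
  expect_equal(sva_reg$status, "enriched")
  sva_non <- res[res$te_class == "SVA" & res$region == "non_regulatory", ]
  expect_lt(sva_non$z, -3)
  expect_equal(sva_non$status, "depleted")
  # empty classes are reported not-applicable, never an error
  expect_true(all(res$status[res$te_class == "Alu"] == "not_applicable"))
  # regulatory set covering the whole genome: zero-sd cells are flagged
  whole <- tibble::tibble(chrom = "c1", start = 0, end = 1e7)
  res_w <- regulatory_enrichment(tevs, whole, sizes, R = 10, seed = 2)
  w <- res_w[res_w$te_class == "SVA" & res_w$region == "regulatory", ]
  expect_equal(w$observed_pct, 100)
  expect_true(w$degenerate_sd)
})

test_that("uniformly placed variants stay within |z| <= 3 in most replicates", {
  sizes <- c(c1 = 1e7, c2 = 8e6)
  reg <- tibble::tibble(chrom = "c1", start = seq(0, 9e6, by = 1e6),
                        end = seq(0, 9e6, by = 1e6) + 2e5)
  zs <- vapply(1:20, function(s) {
    u <- randomize_coordinates(
      tibble::tibble(chrom = rep("c1", 80), start = 0, end = 1),
      sizes, seed = 100 + s)
    tevs <- make_tevs(sprintf("v%02d", 1:80), u$chrom, u$start + 1,
                      rep("Alu", 80), replicate(80, c(S1 = 1L), simplify = FALSE))
    res <- regulatory_enrichment(tevs, reg, sizes, R = 30, seed = 200 + s)
    res$z[res$te_class == "Alu" & res$region == "regulatory"]
  }, numeric(1))
  expect_gte(mean(abs(zs) <= 3), 0.95)
})
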