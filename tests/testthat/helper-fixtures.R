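# Shared fixture builders: everything is generated in code at test time.

# A small but non-degenerate configuration used by most module tests;
# overrides in ... take precedence over the small-scale defaults.
small_config <- function(seed = 1, ...) {
  defaults <- list(
    n_samples = 60L,
    n_variants = c(Alu = 40L, L1 = 8L, SVA = 6L),
    n_genes = 40L,
    chrom_sizes = c(chr1 = 2e7, chr2 = 1.5e7),
    maf_floor = 0.02,
    n_planted = 5L,
    n_randomizations = 10L,
    transcribed_fraction = 0.2,
    seed = seed
  )
  do.call(tev_config, utils::modifyList(defaults, list(...)))
}

# The scan-scale configuration: 200 samples over the default catalog,
# which yields roughly 2,000 cis pairs at the 1 Mbp window.
scan_config <- function(seed = 1, ...) {
  do.call(tev_config, utils::modifyList(
    list(n_samples = 200L, n_planted = 20L, seed = seed), list(...)))
}

# Simulate the in-memory pieces of a bundle in one call.
sim_bundle <- function(config) {
  cohort <- simulate_cohort(config)
  tevs <- simulate_tevs(config, cohort)
  genes <- simulate_genes(config)
  sim <- simulate_expression(config, cohort, tevs, genes)
  list(config = config, cohort = cohort, tevs = tevs, genes = genes,
       expression = sim$expression, planted = sim$planted)
}

# Hand-build a minimal variant tibble with explicit dosages.
make_tevs <- function(variant_id, chrom, pos, te_class, dosages,
                      strand = NULL, deletion_coded = NULL, length = NULL) {
  n <- length(variant_id)
  tibble::tibble(
    variant_id = variant_id,
    chrom = chrom,
    pos = as.integer(pos),
    te_class = te_class,
    strand = if (is.null(strand)) rep("+", n) else strand,
    deletion_coded = if (is.null(deletion_coded)) rep(FALSE, n) else deletion_coded,
    length = as.integer(if (is.null(length)) rep(300L, n) else length),
    dosages = dosages
  )
}

# Write a small VCF by hand (independent of write_tev_vcf) for parser tests.
write_raw_vcf <- function(path, records, samples = c("S1", "S2", "S3")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"t\">",
    "##INFO=<ID=MEINFO,Number=4,Type=String,Description=\"t\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"t\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  path
}
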