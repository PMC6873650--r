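# End-to-end orchestration: simulate or read a bundle, filter, scan,
# enrich, orient, classify, match, and summarize with a consistent
# manifest. One global seed fans out to per-stage child seeds so stages can
# be re-run in isolation.

#' Run the full analysis pipeline
#'
#' Executes catalog input -> carrier filter -> cis-eQTL scan (with optional
#' genotype-randomization validation) -> sliding-window scans for all TEVs
#' and for significant eQTL variants -> regulatory / orientation / context
#' analyses -> RNA-TEV analyses, and emits a per-class summary table
#' (total, filtered, with significant associations) plus a run manifest
#' with internally consistent counts.
#'
#' @param config A [tev_config()]. With `input_dir = NULL` the synthetic
#'   generator supplies all inputs in memory; otherwise the directory must
#'   contain a fixture bundle as written by [write_fixture_bundle()].
#' @param input_dir Optional path to a bundle directory to read instead of
#'   simulating.
#' @param output_dir Optional directory; when given, every stage table is
#'   written as TSV plus a `manifest.json`.
#' @return A list of class `tev_run` with elements `tevs`, `tevs_filtered`,
#'   `samples`, `genes`, `scan`, `permutation`, `windows_tev`,
#'   `windows_eqtl`, `regulatory`, `orientation`, `context`, `band_density`,
#'   `rna_tevs`, `class_ratio`, `presence`, `class_summary`, `manifest`.
#' @export
run_tev_pipeline <- function(config = tev_config(), input_dir = NULL,
                             output_dir = NULL) {
  if (is.null(input_dir)) {
    cohort <- simulate_cohort(config)
    tevs <- simulate_tevs(config, cohort)
    genes <- simulate_genes(config)
    sim <- simulate_expression(config, cohort, tevs, genes)
    expression <- sim$expression
    planted <- sim$planted
    regulatory <- simulate_regulatory(config)
    cytobands <- simulate_cytobands(config)
    calls <- simulate_rna_calls(config, tevs, cohort, genes)
  } else {
    cohort <- read_sample_info(file.path(input_dir, "samples.tsv"))
    tevs <- read_tev_vcf(file.path(input_dir, "tevs.vcf"), cohort$sample_id)
    genes <- read_gene_annotation(file.path(input_dir, "genes.gtf"))
    expression <- read_expression(file.path(input_dir, "expression.tsv"))
    regulatory <- read_regulatory(file.path(input_dir, "regulatory.bed"))
    cytobands <- read_cytobands(file.path(input_dir, "cytoBand.txt"))
    calls <- read_rna_calls(file.path(input_dir, "rna_calls.tsv"))
    planted <- NULL
  }
  n_read <- nrow(tevs)
  tevs_f <- suppressMessages(filter_by_carriers(tevs, config$min_carriers))
  aligned <- suppressMessages(align_samples(expression, tevs_f, cohort))

  pairs <- build_cis_pairs(aligned$tevs, genes, config$cis_window)
  scan <- run_scan(pairs, aligned$expression, aligned$tevs, aligned$samples,
                   fdr_threshold = config$fdr_threshold,
                   log2_transform = config$expression_log2)
  perm <- if (config$run_permutation) {
    permutation_validation(pairs, aligned$expression, aligned$tevs,
                           aligned$samples, R = config$n_randomizations,
                           fdr_threshold = config$fdr_threshold,
                           seed = config$seed,
                           log2_transform = config$expression_log2)
  } else NULL

  loci_all <- tev_loci(tevs_f)
  win_tev <- window_enrichment_scan(loci_all, config$chrom_sizes,
                                    R = config$n_randomizations,
                                    seed = derive_seed(config$seed, 30L),
                                    width = config$window_width,
                                    step = config$window_step,
                                    z_threshold = config$z_threshold)
  sig_ids <- unique(scan$variant_id[scan$significant])
  loci_sig <- loci_all[loci_all$variant_id %in% sig_ids, , drop = FALSE]
  win_eqtl <- window_enrichment_scan(loci_sig, config$chrom_sizes,
                                     R = config$n_randomizations,
                                     seed = derive_seed(config$seed, 31L),
                                     width = config$window_width,
                                     step = config$window_step,
                                     z_threshold = config$z_threshold)
  reg <- regulatory_enrichment(tevs_f, regulatory, config$chrom_sizes,
                               R = config$n_randomizations,
                               seed = derive_seed(config$seed, 32L),
                               z_threshold = config$z_threshold)
  orient <- orientation_concordance(tevs_f, genes)
  ctx <- classify_context(tevs_f, genes)
  bands <- band_density(loci_sig, cytobands)

  rna <- match_rna_calls(tevs_f, calls, config$match_distance)
  rna <- suppressMessages(overlap_with_eqtls(rna, scan))
  ratio <- class_ratio_log2(rna, tevs_f)
  pres <- presence_matrix(rna, cohort)
  rna_context <- if (nrow(rna) > 0) {
    context_enrichment(tevs_f[tevs_f$variant_id %in% rna$variant_id, ], tevs_f, genes)
  } else NULL

  class_summary <- purrr::map_dfr(TE_CLASSES, function(cl) {
    tibble::tibble(
      te_class = cl,
      total = sum(tevs$te_class == cl),
      filtered = sum(tevs_f$te_class == cl),
      significant = length(unique(
        scan$variant_id[scan$significant &
                          scan$variant_id %in% tevs_f$variant_id[tevs_f$te_class == cl]]))
    )
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("tevr")),
    seed = config$seed,
    config = unclass(config),
    counts = list(
      variants_read = n_read,
      variants_filtered = nrow(tevs_f),
      pairs_tested = nrow(scan),
      pairs_skipped = nrow(attr(scan, "skipped")),
      skip_reasons = as.list(table(attr(scan, "skipped")$reason)),
      significant_associations = sum(scan$significant),
      significant_variants = length(sig_ids),
      rna_tevs = nrow(rna),
      rna_tevs_in_eqtl_set = sum(rna$in_eqtl_set)
    )
  )
  run <- list(
    tevs = tevs, tevs_filtered = tevs_f, samples = cohort, genes = genes,
    planted = planted, scan = scan, permutation = perm,
    windows_tev = win_tev, windows_eqtl = win_eqtl, regulatory = reg,
    orientation = orient, context = ctx, band_density = bands,
    rna_tevs = rna, class_ratio = ratio, presence = pres,
    rna_context = rna_context, class_summary = class_summary,
    manifest = manifest
  )
  class(run) <- "tev_run"
  if (!is.null(output_dir)) write_run_outputs(run, output_dir)
  run
}

# Write every tabular stage output as TSV plus the manifest as JSON. No
# timestamps, so identical runs produce byte-identical files.
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    readr::write_tsv(df, file.path(dir, paste0(name, ".tsv")), progress = FALSE)
  }
  w(tidy(run$scan), "eqtl_results")
  w(attr(run$scan, "skipped"), "eqtl_skipped")
  if (!is.null(run$permutation)) w(glance(run$permutation), "permutation_summary")
  w(run$windows_tev, "windows_tev")
  w(run$windows_eqtl, "windows_eqtl")
  w(run$regulatory, "regulatory_enrichment")
  w(run$orientation$by_class, "orientation_by_class")
  w(run$orientation$tests, "orientation_tests")
  w(dplyr::count(run$context, .data$te_class, .data$context), "context_counts")
  w(run$band_density, "band_density")
  w(run$rna_tevs[, c("variant_id", "chrom", "pos", "te_class",
                     "n_supporting_calls", "associated_gene", "in_eqtl_set")],
    "rna_tevs")
  w(run$class_ratio, "class_ratio")
  w(run$presence, "presence_matrix")
  if (!is.null(run$rna_context)) w(run$rna_context, "rna_context")
  w(run$class_summary, "class_summary")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.tev_run <- function(x, ...) {
  cat("tevr pipeline run (seed", x$manifest$seed, ")\n")
  cnt <- x$manifest$counts
  cat(sprintf("  variants: %d read, %d after carrier filter\n",
              cnt$variants_read, cnt$variants_filtered))
  cat(sprintf("  cis-eQTL: %d pairs tested, %d significant\n",
              cnt$pairs_tested, cnt$significant_associations))
  cat(sprintf("  RNA-TEVs: %d matched, %d in eQTL set\n",
              cnt$rna_tevs, cnt$rna_tevs_in_eqtl_set))
  invisible(x)
}

#' Consolidated report of a pipeline run
#'
#' Prints the six summary sections (per-class catalog summary, top enriched
#' windows, regulatory Z table, orientation table, band-density ranking,
#' RNA-TEV summary); sections whose stage did not run are marked "not run".
#' Regenerating the report from the same run is idempotent.
#'
#' @param run A `tev_run` from [run_tev_pipeline()].
#' @param top_n Rows shown for ranked tables.
#' @return A named list of the section tibbles, invisibly.
#' @export
tev_report <- function(run, top_n = 10) {
  sections <- list()
  section <- function(name, value) {
    cat("\n==", name, "==\n")
    if (is.null(value) || (is.data.frame(value) && nrow(value) == 0)) {
      cat("not run\n")
      sections[[name]] <<- NULL
    } else {
      print(value, n = min(top_n, if (is.data.frame(value)) nrow(value) else top_n))
      sections[[name]] <<- value
    }
  }
  section("Per-class catalog summary", run$class_summary)
  top_windows <- run$windows_tev |>
    dplyr::arrange(dplyr::desc(.data$z)) |>
    utils::head(top_n)
  section("Top TEV-enriched windows", top_windows)
  section("Regulatory enrichment (Z)", run$regulatory)
  section("Orientation concordance", run$orientation$by_class)
  section("Band density ranking (significant eQTL variants)",
          utils::head(run$band_density, top_n))
  rna_sum <- if (!is.null(run$rna_tevs) && nrow(run$rna_tevs) > 0) {
    dplyr::count(run$rna_tevs, .data$te_class, .data$in_eqtl_set)
  } else NULL
  section("RNA-TEV summary", rna_sum)
  if (!is.null(run$permutation)) {
    cat("\n== Scan validation ==\n")
    print(run$permutation)
    sections[["Scan validation"]] <- glance(run$permutation)
  }
  invisible(sections)
}
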