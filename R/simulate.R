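# Seeded synthetic cohorts with known ground truth, emitted in the exact
# formats the readers consume. The generator mirrors the fitted model: an
# additive per-allele cis effect on raw RPKM-scale expression with sex and
# population covariates and Gaussian noise, Hardy-Weinberg genotypes over a
# MAF spectrum with a rare tail, strand-annotated insertions, a
# deletion-coded fraction, and jittered RNA-seq insertion calls.

#' Simulation and analysis configuration
#'
#' One configuration object drives both the synthetic-data generator and the
#' analysis thresholds. Defaults describe the emulated study: 445
#' individuals from 5 populations, a three-class catalog with the strong
#' Alu-dominated class imbalance of human MEI catalogs (scaled down), a
#' MAF mixture with a rare tail reaching
#' the 3-carrier floor, a 15% deletion-coded fraction, and the analysis
#' constants (3-carrier filter, 1 Mbp cis window, FDR 0.05, |Z| > 3,
#' 100 randomizations, 50 bp RNA matching, 10/5 Mbp windows).
#'
#' @param n_samples Cohort size.
#' @param populations Named population proportions (must sum to 1).
#' @param male_fraction Probability a sample is male.
#' @param n_variants Named per-class variant counts (`Alu`, `L1`, `SVA`).
#' @param te_length_ranges Per-class element length ranges (bp).
#' @param maf_floor,maf_rare_fraction,maf_max MAF mixture: with probability
#'   `maf_rare_fraction` the MAF is uniform on `(maf_floor, 0.05)` (the rare
#'   tail), otherwise uniform on `(0.05, maf_max)`.
#' @param deletion_coded_fraction Fraction of variants written as `*_DEL`
#'   records (element absent from the reference).
#' @param missing_rate Per-genotype missingness probability.
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param n_genes Number of genes placed on the genome.
#' @param gene_length_range,exon_count_range Gene structure parameters.
#' @param biotype_probs Named gene-biotype proportions.
#' @param regulatory_fraction Approximate fraction of the genome covered by
#'   regulatory intervals.
#' @param regulatory_length_range Regulatory interval length range (bp).
#' @param bands_per_chrom Karyotype bands simulated per chromosome.
#' @param base_expr_meanlog,base_expr_sdlog Log-normal baseline RPKM.
#' @param sex_effect_sd,pop_effect_sd SD of per-gene sex / population
#'   covariate effects (expression units).
#' @param noise_sd Residual Gaussian noise SD (expression units).
#' @param n_planted Number of planted cis effects.
#' @param planted_beta Planted effect magnitude (expression units per
#'   presence allele).
#' @param planted_sign `"both"`, `"positive"` or `"negative"`.
#' @param planted_min_maf Minimum MAF of variants receiving a planted
#'   effect; effects are planted on identifiable (common) variants.
#' @param expression_log2 If `TRUE`, expression is simulated (and later
#'   fitted) on the log2(x+1) scale.
#' @param transcribed_fraction Fraction of variants treated as transcribed
#'   (source of true RNA-seq insertion calls).
#' @param rna_tp_rate Probability a (carrier, transcribed variant) pair
#'   yields an RNA call.
#' @param rna_jitter Positional jitter bound for true calls (bp; should be
#'   below the 50 bp matching radius).
#' @param rna_false_rate Expected false calls per true call.
#' @param min_carriers,cis_window,fdr_threshold,z_threshold,n_randomizations,match_distance,window_width,window_step
#'   Analysis thresholds (catalog filter, cis pairing, FDR, enrichment Z,
#'   randomization count, RNA matching radius, sliding-window geometry).
#' @param run_permutation Whether [run_tev_pipeline()] runs the
#'   genotype-randomization validation of the scan.
#' @param seed Global seed; per-stage child seeds are derived from it.
#' @return A list of class `tev_config`.
#' @export
tev_config <- function(
    n_samples = 445L,
    populations = c(CEU = 0.2, FIN = 0.2, GBR = 0.2, TSI = 0.2, YRI = 0.2),
    male_fraction = 0.5,
    n_variants = c(Alu = 400L, L1 = 60L, SVA = 25L),
    te_length_ranges = list(Alu = c(250, 350), L1 = c(900, 6000), SVA = c(700, 4000)),
    maf_floor = 0.005,
    maf_rare_fraction = 0.35,
    maf_max = 0.5,
    deletion_coded_fraction = 0.15,
    missing_rate = 0,
    chrom_sizes = c(chr1 = 6e7, chr2 = 5e7, chr3 = 4e7),
    n_genes = 300L,
    gene_length_range = c(5e3, 8e4),
    exon_count_range = c(2L, 8L),
    biotype_probs = c(protein_coding = 0.7, pseudogene = 0.1, lincRNA = 0.1, antisense = 0.1),
    regulatory_fraction = 0.08,
    regulatory_length_range = c(200, 2000),
    bands_per_chrom = 8L,
    base_expr_meanlog = log(10),
    base_expr_sdlog = 0.7,
    sex_effect_sd = 0.5,
    pop_effect_sd = 0.5,
    noise_sd = 1,
    n_planted = 20L,
    planted_beta = 1.5,
    planted_sign = c("both", "positive", "negative"),
    planted_min_maf = 0.05,
    expression_log2 = FALSE,
    transcribed_fraction = 0.015,
    rna_tp_rate = 0.9,
    rna_jitter = 20,
    rna_false_rate = 0.05,
    min_carriers = 3L,
    cis_window = 1e6,
    fdr_threshold = 0.05,
    z_threshold = 3,
    n_randomizations = 100L,
    match_distance = 50,
    window_width = 1e7,
    window_step = 5e6,
    run_permutation = TRUE,
    seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), populations = populations,
    male_fraction = male_fraction, n_variants = n_variants,
    te_length_ranges = te_length_ranges, maf_floor = maf_floor,
    maf_rare_fraction = maf_rare_fraction, maf_max = maf_max,
    deletion_coded_fraction = deletion_coded_fraction,
    missing_rate = missing_rate, chrom_sizes = chrom_sizes,
    n_genes = as.integer(n_genes), gene_length_range = gene_length_range,
    exon_count_range = exon_count_range, biotype_probs = biotype_probs,
    regulatory_fraction = regulatory_fraction,
    regulatory_length_range = regulatory_length_range,
    bands_per_chrom = as.integer(bands_per_chrom),
    base_expr_meanlog = base_expr_meanlog, base_expr_sdlog = base_expr_sdlog,
    sex_effect_sd = sex_effect_sd, pop_effect_sd = pop_effect_sd,
    noise_sd = noise_sd, n_planted = as.integer(n_planted),
    planted_beta = planted_beta, planted_sign = match.arg(planted_sign),
    planted_min_maf = planted_min_maf, expression_log2 = expression_log2,
    transcribed_fraction = transcribed_fraction, rna_tp_rate = rna_tp_rate,
    rna_jitter = rna_jitter, rna_false_rate = rna_false_rate,
    min_carriers = as.integer(min_carriers), cis_window = cis_window,
    fdr_threshold = fdr_threshold, z_threshold = z_threshold,
    n_randomizations = as.integer(n_randomizations),
    match_distance = match_distance, window_width = window_width,
    window_step = window_step, run_permutation = isTRUE(run_permutation),
    seed = as.integer(seed)
  )
  class(cfg) <- "tev_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (abs(sum(cfg$populations) - 1) > 1e-8) {
    rlang::abort("Population proportions must sum to 1.")
  }
  if (any(cfg$n_variants < 0) || cfg$n_genes < 0 || cfg$n_planted < 0) {
    rlang::abort("Counts must be non-negative.")
  }
  validate_chrom_sizes(cfg$chrom_sizes)
  if (cfg$maf_floor < 1 / (2 * cfg$n_samples)) {
    rlang::abort("`maf_floor` below 1/(2n): rarest variants could never be observed.")
  }
  if (cfg$rna_tp_rate < 0 || cfg$rna_tp_rate > 1) {
    rlang::abort("`rna_tp_rate` must lie in [0, 1].")
  }
  if (cfg$rna_jitter >= cfg$match_distance) {
    rlang::warn("RNA jitter bound is not below the matching radius; true calls may be unmatchable.")
  }
  cfg
}

#' Read / write a configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_tev_config()`, a `tev_config`; for `write_tev_config()`,
#'   `path` invisibly.
#' @export
read_tev_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("populations", "n_variants", "biotype_probs", "chrom_sizes")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(tev_config, raw)
}

#' @rdname read_tev_config
#' @param config A `tev_config`.
#' @export
write_tev_config <- function(config, path) {
  out <- unclass(config)
  # named vectors must round-trip as YAML maps, not bare sequences
  for (nm in c("populations", "n_variants", "biotype_probs", "chrom_sizes")) {
    out[[nm]] <- as.list(out[[nm]])
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Simulate a cohort of individuals
#'
#' @param config A [tev_config()].
#' @return Tibble with `sample_id`, `sex`, `population`; deterministic given
#'   the config seed.
#' @export
simulate_cohort <- function(config) {
  withr::with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_samples
    tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      sex = sample(c("male", "female"), n, replace = TRUE,
                   prob = c(config$male_fraction, 1 - config$male_fraction)),
      population = sample(names(config$populations), n, replace = TRUE,
                          prob = config$populations)
    )
  })
}

#' Simulate a TEV catalog under Hardy-Weinberg equilibrium
#'
#' Positions are uniform per chromosome (chromosome chosen proportional to
#' its length); per-variant genotypes are Binomial(2, MAF); strand is +/-
#' with equal probability; a configured fraction is deletion-coded.
#'
#' @param config A [tev_config()].
#' @param cohort Output of [simulate_cohort()].
#' @return A variant tibble in the same shape as [read_tev_vcf()] returns,
#'   with a `maf` column recording each variant's generating MAF.
#' @export
simulate_tevs <- function(config, cohort) {
  withr::with_seed(derive_seed(config$seed, 2L), {
    sizes <- config$chrom_sizes
    n_total <- sum(config$n_variants)
    classes <- rep(names(config$n_variants), config$n_variants)
    n_s <- nrow(cohort)
    chrom <- sample(names(sizes), n_total, replace = TRUE, prob = sizes)
    maf <- ifelse(
      runif(n_total) < config$maf_rare_fraction,
      runif(n_total, config$maf_floor, 0.05),
      runif(n_total, 0.05, config$maf_max)
    )
    lens <- vapply(classes, function(cl) {
      r <- config$te_length_ranges[[cl]]
      round(runif(1, r[1], r[2]))
    }, numeric(1))
    pos <- floor(runif(n_total) * (sizes[chrom] - lens)) + 1
    del <- runif(n_total) < config$deletion_coded_fraction
    strand <- sample(c("+", "-"), n_total, replace = TRUE)
    dosages <- lapply(seq_len(n_total), function(i) {
      d <- stats::rbinom(n_s, 2L, maf[i])
      if (config$missing_rate > 0) {
        d[runif(n_s) < config$missing_rate] <- NA_integer_
      }
      stats::setNames(as.integer(d), cohort$sample_id)
    })
    ord <- order(chrom, pos)
    tibble::tibble(
      variant_id = sprintf("%s_%05d", classes, seq_len(n_total)),
      chrom = chrom,
      pos = as.integer(pos),
      te_class = classes,
      strand = strand,
      deletion_coded = del,
      length = as.integer(lens),
      maf = maf,
      dosages = dosages
    )[ord, ]
  })
}

#' Simulate gene models with substructure
#'
#' Genes are laid non-overlapping along each chromosome with random
#' intergenic gaps; protein-coding genes get 5'UTR / exon / intron / 3'UTR
#' blocks (UTRs at the transcription ends given the strand), other biotypes
#' alternate exons and introns only.
#'
#' @param config A [tev_config()].
#' @return Gene tibble as for [read_gene_annotation()], plus `biotype`.
#' @export
simulate_genes <- function(config) {
  withr::with_seed(derive_seed(config$seed, 3L), {
    sizes <- config$chrom_sizes
    n_per <- round(config$n_genes * sizes / sum(sizes))
    out <- list()
    idx <- 0L
    for (chrom in names(sizes)) {
      n <- n_per[[chrom]]
      if (n == 0) next
      lens <- round(runif(n, config$gene_length_range[1], config$gene_length_range[2]))
      slack <- sizes[[chrom]] - sum(lens)
      if (slack <= n) rlang::abort("Chromosome too small for requested gene count.")
      gaps <- floor(diff(c(0, sort(runif(n, 0, slack)))))
      starts <- cumsum(gaps) + cumsum(c(0, lens[-n]))
      for (i in seq_len(n)) {
        idx <- idx + 1L
        strand <- sample(c("+", "-"), 1)
        biotype <- sample(names(config$biotype_probs), 1, prob = config$biotype_probs)
        out[[idx]] <- tibble::tibble(
          gene_id = sprintf("GENE%04d", idx),
          chrom = chrom,
          start = starts[i],
          end = starts[i] + lens[i],
          strand = strand,
          biotype = biotype,
          substructure = list(random_substructure(
            starts[i], starts[i] + lens[i], strand,
            coding = biotype == "protein_coding", config$exon_count_range))
        )
      }
    }
    dplyr::bind_rows(out)
  })
}

# Partition [start, end) into ordered feature blocks. Coding genes receive
# UTRs at the transcript ends (genomically first block is 5'UTR on "+",
# 3'UTR on "-"); non-coding genes alternate exon/intron.
random_substructure <- function(start, end, strand, coding, exon_count_range) {
  len <- end - start
  n_exons <- sample(seq(exon_count_range[1], exon_count_range[2]), 1)
  n_blocks <- 2 * n_exons - 1 + if (coding) 2L else 0L
  w <- runif(n_blocks, 0.5, 1.5)
  w <- pmax(floor(len * w / sum(w)), 1)
  w[n_blocks] <- len - sum(w[-n_blocks])
  bounds <- start + cumsum(c(0, w))
  labels <- rep(c("exon", "intron"), length.out = 2 * n_exons - 1)
  if (coding) {
    labels <- c(if (strand == "+") "five_prime_utr" else "three_prime_utr",
                labels,
                if (strand == "+") "three_prime_utr" else "five_prime_utr")
  }
  tibble::tibble(feature = labels,
                 start = bounds[-length(bounds)],
                 end = bounds[-1])
}

#' Simulate regulatory feature intervals
#'
#' @param config A [tev_config()].
#' @return Tibble with `chrom`, `start`, `end` covering roughly
#'   `regulatory_fraction` of the genome.
#' @export
simulate_regulatory <- function(config) {
  withr::with_seed(derive_seed(config$seed, 4L), {
    sizes <- config$chrom_sizes
    mean_len <- mean(config$regulatory_length_range)
    out <- lapply(names(sizes), function(chrom) {
      n <- max(1L, round(config$regulatory_fraction * sizes[[chrom]] / mean_len))
      lens <- round(runif(n, config$regulatory_length_range[1],
                          config$regulatory_length_range[2]))
      starts <- floor(runif(n) * (sizes[[chrom]] - lens))
      tibble::tibble(chrom = chrom, start = starts, end = starts + lens)
    })
    dplyr::bind_rows(out) |> dplyr::arrange(.data$chrom, .data$start)
  })
}

#' Simulate a karyotype band table
#'
#' @param config A [tev_config()].
#' @return Cytoband tibble as for [read_cytobands()]; each chromosome is cut
#'   into `bands_per_chrom` contiguous bands named p/q-style.
#' @export
simulate_cytobands <- function(config) {
  withr::with_seed(derive_seed(config$seed, 5L), {
    out <- lapply(names(config$chrom_sizes), function(chrom) {
      size <- config$chrom_sizes[[chrom]]
      k <- config$bands_per_chrom
      cuts <- sort(sample(seq(1e5, size - 1e5), k - 1))
      bounds <- c(0, cuts, size)
      half <- ceiling(k / 2)
      band <- c(paste0("p", rev(seq_len(half))), paste0("q", seq_len(k - half)))
      tibble::tibble(
        chrom = chrom,
        start = bounds[-length(bounds)],
        end = bounds[-1],
        band_name = paste0(sub("^chr", "", chrom), band),
        stain = rep(c("gneg", "gpos50"), length.out = k)
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Simulate expression with planted cis effects
#'
#' Generates `y[g, s] = mu_g + a_g 1{male} + b_{g,pop(s)} + sum beta *
#' dosage + noise`, clipped at zero (RPKM are non-negative), where planted
#' `(variant, gene)` pairs are drawn only among cis pairs (distance below
#' the configured window) on variants with MAF at or above
#' `planted_min_maf`.
#'
#' @param config A [tev_config()].
#' @param cohort,tevs,genes Outputs of the respective simulators.
#' @return A list: `expression` (tibble, `gene_id` + one column per sample)
#'   and `planted` (tibble `variant_id`, `gene_id`, `beta`, `distance`).
#' @export
simulate_expression <- function(config, cohort, tevs, genes) {
  pairs <- build_cis_pairs(tevs, genes, max_distance = config$cis_window)
  withr::with_seed(derive_seed(config$seed, 6L), {
    n <- nrow(cohort)
    g_ids <- genes$gene_id
    n_g <- length(g_ids)
    eligible <- pairs
    if ("maf" %in% names(tevs)) {
      ok <- tevs$variant_id[tevs$maf >= config$planted_min_maf]
      eligible <- pairs[pairs$variant_id %in% ok, , drop = FALSE]
    }
    # one effect per gene and per variant keeps ground truth separable
    pool <- eligible[sample.int(nrow(eligible)), , drop = FALSE]
    pool <- pool[!duplicated(pool$gene_id) & !duplicated(pool$variant_id), , drop = FALSE]
    n_p <- min(config$n_planted, nrow(pool))
    if (n_p < config$n_planted) {
      rlang::warn(sprintf("Only %d separable cis pairs for %d requested planted effects.",
                          nrow(pool), config$n_planted))
    }
    planted <- pool[seq_len(n_p), , drop = FALSE]
    sgn <- switch(config$planted_sign,
                  both = sample(c(-1, 1), nrow(planted), replace = TRUE),
                  positive = rep(1, nrow(planted)),
                  negative = rep(-1, nrow(planted)))
    planted$beta <- sgn * config$planted_beta

    mu <- exp(rnorm(n_g, config$base_expr_meanlog, config$base_expr_sdlog))
    a_sex <- rnorm(n_g, 0, config$sex_effect_sd)
    pops <- names(config$populations)
    b_pop <- matrix(rnorm(n_g * length(pops), 0, config$pop_effect_sd),
                    nrow = n_g, dimnames = list(g_ids, pops))
    b_pop[, 1] <- 0  # first population is the baseline
    male <- as.numeric(cohort$sex == "male")
    pop_idx <- match(cohort$population, pops)
    y <- matrix(mu, n_g, n, byrow = FALSE) +
      outer(a_sex, male) +
      b_pop[, pop_idx, drop = FALSE] +
      matrix(rnorm(n_g * n, 0, config$noise_sd), n_g, n)
    if (nrow(planted) > 0) {
      G <- dosage_matrix(tevs[match(planted$variant_id, tevs$variant_id), ],
                         cohort$sample_id)
      G[is.na(G)] <- 0L
      gi <- match(planted$gene_id, g_ids)
      y[gi, ] <- y[gi, ] + planted$beta * G
    }
    y <- pmax(y, 0)
    if (config$expression_log2) y <- log2(y + 1)
    dimnames(y) <- NULL
    expr <- tibble::as_tibble(as.data.frame(y), .name_repair = "minimal")
    names(expr) <- cohort$sample_id
    expr <- dplyr::bind_cols(tibble::tibble(gene_id = g_ids), expr)
    list(expression = expr,
         planted = tibble::as_tibble(planted[, c("variant_id", "gene_id", "beta", "distance")]))
  })
}

#' Simulate RNA-seq derived insertion calls
#'
#' A configured fraction of variants is treated as transcribed. For each
#' (carrier sample, transcribed variant) pair, with probability
#' `rna_tp_rate` a call of the same class is emitted at the variant position
#' plus uniform jitter within `(-rna_jitter, rna_jitter)`. False calls at
#' random positions and classes are added at rate `rna_false_rate` per true
#' call.
#'
#' @param config A [tev_config()].
#' @param tevs Variant tibble.
#' @param cohort Cohort tibble.
#' @param genes Optional gene tibble; when given, transcribed variants are
#'   drawn preferentially among intra-genic ones and calls carry the host
#'   gene id.
#' @return Call tibble (`call_id`, `sample_id`, `chrom`, `pos`, `te_class`,
#'   `annotated_gene`) with attributes `truth` (tibble `call_id`,
#'   `variant_id`; `NA` for false calls) and `transcribed_ids`.
#' @export
simulate_rna_calls <- function(config, tevs, cohort, genes = NULL) {
  withr::with_seed(derive_seed(config$seed, 7L), {
    n_trans <- max(0L, round(config$transcribed_fraction * nrow(tevs)))
    pool <- tevs
    host <- rep(NA_character_, nrow(tevs))
    if (!is.null(genes) && nrow(genes) > 0) {
      hits <- GenomicRanges::findOverlaps(as_granges0(tev_loci(tevs)), as_granges0(genes))
      host[S4Vectors::queryHits(hits)] <- genes$gene_id[S4Vectors::subjectHits(hits)]
      if (sum(!is.na(host)) >= n_trans) pool <- tevs[!is.na(host), , drop = FALSE]
    }
    transcribed <- pool$variant_id[sample.int(nrow(pool), min(n_trans, nrow(pool)))]
    names(host) <- tevs$variant_id
    calls <- list()
    truth <- list()
    k <- 0L
    for (vid in transcribed) {
      row <- tevs[tevs$variant_id == vid, ]
      carriers <- names(row$dosages[[1]])[!is.na(row$dosages[[1]]) & row$dosages[[1]] >= 1]
      emit <- carriers[runif(length(carriers)) < config$rna_tp_rate]
      if (length(emit) == 0) next
      jit <- if (config$rna_jitter > 0) {
        sample(seq(-(config$rna_jitter - 1), config$rna_jitter - 1), length(emit), replace = TRUE)
      } else rep(0L, length(emit))
      k <- k + 1L
      calls[[k]] <- tibble::tibble(
        sample_id = emit, chrom = row$chrom, pos = row$pos + jit,
        te_class = row$te_class, annotated_gene = unname(host[vid])
      )
      truth[[k]] <- tibble::tibble(sample_id = emit, variant_id = vid)
    }
    calls <- dplyr::bind_rows(calls)
    truth <- dplyr::bind_rows(truth)
    n_true <- nrow(calls)
    n_false <- stats::rpois(1, config$rna_false_rate * max(n_true, 1))
    if (n_false > 0) {
      sizes <- config$chrom_sizes
      fchrom <- sample(names(sizes), n_false, replace = TRUE, prob = sizes)
      false_calls <- tibble::tibble(
        sample_id = sample(cohort$sample_id, n_false, replace = TRUE),
        chrom = fchrom,
        pos = floor(runif(n_false) * (sizes[fchrom] - 1)) + 1,
        te_class = sample(TE_CLASSES, n_false, replace = TRUE),
        annotated_gene = NA_character_
      )
      calls <- dplyr::bind_rows(calls, false_calls)
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        sample_id = false_calls$sample_id, variant_id = NA_character_))
    }
    if (nrow(calls) == 0) {
      calls <- tibble::tibble(sample_id = character(0), chrom = character(0),
                              pos = integer(0), te_class = character(0),
                              annotated_gene = character(0))
    }
    calls <- dplyr::bind_cols(
      tibble::tibble(call_id = sprintf("CALL%05d", seq_len(nrow(calls)))), calls)
    truth <- if (nrow(truth) > 0) {
      dplyr::bind_cols(tibble::tibble(call_id = calls$call_id), truth["variant_id"])
    } else tibble::tibble(call_id = character(0), variant_id = character(0))
    attr(calls, "truth") <- truth
    attr(calls, "transcribed_ids") <- transcribed
    calls
  })
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Simulates every input the pipeline consumes and writes them in the
#' standard formats the readers parse: a VCF catalog, an RPKM TSV, sample
#' metadata TSV, a GTF gene annotation, a regulatory BED, a UCSC-style
#' cytoBand TSV, an RNA-call TSV, a ground-truth JSON and a manifest with
#' file hashes and the seed. Byte-identical across runs with the same seed.
#'
#' @param config A [tev_config()].
#' @param dir Output directory; must be empty or absent unless
#'   `overwrite = TRUE`.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Tibble manifest (`file`, `md5`), invisibly; also written as
#'   `manifest.json`.
#' @export
write_fixture_bundle <- function(config, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    rlang::abort("Output directory is not empty; pass `overwrite = TRUE` to proceed.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  tevs <- simulate_tevs(config, cohort)
  genes <- simulate_genes(config)
  sim <- simulate_expression(config, cohort, tevs, genes)
  regulatory <- simulate_regulatory(config)
  cytobands <- simulate_cytobands(config)
  calls <- simulate_rna_calls(config, tevs, cohort, genes)

  paths <- list(
    vcf = file.path(dir, "tevs.vcf"),
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    genes = file.path(dir, "genes.gtf"),
    regulatory = file.path(dir, "regulatory.bed"),
    cytobands = file.path(dir, "cytoBand.txt"),
    rna_calls = file.path(dir, "rna_calls.tsv"),
    truth = file.path(dir, "ground_truth.json"),
    config = file.path(dir, "config.yaml")
  )
  write_tev_vcf(tevs, paths$vcf)
  readr::write_tsv(sim$expression, paths$expression, progress = FALSE)
  readr::write_tsv(cohort, paths$samples, progress = FALSE)
  write_genes_gtf(genes, paths$genes)
  readr::write_tsv(regulatory, paths$regulatory, col_names = FALSE, progress = FALSE)
  readr::write_tsv(
    tibble::tibble(chrom = cytobands$chrom, start = cytobands$start,
                   end = cytobands$end,
                   band = sub("^[^pq]*", "", cytobands$band_name),
                   stain = cytobands$stain),
    paths$cytobands, col_names = FALSE, progress = FALSE)
  readr::write_tsv(calls, paths$rna_calls, progress = FALSE)
  jsonlite::write_json(
    list(seed = config$seed,
         planted = sim$planted,
         transcribed_ids = attr(calls, "transcribed_ids"),
         rna_truth = attr(calls, "truth"),
         maf = tevs[, c("variant_id", "maf")]),
    paths$truth, auto_unbox = TRUE, digits = NA)
  write_tev_config(config, paths$config)
  files <- unlist(paths)
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    seed = config$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

# Minimal Ensembl-flavoured GTF writer (gene + five_prime_utr / exon /
# three_prime_utr rows; introns are derived on read as uncovered gaps).
write_genes_gtf <- function(genes, path) {
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attrs <- sprintf('gene_id "%s"; gene_biotype "%s";', g$gene_id, g$biotype)
    lines <- c(lines, paste(g$chrom, "tevr", "gene", g$start + 1, g$end, ".",
                            g$strand, ".", attrs, sep = "\t"))
    sub <- g$substructure[[1]]
    sub <- sub[sub$feature != "intron", , drop = FALSE]
    if (nrow(sub) > 0) {
      lines <- c(lines, paste(g$chrom, "tevr", sub$feature, sub$start + 1, sub$end,
                              ".", g$strand, ".", attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a MELT-style RNA insertion-call table
#'
#' @param path TSV with columns `sample_id`, `chrom`, `pos`, `te_class` and
#'   optionally `annotated_gene` and `call_id`.
#' @return Call tibble as produced by [simulate_rna_calls()].
#' @export
read_rna_calls <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "chrom", "pos", "te_class")
  if (!all(req %in% names(df))) {
    rlang::abort("RNA call table must have columns sample_id, chrom, pos, te_class.")
  }
  if (!all(df$te_class %in% TE_CLASSES)) {
    rlang::abort("Unknown TE class in RNA call table.")
  }
  if (!"annotated_gene" %in% names(df)) df$annotated_gene <- NA_character_
  if (!"call_id" %in% names(df)) df$call_id <- sprintf("CALL%05d", seq_len(nrow(df)))
  tibble::as_tibble(df[, c("call_id", req, "annotated_gene")])
}
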