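# Regulatory-region enrichment by randomization, intra-genic orientation
# concordance with Fisher tests, per-class contribution tests, and
# genomic-context classification.

CONTEXT_LEVELS <- c("three_prime_utr", "five_prime_utr", "exon", "intron", "intergenic")

#' Regulatory-region enrichment / depletion by randomization
#'
#' For each TE class, the observed percentage of variants overlapping any
#' regulatory interval (any-overlap rule) is compared with `R` randomized
#' placements of the same loci (lengths preserved). Both the regulatory and
#' the complementary non-regulatory cell are reported; `z > z_threshold` is
#' enriched, `z < -z_threshold` depleted.
#'
#' @param tevs Variant tibble.
#' @param regulatory Tibble of regulatory intervals (`chrom`, `start`,
#'   `end`).
#' @param chrom_sizes Named chromosome lengths.
#' @param R Number of randomizations (default 100, >= 2).
#' @param seed Seed for the randomizations.
#' @param z_threshold Significance threshold on |z| (default 3).
#' @return Tibble, two rows (regulatory / non_regulatory) per class:
#'   `te_class`, `region`, `n_variants`, `observed_pct`, `rand_mean_pct`,
#'   `rand_sd_pct`, `z`, `status` (enriched/depleted/neutral/
#'   not_applicable), `degenerate_sd`.
#' @export
regulatory_enrichment <- function(tevs, regulatory, chrom_sizes, R = 100,
                                  seed = 1, z_threshold = 3) {
  if (R < 2) rlang::abort("`R` must be at least 2.")
  reg_gr <- as_granges0(regulatory)
  loci <- tev_loci(tevs)
  pct_overlap <- function(df) {
    if (nrow(df) == 0) return(NA_real_)
    100 * mean(GenomicRanges::countOverlaps(as_granges0(df), reg_gr) > 0)
  }
  out <- lapply(TE_CLASSES, function(cl) {
    sub <- loci[!is.na(loci$te_class) & loci$te_class == cl, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(tibble::tibble(
        te_class = cl, region = c("regulatory", "non_regulatory"),
        n_variants = 0L, observed_pct = NA_real_, rand_mean_pct = NA_real_,
        rand_sd_pct = NA_real_, z = NA_real_, status = "not_applicable",
        degenerate_sd = NA))
    }
    obs <- pct_overlap(sub)
    rand <- withr::with_seed(derive_seed(seed, 20L + match(cl, TE_CLASSES)), {
      vapply(seq_len(R), function(r) {
        pct_overlap(randomize_coordinates(sub, chrom_sizes))
      }, numeric(1))
    })
    cell <- function(region, o, reps) {
      m <- mean(reps); s <- stats::sd(reps)
      z <- safe_z(o, m, s)
      status <- dplyr::case_when(
        s == 0 ~ "not_applicable",
        z > z_threshold ~ "enriched",
        z < -z_threshold ~ "depleted",
        TRUE ~ "neutral"
      )
      tibble::tibble(te_class = cl, region = region, n_variants = nrow(sub),
                     observed_pct = o, rand_mean_pct = m, rand_sd_pct = s,
                     z = z, status = status, degenerate_sd = s == 0)
    }
    dplyr::bind_rows(cell("regulatory", obs, rand),
                     cell("non_regulatory", 100 - obs, 100 - rand))
  })
  dplyr::bind_rows(out)
}

#' Orientation concordance of intra-genic variants
#'
#' Variants overlapping at least one gene are classified concordant when
#' their insertion strand matches the host gene's transcribed strand and
#' discordant otherwise; a variant overlapping genes on both strands counts
#' once, as concordant if any same-strand gene overlaps. Variants with
#' unknown strand go to an `unoriented` bucket. Classes are compared
#' pairwise with two-sided Fisher tests on (concordant, discordant).
#'
#' @param tevs Variant tibble (with `strand`).
#' @param genes Gene tibble (with `strand`).
#' @return A `tev_orientation` list: `by_class` (per-class counts and
#'   percentage concordant) and `tests` (pairwise Fisher p-values).
#' @export
orientation_concordance <- function(tevs, genes) {
  loci <- tev_loci(tevs)
  hits <- GenomicRanges::findOverlaps(as_granges0(loci), as_granges0(genes))
  qh <- S4Vectors::queryHits(hits)
  same <- tevs$strand[qh] == genes$strand[S4Vectors::subjectHits(hits)]
  concordant_any <- tapply(same, qh, any)
  intragenic <- as.integer(names(concordant_any))
  status <- rep(NA_character_, nrow(tevs))
  status[intragenic] <- ifelse(unlist(concordant_any), "concordant", "discordant")
  status[tevs$strand == "unknown" & !is.na(status)] <- "unoriented"
  by_class <- tibble::tibble(te_class = tevs$te_class, status = status) |>
    dplyr::filter(!is.na(.data$status)) |>
    dplyr::count(.data$te_class, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n", values_fill = 0L)
  for (col in c("concordant", "discordant", "unoriented")) {
    if (!col %in% names(by_class)) by_class[[col]] <- 0L
  }
  by_class <- by_class |>
    dplyr::mutate(
      n_intragenic = .data$concordant + .data$discordant,
      pct_concordant = 100 * .data$concordant / pmax(.data$n_intragenic, 1)
    ) |>
    dplyr::select("te_class", "n_intragenic", "concordant", "discordant",
                  "unoriented", "pct_concordant")
  tests <- pairwise_fisher(by_class, "concordant", "discordant")
  structure(list(by_class = by_class, tests = tests), class = "tev_orientation")
}

pairwise_fisher <- function(df, col_a, col_b) {
  cls <- df$te_class
  if (length(cls) < 2) {
    return(tibble::tibble(class_a = character(0), class_b = character(0),
                          p_value = numeric(0), odds_ratio = numeric(0)))
  }
  combos <- utils::combn(seq_along(cls), 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    i <- combos[1, k]; j <- combos[2, k]
    tab <- matrix(c(df[[col_a]][i], df[[col_b]][i],
                    df[[col_a]][j], df[[col_b]][j]), nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tab)
    tibble::tibble(class_a = cls[i], class_b = cls[j],
                   p_value = ft$p.value, odds_ratio = unname(ft$estimate))
  })
}

#' @export
print.tev_orientation <- function(x, ...) {
  cat("Intra-genic orientation concordance\n")
  print(x$by_class)
  cat("\nPairwise Fisher tests (concordant vs discordant):\n")
  print(x$tests)
  invisible(x)
}

#' @rdname orientation_concordance
#' @param x A `tev_orientation`.
#' @param ... Unused.
#' @method tidy tev_orientation
#' @export
tidy.tev_orientation <- function(x, ...) x$by_class

#' @rdname orientation_concordance
#' @method glance tev_orientation
#' @export
glance.tev_orientation <- function(x, ...) {
  tibble::tibble(n_classes = nrow(x$by_class),
                 n_intragenic = sum(x$by_class$n_intragenic),
                 min_pairwise_p = suppressWarnings(min(x$tests$p_value)))
}

#' Per-class contribution to a significant set
#'
#' Pairwise two-sided Fisher tests asking whether one class contributes
#' proportionally more of its variants to the significant set than another:
#' the 2x2 table is (significant, not significant) x (class a, class b).
#'
#' @param counts Tibble with `te_class`, `total` and `significant` columns.
#' @return Tibble `class_a`, `class_b`, `p_value`, `odds_ratio`.
#' @export
class_contribution_test <- function(counts) {
  if (any(counts$significant > counts$total)) {
    rlang::abort("`significant` cannot exceed `total`.")
  }
  if (any(counts$total < 0 | counts$significant < 0)) {
    rlang::abort("Counts must be non-negative.")
  }
  df <- counts
  df$not_significant <- df$total - df$significant
  pairwise_fisher(df, "significant", "not_significant")
}

#' Classify variants by genomic context
#'
#' Labels each variant locus by the gene substructure feature it overlaps,
#' with precedence `three_prime_utr > five_prime_utr > exon > intron` when
#' several features overlap; variants inside a gene span but outside any
#' annotated feature count as intronic, and variants outside all genes as
#' intergenic.
#'
#' @param tevs Variant tibble.
#' @param genes Gene tibble with `substructure` list-column.
#' @return `tevs` with an added `context` factor column (levels
#'   `three_prime_utr`, `five_prime_utr`, `exon`, `intron`, `intergenic`).
#' @export
classify_context <- function(tevs, genes) {
  out <- tevs
  if (nrow(tevs) == 0) {
    out$context <- factor(character(0), levels = CONTEXT_LEVELS)
    return(out)
  }
  loci <- tev_loci(tevs)
  gr_v <- as_granges0(loci)
  context <- rep("intergenic", nrow(tevs))
  gene_hits <- GenomicRanges::findOverlaps(gr_v, as_granges0(genes))
  context[unique(S4Vectors::queryHits(gene_hits))] <- "intron"
  feats <- tidyr::unnest(genes[, c("chrom", "substructure")], "substructure")
  if (nrow(feats) > 0) {
    fh <- GenomicRanges::findOverlaps(gr_v, as_granges0(feats))
    if (length(fh) > 0) {
      prec <- match(feats$feature[S4Vectors::subjectHits(fh)], CONTEXT_LEVELS)
      best <- tapply(prec, S4Vectors::queryHits(fh), min)
      context[as.integer(names(best))] <- CONTEXT_LEVELS[unlist(best)]
    }
  }
  out$context <- factor(context, levels = CONTEXT_LEVELS)
  out
}

#' Context enrichment of one variant set against a background
#'
#' Per-context two-sided Fisher tests and log2 percentage ratios comparing
#' a subset (e.g. RNA-supported variants) with a background set (e.g. all
#' variants).
#'
#' @param subset_tevs,background_tevs Variant tibbles.
#' @param genes Gene tibble with substructure.
#' @return Tibble `context`, `n_subset`, `pct_subset`, `n_background`,
#'   `pct_background`, `log2_ratio`, `p_value`.
#' @export
context_enrichment <- function(subset_tevs, background_tevs, genes) {
  cs <- classify_context(subset_tevs, genes)$context
  cb <- classify_context(background_tevs, genes)$context
  n_s <- length(cs)
  n_b <- length(cb)
  purrr::map_dfr(CONTEXT_LEVELS, function(ctx) {
    a <- sum(cs == ctx)
    b <- sum(cb == ctx)
    p <- stats::fisher.test(matrix(c(a, n_s - a, b, n_b - b), 2, byrow = TRUE))$p.value
    tibble::tibble(
      context = ctx, n_subset = a, pct_subset = 100 * a / n_s,
      n_background = b, pct_background = 100 * b / n_b,
      log2_ratio = log2((a / n_s) / (b / n_b)),
      p_value = p
    )
  })
}

#' Gene-biotype enrichment of one variant set against a background
#'
#' Associates each intra-genic variant with its host gene's biotype and
#' compares biotype composition between a subset and a background set by
#' log2 percentage ratios and per-biotype Fisher tests.
#'
#' @inheritParams context_enrichment
#' @return Tibble `biotype`, `n_subset`, `pct_subset`, `n_background`,
#'   `pct_background`, `log2_ratio`, `p_value`.
#' @export
biotype_enrichment <- function(subset_tevs, background_tevs, genes) {
  host_biotype <- function(tevs) {
    loci <- tev_loci(tevs)
    hits <- GenomicRanges::findOverlaps(as_granges0(loci), as_granges0(genes))
    bt <- tapply(genes$biotype[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits), function(x) x[1])
    unlist(bt)
  }
  bs <- host_biotype(subset_tevs)
  bb <- host_biotype(background_tevs)
  n_s <- length(bs); n_b <- length(bb)
  purrr::map_dfr(sort(unique(genes$biotype)), function(bt) {
    a <- sum(bs == bt); b <- sum(bb == bt)
    p <- if (n_s > 0 && n_b > 0) {
      stats::fisher.test(matrix(c(a, n_s - a, b, n_b - b), 2, byrow = TRUE))$p.value
    } else NA_real_
    tibble::tibble(
      biotype = bt, n_subset = a, pct_subset = 100 * a / max(n_s, 1),
      n_background = b, pct_background = 100 * b / max(n_b, 1),
      log2_ratio = log2((a / max(n_s, 1)) / (b / max(n_b, 1))),
      p_value = p
    )
  })
}
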