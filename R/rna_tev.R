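# Matching of RNA-seq derived insertion calls to DNA-genotyped variants,
# and the derived summaries: class-composition ratios, the per-population
# presence matrix, and overlap with the significant eQTL set.

#' Match RNA-seq insertion calls to DNA variants
#'
#' A call supports a variant iff both are on the same chromosome, of the
#' same TE class, strictly less than `max_distance` bp apart
#' (point-to-point), and the call's sample is a DNA carrier (dosage >= 1)
#' of the variant. Each call is assigned to at most one variant: the
#' nearest, ties broken by the lower variant coordinate. A variant with at
#' least one supporting call becomes an RNA-TEV.
#'
#' @param tevs Variant tibble (dosages needed for the carrier check).
#' @param calls Call tibble from [simulate_rna_calls()] or
#'   [read_rna_calls()].
#' @param max_distance Matching radius in bp (default 50; strict "less
#'   than").
#' @return Tibble of RNA-TEVs, one row per supported variant: `variant_id`,
#'   `chrom`, `pos`, `te_class`, `n_supporting_calls`, `supporting`
#'   (list-column of call tibbles), `carrier_samples` (list-column of DNA
#'   carrier ids), `associated_gene`, `in_eqtl_set` (`NA` until
#'   [overlap_with_eqtls()]). Unassigned calls are in attribute
#'   `unmatched_calls`; the call-to-variant assignment in attribute
#'   `assignments`.
#' @export
match_rna_calls <- function(tevs, calls, max_distance = 50) {
  empty <- tibble::tibble(
    variant_id = character(0), chrom = character(0), pos = integer(0),
    te_class = character(0), n_supporting_calls = integer(0),
    supporting = list(), carrier_samples = list(),
    associated_gene = character(0), in_eqtl_set = logical(0))
  if (nrow(tevs) == 0 || nrow(calls) == 0) {
    attr(empty, "unmatched_calls") <- calls
    attr(empty, "assignments") <- tibble::tibble(call_id = character(0),
                                                 variant_id = character(0))
    return(empty)
  }
  cand <- dplyr::inner_join(
    calls,
    tevs[, c("variant_id", "chrom", "pos", "te_class")] |>
      dplyr::rename(tev_pos = "pos"),
    by = c("chrom", "te_class"),
    relationship = "many-to-many"
  ) |>
    dplyr::mutate(distance = abs(.data$pos - .data$tev_pos)) |>
    dplyr::filter(.data$distance < max_distance)
  if (nrow(cand) > 0) {
    # carrier check: the call's sample must carry the variant at DNA level
    dos_lookup <- stats::setNames(tevs$dosages, tevs$variant_id)
    carrier <- purrr::map2_lgl(cand$variant_id, cand$sample_id, function(v, s) {
      d <- dos_lookup[[v]][s]
      !is.na(d) && d >= 1
    })
    cand <- cand[carrier, , drop = FALSE]
  }
  assigned <- cand |>
    dplyr::group_by(.data$call_id) |>
    dplyr::arrange(.data$distance, .data$tev_pos, .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup()
  if (nrow(assigned) == 0) {
    attr(empty, "unmatched_calls") <- calls
    attr(empty, "assignments") <- tibble::tibble(call_id = character(0),
                                                 variant_id = character(0))
    return(empty)
  }
  sup <- split(assigned, assigned$variant_id)
  matched_ids <- names(sup)
  rows <- tevs[match(matched_ids, tevs$variant_id), , drop = FALSE]
  ord <- order(rows$chrom, rows$pos)
  rows <- rows[ord, ]
  sup <- sup[rows$variant_id]
  out <- tibble::tibble(
    variant_id = rows$variant_id,
    chrom = rows$chrom,
    pos = rows$pos,
    te_class = rows$te_class,
    n_supporting_calls = vapply(sup, nrow, integer(1)),
    supporting = lapply(sup, function(s) {
      tibble::as_tibble(s[, c("call_id", "sample_id", "pos", "distance")])
    }),
    carrier_samples = lapply(rows$dosages, function(d) {
      names(d)[!is.na(d) & d >= 1]
    }),
    associated_gene = vapply(sup, function(s) {
      g <- s$annotated_gene[!is.na(s$annotated_gene)]
      if (length(g) > 0) g[1] else NA_character_
    }, character(1)),
    in_eqtl_set = NA
  )
  attr(out, "unmatched_calls") <- calls[!calls$call_id %in% assigned$call_id, , drop = FALSE]
  attr(out, "assignments") <- tibble::as_tibble(assigned[, c("call_id", "variant_id", "sample_id", "distance")])
  out
}

#' Class-composition log2 ratio of RNA-TEVs versus all variants
#'
#' Percentages are computed within each set; the per-class statistic is
#' `log2(pct_rna / pct_all)`. Classes absent from the RNA set report
#' `-Inf` with a flag.
#'
#' @param rna_tevs RNA-TEV tibble from [match_rna_calls()].
#' @param all_tevs Background variant tibble.
#' @return Tibble `te_class`, `n_rna`, `pct_rna`, `n_all`, `pct_all`,
#'   `log2_ratio`, `flagged`.
#' @export
class_ratio_log2 <- function(rna_tevs, all_tevs) {
  if (nrow(all_tevs) == 0) rlang::abort("Background variant set is empty.")
  n_r <- nrow(rna_tevs)
  n_a <- nrow(all_tevs)
  purrr::map_dfr(TE_CLASSES, function(cl) {
    a <- sum(rna_tevs$te_class == cl)
    b <- sum(all_tevs$te_class == cl)
    pct_r <- if (n_r > 0) 100 * a / n_r else NA_real_
    pct_a <- 100 * b / n_a
    ratio <- if (is.na(pct_r) || pct_a == 0) NA_real_ else log2(pct_r / pct_a)
    tibble::tibble(te_class = cl, n_rna = a, pct_rna = pct_r, n_all = b,
                   pct_all = pct_a, log2_ratio = ratio,
                   flagged = is.na(ratio) || is.infinite(ratio))
  })
}

#' Per-sample presence matrix of RNA-TEVs
#'
#' Binary matrix (RNA-TEV x sample): 1 iff the sample is a DNA-level
#' carrier of the variant. Columns are grouped by population label, rows
#' ordered by genomic coordinate.
#'
#' @param rna_tevs RNA-TEV tibble from [match_rna_calls()].
#' @param samples Sample metadata tibble.
#' @return A tibble with `variant_id` plus one 0/1 column per sample, in
#'   population-grouped order; the sample-to-population map is attached as
#'   attribute `sample_populations`.
#' @export
presence_matrix <- function(rna_tevs, samples) {
  samples <- samples[order(samples$population, samples$sample_id), , drop = FALSE]
  rna_tevs <- rna_tevs[order(rna_tevs$chrom, rna_tevs$pos), , drop = FALSE]
  m <- matrix(0L, nrow(rna_tevs), nrow(samples),
              dimnames = list(rna_tevs$variant_id, samples$sample_id))
  for (i in seq_len(nrow(rna_tevs))) {
    carriers <- intersect(rna_tevs$carrier_samples[[i]], samples$sample_id)
    m[i, carriers] <- 1L
  }
  out <- dplyr::bind_cols(tibble::tibble(variant_id = rownames(m)),
                          tibble::as_tibble(m))
  attr(out, "sample_populations") <-
    stats::setNames(samples$population, samples$sample_id)
  out
}

#' Flag RNA-TEVs present in the significant eQTL set
#'
#' @param rna_tevs RNA-TEV tibble.
#' @param scan A `tev_scan` from [run_scan()] (or any tibble with
#'   `variant_id` and `significant`).
#' @return `rna_tevs` with `in_eqtl_set` set to `TRUE` iff the variant has
#'   at least one significant association; the summary count is logged.
#' @export
overlap_with_eqtls <- function(rna_tevs, scan) {
  sig <- unique(scan$variant_id[scan$significant])
  out <- rna_tevs
  out$in_eqtl_set <- out$variant_id %in% sig
  rlang::inform(sprintf("%d of %d RNA-TEVs are in the significant eQTL set.",
                        sum(out$in_eqtl_set), nrow(out)))
  out
}
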