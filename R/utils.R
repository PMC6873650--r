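# Internal helpers shared across modules.

TE_CLASSES <- c("Alu", "L1", "SVA")

# Deterministic child seed for a pipeline stage. Keeps results reproducible
# from one global seed while allowing stages to be re-run in isolation.
# Always below 2^31 - 1.
derive_seed <- function(seed, offset) {
  seed <- as.numeric(seed)
  if (!is.finite(seed)) rlang::abort("`seed` must be a finite number.")
  as.integer((abs(seed) %% 1000003) * 1009 + 9973 * offset) %% 2147483629L
}

# Convert a tibble of 0-based half-open intervals (chrom/start/end) to a
# GRanges (1-based closed) for overlap arithmetic.
as_granges0 <- function(df, start_col = "start", end_col = "end") {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df[[start_col]] + 1L, end = df[[end_col]])
  )
}

# Genomic locus of each variant as a 0-based half-open interval: point
# insertions occupy 1 bp at their position; deletion-coded variants (TE
# present in individuals but absent from the reference) span their full
# deleted-element length.
tev_loci <- function(tevs) {
  stopifnot(all(c("chrom", "pos") %in% names(tevs)))
  len <- if ("length" %in% names(tevs)) tevs$length else rep(1, nrow(tevs))
  del <- if ("deletion_coded" %in% names(tevs)) tevs$deletion_coded else rep(FALSE, nrow(tevs))
  tibble::tibble(
    variant_id = tevs$variant_id,
    chrom = tevs$chrom,
    start = tevs$pos - 1,
    end = tevs$pos - 1 + ifelse(del, pmax(len, 1), 1),
    te_class = if ("te_class" %in% names(tevs)) tevs$te_class else NA_character_
  )
}

#' Extract the dosage matrix from a variant table
#'
#' @param tevs A variant tibble as returned by [read_tev_vcf()] or
#'   [simulate_tevs()], with a `dosages` list-column of named integer
#'   vectors (values 0/1/2 or `NA` for missing).
#' @param sample_ids Optional character vector giving the column order; by
#'   default the sample order of the first variant is used.
#' @return An integer matrix (variants x samples) with `variant_id` row
#'   names.
#' @export
dosage_matrix <- function(tevs, sample_ids = NULL) {
  if (nrow(tevs) == 0) {
    return(matrix(integer(0), nrow = 0, ncol = length(sample_ids %||% character(0)),
                  dimnames = list(character(0), sample_ids)))
  }
  sample_ids <- sample_ids %||% names(tevs$dosages[[1]])
  m <- do.call(rbind, lapply(tevs$dosages, function(d) unname(d[sample_ids])))
  dimnames(m) <- list(tevs$variant_id, sample_ids)
  storage.mode(m) <- "integer"
  m
}

# Count of carrier samples (dosage >= 1) per variant.
carrier_counts <- function(tevs) {
  vapply(tevs$dosages, function(d) sum(d >= 1, na.rm = TRUE), integer(1))
}

validate_chrom_sizes <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    rlang::abort("`chrom_sizes` must be a named numeric vector.")
  }
  if (any(chrom_sizes <= 0)) {
    rlang::abort("All chromosome lengths must be positive.")
  }
  invisible(chrom_sizes)
}

# Sample-standard-deviation Z score with the degenerate-sd convention used
# throughout the randomization tests: when sd is 0, z is +Inf if the
# observation exceeds the null mean, -Inf if below, and 0 if equal.
safe_z <- function(observed, null_mean, null_sd) {
  z <- (observed - null_mean) / null_sd
  deg <- !is.na(null_sd) & null_sd == 0
  z[deg] <- sign(observed[deg] - null_mean[deg]) * Inf
  z[deg & observed == null_mean] <- 0
  z
}

# Empirical upper-tail p with the +1 pseudocount so p is never 0 at finite R.
empirical_p <- function(observed, replicates) {
  (1 + sum(replicates >= observed)) / (1 + length(replicates))
}
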