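# Sliding-window genome enrichment against randomized coordinate sets, and
# karyotype-band density ranking.

#' Tile a genome into sliding windows
#'
#' Windows start at `0, step, 2*step, ...` while the start is inside the
#' chromosome; the final windows are clipped to the chromosome end, so with
#' the default 10 Mbp windows overlapping by 5 Mbp every interior base is
#' covered by exactly two windows.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param width Window width in bp (default 10 Mbp).
#' @param step Step between window starts (default 5 Mbp; `0 < step <=
#'   width`).
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `index`
#'   (ordinal within chromosome).
#' @export
tile_genome <- function(chrom_sizes, width = 1e7, step = 5e6) {
  validate_chrom_sizes(chrom_sizes)
  if (step <= 0 || step > width) rlang::abort("Require 0 < step <= width.")
  out <- lapply(names(chrom_sizes), function(chrom) {
    L <- chrom_sizes[[chrom]]
    starts <- seq(0, L - 1, by = step)
    tibble::tibble(
      chrom = chrom,
      start = starts,
      end = pmin(starts + width, L),
      index = seq_along(starts)
    )
  })
  dplyr::bind_rows(out)
}

#' Count features overlapping each window
#'
#' A feature increments every window it overlaps under the half-open
#' overlap test, so an interior point feature is counted in `width/step`
#' windows.
#'
#' @param windows Tibble from [tile_genome()].
#' @param features Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return `windows` with an added `count` column.
#' @export
count_in_windows <- function(windows, features) {
  out <- windows
  if (nrow(features) == 0) {
    out$count <- 0L
    return(out)
  }
  out$count <- GenomicRanges::countOverlaps(as_granges0(windows),
                                            as_granges0(features))
  out
}

#' Randomize feature coordinates genome-wide
#'
#' Returns the same number of features with the identical length multiset,
#' each placed uniformly on the genome: the chromosome is chosen with
#' probability proportional to its placeable length (length minus feature
#' length), and the feature lies fully inside it.
#'
#' @param features Tibble with `chrom`, `start`, `end`.
#' @param chrom_sizes Named chromosome lengths.
#' @param seed Optional seed; when given, placement is deterministic.
#' @return Tibble `chrom`, `start`, `end` (length multiset preserved).
#' @export
randomize_coordinates <- function(features, chrom_sizes, seed = NULL) {
  validate_chrom_sizes(chrom_sizes)
  place <- function() {
    n <- nrow(features)
    lens <- features$end - features$start
    if (any(lens > max(chrom_sizes))) {
      rlang::abort("A feature is longer than every chromosome.")
    }
    sizes <- as.numeric(chrom_sizes)
    k <- length(sizes)
    W <- pmax(matrix(sizes, n, k, byrow = TRUE) - lens + 1, 0)
    cw <- t(apply(W, 1, cumsum))
    u <- stats::runif(n) * cw[, k]
    ci <- max.col(cw >= u, ties.method = "first")
    start <- floor(stats::runif(n) * (sizes[ci] - lens + 1))
    # guard against the (measure-zero) boundary draw
    start <- pmin(start, sizes[ci] - lens)
    tibble::tibble(chrom = names(chrom_sizes)[ci], start = start,
                   end = start + lens)
  }
  if (is.null(seed)) place() else withr::with_seed(seed, place())
}

#' Sliding-window enrichment scan against randomized coordinates
#'
#' For each feature class, counts features per window, repeats the count on
#' `R` randomized coordinate sets of the same number and length multiset,
#' and reports per-window `z = (observed - mean) / sd` (sample sd),
#' empirical p with the +1 pseudocount, and BH q over windows. Windows with
#' `z > z_threshold` are called enriched.
#'
#' @param features Tibble with `chrom`, `start`, `end` and optionally
#'   `te_class` (one scan per class; otherwise a single class `"all"`).
#' @param chrom_sizes Named chromosome lengths.
#' @param R Number of randomizations (default 100, >= 2).
#' @param seed Seed for the randomizations.
#' @param width,step Window geometry (default 10 / 5 Mbp).
#' @param z_threshold Enrichment call threshold (default 3).
#' @return A tibble, one row per window per class: `te_class`, `chrom`,
#'   `start`, `end`, `index`, `observed`, `rand_mean`, `rand_sd`, `z`,
#'   `empirical_p`, `neg_log10_p`, `q_value`, `significant`,
#'   `degenerate_sd`.
#' @export
window_enrichment_scan <- function(features, chrom_sizes, R = 100, seed = 1,
                                   width = 1e7, step = 5e6, z_threshold = 3) {
  if (R < 2) rlang::abort("`R` must be at least 2.")
  windows <- tile_genome(chrom_sizes, width, step)
  classes <- if ("te_class" %in% names(features)) {
    split(features, features$te_class)
  } else {
    list(all = features)
  }
  out <- purrr::imap(classes, function(fc, cl) {
    observed <- count_in_windows(windows, fc)$count
    rand <- withr::with_seed(derive_seed(seed, 9L + match(cl, names(classes))), {
      vapply(seq_len(R), function(r) {
        count_in_windows(windows, randomize_coordinates(fc, chrom_sizes))$count
      }, numeric(nrow(windows)))
    })
    rand <- matrix(rand, nrow = nrow(windows))
    rmean <- rowMeans(rand)
    rsd <- apply(rand, 1, stats::sd)
    emp_p <- (1 + rowSums(rand >= observed)) / (1 + R)
    res <- windows
    res$te_class <- cl
    res$observed <- observed
    res$rand_mean <- rmean
    res$rand_sd <- rsd
    res$z <- safe_z(observed, rmean, rsd)
    res$empirical_p <- emp_p
    res$neg_log10_p <- -log10(emp_p)
    res$q_value <- bh_adjust(emp_p)
    res$significant <- res$z > z_threshold
    res$degenerate_sd <- rsd == 0
    res
  })
  dplyr::bind_rows(out) |>
    dplyr::relocate("te_class")
}

#' Rank karyotype bands by feature density
#'
#' Counts features overlapping each band and normalizes by band length;
#' the table is sorted by density, descending. With a `group` column (e.g.
#' tissue), densities and ranks are computed within each group.
#'
#' @param features Tibble with `chrom`, `start`, `end` and optionally a
#'   grouping column named by `group`.
#' @param cytobands Tibble from [read_cytobands()] (non-overlapping bands).
#' @param group Optional name of a grouping column in `features`.
#' @return Tibble `band_name`, `chrom`, `start`, `end`, `count`,
#'   `density` (count per bp), `rank` (1 = densest), plus the group column
#'   when grouping.
#' @export
band_density <- function(features, cytobands, group = NULL) {
  if (any(cytobands$end <= cytobands$start)) {
    rlang::abort("Zero-length karyotype band.")
  }
  one <- function(f, label = NULL) {
    res <- cytobands[, c("band_name", "chrom", "start", "end")]
    res$count <- GenomicRanges::countOverlaps(as_granges0(cytobands), as_granges0(f))
    res$density <- res$count / (res$end - res$start)
    res <- dplyr::arrange(res, dplyr::desc(.data$density))
    res$rank <- seq_len(nrow(res))
    if (!is.null(label)) res[[group]] <- label
    res
  }
  if (is.null(group)) {
    one(features)
  } else {
    dplyr::bind_rows(lapply(split(features, features[[group]]),
                            function(f) one(f, f[[group]][1])))
  }
}
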