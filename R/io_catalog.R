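# Catalog I/O: VCF mobile-element records, RPKM expression tables, genome
# annotation, and the carrier-based catalog filter.
#
# Conventions: positions in the variant table are 1-based (VCF); every
# interval table (genes, regulatory features, cytobands, loci) is 0-based
# half-open. Dosages always count TE-*presence* alleles, so effect signs are
# comparable between insertion records and deletion-coded records (where the
# element is present in carriers but absent from the reference).

INFO_CLASS_MAP <- c(
  ALU = "Alu", LINE1 = "L1", SVA = "SVA",
  ALU_DEL = "Alu", LINE1_DEL = "L1", SVA_DEL = "SVA"
)

#' Read mobile-element variants from a VCF file
#'
#' Parses MEI records (INFO `SVTYPE` one of `ALU`, `LINE1`, `SVA` or their
#' `*_DEL` deletion-coded forms), converts genotypes to TE-presence dosages
#' and skips non-MEI records with a logged count. Genotype mapping: `0/0 ->
#' 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, `./. -> NA`; for `*_DEL` records the
#' ALT allele marks *absence* of the element, so the dosage is recoded to
#' `2 - ALT count`.
#'
#' @param path Path to a VCF 4.x file with per-sample GT fields.
#' @param samples Optional ordered character vector of sample ids to keep;
#'   defaults to all samples in the header. An id absent from the header is
#'   an error.
#' @return A tibble with one row per MEI record: `variant_id`, `chrom`,
#'   `pos` (1-based), `te_class`, `strand`, `deletion_coded`, `length`, and
#'   a `dosages` list-column of named integer vectors. The number of skipped
#'   non-MEI records is attached as attribute `n_skipped`.
#' @export
read_tev_vcf <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(vcf@gt) < 2 || !grepl("GT", vcf@gt[1, "FORMAT"])) {
    rlang::abort("VCF has no GT genotype column; cannot derive dosages.")
  }
  gt <- vcf@gt[, -1, drop = FALSE]
  if (is.null(samples)) {
    samples <- colnames(gt)
  } else {
    missing_s <- setdiff(samples, colnames(gt))
    if (length(missing_s) > 0) {
      rlang::abort(paste0("Samples absent from VCF header: ",
                          paste(missing_s, collapse = ", ")))
    }
    gt <- gt[, samples, drop = FALSE]
  }
  fix <- vcf@fix
  info <- fix[, "INFO"]
  svtype <- stringr::str_match(info, "(?:^|;)SVTYPE=([^;]+)")[, 2]
  keep <- !is.na(svtype) & svtype %in% names(INFO_CLASS_MAP)
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    rlang::inform(paste0("Skipped ", n_skipped, " non-MEI record(s)."))
  }
  if (!any(keep)) {
    out <- tibble::tibble(variant_id = character(0), chrom = character(0),
                          pos = integer(0), te_class = character(0),
                          strand = character(0), deletion_coded = logical(0),
                          length = integer(0), dosages = list())
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  svtype <- svtype[keep]
  info <- info[keep]

  svlen <- suppressWarnings(as.integer(stringr::str_match(info, "(?:^|;)SVLEN=(-?\\d+)")[, 2]))
  meinfo <- stringr::str_match(info, "(?:^|;)MEINFO=([^;]+)")[, 2]
  mei_parts <- stringr::str_split_fixed(meinfo, ",", 4)
  strand <- mei_parts[, 4]
  strand[!strand %in% c("+", "-")] <- "unknown"
  mei_len <- suppressWarnings(as.integer(mei_parts[, 3])) -
    suppressWarnings(as.integer(mei_parts[, 2])) + 1L
  length_bp <- abs(svlen)
  length_bp[is.na(length_bp)] <- mei_len[is.na(length_bp)]
  length_bp[is.na(length_bp) | length_bp < 1] <- 1L

  deletion_coded <- grepl("_DEL$", svtype)

  # Strip phasing and count ALT alleles from the GT subfield.
  gt_field <- sub(":.*", "", gt)
  a1 <- substr(gt_field, 1, 1)
  a2 <- substr(gt_field, 3, 3)
  alt <- matrix((a1 == "1") + (a2 == "1"), nrow = nrow(gt))
  alt[a1 == "." | a2 == "." | !nzchar(a2)] <- NA_integer_
  dos <- alt
  dos[deletion_coded, ] <- 2L - alt[deletion_coded, , drop = FALSE]

  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("tev_", which(is.na(ids) | ids == "."))
  dosages <- lapply(seq_len(nrow(dos)), function(i) {
    stats::setNames(as.integer(dos[i, ]), samples)
  })
  out <- tibble::tibble(
    variant_id = ids,
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    te_class = unname(INFO_CLASS_MAP[svtype]),
    strand = strand,
    deletion_coded = deletion_coded,
    length = as.integer(length_bp),
    dosages = dosages
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write mobile-element variants to a VCF file
#'
#' Inverse of [read_tev_vcf()]: emits symbolic-ALT MEI records with
#' `SVTYPE`, `SVLEN` and `MEINFO` INFO keys and per-sample GT fields.
#' Deletion-coded variants are written with `*_DEL` SVTYPE and ALT counts
#' `2 - dosage`, so a read/write round trip reproduces ids, classes and
#' dosages exactly.
#'
#' @param tevs Variant tibble (see [read_tev_vcf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tev_vcf <- function(tevs, path) {
  samples <- if (nrow(tevs) > 0) names(tevs$dosages[[1]]) else character(0)
  rev_map <- c(Alu = "ALU", L1 = "LINE1", SVA = "SVA")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tevr",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Mobile element class, *_DEL when the element is absent from the reference\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Element length in bp\">",
    "##INFO=<ID=MEINFO,Number=4,Type=String,Description=\"Mobile element info: NAME,START,END,POLARITY\">",
    "##ALT=<ID=INS:ME,Description=\"Mobile element insertion\">",
    "##ALT=<ID=DEL:ME,Description=\"Mobile element deletion (reference-absent element)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", samples),
          collapse = "\t")
  )
  gt_code <- function(alt) {
    out <- rep("./.", length(alt))
    out[!is.na(alt) & alt == 0] <- "0/0"
    out[!is.na(alt) & alt == 1] <- "0/1"
    out[!is.na(alt) & alt == 2] <- "1/1"
    out
  }
  records <- vapply(seq_len(nrow(tevs)), function(i) {
    del <- tevs$deletion_coded[i]
    svtype <- paste0(rev_map[[tevs$te_class[i]]], if (del) "_DEL" else "")
    alt_sym <- if (del) "<DEL:ME>" else "<INS:ME>"
    pol <- if (tevs$strand[i] %in% c("+", "-")) tevs$strand[i] else "."
    dos <- tevs$dosages[[i]][samples]
    alt_count <- if (del) 2L - dos else dos
    info <- sprintf("SVTYPE=%s;SVLEN=%d;MEINFO=%s,1,%d,%s",
                    svtype, tevs$length[i], rev_map[[tevs$te_class[i]]],
                    tevs$length[i], pol)
    paste(c(tevs$chrom[i], tevs$pos[i], tevs$variant_id[i], "N", alt_sym,
            ".", "PASS", info, "GT", gt_code(alt_count)), collapse = "\t")
  }, character(1))
  writeLines(c(header, records), path)
  invisible(path)
}

#' Filter variants by carrier count
#'
#' Retains variants carried (dosage >= 1) by at least `min_carriers`
#' samples, the catalog inclusion rule used throughout the analysis
#' (default: at least 3 carriers). Input order is preserved.
#'
#' @param tevs Variant tibble.
#' @param min_carriers Minimum number of carrier samples (>= 1).
#' @return The filtered tibble, with a `carrier_count` column added and the
#'   implied minimum carrier frequency (percent, attribute
#'   `implied_min_carrier_freq_pct`).
#' @seealso [implied_carrier_frequency()]
#' @export
filter_by_carriers <- function(tevs, min_carriers = 3L) {
  if (min_carriers < 1) rlang::abort("`min_carriers` must be >= 1.")
  cc <- carrier_counts(tevs)
  out <- tevs
  out$carrier_count <- cc
  out <- out[cc >= min_carriers, , drop = FALSE]
  n_samples <- if (nrow(tevs) > 0) length(tevs$dosages[[1]]) else NA_integer_
  freq <- implied_carrier_frequency(min_carriers, n_samples)
  rlang::inform(sprintf(
    "Kept %d/%d variants with >= %d carriers (implied minimum carrier frequency %.1f%%).",
    nrow(out), nrow(tevs), min_carriers, freq))
  attr(out, "implied_min_carrier_freq_pct") <- freq
  out
}

#' Carrier frequency implied by an inclusion threshold
#'
#' @param min_carriers Carrier threshold (e.g. 3).
#' @param n_samples Cohort size (e.g. 445).
#' @param digits Decimal places for rounding (default 1).
#' @return The minimum carrier frequency as a percentage; `3` of `445`
#'   gives `0.7`.
#' @export
implied_carrier_frequency <- function(min_carriers, n_samples, digits = 1) {
  round(100 * min_carriers / n_samples, digits)
}

#' Read a gene-by-sample RPKM expression table
#'
#' Expects a TSV with a gene-id column followed by one numeric column per
#' sample (Geuvadis-style annotation columns such as `Gene_Symbol`, `Chr`,
#' `Coord` are dropped). Values must be non-negative.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `gene_id` plus one column per sample.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1] <- "gene_id"
  drop <- intersect(names(df), c("Gene_Symbol", "Chr", "Coord"))
  df <- df[, setdiff(names(df), drop)]
  if (anyDuplicated(df$gene_id)) rlang::abort("Duplicated gene ids in expression table.")
  vals <- as.matrix(df[, -1])
  if (!is.numeric(vals)) rlang::abort("Expression columns must be numeric.")
  if (any(vals < 0, na.rm = TRUE)) rlang::abort("Negative expression values found.")
  tibble::as_tibble(df)
}

#' Align expression, genotypes and sample metadata on common samples
#'
#' Keeps only samples present in all three inputs, in the order of
#' `samples$sample_id`, and logs how many were dropped from each input.
#'
#' @param expression Expression tibble from [read_expression()].
#' @param tevs Variant tibble.
#' @param samples Sample metadata tibble (`sample_id`, `sex`, `population`).
#' @return A list with elements `expression`, `tevs`, `samples`, all
#'   restricted to the common samples in one canonical order.
#' @export
align_samples <- function(expression, tevs, samples) {
  expr_s <- setdiff(names(expression), "gene_id")
  tev_s <- if (nrow(tevs) > 0) names(tevs$dosages[[1]]) else character(0)
  common <- samples$sample_id[samples$sample_id %in% expr_s & samples$sample_id %in% tev_s]
  if (length(common) == 0) {
    rlang::abort("No samples are shared between expression, genotypes and metadata.")
  }
  dropped <- c(expression = length(expr_s), tevs = length(tev_s),
               samples = nrow(samples)) - length(common)
  if (any(dropped > 0)) {
    rlang::inform(sprintf(
      "Aligned on %d common samples (dropped: %d expression, %d genotype, %d metadata).",
      length(common), dropped[["expression"]], dropped[["tevs"]], dropped[["samples"]]))
  }
  tevs2 <- tevs
  tevs2$dosages <- lapply(tevs$dosages, function(d) d[common])
  list(
    expression = expression[, c("gene_id", common)],
    tevs = tevs2,
    samples = samples[match(common, samples$sample_id), , drop = FALSE]
  )
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `sex`, `population`.
#' @return A tibble; duplicated ids or missing covariates are errors.
#' @export
read_sample_info <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "sex", "population")
  if (!all(req %in% names(df))) {
    rlang::abort("Sample table must have columns sample_id, sex, population.")
  }
  if (anyDuplicated(df$sample_id)) rlang::abort("Duplicated sample ids.")
  if (anyNA(df[req])) rlang::abort("Missing sex or population covariates.")
  tibble::as_tibble(df[req])
}

#' Read a UCSC cytoBand table
#'
#' Five-column headerless TSV (`chrom`, `chromStart`, `chromEnd`, `name`,
#' `gieStain`). Coordinates are already 0-based half-open and pass through;
#' the band name is composed as e.g. `"17q21.31"`.
#'
#' @param path Path to a cytoBand TSV.
#' @return Tibble with `chrom`, `start`, `end`, `band_name`, `stain`.
#' @export
read_cytobands <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "band", "stain"),
                        show_col_types = FALSE, progress = FALSE)
  bad <- which(df$end <= df$start)
  if (length(bad) > 0) {
    rlang::abort(paste0("cytoBand line ", bad[1], ": end <= start."))
  }
  tibble::tibble(
    chrom = df$chrom,
    start = as.numeric(df$start),
    end = as.numeric(df$end),
    band_name = paste0(sub("^chr", "", df$chrom), df$band),
    stain = df$stain
  ) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Read gene models from GTF or BED
#'
#' GTF input (1-based closed) is shifted to the internal 0-based half-open
#' convention; BED passes through. For GTF, gene substructure is assembled
#' from `five_prime_utr`, `three_prime_utr` and `exon` rows: UTR intervals
#' are subtracted from exons, and gaps within the gene span become introns,
#' so the substructure partitions each gene without overlaps. BED genes have
#' empty substructure.
#'
#' @param path Path to a `.gtf` or `.bed` file.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `biotype` and a `substructure` list-column of
#'   `(feature, start, end)` tibbles in genomic order.
#' @export
read_gene_annotation <- function(path) {
  fmt <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gtf"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "bed") {
    return(tibble::tibble(
      gene_id = as.character(gr$name %||% paste0("gene_", seq_along(gr))),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = as.numeric(GenomicRanges::start(gr)) - 1,
      end = as.numeric(GenomicRanges::end(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      biotype = "other",
      substructure = replicate(length(gr), empty_substructure(), simplify = FALSE)
    ))
  }
  md <- S4Vectors::mcols(gr)
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.numeric(GenomicRanges::start(gr)) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene_id = as.character(md$gene_id),
    biotype = as.character(md$gene_biotype %||% rep(NA_character_, length(gr)))
  )
  bad <- which(df$end <= df$start)
  if (length(bad) > 0) rlang::abort(paste0("Annotation line ", bad[1], ": end <= start after normalization."))
  genes <- df[df$type == "gene", , drop = FALSE]
  feats <- df[df$type %in% c("five_prime_utr", "three_prime_utr", "exon"), , drop = FALSE]
  sub_list <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    f <- feats[feats$gene_id == g$gene_id, , drop = FALSE]
    build_substructure(g$start, g$end, f)
  })
  tibble::tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = genes$start,
    end = genes$end,
    strand = genes$strand,
    biotype = normalize_biotype(genes$biotype),
    substructure = sub_list
  )
}

empty_substructure <- function() {
  tibble::tibble(feature = character(0), start = numeric(0), end = numeric(0))
}

normalize_biotype <- function(x) {
  out <- rep("other", length(x))
  out[x %in% "protein_coding"] <- "protein_coding"
  out[grepl("pseudogene", x)] <- "pseudogene"
  out[x %in% c("lincRNA", "lncRNA")] <- "lincRNA"
  out[x %in% "antisense"] <- "antisense"
  out[is.na(x)] <- "other"
  out
}

# Assemble a non-overlapping feature partition of [gene_start, gene_end)
# from possibly-overlapping exon/UTR rows; uncovered gaps become introns.
build_substructure <- function(gene_start, gene_end, feats) {
  ir <- function(d) IRanges::IRanges(start = d$start + 1, end = d$end)
  utr5 <- IRanges::reduce(ir(feats[feats$type == "five_prime_utr", ]))
  utr3 <- IRanges::reduce(ir(feats[feats$type == "three_prime_utr", ]))
  exon <- IRanges::reduce(ir(feats[feats$type == "exon", ]))
  exon <- IRanges::setdiff(exon, IRanges::union(utr5, utr3))
  span <- IRanges::IRanges(start = gene_start + 1, end = gene_end)
  covered <- IRanges::reduce(c(utr5, utr3, exon))
  intron <- IRanges::setdiff(span, covered)
  piece <- function(x, lab) {
    if (length(x) == 0) return(empty_substructure())
    tibble::tibble(feature = lab, start = IRanges::start(x) - 1, end = IRanges::end(x))
  }
  dplyr::bind_rows(
    piece(utr5, "five_prime_utr"),
    piece(exon, "exon"),
    piece(intron, "intron"),
    piece(utr3, "three_prime_utr")
  ) |>
    dplyr::arrange(.data$start)
}

#' Read regulatory feature intervals
#'
#' Accepts BED (pass-through coordinates) or GFF3 (shifted from 1-based
#' closed to 0-based half-open).
#'
#' @param path Path to a `.bed` or `.gff`/`.gff3` file.
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_regulatory <- function(path) {
  fmt <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.numeric(GenomicRanges::start(gr)) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
  bad <- which(out$end <= out$start)
  if (length(bad) > 0) rlang::abort(paste0("Regulatory line ", bad[1], ": end <= start after normalization."))
  out
}
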