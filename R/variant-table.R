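#' Build a validated variant count table
#'
#' A variant table holds, for each somatic variant and each sample, the total
#' read depth and the alternate-allele read count, from which variant allele
#' frequencies (VAFs) are derived. It is stored as a tibble with one row per
#' variant: the locus columns `chrom`, `pos`, `ref`, `alt`, an optional Phred
#' base-quality column `bq`, and per-sample count columns `<id>_total`,
#' `<id>_alt`.
#'
#' @param data A data frame with the columns described above.
#' @param sample_ids Character vector of sample identifiers. Defaults to the
#'   ids inferred from `<id>_total` / `<id>_alt` column pairs.
#' @param sample_sex Named character vector giving `"male"`, `"female"` or
#'   `"unknown"` per sample; unnamed entries are matched positionally.
#'   Defaults to `"unknown"`.
#'
#' @return A tibble of class `variant_table` carrying the sample ids, sexes
#'   and a sex-chromosome calibration flag as attributes.
#' @export
#' @examples
#' tb <- tibble::tibble(
#'   chrom = c("1", "2"), pos = c(100L, 200L), ref = c("A", "C"),
#'   alt = c("T", "G"), s1_total = c(100L, 120L), s1_alt = c(20L, 55L)
#' )
#' variant_table(tb)
variant_table <- function(data, sample_ids = NULL, sample_sex = NULL) {
  data <- tibble::as_tibble(data)
  req <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(sample_ids)) {
    tot <- sub("_total$", "", grep("_total$", names(data), value = TRUE))
    alt <- sub("_alt$", "", grep("_alt$", names(data), value = TRUE))
    sample_ids <- intersect(tot, alt)
  }
  if (length(sample_ids) < 1) {
    stop("no per-sample '<id>_total' / '<id>_alt' column pairs found",
         call. = FALSE)
  }
  for (id in sample_ids) {
    for (col in paste0(id, c("_total", "_alt"))) {
      if (!col %in% names(data)) {
        stop("missing count column: ", col, call. = FALSE)
      }
      x <- data[[col]]
      if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != floor(x))) {
        bad <- which(is.na(x) | x < 0 | x != floor(x))[1]
        stop("column ", col, ": counts must be non-negative integers (row ",
             bad %||% 1L, ")", call. = FALSE)
      }
      data[[col]] <- as.integer(x)
    }
    over <- which(data[[paste0(id, "_alt")]] > data[[paste0(id, "_total")]])
    if (length(over) > 0) {
      stop("sample '", id, "': alternate count exceeds total count at row(s) ",
           paste(head(over, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(data) < 1) stop("variant table must contain at least one variant",
                           call. = FALSE)
  sex <- rep("unknown", length(sample_ids))
  names(sex) <- sample_ids
  if (!is.null(sample_sex)) {
    sample_sex <- tolower(as.character(sample_sex))
    bad_sex <- setdiff(sample_sex, c("male", "female", "unknown"))
    if (length(bad_sex) > 0) {
      stop("sample_sex values must be male/female/unknown", call. = FALSE)
    }
    if (is.null(names(sample_sex))) {
      sex[seq_along(sample_sex)] <- sample_sex
    } else {
      sex[intersect(names(sample_sex), sample_ids)] <-
        sample_sex[intersect(names(sample_sex), sample_ids)]
    }
  }
  structure(
    data,
    class = c("variant_table", class(tibble::tibble())),
    sample_ids = sample_ids,
    sample_sex = sex,
    calibrated = FALSE
  )
}

#' Read a variant table from a tab-separated file
#'
#' The expected dialect is one wide TSV: header columns `CHROM POS REF ALT`,
#' then `<id>_total` and `<id>_alt` for every sample, and an optional `BQ`
#' column with per-variant Phred base qualities. When `BQ` is absent the
#' sequencing-error probability later defaults to 0.01 (Phred 20).
#'
#' @param path Path to the TSV file.
#' @inheritParams variant_table
#' @return A [variant_table].
#' @export
read_variant_table <- function(path, sample_sex = NULL) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  fixed <- c("CHROM", "POS", "REF", "ALT")
  if (!all(fixed %in% hdr)) {
    stop("malformed header: expected columns CHROM POS REF ALT, got: ",
         paste(head(hdr, 8), collapse = " "), call. = FALSE)
  }
  raw <- readr::read_tsv(
    path, progress = FALSE,
    col_types = readr::cols(CHROM = readr::col_character(),
                            REF = readr::col_character(),
                            ALT = readr::col_character()))
  names(raw)[match(fixed, names(raw))] <- c("chrom", "pos", "ref", "alt")
  if ("BQ" %in% names(raw)) names(raw)[names(raw) == "BQ"] <- "bq"
  raw$chrom <- as.character(raw$chrom)
  variant_table(raw, sample_sex = sample_sex)
}

#' Write a variant table to a tab-separated file
#'
#' Inverse of [read_variant_table()]; the round trip preserves counts exactly.
#'
#' @param table A [variant_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(table, path) {
  out <- tibble::as_tibble(table)
  names(out)[match(c("chrom", "pos", "ref", "alt"), names(out))] <-
    c("CHROM", "POS", "REF", "ALT")
  if ("bq" %in% names(out)) names(out)[names(out) == "bq"] <- "BQ"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("# variant_table: %d variants x %d samples (%s)\n",
              nrow(x), length(sample_ids(x)),
              paste(sample_ids(x), collapse = ", ")))
  NextMethod()
}

#' Sample identifiers of a variant table
#' @param table A [variant_table].
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(table) attr(table, "sample_ids")

#' Variant identifiers (`chrom:pos:ref:alt`)
#' @param table A [variant_table].
#' @return Character vector, one id per variant.
#' @export
variant_ids <- function(table) {
  paste(table$chrom, table$pos, table$ref, table$alt, sep = ":")
}

count_matrix <- function(table, what = c("total", "alt")) {
  what <- match.arg(what)
  ids <- sample_ids(table)
  m <- t(as.matrix(tibble::as_tibble(table)[paste0(ids, "_", what)]))
  rownames(m) <- ids
  colnames(m) <- variant_ids(table)
  storage.mode(m) <- "integer"
  m
}

#' Extract count matrices
#'
#' @param table A [variant_table].
#' @return An `m x n` integer matrix (samples by variants).
#' @export
total_counts <- function(table) count_matrix(table, "total")

#' @rdname total_counts
#' @export
alt_counts <- function(table) count_matrix(table, "alt")

#' Per-variant sequencing-error probabilities
#'
#' Converts Phred base qualities to error probabilities with
#' `p = 10^(-BQ/10)` (so BQ 20 gives 0.01). Variants without a base quality
#' get `default`.
#'
#' @param table A [variant_table].
#' @param default Error probability used when no base quality is available.
#' @return Numeric vector of length `n`.
#' @export
p_se_values <- function(table, default = 0.01) {
  n <- nrow(table)
  if (!"bq" %in% names(table)) return(rep(default, n))
  p <- 10^(-as.numeric(table$bq) / 10)
  p[is.na(p)] <- default
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

is_sex_chromosome <- function(chrom) {
  toupper(sub("^chr", "", chrom, ignore.case = TRUE)) %in% c("X", "Y")
}

#' Calibrate sex-chromosome read depth
#'
#' Variants on chrX/chrY in male samples are haploid; their total read counts
#' are doubled so that the diploid VAF model (heterozygous variants at VAF
#' 0.5 per fully clonal mutation) applies uniformly. Alternate counts are
#' unchanged. The operation is guarded by a calibration flag so that applying
#' it twice is a warning no-op.
#'
#' @param table A [variant_table].
#' @return The calibrated [variant_table].
#' @export
calibrate_sex_chromosomes <- function(table) {
  if (isTRUE(attr(table, "calibrated"))) {
    warning("variant table already sex-calibrated; returning unchanged")
    return(table)
  }
  sexchr <- is_sex_chromosome(table$chrom)
  sex <- attr(table, "sample_sex")
  if (any(sexchr) && any(sex == "unknown")) {
    warning("sex-chromosome variants present but sample sex unknown for: ",
            paste(names(sex)[sex == "unknown"], collapse = ", "),
            "; depths left uncalibrated for those samples")
  }
  for (id in names(sex)[sex == "male"]) {
    col <- paste0(id, "_total")
    table[[col]][sexchr] <- 2L * table[[col]][sexchr]
  }
  attr(table, "calibrated") <- TRUE
  table
}

#' Variant allele frequency matrix
#'
#' `f = alt / total`, defined as 0 at zero depth.
#'
#' @param table A [variant_table] (ordinarily sex-calibrated first).
#' @return An `m x n` numeric matrix of VAFs in `[0, 1]`.
#' @export
compute_vaf <- function(table) {
  tot <- total_counts(table)
  alt <- alt_counts(table)
  f <- ifelse(tot == 0L, 0, alt / pmax(tot, 1L))
  dimnames(f) <- dimnames(tot)
  f
}
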