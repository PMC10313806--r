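#' Canonical summary-statistic field names
#'
#' The canonical per-variant fields used throughout the package. Required
#' fields must be mapped in every [column_map()]; `chrom`/`pos` become
#' required only when distance-based clumping is requested, and `eaf`/`n`
#' are optional throughout (but without `eaf`, palindromic SNPs cannot be
#' strand-resolved and are dropped at harmonization).
#'
#' @keywords internal
CANONICAL_FIELDS <- c("variant_id", "chrom", "pos", "effect_allele",
                      "other_allele", "eaf", "beta", "se", "pvalue", "n")

REQUIRED_FIELDS <- c("variant_id", "effect_allele", "other_allele",
                     "beta", "se", "pvalue")

NUMERIC_FIELDS <- c("pos", "eaf", "beta", "se", "pvalue", "n")

#' Column map for delimited GWAS summary-statistic files
#'
#' Describes how the canonical fields map onto the columns of a source file.
#' The delimiter is always explicit: no auto-detection is attempted, so a
#' run is reproducible from its configuration alone.
#'
#' @param ... named arguments `canonical = "source column header"`. Names
#'   must be canonical field names; every required field
#'   (`variant_id`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`)
#'   must be mapped. Unmapped optional fields are read as missing.
#' @param delimiter single field-separator character (default tab).
#' @param missing_token string that encodes a missing value (default "NA").
#' @return an object of class `column_map`.
#' @examples
#' cm <- column_map(variant_id = "SNP", effect_allele = "A1",
#'                  other_allele = "A2", beta = "BETA", se = "SE",
#'                  pvalue = "P", delimiter = "\t")
#' @export
column_map <- function(..., delimiter = "\t", missing_token = "NA") {
  mapping <- list(...)
  if (length(mapping) == 0L) {
    mapping <- as.list(stats::setNames(CANONICAL_FIELDS, CANONICAL_FIELDS))
  }
  bad <- setdiff(names(mapping), CANONICAL_FIELDS)
  if (length(bad) > 0L) {
    stop("unknown canonical field(s) in column map: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  missing_req <- setdiff(REQUIRED_FIELDS, names(mapping))
  if (length(missing_req) > 0L) {
    stop("column map must map required field(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  if (!is.character(delimiter) || nchar(delimiter) != 1L) {
    stop("delimiter must be a single character", call. = FALSE)
  }
  structure(list(mapping = lapply(mapping, as.character),
                 delimiter = delimiter,
                 missing_token = missing_token),
            class = "column_map")
}

#' Default column map: canonical headers, tab-delimited
#' @rdname column_map
#' @export
default_column_map <- function() column_map()

#' Validate one variant association record
#'
#' Checks the per-record invariants and returns human-readable violation
#' descriptions rather than raising, so callers can count and report
#' rejected rows.
#'
#' @param rec a named list or one-row data frame with (a subset of) the
#'   canonical fields.
#' @return character vector of violations; empty when the record is valid.
#' @examples
#' validate_record(list(variant_id = "rs1", effect_allele = "A",
#'                      other_allele = "G", beta = 0.1, se = 0.02,
#'                      pvalue = 0.5))
#' @export
validate_record <- function(rec) {
  rec <- as.list(rec)
  v <- character(0)
  get <- function(f) if (is.null(rec[[f]])) NA else rec[[f]]
  ea <- toupper(as.character(get("effect_allele")))
  oa <- toupper(as.character(get("other_allele")))
  if (is.na(ea) || is.na(oa) || !nzchar(ea) || !nzchar(oa)) {
    v <- c(v, "missing allele")
  } else {
    if (identical(ea, oa)) v <- c(v, "effect_allele equals other_allele")
    if (grepl("[^ACGT]", ea) || grepl("[^ACGT]", oa)) {
      v <- c(v, "allele contains non-ACGT character")
    }
  }
  se <- suppressWarnings(as.numeric(get("se")))
  if (is.na(se)) v <- c(v, "unparseable or missing SE")
  else if (se <= 0) v <- c(v, "nonpositive SE")
  beta <- suppressWarnings(as.numeric(get("beta")))
  if (is.na(beta)) v <- c(v, "unparseable or missing beta")
  p <- suppressWarnings(as.numeric(get("pvalue")))
  if (is.na(p)) v <- c(v, "unparseable or missing pvalue")
  else if (p <= 0 || p > 1) v <- c(v, "pvalue out of (0,1]")
  eaf <- suppressWarnings(as.numeric(get("eaf")))
  if (!is.null(rec[["eaf"]]) && !is.na(rec[["eaf"]]) && !is.na(eaf)) {
    if (eaf < 0 || eaf > 1) v <- c(v, "eaf out of [0,1]")
  }
  v
}

#' Construct a summary-statistics object from a records data frame
#'
#' @param records data frame with canonical columns (missing optional
#'   columns are added as NA). Alleles are uppercased.
#' @param trait_name trait label, e.g. "PCL-Total".
#' @param trait_type `"binary"` (betas on the log-odds scale) or
#'   `"quantitative"` (per-SD units).
#' @param ancestry ancestry label, e.g. "African", "European".
#' @return object of class `summary_stats`: a list with `records` (data
#'   frame, unique `variant_id`), the trait metadata and a `rejected`
#'   report data frame.
#' @export
summary_stats <- function(records, trait_name, trait_type = c("quantitative", "binary"),
                          ancestry = "unspecified") {
  trait_type <- match.arg(trait_type)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (f in setdiff(CANONICAL_FIELDS, names(records))) records[[f]] <- NA
  records <- records[, CANONICAL_FIELDS]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (f in NUMERIC_FIELDS) records[[f]] <- as.numeric(records[[f]])
  dup <- unique(records$variant_id[duplicated(records$variant_id)])
  if (length(dup) > 0L) {
    stop("duplicate variant_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  rownames(records) <- NULL
  structure(list(records = records, trait_name = trait_name,
                 trait_type = trait_type, ancestry = ancestry,
                 rejected = empty_rejection_report()),
            class = "summary_stats")
}

empty_rejection_report <- function() {
  data.frame(row = integer(0), variant_id = character(0),
             reason = character(0), stringsAsFactors = FALSE)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s, %s ancestry)\n",
              x$trait_name, x$trait_type, x$ancestry))
  cat(sprintf("  %d records, %d rejected rows\n",
              nrow(x$records), nrow(x$rejected)))
  invisible(x)
}

#' Number of records in a summary_stats object
#' @param stats a `summary_stats` object.
#' @export
n_records <- function(stats) nrow(stats$records)

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a header-plus-rows delimited table, remaps columns through a
#' [column_map()], validates each row against the record invariants, and
#' returns the valid rows as a [summary_stats()] object. Invalid rows are
#' not silently dropped: they are counted in the returned object's
#' `rejected` report (row number, variant id, reason) and a summary is
#' messaged.
#'
#' @param path path to the file.
#' @param col_map a [column_map()]; defaults to canonical tab-delimited.
#' @param trait_name,trait_type,ancestry trait metadata, see
#'   [summary_stats()].
#' @return a `summary_stats` object; `$rejected` holds the row-level
#'   validation failures.
#' @export
read_summary_stats <- function(path, col_map = default_column_map(),
                               trait_name, trait_type = c("quantitative", "binary"),
                               ancestry = "unspecified") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = col_map$delimiter,
                           na.strings = col_map$missing_token,
                           colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  absent <- setdiff(unlist(col_map$mapping[names(col_map$mapping) %in%
                                             c(REQUIRED_FIELDS)]),
                    names(raw))
  if (length(absent) > 0L) {
    stop("required column(s) missing from header of ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  recs <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in CANONICAL_FIELDS) {
    src <- col_map$mapping[[f]]
    recs[[f]] <- if (!is.null(src) && src %in% names(raw)) raw[[src]] else NA
  }
  reasons <- vapply(seq_len(nrow(recs)), function(i) {
    paste(validate_record(recs[i, , drop = FALSE]), collapse = "; ")
  }, character(1))
  ok <- !nzchar(reasons)
  rejected <- data.frame(row = which(!ok),
                         variant_id = as.character(recs$variant_id[!ok]),
                         reason = reasons[!ok], stringsAsFactors = FALSE)
  dup <- unique(recs$variant_id[ok][duplicated(recs$variant_id[ok])])
  if (length(dup) > 0L) {
    stop("duplicate variant_id in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  out <- summary_stats(recs[ok, , drop = FALSE], trait_name = trait_name,
                       trait_type = trait_type, ancestry = ancestry)
  out$rejected <- rejected
  if (nrow(rejected) > 0L) {
    message(sprintf("read_summary_stats: %d of %d rows rejected (%s)",
                    nrow(rejected), nrow(raw),
                    paste(unique(rejected$reason), collapse = " | ")))
  }
  out
}

#' Write GWAS summary statistics to a delimited text file
#'
#' Writes a header plus one row per record, numeric fields at full
#' precision (15 significant digits), so that a read/write round-trip is
#' the identity to well below 1e-12.
#'
#' @param stats a non-empty `summary_stats` object.
#' @param path output path.
#' @param col_map a [column_map()] giving the output headers and delimiter.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path, col_map = default_column_map()) {
  stopifnot(inherits(stats, "summary_stats"))
  if (nrow(stats$records) == 0L) {
    stop("refusing to write empty summary statistics", call. = FALSE)
  }
  out <- stats$records
  for (f in NUMERIC_FIELDS) {
    out[[f]] <- ifelse(is.na(out[[f]]), col_map$missing_token,
                       sprintf("%.15g", out[[f]]))
  }
  for (f in c("variant_id", "chrom", "effect_allele", "other_allele")) {
    out[[f]] <- ifelse(is.na(out[[f]]), col_map$missing_token, out[[f]])
  }
  keep <- names(col_map$mapping)
  out <- out[, keep, drop = FALSE]
  names(out) <- unlist(col_map$mapping[keep])
  utils::write.table(out, path, sep = col_map$delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
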