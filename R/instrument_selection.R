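#' Filter summary statistics by association p-value
#'
#' Retains exactly the records with `pvalue < p_threshold` (strict
#' inequality), preserving input order. The default threshold is the
#' suggestive 5e-7 used when too few variants reach genome-wide
#' significance.
#'
#' @param stats a `summary_stats` object.
#' @param p_threshold retain records with p strictly below this value.
#' @return a `summary_stats` object with the surviving records.
#' @export
filter_by_pvalue <- function(stats, p_threshold = 5e-7) {
  stopifnot(inherits(stats, "summary_stats"))
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    stop("p_threshold must be in (0,1]", call. = FALSE)
  }
  keep <- !is.na(stats$records$pvalue) & stats$records$pvalue < p_threshold
  out <- stats
  out$records <- stats$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Read a plain-text LD r-squared matrix
#'
#' Square whitespace/tab-delimited matrix with a header row of variant IDs;
#' validated to be symmetric with unit diagonal and entries in [0,1].
#'
#' @param path path to the matrix file.
#' @return numeric matrix with variant-ID dimnames.
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, check.names = FALSE))
  rownames(m) <- colnames(m)
  validate_ld_matrix(m)
  m
}

validate_ld_matrix <- function(m) {
  if (nrow(m) != ncol(m)) stop("LD matrix must be square", call. = FALSE)
  if (is.null(colnames(m))) stop("LD matrix needs variant-ID dimnames", call. = FALSE)
  if (any(abs(m - t(m)) > 1e-8)) stop("LD matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(m) - 1) > 1e-8)) stop("LD matrix diagonal must be 1", call. = FALSE)
  if (any(m < -1e-12 | m > 1 + 1e-12)) stop("LD r2 entries must lie in [0,1]", call. = FALSE)
  invisible(m)
}

#' Greedy LD/distance clumping of p-filtered summary statistics
#'
#' Repeatedly takes the remaining record with the smallest p-value as an
#' index SNP and removes every remaining record on the same chromosome
#' within `window_kb` of it that (when `ld` is supplied) has r-squared at
#' or above `r2_threshold` with the index. Without an LD matrix, distance
#' alone removes (conservative) and a warning is logged. P-value ties are
#' broken by (chrom, pos, variant_id) so the result does not depend on the
#' input row order.
#'
#' @param stats a p-filtered `summary_stats` object; all records need
#'   `chrom` and `pos`.
#' @param window_kb clumping window in kilobases; "within" is the closed
#'   interval |pos - pos_index| <= window_kb * 1000 on the same chromosome.
#' @param r2_threshold remove neighbours with r2 >= this value (only when
#'   `ld` is supplied).
#' @param ld optional LD matrix (variant IDs in dimnames) covering every
#'   record; an uncovered variant is an error.
#' @return `summary_stats` holding the index SNPs in selection order.
#' @export
clump <- function(stats, window_kb = 1000, r2_threshold = 0.01, ld = NULL) {
  stopifnot(inherits(stats, "summary_stats"))
  if (window_kb <= 0) stop("window_kb must be positive", call. = FALSE)
  if (r2_threshold < 0 || r2_threshold > 1) stop("r2_threshold must be in [0,1]", call. = FALSE)
  rec <- stats$records
  if (nrow(rec) == 0L) return(stats)
  if (anyNA(rec$chrom) || anyNA(rec$pos)) {
    stop("clumping requires chrom and pos on every record", call. = FALSE)
  }
  if (!is.null(ld)) {
    validate_ld_matrix(ld)
    missing_ld <- setdiff(rec$variant_id, colnames(ld))
    if (length(missing_ld) > 0L) {
      stop("LD matrix missing variant(s): ",
           paste(missing_ld, collapse = ", "), call. = FALSE)
    }
  } else {
    warning("no LD matrix supplied; clumping by distance alone (conservative)",
            call. = FALSE)
  }
  ord <- order(rec$pvalue, rec$chrom, rec$pos, rec$variant_id)
  rec <- rec[ord, , drop = FALSE]
  remaining <- rep(TRUE, nrow(rec))
  index <- integer(0)
  for (i in seq_len(nrow(rec))) {
    if (!remaining[i]) next
    index <- c(index, i)
    near <- remaining & rec$chrom == rec$chrom[i] &
      abs(rec$pos - rec$pos[i]) <= window_kb * 1000
    near[i] <- FALSE
    if (!is.null(ld)) {
      r2 <- ld[rec$variant_id[i], rec$variant_id]
      near <- near & r2 >= r2_threshold
    }
    remaining[near] <- FALSE
  }
  out <- stats
  out$records <- rec[index, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Single-SNP F-statistic for instrument strength
#'
#' The (beta/se)^2 approximation, which needs no allele frequency or sample
#' size. When `method = "variance_explained"` and both `eaf` and `n` are
#' available, the variance-explained route is used instead:
#' R2 = 2 maf (1-maf) beta^2 and F = R2 (n - 2) / (1 - R2), appropriate for
#' standardized quantitative-trait betas.
#'
#' @param beta per-allele effect estimate(s).
#' @param se standard error(s), strictly positive.
#' @param method `"ratio"` (default) or `"variance_explained"`.
#' @param eaf,n effect-allele frequency and sample size, required for the
#'   variance-explained route.
#' @return numeric vector of F-statistics (strictly positive).
#' @export
f_statistic <- function(beta, se, method = c("ratio", "variance_explained"),
                        eaf = NULL, n = NULL) {
  method <- match.arg(method)
  if (any(is.na(se)) || any(se <= 0)) stop("se must be > 0", call. = FALSE)
  if (method == "ratio") return((beta / se)^2)
  if (is.null(eaf) || is.null(n) || anyNA(eaf) || anyNA(n)) {
    stop("variance_explained F requires eaf and n", call. = FALSE)
  }
  maf <- pmin(eaf, 1 - eaf)
  r2 <- 2 * maf * (1 - maf) * beta^2
  r2 * (n - 2) / (1 - r2)
}

#' Instrument-strength report for a set of instruments
#'
#' Per-SNP F-statistics with summary minimum and mean; the conventional
#' weak-instrument screen is F > 10 for every instrument.
#'
#' @param stats a non-empty `summary_stats` object (typically the clumped
#'   instrument set).
#' @return list of class `instrument_report`: `per_snp` data frame
#'   (variant_id, f), `min_f`, `mean_f`.
#' @seealso [all_above()]
#' @export
instrument_report <- function(stats) {
  stopifnot(inherits(stats, "summary_stats"))
  if (nrow(stats$records) == 0L) stop("no instruments to report on", call. = FALSE)
  f <- f_statistic(stats$records$beta, stats$records$se)
  structure(list(per_snp = data.frame(variant_id = stats$records$variant_id,
                                      f = f, stringsAsFactors = FALSE),
                 min_f = min(f), mean_f = mean(f)),
            class = "instrument_report")
}

#' Do all instruments clear an F-statistic threshold?
#' @param report an [instrument_report()].
#' @param threshold F threshold (default 10, the conventional screen).
#' @return logical scalar.
#' @export
all_above <- function(report, threshold = 10) {
  stopifnot(inherits(report, "instrument_report"))
  report$min_f > threshold
}

#' @export
print.instrument_report <- function(x, ...) {
  cat(sprintf("instrument strength: %d SNPs, min F = %.2f, mean F = %.2f, all F > 10: %s\n",
              nrow(x$per_snp), x$min_f, x$mean_f, all_above(x)))
  invisible(x)
}
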