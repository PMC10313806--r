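COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_allele <- function(a) {
  if (grepl("[^ACGT]", a)) return(NA_character_)
  paste(rev(unname(COMPLEMENT[strsplit(a, "")[[1]]])), collapse = "")
}

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so strand orientation
#' cannot be resolved from the alleles alone. Multi-character (indel)
#' alleles are never palindromic.
#'
#' @param effect_allele,other_allele allele strings.
#' @return logical.
#' @examples
#' is_palindromic("A", "T")  # TRUE
#' is_palindromic("A", "G")  # FALSE
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  mapply(function(ea, oa) {
    if (nchar(ea) != 1L || nchar(oa) != 1L) return(FALSE)
    s <- paste(sort(c(ea, oa)), collapse = "")
    s %in% c("AT", "CG")
  }, toupper(effect_allele), toupper(other_allele), USE.NAMES = FALSE)
}

#' Classify the allele relationship between two records of one variant
#'
#' Compares the outcome record's allele coding with the exposure record's
#' and classifies the action needed to put both on the same effect allele:
#' `aligned` (same alleles, same order), `sign_flipped` (alleles swapped:
#' negate the outcome beta, complement its frequency), `strand_flipped`
#' (reverse-complement pair, same orientation), `strand_and_sign_flipped`,
#' or `dropped_incompatible` when the allele sets cannot be reconciled.
#' For palindromic pairs the allele comparison alone is ambiguous between
#' the plain and the strand-flipped reading; [harmonize()] resolves that
#' ambiguity with allele frequencies.
#'
#' @param exp_ea,exp_oa exposure effect/other alleles.
#' @param out_ea,out_oa outcome effect/other alleles.
#' @return one action string.
#' @export
align_alleles <- function(exp_ea, exp_oa, out_ea, out_oa) {
  exp_ea <- toupper(exp_ea); exp_oa <- toupper(exp_oa)
  out_ea <- toupper(out_ea); out_oa <- toupper(out_oa)
  if (identical(out_ea, exp_ea) && identical(out_oa, exp_oa)) return("aligned")
  if (identical(out_ea, exp_oa) && identical(out_oa, exp_ea)) return("sign_flipped")
  rc_ea <- revcomp_allele(exp_ea)
  rc_oa <- revcomp_allele(exp_oa)
  if (!is.na(rc_ea) && !is.na(rc_oa)) {
    if (identical(out_ea, rc_ea) && identical(out_oa, rc_oa)) return("strand_flipped")
    if (identical(out_ea, rc_oa) && identical(out_oa, rc_ea)) return("strand_and_sign_flipped")
  }
  "dropped_incompatible"
}

#' Harmonize exposure and outcome summary statistics onto a common allele
#'
#' For each exposure instrument, finds the matching outcome record by
#' variant ID and aligns its effect to the exposure's effect allele,
#' resolving swapped codings and strand flips. Palindromic SNPs whose
#' minor-allele frequency exceeds `palindromic_eaf_band` in either dataset
#' (or whose frequency is missing) are dropped as unresolvable; palindromic
#' SNPs outside the band are strand-resolved by frequency agreement between
#' the two datasets. Every instrument is accounted for: retained + dropped
#' equals the number in.
#'
#' @param exposure `summary_stats` holding the clumped instrument set.
#' @param outcome `summary_stats` for the outcome trait.
#' @param palindromic_eaf_band drop palindromic SNPs with
#'   min(eaf, 1-eaf) > this value (default 0.40, i.e. EAF in (0.40, 0.60)).
#' @return list of class `harmonized_set` with
#'   `instruments`: data frame (variant_id, gamma, se_gamma, alpha,
#'   se_alpha, eaf_exposure, eaf_outcome, action), one row per exposure
#'   instrument, and `report`: named action counts. Rows whose action
#'   starts with `dropped_` carry NA effects and are excluded from
#'   estimation by [retained_instruments()].
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_band = 0.40) {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  exp_rec <- exposure$records
  out_rec <- outcome$records
  out_ix <- match(exp_rec$variant_id, out_rec$variant_id)

  one <- function(i) {
    e <- exp_rec[i, ]
    j <- out_ix[i]
    row <- list(variant_id = e$variant_id, gamma = e$beta, se_gamma = e$se,
                alpha = NA_real_, se_alpha = NA_real_,
                eaf_exposure = e$eaf, eaf_outcome = NA_real_,
                action = "dropped_missing")
    if (is.na(j)) return(row)
    o <- out_rec[j, ]
    row$eaf_outcome <- o$eaf
    pal <- is_palindromic(e$effect_allele, e$other_allele)
    action <- align_alleles(e$effect_allele, e$other_allele,
                            o$effect_allele, o$other_allele)
    if (action == "dropped_incompatible") {
      row$action <- "dropped_incompatible"
      return(row)
    }
    alpha <- o$beta
    eaf_o <- o$eaf
    if (pal) {
      maf_e <- min(e$eaf, 1 - e$eaf)
      maf_o <- min(o$eaf, 1 - o$eaf)
      if (is.na(e$eaf) || is.na(o$eaf) ||
          maf_e > palindromic_eaf_band || maf_o > palindromic_eaf_band) {
        row$action <- "dropped_palindromic"
        return(row)
      }
      # allele order gives a nominal action; frequency agreement decides
      # whether the outcome record is additionally on the other strand
      if (action == "sign_flipped") {
        alpha <- -alpha
        eaf_o <- 1 - eaf_o
      }
      if ((e$eaf < 0.5) != (eaf_o < 0.5)) {
        alpha <- -alpha
        eaf_o <- 1 - eaf_o
        action <- if (action == "aligned") "strand_and_sign_flipped" else "strand_flipped"
      }
    } else {
      if (action %in% c("sign_flipped", "strand_and_sign_flipped")) {
        alpha <- -alpha
        if (!is.na(eaf_o)) eaf_o <- 1 - eaf_o
      }
    }
    row$alpha <- alpha
    row$se_alpha <- o$se
    row$eaf_outcome <- eaf_o
    row$action <- action
    row
  }

  rows <- lapply(seq_len(nrow(exp_rec)), one)
  instruments <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(instruments)) {
    instruments <- data.frame(variant_id = character(0), gamma = numeric(0),
                              se_gamma = numeric(0), alpha = numeric(0),
                              se_alpha = numeric(0), eaf_exposure = numeric(0),
                              eaf_outcome = numeric(0), action = character(0),
                              stringsAsFactors = FALSE)
  }
  report <- table(factor(instruments$action,
                         levels = c("aligned", "sign_flipped", "strand_flipped",
                                    "strand_and_sign_flipped",
                                    "dropped_palindromic", "dropped_incompatible",
                                    "dropped_missing")))
  structure(list(instruments = instruments, report = report,
                 palindromic_eaf_band = palindromic_eaf_band),
            class = "harmonized_set")
}

#' Instruments retained for estimation after harmonization
#' @param h a `harmonized_set` (or its `instruments` data frame).
#' @return data frame of retained rows (action not `dropped_*`).
#' @export
retained_instruments <- function(h) {
  df <- if (inherits(h, "harmonized_set")) h$instruments else h
  out <- df[!startsWith(df$action, "dropped"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("harmonized instruments: %d in, %d retained\n",
              nrow(x$instruments), nrow(retained_instruments(x))))
  print(x$report)
  invisible(x)
}

#' Write harmonized instruments as a delimited table
#' @param h a `harmonized_set`.
#' @param path output path (tab-delimited).
#' @export
write_harmonized <- function(h, path) {
  stopifnot(inherits(h, "harmonized_set"))
  utils::write.table(h$instruments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
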