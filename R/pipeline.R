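#' Run a full two-sample MR analysis for one exposure/outcome pair
#'
#' Executes the three-step instrument construction — p-value filtering at
#' `p_threshold`, greedy clumping within `clump_kb` at `clump_r2`, and
#' effect-allele harmonization with the palindromic frequency band —
#' followed by causal estimation. With fewer than two retained instruments
#' the Wald ratio is the main test; otherwise IVW (fixed-effect point
#' estimate, with the multiplicative random-effects row emitted alongside)
#' plus any enabled sensitivity methods: MR-Egger (>= 3 instruments),
#' weighted and simple median (>= 3), and the PRESSO-style global test
#' (>= 4). Instrument attrition is logged at every stage and conserved
#' (in = retained + dropped).
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param ld optional LD r-squared matrix for clumping; without it
#'   clumping is by distance alone.
#' @param p_threshold instrument p-value threshold (default 5e-7).
#' @param clump_kb,clump_r2 clumping window (kb) and r2 threshold.
#' @param palindromic_band palindromic MAF ambiguity band (default 0.40).
#' @param methods sensitivity methods to run alongside the main estimate:
#'   any of `"egger"`, `"weighted_median"`, `"simple_median"`, `"presso"`.
#' @param n_boot bootstrap replicates for median estimators.
#' @param n_sim null simulations for the PRESSO-style test.
#' @param seed integer seed for all stochastic methods (mandatory when any
#'   is enabled).
#' @param out_dir optional directory: writes `results.tsv`,
#'   `instruments.tsv`, `run.log` and a YAML config echo.
#' @param direction label for the direction column (default "forward").
#' @return list of class `mr_analysis`: `results` (one row per method:
#'   exposure, outcome, direction, method, n_snp, beta, se, or, or_low,
#'   or_high, pvalue, egger_intercept, egger_intercept_p, Q, Q_p,
#'   presso_global_p, status), `instruments` (harmonized table),
#'   `attrition` (named stage counts), `log` (character).
#' @export
run_mr <- function(exposure, outcome, ld = NULL,
                   p_threshold = 5e-7, clump_kb = 1000, clump_r2 = 0.01,
                   palindromic_band = 0.40,
                   methods = c("egger", "weighted_median", "simple_median", "presso"),
                   n_boot = 1000, n_sim = 1000, seed = NULL,
                   out_dir = NULL, direction = "forward") {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  methods <- match.arg(methods, several.ok = TRUE)
  needs_seed <- any(c("weighted_median", "simple_median", "presso") %in% methods)
  if (needs_seed && is.null(seed)) {
    stop("a seed is required when bootstrap/simulation methods are enabled",
         call. = FALSE)
  }
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  say("[%s] %s (%s) -> %s (%s)", direction, exposure$trait_name,
      exposure$ancestry, outcome$trait_name, outcome$ancestry)

  selected <- filter_by_pvalue(exposure, p_threshold)
  say("p < %g: %d of %d records retained", p_threshold,
      n_records(selected), n_records(exposure))
  clumped <- if (n_records(selected) > 0) {
    if (is.null(ld)) {
      suppressWarnings(clump(selected, clump_kb, clump_r2, ld = NULL))
    } else {
      clump(selected, clump_kb, clump_r2, ld = ld)
    }
  } else selected
  say("clumping (%d kb, r2 %g%s): %d index SNPs", clump_kb, clump_r2,
      if (is.null(ld)) ", distance only" else "", n_records(clumped))

  attrition <- c(input = n_records(exposure), selected = n_records(selected),
                 clumped = n_records(clumped), harmonized = 0L)

  empty_row <- function(status) {
    data.frame(exposure = exposure$trait_name, outcome = outcome$trait_name,
               ancestry = exposure$ancestry, direction = direction,
               method = NA_character_, n_snp = 0L, beta = NA_real_,
               se = NA_real_, or = NA_real_, or_low = NA_real_,
               or_high = NA_real_, pvalue = NA_real_,
               egger_intercept = NA_real_, egger_intercept_p = NA_real_,
               Q = NA_real_, Q_p = NA_real_, presso_global_p = NA_real_,
               status = status, stringsAsFactors = FALSE)
  }

  if (n_records(clumped) == 0L) {
    say("zero instruments after filtering; recording failed analysis row")
    out <- structure(list(results = empty_row("zero instruments"),
                          instruments = NULL, attrition = attrition, log = log),
                     class = "mr_analysis")
    return(write_analysis(out, out_dir))
  }

  harm <- harmonize(clumped, outcome, palindromic_band)
  inst <- retained_instruments(harm)
  attrition["harmonized"] <- nrow(inst)
  say("harmonization: %d retained (%s)", nrow(inst),
      paste(sprintf("%s=%d", names(harm$report), as.integer(harm$report)),
            collapse = ", "))

  if (nrow(inst) == 0L) {
    out <- structure(list(results = empty_row("zero instruments after harmonization"),
                          instruments = harm$instruments,
                          attrition = attrition, log = log),
                     class = "mr_analysis")
    return(write_analysis(out, out_dir))
  }

  res_row <- function(r, extras = list()) {
    df <- empty_row("ok")
    df$method <- r$method
    df$n_snp <- r$n_snp
    df$beta <- r$beta; df$se <- r$se
    df$or <- r$or_; df$or_low <- r$or_low; df$or_high <- r$or_high
    df$pvalue <- r$pvalue
    if (!is.null(r$intercept)) {
      df$egger_intercept <- r$intercept
      df$egger_intercept_p <- r$intercept_p
    }
    if (!is.null(r$Q)) { df$Q <- r$Q; df$Q_p <- r$Q_pvalue }
    for (nm in names(extras)) df[[nm]] <- extras[[nm]]
    df
  }

  rows <- list()
  if (nrow(inst) < 2L) {
    say("single instrument: Wald ratio is the main test")
    rows$main <- res_row(wald_ratio(inst))
  } else {
    rows$ivw_fixed <- res_row(mr_ivw(inst, "fixed"))
    rows$ivw_mre <- res_row(mr_ivw(inst, "multiplicative_random_effects"))
    presso_p <- NA_real_
    if ("presso" %in% methods && nrow(inst) >= 4L) {
      pr <- presso_global(inst, n_sim = n_sim, seed = seed)
      presso_p <- pr$global_p
      say("PRESSO-style global p = %.4f, %d outlier(s)", pr$global_p,
          sum(pr$outliers$flagged))
    }
    rows$ivw_fixed$presso_global_p <- presso_p
    if ("egger" %in% methods && nrow(inst) >= 3L) {
      rows$egger <- res_row(mr_egger(inst))
    }
    if ("weighted_median" %in% methods && nrow(inst) >= 3L) {
      rows$wm <- res_row(median_estimator(inst, "inverse_variance",
                                          n_boot = n_boot, seed = seed))
    }
    if ("simple_median" %in% methods && nrow(inst) >= 3L) {
      rows$sm <- res_row(median_estimator(inst, "simple",
                                          n_boot = n_boot, seed = seed))
    }
  }
  results <- do.call(rbind, unname(rows))
  out <- structure(list(results = results, instruments = harm$instruments,
                        attrition = attrition, log = log),
                   class = "mr_analysis")
  write_analysis(out, out_dir)
}

write_analysis <- function(analysis, out_dir) {
  if (is.null(out_dir)) return(analysis)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(analysis$results, file.path(out_dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(analysis$instruments)) {
    utils::write.table(analysis$instruments,
                       file.path(out_dir, "instruments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(analysis$log, file.path(out_dir, "run.log"))
  analysis
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat("MR analysis —", paste(sprintf("%s: %d", names(x$attrition),
                                     x$attrition), collapse = ", "), "\n")
  print(x$results[, c("direction", "method", "n_snp", "or", "or_low",
                      "or_high", "pvalue", "status")])
  invisible(x)
}

#' Run the MR analysis in both directions
#'
#' Runs [run_mr()] forward (exposure -> outcome) and reverse (roles
#' swapped) with the same thresholds in each direction, and stacks the
#' results with a distinguishing `direction` column. Both inputs must be
#' full summary statistics, not pre-filtered instrument lists, for the
#' reverse direction to select its own instruments.
#'
#' @inheritParams run_mr
#' @return `mr_analysis` list with combined `results`, per-direction
#'   `instruments` (`$forward`, `$reverse`), `attrition` and `log`.
#' @export
run_bidirectional <- function(exposure, outcome, ld = NULL,
                              p_threshold = 5e-7, clump_kb = 1000,
                              clump_r2 = 0.01, palindromic_band = 0.40,
                              methods = c("egger", "weighted_median",
                                          "simple_median", "presso"),
                              n_boot = 1000, n_sim = 1000, seed = NULL,
                              out_dir = NULL) {
  fwd <- run_mr(exposure, outcome, ld = ld, p_threshold = p_threshold,
                clump_kb = clump_kb, clump_r2 = clump_r2,
                palindromic_band = palindromic_band, methods = methods,
                n_boot = n_boot, n_sim = n_sim, seed = seed,
                direction = "forward")
  rev <- run_mr(outcome, exposure, ld = ld, p_threshold = p_threshold,
                clump_kb = clump_kb, clump_r2 = clump_r2,
                palindromic_band = palindromic_band, methods = methods,
                n_boot = n_boot, n_sim = n_sim, seed = seed,
                direction = "reverse")
  out <- structure(list(results = rbind(fwd$results, rev$results),
                        instruments = list(forward = fwd$instruments,
                                           reverse = rev$instruments),
                        attrition = list(forward = fwd$attrition,
                                         reverse = rev$attrition),
                        log = c(fwd$log, rev$log)),
                   class = "mr_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out$results, file.path(out_dir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(out$log, file.path(out_dir, "run.log"))
  }
  out
}

#' Format MR results as a forest-plot-style table
#'
#' One line per analysis row, ordered by ancestry then exposure trait then
#' direction, with the odds ratio and 95 percent CI formatted as
#' "OR (low-high)" to a fixed number of decimals. The numeric columns are
#' kept alongside the formatted string so the table remains
#' machine-readable.
#'
#' @param results the `results` data frame of an `mr_analysis` (or the
#'   `mr_analysis` itself).
#' @param digits decimals for the OR string (default 2).
#' @return data frame with an `or_ci` column.
#' @export
format_forest_table <- function(results, digits = 2) {
  if (inherits(results, "mr_analysis")) results <- results$results
  stopifnot(is.data.frame(results), nrow(results) > 0)
  ord <- order(results$ancestry, results$exposure, results$direction,
               results$method)
  out <- results[ord, , drop = FALSE]
  fmt <- function(x) formatC(x, digits = digits, format = "f")
  out$or_ci <- ifelse(is.na(out$or), "-",
                      sprintf("%s (%s-%s)", fmt(out$or), fmt(out$or_low),
                              fmt(out$or_high)))
  rownames(out) <- NULL
  out
}

#' IVW/Wald estimate straight from an instrument table file
#'
#' Reads a pre-harmonized per-SNP instrument table (for example a
#' published supplementary table of selected instruments with exposure and
#' outcome effects) through a [column_map()]-style header mapping and
#' computes the primary MR estimate: IVW with two or more instruments,
#' Wald ratio with one.
#'
#' @param path delimited file with per-SNP exposure and outcome effects.
#' @param gamma,se_gamma,alpha,se_alpha source column headers for the
#'   aligned exposure/outcome effects and standard errors.
#' @param variant_id optional source column for the variant ID.
#' @param delimiter field separator (default tab).
#' @return an `mr_result` (method `ivw_fixed` or `wald_ratio`).
#' @export
mr_from_instrument_table <- function(path, gamma = "gamma",
                                     se_gamma = "se_gamma", alpha = "alpha",
                                     se_alpha = "se_alpha",
                                     variant_id = NULL, delimiter = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(gamma, se_gamma, alpha, se_alpha)
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) stop("column(s) not in table: ",
                              paste(miss, collapse = ", "), call. = FALSE)
  inst <- data.frame(gamma = as.numeric(raw[[gamma]]),
                     se_gamma = as.numeric(raw[[se_gamma]]),
                     alpha = as.numeric(raw[[alpha]]),
                     se_alpha = as.numeric(raw[[se_alpha]]),
                     stringsAsFactors = FALSE)
  if (!is.null(variant_id)) inst$variant_id <- as.character(raw[[variant_id]])
  if (nrow(inst) < 2L) wald_ratio(inst) else mr_ivw(inst)
}
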