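#' @title Causal-effect estimators for two-sample MR
#' @description
#' All estimators take the harmonized instruments data frame produced by
#' [harmonize()] (columns `gamma`, `se_gamma`, `alpha`, `se_alpha`:
#' aligned exposure and outcome effects with standard errors) and return an
#' `mr_result`. Throughout, the per-SNP inverse-variance weight is
#' w_i = gamma_i^2 / se_alpha_i^2, so the IVW estimate
#' beta = sum(w_i * alpha_i/gamma_i) / sum(w_i) coincides with the weighted
#' least-squares regression of alpha on gamma through the origin with
#' weights 1/se_alpha_i^2.
#' @name mr_estimators
NULL

new_mr_result <- function(method, beta, se, n_snp, extras = list()) {
  z <- beta / se
  res <- c(list(method = method, beta = beta, se = se,
                ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                pvalue = 2 * stats::pnorm(-abs(z)), n_snp = n_snp),
           extras)
  res <- to_odds_ratio(structure(res, class = "mr_result"))
  res
}

#' Convert an MR estimate to the odds-ratio scale
#'
#' Populates `or_`, `or_low`, `or_high` as exp of the log-odds estimate and
#' its normal-approximation 95 percent bounds. Meaningful when the outcome
#' trait is binary so `beta` is a log odds ratio per exposure unit.
#'
#' @param res an `mr_result`.
#' @return the same `mr_result` with OR fields populated.
#' @export
to_odds_ratio <- function(res) {
  stopifnot(inherits(res, "mr_result"))
  res$or_ <- exp(res$beta)
  res$or_low <- exp(res$beta - 1.96 * res$se)
  res$or_high <- exp(res$beta + 1.96 * res$se)
  res
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (SE %.4f), OR = %.3f (95%% CI %.3f-%.3f), p = %.3g, nSNP = %d\n",
              x$method, x$beta, x$se, x$or_, x$or_low, x$or_high,
              x$pvalue, x$n_snp))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.5f (SE %.5f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  cols <- c("method", "beta", "se", "ci_low", "ci_high", "or_", "or_low",
            "or_high", "pvalue", "n_snp")
  out <- as.data.frame(unclass(x)[cols], stringsAsFactors = FALSE)
  out$egger_intercept <- if (is.null(x$intercept)) NA_real_ else x$intercept
  out$egger_intercept_p <- if (is.null(x$intercept_p)) NA_real_ else x$intercept_p
  out
}

check_instruments <- function(instruments, min_n, caller) {
  stopifnot(is.data.frame(instruments))
  need <- c("gamma", "se_gamma", "alpha", "se_alpha")
  miss <- setdiff(need, names(instruments))
  if (length(miss) > 0L) stop(caller, ": instruments lack column(s) ",
                              paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(instruments) < min_n) {
    hint <- if (caller == "ivw") " (use wald_ratio for a single instrument)" else ""
    stop(sprintf("%s requires at least %d instruments, got %d%s",
                 caller, min_n, nrow(instruments), hint), call. = FALSE)
  }
  if (any(instruments$se_alpha <= 0) || any(instruments$se_gamma <= 0)) {
    stop(caller, ": standard errors must be positive", call. = FALSE)
  }
  invisible(instruments)
}

#' Wald ratio causal estimate from a single instrument
#'
#' beta = alpha/gamma with the first-order delta-method standard error
#' se_alpha/|gamma| (default), or the second-order delta method
#' sqrt(se_alpha^2/gamma^2 + alpha^2 se_gamma^2 / gamma^4) which also
#' propagates the exposure-side uncertainty. Used as the main test when
#' fewer than two instruments are available.
#'
#' @param inst one-row instruments data frame (or a list with gamma,
#'   se_gamma, alpha, se_alpha).
#' @param second_order use the second-order delta-method SE.
#' @return an `mr_result` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(inst, second_order = FALSE) {
  inst <- as.list(as.data.frame(inst)[1, ])
  if (is.na(inst$gamma) || inst$gamma == 0) {
    stop("wald_ratio undefined for gamma = 0", call. = FALSE)
  }
  beta <- inst$alpha / inst$gamma
  se <- if (second_order) {
    sqrt(inst$se_alpha^2 / inst$gamma^2 +
           inst$alpha^2 * inst$se_gamma^2 / inst$gamma^4)
  } else {
    inst$se_alpha / abs(inst$gamma)
  }
  new_mr_result("wald_ratio", beta, se, 1L)
}

#' Inverse-variance weighted causal estimate
#'
#' The main MR method: the inverse-variance weighted average of per-SNP
#' Wald ratios, beta = sum(w_i alpha_i/gamma_i)/sum(w_i) with
#' w_i = gamma_i^2/se_alpha_i^2. The fixed-effect standard error is
#' 1/sqrt(sum w_i); the multiplicative random-effects model inflates it by
#' max(1, sqrt(Q/(n-1))) where Q is Cochran's heterogeneity statistic, so
#' the point estimate is identical under both models.
#'
#' @param instruments harmonized instruments data frame, >= 2 rows, all
#'   gamma nonzero.
#' @param model `"fixed"` or `"multiplicative_random_effects"`.
#' @return `mr_result` with method `"ivw_fixed"` or `"ivw_mre"` and extras
#'   `Q`, `Q_df`, `Q_pvalue`.
#' @export
mr_ivw <- function(instruments, model = c("fixed", "multiplicative_random_effects")) {
  model <- match.arg(model)
  check_instruments(instruments, 2L, "ivw")
  if (any(instruments$gamma == 0)) stop("ivw requires all gamma nonzero", call. = FALSE)
  w <- instruments$gamma^2 / instruments$se_alpha^2
  ratio <- instruments$alpha / instruments$gamma
  beta <- sum(w * ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  het <- cochran_q(instruments, beta)
  method <- "ivw_fixed"
  if (model == "multiplicative_random_effects") {
    se <- se * max(1, sqrt(het$Q / het$df))
    method <- "ivw_mre"
  }
  new_mr_result(method, beta, se, nrow(instruments),
                extras = list(Q = het$Q, Q_df = het$df, Q_pvalue = het$pvalue))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects alpha on the exposure
#' effects gamma with a free intercept and weights 1/se_alpha^2.
#' Instruments are first re-oriented so that every gamma is non-negative
#' (negating gamma and alpha jointly), which the intercept needs to be
#' interpretable; the fit is invariant to the original orientations. A
#' non-zero intercept indicates directional (unbalanced) horizontal
#' pleiotropy; the slope is the pleiotropy-adjusted causal estimate under
#' the InSIDE assumption. Standard errors carry a multiplicative
#' overdispersion factor bounded below by 1.
#'
#' @param instruments harmonized instruments data frame, >= 3 rows.
#' @param t_dist use t-based p-values/CIs with n-2 degrees of freedom
#'   instead of the normal approximation.
#' @return `mr_result` with method `"egger"` and extras `intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(instruments, t_dist = FALSE) {
  check_instruments(instruments, 3L, "mr_egger")
  flip <- sign(instruments$gamma)
  flip[flip == 0] <- 1
  g <- instruments$gamma * flip
  a <- instruments$alpha * flip
  w <- 1 / instruments$se_alpha^2
  fit <- stats::lm(a ~ g, weights = w)
  cf <- summary(fit)$coefficients
  sigma <- summary(fit)$sigma
  infl <- max(1, sigma) / sigma  # bound the overdispersion factor below by 1
  slope <- cf["g", "Estimate"]
  slope_se <- cf["g", "Std. Error"] * infl
  int <- cf["(Intercept)", "Estimate"]
  int_se <- cf["(Intercept)", "Std. Error"] * infl
  n <- nrow(instruments)
  pfun <- if (t_dist) function(z) 2 * stats::pt(-abs(z), df = n - 2)
          else function(z) 2 * stats::pnorm(-abs(z))
  res <- new_mr_result("egger", slope, slope_se, n,
                       extras = list(intercept = int, intercept_se = int_se,
                                     intercept_p = pfun(int / int_se)))
  res$pvalue <- pfun(slope / slope_se)
  res
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(r[1])
  if (cum[length(cum)] <= 0.5) return(r[length(r)])
  below <- max(which(cum < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - cum[below]) /
    (cum[below + 1] - cum[below])
}

#' Median-based causal estimators
#'
#' Per-SNP Wald ratios are sorted and the (weighted) median taken: the
#' point where the cumulative normalized weight crosses one half, with
#' linear interpolation between the bracketing ratios. The simple median
#' uses equal weights; the weighted median uses the inverse-variance
#' weights w_i = gamma_i^2/se_alpha_i^2 and is consistent when instruments
#' carrying at least half of the weight are valid. The standard error is
#' the standard deviation of `n_boot` parametric-bootstrap replicates in
#' which alpha_i and gamma_i are resampled from their normal sampling
#' distributions; results are bit-reproducible under a fixed seed.
#'
#' @param instruments harmonized instruments data frame, >= 3 rows.
#' @param weighting `"inverse_variance"` (default) or `"simple"`.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap (mandatory).
#' @return `mr_result` with method `"weighted_median"` or
#'   `"simple_median"` and extra `seed`.
#' @export
median_estimator <- function(instruments,
                             weighting = c("inverse_variance", "simple"),
                             n_boot = 1000, seed) {
  weighting <- match.arg(weighting)
  check_instruments(instruments, 3L, "median_estimator")
  if (missing(seed)) stop("median_estimator requires an explicit seed", call. = FALSE)
  wfun <- function(g, a, se_a) {
    if (weighting == "simple") rep(1, length(g)) else g^2 / se_a^2
  }
  g <- instruments$gamma
  a <- instruments$alpha
  beta <- weighted_median_point(a / g, wfun(g, a, instruments$se_alpha))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      gb <- stats::rnorm(length(g), g, instruments$se_gamma)
      ab <- stats::rnorm(length(a), a, instruments$se_alpha)
      weighted_median_point(ab / gb, wfun(gb, ab, instruments$se_alpha))
    }, numeric(1))
  })
  se <- stats::sd(boot)
  method <- if (weighting == "simple") "simple_median" else "weighted_median"
  new_mr_result(method, beta, se, nrow(instruments), extras = list(seed = seed))
}

#' Cochran's Q heterogeneity statistic across per-SNP causal estimates
#'
#' Q = sum(w_i (alpha_i/gamma_i - beta_ivw)^2) with
#' w_i = gamma_i^2/se_alpha_i^2, referred to a chi-square with n-1 degrees
#' of freedom. Excess heterogeneity suggests pleiotropy or invalid
#' instruments.
#'
#' @param instruments harmonized instruments data frame, >= 2 rows.
#' @param beta_ivw the IVW point estimate to measure dispersion around; if
#'   missing it is computed from the instruments.
#' @return list of class `heterogeneity_result`: `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(instruments, beta_ivw) {
  check_instruments(instruments, 2L, "cochran_q")
  w <- instruments$gamma^2 / instruments$se_alpha^2
  ratio <- instruments$alpha / instruments$gamma
  if (missing(beta_ivw)) beta_ivw <- sum(w * ratio) / sum(w)
  q <- sum(w * (ratio - beta_ivw)^2)
  df <- nrow(instruments) - 1L
  structure(list(Q = q, df = df,
                 pvalue = stats::pchisq(q, df, lower.tail = FALSE)),
            class = "heterogeneity_result")
}

loo_ivw_beta <- function(g, a, se_a) {
  # leave-one-out IVW point estimates, all i at once
  num <- g * a / se_a^2
  den <- g^2 / se_a^2
  (sum(num) - num) / (sum(den) - den)
}

#' PRESSO-style global pleiotropy test with per-SNP outlier detection
#'
#' A simplified residual-sum-of-squares pleiotropy test. The observed
#' statistic is RSS = sum(w_i (alpha_i - b_(-i) gamma_i)^2), where b_(-i)
#' is the IVW estimate leaving instrument i out and
#' w_i = gamma_i^2/se_alpha_i^2, so each instrument is scored against a
#' fit that excludes it. The null hypothesis is a single common causal
#' slope, so the null distribution is built by `n_sim` parametric
#' simulations that redraw both sides of each instrument around that
#' model — gamma*_i ~ Normal(gamma_i, se_gamma_i) and
#' alpha*_i ~ Normal(b_ivw gamma_i, se_alpha_i) — and recompute RSS
#' (including the leave-one-out estimates and weights) on each simulated
#' dataset. Both choices matter for calibration: centering on the
#' leave-one-out fits transmits the observed residual spread into the
#' null draws (markedly conservative), while holding gamma fixed omits
#' the exposure-noise component of the observed residuals (mildly
#' anticonservative). The global p-value is
#' (1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1). Per-SNP outlier p-values
#' compare each observed term with its simulated counterparts, flagged at
#' a Bonferroni-corrected `outlier_alpha`; with `n_sim` simulations the
#' smallest attainable p-value is 1/(n_sim+1), so several contaminated
#' instruments can tie at the floor — ranking ties are broken by the
#' observed RSS term, reported alongside. The distortion test of the full
#' method is not implemented.
#'
#' @param instruments harmonized instruments data frame, >= 4 rows.
#' @param n_sim number of null simulations (default 1000).
#' @param seed integer seed (mandatory; results are bit-reproducible).
#' @param outlier_alpha familywise level for outlier flagging (default 0.05).
#' @return list of class `presso_result`: `rss_observed`, `global_p`,
#'   `outliers` data frame (variant_id, rss_term, pvalue, flagged, ranked
#'   by pvalue with ties broken by rss_term), `n_sim`, `seed`.
#' @export
presso_global <- function(instruments, n_sim = 1000, seed, outlier_alpha = 0.05) {
  check_instruments(instruments, 4L, "presso_global")
  if (missing(seed)) stop("presso_global requires an explicit seed", call. = FALSE)
  g <- instruments$gamma
  a <- instruments$alpha
  se_a <- instruments$se_alpha
  n <- length(g)
  w <- g^2 / se_a^2
  b_loo <- loo_ivw_beta(g, a, se_a)
  terms_obs <- w * (a - b_loo * g)^2
  rss_obs <- sum(terms_obs)

  se_g <- instruments$se_gamma
  b_ivw <- sum(g * a / se_a^2) / sum(g^2 / se_a^2)
  sims <- with_seed(seed, {
    gstar <- matrix(stats::rnorm(n_sim * n, mean = rep(g, each = n_sim),
                                 sd = rep(se_g, each = n_sim)),
                    nrow = n_sim, ncol = n)
    astar <- matrix(stats::rnorm(n_sim * n, mean = rep(b_ivw * g, each = n_sim),
                                 sd = rep(se_a, each = n_sim)),
                    nrow = n_sim, ncol = n)
    # leave-one-out IVW per simulated dataset, vectorized over sims
    se2 <- matrix(se_a^2, n_sim, n, byrow = TRUE)
    numm <- gstar * astar / se2
    denm <- gstar^2 / se2
    b_loo_star <- (rowSums(numm) - numm) / (rowSums(denm) - denm)
    terms_star <- denm * (astar - b_loo_star * gstar)^2
    list(rss = rowSums(terms_star), terms = terms_star)
  })
  global_p <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  per_snp_p <- (1 + colSums(sims$terms >= matrix(terms_obs, n_sim, n, byrow = TRUE))) /
    (n_sim + 1)
  flagged <- per_snp_p < outlier_alpha / n
  vid <- if ("variant_id" %in% names(instruments)) instruments$variant_id
         else as.character(seq_len(n))
  outliers <- data.frame(variant_id = vid, rss_term = terms_obs,
                         pvalue = per_snp_p, flagged = flagged,
                         stringsAsFactors = FALSE)
  outliers <- outliers[order(outliers$pvalue, -outliers$rss_term), ]
  rownames(outliers) <- NULL
  structure(list(rss_observed = rss_obs, global_p = global_p,
                 outliers = outliers, n_sim = n_sim, seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("PRESSO-style global test: RSS = %.3f, global p = %.4f (%d sims), %d outlier(s) flagged\n",
              x$rss_observed, x$global_p, x$n_sim, sum(x$outliers$flagged)))
  invisible(x)
}

# Run code with a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
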