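#' Simulate harmonized instruments directly at the summary level
#'
#' A lightweight generator for estimator calibration experiments: it draws
#' per-SNP exposure and outcome effects from the same generative model as
#' [simulate_pair()] but skips the allele/corruption layer, returning a
#' ready-to-estimate instruments data frame. Per SNP: maf ~ U(maf_range);
#' true gamma ~ N(0, gamma_sd^2); se_gamma = 1/sqrt(2 n_exposure maf(1-maf));
#' a pleiotropic direct effect delta ~ N(pleiotropy_mean, pleiotropy_sd^2)
#' with probability pleiotropy_fraction, applied relative to the
#' exposure-increasing allele (multiplied by sign(gamma)), the convention
#' under which a nonzero pleiotropy mean is "directional" and biases the
#' Egger intercept; the true outcome effect is true_beta * gamma + delta
#' and both observed effects add independent normal noise (two-sample
#' design).
#'
#' Draws come from the caller's RNG stream, so replicate loops under one
#' `set.seed()` are reproducible.
#'
#' @param k number of instruments.
#' @param true_beta causal effect.
#' @param gamma_sd SD of true exposure effects. Calibration experiments
#'   use strong instruments (large gamma_sd) so that weak-instrument
#'   dilution, of order 1/F, is negligible against Monte-Carlo error.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param maf_range minor-allele frequency range.
#' @param pleiotropy_fraction,pleiotropy_mean,pleiotropy_sd direct-effect
#'   settings as in [simulation_config()].
#' @return data frame with variant_id, gamma, se_gamma, alpha, se_alpha
#'   and attribute `true_beta`.
#' @export
simulate_instruments <- function(k = 50, true_beta = 0.2, gamma_sd = 0.3,
                                 n_exposure = 186689, n_outcome = 440328,
                                 maf_range = c(0.05, 0.5),
                                 pleiotropy_fraction = 0,
                                 pleiotropy_mean = 0, pleiotropy_sd = 0.01) {
  maf <- stats::runif(k, maf_range[1], maf_range[2])
  gamma_true <- stats::rnorm(k, 0, gamma_sd)
  se_g <- 1 / sqrt(2 * n_exposure * maf * (1 - maf))
  se_a <- 1 / sqrt(2 * n_outcome * maf * (1 - maf))
  delta <- ifelse(stats::runif(k) < pleiotropy_fraction,
                  sign(gamma_true) *
                    stats::rnorm(k, pleiotropy_mean, pleiotropy_sd), 0)
  out <- data.frame(variant_id = sprintf("snp%03d", seq_len(k)),
                    gamma = gamma_true + stats::rnorm(k, 0, se_g),
                    se_gamma = se_g,
                    alpha = true_beta * gamma_true + delta +
                      stats::rnorm(k, 0, se_a),
                    se_alpha = se_a, stringsAsFactors = FALSE)
  attr(out, "true_beta") <- true_beta
  out
}

#' IVW parameter recovery and confidence-interval coverage
#'
#' Repeatedly simulates k valid instruments with a known causal effect,
#' estimates by fixed-effect IVW, and summarizes the estimator's mean,
#' its Monte-Carlo standard error, and the empirical coverage of the
#' nominal 95 percent CI.
#'
#' @param n_rep replicates.
#' @param k instruments per replicate.
#' @param true_beta causal effect.
#' @param seed integer seed.
#' @param ... further arguments to [simulate_instruments()].
#' @return list: `mean_beta`, `se_mean` (Monte-Carlo SE of the mean),
#'   `coverage`, `true_beta`, `n_rep`.
#' @export
experiment_ivw_recovery <- function(n_rep = 1000, k = 50, true_beta = 0.2,
                                    seed = 1L, ...) {
  with_seed(seed, {
    est <- matrix(NA_real_, n_rep, 2)
    for (r in seq_len(n_rep)) {
      inst <- simulate_instruments(k = k, true_beta = true_beta, ...)
      fit <- mr_ivw(inst, "fixed")
      est[r, ] <- c(fit$beta, fit$se)
    }
    covered <- abs(est[, 1] - true_beta) <= 1.96 * est[, 2]
    list(mean_beta = mean(est[, 1]),
         se_mean = stats::sd(est[, 1]) / sqrt(n_rep),
         coverage = mean(covered), true_beta = true_beta, n_rep = n_rep)
  })
}

#' IVW type-I error under the causal null
#'
#' Simulates valid instruments with zero causal effect and no pleiotropy
#' and records how often the fixed-effect IVW p-value falls below
#' `alpha`.
#'
#' @inheritParams experiment_ivw_recovery
#' @param alpha nominal level (default 0.05).
#' @return list: `rejection_rate`, `binomial_se`, `alpha`, `n_rep`.
#' @export
experiment_ivw_type1 <- function(n_rep = 2000, k = 50, alpha = 0.05,
                                 seed = 1L, ...) {
  with_seed(seed, {
    rej <- logical(n_rep)
    for (r in seq_len(n_rep)) {
      inst <- simulate_instruments(k = k, true_beta = 0, ...)
      rej[r] <- mr_ivw(inst, "fixed")$pvalue < alpha
    }
    list(rejection_rate = mean(rej),
         binomial_se = sqrt(alpha * (1 - alpha) / n_rep),
         alpha = alpha, n_rep = n_rep)
  })
}

#' Egger intercept recovery under directional pleiotropy
#'
#' Plants a directional pleiotropic effect (mean `pleiotropy_mean` on
#' every instrument, InSIDE satisfied) and compares the mean Egger
#' intercept with the planted mean, and the Egger slope bias with the IVW
#' slope bias.
#'
#' @inheritParams experiment_ivw_recovery
#' @param pleiotropy_mean planted mean direct effect.
#' @param pleiotropy_sd SD of direct effects.
#' @return list: `intercept_mean`, `intercept_se_mean`, `pleiotropy_mean`,
#'   `egger_bias`, `ivw_bias`, `n_rep`.
#' @export
experiment_egger_pleiotropy <- function(n_rep = 200, k = 50, true_beta = 0.2,
                                        pleiotropy_mean = 0.01,
                                        pleiotropy_sd = 0.005, seed = 1L, ...) {
  with_seed(seed, {
    ic <- eg <- iv <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      inst <- simulate_instruments(k = k, true_beta = true_beta,
                                   pleiotropy_fraction = 1,
                                   pleiotropy_mean = pleiotropy_mean,
                                   pleiotropy_sd = pleiotropy_sd, ...)
      e <- mr_egger(inst)
      ic[r] <- e$intercept
      eg[r] <- e$beta
      iv[r] <- mr_ivw(inst)$beta
    }
    list(intercept_mean = mean(ic),
         intercept_se_mean = stats::sd(ic) / sqrt(n_rep),
         pleiotropy_mean = pleiotropy_mean,
         egger_bias = mean(eg) - true_beta,
         ivw_bias = mean(iv) - true_beta, n_rep = n_rep)
  })
}

#' Weighted-median robustness with planted invalid instruments
#'
#' Gives a minority fraction of instruments a directional pleiotropic
#' effect and compares the absolute bias of the weighted median (which is
#' consistent while valid instruments hold a weight majority) with that
#' of IVW.
#'
#' @inheritParams experiment_ivw_recovery
#' @param invalid_fraction fraction of invalid instruments (< 0.5).
#' @param pleiotropy_mean direct effect mean for the invalid minority.
#' @param n_boot bootstrap replicates per weighted-median fit.
#' @return list: `wm_bias`, `ivw_bias`, `invalid_fraction`, `n_rep`.
#' @export
experiment_median_invalid <- function(n_rep = 200, k = 50, true_beta = 0.2,
                                      invalid_fraction = 0.3,
                                      pleiotropy_mean = 0.05, seed = 1L,
                                      n_boot = 50, ...) {
  with_seed(seed, {
    wm <- iv <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      inst <- simulate_instruments(k = k, true_beta = true_beta,
                                   pleiotropy_fraction = invalid_fraction,
                                   pleiotropy_mean = pleiotropy_mean,
                                   pleiotropy_sd = 0.01, ...)
      wm[r] <- median_estimator(inst, "inverse_variance", n_boot = n_boot,
                                seed = r)$beta
      iv[r] <- mr_ivw(inst)$beta
    }
    list(wm_bias = mean(wm) - true_beta, ivw_bias = mean(iv) - true_beta,
         invalid_fraction = invalid_fraction, n_rep = n_rep)
  })
}

#' Harmonization recovery against the synthetic corruption manifest
#'
#' Simulates a corruption-heavy exposure/outcome pair, harmonizes it, and
#' scores the result against ground truth: every retained non-palindromic
#' record must recover the pre-corruption outcome effect exactly, and
#' every palindromic record inside the frequency ambiguity band must be
#' dropped.
#'
#' @param n_snp number of variants.
#' @param seed integer seed.
#' @param palindromic_eaf_band ambiguity band (default 0.40).
#' @return list: `recovery_pct` (percent of retained non-palindromic
#'   records with exactly recovered effects), `n_nonpalindromic`,
#'   `inband_dropped_pct`, `n_inband_palindromic`.
#' @export
experiment_harmonization_recovery <- function(n_snp = 200, seed = 1L,
                                              palindromic_eaf_band = 0.40) {
  cfg <- simulation_config(n_snp = n_snp, sign_flip_prob = 0.4,
                           strand_flip_prob = 0.4,
                           palindromic_fraction = 0.3, seed = seed)
  sim <- simulate_pair(cfg)
  h <- harmonize(sim$exposure, sim$outcome, palindromic_eaf_band)
  inst <- h$instruments
  tr <- sim$truth[match(inst$variant_id, sim$truth$variant_id), ]
  nonpal <- !tr$palindromic
  retained <- !startsWith(inst$action, "dropped")
  recovered <- retained & abs(inst$alpha - tr$alpha_clean) < 1e-12
  maf_in <- pmin(sim$exposure$records$eaf, 1 - sim$exposure$records$eaf)
  inband <- tr$palindromic & maf_in[match(inst$variant_id,
                                          sim$exposure$records$variant_id)] >
    palindromic_eaf_band
  list(recovery_pct = 100 * mean(recovered[nonpal]),
       n_nonpalindromic = sum(nonpal),
       inband_dropped_pct = if (any(inband)) {
         100 * mean(inst$action[inband] == "dropped_palindromic")
       } else NA_real_,
       n_inband_palindromic = sum(inband))
}

#' Calibration of the PRESSO-style global test under the null
#'
#' Simulates valid instruments (no pleiotropy) repeatedly and records the
#' rejection rate of the global test at `alpha`; under the null it should
#' sit at the nominal level up to Monte-Carlo error.
#'
#' @inheritParams experiment_ivw_recovery
#' @param n_sim null simulations per test.
#' @param alpha nominal level.
#' @return list: `rejection_rate`, `binomial_se`, `n_rep`, `n_sim`.
#' @export
experiment_presso_null <- function(n_rep = 500, k = 10, n_sim = 200,
                                   alpha = 0.05, seed = 1L, ...) {
  with_seed(seed, {
    rej <- logical(n_rep)
    for (r in seq_len(n_rep)) {
      inst <- simulate_instruments(k = k, true_beta = 0.2, ...)
      rej[r] <- presso_global(inst, n_sim = n_sim, seed = r)$global_p < alpha
    }
    list(rejection_rate = mean(rej),
         binomial_se = sqrt(alpha * (1 - alpha) / n_rep),
         n_rep = n_rep, n_sim = n_sim)
  })
}
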