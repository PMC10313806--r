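# Independent oracles and small fixture builders, kept deliberately
# separate from the implementation paths they check.

# WLS through the origin via R's QR-based lm, not the closed-form sums
oracle_wls_origin <- function(inst) {
  fit <- lm(alpha ~ 0 + gamma, data = inst, weights = 1 / inst$se_alpha^2)
  unname(coef(fit)[1])
}

# weighted regression with intercept solved from explicit normal equations
oracle_wls_intercept <- function(g, a, w) {
  X <- cbind(1, g)
  xtw <- t(X * w)
  solve(xtw %*% X, xtw %*% a)[, 1]
}

# weighted median by stepwise cumulative-weight scan with interpolation
oracle_weighted_median <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- w[ord] / sum(w)
  acc <- 0
  prev_mid <- NA
  prev_r <- NA
  for (i in seq_along(r)) {
    mid <- acc + w[i] / 2
    if (mid >= 0.5) {
      if (i == 1) return(r[1])
      return(prev_r + (r[i] - prev_r) * (0.5 - prev_mid) / (mid - prev_mid))
    }
    acc <- acc + w[i]
    prev_mid <- mid
    prev_r <- r[i]
  }
  r[length(r)]
}

# greedy clumping, "keep" formulation: a SNP survives iff it does not
# conflict with any already-kept index SNP
oracle_clump_ids <- function(rec, window_kb, r2_threshold, ld = NULL) {
  ord <- order(rec$pvalue, rec$chrom, rec$pos, rec$variant_id)
  rec <- rec[ord, ]
  kept <- rec[0, ]
  for (i in seq_len(nrow(rec))) {
    conflict <- FALSE
    for (j in seq_len(nrow(kept))) {
      same <- rec$chrom[i] == kept$chrom[j] &&
        abs(rec$pos[i] - kept$pos[j]) <= window_kb * 1000
      if (same && !is.null(ld)) {
        same <- ld[rec$variant_id[i], kept$variant_id[j]] >= r2_threshold
      }
      if (same) { conflict <- TRUE; break }
    }
    if (!conflict) kept <- rbind(kept, rec[i, ])
  }
  kept$variant_id
}

# quick summary_stats builder for hand-written records
make_stats <- function(df, trait = "trait", type = "quantitative",
                       ancestry = "test") {
  summary_stats(df, trait_name = trait, trait_type = type, ancestry = ancestry)
}

random_instruments <- function(k) {
  data.frame(variant_id = sprintf("v%d", seq_len(k)),
             gamma = rnorm(k, 0, 0.2) + sample(c(-1, 1), k, TRUE) * 0.05,
             se_gamma = runif(k, 0.005, 0.05),
             alpha = rnorm(k, 0, 0.05),
             se_alpha = runif(k, 0.005, 0.05),
             stringsAsFactors = FALSE)
}
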