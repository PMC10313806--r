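make_pair <- function(exp_ea, exp_oa, exp_beta, exp_eaf,
                      out_ea, out_oa, out_beta, out_eaf) {
  exposure <- make_stats(data.frame(variant_id = "rs1", effect_allele = exp_ea,
                                    other_allele = exp_oa, eaf = exp_eaf,
                                    beta = exp_beta, se = 0.02, pvalue = 1e-8))
  outcome <- make_stats(data.frame(variant_id = "rs1", effect_allele = out_ea,
                                   other_allele = out_oa, eaf = out_eaf,
                                   beta = out_beta, se = 0.01, pvalue = 0.5))
  harmonize(exposure, outcome)
}

test_that("palindromic detection covers both ambiguous pairs", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("g", "c"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("AT", "A"))  # indels are not palindromizable
})

test_that("allele alignment classifies all strand/order combinations", {
  expect_equal(align_alleles("A", "G", "A", "G"), "aligned")
  expect_equal(align_alleles("A", "G", "G", "A"), "sign_flipped")
  expect_equal(align_alleles("A", "G", "T", "C"), "strand_flipped")
  expect_equal(align_alleles("A", "G", "C", "T"), "strand_and_sign_flipped")
  expect_equal(align_alleles("A", "G", "A", "C"), "dropped_incompatible")
})

test_that("a swapped outcome coding is sign-corrected", {
  h <- make_pair("A", "G", 0.10, 0.3, "G", "A", -0.05, 0.7)
  inst <- retained_instruments(h)
  expect_equal(nrow(inst), 1L)
  expect_equal(inst$action, "sign_flipped")
  expect_equal(inst$alpha, 0.05)
  expect_equal(inst$eaf_outcome, 0.3)
})

test_that("palindromic SNPs inside the 40% frequency band are dropped", {
  h <- make_pair("A", "T", 0.10, 0.50, "A", "T", 0.05, 0.50)
  expect_equal(h$instruments$action, "dropped_palindromic")
  # frequency missing: cannot adjudicate, dropped
  h2 <- make_pair("A", "T", 0.10, NA, "A", "T", 0.05, 0.10)
  expect_equal(h2$instruments$action, "dropped_palindromic")
  # band edge is exclusive: maf 0.40 exactly is retained
  h3 <- make_pair("C", "G", 0.10, 0.40, "C", "G", 0.05, 0.41)
  expect_equal(h3$instruments$action, "dropped_palindromic")  # outcome maf 0.41
  h4 <- make_pair("C", "G", 0.10, 0.40, "C", "G", 0.05, 0.40)
  expect_equal(h4$instruments$action, "aligned")
})

test_that("frequency agreement strand-resolves out-of-band palindromic SNPs", {
  # among the strand hypotheses only one is frequency-consistent
  h <- make_pair("A", "T", 0.10, 0.10, "A", "T", 0.05, 0.12)
  expect_equal(h$instruments$action, "aligned")
  expect_equal(retained_instruments(h)$alpha, 0.05)
  # same alleles but complementary frequency: other strand, sign flips
  h2 <- make_pair("A", "T", 0.10, 0.10, "A", "T", 0.05, 0.88)
  expect_equal(h2$instruments$action, "strand_and_sign_flipped")
  expect_equal(retained_instruments(h2)$alpha, -0.05)
  # swapped order, consistent after the nominal sign flip
  h3 <- make_pair("A", "T", 0.10, 0.10, "T", "A", 0.05, 0.90)
  expect_equal(h3$instruments$action, "sign_flipped")
  expect_equal(retained_instruments(h3)$alpha, -0.05)
})

test_that("instruments missing from the outcome are dropped with trace", {
  exposure <- make_stats(data.frame(variant_id = c("rs1", "rs2"),
                                    effect_allele = "A", other_allele = "G",
                                    eaf = 0.3, beta = 0.1, se = 0.02,
                                    pvalue = 1e-8))
  outcome <- make_stats(data.frame(variant_id = "rs1", effect_allele = "A",
                                   other_allele = "G", eaf = 0.3, beta = 0.05,
                                   se = 0.01, pvalue = 0.5))
  h <- harmonize(exposure, outcome)
  expect_equal(sum(h$report), 2)  # conservation: retained + dropped = in
  expect_equal(h$instruments$action[h$instruments$variant_id == "rs2"],
               "dropped_missing")
})

test_that("harmonization is idempotent and orientation-symmetric", {
  cfg <- simulation_config(n_snp = 60, sign_flip_prob = 0.4,
                           strand_flip_prob = 0.4, palindromic_fraction = 0.3,
                           gamma_sd = 0.3, seed = 21)
  sim <- simulate_pair(cfg)
  h1 <- harmonize(sim$exposure, sim$outcome)
  inst1 <- retained_instruments(h1)

  # re-harmonizing the harmonized pair: all aligned, identical numbers
  rebuilt_out <- sim$exposure
  rebuilt_out$records <- sim$exposure$records[
    match(inst1$variant_id, sim$exposure$records$variant_id), ]
  rebuilt_out$records$beta <- inst1$alpha
  rebuilt_out$records$se <- inst1$se_alpha
  rebuilt_out$records$eaf <- inst1$eaf_outcome
  rebuilt_exp <- sim$exposure
  rebuilt_exp$records <- rebuilt_out$records
  rebuilt_exp$records$beta <- inst1$gamma
  rebuilt_exp$records$se <- inst1$se_gamma
  rebuilt_exp$records$eaf <- inst1$eaf_exposure
  h2 <- harmonize(rebuilt_exp, rebuilt_out)
  keep2 <- retained_instruments(h2)
  expect_true(all(keep2$action == "aligned"))
  expect_equal(keep2$alpha, inst1$alpha[match(keep2$variant_id, inst1$variant_id)])

  # negating the exposure coding leaves gamma*alpha products unchanged
  flipped_exp <- sim$exposure
  flipped_exp$records$beta <- -flipped_exp$records$beta
  tmp <- flipped_exp$records$effect_allele
  flipped_exp$records$effect_allele <- flipped_exp$records$other_allele
  flipped_exp$records$other_allele <- tmp
  flipped_exp$records$eaf <- 1 - flipped_exp$records$eaf
  h3 <- harmonize(flipped_exp, sim$outcome)
  inst3 <- retained_instruments(h3)
  common <- intersect(inst1$variant_id, inst3$variant_id)
  expect_equal(length(common), nrow(inst1))
  i1 <- inst1[match(common, inst1$variant_id), ]
  i3 <- inst3[match(common, inst3$variant_id), ]
  expect_equal(i1$gamma * i1$alpha, i3$gamma * i3$alpha, tolerance = 1e-12)
  expect_equal(mr_ivw(i1)$beta, mr_ivw(i3)$beta, tolerance = 1e-12)
})

test_that("planted corruption is recovered exactly on non-palindromic records", {
  r <- experiment_harmonization_recovery(n_snp = 200, seed = 4)
  expect_equal(r$recovery_pct, 100)
  expect_equal(r$inband_dropped_pct, 100)
  expect_gt(r$n_inband_palindromic, 0)
})

test_that("forced sign corruption is reported as 100% sign-flipped", {
  cfg <- simulation_config(n_snp = 40, sign_flip_prob = 1, strand_flip_prob = 0,
                           palindromic_fraction = 0.2, gamma_sd = 0.3, seed = 8)
  sim <- simulate_pair(cfg)
  inst <- retained_instruments(harmonize(sim$exposure, sim$outcome))
  expect_gt(nrow(inst), 0)
  expect_true(all(inst$action == "sign_flipped"))
})
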