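test_that("p-value filtering is strict, order-preserving and idempotent", {
  s <- make_stats(data.frame(variant_id = c("a", "b", "c"),
                             effect_allele = "A", other_allele = "G",
                             beta = 0.1, se = 0.02,
                             pvalue = c(1e-8, 4.9e-7, 6e-7)))
  out <- filter_by_pvalue(s, 5e-7)
  expect_identical(out$records$variant_id, c("a", "b"))  # strict inequality
  expect_identical(filter_by_pvalue(out, 5e-7)$records, out$records)
  expect_equal(n_records(filter_by_pvalue(s, 1)), 3L)  # p < 1 all retained
  expect_error(filter_by_pvalue(s, 0), "p_threshold")

  set.seed(12)
  big <- make_stats(data.frame(variant_id = sprintf("v%d", 1:1000),
                               effect_allele = "A", other_allele = "G",
                               beta = 0.1, se = 0.02, pvalue = runif(1000)))
  thr <- 0.37
  expect_identical(filter_by_pvalue(big, thr)$records$variant_id,
                   big$records$variant_id[big$records$pvalue < thr])
})

test_that("clumping keeps the stronger of two nearby correlated SNPs", {
  s <- make_stats(data.frame(variant_id = c("lead", "shadow"), chrom = "1",
                             pos = c(1e6, 1.5e6), effect_allele = "A",
                             other_allele = "G", beta = 0.1, se = 0.02,
                             pvalue = c(1e-9, 1e-8)))
  ld <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("lead", "shadow"),
                                                     c("lead", "shadow")))
  out <- clump(s, window_kb = 1000, r2_threshold = 0.01, ld = ld)
  expect_identical(out$records$variant_id, "lead")
})

test_that("cross-chromosome pairs never clump", {
  s <- make_stats(data.frame(variant_id = c("a", "b"), chrom = c("1", "2"),
                             pos = c(1e6, 1e6), effect_allele = "A",
                             other_allele = "G", beta = 0.1, se = 0.02,
                             pvalue = c(1e-9, 1e-8)))
  ld <- diag(2); dimnames(ld) <- list(c("a", "b"), c("a", "b"))
  expect_equal(n_records(clump(s, ld = ld)), 2L)
})

test_that("clumping matches the brute-force oracle on block-LD fixtures", {
  cfg <- simulation_config(n_snp = 50, ld_block_size = 10, ld_r2 = 0.8,
                           gamma_sd = 0.3, seed = 77)
  sim <- simulate_pair(cfg)
  ld <- simulate_ld_blocks(cfg)
  sel <- filter_by_pvalue(sim$exposure, 5e-7)
  got <- clump(sel, 1000, 0.01, ld = ld)$records$variant_id
  want <- oracle_clump_ids(sel$records, 1000, 0.01, ld = ld)
  expect_identical(got, want)
  # 5 blocks of 10 within-window, high LD: one index SNP per block
  expect_equal(length(got),
               length(unique((match(got, sim$exposure$records$variant_id) - 1) %/% 10)))

  # every removed SNP conflicts with some earlier index SNP (certificate)
  removed <- setdiff(sel$records$variant_id, got)
  for (v in removed) {
    vr <- sel$records[sel$records$variant_id == v, ]
    conflicts <- vapply(got, function(g) {
      gr <- sel$records[sel$records$variant_id == g, ]
      gr$chrom == vr$chrom && abs(gr$pos - vr$pos) <= 1e6 &&
        ld[g, v] >= 0.01 && gr$pvalue <= vr$pvalue
    }, logical(1))
    expect_true(any(conflicts))
  }
})

test_that("clumping output is invariant to input row order", {
  cfg <- simulation_config(n_snp = 40, ld_block_size = 5, ld_r2 = 0.9,
                           gamma_sd = 0.3, seed = 5)
  sim <- simulate_pair(cfg)
  ld <- simulate_ld_blocks(cfg)
  sel <- filter_by_pvalue(sim$exposure, 5e-7)
  shuffled <- sel
  set.seed(1)
  shuffled$records <- shuffled$records[sample.int(nrow(shuffled$records)), ]
  expect_identical(clump(sel, ld = ld)$records$variant_id,
                   clump(shuffled, ld = ld)$records$variant_id)
})

test_that("clumping without LD removes by distance alone, with a warning", {
  s <- make_stats(data.frame(variant_id = c("a", "b"), chrom = "1",
                             pos = c(1e6, 1.5e6), effect_allele = "A",
                             other_allele = "G", beta = 0.1, se = 0.02,
                             pvalue = c(1e-9, 1e-8)))
  expect_warning(out <- clump(s), "distance alone")
  expect_identical(out$records$variant_id, "a")
  ld <- matrix(1, 1, 1, dimnames = list("a", "a"))
  expect_error(clump(s, ld = ld), "\\bb\\b")
})

test_that("F-statistics follow the squared t approximation", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(-0.1, 0.02), 25)  # sign-invariant
  expect_equal(f_statistic(3 * 0.1, 3 * 0.02), 25)  # scale-invariant
  expect_error(f_statistic(0.1, 0), "se")
  expect_error(f_statistic(0.1, 0.02, method = "variance_explained"), "eaf")
  f_ve <- f_statistic(0.1, 0.02, "variance_explained", eaf = 0.3, n = 1e5)
  expect_gt(f_ve, 0)
})

test_that("instrument reports total up from per-SNP F values", {
  set.seed(9)
  df <- data.frame(variant_id = sprintf("v%d", 1:20), effect_allele = "A",
                   other_allele = "G", beta = rnorm(20, 0.2, 0.05),
                   se = runif(20, 0.01, 0.03), pvalue = 1e-8)
  rep_ <- instrument_report(make_stats(df))
  expect_equal(rep_$per_snp$f, f_statistic(df$beta, df$se))
  expect_equal(rep_$mean_f, mean(rep_$per_snp$f))
  expect_equal(rep_$min_f, min(rep_$per_snp$f))
  one <- instrument_report(make_stats(df[1, ]))
  one$min_f <- 9.9
  expect_false(all_above(one, 10))
  strong <- make_stats(data.frame(variant_id = "v", effect_allele = "A",
                                  other_allele = "G", beta = 0.32, se = 0.1,
                                  pvalue = 1e-8))
  expect_true(all_above(instrument_report(strong), 10))  # |b/se| = 3.2 > sqrt(10)
})

test_that("LD matrices round-trip through the plain-text reader", {
  cfg <- simulation_config(n_snp = 12, ld_block_size = 4, ld_r2 = 0.6)
  m <- simulate_ld_blocks(cfg)
  f <- withr::local_tempfile(fileext = ".txt")
  write.table(m, f, sep = "\t", quote = FALSE, row.names = FALSE)
  m2 <- read_ld_matrix(f)
  expect_equal(m2, m, tolerance = 1e-12)
})
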