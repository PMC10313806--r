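#' Configuration for the synthetic paired-GWAS generator
#'
#' Defines the data-generating conditions for a two-sample MR design:
#' an exposure GWAS and an outcome GWAS linked by a scalar causal effect,
#' with optional horizontal pleiotropy, block LD, and allele-coding/strand
#' corruption of the outcome file. The defaults emulate a large
#' quantitative PTSD-trait exposure GWAS (N = 186,689) against an ischemic
#' stroke case-control GWAS (N = 440,328) with a causal log-odds effect of
#' 0.2 per exposure SD and no pleiotropy; per-SNP standard errors follow
#' se = 1/sqrt(2 N maf (1-maf)), the standardized-trait approximation.
#'
#' @param n_snp number of candidate variants.
#' @param true_beta causal effect (log-odds of outcome per exposure SD).
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param maf_range minor-allele frequency range, a subset of (0, 0.5].
#' @param gamma_sd SD of the true per-SNP exposure effects.
#' @param pleiotropy_fraction fraction of SNPs with a direct effect on the
#'   outcome.
#' @param pleiotropy_mean,pleiotropy_sd distribution of direct effects;
#'   a nonzero mean gives directional pleiotropy, zero mean balanced.
#' @param ld_block_size SNPs per LD block (1 = no LD).
#' @param ld_r2 within-block squared correlation.
#' @param sign_flip_prob probability an outcome record has its allele
#'   coding swapped (beta negated, eaf complemented).
#' @param strand_flip_prob probability an outcome record is reported on
#'   the opposite strand (alleles reverse-complemented).
#' @param palindromic_fraction fraction of SNPs given A/T or C/G alleles.
#' @param seed integer seed; every draw is reproducible from it.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_snp = 50, true_beta = 0.2,
                              n_exposure = 186689, n_outcome = 440328,
                              maf_range = c(0.05, 0.5), gamma_sd = 0.03,
                              pleiotropy_fraction = 0, pleiotropy_mean = 0,
                              pleiotropy_sd = 0.01,
                              ld_block_size = 1, ld_r2 = 0,
                              sign_flip_prob = 0.1, strand_flip_prob = 0.1,
                              palindromic_fraction = 0.15, seed = 1L) {
  cfg <- list(n_snp = as.integer(n_snp), true_beta = true_beta,
              n_exposure = n_exposure, n_outcome = n_outcome,
              maf_range = maf_range, gamma_sd = gamma_sd,
              pleiotropy_fraction = pleiotropy_fraction,
              pleiotropy_mean = pleiotropy_mean,
              pleiotropy_sd = pleiotropy_sd,
              ld_block_size = as.integer(ld_block_size), ld_r2 = ld_r2,
              sign_flip_prob = sign_flip_prob,
              strand_flip_prob = strand_flip_prob,
              palindromic_fraction = palindromic_fraction,
              seed = as.integer(seed))
  bad <- character(0)
  if (cfg$n_snp < 1) bad <- c(bad, "n_snp")
  if (cfg$n_exposure <= 0 || cfg$n_outcome <= 0) bad <- c(bad, "sample sizes")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) bad <- c(bad, "maf_range")
  if (cfg$gamma_sd <= 0) bad <- c(bad, "gamma_sd")
  for (p in c("pleiotropy_fraction", "sign_flip_prob", "strand_flip_prob",
              "palindromic_fraction", "ld_r2")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) bad <- c(bad, p)
  }
  if (cfg$ld_block_size < 1) bad <- c(bad, "ld_block_size")
  if (length(bad) > 0L) {
    stop("invalid simulation config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

NONPAL_PAIRS <- list(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                     c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
PAL_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate a paired exposure/outcome GWAS with known causal structure
#'
#' Per SNP j: maf_j ~ Uniform(maf_range); true gamma_j ~ N(0, gamma_sd^2);
#' se_gamma_j = 1/sqrt(2 n_exposure maf_j (1-maf_j)); the observed exposure
#' effect adds N(0, se^2) noise. A direct (pleiotropic) effect delta_j is
#' drawn from N(pleiotropy_mean, pleiotropy_sd^2) with probability
#' pleiotropy_fraction (else 0), the true outcome effect is
#' true_beta * gamma_j + delta_j, and the observed outcome effect adds
#' independent noise with se_alpha_j = 1/sqrt(2 n_outcome maf_j (1-maf_j))
#' — independent draws on the two sides enforce the two-sample,
#' no-overlap design. P-values are two-sided normal. The outcome file is
#' then corrupted: with `sign_flip_prob` a record's alleles are swapped
#' (beta negated, eaf complemented) and with `strand_flip_prob` its
#' alleles are reverse-complemented; every change is logged in the truth
#' manifest so harmonization can be checked against ground truth.
#'
#' Positions lie on one synthetic chromosome with LD-block members 10 kb
#' apart and 2 Mb between blocks, so a 1000-kb clumping window separates
#' blocks cleanly.
#'
#' @param config a [simulation_config()].
#' @return list with `exposure` and `outcome` (`summary_stats`) and
#'   `truth`: a data frame manifest (variant_id, ld_block, maf, true_gamma,
#'   delta, palindromic, sign_flipped, strand_flipped) plus attributes
#'   `true_beta` and `config`.
#' @export
simulate_pair <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_snp
    id <- sprintf("rs%06d", seq_len(n))
    block <- (seq_len(n) - 1L) %/% config$ld_block_size + 1L
    within <- (seq_len(n) - 1L) %% config$ld_block_size
    pos <- (block - 1L) * 2e6 + within * 1e4 + 1
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    eaf <- ifelse(stats::runif(n) < 0.5, maf, 1 - maf)

    pal <- stats::runif(n) < config$palindromic_fraction
    pair_ix_pal <- sample.int(length(PAL_PAIRS), n, replace = TRUE)
    pair_ix_non <- sample.int(length(NONPAL_PAIRS), n, replace = TRUE)
    ea <- ifelse(pal, vapply(pair_ix_pal, function(i) PAL_PAIRS[[i]][1], ""),
                 vapply(pair_ix_non, function(i) NONPAL_PAIRS[[i]][1], ""))
    oa <- ifelse(pal, vapply(pair_ix_pal, function(i) PAL_PAIRS[[i]][2], ""),
                 vapply(pair_ix_non, function(i) NONPAL_PAIRS[[i]][2], ""))

    gamma_true <- stats::rnorm(n, 0, config$gamma_sd)
    se_g <- 1 / sqrt(2 * config$n_exposure * maf * (1 - maf))
    gamma_hat <- gamma_true + stats::rnorm(n, 0, se_g)

    # a nonzero pleiotropy mean is directional relative to the
    # exposure-increasing allele, hence the sign(gamma) factor
    delta <- ifelse(stats::runif(n) < config$pleiotropy_fraction,
                    sign(gamma_true) *
                      stats::rnorm(n, config$pleiotropy_mean, config$pleiotropy_sd),
                    0)
    alpha_true <- config$true_beta * gamma_true + delta
    se_a <- 1 / sqrt(2 * config$n_outcome * maf * (1 - maf))
    alpha_hat <- alpha_true + stats::rnorm(n, 0, se_a)

    # outcome EAF measured with small noise but on the same side of 0.5,
    # so frequency-based strand resolution of palindromic SNPs is testable
    eaf_out <- eaf + stats::rnorm(n, 0, 0.01)
    eaf_out <- pmin(pmax(eaf_out, 0.01), 0.99)
    crossed <- (eaf < 0.5) != (eaf_out < 0.5)
    eaf_out[crossed] <- 1 - eaf_out[crossed]

    exposure <- summary_stats(
      data.frame(variant_id = id, chrom = "1", pos = pos,
                 effect_allele = ea, other_allele = oa, eaf = eaf,
                 beta = gamma_hat, se = se_g,
                 pvalue = pmax(2 * stats::pnorm(-abs(gamma_hat / se_g)),
                               .Machine$double.xmin),
                 n = config$n_exposure, stringsAsFactors = FALSE),
      trait_name = "synthetic PTSD trait", trait_type = "quantitative",
      ancestry = "synthetic")

    # corrupt the outcome coding; the manifest records every change
    sign_flip <- stats::runif(n) < config$sign_flip_prob
    strand_flip <- stats::runif(n) < config$strand_flip_prob
    out_ea <- ea; out_oa <- oa
    out_beta <- alpha_hat; out_eaf <- eaf_out
    sw <- sign_flip
    tmp <- out_ea[sw]; out_ea[sw] <- out_oa[sw]; out_oa[sw] <- tmp
    out_beta[sw] <- -out_beta[sw]
    out_eaf[sw] <- 1 - out_eaf[sw]
    sf <- strand_flip
    out_ea[sf] <- unname(COMPLEMENT[out_ea[sf]])
    out_oa[sf] <- unname(COMPLEMENT[out_oa[sf]])

    outcome <- summary_stats(
      data.frame(variant_id = id, chrom = "1", pos = pos,
                 effect_allele = out_ea, other_allele = out_oa,
                 eaf = out_eaf, beta = out_beta, se = se_a,
                 pvalue = pmax(2 * stats::pnorm(-abs(out_beta / se_a)),
                               .Machine$double.xmin),
                 n = config$n_outcome, stringsAsFactors = FALSE),
      trait_name = "synthetic ischemic stroke", trait_type = "binary",
      ancestry = "synthetic")

    truth <- data.frame(variant_id = id, ld_block = block, maf = maf,
                        true_gamma = gamma_true, delta = delta,
                        alpha_clean = alpha_hat, eaf_outcome_clean = eaf_out,
                        palindromic = pal, sign_flipped = sign_flip,
                        strand_flipped = strand_flip,
                        stringsAsFactors = FALSE)
    attr(truth, "true_beta") <- config$true_beta
    attr(truth, "config") <- config
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Block-diagonal LD matrix matching a simulation's block assignments
#'
#' Within-block entries equal `ld_r2`, off-block entries are zero, the
#' diagonal is exactly one. Variant IDs and block assignments follow
#' [simulate_pair()] under the same config.
#'
#' @param config a [simulation_config()].
#' @return numeric r-squared matrix with variant-ID dimnames.
#' @export
simulate_ld_blocks <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_snp
  id <- sprintf("rs%06d", seq_len(n))
  block <- (seq_len(n) - 1L) %/% config$ld_block_size + 1L
  m <- outer(block, block, function(a, b) ifelse(a == b, config$ld_r2, 0))
  diag(m) <- 1
  dimnames(m) <- list(id, id)
  m
}

#' Write a deterministic suite of test fixtures
#'
#' Four exposure/outcome pairs with truth manifests and a YAML config
#' echo: a valid-instrument pair, a directional-pleiotropy pair, a pair
#' with one planted large pleiotropic outlier, and a corruption-heavy
#' pair. Regeneration under the same seed is byte-identical.
#'
#' @param out_dir writable directory (created if needed).
#' @param seed base seed for the suite.
#' @return named list of the per-fixture directories, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 20230701L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfgs <- list(
    valid = simulation_config(n_snp = 30, seed = seed),
    directional_pleiotropy = simulation_config(
      n_snp = 30, pleiotropy_fraction = 1, pleiotropy_mean = 0.01,
      pleiotropy_sd = 0.005, seed = seed + 1L),
    planted_outlier = simulation_config(n_snp = 12, palindromic_fraction = 0,
                                        seed = seed + 2L),
    corruption_heavy = simulation_config(
      n_snp = 30, sign_flip_prob = 0.5, strand_flip_prob = 0.5,
      palindromic_fraction = 0.3, seed = seed + 3L)
  )
  dirs <- character(0)
  for (nm in names(cfgs)) {
    d <- file.path(out_dir, nm)
    dir.create(d, showWarnings = FALSE)
    sim <- simulate_pair(cfgs[[nm]])
    if (nm == "planted_outlier") {
      # give the first SNP a large direct effect on the outcome
      k <- 25 * sim$outcome$records$se[1]
      sim$outcome$records$beta[1] <- sim$outcome$records$beta[1] + k
      sim$truth$delta[1] <- sim$truth$delta[1] + k
    }
    write_summary_stats(sim$exposure, file.path(d, "exposure.tsv"))
    write_summary_stats(sim$outcome, file.path(d, "outcome.tsv"))
    tr <- sim$truth
    num <- vapply(tr, is.numeric, logical(1))
    tr[num] <- lapply(tr[num], function(x) sprintf("%.15g", x))
    utils::write.table(tr, file.path(d, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg <- unclass(cfgs[[nm]])
    cfg$true_beta_after_planting <- NULL
    yaml::write_yaml(cfg, file.path(d, "config.yaml"))
    dirs[nm] <- d
  }
  invisible(dirs)
}
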