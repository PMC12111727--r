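#' Block-diagonal AR(1) LD matrix
#'
#' Builds a linkage-disequilibrium fabric of consecutive blocks in which the
#' correlation between SNPs i and j of the same block is `rho^|i-j|` and
#' SNPs in different blocks are uncorrelated. AR(1) blocks are positive
#' semidefinite by construction.
#'
#' @param n_snps total number of variants.
#' @param block_size SNPs per block (the final block may be shorter).
#' @param rho within-block adjacent correlation, `0 <= rho < 1`.
#' @param snps optional rsid vector (defaults to rs000001...).
#' @return an `ld_matrix`.
#' @export
make_ld <- function(n_snps, block_size, rho, snps = NULL) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  stopifnot(n_snps >= 1, block_size >= 1)
  if (is.null(snps)) snps <- sprintf("rs%06d", seq_len(n_snps))
  r <- matrix(0, n_snps, n_snps)
  starts <- seq(1, n_snps, by = block_size)
  for (s in starts) {
    e <- min(s + block_size - 1L, n_snps)
    idx <- s:e
    r[idx, idx] <- rho^abs(outer(seq_along(idx), seq_along(idx), "-"))
  }
  ld_matrix(snps, r)
}

substream <- function(seed, k) {
  # widely spaced derived seeds so scenarios with nearby base seeds never
  # share an rnorm stream across roles
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483646) + 1L
}

sampling_sd <- function(trait_type, n, maf, case_fraction = NA_real_) {
  s <- if (trait_type == "binary") {
    # liability-scale approximation: log-odds SE inflated by the case/control split
    1 / sqrt(case_fraction * (1 - case_fraction))
  } else {
    1
  }
  s / sqrt(2 * n * maf * (1 - maf))
}

sim_sumstats_from_joint <- function(truth, joint, trait_id, trait_type, n,
                                    sub_seed, noise_scale = 1) {
  marginal <- as.numeric(truth$ld$r %*% joint)
  se <- sampling_sd(trait_type, n, truth$maf, truth$case_fraction)
  ld_chol <- truth$ld_chol
  if (is.null(ld_chol)) ld_chol <- chol(truth$ld$r + diag(truth$n_snps) * 1e-8)
  set.seed(sub_seed)
  # summary-statistics likelihood: z-scale noise ~ N(0, R_ld), so each
  # marginal estimate has sd se_j but neighbouring estimates are correlated
  z_noise <- as.numeric(crossprod(ld_chol, stats::rnorm(truth$n_snps)))
  beta <- marginal + noise_scale * se * z_noise
  pval <- 2 * stats::pnorm(-abs(beta / se))
  sumstats(
    data.frame(rsid = truth$rsid, chrom = truth$chrom, pos = truth$pos,
               effect_allele = truth$effect_allele, other_allele = truth$other_allele,
               beta = beta, se = se, pval = pval, eaf = truth$maf, n = n,
               stringsAsFactors = FALSE),
    trait_id = trait_id, trait_type = trait_type
  )
}

trait_joint <- function(truth, trait) {
  switch(trait,
    X = truth$exposure_effects,
    R = truth$beta1_true * truth$exposure_effects + truth$mediator_own_effects,
    Y = (truth$direct_true + truth$beta1_true * truth$beta2_true) * truth$exposure_effects +
        truth$beta2_true * truth$mediator_own_effects + truth$outcome_own_effects,
    stop("unknown trait: ", trait))
}

#' Simulate observed GWAS summary statistics for one trait
#'
#' Maps the generating joint per-SNP effects of the requested trait to
#' marginal effects through the LD matrix (`marginal = R_ld joint`), then
#' draws observed effects `beta_j ~ N(marginal_j, se_j)` jointly, with
#' z-scale noise covariance equal to the LD matrix (the summary-statistics
#' likelihood: estimates at linked SNPs share samples, so their errors are
#' correlated). The standard GWAS sampling error is
#' `se_j = s / sqrt(2 n maf_j (1 - maf_j))`, where `s`
#' is 1 for a quantitative trait and `1/sqrt(phi(1-phi))` (case fraction
#' `phi`) for the binary outcome on the log-odds scale. P-values are
#' two-sided z tests. Each trait uses its own RNG substream derived from the
#' scenario seed, so the three cohorts carry independent noise (the
#' two-sample design).
#'
#' @param truth a `sim_truth` from [simulate_mediation_scenario()].
#' @param trait `"X"` (exposure), `"R"` (mediator) or `"Y"` (outcome).
#' @param noise_scale multiplier on the sampling noise (0 gives the
#'   noiseless marginal truth; reported SEs are unchanged).
#' @return a `sumstats` object.
#' @export
simulate_trait_sumstats <- function(truth, trait = c("X", "R", "Y"), noise_scale = 1) {
  trait <- match.arg(trait)
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- switch(trait,
    X = list(id = truth$exposure_id, type = "quantitative", n = truth$n_exp, off = 1L),
    R = list(id = truth$mediator_id, type = "quantitative", n = truth$n_med, off = 2L),
    Y = list(id = truth$outcome_id, type = "binary", n = truth$n_out, off = 3L))
  sim_sumstats_from_joint(truth, trait_joint(truth, trait), cfg$id, cfg$type,
                          cfg$n, substream(truth$seed, cfg$off), noise_scale)
}

#' Simulate a two-sample MR mediation scenario
#'
#' Generates mutually consistent summary statistics for a quantitative
#' exposure protein X, a quantitative protein-ratio mediator R, and a binary
#' (log-odds scale) outcome Y under the causal structure
#' `R = beta1 X + own SNP effects` and `Y = direct X + beta2 R`, so the
#' three univariable IVW estimands are `beta1_true`, `beta2_true` and
#' `total_true = direct_true + beta1_true * beta2_true` (the mediation
#' identity holds by construction). Exposure instruments, mediator-own SNPs
#' and decoy-mediator SNPs are placed in disjoint LD blocks, so instrument
#' sets do not leak across traits. Decoy mediators have no X-to-mediator
#' path and no outcome effect, for specificity testing.
#'
#' Default scenario: 500 SNPs in AR(1) blocks of 10 (rho 0.5), 20 exposure
#' instruments, 15 mediator-own SNPs, two 5-SNP decoys, 5 outcome-own SNPs
#' (so the reverse-direction analyses are estimable, as they are for a real
#' disease GWAS), 50,000 samples per cohort, case fraction 0.1997,
#' instrument effect magnitudes 0.07-0.12 on common variants (MAF 0.2-0.5)
#' so every instrument is strong (F well above 10). Sampling noise is drawn
#' on the z scale with covariance equal to the LD matrix, the standard
#' summary-statistics likelihood for marginal GWAS estimates.
#'
#' @param beta1_true exposure-to-mediator causal effect.
#' @param beta2_true mediator-to-outcome causal effect (log-odds).
#' @param direct_true direct exposure-to-outcome effect (log-odds).
#' @param n_snps,block_size,rho LD fabric parameters.
#' @param n_instruments,n_mediator_snps,n_decoys,n_decoy_snps,n_outcome_snps
#'   causal architecture (counts of causal SNPs per trait, one per LD block).
#' @param n_exp,n_med,n_out cohort sizes (disjoint cohorts).
#' @param case_fraction outcome case fraction for the log-odds SE scale.
#' @param effect_range magnitude range for causal SNP effects.
#' @param seed integer scenario seed; all draws derive from it.
#' @return list with `exposure`, `mediator`, `outcome` (`sumstats`),
#'   `decoys` (named list of `sumstats`), `ld` (`ld_matrix`) and `truth`
#'   (`sim_truth`).
#' @export
simulate_mediation_scenario <- function(beta1_true = -0.1, beta2_true = 0.2,
                                        direct_true = -0.12,
                                        n_snps = 500, block_size = 10, rho = 0.5,
                                        n_instruments = 20, n_mediator_snps = 15,
                                        n_decoys = 2, n_decoy_snps = 5,
                                        n_outcome_snps = 5,
                                        n_exp = 50000, n_med = 50000, n_out = 50000,
                                        case_fraction = 0.1997,
                                        effect_range = c(0.07, 0.12),
                                        seed = 1L) {
  n_blocks <- ceiling(n_snps / block_size)
  needed <- n_instruments + n_mediator_snps + n_decoys * n_decoy_snps + n_outcome_snps
  if (needed > n_blocks) stop("not enough LD blocks for the requested architecture")
  set.seed(substream(seed, 0L))

  rsid <- sprintf("rs%06d", seq_len(n_snps))
  ld <- make_ld(n_snps, block_size, rho, snps = rsid)
  maf <- stats::runif(n_snps, 0.05, 0.5)

  # one causal SNP per block, mid-block, blocks assigned disjointly per trait
  block_mid <- function(b) pmin((b - 1L) * block_size + ceiling(block_size / 2), n_snps)
  b <- 0L
  take_blocks <- function(k) {
    out <- block_mid(b + seq_len(k))
    b <<- b + k
    out
  }
  x_idx <- take_blocks(n_instruments)
  r_idx <- take_blocks(n_mediator_snps)
  decoy_idx <- lapply(seq_len(n_decoys), function(i) take_blocks(n_decoy_snps))
  y_idx <- take_blocks(n_outcome_snps)

  draw_effects <- function(idx, scale = 1) {
    eff <- numeric(n_snps)
    eff[idx] <- scale * stats::runif(length(idx), effect_range[1], effect_range[2]) *
      sample(c(-1, 1), length(idx), replace = TRUE)
    eff
  }
  causal <- c(x_idx, r_idx, unlist(decoy_idx), y_idx)
  maf[causal] <- stats::runif(length(causal), 0.2, 0.5)
  # outcome-own effects live on the log-odds scale; matching the quantitative
  # instruments' z-scores requires the case-fraction inflation factor
  s_bin <- 1 / sqrt(case_fraction * (1 - case_fraction))

  truth <- structure(
    list(seed = as.integer(seed), n_snps = n_snps, rsid = rsid,
         chrom = rep("1", n_snps), pos = seq_len(n_snps) * 5000,
         effect_allele = rep("A", n_snps), other_allele = rep("G", n_snps),
         maf = maf, ld = ld, block_size = block_size, rho = rho,
         exposure_effects = draw_effects(x_idx),
         mediator_own_effects = draw_effects(r_idx),
         decoy_effects = lapply(decoy_idx, draw_effects),
         outcome_own_effects = draw_effects(y_idx, scale = s_bin),
         instrument_idx = x_idx, mediator_idx = r_idx, decoy_idx = decoy_idx,
         outcome_idx = y_idx, ld_chol = chol(ld$r + diag(n_snps) * 1e-8),
         beta1_true = beta1_true, beta2_true = beta2_true,
         direct_true = direct_true,
         total_true = direct_true + beta1_true * beta2_true,
         n_exp = n_exp, n_med = n_med, n_out = n_out,
         case_fraction = case_fraction,
         exposure_id = "X", mediator_id = "R", outcome_id = "Y"),
    class = "sim_truth"
  )

  decoys <- lapply(seq_len(n_decoys), function(i) {
    sim_sumstats_from_joint(truth, truth$decoy_effects[[i]],
                            trait_id = sprintf("decoy%d", i),
                            trait_type = "quantitative", n = n_med,
                            sub_seed = substream(seed, 10L + i))
  })
  names(decoys) <- vapply(decoys, `[[`, "", "trait_id")

  list(exposure = simulate_trait_sumstats(truth, "X"),
       mediator = simulate_trait_sumstats(truth, "R"),
       outcome = simulate_trait_sumstats(truth, "Y"),
       decoys = decoys, ld = ld, truth = truth)
}

#' Simulate a null exposure-outcome pair
#'
#' An exposure with genuine instruments but no causal effect on the outcome
#' (the outcome's true marginal effects are all zero). Used for type-I-error
#' calibration of the forward screen.
#'
#' @param n_snps,block_size,rho,n_instruments,effect_range architecture.
#' @param n sample size per cohort.
#' @param case_fraction outcome case fraction.
#' @param seed integer seed.
#' @return list with `exposure`, `outcome` and `ld`.
#' @export
simulate_null_pair <- function(n_snps = 100, block_size = 10, rho = 0.5,
                               n_instruments = 10, n = 50000,
                               case_fraction = 0.1997,
                               effect_range = c(0.07, 0.12), seed = 1L) {
  sc <- simulate_mediation_scenario(
    beta1_true = 0, beta2_true = 0, direct_true = 0,
    n_snps = n_snps, block_size = block_size, rho = rho,
    n_instruments = n_instruments, n_mediator_snps = 0, n_decoys = 0,
    n_decoy_snps = 0, n_outcome_snps = 0, n_exp = n, n_med = n, n_out = n,
    case_fraction = case_fraction, effect_range = effect_range, seed = seed)
  list(exposure = sc$exposure, outcome = sc$outcome, ld = sc$ld)
}

#' Simulate a colocalization region
#'
#' One AR(1) region observed in two traits (a quantitative exposure and the
#' binary outcome). In `"shared"` mode a single mid-region causal variant
#' drives both traits with marginal z-score `z_strength`; in `"distinct"`
#' mode each trait has its own causal variant, placed at the region's
#' quarter points so their LD is negligible.
#'
#' @param mode `"shared"` or `"distinct"`.
#' @param region_size number of SNPs (at least 10).
#' @param z_strength causal-variant marginal z-score (default 8).
#' @param rho AR(1) adjacent correlation (default 0.9).
#' @param n1,n2 sample sizes.
#' @param case_fraction trait-2 case fraction.
#' @param seed integer seed.
#' @return list with `trait1`, `trait2` (`sumstats`) and `truth` (list with
#'   the causal indices and parameters).
#' @export
simulate_coloc_scenario <- function(mode = c("shared", "distinct"),
                                    region_size = 200, z_strength = 8,
                                    rho = 0.9, n1 = 50000, n2 = 50000,
                                    case_fraction = 0.1997, seed = 1L) {
  mode <- match.arg(mode)
  if (region_size < 10) stop("region_size must be at least 10")
  set.seed(substream(seed, 0L))
  rsid <- sprintf("rs%06d", seq_len(region_size))
  ld <- make_ld(region_size, block_size = region_size, rho = rho, snps = rsid)
  maf <- stats::runif(region_size, 0.1, 0.5)

  truth_sk <- structure(
    list(seed = as.integer(seed), n_snps = region_size, rsid = rsid,
         chrom = rep("1", region_size), pos = seq_len(region_size) * 2000,
         effect_allele = rep("A", region_size), other_allele = rep("G", region_size),
         maf = maf, ld = ld, case_fraction = case_fraction,
         ld_chol = chol(ld$r + diag(region_size) * 1e-8)),
    class = "sim_truth"
  )

  se1 <- sampling_sd("quantitative", n1, maf)
  se2 <- sampling_sd("binary", n2, maf, case_fraction)
  if (mode == "shared") {
    c1 <- c2 <- region_size %/% 2
  } else {
    c1 <- region_size %/% 4
    c2 <- (3 * region_size) %/% 4
  }
  joint1 <- numeric(region_size); joint1[c1] <- z_strength * se1[c1]
  joint2 <- numeric(region_size); joint2[c2] <- z_strength * se2[c2]

  trait1 <- sim_sumstats_from_joint(truth_sk, joint1, "trait1", "quantitative",
                                    n1, substream(seed, 1L))
  trait2 <- sim_sumstats_from_joint(truth_sk, joint2, "trait2", "binary",
                                    n2, substream(seed, 2L))
  list(trait1 = trait1, trait2 = trait2,
       truth = list(mode = mode, causal1 = c1, causal2 = c2,
                    z_strength = z_strength, rho = rho, seed = seed,
                    snps = rsid))
}
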