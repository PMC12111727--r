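logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logdiffexp <- function(a, b) {
  # log(exp(a) - exp(b)), floored at -Inf when numerically non-positive
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Wakefield log approximate Bayes factor
#'
#' Per-SNP evidence for association from an estimate and its SE under a
#' Gaussian effect prior. With `V = se^2`, `W = prior_sd^2` and
#' `z = beta/se`:
#' `log ABF = 0.5 log(V/(V+W)) + 0.5 z^2 W/(V+W)`.
#'
#' @param beta,se per-SNP estimate and standard error (`se > 0`).
#' @param prior_sd prior standard deviation of a true effect (> 0).
#' @return numeric vector of log Bayes factors (association vs null).
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(prior_sd <= 0)) stop("prior_sd must be positive")
  v <- se^2
  w <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * log(v / (v + w)) + 0.5 * z2 * w / (v + w)
}

default_prior_sd <- function(trait_type) {
  switch(trait_type, quantitative = 0.20, binary = 0.15,
         stop("unknown trait type: ", trait_type))
}

#' Colocalization input over a shared region
#'
#' Bundles two traits' per-SNP effects on a common variant frame. Effect
#' prior SDs default to 0.20 for quantitative traits and 0.15 for binary
#' (log-odds) traits.
#'
#' @param snps character vector of shared rsids.
#' @param beta1,se1 trait-1 effects and SEs.
#' @param beta2,se2 trait-2 effects and SEs.
#' @param type1,type2 `"quantitative"` or `"binary"`.
#' @param prior_sd1,prior_sd2 optional prior effect SDs.
#' @return an object of class `coloc_input`.
#' @export
coloc_input <- function(snps, beta1, se1, beta2, se2,
                        type1 = "quantitative", type2 = "binary",
                        prior_sd1 = NULL, prior_sd2 = NULL) {
  n <- length(snps)
  stopifnot(n >= 1L, length(beta1) == n, length(se1) == n,
            length(beta2) == n, length(se2) == n)
  if (any(se1 <= 0) || any(se2 <= 0)) stop("all SEs must be positive")
  if (is.null(prior_sd1)) prior_sd1 <- default_prior_sd(type1)
  if (is.null(prior_sd2)) prior_sd2 <- default_prior_sd(type2)
  structure(
    list(snps = as.character(snps), beta1 = beta1, se1 = se1,
         beta2 = beta2, se2 = se2, type1 = type1, type2 = type2,
         prior_sd1 = prior_sd1, prior_sd2 = prior_sd2),
    class = "coloc_input"
  )
}

#' Bayesian colocalization posteriors (PPH0-PPH4)
#'
#' Evaluates the five single-causal-variant hypotheses for a region shared
#' by two traits: H0 no association with either trait; H1/H2 association
#' with one trait only; H3 association with both via distinct causal
#' variants; H4 a shared causal variant. Per-SNP Wakefield log ABFs are
#' combined with per-SNP prior probabilities `p1`, `p2` (single-trait
#' causal) and `p12` (shared causal); all mixture arithmetic is in log
#' space. The H3 sum over ordered distinct SNP pairs is computed as
#' `log(exp(S1 + S2) - exp(S12))` with a floor at -Inf, and is 0 by
#' construction for a single-SNP region. A pair is conventionally declared
#' colocalized when `pph4 > 0.75`.
#'
#' @param inp a `coloc_input`.
#' @param p1,p2,p12 per-SNP prior probabilities (defaults 1e-4, 1e-4, 1e-5);
#'   `p1 + p2 + p12` must be < 1.
#' @return an object of class `coloc_result`: `pph0`..`pph4`, `n_snp`,
#'   `p1`, `p2`, `p12`.
#' @export
colocalize <- function(inp, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(inherits(inp, "coloc_input"))
  if (p1 + p2 + p12 >= 1) stop("p1 + p2 + p12 must be < 1")
  l1 <- log_abf(inp$beta1, inp$se1, inp$prior_sd1)
  l2 <- log_abf(inp$beta2, inp$se2, inp$prior_sd2)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  lw <- c(
    h0 = 0,
    h1 = log(p1) + s1,
    h2 = log(p2) + s2,
    h3 = if (length(l1) >= 2L) log(p1) + log(p2) + logdiffexp(s1 + s2, s12) else -Inf,
    h4 = log(p12) + s12
  )
  post <- exp(lw - logsumexp(lw))
  structure(
    list(pph0 = post[["h0"]], pph1 = post[["h1"]], pph2 = post[["h2"]],
         pph3 = post[["h3"]], pph4 = post[["h4"]],
         n_snp = length(inp$snps), p1 = p1, p2 = p2, p12 = p12),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d SNPs: PPH0 %.3f | PPH1 %.3f | PPH2 %.3f | PPH3 %.3f | PPH4 %.3f%s\n",
              x$n_snp, x$pph0, x$pph1, x$pph2, x$pph3, x$pph4,
              if (x$pph4 > 0.75) "  [colocalized]" else ""))
  invisible(x)
}

#' Colocalize two traits around a lead variant
#'
#' Assembles the region within `window_kb` of the exposure's lead SNP,
#' harmonizes alleles against the outcome (palindromic variants dropped),
#' and runs [colocalize()] with trait-type default priors.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param lead rsid of the lead variant; must be present in `exposure`. When
#'   `NULL`, the exposure's smallest-p variant is used.
#' @param window_kb half-width of the region in kb (default 500).
#' @param p1,p2,p12 passed to [colocalize()].
#' @param prior_sd1,prior_sd2 optional prior effect SD overrides.
#' @return a `coloc_result` with attributes `lead` and trait ids.
#' @export
coloc_region <- function(exposure, outcome, lead = NULL, window_kb = 500,
                         p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         prior_sd1 = NULL, prior_sd2 = NULL) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  ex <- exposure$records
  if (is.null(lead)) lead <- ex$rsid[which.min(ex$pval)]
  i <- match(lead, ex$rsid)
  if (is.na(i)) stop("lead variant not found in exposure: ", lead)
  in_region <- ex$chrom == ex$chrom[i] & abs(ex$pos - ex$pos[i]) <= window_kb * 1000
  ex_sub <- subset_sumstats(exposure, ex$rsid[in_region])
  shared <- intersect(ex_sub$records$rsid, outcome$records$rsid)
  if (length(shared) < 2L) stop("fewer than 2 shared variants in the region")
  h <- harmonize(ex_sub, subset_sumstats(outcome, shared))
  if (nrow(h$rows) < 2L) stop("fewer than 2 harmonized variants in the region")
  inp <- coloc_input(h$rows$rsid, h$rows$beta_exp, h$rows$se_exp,
                     h$rows$beta_out, h$rows$se_out,
                     type1 = exposure$trait_type, type2 = outcome$trait_type,
                     prior_sd1 = prior_sd1, prior_sd2 = prior_sd2)
  res <- colocalize(inp, p1 = p1, p2 = p2, p12 = p12)
  attr(res, "lead") <- lead
  attr(res, "exposure_id") <- exposure$trait_id
  attr(res, "outcome_id") <- outcome$trait_id
  res
}
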