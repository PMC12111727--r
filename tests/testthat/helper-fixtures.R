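# small builders used across test files

make_ss <- function(rsid, beta, se, pval = NULL, chrom = "1",
                    pos = seq_along(rsid) * 1000,
                    ea = "A", oa = "G", trait_id = "trait",
                    trait_type = "quantitative", eaf = NA_real_, n = NA_real_) {
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  k <- length(rsid)
  rep_k <- function(x) rep_len(x, k)
  sumstats(data.frame(rsid = rsid, chrom = rep_k(chrom), pos = rep_k(pos),
                      effect_allele = rep_k(ea), other_allele = rep_k(oa),
                      beta = beta, se = rep_k(se), pval = pval,
                      eaf = rep_k(eaf), n = rep_k(n),
                      stringsAsFactors = FALSE),
           trait_id = trait_id, trait_type = trait_type)
}

make_h <- function(beta_exp, se_exp, beta_out, se_out,
                   rsid = sprintf("rs%03d", seq_along(beta_exp))) {
  structure(list(
    exposure_id = "exp", outcome_id = "out",
    rows = data.frame(rsid = rsid, beta_exp = beta_exp, se_exp = se_exp,
                      beta_out = beta_out, se_out = se_out, flipped = FALSE,
                      stringsAsFactors = FALSE),
    n_dropped_palindromic = 0L, n_dropped_unmatched = 0L),
    class = "harmonized_set")
}

# harmonized set -> two sumstats on the shared allele frame (for idempotence
# and region-level checks)
h_to_sumstats <- function(h, pos = seq_len(nrow(h$rows)) * 1000) {
  list(
    exposure = make_ss(h$rows$rsid, h$rows$beta_exp, h$rows$se_exp,
                       pos = pos, trait_id = h$exposure_id),
    outcome = make_ss(h$rows$rsid, h$rows$beta_out, h$rows$se_out,
                      pos = pos, trait_id = h$outcome_id)
  )
}
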