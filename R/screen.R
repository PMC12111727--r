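#' Screening configuration
#'
#' Collects every threshold of the screening cascade with the conventional
#' defaults: instrument p < 1e-5, clumping r^2 < 0.001 within +/-10,000 kb,
#' F > 10, nominal alpha 0.05, FDR alpha 0.05, colocalization evidence bar
#' PPH4 > 0.75, at least 2 instruments per exposure, multiplicative
#' random-effects IVW, 1000 outlier-test simulations.
#'
#' @param p_instrument instrument significance threshold.
#' @param r2 clumping squared-correlation threshold.
#' @param window_kb clumping window half-width, kb.
#' @param f_min weak-instrument bound (strict `F > f_min`).
#' @param alpha nominal significance level for causal and diagnostic tests.
#' @param fdr_alpha Benjamini-Hochberg adjusted-p threshold.
#' @param pph4_threshold colocalization evidence threshold.
#' @param min_snps minimum instruments required per exposure.
#' @param ivw_mode `"mre"` or `"fixed"`.
#' @param presso_n_sim simulations for the outlier test.
#' @param coloc_window_kb region half-width for colocalization, kb.
#' @param seed integer seed recorded in every report and used by every
#'   stochastic step.
#' @return an object of class `screen_config`.
#' @export
screen_config <- function(p_instrument = 1e-5, r2 = 0.001, window_kb = 10000,
                          f_min = 10, alpha = 0.05, fdr_alpha = 0.05,
                          pph4_threshold = 0.75, min_snps = 2,
                          ivw_mode = c("mre", "fixed"), presso_n_sim = 1000,
                          coloc_window_kb = 500, seed = 1L) {
  ivw_mode <- match.arg(ivw_mode)
  stopifnot(p_instrument > 0, p_instrument <= 1, r2 >= 0, window_kb > 0,
            f_min >= 0, alpha >= 0, alpha <= 1, fdr_alpha >= 0, fdr_alpha <= 1,
            pph4_threshold > 0, pph4_threshold < 1, min_snps >= 1,
            presso_n_sim >= 100)
  structure(
    list(p_instrument = p_instrument, r2 = r2, window_kb = window_kb,
         f_min = f_min, alpha = alpha, fdr_alpha = fdr_alpha,
         pph4_threshold = pph4_threshold, min_snps = as.integer(min_snps),
         ivw_mode = ivw_mode, presso_n_sim = as.integer(presso_n_sim),
         coloc_window_kb = coloc_window_kb, seed = as.integer(seed)),
    class = "screen_config"
  )
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment: with p-values ranked ascending,
#' `adj_(i) = min_(j >= i) m p_(j) / j`, capped at 1, returned in the input
#' order. Output dominates the input elementwise.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(pvals)
  ord <- order(pvals)
  ranked <- pvals[ord] * m / seq_len(m)
  adj_sorted <- pmin(1, rev(cummin(rev(ranked))))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

#' Two-step MR mediated proportion
#'
#' Given the exposure-to-mediator effect `beta1`, the mediator-to-outcome
#' effect `beta2` and the total exposure-to-outcome effect `total_beta`
#' (each a univariable IVW estimate), the indirect effect is
#' `beta1 * beta2` and the mediated proportion is
#' `100 * beta1 * beta2 / total_beta` percent. The proportion is signed: a
#' negative value means the mediated path runs contrary to the total effect.
#' `direction_consistent` is defined only when both the indirect and total
#' effects are nonzero.
#'
#' @param beta1,beta2,total_beta the three IVW estimates.
#' @param exposure_id,mediator_id,outcome_id optional trait labels.
#' @return an object of class `mediation_result`.
#' @export
mediation <- function(beta1, beta2, total_beta,
                      exposure_id = NA_character_, mediator_id = NA_character_,
                      outcome_id = NA_character_) {
  indirect <- beta1 * beta2
  if (total_beta == 0) {
    warning("total effect is zero; mediated proportion undefined")
    proportion <- NA_real_
  } else {
    proportion <- 100 * indirect / total_beta
  }
  direction_consistent <- if (indirect != 0 && total_beta != 0) {
    sign(indirect) == sign(total_beta)
  } else {
    NA
  }
  structure(
    list(exposure_id = exposure_id, mediator_id = mediator_id,
         outcome_id = outcome_id, beta1 = beta1, beta2 = beta2,
         total_beta = total_beta, indirect = indirect,
         proportion = proportion, direction_consistent = direction_consistent),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation> beta1 = %.3f, beta2 = %.3f, total = %.3f -> indirect = %.4f, proportion = %.3f%%%s\n",
              x$beta1, x$beta2, x$total_beta, x$indirect, x$proportion,
              if (isTRUE(x$direction_consistent)) " (consistent)"
              else if (isFALSE(x$direction_consistent)) " (contrary)" else ""))
  invisible(x)
}

#' One exposure-outcome MR analysis with diagnostics
#'
#' The per-pair workhorse behind the screens: selects instruments from the
#' exposure, harmonizes them against the outcome, and (when at least
#' `min_snps` instruments survive) runs IVW, MR-Egger (from 3 instruments)
#' and, when the Egger intercept flags directional pleiotropy at `alpha`,
#' the simulation-based outlier test with removal and IVW re-test.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param ld an `ld_matrix`.
#' @param cfg a `screen_config`.
#' @return a list: `mr` (the headline `mr_result`, outlier-corrected when
#'   pleiotropy was flagged), `egger`, `presso`, `n_snp`,
#'   `pleiotropy_flag`, `heterogeneity_flag`, and `reason` (`NULL` when the
#'   analysis ran, otherwise why it was skipped).
#' @export
mr_pair <- function(exposure, outcome, ld, cfg) {
  stopifnot(inherits(cfg, "screen_config"))
  sel <- select_instruments(exposure, ld, p_threshold = cfg$p_instrument,
                            r2_threshold = cfg$r2, window_kb = cfg$window_kb,
                            f_min = cfg$f_min)
  empty <- list(mr = NULL, egger = NULL, presso = NULL, n_snp = 0L,
                pleiotropy_flag = NA, heterogeneity_flag = NA,
                selection = sel, reason = NULL)
  if (length(sel$kept) < cfg$min_snps) {
    empty$reason <- "min_snps"
    empty$n_snp <- length(sel$kept)
    return(empty)
  }
  h <- tryCatch(harmonize(subset_sumstats(exposure, sel$kept), outcome),
                error = function(e) NULL)
  if (is.null(h) || nrow(h$rows) < cfg$min_snps) {
    empty$reason <- if (is.null(h)) "no_overlap" else "min_snps"
    empty$n_snp <- if (is.null(h)) 0L else nrow(h$rows)
    return(empty)
  }
  mr <- mr_ivw(h, mode = cfg$ivw_mode)
  egger <- if (nrow(h$rows) >= 3L) mr_egger(h) else NULL
  pleio <- !is.null(egger) && egger$egger_intercept_pval < cfg$alpha
  het <- !is.na(mr$q_pval) && mr$q_pval < cfg$alpha
  presso <- NULL
  if (pleio && nrow(h$rows) >= 4L) {
    presso <- mr_presso(h, n_sim = cfg$presso_n_sim, alpha = cfg$alpha,
                        seed = cfg$seed, mode = cfg$ivw_mode)
    if (length(presso$outliers) > 0L && !is.null(presso$corrected)) {
      mr <- presso$corrected
    }
  }
  list(mr = mr, egger = egger, presso = presso, n_snp = mr$n_snp,
       pleiotropy_flag = pleio, heterogeneity_flag = het,
       selection = sel, reason = NULL)
}

new_candidate <- function(exposure_id, outcome_id, pair) {
  structure(
    list(exposure_id = exposure_id, outcome_id = outcome_id,
         forward = pair$mr, egger = pair$egger, presso = pair$presso,
         reverse = NULL, unidirectional = NA,
         pleiotropy_flag = pair$pleiotropy_flag,
         heterogeneity_flag = pair$heterogeneity_flag,
         adj_p = NA_real_, coloc = NULL),
    class = "causal_candidate"
  )
}

#' Forward MR screen of an exposure panel
#'
#' Runs [mr_pair()] for every exposure against the outcome and retains
#' candidates whose IVW p-value is strictly below `cfg$alpha` (the
#' outlier-corrected estimate is used where pleiotropy was flagged).
#' Exposures skipped (too few instruments, no overlap) or non-significant
#' are recorded in the `drops` attribute so the screening funnel is fully
#' observable.
#'
#' @param exposures list of `sumstats` objects.
#' @param outcome outcome `sumstats`.
#' @param ld an `ld_matrix`.
#' @param cfg a `screen_config`.
#' @return list of `causal_candidate` objects with attribute `drops`
#'   (data frame `exposure_id`, `reason`).
#' @export
forward_screen <- function(exposures, outcome, ld, cfg) {
  candidates <- list()
  drops <- data.frame(exposure_id = character(0), reason = character(0),
                      stringsAsFactors = FALSE)
  for (ex in exposures) {
    pair <- mr_pair(ex, outcome, ld, cfg)
    if (!is.null(pair$reason)) {
      drops <- rbind(drops, data.frame(exposure_id = ex$trait_id,
                                       reason = pair$reason))
      next
    }
    if (pair$mr$pval >= cfg$alpha) {
      drops <- rbind(drops, data.frame(exposure_id = ex$trait_id,
                                       reason = "not_significant"))
      next
    }
    candidates[[length(candidates) + 1L]] <- new_candidate(ex$trait_id,
                                                           outcome$trait_id, pair)
  }
  attr(candidates, "drops") <- drops
  candidates
}

#' Reverse MR screen of forward candidates
#'
#' Re-runs the identical MR machinery with the roles swapped (the outcome
#' trait as exposure, each candidate exposure as outcome), fills the
#' `reverse` slot, and sets `unidirectional`: forward-significant and
#' either no estimable reverse analysis or reverse p at or above `alpha`.
#' Candidates with reverse p strictly below `alpha` exhibit reverse
#' causation and are marked for exclusion.
#'
#' @param candidates output of [forward_screen()].
#' @param outcome_as_exposure the outcome trait's `sumstats` (now exposure).
#' @param exposure_stats named list mapping exposure id to its `sumstats`.
#' @param ld an `ld_matrix`.
#' @param cfg a `screen_config`.
#' @return the candidates, each with `reverse` and `unidirectional` set.
#' @export
reverse_screen <- function(candidates, outcome_as_exposure, exposure_stats, ld, cfg) {
  out <- lapply(candidates, function(cand) {
    ex_ss <- exposure_stats[[cand$exposure_id]]
    if (is.null(ex_ss)) stop("missing summary statistics for ", cand$exposure_id)
    pair <- mr_pair(outcome_as_exposure, ex_ss, ld, cfg)
    cand$reverse <- pair$mr
    fwd_sig <- cand$forward$pval < cfg$alpha
    cand$unidirectional <- fwd_sig &&
      (is.null(pair$mr) || pair$mr$pval >= cfg$alpha)
    cand
  })
  attr(out, "drops") <- attr(candidates, "drops")
  out
}

#' Mediator screen for one surviving exposure
#'
#' For each candidate mediator: (1) bidirectional MR between the exposure
#' and the mediator, keeping mediators with a unidirectional
#' exposure-to-mediator effect (forward p < alpha, reverse p not < alpha);
#' (2) MR of each surviving mediator on the outcome, with Benjamini-Hochberg
#' adjustment across this exposure's mediator family, keeping adjusted p <
#' `fdr_alpha`; (3) regional colocalization of each survivor against the
#' outcome (survivors failing the PPH4 bar are retained but labeled, since
#' a shared causal variant being unproven does not rule the pair out).
#'
#' @param exposure a `sumstats` that survived the forward+reverse screens.
#' @param mediators list of mediator `sumstats`.
#' @param outcome outcome `sumstats`.
#' @param ld an `ld_matrix`.
#' @param cfg a `screen_config`.
#' @return list of `causal_candidate` objects (exposure -> mediator), each
#'   carrying `mediator_outcome` (an `mr_result`), `adj_p`, `coloc` and
#'   `coloc_established`; attribute `drops` records every exclusion.
#' @export
mediator_screen <- function(exposure, mediators, outcome, ld, cfg) {
  drops <- data.frame(exposure_id = character(0), reason = character(0),
                      stringsAsFactors = FALSE)
  surv <- list()
  for (med in mediators) {
    fwd <- mr_pair(exposure, med, ld, cfg)
    if (!is.null(fwd$reason)) {
      drops <- rbind(drops, data.frame(exposure_id = med$trait_id, reason = fwd$reason))
      next
    }
    if (fwd$mr$pval >= cfg$alpha) {
      drops <- rbind(drops, data.frame(exposure_id = med$trait_id,
                                       reason = "no_exposure_effect"))
      next
    }
    rev <- mr_pair(med, exposure, ld, cfg)
    if (!is.null(rev$mr) && rev$mr$pval < cfg$alpha) {
      drops <- rbind(drops, data.frame(exposure_id = med$trait_id,
                                       reason = "bidirectional"))
      next
    }
    cand <- new_candidate(exposure$trait_id, med$trait_id, fwd)
    cand$reverse <- rev$mr
    cand$unidirectional <- TRUE
    surv[[length(surv) + 1L]] <- cand
  }

  # mediator -> outcome MR, FDR within this exposure's mediator family
  med_by_id <- stats::setNames(mediators, vapply(mediators, `[[`, "", "trait_id"))
  mo <- lapply(surv, function(cand) mr_pair(med_by_id[[cand$outcome_id]], outcome, ld, cfg))
  estimable <- vapply(mo, function(p) is.null(p$reason), logical(1))
  for (i in which(!estimable)) {
    drops <- rbind(drops, data.frame(exposure_id = surv[[i]]$outcome_id,
                                     reason = mo[[i]]$reason))
  }
  surv <- surv[estimable]
  mo <- mo[estimable]
  if (length(surv) > 0L) {
    adj <- bh_fdr(vapply(mo, function(p) p$mr$pval, numeric(1)))
    keep <- adj < cfg$fdr_alpha
    for (i in which(!keep)) {
      drops <- rbind(drops, data.frame(exposure_id = surv[[i]]$outcome_id,
                                       reason = "fdr"))
    }
    surv <- mapply(function(cand, pair, a) {
      cand$mediator_outcome <- pair$mr
      cand$adj_p <- a
      cand
    }, surv, mo, adj, SIMPLIFY = FALSE)[keep]
  }

  surv <- lapply(surv, function(cand) {
    cand$coloc <- tryCatch(
      coloc_region(med_by_id[[cand$outcome_id]], outcome,
                   window_kb = cfg$coloc_window_kb),
      error = function(e) NULL)
    cand$coloc_established <- !is.null(cand$coloc) &&
      cand$coloc$pph4 > cfg$pph4_threshold
    cand
  })
  attr(surv, "drops") <- drops
  surv
}
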