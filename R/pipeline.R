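fmt_or_ci <- function(mr) {
  sprintf("%.3f(%.3f-%.3f)", mr$or, mr$ci_low, mr$ci_high)
}

fmt_p <- function(p) {
  ifelse(is.na(p), "NA", sprintf("%.4g", p))
}

write_tsv_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

candidate_table_row <- function(cand) {
  rev_p <- if (is.null(cand$reverse)) NA_real_ else cand$reverse$pval
  paste(cand$exposure_id, cand$outcome_id, cand$forward$n_snp,
        fmt_or_ci(cand$forward), fmt_p(cand$forward$pval),
        fmt_p(cand$forward$q_pval),
        fmt_p(if (is.null(cand$egger)) NA_real_ else cand$egger$egger_intercept_pval),
        fmt_p(rev_p), sep = "\t")
}

#' Run the full screening and mediation pipeline
#'
#' Executes the whole cascade on one dataset bundle: forward MR of every
#' exposure on the outcome, reverse MR to exclude reverse causation, the
#' same bidirectional screen for the mediator panel, then for every
#' surviving exposure the mediator screen (exposure-to-mediator MR,
#' family-wise FDR on the mediator-to-outcome estimates, regional
#' colocalization) and the two-step mediated-proportion calculation. Three
#' TSV report tables and a run manifest are written to `out_dir`:
#' `table1_exposure_outcome.tsv` (bidirectional exposure results),
#' `table2_reverse.tsv` (mediators excluded for reverse causation),
#' `table3_mediation.tsv` (the mediation triples and proportions), and
#' `manifest.txt` (config snapshot, seed, per-gate counts, input digests).
#' All tables are byte-deterministic under a fixed `cfg$seed`; the manifest
#' additionally carries a `generated_at` timestamp.
#'
#' @param datasets list with `exposures` (list of `sumstats`), `mediators`
#'   (list of `sumstats`), `outcome` (`sumstats`), `ld` (`ld_matrix`) and
#'   optionally `input_paths` (character vector of source files to digest).
#' @param cfg a `screen_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the candidate sets, the mediation results
#'   and the per-gate counts.
#' @export
run_pipeline <- function(datasets, cfg, out_dir) {
  stopifnot(inherits(cfg, "screen_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exposures <- datasets$exposures
  mediators <- datasets$mediators
  outcome <- datasets$outcome
  ld <- datasets$ld
  ex_by_id <- stats::setNames(exposures, vapply(exposures, `[[`, "", "trait_id"))
  med_by_id <- stats::setNames(mediators, vapply(mediators, `[[`, "", "trait_id"))

  # exposure panel: forward then reverse
  fwd <- forward_screen(exposures, outcome, ld, cfg)
  rev <- reverse_screen(fwd, outcome, ex_by_id, ld, cfg)
  surviving_exposures <- Filter(function(cand) isTRUE(cand$unidirectional), rev)

  # mediator panel: forward then reverse against the outcome
  fwd_med <- forward_screen(mediators, outcome, ld, cfg)
  rev_med <- reverse_screen(fwd_med, outcome, med_by_id, ld, cfg)
  reverse_excluded <- Filter(function(cand) !isTRUE(cand$unidirectional), rev_med)
  surviving_mediators <- Filter(function(cand) isTRUE(cand$unidirectional), rev_med)
  med_panel <- lapply(surviving_mediators, function(cand) med_by_id[[cand$exposure_id]])

  # per-exposure mediator screen + mediation
  med_results <- list()
  med_cands <- list()
  for (cand in surviving_exposures) {
    ex_ss <- ex_by_id[[cand$exposure_id]]
    mc <- if (length(med_panel) > 0L) {
      mediator_screen(ex_ss, med_panel, outcome, ld, cfg)
    } else {
      list()
    }
    med_cands[[cand$exposure_id]] <- mc
    for (m in mc) {
      med_results[[length(med_results) + 1L]] <- mediation(
        beta1 = m$forward$beta, beta2 = m$mediator_outcome$beta,
        total_beta = cand$forward$beta,
        exposure_id = cand$exposure_id, mediator_id = m$outcome_id,
        outcome_id = outcome$trait_id)
    }
  }

  # table 1: exposures with bidirectional results
  t1 <- paste("Exposure", "Outcome", "SNPs", "OR_95CI", "P_IVW",
              "P_Heterogeneity", "P_Pleiotropy", "Reverse_MR_P_IVW", sep = "\t")
  for (cand in rev) t1 <- c(t1, candidate_table_row(cand))

  # table 2: mediators excluded for reverse causation (outcome as exposure)
  t2 <- paste("Exposure", "Outcome", "SNPs", "OR_95CI", "P_IVW", sep = "\t")
  for (cand in reverse_excluded) {
    if (is.null(cand$reverse)) next
    t2 <- c(t2, paste(outcome$trait_id, cand$exposure_id, cand$reverse$n_snp,
                      fmt_or_ci(cand$reverse), fmt_p(cand$reverse$pval), sep = "\t"))
  }

  # table 3: mediation triples
  t3 <- paste("Exposure", "Mediator", "Outcome", "Beta1", "Beta2",
              "Total_Beta", "Mediated_Proportion", "Direction_Consistent", sep = "\t")
  for (m in med_results) {
    t3 <- c(t3, paste(m$exposure_id, m$mediator_id, m$outcome_id,
                      sprintf("%.6g", m$beta1), sprintf("%.6g", m$beta2),
                      sprintf("%.6g", m$total_beta),
                      sprintf("%.3f%%", m$proportion),
                      ifelse(isTRUE(m$direction_consistent), "yes", "no"),
                      sep = "\t"))
  }

  counts <- c(
    exposures_in = length(exposures),
    exposures_forward = length(fwd),
    exposures_unidirectional = length(surviving_exposures),
    mediators_in = length(mediators),
    mediators_forward = length(fwd_med),
    mediators_unidirectional = length(surviving_mediators),
    mediation_pairs = length(med_results)
  )

  write_tsv_lines(t1, file.path(out_dir, "table1_exposure_outcome.tsv"))
  write_tsv_lines(t2, file.path(out_dir, "table2_reverse.tsv"))
  write_tsv_lines(t3, file.path(out_dir, "table3_mediation.tsv"))
  write_manifest(file.path(out_dir, "manifest.txt"), cfg, counts,
                 datasets$input_paths)

  invisible(list(exposure_candidates = rev, mediator_candidates = rev_med,
                 per_exposure_mediators = med_cands, mediation = med_results,
                 counts = counts))
}

write_manifest <- function(path, cfg, counts, input_paths = NULL) {
  lines <- c(
    sprintf("tool_version: ratiomr %s",
            as.character(utils::packageVersion("ratiomr"))),
    sprintf("generated_at: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed: %d", cfg$seed),
    vapply(setdiff(names(cfg), "seed"), function(k) {
      sprintf("config.%s: %s", k, format(cfg[[k]], scientific = FALSE))
    }, character(1)),
    vapply(names(counts), function(k) {
      sprintf("counts.%s: %d", k, counts[[k]])
    }, character(1))
  )
  if (!is.null(input_paths)) {
    digests <- tools::md5sum(input_paths)
    lines <- c(lines, sprintf("input.%s: %s", basename(input_paths), digests))
  }
  write_tsv_lines(lines, path)
}
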