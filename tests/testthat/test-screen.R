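test_that("screen_config validates thresholds and records defaults", {
  cfg <- screen_config(seed = 5)
  expect_equal(cfg$p_instrument, 1e-5)
  expect_equal(cfg$r2, 0.001)
  expect_equal(cfg$window_kb, 10000)
  expect_equal(cfg$f_min, 10)
  expect_equal(cfg$pph4_threshold, 0.75)
  expect_equal(cfg$ivw_mode, "mre")
  expect_equal(cfg$seed, 5L)
  expect_error(screen_config(p_instrument = 0))
  expect_error(screen_config(min_snps = 0))
  expect_error(screen_config(presso_n_sim = 10))
})

test_that("bh_fdr reproduces the hand step-up oracle and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(0.42), 0.42)
  expect_error(bh_fdr(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\(0, 1\\]")

  set.seed(41)
  for (i in 1:10) {
    p <- runif(sample(1:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p))
    expect_equal(adj, p.adjust(p, method = "BH"))  # independent cross-check
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
})

test_that("mediation computes signed percent proportions and consistency", {
  m <- mediation(0, 0.5, 1.0)
  expect_equal(m$proportion, 0)
  expect_true(is.na(m$direction_consistent))
  expect_warning(mz <- mediation(0.1, 0.2, 0), "undefined")
  expect_true(is.na(mz$proportion))
  mc <- mediation(-0.2, 0.3, 0.1)
  expect_false(mc$direction_consistent)
  expect_equal(mc$proportion, -60)
})

test_that("mediation is invariant to compensating rescaling of beta1 and beta2", {
  m0 <- mediation(-0.084, 0.159, -0.143)
  for (c_ in c(0.2, 3, 17)) {
    m <- mediation(-0.084 * c_, 0.159 / c_, -0.143)
    expect_equal(m$indirect, m0$indirect, tolerance = 1e-12)
    expect_equal(m$proportion, m0$proportion, tolerance = 1e-12)
  }
})

test_that("forward_screen keeps true signals, drops 1-instrument exposures", {
  # screen against the mediator: the X -> R effect is strong by construction
  sc <- simulate_mediation_scenario(seed = 101)
  cfg <- screen_config(seed = 101)
  # exposure restricted to its first instrument's LD block: a single
  # clump-surviving instrument -> excluded as min_snps
  one_snp <- subset_sumstats(sc$exposure, sc$truth$rsid[1:10])
  one_snp$trait_id <- "one_instrument"
  cands <- forward_screen(list(sc$exposure, one_snp), sc$mediator, sc$ld, cfg)
  expect_equal(vapply(cands, `[[`, "", "exposure_id"), "X")
  drops <- attr(cands, "drops")
  expect_equal(drops$reason[drops$exposure_id == "one_instrument"], "min_snps")
  expect_lt(cands[[1]]$forward$pval, cfg$alpha)
})

test_that("forward_screen on an empty exposure list returns an empty set", {
  sc <- simulate_null_pair(seed = 3)
  cands <- forward_screen(list(), sc$outcome, sc$ld, screen_config(seed = 3))
  expect_length(cands, 0)
})

test_that("reverse_screen separates unidirectional from reverse-causal candidates", {
  # X causally affects R; the reverse analysis (R's instruments on X) is null
  sc <- simulate_mediation_scenario(seed = 55)
  cfg <- screen_config(seed = 55)
  cands <- forward_screen(list(sc$exposure), sc$mediator, sc$ld, cfg)
  expect_length(cands, 1)
  rev <- reverse_screen(cands, sc$mediator, list(X = sc$exposure), sc$ld, cfg)
  expect_true(rev[[1]]$unidirectional)
  expect_gte(rev[[1]]$reverse$pval, cfg$alpha)

  # swap the roles: R <- X is now the "reverse" test and is significant
  cands2 <- forward_screen(list(sc$mediator), sc$exposure, sc$ld, cfg)
  if (length(cands2) > 0) {
    rev2 <- reverse_screen(cands2, sc$exposure, list(R = sc$mediator), sc$ld, cfg)
    expect_false(rev2[[1]]$unidirectional)
  }
})

test_that("a reverse p exactly at alpha is retained (strict < for exclusion)", {
  sc <- simulate_mediation_scenario(seed = 56)
  cands <- forward_screen(list(sc$exposure), sc$mediator, sc$ld, screen_config(seed = 56))
  rev0 <- reverse_screen(cands, sc$mediator, list(X = sc$exposure), sc$ld,
                         screen_config(seed = 56))
  p_rev <- rev0[[1]]$reverse$pval
  expect_true(is.finite(p_rev))
  # re-run with alpha set exactly to the observed reverse p: forward stays
  # significant (X -> R is overwhelming), reverse is not < alpha -> retained
  cfg_edge <- screen_config(alpha = p_rev, seed = 56)
  rev1 <- reverse_screen(cands, sc$mediator, list(X = sc$exposure), sc$ld, cfg_edge)
  expect_true(rev1[[1]]$unidirectional)
})

test_that("mediator_screen keeps the planted mediator and rejects decoys", {
  sc <- simulate_mediation_scenario(seed = 77)
  cfg <- screen_config(seed = 77)
  meds <- c(list(sc$mediator), unname(sc$decoys))
  surv <- mediator_screen(sc$exposure, meds, sc$outcome, sc$ld, cfg)
  expect_equal(vapply(surv, `[[`, "", "outcome_id"), "R")
  expect_lt(surv[[1]]$adj_p, cfg$fdr_alpha)
  drops <- attr(surv, "drops")
  expect_setequal(drops$exposure_id, c("decoy1", "decoy2"))
  expect_true(all(drops$reason == "no_exposure_effect"))
  expect_s3_class(surv[[1]]$coloc, "coloc_result")
})

test_that("run_pipeline produces the three report tables with the planted pair", {
  sc <- simulate_mediation_scenario(seed = 88)
  cfg <- screen_config(seed = 88)
  out <- withr::local_tempdir()
  datasets <- list(exposures = list(sc$exposure),
                   mediators = c(list(sc$mediator), unname(sc$decoys)),
                   outcome = sc$outcome, ld = sc$ld)
  res <- run_pipeline(datasets, cfg, out)
  expect_true(all(file.exists(file.path(out, c(
    "table1_exposure_outcome.tsv", "table2_reverse.tsv",
    "table3_mediation.tsv", "manifest.txt")))))
  t3 <- read.delim(file.path(out, "table3_mediation.tsv"), check.names = FALSE)
  expect_equal(nrow(t3), 1L)
  expect_equal(t3$Exposure, "X")
  expect_equal(t3$Mediator, "R")
  # recovered proportion should be within Monte-Carlo range of the truth (14.3%)
  prop <- as.numeric(sub("%", "", t3$Mediated_Proportion))
  expect_gt(prop, 0)
  expect_lt(abs(prop - 100 * sc$truth$beta1_true * sc$truth$beta2_true /
                  sc$truth$total_true), 30)
  expect_equal(unname(res$counts["mediation_pairs"]), 1L)
  # gate counts are monotone non-increasing along each cascade
  expect_lte(res$counts[["exposures_forward"]], res$counts[["exposures_in"]])
  expect_lte(res$counts[["exposures_unidirectional"]], res$counts[["exposures_forward"]])
  expect_lte(res$counts[["mediators_forward"]], res$counts[["mediators_in"]])
  expect_lte(res$counts[["mediators_unidirectional"]], res$counts[["mediators_forward"]])
})

test_that("run_pipeline with alpha = 0 completes with empty gates", {
  sc <- simulate_mediation_scenario(seed = 89, n_snps = 200, n_instruments = 5,
                                    n_mediator_snps = 5, n_decoys = 0)
  cfg <- screen_config(alpha = 0, seed = 89)
  out <- withr::local_tempdir()
  res <- run_pipeline(list(exposures = list(sc$exposure),
                           mediators = list(sc$mediator),
                           outcome = sc$outcome, ld = sc$ld), cfg, out)
  expect_equal(unname(res$counts["exposures_forward"]), 0L)
  expect_equal(unname(res$counts["mediation_pairs"]), 0L)
  # explicit empty tables, not crashes
  expect_length(readLines(file.path(out, "table3_mediation.tsv")), 1L)
})
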