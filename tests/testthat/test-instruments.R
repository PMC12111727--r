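test_that("f_statistic is beta^2/se^2 and guards its domain", {
  expect_equal(f_statistic(0.10, 0.05), 4.0)
  expect_equal(f_statistic(0.0, 0.1), 0.0)
  expect_equal(f_statistic(0.2, 0.02), 100.0)
  expect_error(f_statistic(0.1, 0), "positive")
})

test_that("filter_significant uses a strict inequality", {
  ss <- make_ss(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.1, 0.1),
                se = c(0.01, 0.01, 0.01), pval = c(9e-6, 1e-5, 0.5))
  kept <- filter_significant(ss)
  expect_equal(kept$records$rsid, "rs1")
  empty <- filter_significant(make_ss(character(0), numeric(0), numeric(0)))
  expect_equal(n_variants(empty), 0L)
})

test_that("ld_matrix validates symmetry, diagonal and range", {
  r <- diag(2)
  expect_s3_class(ld_matrix(c("a", "b"), r), "ld_matrix")
  bad <- r; bad[1, 2] <- 0.5
  expect_error(ld_matrix(c("a", "b"), bad), "symmetric")
  bad <- r; diag(bad) <- 0.9
  expect_error(ld_matrix(c("a", "b"), bad), "diagonal")
  bad <- matrix(c(1, 1.5, 1.5, 1), 2)
  expect_error(ld_matrix(c("a", "b"), bad), "\\[-1, 1\\]")
  expect_error(ld_matrix("a", diag(2)), "dimension")
})

test_that("read_ld parses square and triplet dialects identically", {
  r <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  sq <- withr::local_tempfile()
  writeLines(c("rsid\trs1\trs2", "rs1\t1\t0.4", "rs2\t0.4\t1"), sq)
  tri <- withr::local_tempfile()
  writeLines(c("rsid_a\trsid_b\tr", "rs1\trs2\t0.4"), tri)
  m1 <- read_ld(sq)
  m2 <- read_ld(tri)
  expect_equal(m1$r, r)
  expect_equal(m2$r[m1$snps, m1$snps], r)
})

test_that("clump keeps the dominant SNP of a correlated pair", {
  ss <- make_ss(c("rsA", "rsB"), beta = c(0.1, 0.1), se = c(0.01, 0.01),
                pval = c(1e-8, 1e-6), pos = c(1e5, 2e5))
  r <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2)
  ld <- ld_matrix(c("rsA", "rsB"), r)
  sel <- clump(ss, ld)
  expect_equal(sel$kept, "rsA")
  expect_equal(sel$dropped_ld, 1L)
})

test_that("SNPs on different chromosomes are never clumped", {
  ss <- make_ss(c("rsA", "rsB"), beta = c(0.1, 0.1), se = c(0.01, 0.01),
                pval = c(1e-8, 1e-6), chrom = c("1", "2"), pos = c(1e5, 1e5))
  ld <- ld_matrix(c("rsA", "rsB"), matrix(c(1, 0.9, 0.9, 1), 2))
  sel <- clump(ss, ld)
  expect_setequal(sel$kept, c("rsA", "rsB"))
})

test_that("clump matches the exhaustive greedy oracle on random instances", {
  for (seed in 1:12) {
    inst <- random_clump_instance(seed, n = sample(4:10, 1))
    ss <- sumstats(data.frame(
      rsid = inst$rec$rsid, chrom = inst$rec$chrom, pos = inst$rec$pos,
      effect_allele = "A", other_allele = "G",
      beta = inst$rec$beta, se = inst$rec$se, pval = inst$rec$pval), "t")
    ld <- ld_matrix(rownames(inst$r), inst$r)
    for (r2 in c(0.001, 0.1, 0.5)) {
      got <- clump(ss, ld, r2_threshold = r2, window_kb = 300)$kept
      want <- oracle_clump(inst$rec, inst$r, r2, 300)
      expect_identical(got, want)
    }
  }
})

test_that("clump output is invariant to input row order", {
  inst <- random_clump_instance(99, n = 9)
  df <- data.frame(rsid = inst$rec$rsid, chrom = inst$rec$chrom,
                   pos = inst$rec$pos, effect_allele = "A", other_allele = "G",
                   beta = inst$rec$beta, se = inst$rec$se, pval = inst$rec$pval)
  ld <- ld_matrix(rownames(inst$r), inst$r)
  base <- clump(sumstats(df, "t"), ld, 0.05, 500)$kept
  for (i in 1:5) {
    perm <- df[sample(nrow(df)), ]
    expect_identical(clump(sumstats(perm, "t"), ld, 0.05, 500)$kept, base)
  }
})

test_that("every LD-dropped SNP is dominated by a kept SNP within the window", {
  inst <- random_clump_instance(7, n = 10)
  df <- inst$rec
  ss <- sumstats(data.frame(rsid = df$rsid, chrom = df$chrom, pos = df$pos,
                            effect_allele = "A", other_allele = "G",
                            beta = df$beta, se = df$se, pval = df$pval), "t")
  ld <- ld_matrix(rownames(inst$r), inst$r)
  r2_thr <- 0.05; win <- 400
  kept <- clump(ss, ld, r2_thr, win)$kept
  dropped <- setdiff(df$rsid, kept)
  for (d in dropped) {
    i <- match(d, df$rsid)
    dominated <- FALSE
    for (k in kept) {
      j <- match(k, df$rsid)
      if (df$chrom[j] == df$chrom[i] && abs(df$pos[j] - df$pos[i]) <= win * 1000 &&
          inst$r[match(k, rownames(inst$r)), match(d, rownames(inst$r))]^2 >= r2_thr &&
          (df$pval[j] < df$pval[i] ||
           (df$pval[j] == df$pval[i] && df$rsid[j] <= df$rsid[i]))) {
        dominated <- TRUE
      }
    }
    expect_true(dominated, label = sprintf("SNP %s dominated", d))
  }
})

test_that("variants missing from the LD reference are assumed uncorrelated", {
  ss <- make_ss(c("rsA", "rsZ"), beta = c(0.1, 0.1), se = c(0.01, 0.01),
                pval = c(1e-8, 1e-6), pos = c(1e5, 1.5e5))
  ld <- ld_matrix("rsA", matrix(1))
  expect_warning(sel <- clump(ss, ld), "absent")
  expect_setequal(sel$kept, c("rsA", "rsZ"))
})

test_that("select_instruments applies the F > 10 gate strictly and counts drops", {
  ss <- make_ss(c("rs1", "rs2", "rs3"),
                beta = c(0.1, 0.2, 0.0316227766), se = c(0.05, 0.02, 0.01),
                pval = c(1e-8, 1e-9, 1e-7), pos = c(1e5, 5e6, 9e6))
  ld <- make_ld(3, 1, 0, snps = c("rs1", "rs2", "rs3"))
  sel <- select_instruments(ss, ld)
  # rs1: F = 4 (dropped); rs3: F = 10.000... borderline -> strictly > 10 required
  expect_false("rs1" %in% sel$kept)
  expect_equal(sel$dropped_f, 2L)
  expect_equal(sel$kept, "rs2")
  expect_true(all(sel$f_stats > 10))
  # counts partition the input
  expect_equal(length(sel$kept) + sel$dropped_p + sel$dropped_ld + sel$dropped_f,
               n_variants(ss))
})

test_that("select_instruments is the identity under permissive thresholds", {
  inst <- random_clump_instance(3, n = 8)
  ss <- sumstats(data.frame(rsid = inst$rec$rsid, chrom = inst$rec$chrom,
                            pos = inst$rec$pos, effect_allele = "A",
                            other_allele = "G", beta = inst$rec$beta,
                            se = inst$rec$se, pval = inst$rec$pval), "t")
  ld <- ld_matrix(rownames(inst$r), inst$r)
  sel <- select_instruments(ss, ld, p_threshold = 1, r2_threshold = 1.5, f_min = 0)
  expect_setequal(sel$kept, ss$records$rsid)
})

test_that("select_instruments kept set is invariant to row permutation", {
  inst <- random_clump_instance(21, n = 10)
  df <- data.frame(rsid = inst$rec$rsid, chrom = inst$rec$chrom,
                   pos = inst$rec$pos, effect_allele = "A", other_allele = "G",
                   beta = inst$rec$beta, se = inst$rec$se, pval = inst$rec$pval)
  ld <- ld_matrix(rownames(inst$r), inst$r)
  base <- select_instruments(sumstats(df, "t"), ld, p_threshold = 1e-4,
                             r2_threshold = 0.1, f_min = 10)$kept
  perm <- df[sample(nrow(df)), ]
  expect_identical(select_instruments(sumstats(perm, "t"), ld, p_threshold = 1e-4,
                                      r2_threshold = 0.1, f_min = 10)$kept, base)
})
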