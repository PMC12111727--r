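#' Linkage-disequilibrium matrix
#'
#' Validates a square pairwise-correlation matrix over a set of variants.
#' The diagonal must be exactly 1, the matrix symmetric, and all |r| <= 1.
#'
#' @param snps ordered character vector of rsids.
#' @param r square numeric matrix of pairwise correlations (r, not r^2).
#' @return an object of class `ld_matrix`.
#' @export
ld_matrix <- function(snps, r) {
  snps <- as.character(snps)
  r <- as.matrix(r)
  if (nrow(r) != length(snps) || ncol(r) != length(snps)) {
    stop("LD matrix dimension does not match number of snps")
  }
  if (any(abs(r - t(r)) > 1e-12)) stop("LD matrix must be symmetric")
  if (any(abs(diag(r) - 1) > 1e-12)) stop("LD matrix diagonal must be 1")
  if (any(abs(r) > 1 + 1e-12)) stop("LD correlations must lie in [-1, 1]")
  dimnames(r) <- list(snps, snps)
  structure(list(snps = snps, r = r), class = "ld_matrix")
}

#' Read an LD matrix from file
#'
#' Two dialects are supported and auto-detected: a square tab-separated
#' matrix with an rsid header row and first column, or a long-format triplet
#' file with columns `rsid_a`, `rsid_b`, `r`. Pairs absent from a triplet
#' file are taken as uncorrelated.
#'
#' @param path file path.
#' @return an `ld_matrix`.
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (identical(header[1:3], c("rsid_a", "rsid_b", "r"))) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    snps <- sort(unique(c(df$rsid_a, df$rsid_b)))
    r <- diag(length(snps))
    dimnames(r) <- list(snps, snps)
    for (i in seq_len(nrow(df))) {
      r[df$rsid_a[i], df$rsid_b[i]] <- df$r[i]
      r[df$rsid_b[i], df$rsid_a[i]] <- df$r[i]
    }
    return(ld_matrix(snps, r))
  }
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  ld_matrix(rownames(m), m)
}

#' Instrument-strength F-statistic
#'
#' The single-SNP instrument-strength statistic `F = beta^2 / se^2`; values
#' above 10 are the conventional bar against weak-instrument bias.
#'
#' @param beta,se per-allele effect and its standard error (`se > 0`).
#' @return non-negative numeric vector.
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive")
  (beta / se)^2
}

#' Filter variants by association significance
#'
#' Retains records with `pval` strictly below the threshold (the genome-wide
#' screen uses p < 1e-5 for instrument candidacy).
#'
#' @param ss a `sumstats` object.
#' @param p_threshold strict upper bound on p (default `1e-5`).
#' @return a `sumstats` object (possibly with zero records).
#' @export
filter_significant <- function(ss, p_threshold = 1e-5) {
  stopifnot(inherits(ss, "sumstats"))
  ss$records <- ss$records[ss$records$pval < p_threshold, , drop = FALSE]
  rownames(ss$records) <- NULL
  ss
}

new_instrument_selection <- function(kept, dropped_p, dropped_ld, dropped_f, f_stats) {
  structure(
    list(kept = kept, dropped_p = as.integer(dropped_p),
         dropped_ld = as.integer(dropped_ld), dropped_f = as.integer(dropped_f),
         f_stats = f_stats),
    class = "instrument_selection"
  )
}

#' @export
print.instrument_selection <- function(x, ...) {
  cat(sprintf("<instrument_selection> kept %d (dropped: %d by p, %d by LD, %d by F)\n",
              length(x$kept), x$dropped_p, x$dropped_ld, x$dropped_f))
  invisible(x)
}

ld_r_lookup <- function(ld, rsid_a, rsid_b) {
  # variants absent from the reference are assumed uncorrelated
  ia <- match(rsid_a, ld$snps)
  ib <- match(rsid_b, ld$snps)
  if (is.na(ia) || is.na(ib)) return(0)
  ld$r[ia, ib]
}

#' Greedy LD clumping
#'
#' Orders candidate variants by ascending p-value (ties broken by rsid,
#' lexicographically, for determinism), then repeatedly keeps the best
#' remaining variant as an index SNP and discards all remaining variants on
#' the same chromosome within `window_kb` of it whose squared correlation
#' with it is at or above `r2_threshold`. Variants on different chromosomes
#' are never clumped against each other. Variants missing from the LD matrix
#' are treated as uncorrelated, with a warning.
#'
#' @param ss a `sumstats` object (typically already significance-filtered).
#' @param ld an `ld_matrix`.
#' @param r2_threshold squared-correlation threshold (default 0.001): a
#'   variant is removed when r^2 with the index SNP is `>=` this value.
#' @param window_kb half-width of the clumping window in kb, center-to-center
#'   from the index SNP (default 10000, i.e. +/-10 Mb).
#' @return an `instrument_selection` with `dropped_ld` counted; `dropped_p`
#'   and `dropped_f` are zero at this stage.
#' @export
clump <- function(ss, ld, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(ss, "sumstats"), inherits(ld, "ld_matrix"))
  rec <- ss$records
  if (nrow(rec) == 0L) {
    return(new_instrument_selection(character(0), 0L, 0L, 0L, numeric(0)))
  }
  missing_ld <- setdiff(rec$rsid, ld$snps)
  if (length(missing_ld) > 0L) {
    warning(sprintf("%d variant(s) absent from the LD reference; assumed uncorrelated",
                    length(missing_ld)))
  }
  ord <- order(rec$pval, rec$rsid)
  rec <- rec[ord, , drop = FALSE]

  kept <- character(0)
  remaining <- seq_len(nrow(rec))
  window_bp <- window_kb * 1000
  while (length(remaining) > 0L) {
    idx <- remaining[1]
    kept <- c(kept, rec$rsid[idx])
    remaining <- remaining[-1]
    if (length(remaining) == 0L) break
    same_chrom <- rec$chrom[remaining] == rec$chrom[idx]
    in_window <- abs(rec$pos[remaining] - rec$pos[idx]) <= window_bp
    r2 <- vapply(remaining, function(j) {
      ld_r_lookup(ld, rec$rsid[j], rec$rsid[idx])^2
    }, numeric(1))
    drop <- same_chrom & in_window & r2 >= r2_threshold
    remaining <- remaining[!drop]
  }
  f <- f_statistic(rec$beta[match(kept, rec$rsid)], rec$se[match(kept, rec$rsid)])
  names(f) <- kept
  new_instrument_selection(kept, 0L, nrow(rec) - length(kept), 0L, f)
}

#' Select instrumental variables for one exposure
#'
#' The full instrument-selection cascade: significance filter (p strictly
#' below `p_threshold`), greedy LD clumping, then removal of weak instruments
#' (kept only when F-statistic is strictly greater than `f_min`). All drop
#' counts are recorded.
#'
#' @param ss exposure `sumstats`.
#' @param ld an `ld_matrix`.
#' @param p_threshold significance threshold (default `1e-5`).
#' @param r2_threshold,window_kb clumping parameters (defaults 0.001, 10000).
#' @param f_min weak-instrument bound; instruments require `F > f_min`
#'   (default 10).
#' @return an `instrument_selection`.
#' @export
select_instruments <- function(ss, ld, p_threshold = 1e-5, r2_threshold = 0.001,
                               window_kb = 10000, f_min = 10) {
  stopifnot(inherits(ss, "sumstats"))
  n_in <- nrow(ss$records)
  sig <- filter_significant(ss, p_threshold)
  dropped_p <- n_in - nrow(sig$records)
  cl <- clump(sig, ld, r2_threshold = r2_threshold, window_kb = window_kb)
  strong <- cl$f_stats > f_min
  kept <- cl$kept[strong]
  new_instrument_selection(kept, dropped_p, cl$dropped_ld,
                           sum(!strong), cl$f_stats[strong])
}
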