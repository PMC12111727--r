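#' GWAS summary-statistics container
#'
#' Builds a validated `sumstats` object from a data frame of per-variant
#' marginal associations. Rows violating the record invariants (non-positive
#' SE, p-value outside (0, 1], invalid or identical alleles, position < 1,
#' empty or duplicated rsid) are dropped with a warning that reports the
#' count, mirroring how summary files from heterogeneous sources are cleaned
#' in practice.
#'
#' @param records data frame with columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval` and optionally
#'   `eaf` (effect-allele frequency) and `n` (sample size). Missing optionals
#'   are filled with `NA`.
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"binary"`; for binary traits `beta`
#'   is on the log-odds scale.
#' @return An object of class `sumstats`: a list with elements `trait_id`,
#'   `trait_type` and `records` (the validated data frame).
#' @export
sumstats <- function(records, trait_id, trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait_id), length(trait_id) == 1L, nzchar(trait_id))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "pval")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"eaf" %in% names(records)) records$eaf <- NA_real_
  if (!"n" %in% names(records)) records$n <- NA_real_
  records <- records[c(required, "eaf", "n")]
  records$rsid <- as.character(records$rsid)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "beta", "se", "pval", "eaf", "n")) {
    records[[col]] <- as.numeric(records[[col]])
  }

  valid <- validate_assoc_rows(records)
  n_bad <- sum(!valid)
  if (n_bad > 0L) {
    warning(sprintf("dropped %d invalid record(s) for trait '%s'", n_bad, trait_id))
    records <- records[valid, , drop = FALSE]
  }
  dup <- duplicated(records$rsid)
  if (any(dup)) {
    warning(sprintf("dropped %d duplicated rsid record(s) for trait '%s'",
                    sum(dup), trait_id))
    records <- records[!dup, , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(
    list(trait_id = trait_id, trait_type = trait_type, records = records),
    class = "sumstats"
  )
}

NUCLEOTIDES <- c("A", "C", "G", "T")

validate_assoc_rows <- function(df) {
  ok <- !is.na(df$rsid) & nzchar(df$rsid) &
    !is.na(df$pos) & df$pos >= 1 &
    df$effect_allele %in% NUCLEOTIDES &
    df$other_allele %in% NUCLEOTIDES &
    df$effect_allele != df$other_allele &
    !is.na(df$beta) & is.finite(df$beta) &
    !is.na(df$se) & df$se > 0 &
    !is.na(df$pval) & df$pval > 0 & df$pval <= 1
  # optional fields: when present they must be sane
  ok & (is.na(df$eaf) | (df$eaf > 0 & df$eaf < 1)) & (is.na(df$n) | df$n > 0)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s' (%s), %d variants\n",
              x$trait_id, x$trait_type, nrow(x$records)))
  invisible(x)
}

#' Number of variants in a summary-statistics set
#' @param ss a `sumstats` object
#' @return integer count of records
#' @export
n_variants <- function(ss) nrow(ss$records)

SUMSTATS_COLUMNS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                      "beta", "se", "pval", "eaf", "n")

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-separated table (delimiter auto-detected from the
#' header line) into a validated [sumstats()] object. Heterogeneous headers
#' are handled through `column_map`, a named character vector mapping the
#' canonical column names (`rsid`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `pval`, `eaf`, `n`) to the names used in the
#' file. `"NA"` encodes missing optional values.
#'
#' @param path file path.
#' @param trait_id,trait_type passed to [sumstats()].
#' @param column_map optional named character vector, canonical -> file name.
#' @return a `sumstats` object.
#' @export
read_sumstats <- function(path, trait_id, trait_type = c("quantitative", "binary"),
                          column_map = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = NA, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) stop("mapped column not found in file: ", src)
      names(df)[names(df) == src] <- canon
    }
  }
  missing_cols <- setdiff(setdiff(SUMSTATS_COLUMNS, c("eaf", "n")), names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mapped column(s): ", paste(missing_cols, collapse = ", "))
  }
  ss <- sumstats(df, trait_id = trait_id, trait_type = trait_type)
  if (nrow(ss$records) == 0L) stop("no valid rows in ", path)
  ss
}

fmt_num <- function(x, scientific = FALSE) {
  out <- if (scientific) sprintf("%.6e", x) else sprintf("%.10g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write summary statistics to a tab-separated file
#'
#' Serializes with a fixed header (`rsid  chrom  pos  effect_allele
#' other_allele  beta  se  pval  eaf  n`). Betas, SEs, frequencies and sample
#' sizes are written with 10 significant digits; p-values in scientific
#' notation. [read_sumstats()] inverts the format exactly for the stored
#' precision, so write-read-write is byte-idempotent.
#'
#' @param ss a `sumstats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  stopifnot(inherits(ss, "sumstats"))
  r <- ss$records
  lines <- paste(SUMSTATS_COLUMNS, collapse = "\t")
  if (nrow(r) > 0L) {
    body <- paste(r$rsid, r$chrom, fmt_num(r$pos), r$effect_allele, r$other_allele,
                  fmt_num(r$beta), fmt_num(r$se), fmt_num(r$pval, scientific = TRUE),
                  fmt_num(r$eaf), fmt_num(r$n), sep = "\t")
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

#' Is an allele pair palindromic (strand-ambiguous)?
#'
#' A/T and C/G pairs read the same on both strands, so the effect allele
#' cannot be matched across studies without frequency information; such
#' variants are excluded during harmonization.
#'
#' @param effect_allele,other_allele single nucleotides (A/C/G/T), distinct.
#' @return logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  if (any(!ea %in% NUCLEOTIDES) || any(!oa %in% NUCLEOTIDES)) {
    stop("invalid allele symbol")
  }
  if (any(ea == oa)) stop("alleles must be distinct")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(comp[ea] == oa)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins two summary sets on rsid and places both effects on the
#' exposure's effect-allele frame. Outcome rows whose alleles are swapped
#' relative to the exposure get their beta negated (`flipped = TRUE`); rows
#' whose allele pair matches neither orientation are dropped and counted
#' (strand mismatches are treated as unmatched, not complemented).
#' Palindromic (A/T, C/G) variants are dropped when `drop_palindromic`.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param drop_palindromic drop strand-ambiguous variants (default `TRUE`).
#' @return An object of class `harmonized_set`: list with `exposure_id`,
#'   `outcome_id`, `rows` (data frame `rsid`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`, `flipped`), `n_dropped_palindromic`,
#'   `n_dropped_unmatched`.
#' @export
harmonize <- function(exposure, outcome, drop_palindromic = TRUE) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  ex <- exposure$records
  ou <- outcome$records
  shared <- intersect(ex$rsid, ou$rsid)
  if (length(shared) == 0L) stop("no shared variants between exposure and outcome")
  ex <- ex[match(shared, ex$rsid), , drop = FALSE]
  ou <- ou[match(shared, ou$rsid), , drop = FALSE]

  n_pal <- 0L
  if (drop_palindromic) {
    pal <- is_palindromic(ex$effect_allele, ex$other_allele)
    n_pal <- sum(pal)
    ex <- ex[!pal, , drop = FALSE]
    ou <- ou[!pal, , drop = FALSE]
  }

  same <- ex$effect_allele == ou$effect_allele & ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele & ex$other_allele == ou$effect_allele
  unmatched <- !(same | swapped)
  n_unmatched <- sum(unmatched)

  keep_ex <- ex[!unmatched, , drop = FALSE]
  keep_ou <- ou[!unmatched, , drop = FALSE]
  flip <- swapped[!unmatched]

  rows <- data.frame(
    rsid = keep_ex$rsid,
    beta_exp = keep_ex$beta,
    se_exp = keep_ex$se,
    beta_out = ifelse(flip, -keep_ou$beta, keep_ou$beta),
    se_out = keep_ou$se,
    flipped = flip,
    stringsAsFactors = FALSE
  )
  rownames(rows) <- NULL
  structure(
    list(exposure_id = exposure$trait_id,
         outcome_id = outcome$trait_id,
         rows = rows,
         n_dropped_palindromic = n_pal,
         n_dropped_unmatched = n_unmatched),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d variants (%d palindromic, %d unmatched dropped)\n",
              x$exposure_id, x$outcome_id, nrow(x$rows),
              x$n_dropped_palindromic, x$n_dropped_unmatched))
  invisible(x)
}

#' Restrict a summary-statistics set to a subset of variants
#' @param ss a `sumstats` object
#' @param rsids character vector of variant ids to keep
#' @return a `sumstats` object with only the requested records
#' @export
subset_sumstats <- function(ss, rsids) {
  stopifnot(inherits(ss, "sumstats"))
  ss$records <- ss$records[ss$records$rsid %in% rsids, , drop = FALSE]
  rownames(ss$records) <- NULL
  ss
}
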