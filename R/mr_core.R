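#' Per-SNP Wald ratio
#'
#' The single-instrument causal estimate: outcome effect divided by exposure
#' effect, with the first-order delta-method standard error
#' `se_out / |beta_exp|` (exposure-side noise ignored, the standard default
#' for strong instruments).
#'
#' @param beta_exp,se_exp exposure effect and SE.
#' @param beta_out,se_out outcome effect and SE.
#' @return list with numeric vectors `ratio` and `se`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (any(beta_exp == 0)) stop("beta_exp must be nonzero for a Wald ratio")
  list(ratio = beta_out / beta_exp, se = se_out / abs(beta_exp))
}

#' Odds ratio with 95% confidence interval
#'
#' Maps a log-odds estimate and SE to the odds-ratio scale:
#' `exp(beta)`, `exp(beta -/+ 1.96 se)`.
#'
#' @param beta log-odds estimate.
#' @param se its standard error (> 0).
#' @return list `or`, `ci_low`, `ci_high`.
#' @export
or_ci <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive")
  list(or = exp(beta), ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se))
}

new_mr_result <- function(method, n_snp, beta, se, pval,
                          q = NA_real_, q_df = NA_real_, q_pval = NA_real_,
                          egger_intercept = NA_real_, egger_intercept_se = NA_real_,
                          egger_intercept_pval = NA_real_) {
  ci <- or_ci(beta, se)
  structure(
    list(method = method, n_snp = as.integer(n_snp), beta = beta, se = se,
         pval = pval, or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high,
         q = q, q_df = q_df, q_pval = q_pval,
         egger_intercept = egger_intercept,
         egger_intercept_se = egger_intercept_se,
         egger_intercept_pval = egger_intercept_pval),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: %d SNPs, beta = %.4f (se %.4f), OR %.3f (%.3f-%.3f), p = %.3g\n",
              x$method, x$n_snp, x$beta, x$se, x$or, x$ci_low, x$ci_high, x$pval))
  if (!is.na(x$q)) {
    cat(sprintf("  Cochran's Q = %.3f on %d df (p = %.3g)\n", x$q, x$q_df, x$q_pval))
  }
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4f (se %.4f, p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_pval))
  }
  invisible(x)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-SNP Wald ratios `r_j` with weights `w_j = 1/ratio_se_j^2`.
#' The fixed-effect SE is `sqrt(1/sum(w))`; the multiplicative
#' random-effects mode (`"mre"`, the default) scales it by
#' `sqrt(max(1, Q/df))` where Q is Cochran's heterogeneity statistic
#' `sum(w_j (r_j - beta)^2)` on `n_snp - 1` df. The p-value is a two-sided
#' normal test of `beta/se`. With a single SNP the estimate equals the Wald
#' ratio and the heterogeneity fields are reported as `NA`.
#'
#' @param h a `harmonized_set`.
#' @param mode `"mre"` (multiplicative random effects) or `"fixed"`.
#' @return an `mr_result`.
#' @export
mr_ivw <- function(h, mode = c("mre", "fixed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(h, "harmonized_set"))
  rows <- h$rows
  n <- nrow(rows)
  if (n == 0L) stop("no instruments in harmonized set")
  wr <- wald_ratio(rows$beta_exp, rows$se_exp, rows$beta_out, rows$se_out)
  w <- 1 / wr$se^2
  beta <- sum(w * wr$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  if (n >= 2L) {
    q <- sum(w * (wr$ratio - beta)^2)
    q_df <- n - 1L
    q_pval <- stats::pchisq(q, df = q_df, lower.tail = FALSE)
  } else {
    q <- q_df <- q_pval <- NA_real_
  }
  se <- if (mode == "mre" && n >= 2L) se_fixed * sqrt(max(1, q / q_df)) else se_fixed
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_result(paste0("ivw_", mode), n, beta, se, pval, q, q_df, q_pval)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a free
#' intercept, weights `1/se_out^2`, after orienting every row so the exposure
#' effect is non-negative (both betas negated where needed). A nonzero
#' intercept indicates directional horizontal pleiotropy. Coefficient
#' standard errors are put on a multiplicative random-effects footing by
#' scaling the unit-variance SEs by `max(1, sigma)` where `sigma` is the
#' residual standard deviation of the weighted fit; p-values use a t
#' reference with `n_snp - 2` df.
#'
#' @param h a `harmonized_set` with at least 3 instruments.
#' @return an `mr_result` with slope statistics in `beta`/`se`/`pval` and the
#'   intercept diagnostics in the `egger_*` fields.
#' @export
mr_egger <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  rows <- h$rows
  n <- nrow(rows)
  if (n < 3L) stop("MR-Egger requires at least 3 instruments")
  sgn <- ifelse(rows$beta_exp < 0, -1, 1)
  bx <- rows$beta_exp * sgn
  by <- rows$beta_out * sgn
  w <- 1 / rows$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  # unit-variance SEs times max(1, sigma): never narrower than fixed-effect
  scale <- max(1, sm$sigma) / sm$sigma
  est <- sm$coefficients[, "Estimate"]
  ses <- sm$coefficients[, "Std. Error"] * scale
  tval <- est / ses
  pvals <- 2 * stats::pt(-abs(tval), df = n - 2)
  new_mr_result("egger", n, beta = est[["bx"]], se = ses[["bx"]], pval = pvals[["bx"]],
                egger_intercept = est[["(Intercept)"]],
                egger_intercept_se = ses[["(Intercept)"]],
                egger_intercept_pval = pvals[["(Intercept)"]])
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("<mr_presso> global RSS = %.3f, global p = %.3g, %d outlier(s) of %d SNPs (n_sim = %d)\n",
              x$global_rss, x$global_pval, length(x$outliers),
              length(x$per_snp_pval), x$n_sim))
  invisible(x)
}

loo_ivw_slopes <- function(bx, by, w) {
  # leave-one-out no-intercept WLS slope of by on bx, weights w
  swxy <- sum(w * bx * by)
  swxx <- sum(w * bx^2)
  (swxy - w * bx * by) / (swxx - w * bx^2)
}

#' Simulation-based pleiotropy outlier test (MR-PRESSO-style)
#'
#' Global test: the observed residual sum of squares
#' `RSS = sum_j w_j (beta_out_j - b_(-j) beta_exp_j)^2`, where `b_(-j)` is
#' the leave-one-out IVW slope and `w_j = 1/se_out_j^2`, is compared against
#' a parametric null in which `beta_out*_j ~ N(b_(-j) beta_exp_j, se_out_j)`
#' and `beta_exp*_j ~ N(beta_exp_j, se_exp_j)`; the global p-value is the
#' fraction of simulated RSS at or above the observed one. Per-SNP outlier
#' p-values compare each observed weighted squared residual with its
#' simulated counterparts, Bonferroni-multiplied by the number of SNPs and
#' capped at 1; SNPs with adjusted p below `alpha` are flagged and removed,
#' and the IVW estimate is recomputed on the remainder. Fully reproducible
#' under a fixed seed.
#'
#' @param h a `harmonized_set` with at least 4 instruments.
#' @param n_sim number of parametric null draws (minimum 100; default 1000).
#' @param alpha outlier significance level on the adjusted p (default 0.05).
#' @param seed integer RNG seed (required for reproducibility).
#' @param mode IVW mode for the corrected estimate.
#' @return an object of class `mr_presso`: `global_rss`, `global_pval`,
#'   `per_snp_pval` (named, Bonferroni-adjusted), `outliers`, `corrected`
#'   (an `mr_result` on the retained SNPs), `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, alpha = 0.05, seed, mode = c("mre", "fixed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(h, "harmonized_set"))
  rows <- h$rows
  n <- nrow(rows)
  if (n < 4L) stop("MR-PRESSO requires at least 4 instruments")
  if (n_sim < 100) stop("n_sim must be at least 100")
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)

  bx <- rows$beta_exp
  by <- rows$beta_out
  sx <- rows$se_exp
  sy <- rows$se_out
  w <- 1 / sy^2

  b_loo <- loo_ivw_slopes(bx, by, w)
  d_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(d_obs)

  mu_y <- b_loo * bx
  BX <- matrix(stats::rnorm(n * n_sim, mean = bx, sd = sx), nrow = n)
  BY <- matrix(stats::rnorm(n * n_sim, mean = mu_y, sd = sy), nrow = n)

  SWXY <- colSums(w * BX * BY)
  SWXX <- colSums(w * BX^2)
  BLOO <- (rep(SWXY, each = n) - w * BX * BY) / (rep(SWXX, each = n) - w * BX^2)
  D <- w * (BY - BLOO * BX)^2
  rss_sim <- colSums(D)

  global_pval <- mean(rss_sim >= rss_obs)
  per_snp_raw <- rowMeans(D >= d_obs)
  per_snp_pval <- pmin(1, per_snp_raw * n)
  names(per_snp_pval) <- rows$rsid
  outliers <- rows$rsid[per_snp_pval < alpha]

  h_kept <- h
  h_kept$rows <- rows[!rows$rsid %in% outliers, , drop = FALSE]
  corrected <- if (nrow(h_kept$rows) >= 1L) mr_ivw(h_kept, mode = mode) else NULL

  structure(
    list(global_rss = rss_obs, global_pval = global_pval,
         per_snp_pval = per_snp_pval, outliers = outliers,
         corrected = corrected, n_sim = as.integer(n_sim), seed = seed),
    class = "mr_presso"
  )
}
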