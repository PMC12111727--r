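# Independent reference implementations, deliberately written with different
# algorithmic structure from the package code paths they check.

# Exhaustive greedy clumping: re-scans the full pair list at every step.
oracle_clump <- function(rec, r_mat, r2_threshold, window_kb) {
  rec <- rec[order(rec$pval, rec$rsid), , drop = FALSE]
  kept <- character(0)
  alive <- rep(TRUE, nrow(rec))
  repeat {
    cand <- which(alive)
    if (length(cand) == 0L) break
    idx <- cand[1]
    kept <- c(kept, rec$rsid[idx])
    alive[idx] <- FALSE
    for (j in which(alive)) {
      if (rec$chrom[j] != rec$chrom[idx]) next
      if (abs(rec$pos[j] - rec$pos[idx]) > window_kb * 1000) next
      r <- 0
      ia <- match(rec$rsid[idx], rownames(r_mat))
      ja <- match(rec$rsid[j], rownames(r_mat))
      if (!is.na(ia) && !is.na(ja)) r <- r_mat[ia, ja]
      if (r^2 >= r2_threshold) alive[j] <- FALSE
    }
  }
  kept
}

# Step-up FDR by explicit double loop over ranks.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    vals <- numeric(0)
    for (k in rank_i:m) {
      vals <- c(vals, m * p[ord[k]] / k)
    }
    adj[i] <- min(1, min(vals))
  }
  adj
}

# Colocalization hypothesis weights by explicit enumeration of causal
# configurations, in linear space (usable up to ~12 SNPs, moderate z).
oracle_coloc <- function(beta1, se1, beta2, se2, sd1, sd2, p1, p2, p12) {
  abf <- function(b, s, w) {
    v <- s^2
    sqrt(v / (v + w^2)) * exp(0.5 * (b / s)^2 * w^2 / (v + w^2))
  }
  bf1 <- abf(beta1, se1, sd1)
  bf2 <- abf(beta2, se2, sd2)
  n <- length(bf1)
  w0 <- 1
  w1 <- p1 * sum(bf1)
  w2 <- p2 * sum(bf2)
  w3 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) w3 <- w3 + p1 * p2 * bf1[i] * bf2[j]
    }
  }
  w4 <- p12 * sum(bf1 * bf2)
  w <- c(w0, w1, w2, w3, w4)
  w / sum(w)
}

# Weighted least squares with intercept via the normal equations.
oracle_wls <- function(x, y, w) {
  X <- cbind(1, x)
  xtwx <- t(X) %*% (w * X)
  coef <- solve(xtwx, t(X) %*% (w * y))
  c(intercept = coef[1], slope = coef[2])
}

random_clump_instance <- function(seed, n = 8) {
  set.seed(seed)
  rsid <- sprintf("rs%03d", sample(100, n))
  rec <- data.frame(
    rsid = rsid,
    chrom = sample(c("1", "2"), n, replace = TRUE),
    pos = sample(1e6, n),
    beta = rnorm(n, 0, 0.1),
    se = runif(n, 0.01, 0.05),
    pval = runif(n, 1e-10, 1e-4),
    stringsAsFactors = FALSE
  )
  a <- matrix(rnorm(n * n), n)
  r <- stats::cov2cor(crossprod(a) + diag(n) * 0.5)
  dimnames(r) <- list(rsid, rsid)
  list(rec = rec, r = r)
}
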