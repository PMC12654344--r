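# Independent oracles: brute-force / closed-form re-derivations kept
# deliberately separate from the package's implementation paths.

# origin-constrained weighted least squares via explicit normal equations
oracle_ivw <- function(bx, by, sy) {
  w <- diag(1 / sy^2, nrow = length(sy))
  x <- matrix(bx, ncol = 1)
  beta <- solve(t(x) %*% w %*% x, t(x) %*% w %*% by)
  list(beta = drop(beta), se = sqrt(drop(solve(t(x) %*% w %*% x))))
}

# weighted least squares with intercept after orienting bx >= 0
oracle_egger <- function(bx, by, sy) {
  s <- ifelse(bx < 0, -1, 1)
  bx <- s * bx
  by <- s * by
  w <- diag(1 / sy^2, nrow = length(sy))
  x <- cbind(1, bx)
  coefs <- solve(t(x) %*% w %*% x, t(x) %*% w %*% by)
  list(intercept = coefs[1], slope = coefs[2])
}

# term-by-term summation, scalar loop
oracle_q <- function(bx, by, sy, beta_ref) {
  q <- 0
  for (j in seq_along(bx)) {
    q <- q + (by[j] - beta_ref * bx[j])^2 / sy[j]^2
  }
  q
}

oracle_dl_tau2 <- function(y, se) {
  w <- 1 / se^2
  mu <- sum(w * y) / sum(w)
  q <- 0
  for (i in seq_along(y)) q <- q + w[i] * (y[i] - mu)^2
  df <- length(y) - 1
  max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
}

# greedy clumping re-derived as a while-loop over a plain data frame
oracle_clump <- function(df, ld, r2_threshold, window_kb) {
  remaining <- df[order(df$pvalue, df$pos, df$snp), ]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    idx <- remaining[1, ]
    kept <- c(kept, idx$snp)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    drop <- logical(nrow(remaining))
    for (j in seq_len(nrow(remaining))) {
      cand <- remaining[j, ]
      r2 <- if (idx$snp %in% rownames(ld) && cand$snp %in% rownames(ld)) {
        ld[idx$snp, cand$snp]
      } else {
        0
      }
      drop[j] <- cand$chrom == idx$chrom &&
        abs(cand$pos - idx$pos) <= window_kb * 1000 &&
        r2 >= r2_threshold
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept
}

# all permutations of 1..n, recursively
all_permutations <- function(n) {
  if (n == 1) {
    return(list(1L))
  }
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

oracle_mantel_exhaustive <- function(da, db) {
  lt <- lower.tri(da)
  r_obs <- cor(da[lt], db[lt])
  perms <- all_permutations(nrow(da))
  r_all <- vapply(perms, function(p) cor(da[lt], db[p, p][lt]), numeric(1))
  list(r = r_obs, pvalue = mean(r_all >= r_obs))
}
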