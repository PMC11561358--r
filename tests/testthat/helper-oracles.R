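## Independent oracles used across test files. These re-derive expected
## values by brute force or enumeration and must stay independent of the
## package code paths they check.

## build a genotype_set quickly from a dosage matrix
make_geno <- function(dosage, chrom = NULL, pos = NULL, ids = NULL,
                      a1 = "A", a2 = "G") {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  variants <- data.frame(
    id = ids %||% sprintf("v%03d", seq_len(m)),
    chrom = chrom %||% rep("1", m),
    pos = pos %||% (seq_len(m) * 1000L),
    counted_allele = rep(a1, length.out = m),
    other_allele = rep(a2, length.out = m),
    stringsAsFactors = FALSE)
  genotype_set(dosage, variants,
               sprintf("S%03d", seq_len(nrow(dosage))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## brute-force greedy clumping: recompute the survivor set from scratch at
## every step (no shared code with ld_clump)
clump_oracle <- function(tab, dosage, r2_max, window_bp) {
  remaining <- tab
  kept <- character(0)
  while (nrow(remaining) > 0) {
    o <- order(remaining$p, remaining$chrom, remaining$pos, remaining$id)
    idx <- remaining[o[1], ]
    kept <- c(kept, idx$id)
    drop <- vapply(seq_len(nrow(remaining)), function(j) {
      r <- remaining[j, ]
      if (r$id == idx$id) return(TRUE)
      if (r$chrom != idx$chrom) return(FALSE)
      if (abs(r$pos - idx$pos) > window_bp) return(FALSE)
      stats::cor(dosage[, idx$id], dosage[, r$id])^2 > r2_max
    }, logical(1))
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept
}

## conditional-logistic log-likelihood by exhaustive enumeration over all
## case assignments within each stratum
clogit_loglik_enum <- function(beta, X, y, strata) {
  X <- as.matrix(X)
  ll <- 0
  for (s in unique(strata)) {
    i <- which(strata == s)
    k <- sum(y[i])
    if (k == 0 || k == length(i)) next
    eta <- as.vector(X[i, , drop = FALSE] %*% beta)
    subsets <- utils::combn(length(i), k)
    denom <- sum(apply(subsets, 2, function(ix) exp(sum(eta[ix]))))
    ll <- ll + sum(eta[y[i] == 1]) - log(denom)
  }
  ll
}

## Benjamini-Hochberg by the literal step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

skewness <- function(x) {
  x <- x[!is.na(x)]
  mean((x - mean(x))^3) / stats::sd(x)^3
}
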