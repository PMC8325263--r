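# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: genetic values are evaluated by a local
# formula, testcross family distributions by explicit enumeration of tester
# gamete configurations, and linear-model quantities by direct solves of
# the normal equations.

oracle_haldane <- function(d) 0.5 * (1 - exp(-d / 50))

# genotypic value of a single resolved genotype vector (codes -1/0/+1)
oracle_gv <- function(x, arch) {
  z <- as.numeric(x == 0)
  v <- arch$mu + sum(arch$loci$a * x) + sum(arch$loci$d * z)
  if (nrow(arch$pairs) > 0) {
    for (k in seq_len(nrow(arch$pairs))) {
      i <- arch$pairs$locus_i[k]
      j <- arch$pairs$locus_j[k]
      w <- switch(arch$pairs$kind[k],
                  aa = x[i] * x[j], ad = x[i] * z[j],
                  da = z[i] * x[j], dd = z[i] * z[j])
      v <- v + arch$pairs$coefficient[k] * w
    }
  }
  v
}

# Exact mean/variance of TC(F) progeny genotypic values for one line with
# homozygous codes q (+-1 at each truth locus), enumerating every tester
# F1 gamete with its chain probability along each chromosome.
oracle_tcf <- function(q, arch) {
  L <- nrow(arch$loci)
  configs <- as.matrix(expand.grid(rep(list(c(1, -1)), L)))
  probs <- apply(configs, 1, function(g) {
    p <- 1
    for (cc in unique(arch$loci$chrom)) {
      idx <- which(arch$loci$chrom == cc)
      idx <- idx[order(arch$loci$pos_cM[idx])]
      p <- p * 0.5
      if (length(idx) > 1) {
        for (k in 2:length(idx)) {
          r <- oracle_haldane(arch$loci$pos_cM[idx[k]] -
                                arch$loci$pos_cM[idx[k - 1]])
          p <- p * if (g[idx[k]] == g[idx[k - 1]]) 1 - r else r
        }
      }
    }
    p
  })
  vals <- apply(configs, 1, function(g) oracle_gv((q + g) / 2, arch))
  m <- sum(probs * vals)
  list(mean = m, var = sum(probs * vals^2) - m^2)
}

# expected testcross means against the inbred testers (deterministic)
oracle_h1 <- function(q, arch) oracle_gv((q + 1) / 2, arch)
oracle_h2 <- function(q, arch) oracle_gv((q - 1) / 2, arch)

# genotype + block fixed-effects marginal means by direct normal-equation
# solve (sum-to-zero block contrasts, then average over blocks)
oracle_blues <- function(df) {
  g <- factor(df$geno)
  b <- factor(df$block)
  X <- cbind(stats::model.matrix(~ 0 + g), stats::model.matrix(~b)[, -1, drop = FALSE])
  beta <- solve(crossprod(X), crossprod(X, df$value))
  ng <- nlevels(g)
  bcoef <- c(0, beta[-(1:ng)])
  setNames(as.vector(beta[1:ng]) + mean(bcoef), levels(g))
}

# textbook one-way ANOVA sums of squares
oracle_anova <- function(y, g) {
  g <- factor(g)
  gm <- tapply(y, g, mean)
  ssb <- sum(tapply(y, g, length) * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  dfb <- nlevels(g) - 1
  dfw <- length(y) - nlevels(g)
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, p = pf(f, dfb, dfw, lower.tail = FALSE))
}

# a small deterministic map for fast tests
tiny_map <- function(n_chrom = 2, m = 6, len = 100) {
  ttcqtl::build_map(n_chrom, m, len)
}
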