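# Independent reference implementations used to validate the package's
# forward-backward recursions, plus small fixture builders. These oracles
# enumerate every hidden-state path explicitly and therefore stay
# independent of the scaled recursions they check.

# Exhaustive path-sum oracle for the haplotype-copying HMM.
paint_oracle <- function(target, donors, Ne, mu, cm, w) {
  L <- length(target); K <- ncol(donors)
  d <- diff(cm) / 100
  rho <- 1 - exp(-Ne * d)
  E <- ifelse(donors == target, 1 - mu, mu)
  paths <- as.matrix(expand.grid(rep(list(1:K), L)))
  len <- numeric(K); cnt <- numeric(K); tot <- 0
  for (p in seq_len(nrow(paths))) {
    z <- paths[p, ]
    pr <- 1 / K * E[1, z[1]]
    if (L > 1) for (t in 1:(L - 1)) {
      trans <- (1 - rho[t]) * (z[t + 1] == z[t]) + rho[t] / K
      pr <- pr * trans * E[t + 1, z[t + 1]]
    }
    tot <- tot + pr
    for (k in 1:K) {
      len[k] <- len[k] + pr * sum(w[z == k])
      cnt[k] <- cnt[k] + pr * ((z[1] == k) + sum(z[-1] == k & z[-L] != k))
    }
  }
  list(lengths = len / tot, counts = cnt / tot, loglik = log(tot))
}

# Exhaustive oracle for the 3-state diploid local-ancestry HMM:
# site-level posteriors by summing over all 3^L state paths.
diploid_oracle <- function(geno, q, fE, fI, cm, g) {
  L <- length(geno)
  E <- admixpaint:::diploid_emission(geno, fE, fI)
  init <- dbinom(0:2, 2, q)
  A <- lapply(diff(cm) / 100, admixpaint:::diploid_transition, g = g, q = q)
  paths <- as.matrix(expand.grid(rep(list(0:2), L)))
  post <- matrix(0, L, 3); tot <- 0
  for (p in seq_len(nrow(paths))) {
    z <- paths[p, ]
    pr <- init[z[1] + 1] * E[1, z[1] + 1]
    if (L > 1) for (t in 1:(L - 1))
      pr <- pr * A[[t]][z[t] + 1, z[t + 1] + 1] * E[t + 1, z[t + 1] + 1]
    tot <- tot + pr
    for (t in 1:L) post[t, z[t] + 1] <- post[t, z[t] + 1] + pr
  }
  post / tot
}

# Hudson FST (ratio of means, sample-size corrected) between two panels
# of 0/1 haplotypes (sites x haplotypes).
hudson_fst <- function(h1, h2) {
  n1 <- ncol(h1); n2 <- ncol(h2)
  p1 <- rowMeans(h1); p2 <- rowMeans(h2)
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(N) / sum(D)
}

# simulate a target haplotype from the copying model itself
simulate_copying_target <- function(donors, Ne, mu, map) {
  L <- nrow(donors); K <- ncol(donors)
  target <- integer(L)
  z <- sample.int(K, 1)
  d <- c(0, diff(map$cm) / 100)
  new_chrom <- c(TRUE, diff(as.integer(factor(map$chrom,
                 levels = unique(map$chrom)))) != 0)
  for (t in seq_len(L)) {
    if (new_chrom[t]) z <- sample.int(K, 1)
    else if (runif(1) < 1 - exp(-Ne * d[t])) z <- sample.int(K, 1)
    a <- donors[t, z]
    target[t] <- if (runif(1) < mu) 1L - a else a
  }
  target
}

# small uniform test map
tiny_map <- function(L, cm_gap = 1, chrom = "1") {
  genetic_map(rep(chrom, L), seq_len(L) * 1000L, (seq_len(L) - 1) * cm_gap)
}
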