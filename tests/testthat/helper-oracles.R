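# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive (enumeration, direct formulas) and
# separate from the package's code paths.

# Exhaustive hidden-path sum for the two-state HBD chain: enumerates all 2^L
# state paths of one chromosome, multiplies stationary start, exponential
# transition and emission probabilities, and sums. Tractable for L <= 12.
oracle_hmm_exhaustive <- function(ehbd, enon, dist, f, a) {
  L <- length(ehbd)
  paths <- as.matrix(expand.grid(rep(list(c(0, 1)), L)))
  pprob <- numeric(nrow(paths))
  for (k in seq_len(nrow(paths))) {
    st <- paths[k, ]
    pr <- ifelse(st[1] == 1, f, 1 - f) * ifelse(st[1] == 1, ehbd[1], enon[1])
    if (L > 1) for (i in 2:L) {
      r <- exp(-a * dist[i])
      tp <- if (st[i - 1] == 1) {
        if (st[i] == 1) r + f * (1 - r) else (1 - f) * (1 - r)
      } else {
        if (st[i] == 1) f * (1 - r) else r + (1 - f) * (1 - r)
      }
      pr <- pr * tp * (if (st[i] == 1) ehbd[i] else enon[i])
    }
    pprob[k] <- pr
  }
  list(loglik = log(sum(pprob)),
       posterior = unname(colSums(paths * pprob) / sum(pprob)))
}

# Emission probabilities recomputed independently (epsilon = 0 model).
oracle_emissions <- function(g, p) {
  q <- 1 - p
  list(hbd = ifelse(is.na(g), 1, ifelse(g == 2, p, ifelse(g == 1, 0, q))),
       non = ifelse(is.na(g), 1, ifelse(g == 2, p^2, ifelse(g == 1, 2 * p * q, q^2))))
}

# HWE exact p-value by direct log-gamma enumeration over all heterozygote
# counts compatible with the allele counts.
oracle_hwe_enum <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  na <- 2 * naa + nab
  rare <- min(na, 2 * n - na)
  if (rare == 0) return(1)
  h <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(h, function(k) {
    aa <- (rare - k) / 2
    bb <- n - aa - k
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(k + 1) - lgamma(bb + 1) +
      k * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(nab, h)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Spearman rho by hand: average ranks, then the Pearson formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Genotypes for one individual at known inbreeding f: each locus is HBD with
# probability f (shared allele draw), otherwise Hardy-Weinberg.
sim_inbred_genotypes <- function(p, f) {
  hbd <- runif(length(p)) < f
  a1 <- rbinom(length(p), 1, p)
  a2 <- ifelse(hbd, a1, rbinom(length(p), 1, p))
  as.integer(a1 + a2)
}

# Simulate one individual from the HMM's own generative model: the hidden
# HBD chain along the map (stationary start per chromosome, exponential
# transitions) and epsilon-free emissions.
sim_hmm_individual <- function(map, f, a) {
  L <- nrow(map)
  st <- integer(L)
  g <- integer(L)
  for (i in seq_len(L)) {
    new_chrom <- i == 1 || map$chrom[i] != map$chrom[i - 1]
    if (new_chrom) {
      st[i] <- rbinom(1, 1, f)
    } else {
      r <- exp(-a * (map$pos_m[i] - map$pos_m[i - 1]))
      p1 <- if (st[i - 1] == 1) r + f * (1 - r) else f * (1 - r)
      st[i] <- rbinom(1, 1, p1)
    }
    p <- map$freq_a1[i]
    g[i] <- if (st[i] == 1) 2L * rbinom(1, 1, p)
            else rbinom(1, 1, p) + rbinom(1, 1, p)
  }
  list(genotypes = g, states = st)
}

# Tiny PED/MAP text fixture: 2 individuals x 3 markers, written to tempdir.
# Individual 1: het, hom(first allele), missing; individual 2: hom(other),
# het, hom(first).
write_toy_plink <- function(dir = tempdir()) {
  ped <- file.path(dir, "toy.ped")
  map <- file.path(dir, "toy.map")
  writeLines(c(
    "fam1 ind1 0 0 1 -9 A C G G 0 0",
    "fam1 ind2 0 0 2 -9 C C G T T T"
  ), ped)
  writeLines(c(
    "1\trs1\t0.8\t1000",
    "1\trs2\t1.6\t2000",
    "2\trs3\t0.4\t500"
  ), map)
  list(ped = ped, map = map)
}
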