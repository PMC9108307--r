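# Independent oracles used across the suite. Each is a direct, scalar
# transcription of the published definition, deliberately written in a
# different style from the package implementation it checks.

# Weir & Cockerham (1984) theta for one biallelic locus over r populations,
# from a list of genotype vectors (0/1/2 dosage, NA = missing). Returns the
# (a, b, c) variance components and theta = a / (a + b + c).
oracle_wc_locus <- function(geno_by_pop) {
  r <- length(geno_by_pop)
  n <- p <- h <- numeric(r)
  for (i in seq_len(r)) {
    gi <- geno_by_pop[[i]]
    gi <- gi[!is.na(gi)]
    n[i] <- length(gi)
    p[i] <- sum(gi) / (2 * length(gi))
    h[i] <- sum(gi == 1) / length(gi)
  }
  n_bar <- sum(n) / r
  n_c <- (r * n_bar - sum(n^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n * p) / (r * n_bar)
  s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n * h) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# brute-force likelihood grid over the wild proportion q for one individual
# (dosage g, wild/farm reference-allele frequencies pw/pf)
oracle_grid_q <- function(g, pw, pf, step = 0.001) {
  qs <- seq(0, 1, by = step)
  ll <- vapply(qs, function(q) {
    pi_l <- q * pw + (1 - q) * pf
    sum(g * log(pi_l) + (2 - g) * log(1 - pi_l))
  }, numeric(1))
  qs[which.max(ll)]
}

# brute-force 2-parameter logistic likelihood grid for y ~ b0 + b1 * x
oracle_grid_logit <- function(x, y, b0_range = c(-4, 4), b1_range = c(-8, 8),
                              n_grid = 401) {
  b0s <- seq(b0_range[1], b0_range[2], length.out = n_grid)
  b1s <- seq(b1_range[1], b1_range[2], length.out = n_grid)
  best <- c(NA, NA, -Inf)
  ym <- matrix(y, length(b1s), length(x), byrow = TRUE)
  for (b0 in b0s) {
    eta <- outer(b1s, x) + b0
    p <- 1 / (1 + exp(-eta))
    ll <- rowSums(log(ifelse(ym == 1, p, 1 - p)))
    k <- which.max(ll)
    if (ll[k] > best[3]) best <- c(b0, b1s[k], ll[k])
  }
  list(b0 = best[1], b1 = best[2], loglik = best[3])
}

# small two-population reference system used by many tests
make_ref_system <- function(n_loci = 300, divergence = 0.3, n_each = 80,
                            seed = 42) {
  freqs <- sim_baseline_frequencies(n_loci, divergence, seed = seed)
  wild <- sim_genotypes(freqs, n_each, "wild", seed = seed + 1)
  farm <- sim_genotypes(freqs, n_each, "farm", seed = seed + 2)
  list(freqs = freqs, wild = wild, farm = farm)
}

# frequency table with a fixed wild/farm separation at every locus
make_diverged_freqs <- function(n_loci, p_wild = 0.8, p_farm = 0.2) {
  structure(data.frame(locus_id = sprintf("locus_%05d", seq_len(n_loci)),
                       p_wild = rep(p_wild, n_loci),
                       p_farm = rep(p_farm, n_loci),
                       stringsAsFactors = FALSE),
            divergence = NA, class = c("pop_frequencies", "data.frame"))
}
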