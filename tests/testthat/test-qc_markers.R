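test_that("call-rate filtering matches brute-force enumeration", {
  g <- sim_genotypes(rep(0.5, 10), 10, seed = 1)
  expect_identical(unclass(filter_call_rate(g)$genotypes), unclass(g))

  # hand-placed missingness on a 10x10 toy matrix
  dos <- unclass(g)
  dos[1, ] <- NA_integer_             # sample 1: call rate 0
  dos[2, 1:3] <- NA_integer_          # sample 2: call rate 0.7 < 0.85
  dos[3:4, 4] <- NA_integer_          # locus 4 loses calls
  gt <- genotype_matrix(dos)
  res <- filter_call_rate(gt, snp_threshold = 0.97, sample_threshold = 0.85)
  # brute force: samples 1-2 go first; then per-locus rates over survivors
  surv <- dos[-(1:2), ]
  keep_loci <- colMeans(!is.na(surv)) >= 0.97
  expect_setequal(res$discarded_samples, rownames(g)[1:2])
  expect_identical(colnames(res$genotypes), colnames(g)[keep_loci])
  expect_identical(dim(res$genotypes), c(8L, sum(keep_loci)))

  # single low-call-rate locus is removed at the default threshold (the
  # affected sample keeps a 0.9 call rate and survives the sample filter)
  dos2 <- unclass(sim_genotypes(rep(0.5, 10), 20, seed = 2))
  dos2[1, 2] <- NA_integer_           # locus 2: call rate 0.95 < 0.97
  res2 <- filter_call_rate(genotype_matrix(dos2))
  expect_identical(res2$discarded_loci, colnames(dos2)[2])
  expect_length(res2$discarded_samples, 0)

  # PolyHighResolution flag filters when provided
  flag <- setNames(rep(TRUE, 10), colnames(g))
  flag[5] <- FALSE
  res3 <- filter_call_rate(g, poly_high_resolution = flag)
  expect_false(colnames(g)[5] %in% colnames(res3$genotypes))
  expect_error(filter_call_rate(g, sample_threshold = 2), "thresholds")
  allna <- genotype_matrix(matrix(NA_integer_, 3, 3))
  expect_error(filter_call_rate(allna), "empty after QC")
})

test_that("Weir-Cockerham F_ST matches the hand-coded 1984 oracle", {
  # fixed difference with equal sample sizes gives exactly 1
  gfix <- genotype_matrix(rbind(matrix(2L, 8, 1), matrix(0L, 8, 1)),
                          labels = rep(c("wild_hist", "farm"), each = 8))
  expect_equal(weir_cockerham_fst(gfix)$fst, 1)

  # no differentiation: Hardy-Weinberg genotype counts, identical frequencies
  hw <- rep(c(0L, 1L, 1L, 2L), times = 8)            # n = 16 per population
  geq <- genotype_matrix(matrix(rep(hw, 2), ncol = 1),
                         labels = rep(c("wild_hist", "farm"), each = 16))
  expect_lt(abs(weir_cockerham_fst(geq)$fst), 0.05)  # small-n estimator bias

  # spec toy locus: pop1 genotype counts (0,1,2) = (4,4,2), pop2 = (1,3,6)
  g1 <- c(rep(0L, 4), rep(1L, 4), rep(2L, 2))
  g2 <- c(rep(0L, 1), rep(1L, 3), rep(2L, 6))
  gt <- genotype_matrix(matrix(c(g1, g2), ncol = 1),
                        labels = rep(c("wild_hist", "farm"), each = 10))
  expect_equal(weir_cockerham_fst(gt)$fst,
               oracle_wc_locus(list(g1, g2))$theta, tolerance = 1e-12)

  # 50 random toy loci, with missingness: agreement to >= 10 significant figures
  set.seed(99)
  for (k in 1:50) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    x1 <- rbinom(n1, 2, runif(1, 0.05, 0.95))
    x2 <- rbinom(n2, 2, runif(1, 0.05, 0.95))
    if (runif(1) < 0.3) x1[sample(n1, 1)] <- NA
    dos <- matrix(c(x1, x2), ncol = 1)
    gk <- genotype_matrix(dos, labels = rep(c("wild_hist", "farm"), c(n1, n2)))
    got <- weir_cockerham_fst(gk)$fst
    want <- oracle_wc_locus(list(x1, x2))$theta
    if (is.na(want) || !is.finite(want)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, want, tolerance = 1e-10)
    }
  }

  # negative estimates are retained; >2 populations rejected
  g3 <- genotype_matrix(matrix(rbinom(30, 2, 0.5), ncol = 1),
                        labels = rep(c("wild_hist", "farm", "contemporary"), 10))
  expect_error(weir_cockerham_fst(g3), "two populations")
})

test_that("multilocus F_ST is the ratio of summed components", {
  sys <- make_ref_system(200, 0.2, 60, seed = 3)
  tab <- weir_cockerham_fst(rbind_genotypes(sys$wild, sys$farm))
  expect_equal(multilocus_fst(tab),
               sum(tab$a, na.rm = TRUE) / sum(tab$denom, na.rm = TRUE))
  expect_false(isTRUE(all.equal(multilocus_fst(tab),
                                mean(tab$fst, na.rm = TRUE))))
})

test_that("DAPC contributions find the discriminating locus and normalise", {
  set.seed(4)
  # 99 noise loci plus one perfectly discriminating locus
  noise <- matrix(rbinom(60 * 99, 2, 0.5), 60, 99)
  signal <- rep(c(2L, 0L), each = 30)
  g <- genotype_matrix(cbind(noise, signal),
                       labels = rep(c("wild_hist", "farm"), each = 30))
  contrib <- dapc_contributions(g, n_pcs = 10)
  expect_equal(sum(contrib), 1)
  expect_true(all(contrib >= 0))
  expect_equal(unname(which.max(contrib)), 100L)

  # relabeling the two groups leaves contributions unchanged
  g_sw <- genotype_matrix(unclass(g),
                          labels = rep(c("farm", "wild_hist"), each = 30))
  expect_equal(dapc_contributions(g_sw, n_pcs = 10), contrib, tolerance = 1e-8)

  # permuting labels destroys the signal locus' dominance on average
  perm_max <- replicate(10, {
    lab <- sample(origin_labels(g))
    cp <- dapc_contributions(genotype_matrix(unclass(g), labels = lab),
                             n_pcs = 10)
    cp[100]
  })
  expect_lt(mean(perm_max), contrib[100] / 2)

  expect_error(dapc_contributions(g, n_pcs = 60), "n_pcs")
  small <- genotype_matrix(matrix(0:1, 2, 4), labels = c("wild_hist", "farm"))
  expect_error(dapc_contributions(small), "2 members")
})

test_that("panel selection is the top-quantile intersection and is monotone", {
  # hand-assigned ranks: top-3 F_ST = {1,2,3}, top-3 DAPC = {2,3,4}
  stats <- data.frame(
    locus_id = paste0("L", 1:10),
    call_rate = 1, fst = c(10:1) / 10,
    dapc_contribution = c(0.05, 0.3, 0.25, 0.2, 0.05, 0.04, 0.04, 0.03, 0.02, 0.02),
    stringsAsFactors = FALSE)
  stats$rank_fst <- rank(-stats$fst, ties.method = "first")
  stats$rank_dapc <- rank(-stats$dapc_contribution, ties.method = "first")
  p <- select_panel(stats, 0.3)
  expect_setequal(p$locus_ids, c("L2", "L3"))   # brute-force intersection
  expect_equal(p$n_selected, 2L)
  # fraction 1 returns everything
  expect_setequal(select_panel(stats, 1)$locus_ids, stats$locus_id)
  # perfectly concordant criteria give exactly ceil(fraction * L) loci
  conc <- stats
  conc$dapc_contribution <- conc$fst
  conc$rank_dapc <- conc$rank_fst
  expect_equal(select_panel(conc, 0.3)$n_selected, 3L)
  expect_error(select_panel(stats, 0), "fraction")

  # monotonicity on simulated data: panel(q1) within panel(q2) for q1 <= q2
  sys <- make_ref_system(400, 0.2, 50, seed = 5)
  st <- locus_stats(rbind_genotypes(sys$wild, sys$farm), n_pcs = 20)
  fr <- c(0.01, 0.05, 0.2, 0.5, 1)
  panels <- lapply(fr, function(q) select_panel(st, q)$locus_ids)
  for (i in seq_len(length(fr) - 1)) {
    expect_true(all(panels[[i]] %in% panels[[i + 1]]))
  }
})

test_that("low-divergence systems degrade gracefully", {
  fr <- sim_baseline_frequencies(300, divergence = 0, seed = 6)
  w <- sim_genotypes(fr, 40, "wild", seed = 7)
  f <- sim_genotypes(fr, 40, "farm", seed = 8)
  tab <- weir_cockerham_fst(rbind_genotypes(w, f))
  expect_lt(abs(mean(tab$fst, na.rm = TRUE)), 0.02)
  st <- locus_stats(rbind_genotypes(w, f), n_pcs = 10)
  expect_s3_class(select_panel(st, 0.05), "marker_panel")
})
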