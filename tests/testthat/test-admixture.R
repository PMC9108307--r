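cfg_em <- sampler_config(engine = "em", seed = 1)
cfg_gibbs_short <- sampler_config(burn_in = 300, repetitions = 2000,
                                  engine = "gibbs", seed = 1)

test_that("saturating likelihoods push the estimate to the boundary", {
  fr <- make_diverged_freqs(80, 0.99, 0.01)
  wild <- sim_genotypes(fr, 60, "wild", seed = 2)
  farm <- sim_genotypes(fr, 60, "farm", seed = 3)
  test_ind <- sim_genotypes(fr, 1, "wild", seed = 4)
  r <- estimate_admixture_single(test_ind, wild, farm, cfg_em)
  expect_gt(r$p_wild_raw, 0.95)
  expect_equal(r$admixture_raw, 1 - r$p_wild_raw)
  rg <- estimate_admixture_single(test_ind, wild, farm, cfg_gibbs_short)
  expect_gt(rg$p_wild_raw, 0.9)
  expect_gte(rg$mc_se, 0)
})

test_that("EM optimum matches the brute-force likelihood grid", {
  set.seed(5)
  for (k in 1:50) {
    L <- sample(20:60, 1)
    pw <- runif(L, 0.1, 0.9)
    pf <- runif(L, 0.1, 0.9)
    q_true <- runif(1)
    g <- rbinom(L, 2, q_true * pw + (1 - q_true) * pf)
    # references large enough that posterior-mean frequencies sit near pw/pf
    fr <- structure(data.frame(locus_id = sprintf("locus_%05d", 1:L),
                               p_wild = pw, p_farm = pf),
                    class = c("pop_frequencies", "data.frame"))
    wild <- sim_genotypes(fr, 150, "wild", seed = 600 + k)
    farm <- sim_genotypes(fr, 150, "farm", seed = 700 + k)
    names(g) <- fr$locus_id
    r <- estimate_admixture_single(g, wild, farm, cfg_em)
    # the oracle grid uses the same fixed frequencies the EM engine used
    cw <- colSums(unclass(wild)); cf <- colSums(unclass(farm))
    pw_hat <- (cw + 1) / (2 * 150 + 2)
    pf_hat <- (cf + 1) / (2 * 150 + 2)
    q_grid <- oracle_grid_q(g, pw_hat, pf_hat, step = 0.001)
    expect_lt(abs(r$p_wild_raw - q_grid), 0.001 + 1e-9)
  }
})

test_that("gibbs and EM engines agree within Monte-Carlo error", {
  sys <- make_ref_system(120, 0.4, 80, seed = 6)
  tests <- sim_admixed_genotypes(sys$freqs, c(0.15, 0.5, 0.85), seed = 7)
  for (i in 1:3) {
    em <- estimate_admixture_single(tests[i, ], sys$wild, sys$farm, cfg_em)
    gb <- estimate_admixture_single(tests[i, ], sys$wild, sys$farm,
                                    cfg_gibbs_short)
    expect_lt(abs(em$p_wild_raw - gb$p_wild_raw),
              max(3 * gb$mc_se, 0.03))
  }
})

test_that("gibbs posterior mean is stable across independent seeds", {
  sys <- make_ref_system(100, 0.4, 60, seed = 8)
  test_ind <- sim_admixed_genotypes(sys$freqs, 0.4, seed = 9)
  runs <- lapply(c(11, 22, 33), function(s) {
    cfg <- sampler_config(burn_in = 300, repetitions = 3000,
                          engine = "gibbs", seed = s)
    estimate_admixture_single(test_ind[1, ], sys$wild, sys$farm, cfg)
  })
  for (i in 1:2) for (j in (i + 1):3) {
    se_ij <- sqrt(runs[[i]]$mc_se^2 + runs[[j]]$mc_se^2)
    expect_lt(abs(runs[[i]]$p_wild_raw - runs[[j]]$p_wild_raw),
              max(3 * se_ij, 0.02))
  }
})

test_that("label swap maps p_wild to its complement", {
  sys <- make_ref_system(150, 0.35, 70, seed = 10)
  tests <- sim_admixed_genotypes(sys$freqs, c(0.2, 0.6), seed = 11)
  for (i in 1:2) {
    fwd <- estimate_admixture_single(tests[i, ], sys$wild, sys$farm, cfg_em)
    rev <- estimate_admixture_single(tests[i, ], sys$farm, sys$wild, cfg_em)
    expect_equal(fwd$p_wild_raw, 1 - rev$p_wild_raw, tolerance = 1e-6)
  }
})

test_that("truth round-trip: known admixture recovered with small bias", {
  # informative system: |p_wild - p_farm| = 0.6 at 150 loci, 20 seeds
  fr <- make_diverged_freqs(150, 0.8, 0.2)
  err <- vapply(1:20, function(s) {
    wild <- sim_genotypes(fr, 120, "wild", seed = 1000 + s)
    farm <- sim_genotypes(fr, 120, "farm", seed = 2000 + s)
    q_true <- 0.35
    ti <- sim_admixed_genotypes(fr, q_true, seed = 3000 + s)
    estimate_admixture_single(ti[1, ], wild, farm, cfg_em)$p_wild_raw - q_true
  }, numeric(1))
  expect_lt(abs(mean(err)), 0.02)
})

test_that("leave-one-in batches are order-invariant and fault-tolerant", {
  sys <- make_ref_system(100, 0.4, 50, seed = 12)
  tests <- sim_admixed_genotypes(sys$freqs, c(0.1, 0.5, 0.9), seed = 13)
  cfg <- sampler_config(burn_in = 100, repetitions = 600, engine = "gibbs",
                        seed = 5)
  r1 <- leave_one_in(tests, sys$wild, sys$farm, cfg)
  # batch of one equals the single-individual estimate
  single <- estimate_admixture_single(tests[2, ], sys$wild, sys$farm, cfg)
  expect_equal(r1$p_wild_raw[2], single$p_wild_raw)
  # permuted input order gives identical per-individual results
  r2 <- leave_one_in(tests[c(3, 1, 2), ], sys$wild, sys$farm, cfg)
  expect_equal(r2[match(r1$individual_id, r2$individual_id), "p_wild_raw"],
               r1$p_wild_raw)
  # an all-missing individual is flagged, not fatal
  dos <- unclass(tests)
  dos[1, ] <- NA_integer_
  r3 <- leave_one_in(genotype_matrix(dos, labels = "contemporary"),
                     sys$wild, sys$farm, cfg)
  expect_true(r3$failed[1])
  expect_false(any(r3$failed[-1]))
})

test_that("rank correlation between true and estimated admixture is high", {
  sys <- make_ref_system(800, 0.15, 100, seed = 14)
  st <- locus_stats(rbind_genotypes(sys$wild, sys$farm), n_pcs = 30)
  panel <- select_panel(st, 0.15)
  set.seed(15)
  q_true <- runif(60)
  tests <- sim_admixed_genotypes(sys$freqs, q_true, seed = 16)
  res <- leave_one_in(tests, sys$wild, sys$farm, cfg_em, panel)
  expect_gt(cor(q_true, res$p_wild_raw, method = "spearman"), 0.95)
})

test_that("reference constants and calibration behave per the formula", {
  # perfectly diverged system saturates the constants
  fr <- make_diverged_freqs(60, 1, 0)
  wild <- sim_genotypes(fr, 40, "wild", seed = 17)
  farm <- sim_genotypes(fr, 40, "farm", seed = 18)
  wh <- sim_genotypes(fr, 10, "wild", seed = 19)
  fh <- sim_genotypes(fr, 10, "farm", seed = 20)
  rownames(wh) <- paste0("wh_", 1:10); rownames(fh) <- paste0("fh_", 1:10)
  cc <- compute_reference_constants(wh, fh, wild, farm, cfg_em)
  expect_gt(cc$wild_ref, 0.999)
  expect_lt(cc$farm_ref, 0.001)

  # moderate divergence keeps the constants interior, reproducibly
  sys <- make_ref_system(200, 0.25, 60, seed = 21)
  wh2 <- sim_genotypes(sys$freqs, 15, "wild", seed = 22)
  fh2 <- sim_genotypes(sys$freqs, 15, "farm", seed = 23)
  rownames(wh2) <- paste0("wh_", 1:15); rownames(fh2) <- paste0("fh_", 1:15)
  c1 <- compute_reference_constants(wh2, fh2, sys$wild, sys$farm, cfg_em)
  c2 <- compute_reference_constants(wh2, fh2, sys$wild, sys$farm, cfg_em)
  expect_lt(c1$wild_ref, 1)
  expect_gt(c1$farm_ref, 0)
  expect_identical(c1$wild_ref, c2$wild_ref)
  expect_error(
    compute_reference_constants(sys$wild[1:5, ], fh2, sys$wild, sys$farm, cfg_em),
    "disjoint")

  # affine calibration: fixed points and the printed-arithmetic example
  k <- list(wild_ref = 0.95, farm_ref = 0.10)
  expect_equal(calibrate(0.95, k), 1)
  expect_equal(calibrate(0.10, k), 0)
  expect_equal(calibrate(0.70, k), 0.60 / 0.85)
  expect_equal(calibrate(c(1.0, 0.05), k, clamp = TRUE), c(1, 0))
  expect_error(calibrate(0.5, list(wild_ref = 0.2, farm_ref = 0.4)),
               "degenerate")
})

test_that("estimator rejects invalid inputs", {
  sys <- make_ref_system(50, 0.3, 20, seed = 24)
  ti <- sim_admixed_genotypes(sys$freqs, 0.5, seed = 25)
  empty <- sys$wild[integer(0), ]
  expect_error(estimate_admixture_single(ti[1, ], empty, sys$farm, cfg_em),
               "empty reference")
  na_ind <- rep(NA_integer_, 50)
  names(na_ind) <- colnames(sys$wild)
  expect_error(estimate_admixture_single(na_ind, sys$wild, sys$farm, cfg_em),
               "missing")
  expect_error(sampler_config(repetitions = 0), "invalid")
})
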