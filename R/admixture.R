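#' Sampler configuration for supervised admixture estimation
#'
#' Defaults follow the field protocol for single-individual supervised runs:
#' 10,000 burn-in sweeps and 100,000 retained sweeps for the Gibbs engine, a
#' symmetric Dirichlet/Beta concentration of 1 on population allele
#' frequencies, and a uniform Beta(1, 1) prior on the individual's wild
#' proportion q. The model is the uncorrelated-frequencies admixture model:
#' reference individuals enter the allele-frequency conditionals as
#' fixed-origin data (supervision), the test individual carries latent
#' per-allele-copy origin indicators. The `"em"` engine fixes the reference
#' frequencies at their posterior means and maximises the test individual's
#' likelihood over q deterministically; it is exact, fast and reproducible,
#' and agrees with the Gibbs posterior mean within Monte-Carlo error.
#'
#' @param burn_in discarded sweeps (Gibbs engine).
#' @param repetitions retained sweeps (Gibbs engine).
#' @param lambda Beta concentration for allele frequencies, > 0.
#' @param thinning keep every `thinning`-th retained sweep.
#' @param engine `"em"` or `"gibbs"`.
#' @param seed base RNG seed; per-individual seeds are derived from it and the
#'   individual id, so batch results do not depend on processing order.
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(burn_in = 10000, repetitions = 100000, lambda = 1,
                           thinning = 1, engine = c("em", "gibbs"), seed = 1) {
  engine <- match.arg(engine)
  if (burn_in < 0 || repetitions < 1 || lambda <= 0 || thinning < 1) {
    stop("invalid sampler configuration")
  }
  structure(list(burn_in = as.integer(burn_in),
                 repetitions = as.integer(repetitions),
                 lambda = lambda, thinning = as.integer(thinning),
                 engine = engine, seed = as.integer(seed)),
            class = "sampler_config")
}

# reference-allele and alternative-allele counts per locus for a reference pool
ref_allele_counts <- function(refs) {
  dos <- unclass(refs)
  n_ok <- colSums(!is.na(dos))
  ref <- colSums(dos, na.rm = TRUE)
  list(ref = ref, alt = 2 * n_ok - ref)
}

# log-likelihood of one individual's dosages given q and the two frequency
# vectors; copies independent: P(copy = ref) = q p_w + (1 - q) p_f
loglik_q <- function(q, g, pw, pf) {
  pi_l <- q * pw + (1 - q) * pf
  sum(g * log(pi_l) + (2 - g) * log1p(-pi_l))
}

# EM for the wild proportion of one individual (g: non-missing dosages only)
em_q <- function(g, pw, pf, tol = 1e-10, max_iter = 1000) {
  q <- 0.5
  for (it in seq_len(max_iter)) {
    # E: expected wild origin per carried copy
    w_ref <- q * pw / (q * pw + (1 - q) * pf)
    w_alt <- q * (1 - pw) / (q * (1 - pw) + (1 - q) * (1 - pf))
    q_new <- sum(g * w_ref + (2 - g) * w_alt) / (2 * length(g))
    if (abs(q_new - q) < tol) {
      q <- q_new
      break
    }
    q <- q_new
  }
  q
}

#' Estimate one individual's admixture against two reference panels
#'
#' Supervised two-population assignment of a single unlabeled test individual
#' given wild and farm reference panels genotyped at the same loci. The
#' returned `p_wild_raw` is the estimated proportion of the individual's
#' genome of wild origin; `admixture_raw = 1 - p_wild_raw` is the admixture
#' estimate on the domesticated scale.
#'
#' The Gibbs engine samples, in turn: latent origins of each of the test
#' individual's allele copies (wild with probability proportional to
#' `q * p_wild` against `(1-q) * p_farm` for the carried allele); the wild
#' proportion q from Beta(1 + wild-assigned copies, 1 + farm-assigned copies);
#' and per-locus population frequencies from Beta(lambda + reference counts +
#' assigned test copies). `p_wild_raw` is the posterior mean of q over
#' retained sweeps and `mc_se` its batch-means Monte-Carlo standard error.
#' The EM engine fixes frequencies at `(count + lambda) / (total + 2 lambda)`
#' and maximises the likelihood over q; it is deterministic and its optimum
#' matches a brute-force likelihood grid.
#'
#' @param test numeric/integer dosage vector for the test individual (NA =
#'   missing), or a one-row [genotype_matrix()].
#' @param wild_refs,farm_refs reference [genotype_matrix()] objects sharing
#'   the test individual's locus list.
#' @param cfg a [sampler_config()].
#' @return a one-row data frame: `individual_id`, `p_wild_raw`,
#'   `admixture_raw`, `mc_se` (NA for EM), `n_loci_used`.
#' @export
estimate_admixture_single <- function(test, wild_refs, farm_refs,
                                      cfg = sampler_config()) {
  if (inherits(test, "genotype_matrix")) {
    stopifnot(nrow(test) == 1)
    id <- rownames(test)[1]
    test <- unclass(test)[1, ]
  } else {
    id <- names(test)[1]
    if (is.null(id) || length(unique(names(test))) > 1) id <- "test"
  }
  if (nrow(wild_refs) == 0 || nrow(farm_refs) == 0) {
    stop("empty reference panel")
  }
  if (!identical(colnames(wild_refs), colnames(farm_refs)) ||
      length(test) != ncol(wild_refs)) {
    stop("test individual and reference panels must share one locus list")
  }
  ok <- !is.na(test)
  if (!any(ok)) stop("all test loci are missing")
  g <- as.numeric(test[ok])
  cw <- ref_allele_counts(wild_refs[, ok])
  cf <- ref_allele_counts(farm_refs[, ok])
  lam <- cfg$lambda

  if (cfg$engine == "em") {
    pw <- (cw$ref + lam) / (cw$ref + cw$alt + 2 * lam)
    pf <- (cf$ref + lam) / (cf$ref + cf$alt + 2 * lam)
    q <- em_q(g, pw, pf)
    mc_se <- NA_real_
  } else {
    set.seed(derive_seed(cfg$seed, id))
    L <- length(g)
    q <- 0.5
    total <- cfg$burn_in + cfg$repetitions
    kept <- numeric(ceiling(cfg$repetitions / cfg$thinning))
    ki <- 0L
    pw <- stats::rbeta(L, lam + cw$ref, lam + cw$alt)
    pf <- stats::rbeta(L, lam + cf$ref, lam + cf$alt)
    for (s in seq_len(total)) {
      prob_w_ref <- q * pw / (q * pw + (1 - q) * pf)
      prob_w_alt <- q * (1 - pw) / (q * (1 - pw) + (1 - q) * (1 - pf))
      w_ref <- stats::rbinom(L, g, prob_w_ref)
      w_alt <- stats::rbinom(L, 2 - g, prob_w_alt)
      n_wild <- sum(w_ref + w_alt)
      q <- stats::rbeta(1, 1 + n_wild, 1 + 2 * L - n_wild)
      # frequency update with the assigned test copies folded into the counts
      pw <- stats::rbeta(L, lam + cw$ref + w_ref, lam + cw$alt + w_alt)
      pf <- stats::rbeta(L, lam + cf$ref + (g - w_ref),
                         lam + cf$alt + ((2 - g) - w_alt))
      if (s > cfg$burn_in && ((s - cfg$burn_in) %% cfg$thinning == 0L)) {
        ki <- ki + 1L
        kept[ki] <- q
      }
    }
    kept <- kept[seq_len(ki)]
    q <- mean(kept)
    nb <- min(50L, max(2L, ki %/% 20L))
    bm <- tapply(kept, cut(seq_len(ki), nb, labels = FALSE), mean)
    mc_se <- stats::sd(bm) / sqrt(length(bm))
  }
  data.frame(individual_id = id, p_wild_raw = q, admixture_raw = 1 - q,
             mc_se = mc_se, n_loci_used = sum(ok),
             stringsAsFactors = FALSE)
}

#' Leave-one-in admixture estimation for a batch of test individuals
#'
#' Each test individual is estimated in its own supervised run against the
#' full, fixed reference panels (the leave-one-in protocol: one unlabeled test
#' fish plus the labelled references per run). Runs are independent; each
#' individual's RNG seed derives from the base seed and its id, so the result
#' table is invariant to processing order. Per-individual failures are caught,
#' flagged and reported without aborting the batch.
#'
#' @param tests a [genotype_matrix()] of test individuals.
#' @param wild_refs,farm_refs reference panels.
#' @param cfg a [sampler_config()].
#' @param panel optional [select_panel()] result (or character vector of locus
#'   ids); estimation is restricted to these loci.
#' @return data frame with one row per test individual: `individual_id`,
#'   `p_wild_raw`, `admixture_raw`, `mc_se`, `n_loci_used`, `failed`,
#'   `message`.
#' @export
leave_one_in <- function(tests, wild_refs, farm_refs, cfg = sampler_config(),
                         panel = NULL) {
  if (!is.null(panel)) {
    ids <- if (inherits(panel, "marker_panel")) panel$locus_ids else as.character(panel)
    missing_loci <- setdiff(ids, colnames(tests))
    if (length(missing_loci) > 0) {
      stop("panel loci absent from test matrix: ",
           paste(utils::head(missing_loci, 3), collapse = ", "))
    }
    tests <- tests[, ids]
    wild_refs <- wild_refs[, ids]
    farm_refs <- farm_refs[, ids]
  }
  rows <- lapply(rownames(tests), function(id) {
    res <- tryCatch(
      estimate_admixture_single(tests[id, ], wild_refs, farm_refs, cfg),
      error = function(e) {
        data.frame(individual_id = id, p_wild_raw = NA_real_,
                   admixture_raw = NA_real_, mc_se = NA_real_,
                   n_loci_used = NA_integer_, stringsAsFactors = FALSE,
                   message = conditionMessage(e))
      })
    if (is.null(res$message)) res$message <- ""
    res
  })
  out <- do.call(rbind, rows)
  out$failed <- out$message != ""
  rownames(out) <- NULL
  out
}

#' Reference self-assignment constants for calibration
#'
#' Runs held-out wild and farm reference individuals through the estimator as
#' unlabeled tests (against reference panels from which they are excluded) and
#' returns the two group means of raw p(wild). Because real panels are not
#' fully diverged, the wild mean falls below one and the farm mean above zero;
#' these constants anchor the affine calibration of [calibrate()].
#'
#' @param wild_holdout,farm_holdout held-out individuals, disjoint from the
#'   reference panels.
#' @param wild_refs,farm_refs reference panels used for every run.
#' @param cfg a [sampler_config()].
#' @param panel optional marker panel restriction.
#' @return list of class `calibration_constants`: `wild_ref`, `farm_ref`,
#'   `n_wild_holdout`, `n_farm_holdout`, plus the per-individual tables.
#' @export
compute_reference_constants <- function(wild_holdout, farm_holdout,
                                        wild_refs, farm_refs,
                                        cfg = sampler_config(), panel = NULL) {
  if (length(intersect(rownames(wild_holdout), rownames(wild_refs))) > 0 ||
      length(intersect(rownames(farm_holdout), rownames(farm_refs))) > 0) {
    stop("holdout individuals must be disjoint from the reference panels")
  }
  rw <- leave_one_in(wild_holdout, wild_refs, farm_refs, cfg, panel)
  rf <- leave_one_in(farm_holdout, wild_refs, farm_refs, cfg, panel)
  structure(list(
    wild_ref = mean(rw$p_wild_raw, na.rm = TRUE),
    farm_ref = mean(rf$p_wild_raw, na.rm = TRUE),
    n_wild_holdout = nrow(wild_holdout),
    n_farm_holdout = nrow(farm_holdout),
    wild_holdout_results = rw,
    farm_holdout_results = rf
  ), class = "calibration_constants")
}

#' @export
print.calibration_constants <- function(x, ...) {
  cat(sprintf("calibration constants: Wild_ref = %.4f (n = %d), Farm_ref = %.4f (n = %d)\n",
              x$wild_ref, x$n_wild_holdout, x$farm_ref, x$n_farm_holdout))
  invisible(x)
}

#' Affine calibration of raw wild-assignment probabilities
#'
#' Applies `(p_wild - Farm_ref) / (Wild_ref - Farm_ref)`, the reference-based
#' rescaling that maps the mean wild-reference self-assignment to a wild
#' proportion of 1 and the mean farm-reference self-assignment to 0. Values
#' are unclamped by default (calibrated values can fall slightly outside
#' \[0, 1\]); `clamp = TRUE` truncates into the unit interval.
#'
#' @param p_wild_values numeric raw p(wild) values.
#' @param constants a [compute_reference_constants()] result (or a list with
#'   `wild_ref` and `farm_ref`).
#' @param clamp clamp calibrated values into \[0, 1\].
#' @return numeric vector of calibrated wild proportions; the corresponding
#'   calibrated admixture is one minus the result.
#' @export
calibrate <- function(p_wild_values, constants, clamp = FALSE) {
  if (constants$wild_ref <= constants$farm_ref) {
    stop("degenerate calibration: wild_ref must exceed farm_ref")
  }
  out <- (p_wild_values - constants$farm_ref) /
    (constants$wild_ref - constants$farm_ref)
  if (clamp) out <- pmin(pmax(out, 0), 1)
  out
}
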