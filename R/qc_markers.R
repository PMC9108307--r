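#' Per-locus and per-individual call rates
#' @param g a [genotype_matrix()].
#' @return list with numeric vectors `locus` and `sample` of fractions of
#'   non-missing calls.
#' @export
call_rates <- function(g) {
  list(locus = colMeans(!is.na(unclass(g))),
       sample = rowMeans(!is.na(unclass(g))))
}

#' Filter genotypes by call rate
#'
#' Samples are filtered first, then loci (both strict: a call rate *lower
#' than* the threshold discards). Defaults follow standard array QC practice
#' for this assay: 0.97 for SNPs, 0.85 for samples. When a logical
#' `poly_high_resolution` flag is supplied, loci flagged `FALSE` are dropped
#' after the call-rate passes (the flag is produced by the array genotyping
#' software; this package only consumes it).
#'
#' @param g a [genotype_matrix()].
#' @param snp_threshold minimum locus call rate, in \[0, 1\].
#' @param sample_threshold minimum sample call rate, in \[0, 1\].
#' @param poly_high_resolution optional named (or positionally matched)
#'   logical vector over loci; `FALSE`/`NA` loci are discarded.
#' @return a list of class `qc_result`: `genotypes` (the filtered matrix),
#'   `discarded_samples`, `discarded_loci` (ids), and `call_rate_summary`.
#' @export
filter_call_rate <- function(g, snp_threshold = 0.97, sample_threshold = 0.85,
                             poly_high_resolution = NULL) {
  if (snp_threshold < 0 || snp_threshold > 1 ||
      sample_threshold < 0 || sample_threshold > 1) {
    stop("call-rate thresholds must lie in [0, 1]")
  }
  cr_sample <- rowMeans(!is.na(unclass(g)))
  keep_s <- cr_sample >= sample_threshold
  if (!any(keep_s)) stop("empty after QC: all samples discarded")
  g2 <- g[keep_s, ]
  cr_locus <- colMeans(!is.na(unclass(g2)))
  keep_l <- cr_locus >= snp_threshold
  if (!is.null(poly_high_resolution)) {
    flag <- poly_high_resolution
    if (!is.null(names(flag))) flag <- flag[colnames(g2)]
    flag[is.na(flag)] <- FALSE
    keep_l <- keep_l & rep_len(as.logical(flag), ncol(g2))
  }
  if (!any(keep_l)) stop("empty after QC: all loci discarded")
  out <- list(
    genotypes = g2[, keep_l],
    discarded_samples = rownames(g)[!keep_s],
    discarded_loci = colnames(g2)[!keep_l],
    call_rate_summary = list(
      sample = summary(cr_sample),
      locus = summary(cr_locus),
      snp_threshold = snp_threshold,
      sample_threshold = sample_threshold
    )
  )
  class(out) <- "qc_result"
  out
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("QC: discarded %d samples, %d loci; retained %d x %d\n",
              length(x$discarded_samples), length(x$discarded_loci),
              nrow(x$genotypes), ncol(x$genotypes)))
  invisible(x)
}

# two-population partition from origin labels or an explicit vector; returns a
# factor with exactly two levels, level order fixed as (first, second)
two_pop_factor <- function(g, labels) {
  if (is.null(labels)) labels <- origin_labels(g)
  labels <- rep_len(as.character(labels), nrow(g))
  lev <- unique(labels)
  if (length(lev) != 2) {
    stop("exactly two populations are required, got: ",
         paste(lev, collapse = ", "))
  }
  factor(labels, levels = lev)
}

#' Per-locus Weir-Cockerham F_ST between two populations
#'
#' The Weir & Cockerham (1984) variance-components estimator theta computed
#' locus by locus for a two-population partition: theta = a / (a + b + c)
#' where a, b, c are the among-population, among-individual-within-population
#' and within-individual components. Missing genotypes are excluded per locus
#' (pairwise-complete); negative estimates are retained, not truncated. A
#' locus needs at least two non-missing genotypes in each population and must
#' be polymorphic overall, otherwise its estimate is `NA` (flagged
#' undefined and excluded from ranking downstream). The multilocus estimate is
#' the ratio of summed numerators to summed denominators, not the mean of
#' ratios.
#'
#' @param g a [genotype_matrix()].
#' @param labels optional two-level per-individual partition; defaults to the
#'   matrix origin labels.
#' @return data frame with columns `locus_id`, `fst`, `a` (numerator) and
#'   `denom` (a + b + c), plus attribute `multilocus` = sum(a)/sum(denom).
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics for
#'   the analysis of population structure. Evolution 38:1358-1370.
#' @export
weir_cockerham_fst <- function(g, labels = NULL) {
  pop <- two_pop_factor(g, labels)
  dos <- unclass(g)
  g1 <- dos[pop == levels(pop)[1], , drop = FALSE]
  g2 <- dos[pop == levels(pop)[2], , drop = FALSE]

  n1 <- colSums(!is.na(g1))
  n2 <- colSums(!is.na(g2))
  p1 <- colMeans(g1, na.rm = TRUE) / 2
  p2 <- colMeans(g2, na.rm = TRUE) / 2
  h1 <- colMeans(g1 == 1L, na.rm = TRUE)
  h2 <- colMeans(g2 == 1L, na.rm = TRUE)

  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)

  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  denom <- a + b + cc

  undefined <- n1 < 2 | n2 < 2 | !is.finite(denom) | denom == 0
  fst <- a / denom
  fst[undefined] <- NA_real_
  a[undefined] <- NA_real_
  denom[undefined] <- NA_real_

  out <- data.frame(locus_id = colnames(g), fst = fst, a = a, denom = denom,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "multilocus") <- sum(a, na.rm = TRUE) / sum(denom, na.rm = TRUE)
  out
}

#' Multilocus Weir-Cockerham estimate from per-locus components
#' @param fst_table output of [weir_cockerham_fst()].
#' @return the ratio-of-sums multilocus theta.
#' @export
multilocus_fst <- function(fst_table) {
  sum(fst_table$a, na.rm = TRUE) / sum(fst_table$denom, na.rm = TRUE)
}

#' Per-locus DAPC variance contributions
#'
#' Discriminant analysis of principal components for a two-group partition:
#' missing dosages are mean-imputed, columns centred and (optionally) scaled
#' by the binomial standard deviation sqrt(2 p (1 - p)) with the allele
#' frequency floored away from 0/1; a PCA retains `n_pcs` components; a linear
#' discriminant analysis on the retained scores yields the single discriminant
#' axis; the axis is back-projected to locus space through the PCA loadings;
#' each locus' contribution is its squared coordinate on that axis, normalised
#' to sum to one.
#'
#' @param g a [genotype_matrix()].
#' @param labels optional two-level partition; defaults to origin labels.
#' @param n_pcs number of principal components retained; default
#'   `min(floor(n/3), 100)`.
#' @param scale logical; scale loci by binomial sd (default `TRUE`).
#' @param freq_floor allele-frequency floor used in the scaling sd.
#' @return numeric vector of per-locus contributions (named by locus), summing
#'   to 1.
#' @export
dapc_contributions <- function(g, labels = NULL, n_pcs = NULL, scale = TRUE,
                               freq_floor = 0.005) {
  pop <- two_pop_factor(g, labels)
  if (any(table(pop) < 2)) stop("each group needs at least 2 members")
  n <- nrow(g)
  if (is.null(n_pcs)) n_pcs <- min(floor(n / 3), 100)
  if (n_pcs >= n) stop("n_pcs must be smaller than the number of individuals")
  if (n_pcs < 1) stop("n_pcs must be >= 1")

  X <- unclass(g)
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  na_idx <- which(is.na(X))
  if (length(na_idx) > 0) X[na_idx] <- mu[((na_idx - 1) %/% n) + 1]
  X <- sweep(X, 2, mu)
  if (scale) {
    p <- pmin(pmax(mu / 2, freq_floor), 1 - freq_floor)
    X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  }
  sv <- svd(X, nu = n_pcs, nv = n_pcs)
  keep <- sv$d[seq_len(n_pcs)] > sv$d[1] * 1e-9
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[seq_len(n_pcs)][keep],
                                                sum(keep))
  ld <- MASS::lda(scores, grouping = pop)
  axis_loci <- sv$v[, keep, drop = FALSE] %*% ld$scaling[, 1]
  contrib <- as.numeric(axis_loci)^2
  contrib <- contrib / sum(contrib)
  names(contrib) <- colnames(g)
  contrib
}

#' Per-locus statistics table for panel selection
#'
#' Combines call rate, Weir-Cockerham F_ST and DAPC contribution per locus,
#' with descending ranks for the two selection criteria (rank 1 = most
#' differentiated). Loci with undefined F_ST get rank `NA` and are never
#' selected.
#'
#' @param g a [genotype_matrix()] restricted to the two reference populations.
#' @param labels optional two-level partition; defaults to origin labels.
#' @param n_pcs passed to [dapc_contributions()].
#' @param scale passed to [dapc_contributions()].
#' @return data frame `locus_id`, `call_rate`, `fst`, `dapc_contribution`,
#'   `rank_fst`, `rank_dapc`.
#' @export
locus_stats <- function(g, labels = NULL, n_pcs = NULL, scale = TRUE) {
  fst <- weir_cockerham_fst(g, labels)
  dapc <- dapc_contributions(g, labels, n_pcs = n_pcs, scale = scale)
  cr <- colMeans(!is.na(unclass(g)))
  out <- data.frame(
    locus_id = colnames(g),
    call_rate = as.numeric(cr),
    fst = fst$fst,
    dapc_contribution = as.numeric(dapc),
    stringsAsFactors = FALSE
  )
  # ties broken by locus (column) order for reproducibility
  rk <- function(v) {
    r <- rep(NA_integer_, length(v))
    ok <- !is.na(v)
    r[ok] <- rank(-v[ok], ties.method = "first")
    r
  }
  out$rank_fst <- rk(out$fst)
  out$rank_dapc <- rk(out$dapc_contribution)
  out
}

#' Select a marker panel by joint top-quantile F_ST and DAPC contribution
#'
#' The panel is the intersection of the top `ceil(fraction * L)` loci by F_ST
#' and the top `ceil(fraction * L)` loci by DAPC contribution (L = number of
#' loci with defined ranks). Because the intersection can be smaller than
#' either list, the selected panel may hold fewer than `ceil(fraction * L)`
#' markers. An empty intersection yields a warning and an empty panel.
#'
#' @param stats a [locus_stats()] table.
#' @param fraction selection quantile in (0, 1\].
#' @return list of class `marker_panel`: `fraction`, `locus_ids`,
#'   `n_selected`.
#' @export
select_panel <- function(stats, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  ok <- !is.na(stats$rank_fst) & !is.na(stats$rank_dapc)
  L <- sum(ok)
  k <- ceiling(fraction * L)
  top_fst <- stats$locus_id[ok][stats$rank_fst[ok] <= k]
  top_dapc <- stats$locus_id[ok][stats$rank_dapc[ok] <= k]
  sel <- intersect(top_fst, top_dapc)
  sel <- stats$locus_id[stats$locus_id %in% sel]  # keep locus order
  if (length(sel) == 0) warning("empty panel: the two top lists do not intersect")
  structure(list(fraction = fraction, locus_ids = sel, n_selected = length(sel)),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d loci at fraction %.3g\n", x$n_selected, x$fraction))
  invisible(x)
}
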