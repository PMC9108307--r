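#' Genotype matrix container
#'
#' All modules share one genotype representation: an individuals x loci integer
#' matrix of reference-allele dosages (0, 1, 2), with `NA` marking a missing
#' genotype call. Row names are individual ids, column names locus ids, and a
#' per-individual origin label (one of `"wild_hist"`, `"farm"`,
#' `"contemporary"`, `"simulated"`) records which sample set each fish belongs
#' to.
#'
#' @param dosage integer matrix of reference-allele counts in \{0, 1, 2, NA\},
#'   individuals in rows, loci in columns. Row and column names are used as
#'   individual and locus ids; defaults are generated when absent.
#' @param labels character vector of per-individual origin labels, recycled if
#'   length one.
#' @return an object of class `genotype_matrix` (an integer matrix with a
#'   `labels` attribute).
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2), labels = "simulated")
#' dim(g)
#' @export
genotype_matrix <- function(dosage, labels = "simulated") {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  ok <- is.na(dosage) | (dosage >= 0L & dosage <= 2L)
  if (!all(ok)) {
    stop("dosage values must be 0, 1, 2 or NA; offending entries at rows ",
         paste(utils::head(unique(which(!ok, arr.ind = TRUE)[, 1]), 5),
               collapse = ", "))
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("ind_%04d", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("locus_%05d", seq_len(ncol(dosage)))
  }
  labels <- rep_len(as.character(labels), nrow(dosage))
  bad <- setdiff(unique(labels), c("wild_hist", "farm", "contemporary", "simulated"))
  if (length(bad) > 0) {
    stop("unknown origin label(s): ", paste(bad, collapse = ", "))
  }
  structure(dosage, labels = labels, class = c("genotype_matrix", class(dosage)))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci\n", nrow(x), ncol(x)))
  tab <- table(attr(x, "labels"))
  cat("origins:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(x))
  cat(sprintf("missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Origin labels of a genotype matrix
#' @param g a `genotype_matrix`.
#' @return character vector of per-individual labels.
#' @export
origin_labels <- function(g) {
  attr(g, "labels")
}

#' Subset a genotype matrix, keeping labels in step
#' @param x a `genotype_matrix`.
#' @param i,j row (individual) and column (locus) indices.
#' @param drop ignored; subsetting always returns a matrix.
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  lab <- attr(x, "labels")
  m <- unclass(x)
  attr(m, "labels") <- NULL
  out <- m[i, j, drop = FALSE]
  if (!missing(i)) {
    ii <- i
    if (is.character(ii)) ii <- match(ii, rownames(m))
    lab <- lab[ii]
  }
  genotype_matrix(out, labels = lab)
}

#' Bind genotype matrices over individuals
#' @param ... `genotype_matrix` objects sharing one locus list.
#' @return a `genotype_matrix` stacking all individuals.
#' @export
rbind_genotypes <- function(...) {
  gs <- list(...)
  loci <- colnames(gs[[1]])
  for (g in gs[-1]) {
    if (!identical(colnames(g), loci)) {
      stop("genotype matrices do not share the same locus list")
    }
  }
  dos <- do.call(rbind, lapply(gs, unclass))
  genotype_matrix(dos, labels = unlist(lapply(gs, origin_labels)))
}

# internal: stable per-individual seed from a base seed and an id string,
# so batch results do not depend on execution order. Polynomial string hash
# mod a Mersenne prime keeps the result a valid 32-bit seed.
derive_seed <- function(base_seed, id) {
  h <- 0
  for (k in utf8ToInt(as.character(id))) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(base_seed) %% 2147483647 + h) %% 2147483647)
}
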