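#' File formats
#'
#' The canonical on-disk genotype format is a TSV dosage table (individuals as
#' rows; columns `individual_id`, `origin`, then one column per locus holding
#' reference-allele dosage 0/1/2 with `NA` for missing). VCF is supported for
#' interoperability (diploid GT fields; `./.` = missing; multi-allelic records
#' are rejected). A classic STRUCTURE two-rows-per-individual text writer and
#' reader are provided as well. Every file written by this package starts with
#' `#`-prefixed provenance comment lines (package version, stage, seed) which
#' all readers skip.
#'
#' @name io_formats
NULL

provenance_header <- function(stage, seed) {
  c(sprintf("# domadmix %s", as.character(utils::packageVersion("domadmix"))),
    sprintf("# stage=%s seed=%s date=%s", stage,
            if (is.null(seed)) "NA" else seed, format(Sys.Date())))
}

#' Write genotypes to TSV or VCF
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @param seed seed recorded in the provenance header.
#' @param stage stage name recorded in the provenance header.
#' @return the path, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("tsv", "vcf"), seed = NULL,
                            stage = "genotypes") {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(provenance_header(stage, seed), con)
    df <- data.frame(individual_id = rownames(g), origin = origin_labels(g),
                     unclass(g), check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines("##fileformat=VCFv4.2", con)
    writeLines(sub("^# ", "##", provenance_header(stage, seed)), con)
    writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
    writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g)), collapse = "\t"), con)
    # dosage counts REFERENCE alleles: 2 -> 0/0, 1 -> 0/1, 0 -> 1/1
    gt_code <- c("1/1", "0/1", "0/0")
    for (l in seq_len(ncol(g))) {
      dos <- unclass(g)[, l]
      gt <- ifelse(is.na(dos), "./.", gt_code[dos + 1L])
      writeLines(paste(c("1", l, colnames(g)[l], "A", "C", ".", "PASS", ".",
                         "GT", gt), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read genotypes from TSV or VCF
#'
#' @param path input path.
#' @param format `"tsv"` or `"vcf"`; guessed from the extension by default.
#' @param labels optional origin labels overriding any `origin` column.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = NULL, labels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (!"individual_id" %in% names(df)) {
      stop("malformed genotype TSV (no individual_id column): ", path)
    }
    ids <- df$individual_id
    org <- if ("origin" %in% names(df)) df$origin else "simulated"
    loci <- setdiff(names(df), c("individual_id", "origin"))
    dos <- as.matrix(df[, loci, drop = FALSE])
    rownames(dos) <- ids
    g <- genotype_matrix(dos, labels = if (is.null(labels)) org else labels)
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    alt <- vcfR::getALT(v)
    multi <- grepl(",", alt)
    if (any(multi)) {
      stop("multi-allelic VCF record(s) not supported: ",
           paste(utils::head(vcfR::getID(v)[multi], 3), collapse = ", "))
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gsub("|", "/", gt, fixed = TRUE)
    alt_count <- matrix(NA_integer_, nrow(gt), ncol(gt))
    alt_count[gt %in% c("0/0")] <- 0L
    alt_count[gt %in% c("0/1", "1/0")] <- 1L
    alt_count[gt %in% c("1/1")] <- 2L
    bad <- !is.na(gt) & !(gt %in% c("0/0", "0/1", "1/0", "1/1", "./."))
    if (any(bad)) {
      stop("unparseable GT field(s), e.g. '", gt[which(bad)[1]], "' at record ",
           which(bad, arr.ind = TRUE)[1, 1])
    }
    dos <- t(2L - alt_count)                     # back to reference dosage
    rownames(dos) <- colnames(gt)
    colnames(dos) <- vcfR::getID(v)
    g <- genotype_matrix(dos,
                         labels = if (is.null(labels)) "simulated" else labels)
  }
  g
}

#' Write a classic STRUCTURE two-rows-per-individual file
#'
#' Layout: a header row of locus ids, then two rows per individual, each
#' `<id> <pop> <popflag>` followed by one allele (1 = reference, 0 =
#' alternative, -9 = missing) per locus. Populations are coded 1 (wild
#' reference), 2 (farm reference), 0 (test); popflag is 1 for reference
#' individuals and 0 for tests, matching supervised usage.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_structure_file <- function(g, path) {
  if (nrow(g) == 0 || ncol(g) == 0) stop("empty genotype matrix")
  pop_code <- c(wild_hist = 1L, farm = 2L, contemporary = 0L, simulated = 0L)
  pops <- pop_code[origin_labels(g)]
  flags <- as.integer(pops != 0L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(g), collapse = " "), con)
  dos <- unclass(g)
  for (i in seq_len(nrow(g))) {
    a1 <- ifelse(is.na(dos[i, ]), -9L, as.integer(dos[i, ] >= 1L))
    a2 <- ifelse(is.na(dos[i, ]), -9L, as.integer(dos[i, ] == 2L))
    pre <- paste(rownames(g)[i], pops[i], flags[i])
    writeLines(paste(pre, paste(a1, collapse = " ")), con)
    writeLines(paste(pre, paste(a2, collapse = " ")), con)
  }
  invisible(path)
}

#' Read a STRUCTURE file written by [write_structure_file()]
#' @param path input path.
#' @return a [genotype_matrix()].
#' @export
read_structure_file <- function(path) {
  lines <- readLines(path)
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- do.call(rbind, strsplit(trimws(lines[-1]), "\\s+"))
  if (nrow(body) %% 2 != 0) stop("malformed STRUCTURE file: odd row count")
  ids <- body[seq(1, nrow(body), 2), 1]
  pops <- as.integer(body[seq(1, nrow(body), 2), 2])
  al <- matrix(as.integer(body[, -(1:3)]), nrow = nrow(body))
  a1 <- al[seq(1, nrow(al), 2), , drop = FALSE]
  a2 <- al[seq(2, nrow(al), 2), , drop = FALSE]
  dos <- a1 + a2
  dos[a1 == -9L | a2 == -9L] <- NA_integer_
  rownames(dos) <- ids
  colnames(dos) <- loci
  lab <- c("contemporary", "wild_hist", "farm")[pops + 1L]
  genotype_matrix(dos, labels = lab)
}

#' Write / read a phenotype table as CSV
#' @param pheno a phenotype data frame.
#' @param path file path.
#' @param seed seed recorded in the provenance header.
#' @return the path (writer, invisibly) or the data frame (reader).
#' @export
write_phenotypes <- function(pheno, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header("phenotypes", seed), con)
  utils::write.csv(pheno, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write an admixture result table as TSV
#' @param results a [leave_one_in()] result.
#' @param path file path.
#' @param seed seed recorded in the provenance header.
#' @export
write_admixture_results <- function(results, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header("admixture", seed), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
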