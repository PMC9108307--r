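#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. Unknown keys
#' are rejected. A configuration is either simulation-driven (a `simulate`
#' block describes the synthetic system) or file-driven (paths to genotype and
#' phenotype files plus a population file mapping individual ids to origin
#' labels).
#'
#' @param seed base seed for every stochastic stage.
#' @param simulate list: `n_loci`, `divergence`, `n_wild_ref`, `n_farm_ref`,
#'   `n_contemporary`, `admixture_beta` (shape1, shape2 of the true-admixture
#'   Beta distribution), optional `locus_missingness`.
#' @param paths list: `genotypes`, `population`, `phenotypes` (file-driven
#'   runs).
#' @param qc list: `snp_call_rate`, `sample_call_rate`.
#' @param panel list: `fraction`, optional `n_pcs`.
#' @param sampler list: `engine`, `burn_in`, `repetitions`.
#' @param holdout list: `n_wild`, `n_farm`.
#' @param validate list: `n_hybrids`, or `NULL` to skip F1 validation.
#' @param associate character vector of linear-model responses and the two
#'   binary outcomes to fit, or `NULL` to skip association models.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            simulate = list(n_loci = 2000, divergence = 0.15,
                                            n_wild_ref = 250, n_farm_ref = 250,
                                            n_contemporary = 100,
                                            admixture_beta = c(2, 6)),
                            paths = NULL,
                            qc = list(snp_call_rate = 0.97,
                                      sample_call_rate = 0.85),
                            panel = list(fraction = 0.01),
                            sampler = list(engine = "em", burn_in = 1000,
                                           repetitions = 10000),
                            holdout = list(n_wild = 100, n_farm = 100),
                            validate = list(n_hybrids = 200),
                            associate = c("return_day", "length_cm",
                                          "smolt_age_3plus", "one_sea_winter")) {
  cfg <- list(seed = seed, simulate = simulate, paths = paths, qc = qc,
              panel = panel, sampler = sampler, holdout = holdout,
              validate = validate, associate = associate)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  known <- c("seed", "simulate", "paths", "qc", "panel", "sampler", "holdout",
             "validate", "associate")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  if (is.null(cfg$simulate) && is.null(cfg$paths)) {
    stop("config needs either a 'simulate' block or input 'paths'")
  }
  if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    need <- c("n_loci", "divergence", "n_wild_ref", "n_farm_ref", "n_contemporary")
    miss <- setdiff(need, names(s))
    if (length(miss) > 0) stop("simulate block lacks: ", paste(miss, collapse = ", "))
    counts <- unlist(s[c("n_loci", "n_wild_ref", "n_farm_ref", "n_contemporary")])
    if (any(counts < 1)) stop("simulate counts must be positive")
  }
  if (cfg$panel$fraction <= 0 || cfg$panel$fraction > 1) {
    stop("panel fraction must lie in (0, 1]")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the full admixture pipeline
#'
#' Executes, in order: (optional) simulation of the two-population system and
#' phenotypes; call-rate QC; locus statistics and panel selection; reference
#' calibration constants from held-out reference individuals; leave-one-in
#' admixture estimation of the contemporary sample; calibration and
#' distribution summary; (optional) F1-hybrid accuracy validation; (optional)
#' admixture-phenotype association models. All stage outputs are written under
#' `output_dir` with provenance headers, together with the resolved config; a
#' rerun with the same config and seed reproduces every output.
#'
#' @param config a [pipeline_config()] or a YAML path.
#' @param output_dir directory for stage outputs (created if needed).
#' @param quiet suppress progress messages.
#' @return a list with the main stage results (`panel`, `constants`,
#'   `admixture`, `distribution`, `accuracy`, `models`).
#' @export
run_pipeline <- function(config, output_dir = tempfile("domadmix_run_"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed
  write_pipeline_config(config, file.path(output_dir, "config.yaml"))

  stage <- "simulate"
  result <- tryCatch({
    if (!is.null(config$simulate)) {
      s <- config$simulate
      freqs <- sim_baseline_frequencies(s$n_loci, s$divergence,
                                        seed = derive_seed(seed, "freqs"))
      wild_all <- sim_genotypes(freqs, s$n_wild_ref + config$holdout$n_wild,
                                "wild", seed = derive_seed(seed, "wild"))
      farm_all <- sim_genotypes(freqs, s$n_farm_ref + config$holdout$n_farm,
                                "farm", seed = derive_seed(seed, "farm"))
      ab <- if (is.null(s$admixture_beta)) c(2, 6) else s$admixture_beta
      set.seed(derive_seed(seed, "trueq"))
      true_admix <- stats::rbeta(s$n_contemporary, ab[1], ab[2])
      contemporary <- sim_admixed_genotypes(freqs, 1 - true_admix,
                                            seed = derive_seed(seed, "contemp"))
      if (!is.null(s$locus_missingness) && s$locus_missingness > 0) {
        wild_all <- sim_missingness(wild_all, s$locus_missingness,
                                    seed = derive_seed(seed, "miss_w"))
        farm_all <- sim_missingness(farm_all, s$locus_missingness,
                                    seed = derive_seed(seed, "miss_f"))
        contemporary <- sim_missingness(contemporary, s$locus_missingness,
                                        seed = derive_seed(seed, "miss_c"))
      }
      pheno <- sim_phenotypes(true_admix, seed = derive_seed(seed, "pheno"),
                              ids = rownames(contemporary))
      utils::write.csv(data.frame(individual_id = rownames(contemporary),
                                  true_admixture = true_admix),
                       file.path(output_dir, "truth.csv"), row.names = FALSE)
      write_phenotypes(pheno, file.path(output_dir, "phenotypes.csv"), seed)
      say("simulated %d loci, %d+%d refs, %d contemporary", s$n_loci,
          nrow(wild_all), nrow(farm_all), nrow(contemporary))
    } else {
      g <- read_genotypes(config$paths$genotypes)
      popfile <- utils::read.table(config$paths$population, header = TRUE,
                                   stringsAsFactors = FALSE)
      lab <- popfile$label[match(rownames(g), popfile$individual_id)]
      g <- genotype_matrix(unclass(g), labels = lab)
      wild_all <- g[origin_labels(g) == "wild_hist", ]
      farm_all <- g[origin_labels(g) == "farm", ]
      contemporary <- g[origin_labels(g) == "contemporary", ]
      pheno <- if (!is.null(config$paths$phenotypes)) {
        read_phenotypes(config$paths$phenotypes)
      }
      true_admix <- NULL
    }

    stage <- "qc"
    refs_all <- rbind_genotypes(wild_all, farm_all)
    qcres <- filter_call_rate(refs_all, config$qc$snp_call_rate,
                              config$qc$sample_call_rate)
    refs <- qcres$genotypes
    say("QC: %d loci retained of %d", ncol(refs), ncol(refs_all))

    stage <- "select-panel"
    wild_q <- refs[origin_labels(refs) == "wild_hist", ]
    farm_q <- refs[origin_labels(refs) == "farm", ]
    n_wild_ref <- nrow(wild_q) - config$holdout$n_wild
    n_farm_ref <- nrow(farm_q) - config$holdout$n_farm
    if (n_wild_ref < 2 || n_farm_ref < 2) {
      stop("too few reference individuals after QC and holdout split")
    }
    wild_refs <- wild_q[seq_len(n_wild_ref), ]
    farm_refs <- farm_q[seq_len(n_farm_ref), ]
    wild_hold <- wild_q[n_wild_ref + seq_len(config$holdout$n_wild), ]
    farm_hold <- farm_q[n_farm_ref + seq_len(config$holdout$n_farm), ]
    stats_tab <- locus_stats(rbind_genotypes(wild_refs, farm_refs),
                             n_pcs = config$panel$n_pcs)
    panel <- select_panel(stats_tab, config$panel$fraction)
    utils::write.table(stats_tab, file.path(output_dir, "locus_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(panel$locus_ids, file.path(output_dir, "panel.tsv"))
    say("panel: %d loci at fraction %.3g", panel$n_selected, panel$fraction)

    stage <- "reference-constants"
    scfg <- sampler_config(burn_in = config$sampler$burn_in,
                           repetitions = config$sampler$repetitions,
                           engine = config$sampler$engine, seed = seed)
    constants <- compute_reference_constants(wild_hold, farm_hold,
                                             wild_refs, farm_refs, scfg, panel)
    jsonlite::write_json(
      list(wild_ref = constants$wild_ref, farm_ref = constants$farm_ref,
           n_wild_holdout = constants$n_wild_holdout,
           n_farm_holdout = constants$n_farm_holdout, seed = seed),
      file.path(output_dir, "calibration_constants.json"), auto_unbox = TRUE)
    say("constants: Wild_ref=%.4f Farm_ref=%.4f", constants$wild_ref,
        constants$farm_ref)

    stage <- "admixture"
    contemporary_p <- contemporary[, colnames(refs)]
    adm <- leave_one_in(contemporary_p, wild_refs, farm_refs, scfg, panel)
    adm$p_wild_calibrated <- calibrate(adm$p_wild_raw, constants)
    write_admixture_results(adm, file.path(output_dir, "admixture.tsv"), seed)

    stage <- "summarise"
    dist_sum <- admixture_distribution_summary(adm, constants)

    stage <- "validate"
    accuracy <- NULL
    if (!is.null(config$validate)) {
      hybrids <- hybridize(wild_refs, farm_refs, config$validate$n_hybrids,
                           seed = derive_seed(seed, "hybrids"))
      accuracy <- evaluate_hybrid_accuracy(hybrids, wild_refs, farm_refs,
                                           panel, scfg)
      say("F1 accuracy: MSE=%.4f", accuracy$mse)
    }

    stage <- "associate"
    models <- list()
    if (!is.null(config$associate) && !is.null(pheno)) {
      tab <- merge(pheno[setdiff(names(pheno), "admixture")],
                   data.frame(individual_id = adm$individual_id,
                              admixture = adm$admixture_raw),
                   by = "individual_id")
      for (a in config$associate) {
        models[[a]] <- if (a %in% c("smolt_age_3plus", "one_sea_winter")) {
          fit_binary_model(tab, a)
        } else if (a %in% c("smolt_length_cm", "first_seawinter_length_cm")) {
          fit_growth_model(tab, a)
        } else {
          fit_size_model(tab, a)
        }
      }
    }

    list(panel = panel, constants = constants, admixture = adm,
         distribution = dist_sum, accuracy = accuracy, models = models,
         true_admixture = true_admix, output_dir = output_dir)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}
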