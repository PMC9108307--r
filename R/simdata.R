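#' Simulate diverged wild/farm allele frequencies (Balding-Nichols model)
#'
#' Draws per-locus ancestral frequencies uniformly on `ancestral_freq_range`
#' and, for each of the two populations independently, a population frequency
#' from the Balding-Nichols beta distribution
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with F = `divergence`. Across many loci the
#' expected Weir-Cockerham F_ST between large samples of the two populations
#' approximates `divergence`, so the parameter is documented as an expected
#' F_ST. The limit `divergence -> 0` gives both populations the ancestral
#' frequency exactly.
#'
#' @param n_loci number of loci to simulate.
#' @param divergence Balding-Nichols divergence parameter in (0, 1); values of
#'   0 are accepted and give undifferentiated populations.
#' @param ancestral_freq_range length-2 interval for the uniform ancestral
#'   frequency draw.
#' @param seed RNG seed.
#' @return a `pop_frequencies` data frame with columns `locus_id`, `p_wild`,
#'   `p_farm` and attributes `divergence` and `seed`.
#' @examples
#' fr <- sim_baseline_frequencies(100, divergence = 0.15, seed = 1)
#' head(fr)
#' @export
sim_baseline_frequencies <- function(n_loci, divergence = 0.15,
                                     ancestral_freq_range = c(0.05, 0.95),
                                     seed = NULL) {
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (divergence < 0 || divergence >= 1) {
    stop("divergence must lie in [0, 1)")
  }
  if (length(ancestral_freq_range) != 2 ||
      any(ancestral_freq_range < 0 | ancestral_freq_range > 1) ||
      ancestral_freq_range[1] > ancestral_freq_range[2]) {
    stop("ancestral_freq_range must be an ordered interval within [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  p_anc <- stats::runif(n_loci, ancestral_freq_range[1], ancestral_freq_range[2])
  if (divergence == 0) {
    p_wild <- p_anc
    p_farm <- p_anc
  } else {
    k <- (1 - divergence) / divergence
    p_wild <- stats::rbeta(n_loci, p_anc * k, (1 - p_anc) * k)
    p_farm <- stats::rbeta(n_loci, p_anc * k, (1 - p_anc) * k)
  }
  out <- data.frame(
    locus_id = sprintf("locus_%05d", seq_len(n_loci)),
    p_wild = p_wild,
    p_farm = p_farm,
    stringsAsFactors = FALSE
  )
  attr(out, "divergence") <- divergence
  attr(out, "seed") <- seed
  class(out) <- c("pop_frequencies", class(out))
  out
}

#' Simulate genotypes at given allele frequencies
#'
#' Each genotype is an independent Binomial(2, freq) reference-allele dosage;
#' no missingness is introduced (see [sim_missingness()]).
#'
#' @param freqs numeric vector of per-locus reference-allele frequencies, or a
#'   `pop_frequencies` object together with `population`.
#' @param n number of individuals.
#' @param population which column of a `pop_frequencies` object to use,
#'   `"wild"` or `"farm"`; ignored for a plain numeric vector.
#' @param label origin label for the output individuals.
#' @param seed RNG seed.
#' @param id_prefix prefix for generated individual ids.
#' @return a [genotype_matrix()].
#' @export
sim_genotypes <- function(freqs, n, population = c("wild", "farm"),
                          label = NULL, seed = NULL, id_prefix = NULL) {
  population <- match.arg(population)
  if (inherits(freqs, "pop_frequencies")) {
    locus_ids <- freqs$locus_id
    p <- if (population == "wild") freqs$p_wild else freqs$p_farm
    if (is.null(label)) label <- if (population == "wild") "wild_hist" else "farm"
    if (is.null(id_prefix)) id_prefix <- population
  } else {
    p <- as.numeric(freqs)
    locus_ids <- names(freqs)
    if (is.null(locus_ids)) locus_ids <- sprintf("locus_%05d", seq_along(p))
    if (is.null(label)) label <- "simulated"
    if (is.null(id_prefix)) id_prefix <- "sim"
  }
  if (any(p < 0 | p > 1)) stop("allele frequencies must lie in [0, 1]")
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  dos <- matrix(stats::rbinom(n * length(p), 2L, rep(p, each = n)),
                nrow = n, ncol = length(p))
  rownames(dos) <- sprintf("%s_%04d", id_prefix, seq_len(n))
  colnames(dos) <- locus_ids
  genotype_matrix(dos, labels = label)
}

#' Simulate admixed individuals with known wild proportion
#'
#' Each of the two allele copies at each locus is drawn independently from the
#' wild allele frequency with probability `q` and from the farm frequency
#' otherwise -- exactly the admixture model the supervised estimator assumes,
#' so these individuals carry a known truth for parameter-recovery tests.
#'
#' @param freqs a `pop_frequencies` object.
#' @param q per-individual true wild proportion(s) in \[0, 1\].
#' @param seed RNG seed.
#' @param id_prefix prefix for individual ids.
#' @return a [genotype_matrix()] with one row per element of `q`, carrying the
#'   truth in attribute `true_q_wild`.
#' @export
sim_admixed_genotypes <- function(freqs, q, seed = NULL, id_prefix = "adm") {
  stopifnot(inherits(freqs, "pop_frequencies"))
  if (any(q < 0 | q > 1)) stop("admixture proportions q must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(q)
  L <- nrow(freqs)
  # per copy: P(ref) = q * p_wild + (1 - q) * p_farm; copies independent
  pw <- matrix(freqs$p_wild, n, L, byrow = TRUE)
  pf <- matrix(freqs$p_farm, n, L, byrow = TRUE)
  pi_mat <- q * pw + (1 - q) * pf
  dos <- matrix(stats::rbinom(n * L, 2L, pi_mat), n, L)
  rownames(dos) <- sprintf("%s_%04d", id_prefix, seq_len(n))
  colnames(dos) <- freqs$locus_id
  g <- genotype_matrix(dos, labels = "contemporary")
  attr(g, "true_q_wild") <- q
  g
}

#' Simulate F1 hybrids from two parental samples
#'
#' Each F1 individual receives at each locus one gamete drawn from the
#' empirical allele frequency of `parents_a` and one from `parents_b`
#' (frequency-based gametes; no parent pairs are sampled). The true wild
#' proportion of every hybrid is therefore 0.5 when the parents are the two
#' reference pools. A pair-sampling variant, in which each hybrid draws one
#' actual parent per pool and receives one transmitted allele from each, is
#' available behind `method = "pairs"`.
#'
#' @param parents_a,parents_b `genotype_matrix` objects sharing one locus list.
#' @param n number of hybrids to generate.
#' @param method `"frequency"` (default, gametes from empirical pool
#'   frequencies) or `"pairs"` (gametes from sampled parents).
#' @param seed RNG seed.
#' @param id_prefix prefix for hybrid ids.
#' @return a [genotype_matrix()] of `n` hybrids labelled `"simulated"`.
#' @export
hybridize <- function(parents_a, parents_b, n, method = c("frequency", "pairs"),
                      seed = NULL, id_prefix = "F1") {
  method <- match.arg(method)
  if (!identical(colnames(parents_a), colnames(parents_b))) {
    stop("parental matrices do not share the same locus list")
  }
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(parents_a)
  if (method == "frequency") {
    fa <- colMeans(unclass(parents_a), na.rm = TRUE) / 2
    fb <- colMeans(unclass(parents_b), na.rm = TRUE) / 2
    ga <- matrix(stats::rbinom(n * L, 1L, rep(fa, each = n)), n, L)
    gb <- matrix(stats::rbinom(n * L, 1L, rep(fb, each = n)), n, L)
    dos <- ga + gb
  } else {
    dos <- matrix(0L, n, L)
    for (i in seq_len(n)) {
      pa <- unclass(parents_a)[sample.int(nrow(parents_a), 1), ]
      pb <- unclass(parents_b)[sample.int(nrow(parents_b), 1), ]
      # transmitted allele per locus: heterozygote transmits ref w.p. 1/2
      dos[i, ] <- stats::rbinom(L, 1L, pa / 2) + stats::rbinom(L, 1L, pb / 2)
    }
  }
  rownames(dos) <- sprintf("%s_%04d", id_prefix, seq_len(n))
  colnames(dos) <- colnames(parents_a)
  g <- genotype_matrix(dos, labels = "simulated")
  attr(g, "true_q_wild") <- rep(0.5, n)
  g
}

#' Introduce missing genotype calls
#'
#' Entries are set missing independently; the missingness probability of entry
#' (i, l) is `1 - (1 - locus_rates[l]) * (1 - sample_rates[i])`, i.e. locus and
#' sample failure processes combine independently. With only locus rates the
#' achieved per-locus call rate is `1 - locus_rates[l]` in expectation.
#'
#' @param g a [genotype_matrix()].
#' @param locus_rates per-locus missingness rate(s) in \[0, 1\], recycled.
#' @param sample_rates per-individual missingness rate(s) in \[0, 1\], recycled.
#' @param seed RNG seed.
#' @return the matrix with additional entries set to `NA`.
#' @export
sim_missingness <- function(g, locus_rates = 0, sample_rates = 0, seed = NULL) {
  locus_rates <- rep_len(locus_rates, ncol(g))
  sample_rates <- rep_len(sample_rates, nrow(g))
  if (any(locus_rates < 0 | locus_rates > 1) ||
      any(sample_rates < 0 | sample_rates > 1)) {
    stop("missingness rates must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  p_miss <- 1 - outer(1 - sample_rates, 1 - locus_rates)
  drop_mask <- matrix(stats::runif(length(p_miss)) < p_miss, nrow(g), ncol(g))
  dos <- unclass(g)
  dos[drop_mask] <- NA_integer_
  genotype_matrix(dos, labels = origin_labels(g))
}

#' Default phenotype effect parameters
#'
#' Effect sizes follow the published contrasts for the river Etne population:
#' a 26-day later river return for fully admixed fish around a July 16
#' baseline; sex-specific adult length (+3.8 cm males, +8.3 cm females) and
#' weight (+0.7 / +1.9 kg) contrasts; +2.0 cm back-calculated smolt length and
#' +5.0 cm first-sea-winter length; a male smolt-age logit taking P(3-year
#' smolt) from 57% at admixture 0 to 11% at admixture 1 with no female effect;
#' and a male-only increase in the probability of maturing after one sea
#' winter. Intercepts, residual standard deviations and the maturation logit
#' (not printed in the source material) are field-plausible defaults and are
#' documented in the methods vignette. Year and sea-winter effects default to
#' zero but stay in the generated tables as factors.
#'
#' Admixture is on the domesticated scale throughout: 0 = pure wild ancestry,
#' 1 = pure domesticated.
#'
#' @param ... named overrides of any default component.
#' @return a named list of class `phenotype_effect_params`.
#' @export
phenotype_effect_defaults <- function(...) {
  p <- list(
    return_day_intercept = 197,       # day-of-year ~ July 16
    return_day_slope = 26,            # days per unit admixture
    return_day_sd = 25,
    length_intercept = 65,            # cm, 1-sea-winter nonadmixed female
    length_slope_male = 3.8,
    length_slope_female = 8.3,
    length_sex_effect_male = 0,
    length_sw_effect = 0,             # cm per extra sea winter
    length_sd = 5,
    weight_intercept = 3.5,           # kg
    weight_slope_male = 0.7,
    weight_slope_female = 1.9,
    weight_sex_effect_male = 0,
    weight_sw_effect = 0,
    weight_sd = 1,
    smolt_length_intercept = 12,      # cm
    smolt_length_slope = 2.0,
    smolt_length_sd = 2,
    first_seawinter_length_intercept = 35,  # cm after ~7 months at sea
    first_seawinter_length_slope = 5.0,
    first_seawinter_length_sd = 3.5,
    # P(3-year smolt): males 0.57 at admix 0 -> 0.11 at admix 1
    smolt_age_logit_intercept_male = stats::qlogis(0.57),
    smolt_age_logit_slope_male = stats::qlogis(0.11) - stats::qlogis(0.57),
    smolt_age_logit_intercept_female = stats::qlogis(0.57),
    smolt_age_logit_slope_female = 0,
    # P(one sea winter, i.e. early maturation)
    maturation_logit_intercept_male = stats::qlogis(0.30),
    maturation_logit_slope_male = 1.5,
    maturation_logit_intercept_female = stats::qlogis(0.30),
    maturation_logit_slope_female = 0,
    year_effects = NULL,              # named day/cm/kg shifts per year level
    return_day_year_effects = NULL
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad) > 0) stop("unknown effect parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  sds <- grep("_sd$", names(p), value = TRUE)
  if (any(unlist(p[sds]) <= 0)) stop("residual sds must be > 0")
  class(p) <- "phenotype_effect_params"
  p
}

#' Simulate a phenotype table from true admixture values
#'
#' Continuous traits follow `trait = intercept + SW effect + sex effect +
#' slope * admixture + year effect + Gaussian noise`; the two binary life
#' history traits (3-year smolt age, one-sea-winter maturation) are Bernoulli
#' draws with sex-specific logit-linear probabilities in admixture. Sex,
#' capture year and sea winters are drawn when not supplied; sea winters are
#' taken from the maturation model so that the two are consistent.
#'
#' @param admixture per-individual true admixture on the domesticated scale
#'   (0 = pure wild).
#' @param sex optional `"male"`/`"female"` vector; default balanced Bernoulli.
#' @param year optional capture-year vector; default uniform over 2013-2016.
#' @param sea_winters optional sea-winter counts; default drawn from the
#'   maturation model (1 with the modelled probability, otherwise 2 or 3).
#' @param params a [phenotype_effect_defaults()] list.
#' @param seed RNG seed.
#' @param ids optional individual ids.
#' @return a data frame with columns `individual_id`, `sex`, `capture_year`,
#'   `sea_winters`, `return_day`, `length_cm`, `weight_kg`, `smolt_age`,
#'   `smolt_length_cm`, `first_seawinter_length_cm`, `admixture`; the
#'   generating parameters are attached as attribute `params`.
#' @export
sim_phenotypes <- function(admixture, sex = NULL, year = NULL,
                           sea_winters = NULL,
                           params = phenotype_effect_defaults(),
                           seed = NULL, ids = NULL) {
  if (any(admixture < 0 | admixture > 1)) stop("admixture must lie in [0, 1]")
  stopifnot(inherits(params, "phenotype_effect_params"))
  n <- length(admixture)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sex)) sex <- sample(c("male", "female"), n, replace = TRUE)
  sex <- rep_len(sex, n)
  if (!all(sex %in% c("male", "female"))) stop("sex must be 'male' or 'female'")
  if (is.null(year)) year <- sample(2013:2016, n, replace = TRUE)
  year <- rep_len(year, n)
  male <- sex == "male"

  lin <- function(int_m, sl_m, int_f, sl_f) {
    ifelse(male, int_m + sl_m * admixture, int_f + sl_f * admixture)
  }
  p_one_sw <- stats::plogis(lin(params$maturation_logit_intercept_male,
                                params$maturation_logit_slope_male,
                                params$maturation_logit_intercept_female,
                                params$maturation_logit_slope_female))
  if (is.null(sea_winters)) {
    one_sw <- stats::rbinom(n, 1L, p_one_sw)
    sea_winters <- ifelse(one_sw == 1L, 1L,
                          sample(c(2L, 3L), n, replace = TRUE, prob = c(0.8, 0.2)))
  }
  sea_winters <- rep_len(as.integer(sea_winters), n)
  if (any(sea_winters < 1)) stop("sea_winters must be >= 1")

  yr_eff <- function(tab) {
    if (is.null(tab)) return(rep(0, n))
    v <- tab[as.character(year)]
    v[is.na(v)] <- 0
    as.numeric(v)
  }
  p3 <- stats::plogis(lin(params$smolt_age_logit_intercept_male,
                          params$smolt_age_logit_slope_male,
                          params$smolt_age_logit_intercept_female,
                          params$smolt_age_logit_slope_female))
  smolt_age <- 2L + stats::rbinom(n, 1L, p3)

  sw_c <- sea_winters - 1L
  return_day <- params$return_day_intercept +
    params$return_day_slope * admixture +
    yr_eff(params$return_day_year_effects) +
    stats::rnorm(n, 0, params$return_day_sd)
  length_cm <- params$length_intercept +
    params$length_sw_effect * sw_c +
    ifelse(male, params$length_sex_effect_male, 0) +
    ifelse(male, params$length_slope_male, params$length_slope_female) * admixture +
    yr_eff(params$year_effects) +
    stats::rnorm(n, 0, params$length_sd)
  weight_kg <- params$weight_intercept +
    params$weight_sw_effect * sw_c +
    ifelse(male, params$weight_sex_effect_male, 0) +
    ifelse(male, params$weight_slope_male, params$weight_slope_female) * admixture +
    stats::rnorm(n, 0, params$weight_sd)
  smolt_length_cm <- params$smolt_length_intercept +
    params$smolt_length_slope * admixture +
    stats::rnorm(n, 0, params$smolt_length_sd)
  first_seawinter_length_cm <- params$first_seawinter_length_intercept +
    params$first_seawinter_length_slope * admixture +
    stats::rnorm(n, 0, params$first_seawinter_length_sd)

  if (is.null(ids)) ids <- sprintf("ind_%04d", seq_len(n))
  out <- data.frame(
    individual_id = ids,
    sex = sex,
    capture_year = year,
    sea_winters = sea_winters,
    return_day = return_day,
    length_cm = length_cm,
    weight_kg = weight_kg,
    smolt_age = smolt_age,
    smolt_length_cm = smolt_length_cm,
    first_seawinter_length_cm = first_seawinter_length_cm,
    admixture = admixture,
    stringsAsFactors = FALSE
  )
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  out
}
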