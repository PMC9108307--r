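#' Admixture-phenotype association models
#'
#' Linear models relate body size and river-entry timing to admixture with sea
#' winters, sex and capture year as covariates; binomial logit models relate
#' the two binary life history traits (3-year smolt age, one-sea-winter
#' maturation) to admixture with a sex-specific admixture effect and a year
#' factor. All fits return a `model_fit` object holding the coefficient table,
#' the 1-df test of the admixture term, predictions at admixture 0 / 0.5 / 1,
#' and row-drop accounting.
#'
#' @name phenomodels
NULL

inv_logit <- stats::plogis

prepare_pheno <- function(data, vars) {
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    stop("phenotype table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  d <- data[, vars, drop = FALSE]
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  if ("sex" %in% vars) d$sex <- factor(d$sex, levels = c("female", "male"))
  if ("capture_year" %in% vars) d$capture_year <- factor(d$capture_year)
  attr(d, "n_dropped") <- sum(!keep)
  d
}

# detect exactly collinear columns in the design and name them
check_aliasing <- function(fit) {
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("rank-deficient design: aliased term(s) ",
         paste(names(co)[is.na(co)], collapse = ", "),
         " are collinear with the remaining columns")
  }
  invisible(NULL)
}

new_model_fit <- function(model, formula_description, admix_test, predictions,
                          n_used, n_dropped, kind) {
  structure(list(model = model,
                 formula_description = formula_description,
                 coefficients = summary(model)$coefficients,
                 admix_test = admix_test,
                 predictions = predictions,
                 n_used = n_used, n_dropped = n_dropped, kind = kind),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("model:", x$formula_description, "\n")
  cat(sprintf("n used = %d (%d rows dropped for missing values)\n",
              x$n_used, x$n_dropped))
  print(round(x$coefficients, 4))
  at <- x$admix_test
  if (is.data.frame(at)) {
    print(at, row.names = FALSE)
  } else {
    cat(sprintf("admixture term: df = %d, %s = %.3g, p = %.3g\n",
                at$df, at$statistic_name, at$statistic, at$p_value))
  }
  if (!is.null(x$predictions)) {
    cat("predictions at fixed admixture:\n")
    print(x$predictions, row.names = FALSE)
  }
  invisible(x)
}

# population-averaged design row: numeric covariates at their mean, factor
# levels at their observed frequencies, admixture forced to `a`
averaged_prediction <- function(fit, data, admix_values, response_is_day,
                                year0 = NULL) {
  X <- stats::model.matrix(fit)
  xbar <- colMeans(X)
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  adm_col <- "admixture"
  rows <- lapply(admix_values, function(a) {
    x <- xbar
    x[adm_col] <- a
    est <- sum(x * beta)
    se <- sqrt(drop(t(x) %*% V %*% x))
    data.frame(admixture = a, fit = est,
               lwr = est - 1.96 * se, upr = est + 1.96 * se, se = se)
  })
  out <- do.call(rbind, rows)
  if (response_is_day) {
    if (is.null(year0)) year0 <- 2015
    out$date <- format(as.Date(round(out$fit) - 1,
                               origin = sprintf("%d-01-01", year0)), "%B %d")
  }
  out
}

fit_lm_admix <- function(data, response, covars, description) {
  vars <- c(response, covars, "admixture")
  d <- prepare_pheno(data, vars)
  if (nrow(d) < 4) stop("too few complete rows to fit the model")
  # a single capture-year level is absorbed by the intercept, not an error
  if ("capture_year" %in% covars && nlevels(d$capture_year) < 2) {
    covars <- setdiff(covars, "capture_year")
  }
  rhs <- paste(c(covars, "admixture"), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = d)
  check_aliasing(fit)
  red <- stats::lm(stats::as.formula(paste(response, "~",
                                           paste(covars, collapse = " + "))),
                   data = d)
  an <- stats::anova(red, fit)
  admix_test <- list(df = 1L, statistic_name = "F",
                     statistic = an$F[2], p_value = an$`Pr(>F)`[2])
  preds <- averaged_prediction(fit, d, c(0, 0.5, 1),
                               response_is_day = response == "return_day")
  new_model_fit(fit, description, admix_test, preds,
                n_used = nrow(d), n_dropped = attr(d, "n_dropped"),
                kind = "linear")
}

#' Linear model of adult size or return date on admixture
#'
#' Fits `response ~ sea_winters + sex + admixture + capture_year` by least
#' squares (sea winters numeric, sex and year categorical with female and the
#' first year as reference levels). The admixture test is the 1-df partial F
#' comparing the full model against the model without the admixture term; for
#' a single-df term it equals the squared t statistic of the coefficient.
#' Predictions at admixture 0 / 0.5 / 1 are population-averaged: numeric
#' covariates at their means, factor levels weighted by observed frequencies;
#' return-day predictions are also rendered as calendar dates.
#'
#' @param data a phenotype table (see [sim_phenotypes()] for the column
#'   contract) with an `admixture` column on the domesticated scale.
#' @param response one of `"length_cm"`, `"weight_kg"`, `"return_day"`.
#' @return a `model_fit` object.
#' @export
fit_size_model <- function(data,
                           response = c("length_cm", "weight_kg", "return_day")) {
  response <- match.arg(response)
  fit_lm_admix(data, response,
               covars = c("sea_winters", "sex", "capture_year"),
               description = paste(response, "~ SW + sex + admix + year"))
}

#' Linear model of back-calculated freshwater/early-marine growth
#'
#' As [fit_size_model()] but without the sea-winter covariate: the
#' back-calculated smolt length and first-sea-winter length predate later sea
#' winters, so sea age is not a meaningful covariate for them.
#'
#' @param data phenotype table.
#' @param response `"smolt_length_cm"` or `"first_seawinter_length_cm"`.
#' @return a `model_fit` object.
#' @export
fit_growth_model <- function(data,
                             response = c("smolt_length_cm",
                                          "first_seawinter_length_cm")) {
  response <- match.arg(response)
  fit_lm_admix(data, response, covars = c("sex", "capture_year"),
               description = paste(response, "~ sex + admix + year"))
}

#' Binomial logit model of a binary life history trait on admixture
#'
#' `outcome = "smolt_age_3plus"` models the probability of migrating as a
#' 3-year-old smolt, restricted to smolt ages 2 and 3 (other ages -- about 1%
#' of fish -- are dropped and counted). `outcome = "one_sea_winter"` models
#' the probability of maturing after a single sea winter (early maturation)
#' against 2+ sea winters. Both use a logit link with a sex-specific admixture
#' effect (the admix x sex interaction, coded as separate female and male
#' admixture slopes) plus a capture-year factor. The admixture test is
#' reported per sex as the 1-df marginal likelihood-ratio chi-square for that
#' sex's admixture slope. Sex-specific probability curves with delta-method
#' 95% bands (inverse-logit of the linear predictor +- 1.96 se) are returned
#' at admixture 0 / 0.5 / 1. Complete separation is detected and reported as
#' an error rather than silent non-convergence.
#'
#' @param data phenotype table.
#' @param outcome `"smolt_age_3plus"` or `"one_sea_winter"`.
#' @return a `model_fit` object; `admix_test` is a two-row data frame (one row
#'   per sex).
#' @export
fit_binary_model <- function(data,
                             outcome = c("smolt_age_3plus", "one_sea_winter")) {
  outcome <- match.arg(outcome)
  if (outcome == "smolt_age_3plus") {
    base_vars <- c("smolt_age", "sex", "capture_year", "admixture")
    d <- prepare_pheno(data, base_vars)
    n_dropped <- attr(d, "n_dropped")
    n_excluded_age <- sum(!(d$smolt_age %in% c(2L, 3L)))
    d <- d[d$smolt_age %in% c(2L, 3L), , drop = FALSE]
    d$y <- as.integer(d$smolt_age == 3L)
  } else {
    base_vars <- c("sea_winters", "sex", "capture_year", "admixture")
    d <- prepare_pheno(data, base_vars)
    n_dropped <- attr(d, "n_dropped")
    n_excluded_age <- 0L
    d$y <- as.integer(d$sea_winters == 1L)
  }
  if (length(unique(d$y)) < 2) stop("outcome has a single observed class")
  d$admix_female <- d$admixture * (d$sex == "female")
  d$admix_male <- d$admixture * (d$sex == "male")
  covars <- c("sex", if (nlevels(d$capture_year) > 1) "capture_year")
  rhs <- paste(c(covars, "admix_female", "admix_male"), collapse = " + ")
  fit <- stats::glm(stats::as.formula(paste("y ~", rhs)), data = d,
                    family = stats::binomial())
  check_aliasing(fit)
  if (!fit$converged) stop("IRLS did not converge after ", fit$iter, " iterations")
  fv <- fit$fitted.values
  perfect <- all(fv[d$y == 1L] > 1 - 1e-4) && all(fv[d$y == 0L] < 1e-4)
  if (perfect || any(abs(stats::coef(fit)) > 15)) {
    stop("complete or quasi-complete separation detected: ",
         "coefficients diverge and fitted probabilities saturate")
  }

  lr_test <- function(drop_term) {
    red <- stats::update(fit, stats::as.formula(paste(". ~ . -", drop_term)))
    an <- stats::anova(red, fit, test = "Chisq")
    data.frame(sex = sub("admix_", "", drop_term), df = 1L,
               chi_square = an$Deviance[2], p_value = an$`Pr(>Chi)`[2],
               stringsAsFactors = FALSE)
  }
  admix_test <- rbind(lr_test("admix_female"), lr_test("admix_male"))

  # sex-specific probability curves at fixed admixture, year-averaged
  X <- stats::model.matrix(fit)
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  curve_rows <- list()
  for (s in c("female", "male")) {
    xs <- colMeans(X)                      # year levels at observed weights
    xs["sexmale"] <- as.numeric(s == "male")
    for (a in c(0, 0.5, 1)) {
      xs["admix_female"] <- if (s == "female") a else 0
      xs["admix_male"] <- if (s == "male") a else 0
      eta <- sum(xs * beta)
      se <- sqrt(drop(t(xs) %*% V %*% xs))
      curve_rows[[length(curve_rows) + 1]] <- data.frame(
        sex = s, admixture = a, probability = inv_logit(eta),
        lwr = inv_logit(eta - 1.96 * se), upr = inv_logit(eta + 1.96 * se))
    }
  }
  preds <- do.call(rbind, curve_rows)
  out <- new_model_fit(fit, paste0("logit P(", outcome, ") ~ admix*sex + year"),
                       admix_test, preds, n_used = nrow(d),
                       n_dropped = n_dropped, kind = "logit")
  out$n_excluded_age <- n_excluded_age
  out
}

#' Predictions at fixed admixture values
#'
#' Evaluates a fitted association model at requested admixture values for a
#' covariate profile. The default profile is population-averaged (numeric
#' covariates at their means, factor levels at observed frequencies); for
#' logit fits the curves are sex-specific. Return-day predictions are also
#' rendered as calendar dates (day-of-year arithmetic on the stated year).
#' Admixture values outside \[0, 1\] trigger an extrapolation warning, not an
#' error.
#'
#' @param fit a `model_fit` from [fit_size_model()], [fit_growth_model()] or
#'   [fit_binary_model()].
#' @param admix_values admixture values to evaluate at.
#' @param year calendar year used to render day-of-year as a date.
#' @return a data frame of predictions with 95% bands.
#' @export
predict_at_admixture <- function(fit, admix_values = c(0, 0.5, 1), year = 2015) {
  stopifnot(inherits(fit, "model_fit"))
  if (any(admix_values < 0 | admix_values > 1)) {
    warning("admixture values outside [0, 1]: extrapolating beyond the data")
  }
  if (fit$kind == "linear") {
    resp <- all.vars(stats::formula(fit$model))[1]
    averaged_prediction(fit$model, NULL, admix_values,
                        response_is_day = resp == "return_day", year0 = year)
  } else {
    X <- stats::model.matrix(fit$model)
    beta <- stats::coef(fit$model)
    V <- stats::vcov(fit$model)
    rows <- list()
    for (s in c("female", "male")) {
      xs <- colMeans(X)
      xs["sexmale"] <- as.numeric(s == "male")
      for (a in admix_values) {
        xs["admix_female"] <- if (s == "female") a else 0
        xs["admix_male"] <- if (s == "male") a else 0
        eta <- sum(xs * beta)
        se <- sqrt(drop(t(xs) %*% V %*% xs))
        rows[[length(rows) + 1]] <- data.frame(
          sex = s, admixture = a, probability = inv_logit(eta),
          lwr = inv_logit(eta - 1.96 * se), upr = inv_logit(eta + 1.96 * se))
      }
    }
    do.call(rbind, rows)
  }
}
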