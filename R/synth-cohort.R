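## Generic named covariates per clinical category. Within each category,
## covariates load on a shared latent factor so that within-category
## correlation structure exists for the covariate network stage.
cohortCovariateDef <- function() {
  data.frame(
    covariate = c(
      "bmi", "height_cm", "weight_kg", "muac_cm",
      "hemoglobin", "glucose", "wbc_count", "ferritin",
      "hypertension", "diabetes", "chronic_anemia",
      "gravidity", "parity", "prior_ptb", "prior_cesarean",
      "prior_stillbirth", "prior_miscarriage",
      "age_years", "education_years", "employed", "household_size",
      "multiple_fetuses", "fetal_bpd_mm", "fetal_fl_mm", "placenta_previa"
    ),
    type = c(
      "continuous", "continuous", "continuous", "continuous",
      "continuous", "continuous", "continuous", "continuous",
      "binary", "binary", "binary",
      "ordinal", "ordinal", "binary", "binary", "binary", "binary",
      "continuous", "ordinal", "binary", "ordinal",
      "binary", "continuous", "continuous", "binary"
    ),
    category = c(
      rep("maternal anthropometry", 4),
      rep("maternal bloodwork", 4),
      rep("medical history", 3),
      rep("obstetric history", 6),
      rep("socioeconomic determinants", 4),
      rep("ultrasound measurements", 4)
    ),
    stringsAsFactors = FALSE
  )
}

## latent helper: y = lambda * f + sqrt(1-lambda^2) * e, standard normal
loadOn <- function(f, lambda) lambda * f + sqrt(1 - lambda^2) * stats::rnorm(length(f))

#' Generate the synthetic full epidemiological cohort
#'
#' Draws \code{n_full} participants across the configured sites. Covariates
#' are generated per clinical category from latent-factor models (shared
#' within-category factors create realistic within-category correlation);
#' the PTB outcome is drawn from a logistic model whose strongest risk
#' covariates are multiple fetuses, prior preterm birth and prior Cesarean
#' delivery, with the intercept calibrated so the realized prevalence matches
#' \code{ptb_prevalence_target}. GA at birth is continuous in weeks and
#' consistent with the PTB flag (PTB iff GA at birth < 37).
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @return list with elements \code{cohort} (\linkS4class{CohortTable}) and
#'   \code{truth} (\linkS4class{SyntheticTruth}, cohort-level slots filled).
#' @export
generateFullCohort <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@n_full

  site <- sample(config@sites, n, replace = TRUE,
                 prob = rep(1 / length(config@sites), length(config@sites)))

  ## --- socioeconomic / demographic block (incl. age) ---
  f_soc <- stats::rnorm(n)
  age_z <- loadOn(f_soc, 0.45)
  age_years <- round(pmax(15, 25 + 5 * age_z), 1)
  education_years <- pmax(0L, round(8 + 3.5 * loadOn(f_soc, 0.6)))
  employed <- as.integer(loadOn(f_soc, 0.5) > 0.4)
  household_size <- pmax(1L, round(5 + 2 * loadOn(f_soc, 0.4)))

  ## --- obstetric history, correlated with age ---
  f_obs <- 0.6 * age_z + 0.8 * stats::rnorm(n)
  grav_latent <- loadOn(f_obs, 0.85)
  gravidity <- pmax(1L, round(2.8 + 1.8 * grav_latent))
  parity <- pmax(0L, gravidity - 1L -
                   stats::rbinom(n, pmax(0L, gravidity - 1L), 0.25))
  parous <- parity > 0L
  prior_ptb <- as.integer(parous & stats::runif(n) < stats::plogis(-2.3 + 0.35 * grav_latent))
  prior_cesarean <- as.integer(parous & stats::runif(n) < 0.10)
  prior_stillbirth <- as.integer(parous & stats::runif(n) < 0.09)
  prior_miscarriage <- as.integer(gravidity > 1L & stats::runif(n) < 0.23)

  ## --- anthropometry ---
  f_anth <- stats::rnorm(n)
  bmi <- round(pmax(14, 22.5 + 4 * loadOn(f_anth, 0.8)), 1)
  height_cm <- round(155 + 6 * loadOn(f_anth, 0.35), 1)
  weight_kg <- round(bmi * (height_cm / 100)^2, 1)
  muac_cm <- round(26 + 2.5 * loadOn(f_anth, 0.7), 1)

  ## --- bloodwork ---
  f_blood <- stats::rnorm(n)
  hemoglobin <- round(11.5 + 1.4 * loadOn(f_blood, 0.7), 1)
  glucose <- round(85 + 12 * loadOn(f_blood, 0.5), 1)
  wbc_count <- round(8.5 + 2 * loadOn(f_blood, 0.55), 2)
  ferritin <- round(exp(3.3 + 0.5 * loadOn(f_blood, 0.6)), 1)

  ## --- medical history ---
  f_med <- 0.3 * f_anth + 0.95 * stats::rnorm(n)
  hypertension <- as.integer(loadOn(f_med, 0.6) > stats::qnorm(1 - 0.03))
  diabetes <- as.integer(loadOn(f_med, 0.6) > stats::qnorm(1 - 0.005))
  chronic_anemia <- as.integer(-hemoglobin + stats::rnorm(n, sd = 1.2) >
                                 stats::quantile(-hemoglobin, 0.93))

  ## --- ultrasound ---
  multiple_fetuses <- as.integer(stats::runif(n) < 0.015)
  f_us <- stats::rnorm(n)
  fetal_bpd_mm <- round(24 + 3 * loadOn(f_us, 0.8), 1)
  fetal_fl_mm <- round(12 + 2.5 * loadOn(f_us, 0.8), 1)
  placenta_previa <- as.integer(stats::runif(n) < 0.01)

  ## --- PTB outcome: logistic on designated risk covariates ---
  ## effect sizes calibrated so the population risk-score AUROC is ~0.70,
  ## the discrimination regime of large multi-site cohorts
  underweight <- as.integer(bmi < 18.5)
  lp <- config@risk_scale * (
    2.2 * multiple_fetuses + 1.5 * prior_ptb + 1.0 * prior_cesarean +
      0.7 * prior_stillbirth + 0.7 * underweight + 0.6 * hypertension +
      0.40 * (parity == 0L) + 0.5 * chronic_anemia -
      0.06 * (education_years - 8) - 0.18 * (hemoglobin - 11.5)
  )
  intercept <- calibratePrevalence(lp, config@ptb_prevalence_target)
  ptb <- stats::runif(n) < stats::plogis(intercept + lp)

  ## GA at birth consistent with outcome; extreme preterm (<28 wk) excluded
  ga_birth <- numeric(n)
  n_ptb <- sum(ptb)
  ga_birth[ptb] <- 37 - 8.5 * stats::rbeta(n_ptb, 2, 3.2)
  ga_birth[!ptb] <- 37 + 5 * stats::rbeta(n - n_ptb, 2.0, 2.3)
  ga_birth <- round(ga_birth, 2)

  ## GA at sampling: early-to-mid pregnancy visit
  ga_sampling <- round(pmin(pmax(stats::rnorm(n, 12.2, 3.2), 6), 20), 2)

  dat <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    site = site,
    ga_sampling_weeks = ga_sampling,
    ga_birth_weeks = ga_birth,
    ptb = as.logical(ptb),
    bmi = bmi, height_cm = height_cm, weight_kg = weight_kg, muac_cm = muac_cm,
    hemoglobin = hemoglobin, glucose = glucose, wbc_count = wbc_count,
    ferritin = ferritin,
    hypertension = hypertension, diabetes = diabetes,
    chronic_anemia = chronic_anemia,
    gravidity = gravidity, parity = parity, prior_ptb = prior_ptb,
    prior_cesarean = prior_cesarean, prior_stillbirth = prior_stillbirth,
    prior_miscarriage = prior_miscarriage,
    age_years = age_years, education_years = education_years,
    employed = employed, household_size = household_size,
    multiple_fetuses = multiple_fetuses, fetal_bpd_mm = fetal_bpd_mm,
    fetal_fl_mm = fetal_fl_mm, placenta_previa = placenta_previa,
    stringsAsFactors = FALSE
  )

  ## heterogeneous covariate completeness, as in real antenatal registries:
  ## obstetric-history items are unknown for a fraction of participants
  miss_hist <- stats::runif(n) < 0.20
  dat[miss_hist, c("prior_ptb", "prior_cesarean", "prior_stillbirth",
                   "prior_miscarriage")] <- NA
  for (col in c("hemoglobin", "glucose", "wbc_count", "ferritin")) {
    dat[[col]][stats::runif(n) < 0.03] <- NA
  }

  cohort <- CohortTable(dat, cohortCovariateDef())
  truth <- new("SyntheticTruth",
    signals = signalLedger(config),
    minimal_panel = config@minimal_panel,
    clock_shift_weeks = config@clock_shift_weeks,
    participants = data.frame(
      participant_id = dat$participant_id,
      ttd_weeks = dat$ga_birth_weeks - dat$ga_sampling_weeks,
      ptb = dat$ptb,
      linear_predictor = intercept + lp,
      stringsAsFactors = FALSE
    )
  )
  list(cohort = cohort, truth = truth)
}

## Solve the logistic intercept so mean predicted probability hits the target.
calibratePrevalence <- function(lp, target) {
  f <- function(b0) mean(stats::plogis(b0 + lp)) - target
  sol <- tryCatch(
    stats::uniroot(f, interval = c(-20, 20), tol = 1e-10),
    error = function(e) NULL
  )
  if (is.null(sol)) {
    stop("prevalence calibration failed to converge for target ",
         target, "; risk effects may be infeasible")
  }
  sol$root
}

signalLedger <- function(config) {
  out <- lapply(names(config@signal_spec), function(tgt) {
    sp <- config@signal_spec[[tgt]]
    data.frame(
      target = tgt,
      feature_id = featureIdFor(sp$omic, sp$index),
      omic = sp$omic,
      loading = signalLoadings(sp$weight, sp$r2),
      ga_loading = if (!is.null(sp$ga_loading)) sp$ga_loading else 0,
      age_independent = if (!is.null(sp$age_independent)) sp$age_independent else FALSE,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
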