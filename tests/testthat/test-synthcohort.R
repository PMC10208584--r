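test_that("full cohort hits the target PTB prevalence and is consistent", {
  cfg <- generatorConfig(seed = 1)
  fc <- generateFullCohort(cfg)
  d <- cohortData(fc$cohort)
  expect_equal(nrow(d), 2000)
  prev <- mean(d$ptb)
  expect_gte(prev, 0.094)
  expect_lte(prev, 0.134)
  # PTB flag is exactly the clinical GA cut
  expect_identical(d$ptb, d$ga_birth_weeks < 37)
  # six clinical categories, all declared
  expect_setequal(unique(covariateInfo(fc$cohort)$category),
                  c("maternal anthropometry", "maternal bloodwork",
                    "medical history", "obstetric history",
                    "socioeconomic determinants", "ultrasound measurements"))
  expect_length(unique(d$site), 5)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- tinyConfig(seed = 7)
  a <- generateFullCohort(cfg)
  b <- generateFullCohort(cfg)
  expect_identical(cohortData(a$cohort), cohortData(b$cohort))
  sa <- generateMultiomicsSubcohort(cfg, a$cohort)
  sb <- generateMultiomicsSubcohort(cfg, b$cohort)
  expect_identical(featureMatrix(sa$proteome), featureMatrix(sb$proteome))
  expect_identical(featureMatrix(sa$metabolome), featureMatrix(sb$metabolome))
  expect_identical(sa$truth@participants, sb$truth@participants)
})

test_that("zeroed risk effects leave no learnable PTB signal", {
  cfg <- generatorConfig(seed = 4, risk_scale = 0)
  fc <- generateFullCohort(cfg)
  d <- cohortData(fc$cohort)
  # prevalence calibration still holds without any signal
  expect_lt(abs(mean(d$ptb) - 0.114), 0.02)
  cov_mat <- sapply(covariateInfo(fc$cohort)$covariate,
                    function(v) as.numeric(d[[v]]))
  rownames(cov_mat) <- d$participant_id
  res <- repeatedCV(cov_mat, d$ptb,
                    harnessConfig("classification", n_reps = 15, seed = 44,
                                  bootstrap_ci_reps = 0))
  expect_gte(cvMetrics(res)$auroc, 0.4)
  expect_lte(cvMetrics(res)$auroc, 0.6)
})

test_that("prevalence calibration fails loudly when infeasible", {
  cfg <- generatorConfig(seed = 1, ptb_prevalence_target = 0.9999999999)
  expect_error(generateFullCohort(cfg), "calibration")
})

test_that("subcohort is case-control matched on GA at sampling within site", {
  dat <- defaultDataset()
  d <- cohortData(dat$sub)
  expect_equal(nrow(d), 231)
  # ~1:1 case-control design
  expect_lt(abs(mean(d$ptb) - 0.489), 0.05)
  # matched pairs share a site and sit close in GA at sampling
  tp <- dat$truth@participants
  paired <- split(seq_len(nrow(tp)), tp$matched_pair)
  gaps <- vapply(paired, function(i) abs(diff(d$ga_sampling_weeks[i])), numeric(1))
  sites_match <- vapply(paired, function(i) length(unique(d$site[i])) == 1L, logical(1))
  expect_true(all(sites_match))
  expect_lte(median(gaps), 1)
})

test_that("matching fails with per-site counts when cases are insufficient", {
  cfg <- tinyConfig(seed = 3, n_full = 200L, n_sub = 180L)
  fc <- generateFullCohort(cfg)
  expect_error(generateMultiomicsSubcohort(cfg, fc$cohort),
               "insufficient PTB cases")
})

test_that("missing_rate controls omics missingness", {
  cfg0 <- tinyConfig(seed = 5, missing_rate = 0)
  fc <- generateFullCohort(cfg0)
  sub <- generateMultiomicsSubcohort(cfg0, fc$cohort)
  expect_false(anyNA(featureMatrix(sub$proteome)))
  expect_false(anyNA(featureMatrix(sub$metabolome)))
  cfg2 <- tinyConfig(seed = 5, missing_rate = 0.1)
  fc2 <- generateFullCohort(cfg2)
  sub2 <- generateMultiomicsSubcohort(cfg2, fc2$cohort)
  rate <- mean(is.na(featureMatrix(sub2$metabolome)))
  expect_gt(rate, 0.07)
  expect_lt(rate, 0.13)
})

test_that("planted block correlation survives the copula transform", {
  # within-block latent rho 0.9 should appear as Spearman ~0.8-0.95 after the
  # monotone marginal transforms (Gaussian-copula rank attenuation is mild)
  cfg <- tinyConfig(
    seed = 9,
    block_spec = list(
      proteome = list(n_blocks = 2L, block_size = 5L, rho = 0.9),
      metabolome = list(n_blocks = 3L, block_size = 8L, rho = 0.9),
      lipidome = list(n_blocks = 2L, block_size = 4L, rho = 0.9)
    ),
    missing_rate = 0
  )
  fc <- generateFullCohort(cfg)
  sub <- generateMultiomicsSubcohort(cfg, fc$cohort)
  vals <- featureMatrix(sub$metabolome)[, 1:8]
  rho <- cor(apply(vals, 2, rank))
  within <- rho[upper.tri(rho)]
  expect_gte(median(within), 0.8)
  expect_lte(median(within), 0.95)
})

test_that("signal-loading calibration solves the closed-form SNR identity", {
  # loadings a_j must satisfy sum a^2/(1-a^2) = R2/(1-R2)
  for (r2 in c(0.3, 0.5, 0.7)) {
    a <- ptbomics:::signalLoadings(c(6, 6, 6, 1, 1, 1), r2)
    s <- sum(a^2 / (1 - a^2))
    expect_equal(s / (1 + s), r2, tolerance = 1e-12)
  }
})

test_that("a purely calibrated R2=0.5 signal is recovered in the declared band", {
  # with the gestational coupling of the panel switched off, the planted
  # time-to-delivery signal is exactly the closed-form R^2 = 0.5 calibration;
  # the cross-validated Pearson r of the full multiomic model must then fall
  # in the recoverability band stated for that calibration
  spec <- ptbomics:::defaultSignalSpec()
  spec$ttd$ga_loading <- rep(0, 6)
  cfg <- generatorConfig(seed = 2, signal_spec = spec)
  fc <- generateFullCohort(cfg)
  sub <- generateMultiomicsSubcohort(cfg, fc$cohort)
  comb <- combineOmics(meanImpute(sub$proteome), meanImpute(sub$metabolome),
                       meanImpute(sub$lipidome))
  d <- cohortData(sub$subcohort)
  ttd <- d$ga_birth_weeks - d$ga_sampling_weeks
  cv <- repeatedCV(featureMatrix(comb), ttd,
                   harnessConfig("regression", n_reps = 15, seed = 302,
                                 bootstrap_ci_reps = 0))
  expect_gte(cvMetrics(cv)$r, 0.55)
  expect_lte(cvMetrics(cv)$r, 0.80)
})

test_that("truth ledger features exist in the generated matrices", {
  dat <- tinyDataset()
  sig <- truthSignals(dat$truth)
  expect_true(all(sig$feature_id %in% featureIds(dat$combined)))
  expect_true(all(minimalPanel(dat$truth) %in%
                    sig$feature_id[sig$target == "ttd"]))
})

test_that("config YAML round-trips every field", {
  cfg <- tinyConfig(seed = 21, clock_shift_weeks = 1.5, missing_rate = 0.05)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeGeneratorConfig(cfg, path)
  back <- readGeneratorConfig(path)
  expect_equal(back@omic_sizes, cfg@omic_sizes)
  expect_equal(back@signal_spec, cfg@signal_spec)
  expect_identical(cohortData(generateFullCohort(back)$cohort),
                   cohortData(generateFullCohort(cfg)$cohort))
})
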