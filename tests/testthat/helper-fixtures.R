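# Shared fixtures. Everything is generated in code; the default-scale
# dataset is built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# reduced-scale generator config for fast unit tests
tinyConfig <- function(seed = 11L, ...) {
  args <- list(
    seed = seed,
    n_full = 800L, n_sub = 60L,
    omic_sizes = c(proteome = 40L, metabolome = 60L, lipidome = 20L),
    signal_spec = list(
      ttd = list(omic = rep("proteome", 4L), index = 11:14,
                 weight = c(10, 10, 10, 1), r2 = 0.55,
                 ga_loading = c(-0.25, -0.25, -0.25, 0)),
      ga_sampling = list(omic = c(rep("proteome", 2L), rep("metabolome", 3L)),
                         index = c(15L, 16L, 25L, 27L, 28L),
                         weight = rep(1, 5), r2 = 0.7),
      bmi = list(omic = c("proteome", "lipidome"), index = c(17L, 9L),
                 weight = c(1, 1), r2 = 0.65),
      age = list(omic = rep("proteome", 2L), index = 18:19,
                 weight = c(1, 1), r2 = 0.35),
      gravidity = list(omic = c("proteome", "metabolome"), index = c(20L, 26L),
                       weight = c(1, 1), r2 = 0.30,
                       age_independent = c(FALSE, TRUE))
    ),
    minimal_panel = c("prot_011", "prot_012", "prot_013"),
    block_spec = list(
      proteome = list(n_blocks = 2L, block_size = 5L, rho = 0.5),
      metabolome = list(n_blocks = 3L, block_size = 8L, rho = 0.5),
      lipidome = list(n_blocks = 2L, block_size = 4L, rho = 0.6)
    )
  )
  do.call(generatorConfig, utils::modifyList(args, list(...)))
}

tinyDataset <- function(seed = 11L) {
  key <- paste0("tiny_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- tinyConfig(seed)
  fc <- generateFullCohort(cfg)
  sub <- generateMultiomicsSubcohort(cfg, fc$cohort)
  out <- list(config = cfg, full = fc$cohort, truth = sub$truth,
              sub = sub$subcohort,
              proteome = sub$proteome, metabolome = sub$metabolome,
              lipidome = sub$lipidome,
              combined = combineOmics(meanImpute(sub$proteome),
                                      meanImpute(sub$metabolome),
                                      meanImpute(sub$lipidome)))
  .fixture_cache[[key]] <- out
  out
}

# default study-scale dataset (231-participant subcohort), built once
defaultDataset <- function() {
  if (!is.null(.fixture_cache$default)) return(.fixture_cache$default)
  cfg <- generatorConfig(seed = 1L)
  fc <- generateFullCohort(cfg)
  sub <- generateMultiomicsSubcohort(cfg, fc$cohort)
  out <- list(config = cfg, full = fc$cohort, full_truth = fc$truth,
              truth = sub$truth, sub = sub$subcohort,
              proteome = sub$proteome, metabolome = sub$metabolome,
              lipidome = sub$lipidome,
              combined = combineOmics(meanImpute(sub$proteome),
                                      meanImpute(sub$metabolome),
                                      meanImpute(sub$lipidome)))
  .fixture_cache$default <- out
  out
}

# small random omics matrix with named features
randomOmics <- function(n = 12, f = 8, omic = "proteome", seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n * f), nrow = n,
              dimnames = list(sprintf("P%03d", seq_len(n)),
                              sprintf("%s_%03d", substr(omic, 1, 4), seq_len(f))))
  OmicsMatrix(m, omic)
}

fastHarness <- function(task = "regression", n_reps = 10L, seed = 1L, ...) {
  harnessConfig(task, n_reps = n_reps, seed = seed, nrounds = 60L,
                bootstrap_ci_reps = 200L, ...)
}
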