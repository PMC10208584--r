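## Default planted-signal specification. Loadings are expressed as relative
## signal-to-noise weights per feature plus a per-target population R^2 for
## the optimal linear read-out; the generator converts these to per-feature
## latent loadings with the closed form a^2 = s/(1+s), s_j = w_j/sum(w) * R2/(1-R2)
## (independent noises add on the SNR scale).
defaultSignalSpec <- function() {
  list(
    ttd = list(
      omic = rep("proteome", 6L), index = 61:66,
      weight = c(20, 20, 20, 1, 1, 1), r2 = 0.5,
      # secondary loading on the gestational-age axis: panel features track
      # gestational progression as placental/fetal proteins do, which makes
      # them marginally dominant time-to-delivery correlates
      ga_loading = c(-0.25, -0.25, -0.25, 0, 0, 0)
    ),
    ga_sampling = list(
      omic = c(rep("proteome", 5L), rep("metabolome", 9L)),
      index = c(67:71, 201:209),
      weight = rep(1, 14), r2 = 0.7
    ),
    bmi = list(
      omic = c(rep("proteome", 4L), rep("lipidome", 4L)),
      index = c(72:75, 41:44),
      weight = c(2, 2, 1, 1, 1, 1, 1, 1), r2 = 0.65
    ),
    age = list(
      omic = c(rep("proteome", 4L), rep("metabolome", 3L)),
      index = c(76:79, 210:212),
      weight = rep(1, 7), r2 = 0.35
    ),
    gravidity = list(
      omic = c(rep("proteome", 4L), rep("metabolome", 2L)),
      index = c(80:83, 213:214),
      weight = rep(1, 6), r2 = 0.30,
      # TRUE = loads on the age-orthogonal component of gravidity
      age_independent = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
    )
  )
}

defaultBlockSpec <- function() {
  list(
    proteome = list(n_blocks = 6L, block_size = 10L, rho = 0.5),
    metabolome = list(n_blocks = 10L, block_size = 20L, rho = 0.5),
    lipidome = list(n_blocks = 5L, block_size = 8L, rho = 0.6)
  )
}

## Coupled block pairs share a latent factor with the given weight; coupling
## is concentrated in lipid-metabolite and protein-metabolite links.
defaultInteromicCoupling <- function() {
  list(
    list(pair = c("metabolome", "lipidome"), n_links = 3L, strength = 0.6),
    list(pair = c("proteome", "metabolome"), n_links = 2L, strength = 0.5),
    list(pair = c("proteome", "lipidome"), n_links = 0L, strength = 0)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Assembles and validates a \linkS4class{GeneratorConfig}. Defaults emulate
#' the study regime the package is designed for: ~11.4\% preterm-birth (PTB)
#' prevalence across five sites, a GA-at-sampling-matched case-control
#' multiomic subcohort of 231, three omic blocks (proteome/metabolome/
#' lipidome), intra-omic correlation blocks with sparser inter-omic coupling
#' concentrated in lipid-metabolite and protein-metabolite links, planted
#' monotone signals for time-to-delivery (including a designated 3-feature
#' minimal panel), GA at sampling (with a forward clock shift in the PTB
#' group), BMI, maternal age and gravidity (including age-independent
#' gravidity features), and 2\% missingness.
#'
#' @param seed integer RNG seed; identical configs produce identical output.
#' @param n_full full epidemiological cohort size (default 2000; the regime
#'   emulated at full scale is 13841).
#' @param n_sub multiomic subcohort size (default 231).
#' @param sites site labels (default 5 generic sites).
#' @param omic_sizes named feature counts; defaults proteome 120,
#'   metabolome 430, lipidome 64 (full scale 1196/4329/632).
#' @param ptb_prevalence_target fraction of PTBs in the full cohort (0.114).
#' @param clock_shift_weeks forward shift, in weeks, applied to the PTB
#'   group's GA-signal features (default 1).
#' @param signal_spec per-target list of planted features: omic, index
#'   (within omic), relative SNR weight, and target population R^2.
#' @param minimal_panel 3 feature ids designated as the recoverable minimal
#'   time-to-delivery panel (must be among the ttd signal features).
#' @param missing_rate fraction of omics cells set missing (default 0.02).
#' @param risk_scale multiplier on all PTB risk effects (default 1; 0 removes
#'   the epidemiological signal entirely while keeping the prevalence
#'   calibration, so downstream classifiers should score at chance).
#' @param block_spec per-omic intra-omic correlation block layout.
#' @param interomic_coupling list of coupled omic pairs (shared block
#'   factors) with link counts and strengths.
#' @return A validated \linkS4class{GeneratorConfig}.
#' @export
generatorConfig <- function(seed = 1L,
                            n_full = 2000L,
                            n_sub = 231L,
                            sites = paste0("site_", 1:5),
                            omic_sizes = c(proteome = 120L, metabolome = 430L,
                                           lipidome = 64L),
                            ptb_prevalence_target = 0.114,
                            clock_shift_weeks = 1.0,
                            signal_spec = defaultSignalSpec(),
                            minimal_panel = c("prot_061", "prot_062", "prot_063"),
                            missing_rate = 0.02,
                            risk_scale = 1.0,
                            block_spec = defaultBlockSpec(),
                            interomic_coupling = defaultInteromicCoupling()) {
  om <- as.integer(omic_sizes)
  names(om) <- names(omic_sizes)
  new("GeneratorConfig",
    seed = as.integer(seed), n_full = as.integer(n_full),
    n_sub = as.integer(n_sub), sites = as.character(sites),
    omic_sizes = om,
    ptb_prevalence_target = ptb_prevalence_target,
    clock_shift_weeks = clock_shift_weeks,
    signal_spec = signal_spec, minimal_panel = as.character(minimal_panel),
    missing_rate = missing_rate, risk_scale = risk_scale,
    block_spec = block_spec,
    interomic_coupling = interomic_coupling
  )
}

featureIdFor <- function(omic, index) {
  prefix <- c(proteome = "prot", metabolome = "met", lipidome = "lip")[omic]
  width <- c(proteome = 3L, metabolome = 4L, lipidome = 3L)[omic]
  sprintf("%s_%0*d", prefix, width, index)
}

#' Write / read a generator configuration as YAML
#'
#' Every \linkS4class{GeneratorConfig} field is addressable in the file;
#' round-trips are lossless.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param path file path.
#' @return \code{readGeneratorConfig} returns the reconstructed config.
#' @export
writeGeneratorConfig <- function(config, path) {
  x <- list(
    seed = config@seed, n_full = config@n_full, n_sub = config@n_sub,
    sites = config@sites, omic_sizes = as.list(config@omic_sizes),
    ptb_prevalence_target = config@ptb_prevalence_target,
    clock_shift_weeks = config@clock_shift_weeks,
    signal_spec = config@signal_spec,
    minimal_panel = config@minimal_panel,
    missing_rate = config@missing_rate,
    risk_scale = config@risk_scale,
    block_spec = config@block_spec,
    interomic_coupling = config@interomic_coupling
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeGeneratorConfig
#' @export
readGeneratorConfig <- function(path) {
  x <- yaml::read_yaml(path)
  x$omic_sizes <- unlist(x$omic_sizes)
  x$signal_spec <- lapply(x$signal_spec, function(sp) {
    sp$omic <- as.character(sp$omic)
    sp$index <- as.integer(sp$index)
    sp$weight <- as.numeric(sp$weight)
    sp
  })
  do.call(generatorConfig, x)
}

## closed-form loading calibration: population R^2 of the optimal linear
## combiner of m features x_j = a_j t + e_j equals S/(1+S), S = sum a_j^2/(1-a_j^2).
signalLoadings <- function(weight, r2) {
  s_total <- r2 / (1 - r2)
  s_j <- weight / sum(weight) * s_total
  sqrt(s_j / (1 + s_j))
}
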