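#' Generate the matched multiomic subcohort with planted structure
#'
#' Selects a case-control subcohort from a generated full cohort (cases and
#' controls matched within site on GA at sampling by greedy nearest-neighbour
#' matching without replacement), then simulates the three omic blocks on a
#' Gaussian-copula latent layer: intra-omic correlation blocks, shared-factor
#' inter-omic coupling, planted linear signals on the latent targets
#' (time-to-delivery, GA at sampling, BMI, age, gravidity), the forward clock
#' shift of the PTB group's GA-signal features, and MCAR missingness. Omic
#' marginals mirror assay scales: unbounded NPX-like proteome, right-skewed
#' log-normal metabolome, positive lipid concentrations. The marginal
#' transforms are strictly monotone, so planted rank correlations and
#' monotone signals survive them.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param cohort the \linkS4class{CohortTable} from
#'   \code{\link{generateFullCohort}} under the same config.
#' @return list with \code{proteome}, \code{metabolome}, \code{lipidome}
#'   (\linkS4class{OmicsMatrix}), \code{subcohort} (\linkS4class{CohortTable}
#'   restricted to the selected participants) and \code{truth}
#'   (\linkS4class{SyntheticTruth} with per-participant latent targets).
#' @export
generateMultiomicsSubcohort <- function(config, cohort) {
  stopifnot(is(config, "GeneratorConfig"), is(cohort, "CohortTable"))
  set.seed(config@seed + 1L)
  d <- cohortData(cohort)

  sel <- selectMatchedSubcohort(d, config@n_sub)
  sub <- d[match(sel$participant_id, d$participant_id), , drop = FALSE]
  rownames(sub) <- NULL
  n <- nrow(sub)

  ## latent targets (standardized over the subcohort)
  ttd <- sub$ga_birth_weeks - sub$ga_sampling_weeks
  ga_eff <- sub$ga_sampling_weeks + ifelse(sub$ptb, config@clock_shift_weeks, 0)
  ga_z <- (ga_eff - mean(sub$ga_sampling_weeks)) / stats::sd(sub$ga_sampling_weeks)
  targets <- list(
    ttd = as.numeric(scale(ttd)),
    ga_sampling = ga_z,
    bmi = as.numeric(scale(sub$bmi)),
    age = as.numeric(scale(sub$age_years)),
    gravidity = as.numeric(scale(sub$gravidity))
  )
  r_ag <- stats::cor(targets$age, targets$gravidity)
  targets$gravidity_resid <-
    (targets$gravidity - r_ag * targets$age) / sqrt(1 - r_ag^2)

  latent <- lapply(OMIC_LEVELS, function(om) {
    latentOmicLayer(n, config@omic_sizes[[om]], config@block_spec[[om]])
  })
  names(latent) <- OMIC_LEVELS
  latent <- coupleOmics(latent, config)
  latent <- plantSignals(latent, config, targets)

  mats <- list(
    proteome = round(5 + 2 * latent$proteome$z, 4),
    metabolome = round(exp(1 + 0.8 * latent$metabolome$z), 2),
    lipidome = round(10 * exp(0.5 + 0.6 * latent$lipidome$z), 3)
  )
  out <- lapply(OMIC_LEVELS, function(om) {
    m <- mats[[om]]
    rownames(m) <- sub$participant_id
    colnames(m) <- featureIdFor(rep(om, ncol(m)), seq_len(ncol(m)))
    if (config@missing_rate > 0) {
      hole <- matrix(stats::runif(length(m)) < config@missing_rate,
                     nrow = nrow(m))
      m[hole] <- NA_real_
    }
    OmicsMatrix(m, om)
  })
  names(out) <- OMIC_LEVELS

  truth <- new("SyntheticTruth",
    signals = signalLedger(config),
    minimal_panel = config@minimal_panel,
    clock_shift_weeks = config@clock_shift_weeks,
    participants = data.frame(
      participant_id = sub$participant_id,
      ttd_weeks = ttd,
      ga_sampling_weeks = sub$ga_sampling_weeks,
      ga_effective_weeks = ga_eff,
      ptb = sub$ptb,
      matched_pair = sel$pair,
      stringsAsFactors = FALSE
    )
  )
  c(out, list(subcohort = CohortTable(sub, covariateInfo(cohort)),
              truth = truth))
}

## Case-control selection: cases allocated to sites proportionally to the
## available site case counts; within each site every selected case is
## greedily matched to the unused control nearest in GA at sampling; the
## control surplus (n_sub is odd in the default design) is filled with the
## next-nearest controls.
selectMatchedSubcohort <- function(d, n_sub) {
  n_cases <- n_sub %/% 2L
  n_controls <- n_sub - n_cases
  sites <- sort(unique(d$site))
  avail <- vapply(sites, function(s) sum(d$ptb & d$site == s), integer(1))
  if (sum(avail) < n_cases) {
    stop("insufficient PTB cases for matching: need ", n_cases,
         ", available per site: ",
         paste(sprintf("%s=%d", sites, avail), collapse = ", "))
  }
  alloc <- largestRemainder(n_cases * avail / sum(avail), n_cases)
  alloc <- pmin(alloc, avail)
  short <- n_cases - sum(alloc)
  while (short > 0) { # cap spill-over
    room <- which(alloc < avail)
    alloc[room[1]] <- alloc[room[1]] + 1L
    short <- short - 1L
  }

  ids <- character(0); pair <- integer(0); k <- 0L
  extras_needed <- n_controls - n_cases
  extra_sites <- rep(sites, length.out = max(extras_needed, 0))
  for (i in seq_along(sites)) {
    s <- sites[i]
    cases <- d[d$ptb & d$site == s, c("participant_id", "ga_sampling_weeks")]
    ctrls <- d[!d$ptb & d$site == s, c("participant_id", "ga_sampling_weeks")]
    take <- cases[sample(nrow(cases), alloc[i]), , drop = FALSE]
    used <- logical(nrow(ctrls))
    for (j in seq_len(nrow(take))) {
      dist <- abs(ctrls$ga_sampling_weeks - take$ga_sampling_weeks[j])
      dist[used] <- Inf
      if (all(is.infinite(dist))) {
        stop("insufficient controls in site ", s, " for matching")
      }
      hit <- which.min(dist)
      used[hit] <- TRUE
      k <- k + 1L
      ids <- c(ids, take$participant_id[j], ctrls$participant_id[hit])
      pair <- c(pair, k, k)
    }
    n_extra <- sum(extra_sites == s)
    if (n_extra > 0 && nrow(take) > 0) {
      for (e in seq_len(n_extra)) {
        dist <- abs(ctrls$ga_sampling_weeks - mean(take$ga_sampling_weeks))
        dist[used] <- Inf
        hit <- which.min(dist)
        used[hit] <- TRUE
        ids <- c(ids, ctrls$participant_id[hit])
        pair <- c(pair, NA_integer_)
      }
    }
  }
  data.frame(participant_id = ids, pair = pair, stringsAsFactors = FALSE)
}

largestRemainder <- function(x, total) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    up <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[up] <- fl[up] + 1
  }
  as.integer(fl)
}

## standard-normal latent layer with equicorrelated blocks:
## z_ij = sqrt(rho) u_b + sqrt(1-rho) e_ij within block b, pure noise outside.
latentOmicLayer <- function(n, n_feat, spec) {
  z <- matrix(stats::rnorm(n * n_feat), nrow = n)
  n_blocks <- min(spec$n_blocks, n_feat %/% spec$block_size)
  factors <- matrix(stats::rnorm(n * max(n_blocks, 1)), nrow = n)
  if (n_blocks > 0) {
    for (b in seq_len(n_blocks)) {
      cols <- ((b - 1) * spec$block_size + 1):(b * spec$block_size)
      z[, cols] <- sqrt(spec$rho) * factors[, b] +
        sqrt(1 - spec$rho) * z[, cols]
    }
  }
  list(z = z, factors = factors, spec = spec, n_blocks = n_blocks)
}

## inter-omic coupling: re-express block factors of the second omic of each
## coupled pair as a mixture with the first omic's block factor, then rebuild
## the affected block columns.
coupleOmics <- function(latent, config) {
  for (link in config@interomic_coupling) {
    if (link$n_links <= 0) next
    a <- link$pair[1]; b <- link$pair[2]
    nl <- min(link$n_links, latent[[a]]$n_blocks, latent[[b]]$n_blocks)
    for (l in seq_len(nl)) {
      fa <- latent[[a]]$factors[, l]
      fb <- latent[[b]]$factors[, l]
      mixed <- link$strength * fa + sqrt(1 - link$strength^2) * fb
      latent[[b]]$factors[, l] <- mixed
      spec <- latent[[b]]$spec
      cols <- ((l - 1) * spec$block_size + 1):(l * spec$block_size)
      fresh <- matrix(stats::rnorm(length(cols) * length(mixed)),
                      nrow = length(mixed))
      latent[[b]]$z[, cols] <- sqrt(spec$rho) * mixed +
        sqrt(1 - spec$rho) * fresh
    }
  }
  latent
}

## overwrite designated columns with calibrated linear signal + noise;
## time-to-delivery features may carry a secondary loading on the
## gestational-age axis (shifted in the PTB group), composed so the feature
## keeps unit latent variance
plantSignals <- function(latent, config, targets) {
  for (tgt in names(config@signal_spec)) {
    sp <- config@signal_spec[[tgt]]
    a <- signalLoadings(sp$weight, sp$r2)
    for (j in seq_along(sp$index)) {
      tvec <- targets[[tgt]]
      if (!is.null(sp$age_independent) && isTRUE(sp$age_independent[j]) &&
          tgt == "gravidity") {
        tvec <- targets$gravidity_resid
      }
      g <- if (!is.null(sp$ga_loading)) sp$ga_loading[j] else 0
      mu <- a[j] * tvec
      if (g != 0) mu <- mu + g * targets$ga_sampling
      v <- stats::var(mu) * (length(mu) - 1) / length(mu)
      if (v >= 1) {
        stop("signal_spec[", tgt, "]: combined loadings exceed unit variance")
      }
      latent[[sp$omic[j]]]$z[, sp$index[j]] <-
        mu + sqrt(1 - v) * stats::rnorm(length(mu))
    }
  }
  latent
}
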