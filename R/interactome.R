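#' Analytic Bonferroni-derived Spearman significance threshold
#'
#' The smallest absolute Spearman rho whose two-sided t-approximation p-value
#' passes the Bonferroni-corrected level alpha/n_tests. Obtained by inverting
#' the t quantile: rho* = t*/sqrt(t*^2 + df) with df = n_participants - 2 and
#' t* the upper alpha/(2 n_tests) quantile of the t distribution. The quantile
#' is evaluated in log space, so extreme test counts do not underflow.
#'
#' At the scale of a 231-participant, 6157-feature interactome
#' (18,951,246 pairs, alpha 0.05) this yields 0.38.
#'
#' @param n_participants number of participants correlations are computed on.
#' @param n_tests size of the Bonferroni family (number of feature pairs).
#' @param alpha family-wise significance level.
#' @return the threshold on |rho|.
#' @export
bonferroniRhoThreshold <- function(n_participants, n_tests, alpha = 0.05) {
  df <- n_participants - 2
  if (df < 3) stop("need at least 5 participants (df >= 3)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  log_half_p <- log(alpha) - log(2) - log(n_tests)
  if (!is.finite(log_half_p)) {
    stop("alpha/n_tests not representable; evaluate in log space")
  }
  tstar <- stats::qt(log_half_p, df = df, lower.tail = FALSE, log.p = TRUE)
  tstar / sqrt(tstar^2 + df)
}

## two-sided p of a Spearman rho under the t approximation, df = n - 2
spearmanPvalue <- function(rho, n) {
  rho <- pmin(1 - 1e-15, pmax(-1 + 1e-15, rho))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

canonicalOmicPair <- function(omic_a, omic_b) {
  ia <- match(omic_a, OMIC_LEVELS)
  ib <- match(omic_b, OMIC_LEVELS)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  paste(OMIC_LEVELS[lo], OMIC_LEVELS[hi], sep = "-")
}

## strength bins on |rho|: (threshold, 0.6], (0.6, 0.8], (0.8, 1.0];
## boundary values fall in the lower bin; non-significant pairs bin "none"
strengthBin <- function(abs_rho, threshold) {
  bin <- rep("none", length(abs_rho))
  bin[abs_rho > threshold & abs_rho <= 0.6] <- "weak"
  bin[abs_rho > 0.6 & abs_rho <= 0.8] <- "moderate"
  bin[abs_rho > 0.8] <- "strong"
  bin[is.na(abs_rho)] <- NA_character_
  ## a threshold above a bin edge empties that bin rather than shifting it
  bin[!is.na(abs_rho) & abs_rho <= threshold] <- "none"
  factor(bin, levels = c("none", "weak", "moderate", "strong"))
}

#' All-pairs Spearman interactome
#'
#' For every unordered feature pair of the (imputed) matrix: Spearman rho via
#' midrank transform followed by product-moment correlation of the ranks; raw
#' two-sided p from the t approximation t = rho sqrt((n-2)/(1-rho^2)) on
#' n - 2 degrees of freedom; Bonferroni-adjusted p = min(1, p x n_tests)
#' where n_tests counts all F(F-1)/2 pairs; intra-/inter-omic class, omic
#' pair label and strength bin. A pair is flagged significant exactly when
#' |rho| exceeds the analytic threshold of
#' \code{\link{bonferroniRhoThreshold}}.
#'
#' Constant features (zero rank variance) yield undefined rho: such pairs are
#' kept with \code{NA} statistics, excluded from significance counts, and a
#' warning names the features.
#'
#' @param m an imputed \linkS4class{OmicsMatrix} (no missing values) with at
#'   least 4 participants.
#' @param alpha family-wise significance level (default 0.05).
#' @return a \linkS4class{CorrelationSet}.
#' @export
spearmanAllPairs <- function(m, alpha = 0.05) {
  stopifnot(is(m, "OmicsMatrix"))
  vals <- featureMatrix(m)
  if (anyNA(vals)) stop("matrix contains missing values; run meanImpute first")
  n <- nrow(vals)
  if (n < 4) stop("need at least 4 participants")
  f <- ncol(vals)
  n_tests <- choose(f, 2)
  threshold <- bonferroniRhoThreshold(n, n_tests, alpha)

  ranks <- apply(vals, 2, rank) # midranks
  const <- apply(vals, 2, function(x) length(unique(x)) == 1L)
  if (any(const)) {
    warning("constant feature(s), rho undefined: ",
            paste(colnames(vals)[const], collapse = ", "))
  }
  rho <- suppressWarnings(stats::cor(ranks)) # Pearson on midranks
  rho[const, ] <- NA
  rho[, const] <- NA

  ut <- which(upper.tri(rho), arr.ind = TRUE)
  omic <- omicOf(m)
  r <- rho[ut]
  p_raw <- spearmanPvalue(r, n)
  pairs <- data.frame(
    feature_a = colnames(vals)[ut[, 1]],
    feature_b = colnames(vals)[ut[, 2]],
    rho = r,
    p_raw = p_raw,
    p_adj = pmin(1, p_raw * n_tests),
    class = ifelse(omic[ut[, 1]] == omic[ut[, 2]], "intra", "inter"),
    omic_pair = canonicalOmicPair(omic[ut[, 1]], omic[ut[, 2]]),
    stringsAsFactors = FALSE
  )
  pairs$bin <- strengthBin(abs(pairs$rho), threshold)
  pairs$significant <- !is.na(pairs$rho) & abs(pairs$rho) > threshold
  sizes <- vapply(split(seq_len(f), factor(omic, OMIC_LEVELS)), length, integer(1))
  new("CorrelationSet",
    pairs = pairs, n_participants = as.integer(n), n_tests = n_tests,
    alpha = alpha, rho_threshold = threshold,
    omic_sizes = sizes
  )
}

#' Summarize an interactome by omic pair and strength bin
#'
#' Counts significant correlations per omic pair and strength bin, and
#' normalizes each omic pair's significant count to the number of possible
#' pairs for that omic pair (F_i(F_i - 1)/2 within an omic, F_i x F_j
#' between omics).
#'
#' @param cs a \linkS4class{CorrelationSet}.
#' @return list with \code{per_pair} (omic_pair, class, weak/moderate/strong
#'   counts, significant count, possible pairs, normalized link weight),
#'   \code{total_significant}, \code{significant_fraction} (of all pairs) and
#'   \code{intra_share} (intra-omic share of significant correlations).
#' @export
summarizeInteractome <- function(cs) {
  stopifnot(is(cs, "CorrelationSet"))
  p <- cs@pairs
  sizes <- cs@omic_sizes
  combos <- expand.grid(i = seq_along(OMIC_LEVELS), j = seq_along(OMIC_LEVELS))
  combos <- combos[combos$i <= combos$j, ]
  per <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
    oi <- OMIC_LEVELS[combos$i[k]]; oj <- OMIC_LEVELS[combos$j[k]]
    lab <- paste(oi, oj, sep = "-")
    sub <- p[p$omic_pair == lab, ]
    possible <- if (oi == oj) choose(sizes[[oi]], 2) else sizes[[oi]] * sizes[[oj]]
    sig <- sub[which(sub$significant), ]
    data.frame(
      omic_pair = lab,
      class = if (oi == oj) "intra" else "inter",
      weak = sum(sig$bin == "weak"),
      moderate = sum(sig$bin == "moderate"),
      strong = sum(sig$bin == "strong"),
      significant = nrow(sig),
      possible = possible,
      normalized_weight = if (possible > 0) nrow(sig) / possible else 0,
      stringsAsFactors = FALSE
    )
  }))
  rownames(per) <- NULL
  total_sig <- sum(per$significant)
  list(
    per_pair = per,
    total_significant = total_sig,
    significant_fraction = total_sig / cs@n_tests,
    intra_share = if (total_sig > 0) {
      sum(per$significant[per$class == "intra"]) / total_sig
    } else NA_real_
  )
}

#' Bootstrap null distribution of the significant-correlation fraction
#'
#' Destroys cross-feature coupling by independently resampling each feature's
#' values with replacement, re-runs the full interactome, and records the
#' fraction of pairs called significant. Repeating this yields the null
#' distribution against which the observed significant fraction is compared.
#'
#' @param m an imputed \linkS4class{OmicsMatrix}.
#' @param n_sets number of null datasets (0 gives an empty result).
#' @param seed RNG seed; fixed seed gives reproducible fractions.
#' @param alpha family-wise significance level.
#' @return numeric vector of per-set significant fractions.
#' @export
bootstrapNull <- function(m, n_sets, seed = 1L, alpha = 0.05) {
  stopifnot(is(m, "OmicsMatrix"), n_sets >= 0)
  if (n_sets == 0) return(numeric(0))
  vals <- featureMatrix(m)
  if (anyNA(vals)) stop("matrix contains missing values; run meanImpute first")
  set.seed(seed)
  n <- nrow(vals)
  vapply(seq_len(n_sets), function(s) {
    null_vals <- apply(vals, 2, function(x) sample(x, n, replace = TRUE))
    rownames(null_vals) <- rownames(vals)
    cs <- suppressWarnings(spearmanAllPairs(OmicsMatrix(null_vals, omicOf(m)),
                                            alpha = alpha))
    sum(cs@pairs$significant) / cs@n_tests
  }, numeric(1))
}

#' Dataset modularity: principal components to reach 90\% variance
#'
#' Features are standardized to unit variance, then the smallest number k of
#' principal components whose cumulative explained-variance ratio reaches
#' 0.90 is returned; k is bounded by the rank of the matrix. Constant
#' features carry no variance and are dropped with a warning.
#'
#' @param m an imputed \linkS4class{OmicsMatrix}.
#' @param omic optional omic label to restrict to (default: all features).
#' @param ratio cumulative explained-variance target (default 0.90).
#' @return integer component count.
#' @export
modularityPC90 <- function(m, omic = NULL, ratio = 0.90) {
  stopifnot(is(m, "OmicsMatrix"))
  vals <- featureMatrix(m)
  if (anyNA(vals)) stop("matrix contains missing values; run meanImpute first")
  if (!is.null(omic)) {
    stopifnot(omic %in% OMIC_LEVELS)
    vals <- vals[, omicOf(m) == omic, drop = FALSE]
  }
  if (ncol(vals) < 2) stop("need at least 2 features")
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(colnames(vals)[sds == 0], collapse = ", "))
    vals <- vals[, sds > 0, drop = FALSE]
  }
  z <- scale(vals)
  sv <- svd(z, nu = 0, nv = 0)$d
  ev <- sv^2
  ev <- ev[ev > max(ev) * 1e-12] # numerical rank
  cum <- cumsum(ev) / sum(ev)
  which(cum >= ratio)[1]
}

#' Two-dimensional embedding of the feature correlation space
#'
#' Embeds features under the dissimilarity 1 - |rho| so that strongly
#' correlated features land close together. The embedding algorithm is
#' pluggable in principle; the default is classical multidimensional scaling,
#' which is deterministic (the \code{seed} argument is accepted for interface
#' stability). The contract is geometric, not algorithmic: for planted
#' correlation blocks, mean within-block embedded distance is smaller than
#' mean between-block distance.
#'
#' @param cs a \linkS4class{CorrelationSet}.
#' @param seed accepted for interface stability; the default embedder is
#'   fully deterministic.
#' @return matrix of 2-D coordinates, one row per feature.
#' @export
embedCorrelationSpace <- function(cs, seed = 1L) {
  stopifnot(is(cs, "CorrelationSet"))
  p <- cs@pairs
  feats <- sort(unique(c(p$feature_a, p$feature_b)))
  k <- length(feats)
  coords <- matrix(0, nrow = k, ncol = 2,
                   dimnames = list(feats, c("dim1", "dim2")))
  if (k <= 2) return(coords) # degenerate, no failure
  d <- matrix(1, k, k, dimnames = list(feats, feats))
  diag(d) <- 0
  ia <- match(p$feature_a, feats); ib <- match(p$feature_b, feats)
  dis <- 1 - abs(p$rho)
  dis[is.na(dis)] <- 1
  d[cbind(ia, ib)] <- dis
  d[cbind(ib, ia)] <- dis
  set.seed(seed)
  fit <- stats::cmdscale(stats::as.dist(d), k = 2)
  coords[rownames(fit), ] <- fit
  coords
}

#' Number of unordered feature pairs
#'
#' @param n_features feature count F.
#' @return F(F-1)/2.
#' @export
pairCount <- function(n_features) choose(n_features, 2)
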