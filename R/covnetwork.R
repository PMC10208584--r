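## numeric coding for mixed covariate types: binary as 0/1, ordinal as their
## numeric codes, continuous as-is; rank correlation downstream makes the
## coding choice immaterial beyond order
covariateNumericMatrix <- function(cohort) {
  d <- cohortData(cohort)
  cv <- covariateInfo(cohort)
  m <- sapply(cv$covariate, function(v) as.numeric(d[[v]]))
  rownames(m) <- d$participant_id
  m
}

## Spearman on pairwise-complete cases with a minimum pair count; returns
## rho, p (t approximation on the pairwise n) and n per pair
pairwiseSpearman <- function(m, min_pairs = 10L) {
  k <- ncol(m)
  rho <- p <- nobs <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      n <- sum(ok)
      nobs[i, j] <- nobs[j, i] <- n
      if (n < min_pairs) next
      if (stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) next
      r <- stats::cor(rank(m[ok, i]), rank(m[ok, j]))
      rho[i, j] <- rho[j, i] <- r
      p[i, j] <- p[j, i] <- spearmanPvalue(r, n)
    }
  }
  list(rho = rho, p = p, n = nobs)
}

#' Build the covariate correlation network
#'
#' Per clinical category, the Spearman correlation matrix of the category's
#' covariates (pairwise-complete observations, minimum 10 complete pairs per
#' edge) is reduced to a minimum spanning tree on edge weights 1 - |rho|
#' (ties broken by lexicographic pair id). Category MSTs are unioned into
#' one graph, then edges are added between covariate pairs (of any
#' category) whose correlation is significant after Bonferroni correction
#' over all tested covariate pairs. The layout is a seeded
#' Fruchterman-Reingold force-directed embedding; layout never alters
#' topology. Zero-variance covariates become isolated nodes with a warning.
#'
#' @param cohort a \linkS4class{CohortTable}.
#' @param node_scores optional data.frame from
#'   \code{\link{covariateNodeScores}} merged onto the node table.
#' @param alpha family-wise level for the extra significant edges.
#' @param min_pairs minimum pairwise-complete observations per tested pair.
#' @param seed layout seed.
#' @return a \linkS4class{CovariateNetwork}.
#' @export
buildCovariateNetwork <- function(cohort, node_scores = NULL, alpha = 0.05,
                                  min_pairs = 10L, seed = 1L) {
  cv <- covariateInfo(cohort)
  m <- covariateNumericMatrix(cohort)
  zerovar <- apply(m, 2, function(x) stats::sd(x, na.rm = TRUE) == 0)
  if (any(zerovar)) {
    warning("zero-variance covariate(s) kept as isolated nodes: ",
            paste(colnames(m)[zerovar], collapse = ", "))
  }
  ps <- pairwiseSpearman(m, min_pairs)

  ## per-category MSTs
  mst_edges <- do.call(rbind, lapply(split(cv$covariate, cv$category), function(vars) {
    vars <- setdiff(vars, colnames(m)[zerovar])
    if (length(vars) < 2) return(NULL)
    categoryMST(ps$rho[vars, vars, drop = FALSE])
  }))

  ## Bonferroni family: every covariate pair actually tested
  tested <- which(upper.tri(ps$p) & !is.na(ps$p), arr.ind = TRUE)
  n_tests <- nrow(tested)
  sig <- data.frame(
    from = colnames(m)[tested[, 1]],
    to = colnames(m)[tested[, 2]],
    rho = ps$rho[tested],
    p_adj = pmin(1, ps$p[tested] * n_tests),
    stringsAsFactors = FALSE
  )
  sig <- sig[sig$p_adj < alpha, ]

  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- data.frame(
    from = c(mst_edges$from, sig$from),
    to = c(mst_edges$to, sig$to),
    rho = c(mst_edges$rho, sig$rho),
    mst_flag = c(rep(TRUE, nrow(mst_edges)), rep(FALSE, nrow(sig))),
    stringsAsFactors = FALSE
  )
  edges <- edges[!duplicated(key(edges$from, edges$to)), ]
  edges$weight <- 1 - abs(edges$rho)
  edges$significant_flag <- key(edges$from, edges$to) %in% key(sig$from, sig$to)
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL

  nodes <- data.frame(covariate = cv$covariate, category = cv$category,
                      stringsAsFactors = FALSE)
  if (!is.null(node_scores)) {
    nodes <- merge(nodes, node_scores, by = "covariate", all.x = TRUE,
                   sort = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  set.seed(seed)
  lay <- igraph::layout_with_fr(g)
  rownames(lay) <- nodes$covariate
  colnames(lay) <- c("x", "y")
  new("CovariateNetwork", nodes = nodes, edges = edges, layout = lay, graph = g)
}

## MST of one category on weights 1 - |rho|; untested pairs are unusable
## (infinite weight); deterministic tie-break by lexicographic pair id
categoryMST <- function(rho) {
  vars <- colnames(rho)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  e <- data.frame(
    from = vars[ut[, 1]], to = vars[ut[, 2]],
    rho = rho[ut], stringsAsFactors = FALSE
  )
  e <- e[!is.na(e$rho), ]
  if (nrow(e) == 0) return(NULL)
  lo <- pmin(e$from, e$to); hi <- pmax(e$from, e$to)
  e <- e[order(1 - abs(e$rho), lo, hi), ] # tie-break: weight, then pair id
  g <- igraph::graph_from_data_frame(e, directed = FALSE, vertices = vars)
  igraph::E(g)$weight <- 1 - abs(e$rho)
  tree <- igraph::mst(g, algorithm = "prim")
  te <- igraph::as_data_frame(tree, what = "edges")
  data.frame(from = te$from, to = te$to, rho = te$rho,
             stringsAsFactors = FALSE)
}

#' Per-covariate PTB-association and multiomic-predictability scores
#'
#' The association score is -log10 of the Bonferroni-adjusted two-sided
#' rank-sum p comparing the covariate between PTB and term participants
#' (adjusted over all scored covariates; for binary covariates the rank-sum
#' reduces to a two-proportion rank test). The predictability score is
#' -log10 of the Pearson p of the repeated-CV regression of the covariate on
#' the combined omics matrix. Covariates missing for more than half the
#' participants are scored on the available cases with a message.
#'
#' @param cohort a \linkS4class{CohortTable}.
#' @param omics optional combined \linkS4class{OmicsMatrix}; when absent,
#'   predictability scores are \code{NA}.
#' @param cfg regression \code{\link{harnessConfig}} for predictability.
#' @param covariates subset of covariates to score (default all).
#' @return data.frame: covariate, assoc_p_adj, assoc_score,
#'   predictability_p, predictability_score.
#' @export
covariateNodeScores <- function(cohort, omics = NULL,
                                cfg = harnessConfig("regression"),
                                covariates = NULL) {
  d <- cohortData(cohort)
  cv <- covariateInfo(cohort)
  if (is.null(covariates)) covariates <- cv$covariate
  stopifnot(all(covariates %in% cv$covariate))
  omat <- NULL
  if (!is.null(omics)) {
    omat <- if (is(omics, "OmicsMatrix")) featureMatrix(omics) else as.matrix(omics)
    d_sub <- d[match(rownames(omat), d$participant_id), ]
  }
  raw_p <- vapply(covariates, function(v) {
    x <- as.numeric(d[[v]])
    if (mean(is.na(x)) > 0.5) {
      message("covariate ", v, " missing for >50% of participants; scored on n = ",
              sum(!is.na(x)))
    }
    wilcoxonRankSum(x[d$ptb], x[!d$ptb])$p
  }, numeric(1))
  p_adj <- pmin(1, raw_p * length(covariates))
  out <- data.frame(
    covariate = covariates,
    assoc_p_adj = p_adj,
    assoc_score = -log10(pmax(p_adj, .Machine$double.xmin)),
    predictability_p = NA_real_,
    predictability_score = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(omat)) {
    for (i in seq_along(covariates)) {
      v <- covariates[i]
      y <- as.numeric(d_sub[[v]])
      ok <- !is.na(y)
      if (sum(ok) < 20 || stats::sd(y[ok]) == 0) next
      res <- repeatedCV(omat[ok, , drop = FALSE], y[ok], cfg)
      out$predictability_p[i] <- cvMetrics(res)$p
      out$predictability_score[i] <-
        -log10(pmax(cvMetrics(res)$p, .Machine$double.xmin))
    }
  }
  out
}

#' Write a covariate network as plain-text tables
#'
#' Emits the node table, edge table and layout coordinates as TSV plus a
#' GraphML file of the full graph.
#'
#' @param net a \linkS4class{CovariateNetwork}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCovariateNetwork <- function(net, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("nodes.tsv", "edges.tsv", "layout.tsv",
                            "network.graphml"))
  utils::write.table(net@nodes, paths[1], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(net@edges, paths[2], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(covariate = rownames(net@layout), net@layout),
    paths[3], sep = "\t", row.names = FALSE, quote = FALSE
  )
  igraph::write_graph(net@graph, paths[4], format = "graphml")
  invisible(paths)
}
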