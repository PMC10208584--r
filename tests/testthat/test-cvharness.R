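# small, strongly-signalled regression problem used by several tests
makeRegressionProblem <- function(n = 80, f = 12, seed = 5, r2 = 0.8) {
  set.seed(seed)
  y <- rnorm(n)
  a <- sqrt(r2)
  x <- sapply(seq_len(f), function(j) {
    if (j <= 3) a * y + sqrt(1 - a^2) * rnorm(n) else rnorm(n)
  })
  dimnames(x) <- list(sprintf("P%03d", seq_len(n)), sprintf("f%02d", seq_len(f)))
  list(x = x, y = y)
}

test_that("an oracle feature leaks through to near-perfect predictions", {
  set.seed(1)
  n <- 100
  y <- rnorm(n)
  x <- cbind(leak = y, matrix(rnorm(n * 5), n))
  colnames(x) <- c("leak", paste0("f", 1:5))
  rownames(x) <- sprintf("P%03d", 1:n)
  # deep enough boosting to let the oracle feature saturate the fit
  cfg <- harnessConfig("regression", n_reps = 10, bootstrap_ci_reps = 0,
                       nrounds = 300,
                       params = list(max_depth = 4, eta = 0.3, subsample = 1,
                                     colsample_bytree = 1))
  res <- repeatedCV(x, y, cfg)
  expect_gt(cvMetrics(res)$r, 0.99)

  lab <- y > 0
  res2 <- repeatedCV(cbind(x, leak2 = as.numeric(lab)), lab,
                     fastHarness("classification", n_reps = 10))
  expect_gt(cvMetrics(res2)$auroc, 0.99)
})

test_that("pure noise with permuted labels scores at chance", {
  set.seed(2)
  n <- 120
  x <- matrix(rnorm(n * 15), n, dimnames = list(sprintf("P%03d", 1:n),
                                                paste0("f", 1:15)))
  lab <- sample(c(rep(TRUE, 30), rep(FALSE, 90)))
  res <- repeatedCV(x, lab, fastHarness("classification", n_reps = 20))
  expect_gte(cvMetrics(res)$auroc, 0.4)
  expect_lte(cvMetrics(res)$auroc, 0.6)
})

test_that("per-participant averages use only models that never saw them", {
  prob <- makeRegressionProblem(n = 40, seed = 9)
  res <- repeatedCV(prob$x, prob$y, fastHarness("regression", n_reps = 12))
  mem <- res@train_membership
  pred <- cvPredictions(res)
  # structural no-leak assertion from the membership ledger: the number of
  # test appearances equals the number of reps that excluded the participant
  expect_equal(pred$n_test, colSums(!mem)[pred$participant_id],
               ignore_attr = TRUE)
  # split sizes are even per repetition
  expect_true(all(rowSums(mem) == 20))
  expect_equal(sum(pred$n_test), 12 * 20)
})

test_that("repetition splits are stratified and seeded deterministically", {
  set.seed(3)
  n <- 100
  x <- matrix(rnorm(n * 8), n, dimnames = list(sprintf("P%03d", 1:n),
                                               paste0("f", 1:8)))
  lab <- c(rep(TRUE, 12), rep(FALSE, 88))
  cfg <- fastHarness("classification", n_reps = 6, seed = 42)
  res1 <- repeatedCV(x, lab, cfg)
  res2 <- repeatedCV(x, lab, cfg)
  expect_identical(cvPredictions(res1), cvPredictions(res2))
  # stratification keeps both classes in every training half
  for (r in seq_len(6)) {
    expect_equal(sum(res1@train_membership[r, ] & lab), 6)
  }
})

test_that("averaging stabilizes the metric as repetitions double", {
  prob <- makeRegressionProblem(n = 100, f = 10, seed = 13, r2 = 0.75)
  r1 <- cvMetrics(repeatedCV(prob$x, prob$y, fastHarness("regression", n_reps = 15, seed = 1)))$r
  r2 <- cvMetrics(repeatedCV(prob$x, prob$y, fastHarness("regression", n_reps = 30, seed = 1)))$r
  expect_lt(abs(r1 - r2), 0.02)
})

test_that("per-site metrics recompute from shared predictions", {
  prob <- makeRegressionProblem(n = 90, seed = 21)
  sites <- rep(c("A", "B", "C"), each = 30)
  res <- repeatedCV(prob$x, prob$y, fastHarness("regression", n_reps = 10),
                    sites = sites)
  tab <- res@per_site
  expect_setequal(tab$site, c("A", "B", "C", "combined"))
  comb <- tab[tab$site == "combined", ]
  expect_equal(comb$r, cvMetrics(res)$r)
  expect_equal(comb$n, 90)
  # permuting site labels leaves the combined row unchanged
  res2 <- perSiteMetrics(res, sites = sample(sites))
  expect_equal(res2[res2$site == "combined", ]$r, comb$r)
  # single site collapses to one site row plus the combined row
  one <- perSiteMetrics(res, sites = rep("Z", 90))
  expect_equal(one$r[one$site == "Z"], one$r[one$site == "combined"])
})

test_that("classification metrics carry bootstrap CIs and rank-sum p", {
  set.seed(6)
  n <- 150
  y <- c(rep(TRUE, 40), rep(FALSE, 110))
  x <- cbind(sapply(1:3, function(i) y + rnorm(n, sd = 0.8)),
             matrix(rnorm(n * 5), n))
  dimnames(x) <- list(sprintf("P%03d", 1:n), paste0("f", 1:8))
  res <- repeatedCV(x, y, fastHarness("classification", n_reps = 10))
  m <- cvMetrics(res)
  expect_gte(m$auroc, m$auroc_ci[1])
  expect_lte(m$auroc, m$auroc_ci[2])
  expect_gte(m$auprc, m$auprc_ci[1])
  expect_lte(m$auprc, m$auprc_ci[2])
  expect_equal(m$lift, m$auprc / mean(y))
  expect_lt(m$rank_sum_p, 0.01)
})

test_that("site transfer comparison favours pooling for exchangeable sites", {
  prob <- makeRegressionProblem(n = 120, f = 10, seed = 31, r2 = 0.7)
  sites <- rep(c("A", "B"), each = 60)
  tab <- siteTransferComparison(prob$x, prob$y,
                                fastHarness("regression", n_reps = 8), sites)
  expect_equal(nrow(tab), 2)
  # exchangeable sites: pooled training should not hurt on average
  expect_gt(mean(tab$delta), -0.05)
  expect_error(siteTransferComparison(prob$x, prob$y,
                                      fastHarness("regression", n_reps = 4),
                                      rep("A", 120)),
               "at least 2 sites")
})

test_that("prevalence-matched evaluation shifts AUPRC but not AUROC", {
  set.seed(8)
  n <- 200
  y <- c(rep(TRUE, 90), rep(FALSE, 110))
  x <- cbind(s1 = y + rnorm(n, sd = 0.7), s2 = y + rnorm(n, sd = 0.9),
             matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4))))
  rownames(x) <- sprintf("P%03d", 1:n)
  res <- repeatedCV(x, y, fastHarness("classification", n_reps = 10))
  draws <- prevalenceMatchedEval(res, target_prevalence = 0.15,
                                 n_draws = 30, seed = 4)
  expect_equal(nrow(draws), 30)
  expect_lt(max(abs(draws$prevalence - 0.15)), 0.02)
  m <- cvMetrics(res)
  # AUROC is a rank metric, approximately invariant to prevalence
  expect_lt(abs(mean(draws$auroc) - m$auroc), 0.05)
  # AUPRC drops towards the new, lower baseline
  expect_lt(mean(draws$auprc), m$auprc)
  # reproducible under a fixed seed
  draws2 <- prevalenceMatchedEval(res, target_prevalence = 0.15,
                                  n_draws = 30, seed = 4)
  expect_identical(draws, draws2)
  # matching the observed prevalence centers on the observed metrics
  obs <- prevalenceMatchedEval(res, target_prevalence = mean(y),
                               n_draws = 20, seed = 5)
  expect_lt(abs(mean(obs$auroc) - m$auroc), 0.03)
})
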