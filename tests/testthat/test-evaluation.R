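# builds a small benchmark state shared by the metric tests
eval_fixture <- function(seed = 1) {
  ds <- random_dataset(n_prot = 8, pep_per = 4, s = 5, miss = 0.2, seed = seed)
  plan <- make_masked_split(ds, 0.15, 0.1, seed = seed + 1)
  Z <- log_standardize(ds)$matrix
  trainZ <- apply_mask_plan(Z, plan)
  list(ds = ds, plan = plan, trainZ = trainZ)
}

test_that("sample-wise RMSE equals the group-by oracle", {
  fx <- eval_fixture()
  tab <- error_table(fx$plan, impute_median(fx$trainZ), "Median", fx$ds)
  rmse <- samplewise_rmse(tab)
  for (sid in names(rmse)) {
    e <- tab$abs_error[tab$sample_id == sid]
    expect_equal(unname(rmse[sid]), sqrt(mean(e^2)))
  }
  # closed-form examples
  tab2 <- tab[1:2, ]
  tab2$sample_id <- "S1"
  tab2$abs_error <- c(3, 4)
  expect_equal(unname(samplewise_rmse(tab2)), sqrt(12.5))
  tab2$abs_error <- c(0, 0)
  expect_equal(unname(samplewise_rmse(tab2)), 0)
  expect_error(samplewise_rmse(tab[0, ]), "empty")
})

test_that("MAE and RMSE match brute force on random tables", {
  fx <- eval_fixture(3)
  tab <- error_table(fx$plan, impute_knn(fx$trainZ, k = 5), "KNN", fx$ds)
  expect_equal(dataset_mae(tab), mean(abs(tab$predicted - tab$truth)))
  expect_equal(dataset_rmse(tab), sqrt(mean((tab$predicted - tab$truth)^2)))
  tab$abs_error <- c(1, 1, rep(0, nrow(tab) - 2))
  expect_equal(dataset_mae(tab), 2 / nrow(tab))
})

test_that("bootstrap interval behaves on constants and is seeded", {
  expect_equal(bootstrap_ci(rep(2.5, 10), seed = 1), c(2.5, 2.5))
  v <- rnorm(30)
  expect_identical(bootstrap_ci(v, seed = 4), bootstrap_ci(v, seed = 4))
  expect_error(bootstrap_ci(1), "at least 2")
})

test_that("bootstrap interval covers the truth at near-nominal rate", {
  set.seed(10)
  hits <- vapply(seq_len(200), function(r) {
    x <- rnorm(100)
    ci <- bootstrap_ci(x, reps = 200, seed = r)
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("signed-rank matrix detects a strictly better method", {
  fx <- eval_fixture(5)
  base <- error_table(fx$plan, impute_median(fx$trainZ), "A", fx$ds)
  n <- nrow(base)
  better <- base
  better$abs_error <- base$abs_error * 0.5
  worse <- base
  worse$abs_error <- base$abs_error + 0.3
  res <- pairwise_wilcoxon_matrix(list(A = better, B = base, C = worse))
  expect_lt(res$p_matrix["A", "B"], 0.05)
  expect_lt(res$p_matrix["A", "C"], 0.05)
  expect_gt(res$p_matrix["C", "A"], 0.5)
  expect_equal(unname(res$win_counts["A"]), 2)
  expect_equal(unname(res$win_counts["C"]), 0)
  # win-count conservation: k(k-1)/2 mass in total
  expect_equal(sum(res$win_counts), 3)
})

test_that("identical methods split the win mass half-and-half", {
  fx <- eval_fixture(6)
  tab <- error_table(fx$plan, impute_median(fx$trainZ), "A", fx$ds)
  res <- pairwise_wilcoxon_matrix(list(A = tab, B = tab))
  expect_equal(res$p_matrix["A", "B"], 1)  # all-zero differences convention
  expect_equal(unname(res$win_counts), c(0.5, 0.5))
})

test_that("signed-rank p-values are exact for small n", {
  # exhaustive sign-flip oracle for the one-sided statistic
  exact_wilcox_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d < 0])  # statistic favouring "less"
    total <- 0L
    hits <- 0L
    for (mask in 0:(2^n - 1)) {
      signs <- as.integer(intToBits(mask))[seq_len(n)]
      w <- sum(r[signs == 1])
      total <- total + 1L
      if (w >= w_obs) hits <- hits + 1L
    }
    hits / total
  }
  set.seed(20)
  for (rep in 1:5) {
    d <- rnorm(9)
    p_pkg <- suppressWarnings(wilcox.test(d, alternative = "less")$p.value)
    expect_equal(p_pkg, exact_wilcox_p(d), tolerance = 1e-12)
  }
})

test_that("a uniformly smaller error vector wins at n = 30", {
  ds <- random_dataset(n_prot = 20, pep_per = 4, s = 6, miss = 0.1, seed = 7)
  plan <- make_masked_split(ds, 0.15, 0.1, seed = 8)
  trainZ <- apply_mask_plan(log_standardize(ds)$matrix, plan)
  tab <- error_table(plan, impute_median(trainZ), "A", ds)
  tab <- tab[1:30, ]
  b <- tab
  b$abs_error <- tab$abs_error + 0.01
  res <- pairwise_wilcoxon_matrix(list(A = tab, B = b))
  # one-sided extreme at n = 30: p = 2^-30 before correction
  expect_equal(res$p_matrix["A", "B"], 2 * 2^-30, tolerance = 1e-6)
  expect_lt(res$p_matrix["A", "B"], 0.05)
})

test_that("stratified RMSE partitions the test set by peptide missingness", {
  fx <- eval_fixture(8)
  tab <- error_table(fx$plan, impute_median(fx$trainZ), "M", fx$ds)
  out <- stratified_rmse(tab, bins = c(0, 0.5, 1))
  expect_equal(sum(out$n), nrow(tab))
  # brute force per bin
  lo <- tab$miss_frac < 0.5
  if (any(lo))
    expect_equal(out$rmse[out$bin == "[0,0.5)"],
                 sqrt(mean(tab$abs_error[lo]^2)))
  # all peptides in one bin
  tab2 <- tab
  tab2$miss_frac <- 0.6
  out2 <- stratified_rmse(tab2, bins = c(0, 0.5, 1))
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$bin, "[0.5,1]")
  expect_error(stratified_rmse(tab, bins = c(0.2, 1)), "bins")
})

test_that("Welch test matches the hand-computed example and t.test", {
  mat <- matrix(c(1, 2, 3, 4, 5, 6), 1)
  colnames(mat) <- paste0("S", 1:6)
  groups <- setNames(rep(c("a", "b"), each = 3), colnames(mat))
  res <- welch_de(mat, groups)
  expect_equal(res$table$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$table$df, 4, tolerance = 1e-12)
  expect_equal(res$table$p, 0.02131164, tolerance = 1e-6)
  # vectorized result equals stats::t.test row by row on random data
  set.seed(30)
  M <- matrix(rnorm(8 * 10), 10, 8)
  colnames(M) <- paste0("S", 1:8)
  g <- setNames(rep(c("a", "b"), each = 4), colnames(M))
  res <- welch_de(M, g)
  for (i in c(1, 5, 10)) {
    tt <- t.test(M[i, 1:4], M[i, 5:8])
    expect_equal(res$table$t[res$table$row == i], unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(res$table$p[res$table$row == i], tt$p.value,
                 tolerance = 1e-10)
  }
  # identical groups give t = 0, p = 1
  M2 <- rbind(rep(c(1, 2, 3, 4), 2))
  colnames(M2) <- paste0("S", 1:8)
  res2 <- welch_de(M2, g)
  expect_equal(res2$table$t, 0)
  expect_equal(res2$table$p, 1)
})

test_that("peptides without two observations per group are excluded", {
  M <- matrix(rnorm(24), 3, 8)
  colnames(M) <- paste0("S", 1:8)
  M[2, 1:3] <- NA  # one observation left in group a
  g <- setNames(rep(c("a", "b"), each = 4), colnames(M))
  res <- welch_de(M, g)
  expect_equal(res$excluded, 2L)
  expect_equal(res$table$row, c(1L, 3L))
  expect_error(welch_de(M, setNames(rep("a", 8), colnames(M))),
               "two conditions")
})

test_that("BH adjustment follows the step-up procedure", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  M <- matrix(rnorm(4 * 8), 4, 8)
  # check against the closed form via p.adjust equivalence on a known case
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  fx <- eval_fixture(9)
  groups <- setNames(rep(c("a", "b"), length.out = 5), fx$ds$sample_ids)
  res <- welch_de(impute_median(fx$trainZ), groups)
  expect_equal(res$table$q, p.adjust(res$table$p, "BH"))
  # q-values respect BH monotonicity in p-rank
  ord <- order(res$table$p)
  expect_true(all(diff(res$table$q[ord]) >= -1e-12))
})

test_that("ROC analysis handles separation, ties and the rank-sum identity", {
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  perfect <- roc_pr(labels, c(0.01, 0.02, 0.03, 0.5, 0.6, 0.7))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$roc$fpr[1], 0)
  expect_equal(perfect$roc$tpr[nrow(perfect$roc)], 1)
  inverted <- roc_pr(labels, c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3))
  expect_equal(inverted$auc, 0)
  # AUC equals the pairwise-concordance statistic on random scores
  set.seed(40)
  for (rep in 1:5) {
    lab <- runif(25) < 0.4
    if (!any(lab) || all(lab)) next
    sc <- round(runif(25), 1)  # ties on purpose
    pos <- sc[lab]; neg <- sc[!lab]
    conc <- mean(outer(pos, neg, function(a, b)
      (a < b) + 0.5 * (a == b)))
    expect_equal(roc_pr(lab, sc)$auc, conc, tolerance = 1e-12)
  }
  # monotone transforms leave the AUC unchanged
  lab <- runif(40) < 0.5
  sc <- runif(40)
  expect_equal(roc_pr(lab, sc)$auc, roc_pr(lab, sc^3)$auc)
  expect_error(roc_pr(rep(TRUE, 4), runif(4)), "both classes")
})

test_that("random scores give AUC near one half", {
  set.seed(41)
  lab <- rep(c(TRUE, FALSE), 500)
  aucs <- vapply(1:20, function(i) roc_pr(lab, runif(1000))$auc, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("ROC curves are monotone and agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(42)
  lab <- runif(60) < 0.5
  sc <- runif(60)
  res <- roc_pr(lab, sc)
  expect_true(all(diff(res$roc$fpr) >= 0))
  expect_true(all(diff(res$roc$tpr) >= 0))
  ref <- pROC::auc(pROC::roc(lab, sc, direction = ">", quiet = TRUE))
  expect_equal(res$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("uncertainty-quantile RMSE is a prefix statistic", {
  fx <- eval_fixture(11)
  tab <- error_table(fx$plan, impute_median(fx$trainZ), "M", fx$ds)
  set.seed(50)
  tab$sigma <- runif(nrow(tab))
  out <- uncertainty_quantile_rmse(tab, quantiles = c(0.25, 0.5, 1))
  expect_equal(out$rmse[out$quantile == 1], dataset_rmse(tab))
  ord <- order(tab$sigma)
  m <- ceiling(0.25 * nrow(tab))
  expect_equal(out$rmse[out$quantile == 0.25],
               sqrt(mean(tab$abs_error[ord][1:m]^2)))
  # sigma perfectly ranked with |error| makes the curve non-decreasing
  tab$sigma <- rank(tab$abs_error)
  out2 <- uncertainty_quantile_rmse(tab, quantiles = c(0.25, 0.5, 0.75, 1))
  expect_true(all(diff(out2$rmse) >= 0))
  tab$sigma[1] <- NA
  expect_error(uncertainty_quantile_rmse(tab), "sigma required")
})

test_that("uncertainty filtering reduces to its two limit cases", {
  gen <- make_benchmark_fixture("small")
  ds <- gen$dataset
  # fabricate an imputation_result without training: median fills + fake sigma
  std <- log_standardize(ds)
  filled <- impute_median(std$matrix)
  obs <- !is.na(std$matrix)
  set.seed(60)
  sigma2 <- matrix(runif(length(filled), 0.01, 1), nrow(filled))
  res <- structure(list(
    completed = ifelse(obs, ds$abundance, inverse_transform(filled, std$state)),
    mu = filled, sigma2 = sigma2,
    provenance = ifelse(obs, "observed", "imputed"),
    uncertainty = ifelse(obs, NA, sqrt(sigma2)),
    state = std$state), class = "imputation_result")
  groups <- setNames(rep(c("a", "b"), length.out = ncol(filled)),
                     ds$sample_ids)
  labels <- gen$truth$de_labels
  labels[seq_len(20)] <- TRUE  # ensure both classes for the single-condition fixture
  hi <- uncertainty_filtered_de(res, groups, Inf, labels)
  lo <- uncertainty_filtered_de(res, groups, 1e-9, labels)
  # threshold above all sigmas = unfiltered; below all = unimputed matrix
  unfiltered <- welch_de(filled, groups)
  expect_equal(hi$de$table$p, unfiltered$table$p)
  expect_equal(hi$n_filtered, 0)
  Mun <- std$matrix
  unimputed <- welch_de(Mun, groups)
  expect_equal(lo$de$table$p, unimputed$table$p, tolerance = 1e-12)
  expect_equal(lo$n_filtered, sum(!obs))
  expect_error(uncertainty_filtered_de(res, groups, -1, labels), "positive")
})
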