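# Evaluation surfaces: abundance error tables and metrics, paired
# signed-rank method comparison, differential-expression ROC analysis, and
# uncertainty diagnostics.

#' Build an error table for one method on a mask plan
#'
#' One row per test position: the predicted and true (standardized log-scale)
#' values, the absolute error, peptide/sample ids, the peptide's missingness
#' fraction in the source dataset (before any evaluation masking), and the
#' predicted sigma where the method provides one.
#'
#' @param plan the shared [mask_plan].
#' @param imputed_std completed matrix on the standardized log scale (e.g. a
#'   baseline output, or the `mu` matrix of a GNN [impute_gnn()] result).
#' @param method method name recorded in the table.
#' @param ds the source [peptide_dataset()] (for ids and missingness
#'   fractions).
#' @param sigma optional matrix of predicted standard deviations.
#' @return `data.frame` of class `error_table`.
#' @export
error_table <- function(plan, imputed_std, method, ds, sigma = NULL) {
  idx <- plan$test_idx
  pred <- imputed_std[idx]
  miss_frac <- rowMeans(is.na(ds$abundance))
  df <- data.frame(
    method = method,
    peptide_id = ds$peptide_ids[idx[, 1L]],
    sample_id = ds$sample_ids[idx[, 2L]],
    row = idx[, 1L], col = idx[, 2L],
    predicted = pred, truth = plan$truth_test,
    abs_error = abs(pred - plan$truth_test),
    miss_frac = miss_frac[idx[, 1L]],
    sigma = if (is.null(sigma)) NA_real_ else sigma[idx],
    stringsAsFactors = FALSE)
  class(df) <- c("error_table", "data.frame")
  df
}

#' Sample-wise RMSE
#'
#' RMSE of a method's test-position errors computed separately per sample,
#' which provides the replicate structure needed for variance estimates and
#' bootstrap confidence intervals.
#'
#' @param errors an [error_table()].
#' @return Named numeric vector of per-sample RMSE values (samples with no
#'   test position are omitted, with a warning if any exist).
#' @export
samplewise_rmse <- function(errors) {
  if (!nrow(errors)) stop("empty error table")
  out <- vapply(split(errors$abs_error, errors$sample_id),
                function(e) sqrt(mean(e^2)), numeric(1))
  out
}

#' Dataset-wise mean absolute error
#' @param errors an [error_table()].
#' @return scalar MAE over all test positions.
#' @export
dataset_mae <- function(errors) {
  if (!nrow(errors)) stop("empty error table")
  mean(errors$abs_error)
}

#' Dataset-wise RMSE over all test positions
#' @param errors an [error_table()].
#' @return scalar RMSE.
#' @export
dataset_rmse <- function(errors) {
  if (!nrow(errors)) stop("empty error table")
  sqrt(mean(errors$abs_error^2))
}

#' Nonparametric percentile bootstrap confidence interval
#'
#' @param values numeric vector (e.g. per-sample RMSEs).
#' @param level confidence level (default 0.95).
#' @param reps bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return Length-2 numeric `(low, high)`.
#' @export
bootstrap_ci <- function(values, level = 0.95, reps = 1000L, seed = 1L) {
  if (length(values) < 2L) stop("need at least 2 values to bootstrap")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  means <- vapply(seq_len(reps), function(r)
    mean(sample(values, length(values), replace = TRUE)), numeric(1))
  a <- (1 - level) / 2
  unname(quantile(means, c(a, 1 - a), names = FALSE))
}

#' Pairwise signed-rank comparison of imputation methods
#'
#' For every ordered pair of methods (A, B), a one-sided paired Wilcoxon
#' signed-rank test of the alternative "A's absolute errors are smaller than
#' B's" over the shared test positions; p-values are Bonferroni-corrected
#' over all `k(k-1)` ordered pairs. Win counts follow the tournament rule:
#' a significant win (corrected p < alpha) scores 1 for the winner, an
#' insignificant comparison scores 0.5 for both methods. Zero differences
#' are dropped before ranking (classic Wilcoxon handling); an all-zero
#' comparison yields p = 1 by convention.
#'
#' @param error_tables named list of [error_table()]s for k >= 2 methods,
#'   all evaluated on the identical test-position set.
#' @param alpha significance level after correction (default 0.05).
#' @return list with `p_matrix` (k x k corrected p-values, `p_matrix[A, B]`
#'   testing "A better than B"; diagonal `NA`) and `win_counts`.
#' @export
pairwise_wilcoxon_matrix <- function(error_tables, alpha = 0.05) {
  k <- length(error_tables)
  if (k < 2L) stop("need at least two methods")
  nms <- names(error_tables)
  key <- function(tab) paste(tab$row, tab$col)
  ref <- key(error_tables[[1L]])
  for (tab in error_tables)
    if (!identical(key(tab), ref))
      stop("all methods must be evaluated on the identical test set")
  n_pairs <- k * (k - 1L)
  p_mat <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) next
    d <- error_tables[[a]]$abs_error - error_tables[[b]]$abs_error
    d <- d[d != 0]
    p <- if (!length(d)) 1 else
      suppressWarnings(wilcox.test(d, alternative = "less")$p.value)
    p_mat[a, b] <- min(1, p * n_pairs)
  }
  wins <- setNames(numeric(k), nms)
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    if (p_mat[a, b] < alpha) {
      wins[a] <- wins[a] + 1
    } else if (p_mat[b, a] < alpha) {
      wins[b] <- wins[b] + 1
    } else {
      wins[a] <- wins[a] + 0.5
      wins[b] <- wins[b] + 0.5
    }
  }
  list(p_matrix = p_mat, win_counts = wins)
}

#' RMSE stratified by peptide missingness fraction
#'
#' Test positions are binned by their peptide's fraction of missing values in
#' the source dataset; RMSE is reported per bin. Bins are half-open
#' `[lo, hi)` except the last, which is closed.
#'
#' @param errors an [error_table()].
#' @param bins increasing vector of bin edges partitioning `[0, 1]`.
#' @return `data.frame` with `bin`, `n` and `rmse` (empty bins omitted).
#' @export
stratified_rmse <- function(errors, bins = c(0, 0.25, 0.5, 0.75, 1)) {
  if (bins[1L] > 0 || bins[length(bins)] < 1 || is.unsorted(bins, strictly = TRUE))
    stop("bins must be increasing edges partitioning [0, 1]")
  cut_idx <- findInterval(errors$miss_frac, bins, rightmost.closed = TRUE)
  labels <- paste0("[", head(bins, -1L), ",", bins[-1L],
                   c(rep(")", length(bins) - 2L), "]"))
  out <- do.call(rbind, lapply(seq_len(length(bins) - 1L), function(b) {
    e <- errors$abs_error[cut_idx == b]
    if (!length(e)) return(NULL)
    data.frame(bin = labels[b], n = length(e), rmse = sqrt(mean(e^2)))
  }))
  if (is.null(out)) stop("no test positions fell into any bin")
  out
}

#' Welch's t-test per peptide between two sample groups
#'
#' Vectorized Welch statistic with Welch-Satterthwaite degrees of freedom,
#' two-sided p-values and Benjamini-Hochberg adjustment across all tested
#' peptides. Peptides with fewer than two observed values in either group are
#' excluded from testing and reported separately.
#'
#' @param mat matrix of (possibly partially missing) abundance values on any
#'   fixed scale (the statistic is scale-invariant), peptides in rows.
#' @param groups named character vector mapping each column (sample) to one
#'   of exactly two condition labels.
#' @return list with `table` (`data.frame`: peptide row, n per group, t, df,
#'   p, q) and `excluded` (row indices failing the >= 2-per-group rule).
#' @export
welch_de <- function(mat, groups) {
  if (is.null(colnames(mat)) && !is.null(names(groups)))
    colnames(mat) <- names(groups)[seq_len(ncol(mat))]
  g <- groups[colnames(mat)]
  if (anyNA(g)) stop("groups must cover all sample columns")
  lev <- unique(g)
  if (length(lev) != 2L) stop("need exactly two conditions")
  m1 <- mat[, g == lev[1L], drop = FALSE]
  m2 <- mat[, g == lev[2L], drop = FALSE]
  n1 <- rowSums(!is.na(m1)); n2 <- rowSums(!is.na(m2))
  ok <- n1 >= 2L & n2 >= 2L
  mu1 <- rowMeans(m1, na.rm = TRUE); mu2 <- rowMeans(m2, na.rm = TRUE)
  v1 <- apply(m1, 1, var, na.rm = TRUE); v2 <- apply(m2, 1, var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mu1 - mu2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  zero <- which(ok & se2 == 0)  # constant groups: t undefined
  p[zero] <- ifelse(mu1[zero] == mu2[zero], 1, 0)
  tab <- data.frame(row = which(ok), n1 = n1[ok], n2 = n2[ok],
                    t = tstat[ok], df = df[ok], p = p[ok])
  tab$q <- p.adjust(tab$p, method = "BH")
  list(table = tab, excluded = which(!ok))
}

#' ROC and precision-recall curves from per-peptide significance scores
#'
#' Scores are significance values (e.g. BH-adjusted q-values): smaller means
#' "called differential". The threshold sweep groups tied scores into single
#' steps; AUC is the trapezoidal area. The operating point at
#' `score <= fdr_mark` is reported for marking on the curve.
#'
#' @param labels logical (or 0/1) vector of ground-truth differential status.
#' @param scores numeric vector of the same length; both classes must be
#'   present in `labels`.
#' @param fdr_mark threshold for the marked operating point (default 0.05).
#' @return list with `roc` (`data.frame` fpr/tpr/threshold), `auc`,
#'   `pr` (`data.frame` recall/precision), `pr_auc` and `operating_point`.
#' @export
roc_pr <- function(labels, scores, fdr_mark = 0.05) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores)) stop("length mismatch")
  if (!any(labels) || all(labels)) stop("both classes must be present")
  ord <- order(scores)
  sc <- scores[ord]; lb <- labels[ord]
  np <- sum(lb); nn <- sum(!lb)
  tp <- cumsum(lb); fp <- cumsum(!lb)
  last <- !duplicated(sc, fromLast = TRUE)  # one step per distinct score
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  thr <- c(-Inf, sc[last])
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
  prec <- c(1, (tp[last] / (tp[last] + fp[last])))
  rec <- tpr
  pr_auc <- sum(diff(rec) * (head(prec, -1L) + prec[-1L]) / 2)
  op_i <- which(thr <= fdr_mark)
  op <- c(fpr = fpr[max(op_i)], tpr = tpr[max(op_i)])
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc,
       pr = data.frame(recall = rec, precision = prec), pr_auc = pr_auc,
       operating_point = op)
}

#' RMSE over increasing uncertainty quantiles
#'
#' Test positions are sorted by predicted sigma; for each quantile `q` the
#' RMSE over the lowest-sigma fraction `q` of positions is reported. If the
#' predicted uncertainty is informative the curve increases with `q`, and
#' `q = 1` equals the overall RMSE.
#'
#' @param errors an [error_table()] with a `sigma` column.
#' @param quantiles increasing quantile levels in (0, 1].
#' @return `data.frame` with `quantile`, `n` and `rmse`.
#' @export
uncertainty_quantile_rmse <- function(errors,
                                      quantiles = c(0.25, 0.5, 0.75, 1)) {
  if (anyNA(errors$sigma)) stop("sigma required for all test positions")
  ord <- order(errors$sigma)
  e <- errors$abs_error[ord]
  do.call(rbind, lapply(quantiles, function(qq) {
    m <- max(1L, as.integer(ceiling(qq * length(e))))
    data.frame(quantile = qq, n = m, rmse = sqrt(mean(e[seq_len(m)]^2)))
  }))
}

#' Differential-expression analysis after uncertainty filtering
#'
#' Imputed entries whose predicted sigma exceeds `threshold` are reverted to
#' missing, and the Welch/BH analysis is re-run on the partially completed
#' matrix. Peptides that then fail the two-per-group rule are excluded from
#' ROC scoring (they have no score), unless `score_excluded_as_one = TRUE`
#' in which case they enter with q = 1.
#'
#' @param result an [impute_gnn()] `imputation_result`.
#' @param groups sample-to-condition map with exactly two conditions.
#' @param threshold sigma cutoff (> 0) on the standardized log scale;
#'   `Inf` reproduces the unfiltered analysis.
#' @param labels ground-truth differential labels per peptide row.
#' @param score_excluded_as_one include excluded peptides with score 1?
#' @return list with `de` (the [welch_de()] output), `roc` (a [roc_pr()]
#'   result over the scored peptides), `threshold`, `n_filtered` and
#'   `n_excluded`.
#' @export
uncertainty_filtered_de <- function(result, groups, threshold, labels,
                                    score_excluded_as_one = FALSE) {
  stopifnot(inherits(result, "imputation_result"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive")
  M <- result$mu
  obs <- result$provenance == "observed"
  # observed values on the standardized scale; imputed values = mu
  M[obs] <- (log(result$completed[obs]) - result$state$mean) / result$state$sd
  drop <- !obs & result$uncertainty > threshold
  M[drop] <- NA
  de <- welch_de(M, groups)
  scored <- de$table$row
  lab <- labels[scored]
  sc <- de$table$q
  if (score_excluded_as_one && length(de$excluded)) {
    lab <- c(lab, labels[de$excluded])
    sc <- c(sc, rep(1, length(de$excluded)))
  }
  roc <- roc_pr(lab, sc)
  list(de = de, roc = roc, threshold = threshold,
       n_filtered = sum(drop), n_excluded = length(de$excluded))
}
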