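#' Mask plans: held-out ground truth for imputation evaluation
#'
#' A `mask_plan` records which matrix positions form the test and validation
#' sets, the ground-truth values at those positions on the standardized log
#' scale, the mechanism that produced them (`"masked"` for random masking of
#' observed values, `"dda_dia"` for orthogonal DIA ground truth) and the
#' [log_standardize()] state of the source dataset. All imputers in a
#' benchmark run share one plan so their errors are paired position by
#' position.
#'
#' @name mask_plan
NULL

new_mask_plan <- function(test_idx, val_idx, truth_test, truth_val,
                          mechanism, state, dim) {
  colnames(test_idx) <- colnames(val_idx) <- c("row", "col")
  structure(list(test_idx = test_idx, val_idx = val_idx,
                 truth_test = truth_test, truth_val = truth_val,
                 mechanism = mechanism, state = state, dim = dim),
            class = "mask_plan")
}

#' @export
print.mask_plan <- function(x, ...) {
  cat(sprintf("mask_plan (%s): %d test, %d validation positions on %d x %d\n",
              x$mechanism, nrow(x$test_idx), nrow(x$val_idx),
              x$dim[1L], x$dim[2L]))
  invisible(x)
}

idx_to_linear <- function(idx, nrow) (idx[, 2L] - 1L) * nrow + idx[, 1L]

linear_to_idx <- function(lin, nrow) {
  cbind(row = ((lin - 1L) %% nrow) + 1L, col = ((lin - 1L) %/% nrow) + 1L)
}

# floor(frac * count) with a minimum of one position
split_size <- function(frac, count) {
  if (frac <= 0 || frac >= 1) stop("fraction must lie in (0, 1)")
  max(1L, as.integer(floor(frac * count)))
}

#' Create a random-masking evaluation split
#'
#' Draws a test set uniformly at random from the observed entries of the
#' dataset, then a validation set uniformly from the remaining observed
#' entries. Ground truth is the standardized log-scale value at each masked
#' position. Set sizes are `floor(frac * available)` with a minimum of one.
#'
#' @param ds a [peptide_dataset()].
#' @param test_frac fraction of observed entries for the test set.
#' @param val_frac fraction of the *remaining* observed entries for the
#'   validation set.
#' @param seed integer seed; the split is fully reproducible.
#' @return A [mask_plan] with mechanism `"masked"`.
#' @export
make_masked_split <- function(ds, test_frac = 0.10, val_frac = 0.10, seed) {
  if (missing(seed)) stop("seed is required for a reproducible split")
  std <- log_standardize(ds)
  Z <- std$matrix
  n <- nrow(Z)
  obs_lin <- which(!is.na(Z))
  if (length(obs_lin) < 2L) stop("not enough observed entries to split")
  n_test <- split_size(test_frac, length(obs_lin))
  withr_seed <- seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)
  test_lin <- sort(sample(obs_lin, n_test))
  rest <- setdiff(obs_lin, test_lin)
  if (!length(rest)) stop("no observed entries left for validation")
  n_val <- split_size(val_frac, length(rest))
  val_lin <- sort(sample(rest, n_val))
  new_mask_plan(linear_to_idx(test_lin, n), linear_to_idx(val_lin, n),
                Z[test_lin], Z[val_lin], "masked", std$state, dim(Z))
}

# save/restore the global RNG so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Create a DDA/DIA evaluation split
#'
#' For paired acquisitions of the same samples, the more complete DIA run
#' provides orthogonal ground truth for values genuinely missing in the DDA
#' run. Peptides and samples are intersected; DIA log-values are shifted so
#' their observed mean matches the DDA observed log-mean (an additive shift on
#' the log scale, i.e. a multiplicative rescaling of raw intensities). Test
#' positions are those missing in DDA but observed in the scaled DIA matrix;
#' the validation set is drawn from the observed DDA entries as in
#' [make_masked_split()].
#'
#' @param dda,dia [peptide_dataset()] objects sharing peptide and sample ids.
#' @param val_frac validation fraction of observed DDA entries.
#' @param seed integer seed for the validation draw.
#' @param scale one of `"log_additive"` (default) or `"raw_multiplicative"`;
#'   how the DIA-to-DDA mean matching is performed.
#' @return list with `scaled_dia` (raw-scale DIA matrix after mean matching,
#'   aligned to the intersected DDA layout) and `plan`, a [mask_plan] with
#'   mechanism `"dda_dia"` whose state comes from the intersected DDA data.
#' @export
make_dda_dia_split <- function(dda, dia, val_frac = 0.10, seed,
                               scale = c("log_additive", "raw_multiplicative")) {
  if (missing(seed)) stop("seed is required")
  scale <- match.arg(scale)
  peps <- intersect(dda$peptide_ids, dia$peptide_ids)
  samps <- intersect(dda$sample_ids, dia$sample_ids)
  if (!length(peps) || !length(samps))
    stop("empty peptide/sample intersection between DDA and DIA")
  if (length(peps) < length(union(dda$peptide_ids, dia$peptide_ids)) ||
      length(samps) < length(union(dda$sample_ids, dia$sample_ids)))
    warning("DDA/DIA ids only partially overlap; dropping non-shared entries")
  A_dda <- dda$abundance[peps, samps, drop = FALSE]
  A_dia <- dia$abundance[peps, samps, drop = FALSE]
  keep <- lapply(match(peps, dda$peptide_ids), function(i) dda$protein_groups[[i]])
  ds_dda <- peptide_dataset(A_dda, peps, keep, samps,
                            dda$sample_groups[samps])
  std <- log_standardize(ds_dda)
  if (scale == "log_additive") {
    shift <- mean(log(A_dda[!is.na(A_dda)])) - mean(log(A_dia[!is.na(A_dia)]))
    scaled_dia <- exp(log(A_dia) + shift)
  } else {
    fac <- mean(A_dda[!is.na(A_dda)]) / mean(A_dia[!is.na(A_dia)])
    scaled_dia <- A_dia * fac
  }
  test_lin <- which(is.na(A_dda) & !is.na(scaled_dia))
  if (!length(test_lin)) stop("no position is missing in DDA but observed in DIA")
  truth_test <- (log(scaled_dia[test_lin]) - std$state$mean) / std$state$sd
  obs_lin <- which(!is.na(A_dda))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_val <- split_size(val_frac, length(obs_lin))
  val_lin <- sort(sample(obs_lin, n_val))
  plan <- new_mask_plan(linear_to_idx(test_lin, nrow(A_dda)),
                        linear_to_idx(val_lin, nrow(A_dda)),
                        truth_test, std$matrix[val_lin],
                        "dda_dia", std$state, dim(A_dda))
  list(scaled_dia = scaled_dia, plan = plan, dataset = ds_dda)
}

#' Training view of a standardized matrix under a mask plan
#'
#' Sets all test and validation positions to missing so that neither the GNN
#' imputer nor any baseline can see held-out ground truth.
#'
#' @param z standardized log-scale matrix of the plan's source dataset.
#' @param plan a [mask_plan].
#' @return The matrix with test/validation positions set to `NA`.
#' @export
apply_mask_plan <- function(z, plan) {
  stopifnot(inherits(plan, "mask_plan"), all(dim(z) == plan$dim))
  z[rbind(plan$test_idx, plan$val_idx)] <- NA
  z
}

#' Serialize / read a mask plan as TSV (for audit of benchmark runs)
#' @param plan a [mask_plan].
#' @param path output path.
#' @export
write_mask_plan <- function(plan, path) {
  df <- rbind(
    data.frame(set = "test", row = plan$test_idx[, 1L],
               col = plan$test_idx[, 2L], truth = plan$truth_test),
    data.frame(set = "val", row = plan$val_idx[, 1L],
               col = plan$val_idx[, 2L], truth = plan$truth_val))
  header <- sprintf("# mechanism=%s nrow=%d ncol=%d mean=%.17g sd=%.17g",
                    plan$mechanism, plan$dim[1L], plan$dim[2L],
                    plan$state$mean[1L], plan$state$sd[1L])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(format(df, digits = 17, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
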