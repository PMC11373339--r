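#' Construct a peptide abundance dataset
#'
#' The central container of the package: an `n x s` matrix of raw-scale
#' peptide intensities (strictly positive where observed, `NA` where missing)
#' together with the peptide-to-protein mapping and optional sample group
#' labels. Peptides may map to more than one protein (shared peptides); the
#' mapping is what induces the peptide-peptide graph used by the GNN imputer.
#'
#' @param abundance numeric matrix, peptides in rows, samples in columns.
#'   Missing values as `NA`; all observed values must be strictly positive
#'   (raw measurement scale, not log).
#' @param peptide_ids character vector of unique peptide identifiers
#'   (typically the amino-acid sequence), one per row.
#' @param protein_groups list of character vectors, one per peptide; each the
#'   non-empty set of protein accessions the peptide maps to.
#' @param sample_ids character vector of unique sample names, one per column.
#' @param sample_groups optional named character vector mapping sample id to
#'   condition label (used for differential-expression evaluation).
#' @return An object of class `peptide_dataset` with fields `abundance`,
#'   `peptide_ids`, `protein_groups`, `sample_ids`, `sample_groups`.
#' @export
peptide_dataset <- function(abundance, peptide_ids, protein_groups,
                            sample_ids = colnames(abundance),
                            sample_groups = NULL) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  n <- nrow(abundance)
  s <- ncol(abundance)
  if (n < 1L) stop("dataset must contain at least one peptide")
  if (s < 2L) stop("dataset must contain at least two samples")
  if (length(peptide_ids) != n) stop("peptide_ids length must match row count")
  if (anyDuplicated(peptide_ids)) stop("duplicate peptide ids")
  if (length(protein_groups) != n) stop("protein_groups length must match row count")
  protein_groups <- lapply(protein_groups, function(p) unique(as.character(p)))
  if (any(vapply(protein_groups, length, 1L) == 0L))
    stop("every peptide must map to at least one protein")
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(s))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != s || anyDuplicated(sample_ids))
    stop("sample_ids must be unique and match column count")
  obs <- abundance[!is.na(abundance)]
  if (length(obs) && any(obs <= 0))
    stop("all observed abundances must be strictly positive (raw scale)")
  if (!is.null(sample_groups)) {
    sample_groups <- sample_groups[sample_ids]
    if (anyNA(sample_groups)) stop("sample_groups must cover all sample_ids")
    names(sample_groups) <- sample_ids
  }
  dimnames(abundance) <- list(peptide_ids, sample_ids)
  structure(
    list(abundance = abundance, peptide_ids = as.character(peptide_ids),
         protein_groups = protein_groups, sample_ids = sample_ids,
         sample_groups = sample_groups),
    class = "peptide_dataset")
}

#' @export
print.peptide_dataset <- function(x, ...) {
  n_miss <- sum(is.na(x$abundance))
  cat(sprintf("peptide_dataset: %d peptides x %d samples, %.1f%% missing\n",
              nrow(x$abundance), ncol(x$abundance),
              100 * n_miss / length(x$abundance)))
  n_prot <- length(unique(unlist(x$protein_groups)))
  cat(sprintf("  %d proteins; %d shared peptides\n", n_prot,
              sum(vapply(x$protein_groups, length, 1L) > 1L)))
  if (!is.null(x$sample_groups))
    cat("  groups:", paste(unique(x$sample_groups), collapse = ", "), "\n")
  invisible(x)
}

#' Table dialect for wide peptide tables
#'
#' Describes how a wide peptide table on disk is interpreted. Defaults follow
#' the MaxQuant `peptides.txt` conventions: tab separation, `;`-separated
#' protein accessions, and intensities of zero treated as missing.
#'
#' @param sep field separator.
#' @param peptide_col name of the peptide id column.
#' @param protein_col name of the protein group column.
#' @param protein_sep separator between accessions within the protein column.
#' @param missing_tokens character values parsed as missing in sample columns.
#' @param zero_as_missing should numeric zeros be treated as missing?
#' @return A list of class `table_dialect`.
#' @export
table_dialect <- function(sep = "\t", peptide_col = "peptide_id",
                          protein_col = "protein_groups", protein_sep = ";",
                          missing_tokens = c("", "NA", "NaN"),
                          zero_as_missing = TRUE) {
  structure(list(sep = sep, peptide_col = peptide_col,
                 protein_col = protein_col, protein_sep = protein_sep,
                 missing_tokens = missing_tokens,
                 zero_as_missing = zero_as_missing),
            class = "table_dialect")
}

#' Read a wide peptide table
#'
#' Parses a TSV/CSV with one row per peptide: an id column, a protein-group
#' column (accessions separated by `dialect$protein_sep`), and at least two
#' numeric sample columns. Blank cells, listed missing tokens and (by default)
#' zeros become missing values.
#'
#' @param path path to the table.
#' @param dialect a [table_dialect()].
#' @return A [peptide_dataset()].
#' @export
load_peptide_table <- function(path, dialect = table_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = dialect$sep, header = TRUE,
                   check.names = FALSE, colClasses = "character",
                   na.strings = NULL, stringsAsFactors = FALSE)
  need <- c(dialect$peptide_col, dialect$protein_col)
  if (!all(need %in% names(df)))
    stop("malformed header: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  sample_cols <- setdiff(names(df), need)
  if (length(sample_cols) < 2L)
    stop("dimension error: need at least 2 sample columns, found ",
         length(sample_cols))
  ids <- df[[dialect$peptide_col]]
  if (anyDuplicated(ids)) stop("duplicate peptide id: ",
                               ids[duplicated(ids)][1L])
  prot <- strsplit(df[[dialect$protein_col]], dialect$protein_sep, fixed = TRUE)
  mat <- vapply(sample_cols, function(cn) {
    v <- df[[cn]]
    v[v %in% dialect$missing_tokens] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(out)
    if (any(bad)) stop("non-numeric value '", v[bad][1L],
                       "' in sample column ", cn)
    out
  }, numeric(nrow(df)))
  mat <- matrix(mat, nrow = nrow(df),
                dimnames = list(ids, sample_cols))
  if (isTRUE(dialect$zero_as_missing)) mat[!is.na(mat) & mat == 0] <- NA
  peptide_dataset(mat, ids, prot, sample_cols)
}

#' Write a peptide dataset as a wide table
#'
#' Inverse of [load_peptide_table()]: emits peptide id, `;`-joined protein
#' groups, then one column per sample. Missing values are written as `NA`.
#'
#' @param ds a [peptide_dataset()].
#' @param path output path.
#' @param dialect a [table_dialect()] (separator and column names are used).
#' @export
write_peptide_table <- function(ds, path, dialect = table_dialect()) {
  df <- data.frame(
    id = ds$peptide_ids,
    prot = vapply(ds$protein_groups, paste, "", collapse = dialect$protein_sep),
    check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(dialect$peptide_col, dialect$protein_col)
  ab <- ds$abundance
  for (j in seq_len(ncol(ab))) df[[ds$sample_ids[j]]] <- ab[, j]
  write.table(df, path, sep = dialect$sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read peptide sequences from a FASTA file
#'
#' @param path FASTA path; record names must match the dataset's peptide ids.
#' @return Named character vector of amino-acid sequences.
#' @export
read_peptide_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}

#' Write peptide sequences to a FASTA file
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_peptide_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read sample-group metadata
#'
#' Two-column tab-separated file `sample_id<TAB>group`.
#' @param path path to the file.
#' @return Named character vector mapping sample id to group label.
#' @export
read_sample_groups <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) stop("sample-group file needs two columns")
  setNames(df[[2L]], df[[1L]])
}

#' Write sample-group metadata
#' @param groups named character vector (names = sample ids).
#' @param path output path.
#' @export
write_sample_groups <- function(groups, path) {
  write.table(data.frame(sample_id = names(groups), group = unname(groups)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-transform and standardize an abundance matrix
#'
#' Takes natural logarithms of all observed entries and standardizes them to
#' zero mean and unit variance with a single global mean and standard
#' deviation computed over all observed entries (missing values are ignored).
#' All model fitting and all baseline imputers operate on this scale.
#'
#' @param x a [peptide_dataset()] or a raw-scale numeric matrix with `NA`
#'   missing values.
#' @param per_sample if `TRUE`, standardize each sample column separately
#'   (off by default; the global scheme matches the matrix-level model).
#' @return list with `matrix` (standardized log-scale, `NA` preserved) and
#'   `state`, a `transform_state` holding the global mean and sd (or the
#'   per-sample vectors) needed by [inverse_transform()].
#' @export
log_standardize <- function(x, per_sample = FALSE) {
  A <- if (inherits(x, "peptide_dataset")) x$abundance else as.matrix(x)
  obs <- !is.na(A)
  if (!any(obs)) stop("all entries missing; cannot standardize")
  if (any(A[obs] <= 0)) stop("non-positive abundance: log transform undefined")
  L <- A
  L[obs] <- log(A[obs])
  if (per_sample) {
    m <- apply(L, 2, function(v) mean(v, na.rm = TRUE))
    s <- apply(L, 2, function(v) sd(v, na.rm = TRUE))
    if (any(!is.finite(s)) || any(s == 0))
      stop("degenerate data: zero variance in a sample column")
    Z <- sweep(sweep(L, 2, m, "-"), 2, s, "/")
  } else {
    m <- mean(L[obs])
    s <- sd(L[obs])
    if (!is.finite(s) || s == 0) stop("degenerate data: zero variance")
    Z <- (L - m) / s
  }
  state <- structure(list(mean = m, sd = s, per_sample = per_sample),
                     class = "transform_state")
  list(matrix = Z, state = state)
}

#' Map a standardized log-scale matrix back to the raw scale
#'
#' Elementwise `exp(z * sd + mean)`; missing values stay missing.
#'
#' @param z standardized log-scale matrix.
#' @param state the `transform_state` returned by [log_standardize()].
#' @return Raw-scale matrix of the same shape.
#' @export
inverse_transform <- function(z, state) {
  stopifnot(inherits(state, "transform_state"))
  z <- as.matrix(z)
  if (isTRUE(state$per_sample)) {
    if (ncol(z) != length(state$mean)) stop("shape mismatch with state")
    exp(sweep(sweep(z, 2, state$sd, "*"), 2, state$mean, "+"))
  } else {
    exp(z * state$sd + state$mean)
  }
}
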