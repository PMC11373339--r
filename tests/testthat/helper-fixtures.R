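# Shared test fixtures, all built in code.

# unique amino-acid-alphabet id for row i (so hash embeddings work)
aa_id <- function(i, prefix = "PEP") {
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  suffix <- character(0)
  i <- i - 1
  repeat {
    suffix <- c(alpha[i %% 20 + 1], suffix)
    i <- i %/% 20
    if (i == 0) break
  }
  paste0(prefix, paste(suffix, collapse = ""), "K")
}

# tiny hand-made dataset: 4 peptides (two proteins, one shared), 4 samples
tiny_dataset <- function() {
  A <- matrix(c(
    10, 12, 11, NA,
    9, NA, 10, 11,
    100, 110, NA, 105,
    50, 55, 52, 51), nrow = 4, byrow = TRUE)
  peptide_dataset(A,
                  peptide_ids = c("AAAK", "CCCR", "DDDK", "EEER"),
                  protein_groups = list("P1", c("P1", "P2"), "P2", "P3"),
                  sample_ids = paste0("S", 1:4))
}

# random dataset with given protein membership structure, raw scale
random_dataset <- function(n_prot = 5, pep_per = 3, s = 6, miss = 0.2,
                           seed = 1) {
  set.seed(seed)
  n <- n_prot * pep_per
  A <- matrix(exp(rnorm(n * s, 10, 1)), n, s)
  A[matrix(runif(n * s) < miss, n, s)] <- NA
  # keep at least one observed value per column and row
  for (j in seq_len(s)) if (all(is.na(A[, j]))) A[1, j] <- exp(10)
  for (i in seq_len(n)) if (all(is.na(A[i, ]))) A[i, 1] <- exp(10)
  peptide_dataset(A, vapply(seq_len(n), aa_id, ""),
                  as.list(sprintf("P%d", rep(seq_len(n_prot), each = pep_per))),
                  sprintf("S%d", seq_len(s)))
}

# random membership table for graph oracle tests: each peptide gets 1-2
# proteins drawn from a pool
random_membership <- function(n, n_prot, p_shared = 0.2, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- 1L + (runif(1) < p_shared)
    sample(sprintf("P%d", seq_len(n_prot)), k)
  })
}

membership_dataset <- function(protein_groups, s = 3, seed = 1) {
  set.seed(seed)
  n <- length(protein_groups)
  A <- matrix(exp(rnorm(n * s, 8, 1)), n, s)
  peptide_dataset(A, vapply(seq_len(n), aa_id, "", prefix = "SEQ"),
                  protein_groups,
                  sprintf("S%d", seq_len(s)))
}

# brute-force O(n^2) edge set: pairs with intersecting protein sets
brute_force_edges <- function(protein_groups) {
  n <- length(protein_groups)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (length(intersect(protein_groups[[i]], protein_groups[[j]])))
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

# matrix with controlled missingness on the standardized scale
std_test_matrix <- function(n = 30, s = 6, miss = 0.2, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * s), n, s)
  A[matrix(runif(n * s) < miss, n, s)] <- NA
  for (j in seq_len(s)) if (all(is.na(A[, j]))) A[1, j] <- 0
  A
}
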