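# Seeded generative model of bottom-up proteomics peptide tables. It
# reproduces the statistical structure the GNN imputer exploits -- correlated
# peptide abundances within protein cliques, shared peptides bridging
# proteins, heteroscedastic log-normal noise, MCAR and abundance-dependent
# MNAR missingness, two-condition spike-in designs and informative-but-noisy
# sequence embeddings -- and carries complete ground truth for every
# evaluation surface.

#' Specification of a synthetic peptide dataset
#'
#' The hierarchical model on the natural-log scale: each protein gets a base
#' level `b_p ~ N(base_mean, base_sd^2)` and per-sample biological effects
#' `u_pj ~ N(0, protein_sd^2)`; proteins selected as differential
#' additionally get `de_effect` added in condition-2 samples. Peptide `i` of
#' protein `p` has log-abundance
#' `y_ij = b_p + u_pj (+ effect) + o_i + e_ij` with a peptide-specific
#' ionization offset `o_i ~ N(0, peptide_offset_sd^2)` and heteroscedastic
#' noise `e_ij ~ N(0, sd_i^2)`, `sd_i ~ U(noise_sd_range)`. A fraction of
#' peptides is shared between two proteins and receives the average of both
#' parents' protein-level signals. Missingness is the union of an i.i.d.
#' MCAR mask with rate `mcar_rate` and an abundance-dependent MNAR mask with
#' probability `plogis((mnar_threshold - y_ij) / mnar_beta)`
#' (`mnar_beta = 0` disables MNAR).
#'
#' @param n_proteins number of proteins.
#' @param peptides_per_protein integer, or length-2 range sampled uniformly
#'   per protein.
#' @param shared_peptide_fraction fraction of peptides assigned a second
#'   parent protein, in `[0, 1)`.
#' @param n_samples number of samples (>= 4 when `n_conditions == 2`).
#' @param n_conditions 1 or 2; condition labels split the samples in half.
#' @param de_fraction fraction of proteins differential between conditions.
#' @param de_effect log-scale effect size added in condition 2.
#' @param base_mean,base_sd protein base-level distribution (natural-log
#'   intensity units; the defaults put raw intensities around `e^14`).
#' @param protein_sd between-sample biological variation of a protein.
#' @param peptide_offset_sd spread of peptide ionization offsets.
#' @param noise_sd_range range of per-peptide residual noise sds.
#' @param mcar_rate completely-at-random missingness rate in `[0, 1)`.
#' @param mnar_threshold,mnar_beta logistic MNAR location / steepness scale
#'   on the log-abundance axis.
#' @param embedding_dim dimension of the emitted sequence-embedding matrix.
#' @param embedding_noise sd of the noise added to the embedded latent
#'   peptide properties.
#' @param seed mandatory integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 40L, peptides_per_protein = 5L,
                           shared_peptide_fraction = 0.05, n_samples = 8L,
                           n_conditions = 1L, de_fraction = 0.1,
                           de_effect = 1.0, base_mean = 14, base_sd = 1.5,
                           protein_sd = 0.5, peptide_offset_sd = 0.8,
                           noise_sd_range = c(0.1, 0.5), mcar_rate = 0.1,
                           mnar_threshold = -Inf, mnar_beta = 0,
                           embedding_dim = 64L, embedding_noise = 0.3,
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_proteins >= 1L, all(peptides_per_protein >= 1L),
            shared_peptide_fraction >= 0, shared_peptide_fraction < 1,
            n_samples >= 2L, n_conditions %in% c(1L, 2L),
            de_fraction >= 0, de_fraction <= 1,
            length(noise_sd_range) == 2L, all(noise_sd_range > 0),
            mcar_rate >= 0, mcar_rate < 1, mnar_beta >= 0,
            embedding_dim >= 2L, embedding_noise >= 0)
  if (n_conditions == 2L && n_samples < 4L)
    stop("two-condition designs need at least 4 samples")
  structure(as.list(environment()), class = "synthetic_spec")
}

random_peptide_seq <- function(n, min_len = 7L, max_len = 14L) {
  interior <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]  # tryptic-like body
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(L) {
    paste0(paste(sample(interior, L - 1L, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1L))
  }, character(1))
}

#' Generate a synthetic peptide dataset with full ground truth
#'
#' Draws one dataset from a [synthetic_spec()]. The returned truth object
#' carries the complete pre-missingness log-abundance matrix, per-entry
#' missingness causes (an entry hit by both mechanisms is attributed to
#' MCAR), per-peptide differential labels (a peptide is differential if any
#' parent protein is), and the latent peptide offsets and noise sds. The
#' embedding matrix is a noisy linear embedding of the latent peptide
#' properties, so sequence features carry genuine but imperfect signal.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (a [peptide_dataset()]), `truth` (class
#'   `synthetic_truth`) and `embeddings` (`n x embedding_dim`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  P <- spec$n_proteins
  ppp <- spec$peptides_per_protein
  k_per <- if (length(ppp) == 2L)
    sample(ppp[1L]:ppp[2L], P, replace = TRUE) else rep(ppp, P)
  n <- sum(k_per)
  s <- spec$n_samples
  protein_ids <- sprintf("P%04d", seq_len(P))
  parent1 <- rep(seq_len(P), k_per)
  # condition design: first half condition 1
  cond <- if (spec$n_conditions == 2L)
    rep(c("c1", "c2"), c(ceiling(s / 2), floor(s / 2))) else rep("c1", s)
  sample_ids <- sprintf("S%02d", seq_len(s))
  de_protein <- rep(FALSE, P)
  if (spec$n_conditions == 2L && spec$de_fraction > 0) {
    n_de <- max(1L, round(spec$de_fraction * P))
    de_protein[sample(P, n_de)] <- TRUE
  }
  b <- rnorm(P, spec$base_mean, spec$base_sd)
  U <- matrix(rnorm(P * s, 0, spec$protein_sd), P, s)
  effect <- outer(de_protein * spec$de_effect, cond == "c2")
  prot_signal <- b + U + effect                       # P x s
  # shared peptides: a second parent, signal = mean of both parents
  parent2 <- rep(NA_integer_, n)
  n_shared <- floor(spec$shared_peptide_fraction * n)
  if (n_shared > 0 && P >= 2L) {
    shared_idx <- sample(n, n_shared)
    parent2[shared_idx] <- vapply(shared_idx, function(i) {
      sample(setdiff(seq_len(P), parent1[i]), 1L)
    }, integer(1))
  }
  signal <- prot_signal[parent1, , drop = FALSE]
  has2 <- !is.na(parent2)
  if (any(has2))
    signal[has2, ] <- (signal[has2, , drop = FALSE] +
                         prot_signal[parent2[has2], , drop = FALSE]) / 2
  offset <- rnorm(n, 0, spec$peptide_offset_sd)
  noise_sd <- runif(n, spec$noise_sd_range[1L], spec$noise_sd_range[2L])
  Y <- signal + offset + matrix(rnorm(n * s), n, s) * noise_sd
  # missingness: MCAR union abundance-dependent MNAR
  mcar <- matrix(runif(n * s) < spec$mcar_rate, n, s)
  mnar <- if (spec$mnar_beta > 0) {
    matrix(runif(n * s), n, s) <
      plogis((spec$mnar_threshold - Y) / spec$mnar_beta)
  } else matrix(FALSE, n, s)
  cause <- matrix("observed", n, s)
  cause[mnar] <- "mnar"
  cause[mcar] <- "mcar"  # double-masked entries attributed to MCAR
  A <- exp(Y)
  A[mcar | mnar] <- NA
  seqs <- random_peptide_seq(n)
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- random_peptide_seq(length(dup))
  }
  prot_groups <- lapply(seq_len(n), function(i) {
    g <- protein_ids[parent1[i]]
    if (has2[i]) g <- c(g, protein_ids[parent2[i]])
    g
  })
  groups <- if (spec$n_conditions == 2L) setNames(cond, sample_ids) else NULL
  ds <- peptide_dataset(A, seqs, prot_groups, sample_ids, groups)
  # embeddings: noisy linear embedding of latent peptide properties
  latent <- cbind(offset, noise_sd)
  proj <- matrix(rnorm(spec$embedding_dim * ncol(latent)),
                 spec$embedding_dim, ncol(latent))
  emb <- latent %*% t(proj) +
    matrix(rnorm(n * spec$embedding_dim, 0, spec$embedding_noise),
           n, spec$embedding_dim)
  rownames(emb) <- seqs
  de_peptide <- de_protein[parent1]
  de_peptide[has2] <- de_peptide[has2] | de_protein[parent2[has2]]
  truth <- structure(
    list(log_abundance = Y, cause = cause, de_labels = de_peptide,
         offsets = offset, noise_sds = noise_sd, de_proteins = de_protein,
         parent1 = parent1, parent2 = parent2, spec = spec),
    class = "synthetic_truth")
  list(dataset = ds, truth = truth, embeddings = emb)
}

#' Expected within-protein peptide correlation of the generator
#'
#' Closed form for the Pearson correlation between the log-abundances of two
#' distinct peptides of the same protein, over random proteins, peptides and
#' samples: shared variance is the protein base-level plus the per-sample
#' protein effect, `base_sd^2 + protein_sd^2`; peptide-specific variance adds
#' the ionization offset and the mean residual noise variance
#' `E[sd^2] = (a^2 + ab + b^2) / 3` for `sd ~ U(a, b)`. Hence
#' `r = (base_sd^2 + protein_sd^2) / (base_sd^2 + protein_sd^2 +
#' peptide_offset_sd^2 + E[sd^2])`.
#'
#' The formula describes peptides with a single parent protein; shared
#' peptides average two proteins' signals and are therefore less correlated
#' with their clique mates, diluting the pooled empirical estimate when
#' `shared_peptide_fraction > 0`.
#'
#' @param spec a [synthetic_spec()].
#' @return scalar expected correlation.
#' @export
expected_clique_correlation <- function(spec) {
  a <- spec$noise_sd_range[1L]; b <- spec$noise_sd_range[2L]
  mean_noise_var <- (a^2 + a * b + b^2) / 3
  shared <- spec$base_sd^2 + spec$protein_sd^2
  shared / (shared + spec$peptide_offset_sd^2 + mean_noise_var)
}

#' Deterministic benchmark fixtures
#'
#' Three preset synthetic datasets with fixed seeds, used throughout the
#' test suite and documentation:
#' * `"small"` — 200 peptides x 8 samples (40 proteins of 5), 15% MCAR plus
#'   mild MNAR; quick end-to-end runs.
#' * `"medium"` — 2000 peptides x 12 samples (250 proteins of 8), 30% MCAR,
#'   no MNAR, within-protein correlation about 0.84.
#' * `"de_spikein"` — two conditions (6 + 6 samples), 10% differential
#'   proteins with log-effect 1.2, MNAR-dominated missingness; for
#'   differential-expression evaluation.
#'
#' @param name preset name.
#' @param mask_seed seed for the attached evaluation [mask_plan] (defaults
#'   to the preset seed + 1).
#' @return list with `dataset`, `truth`, `embeddings` and `plan` (a 10%/10%
#'   [make_masked_split()]).
#' @export
make_benchmark_fixture <- function(name = c("small", "medium", "de_spikein"),
                                   mask_seed = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
    small = synthetic_spec(n_proteins = 40L, peptides_per_protein = 5L,
                           n_samples = 8L, mcar_rate = 0.15,
                           mnar_threshold = 11.5, mnar_beta = 0.7,
                           seed = 101L),
    medium = synthetic_spec(n_proteins = 250L, peptides_per_protein = 8L,
                            n_samples = 12L, mcar_rate = 0.30,
                            peptide_offset_sd = 0.6, seed = 202L),
    de_spikein = synthetic_spec(n_proteins = 80L, peptides_per_protein = 5L,
                                n_samples = 12L, n_conditions = 2L,
                                de_fraction = 0.1, de_effect = 1.2,
                                mcar_rate = 0.05, mnar_threshold = 12.5,
                                mnar_beta = 0.7, seed = 303L))
  gen <- generate_dataset(spec)
  if (is.null(mask_seed)) mask_seed <- spec$seed + 1L
  gen$plan <- make_masked_split(gen$dataset, 0.10, 0.10, seed = mask_seed)
  gen$spec <- spec
  gen
}

#' Write a generated dataset to disk in the package's interchange formats
#'
#' Emits the wide peptide table, a FASTA of the peptide sequences, the
#' embedding table, sample-group metadata (when present) and a ground-truth
#' cause/label table — the same formats the loaders read back.
#'
#' @param gen output of [generate_dataset()] or [make_benchmark_fixture()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synthetic_dataset <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- gen$dataset
  paths <- c(table = file.path(dir, "peptides.tsv"),
             fasta = file.path(dir, "peptides.fasta"),
             embeddings = file.path(dir, "embeddings.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_peptide_table(ds, paths["table"])
  write_peptide_fasta(setNames(ds$peptide_ids, ds$peptide_ids), paths["fasta"])
  write_embedding_table(gen$embeddings, ds$peptide_ids, paths["embeddings"])
  tr <- gen$truth
  truth_df <- data.frame(peptide_id = rep(ds$peptide_ids, ncol(ds$abundance)),
                         sample_id = rep(ds$sample_ids,
                                         each = nrow(ds$abundance)),
                         log_abundance = as.vector(tr$log_abundance),
                         cause = as.vector(tr$cause))
  write.table(truth_df, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  de_path <- file.path(dir, "de_labels.tsv")
  write.table(data.frame(peptide_id = ds$peptide_ids,
                         de = as.integer(tr$de_labels)),
              de_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, de_labels = de_path)
  if (!is.null(ds$sample_groups)) {
    gp <- file.path(dir, "sample_groups.tsv")
    write_sample_groups(ds$sample_groups, gp)
    paths <- c(paths, groups = gp)
  }
  invisible(paths)
}
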