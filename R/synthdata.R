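## Population-genetic simulator: Balding-Nichols populations, admixture,
## stepping-stone grids, and cluster-structured phenotypes. Every downstream
## stage of the package is testable against these cohorts.

## One global seed expands into per-stage substreams by fixed offsets, so each
## stage is independently reproducible.
.substream <- function(seed, offset) {
  set.seed((as.integer(seed) + offset * 100003L) %% 2147483629L)
}

#' Specification of a simulated population design
#'
#' Describes a cohort of `n_pops` populations drifted from a common ancestral
#' allele-frequency pool under the Balding-Nichols model: per SNP, an
#' ancestral frequency p is drawn uniformly on `ancestral_freq_range`, and
#' population j's frequency is Beta-distributed with mean p and variance
#' `F[j] * p * (1 - p)` (shape parameters `p(1-F)/F`, `(1-p)(1-F)/F`). `F` is
#' the drift/differentiation parameter in [0, 1).
#'
#' @param n_pops number of populations.
#' @param pop_sizes integer vector of population sizes (recycled).
#' @param F drift parameter per population in [0, 1) (recycled).
#' @param n_snps number of variants.
#' @param ancestral_freq_range interval within (0, 1) for ancestral
#'   frequencies; the default (0.05, 0.95) avoids near-monomorphic SNPs,
#'   mirroring a MAF 0.05 input filter.
#' @param admixture optional ancestry-proportion matrix Q: either one row per
#'   population (all members share that ancestry) or one row per individual;
#'   columns are source populations and rows must sum to 1. One-hot rows mean
#'   no admixture.
#' @param grid optional `list(rows, cols, m)` for a stepping-stone design
#'   with migration weight `m` in [0, 0.5]; `rows * cols` must equal
#'   `n_pops`.
#' @param seed integer seed; identical specs and seeds give bit-identical
#'   cohorts.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_pops, pop_sizes, F, n_snps,
                            ancestral_freq_range = c(0.05, 0.95),
                            admixture = NULL, grid = NULL, seed = 1L) {
  n_pops <- as.integer(n_pops)
  pop_sizes <- as.integer(rep_len(pop_sizes, n_pops))
  F <- rep_len(as.numeric(F), n_pops)
  if (any(pop_sizes < 1L)) stop("pop_sizes must all be >= 1")
  if (any(F < 0 | F >= 1)) stop("F must lie in [0, 1)")
  if (length(ancestral_freq_range) != 2L ||
      ancestral_freq_range[1] <= 0 || ancestral_freq_range[2] >= 1 ||
      diff(ancestral_freq_range) < 0)
    stop("ancestral_freq_range must be an interval within (0, 1)")
  if (!is.null(admixture)) {
    admixture <- as.matrix(admixture)
    if (ncol(admixture) != n_pops)
      stop("admixture must have one column per source population")
    if (!nrow(admixture) %in% c(n_pops, sum(pop_sizes)))
      stop("admixture needs one row per population or per individual")
    if (any(abs(rowSums(admixture) - 1) > 1e-9))
      stop("admixture rows must sum to 1")
    if (any(admixture < 0)) stop("admixture proportions must be >= 0")
  }
  if (!is.null(grid)) {
    if (!all(c("rows", "cols", "m") %in% names(grid)))
      stop("grid must be list(rows, cols, m)")
    if (grid$rows * grid$cols != n_pops)
      stop("grid rows * cols must equal n_pops")
    if (grid$m < 0 || grid$m > 0.5) stop("grid migration m must be in [0, 0.5]")
  }
  structure(list(n_pops = n_pops, pop_sizes = pop_sizes, F = F,
                 n_snps = as.integer(n_snps),
                 ancestral_freq_range = as.numeric(ancestral_freq_range),
                 admixture = admixture, grid = grid,
                 seed = as.integer(seed)),
            class = "population_spec")
}

## Balding-Nichols population frequencies: one column per population.
.bn_frequencies <- function(spec) {
  .substream(spec$seed, 1L)
  r <- spec$ancestral_freq_range
  p_anc <- stats::runif(spec$n_snps, r[1], r[2])
  P <- matrix(0, spec$n_snps, spec$n_pops)
  for (j in seq_len(spec$n_pops)) {
    Fj <- spec$F[j]
    P[, j] <- if (Fj == 0) p_anc else
      stats::rbeta(spec$n_snps, p_anc * (1 - Fj) / Fj,
                   (1 - p_anc) * (1 - Fj) / Fj)
  }
  list(p_anc = p_anc, P = P)
}

.cohort <- function(counts, labels, Q, spec, pop_freqs) {
  n <- nrow(counts)
  ids <- sprintf("S%05d", seq_len(n))
  g <- genotype_matrix(counts, sample_ids = ids)
  structure(list(genotypes = g,
                 true_labels = as.integer(labels),
                 Q_true = Q,
                 phenotype = NULL,
                 pop_freqs = pop_freqs,
                 spec = spec),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("simulated_cohort:", nrow(x$genotypes$counts), "individuals x",
      ncol(x$genotypes$counts), "SNPs,",
      length(unique(x$true_labels)), "populations\n")
  invisible(x)
}

#' Simulate discrete Balding-Nichols populations
#'
#' Genotypes are Binomial(2, p_j) draws from each population's
#' Beta-distributed allele frequencies. Deterministic given the spec seed.
#'
#' @param spec a [population_spec()] without admixture or grid.
#' @return an object of class `simulated_cohort` with elements `genotypes`
#'   (a `genotype_matrix`), `true_labels` (0-based population index),
#'   `Q_true` (one-hot ancestry matrix) and `pop_freqs` (SNP x population
#'   frequency matrix, useful for calibration checks).
#' @export
simulate_discrete <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(spec$admixture)) stop("spec has admixture; use simulate_admixed")
  if (!is.null(spec$grid)) stop("spec has a grid; use simulate_stepping_stone")
  fq <- .bn_frequencies(spec)
  .substream(spec$seed, 2L)
  counts <- do.call(rbind, lapply(seq_len(spec$n_pops), function(j) {
    nj <- spec$pop_sizes[j]
    matrix(stats::rbinom(nj * spec$n_snps, 2L, rep(fq$P[, j], each = nj)),
           nrow = nj)
  }))
  labels <- rep(seq_len(spec$n_pops) - 1L, spec$pop_sizes)
  Q <- diag(spec$n_pops)[labels + 1L, , drop = FALSE]
  .cohort(counts, labels, Q, spec, fq$P)
}

#' Simulate populations with admixture
#'
#' Each of an individual's two allele copies at each SNP independently picks
#' a source population s with probability Q[i, s] and is then Bernoulli(p_s).
#' Unadmixed populations (one-hot Q rows) reduce exactly to
#' [simulate_discrete()] sampling.
#'
#' @param spec a [population_spec()] with an `admixture` matrix.
#' @return a `simulated_cohort`; `Q_true` holds per-individual ancestry.
#' @export
simulate_admixed <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (is.null(spec$admixture)) stop("spec has no admixture matrix")
  fq <- .bn_frequencies(spec)
  n_total <- sum(spec$pop_sizes)
  labels <- rep(seq_len(spec$n_pops) - 1L, spec$pop_sizes)
  Q <- spec$admixture
  if (nrow(Q) == spec$n_pops) Q <- Q[labels + 1L, , drop = FALSE]
  .substream(spec$seed, 2L)
  m <- spec$n_snps
  counts <- matrix(0L, n_total, m)
  cumQ <- t(apply(Q, 1L, cumsum))
  for (copy in 1:2) {
    u <- matrix(stats::runif(n_total * m), n_total, m)
    src <- matrix(0L, n_total, m)
    for (s in seq_len(spec$n_pops))
      src <- src + (u > cumQ[, s])  # 0-based source index
    p_draw <- fq$P[cbind(rep(seq_len(m), each = n_total), as.vector(src) + 1L)]
    counts <- counts + matrix(stats::rbinom(n_total * m, 1L, p_draw),
                              n_total, m)
  }
  .cohort(counts, labels, Q, spec, fq$P)
}

## Rook-adjacent neighbours of deme (r, c) on a rows x cols grid,
## as 1-based deme indices in row-major order.
.rook_neighbours <- function(r, c, rows, cols) {
  nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
  nb <- nb[nb[, 1] >= 1 & nb[, 1] <= rows & nb[, 2] >= 1 & nb[, 2] <= cols, ,
           drop = FALSE]
  (nb[, 1] - 1L) * cols + nb[, 2]
}

#' Simulate a stepping-stone grid of populations
#'
#' Demes sit on a rows x cols grid; each deme's allele frequency is a
#' weighted average of its own Balding-Nichols draw (weight 1 - m) and the
#' mean draw of its rook-adjacent neighbours (total weight m), so the cohort
#' carries both discrete structure (demes) and continuous structure
#' (isolation by distance). `m = 0` reduces exactly to
#' [simulate_discrete()].
#'
#' @param spec a [population_spec()] with a `grid`.
#' @return a `simulated_cohort`; deme labels are row-major, 0-based.
#' @export
simulate_stepping_stone <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (is.null(spec$grid)) stop("spec has no grid")
  fq <- .bn_frequencies(spec)
  rows <- spec$grid$rows; cols <- spec$grid$cols; m <- spec$grid$m
  P <- fq$P
  Psm <- P
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    j <- (r - 1L) * cols + c
    nb <- .rook_neighbours(r, c, rows, cols)
    Psm[, j] <- (1 - m) * P[, j] + m * rowMeans(P[, nb, drop = FALSE])
  }
  .substream(spec$seed, 2L)
  counts <- do.call(rbind, lapply(seq_len(spec$n_pops), function(j) {
    nj <- spec$pop_sizes[j]
    matrix(stats::rbinom(nj * spec$n_snps, 2L, rep(Psm[, j], each = nj)),
           nrow = nj)
  }))
  labels <- rep(seq_len(spec$n_pops) - 1L, spec$pop_sizes)
  Q <- diag(spec$n_pops)[labels + 1L, , drop = FALSE]
  .cohort(counts, labels, Q, spec, Psm)
}

#' Canonical two-source admixture design
#'
#' The four-population demonstration cohort: two source populations, an
#' admixed population averaging 75%/25% ancestry from them, and an
#' outgroup, each of `n_per_pop` individuals. Admixed individuals draw
#' their own ancestry proportion from a scaled Beta(2, 2) on
#' `ancestry_range`, so the admixed cloud is elongated along the
#' inter-source axis (which defeats centroid-based clustering) while
#' staying bounded away from the sources (so a density gap exists).
#'
#' @param n_per_pop individuals per population.
#' @param n_snps number of SNPs (the default 3000 keeps the density gap
#'   resolvable against genotype sampling noise at these sample sizes).
#' @param F drift parameter.
#' @param ancestry_range support of the admixed individuals' source-1
#'   ancestry fraction.
#' @param seed integer seed (drives both the ancestry draw and the
#'   genotype simulation).
#' @return a [population_spec()] ready for [simulate_admixed()].
#' @export
admixed_demo_spec <- function(n_per_pop = 1000L, n_snps = 3000L, F = 0.1,
                              ancestry_range = c(0.6, 0.9), seed = 1L) {
  .substream(seed, 4L)
  th <- ancestry_range[1] + diff(ancestry_range) *
    stats::rbeta(n_per_pop, 2, 2)
  one <- function(j) diag(4)[rep(j, n_per_pop), ]
  Q <- rbind(one(1), one(2), cbind(th, 1 - th, 0, 0), one(4))
  population_spec(4L, n_per_pop, F = F, n_snps = n_snps,
                  admixture = Q, seed = seed)
}

#' Attach a cluster-shifted phenotype to a simulated cohort
#'
#' phenotype_i = shift[label_i] + Normal(0, noise_sd). The shifts create
#' cluster-structured residuals that principal components need not span --
#' the situation ensemble phenotype smoothing is designed to reveal.
#'
#' @param cohort a `simulated_cohort`.
#' @param cluster_shift numeric vector of per-population shifts, either
#'   unnamed (position = label 0, 1, ...) or named by label.
#' @param noise_sd residual standard deviation.
#' @param seed integer seed for the noise draw (defaults to the cohort's
#'   spec seed).
#' @return the cohort with `$phenotype` filled in.
#' @export
attach_phenotype <- function(cohort, cluster_shift, noise_sd, seed = NULL) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  labs <- cohort$true_labels
  if (is.null(labs)) stop("cohort has no labels")
  if (is.null(seed)) seed <- cohort$spec$seed
  sh <- if (!is.null(names(cluster_shift)))
    unname(cluster_shift[as.character(labs)])
  else cluster_shift[labs + 1L]
  if (anyNA(sh)) stop("cluster_shift missing a label present in the cohort")
  .substream(seed, 3L)
  cohort$phenotype <- sh + stats::rnorm(length(labs), 0, noise_sd)
  cohort
}

#' Write a simulated cohort to PLINK files plus a metadata table
#'
#' Writes `<prefix>.bed/.bim/.fam` via [write_plink()] and
#' `<prefix>.meta.tsv` with sample id, true label, ancestry proportions and
#' phenotype.
#'
#' @param cohort a `simulated_cohort`.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  write_plink(cohort$genotypes, prefix)
  meta <- data.frame(sample_id = cohort$genotypes$sample_ids,
                     true_label = cohort$true_labels)
  Q <- cohort$Q_true
  if (!is.null(Q)) {
    colnames(Q) <- paste0("Q", seq_len(ncol(Q)))
    meta <- cbind(meta, Q)
  }
  if (!is.null(cohort$phenotype)) meta$phenotype <- cohort$phenotype
  utils::write.table(meta, paste0(prefix, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
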