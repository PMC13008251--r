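## Quantitative evaluation: partition agreement, k-means baselines,
## between-group differentiation, polygenic-score accuracy, and
## cross-validated model comparison.
##
## A caveat carried through the documentation and report metadata: Fst
## between clusters that were themselves defined from the genotype data is
## artificially inflated overall by the clustering process, so no
## significance statements are attached to cluster-derived statistics here.

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, from the pair-count
#' contingency table under the permutation model. Noise labels (-1) are
#' handled per `noise_policy`: `"own_cluster"` (default) treats noise as an
#' ordinary label; `"exclude"` drops positions where either labelling is
#' noise.
#'
#' @param a,b aligned label vectors.
#' @param noise_policy `"own_cluster"` or `"exclude"`.
#' @return the ARI, 1 for identical partitions (up to relabelling), about 0
#'   for independent ones.
#' @export
adjusted_rand_index <- function(a, b,
                                noise_policy = c("own_cluster", "exclude")) {
  noise_policy <- match.arg(noise_policy)
  if (inherits(a, "cluster_labels")) a <- a$labels
  if (inherits(b, "cluster_labels")) b <- b$labels
  if (length(a) != length(b)) stop("label vectors must be aligned")
  if (noise_policy == "exclude") {
    keep <- a != -1L & b != -1L
    a <- a[keep]; b <- b[keep]
  }
  n <- length(a)
  if (n < 2L) stop("need at least 2 points")
  tab <- table(a, b)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  e <- sa * sb / choose(n, 2)
  den <- (sa + sb) / 2 - e
  if (den == 0) return(1)   # both partitions trivial and identical in pairs
  (si - e) / den
}

#' k-means baseline clustering
#'
#' k-means with k-means++ seeding and `n_init` restarts (best total
#' within-cluster sum of squares kept); deterministic given the seed. The
#' typological baseline against which topological clustering is compared:
#' on admixture designs it characteristically splits the admixed group
#' between source-population centres.
#'
#' @param X numeric matrix (e.g. leading PC scores or admixture
#'   proportions).
#' @param K number of clusters.
#' @param seed integer seed.
#' @param n_init number of restarts.
#' @return integer labels, 0-based.
#' @export
kmeans_baseline <- function(X, K, seed = 1L, n_init = 10L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (K > n) stop("K exceeds the number of points")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    centers <- .kmeanspp_centers(X, K)
    fit <- tryCatch(stats::kmeans(X, centers = centers, iter.max = 100L),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed for every initialization")
  best$cluster - 1L
}

## k-means++ seeding: each next centre sampled with probability
## proportional to squared distance from the nearest chosen centre.
.kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1L)
  d2 <- colSums((t(X) - X[idx[1], ])^2)
  for (k in seq_len(K - 1L) + 1L) {
    pr <- d2 / sum(d2)
    if (!all(is.finite(pr)) || sum(d2) == 0) pr <- rep(1 / n, n)
    idx[k] <- sample.int(n, 1L, prob = pr)
    d2 <- pmin(d2, colSums((t(X) - X[idx[k], ])^2))
  }
  X[idx, , drop = FALSE] + matrix(stats::rnorm(K * ncol(X), 0, 1e-10), K)
}

#' Hudson's Fst between two sample sets
#'
#' Ratio-of-sums Hudson estimator: per SNP the numerator is
#' `(pa - pb)^2 - pa(1-pa)/(na-1) - pb(1-pb)/(nb-1)` and the denominator
#' `pa(1-pb) + pb(1-pa)`, with allele numbers `na`, `nb` counted as twice
#' the genotyped samples minus missing alleles; sums are taken across SNPs
#' before the ratio. Low bias for unbalanced group sizes. Note that Fst
#' between clusters defined from the same genotype data is inflated by the
#' clustering process itself; no inference is attached to these values.
#'
#' @param g a [genotype_matrix()].
#' @param a,b index vectors (integer positions, logical masks, or sample
#'   ids) of the two groups, each of at least 2 samples.
#' @return Hudson's Fst (a single number, <= 1).
#' @export
hudson_fst <- function(g, a, b) {
  stopifnot(inherits(g, "genotype_matrix"))
  resolve <- function(x) {
    if (is.character(x)) x <- match(x, g$sample_ids)
    if (is.logical(x)) x <- which(x)
    if (anyNA(x)) stop("unknown sample in group")
    x
  }
  a <- resolve(a); b <- resolve(b)
  if (length(a) < 2L || length(b) < 2L) stop("both groups need >= 2 samples")
  stat <- function(idx) {
    cnt <- g$counts[idx, , drop = FALSE]
    nal <- 2 * colSums(!is.na(cnt))
    p <- colSums(cnt, na.rm = TRUE) / nal
    list(p = p, n = nal)
  }
  sa <- stat(a); sb <- stat(b)
  ok <- sa$n > 2 & sb$n > 2
  pa <- sa$p[ok]; pb <- sb$p[ok]; na <- sa$n[ok]; nb <- sb$n[ok]
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  if (sum(den, na.rm = TRUE) == 0)
    stop("Fst undefined: all SNPs monomorphic in the union")
  sum(num, na.rm = TRUE) / sum(den, na.rm = TRUE)
}

## In-sample R-squared of OLS y ~ [1, X].
.ols_r2 <- function(y, X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Incremental R-squared of a score
#'
#' `R2(Full) - R2(Null)` for the nested in-sample OLS fits
#' Full: y ~ score + covariates, Null: y ~ covariates. Non-negative by
#' construction. The standard measure of a polygenic score's added
#' explanatory value over covariates.
#'
#' @param y phenotype vector.
#' @param score per-individual score vector.
#' @param covariates optional matrix or data frame (an intercept is always
#'   included).
#' @return the incremental R-squared.
#' @export
incremental_r2 <- function(y, score, covariates = NULL) {
  y <- as.numeric(y); score <- as.numeric(score)
  if (anyNA(y) || anyNA(score)) stop("missing values in y or score")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  r2_null <- if (is.null(C)) 0 else .ols_r2(y, C)
  r2_full <- .ols_r2(y, cbind(score, C))
  r2_full - r2_null
}

#' Regress per-cluster score accuracy on per-cluster allele frequency
#'
#' For each SNP, a simple OLS of cluster-level R-squared on cluster-level
#' minor allele frequency; reports slope, intercept, fit R-squared and the
#' two-sided p-value of the slope, ranked by p. SNPs whose MAF is constant
#' across clusters are skipped.
#'
#' @param r2 numeric vector of per-cluster R-squared values (>= 3
#'   clusters).
#' @param maf numeric vector (one SNP) or clusters x SNPs matrix of
#'   per-cluster minor allele frequencies.
#' @return a data frame (snp, slope, intercept, r_squared, p) ordered by p.
#' @export
regress_r2_on_maf <- function(r2, maf) {
  r2 <- as.numeric(r2)
  if (length(r2) < 3L) stop("need >= 3 clusters")
  maf <- as.matrix(maf)
  if (nrow(maf) != length(r2)) stop("maf rows must match clusters")
  snps <- colnames(maf) %||% paste0("snp", seq_len(ncol(maf)))
  rows <- lapply(seq_len(ncol(maf)), function(j) {
    x <- maf[, j]
    if (stats::sd(x) == 0) return(NULL)
    fit <- stats::lm(r2 ~ x)
    s <- summary(fit)
    data.frame(snp = snps[j],
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = s$r.squared,
               p = s$coefficients[2, 4])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no SNP with varying MAF")
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Cross-validated comparison of PC-only and cluster-smoothed models
#'
#' k-fold cross-validation of two phenotype models: `PCA` regresses the
#' phenotype on covariates plus PC scores; `CLS` adds the ensemble
#' cluster-smoothed residual estimate mu_i as a further predictor. To avoid
#' leakage, mu is recomputed within training folds only: a test individual
#' receives, per run, the mean training-fold residual of its cluster mates
#' (0 -- the training residual scale's centre -- when it has none), then the
#' across-run average. `naive_smoothing = TRUE` instead smooths once on all
#' data before splitting.
#'
#' @param y phenotype vector.
#' @param covariates optional covariate matrix.
#' @param pcs `pc_matrix` or score matrix.
#' @param runs list of `cluster_labels` from [run_grid()].
#' @param folds number of folds (>= 2; `folds = n` is leave-one-out).
#' @param seed seed for the fold assignment.
#' @param subgroups optional named list of logical masks; test MSE is also
#'   reported within each mask (each must contain at least `folds`
#'   members).
#' @param naive_smoothing reproduce the leaky variant (all-data smoothing).
#' @return a data frame (model, subgroup, mse, n) of mean test MSEs.
#' @export
cv_compare <- function(y, covariates = NULL, pcs, runs, folds = 5L,
                       seed = 1L, subgroups = NULL, naive_smoothing = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  folds <- as.integer(folds)
  if (folds < 2L || folds > n) stop("folds must be in [2, n]")
  P <- if (inherits(pcs, "pc_matrix")) pcs$scores else as.matrix(pcs)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (inherits(runs, "cluster_labels")) runs <- list(runs)
  if (!is.null(subgroups)) {
    bad <- vapply(subgroups, function(m) sum(m) < folds, logical(1))
    if (any(bad)) stop("subgroup smaller than the number of folds: ",
                       paste(names(subgroups)[bad], collapse = ", "))
  }
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))

  base_design <- cbind(P, C)
  smooth_on <- function(res_tr, train_idx) {
    ## per-run means of training residuals, evaluated for everyone
    vals <- vapply(runs, function(cl) {
      lab <- cl$labels
      mu_run <- numeric(n)
      for (cl_id in unique(lab)) {
        if (cl_id == -1L) next
        members <- which(lab == cl_id)
        tr_members <- intersect(members, train_idx)
        mu_run[members] <- if (length(tr_members))
          mean(res_tr[match(tr_members, train_idx)]) else 0
      }
      ## a training noise point keeps its own residual (singleton cluster);
      ## a test noise point has no training mates and stays at 0
      noise_tr <- intersect(which(lab == -1L), train_idx)
      mu_run[noise_tr] <- res_tr[match(noise_tr, train_idx)]
      mu_run
    }, numeric(n))
    rowMeans(matrix(vals, nrow = n))
  }

  err <- list(PCA = numeric(n), CLS = numeric(n))
  for (f in seq_len(folds)) {
    te <- which(fold_id == f); tr <- which(fold_id != f)
    X1 <- cbind(1, base_design)
    fit1 <- stats::lm.fit(X1[tr, , drop = FALSE], y[tr])
    beta1 <- ifelse(is.na(fit1$coefficients), 0, fit1$coefficients)
    err$PCA[te] <- (y[te] - X1[te, , drop = FALSE] %*% beta1)^2

    res_tr <- stats::lm.fit(X1[tr, , drop = FALSE], y[tr])$residuals
    mu <- if (naive_smoothing) {
      res_all <- stats::lm.fit(X1, y)$residuals
      smooth_phenotype(res_all, runs)$mu
    } else smooth_on(res_tr, tr)
    X2 <- cbind(X1, mu)
    fit2 <- stats::lm.fit(X2[tr, , drop = FALSE], y[tr])
    beta2 <- ifelse(is.na(fit2$coefficients), 0, fit2$coefficients)
    err$CLS[te] <- (y[te] - X2[te, , drop = FALSE] %*% beta2)^2
  }

  masks <- c(list(all = rep(TRUE, n)), subgroups)
  out <- do.call(rbind, lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    data.frame(model = c("PCA", "CLS"), subgroup = nm,
               mse = c(mean(err$PCA[m]), mean(err$CLS[m])),
               n = sum(m))
  }))
  rownames(out) <- NULL
  out
}
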