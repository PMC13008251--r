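test_that("adjusted Rand index matches the pair-count oracle", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  ## any labelling against one big cluster scores 0
  set.seed(22)
  a <- sample(0:3, 40, replace = TRUE)
  expect_equal(adjusted_rand_index(a, rep(0L, 40)), 0)
  ## explicit pair-count value on the worked example
  a4 <- c(0, 0, 1, 1); b4 <- c(0, 1, 1, 1)
  expect_equal(adjusted_rand_index(a4, b4), ari_pair_oracle(a4, b4))
  ## random fixtures: equality with both the pair oracle and an
  ## independent implementation
  for (s in 1:5) {
    set.seed(s)
    x <- sample(0:2, 30, replace = TRUE)
    y <- sample(0:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), ari_pair_oracle(x, y))
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y))
    ## symmetry and label-permutation invariance
    expect_equal(adjusted_rand_index(x, y), adjusted_rand_index(y, x))
    expect_equal(adjusted_rand_index(2 - x, y), adjusted_rand_index(x, y))
  }
  expect_error(adjusted_rand_index(0L, 0L), "at least 2")
})

test_that("noise policies differ when noise points exist", {
  a <- c(-1, -1, 0, 0, 1, 1)
  b <- c(0, 1, 0, 0, 1, 1)
  own <- adjusted_rand_index(a, b, "own_cluster")
  exc <- adjusted_rand_index(a, b, "exclude")
  expect_equal(exc, 1)        # perfect once noise is dropped
  expect_lt(own, 1)
})

test_that("k-means baseline recovers trivial structure deterministically", {
  set.seed(24)
  X <- matrix(rnorm(60 * 2), 60)
  k1 <- kmeans_baseline(X, 1, seed = 1)
  expect_true(all(k1 == 0L))
  b <- make_blobs(c(30, 30), rbind(c(0, 0), c(20, 0)), sd = 0.5, seed = 25)
  k2 <- kmeans_baseline(b$X, 2, seed = 1)
  expect_equal(adjusted_rand_index(k2, b$labels), 1)
  expect_identical(kmeans_baseline(b$X, 2, seed = 9),
                   kmeans_baseline(b$X, 2, seed = 9))
})

test_that("Hudson Fst matches hand-evaluated values", {
  ## identical subsamples of one undifferentiated population: ~ 0
  co <- simulate_discrete(population_spec(1, 400, F = 0, n_snps = 1000,
                                          seed = 26))
  fst0 <- hudson_fst(co$genotypes, 1:200, 201:400)
  expect_lt(abs(fst0), 0.01)
  ## fixed difference at every SNP: exactly 1
  g1 <- genotype_matrix(rbind(matrix(0L, 5, 8), matrix(2L, 5, 8)))
  expect_equal(hudson_fst(g1, 1:5, 6:10), 1)
  ## hand oracle at pa = 0.2, pb = 0.8 with 5 diploids per group:
  ## num = 0.36 - 2 * (0.16 / 9), den = 0.2^2 + 0.8^2
  ga <- c(1L, 1L, 0L, 0L, 0L)      # 2 / 10 alleles
  gb <- c(2L, 2L, 2L, 1L, 1L)      # 8 / 10 alleles
  g2 <- genotype_matrix(cbind(c(ga, gb)))
  hand <- (0.36 - 2 * (0.2 * 0.8 / 9)) / (0.2 * 0.2 + 0.8 * 0.8)
  expect_equal(hudson_fst(g2, 1:5, 6:10), hand, tolerance = 1e-12)
  ## symmetry and SNP-order invariance
  co2 <- small_cohort(n_pops = 2, n_per = 50, n_snps = 100, seed = 27)
  a <- co2$true_labels == 0L; b <- co2$true_labels == 1L
  f <- hudson_fst(co2$genotypes, a, b)
  expect_equal(hudson_fst(co2$genotypes, b, a), f)
  gperm <- genotype_matrix(co2$genotypes$counts[, sample(100)])
  expect_equal(hudson_fst(gperm, a, b), f)
  ## monomorphic union is an error
  gmono <- genotype_matrix(matrix(0L, 6, 3))
  expect_error(hudson_fst(gmono, 1:3, 4:6), "monomorphic")
})

test_that("incremental R-squared matches nested-OLS oracles", {
  set.seed(28)
  y <- rnorm(50)
  expect_equal(incremental_r2(y, y), 1, tolerance = 1e-10)
  ## orthogonal score adds nothing
  score <- rnorm(50)
  score <- score - mean(score)
  score <- score - sum(score * (y - mean(y))) / sum((y - mean(y))^2) *
    (y - mean(y))
  expect_lt(incremental_r2(y, score), 1e-10)
  ## hand oracle: y = 1:4, score = (1,1,2,2), intercept-only null
  ## beta = Sxy/Sxx = 2, R2 = 4/5
  expect_equal(incremental_r2(c(1, 2, 3, 4), c(1, 1, 2, 2)), 0.8,
               tolerance = 1e-12)
  ## in-sample non-negativity on random designs with covariates
  for (s in 1:5) {
    set.seed(s)
    yy <- rnorm(40); sc <- rnorm(40); cv <- matrix(rnorm(80), 40)
    expect_gte(incremental_r2(yy, sc, cv), -1e-12)
  }
})

test_that("per-SNP R2-on-MAF regression reports exact fits and skips", {
  r2 <- c(0.1, 0.2, 0.3, 0.4)
  maf <- cbind(lin = c(0.1, 0.2, 0.3, 0.4),      # perfect linear relation
               flat = rep(0.25, 4),               # constant: skipped
               noise = c(0.3, 0.1, 0.4, 0.15))
  out <- suppressWarnings(regress_r2_on_maf(r2, maf))
  expect_false("flat" %in% out$snp)
  lin <- out[out$snp == "lin", ]
  expect_equal(lin$slope, 1, tolerance = 1e-10)
  expect_equal(lin$r_squared, 1, tolerance = 1e-10)
  expect_lt(lin$p, 1e-10)
  expect_equal(out$snp[1], "lin")   # ranked by p
  ## three collinear points: fit R-squared 1
  out3 <- suppressWarnings(regress_r2_on_maf(c(1, 2, 3), c(0.1, 0.2, 0.3)))
  expect_equal(out3$r_squared, 1, tolerance = 1e-10)
  expect_error(regress_r2_on_maf(c(0.1, 0.2), c(0.1, 0.2)), ">= 3")
})

test_that("slope p-values are calibrated under the null", {
  set.seed(29)
  p_vals <- replicate(400, {
    out <- regress_r2_on_maf(rnorm(8), rnorm(8))
    out$p
  })
  expect_gt(ks.test(p_vals, "punif")$p.value, 0.001)
})

test_that("leave-one-out cv_compare matches a brute-force oracle", {
  set.seed(30)
  n <- 10
  pcs <- matrix(rnorm(n * 2), n)
  y <- 0.5 * pcs[, 1] + rnorm(n, 0, 0.3)
  lab <- rep(0:1, each = 5)
  runs <- list(structure(list(labels = lab, n_clusters = 2L, params = NULL),
                         class = "cluster_labels"))
  res <- cv_compare(y, covariates = NULL, pcs = pcs, runs = runs,
                    folds = n, seed = 7)
  ## brute-force LOO for the PC model
  loo <- vapply(seq_len(n), function(i) {
    fit <- lm(y ~ pcs[, 1] + pcs[, 2], subset = seq_len(n) != i)
    (y[i] - sum(c(1, pcs[i, ]) * coef(fit)))^2
  }, numeric(1))
  expect_equal(res$mse[res$model == "PCA" & res$subgroup == "all"],
               mean(loo), tolerance = 1e-10)
  ## reproducible given seed
  res2 <- cv_compare(y, covariates = NULL, pcs = pcs, runs = runs,
                     folds = n, seed = 7)
  expect_identical(res, res2)
})

test_that("cluster-smoothed model beats PCs when shifts escape the PC span", {
  set.seed(31)
  n <- 300
  pcs <- matrix(rnorm(n * 4), n)                 # structure-free "PCs"
  lab <- sample(0:2, n, replace = TRUE)
  shift <- c(-1, 0, 1.5)[lab + 1L]
  y <- shift + rnorm(n, 0, 0.5)
  runs <- list(structure(list(labels = lab, n_clusters = 3L, params = NULL),
                         class = "cluster_labels"))
  res <- cv_compare(y, covariates = NULL, pcs = pcs, runs = runs,
                    folds = 5, seed = 8)
  mse <- setNames(res$mse[res$subgroup == "all"],
                  res$model[res$subgroup == "all"])
  expect_lt(mse["CLS"], mse["PCA"])
  ## with no shift the two models tie within CV noise
  y0 <- rnorm(n, 0, 0.5)
  res0 <- cv_compare(y0, covariates = NULL, pcs = pcs, runs = runs,
                     folds = 5, seed = 8)
  m0 <- setNames(res0$mse[res0$subgroup == "all"],
                 res0$model[res0$subgroup == "all"])
  expect_equal(unname(m0["CLS"] / m0["PCA"]), 1, tolerance = 0.1)
  ## subgroup masks are honoured and sized
  grp <- list(g1 = lab == 0L)
  resg <- cv_compare(y, pcs = pcs, runs = runs, folds = 5, seed = 8,
                     subgroups = grp)
  expect_true("g1" %in% resg$subgroup)
  expect_equal(unique(resg$n[resg$subgroup == "g1"]), sum(lab == 0L))
  expect_error(cv_compare(y, pcs = pcs, runs = runs, folds = 5, seed = 8,
                          subgroups = list(tiny = seq_len(n) <= 3)),
               "subgroup smaller")
})
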