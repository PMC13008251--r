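test_that("VCF fixture decodes to hand-derived allele counts", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB\tC",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1|1\t./.\t0|1"), vcf)
  g <- read_genotypes(vcf, "vcf")
  ## hand decoding: rows = samples A, B, C; columns = rs1, rs2
  expect_equal(unname(g$counts), rbind(c(0L, 2L), c(1L, NA), c(2L, 1L)))
  expect_equal(g$sample_ids, c("A", "B", "C"))
  expect_equal(g$variants$id, c("rs1", "rs2"))

  empty <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA"), empty)
  expect_error(read_genotypes(empty, "vcf"))
})

test_that("PLINK bed round-trips exactly, including missing calls", {
  set.seed(13)
  n <- 7; m <- 5   # odd sample count exercises byte padding
  counts <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  counts[3, 2] <- NA
  g <- genotype_matrix(counts, sample_ids = paste0("id", 1:n))
  prefix <- file.path(withr::local_tempdir(), "trio")
  write_plink(g, prefix)
  g2 <- read_genotypes(prefix, "plink")
  expect_identical(unname(g2$counts), unname(g$counts))
  expect_equal(g2$sample_ids, g$sample_ids)
  expect_equal(g2$variants$id, g$variants$id)
  expect_equal(g2$variants$pos, g$variants$pos)
  expect_equal(sum(is.na(g2$counts)), 1L)

  ## corrupted magic is refused
  bad <- file.path(withr::local_tempdir(), "bad")
  write_plink(g, bad)
  raw <- readBin(paste0(bad, ".bed"), "raw", 100)
  raw[1] <- as.raw(0)
  writeBin(raw, paste0(bad, ".bed"))
  expect_error(read_genotypes(bad, "plink"), "magic")
})

test_that("variant filters implement the standard thresholds", {
  set.seed(17)
  n <- 200
  common <- rbinom(n, 2, 0.4)
  rare <- rbinom(n, 2, 0.01)            # MAF ~0.01: removed at maf 0.05
  mono <- rep(0L, n)                    # monomorphic: removed
  dup <- common                         # r^2 = 1 with 'common'
  other <- rbinom(n, 2, 0.5)
  hwe_bad <- rep(1L, n)                 # all heterozygous: fails HWE
  counts <- cbind(common, rare, mono, dup, other, hwe_bad)
  colnames(counts) <- NULL
  g <- genotype_matrix(counts)
  f <- filter_config(maf_min = 0.05, hwe_p_min = 1e-6, ld_window = 10,
                     ld_step = 5, ld_r2 = 0.1)
  out <- apply_filters(g, f)
  kept <- out$variants$id
  expect_true("snp000001" %in% kept)    # common kept
  expect_false("snp000002" %in% kept)   # rare removed
  expect_false("snp000003" %in% kept)   # monomorphic removed
  expect_false("snp000004" %in% kept)   # duplicate pruned (later index)
  expect_false("snp000006" %in% kept)   # HWE failure removed
  ## idempotent
  out2 <- apply_filters(out, f)
  expect_identical(out2$counts, out$counts)
})

test_that("sample missingness, exclusion regions and empty results", {
  set.seed(19)
  counts <- matrix(rbinom(40 * 6, 2, 0.5), 40, 6)
  counts[1, 1:4] <- NA                  # sample 1: 67% missing
  g <- genotype_matrix(counts,
                       variants = data.frame(chrom = c(1, 1, 1, 6, 6, 2),
                                             pos = c(1e5, 2e5, 3e5, 26e6,
                                                     34e6, 1e5),
                                             id = paste0("v", 1:6),
                                             ref = "A", alt = "B"))
  f <- filter_config(maf_min = 0, mind_max = 0.5, geno_max = 1,
                     hwe_p_min = 0, ld_r2 = 0.999, ld_window = 3,
                     exclusion_regions = hla_region())
  out <- apply_filters(g, f)
  expect_equal(nrow(out$counts), 39L)           # high-missingness sample gone
  expect_false("v4" %in% out$variants$id)       # inside HLA window
  expect_true("v5" %in% out$variants$id)        # outside (34 Mb > 33.5 Mb)
  gmono <- genotype_matrix(matrix(0L, 10, 4))
  expect_error(apply_filters(gmono, filter_config(maf_min = 0.05)),
               "all variants removed")
})

test_that("Hardy-Weinberg mid-p agrees with a permutation oracle", {
  cases <- list(c(5, 10, 5), c(12, 4, 4), c(30, 10, 0), c(2, 16, 2))
  for (cs in cases) {
    n <- sum(cs)
    alleles <- rep(c(0L, 1L), c(2 * cs[1] + cs[2], 2 * cs[3] + cs[2]))
    set.seed(sum(cs) + cs[2])
    hets <- replicate(4000, {
      a <- sample(alleles)
      sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
    })
    ## mid-p from the empirical heterozygote-count distribution
    tab <- table(hets) / length(hets)
    p_obs <- tab[as.character(cs[2])]
    if (is.na(p_obs)) p_obs <- 0
    emp <- sum(tab[tab < p_obs]) + 0.5 * sum(tab[abs(tab - p_obs) < 1e-12])
    expect_equal(hwe_exact_midp(cs[1], cs[2], cs[3]), unname(emp),
                 tolerance = 0.05)
  }
  ## extreme departure is tiny
  expect_lt(hwe_exact_midp(0, 60, 0), 1e-6)
})

test_that("genotype PCA separates structure and satisfies its contracts", {
  ## two populations with fixed differences: PC1 separates them exactly
  n <- 40
  counts <- rbind(matrix(0L, n / 2, 20), matrix(2L, n / 2, 20))
  counts <- cbind(counts, matrix(rbinom(n * 10, 2, 0.5), n, 10))
  g <- genotype_matrix(counts)
  p <- suppressWarnings(pca(g, k = 3))
  grp <- rep(1:2, each = n / 2)
  expect_true(max(p$scores[grp == 1, 1]) < min(p$scores[grp == 2, 1]) ||
                min(p$scores[grp == 1, 1]) > max(p$scores[grp == 2, 1]))
  ## diagonal score covariance, orthonormal loadings, ordered variance
  cv <- crossprod(p$scores)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-8)
  expect_equal(crossprod(p$loadings), diag(3), tolerance = 1e-8)
  expect_true(all(diff(p$explained_variance) <= 1e-8))
  ## sign convention: largest-magnitude loading positive
  for (j in 1:3) {
    l <- p$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("PCA is sample-permutation equivariant up to sign", {
  co <- small_cohort(n_per = 50, n_snps = 200)
  p1 <- pca(co$genotypes, k = 4)
  set.seed(23)
  perm <- sample(nrow(co$genotypes$counts))
  g2 <- genotype_matrix(co$genotypes$counts[perm, ],
                        sample_ids = co$genotypes$sample_ids[perm])
  p2 <- pca(g2, k = 4)
  for (j in 1:4) {
    cc <- cor(p1$scores[perm, j], p2$scores[, j])
    expect_equal(abs(cc), 1, tolerance = 1e-6)
  }
})

test_that("eigenvec-style PC tables read with and without headers", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "pcs_hdr.tsv")
  writeLines(c("sample_id\tPC1\tPC2", "s1\t0.1\t-0.2", "s2\t0.3\t0.4"), p1)
  r1 <- read_pcs(p1)
  expect_equal(r1$sample_ids, c("s1", "s2"))
  expect_equal(r1$scores, rbind(c(0.1, -0.2), c(0.3, 0.4)))
  ## FID IID PC1 PC2, no header (plink eigenvec dialect)
  p2 <- file.path(dir, "pcs_nohdr.txt")
  writeLines(c("f1 s1 0.1 -0.2", "f2 s2 0.3 0.4"), p2)
  r2 <- read_pcs(p2)
  expect_equal(r2$sample_ids, c("s1", "s2"))
  expect_equal(ncol(r2$scores), 2L)
  ## write_pcs round trip
  p3 <- file.path(dir, "out.tsv")
  write_pcs(r1, p3)
  r3 <- read_pcs(p3)
  expect_equal(r3$scores, r1$scores)
})
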