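## Genotype I/O, variant/sample filtering, and genotype PCA.

#' Construct a genotype matrix
#'
#' The cohort container: an individuals x variants matrix of allele counts
#' (0/1/2, NA = missing call) with sample and variant metadata.
#'
#' @param counts integer matrix, individuals in rows.
#' @param sample_ids character vector (defaults to S00001, ...).
#' @param variants data frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt` (generated if omitted).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(counts, sample_ids = NULL, variants = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  bad <- !is.na(counts) & !(counts %in% 0:2)
  if (any(bad)) stop("genotype counts must be 0, 1, 2 or NA")
  n <- nrow(counts); m <- ncol(counts)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(n))
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (length(sample_ids) != n) stop("sample_ids length mismatch")
  if (is.null(variants))
    variants <- data.frame(chrom = rep(1L, m), pos = seq_len(m),
                           id = sprintf("snp%06d", seq_len(m)),
                           ref = rep("A", m), alt = rep("B", m))
  if (nrow(variants) != m) stop("variants row count mismatch")
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  structure(list(counts = counts, sample_ids = as.character(sample_ids),
                 variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$counts))
  cat("genotype_matrix:", nrow(x$counts), "individuals x", ncol(x$counts),
      "variants,", sprintf("%.2f%%", 100 * miss), "missing\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

## ---- PLINK .bed/.bim/.fam ----

## Per-byte 2-bit decode table (SNP-major .bed): 00 -> 2 copies of allele 1,
## 01 -> missing, 10 -> 1, 11 -> 0. Returned as a 256 x 4 integer matrix.
.bed_decode_table <- function() {
  codes <- c(2L, NA_integer_, 1L, 0L)
  tab <- matrix(0L, 256L, 4L)
  for (b in 0:255)
    tab[b + 1L, ] <- codes[1L + c(bitwAnd(b, 3L),
                                  bitwAnd(bitwShiftR(b, 2L), 3L),
                                  bitwAnd(bitwShiftR(b, 4L), 3L),
                                  bitwAnd(bitwShiftR(b, 6L), 3L))]
  tab
}

#' Read genotypes from PLINK or VCF files
#'
#' PLINK input is the binary `.bed` (v1.0 magic, SNP-major) with its `.bim`
#' and `.fam` companions; counts are dosages of the `.bim` A1 allele
#' (conventionally the minor allele). VCF input (plain or bgzipped) is read
#' with `vcfR` and counts are alternate-allele dosages. Sample order is
#' preserved.
#'
#' @param path PLINK prefix (without extension) or VCF path.
#' @param format `"plink"` or `"vcf"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("plink", "vcf")) {
  format <- match.arg(format)
  if (format == "plink") .read_plink(path) else .read_vcf(path)
}

.read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  ## .bim columns: chrom, id, cm, pos, allele1 (A1), allele2 (A2)
  bimd <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("chrom", "id", "cm", "pos",
                                          "a1", "a2"))
  famd <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(famd); m <- nrow(bimd)
  if (m == 0L) stop("empty variant set in ", bim)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic): ", bed)
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed supported: ", bed)
  bpv <- ceiling(n / 4)
  if (length(raw) - 3L != bpv * m)
    stop("sample/variant count mismatch in ", bed, ": expected ",
         bpv * m, " data bytes, found ", length(raw) - 3L)
  tab <- .bed_decode_table()
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv)
  counts <- matrix(NA_integer_, n, m)
  for (v in seq_len(m)) {
    g <- as.vector(t(tab[body[, v] + 1L, , drop = FALSE]))
    counts[, v] <- g[seq_len(n)]
  }
  variants <- data.frame(chrom = bimd$chrom, pos = bimd$pos, id = bimd$id,
                         ref = bimd$a2, alt = bimd$a1,
                         stringsAsFactors = FALSE)
  genotype_matrix(counts, sample_ids = as.character(famd[[2]]),
                  variants = variants)
}

.read_vcf <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)) || nrow(fix) == 0L) stop("empty variant set in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("no GT field in ", path)
  alt_count <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al != "0")
  }
  counts <- t(apply(gt, c(1, 2), alt_count))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[is.na(ids) | ids == ".", "CHROM"], ":",
           fix[is.na(ids) | ids == ".", "POS"])
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         id = ids, ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  genotype_matrix(counts, sample_ids = colnames(gt), variants = variants)
}

#' Write a genotype matrix to PLINK .bed/.bim/.fam
#'
#' Inverse of the PLINK reader: counts are encoded as A1 dosages in a
#' SNP-major v1.0 `.bed`. Round-trips exactly ([read_genotypes()] of the
#' output reproduces the counts, ids and positions).
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  counts <- g$counts; n <- nrow(counts); m <- ncol(counts)
  v <- g$variants
  utils::write.table(data.frame(v$chrom, v$id, 0L, v$pos, v$alt, v$ref),
                     paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(g$sample_ids, g$sample_ids, 0L, 0L, 0L, -9L),
                     paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ## 2-bit encode: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, n, m)
  code[counts == 2L] <- 0L
  code[counts == 1L] <- 2L
  code[is.na(counts)] <- 1L
  bpv <- ceiling(n / 4)
  pad <- bpv * 4L - n
  if (pad > 0L) code <- rbind(code, matrix(0L, pad, m))
  i1 <- seq(1L, nrow(code), by = 4L)
  bytes <- code[i1, , drop = FALSE] +
    4L * code[i1 + 1L, , drop = FALSE] +
    16L * code[i1 + 2L, , drop = FALSE] +
    64L * code[i1 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

## ---- filters ----

#' Variant and sample filter configuration
#'
#' Defaults follow the conventional biobank preprocessing recipe:
#' minor-allele frequency >= 0.05, per-sample missingness <= 0.1,
#' per-variant missingness <= 0.1, Hardy-Weinberg exact mid-p >= 1e-6, and
#' sliding-window LD pruning (window 1000 variants, step 50, r-squared
#' threshold 0.1). `exclusion_regions` takes a data frame with columns
#' `chrom`, `start`, `end`; [hla_region()] supplies the customary extended
#' HLA exclusion.
#'
#' @param maf_min minimum minor allele frequency.
#' @param mind_max maximum per-sample missingness.
#' @param geno_max maximum per-variant missingness.
#' @param hwe_p_min minimum Hardy-Weinberg exact mid-p value.
#' @param ld_window,ld_step,ld_r2 LD pruning window (variants), step, and
#'   r-squared threshold.
#' @param exclusion_regions data frame (`chrom`, `start`, `end`) or NULL.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(maf_min = 0.05, mind_max = 0.1, geno_max = 0.1,
                          hwe_p_min = 1e-6, ld_window = 1000L, ld_step = 50L,
                          ld_r2 = 0.1, exclusion_regions = NULL) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, mind_max >= 0, mind_max <= 1,
            geno_max >= 0, geno_max <= 1, hwe_p_min >= 0, hwe_p_min <= 1,
            ld_window >= 2, ld_step >= 1, ld_r2 > 0, ld_r2 <= 1)
  structure(list(maf_min = maf_min, mind_max = mind_max, geno_max = geno_max,
                 hwe_p_min = hwe_p_min, ld_window = as.integer(ld_window),
                 ld_step = as.integer(ld_step), ld_r2 = ld_r2,
                 exclusion_regions = exclusion_regions),
            class = "filter_config")
}

#' The extended HLA exclusion region
#'
#' Chromosome 6, 25,000,000-33,500,000: the major histocompatibility complex
#' plus flanks, customarily excluded before genotype PCA because its long,
#' strong LD otherwise dominates leading components.
#' @return a one-row data frame (`chrom`, `start`, `end`).
#' @export
hla_region <- function() {
  data.frame(chrom = "6", start = 25000000, end = 33500000)
}

#' Hardy-Weinberg exact test (mid-p)
#'
#' Exact test on genotype counts conditioning on allele counts, with the
#' mid-p correction (half weight on outcomes exactly as probable as the
#' observed heterozygote count).
#'
#' @param n_hom1,n_het,n_hom2 genotype counts.
#' @return the mid-p value.
#' @export
hwe_exact_midp <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  if (n == 0L) return(1)
  n_a <- 2L * n_hom1 + n_het
  n_b <- 2L * n_hom2 + n_het
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2L, rare, by = 2L)
  ## log-probabilities of heterozygote counts conditional on allele counts;
  ## the h-independent normalizer cancels below
  lp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[hets == n_het]
  tie <- abs(pr - p_obs) <= 1e-12 * p_obs
  ## mid-p: full weight on strictly less probable outcomes, half on ties
  ## (the observed outcome included)
  sum(pr[pr < p_obs & !tie]) + 0.5 * sum(pr[tie])
}

## Pairwise r^2 between genotype columns after mean imputation.
.geno_r2 <- function(counts) {
  Z <- counts
  cm <- colMeans(Z, na.rm = TRUE)
  for (j in seq_len(ncol(Z))) Z[is.na(Z[, j]), j] <- cm[j]
  suppressWarnings(stats::cor(Z))^2
}

#' Apply variant and sample filters
#'
#' In order: samples with missingness above `mind_max` are dropped; then
#' variants with missingness above `geno_max`, minor allele frequency below
#' `maf_min`, Hardy-Weinberg exact mid-p below `hwe_p_min`, or inside an
#' exclusion region; finally greedy LD pruning in sliding windows
#' (`ld_window` variants, step `ld_step`): of any remaining pair with
#' r-squared above `ld_r2` the later variant in genome order is removed.
#' Pruning passes repeat until no removal occurs, which makes the whole
#' operation idempotent.
#'
#' @param g a [genotype_matrix()].
#' @param f a [filter_config()].
#' @return the filtered `genotype_matrix`.
#' @export
apply_filters <- function(g, f = filter_config()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(f, "filter_config"))
  counts <- g$counts
  keep_s <- rowMeans(is.na(counts)) <= f$mind_max
  counts <- counts[keep_s, , drop = FALSE]
  ids <- g$sample_ids[keep_s]
  v <- g$variants

  miss <- colMeans(is.na(counts))
  p <- colMeans(counts, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep_v <- miss <= f$geno_max & maf >= f$maf_min

  if (f$hwe_p_min > 0) {
    for (j in which(keep_v)) {
      x <- counts[, j]
      hw <- hwe_exact_midp(sum(x == 0L, na.rm = TRUE),
                           sum(x == 1L, na.rm = TRUE),
                           sum(x == 2L, na.rm = TRUE))
      if (hw < f$hwe_p_min) keep_v[j] <- FALSE
    }
  }
  if (!is.null(f$exclusion_regions)) {
    for (k in seq_len(nrow(f$exclusion_regions))) {
      r <- f$exclusion_regions[k, ]
      keep_v <- keep_v & !(as.character(v$chrom) == as.character(r$chrom) &
                             v$pos >= r$start & v$pos <= r$end)
    }
  }
  counts <- counts[, keep_v, drop = FALSE]
  v <- v[keep_v, , drop = FALSE]
  if (ncol(counts) == 0L)
    stop("all variants removed; relax maf_min/geno_max/hwe_p_min thresholds")

  ## greedy LD pruning to a fixed point
  repeat {
    m <- ncol(counts)
    keep <- rep(TRUE, m)
    starts <- seq(1L, max(1L, m), by = f$ld_step)
    removed <- FALSE
    for (s in starts) {
      e <- min(s + f$ld_window - 1L, m)
      if (e <= s) next
      idx <- s:e
      live <- idx[keep[idx]]
      if (length(live) < 2L) next
      r2 <- .geno_r2(counts[, live, drop = FALSE])
      for (a in seq_along(live)) {
        if (!keep[live[a]]) next
        for (b in seq_along(live)) {
          if (b <= a || !keep[live[b]]) next
          if (!is.na(r2[a, b]) && r2[a, b] > f$ld_r2) {
            keep[live[b]] <- FALSE
            removed <- TRUE
          }
        }
      }
      if (e == m) break
    }
    counts <- counts[, keep, drop = FALSE]
    v <- v[keep, , drop = FALSE]
    if (!removed) break
  }
  genotype_matrix(counts, sample_ids = ids, variants = v)
}

## ---- PCA ----

## Top-k SVD. Small problems use LAPACK directly; large ones use randomized
## subspace iteration (Halko-Martinsson-Tropp) with a fixed internal seed,
## which keeps the result deterministic and exactly equivariant under row
## permutations (the test matrix depends only on the column count). The
## returned factors are orthonormal by construction.
.truncated_svd <- function(Z, k, oversample = 10L, power_iter = 4L) {
  m <- ncol(Z); n <- nrow(Z)
  if (min(m, n) <= 512L || k > min(m, n) / 4) return(svd(Z, nu = k, nv = k))
  l <- min(k + oversample, m, n)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(771L)
  Omega <- matrix(stats::rnorm(m * l), m, l)
  Q <- qr.Q(qr(Z %*% Omega))
  for (i in seq_len(power_iter)) {
    Q <- qr.Q(qr(crossprod(Z, Q)))
    Q <- qr.Q(qr(Z %*% Q))
  }
  B <- crossprod(Q, Z)          # l x m
  sb <- svd(B, nu = k, nv = k)
  list(u = Q %*% sb$u, d = sb$d, v = sb$v)
}

#' Principal components of standardized genotypes
#'
#' Missing calls are mean-imputed per variant; columns are centred at twice
#' the allele frequency and scaled by sqrt(2 p (1 - p)), the customary
#' drift-variance standardization for genotype PCA; the top-k components
#' come from the singular value decomposition. Sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param g a [genotype_matrix()], or a plain numeric matrix which is then
#'   centred and scaled by column standard deviations.
#' @param k number of components.
#' @return an object of class `pc_matrix`: `scores` (n x k),
#'   `explained_variance` (non-increasing), `loadings` (orthonormal
#'   columns), `sample_ids`, `k`.
#' @export
pca <- function(g, k = 10L) {
  if (inherits(g, "genotype_matrix")) {
    counts <- g$counts
    p <- colMeans(counts, na.rm = TRUE) / 2
    keep <- p > 0 & p < 1
    if (!all(keep)) {
      warning(sum(!keep), " zero-variance variant(s) dropped before PCA")
      counts <- counts[, keep, drop = FALSE]
      p <- p[keep]
    }
    Z <- sweep(counts, 2L, 2 * p)
    Z[is.na(Z)] <- 0
    Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
    ids <- g$sample_ids
  } else {
    Z <- scale(as.matrix(g))
    Z[is.na(Z)] <- 0
    ids <- rownames(g)
  }
  n <- nrow(Z)
  k <- as.integer(min(k, dim(Z)))
  sv <- .truncated_svd(Z, k)
  flip <- vapply(seq_len(k), function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u, 2L, sv$d[seq_len(k)] * flip, "*")
  loadings <- sweep(sv$v, 2L, flip, "*")
  structure(list(scores = scores,
                 explained_variance = sv$d[seq_len(k)]^2 / (n - 1),
                 loadings = loadings, sample_ids = ids, k = k),
            class = "pc_matrix")
}

#' @export
print.pc_matrix <- function(x, ...) {
  cat("pc_matrix:", nrow(x$scores), "individuals x", x$k, "components\n")
  invisible(x)
}

#' Read a precomputed principal-component table
#'
#' Accepts the eigenvec dialect: whitespace- or tab-delimited, an optional
#' header, either `FID IID PC1 ...` or `ID PC1 ...` layouts.
#'
#' @param path file path.
#' @return a `pc_matrix` (with `explained_variance` unknown, set to NA).
#' @export
read_pcs <- function(path) {
  first <- readLines(path, n = 1L)
  toks <- strsplit(trimws(first), "[ \t]+")[[1]]
  ## a header line has no numeric token at all
  header <- suppressWarnings(all(is.na(as.numeric(toks))))
  d <- utils::read.table(path, header = header, stringsAsFactors = FALSE)
  num <- vapply(d, is.numeric, logical(1))
  first_num <- which(num)[1]
  ids <- as.character(d[[max(1L, first_num - 1L)]])
  scores <- as.matrix(d[, num, drop = FALSE])
  structure(list(scores = unname(scores),
                 explained_variance = rep(NA_real_, ncol(scores)),
                 loadings = NULL, sample_ids = ids, k = ncol(scores)),
            class = "pc_matrix")
}

#' Write principal-component scores as a TSV
#' @param pcs a `pc_matrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pcs <- function(pcs, path) {
  d <- data.frame(sample_id = pcs$sample_ids %||% seq_len(nrow(pcs$scores)),
                  pcs$scores)
  names(d)[-1] <- paste0("PC", seq_len(ncol(pcs$scores)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
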