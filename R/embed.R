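## Low-dimensional neighborhood-preserving embedding of genotype PCs.
##
## The construction follows the UMAP recipe: a fuzzy k-nearest-neighbour
## graph with locally adaptive bandwidths is built in the input space, and
## low-dimensional coordinates are optimized so that graph neighbours
## attract (through the smooth output kernel 1 / (1 + a d^(2b)) whose shape
## encodes min_dist) while sampled non-neighbours repel. Initialization is
## the scaled leading principal components, so optimization is deterministic
## given the seed. Exact (brute-force) nearest neighbours are used; the
## implementation targets cohorts up to a few tens of thousands of samples.

#' Embedding parameters
#'
#' Two parameter doctrines apply. For clustering, reduce to 3 or more
#' dimensions with `min_dist` near 0 so that dense clumps stay dense
#' (defaults: 5 components, 50 neighbours, min_dist 0). For visualization,
#' reduce to 2 dimensions with a relatively high `min_dist` (0.3-0.5) for
#' legibility; [embed_params_viz()] supplies those defaults.
#'
#' @param n_components output dimensionality (>= 2).
#' @param n_neighbors neighbourhood size of the fuzzy graph (>= 2).
#' @param min_dist minimum spacing of points in the output space (>= 0).
#' @param seed integer seed for the layout optimization.
#' @param input_dims number of leading input PCs consumed (default 40).
#' @param n_epochs layout optimization iterations.
#' @return an object of class `embed_params`.
#' @export
embed_params <- function(n_components = 5L, n_neighbors = 50L,
                         min_dist = 0, seed = 1L, input_dims = 40L,
                         n_epochs = 200L) {
  n_components <- as.integer(n_components)
  n_neighbors <- as.integer(n_neighbors)
  if (n_components < 2L) stop("n_components must be >= 2")
  if (n_neighbors < 2L) stop("n_neighbors must be >= 2")
  if (min_dist < 0) stop("min_dist must be >= 0")
  structure(list(n_components = n_components, n_neighbors = n_neighbors,
                 min_dist = min_dist, seed = as.integer(seed),
                 input_dims = as.integer(input_dims),
                 n_epochs = as.integer(n_epochs)),
            class = "embed_params")
}

#' @rdname embed_params
#' @export
embed_params_viz <- function(n_components = 2L, n_neighbors = 50L,
                             min_dist = 0.3, seed = 1L, input_dims = 40L,
                             n_epochs = 200L) {
  embed_params(n_components, n_neighbors, min_dist, seed, input_dims,
               n_epochs)
}

## k nearest neighbours (self excluded), exact. Returns index and distance
## matrices of dimension n x k.
.knn_exact <- function(X, k) {
  D <- .dense_dist(X)
  n <- nrow(D)
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    o <- order(D[i, ])          # self first (distance 0)
    o <- o[o != i][seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- D[i, o]
  }
  list(idx = idx, dist = dst)
}

## Locally adaptive bandwidths: for each point find sigma_i such that
## sum_j exp(-(d_ij - rho_i)/sigma_i) = log2(k), rho_i the nearest distance.
.smooth_knn_weights <- function(knn) {
  k <- ncol(knn$dist)
  target <- log2(k)
  n <- nrow(knn$dist)
  W <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- knn$dist[i, ]
    rho <- min(d[d > 0], Inf)
    if (!is.finite(rho)) { W[i, ] <- 1; next }
    dd <- pmax(d - rho, 0)
    lo <- 0; hi <- Inf; sigma <- 1
    for (it in 1:64) {
      s <- sum(exp(-dd / sigma))
      if (abs(s - target) < 1e-5) break
      if (s > target) { hi <- sigma; sigma <- (lo + hi) / 2 }
      else { lo <- sigma; sigma <- if (is.finite(hi)) (lo + hi) / 2 else sigma * 2 }
    }
    W[i, ] <- exp(-dd / sigma)
  }
  W
}

## Fit the output kernel 1 / (1 + a d^(2b)) to the min_dist plateau curve.
.find_ab <- function(min_dist, spread = 1) {
  x <- seq(1e-3, 3 * spread, length.out = 300)
  y <- ifelse(x <= min_dist, 1, exp(-(x - min_dist) / spread))
  fit <- try(stats::nls(y ~ 1 / (1 + a * x^(2 * b)),
                        start = list(a = 1.5, b = 1),
                        control = stats::nls.control(maxiter = 200,
                                                     warnOnly = TRUE)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(c(a = 1.929, b = 0.7915))
  cf <- stats::coef(fit)
  c(a = unname(cf["a"]), b = unname(cf["b"]))
}

#' Embed principal components into a low-dimensional space
#'
#' Builds the fuzzy k-NN graph on the leading `input_dims` PCs and
#' optimizes `n_components` output coordinates with attraction along graph
#' edges and repulsion against sampled non-neighbours. Deterministic given
#' `p$seed`.
#'
#' @param pcs a `pc_matrix` (or plain matrix of coordinates).
#' @param p an [embed_params()] object.
#' @return an object of class `embedding` with `coords` (n x n_components)
#'   and `params`.
#' @export
embed <- function(pcs, p = embed_params()) {
  X <- if (inherits(pcs, "pc_matrix")) pcs$scores else as.matrix(pcs)
  d_in <- min(p$input_dims, ncol(X))
  X <- X[, seq_len(d_in), drop = FALSE]
  n <- nrow(X)
  if (p$n_neighbors >= n) stop("n_neighbors must be smaller than the sample size")
  knn <- .knn_exact(X, p$n_neighbors)
  W <- .smooth_knn_weights(knn)

  ## symmetrize: w_sym = w + w' - w w'  on the union of directed edges
  ei <- rep(seq_len(n), p$n_neighbors)
  ej <- as.vector(knn$idx)
  ew <- as.vector(W)
  key <- pmin(ei, ej) * (n + 1) + pmax(ei, ej)
  first <- !duplicated(key)
  grp <- match(key, key[first])
  w1 <- ew[first]
  w2 <- numeric(sum(first))
  dup <- duplicated(key)
  w2[grp[dup]] <- ew[dup]
  ui <- pmin(ei, ej)[first]; uj <- pmax(ei, ej)[first]
  uw <- w1 + w2 - w1 * w2

  ab <- .find_ab(p$min_dist)
  a <- ab["a"]; b <- ab["b"]

  ## PCA initialization, scaled to a 10-unit radius, with a seeded jitter to
  ## break exact coincidences
  set.seed(p$seed)
  Y <- matrix(0, n, p$n_components)
  dd <- min(p$n_components, ncol(X))
  Y[, seq_len(dd)] <- X[, seq_len(dd), drop = FALSE]
  Y <- Y / max(abs(Y)) * 10
  Y <- Y + matrix(stats::rnorm(n * p$n_components, 0, 1e-4), n)

  n_neg <- 5L
  eps <- 1e-3
  n_edge <- length(ui)
  ## signed incidence matrix: force on an edge maps to +/- on its endpoints
  inc <- Matrix::sparseMatrix(i = c(ui, uj), j = rep(seq_len(n_edge), 2L),
                              x = rep(c(1, -1), each = n_edge),
                              dims = c(n, n_edge))
  ## per-point incident edge mass, to normalize so dense hubs do not overshoot
  mass <- as.vector(Matrix::sparseMatrix(i = c(ui, uj),
                                         j = rep(1L, 2L * n_edge),
                                         x = rep(uw, 2L),
                                         dims = c(n, 1L)))
  mass <- pmax(mass, 1)
  ridx <- seq_len(n)
  for (it in seq_len(p$n_epochs)) {
    alpha <- 1 - (it - 1) / p$n_epochs
    ## attraction along graph edges
    diff <- Y[ui, , drop = FALSE] - Y[uj, , drop = FALSE]
    d2 <- rowSums(diff * diff)
    coef <- (-2 * a * b * d2^(b - 1)) / (a * d2^b + 1)
    coef[!is.finite(coef)] <- 0
    g <- coef * diff
    g[g > 4] <- 4; g[g < -4] <- -4
    disp <- as.matrix(inc %*% (g * uw))
    Y <- Y + alpha * disp / mass
    ## repulsion from sampled non-neighbours
    rj <- sample.int(n, n * n_neg, replace = TRUE)
    diff <- Y[rep.int(ridx, n_neg), , drop = FALSE] - Y[rj, , drop = FALSE]
    d2 <- rowSums(diff * diff)
    coef <- (2 * b) / ((eps + d2) * (a * d2^b + 1))
    g <- coef * diff
    g[g > 4] <- 4; g[g < -4] <- -4
    rep_disp <- g[ridx, , drop = FALSE]
    for (s in seq_len(n_neg - 1L))
      rep_disp <- rep_disp + g[s * n + ridx, , drop = FALSE]
    Y <- Y + alpha * rep_disp / n_neg
  }
  structure(list(coords = Y, params = p), class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("embedding:", nrow(x$coords), "points in", ncol(x$coords),
      "dimensions (n_neighbors =", x$params$n_neighbors,
      ", min_dist =", x$params$min_dist, ")\n")
  invisible(x)
}

#' Neighborhood preservation of an embedding
#'
#' Mean Jaccard overlap between each point's k-nearest-neighbour set in the
#' input space and in the embedded space. 1 means the local neighbourhoods
#' are perfectly preserved; a random embedding scores about k / (n - 1).
#'
#' @param pcs input coordinates (`pc_matrix` or matrix).
#' @param e an [embed()] result (or plain coordinate matrix).
#' @param k neighbourhood size (< n).
#' @return a number in `[0, 1]`.
#' @export
neighborhood_preservation <- function(pcs, e, k = 15L) {
  X <- if (inherits(pcs, "pc_matrix")) pcs$scores else as.matrix(pcs)
  if (inherits(e, "embedding")) {
    X <- X[, seq_len(min(e$params$input_dims, ncol(X))), drop = FALSE]
    Y <- e$coords
  } else Y <- as.matrix(e)
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the sample size")
  a <- .knn_exact(X, k)$idx
  b <- .knn_exact(Y, k)$idx
  mean(vapply(seq_len(n), function(i) {
    inter <- length(intersect(a[i, ], b[i, ]))
    inter / (2 * k - inter)
  }, numeric(1)))
}
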