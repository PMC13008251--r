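## Grids of pipeline parametrizations and ensemble phenotype smoothing.
##
## A single clustering is sensitive to parameter choices; averaging
## per-cluster phenotype means over many parametrizations gives a smoothed
## per-individual estimate mu_i whose averaging neighbourhood adapts to the
## topology of the data: for individual i with phenotype m(i) and cluster
## mates s_p(i) in parametrization p, mu_{p,i} = mean of m over s_p(i) and
## mu_i = mean of mu_{p,i} over the parametrization set P.

#' Construct a grid of pipeline parametrizations
#'
#' Cartesian product of embedding and clustering settings. The default grid
#' (dims 3/4/5 x neighbours 10/15/25/50 x min_dist 0/0.01 x epsilon-hat
#' 0.3/0.4/0.5 x min cluster size 25/100 x 2 seeds) has 288 parametrizations,
#' matching the ensemble size used for biobank-scale smoothing.
#'
#' @param dims,n_neighbors,min_dist embedding settings to cross.
#' @param epsilon_hat,min_cluster_size clustering settings to cross.
#' @param seeds embedding seeds to cross.
#' @param input_dims,n_epochs shared embedding settings.
#' @return an object of class `param_grid`: a list of parametrizations,
#'   each `list(embed = embed_params, cluster = cluster_params)`.
#' @export
param_grid <- function(dims = c(3L, 4L, 5L),
                       n_neighbors = c(10L, 15L, 25L, 50L),
                       min_dist = c(0, 0.01),
                       epsilon_hat = c(0.3, 0.4, 0.5),
                       min_cluster_size = c(25L, 100L),
                       seeds = 1:2,
                       input_dims = 40L, n_epochs = 200L) {
  cfg <- expand.grid(dim = dims, nb = n_neighbors, md = min_dist,
                     eps = epsilon_hat, mcs = min_cluster_size, seed = seeds,
                     KEEP.OUT.ATTRS = FALSE)
  if (anyDuplicated(cfg)) stop("duplicate parametrization in grid")
  grid <- lapply(seq_len(nrow(cfg)), function(r) {
    list(embed = embed_params(n_components = cfg$dim[r],
                              n_neighbors = cfg$nb[r],
                              min_dist = cfg$md[r], seed = cfg$seed[r],
                              input_dims = input_dims, n_epochs = n_epochs),
         cluster = cluster_params(min_cluster_size = cfg$mcs[r],
                                  epsilon_hat = cfg$eps[r]))
  })
  structure(grid, class = "param_grid")
}

#' @export
print.param_grid <- function(x, ...) {
  cat("param_grid:", length(x), "parametrizations\n")
  invisible(x)
}

#' Residualize a phenotype on covariates and principal components
#'
#' Ordinary least squares of the phenotype on an intercept, the covariates,
#' and the PC scores; collinear columns are dropped with a warning. The
#' returned residual (and its standard deviation sigma) is the input to
#' [smooth_phenotype()]: structure remaining in it is what PC adjustment
#' failed to absorb.
#'
#' @param phenotype numeric vector.
#' @param covariates optional numeric matrix or data frame (e.g. sex, age,
#'   age squared).
#' @param pcs optional `pc_matrix` or matrix of scores.
#' @return a list with `residuals`, `sigma`, and `fitted`.
#' @export
residualize <- function(phenotype, covariates = NULL, pcs = NULL) {
  y <- as.numeric(phenotype)
  X <- matrix(1, length(y), 1)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (!is.null(pcs))
    X <- cbind(X, if (inherits(pcs, "pc_matrix")) pcs$scores else as.matrix(pcs))
  if (anyNA(y) || anyNA(X)) stop("missing values in phenotype or design")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    warning(ncol(X) - qr_x$rank, " collinear design column(s) dropped")
  res <- qr.resid(qr_x, y)
  list(residuals = res, sigma = stats::sd(res), fitted = y - res)
}

#' Run a grid of clustering parametrizations
#'
#' Executes embed-then-cluster once per parametrization. A failing run is
#' dropped with a warning (the effective ensemble size shrinks accordingly).
#'
#' @param pcs a `pc_matrix`.
#' @param grid a [param_grid()].
#' @return a list of `cluster_labels`, one per successful run, each carrying
#'   its parametrization as provenance.
#' @export
run_grid <- function(pcs, grid) {
  stopifnot(length(grid) >= 1L)
  runs <- lapply(seq_along(grid), function(r) {
    p <- grid[[r]]
    tryCatch({
      e <- embed(pcs, p$embed)
      cl <- cluster(e$coords, p$cluster)
      cl$params <- list(embed = p$embed, cluster = p$cluster)
      cl
    }, error = function(err) {
      warning("parametrization ", r, " failed: ", conditionMessage(err))
      NULL
    })
  })
  runs[!vapply(runs, is.null, logical(1))]
}

#' Ensemble phenotype smoothing across parametrizations
#'
#' For each run p, every individual receives the mean phenotype of its
#' cluster (a noise point forms a singleton and keeps its own value); the
#' smoothed value mu_i is the average of these per-run cluster means over
#' all runs. With a single run this is the ordinary per-cluster mean; with
#' identical runs it collapses to the same.
#'
#' @param m numeric phenotype (typically a PC-adjusted residual).
#' @param runs a list of `cluster_labels` (or a single one).
#' @param keep_per_run if TRUE, retain the n x |P| matrix of per-run means.
#' @return an object of class `smoothed_phenotype` with `mu`,
#'   `ensemble_size`, and `phenotype_sd`.
#' @export
smooth_phenotype <- function(m, runs, keep_per_run = FALSE) {
  if (inherits(runs, "cluster_labels")) runs <- list(runs)
  if (length(runs) == 0L) stop("no runs supplied")
  m <- as.numeric(m)
  if (anyNA(m)) stop("phenotype must be finite")
  per_run <- vapply(runs, function(cl) {
    lab <- cl$labels
    if (length(lab) != length(m)) stop("run length does not match phenotype")
    grp <- ifelse(lab == -1L, -seq_along(lab) - 1L, lab)  # noise: singleton
    stats::ave(m, grp)
  }, numeric(length(m)))
  per_run <- matrix(per_run, nrow = length(m))
  mu <- rowMeans(per_run)
  structure(list(mu = mu,
                 per_run = if (keep_per_run) per_run else NULL,
                 ensemble_size = length(runs),
                 phenotype_sd = stats::sd(m)),
            class = "smoothed_phenotype")
}

#' @export
print.smoothed_phenotype <- function(x, ...) {
  cat("smoothed_phenotype:", length(x$mu), "individuals, ensemble of",
      x$ensemble_size, "runs (sd of input:",
      signif(x$phenotype_sd, 4), ")\n")
  invisible(x)
}
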