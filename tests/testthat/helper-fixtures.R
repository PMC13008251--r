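## Fixtures built in code; all randomness behind explicit seeds.

## Random blob centres with a minimum pairwise separation, so clustering
## outcomes are invariant to tie-resolution in the mutual reachability
## graph (overlapping clouds make boundary labels tie-dependent).
separated_centers <- function(k, d, min_sep, seed) {
  set.seed(seed)
  repeat {
    ctr <- matrix(runif(k * d, -10, 10), k, d)
    if (min(dist(ctr)) >= min_sep) return(ctr)
  }
}

## Gaussian blobs around given centres (matrix: one row per blob).
make_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  centers <- as.matrix(centers)
  n_per <- rep_len(n_per, nrow(centers))
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    sweep(matrix(rnorm(n_per[k] * ncol(centers), 0, sd), n_per[k]),
          2, centers[k, ], "+")
  }))
  list(X = X, labels = rep(seq_len(nrow(centers)), n_per))
}

## Three spatial scales in 2D: three far-apart groups (distance 6), each of
## three micro-blobs 0.35 apart, plus a sparse ring of stragglers at radius
## 0.8 per group. At epsilon-hat 0 the micro-blobs are separate clusters and
## the stragglers are noise; at 0.5 each group merges into one cluster that
## absorbs its stragglers.
three_scale_fixture <- function(seed = 42) {
  set.seed(seed)
  groups <- rbind(c(0, 0), c(6, 0), c(0, 6))
  micro <- rbind(c(0, 0), c(0.35, 0), c(0, 0.35))
  X <- NULL
  for (g in seq_len(3)) {
    for (m in seq_len(3)) {
      X <- rbind(X, sweep(matrix(rnorm(24, 0, 0.02), 12), 2,
                          groups[g, ] + micro[m, ], "+"))
    }
    ang <- runif(6, 0, 2 * pi)
    X <- rbind(X, sweep(cbind(cos(ang), sin(ang)) * 0.8, 2, groups[g, ], "+"))
  }
  X
}

## Independent brute-force Kruskal MST total weight on a dense matrix.
kruskal_total_weight <- function(M) {
  n <- nrow(M)
  pairs <- which(upper.tri(M), arr.ind = TRUE)
  ord <- order(M[upper.tri(M)])
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  total <- 0; used <- 0L
  for (e in ord) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      total <- total + M[i, j]
      used <- used + 1L
      if (used == n - 1L) break
    }
  }
  total
}

## Mutual reachability matrix computed independently of the package path.
mutual_reachability_oracle <- function(X, min_samples) {
  D <- as.matrix(dist(X))
  core <- apply(D, 1, function(r) sort(r)[min_samples])
  pmax(D, outer(core, core, pmax))
}

## Pair-counting ARI oracle: direct loop over all C(n,2) pairs.
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  s_both <- s_a <- s_b <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ai <- a[i] == a[j]; bi <- b[i] == b[j]
    s_both <- s_both + (ai && bi)
    s_a <- s_a + ai; s_b <- s_b + bi
  }
  e <- s_a * s_b / choose(n, 2)
  (s_both - e) / ((s_a + s_b) / 2 - e)
}

## Small discrete cohort shared across tests.
small_cohort <- function(n_pops = 3, n_per = 60, n_snps = 400, F = 0.15,
                         seed = 11) {
  simulate_discrete(population_spec(n_pops, n_per, F = F, n_snps = n_snps,
                                    seed = seed))
}
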