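#' Clustering parameters for epsilon-augmented hierarchical density clustering
#'
#' Bundles the tuning parameters of the density clustering stage. The central
#' parameter is `epsilon_hat`, a distance threshold below which splits in the
#' cluster hierarchy are ignored: micro-clusters first appearing at a distance
#' smaller than `epsilon_hat` are merged into their enclosing branch, which
#' sharply reduces the number of points discarded as noise. `epsilon_hat = 0`
#' recovers classic excess-of-mass HDBSCAN.
#'
#' @param min_cluster_size minimum number of points a cluster must contain
#'   (>= 2).
#' @param min_samples number of neighbours (counting the point itself) used
#'   for the core-distance density estimate; defaults to `min_cluster_size`.
#' @param epsilon_hat cluster-selection distance threshold (>= 0), in the
#'   units of the embedded space. Useful values in practice lie around
#'   0.3--0.5 for embeddings on the default coordinate scale.
#' @param metric distance metric; only `"euclidean"` is supported.
#' @return an object of class `cluster_params`.
#' @export
cluster_params <- function(min_cluster_size = 25L, min_samples = NULL,
                           epsilon_hat = 0.5, metric = "euclidean") {
  min_cluster_size <- as.integer(min_cluster_size)
  if (is.na(min_cluster_size) || min_cluster_size < 2L)
    stop("min_cluster_size must be an integer >= 2")
  if (is.null(min_samples)) min_samples <- min_cluster_size
  min_samples <- as.integer(min_samples)
  if (is.na(min_samples) || min_samples < 1L)
    stop("min_samples must be an integer >= 1")
  if (!is.numeric(epsilon_hat) || length(epsilon_hat) != 1L || epsilon_hat < 0)
    stop("epsilon_hat must be a single non-negative number")
  metric <- match.arg(metric, "euclidean")
  structure(list(min_cluster_size = min_cluster_size,
                 min_samples = min_samples,
                 epsilon_hat = epsilon_hat,
                 metric = metric),
            class = "cluster_params")
}

#' @export
print.cluster_params <- function(x, ...) {
  cat("cluster_params: min_cluster_size =", x$min_cluster_size,
      ", min_samples =", x$min_samples,
      ", epsilon_hat =", x$epsilon_hat, "\n")
  invisible(x)
}

## Dense Euclidean distance matrix. Kept as a helper so every stage shares
## one definition (and its zero-clamping of negative rounding error).
.dense_dist <- function(X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite coordinates in input")
  D <- as.matrix(stats::dist(X))
  dimnames(D) <- NULL
  D
}

#' Core distances
#'
#' The core distance of a point is the distance to its `min_samples`-th
#' nearest neighbour, counting the point itself as the first. It is the
#' local-density proxy from which mutual reachability distances are built:
#' points in sparse regions get large core distances and are therefore pushed
#' apart in the mutual reachability metric.
#'
#' @param X numeric matrix of coordinates (rows = points).
#' @param min_samples neighbour count, self included.
#' @return numeric vector of per-point core distances.
#' @export
core_distances <- function(X, min_samples) {
  X <- as.matrix(X)
  n <- nrow(X)
  min_samples <- as.integer(min_samples)
  if (min_samples > n) stop("min_samples exceeds the number of points")
  if (min_samples == 1L) return(numeric(n))
  D <- .dense_dist(X)
  apply(D, 1L, function(r) sort.int(r, partial = min_samples)[min_samples])
}

## Prim's algorithm on a dense symmetric weight matrix. Ties are resolved
## towards the lowest vertex index, which which.min provides.
.prim_mst <- function(M) {
  n <- nrow(M)
  from <- integer(n - 1L); to <- integer(n - 1L); w <- numeric(n - 1L)
  in_tree <- logical(n); in_tree[1L] <- TRUE
  best_w <- M[1L, ]
  best_from <- rep.int(1L, n)
  best_w[1L] <- Inf
  for (step in seq_len(n - 1L)) {
    v <- which.min(best_w)
    from[step] <- best_from[v]; to[step] <- v; w[step] <- best_w[v]
    in_tree[v] <- TRUE
    best_w[v] <- Inf
    mv <- M[v, ]
    upd <- !in_tree & mv < best_w
    if (any(upd)) {
      best_w[upd] <- mv[upd]
      best_from[upd] <- v
    }
  }
  data.frame(i = pmin(from, to), j = pmax(from, to), weight = w)
}

#' Mutual reachability graph and its minimum spanning tree
#'
#' The mutual reachability distance between two points is
#' `max(core(a), core(b), d(a, b))`; it smooths the raw metric so that points
#' in locally sparse regions cannot form spuriously tight links. The cluster
#' hierarchy is the single-linkage tree of this metric, obtained from its
#' minimum spanning tree.
#'
#' @param X numeric coordinate matrix.
#' @param params a [cluster_params()] object.
#' @return an object of class `mutual_reachability_graph` with elements
#'   `core_dist` (per point) and `mst_edges` (data frame `i`, `j`, `weight`,
#'   `n - 1` rows).
#' @export
mutual_reachability_mst <- function(X, params = cluster_params()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 points")
  if (!all(is.finite(X))) stop("non-finite coordinates in input")
  D <- .dense_dist(X)
  ms <- min(params$min_samples, n)
  core <- if (ms == 1L) numeric(n) else
    apply(D, 1L, function(r) sort.int(r, partial = ms)[ms])
  M <- pmax(D, outer(core, core, pmax))
  edges <- .prim_mst(M)
  structure(list(core_dist = core, mst_edges = edges, n = n),
            class = "mutual_reachability_graph")
}

## Single-linkage tree from MST edges via union-find.
## Returns children (2n-1 x 2), heights, sizes; nodes 1..n are points,
## node 2n-1 is the root.
.single_linkage <- function(edges, n) {
  ord <- order(edges$weight, edges$i, edges$j)
  ei <- edges$i[ord]; ej <- edges$j[ord]; ew <- edges$weight[ord]
  parent_uf <- seq_len(n)              # union-find over points
  node_of <- seq_len(n)                # uf root -> current SLT node
  total <- 2L * n - 1L
  children <- matrix(0L, total, 2L)
  heights <- numeric(total)
  sizes <- c(rep.int(1L, n), integer(n - 1L))
  uf_find <- function(x) {
    while (parent_uf[x] != x) {
      parent_uf[x] <<- parent_uf[parent_uf[x]]
      x <- parent_uf[x]
    }
    x
  }
  for (k in seq_len(n - 1L)) {
    ra <- uf_find(ei[k]); rb <- uf_find(ej[k])
    node <- n + k
    children[node, ] <- c(node_of[ra], node_of[rb])
    heights[node] <- ew[k]
    sizes[node] <- sizes[node_of[ra]] + sizes[node_of[rb]]
    parent_uf[rb] <- ra
    node_of[ra] <- node
  }
  list(children = children, heights = heights, sizes = sizes, root = total)
}

## All leaf point indices under an SLT node, iteratively.
.slt_leaves <- function(children, node, n) {
  if (node <= n) return(node)
  stack <- node
  out <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n) out[length(out) + 1L] <- v
    else stack <- c(stack, children[v, 1L], children[v, 2L])
  }
  out
}

#' Condensed cluster hierarchy
#'
#' Walks the single-linkage hierarchy from the root down and prunes it by
#' `min_cluster_size`: at each split, a side with fewer than
#' `min_cluster_size` points "falls out" of its parent cluster at that
#' density (recorded as individual point departures at lambda = 1/distance),
#' while a sufficiently large side becomes a child cluster. Cluster
#' stabilities -- the total excess of mass sum((lambda_leave - lambda_birth))
#' over member points -- drive the later extraction step.
#'
#' @param g a [mutual_reachability_mst()] result.
#' @param min_cluster_size minimum cluster size.
#' @return an object of class `condensed_tree`: a departure table
#'   (`parent`, `child`, `lambda_val`, `child_size`; children `<= n` are
#'   points, larger ids are clusters), plus per-cluster `lambda_birth` and
#'   `stability`. The root cluster has id `n + 1`.
#' @export
build_condensed_tree <- function(g, min_cluster_size) {
  stopifnot(inherits(g, "mutual_reachability_graph"))
  n <- g$n
  mcs <- as.integer(min_cluster_size)
  slt <- .single_linkage(g$mst_edges, n)
  children <- slt$children; heights <- slt$heights; sizes <- slt$sizes

  cap <- 3L * n + 2L
  r_parent <- integer(cap); r_child <- integer(cap)
  r_lambda <- numeric(cap); r_size <- integer(cap)
  nrows <- 0L
  add_row <- function(p, c, l, s) {
    nrows <<- nrows + 1L
    r_parent[nrows] <<- p; r_child[nrows] <<- c
    r_lambda[nrows] <<- l; r_size[nrows] <<- s
  }

  relabel <- integer(2L * n - 1L)
  next_cluster <- n + 1L
  relabel[slt$root] <- next_cluster
  queue <- integer(2L * n); queue[1L] <- slt$root
  qh <- 1L; qt <- 1L
  while (qh <= qt) {
    node <- queue[qh]; qh <- qh + 1L
    cl <- relabel[node]
    a <- children[node, 1L]; b <- children[node, 2L]
    d <- heights[node]
    lam <- if (d > 0) 1 / d else Inf
    na <- sizes[a]; nb <- sizes[b]
    if (na >= mcs && nb >= mcs) {
      for (ch in c(a, b)) {
        next_cluster <- next_cluster + 1L
        relabel[ch] <- next_cluster
        add_row(cl, next_cluster, lam, sizes[ch])
        qt <- qt + 1L; queue[qt] <- ch
      }
    } else if (na < mcs && nb < mcs) {
      for (p in c(.slt_leaves(children, a, n), .slt_leaves(children, b, n)))
        add_row(cl, p, lam, 1L)
    } else {
      big <- if (na >= mcs) a else b
      small <- if (na >= mcs) b else a
      relabel[big] <- cl
      for (p in .slt_leaves(children, small, n)) add_row(cl, p, lam, 1L)
      if (big > n) { qt <- qt + 1L; queue[qt] <- big }
      else add_row(cl, big, if (d > 0) 1 / d else Inf, 1L)  # mcs == 1 guard
    }
  }

  parent <- r_parent[seq_len(nrows)]; child <- r_child[seq_len(nrows)]
  lambda_val <- r_lambda[seq_len(nrows)]; child_size <- r_size[seq_len(nrows)]

  cluster_ids <- sort(unique(c(n + 1L, parent, child[child > n])))
  nc <- length(cluster_ids)
  idx <- function(id) id - n            # cluster ids are contiguous n+1, n+2, ...
  lambda_birth <- numeric(nc)           # root birth density is 0
  cluster_parent <- integer(nc)         # 0 for root
  is_cl_row <- child > n
  lambda_birth[idx(child[is_cl_row])] <- lambda_val[is_cl_row]
  cluster_parent[idx(child[is_cl_row])] <- parent[is_cl_row]

  stability <- numeric(nc)
  contrib <- (lambda_val - lambda_birth[idx(parent)]) * child_size
  agg <- rowsum(contrib, group = parent)
  stability[idx(as.integer(rownames(agg)))] <- agg[, 1L]

  structure(list(parent = parent, child = child, lambda_val = lambda_val,
                 child_size = child_size, n_points = n, root = n + 1L,
                 cluster_ids = cluster_ids, lambda_birth = lambda_birth,
                 cluster_parent = cluster_parent, stability = stability),
            class = "condensed_tree")
}

#' @export
print.condensed_tree <- function(x, ...) {
  cat("condensed_tree:", x$n_points, "points,",
      length(x$cluster_ids), "clusters (incl. root)\n")
  invisible(x)
}

#' Extract flat clusters from a condensed tree
#'
#' Selection proceeds in two steps. First, excess-of-mass: bottom-up, a
#' cluster is selected when its own stability is at least the summed
#' stability of its selected descendants (the root is never selected).
#' Second, the epsilon-hat merge rule: a selected cluster first appearing at
#' a distance `1/lambda_birth < epsilon_hat` is replaced by its lowest
#' ancestor born at a distance `>= epsilon_hat` (or, failing that, the
#' ancestor directly below the root), merging all selected siblings beneath
#' it. Points that departed the hierarchy above every selected cluster are
#' labelled noise (-1). Cluster labels are renumbered by decreasing size.
#'
#' @param t a [build_condensed_tree()] result.
#' @param params a [cluster_params()] object (only `epsilon_hat` is used
#'   here; sizes were fixed when the tree was condensed).
#' @return an object of class `cluster_labels` with elements `labels`
#'   (integer vector, -1 = noise), `n_clusters`, and `params`.
#' @export
extract_clusters <- function(t, params = cluster_params()) {
  stopifnot(inherits(t, "condensed_tree"))
  n <- t$n_points
  ids <- t$cluster_ids
  nc <- length(ids)
  idx <- function(id) id - n
  root_i <- idx(t$root)

  kids <- vector("list", nc)
  is_cl <- t$child > n
  for (k in which(is_cl)) {
    pi <- idx(t$parent[k])
    kids[[pi]] <- c(kids[[pi]], idx(t$child[k]))
  }

  selected <- logical(nc)
  subtree_stab <- t$stability
  deselect_subtree <- function(i) {
    stack <- kids[[i]]
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      selected[v] <<- FALSE
      stack <- c(stack, kids[[v]])
    }
  }
  for (i in rev(seq_len(nc))) {
    ks <- kids[[i]]
    if (length(ks) == 0L) {
      selected[i] <- i != root_i
    } else {
      s_kids <- sum(subtree_stab[ks])
      if (i != root_i && t$stability[i] >= s_kids) {
        selected[i] <- TRUE
        deselect_subtree(i)
        subtree_stab[i] <- t$stability[i]
      } else {
        subtree_stab[i] <- s_kids
      }
    }
  }

  eps <- params$epsilon_hat
  if (eps > 0 && any(selected)) {
    birth_dist <- ifelse(t$lambda_birth > 0, 1 / t$lambda_birth, Inf)
    cl_parent_i <- ifelse(t$cluster_parent > 0L, idx(t$cluster_parent), 0L)
    processed <- logical(nc)
    new_sel <- logical(nc)
    mark_subtree <- function(i) {
      stack <- i
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        processed[v] <<- TRUE
        stack <- c(stack, kids[[v]])
      }
    }
    for (i in which(selected)) {
      if (processed[i]) next
      if (birth_dist[i] >= eps) {
        new_sel[i] <- TRUE
        processed[i] <- TRUE
      } else {
        cur <- i
        repeat {
          par <- cl_parent_i[cur]
          if (par == 0L || par == root_i) break
          cur <- par
          if (birth_dist[cur] >= eps) break
        }
        new_sel[cur] <- TRUE
        mark_subtree(cur)
      }
    }
    selected <- new_sel
  }

  ## nearest selected ancestor-or-self, top-down (parents precede children)
  nearest_sel <- integer(nc)
  for (i in seq_len(nc)) {
    if (selected[i]) nearest_sel[i] <- i
    else {
      p <- if (t$cluster_parent[i] > 0L) idx(t$cluster_parent[i]) else 0L
      nearest_sel[i] <- if (p > 0L) nearest_sel[p] else 0L
    }
  }

  labels <- rep.int(-1L, n)
  pt <- t$child <= n
  dep_parent_i <- idx(t$parent[pt])
  lab_cluster <- nearest_sel[dep_parent_i]
  labels[t$child[pt]] <- ifelse(lab_cluster > 0L, lab_cluster, -1L)

  ## renumber by decreasing support, ties by cluster id
  present <- sort(unique(labels[labels > 0L]))
  if (length(present)) {
    supp <- vapply(present, function(cl) sum(labels == cl), integer(1))
    ord <- present[order(-supp, present)]
    remap <- integer(nc)
    remap[ord] <- seq_along(ord) - 1L
    labels[labels > 0L] <- remap[labels[labels > 0L]]
  }

  structure(list(labels = labels,
                 n_clusters = length(present),
                 params = params),
            class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat("cluster_labels:", length(x$labels), "points,",
      x$n_clusters, "clusters,",
      sum(x$labels == -1L), "noise\n")
  invisible(x)
}

#' Epsilon-augmented hierarchical density clustering
#'
#' End-to-end density clustering: core distances, mutual reachability
#' minimum spanning tree, condensed hierarchy, and stability-based
#' extraction with the epsilon-hat merge rule. Fully deterministic
#' (no randomness; ties resolved by index).
#'
#' @param X numeric coordinate matrix (rows = points), typically a
#'   low-dimensional embedding of genotype principal components.
#' @param params a [cluster_params()] object.
#' @return a `cluster_labels` object; labels are 0-based, -1 is noise.
#' @examples
#' X <- rbind(matrix(rnorm(60, 0, .2), ncol = 2),
#'            matrix(rnorm(60, 5, .2), ncol = 2))
#' cluster(X, cluster_params(min_cluster_size = 10, epsilon_hat = 0))
#' @export
cluster <- function(X, params = cluster_params()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0L) stop("empty input")
  if (n == 1L) {
    return(structure(list(labels = -1L, n_clusters = 0L, params = params),
                     class = "cluster_labels"))
  }
  if (n <= params$min_cluster_size) {
    return(structure(list(labels = rep.int(-1L, n), n_clusters = 0L,
                          params = params),
                     class = "cluster_labels"))
  }
  g <- mutual_reachability_mst(X, params)
  t <- build_condensed_tree(g, params$min_cluster_size)
  extract_clusters(t, params)
}
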