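## Post-hoc cluster characterization from categorical metadata.
##
## Clusters are built from genotypes alone; auxiliary variables (country of
## birth, ethnic background, ...) describe them afterwards. Noise points
## (label -1) are reported as their own stratum, and missing category
## values are kept as the literal category "missing" -- differential
## missingness is itself informative.

#' Cross-tabulate clusters against a categorical variable
#'
#' Computes the full cluster x value frequency table with within-cluster
#' proportions, plus a reported view that suppresses values below
#' `min_prop` (default 0.05) while retaining the suppressed remainder mass
#' per cluster as the pseudo-value `"Other/suppressed"`.
#'
#' @param labels a `cluster_labels` object or an integer vector (-1 =
#'   noise).
#' @param variable character (or factor) vector aligned with the samples;
#'   NA becomes the category `"missing"`.
#' @param min_prop reporting threshold on within-cluster proportion; 0
#'   reproduces the full table.
#' @return an object of class `stratum_table` with elements `table` (full
#'   cross-tabulation: cluster, value, count, proportion), `reported`
#'   (thresholded view), `cluster_sizes`, and `modal` (modal value per
#'   cluster).
#' @export
characterize <- function(labels, variable, min_prop = 0.05) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else
    as.integer(labels)
  v <- as.character(variable)
  if (length(v) != length(lab)) stop("variable not aligned with labels")
  v[is.na(v)] <- "missing"
  full <- as.data.frame(table(cluster = lab, value = v),
                        stringsAsFactors = FALSE)
  names(full)[3] <- "count"
  full$cluster <- as.integer(full$cluster)
  full <- full[full$count > 0L, , drop = FALSE]
  sizes <- tapply(full$count, full$cluster, sum)
  full$proportion <- full$count / as.vector(sizes[as.character(full$cluster)])
  full <- full[order(full$cluster, -full$proportion, full$value), ]
  rownames(full) <- NULL

  modal <- vapply(split(full, full$cluster),
                  function(d) d$value[which.max(d$proportion)], character(1))

  keep <- full$proportion >= min_prop
  reported <- full[keep, , drop = FALSE]
  rest <- full[!keep, , drop = FALSE]
  if (nrow(rest)) {
    rem <- stats::aggregate(cbind(count, proportion) ~ cluster, data = rest,
                            FUN = sum)
    rem$value <- "Other/suppressed"
    reported <- rbind(reported, rem[, c("cluster", "value", "count",
                                        "proportion")])
    reported <- reported[order(reported$cluster, -reported$proportion), ]
    rownames(reported) <- NULL
  }

  structure(list(table = full, reported = reported,
                 cluster_sizes = sizes, modal = modal,
                 min_prop = min_prop),
            class = "stratum_table")
}

#' @export
print.stratum_table <- function(x, n = 20L, ...) {
  cat("stratum_table:", length(x$cluster_sizes), "strata,",
      sum(x$cluster_sizes), "individuals (reporting threshold",
      x$min_prop, ")\n")
  print(utils::head(x$reported, n))
  invisible(x)
}

#' Flag quality-control anomalies in a stratum table
#'
#' Surfaces (cluster, value) pairs where a categorically disjoint value
#' holds a non-trivial minority of a cluster -- the signature of coding or
#' bookkeeping errors (e.g. a cluster of mostly North-African-born
#' individuals containing 11% recorded as born in a South Pacific
#' territory). A value is flagged when its within-cluster proportion is at
#' least `min_prop` and its group under `grouping` differs from the modal
#' value's group. Pure reporting; nothing is mutated.
#'
#' @param t a [characterize()] result.
#' @param grouping named character vector mapping values to groups (e.g.
#'   countries to regions). Values missing from the map inherit the group
#'   `"unknown"`, which never triggers a flag against itself.
#' @param min_prop minority-proportion floor (default 0.05).
#' @return a data frame (cluster, value, proportion, group, modal_value,
#'   modal_group); zero rows when nothing is anomalous. Without a grouping
#'   map, flags are disabled with a warning.
#' @export
flag_anomalies <- function(t, grouping = NULL, min_prop = 0.05) {
  stopifnot(inherits(t, "stratum_table"))
  empty <- data.frame(cluster = integer(0), value = character(0),
                      proportion = numeric(0), group = character(0),
                      modal_value = character(0), modal_group = character(0))
  if (is.null(grouping)) {
    warning("no grouping map supplied; anomaly flags disabled")
    return(empty)
  }
  grp <- function(v) {
    g <- unname(grouping[v])
    g[is.na(g)] <- "unknown"
    g
  }
  d <- t$table
  d$group <- grp(d$value)
  d$modal_value <- t$modal[as.character(d$cluster)]
  d$modal_group <- grp(d$modal_value)
  hit <- d$proportion >= min_prop & d$value != d$modal_value &
    d$group != d$modal_group & d$group != "unknown" & d$modal_group != "unknown"
  out <- d[hit, c("cluster", "value", "proportion", "group", "modal_value",
                  "modal_group")]
  rownames(out) <- NULL
  out
}
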