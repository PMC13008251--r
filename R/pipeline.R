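## End-to-end orchestration with config, logging, and provenance.

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = "")))
}

.hash_file <- function(path) unname(tools::md5sum(path))

#' Run the stratification pipeline from a config
#'
#' Executes the requested stages in dependency order -- simulate or ingest,
#' filter, PCA, embed, cluster, characterize -- writing each stage's output
#' as TSV under `out_dir` together with a JSON manifest (config snapshot,
#' seeds, output hashes, timings). Re-running the same config and seed
#' reproduces identical label files.
#'
#' Config structure (YAML file or list): an `out_dir`; either a `simulate`
#' section (`design`: discrete/admixed/stepping_stone, plus
#' [population_spec()] fields) or an `input` section (`format`: plink/vcf,
#' `path`); optional `filters` ([filter_config()] fields); `pca` (`k`);
#' `embed` ([embed_params()] fields); `cluster` ([cluster_params()]
#' fields); optional `characterize` (`variable`: name of a metadata column,
#' requires simulated metadata or `meta` path).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  if (is.null(config$out_dir)) stop("config field missing: out_dir")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  manifest <- list(config = config, stages = list(),
                   started = format(t_start))
  outputs <- character(0)
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    r <- force(expr)
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    r
  }

  ## --- genotypes ---
  meta <- NULL
  if (!is.null(config$simulate)) {
    s <- config$simulate
    if (is.null(s$design)) stop("config field missing: simulate$design")
    spec <- population_spec(
      n_pops = s$n_pops, pop_sizes = s$pop_sizes, F = s$F,
      n_snps = s$n_snps,
      ancestral_freq_range = s$ancestral_freq_range %||% c(0.05, 0.95),
      admixture = if (!is.null(s$admixture)) do.call(rbind, s$admixture),
      grid = s$grid, seed = s$seed %||% 1L)
    co <- tick("simulate", switch(s$design,
      discrete = simulate_discrete(spec),
      admixed = simulate_admixed(spec),
      stepping_stone = simulate_stepping_stone(spec),
      stop("unknown simulate$design: ", s$design)))
    g <- co$genotypes
    meta <- data.frame(sample_id = g$sample_ids, true_label = co$true_labels)
    .stage_log("simulate", s$design, ": ", nrow(g$counts), " x ",
               ncol(g$counts))
  } else if (!is.null(config$input)) {
    g <- tick("ingest", read_genotypes(config$input$path,
                                       config$input$format %||% "plink"))
    .stage_log("ingest", config$input$path, ": ", nrow(g$counts), " x ",
               ncol(g$counts))
  } else stop("config needs a simulate or input section")

  if (!is.null(config$meta)) {
    meta <- utils::read.table(config$meta, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  }

  ## --- filters ---
  if (!is.null(config$filters)) {
    f <- do.call(filter_config, config$filters)
    g <- tick("filter", apply_filters(g, f))
    .stage_log("filter", "kept ", nrow(g$counts), " x ", ncol(g$counts))
  }

  ## --- pca ---
  k <- config$pca$k %||% 10L
  pcs <- tick("pca", pca(g, k = k))
  pcs_path <- file.path(out, "pcs.tsv")
  write_pcs(pcs, pcs_path)
  outputs <- c(outputs, pcs_path)
  .stage_log("pca", "k = ", pcs$k)

  ## --- embed ---
  ep <- do.call(embed_params, config$embed %||% list())
  emb <- tick("embed", embed(pcs, ep))
  emb_path <- file.path(out, "embedding.tsv")
  ed <- data.frame(sample_id = g$sample_ids, emb$coords)
  names(ed)[-1] <- paste0("D", seq_len(ncol(emb$coords)))
  utils::write.table(ed, emb_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(ep), file.path(out, "embed_params.json"),
                       auto_unbox = TRUE)
  outputs <- c(outputs, emb_path, file.path(out, "embed_params.json"))
  .stage_log("embed", ep$n_components, "D, ", ep$n_neighbors, " neighbours")

  ## --- cluster ---
  cp <- do.call(cluster_params, config$cluster %||% list())
  cl <- tick("cluster", cluster(emb$coords, cp))
  lab_path <- file.path(out, "labels.tsv")
  utils::write.table(data.frame(sample_id = g$sample_ids,
                                cluster = cl$labels),
                     lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, lab_path)
  .stage_log("cluster", cl$n_clusters, " clusters, ",
             sum(cl$labels == -1L), " noise")

  ## --- characterize ---
  if (!is.null(config$characterize)) {
    varname <- config$characterize$variable
    if (is.null(meta) || is.null(meta[[varname]]))
      stop("characterize variable not found in metadata: ", varname)
    st <- tick("characterize",
               characterize(cl, meta[[varname]],
                            min_prop = config$characterize$min_prop %||% 0.05))
    st_path <- file.path(out, "strata.tsv")
    utils::write.table(st$reported, st_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, st_path)
    .stage_log("characterize", varname)
  }

  manifest$seeds <- list(simulate = config$simulate$seed %||% NA,
                         embed = ep$seed)
  manifest$n_clusters <- cl$n_clusters
  manifest$n_noise <- sum(cl$labels == -1L)
  manifest$outputs <- lapply(stats::setNames(outputs, basename(outputs)),
                             .hash_file)
  manifest$timings <- timings
  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
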