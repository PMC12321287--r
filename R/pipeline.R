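# End-to-end orchestration: QC -> normalize -> HVG -> PCA -> Harmony ->
# neighbors -> Leiden -> UMAP -> markers -> merge, with YAML-configurable
# parameters, per-stage seeds fanned out from one global seed, structured
# logging, stage outputs written as files, and resumable cached artifacts
# keyed by a config hash.

PIPELINE_STAGES <- c("qc", "normalize", "hvg", "pca", "harmony", "neighbors",
                     "leiden", "umap", "markers", "merge")

#' Default pipeline configuration
#'
#' Returns the full default parameter tree; any subset can be overridden by
#' the user's config (unknown keys are rejected).
#' @return nested list of stage parameter blocks.
#' @export
default_config <- function() {
  list(
    input = list(path = NULL, format = "mtx_dir", batch_key = NULL),
    storage_mode = "host",
    max_nnz = INT32_CAP,
    seed = 0,
    out_dir = "chunkcell_out",
    qc = list(min_genes_per_cell = 200, min_counts_per_cell = 0,
              max_counts_per_cell = Inf, min_cells_per_gene = 3),
    normalize = list(target_sum = 1e4),
    hvg = list(n_top = 2000, span = 0.3, clip = "sqrt_n"),
    pca = list(d = 50, scale = FALSE),
    harmony = list(theta = 2, sigma = 0.1, lambda = 1, max_iter = 10,
                   tol = 1e-4, init = "two_step"),
    neighbors = list(k = 15),
    leiden = list(resolution = 1),
    umap = list(enabled = TRUE, n_neighbors = 15, min_dist = 0.5),
    markers = list(m = 5, n_candidates = 30, min_binary = 0.1, beta = 0.5,
                   nrounds = 100, max_depth = 6, eta = 0.3, min_cells = 10),
    merge = list(t_C = 0.5, t_G = 1, direction = "both")
  )
}

# Merge a user config over the defaults, rejecting unknown keys.
merge_config <- function(user, defaults = default_config()) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      sub_unknown <- setdiff(names(user[[nm]]), names(defaults[[nm]]))
      if (length(sub_unknown)) {
        stop("unknown config key(s) under '", nm, "': ",
             paste(sub_unknown, collapse = ", "))
      }
      defaults[[nm]][names(user[[nm]])] <- user[[nm]]
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Read a pipeline config from YAML
#' @param path YAML file.
#' @return full config (user values over defaults).
#' @export
read_config <- function(path) {
  merge_config(yaml::read_yaml(path))
}

log_json <- function(stage, event, ...) {
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, event = event), list(...))
  message(jsonlite::toJSON(rec, auto_unbox = TRUE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Stages execute in workflow order; each stage's effective parameters and
#' derived seed are logged as line-delimited JSON and recorded in a
#' provenance manifest sufficient to re-execute the run. Deterministic stages
#' reproduce bit-identically for a fixed config and seed.
#'
#' @param config a config list (see [default_config()]) or path to a YAML
#'   file. `input$path` may be omitted when `store` is given directly.
#' @param store optional pre-opened `ChunkedMatrix` (takes precedence over
#'   `input$path`).
#' @param until stop after this stage (one of `r toString(PIPELINE_STAGES)`).
#' @param resume reuse cached stage artifacts from a previous run with the
#'   same config hash.
#' @return invisible list of in-memory results (`store`, `hvg`, `embedding`,
#'   `corrected`, `labels`, `merged_labels`, `markers`, `umap`, ...); files
#'   are written under `config$out_dir`.
#' @export
run_pipeline <- function(config = list(), store = NULL, until = NULL,
                         resume = FALSE) {
  cfg <- if (is.character(config)) read_config(config) else merge_config(config)
  if (!is.null(until) && !until %in% PIPELINE_STAGES) {
    stop("unknown stage: ", until)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- digest::digest(cfg)
  cache_dir <- file.path(cfg$out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  cached <- function(name, compute) {
    f <- file.path(cache_dir, paste0(cfg_hash, "_", name, ".rds"))
    if (resume && file.exists(f)) {
      log_json(name, "resume", cache = f)
      return(readRDS(f))
    }
    val <- compute()
    saveRDS(val, f)
    val
  }
  res <- list(config = cfg)
  stage_seed <- function(stage) derive_seed(cfg$seed, stage)
  done <- function(stage) !is.null(until) && stage == until

  if (is.null(store)) {
    if (is.null(cfg$input$path)) stop("no input: give store= or input$path")
    store <- open_store(cfg$input$path, fmt = cfg$input$format,
                        mode = cfg$storage_mode, max_nnz = cfg$max_nnz,
                        batch_key = cfg$input$batch_key)
  }
  log_json("load", "done", n_cells = store$n_cells, n_genes = store$n_genes,
           chunks = n_chunks(store), mode = store$storage_mode)

  # -- qc ---------------------------------------------------------------
  stats <- cached("qc_stats", function() accumulate_qc(store))
  mask <- do.call(build_qc_mask, c(list(stats), cfg$qc))
  filtered <- apply_qc(store, mask)
  write_tsv(data.frame(cell = store$cell_ids,
                       genes_per_cell = stats$genes_per_cell,
                       counts_per_cell = stats$counts_per_cell,
                       keep = mask$cell_keep),
            file.path(cfg$out_dir, "qc_cells.tsv"))
  write_tsv(data.frame(gene = store$gene_ids,
                       cells_per_gene = stats$cells_per_gene,
                       keep = mask$gene_keep),
            file.path(cfg$out_dir, "qc_genes.tsv"))
  log_json("qc", "done", cells_kept = sum(mask$cell_keep),
           genes_kept = sum(mask$gene_keep), params = cfg$qc)
  res$qc <- list(stats = stats, mask = mask)
  res$store <- filtered
  if (done("qc")) return(finish_pipeline(res, cfg))

  # -- normalize --------------------------------------------------------
  norm <- normalize_log1p(filtered, target_sum = cfg$normalize$target_sum)
  log_json("normalize", "done", params = cfg$normalize)
  res$normalized <- norm
  if (done("normalize")) return(finish_pipeline(res, cfg))

  # -- hvg (on raw counts, post-QC) ------------------------------------
  hvg <- cached("hvg", function() {
    do.call(find_hvgs, c(list(filtered), cfg$hvg))
  })
  write_tsv(data.frame(gene = filtered$gene_ids, mu = hvg$mu, var = hvg$var,
                       fitted_sd = hvg$fitted_sd, norm_var = hvg$norm_var,
                       rank = hvg$rank, is_hvg = hvg$is_hvg),
            file.path(cfg$out_dir, "hvg.tsv"))
  log_json("hvg", "done", n_hvg = sum(hvg$is_hvg), params = cfg$hvg)
  res$hvg <- hvg
  if (done("hvg")) return(finish_pipeline(res, cfg))

  # -- pca --------------------------------------------------------------
  hv <- hvg$is_hvg
  norm_hvg <- map_chunks(norm, function(b) b[, hv, drop = FALSE],
                         new_gene_ids = norm$gene_ids[hv])
  d_use <- min(cfg$pca$d, norm_hvg$n_genes)
  model <- cached("pca", function() {
    fit_pca(norm_hvg, d = d_use, scale = cfg$pca$scale)
  })
  embedding <- pca_transform(norm_hvg, model)
  write_tsv(data.frame(gene = model$gene_ids, model$components),
            file.path(cfg$out_dir, "pca_loadings.tsv"))
  log_json("pca", "done", d = d_use, params = cfg$pca)
  res$pca <- model
  res$embedding <- embedding
  if (done("pca")) return(finish_pipeline(res, cfg))

  # -- harmony ----------------------------------------------------------
  if (!is.null(filtered$batch) && length(unique(filtered$batch)) >= 1) {
    harm <- cached("harmony", function() {
      run_harmony(embedding, filtered$batch,
                  theta = cfg$harmony$theta, sigma = cfg$harmony$sigma,
                  lambda = cfg$harmony$lambda, max_iter = cfg$harmony$max_iter,
                  tol = cfg$harmony$tol, seed = stage_seed("harmony"),
                  init = cfg$harmony$init)
    })
    corrected <- harm$embedding
    res$harmony <- harm
    log_json("harmony", "done", batches = length(unique(filtered$batch)),
             iterations = harm$iterations)
  } else {
    corrected <- embedding
    log_json("harmony", "skipped", reason = "no batch labels")
  }
  res$corrected <- corrected
  if (done("harmony")) return(finish_pipeline(res, cfg))

  # -- neighbors --------------------------------------------------------
  graph <- cached("neighbors", function() exact_knn(corrected, k = cfg$neighbors$k))
  conn <- connectivities_from_knn(graph)
  log_json("neighbors", "done", k = cfg$neighbors$k)
  res$graph <- graph
  res$connectivities <- conn
  if (done("neighbors")) return(finish_pipeline(res, cfg))

  # -- leiden -----------------------------------------------------------
  labels <- cached("leiden", function() {
    cluster_leiden_graph(conn, resolution = cfg$leiden$resolution,
                         seed = stage_seed("leiden"))
  })
  write_tsv(data.frame(cell = filtered$cell_ids, cluster = labels),
            file.path(cfg$out_dir, "labels.tsv"))
  log_json("leiden", "done", n_clusters = length(unique(labels)),
           resolution = cfg$leiden$resolution)
  res$labels <- labels
  if (done("leiden")) return(finish_pipeline(res, cfg))

  # -- umap -------------------------------------------------------------
  if (isTRUE(cfg$umap$enabled)) {
    um <- cached("umap", function() {
      embed_umap(corrected, seed = stage_seed("umap"),
                 n_neighbors = cfg$umap$n_neighbors,
                 min_dist = cfg$umap$min_dist)
    })
    write_tsv(data.frame(cell = filtered$cell_ids, umap1 = um[, 1],
                         umap2 = um[, 2]),
              file.path(cfg$out_dir, "umap.tsv"))
    res$umap <- um
    log_json("umap", "done")
  } else {
    log_json("umap", "skipped")
  }
  if (done("umap")) return(finish_pipeline(res, cfg))

  # -- markers ----------------------------------------------------------
  mk <- cached("markers", function() {
    do.call(find_markers, c(list(norm, labels, seed = stage_seed("markers")),
                            cfg$markers))
  })
  mk_df <- do.call(rbind, lapply(names(mk$markers), function(c) {
    df <- mk$markers[[c]]
    if (nrow(df) == 0) return(NULL)
    data.frame(cluster = c, rank = seq_len(nrow(df)), df, S = mk$S[[c]])
  }))
  write_tsv(mk_df %||% data.frame(), file.path(cfg$out_dir, "markers.tsv"))
  write_tsv(marker_dotplot_table(norm, labels, mk),
            file.path(cfg$out_dir, "marker_dotplot.tsv"))
  log_json("markers", "done", clusters = length(mk$markers))
  res$markers <- mk
  if (done("markers")) return(finish_pipeline(res, cfg))

  # -- merge ------------------------------------------------------------
  merged <- merge_clusters(labels, mk, t_C = cfg$merge$t_C, t_G = cfg$merge$t_G,
                           direction = cfg$merge$direction)
  write_tsv(data.frame(cell = filtered$cell_ids, cluster = merged$labels),
            file.path(cfg$out_dir, "merged_labels.tsv"))
  pairs <- merged$plan$pairs
  write_tsv(if (nrow(pairs)) cbind(pairs,
                                   quality_i = merged$plan$quality[pairs$i],
                                   quality_j = merged$plan$quality[pairs$j])
            else data.frame(),
            file.path(cfg$out_dir, "merge_report.tsv"))
  log_json("merge", "done",
           n_before = length(unique(labels)),
           n_after = length(unique(merged$labels)), params = cfg$merge)
  res$merged_labels <- merged$labels
  res$merge_plan <- merged$plan
  finish_pipeline(res, cfg)
}

finish_pipeline <- function(res, cfg) {
  manifest <- list(
    config = rapply(cfg, function(x) if (is.numeric(x) && !is.finite(x)) "Inf" else x,
                    how = "replace"),
    seed = cfg$seed,
    stage_seeds = stats::setNames(
      lapply(PIPELINE_STAGES, function(s) derive_seed(cfg$seed, s)),
      PIPELINE_STAGES),
    versions = list(chunkcell = as.character(utils::packageVersion("chunkcell")),
                    R = R.version.string,
                    Matrix = as.character(utils::packageVersion("Matrix")),
                    igraph = as.character(utils::packageVersion("igraph")),
                    xgboost = as.character(utils::packageVersion("xgboost")),
                    uwot = as.character(utils::packageVersion("uwot"))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
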