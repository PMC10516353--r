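#' Preprocess a reference/query pair end to end
#'
#' Chains QC filtering, depth normalization, highly-variable-gene selection
#' on the reference, query gene alignment, optional batch correction and
#' reference-fitted `[0, 1]` scaling, producing the scaled matrices the image
#' converter consumes.
#'
#' @param reference,query `ExpressionMatrix` objects with
#'   `layer_tag = "counts"`.
#' @param n_hvg Number of highly variable genes kept (all genes if fewer).
#' @param norm_method Passed to [normalize_counts()].
#' @param batch_correction Apply [correct_batch()] to the query?
#' @param mt_prefix,min_features,max_features,max_pct_mt QC parameters.
#' @return A list: `reference` and `query` (scaled `ExpressionMatrix`),
#'   `scaling` (the fitted `GeneScaling`), `qc_report_reference`,
#'   `qc_report_query`.
#' @export
preprocess_pair <- function(reference, query, n_hvg = 2000,
                            norm_method = "pearson_residual",
                            batch_correction = TRUE, mt_prefix = "MT-",
                            min_features = 300, max_features = 4000,
                            max_pct_mt = 15) {
  ref_f <- filter_cells(reference, compute_qc(reference, mt_prefix),
                        min_features, max_features, max_pct_mt)
  qry_f <- filter_cells(query, compute_qc(query, mt_prefix),
                        min_features, max_features, max_pct_mt)
  ref_rep <- attr(ref_f, "qc_report")
  qry_rep <- attr(qry_f, "qc_report")
  ref_n <- normalize_counts(ref_f, norm_method)
  nm <- if (norm_method == "pearson_residual") fit_normalization(ref_f)
  qry_n <- normalize_counts(qry_f, norm_method, model = nm)
  ref_n <- select_hvg(ref_n, n_hvg)
  qry_n <- align_query_genes(ref_n$gene_ids, qry_n)
  if (batch_correction) qry_n <- correct_batch(ref_n, qry_n)
  scaling <- fit_scaling(ref_n)
  list(reference = apply_scaling(ref_n, scaling),
       query = apply_scaling(qry_n, scaling),
       scaling = scaling,
       qc_report_reference = ref_rep, qc_report_query = qry_rep)
}

#' Default pipeline configuration
#'
#' One section per stage; every stage seed derives deterministically from the
#' global seed. Serializes losslessly to YAML via [write_pipeline_config()].
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Global seed; stage seeds are `seed + 1..3`.
#' @param ... Overrides for any nested field, as `section.field = value`
#'   pairs (e.g. `preprocess.batch_correction = FALSE`).
#' @return A nested configuration list.
#' @export
pipeline_config <- function(out_dir, seed = 17, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    simulate = list(preset = "standard", seed = as.integer(seed)),
    qc = list(min_features = 300, max_features = 4000, max_pct_mt = 15,
              mt_prefix = "MT-"),
    preprocess = list(n_hvg = 2000, norm_method = "pearson_residual",
                      batch_correction = TRUE),
    map = list(method = "tsne", perplexity = 30, pixel_size = 64,
               aggregator = "mean", seed = as.integer(seed) + 1L),
    fit = list(max_epochs = 30, patience = 5, batch_size = 64,
               val_fraction = 0.15, label_smoothing_eps = 0.2,
               learning_rate = 3e-3, dropout = 0.5,
               brightness_jitter = 0.5, outlier_exposure = 0.25,
               seed = as.integer(seed) + 2L),
    predict = list(unknown_quantile = 0.01),
    markers = list(top_k = 20, seed = as.integer(seed) + 3L)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) cfg[[parts]] <- dots[[nm]]
    else cfg[[parts[1]]][[parts[2]]] <- dots[[nm]]
  }
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param cfg A configuration list. @param path YAML path.
#' @return `path` (write) or the configuration list (read).
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

config_hash <- function(cfg) {
  stable_hash(yaml::as.yaml(cfg))
}

#' Run the full annotation pipeline
#'
#' Executes simulate -> qc/preprocess -> map -> fit -> predict -> markers in
#' order, writing `MAP.json`, `MODEL/`, `pred.tsv`, `markers.tsv` and a run
#' manifest (`manifest.json` with seeds, stage timings and output hashes)
#' under `cfg$out_dir`. Stages whose outputs already exist under an
#' unchanged configuration are skipped. Input data may be supplied instead
#' of simulated by passing `reference`/`query`.
#'
#' @param cfg A [pipeline_config()].
#' @param reference,query Optional `ExpressionMatrix` inputs (counts); when
#'   omitted the simulate stage generates them.
#' @param truth Optional truth record (as from [simulate_counts()]) used only
#'   to score the run in the manifest.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(cfg, reference = NULL, query = NULL, truth = NULL) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  prev <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  }
  reuse <- !is.null(prev) && identical(prev$config_hash, hash)
  paths <- list(
    sim = file.path(cfg$out_dir, "sim.rds"),
    prep = file.path(cfg$out_dir, "prep.rds"),
    map = file.path(cfg$out_dir, "MAP.json"),
    images = file.path(cfg$out_dir, "images.rds"),
    model = file.path(cfg$out_dir, "MODEL"),
    pred = file.path(cfg$out_dir, "pred.tsv"),
    markers = file.path(cfg$out_dir, "markers.tsv"))
  stages <- list()
  timed <- function(name, outputs, run) {
    if (reuse && all(file.exists(unlist(outputs)))) {
      stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    run()
    stages[[name]] <<- list(status = "run",
                            seconds = round(proc.time()[["elapsed"]] - t0, 2))
    invisible(NULL)
  }

  timed("simulate", paths$sim, function() {
    if (is.null(reference)) {
      sim <- simulate_counts(sim_spec(seed = cfg$simulate$seed))
      saveRDS(sim, paths$sim)
    } else {
      saveRDS(list(reference = reference, query = query, truth = truth),
              paths$sim)
    }
  })
  sim <- readRDS(paths$sim)

  timed("preprocess", paths$prep, function() {
    prep <- preprocess_pair(
      sim$reference, sim$query,
      n_hvg = cfg$preprocess$n_hvg, norm_method = cfg$preprocess$norm_method,
      batch_correction = cfg$preprocess$batch_correction,
      mt_prefix = cfg$qc$mt_prefix, min_features = cfg$qc$min_features,
      max_features = cfg$qc$max_features, max_pct_mt = cfg$qc$max_pct_mt)
    saveRDS(prep, paths$prep)
  })
  prep <- readRDS(paths$prep)

  timed("map", paths$map, function() {
    coords <- embed_features(prep$reference, cfg$map$method,
                             perplexity = cfg$map$perplexity,
                             seed = cfg$map$seed)
    fmap <- build_feature_map(coords, cfg$map$pixel_size,
                              perplexity = cfg$map$perplexity,
                              seed = cfg$map$seed,
                              aggregator = cfg$map$aggregator)
    write_feature_map(fmap, paths$map)
  })
  fmap <- read_feature_map(paths$map)

  timed("images", paths$images, function() {
    saveRDS(list(reference = cells_to_images(prep$reference, fmap),
                 query = cells_to_images(prep$query, fmap)), paths$images)
  })
  images <- readRDS(paths$images)

  timed("fit", file.path(paths$model, "weights.rds"), function() {
    tc <- train_config(val_fraction = cfg$fit$val_fraction,
                       batch_size = cfg$fit$batch_size,
                       max_epochs = cfg$fit$max_epochs,
                       patience = cfg$fit$patience,
                       label_smoothing_eps = cfg$fit$label_smoothing_eps,
                       learning_rate = cfg$fit$learning_rate,
                       dropout = cfg$fit$dropout,
                       brightness_jitter = cfg$fit$brightness_jitter,
                       outlier_exposure = cfg$fit$outlier_exposure,
                       seed = cfg$fit$seed)
    model <- train_classifier(images$reference, prep$reference$cell_type, tc)
    save_model(model, paths$model)
    saveRDS(model$split, file.path(paths$model, "split.rds"))
  })
  model <- load_model(paths$model)
  split <- readRDS(file.path(paths$model, "split.rds"))

  timed("predict", paths$pred, function() {
    val_stack <- structure(
      list(pixels = images$reference$pixels[split$val_idx, , , drop = FALSE],
           cell_ids = images$reference$cell_ids[split$val_idx],
           map_ref = images$reference$map_ref), class = "ImageStack")
    thr <- calibrate_unknown_threshold(predict_proba(model, val_stack),
                                       cfg$predict$unknown_quantile)
    pred <- annotate(predict_proba(model, images$query), threshold = thr)
    write_predictions(pred, paths$pred)
  })

  timed("markers", paths$markers, function() {
    mk <- top_markers(model, images$query, fmap, k = cfg$markers$top_k,
                      seed = cfg$markers$seed)
    utils::write.table(mk, paths$markers, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  metrics <- NULL
  if (!is.null(sim$truth)) {
    pred_tab <- utils::read.table(paths$pred, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
    truth_cells <- sim$truth$cells
    qtruth <- truth_cells$type[match(pred_tab$barcode, truth_cells$barcode)]
    known <- qtruth != "novel"
    metrics <- list(
      accuracy_known = mean(pred_tab$audit_label[known] == qtruth[known] &
                              !pred_tab$unknown_flag[known]),
      novel_detection_rate = if (any(!known)) mean(pred_tab$unknown_flag[!known]) else NA,
      false_unknown_rate = mean(pred_tab$unknown_flag[known]))
  }
  manifest <- list(config_hash = hash, config = cfg, stages = stages,
                   metrics = metrics,
                   r_version = as.character(getRversion()),
                   outputs = lapply(paths, function(p) {
                     if (file.exists(p) && !dir.exists(p)) {
                       unname(tools::md5sum(p))
                     } else NULL
                   }))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
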