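# Tab-separated matrix dialect: header row, feature ids in column 1.
# gzip input is handled transparently by readr.

#' Read / write a feature-by-sample matrix TSV
#'
#' @param path TSV file (first column feature ids, one column per sample)
#' @return numeric matrix with feature row names
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @param m matrix with row names
#' @param id_col name for the feature id column
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature") {
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  df <- dplyr::bind_cols(stats::setNames(tibble::tibble(rownames(m)), id_col),
                         df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a feature-to-gene mapping TSV
#'
#' Columns `feature<TAB>gene` with optional `weight` and `position`.
#'
#' @param path TSV file
#' @return tibble
#' @export
read_mapping_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("feature", "gene") %in% names(df)))
  df
}

#' Write a simulated dataset to disk in pipeline formats
#'
#' Emits one TSV per modality, mapping TSVs for sub-gene modalities, a
#' labels TSV, the pathway GMT, and a JSON truth file — exactly the formats
#' the pipeline consumes.
#'
#' @param sim a `pathomix_sim`
#' @param dir output directory (created)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in sim$modalities) {
    write_matrix_tsv(m$values, file.path(dir, paste0(m$name, ".tsv")))
    if (m$level != "gene")
      readr::write_tsv(m$feature_to_gene,
                       file.path(dir, paste0(m$name, "_mapping.tsv")),
                       progress = FALSE)
  }
  readr::write_tsv(sim$labels, file.path(dir, "labels.tsv"),
                   progress = FALSE)
  write_gmt(sim$collection, file.path(dir, "pathways.gmt"))
  jsonlite::write_json(
    list(planted_pathways = sim$truth$planted_pathways,
         threshold = sim$truth$rule$threshold),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory
#' @param levels named character vector mapping modality name to level
#'   (default: the simulator's three modalities)
#' @return list with `modalities`, `labels`, `collection`
#' @export
read_dataset <- function(dir, levels = c(expression = "gene",
                                         methylation = "fragment",
                                         cnv = "gene")) {
  modalities <- list()
  for (nm in names(levels)) {
    vals <- read_matrix_tsv(file.path(dir, paste0(nm, ".tsv")))
    mp <- file.path(dir, paste0(nm, "_mapping.tsv"))
    map <- if (file.exists(mp)) read_mapping_tsv(mp) else NULL
    modalities[[nm]] <- modality_input(nm, vals, levels[[nm]], map)
  }
  labels <- readr::read_tsv(file.path(dir, "labels.tsv"),
                            show_col_types = FALSE, progress = FALSE)
  list(modalities = modalities, labels = labels,
       collection = read_gmt(file.path(dir, "pathways.gmt")))
}

#' Build the gene embedding from a set of modality inputs
#'
#' Applies each modality's indicator menu (defaults per level, see
#' [default_indicators()]) over the pathway gene universe and concatenates
#' the results into the compacted multi-modal gene embedding.
#'
#' @param modalities named list of [modality_input()]
#' @param universe gene universe (e.g. a pathway collection's)
#' @param cfg optional [embedding_config()]; defaults per modality level
#' @return a raw (unnormalized) gene embedding `(Ng, Dg, S)` with layout
#' @export
prepare_embedding <- function(modalities, universe, cfg = NULL) {
  parts <- list()
  for (nm in names(modalities)) {
    mi <- modalities[[nm]]
    ind <- if (!is.null(cfg) && nm %in% names(cfg$indicators))
      cfg$indicators[[nm]] else default_indicators(mi$level)
    ws <- if (!is.null(cfg)) cfg$window_size else 5
    parts[[nm]] <- build_modal_features(mi, ind, universe, ws)
  }
  assemble_gene_embedding(parts)
}

# ---- configuration -------------------------------------------------------

config_schema <- function() {
  list(
    seed = 1L,
    output_dir = "pathomix_out",
    verbosity = 1L,
    paths = list(gmt = NULL, labels = NULL, network = NULL,
                 data_dir = NULL, checkpoint = NULL),
    filter = list(min_genes = 15, max_genes = 100, max_overlap = 1,
                  max_subsets = 5),
    crosstalk = list(alpha = 0.05),
    embedding = list(window_size = 5),
    attention = list(n_blocks = 3, n_heads = 8, head_dim = 8, hidden = 32,
                     beta = 1, dropout_p = 0.2, logit_scale = "sqrt_d",
                     network_update = "embedding_correlation",
                     update_denominator = "Dp"),
    train = list(lr = 1e-3, epochs = 50, batch_size = 32, patience = 10,
                 val_fraction = 0.15, dropout_c = 0.2,
                 model_mode = "full", pool = "mean_over_dims",
                 class_weights = "balanced"),
    cv = list(k = 5, repeats = 2),
    simulate = list(n_samples = 300, n_genes = 200, n_pathways = 20,
                    genes_per_pathway = c(15, 25), pathway_overlap = 0.3,
                    n_planted = 3, effect_size = 2,
                    sites_per_gene = c(3, 10), label_noise = 0)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(defaults))
      stop(sprintf("unknown config key '%s'", full))
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]]))
        stop(sprintf("config key '%s' must be a mapping", full))
      defaults[k] <- list(merge_config(defaults[[k]], user[[k]], full))
    } else {
      defaults[k] <- list(user[[k]])    # [ <- list() keeps explicit NULLs
    }
  }
  defaults
}

#' Validate a YAML/JSON run configuration
#'
#' Reads the file, rejects unknown keys (with their full field path), fills
#' defaults, and checks that referenced paths exist.
#'
#' @param path YAML or JSON configuration file
#' @return a `run_config` list with all defaults applied
#' @export
validate_config <- function(path) {
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
    else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(config_schema(), user)
  for (k in c("gmt", "labels", "network", "data_dir", "checkpoint")) {
    p <- cfg$paths[[k]]
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("config field 'paths.%s': file '%s' does not exist", k, p))
  }
  structure(cfg, class = "run_config")
}

# ---- pipeline ------------------------------------------------------------

write_manifest <- function(dir, stage, inputs, cfg, outputs) {
  inputs <- inputs[file.exists(inputs)]
  man <- list(
    stage = stage,
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("pathomix")),
    config_hash = unname(tools::md5sum(
      tmp <- {
        t <- tempfile(); saveRDS(unclass(cfg), t, version = 2L); t
      })),
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)]))
  )
  unlink(tmp)
  jsonlite::write_json(man, file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(man)
}

load_pipeline_data <- function(cfg) {
  dir <- cfg$paths$data_dir
  if (is.null(dir)) stop("config field 'paths.data_dir' is required")
  ds <- read_dataset(dir)
  coll <- filter_pathways(ds$collection, cfg$filter$min_genes,
                          cfg$filter$max_genes, cfg$filter$max_overlap,
                          cfg$filter$max_subsets)
  net <- if (!is.null(cfg$paths$network))
    read_edge_list(cfg$paths$network) else NULL
  ct <- build_crosstalk(coll, net, cfg$crosstalk$alpha)
  eg <- prepare_embedding(ds$modalities, coll$gene_universe,
                          embedding_config(list(),
                                           cfg$embedding$window_size))
  list(ds = ds, coll = coll, mask = build_mask(coll), crosstalk = ct,
       eg = eg, labels = ds$labels$label)
}

cfg_train <- function(cfg) {
  do.call(train_config, c(cfg$train, list(seed = cfg$seed)))
}
cfg_att <- function(cfg) do.call(attention_config, cfg$attention)

#' Run one pipeline stage
#'
#' Stages: `simulate` (write a synthetic dataset), `pathways` (filter the
#' GMT and build mask + crosstalk network), `embed` (build and save the
#' gene embedding), `train` (fit a model, save checkpoint + log),
#' `evaluate` (score a checkpoint on the data; repeated CV is available via
#' [cross_validate()]), `interpret` (modality contributions, SHAP tables,
#' sub-network scores). Each stage writes its artifacts plus a manifest
#' (input/output checksums, seed, config hash) under `output_dir`.
#'
#' @param cfg a `run_config` from [validate_config()]
#' @param command one of simulate, pathways, embed, train, evaluate,
#'   interpret
#' @return invisible list of written artifact paths
#' @export
run_pipeline <- function(cfg, command = c("simulate", "pathways", "embed",
                                          "train", "evaluate", "interpret")) {
  command <- match.arg(command)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  arts <- character(0)

  if (command == "simulate") {
    sc <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
    sim <- generate_dataset(sc)
    ddir <- file.path(out, "data")
    write_dataset(sim, ddir)
    arts <- list.files(ddir, full.names = TRUE)
    write_manifest(out, "simulate", character(0), cfg, arts)
    return(invisible(arts))
  }

  if (command == "pathways") {
    if (is.null(cfg$paths$gmt)) stop("config field 'paths.gmt' is required")
    coll <- read_gmt(cfg$paths$gmt)
    filt <- filter_pathways(coll, cfg$filter$min_genes, cfg$filter$max_genes,
                            cfg$filter$max_overlap, cfg$filter$max_subsets)
    net <- if (!is.null(cfg$paths$network))
      read_edge_list(cfg$paths$network) else NULL
    ct <- build_crosstalk(filt, net, cfg$crosstalk$alpha)
    mask <- build_mask(filt)
    trip <- which(mask == 1, arr.ind = TRUE)
    readr::write_tsv(tibble::tibble(gene = rownames(mask)[trip[, 1L]],
                                    pathway = colnames(mask)[trip[, 2L]],
                                    value = 1),
                     fp1 <- file.path(out, "mask.tsv"), progress = FALSE)
    nz <- which(upper.tri(ct$matrix) & ct$matrix > 0, arr.ind = TRUE)
    readr::write_tsv(tibble::tibble(
      pathway_a = rownames(ct$matrix)[nz[, 1L]],
      pathway_b = colnames(ct$matrix)[nz[, 2L]],
      weight = ct$matrix[nz]),
      fp2 <- file.path(out, "crosstalk.tsv"), progress = FALSE)
    write_gmt(filt, fp3 <- file.path(out, "pathways_filtered.gmt"))
    arts <- c(fp1, fp2, fp3)
    write_manifest(out, "pathways", cfg$paths$gmt, cfg, arts)
    return(invisible(arts))
  }

  pd <- load_pipeline_data(cfg)

  if (command == "embed") {
    fp <- file.path(out, "embedding.rds")
    saveRDS(list(eg = pd$eg, layout = attr(pd$eg, "layout")), fp)
    arts <- fp
  } else if (command == "train") {
    fit <- train_model(pd$eg, pd$labels, pd$mask, pd$crosstalk$matrix,
                       cfg_train(cfg), cfg_att(cfg))
    fp <- file.path(out, "checkpoint.rds")
    saveRDS(serialize_fit(fit), fp)
    readr::write_tsv(fit$history, fp2 <- file.path(out, "training_log.tsv"),
                     progress = FALSE)
    arts <- c(fp, fp2)
  } else if (command == "evaluate") {
    ckpt <- cfg$paths$checkpoint
    if (is.null(ckpt) || !file.exists(ckpt))
      stop("evaluate requires config field 'paths.checkpoint' ",
           "(a checkpoint saved by the train stage)")
    fit <- deserialize_fit(readRDS(ckpt))
    prob <- predict(fit, pd$eg)
    pred <- fit$classes[max.col(prob, ties.method = "first")]
    met <- compute_metrics(factor(pd$labels, levels = fit$classes),
                           factor(pred, levels = fit$classes), prob)
    readr::write_tsv(met, fp <- file.path(out, "metrics.tsv"),
                     progress = FALSE)
    jsonlite::write_json(as.list(met), file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    arts <- c(fp, file.path(out, "metrics.json"))
  } else if (command == "interpret") {
    ckpt <- cfg$paths$checkpoint
    if (is.null(ckpt) || !file.exists(ckpt))
      stop("interpret requires config field 'paths.checkpoint'")
    fit <- deserialize_fit(readRDS(ckpt))
    egn <- apply_normalizer(pd$eg, fit$normalizer)
    fw <- model_forward(fit$model, egn, collect = TRUE)
    arts <- character(0)
    if (!is.null(fw$enc) && length(fw$enc$row_maps) > 0) {
      mc <- modality_contributions(fw$enc$row_maps, fit$model$layout)
      readr::write_tsv(mc, fp <- file.path(out, "modality_contributions.tsv"),
                       progress = FALSE)
      arts <- c(arts, fp)
    }
    imp <- shap_importance(fit, pd$eg, pd$eg, level = "pathway",
                           seed = cfg$seed)
    readr::write_tsv(imp, fp <- file.path(out, "pathway_importance.tsv"),
                     progress = FALSE)
    arts <- c(arts, fp)
    if (!is.null(fw$enc) && length(fw$enc$networks) > 0) {
      sn <- subnetwork_scores(fw$enc$networks, imp)
      sn$members <- vapply(sn$members, paste, "", collapse = ",")
      readr::write_tsv(sn, fp <- file.path(out, "subnetworks.tsv"),
                       progress = FALSE)
      arts <- c(arts, fp)
    }
  }
  write_manifest(out, command,
                 list.files(cfg$paths$data_dir %||% ".", full.names = TRUE),
                 cfg, arts)
  invisible(arts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# checkpoints: strip environments down to plain values for serialization
serialize_fit <- function(fit) {
  params <- model_params(fit$model)
  list(values = lapply(params, function(p) p$value),
       names = vapply(params, function(p) p$name, ""),
       model_spec = list(mask = fit$model$mask, p0 = fit$model$p0,
                         dg = fit$model$dg, n_classes = fit$model$n_classes,
                         att_cfg = fit$model$att_cfg, cfg = fit$model$cfg,
                         layout = fit$model$layout),
       normalizer = fit$normalizer, classes = fit$classes,
       history = fit$history, best_epoch = fit$best_epoch)
}

deserialize_fit <- function(x) {
  sp <- x$model_spec
  model <- init_model(sp$mask, sp$dg, sp$p0, sp$n_classes, sp$att_cfg,
                      sp$cfg, sp$layout)
  params <- model_params(model)
  stopifnot(length(params) == length(x$values))
  for (i in seq_along(params)) params[[i]]$value <- x$values[[i]]
  structure(list(model = model, normalizer = x$normalizer,
                 classes = x$classes, history = x$history,
                 best_epoch = x$best_epoch),
            class = "pathomix_fit")
}
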