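#' Training configuration
#'
#' @param lr Adam learning rate
#' @param epochs maximum training epochs
#' @param batch_size minibatch size
#' @param patience early-stopping patience on validation macro-F1
#' @param val_fraction fraction of the training samples held out (stratified)
#'   for early stopping
#' @param dropout_c dropout probability between classifier layers
#' @param seed RNG seed controlling initialization, shuffling and dropout
#' @param model_mode `"full"` (full model), `"cc_attention"` (no
#'   crosstalk bias), `"transformer"` (no bias, no row attention),
#'   `"psnn"` (pathway embedding straight to classifier) or `"nn"` (gene
#'   embedding straight to classifier)
#' @param pool classifier input pooling over embedding dimensions:
#'   `"mean_over_dims"`, `"flatten"` or `"max_over_dims"`
#' @param class_weights `"balanced"` (inverse-frequency weighting of the
#'   cross-entropy) or `"none"`
#' @return a `train_config`
#' @export
train_config <- function(lr = 1e-3, epochs = 50, batch_size = 32,
                         patience = 10, val_fraction = 0.15,
                         dropout_c = 0.2, seed = 1,
                         model_mode = c("full", "cc_attention",
                                        "transformer", "psnn", "nn"),
                         pool = c("mean_over_dims", "flatten",
                                  "max_over_dims"),
                         class_weights = c("balanced", "none")) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1, patience >= 1,
            dropout_c >= 0, dropout_c < 1)
  structure(list(lr = lr, epochs = epochs, batch_size = batch_size,
                 patience = patience, val_fraction = val_fraction,
                 dropout_c = dropout_c, seed = as.integer(seed),
                 model_mode = match.arg(model_mode),
                 pool = match.arg(pool),
                 class_weights = match.arg(class_weights)),
            class = "train_config")
}

dense_layer <- function(n_in, n_out, name) {
  list(w = glorot(n_in, n_out, paste0(name, "_w")),
       b = px_param(matrix(0, 1L, n_out), paste0(name, "_b")))
}

#' Initialize a full classification model
#'
#' Builds the sparse gene-to-pathway projection, the criss-cross attention
#' blocks (for modes that use them) and the fully connected classifier head
#' (300, 200 and 100 neurons, then the class logits).
#'
#' @param mask binary gene x pathway matrix from [build_mask()]
#' @param dg gene embedding dimension
#' @param p0 initial crosstalk matrix (`Np x Np`)
#' @param n_classes number of class labels
#' @param att_cfg an [attention_config()]
#' @param cfg a [train_config()]
#' @param layout embedding layout tibble (dimension -> modality), kept for
#'   interpretation
#' @return a `pathomix_model`
#' @export
init_model <- function(mask, dg, p0, n_classes, att_cfg = attention_config(),
                       cfg = train_config(), layout = NULL) {
  np <- ncol(mask); ng <- nrow(mask)
  mode <- cfg$model_mode
  proj <- if (mode != "nn") sparse_projection(mask, dg) else NULL
  blocks <- if (mode %in% c("full", "cc_attention", "transformer"))
    lapply(seq_len(att_cfg$n_blocks), function(b)
      init_block_params(np, dg, att_cfg, b))
  else NULL
  n_in <- switch(cfg$pool,
    mean_over_dims = if (mode == "nn") ng else np,
    max_over_dims = if (mode == "nn") ng else np,
    flatten = (if (mode == "nn") ng else np) * dg)
  head <- list(dense_layer(n_in, 300L, "fc1"),
               dense_layer(300L, 200L, "fc2"),
               dense_layer(200L, 100L, "fc3"),
               dense_layer(100L, n_classes, "fc_out"))
  structure(list(proj = proj, blocks = blocks, head = head,
                 att_cfg = att_cfg, cfg = cfg, mask = mask,
                 p0 = as.matrix(p0), dg = dg, n_classes = n_classes,
                 layout = layout),
            class = "pathomix_model")
}

model_params <- function(model) {
  out <- list()
  if (!is.null(model$proj))
    out <- c(out, list(model$proj$weights, model$proj$bias))
  if (!is.null(model$blocks))
    out <- c(out, block_param_list(model$blocks))
  for (l in model$head) out <- c(out, list(l$w, l$b))
  out
}

head_forward <- function(x, head, dropout_c, training = FALSE) {
  h <- x
  for (i in seq_len(length(head) - 1L)) {
    h <- px_relu(px_add(px_bmm(h, px_use(head[[i]]$w)),
                        px_use(head[[i]]$b)))
    h <- px_dropout(h, dropout_c, training)
  }
  lst <- head[[length(head)]]
  px_add(px_bmm(h, px_use(lst$w)), px_use(lst$b))
}

pool_node <- function(x, pool) {
  switch(pool,
    mean_over_dims = px_pool_rows(x),
    max_over_dims = px_pool_rows_max(x),
    flatten = px_flatten(x),
    stop(sprintf("unknown pooling mode '%s'", pool)))
}

#' Pool a pathway embedding into a classifier input vector
#'
#' @param ep array `(Np, Dp, S)` or a single-sample `Np x Dp` matrix
#' @param mode `"mean_over_dims"` (default; per-pathway mean),
#'   `"flatten"`, or `"max_over_dims"`
#' @return matrix, samples x features
#' @export
pool_embedding <- function(ep, mode = "mean_over_dims") {
  ep <- as_cube(ep)
  pooled <- node_val(pool_node(ep, mode))
  t(matrix(pooled, nrow = dim(pooled)[2L]))
}

#' Full model forward pass
#'
#' Runs embedding projection, the configured encoder variant, pooling and
#' the classifier head. With plain array input this is an evaluation-mode
#' forward; inside [px_record()] with `training = TRUE` it builds the
#' differentiable training graph.
#'
#' @param model a `pathomix_model`
#' @param eg gene embedding `(Ng, Dg, S)` (array or node)
#' @param training training mode (dropout active)
#' @param collect collect encoder attention maps and updated networks
#' @return list with `logits` `(1, K, S)`, `ep_final`, `pooled` and `enc`
#'   (encoder internals or NULL)
#' @export
model_forward <- function(model, eg, training = FALSE, collect = FALSE) {
  mode <- model$cfg$model_mode
  enc <- NULL
  if (mode == "nn") {
    ep <- eg
  } else {
    ep <- psnn_forward(eg, model$proj)
    if (mode %in% c("full", "cc_attention", "transformer")) {
      enc <- encoder(ep, model$p0, model$blocks, model$att_cfg,
                     training = training,
                     use_bias = mode == "full",
                     use_row = mode %in% c("full", "cc_attention"))
      ep <- enc$ep
    }
  }
  pooled <- pool_node(ep, model$cfg$pool)
  logits <- head_forward(pooled, model$head, model$cfg$dropout_c, training)
  list(logits = logits, ep_final = ep, pooled = pooled,
       enc = if (collect) enc else NULL)
}

softmax_mat <- function(logits_cube) {
  m <- matrix(logits_cube, nrow = dim(logits_cube)[2L])   # K x S
  m <- sweep(m, 2L, apply(m, 2L, max))
  p <- sweep(exp(m), 2L, colSums(exp(m)), "/")
  t(p)                                                    # S x K
}
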