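#' Cross-validation plan
#'
#' Stratified k-fold cross-validation repeated with reshuffling; the paper
#' protocol is 5 folds repeated twice (10 fold-level metric sets).
#'
#' @param k number of folds
#' @param repeats number of reshuffled repeats
#' @param seed RNG seed for fold assignment
#' @return a `cv_plan`
#' @export
cv_plan <- function(k = 5, repeats = 2, seed = 1) {
  stopifnot(k >= 2, repeats >= 1)
  structure(list(k = k, repeats = repeats, seed = as.integer(seed)),
            class = "cv_plan")
}

#' Stratified fold assignments
#'
#' @param labels class labels
#' @param plan a [cv_plan()]
#' @return tibble with columns `repeat_id`, `fold`, `sample_idx`
#' @export
make_folds <- function(labels, plan) {
  n <- length(labels)
  out <- list()
  for (r in seq_len(plan$repeats)) {
    set.seed(plan$seed + 1000L * (r - 1L))
    fold <- integer(n)
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(plan$k), length(idx))
    }
    out[[r]] <- tibble::tibble(repeat_id = r, fold = fold,
                               sample_idx = seq_len(n))
  }
  dplyr::bind_rows(out)
}

snapshot_params <- function(params) lapply(params, function(p) p$value)
restore_params <- function(params, snap) {
  for (i in seq_along(params)) params[[i]]$value <- snap[[i]]
  invisible(NULL)
}

#' Train a classification model
#'
#' End-to-end training of the configured model variant with Adam,
#' class-weighted cross-entropy, and early stopping on validation macro-F1
#' (a stratified fraction of the training samples is held out internally).
#' The feature normalizer is fitted on the supplied samples only, so test
#' data must be held out by the caller (as [cross_validate()] does).
#' Deterministic given `cfg$seed`.
#'
#' @param eg raw (unnormalized) gene embedding `(Ng, Dg, S)` from
#'   [assemble_gene_embedding()]
#' @param labels integer or factor labels, length S, at least 2 classes
#' @param mask gene x pathway mask from [build_mask()]
#' @param p0 initial crosstalk matrix ([build_crosstalk()] `$matrix`)
#' @param cfg a [train_config()]
#' @param att_cfg an [attention_config()]
#' @param normalizer optionally a pre-fitted normalizer (else fitted here)
#' @return a `pathomix_fit`: the trained model, the fitted normalizer, the
#'   class levels and a per-epoch training log
#' @export
train_model <- function(eg, labels, mask, p0, cfg = train_config(),
                        att_cfg = attention_config(), normalizer = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (any(table(labels) < 2L)) stop("need at least 2 samples per class")
  y <- as.integer(labels)
  S <- dim(eg)[3L]
  stopifnot(length(y) == S)
  set.seed(cfg$seed)

  if (is.null(normalizer)) normalizer <- fit_normalizer(eg)
  layout <- attr(eg, "layout")
  egn <- apply_normalizer(eg, normalizer)

  # stratified early-stopping split
  val_idx <- integer(0)
  if (cfg$val_fraction > 0) {
    for (k in seq_len(nlevels(labels))) {
      idx <- which(y == k)
      n_val <- max(1L, round(length(idx) * cfg$val_fraction))
      if (length(idx) - n_val >= 1L)
        val_idx <- c(val_idx, sample(idx, n_val))
    }
  }
  tr_idx <- setdiff(seq_len(S), val_idx)

  K <- nlevels(labels)
  cw <- if (cfg$class_weights == "balanced") {
    tab <- table(factor(y, levels = seq_len(K)))
    as.numeric(length(y) / (K * pmax(tab, 1L)))
  } else rep(1, K)

  model <- init_model(mask, dim(eg)[2L], p0, K, att_cfg, cfg, layout)
  params <- model_params(model)

  history <- list()
  best <- list(score = -Inf, loss = Inf, snap = snapshot_params(params),
               epoch = 0L)
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      step <- step + 1L
      loss <- px_record({
        fw <- model_forward(model,
                            egn[, , b, drop = FALSE], training = TRUE)
        px_ce_loss(fw$logits, y[b], cw)
      })
      if (!is.finite(node_val(loss)))
        stop(sprintf("non-finite loss at epoch %d; try a smaller lr", epoch))
      px_backward(loss)
      adam_step(params, cfg$lr, step)
      ep_loss <- ep_loss + as.numeric(node_val(loss)) * length(b)
    }
    ep_loss <- ep_loss / length(ord)

    val_f1 <- NA_real_
    if (length(val_idx) > 0L) {
      pv <- softmax_mat(node_val(model_forward(
        model, egn[, , val_idx, drop = FALSE])$logits))
      val_f1 <- compute_metrics(y[val_idx],
                                max.col(pv, ties.method = "first"))$macro_f1
      # the patience clock runs on validation macro-F1 alone; among
      # epochs tied on it the snapshot goes to the lowest training loss.
      # On easily separable data the validation ceiling is reached within
      # a couple of epochs, and restoring a barely-trained model would
      # freeze the random initial asymmetries instead of letting weight
      # spread across redundant informative features.
      if (val_f1 > best$score) best$epoch <- epoch
      if (val_f1 > best$score ||
          (val_f1 == best$score && ep_loss < best$loss)) {
        best$score <- val_f1; best$loss <- ep_loss
        best$snap <- snapshot_params(params)
      }
    } else {
      best <- list(score = -ep_loss, loss = ep_loss,
                   snap = snapshot_params(params), epoch = epoch)
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, loss = ep_loss,
                                       val_macro_f1 = val_f1)
    if (length(val_idx) > 0L && epoch - best$epoch >= cfg$patience) break
  }
  restore_params(params, best$snap)

  structure(list(model = model, normalizer = normalizer,
                 classes = levels(labels),
                 history = dplyr::bind_rows(history),
                 best_epoch = best$epoch),
            class = "pathomix_fit")
}

#' @export
print.pathomix_fit <- function(x, ...) {
  cat(sprintf("<pathomix_fit> mode=%s, %d classes, best epoch %d\n",
              x$model$cfg$model_mode, x$model$n_classes, x$best_epoch))
  invisible(x)
}

#' Predict class probabilities or labels
#'
#' @param object a `pathomix_fit`
#' @param eg raw gene embedding `(Ng, Dg, S)` of new samples
#' @param type `"prob"` for a samples x classes probability matrix,
#'   `"class"` for predicted labels
#' @param ... unused
#' @export
predict.pathomix_fit <- function(object, eg, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  egn <- apply_normalizer(eg, object$normalizer)
  p <- softmax_mat(node_val(model_forward(object$model, egn)$logits))
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  object$classes[max.col(p, ties.method = "first")]
}

#' Repeated stratified cross-validation
#'
#' Runs the paper's evaluation protocol: stratified k-fold cross-validation
#' repeated with reshuffling. Normalization is fitted on each training fold
#' only, and test folds never inform model selection.
#'
#' @param eg raw gene embedding `(Ng, Dg, S)`
#' @param labels class labels, length S
#' @param mask gene x pathway mask
#' @param p0 initial crosstalk matrix
#' @param plan a [cv_plan()]
#' @param cfg a [train_config()]
#' @param att_cfg an [attention_config()]
#' @param leak_normalizer fit the normalizer on all samples instead of the
#'   training fold (deliberate leakage, for regression-testing the
#'   no-leakage contract; never use for evaluation)
#' @return a `pathomix_cv`: tibble of per-fold metrics plus summary
#' @export
cross_validate <- function(eg, labels, mask, p0, plan = cv_plan(),
                           cfg = train_config(),
                           att_cfg = attention_config(),
                           leak_normalizer = FALSE) {
  labels <- factor(labels)
  y <- as.integer(labels)
  folds <- make_folds(y, plan)
  rows <- list()
  for (r in seq_len(plan$repeats)) {
    fr <- folds[folds$repeat_id == r, ]
    for (f in seq_len(plan$k)) {
      test_idx <- fr$sample_idx[fr$fold == f]
      train_idx <- fr$sample_idx[fr$fold != f]
      if (length(unique(y[train_idx])) < nlevels(labels))
        stop("a class is absent from a training fold; review stratification")
      norm <- if (leak_normalizer) fit_normalizer(eg)
        else fit_normalizer(eg, train_idx)
      fit <- train_model(eg[, , train_idx, drop = FALSE], y[train_idx],
                         mask, p0, cfg, att_cfg, normalizer = norm)
      prob <- predict(fit, eg[, , test_idx, drop = FALSE])
      pred <- max.col(prob, ties.method = "first")
      met <- compute_metrics(y[test_idx], pred, prob)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(repeat_id = r, fold = f), met)
    }
  }
  per_fold <- dplyr::bind_rows(rows)
  structure(list(per_fold = per_fold, plan = plan, cfg = cfg),
            class = "pathomix_cv")
}

#' @export
print.pathomix_cv <- function(x, ...) {
  s <- glance(x)
  cat(sprintf(
    "<pathomix_cv> %dx%d folds: macro-F1 %.3f +/- %.3f, AUC %.3f\n",
    x$plan$k, x$plan$repeats, s$mean_macro_f1, s$sd_macro_f1, s$mean_auc))
  invisible(x)
}
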