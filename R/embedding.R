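#' Construct a modality input
#'
#' Bundles one omics modality: a feature-by-sample value matrix, its
#' resolution level, and the feature-to-gene mapping used to compact
#' sub-gene features (CpG sites, editing sites, fragments, ...) into
#' gene-level statistics.
#'
#' @param name modality name (e.g. "expression", "methylation", "cnv")
#' @param values numeric matrix, features x samples, with feature row names
#' @param level one of "gene", "fragment", "nucleotide"
#' @param feature_to_gene data frame with columns `feature`, `gene` and
#'   optional `weight` (positive) and `position` (integer coordinate within
#'   the gene); defaults to the identity mapping for gene-level modalities
#' @return a `modality_input`
#' @export
modality_input <- function(name, values, level = c("gene", "fragment", "nucleotide"),
                           feature_to_gene = NULL) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("`values` must have feature row names")
  if (is.null(feature_to_gene)) {
    if (level != "gene")
      stop("feature_to_gene is required for sub-gene level modalities")
    feature_to_gene <- tibble::tibble(feature = rownames(values),
                                      gene = rownames(values))
  }
  feature_to_gene <- tibble::as_tibble(feature_to_gene)
  stopifnot(all(c("feature", "gene") %in% names(feature_to_gene)))
  if ("weight" %in% names(feature_to_gene) &&
      any(!is.finite(feature_to_gene$weight) | feature_to_gene$weight <= 0))
    stop("feature weights must be positive and finite")
  structure(list(name = name, values = values, level = level,
                 feature_to_gene = feature_to_gene),
            class = "modality_input")
}

#' @export
print.modality_input <- function(x, ...) {
  cat(sprintf("<modality_input> %s (%s level): %d features x %d samples\n",
              x$name, x$level, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Statistical indicators compacting sub-gene features to gene level
#'
#' Applies one indicator to the feature values mapped to a single gene in a
#' single sample. Available kinds: `gene_level_score` (the single gene-level
#' value), `count`, `min`, `max`, `mean`, `entropy` (Shannon entropy, natural
#' log, of values normalized to proportions; `0*log(0) = 0`),
#' `weighted_mean_gene` (weighted mean over the whole gene) and
#' `weighted_mean_window` (mean over fixed-width positional windows of
#' within-window weighted means).
#'
#' @param values numeric vector of the gene's feature values in one sample
#' @param kind indicator name
#' @param weights optional positive weights (required for the weighted means)
#' @param positions optional integer positions (required for the window mean)
#' @param window_size window width in position units
#' @param fill value returned for an empty feature set
#' @return a single numeric value
#' @export
apply_indicator <- function(values, kind, weights = NULL, positions = NULL,
                            window_size = 5, fill = NA_real_) {
  if (length(values) == 0L)
    return(if (kind == "count") 0 else fill)
  switch(kind,
    gene_level_score = {
      if (length(values) != 1L)
        stop("gene_level_score expects exactly one value per gene")
      values
    },
    count = length(values),
    min = min(values),
    max = max(values),
    mean = mean(values),
    entropy = {
      if (any(values < 0)) stop("entropy requires non-negative values")
      tot <- sum(values)
      if (tot == 0) return(0)
      p <- values / tot
      p <- p[p > 0]
      -sum(p * log(p))
    },
    weighted_mean_gene = {
      if (is.null(weights)) stop("weighted_mean_gene requires weights")
      if (sum(weights) == 0) stop("weighted mean with all-zero weights")
      sum(weights * values) / sum(weights)
    },
    weighted_mean_window = {
      if (is.null(positions)) stop("weighted_mean_window requires positions")
      if (is.null(weights)) weights <- rep(1, length(values))
      win <- floor((positions - min(positions)) / window_size)
      wm <- vapply(split(seq_along(values), win), function(i)
        sum(weights[i] * values[i]) / sum(weights[i]), 0)
      mean(wm)
    },
    stop(sprintf("unknown indicator '%s'", kind))
  )
}

#' Default indicator menu for a modality level
#'
#' Gene-level modalities carry a single gene-level score; sub-gene
#' modalities are summarized by count, min, max, mean and entropy.
#'
#' @param level modality level
#' @return character vector of indicator kinds
#' @export
default_indicators <- function(level) {
  if (level == "gene") "gene_level_score"
  else c("count", "min", "max", "mean", "entropy")
}

#' Embedding configuration
#'
#' @param indicators named list: per-modality character vector of indicator
#'   kinds (see [apply_indicator()]); gene-level modalities may only use
#'   `gene_level_score`
#' @param window_size window width for `weighted_mean_window`
#' @return an `embedding_config`
#' @export
embedding_config <- function(indicators, window_size = 5) {
  structure(list(indicators = indicators, window_size = window_size),
            class = "embedding_config")
}

#' Gene-level modal feature tensor for one modality
#'
#' Applies the configured indicators to every gene's mapped features in
#' every sample, yielding an `Ng x e_i x S` array indexed by the gene
#' universe. Genes with no mapped features get `NA` (replaced by the
#' population mean, i.e. 0, after z-scoring). Features mapping to genes
#' outside the universe are dropped; more than 50% unmapped raises a
#' warning, 100% an error.
#'
#' @param mi a [modality_input()]
#' @param indicators character vector of indicator kinds for this modality
#' @param universe character vector of gene ids defining the row order
#' @param window_size window width for `weighted_mean_window`
#' @return numeric array of dim `(Ng, e_i, S)` with dimnames
#' @export
build_modal_features <- function(mi, indicators, universe, window_size = 5) {
  if (mi$level == "gene" && !all(indicators == "gene_level_score"))
    stop("gene-level modalities may only use the gene_level_score indicator")
  map <- mi$feature_to_gene
  map <- map[map$feature %in% rownames(mi$values), , drop = FALSE]
  n_all <- nrow(map)
  map <- map[map$gene %in% universe, , drop = FALSE]
  dropped <- n_all - nrow(map)
  if (nrow(map) == 0L)
    stop(sprintf("modality '%s': no features map to the gene universe", mi$name))
  if (dropped / n_all > 0.5)
    warning(sprintf("modality '%s': %d/%d features map outside the gene universe",
                    mi$name, dropped, n_all), call. = FALSE)
  S <- ncol(mi$values)
  out <- array(NA_real_, c(length(universe), length(indicators), S),
               dimnames = list(universe, indicators, colnames(mi$values)))
  ridx <- match(map$feature, rownames(mi$values))
  by_gene <- split(seq_len(nrow(map)), map$gene)
  w_all <- if ("weight" %in% names(map)) map$weight else NULL
  p_all <- if ("position" %in% names(map)) map$position else NULL
  for (g in names(by_gene)) {
    sel <- by_gene[[g]]
    sub <- mi$values[ridx[sel], , drop = FALSE]
    w <- if (!is.null(w_all)) w_all[sel] else NULL
    p <- if (!is.null(p_all)) p_all[sel] else NULL
    gi <- match(g, universe)
    for (k in seq_along(indicators)) {
      out[gi, k, ] <- vapply(seq_len(S), function(s)
        apply_indicator(sub[, s], indicators[k], weights = w, positions = p,
                        window_size = window_size), 0)
    }
  }
  out
}

#' Concatenate per-modality features into the gene embedding
#'
#' Stacks the modal feature tensors along the feature axis, in the given
#' modality order, producing the compacted multi-modal gene embedding of
#' dim `(Ng, Dg, S)` with `Dg` the total indicator count.
#'
#' @param parts named list of arrays from [build_modal_features()]
#' @return a `gene_embedding`: array of dim `(Ng, Dg, S)` with attribute
#'   `layout`, a tibble mapping each embedding dimension to its modality
#'   and indicator
#' @export
assemble_gene_embedding <- function(parts) {
  stopifnot(length(parts) >= 1L)
  d1 <- dim(parts[[1L]])
  for (p in parts)
    if (!identical(dim(p)[c(1L, 3L)], d1[c(1L, 3L)]))
      stop("modal feature tensors disagree in gene or sample count")
  dg <- sum(vapply(parts, function(p) dim(p)[2L], 0L))
  eg <- array(NA_real_, c(d1[1L], dg, d1[3L]))
  dimnames(eg) <- list(dimnames(parts[[1L]])[[1L]], NULL,
                       dimnames(parts[[1L]])[[3L]])
  layout <- tibble::tibble(dim = integer(), modality = character(),
                           indicator = character())
  at <- 0L
  for (m in names(parts)) {
    e <- dim(parts[[m]])[2L]
    eg[, at + seq_len(e), ] <- parts[[m]]
    layout <- dplyr::bind_rows(layout, tibble::tibble(
      dim = at + seq_len(e), modality = m,
      indicator = dimnames(parts[[m]])[[2L]]))
    at <- at + e
  }
  structure(eg, layout = layout, class = c("gene_embedding", "array"))
}

#' Fit / apply per-feature z-score normalization
#'
#' Standardizes each (gene, embedding-dimension) column across samples.
#' Fitting uses only the given samples (training folds) to avoid leakage;
#' missing entries are ignored when fitting and set to 0 (the standardized
#' population mean) after scaling.
#'
#' @param eg gene embedding array `(Ng, Dg, S)`
#' @param sample_idx samples to fit on (default: all)
#' @return `fit_normalizer`: list of `center` and `scale` matrices (Ng x Dg)
#' @export
fit_normalizer <- function(eg, sample_idx = NULL) {
  if (is.null(sample_idx)) sample_idx <- seq_len(dim(eg)[3L])
  tr <- eg[, , sample_idx, drop = FALSE]
  center <- apply(tr, c(1L, 2L), function(v) mean(v, na.rm = TRUE))
  scale <- apply(tr, c(1L, 2L), function(v) stats::sd(v, na.rm = TRUE))
  center[!is.finite(center)] <- 0
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale), class = "px_normalizer")
}

#' @rdname fit_normalizer
#' @param norm a fitted normalizer
#' @export
apply_normalizer <- function(eg, norm) {
  out <- eg
  for (s in seq_len(dim(eg)[3L]))
    out[, , s] <- (eg[, , s] - norm$center) / norm$scale
  out[is.na(out)] <- 0
  attributes(out) <- attributes(eg)
  out
}

#' Initialize the pathway-based sparse projection
#'
#' A linear map from gene embedding to pathway embedding whose weight
#' support is the gene-pathway membership mask: weights outside the mask
#' are exactly zero at initialization and stay zero through training.
#' Weights on the support are drawn uniformly in `(-1/sqrt(k_p), 1/sqrt(k_p))`
#' where `k_p` is pathway p's gene count; the bias is one value per pathway
#' per embedding dimension (set `bias = "scalar"` for one per pathway).
#'
#' @param mask binary gene x pathway matrix from [build_mask()]
#' @param dg embedding dimension
#' @param bias "per_dim" or "scalar"
#' @return a `sparse_projection`: list with `weights` and `bias` parameters
#'   and the `mask`
#' @export
sparse_projection <- function(mask, dg, bias = c("per_dim", "scalar")) {
  bias <- match.arg(bias)
  k <- pmax(colSums(mask), 1)
  lim <- matrix(1 / sqrt(k), nrow(mask), ncol(mask), byrow = TRUE)
  w <- matrix(stats::runif(length(mask), -1, 1), nrow(mask)) * lim * mask
  b <- matrix(0, ncol(mask), if (bias == "per_dim") dg else 1L)
  structure(list(
    weights = px_param(w, "w_sparse", mask = mask),
    bias = px_param(b, "b_sparse"),
    mask = mask, dg = dg, bias_kind = bias
  ), class = "sparse_projection")
}

#' Project gene embeddings to pathway embeddings
#'
#' Computes `E_P = (mask o W)^T E_G + B` per sample. Accepts plain arrays
#' (evaluation) or autodiff nodes (training); gradients never flow through
#' masked-out weights.
#'
#' @param eg gene embedding `(Ng, Dg, S)` (array or node)
#' @param proj a [sparse_projection()]
#' @return pathway embedding `(Np, Dp, S)` with `Dp = Dg`
#' @export
psnn_forward <- function(eg, proj) {
  weff <- px_mul(px_use(proj$weights), as_cube(proj$mask))
  ep <- px_bmm(weff, eg, ta = TRUE)
  b <- px_use(proj$bias)
  if (proj$bias_kind == "scalar") {
    ep <- px_add(ep, b)                       # (Np x 1) broadcast over dims
  } else {
    ep <- px_add(ep, b)
  }
  v <- node_val(ep)
  if (!all(is.finite(v))) {
    bad <- which(apply(!is.finite(v), 1L, any))[1L]
    stop(sprintf("non-finite pathway embedding at pathway index %d", bad))
  }
  ep
}
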