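#' Modality contributions from row-attention maps
#'
#' Element-wise averages all row-attention maps (across blocks, heads and
#' samples) into one `Dp x Dp` matrix; its column means give per-dimension
#' attention weights (summing to 1 because rows are stochastic), and each
#' modality's contribution is the sum of its dimensions' weights.
#'
#' @param row_maps nested list of row-attention arrays `(Dp, Dp, S)`, as in
#'   the `row_maps` element returned by [encoder()] / [model_forward()]
#' @param layout tibble mapping embedding dimension to modality (the
#'   `layout` attribute of [assemble_gene_embedding()])
#' @return tibble with columns `modality`, `weight` (non-negative, sum 1)
#' @export
modality_contributions <- function(row_maps, layout) {
  maps <- unlist(row_maps, recursive = FALSE)
  stopifnot(length(maps) > 0L)
  dp <- dim(maps[[1L]])[1L]
  if (!all(seq_len(dp) %in% layout$dim))
    stop("embedding layout does not cover all pathway-embedding dimensions")
  acc <- matrix(0, dp, dp); n <- 0L
  for (m in maps) {
    acc <- acc + rowSums(m, dims = 2L)
    n <- n + dim(m)[3L]
  }
  avg <- acc / n
  w_dim <- colMeans(avg)
  out <- tibble::tibble(dim = seq_len(dp), weight = w_dim)
  out <- dplyr::left_join(out, layout[, c("dim", "modality")], by = "dim")
  dplyr::summarise(dplyr::group_by(out, modality),
                   weight = sum(weight), .groups = "drop")
}

#' Per-sample pathway activity scores
#'
#' The per-pathway score of a sample is the mean of its pathway embedding
#' across embedding dimensions.
#'
#' @param ep pathway embedding `(Np, Dp, S)` (evaluation mode)
#' @param pathway_ids optional row names
#' @return matrix, samples x pathways
#' @export
pathway_scores <- function(ep, pathway_ids = NULL) {
  ep <- as_cube(ep)
  s <- t(apply(ep, 3L, rowMeans))
  if (dim(ep)[3L] == 1L) s <- matrix(s, nrow = 1L)
  colnames(s) <- pathway_ids
  s
}

# interventional value function: E_bg f(x with features outside the
# coalition replaced by background values); groups index columns of X
shap_engine <- function(f, X_eval, X_bg, groups, method = c("auto", "exact",
                                                            "sampling"),
                        exact_limit = 12L, n_perm = 32L, seed = 1L) {
  method <- match.arg(method)
  p <- length(groups)
  if (method == "exact" && p > 2000L)
    stop("too many entities for exact Shapley explanation; ",
         "use the sampling approximation")
  n_eval <- nrow(X_eval); n_bg <- nrow(X_bg)
  if (method == "auto") {
    # exact mode costs 2^p coalitions x n_bg x n_eval model evaluations;
    # fall back to sampling when that blows past a fixed budget even for
    # small p (model-backed value functions are the expensive case)
    method <- if (p <= exact_limit &&
                  2^p * n_bg * n_eval <= 2e5) "exact" else "sampling"
  }
  phi <- matrix(0, n_eval, p)

  if (method == "exact") {
    subsets <- 0:(2^p - 1)
    inset <- vapply(seq_len(p), function(i) bitwAnd(subsets, 2^(i - 1)) > 0,
                    logical(length(subsets)))
    if (is.null(dim(inset))) dim(inset) <- c(length(subsets), p)
    vmat <- matrix(0, length(subsets), n_eval)
    for (si in seq_along(subsets)) {
      keep <- unlist(groups[inset[si, ]])
      rows <- X_bg[rep(seq_len(n_bg), times = n_eval), , drop = FALSE]
      if (length(keep) > 0L) {
        xe <- X_eval[rep(seq_len(n_eval), each = n_bg), keep, drop = FALSE]
        rows[, keep] <- xe
      }
      fx <- f(rows)
      vmat[si, ] <- colMeans(matrix(fx, nrow = n_bg))
    }
    sizes <- rowSums(inset)
    fact <- factorial(0:p)
    for (i in seq_len(p)) {
      without <- which(!inset[, i])
      with_i <- without + 2^(i - 1)  # subset index offset (0-based ids)
      wsz <- sizes[without]
      w <- fact[wsz + 1L] * fact[p - wsz] / fact[p + 1L]
      phi[, i] <- colSums(w * (vmat[match(subsets[without] + 2^(i - 1),
                                          subsets), , drop = FALSE] -
                                 vmat[without, , drop = FALSE]))
    }
  } else {
    set.seed(seed)
    for (s in seq_len(n_eval)) {
      x <- X_eval[s, ]
      contrib <- matrix(0, n_perm, p)
      rows <- matrix(0, n_perm * (p + 1L), ncol(X_eval))
      ords <- matrix(0L, n_perm, p)
      at <- 0L
      for (pm in seq_len(n_perm)) {
        ord <- sample.int(p)
        ords[pm, ] <- ord
        z <- X_bg[((pm - 1L) %% n_bg) + 1L, ]
        rows[at + 1L, ] <- z
        for (j in seq_len(p)) {
          z[groups[[ord[j]]]] <- x[groups[[ord[j]]]]
          rows[at + 1L + j, ] <- z
        }
        at <- at + p + 1L
      }
      fx <- matrix(f(rows), nrow = p + 1L)
      for (pm in seq_len(n_perm))
        contrib[pm, ords[pm, ]] <- diff(fx[, pm])
      phi[s, ] <- colMeans(contrib)
    }
  }
  phi
}

#' Shapley-value importance of pathways, genes or gene-modality features
#'
#' Computes per-entity SHAP values of the fitted model with an
#' interventional value function (absent features replaced by background
#' samples). Pathway-level explanations act on the pooled classifier input;
#' gene-level and gene-modality-level explanations act on the gene
#' embedding, optionally restricted to one pathway's member genes. Exact
#' coalition enumeration is used up to `exact_limit` entities, a seeded
#' permutation-sampling approximation beyond.
#'
#' @param fit a `pathomix_fit`
#' @param eg_bg raw gene embedding of background samples (>= 10 recommended)
#' @param eg_eval raw gene embedding of samples to explain
#' @param level `"pathway"`, `"gene"` or `"gene_modality"`
#' @param pathway for gene-level explanations, restrict to this pathway's
#'   member genes (pathway id; NULL = all genes)
#' @param class_index class whose probability is explained (default: last)
#' @param method `"auto"`, `"exact"` or `"sampling"`; auto picks exact
#'   enumeration only while both the entity count and the implied number
#'   of model evaluations stay small
#' @param exact_limit maximum entity count for exact enumeration
#' @param n_perm permutations per sample in sampling mode
#' @param seed RNG seed for the sampling approximation
#' @param at layer at which pathway entities are masked: `"input"`
#'   (default) masks the embedding rows of a pathway's member genes, so a
#'   pathway is credited for the input information its genes carry into
#'   the model (genes shared between pathways credit each of them);
#'   `"embedding"` masks a pathway's row of the encoder-input pathway
#'   embedding; `"pooled"` masks the pooled classifier input, explaining
#'   only the head's use of the mixed representation
#' @return tibble with columns `entity`, `kind`, `shap` (mean absolute SHAP
#'   across explained samples), `direction` (signed mean), `rank`
#' @export
shap_importance <- function(fit, eg_bg, eg_eval,
                            level = c("pathway", "gene", "gene_modality"),
                            pathway = NULL, class_index = NULL,
                            method = "auto", exact_limit = 12L,
                            n_perm = 32L, seed = 1L,
                            at = c("input", "embedding", "pooled")) {
  level <- match.arg(level)
  at <- match.arg(at)
  model <- fit$model
  if (is.null(class_index)) class_index <- model$n_classes
  bg <- apply_normalizer(eg_bg, fit$normalizer)
  ev <- apply_normalizer(eg_eval, fit$normalizer)
  ng <- dim(ev)[1L]; dg <- dim(ev)[2L]
  genes <- dimnames(ev)[[1L]]
  if (is.null(genes)) genes <- paste0("g", seq_len(ng))

  if (level == "pathway") {
    if (model$cfg$model_mode == "nn")
      stop("pathway-level SHAP requires a model with pathway embeddings")
    ids <- colnames(model$mask)
    np <- length(ids)
    kind <- "pathway"
    if (at == "input") {
      flat_eg <- function(a) {
        out <- t(apply(a, 3L, identity))
        if (dim(a)[3L] == 1L) out <- matrix(as.numeric(a), nrow = 1L)
        out
      }
      X_eval <- flat_eg(ev); X_bg <- flat_eg(bg)
      f <- function(rows) {
        x <- array(t(rows), c(ng, dg, nrow(rows)))
        softmax_mat(node_val(model_forward(model, x)$logits))[, class_index]
      }
      groups <- lapply(seq_len(np), function(p) {
        members <- which(model$mask[, p] > 0)
        as.vector(outer(members, (seq_len(dg) - 1L) * ng, `+`))
      })
    } else if (at == "embedding") {
      ep_of <- function(eg) node_val(psnn_forward(eg, model$proj))
      flat_ep <- function(ep) {
        out <- t(apply(ep, 3L, identity))
        if (dim(ep)[3L] == 1L) out <- matrix(as.numeric(ep), nrow = 1L)
        out
      }
      X_eval <- flat_ep(ep_of(ev)); X_bg <- flat_ep(ep_of(bg))
      mode <- model$cfg$model_mode
      f <- function(rows) {
        ep <- array(t(rows), c(np, dg, nrow(rows)))
        if (mode %in% c("full", "cc_attention", "transformer")) {
          enc <- encoder(ep, model$p0, model$blocks, model$att_cfg,
                         use_bias = mode == "full",
                         use_row = mode %in% c("full", "cc_attention"))
          ep <- node_val(enc$ep)
        }
        pooled <- node_val(pool_node(ep, model$cfg$pool))
        softmax_mat(node_val(head_forward(
          pooled, model$head, 0)))[, class_index]
      }
      groups <- lapply(seq_len(np), function(p) (seq_len(dg) - 1L) * np + p)
    } else {
      pool_of <- function(eg) node_val(model_forward(model, eg)$pooled)
      X_eval <- flat_pool(pool_of(ev)); X_bg <- flat_pool(pool_of(bg))
      f <- function(rows) {
        x <- array(t(rows), c(1L, ncol(rows), nrow(rows)))
        softmax_mat(node_val(head_forward(x, model$head, 0)))[, class_index]
      }
      groups <- as.list(seq_along(ids))
    }
  } else {
    members <- if (!is.null(pathway)) {
      stopifnot(pathway %in% colnames(model$mask))
      which(model$mask[, pathway] > 0)
    } else seq_len(ng)
    X_eval <- t(apply(ev, 3L, identity))   # S x (Ng*Dg), column-major
    if (dim(ev)[3L] == 1L) X_eval <- matrix(as.numeric(ev), nrow = 1L)
    X_bg <- t(apply(bg, 3L, identity))
    if (dim(bg)[3L] == 1L) X_bg <- matrix(as.numeric(bg), nrow = 1L)
    f <- function(rows) {
      x <- array(t(rows), c(ng, dg, nrow(rows)))
      softmax_mat(node_val(model_forward(model, x)$logits))[, class_index]
    }
    col_of <- function(g, d) (d - 1L) * ng + g
    if (level == "gene") {
      groups <- lapply(members, function(g) col_of(g, seq_len(dg)))
      ids <- genes[members]
      kind <- "gene"
    } else {
      layout <- model$layout
      stopifnot(!is.null(layout))
      mods <- unique(layout$modality)
      grid <- expand.grid(gene = members, modality = mods,
                          stringsAsFactors = FALSE)
      groups <- lapply(seq_len(nrow(grid)), function(i) {
        dms <- layout$dim[layout$modality == grid$modality[i]]
        col_of(grid$gene[i], dms)
      })
      ids <- paste(genes[grid$gene], grid$modality, sep = ":")
      kind <- "gene_modality"
    }
  }

  phi <- shap_engine(f, X_eval, X_bg, groups, method = method,
                     exact_limit = exact_limit, n_perm = n_perm, seed = seed)
  out <- tibble::tibble(entity = ids, kind = kind,
                        shap = colMeans(abs(phi)),
                        direction = colMeans(phi))
  out$rank <- rank(-out$shap, ties.method = "first")
  dplyr::arrange(out, rank)
}

flat_pool <- function(pooled) {
  t(matrix(pooled, nrow = dim(pooled)[2L]))
}

#' Core modality of each gene
#'
#' Given a gene-modality importance table, assigns each gene the modality
#' whose SHAP rank is best; exact ties go to the first modality in
#' `modality_order`.
#'
#' @param gene_modality_table output of
#'   `shap_importance(..., level = "gene_modality")`
#' @param modality_order character vector fixing the tie-break order
#' @return tibble with columns `gene`, `core_modality`
#' @export
core_modality <- function(gene_modality_table, modality_order = NULL) {
  tb <- gene_modality_table
  parts <- strsplit(tb$entity, ":", fixed = TRUE)
  tb$gene <- vapply(parts, `[[`, "", 1L)
  tb$modality <- vapply(parts, function(x) paste(x[-1L], collapse = ":"), "")
  if (is.null(modality_order)) modality_order <- unique(tb$modality)
  tb$mod_ord <- match(tb$modality, modality_order)
  tb <- dplyr::arrange(tb, rank, mod_ord)
  dplyr::summarise(dplyr::group_by(tb, gene),
                   core_modality = modality[1L], .groups = "drop")
}

#' Score crosstalk sub-networks concentrating pathway importance
#'
#' Four steps on the per-block updated crosstalk networks: (1) element-wise
#' average across blocks; (2) prune edges at or below the `prune_quantile`
#' of absolute edge weights; (3) from each top-SHAP seed pathway, grow a
#' sub-network by greedily adding the neighbor connected by the strongest
#' edge while the score improves, up to `max_size` members; (4) score each
#' sub-network as the sum of member SHAP values weighted by
#' `1 + normalized within-subnetwork degree`. Sub-networks with member
#' Jaccard overlap above `merge_jaccard` are merged.
#'
#' @param networks list of updated `Np x Np` crosstalk matrices (one per
#'   block, e.g. `enc$networks` from [model_forward()])
#' @param pathway_shap tibble with columns `entity`, `shap` (pathway-level
#'   SHAP table)
#' @param prune_quantile quantile of |edge weight| below which edges are
#'   removed
#' @param max_size maximum sub-network size
#' @param n_seeds number of top-SHAP seed pathways
#' @param merge_jaccard overlap threshold for merging sub-networks
#' @return tibble with list-column `members`, plus `score`, `n_edges`,
#'   sorted by decreasing score
#' @export
subnetwork_scores <- function(networks, pathway_shap, prune_quantile = 0.9,
                              max_size = 20L, n_seeds = 15L,
                              merge_jaccard = 0.5) {
  stopifnot(length(networks) >= 1L)
  avg <- Reduce(`+`, networks) / length(networks)
  ids <- colnames(avg)
  if (is.null(ids)) {
    ids <- paste0("pw", seq_len(ncol(avg)))
    dimnames(avg) <- list(ids, ids)
  }
  diag(avg) <- 0
  ut <- upper.tri(avg)
  thr <- stats::quantile(abs(avg[ut]), prune_quantile)
  keep <- which(ut & abs(avg) > thr, arr.ind = TRUE)
  if (nrow(keep) == 0L) {
    warning("all edges pruned; no sub-networks", call. = FALSE)
    return(tibble::tibble(members = list(), score = numeric(),
                          n_edges = integer()))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[keep[, 1L]], to = ids[keep[, 2L]],
               weight = abs(avg[keep])),
    directed = FALSE, vertices = ids)

  shap <- stats::setNames(pathway_shap$shap, pathway_shap$entity)
  shap_of <- function(v) ifelse(is.na(shap[v]), 0, shap[v])
  score_of <- function(members) {
    sub <- igraph::induced_subgraph(g, members)
    d <- igraph::degree(sub)
    nd <- if (length(members) > 1L) d / (length(members) - 1L) else 0
    sum(shap_of(members) * (1 + nd))
  }

  seeds <- pathway_shap$entity[order(-pathway_shap$shap)]
  connected <- ids[igraph::degree(g) > 0]
  seeds <- utils::head(seeds[seeds %in% connected], n_seeds)
  subs <- list()
  for (seed in seeds) {
    members <- seed
    sc <- score_of(members)
    repeat {
      if (length(members) >= max_size) break
      nbr <- setdiff(unique(unlist(
        igraph::adjacent_vertices(g, members))), match(members, ids))
      nbr_ids <- setdiff(ids[nbr], members)
      if (length(nbr_ids) == 0L) break
      # strongest connecting edge first
      best_w <- vapply(nbr_ids, function(v)
        max(avg[v, members]), 0)
      cand <- nbr_ids[order(-best_w)]
      added <- FALSE
      for (v in cand) {
        sc2 <- score_of(c(members, v))
        if (sc2 > sc) {
          members <- c(members, v); sc <- sc2; added <- TRUE; break
        }
      }
      if (!added) break
    }
    subs[[length(subs) + 1L]] <- list(members = members, score = sc)
  }

  # merge heavily overlapping sub-networks
  merged <- list()
  for (s in subs) {
    hit <- FALSE
    for (i in seq_along(merged)) {
      a <- merged[[i]]$members; b <- s$members
      if (length(intersect(a, b)) / length(union(a, b)) > merge_jaccard) {
        u <- union(a, b)
        merged[[i]] <- list(members = u, score = score_of(u))
        hit <- TRUE
        break
      }
    }
    if (!hit) merged[[length(merged) + 1L]] <- s
  }

  out <- tibble::tibble(
    members = lapply(merged, `[[`, "members"),
    score = vapply(merged, `[[`, 0, "score"),
    n_edges = vapply(merged, function(s)
      as.integer(igraph::ecount(igraph::induced_subgraph(g, s$members))), 0L))
  dplyr::arrange(out, dplyr::desc(score))
}
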