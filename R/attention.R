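#' Criss-cross attention configuration
#'
#' Architecture constants of the transformer encoder: 3 blocks of 8-head
#' column-wise (pathway-axis) attention biased by the pathway crosstalk
#' network, gated multi-head merging, 8-head row-wise (feature/modality-axis)
#' attention, a `beta`-scaled row residual, and a per-block network update.
#'
#' @param n_blocks number of encoder blocks
#' @param n_heads attention heads per sub-layer
#' @param head_dim attention dimension d of each head
#' @param hidden width o of the position-wise feed-forward
#' @param beta constant coefficient scaling the row-attention residual
#' @param dropout_p dropout probability (training mode only)
#' @param logit_scale divide attention logits by `sqrt(d)` (default,
#'   numerically standard) or by `d`
#' @param network_update `"embedding_correlation"` (default): next block's
#'   crosstalk matrix is the scaled Gram matrix of the batch-mean updated
#'   pathway embedding; `"printed_formula"`: `P' = P P^T / Np`
#' @param update_denominator denominator of the correlation update,
#'   `"Dp"` (default) or `"Np"`
#' @return an `attention_config`
#' @export
attention_config <- function(n_blocks = 3, n_heads = 8, head_dim = 8,
                             hidden = 32, beta = 1, dropout_p = 0.2,
                             logit_scale = c("sqrt_d", "d"),
                             network_update = c("embedding_correlation",
                                                "printed_formula"),
                             update_denominator = c("Dp", "Np")) {
  stopifnot(n_blocks >= 1, n_heads >= 1, head_dim >= 1, hidden >= 1,
            dropout_p >= 0, dropout_p < 1)
  structure(list(
    n_blocks = n_blocks, n_heads = n_heads, head_dim = head_dim,
    hidden = hidden, beta = beta, dropout_p = dropout_p,
    logit_scale = match.arg(logit_scale),
    network_update = match.arg(network_update),
    update_denominator = match.arg(update_denominator)
  ), class = "attention_config")
}

glorot <- function(nr, nc, name) {
  a <- sqrt(6 / (nr + nc))
  px_param(matrix(stats::runif(nr * nc, -a, a), nr, nc), name)
}

# H per-head (nr x d) matrices stored column-stacked as nr x (H*d);
# initialization scaled by the per-head fan
glorot_heads <- function(nr, d, H, name, fan_out = d) {
  a <- sqrt(6 / (nr + fan_out))
  px_param(matrix(stats::runif(nr * d * H, -a, a), nr, d * H), name)
}

#' Initialize the parameters of one encoder block
#'
#' Per-head query/key/value/gate projections and per-head output maps are
#' stored column-stacked (`W[, ((h-1)*d+1):(h*d)]` is head h's matrix) so
#' all heads share one batched product.
#'
#' @param np number of pathways
#' @param dp pathway embedding dimension
#' @param cfg an [attention_config()]
#' @param block block index (used in parameter names)
#' @return list with `col` and `row` sub-layer parameters
#' @keywords internal
init_block_params <- function(np, dp, cfg, block = 1L) {
  H <- cfg$n_heads; d <- cfg$head_dim; o <- cfg$hidden
  nm <- function(s) paste0("b", block, "_", s)
  list(
    col = list(
      wq = glorot_heads(dp, d, H, nm("wq1")),
      wk = glorot_heads(dp, d, H, nm("wk1")),
      wv = glorot_heads(dp, d, H, nm("wv1")),
      wg = glorot_heads(dp, d, H, nm("wg1")),
      wu = glorot(d * H, dp, nm("wu1")),
      wo1 = glorot(dp, o, nm("wo11")), wo2 = glorot(o, dp, nm("wo12"))),
    row = list(
      wq = glorot_heads(np, d, H, nm("wq2")),
      wk = glorot_heads(np, d, H, nm("wk2")),
      wv = glorot_heads(np, d, H, nm("wv2")),
      wg = glorot_heads(np, d, H, nm("wg2")),
      wu = glorot(d * H, np, nm("wu2")),
      wo1 = glorot(np, o, nm("wo21")), wo2 = glorot(o, np, nm("wo22")))
  )
}

logit_div <- function(cfg) {
  if (cfg$logit_scale == "sqrt_d") sqrt(cfg$head_dim) else cfg$head_dim
}

# shared multi-head attention core over the row axis of `x`;
# bias (if any) is added to every head's logits
mha_core <- function(x, side, cfg, bias = NULL, training = FALSE) {
  H <- cfg$n_heads
  q <- px_split_heads(px_bmm(x, px_use(side$wq)), H)
  k <- px_split_heads(px_bmm(x, px_use(side$wk)), H)
  v <- px_split_heads(px_bmm(x, px_use(side$wv)), H)
  logits <- px_scale(px_bmm(q, k, tb = TRUE), 1 / logit_div(cfg))
  if (!is.null(bias)) logits <- px_add(logits, bias)
  if (!all(is.finite(node_val(logits)))) stop("NaN in attention logits")
  aw <- px_softmax_rows(logits)
  a <- px_bmm(px_dropout(aw, cfg$dropout_p, training), v)
  list(a = a, weights = aw, H = H)
}

# gated merge shared by both sub-layers:
# sum_h (sigmoid(x Wg^(h)) o A^(h)) WU^(h), feed-forward and residual
gated_merge <- function(x, att, side, cfg, residual, training = FALSE) {
  H <- att$H
  gate <- px_sigmoid(px_split_heads(px_bmm(x, px_use(side$wg)), H))
  u <- px_bmm(px_merge_heads(px_mul(gate, att$a), H), px_use(side$wu))
  up <- px_add(if (is.null(residual$scale)) u else
    px_scale(u, residual$scale), residual$x)
  ff <- px_bmm(px_dropout(
    px_gelu(px_bmm(px_layernorm_rows(up), px_use(side$wo1))),
    cfg$dropout_p, training), px_use(side$wo2))
  px_add(ff, up)
}

# split a fused attention-weight tensor into per-head plain arrays
split_map_value <- function(aw, H) {
  v <- node_val(aw)
  d <- dim(v); S <- d[3L] %/% H
  lapply(seq_len(H), function(h)
    v[, , h + H * (seq_len(S) - 1L), drop = FALSE])
}

#' Column-wise (pathway-axis) self-attention with crosstalk bias
#'
#' Per head: `Q = E_P W_Q`, `K = E_P W_K`, `V = E_P W_V`; logits are
#' `Q K^T / scale + P` with the crosstalk matrix P as an additive bias;
#' softmax over the second pathway axis; dropout on the attention weights in
#' training mode; output `A = weights V`.
#'
#' @param ep pathway embedding `(Np, Dp, S)` (array or node)
#' @param p_net crosstalk bias: `Np x Np` matrix, `(Np, Np, 1)` array or node
#' @param block block parameter list from [init_block_params()]
#' @param cfg an [attention_config()]
#' @param training apply dropout
#' @return list with `a` (fused per-head outputs, `(Np, d, H*S)`),
#'   `weights` (fused attention weights `(Np, Np, H*S)`) and `H`; use
#'   [attention_heads()] to extract per-head arrays
#' @export
col_attention <- function(ep, p_net, block, cfg, training = FALSE) {
  p_net <- if (is_node(p_net)) p_net else as_cube(p_net)
  mha_core(ep, block$col, cfg, bias = p_net, training = training)
}

#' Per-head outputs / attention maps of an attention result
#'
#' @param att result of [col_attention()] or [row_attention()]
#' @param what `"a"` (head outputs) or `"weights"` (attention maps)
#' @return list of plain arrays, one per head
#' @export
attention_heads <- function(att, what = c("a", "weights")) {
  split_map_value(att[[match.arg(what)]], att$H)
}

#' Gated merge of column-attention heads
#'
#' `U1 = sum_h (sigmoid(E_P W_g^(h)) o A^(h)) W_U^(h)`; residual
#' `U1' = U1 + E_P`; output
#' `O1 = dropout(GELU(LN(U1') W_O1)) W_O2 + U1'`.
#'
#' @param ep the sub-layer input `(Np, Dp, S)`
#' @param att result of [col_attention()] on `ep`
#' @inheritParams col_attention
#' @return `O1`, `(Np, Dp, S)`
#' @export
merge_col <- function(ep, att, block, cfg, training = FALSE) {
  gated_merge(ep, att, block$col, cfg,
              residual = list(x = ep, scale = NULL), training = training)
}

#' Row-wise (feature/modality-axis) self-attention
#'
#' Standard multi-head scaled dot-product attention over the transposed
#' embedding (`Dp x Np` per sample), exchanging information between the
#' embedding dimensions (modalities); no bias term.
#'
#' @param o1 column sub-layer output `(Np, Dp, S)`
#' @inheritParams col_attention
#' @return as [col_attention()], with head outputs `(Dp, d, H*S)` and
#'   weights `(Dp, Dp, H*S)`
#' @export
row_attention <- function(o1, block, cfg, training = FALSE) {
  mha_core(px_transpose(o1), block$row, cfg, training = training)
}

#' Gated merge of row-attention heads with beta-scaled residual
#'
#' `U2 = sum_h (sigmoid(O1^T W_g^(h)) o A^(h)) W_U^(h)`; residual
#' `U2' = beta * U2 + O1^T`; output
#' `O2 = dropout(GELU(LN(U2') W_O1)) W_O2 + U2'`, transposed back to
#' `Np x Dp`. `O2` is the pathway embedding input of the next block.
#'
#' @param o1 column sub-layer output `(Np, Dp, S)`
#' @param att result of [row_attention()] on `o1`
#' @inheritParams col_attention
#' @return `O2`, `(Np, Dp, S)`
#' @export
merge_row <- function(o1, att, block, cfg, training = FALSE) {
  ept <- px_transpose(o1)
  px_transpose(gated_merge(ept, att, block$row, cfg,
                           residual = list(x = ept, scale = cfg$beta),
                           training = training))
}

#' Update the pathway crosstalk network for the next block
#'
#' Default (`embedding_correlation`): the next crosstalk matrix is the
#' Gram matrix of the batch-mean updated embedding,
#' `P' = E_bar E_bar^T / denom` (denom = Dp by default), symmetrized and
#' clamped to a finite range. `printed_formula` instead computes
#' `P' = P P^T / Np` from the current network alone.
#'
#' @param p_net current crosstalk matrix (matrix, `(Np,Np,1)` array or node)
#' @param o2 updated pathway embedding `(Np, Dp, S)`
#' @param cfg an [attention_config()]
#' @return the updated network, `(Np, Np, 1)` (array or node)
#' @export
update_network <- function(p_net, o2, cfg) {
  if (cfg$network_update == "printed_formula") {
    p_net <- if (is_node(p_net)) p_net else as_cube(p_net)
    np <- dim(node_val(p_net))[1L]
    newp <- px_scale(px_bmm(p_net, p_net, tb = TRUE), 1 / np)
  } else {
    eb <- px_mean_slices(o2)
    dims <- dim(node_val(o2))
    denom <- if (cfg$update_denominator == "Dp") dims[2L] else dims[1L]
    newp <- px_scale(px_bmm(eb, eb, tb = TRUE), 1 / denom)
  }
  sym <- px_add(px_scale(newp, 0.5), px_scale(px_transpose(newp), 0.5))
  px_clamp(sym)
}

#' Run the criss-cross attention encoder
#'
#' Applies `n_blocks` of column attention, gated column merge, row
#' attention, gated row merge and network update in sequence, collecting
#' the attention maps for interpretability.
#'
#' @param ep0 initial pathway embedding `(Np, Dp, S)`
#' @param p0 initial crosstalk matrix (`Np x Np`)
#' @param blocks list of block parameter lists (length `n_blocks`)
#' @param cfg an [attention_config()]
#' @param training apply dropout
#' @param use_bias include the crosstalk bias in column attention
#' @param use_row include the row sub-layer and network updates
#' @return list with `ep` (final embedding), `p_net` (final network),
#'   `row_maps` and `col_maps` (per block: list of per-head plain arrays,
#'   `(Dp,Dp,S)` / `(Np,Np,S)`), and `networks` (per-block updated
#'   crosstalk matrices as plain `Np x Np` matrices)
#' @export
encoder <- function(ep0, p0, blocks, cfg, training = FALSE,
                    use_bias = TRUE, use_row = TRUE) {
  np <- dim(node_val(ep0))[1L]
  ep <- ep0
  p_net <- if (use_bias) as_cube(as.matrix(p0)) else
    array(0, c(np, np, 1L))
  row_maps <- list(); col_maps <- list(); networks <- list()
  for (b in seq_len(cfg$n_blocks)) {
    blk <- blocks[[b]]
    catt <- col_attention(ep, p_net, blk, cfg, training)
    o1 <- merge_col(ep, catt, blk, cfg, training)
    col_maps[[b]] <- attention_heads(catt, "weights")
    if (use_row) {
      ratt <- row_attention(o1, blk, cfg, training)
      o2 <- merge_row(o1, ratt, blk, cfg, training)
      row_maps[[b]] <- attention_heads(ratt, "weights")
    } else {
      o2 <- o1
    }
    if (use_bias && use_row) {
      p_net <- update_network(p_net, o2, cfg)
      networks[[b]] <- node_val(p_net)[, , 1L]
    }
    ep <- o2
  }
  list(ep = ep, p_net = p_net, row_maps = row_maps, col_maps = col_maps,
       networks = networks)
}

block_param_list <- function(blocks) {
  out <- list()
  for (blk in blocks)
    for (side in blk)
      for (el in side)
        if (inherits(el, "px_param")) out <- c(out, list(el))
  out
}
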