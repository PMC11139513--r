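#' @useDynLib pathomix, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Reverse-mode automatic differentiation over batched tensors.
#
# Tensors are dense arrays of dim c(R, C, S): an R x C matrix per sample slice.
# A tensor with S = 1 broadcasts across the batch (used for shared parameters
# and the per-batch crosstalk network). Operations dispatch on their inputs:
# called on plain arrays they just compute; called on nodes inside px_record()
# they also append to the tape, and px_backward() replays the tape in reverse
# creation order, which is a valid topological order for a forward-built graph.

the <- new.env(parent = emptyenv())
the$recording <- FALSE
the$tape <- NULL

as_cube <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.matrix(x)) return(array(x, c(nrow(x), ncol(x), 1L)))
  if (is.numeric(x)) return(array(x, c(1L, length(x), 1L)))
  stop("cannot coerce to a batched tensor")
}

is_node <- function(x) inherits(x, "px_node")

node_val <- function(x) if (is_node(x)) x$value else x

new_node <- function(value, parents = list(), bw = NULL, param = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$parents <- parents
  n$bw <- bw
  n$grad <- NULL
  n$param <- param
  class(n) <- "px_node"
  if (the$recording) the$tape[[length(the$tape) + 1L]] <- n
  n
}

#' Record a computation for reverse-mode differentiation
#'
#' Evaluates `expr` with the tape active; every tensor operation on
#' [px_node] inputs is recorded so that [px_backward()] can accumulate
#' gradients. Returns the value of `expr` (typically a scalar loss node).
#'
#' @param expr expression building the computation graph
#' @return the result of `expr`; the tape is kept internally until the next
#'   call to [px_record()]
#' @keywords internal
px_record <- function(expr) {
  the$recording <- TRUE
  the$tape <- list()
  on.exit({ the$recording <- FALSE }, add = TRUE)
  expr
}

#' Backpropagate from a scalar loss node
#'
#' Accumulates gradients along the recorded tape and writes parameter
#' gradients into their [px_param()] environments (`$grad`).
#'
#' @param loss a scalar `px_node` produced inside [px_record()]
#' @keywords internal
px_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  tape <- the$tape
  loss$grad <- array(1, c(1L, 1L, 1L))
  for (i in rev(seq_along(tape))) {
    n <- tape[[i]]
    if (is.null(n$grad)) next
    if (!is.null(n$param)) {
      g <- n$grad[, , 1L, drop = TRUE]
      dim(g) <- dim(n$param$value)
      n$param$grad <- if (is.null(n$param$grad)) g else n$param$grad + g
    }
    if (is.null(n$bw)) next
    pg <- n$bw(n$grad)
    for (j in seq_along(n$parents)) {
      p <- n$parents[[j]]
      if (is_node(p) && !is.null(pg[[j]]))
        p$grad <- if (is.null(p$grad)) pg[[j]] else p$grad + pg[[j]]
    }
  }
  invisible(NULL)
}

#' Create a trainable parameter
#'
#' A parameter is an environment holding its value, accumulated gradient and
#' Adam moments. Use [px_use()] inside a recorded forward pass to obtain a
#' differentiable node; an optional binary `mask` is re-applied after every
#' optimizer step so masked entries stay exactly zero.
#'
#' @param value numeric matrix of initial values
#' @param name identifier used in checkpoints
#' @param mask optional binary matrix; entries where `mask == 0` are frozen at 0
#' @return an environment of class `px_param`
#' @keywords internal
px_param <- function(value, name = "", mask = NULL) {
  p <- new.env(parent = emptyenv())
  if (!is.null(mask)) value <- value * mask
  p$value <- as.matrix(value)
  p$grad <- NULL
  p$m <- NULL
  p$v <- NULL
  p$name <- name
  p$mask <- mask
  class(p) <- "px_param"
  p
}

# Wrap a parameter (or plain matrix, when running un-taped) as a tensor.
px_use <- function(p) {
  if (!inherits(p, "px_param")) return(as_cube(p))
  if (!the$recording) return(as_cube(p$value))
  new_node(as_cube(p$value), param = p)
}

# ---- layout helpers ------------------------------------------------------

# (R*S) x C matrix view with rows ordered (r, s); inverse restores the cube.
rows_mat <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(1L, 3L, 2L)), nrow = d[1L] * d[3L], ncol = d[2L])
}
rows_cube <- function(m, d) {
  aperm(array(m, c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
}

bcast_to <- function(x, d) {
  dx <- dim(x)
  if (all(dx == d)) return(x)
  x <- x[rep_len(seq_len(dx[1L]), d[1L]), , , drop = FALSE]
  x <- x[, rep_len(seq_len(dx[2L]), d[2L]), , drop = FALSE]
  x[, , rep_len(seq_len(dx[3L]), d[3L]), drop = FALSE]
}

reduce_to <- function(g, d) {
  dg <- dim(g)
  if (all(dg == d)) return(g)
  for (ax in 1:3) {
    if (d[ax] == 1L && dim(g)[ax] > 1L) {
      keep <- setdiff(1:3, ax)
      s <- apply(g, keep, sum)
      dim(s) <- dim(g)[keep]
      g <- array(aperm(array(s, c(dim(g)[keep], 1L)),
                       order(c(keep, ax))), replace(dim(g), ax, 1L))
    }
  }
  g
}

# ---- core ops ------------------------------------------------------------

binary_op <- function(a, b, fwd, bwd_a, bwd_b) {
  va <- as_cube(node_val(a)); vb <- as_cube(node_val(b))
  out <- fwd(va, vb)
  if (!the$recording || (!is_node(a) && !is_node(b))) return(out)
  new_node(out, parents = list(a, b), bw = function(g) {
    list(if (is_node(a)) bwd_a(g, va, vb) else NULL,
         if (is_node(b)) bwd_b(g, va, vb) else NULL)
  })
}

unary_op <- function(a, fwd, bwd) {
  va <- as_cube(node_val(a))
  out <- fwd(va)
  if (!the$recording || !is_node(a)) return(out)
  new_node(out, parents = list(a), bw = function(g) list(bwd(g, va, out)))
}

# batched matrix product; either operand may broadcast (single slice)
px_bmm <- function(a, b, ta = FALSE, tb = FALSE) {
  grad_a <- function(g, va, vb) {
    ga <- if (!ta && !tb) list(g, vb, FALSE, TRUE)
      else if (ta && !tb)  list(vb, g, FALSE, TRUE)
      else if (!ta && tb)  list(g, vb, FALSE, FALSE)
      else                 list(vb, g, TRUE, TRUE)
    if (dim(va)[3L] == 1L && max(dim(g)[3L], dim(vb)[3L]) > 1L) {
      m <- cube_bmm_sum(ga[[1L]], ga[[2L]], ga[[3L]], ga[[4L]])
      array(m, c(dim(m), 1L))
    } else cube_bmm(ga[[1L]], ga[[2L]], ga[[3L]], ga[[4L]])
  }
  grad_b <- function(g, va, vb) {
    gb <- if (!ta && !tb) list(va, g, TRUE, FALSE)
      else if (ta && !tb)  list(va, g, FALSE, FALSE)
      else if (!ta && tb)  list(g, va, TRUE, FALSE)
      else                 list(g, va, TRUE, TRUE)
    if (dim(vb)[3L] == 1L && max(dim(g)[3L], dim(va)[3L]) > 1L) {
      m <- cube_bmm_sum(gb[[1L]], gb[[2L]], gb[[3L]], gb[[4L]])
      array(m, c(dim(m), 1L))
    } else cube_bmm(gb[[1L]], gb[[2L]], gb[[3L]], gb[[4L]])
  }
  binary_op(a, b, function(va, vb) cube_bmm(va, vb, ta, tb), grad_a, grad_b)
}

px_add <- function(a, b) {
  binary_op(a, b,
    function(va, vb) {
      d <- pmax(dim(va), dim(vb)); bcast_to(va, d) + bcast_to(vb, d)
    },
    function(g, va, vb) reduce_to(g, dim(va)),
    function(g, va, vb) reduce_to(g, dim(vb)))
}

px_mul <- function(a, b) {
  binary_op(a, b,
    function(va, vb) {
      d <- pmax(dim(va), dim(vb)); bcast_to(va, d) * bcast_to(vb, d)
    },
    function(g, va, vb) reduce_to(g * bcast_to(vb, dim(g)), dim(va)),
    function(g, va, vb) reduce_to(g * bcast_to(va, dim(g)), dim(vb)))
}

px_scale <- function(a, k) {
  unary_op(a, function(v) v * k, function(g, v, o) g * k)
}

px_sigmoid <- function(a) {
  unary_op(a, function(v) 1 / (1 + exp(-v)), function(g, v, o) g * o * (1 - o))
}

px_relu <- function(a) {
  unary_op(a, function(v) pmax(v, 0), function(g, v, o) g * (v > 0))
}

# exact GELU: x * Phi(x)
px_gelu <- function(a) {
  unary_op(a, function(v) v * stats::pnorm(v),
           function(g, v, o) g * (stats::pnorm(v) + v * stats::dnorm(v)))
}

px_transpose <- function(a) {
  unary_op(a, function(v) aperm(v, c(2L, 1L, 3L)),
           function(g, v, o) aperm(g, c(2L, 1L, 3L)))
}

# softmax over the column axis of each row, per slice
px_softmax_rows <- function(a) {
  unary_op(a, cube_softmax_rows,
           function(g, v, o) cube_softmax_rows_grad(g, o))
}

# layer normalization over the column axis (no affine terms)
px_layernorm_rows <- function(a, eps = 1e-5) {
  unary_op(a, function(v) cube_layernorm_rows(v, eps),
           function(g, v, o) cube_layernorm_rows_grad(g, v, eps))
}

# mean across batch slices -> single-slice tensor
px_mean_slices <- function(a) {
  unary_op(a,
    function(v) {
      d <- dim(v)
      array(rowMeans(matrix(v, ncol = d[3L])), c(d[1L], d[2L], 1L))
    },
    function(g, v, o) {
      d <- dim(v)
      bcast_to(g, d) / d[3L]
    })
}

# per-slice row means: (R, C, S) -> (1, R, S)
px_pool_rows <- function(a) {
  unary_op(a,
    function(v) {
      d <- dim(v)
      array(apply(v, 3L, rowMeans), c(1L, d[1L], d[3L]))
    },
    function(g, v, o) {
      d <- dim(v)
      gr <- aperm(g, c(2L, 1L, 3L))            # (R, 1, S)
      gr[, rep(1L, d[2L]), , drop = FALSE] / d[2L]
    })
}

# head fusion: (R, H*d, S) with columns grouped by head -> (R, d, H*S),
# slice index h + H*(s-1); lets all heads share one batched matmul
split_heads <- function(v, H) {
  d <- dim(v)
  array(v, c(d[1L], d[2L] %/% H, H * d[3L]))
}
merge_heads_val <- function(v, H) {
  d <- dim(v)
  array(v, c(d[1L], d[2L] * H, d[3L] %/% H))
}

px_split_heads <- function(a, H) {
  unary_op(a, function(v) split_heads(v, H),
           function(g, v, o) merge_heads_val(g, H))
}

px_merge_heads <- function(a, H) {
  unary_op(a, function(v) merge_heads_val(v, H),
           function(g, v, o) split_heads(g, H))
}

# per-slice row maxima: (R, C, S) -> (1, R, S); subgradient at the argmax
px_pool_rows_max <- function(a) {
  unary_op(a,
    function(v) {
      d <- dim(v)
      array(apply(v, 3L, function(m) apply(m, 1L, max)), c(1L, d[1L], d[3L]))
    },
    function(g, v, o) {
      d <- dim(v)
      out <- array(0, d)
      for (s in seq_len(d[3L])) {
        m <- v[, , s, drop = FALSE]; dim(m) <- d[1:2]
        j <- max.col(m, ties.method = "first")
        out[cbind(seq_len(d[1L]), j, s)] <- g[1L, , s]
      }
      out
    })
}

# (R, C, S) -> (1, R*C, S), column-major within slice
px_flatten <- function(a) {
  unary_op(a,
    function(v) { d <- dim(v); array(v, c(1L, d[1L] * d[2L], d[3L])) },
    function(g, v, o) array(g, dim(v)))
}

px_dropout <- function(a, p, training = FALSE) {
  if (!training || p <= 0) return(a)
  va <- as_cube(node_val(a))
  keep <- array(stats::rbinom(length(va), 1L, 1 - p), dim(va)) / (1 - p)
  px_mul(a, keep)
}

px_clamp <- function(a, lo = -1e6, hi = 1e6) {
  unary_op(a, function(v) pmin(pmax(v, lo), hi),
           function(g, v, o) g * (v >= lo & v <= hi))
}

# class-weighted softmax cross-entropy over logits of dim (1, K, S)
px_ce_loss <- function(logits, y, class_weights = NULL) {
  vl <- as_cube(node_val(logits))
  K <- dim(vl)[2L]; S <- dim(vl)[3L]
  stopifnot(length(y) == S)
  if (is.null(class_weights)) class_weights <- rep(1, K)
  w <- class_weights[y]
  fwd <- function(v) {
    m <- matrix(v, nrow = K)                  # K x S
    m <- sweep(m, 2L, apply(m, 2L, max))
    lse <- log(colSums(exp(m)))
    logp <- sweep(m, 2L, lse)
    array(sum(w * -logp[cbind(y, seq_len(S))]) / sum(w), c(1L, 1L, 1L))
  }
  out <- fwd(vl)
  if (!the$recording || !is_node(logits)) return(out)
  new_node(out, parents = list(logits), bw = function(g) {
    m <- matrix(vl, nrow = K)
    m <- sweep(m, 2L, apply(m, 2L, max))
    p <- sweep(exp(m), 2L, colSums(exp(m)), "/")
    p[cbind(y, seq_len(S))] <- p[cbind(y, seq_len(S))] - 1
    list(array(sweep(p, 2L, w, "*") / sum(w) * as.numeric(g),
               c(1L, K, S)))
  })
}

# ---- optimizer -----------------------------------------------------------

#' One Adam step over a list of parameters
#'
#' Applies the Adam update with bias correction, zeroes gradients, and
#' re-applies each parameter's mask (if any) so frozen entries remain
#' exactly zero.
#'
#' @param params list of [px_param()] environments
#' @param lr learning rate
#' @param t step counter (1-based)
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer
#' @keywords internal
adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    if (is.null(p$m)) { p$m <- g * 0; p$v <- g * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g^2
    mh <- p$m / (1 - beta1^t)
    vh <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mh / (sqrt(vh) + eps)
    if (!is.null(p$mask)) p$value <- p$value * p$mask
    p$grad <- NULL
  }
  invisible(NULL)
}
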