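# Independent oracles shared by unit and acceptance tests: loop-based
# straight-line evaluations of the attention equations, and a brute-force
# Shapley oracle enumerating permutations with memoized coalition values.

# Independent straight-line oracle for one encoder block on a single
# sample, written with explicit per-head / per-row loops so it shares no
# code with the package's batched implementation.

oracle_softmax_rows <- function(m) {
  out <- m
  for (i in seq_len(nrow(m))) {
    e <- exp(m[i, ] - max(m[i, ]))
    out[i, ] <- e / sum(e)
  }
  out
}

oracle_ln_rows <- function(m, eps = 1e-5) {
  out <- m
  for (i in seq_len(nrow(m))) {
    mu <- mean(m[i, ])
    v <- mean((m[i, ] - mu)^2)
    out[i, ] <- (m[i, ] - mu) / sqrt(v + eps)
  }
  out
}

oracle_gelu <- function(m) m * pnorm(m)

head_slice <- function(p, h, d) p$value[, ((h - 1) * d + 1):(h * d)]

# col sub-layer (attention + gated merge) for one sample
oracle_col <- function(ep, P, side, H, d, scale) {
  heads <- list()
  for (h in seq_len(H)) {
    Q <- ep %*% head_slice(side$wq, h, d)
    K <- ep %*% head_slice(side$wk, h, d)
    V <- ep %*% head_slice(side$wv, h, d)
    A1 <- (Q %*% t(K)) / scale
    heads[[h]] <- oracle_softmax_rows(A1 + P) %*% V
  }
  U1 <- 0
  for (h in seq_len(H)) {
    g <- 1 / (1 + exp(-(ep %*% head_slice(side$wg, h, d))))
    wu_h <- side$wu$value[((h - 1) * d + 1):(h * d), , drop = FALSE]
    U1 <- U1 + (g * heads[[h]]) %*% wu_h
  }
  U1p <- U1 + ep
  oracle_gelu(oracle_ln_rows(U1p) %*% side$wo1$value) %*% side$wo2$value + U1p
}

# row sub-layer on the transposed embedding, with the beta-scaled residual
oracle_row <- function(o1, side, H, d, scale, beta) {
  ept <- t(o1)
  heads <- list()
  for (h in seq_len(H)) {
    Q <- ept %*% head_slice(side$wq, h, d)
    K <- ept %*% head_slice(side$wk, h, d)
    V <- ept %*% head_slice(side$wv, h, d)
    heads[[h]] <- oracle_softmax_rows((Q %*% t(K)) / scale) %*% V
  }
  U2 <- 0
  for (h in seq_len(H)) {
    g <- 1 / (1 + exp(-(ept %*% head_slice(side$wg, h, d))))
    wu_h <- side$wu$value[((h - 1) * d + 1):(h * d), , drop = FALSE]
    U2 <- U2 + (g * heads[[h]]) %*% wu_h
  }
  U2p <- beta * U2 + ept
  t(oracle_gelu(oracle_ln_rows(U2p) %*% side$wo1$value) %*%
      side$wo2$value + U2p)
}


# brute-force Shapley oracle: enumerate all n! permutations, using a
# memoized coalition value table (independent of the package's
# subset-weight formula)
brute_shapley <- function(f, x, X_bg, p) {
  vals <- new.env()
  vof <- function(keep) {
    key <- paste0("k", paste(keep, collapse = ","))
    if (is.null(vals[[key]])) {
      rows <- X_bg
      if (length(keep) > 0)
        rows[, keep] <- matrix(x[keep], nrow(X_bg), length(keep),
                               byrow = TRUE)
      vals[[key]] <- mean(f(rows))
    }
    vals[[key]]
  }
  perms <- combinat_perms(seq_len(p))
  phi <- numeric(p)
  for (ord in perms) {
    prev <- integer(0)
    for (i in ord) {
      phi[i] <- phi[i] + vof(sort(c(prev, i))) - vof(prev)
      prev <- c(prev, i)
    }
  }
  phi / length(perms)
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}


random_stochastic_maps <- function(dp, S, n_maps, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_maps), function(i) {
    a <- array(rexp(dp * dp * S), c(dp, dp, S))
    for (s in seq_len(S)) a[, , s] <- a[, , s] / rowSums(a[, , s])
    a
  })
}

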