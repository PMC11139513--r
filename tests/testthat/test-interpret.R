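test_that("modality contributions are conserved and layout-driven", {
  layout <- tibble::tibble(dim = 1:6,
                           modality = rep(c("expr", "meth", "cnv"),
                                          c(1, 4, 1)))
  maps <- list(random_stochastic_maps(6, 3, 2, seed = 50))
  mc <- modality_contributions(maps, layout)
  expect_equal(sum(mc$weight), 1, tolerance = 1e-6)
  expect_true(all(mc$weight >= 0))
  # identity maps give weights proportional to dimension counts
  id_maps <- list(list(array(diag(6), c(6, 6, 1))))
  mc_id <- modality_contributions(id_maps, layout)
  expect_equal(mc_id$weight[mc_id$modality == "meth"], 4 / 6)
  expect_equal(mc_id$weight[mc_id$modality == "expr"], 1 / 6)
  # a single modality owning every dimension gets weight 1
  lay1 <- tibble::tibble(dim = 1:6, modality = "only")
  expect_equal(modality_contributions(maps, lay1)$weight, 1,
               tolerance = 1e-6)
  # invariant to sample order
  perm_maps <- list(lapply(maps[[1]], function(m) m[, , c(2, 3, 1)]))
  expect_equal(modality_contributions(perm_maps, layout), mc)
  expect_error(modality_contributions(maps, layout[1:3, ]), "cover")
})

test_that("pathway scores are the embedding means and scale linearly", {
  ep <- rand_cube(5, 3, 4, seed = 51)
  ps <- pathway_scores(ep, paste0("p", 1:5))
  expect_equal(dim(ps), c(4L, 5L))
  expect_equal(unname(ps[2, ]), rowMeans(ep[, , 2]))
  expect_equal(pathway_scores(ep * 3), ps * 3, ignore_attr = TRUE)
  # Dp = 1 is the identity; a constant embedding scores the constant
  ep1 <- rand_cube(4, 1, 2, seed = 52)
  expect_equal(unname(pathway_scores(ep1)[1, ]), ep1[, 1, 1])
  expect_equal(unname(pathway_scores(array(2, c(3, 4, 1)))[1, ]), rep(2, 3))
})

test_that("exact Shapley matches permutation enumeration on a surrogate", {
  set.seed(53)
  p <- 5L                                  # 5! = 120 permutations
  beta <- rnorm(p)
  f <- function(rows) as.numeric(tanh(rows %*% beta))
  X_bg <- matrix(rnorm(6 * p), 6, p)
  X_ev <- matrix(rnorm(2 * p), 2, p)
  phi <- px$shap_engine(f, X_ev, X_bg, as.list(seq_len(p)),
                        method = "exact")
  for (s in 1:2)
    expect_equal(phi[s, ], brute_shapley(f, X_ev[s, ], X_bg, p),
                 tolerance = 1e-10)
  # additivity: contributions + base value = model output
  base <- mean(f(X_bg))
  expect_equal(rowSums(phi) + base, f(X_ev), tolerance = 1e-10)
})

test_that("features without effect get zero SHAP and groups are respected", {
  set.seed(54)
  f <- function(rows) as.numeric(rows[, 1] * 2 - rows[, 2])
  X_bg <- matrix(rnorm(15), 5, 3)
  X_ev <- matrix(rnorm(9), 3, 3)
  phi <- px$shap_engine(f, X_ev, X_bg, as.list(1:3), method = "exact")
  expect_equal(phi[, 3], rep(0, 3))        # column 3 unused by f
  # grouped features move together: one group with both active columns
  phi_g <- px$shap_engine(f, X_ev, X_bg, list(c(1L, 2L), 3L),
                          method = "exact")
  base <- mean(f(X_bg))
  expect_equal(phi_g[, 1] + base, f(X_ev), tolerance = 1e-10)
  expect_equal(phi_g[, 2], rep(0, 3))
})

test_that("sampling SHAP approximates the exact values", {
  set.seed(55)
  p <- 6L
  beta <- rnorm(p)
  f <- function(rows) as.numeric(rows %*% beta)
  X_bg <- matrix(rnorm(8 * p), 8, p)
  X_ev <- matrix(rnorm(3 * p), 3, p)
  exact <- px$shap_engine(f, X_ev, X_bg, as.list(seq_len(p)),
                          method = "exact")
  appr <- px$shap_engine(f, X_ev, X_bg, as.list(seq_len(p)),
                         method = "sampling", n_perm = 200, seed = 2)
  expect_lt(max(abs(exact - appr)), 0.15)
  # for a linear model, exact interventional SHAP is beta * (x - mean(bg))
  ref <- sweep(X_ev, 2, colMeans(X_bg)) %*% diag(beta)
  expect_equal(exact, ref, tolerance = 1e-10)
})

test_that("the exact setting refuses absurd entity counts", {
  f <- function(rows) rows[, 1]
  expect_error(
    px$shap_engine(f, matrix(0, 1, 2001), matrix(0, 1, 2001),
                   as.list(1:2001), method = "exact"),
    "sampling")
})

test_that("core modality picks the best SHAP rank with a stable tie-break", {
  tb <- tibble::tibble(
    entity = c("g1:expr", "g1:meth", "g2:expr", "g2:meth"),
    kind = "gene_modality",
    shap = c(0.9, 0.1, 0.5, 0.5),
    direction = 0,
    rank = c(1L, 4L, 2L, 3L))
  cm <- core_modality(tb, modality_order = c("expr", "meth"))
  expect_equal(cm$core_modality[cm$gene == "g1"], "expr")
  expect_equal(cm$core_modality[cm$gene == "g2"], "expr")  # rank 2 < 3
  # exact rank tie resolved by the configured order
  tb$rank <- c(1L, 2L, 3L, 3L)
  cm2 <- core_modality(tb, modality_order = c("meth", "expr"))
  expect_equal(cm2$core_modality[cm2$gene == "g2"], "meth")
  # single-modality gene maps to that modality
  tb3 <- tibble::tibble(entity = "g9:cnv", kind = "gene_modality",
                        shap = 1, direction = 0, rank = 1L)
  expect_equal(core_modality(tb3)$core_modality, "cnv")
})

# exhaustive sub-network oracle: enumerate every connected vertex subset
# of size <= k and score it with the same degree-weighted SHAP sum
exhaustive_best <- function(adj, shap, k) {
  n <- nrow(adj)
  ids <- rownames(adj)
  best <- list(score = -Inf, members = character(0))
  subsets <- unlist(lapply(1:k, function(m) utils::combn(n, m,
                                                         simplify = FALSE)),
                    recursive = FALSE)
  for (ss in subsets) {
    sub <- adj[ss, ss, drop = FALSE] > 0
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    if (igraph::components(g)$no != 1) next
    d <- rowSums(sub) - 0                  # degree within subset
    nd <- if (length(ss) > 1) d / (length(ss) - 1) else 0
    sc <- sum(shap[ids[ss]] * (1 + nd))
    if (sc > best$score) best <- list(score = sc, members = ids[ss])
  }
  best
}

test_that("sub-network scoring finds the planted hub structures", {
  # star network whose hub carries all the SHAP mass
  ids <- paste0("p", 1:6)
  star <- matrix(0, 6, 6, dimnames = list(ids, ids))
  star[1, 2:6] <- star[2:6, 1] <- 0.9
  shap_tb <- tibble::tibble(entity = ids,
                            shap = c(1, rep(0.01, 5)))
  res <- subnetwork_scores(list(star), shap_tb, prune_quantile = 0.5,
                           n_seeds = 3)
  expect_true("p1" %in% res$members[[1]])
  # pruning everything yields an empty result with a warning
  expect_warning(
    empty <- subnetwork_scores(list(star), shap_tb, prune_quantile = 1),
    "pruned")
  expect_equal(nrow(empty), 0L)
})

test_that("the greedy grower matches exhaustive enumeration on two cliques", {
  ids <- paste0("p", 1:6)
  adj <- matrix(0, 6, 6, dimnames = list(ids, ids))
  adj[1:3, 1:3] <- 0.8; adj[4:6, 4:6] <- 0.6
  diag(adj) <- 0
  # SHAP mass split 80/20 between the cliques
  shap <- c(rep(0.8 / 3, 3), rep(0.2 / 3, 3))
  names(shap) <- ids
  shap_tb <- tibble::tibble(entity = ids, shap = shap)
  res <- subnetwork_scores(list(adj), shap_tb, prune_quantile = 0,
                           n_seeds = 6, merge_jaccard = 0.5)
  oracle <- exhaustive_best(adj, shap, 6)
  expect_setequal(res$members[[1]], oracle$members)
  expect_equal(res$score[1], oracle$score, tolerance = 1e-12)
  expect_setequal(res$members[[1]], ids[1:3])   # the 80% clique wins
})

test_that("averaged networks drive the pruning threshold", {
  ids <- paste0("p", 1:4)
  n1 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  n2 <- n1
  n1[1, 2] <- n1[2, 1] <- 1.0
  n2[3, 4] <- n2[4, 3] <- 0.2
  shap_tb <- tibble::tibble(entity = ids, shap = rep(1, 4))
  res <- subnetwork_scores(list(n1, n2), shap_tb, prune_quantile = 0.8,
                           n_seeds = 4)
  # only the strong averaged edge (1-2, weight .5) survives the pruning
  expect_true(all(vapply(res$members, function(m)
    all(m %in% c("p1", "p2")), TRUE)))
})
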