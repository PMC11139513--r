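#' Simulation configuration
#'
#' Describes a synthetic multi-omics study: gene-level log-normal
#' expression, fragment-level Beta-distributed methylation fractions mapped
#' many-to-one onto genes, gene-level categorical copy-number states, and
#' binary labels driven by a planted effect in a chosen set of pathways.
#'
#' @param n_samples number of samples
#' @param n_genes size of the gene pool (pathways draw from it; genes
#'   outside every pathway exercise the drop path)
#' @param n_pathways number of pathways to generate
#' @param genes_per_pathway inclusive size range of each pathway
#' @param pathway_overlap fraction of each pathway's genes drawn from genes
#'   already used by earlier pathways (0 = disjoint sets)
#' @param n_planted number of pathways carrying the class effect
#' @param effect_size standardized mean shift of planted-gene features in
#'   the positive class (log-expression SD units)
#' @param sites_per_gene range of methylation sites per gene
#' @param label_noise probability of flipping each label
#' @param seed RNG seed (mandatory; the generator is fully deterministic)
#' @return a `sim_config`
#' @export
sim_config <- function(n_samples = 300, n_genes = 200, n_pathways = 20,
                       genes_per_pathway = c(15, 25), pathway_overlap = 0.3,
                       n_planted = 3, effect_size = 2,
                       sites_per_gene = c(3, 10), label_noise = 0,
                       seed = 1) {
  stopifnot(effect_size >= 0, label_noise >= 0, label_noise <= 1,
            !missing(seed) || is.numeric(seed))
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_pathways = n_pathways,
                 genes_per_pathway = genes_per_pathway,
                 pathway_overlap = pathway_overlap, n_planted = n_planted,
                 effect_size = effect_size, sites_per_gene = sites_per_gene,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate random pathway gene sets
#'
#' Draws `n_pathways` gene sets of sizes in `genes_per_pathway` from a pool
#' of `n_genes` genes, reusing already-used genes at rate `pathway_overlap`.
#' Deterministic given the seed.
#'
#' @param cfg a [sim_config()]
#' @return a `pathway_collection`
#' @export
generate_pathways <- function(cfg) {
  set.seed(cfg$seed)
  if (cfg$n_genes < max(cfg$genes_per_pathway))
    stop("n_genes smaller than the maximum pathway size")
  genes <- sprintf("gene%03d", seq_len(cfg$n_genes))
  sizes <- sample(cfg$genes_per_pathway[1L]:cfg$genes_per_pathway[2L],
                  cfg$n_pathways, replace = TRUE)
  if (cfg$pathway_overlap == 0 && sum(sizes) > cfg$n_genes)
    stop("disjoint pathways infeasible: total size exceeds the gene pool")
  used <- character(0)
  sets <- vector("list", cfg$n_pathways)
  for (j in seq_len(cfg$n_pathways)) {
    n_old <- min(round(cfg$pathway_overlap * sizes[j]), length(used))
    old <- if (n_old > 0) sample(used, n_old) else character(0)
    fresh_pool <- setdiff(genes, used)
    n_new <- sizes[j] - n_old
    fresh <- if (length(fresh_pool) >= n_new) sample(fresh_pool, n_new)
      else c(fresh_pool, sample(setdiff(used, old),
                                n_new - length(fresh_pool)))
    sets[[j]] <- sort(c(old, fresh))
    used <- union(used, sets[[j]])
  }
  new_pathway_collection(tibble::tibble(
    id = sprintf("pw%02d", seq_len(cfg$n_pathways)),
    name = sprintf("pw%02d", seq_len(cfg$n_pathways)),
    source = "synthetic",
    genes = sets))
}

#' Generate a synthetic multi-modal dataset with planted pathway signal
#'
#' A latent class `c ~ Bernoulli(0.5)` shifts the features of genes in the
#' planted pathways: log-expression means by `effect_size` SD units,
#' methylation-site Beta means by `0.1 * effect_size`, and copy-number state
#' distributions toward gains. Labels equal the latent class flipped with
#' probability `label_noise` (the steep limit of a logistic link on the
#' planted pathway activity). The returned truth object contains the
#' planted pathway ids, per-gene effects, and the linear rule + threshold
#' that reconstructs the noise-free labels from the expression features.
#'
#' @param cfg a [sim_config()]
#' @return a `pathomix_sim`: list with `modalities` (named list of
#'   [modality_input()]), `labels` (tibble `sample`, `label`), `collection`
#'   (the pathway collection), `truth`, and `config`
#' @export
generate_dataset <- function(cfg) {
  coll <- generate_pathways(cfg)
  set.seed(cfg$seed + 1L)
  S <- cfg$n_samples
  genes <- sprintf("gene%03d", seq_len(cfg$n_genes))
  samples <- sprintf("s%03d", seq_len(S))
  planted_idx <- sort(sample(cfg$n_pathways, cfg$n_planted))
  planted <- coll$pathways$id[planted_idx]
  planted_genes <- sort(unique(unlist(coll$pathways$genes[planted_idx])))

  cl <- stats::rbinom(S, 1L, 0.5)

  # gene-level expression: log-normal, planted genes shifted on log scale
  mu <- stats::rnorm(cfg$n_genes, 2, 0.5)
  logx <- matrix(stats::rnorm(cfg$n_genes * S), cfg$n_genes, S) + mu
  shift <- outer(genes %in% planted_genes, cl == 1L) * cfg$effect_size
  expr <- exp(logx + shift)
  dimnames(expr) <- list(genes, samples)

  # fragment-level methylation: Beta sites, 3-10 per gene
  n_sites <- sample(cfg$sites_per_gene[1L]:cfg$sites_per_gene[2L],
                    cfg$n_genes, replace = TRUE)
  site_gene <- rep(genes, n_sites)
  site_id <- sprintf("cpg%05d", seq_along(site_gene))
  site_pos <- unlist(lapply(n_sites, seq_len))
  mu_m <- stats::runif(cfg$n_genes, 0.2, 0.8)[match(site_gene, genes)]
  phi <- 30
  meth <- matrix(0, length(site_id), S, dimnames = list(site_id, samples))
  planted_site <- site_gene %in% planted_genes
  for (s in seq_len(S)) {
    m <- mu_m
    if (cl[s] == 1L)
      m[planted_site] <- pmin(pmax(m[planted_site] +
                                     0.1 * cfg$effect_size, 0.05), 0.95)
    meth[, s] <- stats::rbeta(length(m), m * phi, (1 - m) * phi)
  }

  # gene-level copy-number states 0..4, planted genes biased toward gains
  base_p <- c(0.05, 0.10, 0.60, 0.15, 0.10)
  gain <- min(0.15 * cfg$effect_size, 0.55)
  gain_p <- base_p + c(-0.02, -0.05, -gain, gain * 0.6, gain * 0.4 + 0.07)
  gain_p <- pmax(gain_p, 0.01); gain_p <- gain_p / sum(gain_p)
  cnv <- matrix(0L, cfg$n_genes, S, dimnames = list(genes, samples))
  for (s in seq_len(S)) {
    p_use <- if (cl[s] == 1L) gain_p else base_p
    cnv[, s] <- sample(0:4, cfg$n_genes, replace = TRUE, prob = base_p)
    if (cl[s] == 1L) {
      sel <- genes %in% planted_genes
      cnv[sel, s] <- sample(0:4, sum(sel), replace = TRUE, prob = p_use)
    }
  }

  flip <- stats::rbinom(S, 1L, cfg$label_noise)
  y <- ifelse(flip == 1L, 1L - cl, cl)

  truth <- list(
    planted_pathways = planted,
    gene_effects = stats::setNames(
      ifelse(genes %in% planted_genes, cfg$effect_size, 0), genes),
    rule = list(genes = planted_genes,
                mu = stats::setNames(mu, genes)[planted_genes],
                threshold = cfg$effect_size / 2),
    class = cl)

  modalities <- list(
    expression = modality_input("expression", expr, "gene"),
    methylation = modality_input(
      "methylation", meth, "fragment",
      tibble::tibble(feature = site_id, gene = site_gene,
                     position = site_pos)),
    cnv = modality_input("cnv", cnv, "gene"))

  structure(list(modalities = modalities,
                 labels = tibble::tibble(sample = samples, label = y),
                 collection = coll, truth = truth, config = cfg),
            class = "pathomix_sim")
}

#' Reconstruct noise-free labels from simulated features
#'
#' Applies the stored linear rule: the mean over planted genes of the
#' gene-centered log expression, thresholded at half the effect size.
#' At `label_noise = 0` this reproduces the generated labels.
#'
#' @param sim a `pathomix_sim`
#' @return integer vector of reconstructed labels
#' @export
oracle_labels <- function(sim) {
  rule <- sim$truth$rule
  expr <- sim$modalities$expression$values
  a <- colMeans(log(expr[rule$genes, , drop = FALSE]) - rule$mu)
  as.integer(a > rule$threshold)
}

#' @export
print.pathomix_sim <- function(x, ...) {
  cat(sprintf(
    "<pathomix_sim> %d samples, %d genes, %d pathways (%d planted), effect %.1f\n",
    x$config$n_samples, x$config$n_genes, x$config$n_pathways,
    x$config$n_planted, x$config$effect_size))
  invisible(x)
}
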