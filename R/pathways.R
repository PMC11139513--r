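#' Read pathway gene sets from a GMT file
#'
#' Parses the standard GMT dialect (one pathway per line:
#' `name<TAB>description<TAB>gene1<TAB>gene2...`) into a pathway collection.
#' The description field is kept as the pathway source label (KEGG, Reactome,
#' PID, BioCarta, ...). Duplicate gene tokens within a line are dropped with
#' a warning; duplicate pathway ids are an error.
#'
#' @param path path to a GMT file
#' @return a `pathway_collection`: list with `pathways` (tibble with columns
#'   `id`, `name`, `source` and list-column `genes`) and `gene_universe`
#'   (sorted character vector of all genes in any pathway)
#' @export
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines(c("p1\tKEGG\tA\tB\tC", "p2\tKEGG\tB\tC\tD"), gmt)
#' coll <- read_gmt(gmt)
#' coll$gene_universe
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no pathways: GMT file is empty")
  recs <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(recs, length, 1L) < 3L)
  if (length(bad) > 0L)
    stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
                 bad[1L]))
  ids <- vapply(recs, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate pathway id: %s", ids[duplicated(ids)][1L]))
  genes <- lapply(recs, function(r) {
    g <- r[-(1:2)]
    g <- g[nzchar(g)]
    if (anyDuplicated(g)) {
      warning(sprintf("duplicate gene tokens in pathway '%s' deduplicated",
                      r[[1L]]), call. = FALSE)
      g <- unique(g)
    }
    g
  })
  new_pathway_collection(tibble::tibble(
    id = ids, name = ids,
    source = vapply(recs, `[[`, "", 2L),
    genes = genes
  ))
}

new_pathway_collection <- function(pathways) {
  stopifnot(all(c("id", "name", "source", "genes") %in% names(pathways)))
  if (any(lengths(pathways$genes) == 0L))
    stop("pathway with empty gene set")
  structure(
    list(pathways = pathways,
         gene_universe = sort(unique(unlist(pathways$genes)))),
    class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathways, %d genes\n",
              nrow(x$pathways), length(x$gene_universe)))
  print(utils::head(x$pathways, 5L))
  invisible(x)
}

#' Write a pathway collection to GMT
#'
#' @param coll a `pathway_collection`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gmt <- function(coll, path) {
  lines <- purrr::pmap_chr(coll$pathways, function(id, name, source, genes)
    paste(c(id, source, genes), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Fraction of a pathway's genes present in other pathways
#'
#' The overlap ratio of pathway `id` is the proportion of its genes that
#' appear in at least one other pathway of the collection.
#'
#' @param coll a `pathway_collection` with at least two pathways
#' @param id pathway id
#' @return a fraction in \[0, 1\]
#' @export
overlap_ratio <- function(coll, id) {
  i <- match(id, coll$pathways$id)
  if (is.na(i)) stop(sprintf("pathway '%s' not in collection", id))
  if (nrow(coll$pathways) < 2L)
    stop("overlap ratio undefined for a singleton collection")
  g <- coll$pathways$genes[[i]]
  others <- unique(unlist(coll$pathways$genes[-i]))
  sum(g %in% others) / length(g)
}

#' Number of other pathways fully contained in a pathway
#'
#' @param coll a `pathway_collection`
#' @param id pathway id
#' @return non-negative integer count of other pathways whose gene set is a
#'   subset of pathway `id`'s
#' @export
count_subsets <- function(coll, id) {
  i <- match(id, coll$pathways$id)
  if (is.na(i)) stop(sprintf("pathway '%s' not in collection", id))
  g <- coll$pathways$genes[[i]]
  sum(vapply(coll$pathways$genes[-i], function(q) all(q %in% g), TRUE))
}

#' Per-pathway size, overlap and subset statistics
#'
#' @param coll a `pathway_collection`
#' @return tibble with columns `id`, `n_genes`, `overlap_ratio`, `n_subsets`
#' @export
pathway_stats <- function(coll) {
  ids <- coll$pathways$id
  tibble::tibble(
    id = ids,
    n_genes = lengths(coll$pathways$genes),
    overlap_ratio = vapply(ids, overlap_ratio, 0, coll = coll),
    n_subsets = vapply(ids, function(i) as.numeric(count_subsets(coll, i)), 0)
  )
}

#' Filter pathways by size, overlap ratio and subset count
#'
#' A pathway of size n is kept if any of three clauses holds:
#' `min_genes <= n <= max_genes`, or `n > min_genes` and its overlap ratio is
#' below `max_overlap`, or `n > min_genes` and its number of contained
#' pathway subsets is below `max_subsets`. Overlap and subset statistics are
#' computed against the unfiltered collection; survivor order is preserved
#' and the gene universe is recomputed.
#'
#' @param coll a `pathway_collection`
#' @param min_genes,max_genes inclusive size band for the first clause
#' @param max_overlap strict upper bound on the overlap ratio (second clause)
#' @param max_subsets strict upper bound on the subset count (third clause)
#' @return the filtered `pathway_collection`
#' @export
filter_pathways <- function(coll, min_genes = 15, max_genes = 100,
                            max_overlap = 1, max_subsets = 5) {
  stopifnot(min_genes > 0, max_genes >= min_genes)
  st <- pathway_stats(coll)
  keep <- (st$n_genes >= min_genes & st$n_genes <= max_genes) |
    (st$n_genes > min_genes & st$overlap_ratio < max_overlap) |
    (st$n_genes > min_genes & st$n_subsets < max_subsets)
  if (!any(keep))
    stop("no pathways pass the filter; consider relaxing the thresholds")
  new_pathway_collection(coll$pathways[keep, , drop = FALSE])
}

#' Build the binary gene-by-pathway membership mask
#'
#' Rows follow `gene_universe` order, columns the pathway order; entry
#' `[g, p]` is 1 iff gene g belongs to pathway p. This mask is the support
#' of the sparse gene-to-pathway projection.
#'
#' @param coll a `pathway_collection`
#' @return binary matrix (genes x pathways) with dimnames
#' @export
build_mask <- function(coll) {
  genes <- coll$gene_universe
  m <- matrix(0, length(genes), nrow(coll$pathways),
              dimnames = list(genes, coll$pathways$id))
  for (j in seq_len(ncol(m)))
    m[coll$pathways$genes[[j]], j] <- 1
  m
}

#' Build the initial pathway crosstalk network
#'
#' Tests every pathway pair for crosstalk and records `1 - adjusted p`
#' (Benjamini-Hochberg across all pairs) for pairs significant at `alpha`,
#' 0 otherwise. Without a background gene network the test is a shared-gene
#' hypergeometric enrichment on the collection's gene universe; with one,
#' the observed number of inter-set edges is tested against a binomial null
#' whose success probability is the network's edge density. The result is a
#' symmetric non-negative matrix with zero diagonal, used as the additive
#' bias on pathway-axis attention.
#'
#' @param coll a `pathway_collection`
#' @param gene_network optional data frame with columns `gene_a`, `gene_b`
#'   (an undirected edge list over the gene universe)
#' @param alpha significance level on the BH-adjusted p values
#' @return a `crosstalk_network`: list with `matrix` (Np x Np), `method` and
#'   `params`
#' @export
build_crosstalk <- function(coll, gene_network = NULL, alpha = 0.05) {
  genes <- coll$gene_universe
  sets <- lapply(coll$pathways$genes, intersect, y = genes)
  if (any(lengths(sets) == 0L))
    stop("pathway with no genes in the gene universe")
  np <- length(sets)
  N <- length(genes)
  pairs <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)

  if (is.null(gene_network)) {
    method <- "hypergeometric_shared_genes"
    pvals <- apply(pairs, 1L, function(ij) {
      a <- sets[[ij[1L]]]; b <- sets[[ij[2L]]]
      k <- length(intersect(a, b))
      stats::phyper(k - 1, length(a), N - length(a), length(b),
                    lower.tail = FALSE)
    })
    params <- list(alpha = alpha, universe_size = N)
  } else {
    method <- "binomial_interset_edges"
    stopifnot(all(c("gene_a", "gene_b") %in% names(gene_network)))
    ed <- gene_network[gene_network$gene_a %in% genes &
                         gene_network$gene_b %in% genes &
                         gene_network$gene_a != gene_network$gene_b, ]
    key <- paste(pmin(ed$gene_a, ed$gene_b), pmax(ed$gene_a, ed$gene_b))
    ed <- ed[!duplicated(key), , drop = FALSE]
    dens <- nrow(ed) / choose(N, 2)
    adj <- split(c(ed$gene_b, ed$gene_a), c(ed$gene_a, ed$gene_b))
    pvals <- apply(pairs, 1L, function(ij) {
      a <- sets[[ij[1L]]]; b <- sets[[ij[2L]]]
      cc <- length(intersect(a, b))
      trials <- length(a) * length(b) - cc - choose(cc, 2)
      if (trials <= 0 || dens == 0) return(1)
      obs <- sum(vapply(a, function(u) {
        nb <- adj[[u]]
        if (is.null(nb)) 0L else length(intersect(setdiff(nb, u), b))
      }, 0L))
      # each undirected inter-set edge {u,v} with both ends in both sets is
      # reached from u and v; halve that double count
      both <- sum(vapply(intersect(a, b), function(u) {
        nb <- adj[[u]]
        if (is.null(nb)) 0L else length(intersect(nb, intersect(a, b)))
      }, 0L)) / 2
      obs <- obs - both
      stats::pbinom(obs - 1, trials, dens, lower.tail = FALSE)
    })
    params <- list(alpha = alpha, universe_size = N, edge_density = dens)
  }

  padj <- stats::p.adjust(pvals, method = "BH")
  w <- ifelse(padj < alpha, 1 - padj, 0)
  m <- matrix(0, np, np, dimnames = list(coll$pathways$id, coll$pathways$id))
  m[pairs] <- w
  m[pairs[, c(2L, 1L), drop = FALSE]] <- w
  structure(list(matrix = m, method = method, params = params),
            class = "crosstalk_network")
}

#' @export
print.crosstalk_network <- function(x, ...) {
  cat(sprintf("<crosstalk_network> %d pathways, %d nonzero edges (%s)\n",
              nrow(x$matrix), sum(x$matrix[upper.tri(x$matrix)] > 0),
              x$method))
  invisible(x)
}

#' Read an undirected gene-gene edge list
#'
#' @param path TSV with two columns `gene_a<TAB>gene_b` (header optional,
#'   detected)
#' @return tibble with columns `gene_a`, `gene_b`
#' @export
read_edge_list <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- identical(strsplit(first, "\t")[[1L]][1:2],
                          c("gene_a", "gene_b"))
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene_a", "gene_b")
  tibble::as_tibble(df[, 1:2])
}
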