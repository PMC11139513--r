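# shared fixtures, all generated in code

make_gmt <- function(lines, file = tempfile(fileext = ".gmt")) {
  writeLines(lines, file)
  file
}

toy_collection <- function() {
  read_gmt(make_gmt(c(
    "pA\tsrc\tA\tB\tC",
    "pB\tsrc\tB\tC\tD",
    "pC\tsrc\tE\tF"
  )))
}

# a small simulated study reused across tests (cheap: 60 samples, 8 pathways)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(sim_config(
        n_samples = 60, n_genes = 60, n_pathways = 8,
        genes_per_pathway = c(5, 10), n_planted = 2,
        effect_size = 2, seed = 421))
    cache
  }
})

small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      coll <- sim$collection
      cache <<- list(
        sim = sim, coll = coll, mask = build_mask(coll),
        crosstalk = build_crosstalk(coll),
        eg = prepare_embedding(sim$modalities, coll$gene_universe))
    }
    cache
  }
})

px <- asNamespace("pathomix")

rand_cube <- function(r, c, s, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(r * c * s), c(r, c, s))
}
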