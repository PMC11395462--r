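# Fixtures built in code: a hand-sized knowledge base with known structure,
# a downscaled synthetic config for property tests, and a brute-force
# hypergeometric tail oracle (explicit pmf summation, independent of the
# phyper-based implementation).

tiny_kb <- function() {
  proteins <- tibble::tibble(id = 1:10, symbol = paste0("P", 1:10))
  interactions <- tibble::tibble(
    source = c(1L, 2L, 2L, 4L, 5L),
    target = c(2L, 3L, 4L, 5L, 6L),
    effect = c("activation", "inhibition", "unspecified", "activation", "activation"),
    mechanism = c("binding", "phosphorylation", "binding", "cleavage", "transport")
  )
  pathways <- gene_sets(c("pw1", "pw2"), list(c(1L, 2L, 3L), c(2L, 4L, 6L, 8L)))
  mm <- gene_sets(c("mm1", "mm2", "mm3"),
                  list(c(1L, 2L), c(2L, 3L, 4L), c(2L, 9L)),
                  kind = "metaminer_pathway")
  chains <- tibble::tibble(
    name = c("c1", "c2", "c3", "c4"),
    chain = list(c(1L, 2L, 3L), c(4L, 5L, 6L), c(2L, 4L), c(7L, 8L))
  )
  disorders <- tibble::tibble(
    disorder = c("dA", "dB"),
    biomarkers = list(c(1L, 3L), c(5L, 6L)),
    targets = list(c(2L, 4L), c(4L, 6L)),
    status = list(c(`2` = "validated", `4` = "candidate"),
                  c(`4` = "exploratory", `6` = "validated"))
  )
  similar <- gene_sets(c("simX", "simY"),
                       list(c(2L, 4L, 6L, 7L), c(1L, 9L)),
                       kind = "similar_disease_targets")
  knowledge_base(
    proteins = proteins, interactions = interactions,
    pathway_maps = pathways, metaminer_pathways = mm,
    linear_pathways = chains, disorders = disorders,
    similar_diseases = similar
  )
}

small_synth_config <- function(seed = 11L) {
  synth_config(
    n_proteins = 400L, n_disorders = 4L, module_size = 30L,
    n_shared_targets = 12L, shared_indications_range = c(2L, 3L),
    n_pathway_maps = 30L, pathway_size_range = c(8L, 20L),
    n_metaminer_pathways = 10L, metaminer_size_range = c(8L, 25L),
    n_linear_pathways = 40L, chain_length_range = c(3L, 6L),
    n_similar_diseases = 8L, similar_size = 20L,
    similar_shared_range = c(4L, 8L), n_decoy_diseases = 4L,
    rng_seed = seed
  )
}

# independent oracle: explicit pmf summation of the hypergeometric tail
oracle_tail <- function(r, R, n, N) {
  xs <- r:min(R, n)
  sum(exp(lchoose(n, xs) + lchoose(N - n, R - xs) - lchoose(N, R)))
}

random_test_graph <- function(n, p = 0.05) {
  g <- igraph::sample_gnp(n, p)
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
}

published_tables <- function() {
  dplyr::bind_rows(
    readr::read_tsv(system.file("extdata", "mf_enrichment_known_targets.tsv",
                                package = "mclprio"),
                    col_types = "ciiiid", progress = FALSE),
    readr::read_tsv(system.file("extdata", "mf_enrichment_novel_targets.tsv",
                                package = "mclprio"),
                    col_types = "ciiiid", progress = FALSE)
  )
}
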