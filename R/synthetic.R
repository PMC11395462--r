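# Synthetic knowledge-base generator.  Emulates the statistical structure
# the prioritization pipeline assumes: a scale-free interactome, disorder
# modules in which biomarkers and drug targets cluster topologically,
# pathway collections mixing module-derived and random members, linear
# signaling chains, and similar-disease target sets sampled from the pooled
# disorder targets.  Ground truth (the planted multi-indication targets) is
# returned alongside the knowledge base for recovery benchmarking.

mcl_disorder_names <- c(
  "alzheimer", "anorexia", "anxiety", "bipolar", "bulimia", "depression",
  "mania", "ocd", "parkinson", "gambling", "phobia", "ptsd", "schizophrenia"
)

similar_disease_names <- c(
  "psychosis", "memory_impairment", "sleep_disorder", "vascular_dementia",
  "panic_disorder", "alcoholism", "spinal_cord_injury",
  "mild_cognitive_impairment", "renal_failure", "stroke",
  "traumatic_brain_injury", "atherosclerosis", "ischemic_stroke",
  "sleep_apnea", "neurodegeneration"
)

decoy_disease_names <- c(
  "migraine", "epilepsy", "obesity", "hypertension", "diabetes",
  "chronic_pain", "multiple_sclerosis", "als", "huntington", "autism"
)

#' Configuration for the synthetic knowledge base
#'
#' Defaults define the package's benchmark conditions: 2,000 proteins, 13
#' disorders with 60-protein modules, 50 planted multi-indication targets.
#' See the methods vignette for the rationale behind each default.
#'
#' @param n_proteins Universe size.
#' @param edges_per_node Preferential-attachment edges added per new node.
#' @param n_disorders Number of annotated disorders.
#' @param module_size Proteins per disorder module (BFS-grown, connected).
#' @param biomarker_rate Fraction of a module annotated as biomarkers.
#' @param n_background_biomarkers Extra biomarkers drawn outside the module
#'   (annotation noise).
#' @param target_rate Fraction of a module annotated as single-indication
#'   targets.
#' @param n_background_targets Extra single-indication targets per disorder
#'   drawn outside the module.
#' @param n_shared_targets Planted targets assigned to >= 2 disorders (the
#'   positive controls).
#' @param shared_indications_range Range of indications per planted target.
#' @param n_pathway_maps,pathway_size_range,pathway_signal_fraction Pathway
#'   map count, size range, and fraction of members drawn from a disorder
#'   module (rest random).
#' @param n_metaminer_pathways,metaminer_size_range,metaminer_signal_fraction
#'   Consortium pathway collection controls.
#' @param n_linear_pathways,chain_length_range Linear chain controls.
#' @param n_similar_diseases Similar diseases with a real shared-target
#'   signal (default 15).
#' @param similar_size Genes per similar-disease target set.
#' @param similar_shared_range Targets each similar disease shares with the
#'   pooled disorder targets.
#' @param n_decoy_diseases Candidate diseases sharing < 3 targets (excluded
#'   by the selection rule).
#' @param rng_seed Seed for all generation randomness.
#' @return A list of class `mcl_synth_config`.
#' @export
synth_config <- function(n_proteins = 2000L,
                         edges_per_node = 3L,
                         n_disorders = 13L,
                         module_size = 60L,
                         biomarker_rate = 0.35,
                         n_background_biomarkers = 4L,
                         target_rate = 0.2,
                         n_background_targets = 3L,
                         n_shared_targets = 50L,
                         shared_indications_range = c(2L, 4L),
                         n_pathway_maps = 150L,
                         pathway_size_range = c(10L, 60L),
                         pathway_signal_fraction = 0.6,
                         n_metaminer_pathways = 40L,
                         metaminer_size_range = c(15L, 80L),
                         metaminer_signal_fraction = 0.5,
                         n_linear_pathways = 200L,
                         chain_length_range = c(4L, 10L),
                         n_similar_diseases = 15L,
                         similar_size = 40L,
                         similar_shared_range = c(5L, 15L),
                         n_decoy_diseases = 10L,
                         rng_seed = 7L) {
  cfg <- as.list(environment())
  stopifnot(
    n_proteins >= 100, edges_per_node >= 1, n_disorders >= 2,
    module_size >= 10, biomarker_rate > 0, biomarker_rate <= 1,
    target_rate > 0, target_rate <= 1, n_shared_targets >= 1,
    shared_indications_range[1] >= 2,
    shared_indications_range[2] <= n_disorders,
    chain_length_range[1] >= 2,
    n_similar_diseases >= 1, similar_shared_range[1] >= 3
  )
  if (n_disorders > length(mcl_disorder_names)) {
    abort("At most 13 named disorders are supported.")
  }
  if (n_shared_targets > n_disorders * floor(module_size / 2)) {
    abort("Infeasible: too many shared targets for the module capacity.")
  }
  if (similar_size > n_proteins) abort("Infeasible: similar_size exceeds the universe.")
  if (similar_shared_range[2] > n_shared_targets + n_disorders) {
    abort("Infeasible: similar diseases cannot share more targets than exist.")
  }
  structure(cfg, class = "mcl_synth_config")
}

# sample from a vector regardless of its length (avoids the scalar
# interpretation of base sample())
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

bfs_module <- function(graph, start, size) {
  ord <- igraph::bfs(graph, root = start, order = TRUE)$order
  as.integer(igraph::V(graph)$name[head(ord, size)])
}

simple_walk_chain <- function(graph, start, len) {
  walk <- igraph::random_walk(graph, start = start, steps = 3 * len)
  ids <- as.integer(igraph::V(graph)$name[walk])
  head(unique(ids), len)
}

#' Generate a synthetic knowledge base with planted ground truth
#'
#' Deterministic given the config (including its `rng_seed`): identical
#' configs produce byte-identical serialized knowledge bases.
#'
#' @param config An `mcl_synth_config` (see [synth_config()]).
#' @return List with elements `kb` (an `mcl_kb`) and `truth` (planted
#'   targets, per-disorder module membership, feature-group informativeness
#'   flags).
#' @export
generate_kb <- function(config = synth_config()) {
  stopifnot(inherits(config, "mcl_synth_config"))
  set.seed(config$rng_seed)
  n <- config$n_proteins
  proteins <- tibble(id = seq_len(n), symbol = sprintf("G%05d", seq_len(n)))

  # scale-free interactome via preferential attachment
  g <- igraph::sample_pa(n, power = 1, m = config$edges_per_node, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
  el <- igraph::as_edgelist(g, names = TRUE)
  m_edges <- nrow(el)
  interactions <- tibble(
    source = pmin(as.integer(el[, 1]), as.integer(el[, 2])),
    target = pmax(as.integer(el[, 1]), as.integer(el[, 2])),
    effect = mcl_effects[sample.int(3, m_edges, replace = TRUE, prob = c(0.4, 0.3, 0.3))],
    mechanism = resample(mcl_mechanisms, m_edges, replace = TRUE)
  )
  interactions <- distinct(interactions, .data$source, .data$target, .keep_all = TRUE)
  interactions <- arrange(interactions, .data$source, .data$target)

  # disorder modules: BFS balls around distinct random roots
  n_dis <- config$n_disorders
  disorder_names <- mcl_disorder_names[seq_len(n_dis)]
  roots <- sample.int(n, n_dis)
  modules <- map(roots, function(r) bfs_module(g, as.character(r), config$module_size))
  names(modules) <- disorder_names

  # biomarkers: in-module enrichment plus background annotation noise
  biomarkers <- map(modules, function(mod) {
    inside <- sort(resample(mod, max(3L, round(config$biomarker_rate * length(mod)))))
    outside <- resample(setdiff(seq_len(n), mod), config$n_background_biomarkers)
    sort(unique(c(inside, outside)))
  })

  # planted multi-indication targets: each lives in a home module and is
  # annotated for 2+ disorders; all other targets are globally unique so
  # the planted set IS exactly the >= 2-indication positive-control set.
  home <- rep_len(seq_len(n_dis), config$n_shared_targets)
  used <- integer()
  shared <- integer(config$n_shared_targets)
  for (i in seq_len(config$n_shared_targets)) {
    pool <- setdiff(modules[[home[i]]], used)
    if (!length(pool)) pool <- setdiff(unlist(modules), used)
    if (!length(pool)) abort("Infeasible: module capacity exhausted while planting shared targets.")
    shared[i] <- resample(pool, 1)
    used <- c(used, shared[i])
  }
  n_ind <- resample(seq(config$shared_indications_range[1],
                        config$shared_indications_range[2]),
                    config$n_shared_targets, replace = TRUE)
  target_lists <- setNames(vector("list", n_dis), disorder_names)
  for (i in seq_len(config$n_shared_targets)) {
    others <- resample(setdiff(seq_len(n_dis), home[i]), n_ind[i] - 1)
    for (d in c(home[i], others)) {
      target_lists[[d]] <- c(target_lists[[d]], shared[i])
    }
  }
  for (d in seq_len(n_dis)) {
    n_uniq <- round(config$target_rate * config$module_size)
    pool <- setdiff(modules[[d]], used)
    uniq_in <- resample(pool, min(n_uniq, length(pool)))
    used <- c(used, uniq_in)
    pool_bg <- setdiff(seq_len(n), used)
    uniq_bg <- resample(pool_bg, config$n_background_targets)
    used <- c(used, uniq_bg)
    target_lists[[d]] <- sort(unique(c(target_lists[[d]], uniq_in, uniq_bg)))
  }
  statuses <- map(target_lists, function(tg) {
    setNames(resample(mcl_target_statuses, length(tg), replace = TRUE),
             as.character(tg))
  })

  disorders <- tibble(
    disorder = disorder_names,
    biomarkers = unname(biomarkers),
    targets = unname(target_lists),
    status = unname(statuses)
  )

  # pathway maps: module-derived signal members mixed with random ones
  make_maps <- function(n_maps, size_range, signal_fraction, prefix, kind) {
    sizes <- resample(seq(size_range[1], size_range[2]), n_maps, replace = TRUE)
    members <- map(seq_len(n_maps), function(j) {
      d <- sample.int(n_dis, 1)
      n_sig <- round(signal_fraction * sizes[j])
      sig <- resample(modules[[d]], min(n_sig, length(modules[[d]])))
      bg <- resample(seq_len(n), sizes[j] - length(sig))
      sort(unique(c(sig, bg)))
    })
    gene_sets(sprintf("%s_%03d", prefix, seq_len(n_maps)), members, kind = kind)
  }
  pathway_maps <- make_maps(config$n_pathway_maps, config$pathway_size_range,
                            config$pathway_signal_fraction, "map", "pathway_map")
  metaminer <- make_maps(config$n_metaminer_pathways, config$metaminer_size_range,
                         config$metaminer_signal_fraction, "mm", "metaminer_pathway")

  # linear signaling chains: simple random-walk paths, ligand end to TF end
  lens <- resample(seq(config$chain_length_range[1], config$chain_length_range[2]),
                   config$n_linear_pathways, replace = TRUE)
  starts <- sample.int(n, config$n_linear_pathways, replace = TRUE)
  chains <- map(seq_len(config$n_linear_pathways), function(j) {
    ch <- simple_walk_chain(g, as.character(starts[j]), lens[j])
    if (length(ch) < 2) ch <- c(ch, setdiff(sample.int(n, 2), ch))[1:2]
    ch
  })
  linear_pathways <- tibble(
    name = sprintf("chain_%03d", seq_len(config$n_linear_pathways)),
    chain = chains
  )

  # similar diseases: shared targets drawn mostly from the planted
  # multi-indication set (so the >= 3 shared-target selection rule is
  # exercisable against the gold standard), topped up from the pooled
  # disorder targets; decoys share too few to pass the rule
  pooled_targets <- sort(unique(unlist(target_lists)))
  sim_names <- similar_disease_names[seq_len(min(config$n_similar_diseases,
                                                 length(similar_disease_names)))]
  dec_names <- decoy_disease_names[seq_len(min(config$n_decoy_diseases,
                                               length(decoy_disease_names)))]
  make_similar <- function(nm, shared_lo, shared_hi, from_planted) {
    map(nm, function(x) {
      k <- resample(seq(shared_lo, shared_hi), 1)
      if (from_planted) {
        k_pos <- max(3L, round(0.6 * k))
        sh <- c(resample(shared, min(k_pos, length(shared))),
                resample(pooled_targets, min(k - k_pos, length(pooled_targets))))
      } else {
        sh <- if (k > 0) resample(setdiff(pooled_targets, shared),
                                  min(k, length(setdiff(pooled_targets, shared))))
              else integer()
      }
      bg <- resample(setdiff(seq_len(n), c(sh, shared)),
                     config$similar_size - length(unique(sh)))
      sort(unique(c(sh, bg)))
    })
  }
  sim_members <- make_similar(sim_names, config$similar_shared_range[1],
                              config$similar_shared_range[2], TRUE)
  dec_members <- make_similar(dec_names, 0L, 2L, FALSE)
  similar <- gene_sets(c(sim_names, dec_names), c(sim_members, dec_members),
                       kind = "similar_disease_targets")
  similar <- arrange(similar, .data$name)

  kb <- knowledge_base(
    proteins = proteins, interactions = interactions,
    pathway_maps = pathway_maps, metaminer_pathways = metaminer,
    linear_pathways = linear_pathways, disorders = disorders,
    similar_diseases = similar
  )

  truth <- list(
    planted_targets = sort(shared),
    modules = tibble(
      disorder = rep(disorder_names, each = config$module_size),
      protein_id = unlist(modules)
    ),
    informative_features = tibble(
      feature_group = c("biomarker", "interaction", "pathway", "linear",
                        "metaminer", "network", "similarity"),
      informative = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
    ),
    config = unclass(config)
  )
  stopifnot(setequal(define_positive_controls(kb), truth$planted_targets))
  list(kb = kb, truth = truth)
}

#' Positive-control targets: drug targets of two or more disorders
#'
#' Proteins present (with any development status) in the target sets of at
#' least two annotated disorders.  These are the training labels for the
#' integration step.
#'
#' @param kb An `mcl_kb`.
#' @return Sorted integer vector of protein ids.
#' @export
define_positive_controls <- function(kb) {
  counts <- table(unlist(map(kb$disorders$targets, unique)))
  sort(as.integer(names(counts)[counts >= 2]))
}
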