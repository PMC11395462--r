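# Knowledge-base container: protein table, direct physical interactions,
# pathway collections, linear signaling chains, per-disorder annotations and
# candidate similar-disease target sets.  All scoring modules consume this
# object; nothing downstream touches files.

#' Admissible interaction effect labels
#' @export
mcl_effects <- c("activation", "inhibition", "unspecified")

#' Admissible direct interaction mechanisms
#'
#' Only physically direct mechanisms are admitted into the interactome;
#' indirect influence (e.g. on expression) is excluded at load time.
#' @export
mcl_mechanisms <- c(
  "binding", "competition", "transformation", "cleavage", "catalysis",
  "transport", "receptor_binding", "transport_catalysis",
  "phosphorylation", "dephosphorylation", "ubiquitination",
  "deubiquitination", "sumoylation", "desumoylation", "neddylation",
  "deneddylation", "covalent_modification"
)

#' Development-status labels for known drug targets
#' @export
mcl_target_statuses <- c("validated", "candidate", "exploratory")

gene_set_kinds <- c(
  "pathway_map", "disease_pathway_map", "metaminer_pathway",
  "biomarker_set", "target_set", "annotation_term",
  "similar_disease_targets"
)

#' Construct a gene-set table
#'
#' A tidy gene-set collection: one row per named set, members held in a
#' list-column of integer protein ids.
#'
#' @param name Character vector of set names (non-empty, unique).
#' @param members List of integer vectors of protein ids.
#' @param kind A single kind label (see `gene_set_kinds` in the source).
#' @return A tibble with columns `name`, `kind`, `members`.
#' @export
gene_sets <- function(name = character(), members = list(), kind = "pathway_map") {
  kind <- match.arg(kind, gene_set_kinds)
  if (length(name) != length(members)) {
    abort("`name` and `members` must have equal length.")
  }
  if (any(!nzchar(name))) abort("Gene-set names must be non-empty.")
  tibble(
    name = as.character(name),
    kind = kind,
    members = map(members, function(m) sort(unique(as.integer(m))))
  )
}

#' Assemble and validate a knowledge base
#'
#' @param proteins Tibble with integer `id` (unique) and non-empty `symbol`.
#' @param interactions Tibble with `source`, `target`, `effect`, `mechanism`;
#'   undirected, simple (validated here).
#' @param pathway_maps,metaminer_pathways Gene-set tables (see [gene_sets()]).
#' @param linear_pathways Tibble with `name` and list-column `chain` of
#'   ordered protein ids; each chain starts at a ligand/receptor and ends at
#'   a transcription factor (length >= 2).
#' @param disorders Tibble with `disorder`, list-columns `biomarkers` and
#'   `targets` (integer ids) and `status` (named character vector mapping
#'   target id to development status).  Targets without a status are not
#'   admitted.
#' @param similar_diseases Gene-set table of candidate similar-disease
#'   target sets.
#' @return An object of class `mcl_kb`.
#' @export
knowledge_base <- function(proteins,
                           interactions = empty_interactions(),
                           pathway_maps = gene_sets(),
                           metaminer_pathways = gene_sets(kind = "metaminer_pathway"),
                           linear_pathways = tibble(name = character(), chain = list()),
                           disorders = empty_disorders(),
                           similar_diseases = gene_sets(kind = "similar_disease_targets")) {
  kb <- structure(
    list(
      proteins = as_tibble(proteins),
      interactions = as_tibble(interactions),
      pathway_maps = as_tibble(pathway_maps),
      metaminer_pathways = as_tibble(metaminer_pathways),
      linear_pathways = as_tibble(linear_pathways),
      disorders = as_tibble(disorders),
      similar_diseases = as_tibble(similar_diseases)
    ),
    class = "mcl_kb"
  )
  validate_kb(kb)
}

empty_interactions <- function() {
  tibble(
    source = integer(), target = integer(),
    effect = character(), mechanism = character()
  )
}

empty_disorders <- function() {
  tibble(
    disorder = character(), biomarkers = list(),
    targets = list(), status = list()
  )
}

#' Validate cross-references and graph simplicity of a knowledge base
#'
#' @param kb An `mcl_kb` object.
#' @return `kb`, invisibly usable, after checks; aborts on violation.
#' @export
validate_kb <- function(kb) {
  stopifnot(inherits(kb, "mcl_kb"))
  ids <- kb$proteins$id
  if (anyDuplicated(ids)) abort("Protein ids must be unique.")
  if (any(!nzchar(kb$proteins$symbol))) abort("Protein symbols must be non-empty.")
  ia <- kb$interactions
  if (nrow(ia)) {
    if (any(ia$source == ia$target)) abort("Self-interactions are not allowed.")
    if (!all(c(ia$source, ia$target) %in% ids)) {
      abort("Interaction endpoints must be known proteins.")
    }
    bad <- setdiff(unique(ia$effect), mcl_effects)
    if (length(bad)) abort(paste0("Unknown effect label: ", bad[1]))
    bad <- setdiff(unique(ia$mechanism), mcl_mechanisms)
    if (length(bad)) abort(paste0("Unknown mechanism label: ", bad[1]))
    key <- paste(pmin(ia$source, ia$target), pmax(ia$source, ia$target))
    if (anyDuplicated(key)) abort("Duplicate undirected interactions present.")
  }
  check_members <- function(sets, what) {
    miss <- setdiff(unlist(sets), ids)
    if (length(miss)) {
      abort(paste0(what, " reference unknown protein ids: ",
                   paste(head(miss, 5), collapse = ", ")))
    }
  }
  check_members(kb$pathway_maps$members, "Pathway maps")
  check_members(kb$metaminer_pathways$members, "Consortium pathways")
  check_members(kb$similar_diseases$members, "Similar-disease sets")
  check_members(kb$linear_pathways$chain, "Linear pathways")
  if (nrow(kb$linear_pathways) && any(lengths(kb$linear_pathways$chain) < 2)) {
    abort("Linear pathway chains must have length >= 2.")
  }
  if (nrow(kb$disorders)) {
    check_members(kb$disorders$biomarkers, "Biomarker sets")
    check_members(kb$disorders$targets, "Target sets")
    ok <- map2(kb$disorders$targets, kb$disorders$status, function(tg, st) {
      setequal(as.character(tg), names(st)) &&
        all(st %in% mcl_target_statuses)
    })
    if (!all(unlist(ok))) {
      abort("Every disorder target must carry exactly one development status.")
    }
  }
  kb
}

#' @method print mcl_kb
#' @export
print.mcl_kb <- function(x, ...) {
  cat("<mcl_kb>\n")
  cat("  proteins:          ", nrow(x$proteins), "\n")
  cat("  interactions:      ", nrow(x$interactions), "\n")
  cat("  pathway maps:      ", nrow(x$pathway_maps), "\n")
  cat("  consortium maps:   ", nrow(x$metaminer_pathways), "\n")
  cat("  linear pathways:   ", nrow(x$linear_pathways), "\n")
  cat("  disorders:         ", nrow(x$disorders), "\n")
  cat("  similar diseases:  ", nrow(x$similar_diseases), "\n")
  invisible(x)
}

#' Protein universe of a knowledge base
#' @param kb An `mcl_kb`.
#' @return Sorted integer vector of all protein ids.
#' @export
protein_universe <- function(kb) sort(kb$proteins$id)

# ---- interactome construction ------------------------------------------

#' Build the undirected simple interactome
#'
#' Every protein in the universe becomes a vertex (isolated proteins are
#' kept: prioritization is genome-wide), and each interaction one undirected
#' edge.  Effect and mechanism are carried as edge attributes but play no
#' role in topology-based scoring.
#'
#' @param kb An `mcl_kb`.
#' @return An [igraph::igraph] with vertex names equal to protein ids.
#' @export
build_graph <- function(kb) {
  ids <- as.character(protein_universe(kb))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  ia <- kb$interactions
  if (nrow(ia)) {
    g <- igraph::add_edges(
      g, rbind(as.character(ia$source), as.character(ia$target)),
      effect = ia$effect, mechanism = ia$mechanism
    )
  }
  stopifnot(igraph::is_simple(g))
  g
}

# ---- file formats -------------------------------------------------------

#' Read an interaction edge list
#'
#' Expects a 4-column TSV with header `source_id  target_id  effect
#' mechanism`.  Self-loops are rejected (counted in a warning), duplicate
#' undirected edges are collapsed to one record, and unknown effect or
#' mechanism tokens raise an error naming the offending line.
#'
#' @param path File path.
#' @return Interaction tibble (`source`, `target`, `effect`, `mechanism`),
#'   canonically ordered with `source < target`.
#' @export
read_edge_list <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    source_id = readr::col_integer(),
    target_id = readr::col_integer(),
    effect = readr::col_character(),
    mechanism = readr::col_character()
  ), progress = FALSE)
  line <- seq_len(nrow(df)) + 1L  # account for header
  bad_eff <- which(!df$effect %in% mcl_effects)
  if (length(bad_eff)) {
    abort(sprintf("Line %d: unknown effect token '%s'.",
                  line[bad_eff[1]], df$effect[bad_eff[1]]))
  }
  bad_mech <- which(!df$mechanism %in% mcl_mechanisms)
  if (length(bad_mech)) {
    abort(sprintf("Line %d: unknown mechanism token '%s'.",
                  line[bad_mech[1]], df$mechanism[bad_mech[1]]))
  }
  loops <- df$source_id == df$target_id
  if (any(loops)) {
    warn(sprintf("Rejected %d self-interaction(s).", sum(loops)))
    df <- df[!loops, ]
  }
  out <- tibble(
    source = pmin(df$source_id, df$target_id),
    target = pmax(df$source_id, df$target_id),
    effect = df$effect,
    mechanism = df$mechanism
  )
  out <- distinct(out, .data$source, .data$target, .keep_all = TRUE)
  arrange(out, .data$source, .data$target)
}

#' Write an interaction edge list
#' @param interactions Interaction tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(interactions, path) {
  out <- tibble(
    source_id = interactions$source, target_id = interactions$target,
    effect = interactions$effect, mechanism = interactions$mechanism
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: `name <tab> description <tab> member ids...`.  When a
#' protein universe is supplied, unresolvable member ids are dropped with a
#' warning; sets left empty are skipped with a warning.
#'
#' @param path File path.
#' @param kind Gene-set kind label.
#' @param universe Optional integer vector of admissible protein ids.
#' @return A gene-set tibble (see [gene_sets()]).
#' @export
read_gmt <- function(path, kind = "pathway_map", universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nfield < 3)) {
    abort(sprintf("Malformed GMT line %d: fewer than 3 tab-separated fields.",
                  which(nfield < 3)[1]))
  }
  sets <- fgsea::gmtPathways(path)
  members <- map(sets, function(m) unique(as.integer(m)))
  if (!is.null(universe)) {
    resolved <- map(members, function(m) m[m %in% universe])
    n_dropped <- sum(lengths(members) - lengths(resolved))
    if (n_dropped > 0) {
      warn(sprintf("Dropped %d gene-set member id(s) absent from the universe.",
                   n_dropped))
    }
    members <- resolved
  }
  empty <- lengths(members) == 0
  if (any(empty)) {
    warn(sprintf("Skipped %d empty gene set(s).", sum(empty)))
    members <- members[!empty]
  }
  gene_sets(names(members), unname(members), kind = kind)
}

#' Write gene sets to a GMT file
#' @param sets Gene-set tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- map_chr(seq_len(nrow(sets)), function(i) {
    paste(c(sets$name[i], sets$kind[i], sets$members[[i]]), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read linear signaling chains
#'
#' TSV with columns `name` and `chain`, the latter an ordered `>`-separated
#' id list running from the ligand/receptor end to the transcription factor.
#'
#' @param path File path.
#' @return Tibble with `name` and list-column `chain`.
#' @export
read_linear_pathways <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(), chain = readr::col_character()
  ), progress = FALSE)
  chains <- map(strsplit(df$chain, ">", fixed = TRUE), as.integer)
  if (any(lengths(chains) < 2)) abort("Linear pathway chains must have length >= 2.")
  tibble(name = df$name, chain = chains)
}

#' Write linear signaling chains
#' @param linear_pathways Tibble with `name` and list-column `chain`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linear_pathways <- function(linear_pathways, path) {
  out <- tibble(
    name = linear_pathways$name,
    chain = map_chr(linear_pathways$chain, paste, collapse = ">")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a knowledge base to a directory of plain-text files
#'
#' Layout: `proteins.tsv`, `edges.tsv`, `pathway_maps.gmt`,
#' `metaminer_pathways.gmt`, `linear_pathways.tsv`,
#' `similar_diseases.gmt`, `biomarkers.gmt`, `targets.gmt` and a
#' `disorders.yaml` manifest mapping each disorder to its biomarker and
#' target set entries plus per-target development status.
#'
#' @param kb An `mcl_kb`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_kb <- function(kb, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(kb$proteins, file.path(dir, "proteins.tsv"), progress = FALSE)
  write_edge_list(kb$interactions, file.path(dir, "edges.tsv"))
  write_gmt(kb$pathway_maps, file.path(dir, "pathway_maps.gmt"))
  write_gmt(kb$metaminer_pathways, file.path(dir, "metaminer_pathways.gmt"))
  write_linear_pathways(kb$linear_pathways, file.path(dir, "linear_pathways.tsv"))
  write_gmt(kb$similar_diseases, file.path(dir, "similar_diseases.gmt"))
  bm <- gene_sets(paste0(kb$disorders$disorder, ".biomarkers"),
                  kb$disorders$biomarkers, kind = "biomarker_set")
  tg <- gene_sets(paste0(kb$disorders$disorder, ".targets"),
                  kb$disorders$targets, kind = "target_set")
  write_gmt(bm, file.path(dir, "biomarkers.gmt"))
  write_gmt(tg, file.path(dir, "targets.gmt"))
  manifest <- setNames(
    map(seq_len(nrow(kb$disorders)), function(i) {
      st <- kb$disorders$status[[i]]
      list(
        biomarker_set = paste0(kb$disorders$disorder[i], ".biomarkers"),
        target_set = paste0(kb$disorders$disorder[i], ".targets"),
        target_status = as.list(st[order(as.integer(names(st)))])
      )
    }),
    kb$disorders$disorder
  )
  yaml::write_yaml(manifest, file.path(dir, "disorders.yaml"))
  invisible(dir)
}

#' Read a knowledge base from a directory written by [write_kb()]
#' @param dir Directory path.
#' @return An `mcl_kb`.
#' @export
read_kb <- function(dir) {
  if (!dir.exists(dir)) abort(paste0("Knowledge-base directory not found: ", dir))
  proteins <- readr::read_tsv(file.path(dir, "proteins.tsv"), col_types = readr::cols(
    id = readr::col_integer(), symbol = readr::col_character()
  ), progress = FALSE)
  universe <- proteins$id
  interactions <- read_edge_list(file.path(dir, "edges.tsv"))
  pw <- read_gmt(file.path(dir, "pathway_maps.gmt"), "pathway_map", universe)
  mm <- read_gmt(file.path(dir, "metaminer_pathways.gmt"), "metaminer_pathway", universe)
  lp <- read_linear_pathways(file.path(dir, "linear_pathways.tsv"))
  sd <- read_gmt(file.path(dir, "similar_diseases.gmt"), "similar_disease_targets", universe)
  bm <- read_gmt(file.path(dir, "biomarkers.gmt"), "biomarker_set", universe)
  tg <- read_gmt(file.path(dir, "targets.gmt"), "target_set", universe)
  manifest <- yaml::read_yaml(file.path(dir, "disorders.yaml"))
  disorders <- tibble(
    disorder = names(manifest),
    biomarkers = map(names(manifest), function(d) {
      bm$members[[match(manifest[[d]]$biomarker_set, bm$name)]]
    }),
    targets = map(names(manifest), function(d) {
      tg$members[[match(manifest[[d]]$target_set, tg$name)]]
    }),
    status = map(names(manifest), function(d) {
      st <- unlist(manifest[[d]]$target_status)
      st[order(as.integer(names(st)))]
    })
  )
  knowledge_base(
    proteins = proteins, interactions = interactions, pathway_maps = pw,
    metaminer_pathways = mm, linear_pathways = lp, disorders = disorders,
    similar_diseases = sd
  )
}
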