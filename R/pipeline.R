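#' Pipeline configuration
#'
#' Paths, thresholds and modes for an end-to-end run. Defaults are the
#' conventional screening values for this style of prescription analysis:
#' rules at support >= 30 percent and confidence >= 85 percent, clustering
#' of herbs prescribed more than 30 times cut into 5 groups, backbone
#' significance 0.05 (95 percent confidence), core degree threshold 36.
#'
#' @param kb_path Path to the herb knowledge base.
#' @param prescriptions_path Path to the raw prescriptions file.
#' @param output_dir Directory for the output bundle (created if absent).
#' @param min_support,min_confidence Rule-mining thresholds (fractions).
#' @param cluster_min_count Strict count threshold for clustering.
#' @param k Number of clusters.
#' @param linkage Clustering linkage (see [agglomerate()]).
#' @param backbone_alpha Disparity-filter significance level.
#' @param core_min_degree Degree threshold for the core subgraph.
#' @param on_unknown Unknown-herb policy (see
#'   [standardize_prescriptions()]).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the input was generated
#'   synthetically).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(kb_path, prescriptions_path, output_dir,
                            min_support = 0.30, min_confidence = 0.85,
                            cluster_min_count = 30, k = 5,
                            linkage = "ward",
                            backbone_alpha = 0.05, core_min_degree = 36,
                            on_unknown = "error", seed = 1L) {
  stopifnot(
    min_support > 0, min_support <= 1,
    min_confidence > 0, min_confidence <= 1,
    cluster_min_count >= 0, k >= 1,
    backbone_alpha > 0, backbone_alpha < 1,
    core_min_degree >= 0
  )
  structure(
    list(
      kb_path = kb_path, prescriptions_path = prescriptions_path,
      output_dir = output_dir,
      min_support = min_support, min_confidence = min_confidence,
      cluster_min_count = cluster_min_count, k = k, linkage = linkage,
      backbone_alpha = backbone_alpha, core_min_degree = core_min_degree,
      on_unknown = on_unknown, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_herbminer(paste0("[", stage, "] ", conditionMessage(e)),
                   "herbminer_stage_error", stage = stage, parent = e)
  })
}

#' Run the full mining pipeline
#'
#' Standardizes the prescriptions against the knowledge base, then computes
#' and writes every analysis artifact: the herb frequency table, the four
#' attribute profiles, the association rules, the dendrogram (Newick) and
#' cluster assignment of high-frequency herbs, the co-prescription graph
#' and its backbone (edge-list CSV and GraphML), the core subgraph, and a
#' JSON run manifest recording the configuration and the counts at each
#' stage. Identical inputs and configuration always produce byte-identical
#' CSV outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list of the in-memory results (`db`, `frequency`,
#'   `profiles`, `itemsets`, `rules`, `dendrogram`, `clusters`, `graph`,
#'   `backbone`, `core`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!file.exists(cfg$kb_path)) {
    stop_herbminer(paste0("[config] knowledge-base path not found: ", cfg$kb_path),
                   "herbminer_config_error")
  }
  if (!file.exists(cfg$prescriptions_path)) {
    stop_herbminer(paste0("[config] prescriptions path not found: ",
                          cfg$prescriptions_path),
                   "herbminer_config_error")
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$output_dir, f)

  kb <- pipeline_stage("kb", read_knowledge_base(cfg$kb_path))
  records <- pipeline_stage("standardize", read_prescriptions(cfg$prescriptions_path))
  db <- pipeline_stage("standardize",
                       standardize_prescriptions(records, kb, cfg$on_unknown))
  skip_log <- attr(db, "skip_log")

  freq <- pipeline_stage("profile", herb_frequency(db))
  readr::write_csv(freq, out("herb_frequency.csv"), progress = FALSE)
  profiles <- purrr::map(
    setNames(c("property", "taste", "meridian", "category"),
             c("property", "taste", "meridian", "category")),
    ~ pipeline_stage("profile", attribute_profile(db, kb, .x))
  )
  for (kind in names(profiles)) {
    readr::write_csv(profiles[[kind]], out(paste0("profile_", kind, ".csv")),
                     progress = FALSE)
  }

  itemsets <- pipeline_stage("rules", frequent_itemsets(db, cfg$min_support))
  rules <- pipeline_stage("rules",
                          generate_rules(itemsets, db, cfg$min_confidence))
  write_rules(rules, out("association_rules.csv"))

  high_freq <- pipeline_stage("cluster",
                              select_high_frequency(db, cfg$cluster_min_count))
  dendro <- NULL
  clusters <- tibble(herb = character(0), cluster = integer(0))
  if (length(high_freq) >= 2) {
    d <- pipeline_stage("cluster", herb_distances(db, sort_c(high_freq)))
    dendro <- pipeline_stage("cluster", agglomerate(d, cfg$linkage))
    k_use <- min(cfg$k, length(high_freq))
    clusters <- pipeline_stage("cluster", cut_dendrogram(dendro, k_use))
    dendrogram_newick(dendro, out("dendrogram.nwk"))
  }
  readr::write_csv(clusters, out("clusters.csv"), progress = FALSE)

  graph <- pipeline_stage("network", cooccurrence_graph(db))
  backbone <- pipeline_stage("network",
                             disparity_filter(graph, cfg$backbone_alpha))
  core <- pipeline_stage("network", core_subgraph(backbone, cfg$core_min_degree))
  write_edge_list(graph, out("graph_edges.csv"))
  write_edge_list(backbone, out("backbone_edges.csv"))
  write_graphml(backbone, out("backbone.graphml"))
  readr::write_csv(core$nodes, out("core_nodes.csv"), progress = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("herbminer")),
    config = unclass(cfg),
    n_prescriptions = n_transactions(db),
    n_herbs = length(db$items),
    total_occurrences = sum(db$incidence),
    n_skipped_names = nrow(skip_log),
    skipped_names = skip_log$raw_name,
    n_frequent_itemsets = nrow(itemsets),
    n_rules = nrow(rules),
    n_high_frequency_herbs = length(high_freq),
    n_graph_edges = nrow(graph$edges),
    n_backbone_edges = sum(backbone$edges$retained),
    n_core_herbs = nrow(core$nodes)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(
    db = db, frequency = freq, profiles = profiles, itemsets = itemsets,
    rules = rules, dendrogram = dendro, clusters = clusters, graph = graph,
    backbone = backbone, core = core, manifest = manifest
  ))
}
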