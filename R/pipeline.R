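#' Run the full screening analysis pipeline
#'
#' Orchestrates the analysis stages over a genotype-mean table (and,
#' optionally, a marker score matrix): panel scoring, group summaries,
#' correlation, PCA, Gower + Ward.D2 clustering with cluster profiles, and
#' marker diversity/association. All outputs are plain text (CSV, JSON,
#' Newick) and deterministic given the configuration and seed; a run log
#' records the package version, the echoed configuration and its hash.
#'
#' @param config A named list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{means}{Path to a genotype-mean table; omit to use the packaged
#'       panel ([agt_panel()]).}
#'     \item{markers}{Optional path to a marker score matrix.}
#'     \item{traits}{Trait subset for the multivariate stages; the string
#'       \code{"ag_traits"} selects the anaerobic-germination preset
#'       (default \code{"all"}).}
#'     \item{groupings}{Character vector of grouping columns for the SNK
#'       summaries (default \code{c("tolerance_class", "grain_type_rule")}).}
#'     \item{k}{Cluster count for the phenotypic dendrogram (default 6).}
#'     \item{k_markers}{Cluster count for the marker dendrogram (default 4).}
#'     \item{alpha}{Significance level (default 0.05).}
#'     \item{ga_basis}{GA variant, see [variability_parameters()].}
#'     \item{metric}{Marker distance metric (default \code{"nei_li"}).}
#'     \item{seed}{RNG seed recorded in the log (the phenotype stages are
#'       deterministic; the seed guards any future stochastic stage).}
#'     \item{out}{Output directory (required).}
#'   }
#' @return Invisibly, a list of the in-memory stage results; files are
#'   written under \code{config$out}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(means = NULL, markers = NULL, traits = "all",
                   groupings = c("tolerance_class", "grain_type_rule"),
                   k = 6L, k_markers = 4L, alpha = 0.05,
                   ga_basis = "genotypic", metric = "nei_li", seed = 1L,
                   out = NULL)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$out)) stop("config$out (output directory) is required")
  if (!(config$alpha > 0 && config$alpha < 1)) stop("alpha must be in (0,1)")
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  results <- list()

  records <- stage("read_means", {
    if (is.null(config$means)) agt_panel()
    else read_genotype_means(config$means)
  })

  scored <- stage("score_panel", score_panel(records))
  results$scored <- scored
  utils::write.csv(as.data.frame(scored),
                   file.path(config$out, "scored.csv"), row.names = FALSE)
  tol_counts <- as.list(attr(scored, "tolerance_counts"))
  jsonlite::write_json(
    list(tolerance_counts = tol_counts,
         grain_type_counts = as.list(attr(scored, "grain_type_counts"))),
    file.path(config$out, "class_counts.json"), auto_unbox = TRUE)

  traits <- if (identical(config$traits, "all")) {
    intersect(trait_codes(), names(records))
  } else if (identical(config$traits, "ag_traits")) {
    ag_traits()
  } else config$traits

  for (by in config$groupings) {
    if (!by %in% names(scored)) next
    gs <- stage(paste0("group_summary_", by),
                group_summary(scored, by = by, alpha = config$alpha))
    results[[paste0("groups_", by)]] <- gs
    utils::write.csv(as.data.frame(gs),
                     file.path(config$out, paste0("groups_", by, ".csv")),
                     row.names = FALSE)
  }

  cc <- stage("correlation", correlation_matrix(records, traits))
  results$correlation <- cc
  utils::write.csv(cc$r, file.path(config$out, "correlation_r.csv"))
  utils::write.csv(cc$p, file.path(config$out, "correlation_p.csv"))

  pca <- stage("pca", trait_pca(records, traits))
  results$pca <- pca
  utils::write.csv(
    data.frame(component = seq_along(pca$eigenvalues),
               eigenvalue = pca$eigenvalues,
               variance_pct = pca$variance_pct,
               cumulative_pct = pca$cumulative_pct),
    file.path(config$out, "pca_eigenvalues.csv"), row.names = FALSE)
  utils::write.csv(pca$cos2, file.path(config$out, "pca_cos2.csv"))

  dist_ph <- stage("gower", gower_distance(records, traits))
  clust <- stage("cluster", ward_d2_cluster(dist_ph, k = config$k))
  results$clusters <- clust
  utils::write.csv(
    data.frame(genotype = names(clust$assignments),
               cluster = clust$assignments),
    file.path(config$out, "clusters.csv"), row.names = FALSE)
  cluster_newick(clust, file.path(config$out, "dendrogram_phenotype.nwk"))
  prof <- stage("cluster_profile",
                cluster_profile(clust$assignments, scored, traits = traits,
                                distances = dist_ph,
                                alpha = config$alpha))
  results$cluster_profile <- prof
  utils::write.csv(as.data.frame(prof$summary),
                   file.path(config$out, "cluster_profile.csv"),
                   row.names = FALSE)

  if (!is.null(config$markers)) {
    if (!file.exists(config$markers)) {
      stop(sprintf(
        "pipeline stage 'markers' failed: marker file not found: %s",
        config$markers), call. = FALSE)
    }
    mk <- stage("markers", read_marker_scores(config$markers))
    stats_tab <- stage("allele_stats", allele_stats(mk))
    results$allele_stats <- stats_tab
    utils::write.csv(as.data.frame(stats_tab),
                     file.path(config$out, "marker_allele_stats.csv"),
                     row.names = FALSE)
    dmk <- stage("marker_distance", genetic_distance(mk, config$metric))
    mclust <- stage("marker_cluster",
                    ward_d2_cluster(dmk, k = config$k_markers))
    results$marker_clusters <- mclust
    cluster_newick(mclust, file.path(config$out, "dendrogram_markers.nwk"))
    mta <- stage("single_marker_analysis",
                 single_marker_analysis(mk, records, alpha = config$alpha))
    results$mta <- mta
    utils::write.csv(as.data.frame(mta),
                     file.path(config$out, "marker_trait_association.csv"),
                     row.names = FALSE)
  }

  log <- list(
    package = "agtscreen",
    version = as.character(utils::packageVersion("agtscreen")),
    config = config[!vapply(config, is.null, TRUE)],
    config_hash = config_hash(config),
    n_genotypes = nrow(records)
  )
  jsonlite::write_json(log, file.path(config$out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

# internal: stable md5 of the canonicalized (sorted, JSON-serialized) config
config_hash <- function(config) {
  config <- config[!vapply(config, is.null, TRUE)]
  config <- config[order(names(config))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
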