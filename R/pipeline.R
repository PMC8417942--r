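#' Pipeline configuration
#'
#' Collects every tunable of the stratification pipeline with the final
#' production defaults: country filter at 20 samples, Mapper resolution 85
#' and overlap 0.85, DBSCAN eps at the 0.95 nearest-neighbour quantile with
#' minimum neighbourhood 5, SAFE with 5,000 permutations and neighbourhoods
#' at the 0.5th percentile of node distances, node significance alpha 0.05,
#' and co-enrichment binarization at the 0.5th percentile.
#'
#' @param abundance_path,metadata_path Input files ([load_abundance()] /
#'   [load_metadata()] layouts), or `NULL` when `synthetic` is given.
#' @param synthetic Optional [synthetic_spec()] used instead of input files.
#' @param out_dir Output directory (created if absent).
#' @param min_country_n,resolution,overlap,eps_threshold,min_samples,
#'   n_permutations,neighborhood_percentile,node_alpha,
#'   coenrichment_percentile Stage parameters; see the stage functions.
#' @param seed Single global seed; stage seeds are derived from it and
#'   recorded in the run manifest.
#' @param variables Metadata variables to dummy code.
#' @param taxa Taxon identifiers to test for enrichment; `NULL` = all,
#'   an integer = the that-many most abundant taxa.
#' @param write_distance Write the (possibly large) distance matrix.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(abundance_path = NULL, metadata_path = NULL,
                            synthetic = NULL, out_dir = tempfile("topostrat_"),
                            min_country_n = 20L, resolution = 85L,
                            overlap = 0.85, eps_threshold = 0.95,
                            min_samples = 5L, n_permutations = 5000L,
                            neighborhood_percentile = 0.5, node_alpha = 0.05,
                            coenrichment_percentile = 0.5, seed = 1L,
                            variables = c("country", "sex", "bmi_category"),
                            taxa = NULL, write_distance = FALSE) {
  stopifnot(min_country_n >= 1, resolution >= 1, overlap >= 0, overlap < 1,
            eps_threshold > 0, eps_threshold <= 1, min_samples >= 1,
            n_permutations >= 1, neighborhood_percentile > 0,
            neighborhood_percentile <= 100, node_alpha > 0, node_alpha < 1,
            coenrichment_percentile > 0, coenrichment_percentile <= 100)
  if (is.null(synthetic) && (is.null(abundance_path) || is.null(metadata_path)))
    stop("either input paths or a synthetic spec must be given")
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seeds <- function(seed) {
  list(mds = (seed * 2L + 101L) %% .Machine$integer.max,
       safe = (seed * 3L + 211L) %% .Machine$integer.max)
}

#' Run the full topological stratification pipeline
#'
#' Stages, in order: load (or generate) inputs, filter small countries,
#' total-sum normalize, Bray-Curtis distances, 2-D MDS lens, H0 persistence
#' diagram, Mapper network (cover, DBSCAN, nerve), SAFE enrichment of
#' dummy-coded metadata, age and taxa, variable ranking, pairwise
#' co-enrichment with percentile binarization, and per-node stratification.
#' All tables, the GraphML network, membership JSON and a JSON run manifest
#' (parameters, derived seeds, sample accounting, network statistics) are
#' written to `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all intermediate objects: `metadata`,
#'   `abundance`, `distances`, `lens`, `diagram`, `network`, `safe`
#'   (list of `safe_result`), `ranking`, `coenrichment`, `stratification`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- stage_seeds(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (!is.null(config$synthetic)) {
    ds <- stage("simulate", generate_dataset(config$synthetic))
    abundance <- ds$abundance
    metadata <- ds$metadata
  } else {
    abundance <- stage("load_abundance", load_abundance(config$abundance_path))
    metadata <- stage("load_metadata", load_metadata(config$metadata_path))
  }
  missing_meta <- setdiff(rownames(abundance), metadata$sample_id)
  if (length(missing_meta))
    stop("pipeline stage 'align' failed: sample(s) without metadata: ",
         paste(utils::head(missing_meta, 5L), collapse = ", "))

  metadata <- stage("filter_countries",
                    filter_countries(metadata, config$min_country_n))
  abundance <- abundance[metadata$sample_id, , drop = FALSE]
  n_input <- nrow(abundance)

  summary_tab <- cohort_summary(metadata)
  write_cohort_summary(summary_tab, file.path(config$out_dir, "cohort_summary.tsv"))

  abundance <- stage("normalize", normalize_relative(abundance))
  D <- stage("distances", pairwise_distances(abundance))
  if (isTRUE(config$write_distance))
    write_distance_matrix(D, file.path(config$out_dir, "distances.tsv"))

  lens <- stage("lens", mds_lens(D, seed = seeds$mds))
  diagram <- stage("persistence", h0_persistence(D))
  write_h0_diagram(diagram, file.path(config$out_dir, "h0_diagram.tsv"))

  network <- stage("mapper", build_mapper(
    D, lens, resolution = config$resolution, overlap = config$overlap,
    eps_threshold = config$eps_threshold, min_samples = config$min_samples))
  if (!length(network$nodes))
    stop("pipeline stage 'mapper' failed: no clusters survive; ",
         "lower min_samples or resolution")
  write_network(network, file.path(config$out_dir, "network.graphml"),
                file.path(config$out_dir, "node_membership.json"))

  dummies <- stage("dummy_code", dummy_code(metadata, config$variables))
  taxa_ids <- colnames(abundance)
  if (!is.null(config$taxa)) {
    taxa_ids <- if (is.numeric(config$taxa))
      names(sort(colMeans(abundance), decreasing = TRUE))[seq_len(min(config$taxa, ncol(abundance)))]
    else config$taxa
  }
  age <- matrix(metadata$age, ncol = 1L,
                dimnames = list(metadata$sample_id, "age"))
  vars_mat <- cbind(dummies, age, abundance[, taxa_ids, drop = FALSE])

  safe_res <- stage("safe", safe_analysis(
    network, vars_mat, n_permutations = config$n_permutations,
    alpha = config$node_alpha, percentile = config$neighborhood_percentile,
    seed = seeds$safe))
  write_safe_results(safe_res, file.path(config$out_dir, "safe_nodes.tsv"),
                     file.path(config$out_dir, "safe_ranking.tsv"))
  ranking <- rank_variables(safe_res)

  p_mat <- stage("coenrichment",
                 coenrichment_matrix(safe_res, length(network$nodes)))
  coe <- threshold_binarize(p_mat, config$coenrichment_percentile)
  strat <- stratify_nodes(safe_res)
  write_coenrichment(coe, file.path(config$out_dir, "coenrichment_p.tsv"),
                     file.path(config$out_dir, "coenrichment_binary.tsv"),
                     strat, file.path(config$out_dir, "stratification.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("topostrat")),
    seed = config$seed, stage_seeds = seeds,
    parameters = list(min_country_n = config$min_country_n,
                      resolution = config$resolution, overlap = config$overlap,
                      eps_threshold = config$eps_threshold,
                      eps = network$params$eps,
                      min_samples = config$min_samples,
                      n_permutations = config$n_permutations,
                      neighborhood_percentile = config$neighborhood_percentile,
                      node_alpha = config$node_alpha,
                      coenrichment_percentile = config$coenrichment_percentile),
    samples = list(input = n_input,
                   retained = network$params$n_retained,
                   dropped = network$params$n_dropped,
                   cover_ratio = cover_ratio(network, n_input)),
    network = list(nodes = length(network$nodes), edges = nrow(network$edges),
                   components = igraph::components(network$graph)$no),
    mds_stress = lens$stress
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(metadata = metadata, abundance = abundance, distances = D,
                 lens = lens, diagram = diagram, network = network,
                 safe = safe_res, ranking = ranking, coenrichment = coe,
                 stratification = strat, manifest = manifest))
}

#' Sweep Mapper resolution and overlap
#'
#' Rebuilds the Mapper network over a grid of (resolution, overlap) settings
#' on fixed distances and lens, reporting cover ratio, node count, edge
#' count and connected-component count per setting — the tabular analogue of
#' tuning the network by hand against the persistence diagram.
#'
#' @param D Distance matrix.
#' @param lens An `mds_lens` over the same samples.
#' @param resolutions,overlaps Non-empty numeric grids.
#' @param eps_threshold,min_samples Passed to [build_mapper()].
#' @return data.frame: resolution, overlap, cover_ratio, n_nodes, n_edges,
#'   n_components.
#' @export
parameter_sweep <- function(D, lens, resolutions, overlaps,
                            eps_threshold = 0.95, min_samples = 5L) {
  stopifnot(length(resolutions) >= 1, length(overlaps) >= 1)
  grid <- expand.grid(resolution = resolutions, overlap = overlaps,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    net <- build_mapper(D, lens, resolution = grid$resolution[i],
                        overlap = grid$overlap[i],
                        eps_threshold = eps_threshold,
                        min_samples = min_samples)
    data.frame(resolution = grid$resolution[i], overlap = grid$overlap[i],
               cover_ratio = cover_ratio(net, nrow(lens$coords)),
               n_nodes = length(net$nodes), n_edges = nrow(net$edges),
               n_components = if (length(net$nodes))
                 igraph::components(net$graph)$no else 0L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
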