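#' Pipeline configuration
#'
#' A single configuration object drives the three pipeline stages
#' ([run_simulate()], [run_merge()], [run_analyze()]). Defaults mirror the
#' reference workflow: arcsinh cofactor 5, backbone distance threshold 3,
#' 5% density-dependent downsampling after a 67,000-cell pre-downsample,
#' 500 clusters, 5th/95th-percentile ranges cut into 5 categories, a
#' 50-cell unassigned rule, and a 4-fold enrichment threshold. The
#' `n_events`, `pre_downsample_n` and `k` fields are the knobs to scale a
#' run to desk size.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed; every stochastic step derives from it.
#' @param n_events simulated events per individual.
#' @param backbone_noise_sd simulated tube-to-tube backbone noise SD.
#' @param cofactor arcsinh cofactor.
#' @param backbone_threshold matching distance threshold.
#' @param k number of clusters.
#' @param downsample_fraction density-dependent downsampling fraction.
#' @param pre_downsample_n per-sample uniform pre-downsample size.
#' @param range_probs the two percentile probabilities for marker ranges.
#' @param n_categories number of expression categories.
#' @param min_cells unassigned-cluster threshold.
#' @param fc_threshold enrichment-trend fold-change threshold.
#' @param pseudocount ETC pseudocount (cells).
#' @param max_permutations permutation-test cap.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "results", seed = 1,
                            n_events = 5000, backbone_noise_sd = 0.05,
                            cofactor = 5, backbone_threshold = 3,
                            k = 500, downsample_fraction = 0.05,
                            pre_downsample_n = 67000,
                            range_probs = c(0.05, 0.95), n_categories = 5,
                            min_cells = 50, fc_threshold = 4,
                            pseudocount = 1, max_permutations = 10000) {
  structure(
    list(out_dir = out_dir, seed = seed, n_events = n_events,
         backbone_noise_sd = backbone_noise_sd, cofactor = cofactor,
         backbone_threshold = backbone_threshold, k = k,
         downsample_fraction = downsample_fraction,
         pre_downsample_n = pre_downsample_n, range_probs = range_probs,
         n_categories = n_categories, min_cells = min_cells,
         fc_threshold = fc_threshold, pseudocount = pseudocount,
         max_permutations = max_permutations),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration
#'
#' Configurations serialize to YAML so a run is reproducible from a single
#' human-readable file.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

sanitize_panel <- function(x) gsub("[^A-Za-z0-9_.-]", "", x)

write_manifest <- function(config, dir, stage) {
  manifest <- list(stage = stage, seed = config$seed,
                   package = "cytofuse",
                   version = as.character(utils::packageVersion("cytofuse")),
                   config = unclass(config))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
}

#' Simulate the preset cohort to disk
#'
#' Generates the preset two-condition, three-panel cohort and writes one
#' TSV profile per individual and panel under `<out_dir>/cohort/`, together
#' with per-individual ground truth (`*_truth.tsv`: event id and
#' population, in each tube's row order) and a manifest echoing the
#' configuration and seed. Outputs are byte-identical across runs with the
#' same configuration.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the `cohort_spec` and the simulated
#'   cohort (as returned by [simulate_cohort()]).
#' @export
run_simulate <- function(config) {
  dir <- file.path(config$out_dir, "cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- make_hiv_cohort_preset(seed = config$seed,
                                 n_events = config$n_events,
                                 backbone_noise_sd = config$backbone_noise_sd)
  cohort <- simulate_cohort(spec)
  for (id in names(cohort)) {
    for (panel in names(cohort[[id]]$panels)) {
      prof <- cohort[[id]]$panels[[panel]]
      base <- paste0(id, "_", sanitize_panel(panel))
      write_profile(prof, file.path(dir, paste0(base, ".tsv")), "tsv")
      utils::write.table(
        data.frame(event_id = prof$event_ids,
                   population = cohort[[id]]$truth$population[
                     match(prof$event_ids, cohort[[id]]$truth$event_id)]),
        file.path(dir, paste0(base, "_truth.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  utils::write.table(
    data.frame(individual = names(spec$individuals),
               condition = unname(spec$individuals)),
    file.path(dir, "individuals.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_manifest(config, dir, "simulate")
  invisible(list(spec = spec, cohort = cohort))
}

#' Merge every individual's panel tubes
#'
#' Runs backbone matching and merging for each individual of a simulated
#' cohort and writes the merged profiles plus a combined accounting report
#' (per-panel cell counts, merged cells, excluded cells) under
#' `<out_dir>/merged/`.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional in-memory cohort from [run_simulate()]; when
#'   omitted, profiles are re-read from `<out_dir>/cohort/`.
#' @return invisibly, a named list of `merge_result` objects.
#' @export
run_merge <- function(config, cohort = NULL) {
  cdir <- file.path(config$out_dir, "cohort")
  mdir <- file.path(config$out_dir, "merged")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  spec <- make_hiv_cohort_preset(seed = config$seed,
                                 n_events = config$n_events,
                                 backbone_noise_sd = config$backbone_noise_sd)
  bb <- backbone_spec(spec$panels[[1]]$backbone,
                      threshold = config$backbone_threshold)
  panel_ids <- vapply(spec$panels, `[[`, character(1), "panel_id")
  results <- list()
  report_rows <- list()
  for (id in names(spec$individuals)) {
    tubes <- if (!is.null(cohort)) {
      cohort[[id]]$panels
    } else {
      stats::setNames(lapply(panel_ids, function(panel) {
        read_profile(file.path(cdir, paste0(id, "_", sanitize_panel(panel),
                                            ".tsv")),
                     "tsv", sample_id = id, panel_id = panel)
      }), panel_ids)
    }
    # simulated tubes are already in arcsinh units; only flag them as such
    for (panel in panel_ids) tubes[[panel]]$transformed <- TRUE
    res <- merge_panelset(tubes, bb, order = panel_ids)
    results[[id]] <- res
    write_profile(res$merged, file.path(mdir, paste0(id, "_merged.tsv")),
                  "tsv")
    rep <- merge_report(res)
    rep$individual <- id
    report_rows[[id]] <- rep
  }
  report <- do.call(rbind, report_rows)
  utils::write.table(report, file.path(mdir, "merge_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, mdir, "merge")
  invisible(results)
}

#' Cluster, phenotype and compare the merged cohort
#'
#' The downstream half of the pipeline: per-individual pre-downsampling,
#' density estimation and density-dependent downsampling; pooled
#' agglomerative clustering into `k` clusters on all markers; full
#' upsampling; per-cluster statistics; categorical heatmap with dendrogram
#' orders and rule-based population labels; enrichment-trend
#' classification; and permutation tests of monocyte marker MSIs between
#' conditions. Tables are written under `<out_dir>/analysis/`.
#'
#' @param config a [pipeline_config()].
#' @param merged optional named list of merged profiles (or of
#'   `merge_result` objects); when omitted, merged profiles are re-read
#'   from `<out_dir>/merged/`.
#' @param msi_markers markers to test on monocytes (default: the activation
#'   markers the preset shifts).
#' @return invisibly, a list with `stats`, `heatmap`, `orders`,
#'   `populations`, `etc`, `msi_tests`, `assignments`, `model`.
#' @export
run_analyze <- function(config, merged = NULL,
                        msi_markers = c("CD11a", "CD11b", "CD32", "CD38",
                                        "CD64", "CD83", "CD86", "TLR2")) {
  mdir <- file.path(config$out_dir, "merged")
  adir <- file.path(config$out_dir, "analysis")
  dir.create(adir, recursive = TRUE, showWarnings = FALSE)
  spec <- make_hiv_cohort_preset(seed = config$seed,
                                 n_events = config$n_events,
                                 backbone_noise_sd = config$backbone_noise_sd)
  ids <- names(spec$individuals)
  conditions <- spec$individuals
  if (is.null(merged)) {
    merged <- stats::setNames(lapply(ids, function(id) {
      read_profile(file.path(mdir, paste0(id, "_merged.tsv")), "tsv",
                   sample_id = id, panel_id = "merged")
    }), ids)
  } else {
    merged <- lapply(merged, function(x) {
      if (inherits(x, "merge_result")) x$merged else x
    })
  }
  markers <- profile_markers(merged[[1]])
  cspec <- clustering_spec(markers, k = config$k,
                           downsample_fraction = config$downsample_fraction,
                           pre_downsample_n = config$pre_downsample_n,
                           seed = config$seed)

  pooled <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    prof <- merged[[id]]
    n_pre <- min(cspec$pre_downsample_n, n_events(prof))
    prof <- pre_downsample(prof, n_pre, seed = config$seed + i)
    dens <- estimate_local_density(prof, markers, seed = config$seed + i)
    keep <- density_dependent_downsample(prof, dens, cspec,
                                         seed = config$seed + 100 + i)
    pooled[[id]] <- prof$exprs[keep, , drop = FALSE]
  }
  model <- fit_clusters(do.call(rbind, pooled), cspec)
  assignments <- upsample_assign(model, merged)
  stats_obj <- compute_cluster_stats(assignments, merged, markers,
                                     k = model$k)
  ranges <- compute_marker_ranges(merged, markers,
                                  probs = config$range_probs)
  heatmap <- build_heatmap(stats_obj, ranges, min_cells = config$min_cells,
                           n_categories = config$n_categories)
  orders <- order_heatmap(heatmap, spec$panels[[1]]$backbone)
  populations <- annotate_populations(heatmap)
  etc <- classify_etc(stats_obj$counts, conditions,
                      fc_threshold = config$fc_threshold,
                      pseudocount = config$pseudocount,
                      min_cells = config$min_cells)
  mono_clusters <- which(populations == "monocyte")
  masks <- lapply(assignments, function(a) a %in% mono_clusters)
  msi_tests <- if (length(mono_clusters)) {
    # degenerate small runs can leave one condition without monocytes;
    # the MSI table is then simply omitted
    tryCatch(
      compare_population_msi(merged, masks,
                             intersect(msi_markers, markers), conditions,
                             max_permutations = config$max_permutations,
                             seed = config$seed),
      error = function(e) {
        warning("monocyte MSI comparison skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  } else {
    NULL
  }

  utils::write.csv(
    cbind(data.frame(cluster = seq_len(model$k), population = populations,
                     n_cells = stats_obj$total),
          as.data.frame(heatmap$categories)),
    file.path(adir, "categorical_heatmap.csv"), row.names = FALSE,
    na = "NA")
  utils::write.table(as.data.frame(stats_obj$counts),
                     file.path(adir, "cluster_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(etc, file.path(adir, "etc_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(msi_tests)) {
    utils::write.table(msi_tests, file.path(adir, "monocyte_msi_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(config, adir, "analyze")
  invisible(list(stats = stats_obj, heatmap = heatmap, orders = orders,
                 populations = populations, etc = etc,
                 msi_tests = msi_tests, assignments = assignments,
                 model = model))
}

#' Published cell-count accounting for the six-donor multi-tube study
#'
#' The per-panel and merged cell counts reported for the six whole-blood
#' donors (three healthy, three treated-HIV) of the 72-marker multi-tube
#' mass cytometry study, as shipped in `inst/extdata`. These printed counts
#' are inputs for accounting checks (the excluded-cell identity, per-group
#' means, and merge efficiency); they are not recomputable without the
#' deposited instrument data.
#'
#' @return data.frame with columns `individual`, `condition`, `n_a`,
#'   `n_b`, `n_c` (cells per panel) and `n_merged`.
#' @export
published_merge_counts <- function() {
  path <- system.file("extdata", "published_merge_counts.tsv",
                      package = "cytofuse", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
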