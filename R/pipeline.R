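#' Assemble a pipeline configuration
#'
#' @param input `"simulate"` (default) or a path to a survey CSV.
#' @param design A [design_spec()].
#' @param params A `sim_params` (used only in simulate mode).
#' @param alpha Test level used throughout.
#' @param effect_sizes Ordered minimum-effects boundaries.
#' @param min_prevalence Rare-group exclusion threshold.
#' @param n_perm NPMANOVA / pairwise permutations.
#' @param nmds_k,nmds_starts NMDS dimension and random starts.
#' @param thresholds Biomass cutoffs (g/m2).
#' @param seed Master seed; each stage derives its own stream from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = "simulate",
                            design = design_spec(),
                            params = default_sim_params(),
                            alpha = 0.05,
                            effect_sizes = default_effect_sizes(),
                            min_prevalence = 0.05,
                            n_perm = 9999,
                            nmds_k = 2, nmds_starts = 20,
                            thresholds = c(60, 100, 200),
                            seed = 1L) {
  structure(list(input = input, design = design, params = params,
                 alpha = alpha, effect_sizes = effect_sizes,
                 min_prevalence = min_prevalence, n_perm = n_perm,
                 nmds_k = nmds_k, nmds_starts = nmds_starts,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Derive a stage seed from the master seed
#'
#' Deterministic per-stage streams: adding stages never shifts existing
#' ones. Kept below 2^31.
#'
#' @param master Master integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) %% 65536 * 32749 + h * 7919) %% 2147483647)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> per-taxon mixed ANCOVA with minimum-effects
#' marks -> community analysis (Bray-Curtis, NMDS, NPMANOVA, Holm
#' pairwise) -> biomass summaries. All stage outputs are written as CSV
#' under `out_dir` together with a JSON run manifest (seeds, row counts,
#' settings) sufficient to reproduce the run. Identical configurations
#' produce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE,
                     fileEncoding = "UTF-8")
  }

  # -- data -----------------------------------------------------------
  tab <- stage("data", {
    if (identical(config$input, "simulate")) {
      d <- make_design(config$design, seed = stage_seed(config$seed, "design"))
      simulate_biomass(d, config$params,
                       seed = stage_seed(config$seed, "simulate"))
    } else {
      validate_survey_csv(config$input)
    }
  })
  write_survey_csv(tab, file.path(out_dir, "survey.csv"))

  # -- ANCOVA + minimum effects --------------------------------------
  report <- stage("ancova", {
    tab2 <- add_total_prey(tab)
    taxa <- c(setdiff(unique(tab$taxon_group), "Other"), "Total prey")
    fits <- lapply(taxa, function(g) fit_mixed_ancova(tab2, g))
    ancova_report(fits, config$effect_sizes, config$alpha)
  })
  wcsv(report, "ancova_report.csv")
  wcsv(format_ancova_report(report), "ancova_pvalues_wide.csv")

  # -- community ------------------------------------------------------
  community <- stage("community", {
    M <- build_community_matrix(tab, config$min_prevalence)
    D <- bray_curtis(M)
    ord <- nmds(D, k = config$nmds_k, n_starts = config$nmds_starts,
                seed = stage_seed(config$seed, "nmds"))
    cen <- centroids_ci(ord, interaction(M$meta$period, M$meta$zone,
                                         sep = "-"))
    np <- npmanova(M, n_perm = config$n_perm,
                   seed = stage_seed(config$seed, "npmanova"))
    pw <- pairwise_permutation(M, n_perm = config$n_perm,
                               seed = stage_seed(config$seed, "pairwise"),
                               alpha = config$alpha)
    list(matrix = M, dissimilarity = D, ordination = ord,
         centroids = cen, npmanova = np, pairwise = pw)
  })
  utils::write.csv(as.data.frame(unclass(community$dissimilarity)),
                   file.path(out_dir, "bray_curtis.csv"),
                   fileEncoding = "UTF-8")
  ordcsv <- data.frame(unit = rownames(community$ordination$points),
                       community$ordination$points,
                       stress = community$ordination$stress)
  wcsv(ordcsv, "nmds_coordinates.csv")
  wcsv(community$centroids, "nmds_centroids.csv")
  wcsv(community$npmanova$aov_table, "npmanova.csv")
  wcsv(community$pairwise, "npmanova_pairwise.csv")

  # -- summaries ------------------------------------------------------
  summaries <- stage("summaries", {
    tab2 <- add_total_prey(tab)
    cis <- do.call(rbind, lapply(
      c(setdiff(unique(tab$taxon_group), "Other"), "Total prey"),
      function(g) cbind(taxon_group = g, group_summary_ci(tab2, g))))
    list(cutoffs = cutoff_percentages(tab, thresholds = config$thresholds),
         ranking = rank_dominants(tab),
         summary_ci = cis)
  })
  wcsv(summaries$cutoffs, "amphipod_cutoffs.csv")
  wcsv(summaries$ranking, "dominance_ranking.csv")
  wcsv(summaries$summary_ci, "biomass_summary_ci.csv")

  manifest <- list(
    package = "benthme",
    version = as.character(utils::packageVersion("benthme")),
    master_seed = config$seed,
    stage_seeds = list(design = stage_seed(config$seed, "design"),
                       simulate = stage_seed(config$seed, "simulate"),
                       nmds = stage_seed(config$seed, "nmds"),
                       npmanova = stage_seed(config$seed, "npmanova"),
                       pairwise = stage_seed(config$seed, "pairwise")),
    input = config$input,
    alpha = config$alpha,
    min_prevalence = config$min_prevalence,
    n_perm = config$n_perm,
    nmds = list(k = config$nmds_k, n_starts = config$nmds_starts),
    thresholds = config$thresholds,
    effect_sizes = lapply(config$effect_sizes, function(s)
      list(label = s$label, f = s$f)),
    n_rows = nrow(tab),
    n_stations = length(unique(tab$station_id)),
    nmds_stress = community$ordination$stress,
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(table = tab, ancova = report, community = community,
                 summaries = summaries, manifest = manifest))
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips the scalar settings plus the design specification;
#' simulator parameters are re-derived with [default_sim_params()]
#' unless a calibration target table is embedded.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config`: the path, invisibly. `read_config`: a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$design
  out <- list(
    input = config$input,
    alpha = config$alpha,
    min_prevalence = config$min_prevalence,
    n_perm = config$n_perm,
    nmds = list(k = config$nmds_k, n_starts = config$nmds_starts),
    thresholds = as.numeric(config$thresholds),
    seed = config$seed,
    effect_sizes = lapply(unname(config$effect_sizes), function(s)
      list(label = s$label, f = s$f)),
    design = list(
      zones = spec$zones, periods = spec$periods,
      line_depths = as.list(spec$line_depths),
      planned_stations_per_line = spec$planned_stations_per_line,
      station_spacing_km = spec$station_spacing_km,
      zone_stations_per_line = as.list(spec$zone_stations_per_line),
      stations_sampled = apply(spec$stations_sampled, 1, as.list,
                               simplify = FALSE),
      replicates_per_grid_station = spec$replicates_per_grid_station,
      hotspots_per_zone = as.list(spec$hotspots_per_zone),
      grabs_per_hotspot = spec$grabs_per_hotspot))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  ss <- do.call(rbind, lapply(y$design$stations_sampled, unlist))
  rownames(ss) <- y$design$periods
  spec <- design_spec(
    zones = y$design$zones,
    periods = unlist(y$design$periods),
    line_depths = unlist(y$design$line_depths),
    planned_stations_per_line = y$design$planned_stations_per_line,
    station_spacing_km = y$design$station_spacing_km,
    zone_stations_per_line = unlist(y$design$zone_stations_per_line),
    stations_sampled = ss,
    replicates_per_grid_station = y$design$replicates_per_grid_station,
    hotspots_per_zone = unlist(y$design$hotspots_per_zone),
    grabs_per_hotspot = y$design$grabs_per_hotspot)
  specs <- lapply(y$effect_sizes, function(s) effect_size_spec(s$label, s$f))
  names(specs) <- vapply(specs, `[[`, "", "label")
  pipeline_config(input = y$input, design = spec,
                  alpha = y$alpha, effect_sizes = specs,
                  min_prevalence = y$min_prevalence, n_perm = y$n_perm,
                  nmds_k = y$nmds$k, nmds_starts = y$nmds$n_starts,
                  thresholds = unlist(y$thresholds), seed = y$seed)
}
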