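# Truncated-normal draws by rejection (bounds are ~4+ SDs out for the
# default jitter, so the loop rarely iterates).
.rtrunc_norm <- function(mean, sd, lo, hi) {
  x <- stats::rnorm(length(mean), mean, sd)
  repeat {
    bad <- which(x < lo | x > hi)
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd)
  }
  x
}

#' Simulate a benthic survey table
#'
#' Draws one realization of the survey under the hurdle / shifted
#' lognormal model described in [sim_params()]: station depths are
#' jittered about the nominal isobath depth (truncated to the design's
#' depth range), sediment class is assigned by line, each station carries
#' one random effect per group (shared across periods and, for hotspots,
#' across all 12 grabs), and each grab is either an exact zero (with the
#' group's zero-inflation probability) or a lognormal-shifted biomass.
#'
#' Identical `(design, params, seed)` give a byte-identical table.
#'
#' @param design A `survey_design` from [make_design()].
#' @param params A `sim_params`.
#' @param seed Integer seed.
#' @param hotspot_period Period label attached to hotspot rows (hotspots
#'   were sampled between the first two periods; their cell means are
#'   taken from this period). Default 2.
#' @return Data frame (class `survey_table`) with columns `station_id`,
#'   `zone`, `period`, `design`, `line`, `depth_m`, `sediment`,
#'   `replicate_index`, `taxon_group`, `biomass_wet_g_per_m2`.
#' @export
#' @examples
#' d <- make_design(design_spec())
#' tab <- simulate_biomass(d, default_sim_params(), seed = 42)
#' head(tab)
simulate_biomass <- function(design, params, seed = 1L,
                             hotspot_period = 2L) {
  stopifnot(inherits(design, "survey_design"), inherits(params, "sim_params"))
  if (!all(design$spec$zones %in% params$zones) ||
      !all(design$spec$periods %in% params$periods)) {
    stop("`params` does not cover the design's zones/periods", call. = FALSE)
  }
  set.seed(as.integer(seed))
  groups <- params$groups
  ng <- length(groups)
  st <- design$stations
  nst <- nrow(st)

  # station-level structure: depth, sediment, per-group random effects
  st$depth_m <- .rtrunc_norm(st$nominal_depth_m + 0 * seq_len(nst),
                             params$depth_jitter_sd,
                             params$depth_range[1], params$depth_range[2])
  pmed <- params$sediment_prob_medium[st$line]
  st$sediment <- ifelse(stats::runif(nst) < pmed, "medium", "fine")
  b_grid <- matrix(stats::rnorm(nst * ng, 0,
                                rep(params$sigma_station, each = nst)),
                   nst, ng, dimnames = list(st$station_id, groups))

  hs <- design$hotspots
  b_hot <- NULL
  if (!is.null(hs) && nrow(hs)) {
    b_hot <- matrix(stats::rnorm(nrow(hs) * ng, 0,
                                 rep(params$sigma_station, each = nrow(hs))),
                    nrow(hs), ng, dimnames = list(hs$station_id, groups))
  }

  draw_rows <- function(grabs, b, period, design_label) {
    # grabs: one row per grab with station_id, zone, line, depth_m,
    # sediment, replicate_index; expand by group and draw biomass
    n <- nrow(grabs)
    idx <- rep(seq_len(n), times = ng)
    gidx <- rep(seq_len(ng), each = n)
    z <- (grabs$depth_m[idx] - params$depth_center) / params$depth_scale
    pch <- as.character(period)
    mu <- params$mu_log[cbind(gidx, match(grabs$zone[idx], params$zones),
                              match(pch, as.character(params$periods)))]
    sig <- params$sigma_resid[cbind(gidx,
                                    match(grabs$zone[idx], params$zones),
                                    match(pch, as.character(params$periods)))]
    eta <- mu + params$beta1[gidx] * z + params$beta2[gidx] * z^2 +
      b[cbind(match(grabs$station_id[idx], rownames(b)), gidx)] +
      stats::rnorm(n * ng, 0, sig)
    zero <- stats::runif(n * ng) < params$pi[gidx]
    y <- ifelse(zero, 0, pmax(expm1(eta), 0))
    data.frame(station_id = grabs$station_id[idx],
               zone = grabs$zone[idx],
               period = as.integer(period),
               design = design_label,
               line = grabs$line[idx],
               depth_m = grabs$depth_m[idx],
               sediment = grabs$sediment[idx],
               replicate_index = grabs$replicate_index[idx],
               taxon_group = groups[gidx],
               biomass_wet_g_per_m2 = y)
  }

  out <- list()
  for (p in design$spec$periods) {
    ids <- design$plan$station_id[design$plan$period == p]
    if (!length(ids)) next
    svis <- st[match(ids, st$station_id), ]
    reps <- design$spec$replicates_per_grid_station
    grabs <- svis[rep(seq_len(nrow(svis)), each = reps), ]
    grabs$replicate_index <- rep(seq_len(reps), times = nrow(svis))
    out[[length(out) + 1L]] <- draw_rows(grabs, b_grid, p, "grid")
  }

  if (!is.null(hs) && nrow(hs)) {
    lines <- names(params$line_depths)
    gph <- design$spec$grabs_per_hotspot
    per_line <- ceiling(gph / length(lines))
    hline <- rep(rep(lines, each = per_line)[seq_len(gph)], times = nrow(hs))
    grabs <- data.frame(
      station_id = rep(hs$station_id, each = gph),
      zone = rep(hs$zone, each = gph),
      line = hline,
      replicate_index = rep(seq_len(gph), times = nrow(hs)))
    grabs$depth_m <- .rtrunc_norm(params$line_depths[grabs$line],
                                  params$depth_jitter_sd,
                                  params$depth_range[1],
                                  params$depth_range[2])
    grabs$sediment <- ifelse(
      stats::runif(nrow(grabs)) < params$sediment_prob_medium[grabs$line],
      "medium", "fine")
    out[[length(out) + 1L]] <- draw_rows(grabs, b_hot, hotspot_period,
                                         "hotspot")
  }

  tab <- do.call(rbind, out)
  tab <- tab[order(tab$design, tab$period, tab$station_id,
                   tab$replicate_index,
                   match(tab$taxon_group, groups)), ]
  rownames(tab) <- NULL
  class(tab) <- c("survey_table", "data.frame")
  tab
}

.survey_columns <- c("station_id", "zone", "period", "design", "line",
                     "depth_m", "sediment", "replicate_index",
                     "taxon_group", "biomass_wet_g_per_m2")

#' Write a survey table as CSV
#'
#' UTF-8, comma-separated, header row, "." decimal, fixed column order.
#'
#' @param table A `survey_table` data frame.
#' @param path Output file path.
#' @export
write_survey_csv <- function(table, path) {
  stopifnot(all(.survey_columns %in% names(table)))
  utils::write.csv(table[, .survey_columns], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a survey table
#'
#' Schema check used by [validate_survey_csv()] and the pipeline: column
#' presence, allowed factor levels, non-negative finite biomass, positive
#' depth, and replicate uniqueness within (station, period, design,
#' taxon). Violations are reported with their CSV line numbers (header =
#' line 1).
#'
#' @param table Data frame to check.
#' @param zones,designs,sediments Allowed level sets.
#' @return The table, invisibly, with class `survey_table`; errors list
#'   all violations otherwise.
#' @export
validate_survey <- function(table,
                            zones = c("North", "Middle", "South"),
                            designs = c("grid", "hotspot"),
                            sediments = c("fine", "medium")) {
  missing <- setdiff(.survey_columns, names(table))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  problems <- character()
  note <- function(rows, what) {
    if (length(rows)) {
      problems <<- c(problems, sprintf("line %d: %s", rows + 1L, what))
    }
  }
  note(which(!table$zone %in% zones),
       sprintf("zone not one of {%s}", paste(zones, collapse = ", ")))
  note(which(!table$design %in% designs), "unknown design type")
  note(which(!table$sediment %in% sediments), "unknown sediment class")
  note(which(!is.finite(table$biomass_wet_g_per_m2) |
               table$biomass_wet_g_per_m2 < 0), "biomass must be >= 0")
  note(which(!is.finite(table$depth_m) | table$depth_m <= 0),
       "depth must be > 0")
  key <- paste(table$station_id, table$period, table$design,
               table$taxon_group, table$replicate_index)
  note(which(duplicated(key)), "duplicate replicate_index")
  if (length(problems)) {
    stop("invalid survey table:\n",
         paste(utils::head(problems, 20), collapse = "\n"), call. = FALSE)
  }
  class(table) <- unique(c("survey_table", class(table)))
  invisible(table)
}

#' Read and validate a survey CSV
#'
#' @param path CSV file path (schema of [write_survey_csv()]).
#' @param ... Passed to [validate_survey()] (allowed level sets).
#' @return A validated `survey_table` data frame.
#' @export
validate_survey_csv <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("malformed CSV (", conditionMessage(e), ")",
                             call. = FALSE))
  validate_survey(tab, ...)
}
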