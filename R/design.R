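#' Survey design specification
#'
#' Describes the nearshore detailed-grid design: two station lines along
#' the 9 m and 13 m isobaths with 52 planned stations each at ~2 km
#' spacing, split alongshore into North / Middle / South zones, sampled in
#' three seasonal periods with 3 replicate grabs per station, plus feeding
#' hotspots sampled with 12 grabs each. Defaults reproduce the 2015
#' detailed-grid station counts (Period 1: 22/32/14, Period 2: 42/41/18,
#' Period 3: 21/21/12 for North/Middle/South).
#'
#' Zone sizes per line default to North 21, Middle 21, South 10 stations:
#' the split of 52 that accommodates the largest per-zone sampled counts
#' (42, 41, 18 across the two lines) while keeping stations contiguous
#' alongshore.
#'
#' @param zones Ordered zone labels, north to south.
#' @param periods Integer period labels.
#' @param line_depths Named numeric vector of nominal isobath depths (m).
#' @param planned_stations_per_line Stations planned along each line.
#' @param station_spacing_km Alongshore spacing between stations (km).
#' @param zone_stations_per_line Named integer vector partitioning each
#'   line's stations among the zones (must sum to
#'   `planned_stations_per_line`).
#' @param stations_sampled Matrix `periods x zones` of stations actually
#'   sampled per period and zone (both lines combined).
#' @param replicates_per_grid_station Replicate grabs per grid station.
#' @param hotspots_per_zone Named integer vector of feeding hotspots.
#' @param grabs_per_hotspot Grabs collected within each hotspot.
#' @return A `design_spec` list.
#' @export
design_spec <- function(zones = c("North", "Middle", "South"),
                        periods = 1:3,
                        line_depths = c("9m" = 9, "13m" = 13),
                        planned_stations_per_line = 52L,
                        station_spacing_km = 2,
                        zone_stations_per_line = c(North = 21L, Middle = 21L,
                                                   South = 10L),
                        stations_sampled = rbind(`1` = c(22L, 32L, 14L),
                                                 `2` = c(42L, 41L, 18L),
                                                 `3` = c(21L, 21L, 12L)),
                        replicates_per_grid_station = 3L,
                        hotspots_per_zone = c(North = 6L, Middle = 2L,
                                              South = 3L),
                        grabs_per_hotspot = 12L) {
  zones <- as.character(zones)
  if (is.null(colnames(stations_sampled))) colnames(stations_sampled) <- zones
  if (is.null(rownames(stations_sampled))) rownames(stations_sampled) <- periods
  stopifnot(length(zones) >= 1L, !anyDuplicated(zones),
            length(line_depths) >= 1L, !is.null(names(line_depths)),
            all(line_depths > 0))
  if (!setequal(names(zone_stations_per_line), zones)) {
    stop("`zone_stations_per_line` must be named by zone", call. = FALSE)
  }
  zone_stations_per_line <- zone_stations_per_line[zones]
  if (sum(zone_stations_per_line) != planned_stations_per_line) {
    stop("zone station counts must sum to `planned_stations_per_line`",
         call. = FALSE)
  }
  if (any(stations_sampled < 0) || any(zone_stations_per_line < 0) ||
      any(hotspots_per_zone < 0) || replicates_per_grid_station < 1L ||
      grabs_per_hotspot < 1L) {
    stop("all design counts must be non-negative", call. = FALSE)
  }
  avail <- length(line_depths) * zone_stations_per_line
  over <- sweep(stations_sampled[, zones, drop = FALSE], 2, avail, `>`)
  if (any(over)) {
    bad <- which(over, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "configuration error: period %s samples more stations than exist in zone %s",
      rownames(stations_sampled)[bad[1]], zones[bad[2]]), call. = FALSE)
  }
  structure(list(zones = zones, periods = as.integer(periods),
                 line_depths = line_depths,
                 planned_stations_per_line = as.integer(planned_stations_per_line),
                 station_spacing_km = station_spacing_km,
                 zone_stations_per_line = as.integer(zone_stations_per_line) |>
                   stats::setNames(zones),
                 stations_sampled = stations_sampled[, zones, drop = FALSE],
                 replicates_per_grid_station = as.integer(replicates_per_grid_station),
                 hotspots_per_zone = hotspots_per_zone[zones],
                 grabs_per_hotspot = as.integer(grabs_per_hotspot)),
            class = "design_spec")
}

#' Lay out survey stations and the per-period sampling plan
#'
#' Builds the station table (grid stations on each isobath line plus
#' hotspot stations) and draws which grid stations are visited in each
#' period. Periods that cover fewer stations than the full grid are
#' staggered by sampling stations uniformly without replacement within
#' each zone (the historical stagger is not recoverable, so an
#' exchangeable draw is used).
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed controlling the staggered-sampling draw.
#' @return A `survey_design` list with elements `stations` (grid station
#'   table: `station_id`, `line`, `zone`, `position_km`, `nominal_depth_m`),
#'   `hotspots`, `plan` (data frame of `period`, `station_id`) and `spec`.
#' @export
#' @examples
#' d <- make_design(design_spec())
#' table(d$plan$period)
make_design <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "design_spec"))
  zone_of <- rep(spec$zones, times = spec$zone_stations_per_line)
  lines <- names(spec$line_depths)
  stations <- do.call(rbind, lapply(lines, function(ln) {
    n <- spec$planned_stations_per_line
    data.frame(station_id = sprintf("G%s-%02d", ln, seq_len(n)),
               line = ln, zone = zone_of,
               position_km = (seq_len(n) - 1) * spec$station_spacing_km,
               nominal_depth_m = unname(spec$line_depths[ln]))
  }))
  rownames(stations) <- NULL

  set.seed(as.integer(seed))
  plan <- do.call(rbind, lapply(seq_along(spec$periods), function(pi) {
    p <- spec$periods[pi]
    do.call(rbind, lapply(spec$zones, function(zn) {
      ids <- stations$station_id[stations$zone == zn]
      k <- spec$stations_sampled[pi, zn]
      picked <- if (k == length(ids)) ids else sort(sample(ids, k))
      if (k == 0L) return(NULL)
      data.frame(period = p, station_id = picked)
    }))
  }))
  rownames(plan) <- NULL

  hotspots <- NULL
  if (any(spec$hotspots_per_zone > 0)) {
    hotspots <- do.call(rbind, lapply(spec$zones, function(zn) {
      k <- spec$hotspots_per_zone[[zn]]
      if (k == 0L) return(NULL)
      data.frame(station_id = sprintf("H-%s-%d", substr(zn, 1, 1), seq_len(k)),
                 zone = zn)
    }))
    rownames(hotspots) <- NULL
  }

  structure(list(stations = stations, hotspots = hotspots, plan = plan,
                 spec = spec, seed = as.integer(seed)),
            class = "survey_design")
}

#' Sampled-station counts by period and zone
#'
#' @param design A `survey_design` from [make_design()].
#' @return Matrix of counts, periods in rows, zones in columns.
#' @export
design_counts <- function(design) {
  stopifnot(inherits(design, "survey_design"))
  zn <- design$stations$zone[match(design$plan$station_id,
                                   design$stations$station_id)]
  tab <- table(factor(design$plan$period, levels = design$spec$periods),
               factor(zn, levels = design$spec$zones))
  m <- matrix(tab, nrow = length(design$spec$periods),
              dimnames = list(design$spec$periods, design$spec$zones))
  m
}
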