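#' Total prey biomass per grab
#'
#' Sums, within every grab, the six groups known from gray whale diets
#' (Actinopterygii, Amphipoda, Bivalvia, Cumacea, Isopoda, Polychaeta);
#' Echinoidea and Other are excluded. Each prey group must be present in
#' each grab, as an explicit zero if absent.
#'
#' @param table A `survey_table`.
#' @return Data frame, one row per grab, with the grab's design columns
#'   and `total_prey_g_per_m2`.
#' @export
total_prey <- function(table) {
  pg <- prey_groups()
  sub <- table[table$taxon_group %in% pg, ]
  key <- paste(sub$station_id, sub$period, sub$design, sub$replicate_index,
               sep = "@")
  counts <- table(key)
  if (any(counts != length(pg))) {
    bad <- names(counts)[counts != length(pg)][1]
    stop("grab ", bad, " is missing prey-group rows ",
         "(absent groups must be explicit zeros)", call. = FALSE)
  }
  first <- !duplicated(key)
  out <- sub[first, c("station_id", "zone", "period", "design", "line",
                      "depth_m", "sediment", "replicate_index")]
  tot <- tapply(sub$biomass_wet_g_per_m2, key, sum)
  out$total_prey_g_per_m2 <- as.numeric(tot[key[first]])
  rownames(out) <- NULL
  out
}

#' Threshold-exceedance percentages by period and zone
#'
#' Percentage of replicate-level biomass values of `group` exceeding
#' each threshold, per (period, zone, design) cell. The 60 g/m2 cutoff
#' is the literature minimum amphipod biomass for gray whale feeding;
#' 100 and 200 g/m2 mark progressively extreme concentrations. The two
#' isobath lines are pooled.
#'
#' @param table A `survey_table`.
#' @param group Taxon to summarize; default `"Amphipoda"`.
#' @param thresholds Positive increasing thresholds (g/m2); default
#'   `c(60, 100, 200)`.
#' @param station_means Summarize station-mean values instead of
#'   replicate values; default `FALSE` (replicate level).
#' @return Data frame of class `cutoff_summary`: period, zone, design,
#'   threshold, `percent_exceeding` in `[0, 100]`, `n_values`.
#' @export
cutoff_percentages <- function(table, group = "Amphipoda",
                               thresholds = c(60, 100, 200),
                               station_means = FALSE) {
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE)) {
    stop("`thresholds` must be positive and strictly increasing",
         call. = FALSE)
  }
  sub <- table[table$taxon_group == group, ]
  if (!nrow(sub)) stop("no rows for group ", group, call. = FALSE)
  if (station_means) {
    key <- paste(sub$station_id, sub$period, sub$design, sep = "@")
    y <- tapply(sub$biomass_wet_g_per_m2, key, mean)
    first <- !duplicated(key)
    cell <- data.frame(period = sub$period[first], zone = sub$zone[first],
                       design = sub$design[first], y = as.numeric(y[key[first]]))
  } else {
    cell <- data.frame(period = sub$period, zone = sub$zone,
                       design = sub$design, y = sub$biomass_wet_g_per_m2)
  }
  sp <- split(cell, list(cell$period, cell$zone, cell$design), drop = TRUE)
  rows <- lapply(sp, function(s) {
    data.frame(period = s$period[1], zone = s$zone[1], design = s$design[1],
               threshold = thresholds,
               percent_exceeding = vapply(
                 thresholds, function(t) 100 * mean(s$y > t), numeric(1)),
               n_values = nrow(s))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$design, out$period, out$zone, out$threshold), ]
  rownames(out) <- NULL
  # exceedance is necessarily non-increasing in the threshold
  chk <- tapply(out$percent_exceeding,
                paste(out$period, out$zone, out$design),
                function(v) all(diff(v) <= 0))
  stopifnot(all(unlist(chk)))
  class(out) <- c("cutoff_summary", "data.frame")
  out
}

#' Dominance ranking of groups by mean biomass
#'
#' Per (period, zone) on the detailed grid: group means and SDs over all
#' replicate values, sorted descending by mean (ties broken
#' alphabetically), truncated to the top `n`.
#'
#' @param table A `survey_table`.
#' @param n Number of top groups to keep; default 5.
#' @return Data frame of class `ranking_table`: period, zone, rank,
#'   taxon_group, mean, sd.
#' @export
rank_dominants <- function(table, n = 5L) {
  sub <- table[table$design == "grid", ]
  if (length(unique(sub$taxon_group)) < n) {
    stop("fewer than `n` groups present", call. = FALSE)
  }
  sp <- split(sub, list(sub$period, sub$zone), drop = TRUE)
  rows <- lapply(sp, function(s) {
    m <- tapply(s$biomass_wet_g_per_m2, s$taxon_group, mean)
    sdv <- tapply(s$biomass_wet_g_per_m2, s$taxon_group, stats::sd)
    ord <- order(-m, names(m))
    top <- ord[seq_len(min(n, length(ord)))]
    data.frame(period = s$period[1], zone = s$zone[1],
               rank = seq_along(top), taxon_group = names(m)[top],
               mean = as.numeric(m[top]), sd = as.numeric(sdv[top]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$period, out$zone, out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("ranking_table", "data.frame")
  out
}

#' Mean and confidence interval by period, zone and design
#'
#' Cell means of untransformed biomass with t-based confidence
#' intervals, the numeric version of the mean-and-CI biomass figures.
#' Hotspot cells appear as separate rows. Singleton cells report the
#' mean with an undefined (NA) interval, flagged.
#'
#' @param table A `survey_table`.
#' @param group Taxon group (or `"Total prey"` after
#'   [add_total_prey()]).
#' @param level Confidence level; default 0.95.
#' @return Data frame: period, zone, design, n, mean, ci_lo, ci_hi,
#'   ci_defined.
#' @export
group_summary_ci <- function(table, group, level = 0.95) {
  sub <- table[table$taxon_group == group, ]
  if (!nrow(sub)) stop("no rows for group ", group, call. = FALSE)
  sp <- split(sub, list(sub$period, sub$zone, sub$design), drop = TRUE)
  rows <- lapply(sp, function(s) {
    y <- s$biomass_wet_g_per_m2
    n <- length(y)
    m <- mean(y)
    if (n >= 2L) {
      hw <- stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(y) / sqrt(n)
    } else {
      hw <- NA_real_
    }
    data.frame(period = s$period[1], zone = s$zone[1], design = s$design[1],
               n = n, mean = m, ci_lo = m - hw, ci_hi = m + hw,
               ci_defined = n >= 2L)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$design, out$period, out$zone), ]
  rownames(out) <- NULL
  out
}
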