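# Shared fixtures: small designs and flat (single-source-of-variance)
# simulator parameter sets, built in code.

small_spec <- function(per_zone = c(North = 4L, Middle = 4L, South = 4L),
                       sampled = NULL, periods = 1:3,
                       hotspots = c(North = 0L, Middle = 0L, South = 0L),
                       reps = 3L) {
  if (is.null(sampled)) {
    sampled <- matrix(rep(2L * per_zone, each = length(periods)),
                      nrow = length(periods),
                      dimnames = list(periods, names(per_zone)))
  }
  design_spec(planned_stations_per_line = sum(per_zone),
              zone_stations_per_line = per_zone,
              stations_sampled = sampled,
              periods = periods,
              replicates_per_grid_station = reps,
              hotspots_per_zone = hotspots)
}

# Constant-mean parameters: one shared mu on the ln(X+1) scale, optional
# depth effects, homogeneous variances -- the null model unless stated.
flat_params <- function(mu = 3, sigma_station = 0.4, sigma_resid = 0.6,
                        beta1 = 0, beta2 = 0, pi = 0,
                        groups = benthic_groups(), depth_jitter_sd = 0.5,
                        depth_range = c(7, 15)) {
  ng <- length(groups)
  sim_params(groups = groups,
             mu_log = array(mu, c(ng, 3, 3)),
             sigma_resid = rep(sigma_resid, ng),
             sigma_station = rep(sigma_station, ng),
             beta1 = rep(beta1, ng), beta2 = rep(beta2, ng),
             pi = rep(pi, ng),
             depth_jitter_sd = depth_jitter_sd, depth_range = depth_range)
}

# Hand-built long-format survey rows for exact-value tests.
survey_rows <- function(station_id, zone, period, biomass, taxon_group,
                        replicate_index = seq_along(biomass),
                        design = "grid", line = "9m", depth_m = 9,
                        sediment = "fine") {
  data.frame(station_id = station_id, zone = zone, period = period,
             design = design, line = line, depth_m = depth_m,
             sediment = sediment, replicate_index = replicate_index,
             taxon_group = taxon_group,
             biomass_wet_g_per_m2 = biomass)
}

# All permutations of 1..n (rows), for exhaustive permutation oracles.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Independent two-group PERMANOVA pseudo-F computed straight from the
# within/between decomposition of squared dissimilarities (no Gower
# centering) -- the oracle route.
two_group_pseudo_F <- function(d, g) {
  g <- as.factor(g)
  n <- length(g)
  k <- nlevels(g)
  ss_tot <- sum(d[upper.tri(d)]^2) / n
  ss_w <- 0
  for (lv in levels(g)) {
    idx <- which(g == lv)
    dd <- d[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(dd[upper.tri(dd)]^2) / length(idx)
  }
  ((ss_tot - ss_w) / (k - 1)) / (ss_w / (n - k))
}
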