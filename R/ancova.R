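#' ln(X + 1) biomass transform
#'
#' @param y Non-negative biomass values (g/m2).
#' @return `log(y + 1)`.
#' @export
transform_biomass <- function(y) {
  if (any(!is.finite(y)) || any(y < 0)) {
    stop("biomass must be finite and >= 0", call. = FALSE)
  }
  log1p(y)
}

#' Standardize a depth covariate
#'
#' Centers and scales to sample mean 0 and sample SD 1 (n - 1
#' convention) and returns the squared standardized term used to test
#' nonlinear depth response.
#'
#' @param depths Numeric vector with at least two distinct values.
#' @return List with `z`, `z2`, `center`, `scale`.
#' @export
standardize_depth <- function(depths) {
  if (length(unique(depths)) < 2L) {
    stop("depth standardization undefined for a constant depth column",
         call. = FALSE)
  }
  center <- mean(depths)
  scale <- stats::sd(depths)
  z <- (depths - center) / scale
  list(z = z, z2 = z^2, center = center, scale = scale)
}

.effect_map <- c(zone = "zone", period = "period",
                 `zone:period` = "zone:period", z = "depth", z2 = "depth2")

#' Fit the per-taxon mixed-model ANCOVA
#'
#' Fits, on detailed-grid rows only, the model
#' \deqn{\ln(Y+1) \sim zone * period + z + z^2 + (1 | station)}
#' with sum-to-zero factor contrasts, REML variance components, and
#' marginal (Type-III-style) F tests with Satterthwaite denominator
#' degrees of freedom. Replicate grabs provide the residual
#' (within-station) error; the station random intercept carries the
#' between-station variance and is shared across a station's repeated
#' visits.
#'
#' @param table A `survey_table` (long format).
#' @param taxon_group Which group's rows to analyse (may be a derived
#'   group such as `"Total prey"` added by [add_total_prey()]).
#' @param min_stations_per_cell Minimum stations per zone-by-period cell
#'   (default 2); emptier designs are refused with the offending cell
#'   named.
#' @return An `ancova_fit`: list with `taxon_group`, `coefficients`,
#'   `varcomp` (`sigma_station2`, `sigma_resid2`), `anova_table` (effect,
#'   F_obs, df1, df2, p), `depth_center`, `depth_scale`, `transform`,
#'   `n_obs`, `n_stations` and the underlying `model`.
#' @export
fit_mixed_ancova <- function(table, taxon_group, min_stations_per_cell = 2L) {
  sub <- table[table$design == "grid" & table$taxon_group == taxon_group, ]
  if (!nrow(sub)) stop("no grid rows for group ", taxon_group, call. = FALSE)
  nst <- tapply(sub$station_id, list(sub$zone, sub$period),
                function(x) length(unique(x)))
  nst[is.na(nst)] <- 0L
  if (any(nst < min_stations_per_cell)) {
    bad <- which(nst < min_stations_per_cell, arr.ind = TRUE)[1, ]
    stop(sprintf("singular design: zone %s x period %s has %d station(s)",
                 rownames(nst)[bad[1]], colnames(nst)[bad[2]],
                 nst[bad[1], bad[2]]), call. = FALSE)
  }
  std <- standardize_depth(sub$depth_m)
  dat <- data.frame(
    y = transform_biomass(sub$biomass_wet_g_per_m2),
    zone = factor(sub$zone, levels = unique(table$zone)),
    period = factor(sub$period),
    z = std$z, z2 = std$z2,
    station = factor(sub$station_id))
  dat$zone <- droplevels(dat$zone)

  fit_once <- function(start = NULL) {
    suppressMessages(lmerTest::lmer(
      y ~ zone + period + zone:period + z + z2 + (1 | station),
      data = dat, REML = TRUE, start = start,
      contrasts = list(zone = "contr.sum", period = "contr.sum"),
      control = lme4::lmerControl(check.conv.singular = "ignore")))
  }
  converged <- function(m) {
    cc <- m@optinfo$conv$lme4
    is.null(cc$code) || cc$code >= 0 && !length(cc$messages)
  }
  model <- withCallingHandlers(
    fit_once(),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!converged(model)) {
    for (th in c(1e-4, 1e-2, 1, 10, 100)) {
      model <- withCallingHandlers(
        fit_once(start = list(theta = th)),
        warning = function(w) invokeRestart("muffleWarning"))
      if (converged(model)) break
    }
    if (!converged(model)) {
      stop("mixed ANCOVA did not converge for ", taxon_group, ": ",
           paste(model@optinfo$conv$lme4$messages, collapse = "; "),
           call. = FALSE)
    }
  }

  a3 <- stats::anova(model, type = 3, ddf = "Satterthwaite")
  rn <- rownames(a3)
  eff <- .effect_map[rn]
  ord <- match(c("zone", "period", "zone:period", "depth", "depth2"), eff)
  anova_table <- data.frame(
    effect = eff[ord],
    F_obs = a3$`F value`[ord],
    df1 = a3$NumDF[ord],
    df2 = a3$DenDF[ord],
    p = a3$`Pr(>F)`[ord])
  rownames(anova_table) <- NULL
  vc <- as.data.frame(lme4::VarCorr(model))
  structure(list(
    taxon_group = taxon_group,
    coefficients = lme4::fixef(model),
    varcomp = c(sigma_station2 = vc$vcov[vc$grp == "station"],
                sigma_resid2 = vc$vcov[vc$grp == "Residual"]),
    anova_table = anova_table,
    transform = "ln(x+1)",
    depth_center = std$center, depth_scale = std$scale,
    n_obs = nrow(dat), n_stations = nlevels(dat$station),
    model = model), class = "ancova_fit")
}

#' Add total prey biomass rows to a survey table
#'
#' Appends, for every grab, a `"Total prey"` row holding the sum of the
#' six prey groups ([prey_groups()]); Echinoidea and Other are excluded.
#' Every prey group must be present (possibly as an explicit zero) in
#' every grab.
#'
#' @param table A `survey_table`.
#' @param label Name for the derived group; default `"Total prey"`.
#' @return The table with the derived rows appended.
#' @export
add_total_prey <- function(table, label = "Total prey") {
  tp <- total_prey(table)
  extra <- tp
  names(extra)[names(extra) == "total_prey_g_per_m2"] <- "biomass_wet_g_per_m2"
  extra$taxon_group <- label
  out <- rbind(table[, .survey_columns], extra[, .survey_columns])
  class(out) <- c("survey_table", "data.frame")
  out
}

#' Table-style ANCOVA report with minimum-effects marks
#'
#' Combines per-taxon fits into the standard report shape: one row per
#' (taxon, effect) with the F statistic, Satterthwaite df, p-value, a
#' significance flag at `alpha`, and the minimum-effects classification
#' from [classify_effect()] rendered as asterisk marks (`*` = exceeds
#' small, `**` = exceeds medium, `***` = exceeds large).
#'
#' @param fits List of `ancova_fit` objects.
#' @param specs Ordered effect-size boundaries.
#' @param alpha Significance level; default 0.05.
#' @return Data frame of class `ancova_report`.
#' @export
ancova_report <- function(fits, specs = default_effect_sizes(),
                          alpha = 0.05) {
  stopifnot(length(fits) >= 1L)
  marks <- c("negligible-to-small" = "")
  lab <- vapply(specs, `[[`, "", "label")
  marks[paste0("exceeds-", lab)] <- strrep("*", seq_along(lab))
  rows <- lapply(fits, function(f) {
    at <- f$anova_table
    at$taxon_group <- f$taxon_group
    at$significant <- at$p <= alpha
    at$me_class <- classify_effect(at$F_obs, at$df1, at$df2, specs, alpha)
    at$me_mark <- unname(marks[at$me_class])
    at
  })
  out <- do.call(rbind, rows)
  out <- out[, c("taxon_group", "effect", "F_obs", "df1", "df2", "p",
                 "significant", "me_class", "me_mark")]
  rownames(out) <- NULL
  class(out) <- c("ancova_report", "data.frame")
  out
}

#' Wide p-value view of an ANCOVA report
#'
#' @param report An `ancova_report`.
#' @return Data frame, taxa in rows, one column per effect holding
#'   `"p-value<marks>"` strings.
#' @export
format_ancova_report <- function(report) {
  taxa <- unique(report$taxon_group)
  effs <- unique(report$effect)
  out <- data.frame(taxon_group = taxa)
  for (e in effs) {
    sub <- report[report$effect == e, ]
    sub <- sub[match(taxa, sub$taxon_group), ]
    out[[e]] <- sprintf("%.4f%s", sub$p, sub$me_mark)
  }
  out
}
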